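test_that("DSC and VOE match worked examples and conventions", {
  a <- matrix(FALSE, 4, 4); b <- a
  a[1, 1:4] <- TRUE; b[1, 3:4] <- TRUE; b[2, 1:2] <- TRUE
  # |X| = |Y| = 4, |X n Y| = 2
  expect_equal(dsc(a, b), 0.5)
  # intersect 2, union 6
  expect_equal(voe(a, b), 2 / 3)
  full <- matrix(TRUE, 3, 3); empty <- matrix(FALSE, 3, 3)
  expect_equal(dsc(full, full), 1)
  expect_equal(voe(full, full), 0)
  disj <- matrix(FALSE, 3, 3); disj[1, 1] <- TRUE
  disj2 <- matrix(FALSE, 3, 3); disj2[3, 3] <- TRUE
  expect_equal(dsc(disj, disj2), 0)
  expect_equal(voe(disj, disj2), 1)
  expect_equal(dsc(empty, empty), 1)   # both empty
  expect_equal(voe(empty, empty), 0)
  expect_equal(dsc(empty, full), 0)    # total segmentation failure
  expect_error(dsc(full, matrix(TRUE, 2, 2)), "mismatch")
})

test_that("DSC/VOE are symmetric and satisfy voe = 1 - dsc/(2 - dsc)", {
  withr::with_seed(31, {
    for (rep in 1:100) {
      d <- c(sample(2:6, 1), sample(2:6, 1))
      x <- matrix(runif(prod(d)) < runif(1), d[1], d[2])
      y <- matrix(runif(prod(d)) < runif(1), d[1], d[2])
      expect_equal(dsc(x, y), dsc(y, x))
      expect_equal(voe(x, y), voe(y, x))
      expect_equal(voe(x, y), 1 - dsc(x, y) / (2 - dsc(x, y)),
                   tolerance = 1e-12)
    }
  })
})

test_that("DSC on a 3D stack equals DSC from pooled 2D counts", {
  withr::with_seed(32, {
    xs <- lapply(1:4, function(i) matrix(runif(36) < 0.4, 6, 6))
    ys <- lapply(1:4, function(i) matrix(runif(36) < 0.4, 6, 6))
    vx <- stack_slices(lapply(xs, tissue_mask))
    vy <- stack_slices(lapply(ys, tissue_mask))
    inter <- sum(mapply(function(a, b) sum(a & b), xs, ys))
    tot <- sum(sapply(xs, sum)) + sum(sapply(ys, sum))
    expect_equal(dsc(vx, vy), 2 * inter / tot)
  })
})

test_that("surface extraction finds face-connected boundary voxels", {
  cube <- array(TRUE, c(3, 3, 3))
  s <- extract_surface(tissue_mask(cube))
  expect_equal(nrow(s), 26L)  # all but the centre voxel
  single <- array(FALSE, c(3, 3, 3)); single[2, 2, 2] <- TRUE
  s1 <- extract_surface(tissue_mask(single, spacing = c(2, 3, 4)))
  expect_equal(nrow(s1), 1L)
  expect_equal(as.numeric(s1[1, ]), c(4, 6, 8))  # voxel centre in mm
  rod <- array(TRUE, c(1, 1, 5))
  expect_equal(nrow(extract_surface(tissue_mask(rod))), 5L)
  expect_error(extract_surface(tissue_mask(array(FALSE, c(2, 2, 2)))),
               "empty")
})

test_that("ASD matches closed forms", {
  same <- array(FALSE, c(8, 8, 8)); same[3:5, 3:5, 3:5] <- TRUE
  expect_equal(asd(tissue_mask(same), tissue_mask(same)), 0)
  # two parallel single-voxel-thick planes k voxels apart at spacing s
  for (k in c(2L, 4L)) for (s in c(1, 0.5)) {
    x <- array(FALSE, c(8, 8, 8)); y <- x
    x[2, , ] <- TRUE
    y[2L + k, , ] <- TRUE
    expect_equal(asd(tissue_mask(x, rep(s, 3)), tissue_mask(y, rep(s, 3))),
                 k * s)
  }
  # single voxels offset by (3, 4, 0) at unit spacing: Euclidean 3-4-5
  x <- array(FALSE, c(8, 8, 8)); y <- x
  x[2, 2, 2] <- TRUE; y[5, 6, 2] <- TRUE
  expect_equal(asd(tissue_mask(x), tissue_mask(y)), 5)
  expect_error(asd(tissue_mask(x), tissue_mask(array(FALSE, c(8, 8, 8)))),
               "undefined")
})

test_that("distance-transform ASD equals the brute-force all-pairs oracle", {
  withr::with_seed(33, {
    for (rep in 1:25) {
      d <- c(sample(3:10, 1), sample(3:10, 1), sample(3:10, 1))
      sp <- runif(3, 0.4, 2)
      x <- array(runif(prod(d)) < 0.25, d)
      y <- array(runif(prod(d)) < 0.25, d)
      if (!any(x)) x[1] <- TRUE
      if (!any(y)) y[length(y)] <- TRUE
      expect_equal(asd(tissue_mask(x, sp), tissue_mask(y, sp)),
                   asd_bruteforce(x, y, sp), tolerance = 1e-9)
    }
  })
})

test_that("per-subject evaluation decodes tissues and aggregation uses the
           population standard deviation", {
  sch <- default_label_scheme()
  withr::with_seed(34, {
    masks <- random_mask_set(sch, n = 8L)
    slices <- lapply(0:2, function(k) encode_labels(masks, sch,
                                                    slice_index = k))
    rep_same <- evaluate_subject(slices, slices, sch)
    expect_equal(rep_same$dsc, rep(1, nrow(rep_same)))
    expect_equal(rep_same$voe, rep(0, nrow(rep_same)))
    expect_equal(rep_same$asd, rep(0, nrow(rep_same)))
    # tissue present in truth but absent in prediction scores DSC 0, ASD NA
    empty <- lapply(0:2, function(k)
      label_image(array(0L, c(8, 8, 3)), slice_index = k))
    rep0 <- evaluate_subject(empty, slices, sch)
    present <- names(masks)[vapply(masks, any, logical(1))]
    expect_true(all(rep0$dsc[rep0$tissue %in% present] == 0))
    expect_true(all(is.na(rep0$asd[rep0$tissue %in% present])))
  })
  # two subjects with DSC 0.8 and 1.0: mean 0.9, population sd 0.1
  r1 <- data.frame(tissue = "femur", dsc = 0.8)
  r2 <- data.frame(tissue = "femur", dsc = 1.0)
  agg <- aggregate_reports(list(r1, r2))
  expect_equal(agg$dsc_mean, 0.9)
  expect_equal(agg$dsc_sd, 0.1)
})
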