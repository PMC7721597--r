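test_that("default scheme matches the ten-tissue colour-code table", {
  sch <- default_label_scheme()
  e <- sch$entries
  expect_equal(e$code[e$tissue == "femur"], 50L)
  expect_equal(e$channel[e$tissue == "femur"], "blue")
  expect_equal(e$code[e$tissue == "tibia"], 100L)
  expect_equal(e$code[e$tissue == "patella"], 150L)
  expect_equal(e$code[e$tissue == "acl"], 200L)
  expect_equal(e$channel[e$tissue == "acl"], "blue")
  expect_equal(e$code[e$tissue == "femoral_cartilage"], 50L)
  expect_equal(e$channel[e$tissue == "pcl"], "green")
  expect_equal(e$code[e$tissue == "vastus_medialis"], 100L)
  expect_equal(e$channel[e$tissue == "medial_gastrocnemius"], "red")
  expect_equal(sch$tolerance, 20L)
})

test_that("scheme validation rejects ambiguous or out-of-range codes", {
  expect_error(label_scheme(data.frame(tissue = c("a", "b"),
                                       channel = "blue", code = c(50, 80)),
                            tolerance = 20),
               "2\\*tolerance")
  expect_error(label_scheme(data.frame(tissue = "a", channel = "blue",
                                       code = 0)),
               "reserved")
  expect_error(label_scheme(data.frame(tissue = "a", channel = "cyan",
                                       code = 50)))
})

test_that("encoding writes codes per channel and rejects in-channel overlap", {
  sch <- default_label_scheme()
  m <- matrix(FALSE, 4, 4)
  femur <- m; femur[2, 2] <- TRUE
  li <- encode_labels(list(femur = femur), sch)
  expect_equal(as.integer(li$data[2, 2, ]), c(0L, 0L, 50L))
  expect_true(all(li$data[-2, , ] == 0L))

  # bone and its cartilage live in different channels and may overlap
  cart <- m; cart[2, 2] <- TRUE
  li2 <- encode_labels(list(femur = femur, femoral_cartilage = cart), sch)
  expect_equal(as.integer(li2$data[2, 2, ]), c(0L, 50L, 50L))

  # empty masks give an all-zero label
  expect_true(is_noise_only(encode_labels(list(femur = m), sch)))

  # two tissues of one channel on one pixel is inconsistent ground truth
  tibia <- m; tibia[2, 2] <- TRUE
  expect_error(encode_labels(list(femur = femur, tibia = tibia), sch),
               "overlap")
  expect_error(encode_labels(list(femur = femur,
                                  nonsense = femur), sch), "unknown tissue")
  expect_error(encode_labels(list(femur = matrix(FALSE, 3, 3),
                                  tibia = m), sch), "mismatch")
})

test_that("decode applies the +/-20 window with inclusive bounds", {
  sch <- default_label_scheme()
  li <- array(0L, c(1, 5, 3))
  li[1, , 3] <- c(60L, 75L, 30L, 70L, 71L)
  lab <- label_image(li)
  femur <- decode_tissue_mask(lab, "femur", sch)$data[1, ]
  tibia <- decode_tissue_mask(lab, "tibia", sch)$data[1, ]
  expect_equal(femur, c(TRUE, FALSE, TRUE, TRUE, FALSE))  # |75-50| = 25 > 20
  expect_equal(tibia, c(FALSE, FALSE, FALSE, FALSE, FALSE))  # |75-100| = 25
  expect_error(decode_tissue_mask(lab, "meniscus", sch), "unknown")
  # all-zero label decodes empty for every tissue
  zero <- label_image(array(0L, c(2, 2, 3)))
  for (tn in sch$entries$tissue)
    expect_false(any(decode_tissue_mask(zero, tn, sch)$data))
})

test_that("encode/decode round-trips random valid mask sets", {
  sch <- default_label_scheme()
  withr::with_seed(11, {
    for (rep in 1:50) {
      masks <- random_mask_set(sch)
      li <- encode_labels(masks, sch)
      for (tn in names(masks))
        expect_equal(decode_tissue_mask(li, tn, sch)$data, masks[[tn]])
    }
  })
})

test_that("decode is monotone in tolerance and disjoint within a channel", {
  sch <- default_label_scheme()
  withr::with_seed(12, {
    vals <- array(sample(0:255, 3 * 64 * 3, replace = TRUE), c(3, 64, 3))
    lab <- label_image(vals)
    schemes <- lapply(c(5L, 10L, 20L), function(tol) {
      s <- sch; s$tolerance <- tol; s
    })
    for (tn in sch$entries$tissue) {
      m5 <- decode_tissue_mask(lab, tn, schemes[[1]])$data
      m10 <- decode_tissue_mask(lab, tn, schemes[[2]])$data
      m20 <- decode_tissue_mask(lab, tn, schemes[[3]])$data
      expect_true(all(m10[m5]))   # tolerance 5 mask contained in 10
      expect_true(all(m20[m10]))  # contained in 20
    }
    # default scheme decodes pairwise-disjoint masks within one channel
    for (ch in c("red", "green", "blue")) {
      tissues <- sch$entries$tissue[sch$entries$channel == ch]
      dec <- lapply(tissues, function(tn)
        decode_tissue_mask(lab, tn, sch)$data)
      for (i in seq_along(dec)) for (j in seq_len(i - 1L))
        expect_false(any(dec[[i]] & dec[[j]]))
    }
  })
})

test_that("stack_slices builds ordered volumes and checks shapes", {
  s1 <- tissue_mask(matrix(c(TRUE, FALSE, FALSE, FALSE), 2), c(0.3, 0.3))
  s2 <- tissue_mask(matrix(FALSE, 2, 2), c(0.3, 0.3))
  s3 <- tissue_mask(matrix(TRUE, 2, 2), c(0.3, 0.3))
  vol <- stack_slices(list(s1, s2, s3), slice_spacing = 1.5)
  expect_equal(dim(vol$data), c(3L, 2L, 2L))
  expect_equal(vol$spacing, c(1.5, 0.3, 0.3))
  expect_equal(vol$data[1, , ], s1$data)
  expect_equal(vol$data[3, , ], s3$data)
  expect_equal(sum(vol$data), sum(s1$data) + sum(s2$data) + sum(s3$data))
  expect_error(stack_slices(list()), "empty")
  expect_error(stack_slices(list(s1, tissue_mask(matrix(FALSE, 3, 3)))),
               "shapes")
})

test_that("noise-only detection is a strict all-zero test", {
  zero <- label_image(array(0L, c(4, 4, 3)))
  expect_true(is_noise_only(zero))
  one <- array(0L, c(4, 4, 3)); one[1, 1, 1] <- 1L
  expect_false(is_noise_only(label_image(one)))
})

test_that("noise-only filtering drops flagged pairs and preserves order", {
  mk <- function(v) list(source = matrix(0, 2, 2),
                         label = label_image(array(as.integer(v), c(2, 2, 3))))
  pairs <- list(mk(0), mk(5), mk(0), mk(9), mk(2))
  kept <- filter_dataset(pairs, keep_noise_only = FALSE)
  expect_length(kept, 3L)
  expect_equal(sapply(kept, function(p) p$label$data[1, 1, 1]), c(5L, 9L, 2L))
  expect_identical(filter_dataset(pairs, keep_noise_only = TRUE), pairs)
  expect_length(filter_dataset(list()), 0L)
})
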