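test_that("phantom generation is bit-identical for a fixed config and seed", {
  cfg <- phantom_config(n_subjects = 2L)
  s1 <- generate_subject(cfg, 123L, "s")
  s2 <- generate_subject(cfg, 123L, "s")
  expect_identical(s1, s2)
  s3 <- generate_subject(cfg, 124L, "s")
  expect_false(identical(s1, s3))
})

test_that("noise-only slice count follows the configured fraction", {
  cfg <- phantom_config(slices_per_subject = 10L, noise_only_fraction = 0.2)
  sl <- generate_subject(cfg, 55L, "s")
  flags <- vapply(sl, `[[`, logical(1), "noise_only")
  expect_equal(sum(flags), 2L)
  expect_true(all(vapply(sl[flags], function(p) is_noise_only(p$label),
                         logical(1))))
  expect_false(any(vapply(sl[!flags], function(p) is_noise_only(p$label),
                          logical(1))))
})

test_that("generated labels decode to valid, bounded, paired masks", {
  cfg <- phantom_config()
  sch <- default_label_scheme()
  sl <- generate_subject(cfg, 77L, "s")
  saw <- character(0)
  for (p in sl) {
    expect_equal(dim(p$source), dim(p$label$data)[1:2])  # paired 1:1
    expect_true(all(p$source >= 0 & p$source <= 1))
    for (tn in sch$entries$tissue) {
      m <- decode_tissue_mask(p$label, tn, sch)$data
      expect_lte(mean(m), 0.4)  # class imbalance bound
      if (any(m)) saw <- union(saw, tn)
    }
    # re-encoding the decoded masks must reproduce the label (valid encoding)
    masks <- lapply(sch$entries$tissue, function(tn)
      decode_tissue_mask(p$label, tn, sch)$data)
    names(masks) <- sch$entries$tissue
    masks <- masks[vapply(masks, any, logical(1))]
    if (length(masks))
      expect_equal(encode_labels(masks, sch)$data, p$label$data)
  }
  expect_setequal(saw, sch$entries$tissue)  # all ten tissues occur somewhere
})

test_that("a threshold classifier recovers bones exactly in the noise-free
           limit", {
  cfg <- phantom_config(
    tissue_intensity = lapply(default_tissue_intensity(),
                              function(v) c(v[1], 0)),
    background_noise_std = 0, bias_field_amplitude = 0)
  sch <- default_label_scheme()
  sl <- generate_subject(cfg, 41L, "s")
  for (p in sl[!vapply(sl, `[[`, logical(1), "noise_only")]) {
    bones <- decode_tissue_mask(p$label, "femur", sch)$data |
      decode_tissue_mask(p$label, "tibia", sch)$data |
      decode_tissue_mask(p$label, "patella", sch)$data
    expect_identical(p$source > 0.675, bones)
  }
})

test_that("dataset writing produces paired PNGs, a manifest and an 80/20
           subject split", {
  dir <- withr::local_tempdir()
  cfg <- phantom_config(n_subjects = 10L, slices_per_subject = 4L,
                        image_size = 32L)
  manifest <- generate_dataset(cfg, dir)
  expect_equal(length(unique(manifest$subject[manifest$split == "train"])), 8L)
  expect_equal(length(unique(manifest$subject[manifest$split == "test"])), 2L)
  expect_equal(nrow(manifest), 40L)
  imgs <- list.files(file.path(dir, "images"))
  labs <- list.files(file.path(dir, "labels"))
  expect_equal(length(imgs), nrow(manifest))
  expect_identical(imgs, labs)
  # loader round-trips pixel-exactly (8-bit PNG is lossless)
  pairs <- load_dataset(dir, split = "test")
  expect_equal(length(pairs), 8L)
  ref <- generate_subject(cfg, subject_seeds(cfg)[9L], "subj09")
  expect_equal(pairs[[1]]$label$data, ref[[1]]$label$data)
  expect_lt(max(abs(pairs[[1]]$source - ref[[1]]$source)), 1 / 254)
  expect_equal(vapply(pairs, `[[`, logical(1), "noise_only"),
               manifest$noise_only[manifest$split == "test"])
})

test_that("domain perturbation shifts intensities, rescales geometry and
           validates bounds", {
  cfg <- phantom_config()
  expect_equal(perturb_domain(cfg, 0), cfg)
  shifted <- perturb_domain(cfg, 0.1)
  expect_equal(shifted$tissue_intensity$femur[1],
               cfg$tissue_intensity$femur[1] + 0.1)
  expect_equal(shifted$geometry_scale, 1.1)
  expect_error(perturb_domain(cfg, 0.5), "outside")
})

test_that("NIfTI mask export records spacing and round-trips", {
  path <- withr::local_tempfile(fileext = ".nii.gz")
  vol <- array(FALSE, c(4, 5, 6)); vol[2:3, 2:4, 3] <- TRUE
  m <- tissue_mask(vol, spacing = c(1, 0.29, 0.29), tissue = "femur")
  export_mask_nifti(m, path)
  back <- import_mask_nifti(path, "femur")
  expect_equal(back$data, m$data)
  expect_equal(back$spacing, m$spacing, tolerance = 1e-6)
})
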