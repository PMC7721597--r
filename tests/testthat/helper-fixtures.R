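# Shared fixtures, built in code at test time.

# random per-tissue mask set that is valid for encoding (within-channel
# disjoint by construction: each channel's tissues get disjoint pixel sets)
random_mask_set <- function(scheme, n = 8L, p_pixel = 0.2) {
  masks <- list()
  for (ch in unique(scheme$entries$channel)) {
    tissues <- scheme$entries$tissue[scheme$entries$channel == ch]
    owner <- matrix(sample(c(NA_integer_, seq_along(tissues)), n * n,
                           replace = TRUE,
                           prob = c(1 - p_pixel, rep(p_pixel / length(tissues),
                                                     length(tissues)))),
                    n, n)
    for (i in seq_along(tissues))
      masks[[tissues[i]]] <- !is.na(owner) & owner == i
  }
  masks
}

# brute-force symmetric average surface distance (all-pairs nearest
# neighbour), independent of the distance-transform implementation
asd_bruteforce <- function(x, y, spacing) {
  surf_pts <- function(d) {
    s <- kneecgan:::surface_raster(d)
    sweep(which(s, arr.ind = TRUE), 2L, spacing, `*`)
  }
  px <- surf_pts(x); py <- surf_pts(y)
  # all-pairs squared distances from exact coordinate differences
  d2 <- 0
  for (ax in seq_len(ncol(px)))
    d2 <- d2 + outer(px[, ax], py[, ax], `-`)^2
  nn_xy <- sqrt(apply(d2, 1L, min))
  nn_yx <- sqrt(apply(d2, 2L, min))
  (sum(nn_xy) + sum(nn_yx)) / (nrow(px) + nrow(py))
}

# in-memory phantom dataset: list of pairs with subject ids attached
phantom_pairs <- function(cfg, subjects) {
  seeds <- subject_seeds(cfg)
  do.call(c, lapply(subjects, function(i) {
    sid <- sprintf("subj%02d", i)
    sl <- generate_subject(cfg, seeds[i], sid)
    lapply(sl, function(p) c(p, list(subject = sid)))
  }))
}

# tiny architecture for fast pipeline checks
tiny_gen_spec <- function(size = 16L)
  generator_spec(n_down = 2L, min_channels = 4L, input_size = size)

tiny_train_cfg <- function(epochs = 1L, seed = 1L, mode = "unet",
                           size = 16L, ...)
  train_config(epochs = epochs, crop_size = size,
               jitter_resize = size + 2L, seed = seed, mode = mode, ...)

tiny_pairs <- function(n = 6L, size = 16L, seed = 99L) {
  withr::with_seed(seed, {
    sch <- default_label_scheme()
    lapply(seq_len(n), function(i) {
      m <- matrix(FALSE, size, size)
      r0 <- sample(size - 7L, 1L)
      m[r0:(r0 + 4L), 4:12] <- TRUE
      src <- matrix(0.1 + 0.02 * rnorm(size * size), size, size)
      src[m] <- 0.8
      list(source = pmin(pmax(src, 0), 1),
           label = encode_labels(list(femur = m), sch,
                                 subject_id = "t", slice_index = i - 1L),
           subject = "t", noise_only = FALSE)
    })
  })
}
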