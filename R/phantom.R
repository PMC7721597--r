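#' Synthetic knee phantom configuration
#'
#' The phantom emulates the structure of a sagittal knee MR stack at desk
#' scale: per subject an ordered stack of square grayscale slices containing
#' up to ten tissues — femur and tibia (large elongated bones), a patellar
#' disc on central slices, thin articular cartilage shells on each bone, two
#' lateral muscle blobs, and two thin oblique cruciate-ligament bands on
#' central slices. Tissue intensities are Gaussian around tissue-specific
#' means, modulated by a smooth low-frequency multiplicative bias field
#' (emulating RF coil non-uniformity), and a fraction of slices at both
#' stack peripheries are pure noise with all-zero labels.
#'
#' @param image_size square slice side in px (power of two; default 64 so
#'   that adversarial training smoke runs fit on one CPU).
#' @param n_subjects number of subjects.
#' @param slices_per_subject slices per stack (`>= 3`).
#' @param seed global seed; per-subject seeds are derived from it with a
#'   counter-based splitter so each subject is independently reproducible.
#' @param tissue_intensity named list mapping tissue name to
#'   `c(mean, std)` on the `[0, 1]` intensity scale.
#' @param background_mean,background_noise_std background intensity model.
#' @param bias_field_amplitude multiplicative bias amplitude in `[0, 1)`.
#' @param noise_only_fraction fraction of slices that are noise-only.
#' @param geometry_jitter per-subject random perturbation scale of the
#'   shape parameters (relative units).
#' @param geometry_scale global rescaling of all structure sizes (used by
#'   [perturb_domain()]).
#' @param slice_spacing physical slice spacing in mm.
#' @return A `phantom_config`.
#' @export
phantom_config <- function(image_size = 64L, n_subjects = 10L,
                           slices_per_subject = 10L, seed = 1L,
                           tissue_intensity = default_tissue_intensity(),
                           background_mean = 0.05,
                           background_noise_std = 0.03,
                           bias_field_amplitude = 0.15,
                           noise_only_fraction = 0.2,
                           geometry_jitter = 0.06,
                           geometry_scale = 1,
                           slice_spacing = 1) {
  image_size <- as.integer(image_size)
  if (bitwAnd(image_size, image_size - 1L) != 0L)
    stop("image_size must be a power of two")
  if (slices_per_subject < 3L) stop("slices_per_subject must be >= 3")
  if (noise_only_fraction < 0 || noise_only_fraction >= 1)
    stop("noise_only_fraction must lie in [0, 1)")
  if (bias_field_amplitude < 0 || bias_field_amplitude >= 1)
    stop("bias_field_amplitude must lie in [0, 1)")
  bone_mean <- tissue_intensity$femur[1]
  bone_std <- tissue_intensity$femur[2]
  if (abs(bone_mean - background_mean) <=
      2 * (bone_std + background_noise_std))
    stop("bone and background intensities are not separable")
  structure(list(image_size = image_size, n_subjects = as.integer(n_subjects),
                 slices_per_subject = as.integer(slices_per_subject),
                 seed = as.integer(seed), tissue_intensity = tissue_intensity,
                 background_mean = background_mean,
                 background_noise_std = background_noise_std,
                 bias_field_amplitude = bias_field_amplitude,
                 noise_only_fraction = noise_only_fraction,
                 geometry_jitter = geometry_jitter,
                 geometry_scale = geometry_scale,
                 slice_spacing = slice_spacing),
            class = "phantom_config")
}

#' Default phantom tissue intensity model
#'
#' Bones bright (0.80), cartilages intermediate (0.55), muscles darker
#' (0.35), ligaments darkest (0.22), all with standard deviation 0.03 —
#' distinct enough that a bone/background threshold exists in the noise-free
#' limit while classes remain non-trivially separated under noise and bias.
#'
#' @return Named list of `c(mean, std)` pairs.
#' @export
default_tissue_intensity <- function() {
  list(femur = c(0.80, 0.03), tibia = c(0.80, 0.03), patella = c(0.80, 0.03),
       femoral_cartilage = c(0.55, 0.03), tibial_cartilage = c(0.55, 0.03),
       patellar_cartilage = c(0.55, 0.03),
       vastus_medialis = c(0.35, 0.03), medial_gastrocnemius = c(0.35, 0.03),
       acl = c(0.22, 0.03), pcl = c(0.22, 0.03))
}

# counter-based seed splitter: subjects are independently reproducible
subject_seed <- function(seed, i) {
  s <- (48271 * ((seed + i) %% 44488)) %% 2147483647
  as.integer(if (s == 0) 1 else s)
}

ellipse_mask <- function(n, cy, cx, ry, rx) {
  y <- (row(matrix(0, n, n)) - 0.5) / n
  x <- (col(matrix(0, n, n)) - 0.5) / n
  ((y - cy) / ry)^2 + ((x - cx) / rx)^2 <= 1
}

band_mask <- function(n, p0, p1, width) {
  y <- (row(matrix(0, n, n)) - 0.5) / n
  x <- (col(matrix(0, n, n)) - 0.5) / n
  v <- p1 - p0
  len2 <- sum(v^2)
  t <- ((y - p0[1]) * v[1] + (x - p0[2]) * v[2]) / len2
  t <- pmin(pmax(t, 0), 1)
  dy <- y - (p0[1] + t * v[1])
  dx <- x - (p0[2] + t * v[2])
  sqrt(dy^2 + dx^2) <= width
}

phantom_slice_masks <- function(cfg, n, geom, slice_frac, central) {
  gs <- cfg$geometry_scale
  # through-slice extent: structures thin out towards the stack periphery
  sc <- gs * sqrt(pmax(1 - 0.5 * (2 * slice_frac - 1)^2, 0.2))
  femur <- ellipse_mask(n, geom$femur_cy, geom$femur_cx,
                        sc * geom$femur_ry, sc * geom$femur_rx)
  tibia <- ellipse_mask(n, geom$tibia_cy, geom$tibia_cx,
                        sc * geom$tibia_ry, sc * geom$tibia_rx)
  yy <- (row(matrix(0, n, n)) - 0.5) / n
  xx <- (col(matrix(0, n, n)) - 0.5) / n
  fem_shell <- ellipse_mask(n, geom$femur_cy, geom$femur_cx,
                            sc * geom$femur_ry * 1.18,
                            sc * geom$femur_rx * 1.18) &
    !femur & (yy > geom$femur_cy)
  tib_shell <- ellipse_mask(n, geom$tibia_cy, geom$tibia_cx,
                            sc * geom$tibia_ry * 1.18,
                            sc * geom$tibia_rx * 1.18) &
    !tibia & (yy < geom$tibia_cy) & !fem_shell & !femur
  masks <- list(femur = femur, tibia = tibia,
                femoral_cartilage = fem_shell & !tibia,
                tibial_cartilage = tib_shell)
  masks$vastus_medialis <- ellipse_mask(n, geom$vm_cy, geom$vm_cx,
                                        sc * 0.13, sc * 0.10)
  masks$medial_gastrocnemius <- ellipse_mask(n, geom$gm_cy, geom$gm_cx,
                                             sc * 0.12, sc * 0.09)
  if (central) {
    pat <- ellipse_mask(n, geom$pat_cy, geom$pat_cx, sc * 0.07, sc * 0.06)
    pat <- pat & !femur & !tibia
    pat_shell <- ellipse_mask(n, geom$pat_cy, geom$pat_cx,
                              sc * 0.07 * 1.35, sc * 0.06 * 1.35) &
      !pat & (xx > geom$pat_cx) & !femur & !tibia &
      !masks$femoral_cartilage & !masks$tibial_cartilage
    w <- max(1.2 / n, 0.018) * gs
    acl <- band_mask(n, c(geom$gap_y - 0.05, geom$gap_x - 0.06),
                     c(geom$gap_y + 0.06, geom$gap_x + 0.07), w)
    pcl <- band_mask(n, c(geom$gap_y + 0.05, geom$gap_x - 0.02),
                     c(geom$gap_y - 0.05, geom$gap_x + 0.10), w)
    masks$patella <- pat
    masks$patellar_cartilage <- pat_shell
    masks$acl <- acl & !femur & !tibia & !pat
    masks$pcl <- pcl & !masks$femoral_cartilage & !masks$tibial_cartilage &
      !pat_shell
  }
  masks[vapply(masks, any, logical(1))]
}

#' Generate one phantom subject
#'
#' Deterministic from `(cfg, subject_seed)`: draws per-subject geometry
#' (centres and radii jittered by `geometry_jitter`), renders each slice's
#' tissue masks, encodes them with the default label scheme, and synthesises
#' the source image as tissue means + Gaussian noise, modulated by a smooth
#' random cosine bias field. A `noise_only_fraction` of slices at both ends
#' of the stack are pure background noise with all-zero labels.
#'
#' @param cfg a [phantom_config()].
#' @param subj_seed integer seed for this subject (see [subject_seeds()]).
#' @param subject_id identifier stamped into the label images.
#' @return List of slices, each `list(source, label, noise_only)` with
#'   `source` an `image_size^2` matrix in `[0, 1]` and `label` a
#'   [label_image()].
#' @export
generate_subject <- function(cfg, subj_seed, subject_id = "subj") {
  stopifnot(inherits(cfg, "phantom_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(subj_seed)
  n <- cfg$image_size
  jit <- function(x, s = cfg$geometry_jitter) x + runif(1, -s, s) * x
  geom <- list(
    femur_cy = jit(0.30), femur_cx = jit(0.45),
    femur_ry = jit(0.17), femur_rx = jit(0.22),
    tibia_cy = jit(0.74), tibia_cx = jit(0.50),
    tibia_ry = jit(0.15), tibia_rx = jit(0.24),
    pat_cy = jit(0.34), pat_cx = jit(0.12),
    vm_cy = jit(0.16), vm_cx = jit(0.88),
    gm_cy = jit(0.84), gm_cx = jit(0.87))
  geom$gap_y <- (geom$femur_cy + geom$tibia_cy) / 2
  geom$gap_x <- (geom$femur_cx + geom$tibia_cx) / 2

  ns <- cfg$slices_per_subject
  n_noise <- round(cfg$noise_only_fraction * ns)
  lead <- ceiling(n_noise / 2)
  noise_idx <- c(seq_len(lead), ns - seq_len(n_noise - lead) + 1L)
  anat_idx <- setdiff(seq_len(ns), noise_idx)
  central <- anat_idx[abs(seq_along(anat_idx) / length(anat_idx) - 0.5) <= 0.25]

  scheme <- default_label_scheme()
  slices <- vector("list", ns)
  for (k in seq_len(ns)) {
    noise_only <- k %in% noise_idx
    src <- matrix(cfg$background_mean +
                    rnorm(n * n, 0, cfg$background_noise_std), n, n)
    lab <- array(0L, c(n, n, 3L))
    if (!noise_only) {
      pos <- match(k, anat_idx)
      masks <- phantom_slice_masks(cfg, n, geom,
                                   slice_frac = pos / length(anat_idx),
                                   central = k %in% central)
      # paint bones last so a rare cross-channel overlap never dims them
      paint_order <- intersect(c("acl", "pcl", "vastus_medialis",
                                 "medial_gastrocnemius", "femoral_cartilage",
                                 "tibial_cartilage", "patellar_cartilage",
                                 "patella", "tibia", "femur"), names(masks))
      for (tn in paint_order) {
        ti <- cfg$tissue_intensity[[tn]]
        npx <- sum(masks[[tn]])
        src[masks[[tn]]] <- ti[1] + rnorm(npx, 0, ti[2])
      }
      lab <- encode_labels(masks, scheme, subject_id = subject_id,
                           slice_index = k - 1L)$data
    }
    if (cfg$bias_field_amplitude > 0) {
      src <- src * bias_field(n, cfg$bias_field_amplitude)
    }
    src <- pmin(pmax(src, 0), 1)
    slices[[k]] <- list(source = src,
                        label = label_image(lab, subject_id = subject_id,
                                            slice_index = k - 1L),
                        noise_only = noise_only)
  }
  slices
}

# smooth multiplicative field: 1 + amplitude * sum of low-frequency cosines
bias_field <- function(n, amplitude, n_modes = sample(2:4, 1)) {
  y <- seq(0, 1, length.out = n)
  f <- matrix(0, n, n)
  for (m in seq_len(n_modes)) {
    fy <- runif(1, 0.5, 1.5); fx <- runif(1, 0.5, 1.5)
    py <- runif(1, 0, 2 * pi); px <- runif(1, 0, 2 * pi)
    f <- f + outer(cos(2 * pi * fy * y + py), cos(2 * pi * fx * y + px))
  }
  f <- f / max(abs(f))
  1 + amplitude * f
}

#' Per-subject seeds for a phantom config
#'
#' @param cfg a [phantom_config()].
#' @return Integer vector of `n_subjects` independent seeds.
#' @export
subject_seeds <- function(cfg) {
  vapply(seq_len(cfg$n_subjects), function(i) subject_seed(cfg$seed, i),
         integer(1))
}

#' Generate a phantom dataset on disk
#'
#' Writes paired 8-bit PNGs (`images/<subject>_<slice 04d>.png` grayscale,
#' `labels/<subject>_<slice 04d>.png` RGB), a tab-separated manifest
#' (subject, slice, noise_only, split) and a subject-level 80/20
#' train/test split.
#'
#' @param cfg a [phantom_config()].
#' @param dir destination directory (created if needed).
#' @param train_fraction subject-level training fraction (default 0.8).
#' @return Invisibly, the manifest data.frame.
#' @export
generate_dataset <- function(cfg, dir, train_fraction = 0.8) {
  stopifnot(inherits(cfg, "phantom_config"))
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "labels"), recursive = TRUE, showWarnings = FALSE)
  n_train <- max(1L, min(cfg$n_subjects - 1L,
                         round(train_fraction * cfg$n_subjects)))
  if (cfg$n_subjects == 1L) n_train <- 1L
  rows <- list()
  for (i in seq_len(cfg$n_subjects)) {
    sid <- sprintf("subj%02d", i)
    split <- if (i <= n_train) "train" else "test"
    slices <- generate_subject(cfg, subject_seed(cfg$seed, i), sid)
    for (k in seq_along(slices)) {
      base <- sprintf("%s_%04d.png", sid, k - 1L)
      png::writePNG(slices[[k]]$source, file.path(dir, "images", base))
      png::writePNG(slices[[k]]$label$data / 255,
                    file.path(dir, "labels", base))
      rows[[length(rows) + 1L]] <-
        data.frame(subject = sid, slice = k - 1L,
                   noise_only = slices[[k]]$noise_only, split = split,
                   stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Shift a phantom config into a related appearance domain
#'
#' Returns a config with all tissue intensity means (and the background)
#' shifted by `shift` and structure sizes rescaled by `1 + shift`, giving a
#' second data domain with related but different appearance for
#' pretrain/fine-tune transfer experiments.
#'
#' @param cfg a [phantom_config()].
#' @param shift additive intensity shift; resulting means must stay in
#'   `[0, 1]`.
#' @return A new `phantom_config`.
#' @export
perturb_domain <- function(cfg, shift) {
  stopifnot(inherits(cfg, "phantom_config"))
  ti <- lapply(cfg$tissue_intensity, function(v) c(v[1] + shift, v[2]))
  means <- c(vapply(ti, `[`, numeric(1), 1L), cfg$background_mean + shift)
  if (any(means < 0 | means > 1))
    stop("shift pushes intensity means outside [0, 1]")
  out <- cfg
  out$tissue_intensity <- ti
  out$background_mean <- cfg$background_mean + shift
  out$geometry_scale <- cfg$geometry_scale * (1 + shift)
  out
}
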