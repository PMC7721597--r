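#' Dice similarity coefficient
#'
#' `2|X n Y| / (|X| + |Y|)`. Two empty masks give 1 by convention; one empty
#' and one non-empty give 0 (a complete segmentation failure).
#'
#' @param x,y congruent [tissue_mask()] objects or logical arrays.
#' @return DSC in `[0, 1]`.
#' @export
dsc <- function(x, y) {
  cnt <- overlap_counts(x, y)
  if (cnt$nx + cnt$ny == 0L) return(1)
  2 * cnt$inter / (cnt$nx + cnt$ny)
}

#' Volumetric overlap error
#'
#' `1 - |X n Y| / |X u Y|`; 0 means perfect overlap. Two empty masks give 0
#' by convention.
#'
#' @inheritParams dsc
#' @return VOE in `[0, 1]`.
#' @export
voe <- function(x, y) {
  cnt <- overlap_counts(x, y)
  uni <- cnt$nx + cnt$ny - cnt$inter
  if (uni == 0L) return(0)
  1 - cnt$inter / uni
}

overlap_counts <- function(x, y) {
  xd <- mask_data(x); yd <- mask_data(y)
  if (!identical(dim(xd), dim(yd))) stop("mask shape mismatch")
  list(nx = sum(xd), ny = sum(yd), inter = sum(xd & yd))
}

mask_data <- function(m) if (inherits(m, "tissue_mask")) m$data else m

mask_spacing <- function(m) {
  if (inherits(m, "tissue_mask")) m$spacing else rep(1, length(dim(m)))
}

surface_raster <- function(data) {
  nd <- length(dim(data))
  interior <- data
  pad_shift <- function(d, axis, by) {
    # logical array shifted by `by` along `axis`, FALSE filled at the border
    out <- array(FALSE, dim(d))
    n <- dim(d)[axis]
    if (abs(by) >= n) return(out)
    src <- seq_len(n - abs(by))
    if (by > 0) {
      idx_to <- src + by; idx_from <- src
    } else {
      idx_to <- src; idx_from <- src - by
    }
    if (nd == 2L) {
      if (axis == 1L) out[idx_to, ] <- d[idx_from, ]
      else out[, idx_to] <- d[, idx_from]
    } else {
      if (axis == 1L) out[idx_to, , ] <- d[idx_from, , ]
      else if (axis == 2L) out[, idx_to, ] <- d[, idx_from, ]
      else out[, , idx_to] <- d[, , idx_from]
    }
    out
  }
  for (axis in seq_len(nd)) {
    interior <- interior & pad_shift(data, axis, 1L) &
      pad_shift(data, axis, -1L)
  }
  data & !interior
}

#' Extract the surface of a Boolean mask
#'
#' Surface voxels are mask voxels with at least one face-adjacent neighbour
#' (4-connected in 2D, 6-connected in 3D) outside the mask or outside the
#' raster. Coordinates are voxel centres scaled by the per-axis spacing.
#'
#' @param mask a non-empty [tissue_mask()] or logical array.
#' @param spacing per-axis spacing, used when `mask` is a bare array.
#' @return Matrix of surface voxel coordinates in mm, one row per voxel,
#'   with the logical surface raster attached as attribute `"raster"`.
#' @export
extract_surface <- function(mask, spacing = mask_spacing(mask)) {
  d <- mask_data(mask)
  if (!any(d)) stop("cannot extract the surface of an empty mask")
  surf <- surface_raster(d)
  idx <- which(surf, arr.ind = TRUE)
  coords <- sweep(idx, 2L, spacing, `*`)
  colnames(coords) <- NULL
  attr(coords, "raster") <- surf
  coords
}

#' Symmetric average surface distance
#'
#' Mean Euclidean distance (mm) from each surface voxel of one mask to the
#' nearest surface voxel of the other, averaged symmetrically over both
#' surfaces: `(sum_{p in S_X} d(p, S_Y) + sum_{q in S_Y} d(q, S_X)) /
#' (N_X + N_Y)`. Distances are voxel-centre to voxel-centre and computed
#' with an exact anisotropic Euclidean distance transform. Undefined (and an
#' error) when either mask is empty; use [evaluate_subject()] for the
#' reporting convention.
#'
#' @param x,y congruent, non-empty [tissue_mask()] objects (or logical
#'   arrays) sharing one spacing.
#' @param spacing per-axis spacing in mm, used when masks are bare arrays.
#' @return ASD in mm.
#' @export
asd <- function(x, y, spacing = mask_spacing(x)) {
  xd <- mask_data(x); yd <- mask_data(y)
  if (!identical(dim(xd), dim(yd))) stop("mask shape mismatch")
  if (!any(xd) || !any(yd)) stop("ASD is undefined for empty masks")
  spx <- mask_spacing(x); spy <- mask_spacing(y)
  if (inherits(x, "tissue_mask") && inherits(y, "tissue_mask") &&
      !isTRUE(all.equal(spx, spy)))
    stop("masks must share one spacing")
  sx <- surface_raster(xd)
  sy <- surface_raster(yd)
  dist_sum <- function(from, to) {
    dt <- edt_dist(to, spacing)
    sum(dt[from])
  }
  (dist_sum(sx, sy) + dist_sum(sy, sx)) / (sum(sx) + sum(sy))
}

# exact EDT in mm of the complement of `feature` (0 at feature voxels);
# 2D rasters are lifted to single-slice volumes
edt_dist <- function(feature, spacing) {
  nd <- length(dim(feature))
  if (nd == 2L) {
    f3 <- array(0L, c(dim(feature), 1L))
    f3[, , 1L] <- feature
    d <- edt_mm(f3, c(spacing, 1))
    return(d[, , 1L])
  }
  storage.mode(feature) <- "integer"
  edt_mm(feature, spacing)
}

#' Evaluate a predicted label volume against ground truth
#'
#' Decodes every tissue of the scheme from both volumes and computes the
#' requested overlap and surface metrics per tissue. Conventions: DSC is 1
#' and VOE 0 when the tissue is absent from both volumes; DSC is 0 (total
#' failure) when present in exactly one; ASD is reported as `NA` whenever
#' either mask is empty.
#'
#' @param pred,truth congruent label volumes: `D x H x W x 3` integer arrays
#'   or lists of [label_image()] slices (stacked in list order).
#' @param scheme a [label_scheme()].
#' @param which metrics to compute, subset of `c("dsc", "voe", "asd")`.
#' @param spacing per-axis voxel spacing (slice, row, column) in mm.
#' @return A data.frame with one row per tissue and columns `tissue`,
#'   `dsc`, `voe`, `asd` (requested metrics only).
#' @export
evaluate_subject <- function(pred, truth, scheme,
                             which = c("dsc", "voe", "asd"),
                             spacing = c(1, 1, 1)) {
  which <- match.arg(which, several.ok = TRUE)
  pv <- as_label_volume(pred)
  tv <- as_label_volume(truth)
  if (!identical(dim(pv), dim(tv))) stop("pred and truth volumes differ in shape")
  out <- data.frame(tissue = scheme$entries$tissue, stringsAsFactors = FALSE)
  for (m in which) out[[m]] <- NA_real_
  for (i in seq_len(nrow(scheme$entries))) {
    tn <- scheme$entries$tissue[i]
    pm <- decode_tissue_mask(pv, tn, scheme, spacing = spacing)
    tm <- decode_tissue_mask(tv, tn, scheme, spacing = spacing)
    if ("dsc" %in% which) out$dsc[i] <- dsc(pm, tm)
    if ("voe" %in% which) out$voe[i] <- voe(pm, tm)
    if ("asd" %in% which)
      out$asd[i] <- if (any(pm$data) && any(tm$data))
        asd(pm, tm, spacing) else NA_real_
  }
  out
}

as_label_volume <- function(x) {
  if (is.array(x) && length(dim(x)) == 4L) {
    storage.mode(x) <- "integer"
    return(x)
  }
  if (is.list(x) && length(x) > 0L) {
    first <- if (inherits(x[[1]], "label_image")) x[[1]]$data else x[[1]]
    vol <- array(0L, c(length(x), dim(first)))
    for (k in seq_along(x)) {
      dk <- if (inherits(x[[k]], "label_image")) x[[k]]$data else x[[k]]
      if (!identical(dim(dk), dim(first))) stop("inconsistent slice shapes")
      vol[k, , , ] <- dk
    }
    return(vol)
  }
  stop("expected a D x H x W x 3 array or a list of label images")
}

#' Aggregate per-subject metric reports
#'
#' Computes the unweighted mean and population standard deviation (divide by
#' n) of each metric across subjects, per tissue, matching the
#' `mean +/- standard deviation` reporting convention. `NA` entries (e.g.
#' undefined ASD) are dropped per cell.
#'
#' @param reports list of per-subject data.frames from [evaluate_subject()].
#' @return A data.frame with columns `tissue` and, per metric,
#'   `<metric>_mean` and `<metric>_sd`.
#' @export
aggregate_reports <- function(reports) {
  stopifnot(length(reports) > 0L)
  tissues <- reports[[1]]$tissue
  metrics <- setdiff(names(reports[[1]]), "tissue")
  out <- data.frame(tissue = tissues, stringsAsFactors = FALSE)
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  for (m in metrics) {
    vals <- sapply(reports, function(r) r[[m]][match(tissues, r$tissue)])
    vals <- matrix(vals, nrow = length(tissues))
    out[[paste0(m, "_mean")]] <-
      apply(vals, 1L, function(v) if (all(is.na(v))) NA_real_
            else mean(v[!is.na(v)]))
    out[[paste0(m, "_sd")]] <-
      apply(vals, 1L, function(v) if (all(is.na(v))) NA_real_
            else pop_sd(v[!is.na(v)]))
  }
  out
}
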