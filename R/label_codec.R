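#' Tissue mask
#'
#' A Boolean raster (2D slice or 3D slice stack) for one tissue, with
#' per-axis physical voxel spacing in mm. 3D arrays are slice-ordered stacks
#' along the leading axis, so `spacing` is (slice, row, column) for 3D and
#' (row, column) for 2D.
#'
#' @param data logical matrix (2D) or 3D logical array.
#' @param spacing numeric vector of per-axis voxel sizes in mm, one per axis.
#' @param tissue tissue name.
#' @return A `tissue_mask`.
#' @export
tissue_mask <- function(data, spacing = rep(1, length(dim(data))),
                        tissue = "tissue") {
  if (is.null(dim(data))) stop("mask data must be a matrix or 3D array")
  storage.mode(data) <- "logical"
  nd <- length(dim(data))
  if (!nd %in% c(2L, 3L)) stop("mask must be 2D or 3D")
  spacing <- as.numeric(spacing)
  if (length(spacing) != nd) stop("spacing must have one entry per axis")
  if (any(spacing <= 0)) stop("spacing must be strictly positive")
  structure(list(data = data, spacing = spacing, tissue = tissue),
            class = "tissue_mask")
}

#' @export
print.tissue_mask <- function(x, ...) {
  cat("tissue_mask '", x$tissue, "': ", paste(dim(x$data), collapse = "x"),
      ", ", sum(x$data), " voxels, spacing (",
      paste(format(x$spacing), collapse = ", "), ") mm\n", sep = "")
  invisible(x)
}

#' Colour-coded label image
#'
#' A 3-channel 8-bit raster (H x W x 3, channel order red/green/blue)
#' holding the colour-coded segmentation of one slice.
#'
#' @param data numeric or integer H x W x 3 array with values in 0..255.
#' @param subject_id subject identifier.
#' @param slice_index non-negative integer slice position.
#' @return A `label_image`.
#' @export
label_image <- function(data, subject_id = "subject", slice_index = 0L) {
  d <- dim(data)
  if (length(d) != 3L || d[3] != 3L) stop("label data must be H x W x 3")
  if (any(data < 0 | data > 255)) stop("channel values must lie in [0, 255]")
  storage.mode(data) <- "integer"
  slice_index <- as.integer(slice_index)
  if (slice_index < 0L) stop("slice_index must be >= 0")
  structure(list(data = data, subject_id = subject_id,
                 slice_index = slice_index),
            class = "label_image")
}

#' @export
print.label_image <- function(x, ...) {
  cat("label_image ", x$subject_id, " slice ", x$slice_index, ": ",
      dim(x$data)[1], "x", dim(x$data)[2], ", ",
      sum(x$data != 0L), " non-zero channel values\n", sep = "")
  invisible(x)
}

#' Encode per-tissue masks into a colour-coded label image
#'
#' Writes each tissue's Boolean mask as its colour code into its channel.
#' Channels are written independently, so tissues living in different
#' channels (e.g. femur and femoral cartilage) may overlap spatially; two
#' masks mapped to the same channel must be disjoint — an overlap there
#' would make the ground truth ambiguous and raises an error.
#'
#' @param masks named list of 2D `tissue_mask` objects (or logical matrices),
#'   names being tissue names present in `scheme`.
#' @param scheme a [label_scheme()].
#' @param subject_id,slice_index metadata for the resulting image.
#' @return A [label_image()].
#' @examples
#' m <- matrix(FALSE, 4, 4); m[2, 2] <- TRUE
#' li <- encode_labels(list(femur = m), default_label_scheme())
#' li$data[2, 2, ]   # (0, 0, 50)
#' @export
encode_labels <- function(masks, scheme, subject_id = "subject",
                          slice_index = 0L) {
  stopifnot(inherits(scheme, "label_scheme"))
  if (length(masks) == 0L) stop("no masks given")
  if (is.null(names(masks)) || any(names(masks) == ""))
    stop("masks must be a named list")
  get_data <- function(m) if (inherits(m, "tissue_mask")) m$data else m
  shp <- dim(get_data(masks[[1]]))
  if (length(shp) != 2L) stop("encode_labels operates on 2D slice masks")
  img <- array(0L, c(shp, 3L))
  for (tn in names(masks)) {
    md <- get_data(masks[[tn]])
    if (!identical(dim(md), shp)) stop("mask shape mismatch for ", tn)
    e <- scheme_entry(scheme, tn)
    ch <- channel_index(e$channel)
    plane <- img[, , ch]
    if (any(plane[md] != 0L))
      stop("masks '", tn, "' and another tissue overlap within the ",
           e$channel, " channel")
    plane[md] <- e$code
    img[, , ch] <- plane
  }
  label_image(img, subject_id = subject_id, slice_index = slice_index)
}

#' Decode one tissue's Boolean mask from a label image
#'
#' A pixel belongs to the tissue iff its value in the tissue's channel lies
#' within the scheme tolerance of the tissue's code (inclusive bounds:
#' `|value - code| <= tolerance`). Values falling between code windows
#' decode to background for every tissue.
#'
#' @param label a [label_image()] or an H x W x 3 array; 3D label volumes
#'   (D x H x W x 3) are also accepted and yield 3D masks.
#' @param tissue tissue name.
#' @param scheme a [label_scheme()].
#' @param spacing voxel spacing passed through to the resulting mask.
#' @return A [tissue_mask()].
#' @examples
#' li <- array(0L, c(1, 1, 3)); li[1, 1, 3] <- 60L
#' decode_tissue_mask(label_image(li), "femur", default_label_scheme())$data
#' @export
decode_tissue_mask <- function(label, tissue, scheme, spacing = NULL) {
  stopifnot(inherits(scheme, "label_scheme"))
  dat <- if (inherits(label, "label_image")) label$data else label
  e <- scheme_entry(scheme, tissue)
  ch <- channel_index(e$channel)
  nd <- length(dim(dat))
  if (nd == 3L) {
    plane <- array(dat[, , ch], dim(dat)[1:2])
  } else if (nd == 4L) {
    plane <- array(dat[, , , ch], dim(dat)[1:3])
  } else stop("label must be H x W x 3 or D x H x W x 3")
  mask <- abs(plane - e$code) <= scheme$tolerance
  if (is.null(spacing)) spacing <- rep(1, length(dim(mask)))
  tissue_mask(mask, spacing = spacing, tissue = tissue)
}

#' Stack ordered 2D tissue masks into a 3D volume
#'
#' @param slices list of congruent 2D `tissue_mask` objects, ordered by
#'   slice index along the stacking (leading) axis.
#' @param slice_spacing physical spacing between slices in mm.
#' @return A 3D [tissue_mask()] whose k-th plane is the k-th slice and whose
#'   spacing is `(slice_spacing, in-plane spacing)`.
#' @export
stack_slices <- function(slices, slice_spacing = 1) {
  if (length(slices) == 0L) stop("cannot stack an empty slice list")
  first <- slices[[1]]
  stopifnot(inherits(first, "tissue_mask"))
  shp <- dim(first$data)
  if (length(shp) != 2L) stop("stack_slices expects 2D slices")
  vol <- array(FALSE, c(length(slices), shp))
  for (k in seq_along(slices)) {
    sk <- slices[[k]]
    if (!identical(dim(sk$data), shp)) stop("inconsistent slice shapes")
    vol[k, , ] <- sk$data
  }
  tissue_mask(vol, spacing = c(slice_spacing, first$spacing),
              tissue = first$tissue)
}

#' Is a label image noise-only?
#'
#' A noise-only slice carries no annotated tissue: every channel value is
#' exactly zero. Such slices are excluded from training by default because
#' fitting against all-zero masks is a poor constraint.
#'
#' @param label a [label_image()] or label array.
#' @return `TRUE` iff all channel values are 0.
#' @export
is_noise_only <- function(label) {
  dat <- if (inherits(label, "label_image")) label$data else label
  all(dat == 0L)
}

#' Filter noise-only pairs out of a paired dataset
#'
#' @param pairs list of `list(source =, label =)` pairs.
#' @param keep_noise_only if `FALSE` (default) drop pairs whose label is
#'   noise-only; if `TRUE`, return the list unchanged.
#' @return The filtered list, input order preserved.
#' @export
filter_dataset <- function(pairs, keep_noise_only = FALSE) {
  if (keep_noise_only || length(pairs) == 0L) return(pairs)
  pairs[!vapply(pairs, function(p) is_noise_only(p$label), logical(1))]
}
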