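#' Load a paired image/label dataset from disk
#'
#' Reads the layout written by [generate_dataset()] (and used for any real
#' data prepared the same way): grayscale source PNGs under `images/`, RGB
#' label PNGs under `labels/`, paired by the filename pattern
#' `<subject>_<slice 04d>.png`, plus a tab-separated `manifest.tsv` with
#' columns subject, slice, noise_only, split.
#'
#' @param dir dataset directory.
#' @param split optional `"train"` or `"test"` to subset by the manifest
#'   split column.
#' @return List of pairs `list(source, label, subject, noise_only)`, ordered
#'   by subject then slice index.
#' @export
load_dataset <- function(dir, split = NULL) {
  mf <- file.path(dir, "manifest.tsv")
  if (!file.exists(mf)) stop("no manifest.tsv under ", dir)
  manifest <- utils::read.delim(mf, stringsAsFactors = FALSE)
  if (!is.null(split)) manifest <- manifest[manifest$split == split, ]
  manifest <- manifest[order(manifest$subject, manifest$slice), ]
  lapply(seq_len(nrow(manifest)), function(i) {
    base <- sprintf("%s_%04d.png", manifest$subject[i], manifest$slice[i])
    src <- png::readPNG(file.path(dir, "images", base))
    if (length(dim(src)) == 3L) src <- src[, , 1L]
    lab <- png::readPNG(file.path(dir, "labels", base))
    lab <- round(lab[, , 1:3, drop = FALSE] * 255)
    list(source = src,
         label = label_image(lab, subject_id = manifest$subject[i],
                             slice_index = manifest$slice[i]),
         subject = manifest$subject[i],
         noise_only = isTRUE(manifest$noise_only[i]))
  })
}

#' Export a 3D tissue mask to NIfTI-1
#'
#' Voxel spacing is recorded in the NIfTI pixdim header fields.
#'
#' @param mask a 3D [tissue_mask()].
#' @param path output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
export_mask_nifti <- function(mask, path) {
  stopifnot(inherits(mask, "tissue_mask"), length(dim(mask$data)) == 3L)
  img <- RNifti::asNifti(array(as.integer(mask$data), dim(mask$data)))
  RNifti::pixdim(img) <- mask$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Import a 3D tissue mask from NIfTI-1
#'
#' @param path NIfTI file with a binary volume.
#' @param tissue tissue name for the resulting mask.
#' @return A 3D [tissue_mask()] with spacing taken from the header.
#' @export
import_mask_nifti <- function(path, tissue = "tissue") {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)
  tissue_mask(array(img != 0, dim(img)), spacing = sp[seq_along(dim(img))],
              tissue = tissue)
}
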