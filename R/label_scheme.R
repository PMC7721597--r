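#' Colour-coded label scheme for knee-joint tissues
#'
#' A label scheme maps each tissue to one RGB channel and an 8-bit colour
#' code; a label image stores every tissue's Boolean mask as that code in
#' that channel, so up to three tissue groups (bones+ACL in blue,
#' cartilages+PCL in green, muscles in red) can coexist on one raster.
#' Decoding accepts any value within `tolerance` colour-scale units of the
#' code (inclusive), which makes the scheme robust to the approximately
#' correct colour values a generator network paints.
#'
#' @param entries data.frame with columns `tissue` (character), `channel`
#'   (one of `"red"`, `"green"`, `"blue"`) and `code` (integer in 1..255).
#' @param tolerance decode half-width in colour-scale units (default 20).
#' @return An object of class `label_scheme`.
#' @details Codes within one channel must differ by more than `2 * tolerance`
#'   so that decode windows never overlap; code 0 is reserved for background.
#' @examples
#' sch <- default_label_scheme()
#' sch$entries
#' @export
label_scheme <- function(entries, tolerance = 20L) {
  stopifnot(is.data.frame(entries),
            all(c("tissue", "channel", "code") %in% names(entries)))
  entries$tissue <- as.character(entries$tissue)
  entries$channel <- as.character(entries$channel)
  entries$code <- as.integer(entries$code)
  if (!all(entries$channel %in% c("red", "green", "blue")))
    stop("channel must be one of 'red', 'green', 'blue'")
  if (anyDuplicated(entries$tissue))
    stop("duplicate tissue names in scheme")
  if (any(entries$code < 1L | entries$code > 255L))
    stop("codes must lie in [1, 255]; 0 is reserved for background")
  tolerance <- as.integer(tolerance)
  for (ch in unique(entries$channel)) {
    codes <- sort(entries$code[entries$channel == ch])
    if (length(codes) > 1L && any(diff(codes) <= 2L * tolerance))
      stop("codes within channel '", ch, "' must differ by more than 2*tolerance")
  }
  structure(list(entries = entries, tolerance = tolerance),
            class = "label_scheme")
}

#' Default knee label scheme
#'
#' The ten-tissue scheme used throughout: blue channel femur 50, tibia 100,
#' patella 150, ACL 200; green channel femoral/tibial/patellar cartilage
#' 50/100/150 and PCL 200; red channel vastus medialis 100 and medial
#' gastrocnemius 200. Decode tolerance is +/- 20 colour-scale units.
#'
#' @return A `label_scheme`.
#' @export
default_label_scheme <- function() {
  label_scheme(data.frame(
    tissue = c("femur", "tibia", "patella", "acl",
               "femoral_cartilage", "tibial_cartilage", "patellar_cartilage",
               "pcl", "vastus_medialis", "medial_gastrocnemius"),
    channel = c("blue", "blue", "blue", "blue",
                "green", "green", "green", "green",
                "red", "red"),
    code = c(50L, 100L, 150L, 200L, 50L, 100L, 150L, 200L, 100L, 200L),
    stringsAsFactors = FALSE
  ), tolerance = 20L)
}

#' @export
print.label_scheme <- function(x, ...) {
  cat("label_scheme:", nrow(x$entries), "tissues, tolerance +/-",
      x$tolerance, "\n")
  print(x$entries, row.names = FALSE)
  invisible(x)
}

scheme_entry <- function(scheme, tissue) {
  i <- match(tissue, scheme$entries$tissue)
  if (is.na(i)) stop("unknown tissue name: ", tissue)
  scheme$entries[i, ]
}

channel_index <- function(channel) {
  match(channel, c("red", "green", "blue"))
}
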