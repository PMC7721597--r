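#' Declarative generator (U-Net) architecture specification
#'
#' The generator downsamples the input through `n_down` stride-2 4x4
#' convolutions (channel progression `min_channels`, `2*min_channels`,
#' `4*min_channels`, ... capped at `channel_cap_factor * min_channels`) and
#' mirrors back up through stride-2 4x4 transposed convolutions with skip
#' concatenations between encoder/decoder layers of equal spatial size. With
#' the studied minima 16/32/64/128 and cap factor 8 the maximum widths are
#' 128/256/512/1024. A 512 px input with `n_down = 9` reaches a 1x1
#' bottleneck.
#'
#' @param n_down number of downsampling convolutions (5, 7 and 9 are the
#'   studied depths; any value `>= 2` admitted).
#' @param min_channels width of the first encoder layer (16/32/64/128
#'   studied).
#' @param input_size square input side in px, divisible by `2^n_down`.
#' @param in_channels,out_channels image channels in and out (grayscale
#'   source in, RGB label map out).
#' @param channel_cap_factor maximum width as a multiple of `min_channels`.
#' @param dropout decoder dropout probability (0 disables; off by default).
#' @return A `generator_spec`.
#' @export
generator_spec <- function(n_down = 9L, min_channels = 64L,
                           input_size = 512L, in_channels = 1L,
                           out_channels = 3L, channel_cap_factor = 8L,
                           dropout = 0) {
  n_down <- as.integer(n_down); min_channels <- as.integer(min_channels)
  input_size <- as.integer(input_size)
  if (min_channels < 1L) stop("min_channels must be >= 1")
  if (n_down < 2L) stop("n_down must be >= 2")
  if (input_size %% 2L^n_down != 0L)
    stop("input_size must be divisible by 2^n_down")
  structure(list(n_down = n_down, min_channels = min_channels,
                 input_size = input_size, in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 channel_cap_factor = as.integer(channel_cap_factor),
                 dropout = dropout),
            class = "generator_spec")
}

#' Build the U-Net generator layer graph
#'
#' Expands a [generator_spec()] into explicit encoder/decoder layer tables:
#' kernel, stride, channel counts, spatial sizes, normalisation flags,
#' activations and skip wiring. Batch normalisation is omitted on the first
#' encoder layer and on any layer with 1x1 spatial output (its statistics
#' would be degenerate at batch size 1); the output layer uses `tanh` so
#' labels live on `[-1, 1]`.
#'
#' @param spec a [generator_spec()].
#' @return A `generator_arch` with `$enc` and `$dec` layer data.frames.
#' @export
build_generator <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  n <- spec$n_down
  cap <- spec$channel_cap_factor * spec$min_channels
  enc_ch <- pmin(spec$min_channels * 2L^(seq_len(n) - 1L), cap)
  enc_in <- c(spec$in_channels, enc_ch[-n])
  enc_size <- spec$input_size %/% 2L^seq_len(n)
  enc <- data.frame(
    layer = seq_len(n), kernel = 4L, stride = 2L,
    in_channels = enc_in, out_channels = enc_ch,
    out_size = enc_size,
    # no norm on the first layer (raw-intensity statistics) nor on the
    # innermost layer (near-degenerate bottleneck statistics at batch 1)
    norm = seq_len(n) > 1L & seq_len(n) < n & enc_size > 1L,
    activation = "leaky_relu", stringsAsFactors = FALSE)

  dec_out <- c(enc_ch[rev(seq_len(n - 1L))], spec$out_channels)
  dec_in <- c(enc_ch[n],
              if (n > 1L) 2L * enc_ch[rev(seq_len(n - 1L))])
  dec_size <- spec$input_size %/% 2L^(n - seq_len(n))
  dec <- data.frame(
    layer = seq_len(n), kernel = 4L, stride = 2L,
    in_channels = dec_in, out_channels = dec_out,
    out_size = dec_size,
    norm = seq_len(n) < n & dec_size > 1L,
    activation = c(rep("relu", n - 1L), "tanh"),
    skip_from = c(NA_integer_, seq(n - 1L, 1L)),  # encoder layer concatenated
    stringsAsFactors = FALSE)
  structure(list(spec = spec, enc = enc, dec = dec,
                 bottleneck = spec$input_size %/% 2L^n),
            class = "generator_arch")
}

#' @export
print.generator_arch <- function(x, ...) {
  s <- x$spec
  cat("U-Net generator: input ", s$input_size, "x", s$input_size, "x",
      s$in_channels, ", ", s$n_down, " down / ", s$n_down,
      " up, bottleneck ", x$bottleneck, "x", x$bottleneck,
      ", max width ", max(x$enc$out_channels), "\n", sep = "")
  cat("encoder:\n"); print(x$enc, row.names = FALSE)
  cat("decoder:\n"); print(x$dec, row.names = FALSE)
  invisible(x)
}

#' Build a PatchGAN / PixelGAN discriminator specification
#'
#' Four studied variants, named after their receptive fields: `pixel_1`
#' (all 1x1 convolutions), `patch_34` (two stride-2 4x4 layers), `patch_70`
#' (three stride-2 4x4 layers, the default) and `patch_286` (five stride-2
#' 4x4 layers); each PatchGAN variant ends with one stride-1 4x4 layer and
#' a stride-1 4x4 output layer. Widths start at `base_width` and double per
#' strided layer, capped at `8 * base_width`. The discriminator is
#' conditional: it sees the source image concatenated channel-wise with the
#' (real or generated) label image.
#'
#' @param variant one of `"pixel_1"`, `"patch_34"`, `"patch_70"`,
#'   `"patch_286"`.
#' @param in_channels input channels (source + label; default 1 + 3).
#' @param base_width first-layer width (64 in all studied variants).
#' @return A `discriminator_spec` with a `$layers` data.frame.
#' @export
build_discriminator <- function(variant = c("patch_70", "pixel_1",
                                            "patch_34", "patch_286"),
                                in_channels = 4L, base_width = 64L) {
  variant <- match.arg(variant)
  n_strided <- switch(variant, pixel_1 = 0L, patch_34 = 2L,
                      patch_70 = 3L, patch_286 = 5L)
  cap <- 8L * base_width
  if (variant == "pixel_1") {
    k <- c(1L, 1L, 1L); s <- c(1L, 1L, 1L)
    ch <- c(base_width, 2L * base_width, 1L)
  } else {
    k <- rep(4L, n_strided + 2L)
    s <- c(rep(2L, n_strided), 1L, 1L)
    ch <- c(pmin(base_width * 2L^(seq_len(n_strided) - 1L), cap),
            min(base_width * 2L^n_strided, cap), 1L)
  }
  nl <- length(k)
  layers <- data.frame(
    layer = seq_len(nl), kernel = k, stride = s,
    in_channels = c(in_channels, ch[-nl]), out_channels = ch,
    pad = ifelse(k == 4L, 1L, 0L),
    norm = seq_len(nl) > 1L & seq_len(nl) < nl,
    activation = c(rep("leaky_relu", nl - 1L), "sigmoid"),
    stringsAsFactors = FALSE)
  structure(list(variant = variant, layers = layers, conditional = TRUE,
                 in_channels = as.integer(in_channels)),
            class = "discriminator_spec")
}

#' @export
print.discriminator_spec <- function(x, ...) {
  cat("PatchGAN discriminator '", x$variant, "' (conditional, ",
      x$in_channels, " input channels), receptive field ",
      receptive_field(x), " px\n", sep = "")
  print(x$layers, row.names = FALSE)
  invisible(x)
}

#' Analytic receptive field of a convolution stack
#'
#' Iterates the backward recurrence `r <- r * s + (k - s)` from `r = 1` over
#' the layers in reverse order; the result is the input-pixel footprint
#' (padding-free, i.e. away from borders) that influences one output unit.
#' The four discriminator variants give 1, 34, 70 and 286 px.
#'
#' @param spec a `discriminator_spec`, a `generator_arch` (its encoder), or
#'   a data.frame with `kernel` and `stride` columns.
#' @return Receptive field side length in px.
#' @examples
#' receptive_field(build_discriminator("patch_70"))  # 70
#' @export
receptive_field <- function(spec) {
  layers <- if (inherits(spec, "discriminator_spec")) spec$layers
            else if (inherits(spec, "generator_arch")) spec$enc
            else spec
  stopifnot(is.data.frame(layers), all(c("kernel", "stride") %in% names(layers)))
  if (nrow(layers) == 0L) stop("empty layer list")
  r <- 1L
  for (i in rev(seq_len(nrow(layers))))
    r <- r * layers$stride[i] + (layers$kernel[i] - layers$stride[i])
  as.integer(r)
}

#' Empirical receptive field by delta probing
#'
#' Independent check of [receptive_field()]: instantiates the convolution
#' stack with all-positive (all-ones) weights and linear activations, places
#' a unit gradient on one interior output unit and propagates it back to the
#' input; the side length of the non-zero input footprint is the receptive
#' field. All-positive weights rule out cancellation, so the footprint is
#' exact.
#'
#' @param spec as in [receptive_field()].
#' @param input_size probe raster side in px; must comfortably exceed the
#'   receptive field so the footprint is not clipped at the border.
#' @return Measured footprint side length in px.
#' @export
receptive_field_probe <- function(spec, input_size = 512L) {
  layers <- if (inherits(spec, "discriminator_spec")) spec$layers
            else if (inherits(spec, "generator_arch")) spec$enc
            else spec
  pads <- if ("pad" %in% names(layers)) layers$pad
          else ifelse(layers$kernel > 1L, 1L, 0L)
  # single-channel chain; track spatial sizes forward
  sizes <- integer(nrow(layers) + 1L)
  sizes[1L] <- as.integer(input_size)
  for (i in seq_len(nrow(layers))) {
    sizes[i + 1L] <- (sizes[i] + 2L * pads[i] - layers$kernel[i]) %/%
      layers$stride[i] + 1L
    if (sizes[i + 1L] < 1L) stop("input_size too small for this stack")
  }
  n_out <- sizes[nrow(layers) + 1L]
  dy <- array(0, c(n_out, n_out, 1L))
  mid <- (n_out + 1L) %/% 2L
  dy[mid, mid, 1L] <- 1
  for (i in rev(seq_len(nrow(layers)))) {
    k <- layers$kernel[i]
    W <- matrix(1, nrow = 1L, ncol = k * k)
    x0 <- array(0, c(sizes[i], sizes[i], 1L))
    dy <- nn_conv2d_bw(x0, W, dy, k, layers$stride[i], pads[i])$dx
  }
  nz <- which(dy[, , 1L] != 0, arr.ind = TRUE)
  if (nrow(nz) == 0L) stop("probe produced an empty footprint")
  ext <- pmax(diff(range(nz[, 1L])), diff(range(nz[, 2L]))) + 1L
  if (min(nz) == 1L || max(nz) == input_size)
    stop("footprint clipped at the border; increase input_size")
  as.integer(ext)
}
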