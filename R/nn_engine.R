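# Minimal manual-backprop conv-net engine. Tensors are H x W x C double
# arrays, batch size is fixed at 1, so batch normalisation reduces to
# instance normalisation (statistics over H x W per channel).

NN_EPS <- 1e-5

act_fw <- function(x, kind) {
  switch(kind,
         leaky_relu = ifelse(x > 0, x, 0.2 * x),
         relu = pmax(x, 0),
         tanh = tanh(x),
         sigmoid = 1 / (1 + exp(-x)),
         none = x,
         stop("unknown activation: ", kind))
}

act_bw <- function(dy, x, y, kind) {
  switch(kind,
         leaky_relu = dy * ifelse(x > 0, 1, 0.2),
         relu = dy * (x > 0),
         tanh = dy * (1 - y^2),
         sigmoid = dy * y * (1 - y),
         none = dy,
         stop("unknown activation: ", kind))
}

inorm_fw <- function(x, gamma, beta) {
  d <- dim(x)
  m <- matrix(x, ncol = d[3])
  mu <- colMeans(m)
  xc <- sweep(m, 2L, mu)
  v <- colMeans(xc^2)
  istd <- 1 / sqrt(v + NN_EPS)
  xhat <- sweep(xc, 2L, istd, `*`)
  y <- sweep(sweep(xhat, 2L, gamma, `*`), 2L, beta, `+`)
  list(y = array(y, d), xhat = xhat, istd = istd)
}

inorm_bw <- function(dy, cache, gamma) {
  d <- dim(dy)
  n <- d[1] * d[2]
  dym <- matrix(dy, ncol = d[3])
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  dxhat <- sweep(dym, 2L, gamma, `*`)
  # dL/dx = istd/n * (n*dxhat - sum(dxhat) - xhat * sum(dxhat*xhat))
  t1 <- sweep(dxhat, 2L, colSums(dxhat) / n)
  t2 <- sweep(cache$xhat, 2L, colSums(dxhat * cache$xhat) / n, `*`)
  dx <- sweep(t1 - t2, 2L, cache$istd, `*`)
  list(dx = array(dx, d), dgamma = dgamma, dbeta = dbeta)
}

init_conv_params <- function(kernel, in_ch, out_ch, norm, transposed = FALSE,
                             sd = 0.02) {
  W <- if (transposed)
    matrix(rnorm(in_ch * kernel^2 * out_ch, 0, sd),
           nrow = in_ch, ncol = kernel^2 * out_ch)
  else
    matrix(rnorm(out_ch * kernel^2 * in_ch, 0, sd),
           nrow = out_ch, ncol = kernel^2 * in_ch)
  p <- list(W = W, b = rep(0, out_ch))
  if (norm) {
    p$gamma <- rnorm(out_ch, 1, sd)
    p$beta <- rep(0, out_ch)
  }
  p
}

# conv block: conv -> [instance norm] -> activation
block_fw <- function(p, x, kernel, stride, pad, activation, transposed) {
  y1 <- if (transposed) nn_tconv2d_fw(x, p$W, p$b, kernel, stride, pad)
        else nn_conv2d_fw(x, p$W, p$b, kernel, stride, pad)
  nc <- NULL
  y2 <- y1
  if (!is.null(p$gamma)) {
    nc <- inorm_fw(y1, p$gamma, p$beta)
    y2 <- nc$y
  }
  a <- act_fw(y2, activation)
  list(out = a, x = x, y1 = y1, y2 = y2, norm = nc)
}

block_bw <- function(p, cache, dout, kernel, stride, pad, activation,
                     transposed, dy2_extra = NULL) {
  dy2 <- act_bw(dout, cache$y2, cache$out, activation)
  if (!is.null(dy2_extra)) dy2 <- dy2 + dy2_extra
  grads <- list()
  if (!is.null(p$gamma)) {
    nb <- inorm_bw(dy2, cache$norm, p$gamma)
    dy1 <- nb$dx
    grads$gamma <- nb$dgamma
    grads$beta <- nb$dbeta
  } else dy1 <- dy2
  cb <- if (transposed) nn_tconv2d_bw(cache$x, p$W, dy1, kernel, stride, pad)
        else nn_conv2d_bw(cache$x, p$W, dy1, kernel, stride, pad)
  grads$W <- if (transposed) cb$dWt else cb$dW
  grads$b <- as.vector(cb$db)
  list(dx = cb$dx, grads = grads)
}

# ---------------------------------------------------------------------------
# Adam with bias correction over a nested parameter list.

adam_init <- function(params) {
  zero_like <- function(p) lapply(p, function(v)
    if (is.list(v)) zero_like(v) else array(0, dim(v) %||% length(v)))
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, state, lr = 2e-4, beta1 = 0.5,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  walk <- function(p, g, m, v) {
    keys <- if (!is.null(names(p))) names(p) else seq_along(p)
    for (nm in keys) {
      if (is.list(p[[nm]])) {
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        p[[nm]] <- r$p; m[[nm]] <- r$m; v[[nm]] <- r$v
      } else {
        gv <- g[[nm]]
        m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * gv
        v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * gv^2
        mhat <- m[[nm]] / (1 - beta1^t)
        vhat <- v[[nm]] / (1 - beta2^t)
        p[[nm]] <- p[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
    list(p = p, m = m, v = v)
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}

# ---------------------------------------------------------------------------
# Generator (U-Net) instantiation and passes.

#' Instantiate U-Net generator parameters
#'
#' Draws all convolution weights from a zero-mean Gaussian with standard
#' deviation 0.02 (batch-norm scale from N(1, 0.02), shifts zero) for the
#' layer graph produced by [build_generator()]. Uses the current RNG state;
#' seed beforehand for reproducibility.
#'
#' @param arch a `generator_arch`.
#' @return A `generator_model` holding `$arch` and parameter lists.
#' @export
init_generator <- function(arch) {
  stopifnot(inherits(arch, "generator_arch"))
  enc <- lapply(seq_len(nrow(arch$enc)), function(i) {
    r <- arch$enc[i, ]
    init_conv_params(r$kernel, r$in_channels, r$out_channels, r$norm)
  })
  dec <- lapply(seq_len(nrow(arch$dec)), function(i) {
    r <- arch$dec[i, ]
    init_conv_params(r$kernel, r$in_channels, r$out_channels, r$norm,
                     transposed = TRUE)
  })
  structure(list(arch = arch, params = list(enc = enc, dec = dec)),
            class = "generator_model")
}

generator_forward <- function(model, x, train = TRUE) {
  arch <- model$arch
  n <- arch$spec$n_down
  p_drop <- arch$spec$dropout
  e_caches <- vector("list", n)
  h <- x
  for (i in seq_len(n)) {
    r <- arch$enc[i, ]
    e_caches[[i]] <- block_fw(model$params$enc[[i]], h, r$kernel, r$stride,
                              1L, r$activation, FALSE)
    h <- e_caches[[i]]$out
  }
  d_caches <- vector("list", n)
  for (j in seq_len(n)) {
    r <- arch$dec[j, ]
    # skips carry post-activation encoder features (classical U-Net tap)
    inp <- if (j == 1L) h else {
      skip <- e_caches[[r$skip_from]]$out
      abind3(h, skip)
    }
    d_caches[[j]] <- block_fw(model$params$dec[[j]], inp, r$kernel, r$stride,
                              1L, r$activation, TRUE)
    h <- d_caches[[j]]$out
    if (train && p_drop > 0 && j < n) {
      mask <- array(runif(length(h)) >= p_drop, dim(h)) / (1 - p_drop)
      d_caches[[j]]$drop_mask <- mask
      h <- h * mask
    }
  }
  list(y = h, enc = e_caches, dec = d_caches)
}

generator_backward <- function(model, cache, dy) {
  arch <- model$arch
  n <- arch$spec$n_down
  g_enc <- vector("list", n)
  g_dec <- vector("list", n)
  d_e <- vector("list", n)  # gradient wrt pre-activation encoder skips
  dh <- dy
  for (j in rev(seq_len(n))) {
    r <- arch$dec[j, ]
    if (!is.null(cache$dec[[j]]$drop_mask))
      dh <- dh * cache$dec[[j]]$drop_mask
    bb <- block_bw(model$params$dec[[j]], cache$dec[[j]], dh, r$kernel,
                   r$stride, 1L, r$activation, TRUE)
    g_dec[[j]] <- bb$grads
    if (j == 1L) {
      dh <- bb$dx
    } else {
      nch_prev <- dim(cache$dec[[j - 1L]]$out)[3]
      dh <- bb$dx[, , seq_len(nch_prev), drop = FALSE]
      dskip <- bb$dx[, , -seq_len(nch_prev), drop = FALSE]
      sf <- r$skip_from
      d_e[[sf]] <- if (is.null(d_e[[sf]])) dskip else d_e[[sf]] + dskip
    }
  }
  # dh holds the gradient wrt the bottleneck activation; d_e[[i]] hold the
  # gradients flowing into the post-activation skip taps
  d_e[[n]] <- if (is.null(d_e[[n]])) dh else d_e[[n]] + dh
  dcur <- NULL
  for (i in rev(seq_len(n))) {
    r <- arch$enc[i, ]
    dtot <- d_e[[i]]
    if (!is.null(dcur)) dtot <- dtot + dcur
    bb <- block_bw(model$params$enc[[i]], cache$enc[[i]], dtot, r$kernel,
                   r$stride, 1L, r$activation, FALSE)
    g_enc[[i]] <- bb$grads
    dcur <- bb$dx
    d_e[[i]] <- NULL
  }
  list(grads = list(enc = g_enc, dec = g_dec), dx = dcur)
}

abind3 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3]))
  out[, , seq_len(da[3])] <- a
  out[, , da[3] + seq_len(db[3])] <- b
  out
}

# ---------------------------------------------------------------------------
# Discriminator instantiation and passes.

#' Instantiate PatchGAN discriminator parameters
#'
#' @param spec a `discriminator_spec` from [build_discriminator()].
#' @return A `discriminator_model`.
#' @export
init_discriminator <- function(spec) {
  stopifnot(inherits(spec, "discriminator_spec"))
  layers <- lapply(seq_len(nrow(spec$layers)), function(i) {
    r <- spec$layers[i, ]
    init_conv_params(r$kernel, r$in_channels, r$out_channels, r$norm)
  })
  structure(list(spec = spec, params = layers),
            class = "discriminator_model")
}

#' Run the conditional discriminator on a (source, label) pair
#'
#' Concatenates the source and label channel-wise, runs the convolution
#' stack and returns the per-patch sigmoid score map together with the
#' scalar discriminator output (the mean over all patches).
#'
#' @param model a `discriminator_model`.
#' @param source H x W (or H x W x 1) source image on `[-1, 1]`.
#' @param label H x W x 3 label image on `[-1, 1]`.
#' @return List with `scores` (patch score map in (0,1)), `scalar` (their
#'   mean) and the backward cache.
#' @export
discriminator_forward <- function(model, source, label) {
  stopifnot(inherits(model, "discriminator_model"))
  if (length(dim(source)) == 2L) dim(source) <- c(dim(source), 1L)
  if (!identical(dim(source)[1:2], dim(label)[1:2]))
    stop("source and label shapes differ")
  x <- abind3(source, label)
  if (dim(x)[3] != model$spec$in_channels)
    stop("channel count mismatch with discriminator spec")
  caches <- vector("list", nrow(model$spec$layers))
  h <- x
  for (i in seq_len(nrow(model$spec$layers))) {
    r <- model$spec$layers[i, ]
    caches[[i]] <- block_fw(model$params[[i]], h, r$kernel, r$stride, r$pad,
                            r$activation, FALSE)
    h <- caches[[i]]$out
  }
  list(scores = h, scalar = mean(h), caches = caches)
}

discriminator_backward <- function(model, fwd, dscores) {
  nl <- nrow(model$spec$layers)
  grads <- vector("list", nl)
  dh <- dscores
  for (i in rev(seq_len(nl))) {
    r <- model$spec$layers[i, ]
    bb <- block_bw(model$params[[i]], fwd$caches[[i]], dh, r$kernel,
                   r$stride, r$pad, r$activation, FALSE)
    grads[[i]] <- bb$grads
    dh <- bb$dx
  }
  list(grads = grads, dx = dh)
}
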