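test_that("discriminator variants have the published layer shapes", {
  d70 <- build_discriminator("patch_70")
  expect_equal(nrow(d70$layers), 5L)
  expect_equal(d70$layers$out_channels[nrow(d70$layers)], 1L)
  expect_equal(d70$layers$stride, c(2L, 2L, 2L, 1L, 1L))
  expect_true(d70$conditional)

  p1 <- build_discriminator("pixel_1")
  expect_true(all(p1$layers$kernel == 1L))
  expect_true(all(p1$layers$stride == 1L))

  d286 <- build_discriminator("patch_286")
  expect_equal(nrow(d286$layers), 7L)
  expect_equal(max(d286$layers$out_channels), 512L)  # width cap 8 x 64
  expect_error(build_discriminator("patch_9000"))
})

test_that("analytic receptive fields match the four studied variants", {
  expect_identical(receptive_field(build_discriminator("pixel_1")), 1L)
  expect_identical(receptive_field(build_discriminator("patch_34")), 34L)
  expect_identical(receptive_field(build_discriminator("patch_70")), 70L)
  expect_identical(receptive_field(build_discriminator("patch_286")), 286L)
  # single 1x1 stride-1 layer has the identity footprint
  expect_identical(receptive_field(data.frame(kernel = 1L, stride = 1L)), 1L)
  expect_error(receptive_field(data.frame(kernel = integer(0),
                                          stride = integer(0))), "empty")
})

test_that("generator graph has mirror symmetry, cap and bottleneck contract", {
  arch <- build_generator(generator_spec(9L, 64L, 512L))
  expect_equal(nrow(arch$enc), 9L)
  expect_equal(arch$bottleneck, 1L)                      # 512 / 2^9
  expect_equal(max(arch$enc$out_channels), 512L)         # 8 x 64 cap
  expect_true(all(diff(arch$enc$out_channels) >= 0L))    # monotone widths
  # decoder mirrors encoder spatial sizes for the skip pairs
  for (j in 2:9) {
    i <- arch$dec$skip_from[j]
    expect_equal(arch$dec$out_size[j - 1L], arch$enc$out_size[i])
  }
  # published min -> max width mapping (cap factor 8)
  for (mc in c(16L, 32L, 64L, 128L)) {
    a <- build_generator(generator_spec(9L, mc, 512L))
    expect_equal(max(a$enc$out_channels), 8L * mc)
  }
  expect_equal(build_generator(generator_spec(5L, 16L, 512L))$bottleneck, 16L)
  expect_error(generator_spec(5L, 16L, 100L), "divisible")
  expect_error(generator_spec(5L, 0L, 64L), "min_channels")
})

test_that("generator forward keeps the autoencoder shape contract", {
  withr::with_seed(5, {
    gm <- init_generator(build_generator(tiny_gen_spec(16L)))
    x <- array(rnorm(16 * 16), c(16, 16, 1))
    out <- kneecgan:::generator_forward(gm, x)
    expect_equal(dim(out$y), c(16L, 16L, 3L))
    expect_true(all(out$y >= -1 & out$y <= 1))   # tanh output
    gm64 <- init_generator(build_generator(
      generator_spec(3L, 4L, 64L)))
    y64 <- kneecgan:::generator_forward(gm64, array(0, c(64, 64, 1)))$y
    expect_equal(dim(y64), c(64L, 64L, 3L))
  })
})

test_that("delta-probe footprint equals the analytic receptive field", {
  for (v in c("pixel_1", "patch_34", "patch_70")) {
    spec <- build_discriminator(v)
    expect_identical(receptive_field_probe(spec, 256L),
                     receptive_field(spec))
  }
  spec <- build_discriminator("patch_286")
  expect_identical(receptive_field_probe(spec, 512L), 286L)
})

test_that("discriminator scores are patchwise in (0,1), averaged to a scalar", {
  withr::with_seed(6, {
    dm <- init_discriminator(build_discriminator("patch_34"))
    src <- matrix(runif(64 * 64), 64)
    lab <- array(runif(64 * 64 * 3, -1, 1), c(64, 64, 3))
    out <- discriminator_forward(dm, src, lab)
    expect_true(all(out$scores > 0 & out$scores < 1))
    expect_equal(out$scalar, mean(out$scores))
    # pixel_1 keeps full spatial resolution
    dp <- init_discriminator(build_discriminator("pixel_1"))
    op <- discriminator_forward(dp, src, lab)
    expect_equal(dim(op$scores)[1:2], c(64L, 64L))
    expect_error(discriminator_forward(dm, matrix(0, 32, 32), lab), "differ")
  })
})

test_that("backpropagation matches finite differences through both networks", {
  withr::with_seed(7, {
    gm <- init_generator(build_generator(
      generator_spec(2L, 3L, 8L)))
    x <- array(rnorm(64), c(8, 8, 1))
    y <- array(rnorm(192), c(8, 8, 3))
    fwd <- kneecgan:::generator_forward(gm, x)
    gb <- kneecgan:::generator_backward(
      gm, fwd, kneecgan:::pixel_loss_grad("L2", y, fwd$y))
    eps <- 1e-6
    loss_at <- function(m) {
      f <- kneecgan:::generator_forward(m, x)
      pixel_loss("L2", y, f$y)
    }
    for (part in c("enc", "dec")) for (li in 1:2) {
      for (idx in c(1L, 7L)) {
        m2 <- gm; m2$params[[part]][[li]]$W[idx] <-
          m2$params[[part]][[li]]$W[idx] + eps
        m3 <- gm; m3$params[[part]][[li]]$W[idx] <-
          m3$params[[part]][[li]]$W[idx] - eps
        num <- (loss_at(m2) - loss_at(m3)) / (2 * eps)
        expect_equal(gb$grads[[part]][[li]]$W[idx], num, tolerance = 1e-5)
      }
    }
    dm <- init_discriminator(build_discriminator("patch_34"))
    src <- matrix(rnorm(32 * 32), 32)
    lab <- array(rnorm(32 * 32 * 3), c(32, 32, 3))
    fd <- discriminator_forward(dm, src, lab)
    db <- kneecgan:::discriminator_backward(
      dm, fd, kneecgan:::d_score_grads(fd$scores, TRUE))
    d_loss <- function(m) {
      f <- discriminator_forward(m, src, lab)
      -mean(log(kneecgan:::clamp_scores(f$scores)))
    }
    for (li in c(1L, 3L)) for (idx in c(2L, 9L)) {
      m2 <- dm; m2$params[[li]]$W[idx] <- m2$params[[li]]$W[idx] + eps
      m3 <- dm; m3$params[[li]]$W[idx] <- m3$params[[li]]$W[idx] - eps
      num <- (d_loss(m2) - d_loss(m3)) / (2 * eps)
      expect_equal(db$grads[[li]]$W[idx], num, tolerance = 1e-5)
    }
  })
})
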