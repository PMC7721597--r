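#' Training objective configuration
#'
#' Bundles the pixel-wise loss kind, its weight `lambda` in the combined
#' generator objective `L_cGAN + lambda * L_pixel`, whether an adversarial
#' term is used at all (plain U-Net training sets `adversarial = FALSE`),
#' and an optional mid-training loss switch: from `switch_epoch` onwards the
#' pixel loss changes to `second_phase_pixel_loss` while network weights and
#' optimizer state carry over unchanged.
#'
#' @param pixel_loss one of `"L1"`, `"L2"`, `"SmoothL1"`, `"none"`.
#' @param lambda_weight non-negative pixel-loss weight (0, 0.01, 1, 100 and
#'   10000 are the studied values); must be 0 iff `pixel_loss == "none"`.
#' @param adversarial include the adversarial term (`FALSE` = plain U-Net).
#' @param switch_epoch optional 0-based epoch at which the pixel loss
#'   switches; must lie strictly inside `(0, epochs)`.
#' @param second_phase_pixel_loss pixel loss after the switch.
#' @param epochs total planned epochs (only used to validate `switch_epoch`).
#' @return An `objective_config`.
#' @export
objective_config <- function(pixel_loss = c("L1", "L2", "SmoothL1", "none"),
                             lambda_weight = 100,
                             adversarial = TRUE,
                             switch_epoch = NULL,
                             second_phase_pixel_loss = NULL,
                             epochs = NULL) {
  pixel_loss <- match.arg(pixel_loss)
  if (lambda_weight < 0) stop("lambda_weight must be non-negative")
  if ((pixel_loss == "none") != (lambda_weight == 0))
    stop("pixel_loss is 'none' iff lambda_weight is 0")
  if (!adversarial && pixel_loss == "none")
    stop("plain U-Net training requires a pixel loss")
  if (!is.null(switch_epoch)) {
    if (is.null(second_phase_pixel_loss))
      stop("switch_epoch configured without second_phase_pixel_loss")
    second_phase_pixel_loss <- match.arg(second_phase_pixel_loss,
                                         c("L1", "L2", "SmoothL1"))
    switch_epoch <- as.integer(switch_epoch)
    if (switch_epoch <= 0L) stop("switch_epoch must be > 0")
    if (!is.null(epochs) && switch_epoch >= epochs)
      stop("switch_epoch must lie strictly inside the epoch range")
  }
  structure(list(pixel_loss = pixel_loss, lambda_weight = lambda_weight,
                 adversarial = adversarial, switch_epoch = switch_epoch,
                 second_phase_pixel_loss = second_phase_pixel_loss),
            class = "objective_config")
}

clamp_scores <- function(s, eps = 1e-7) pmin(pmax(s, eps), 1 - eps)

#' Adversarial loss terms
#'
#' Binary cross-entropy form of the conditional-GAN value function with the
#' non-saturating generator term: the discriminator minimises
#' `-[log D(x,y) + log(1 - D(x,G(x)))]` and the generator minimises
#' `-log D(x,G(x))`. Scores are clamped to `[1e-7, 1 - 1e-7]` before the
#' logarithms; expectations are arithmetic means over the patch score map.
#' At the uninformative fixed point (all scores 0.5) the discriminator term
#' equals `2 log 2`, the Nash-equilibrium plateau of a converged GAN.
#'
#' @param d_real discriminator score(s) on the real pair, in (0,1).
#' @param d_fake discriminator score(s) on the generated pair.
#' @return List with `generator` and `discriminator` loss terms.
#' @export
adversarial_losses <- function(d_real, d_fake) {
  if (any(d_real < 0 | d_real > 1) || any(d_fake < 0 | d_fake > 1))
    stop("scores must lie in [0, 1]")
  dr <- clamp_scores(d_real)
  df <- clamp_scores(d_fake)
  list(generator = -mean(log(df)),
       discriminator = -(mean(log(dr)) + mean(log(1 - df))))
}

#' Pixel-wise reconstruction losses
#'
#' `L1` is the mean absolute difference, `L2` the mean squared difference,
#' and `SmoothL1` the element-wise Huber loss with delta 1 (`0.5 d^2` for
#' `|d| < 1`, `|d| - 0.5` otherwise), each averaged over all elements.
#' Inputs are expected on the `[-1, 1]` training scale.
#'
#' @param kind one of `"L1"`, `"L2"`, `"SmoothL1"`.
#' @param y,g congruent target and generated arrays.
#' @return Non-negative scalar loss.
#' @export
pixel_loss <- function(kind = c("L1", "L2", "SmoothL1"), y, g) {
  kind <- match.arg(kind)
  if (!identical(dim(y), dim(g))) stop("shape mismatch between y and g")
  d <- y - g
  switch(kind,
         L1 = mean(abs(d)),
         L2 = mean(d^2),
         SmoothL1 = mean(ifelse(abs(d) < 1, 0.5 * d^2, abs(d) - 0.5)))
}

# gradient of pixel_loss wrt g (mean-normalised)
pixel_loss_grad <- function(kind, y, g) {
  d <- g - y
  n <- length(d)
  switch(kind,
         L1 = sign(d) / n,
         L2 = 2 * d / n,
         SmoothL1 = ifelse(abs(d) < 1, d, sign(d)) / n)
}

#' Combined generator objective
#'
#' `adversarial term + lambda * pixel term`; with `adversarial = FALSE`
#' (U-Net mode) the pixel term alone, with `lambda = 0` the adversarial term
#' alone.
#'
#' @param cfg an [objective_config()].
#' @param adv_term adversarial generator loss term.
#' @param pixel_term pixel loss term.
#' @return Scalar total generator loss.
#' @export
total_generator_loss <- function(cfg, adv_term, pixel_term) {
  stopifnot(inherits(cfg, "objective_config"))
  if (!cfg$adversarial) return(pixel_term)
  if (cfg$lambda_weight == 0) return(adv_term)
  adv_term + cfg$lambda_weight * pixel_term
}

#' Effective pixel loss at a given epoch
#'
#' Implements the mid-training loss switch: before `switch_epoch` (or when
#' no switch is configured) the first-phase pixel loss applies; from
#' `switch_epoch` onwards the second-phase loss applies. Epochs are 0-based.
#'
#' @param cfg an [objective_config()].
#' @param epoch 0-based epoch index.
#' @return The active pixel-loss kind.
#' @export
active_objective <- function(cfg, epoch) {
  stopifnot(inherits(cfg, "objective_config"), epoch >= 0)
  if (is.null(cfg$switch_epoch) || epoch < cfg$switch_epoch)
    cfg$pixel_loss
  else cfg$second_phase_pixel_loss
}
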