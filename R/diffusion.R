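# Core DDPM mathematics: forward corruption, its algebraic inverse, the
# ancestral reverse update, and the noise-prediction losses.
#
# All operations accept a scalar timestep (applied to the whole batch) or a
# per-image timestep vector of length nrow(batch), as used during training
# where each batch element is corrupted at its own level.

# multiply batch (N,C,H,W) by a per-image coefficient vector of length N;
# rep() tiles v with the batch index fastest, matching column-major layout
scale_per_image <- function(x, v) {
  x * rep(v, length(x) / length(v))
}

resolve_t <- function(t, n, s) {
  if (!is.numeric(t) || anyNA(t) || any(t != round(t)) ||
      any(t < 1) || any(t > s$timesteps)) {
    stop(sprintf("timestep out of range: valid timesteps are 1..%d",
                 s$timesteps), call. = FALSE)
  }
  if (length(t) == 1L) rep(as.integer(t), n)
  else if (length(t) == n) as.integer(t)
  else stop("`t` must be a scalar or one timestep per image", call. = FALSE)
}

#' Forward diffusion: corrupt clean images to noise level t
#'
#' Computes `x_t = sqrt(alpha_bar_t) * x0 + sqrt(1 - alpha_bar_t) * eps`,
#' the closed-form marginal of the forward Markov chain. No clamping is
#' applied: `x_t` may leave `[-1, 1]`.
#'
#' @param x0 clean [image_batch()] in the normalized domain.
#' @param t timestep (scalar or per-image vector), 1-based.
#' @param eps a Gaussian noise array shaped like `x0`.
#' @param s a [make_linear_schedule()] object.
#' @return the corrupted batch `x_t` (normalized domain, unclamped).
#' @export
#' @examples
#' s <- make_linear_schedule(300)
#' x0 <- image_batch(array(0, c(2, 1, 4, 4)))
#' eps <- array(rnorm(32), c(2, 1, 4, 4))
#' xt <- q_sample(x0, 150, eps, s)
q_sample <- function(x0, t, eps, s) {
  check_normalized(x0, "x0")
  check_same_shape(x0, eps, "x0", "eps")
  tv <- resolve_t(t, dim(x0)[1], s)
  k <- schedule_constants_at(s, tv)
  y <- scale_per_image(unclass(x0), k$sqrt_alpha_bar) +
    scale_per_image(unclass(eps), k$sqrt_one_minus_alpha_bar)
  as_batch(y)
}

#' Invert the forward map given a noise estimate
#'
#' Computes `x0_hat = (x_t - sqrt(1 - alpha_bar_t) * eps_hat) /
#' sqrt(alpha_bar_t)`, the algebraic inversion of [q_sample()]. With the true
#' noise this recovers `x0` exactly; with a model's noise prediction it gives
#' the implied clean image (useful for previews and diagnostics).
#'
#' @inheritParams q_sample
#' @param xt corrupted batch at level `t`.
#' @param eps_hat noise estimate shaped like `xt`.
#' @return the implied clean batch (normalized domain, unclamped).
#' @export
predict_x0 <- function(xt, t, eps_hat, s) {
  check_normalized(xt, "xt")
  check_same_shape(xt, eps_hat, "xt", "eps_hat")
  tv <- resolve_t(t, dim(xt)[1], s)
  k <- schedule_constants_at(s, tv)
  y <- scale_per_image(
    unclass(xt) - scale_per_image(unclass(eps_hat),
                                  k$sqrt_one_minus_alpha_bar),
    1 / k$sqrt_alpha_bar)
  as_batch(y)
}

#' One ancestral reverse-diffusion step
#'
#' Computes the DDPM reverse update
#' `x_{t-1} = (x_t - beta_t / sqrt(1 - alpha_bar_t) * eps_hat) / sqrt(alpha_t)
#'  + sigma_t * z`,
#' with the noise term suppressed at `t = 1` (the deterministic last step).
#'
#' @inheritParams predict_x0
#' @param z a Gaussian draw shaped like `xt`; ignored where `t = 1`.
#' @return the batch `x_{t-1}` (normalized domain, unclamped).
#' @export
p_sample_step <- function(xt, t, eps_hat, z, s) {
  check_normalized(xt, "xt")
  check_same_shape(xt, eps_hat, "xt", "eps_hat")
  check_same_shape(xt, z, "xt", "z")
  tv <- resolve_t(t, dim(xt)[1], s)
  k <- schedule_constants_at(s, tv)
  mean_part <- scale_per_image(
    unclass(xt) - scale_per_image(unclass(eps_hat),
                                  k$beta / k$sqrt_one_minus_alpha_bar),
    1 / sqrt(k$alpha))
  sig <- ifelse(tv == 1L, 0, k$sigma)
  as_batch(mean_part + scale_per_image(unclass(z), sig))
}

#' Noise-prediction training loss
#'
#' The training objective compares the model's noise estimate against the
#' noise actually injected, averaged over every element of the batch. Three
#' kinds are supported for residual `r = eps_hat - eps`:
#' * `"l1"`: `|r|`;
#' * `"l2"`: `r^2` (plain mean square, no 1/2 factor);
#' * `"huber"`: `r^2 / 2` where `|r| <= delta`, else `delta |r| - delta^2/2`.
#'
#' The Huber quadratic branch carries the 1/2 factor, so its `delta -> Inf`
#' limit is half the L2 loss; loss curves across kinds are therefore on the
#' documented scales `0 <= huber(delta = 1) <= l2 / 2`.
#'
#' @param eps_hat,eps arrays of identical shape.
#' @param kind `"huber"`, `"l1"` or `"l2"` (case-insensitive).
#' @param delta positive Huber threshold; used only by `"huber"`. Default 1.
#' @return a non-negative scalar.
#' @export
#' @examples
#' noise_prediction_loss(array(0.5, c(1, 1, 2, 2)), array(0, c(1, 1, 2, 2)),
#'                       "huber")  # 0.125
noise_prediction_loss <- function(eps_hat, eps,
                                  kind = c("huber", "l1", "l2"),
                                  delta = 1) {
  kind <- match.arg(tolower(kind), c("huber", "l1", "l2"))
  check_same_shape(eps_hat, eps, "eps_hat", "eps")
  if (!is.numeric(delta) || length(delta) != 1L || is.na(delta) ||
      delta <= 0) {
    stop("`delta` must be a positive scalar", call. = FALSE)
  }
  r <- as.numeric(eps_hat) - as.numeric(eps)
  switch(kind,
    l1 = mean(abs(r)),
    l2 = mean(r * r),
    huber = {
      a <- abs(r)
      mean(ifelse(a <= delta, 0.5 * r * r, delta * a - 0.5 * delta^2))
    })
}

# d loss / d eps_hat, elementwise, including the 1/n mean factor
loss_gradient <- function(eps_hat, eps, kind, delta = 1) {
  kind <- match.arg(tolower(kind), c("huber", "l1", "l2"))
  r <- unclass(eps_hat) - unclass(eps)
  n <- length(r)
  g <- switch(kind,
    l1 = sign(r),
    l2 = 2 * r,
    huber = clamp(r, -delta, delta))
  g / n
}
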