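#' Construct a linear noise schedule
#'
#' Builds the per-timestep constants of a denoising diffusion probabilistic
#' model (DDPM) with a linear variance schedule: `betas` are `timesteps`
#' evenly spaced values from `beta_start` to `beta_end` inclusive,
#' `alphas = 1 - betas`, `alpha_bars` is the running product of the alphas
#' (the surviving signal fraction after t corruption steps), and `sigmas` is
#' the reverse-step noise scale.
#'
#' Two conventional choices of the reverse variance are supported:
#' `sigma_variant = "beta"` uses `sigma_t^2 = beta_t` (the simpler DDPM
#' choice, the default), and `"posterior"` uses
#' `sigma_t^2 = beta_t * (1 - alpha_bar_{t-1}) / (1 - alpha_bar_t)` (the true
#' posterior variance; zero at t = 1). Both satisfy `sigma_t^2 <= beta_t`.
#'
#' Timesteps are 1-based everywhere in the public interface: `t = 1` is the
#' first (mildest) corruption step and `t = timesteps` the last.
#'
#' @param timesteps positive integer, number of diffusion steps T.
#' @param beta_start,beta_end schedule endpoints, `0 < beta_start <=
#'   beta_end < 1`. Defaults 1e-4 and 0.02.
#' @param sigma_variant `"beta"` or `"posterior"`.
#' @return an object of class `noise_schedule`: a list with elements
#'   `timesteps`, `betas`, `alphas`, `alpha_bars`, `sigmas`, `sigma_variant`,
#'   `beta_start`, `beta_end`.
#' @export
#' @examples
#' s <- make_linear_schedule(300)
#' s$betas[c(1, 300)]        # 1e-4, 0.02
#' s$alpha_bars[300]         # ~0.048: almost pure noise at t = T
make_linear_schedule <- function(timesteps, beta_start = 1e-4,
                                 beta_end = 0.02,
                                 sigma_variant = c("beta", "posterior")) {
  sigma_variant <- match.arg(sigma_variant)
  if (!is.numeric(timesteps) || length(timesteps) != 1L ||
      is.na(timesteps) || timesteps < 1 || timesteps != round(timesteps)) {
    stop("`timesteps` must be a positive integer", call. = FALSE)
  }
  timesteps <- as.integer(timesteps)
  for (nm in c("beta_start", "beta_end")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0 || v >= 1) {
      stop(sprintf("`%s` must lie in (0, 1)", nm), call. = FALSE)
    }
  }
  if (beta_start > beta_end) {
    stop("`beta_start` must not exceed `beta_end`", call. = FALSE)
  }
  betas <- if (timesteps == 1L) beta_start else
    seq(beta_start, beta_end, length.out = timesteps)
  alphas <- 1 - betas
  alpha_bars <- cumprod(alphas)
  sigmas <- switch(sigma_variant,
    beta = sqrt(betas),
    posterior = {
      ab_prev <- c(1, alpha_bars[-timesteps])
      sqrt(betas * (1 - ab_prev) / (1 - alpha_bars))
    })
  structure(
    list(timesteps = timesteps, betas = betas, alphas = alphas,
         alpha_bars = alpha_bars, sigmas = sigmas,
         sigma_variant = sigma_variant,
         beta_start = beta_start, beta_end = beta_end),
    class = "noise_schedule")
}

#' Query the schedule constants at one or more timesteps
#'
#' @param s a [make_linear_schedule()] object.
#' @param t integer vector of timesteps, each in `1..s$timesteps`.
#' @return a list with numeric elements `beta`, `alpha`, `alpha_bar`,
#'   `sigma`, `sqrt_alpha_bar`, `sqrt_one_minus_alpha_bar`, each of
#'   `length(t)`.
#' @export
#' @examples
#' s <- make_linear_schedule(300)
#' schedule_constants_at(s, 150)$alpha_bar
schedule_constants_at <- function(s, t) {
  stopifnot(inherits(s, "noise_schedule"))
  if (!is.numeric(t) || length(t) < 1L || anyNA(t) || any(t != round(t)) ||
      any(t < 1) || any(t > s$timesteps)) {
    stop(sprintf("timestep out of range: valid timesteps are 1..%d",
                 s$timesteps), call. = FALSE)
  }
  t <- as.integer(t)
  ab <- s$alpha_bars[t]
  list(beta = s$betas[t], alpha = s$alphas[t], alpha_bar = ab,
       sigma = s$sigmas[t],
       sqrt_alpha_bar = sqrt(ab),
       sqrt_one_minus_alpha_bar = sqrt(1 - ab))
}

#' @export
print.noise_schedule <- function(x, ...) {
  cat(sprintf(
    "<noise_schedule> T=%d  beta: %g -> %g (linear)  sigma^2: %s\n",
    x$timesteps, x$beta_start, x$beta_end,
    switch(x$sigma_variant, beta = "beta_t",
           posterior = "beta_t (1-abar_{t-1})/(1-abar_t)")))
  cat(sprintf("  alpha_bar: %.6f -> %.6f\n",
              x$alpha_bars[1], x$alpha_bars[x$timesteps]))
  invisible(x)
}

# serialization helpers used by run configs and checkpoints
schedule_to_list <- function(s) {
  list(timesteps = s$timesteps, beta_start = s$beta_start,
       beta_end = s$beta_end, sigma_variant = s$sigma_variant)
}

schedule_from_list <- function(lst) {
  make_linear_schedule(lst$timesteps, lst$beta_start, lst$beta_end,
                       lst$sigma_variant %||% "beta")
}
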