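# Analytic noise-predictor stubs plugged into the denoise() generic, and
# shared fixtures built in code.

# predicts zero noise everywhere
zero_denoiser <- function(timesteps = NULL) {
  structure(list(schedule_meta = if (!is.null(timesteps))
    list(timesteps = timesteps)), class = "zero_denoiser")
}

denoise.zero_denoiser <- function(model, xt, t, ...) {
  minidiffusion:::as_batch(array(0, dim(xt)))
}
registerS3method("denoise", "zero_denoiser", denoise.zero_denoiser,
                 envir = asNamespace("minidiffusion"))

# with x0 = 0 the forward map is x_t = sqrt(1 - alpha_bar_t) * eps, so the
# injected noise can be recovered exactly from (x_t, t): a perfect oracle
oracle_denoiser <- function(s) {
  structure(list(s = s), class = "oracle_denoiser")
}

denoise.oracle_denoiser <- function(model, xt, t, ...) {
  k <- schedule_constants_at(model$s, t)
  minidiffusion:::as_batch(
    minidiffusion:::scale_per_image(unclass(xt),
                                    1 / k$sqrt_one_minus_alpha_bar))
}
registerS3method("denoise", "oracle_denoiser", denoise.oracle_denoiser,
                 envir = asNamespace("minidiffusion"))

# a small gradient-check architecture on 8x8 inputs
gradcheck_spec <- function() {
  denoiser_spec(base_channels = 8L, channel_multipliers = c(1L, 2L),
                blocks_per_stage = 1L, time_embedding_dim = 8L,
                attention_levels = 2L, num_heads = 2L, image_size = 8L)
}

# phantoms are reused across test files; render each set once
.fixture_env <- new.env(parent = emptyenv())

fixture_phantoms <- function(n, seed = 7) {
  key <- paste0("ph-", n, "-", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- generate_phantoms(phantom_params(n, seed = seed))
  }
  .fixture_env[[key]]
}

expect_batches_identical <- function(a, b) {
  expect_identical(unclass(a), unclass(b))
}
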