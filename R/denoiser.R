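#' Sinusoidal timestep embedding
#'
#' Maps a (noise-level) timestep to a fixed `dim`-dimensional vector: the
#' first `dim/2` entries are `sin(t * w_k)` and the last `dim/2` are
#' `cos(t * w_k)`, with geometrically spaced frequencies
#' `w_k = 10000^(-k / (dim/2 - 1))`, `k = 0 .. dim/2 - 1`. This is the
#' transformer positional encoding applied to the diffusion timestep; it lets
#' one network condition on every noise level.
#'
#' @param t non-negative timestep (scalar).
#' @param dim even positive embedding width.
#' @return numeric vector of length `dim`, each entry in `[-1, 1]`.
#' @export
#' @examples
#' sinusoidal_time_embedding(0, 8)  # sin half all 0, cos half all 1
sinusoidal_time_embedding <- function(t, dim) {
  if (!is.numeric(dim) || length(dim) != 1L || dim < 2 || dim %% 2 != 0) {
    stop("`dim` must be an even positive integer", call. = FALSE)
  }
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0) {
    stop("`t` must be a non-negative scalar", call. = FALSE)
  }
  drop(time_embedding_matrix(t, as.integer(dim)))
}

# vectorized over timesteps: returns length(t) x dim matrix
time_embedding_matrix <- function(t, dim) {
  half <- dim %/% 2L
  w <- if (half == 1L) 1 else exp(-log(10000) * (seq_len(half) - 1) /
                                    (half - 1))
  arg <- outer(as.numeric(t), w)
  cbind(sin(arg), cos(arg))
}

#' Describe a U-Net noise-predictor architecture
#'
#' The denoiser is a compact U-Net: a stem convolution, a stack of
#' resolution levels each holding `blocks_per_stage` time-conditioned
#' residual blocks (group normalization, SiLU, 3x3 convolutions) with
#' optional multi-head self-attention, strided-convolution downsampling
#' between levels, a middle section of residual blocks interleaved with
#' attention, a mirrored decoder using transposed-convolution upsampling and
#' skip connections concatenated from the encoder, and a normalized output
#' convolution. The timestep enters through a sinusoidal embedding passed
#' through a small MLP and added per-channel inside every residual block.
#'
#' @param base_channels width of the first level. Default 28.
#' @param channel_multipliers one per resolution level; level `l` has
#'   `base_channels * channel_multipliers[l]` channels. Default `c(1, 2, 4)`
#'   giving 28x28 -> 14x14 -> 7x7 for 28-pixel inputs.
#' @param blocks_per_stage residual blocks per level. Default 2.
#' @param time_embedding_dim even width of the sinusoidal embedding.
#'   Default `4 * base_channels`.
#' @param attention_levels integer level indices (1 = full resolution) where
#'   self-attention is applied, in both encoder and decoder; the middle
#'   section always carries attention. Default: every level.
#' @param num_heads attention heads; must divide the channel count at every
#'   attention site. Default 4.
#' @param image_size expected input height/width; must be divisible by
#'   `2^(levels - 1)`. Default 28.
#' @return a `denoiser_spec` list.
#' @export
denoiser_spec <- function(base_channels = 28L,
                          channel_multipliers = c(1L, 2L, 4L),
                          blocks_per_stage = 2L,
                          time_embedding_dim = 4L * base_channels,
                          attention_levels = seq_along(channel_multipliers),
                          num_heads = 4L,
                          image_size = 28L) {
  spec <- list(base_channels = as.integer(base_channels),
               channel_multipliers = as.integer(channel_multipliers),
               blocks_per_stage = as.integer(blocks_per_stage),
               time_embedding_dim = as.integer(time_embedding_dim),
               attention_levels = as.integer(attention_levels),
               num_heads = as.integer(num_heads),
               image_size = as.integer(image_size))
  validate_denoiser_spec(spec)
  structure(spec, class = "denoiser_spec")
}

validate_denoiser_spec <- function(spec) {
  L <- length(spec$channel_multipliers)
  if (L < 1L || any(spec$channel_multipliers < 1L)) {
    stop("`channel_multipliers` must be positive integers", call. = FALSE)
  }
  for (nm in c("base_channels", "blocks_per_stage", "num_heads",
               "image_size")) {
    if (length(spec[[nm]]) != 1L || is.na(spec[[nm]]) || spec[[nm]] < 1L) {
      stop(sprintf("`%s` must be a positive integer", nm), call. = FALSE)
    }
  }
  if (spec$time_embedding_dim < 2L || spec$time_embedding_dim %% 2L != 0L) {
    stop("`time_embedding_dim` must be even and positive", call. = FALSE)
  }
  div <- 2L^(L - 1L)
  if (spec$image_size %% div != 0L) {
    stop(sprintf(
      "`image_size` (%d) must be divisible by 2^(levels-1) = %d",
      spec$image_size, div), call. = FALSE)
  }
  if (length(spec$attention_levels) &&
      (any(spec$attention_levels < 1L) || any(spec$attention_levels > L))) {
    stop("`attention_levels` must be level indices in 1..levels",
         call. = FALSE)
  }
  chs <- spec$base_channels * spec$channel_multipliers
  for (l in unique(c(spec$attention_levels, L))) {
    if (chs[l] %% spec$num_heads != 0L) {
      stop(sprintf(
        "`num_heads` (%d) must divide the %d channels of attention level %d",
        spec$num_heads, chs[l], l), call. = FALSE)
    }
  }
  invisible(spec)
}

#' A desk-scale denoiser configuration
#'
#' A small preset used throughout the test suite and the worked examples:
#' 8 base channels, multipliers `(1, 2, 4)`, attention only at the deepest
#' (7x7) level with 2 heads, and a 32-wide time embedding. It trains in
#' minutes on one CPU while exercising every architectural component.
#'
#' @param image_size input height/width, divisible by 4. Default 28.
#' @return a [denoiser_spec()].
#' @export
tiny_denoiser_spec <- function(image_size = 28L) {
  denoiser_spec(base_channels = 8L, channel_multipliers = c(1L, 2L, 4L),
                blocks_per_stage = 2L, time_embedding_dim = 32L,
                attention_levels = 3L, num_heads = 2L,
                image_size = image_size)
}

#' Build a denoiser model with seeded initial parameters
#'
#' Parameters are initialized He-style from a private RNG stream, so
#' identical seeds give bitwise-identical models and the caller's RNG state
#' is untouched. The final output convolution is initialized near (but not
#' at) zero so an untrained model predicts small noise.
#'
#' @param spec a [denoiser_spec()].
#' @param rng_seed integer initialization seed.
#' @return a `denoiser_model` with elements `spec`, `params`, `rng_seed`,
#'   `n_params`.
#' @export
#' @examples
#' m <- build_denoiser(tiny_denoiser_spec(), rng_seed = 17)
#' m$n_params
build_denoiser <- function(spec, rng_seed = 0L) {
  validate_denoiser_spec(spec)
  L <- length(spec$channel_multipliers)
  chs <- spec$base_channels * spec$channel_multipliers
  nb <- spec$blocks_per_stage
  td <- spec$time_embedding_dim
  params <- with_seed(rng_seed, {
    p <- list()
    p$time_mlp <- list(l1 = init_linear(td, 4L * td),
                       l2 = init_linear(4L * td, td))
    p$stem <- init_conv(1L, chs[1], 3L)
    p$down <- vector("list", L)
    for (l in seq_len(L)) {
      cin <- if (l == 1L) chs[1] else chs[l - 1L]
      blocks <- vector("list", nb)
      for (i in seq_len(nb)) {
        blocks[[i]] <- init_resblock(if (i == 1L) cin else chs[l], chs[l], td)
      }
      p$down[[l]] <- list(
        blocks = blocks,
        attn = if (l %in% spec$attention_levels) init_attn(chs[l]) else NULL,
        downsample = if (l < L) init_conv(chs[l], chs[l], 3L) else NULL)
    }
    p$mid <- list(block1 = init_resblock(chs[L], chs[L], td),
                  attn = init_attn(chs[L]),
                  block2 = init_resblock(chs[L], chs[L], td))
    p$up <- vector("list", L)
    for (l in seq_len(L)) {
      cin <- if (l == L) chs[L] else chs[l]
      blocks <- vector("list", nb)
      for (i in seq_len(nb)) {
        blocks[[i]] <- init_resblock(if (i == 1L) cin + chs[l] else chs[l],
                                     chs[l], td)
      }
      p$up[[l]] <- list(
        blocks = blocks,
        attn = if (l %in% spec$attention_levels) init_attn(chs[l]) else NULL,
        upsample = if (l > 1L) init_tconv(chs[l], chs[l - 1L]) else NULL)
    }
    p$out <- list(gn = init_gn(chs[1]),
                  conv = init_conv(chs[1], 1L, 3L, scale = 0.1))
    p
  })
  structure(list(spec = spec, params = params, rng_seed = as.integer(rng_seed),
                 n_params = count_params(params), schedule_meta = NULL),
            class = "denoiser_model")
}

#' @export
print.denoiser_model <- function(x, ...) {
  s <- x$spec
  cat(sprintf(
    "<denoiser_model> U-Net: base=%d mult=(%s) blocks=%d attn@(%s) heads=%d\n",
    s$base_channels, paste(s$channel_multipliers, collapse = ","),
    s$blocks_per_stage, paste(s$attention_levels, collapse = ","),
    s$num_heads))
  cat(sprintf("  %d parameters, init seed %d\n", x$n_params, x$rng_seed))
  invisible(x)
}

# ---- forward / backward over the whole network ------------------------------
# x: internal layout (H, W, N, 1); tvec: one timestep per image

# skip_scale multiplies the encoder skip tensors before decoder
# concatenation; it exists so tests can ablate the skips (scale 0) and
# verify they are actually wired.
unet_fwd <- function(spec, params, x, tvec, skip_scale = 1) {
  L <- length(spec$channel_multipliers)
  nb <- spec$blocks_per_stage
  te0 <- time_embedding_matrix(tvec, spec$time_embedding_dim)
  tl1 <- linear_fwd(te0, params$time_mlp$l1)
  tsl <- silu_fwd(tl1$y)
  tl2 <- linear_fwd(tsl$y, params$time_mlp$l2)
  temb <- tl2$y
  stem <- conv3_fwd(x, params$stem)
  h <- stem$y
  down <- vector("list", L)
  skips <- vector("list", L)
  for (l in seq_len(L)) {
    bc <- vector("list", nb)
    for (i in seq_len(nb)) {
      bc[[i]] <- resblock_fwd(h, temb, params$down[[l]]$blocks[[i]])
      h <- bc[[i]]$y
    }
    ac <- NULL
    if (!is.null(params$down[[l]]$attn)) {
      ac <- attn_fwd(h, params$down[[l]]$attn, spec$num_heads)
      h <- ac$y
    }
    skips[[l]] <- h
    dc <- NULL
    if (!is.null(params$down[[l]]$downsample)) {
      dc <- conv3_fwd(h, params$down[[l]]$downsample, stride = 2L)
      h <- dc$y
    }
    down[[l]] <- list(blocks = bc, attn = ac, down = dc)
  }
  m1 <- resblock_fwd(h, temb, params$mid$block1)
  ma <- attn_fwd(m1$y, params$mid$attn, spec$num_heads)
  m2 <- resblock_fwd(ma$y, temb, params$mid$block2)
  h <- m2$y
  up <- vector("list", L)
  for (l in rev(seq_len(L))) {
    skip <- skips[[l]]
    cin <- dim(h)[4]
    csk <- dim(skip)[4]
    hc <- array(0, c(dim(h)[1:3], cin + csk))
    hc[, , , seq_len(cin)] <- h
    hc[, , , cin + seq_len(csk)] <- skip * skip_scale
    h <- hc
    bc <- vector("list", nb)
    for (i in seq_len(nb)) {
      bc[[i]] <- resblock_fwd(h, temb, params$up[[l]]$blocks[[i]])
      h <- bc[[i]]$y
    }
    ac <- NULL
    if (!is.null(params$up[[l]]$attn)) {
      ac <- attn_fwd(h, params$up[[l]]$attn, spec$num_heads)
      h <- ac$y
    }
    uc <- NULL
    if (!is.null(params$up[[l]]$upsample)) {
      uc <- tconv2_fwd(h, params$up[[l]]$upsample)
      h <- uc$y
    }
    up[[l]] <- list(split = cin, blocks = bc, attn = ac, up = uc)
  }
  og <- gn_fwd(h, params$out$gn, gn_groups(dim(h)[4]))
  os <- silu_fwd(og$y)
  oc <- conv3_fwd(os$y, params$out$conv)
  list(y = oc$y,
       cache = list(tl1 = tl1, tsl = tsl, tl2 = tl2, stem = stem,
                    down = down, mid = list(m1 = m1, ma = ma, m2 = m2),
                    up = up, og = og, os = os, oc = oc))
}

unet_bwd <- function(spec, params, cache, dy) {
  L <- length(spec$channel_multipliers)
  nb <- spec$blocks_per_stage
  g <- list()
  dtemb <- 0 # accumulated over every residual block
  b_oc <- conv3_bwd(dy, params$out$conv, cache$oc)
  d_os <- silu_bwd(b_oc$gx, cache$os)
  b_og <- gn_bwd(d_os, params$out$gn, cache$og)
  g$out <- list(gn = list(g = b_og$gg, b = b_og$gb),
                conv = list(w = b_oc$gw, b = b_oc$gb))
  dh <- b_og$gx
  g$up <- vector("list", L)
  dskips <- vector("list", L)
  for (l in seq_len(L)) { # reverse of the decoder's L..1 order
    uc <- cache$up[[l]]
    gu <- list()
    if (!is.null(uc$up)) {
      bu <- tconv2_bwd(dh, params$up[[l]]$upsample, uc$up)
      gu$upsample <- list(w = bu$gw, b = bu$gb)
      dh <- bu$gx
    }
    if (!is.null(uc$attn)) {
      ba <- attn_bwd(dh, params$up[[l]]$attn, uc$attn)
      gu$attn <- ba$grads
      dh <- ba$gx
    }
    gb <- vector("list", nb)
    for (i in rev(seq_len(nb))) {
      bb <- resblock_bwd(dh, params$up[[l]]$blocks[[i]], uc$blocks[[i]])
      gb[[i]] <- bb$grads
      dtemb <- dtemb + bb$dtemb
      dh <- bb$gx
    }
    gu$blocks <- gb
    cin <- uc$split
    csk <- dim(dh)[4] - cin
    dskips[[l]] <- dh[, , , cin + seq_len(csk), drop = FALSE]
    dh <- dh[, , , seq_len(cin), drop = FALSE]
    g$up[[l]] <- gu
  }
  bm2 <- resblock_bwd(dh, params$mid$block2, cache$mid$m2)
  dtemb <- dtemb + bm2$dtemb
  bma <- attn_bwd(bm2$gx, params$mid$attn, cache$mid$ma)
  bm1 <- resblock_bwd(bma$gx, params$mid$block1, cache$mid$m1)
  dtemb <- dtemb + bm1$dtemb
  g$mid <- list(block1 = bm1$grads, attn = bma$grads, block2 = bm2$grads)
  dh <- bm1$gx
  g$down <- vector("list", L)
  for (l in rev(seq_len(L))) {
    dc <- cache$down[[l]]
    gd <- list()
    if (!is.null(dc$down)) {
      bd <- conv3_bwd(dh, params$down[[l]]$downsample, dc$down)
      gd$downsample <- list(w = bd$gw, b = bd$gb)
      dh <- bd$gx
    } else {
      gd$downsample <- NULL
    }
    dh <- dh + dskips[[l]] # skip connection joins here
    if (!is.null(dc$attn)) {
      ba <- attn_bwd(dh, params$down[[l]]$attn, dc$attn)
      gd$attn <- ba$grads
      dh <- ba$gx
    }
    gb <- vector("list", nb)
    for (i in rev(seq_len(nb))) {
      bb <- resblock_bwd(dh, params$down[[l]]$blocks[[i]], dc$blocks[[i]])
      gb[[i]] <- bb$grads
      dtemb <- dtemb + bb$dtemb
      dh <- bb$gx
    }
    gd$blocks <- gb
    g$down[[l]] <- gd
  }
  bst <- conv3_bwd(dh, params$stem, cache$stem)
  g$stem <- list(w = bst$gw, b = bst$gb)
  btl2 <- linear_bwd(dtemb, params$time_mlp$l2, cache$tl2)
  dts <- silu_bwd(btl2$gx, cache$tsl)
  btl1 <- linear_bwd(dts, params$time_mlp$l1, cache$tl1)
  g$time_mlp <- list(l1 = list(w = btl1$gw, b = btl1$gb),
                     l2 = list(w = btl2$gw, b = btl2$gb))
  g[names(params)]
}

#' Predict the noise in a corrupted batch
#'
#' Runs the U-Net forward pass. The output has exactly the input's shape
#' (the network's shape-preserving contract) and inference is deterministic.
#'
#' `denoise()` is generic so that alternative noise predictors (e.g. analytic
#' stubs in tests) can plug into the training and sampling loops.
#'
#' @param model a [build_denoiser()] model.
#' @param xt an [image_batch()] in the normalized domain,
#'   `n x 1 x size x size`.
#' @param t timestep, scalar or one per image.
#' @param ... passed to methods.
#' @return an array shaped like `xt`: the predicted noise.
#' @export
denoise <- function(model, xt, t, ...) UseMethod("denoise")

#' @rdname denoise
#' @export
denoise.denoiser_model <- function(model, xt, t, ...) {
  check_normalized(xt, "xt")
  d <- dim(xt)
  L <- length(model$spec$channel_multipliers)
  div <- 2L^(L - 1L)
  if (d[3] != d[4] || d[3] %% div != 0L) {
    stop(sprintf("spatial size must be square and divisible by %d", div),
         call. = FALSE)
  }
  tv <- as.integer(t)
  if (length(tv) == 1L) tv <- rep(tv, d[1])
  if (length(tv) != d[1] || anyNA(tv) || any(tv < 0)) {
    stop("`t` must be a scalar or one non-negative timestep per image",
         call. = FALSE)
  }
  xi <- aperm(unclass(xt), c(3, 4, 1, 2)) # (N,C,H,W) -> (H,W,N,C)
  out <- unet_fwd(model$spec, model$params, xi, tv)
  as_batch(aperm(out$y, c(3, 4, 1, 2)))
}

#' Number of trainable parameters of a model
#' @param model a `denoiser_model`.
#' @return integer count.
#' @export
n_params <- function(model) model$n_params
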