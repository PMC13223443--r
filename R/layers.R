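# Internal neural-network primitives with explicit forward/backward passes.
#
# There is no automatic differentiation here: every layer is a pair of pure
# functions, `*_fwd` returning the output plus a cache, and `*_bwd` mapping
# the output gradient and cache to input and parameter gradients. Gradient
# correctness is pinned down by finite-difference tests.
#
# Internal tensor layout is (H, W, N, C) so that
#   matrix(x, H*W*N, C)        is the "pixels x channels" view (convolutions)
#   matrix(x, H*W, N*C)        is the "pixels x (image,channel)" view
#                              (normalization, per-image time conditioning),
# both obtained without copying the data into a new order.

# ---- parameter initialisation -----------------------------------------------

init_conv <- function(cin, cout, k, scale = 1) {
  fan_in <- k * k * cin
  list(w = matrix(stats::rnorm(fan_in * cout, sd = scale * sqrt(2 / fan_in)),
                  fan_in, cout),
       b = numeric(cout))
}

init_linear <- function(din, dout, scale = 1) {
  list(w = matrix(stats::rnorm(din * dout, sd = scale * sqrt(1 / din)),
                  din, dout),
       b = numeric(dout))
}

init_gn <- function(channels) list(g = rep(1, channels), b = numeric(channels))

# transposed conv 2x2 stride 2: 4 offset blocks stored side by side
init_tconv <- function(cin, cout, scale = 1) {
  list(w = matrix(stats::rnorm(cin * 4 * cout, sd = scale * sqrt(2 / cin)),
                  cin, 4 * cout),
       b = numeric(cout))
}

# ---- 3x3 convolution, padding 1, stride 1 or 2 ------------------------------
#
# The im2col gather is driven by precomputed linear indices into the padded
# input, cached per (H, W, N, Cin, stride) shape; the backward pass
# scatter-adds through the same indices (within one kernel offset the
# indices are unique, so 9 vectorized accumulations suffice).

.conv_idx_cache <- new.env(parent = emptyenv())

conv3_indices <- function(H, W, N, Cin, stride) {
  key <- paste(H, W, N, Cin, stride, sep = "x")
  hit <- .conv_idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2L; Wp <- W + 2L
  Ho <- (H + stride - 1L) %/% stride
  Wo <- (W + stride - 1L) %/% stride
  ry <- stride * (seq_len(Ho) - 1L) # 0-based top row in padded coords
  rx <- stride * (seq_len(Wo) - 1L)
  rows <- Ho * Wo * N
  sC <- Hp * Wp * N
  base_n <- rep((0:(N - 1L)) * (Hp * Wp), each = Ho * Wo)
  chan <- rep((0:(Cin - 1L)) * sC, each = rows)
  idxk <- vector("list", 9L)
  k <- 0L
  for (kx in 0:2) for (ky in 0:2) {
    k <- k + 1L
    sp <- as.vector(outer(ry + ky, (rx + kx) * Hp, "+")) # (Ho*Wo), 0-based
    idxk[[k]] <- rep(sp, N) + base_n + chan + 1L
  }
  val <- list(rows = rows, Ho = Ho, Wo = Wo, Hp = Hp, Wp = Wp,
              idx = unlist(idxk, use.names = FALSE), idxk = idxk)
  .conv_idx_cache[[key]] <- val
  val
}

conv3_fwd <- function(x, p, stride = 1L) {
  d <- dim(x)
  y <- .conv3_gemm(x, d[1], d[2], d[3], d[4], p$w, p$b, as.integer(stride))
  list(y = y, x = x, in_dim = d, stride = stride)
}

conv3_bwd <- function(dy, p, cache) {
  d <- cache$in_dim
  .conv3_gemm_bwd(cache$x, dy, d[1], d[2], d[3], d[4], p$w,
                  as.integer(cache$stride))
}

# pure-R reference path for the compiled im2col/col2im pair, used by tests
conv3_fwd_ref <- function(x, p, stride = 1L) {
  d <- dim(x); H <- d[1]; W <- d[2]; N <- d[3]; Cin <- d[4]
  ci <- conv3_indices(H, W, N, Cin, stride)
  xp <- array(0, c(ci$Hp, ci$Wp, N, Cin))
  xp[2:(H + 1L), 2:(W + 1L), , ] <- x
  M <- xp[ci$idx]
  dim(M) <- c(ci$rows, 9L * Cin)
  y <- M %*% p$w
  y <- y + rep(p$b, each = ci$rows)
  dim(y) <- c(ci$Ho, ci$Wo, N, ncol(p$w))
  list(y = y, M = M, in_dim = d, stride = stride)
}

conv3_bwd_ref <- function(dy, p, cache) {
  d <- cache$in_dim; H <- d[1]; W <- d[2]; N <- d[3]; Cin <- d[4]
  ci <- conv3_indices(H, W, N, Cin, cache$stride)
  dym <- dy
  dim(dym) <- c(ci$rows, ncol(p$w))
  gw <- crossprod(cache$M, dym)
  gb <- colSums(dym)
  gM <- tcrossprod(dym, p$w)
  gxp <- numeric(ci$Hp * ci$Wp * N * Cin)
  for (k in 1:9) {
    ik <- ci$idxk[[k]]
    gxp[ik] <- gxp[ik] + gM[, (k - 1L) * Cin + seq_len(Cin)]
  }
  dim(gxp) <- c(ci$Hp, ci$Wp, N, Cin)
  list(gx = gxp[2:(H + 1L), 2:(W + 1L), , , drop = FALSE],
       gw = gw, gb = gb)
}

# ---- 1x1 convolution --------------------------------------------------------

conv1_fwd <- function(x, p) {
  d <- dim(x)
  xm <- matrix(x, prod(d[1:3]), d[4])
  y <- xm %*% p$w
  y <- y + rep(p$b, each = nrow(y))
  dim(y) <- c(d[1:3], ncol(p$w))
  list(y = y, xm = xm, in_dim = d)
}

conv1_bwd <- function(dy, p, cache) {
  d <- cache$in_dim
  dym <- matrix(dy, prod(d[1:3]), ncol(p$w))
  gx <- tcrossprod(dym, p$w)
  dim(gx) <- d
  list(gx = gx, gw = crossprod(cache$xm, dym), gb = colSums(dym))
}

# ---- transposed 2x2 convolution, stride 2 (upsampling) ----------------------

tconv2_fwd <- function(x, p) {
  d <- dim(x); H <- d[1]; W <- d[2]; N <- d[3]; Cin <- d[4]
  Cout <- ncol(p$w) %/% 4L
  xm <- matrix(x, H * W * N, Cin)
  y <- array(0, c(2L * H, 2L * W, N, Cout))
  k <- 0L
  for (dx in 0:1) for (dyo in 0:1) {
    blk <- xm %*% p$w[, k * Cout + seq_len(Cout), drop = FALSE]
    y[seq(1L + dyo, 2L * H, 2L), seq(1L + dx, 2L * W, 2L), , ] <-
      array(blk, c(H, W, N, Cout))
    k <- k + 1L
  }
  ym <- matrix(y, 4L * H * W * N, Cout)
  ym <- ym + rep(p$b, each = nrow(ym))
  dim(ym) <- dim(y)
  list(y = ym, xm = xm, in_dim = d)
}

tconv2_bwd <- function(dy, p, cache) {
  d <- cache$in_dim; H <- d[1]; W <- d[2]; N <- d[3]; Cin <- d[4]
  Cout <- ncol(p$w) %/% 4L
  gw <- matrix(0, Cin, 4L * Cout)
  gx <- matrix(0, H * W * N, Cin)
  k <- 0L
  for (dx in 0:1) for (dyo in 0:1) {
    blk <- matrix(dy[seq(1L + dyo, 2L * H, 2L), seq(1L + dx, 2L * W, 2L), , ,
                     drop = FALSE], H * W * N, Cout)
    gw[, k * Cout + seq_len(Cout)] <- crossprod(cache$xm, blk)
    gx <- gx + tcrossprod(blk, p$w[, k * Cout + seq_len(Cout), drop = FALSE])
    k <- k + 1L
  }
  gb <- colSums(matrix(dy, 4L * H * W * N, Cout))
  dim(gx) <- d
  list(gx = gx, gw = gw, gb = gb)
}

# ---- group normalization ----------------------------------------------------

# mean over the channel axis of an (N, C) matrix within channel groups,
# returning (N, groups)
group_reduce <- function(m, n, cpg, groups) {
  dim(m) <- c(n, cpg, groups)
  colMeans(aperm(m, c(2L, 1L, 3L)))
}

# expand an (N, groups) matrix back to a length-N*C vector (n fastest)
group_expand <- function(m, cpg, groups) {
  as.vector(m[, rep(seq_len(groups), each = cpg)])
}

gn_fwd <- function(x, p, groups, eps = 1e-5) {
  d <- dim(x)
  out <- .gn_fwd_cpp(x, d[1] * d[2], d[3], d[4], groups, p$g, p$b, eps)
  y <- out$y
  dim(y) <- d
  list(y = y, xhat = out$xhat, inv_sd = out$inv_sd, in_dim = d,
       groups = groups)
}

gn_bwd <- function(dy, p, cache) {
  d <- cache$in_dim
  out <- .gn_bwd_cpp(dy, cache$xhat, cache$inv_sd, d[1] * d[2], d[3], d[4],
                     cache$groups, p$g)
  gx <- out$gx
  dim(gx) <- d
  list(gx = gx, gg = out$gg, gb = out$gb)
}

gn_fwd_ref <- function(x, p, groups, eps = 1e-5) {
  d <- dim(x); HW <- d[1] * d[2]; N <- d[3]; C <- d[4]
  cpg <- C %/% groups
  xm <- matrix(x, HW, N * C)
  m1 <- colMeans(xm)
  m2 <- colMeans(xm * xm)
  mu <- group_reduce(m1, N, cpg, groups)           # (N, groups)
  ex2 <- group_reduce(m2, N, cpg, groups)
  inv_sd <- 1 / sqrt(pmax(ex2 - mu * mu, 0) + eps) # (N, groups)
  mu_nc <- group_expand(mu, cpg, groups)
  is_nc <- group_expand(inv_sd, cpg, groups)
  xhat <- (xm - rep(mu_nc, each = HW)) * rep(is_nc, each = HW)
  gcol <- rep(p$g, each = N)
  bcol <- rep(p$b, each = N)
  y <- xhat * rep(gcol, each = HW) + rep(bcol, each = HW)
  dim(y) <- d
  list(y = y, xhat = xhat, inv_sd_nc = is_nc, in_dim = d, groups = groups)
}

gn_bwd_ref <- function(dy, p, cache) {
  d <- cache$in_dim; HW <- d[1] * d[2]; N <- d[3]; C <- d[4]
  groups <- cache$groups
  cpg <- C %/% groups
  dym <- matrix(dy, HW, N * C)
  xhat <- cache$xhat
  s_gx <- colSums(dym * xhat)                       # per (n, c)
  s_dy <- colSums(dym)
  gg <- colSums(matrix(s_gx, N, C))
  gb <- colSums(matrix(s_dy, N, C))
  gcol <- rep(p$g, each = N)
  dxhat <- dym * rep(gcol, each = HW)
  md <- group_reduce(colMeans(dxhat), N, cpg, groups)         # mean(dxhat)
  mdx <- group_reduce(colMeans(dxhat * xhat), N, cpg, groups) # mean(dxhat*xhat)
  md_nc <- group_expand(md, cpg, groups)
  mdx_nc <- group_expand(mdx, cpg, groups)
  gx <- (dxhat - rep(md_nc, each = HW) - xhat * rep(mdx_nc, each = HW)) *
    rep(cache$inv_sd_nc, each = HW)
  dim(gx) <- d
  list(gx = gx, gg = gg, gb = gb)
}

# ---- SiLU activation --------------------------------------------------------

silu_fwd <- function(x) {
  s <- 1 / (1 + exp(-x))
  y <- x * s
  list(y = y, x = x, s = s)
}

silu_bwd <- function(dy, cache) {
  dy * (cache$s * (1 + cache$x * (1 - cache$s)))
}

# ---- linear layer (time embedding MLP, per-block time projections) ----------

linear_fwd <- function(x, p) {
  y <- x %*% p$w
  y <- y + rep(p$b, each = nrow(y))
  list(y = y, x = x)
}

linear_bwd <- function(dy, p, cache) {
  list(gx = tcrossprod(dy, p$w), gw = crossprod(cache$x, dy),
       gb = colSums(dy))
}

# ---- multi-head self-attention over spatial positions -----------------------
#
# Pre-norm residual attention: y = x + proj(attend(groupnorm(x))).
# Q, K, V and the output projection are 1x1 convolutions; softmax attention
# runs per image and per head on (HW x HW) score matrices.

attn_fwd <- function(x, p, num_heads) {
  d <- dim(x); HW <- d[1] * d[2]; N <- d[3]; C <- d[4]
  dh <- C %/% num_heads
  gn <- gn_fwd(x, p$gn, gn_groups(C))
  q <- conv1_fwd(gn$y, p$q); k <- conv1_fwd(gn$y, p$k)
  v <- conv1_fwd(gn$y, p$v)
  qm <- matrix(q$y, HW * N, C); km <- matrix(k$y, HW * N, C)
  vm <- matrix(v$y, HW * N, C)
  om <- matrix(0, HW * N, C)
  P <- array(0, c(HW, HW, num_heads, N))
  sc <- 1 / sqrt(dh)
  for (n in seq_len(N)) {
    rows <- (n - 1L) * HW + seq_len(HW)
    for (h in seq_len(num_heads)) {
      cols <- (h - 1L) * dh + seq_len(dh)
      A <- tcrossprod(qm[rows, cols, drop = FALSE],
                      km[rows, cols, drop = FALSE]) * sc
      A <- exp(A - apply(A, 1L, max))
      Pn <- A / rowSums(A)
      P[, , h, n] <- Pn
      om[rows, cols] <- Pn %*% vm[rows, cols, drop = FALSE]
    }
  }
  oarr <- om; dim(oarr) <- d
  proj <- conv1_fwd(oarr, p$o)
  list(y = x + proj$y, gn = gn, q = q, k = k, v = v, proj = proj,
       qm = qm, km = km, vm = vm, om = om, P = P, in_dim = d,
       num_heads = num_heads)
}

attn_bwd <- function(dy, p, cache) {
  d <- cache$in_dim; HW <- d[1] * d[2]; N <- d[3]; C <- d[4]
  nh <- cache$num_heads
  dh <- C %/% nh
  sc <- 1 / sqrt(dh)
  bp <- conv1_bwd(dy, p$o, cache$proj)
  dom <- matrix(bp$gx, HW * N, C)
  dqm <- matrix(0, HW * N, C); dkm <- matrix(0, HW * N, C)
  dvm <- matrix(0, HW * N, C)
  for (n in seq_len(N)) {
    rows <- (n - 1L) * HW + seq_len(HW)
    for (h in seq_len(nh)) {
      cols <- (h - 1L) * dh + seq_len(dh)
      Pn <- cache$P[, , h, n]
      dO <- dom[rows, cols, drop = FALSE]
      Vn <- cache$vm[rows, cols, drop = FALSE]
      dP <- tcrossprod(dO, Vn)
      dvm[rows, cols] <- crossprod(Pn, dO)
      dA <- Pn * (dP - rowSums(dP * Pn))
      dqm[rows, cols] <- (dA %*% cache$km[rows, cols, drop = FALSE]) * sc
      dkm[rows, cols] <- (crossprod(dA, cache$qm[rows, cols, drop = FALSE])) *
        sc
    }
  }
  dim(dqm) <- d; dim(dkm) <- d; dim(dvm) <- d
  bq <- conv1_bwd(dqm, p$q, cache$q)
  bk <- conv1_bwd(dkm, p$k, cache$k)
  bv <- conv1_bwd(dvm, p$v, cache$v)
  bg <- gn_bwd(bq$gx + bk$gx + bv$gx, p$gn, cache$gn)
  list(gx = dy + bg$gx,
       grads = list(gn = list(g = bg$gg, b = bg$gb),
                    q = list(w = bq$gw, b = bq$gb),
                    k = list(w = bk$gw, b = bk$gb),
                    v = list(w = bv$gw, b = bv$gb),
                    o = list(w = bp$gw, b = bp$gb)))
}

init_attn <- function(channels) {
  list(gn = init_gn(channels),
       q = init_conv(channels, channels, 1L),
       k = init_conv(channels, channels, 1L),
       v = init_conv(channels, channels, 1L),
       o = init_conv(channels, channels, 1L, scale = 0.2))
}

# ---- residual block with time conditioning ----------------------------------
#
#   h = conv3(silu(gn1(x))); h = h + linear(silu(temb)) per (image, channel)
#   h = conv3(silu(gn2(h))); y = h + shortcut(x)

init_resblock <- function(cin, cout, time_dim) {
  list(gn1 = init_gn(cin),
       conv1 = init_conv(cin, cout, 3L),
       temb = init_linear(time_dim, cout),
       gn2 = init_gn(cout),
       conv2 = init_conv(cout, cout, 3L),
       shortcut = if (cin != cout) init_conv(cin, cout, 1L) else NULL)
}

resblock_fwd <- function(x, temb, p) {
  d <- dim(x)
  cin <- d[4]
  g1 <- gn_fwd(x, p$gn1, gn_groups(cin))
  s1 <- silu_fwd(g1$y)
  c1 <- conv3_fwd(s1$y, p$conv1)
  st <- silu_fwd(temb)
  tp <- linear_fwd(st$y, p$temb)        # (N, cout)
  HW <- d[1] * d[2]
  h <- c1$y
  dim(h) <- c(HW, d[3] * ncol(p$temb$w))
  h <- h + rep(as.vector(tp$y), each = HW)
  dim(h) <- dim(c1$y)
  g2 <- gn_fwd(h, p$gn2, gn_groups(dim(h)[4]))
  s2 <- silu_fwd(g2$y)
  c2 <- conv3_fwd(s2$y, p$conv2)
  if (is.null(p$shortcut)) {
    y <- c2$y + x
    sh <- NULL
  } else {
    sh <- conv1_fwd(x, p$shortcut)
    y <- c2$y + sh$y
  }
  list(y = y, g1 = g1, s1 = s1, c1 = c1, st = st, tp = tp, g2 = g2,
       s2 = s2, c2 = c2, sh = sh, in_dim = d)
}

resblock_bwd <- function(dy, p, cache) {
  d <- cache$in_dim
  HW <- d[1] * d[2]
  b2 <- conv3_bwd(dy, p$conv2, cache$c2)
  ds2 <- silu_bwd(b2$gx, cache$s2)
  bg2 <- gn_bwd(ds2, p$gn2, cache$g2)
  dh <- bg2$gx
  # time-projection gradient: sum the per-pixel gradients per (image, channel)
  cout <- ncol(p$temb$w)
  dtp <- matrix(colSums(matrix(dh, HW, d[3] * cout)), d[3], cout)
  bt <- linear_bwd(dtp, p$temb, cache$tp)
  dtemb <- silu_bwd(bt$gx, cache$st)
  b1 <- conv3_bwd(dh, p$conv1, cache$c1)
  ds1 <- silu_bwd(b1$gx, cache$s1)
  bg1 <- gn_bwd(ds1, p$gn1, cache$g1)
  if (is.null(p$shortcut)) {
    gx <- bg1$gx + dy
    gsh <- NULL
  } else {
    bsh <- conv1_bwd(dy, p$shortcut, cache$sh)
    gx <- bg1$gx + bsh$gx
    gsh <- list(w = bsh$gw, b = bsh$gb)
  }
  list(gx = gx, dtemb = dtemb,
       grads = list(gn1 = list(g = bg1$gg, b = bg1$gb),
                    conv1 = list(w = b1$gw, b = b1$gb),
                    temb = list(w = bt$gw, b = bt$gb),
                    gn2 = list(g = bg2$gg, b = bg2$gb),
                    conv2 = list(w = b2$gw, b = b2$gb),
                    shortcut = gsh))
}

# ---- parameter-tree utilities -----------------------------------------------

# apply f(leaf_a, leaf_b) over two parallel nested lists of numerics;
# subtrees of `b` are matched to `a` by name where names exist (the backward
# pass assembles its gradient tree in reverse order)
tree_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    nms <- names(a)
    for (i in seq_along(a)) {
      if (is.null(a[[i]])) next
      bi <- if (!is.null(nms) && nzchar(nms[i])) b[[nms[i]]] else b[[i]]
      out[[i]] <- tree_map2(a[[i]], bi, f)
    }
    out
  } else {
    f(a, b)
  }
}

tree_leaves <- function(a) {
  if (is.list(a)) unlist(lapply(a, tree_leaves), use.names = FALSE)
  else as.vector(a)
}

count_params <- function(a) length(tree_leaves(a))
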