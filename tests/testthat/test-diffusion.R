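s300 <- make_linear_schedule(300)

rand_batch <- function(n, size = 8, seed = 1, lim = 1) {
  minidiffusion:::with_seed(seed, {
    image_batch(array(stats::runif(n * size * size, -lim, lim),
                      c(n, 1, size, size)))
  })
}

test_that("q_sample reduces to pure signal decay with zero noise", {
  x0 <- rand_batch(3)
  z <- array(0, dim(x0))
  for (t in c(1, 150, 300)) {
    k <- schedule_constants_at(s300, t)
    xt <- q_sample(x0, t, z, s300)
    expect_equal(unclass(xt), unclass(x0) * k$sqrt_alpha_bar,
                 tolerance = 1e-14)
  }
})

test_that("the first corruption step is a near-identity", {
  x0 <- rand_batch(2)
  eps <- minidiffusion:::with_seed(2, array(rnorm(length(x0)), dim(x0)))
  xt <- q_sample(x0, 1, eps, s300)
  expect_true(max(abs(unclass(xt) - unclass(x0))) <=
                sqrt(s300$betas[1]) * max(abs(eps)) + 1e-4)
})

test_that("predict_x0 inverts q_sample across every timestep", {
  # one image per timestep, each corrupted at its own t
  x0 <- rand_batch(300, size = 4, seed = 3)
  eps <- minidiffusion:::with_seed(4, array(rnorm(length(x0)), dim(x0)))
  tv <- 1:300
  xhat <- predict_x0(q_sample(x0, tv, eps, s300), tv, eps, s300)
  expect_lt(max(abs(unclass(xhat) - unclass(x0))), 1e-5)
})

test_that("predict_x0 with a zero estimate rescales the input", {
  xt <- rand_batch(2)
  k <- schedule_constants_at(s300, 100)
  out <- predict_x0(xt, 100, array(0, dim(xt)), s300)
  expect_equal(unclass(out), unclass(xt) / k$sqrt_alpha_bar,
               tolerance = 1e-12)
})

test_that("diffusion ops match an independently coded transcription", {
  # second route: explicit per-element formulas from the schedule constants
  x <- rand_batch(5, seed = 5)
  e <- minidiffusion:::with_seed(6, array(rnorm(length(x)), dim(x)))
  z <- minidiffusion:::with_seed(7, array(rnorm(length(x)), dim(x)))
  tv <- c(1L, 2L, 57L, 150L, 300L)
  for (i in seq_along(tv)) {
    t <- tv[i]
    ab <- prod(1 - s300$betas[1:t])
    xi <- unclass(x)[i, , , , drop = FALSE]
    ei <- unclass(e)[i, , , , drop = FALSE]
    zi <- unclass(z)[i, , , , drop = FALSE]
    manual_q <- sqrt(ab) * xi + sqrt(1 - ab) * ei
    got_q <- unclass(q_sample(x, tv, e, s300))[i, , , , drop = FALSE]
    expect_equal(got_q, manual_q, tolerance = 1e-12)
    manual_p <- (manual_q - s300$betas[t] / sqrt(1 - ab) * ei) /
      sqrt(1 - s300$betas[t]) +
      (if (t == 1L) 0 else sqrt(s300$betas[t])) * zi
    got_p <- unclass(p_sample_step(q_sample(x, tv, e, s300), tv, e, z,
                                   s300))[i, , , , drop = FALSE]
    expect_equal(got_p, manual_p, tolerance = 1e-12)
  }
})

test_that("the reverse update fixes the all-zeros state", {
  z4 <- array(0, c(2, 1, 4, 4))
  out <- p_sample_step(image_batch(z4), 10, z4, z4, s300)
  expect_equal(unclass(out), z4, ignore_attr = TRUE)
})

test_that("forward marginals have the scheduled moments", {
  # Monte-Carlo check of Var[x_t] = (1 - alpha_bar_t) for x0 = 0
  n <- 4000
  x0 <- image_batch(array(0, c(n, 1, 2, 2)))
  for (t in c(5L, 200L)) {
    eps <- minidiffusion:::with_seed(100 + t,
                                     array(rnorm(length(x0)), dim(x0)))
    xt <- unclass(q_sample(x0, t, eps, s300))
    v_target <- 1 - s300$alpha_bars[t]
    se <- v_target * sqrt(2 / (n - 1))
    v_pix <- apply(xt, c(3, 4), stats::var)
    expect_true(all(abs(v_pix - v_target) < 3 * se))
  }
})

test_that("diffusion ops reject bad domains and shapes", {
  u8 <- image_batch(array(1L, c(1, 1, 4, 4)), "uint8")
  z <- array(0, c(1, 1, 4, 4))
  expect_error(q_sample(u8, 1, z, s300), "normalize_images")
  expect_error(q_sample(image_batch(z), 1, array(0, c(1, 1, 2, 2)), s300),
               "identical shapes")
  expect_error(q_sample(image_batch(z), 301, z, s300), "1\\.\\.300")
  expect_error(q_sample(image_batch(z), c(1, 2), z, s300),
               "one timestep per image")
})

test_that("noise-prediction losses evaluate their closed forms", {
  d <- c(1, 1, 2, 2)
  expect_identical(noise_prediction_loss(array(0.3, d), array(0.3, d),
                                         "l1"), 0)
  expect_identical(noise_prediction_loss(array(0.3, d), array(0.3, d),
                                         "l2"), 0)
  expect_identical(noise_prediction_loss(array(0.3, d), array(0.3, d),
                                         "huber"), 0)
  r <- array(0.5, d)
  z <- array(0, d)
  expect_equal(noise_prediction_loss(r, z, "huber", 1), 0.125)
  expect_equal(noise_prediction_loss(array(2, d), z, "huber", 1), 1.5)
  expect_equal(noise_prediction_loss(r, z, "l1"), 0.5)
  expect_equal(noise_prediction_loss(r, z, "l2"), 0.25)
  expect_error(noise_prediction_loss(r, z, "l3"))
  expect_error(noise_prediction_loss(r, array(0, c(1, 1, 1, 4)), "l2"),
               "identical shapes")
  expect_error(noise_prediction_loss(r, z, "huber", delta = 0), "positive")
})

test_that("loss ordering and the delta -> Inf Huber limit hold", {
  set.seed(11)
  for (rep in 1:5) {
    r <- array(rnorm(256, sd = 2), c(4, 1, 8, 8))
    z <- array(0, dim(r))
    h <- noise_prediction_loss(r, z, "huber", 1)
    l1 <- noise_prediction_loss(r, z, "l1")
    l2 <- noise_prediction_loss(r, z, "l2")
    expect_gte(h, 0)
    expect_lte(h, l2 / 2 + 1e-12)
    expect_lte(h, 1 * l1 + 1e-12)
    # elementwise brute-force evaluation as the second route
    manual <- mean(ifelse(abs(r) <= 1, r^2 / 2, abs(r) - 0.5))
    expect_equal(h, manual, tolerance = 1e-12)
  }
  small <- array(runif(64, -0.3, 0.3), c(1, 1, 8, 8))
  expect_equal(noise_prediction_loss(small, array(0, dim(small)), "huber", 1),
               noise_prediction_loss(small, array(0, dim(small)), "l2") / 2,
               tolerance = 1e-12)
})

test_that("the Huber loss is continuous at the branch point", {
  d <- c(1, 1, 1, 1)
  eps <- 1e-9
  below <- noise_prediction_loss(array(1 - eps, d), array(0, d), "huber", 1)
  above <- noise_prediction_loss(array(1 + eps, d), array(0, d), "huber", 1)
  expect_equal(below, above, tolerance = 1e-8)
  expect_equal(noise_prediction_loss(array(1, d), array(0, d), "huber", 1),
               0.5, tolerance = 1e-12)
})

test_that("loss gradients match finite differences", {
  set.seed(12)
  r <- array(rnorm(16), c(1, 1, 4, 4))
  z <- array(0, dim(r))
  h <- 1e-6
  for (kind in c("l2", "huber")) {
    g <- minidiffusion:::loss_gradient(r, z, kind, 1)
    for (idx in c(1L, 7L, 16L)) {
      rp <- r; rp[idx] <- rp[idx] + h
      rm <- r; rm[idx] <- rm[idx] - h
      fd <- (noise_prediction_loss(rp, z, kind, 1) -
               noise_prediction_loss(rm, z, kind, 1)) / (2 * h)
      expect_equal(g[idx], fd, tolerance = 1e-5)
    }
  }
})
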