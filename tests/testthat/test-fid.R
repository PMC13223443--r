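test_that("Gaussian summaries match closed forms and a brute-force oracle", {
  same <- matrix(rep(c(1, 2, 3), 4), 4, 3, byrow = TRUE)
  expect_equal(summarize_features(same)$sigma, matrix(0, 3, 3))
  two <- summarize_features(rbind(c(0, 0), c(2, 2)))
  expect_equal(two$mu, c(1, 1))
  expect_equal(two$sigma, matrix(2, 2, 2))
  set.seed(31)
  f <- matrix(rnorm(500), 100, 5)
  got <- summarize_features(f)
  # naive double loop covariance with the n-1 denominator
  mu <- colMeans(f)
  ref <- matrix(0, 5, 5)
  for (i in 1:5) {
    for (j in 1:5) {
      ref[i, j] <- sum((f[, i] - mu[i]) * (f[, j] - mu[j])) / 99
    }
  }
  expect_lt(max(abs(got$sigma - ref)), 1e-10)
  expect_error(summarize_features(matrix(1, 1, 3)), "at least 2")
})

test_that("the Frechet distance matches its univariate closed form", {
  mk <- function(mu, var) {
    structure(list(mu = mu, sigma = matrix(var, 1, 1), n = 10),
              class = "gaussian_summary")
  }
  expect_equal(frechet_distance(mk(0, 1), mk(1, 1)), 1.0,
               tolerance = 1e-10)
  set.seed(32)
  for (i in 1:10) {
    m1 <- rnorm(1); m2 <- rnorm(1)
    v1 <- runif(1, 0.1, 3); v2 <- runif(1, 0.1, 3)
    expect_equal(frechet_distance(mk(m1, v1), mk(m2, v2)),
                 (m1 - m2)^2 + (sqrt(v1) - sqrt(v2))^2, tolerance = 1e-10)
  }
})

test_that("commuting covariance pairs match the eigendecomposition oracle", {
  set.seed(33)
  for (i in 1:5) {
    d <- 6
    q <- qr.Q(qr(matrix(rnorm(d * d), d)))
    ev_a <- runif(d, 0.2, 3)
    ev_b <- runif(d, 0.2, 3)
    a <- structure(list(mu = rnorm(d), sigma = q %*% (ev_a * t(q)), n = 50),
                   class = "gaussian_summary")
    b <- structure(list(mu = rnorm(d), sigma = q %*% (ev_b * t(q)), n = 50),
                   class = "gaussian_summary")
    a$sigma <- (a$sigma + t(a$sigma)) / 2
    b$sigma <- (b$sigma + t(b$sigma)) / 2
    oracle <- sum((a$mu - b$mu)^2) + sum((sqrt(ev_a) - sqrt(ev_b))^2)
    got <- frechet_distance(a, b)
    expect_equal(got, oracle, tolerance = 1e-8)
    # symmetry
    expect_equal(got, frechet_distance(b, a), tolerance = 1e-8)
  }
})

test_that("the Frechet distance agrees with a direct matrix square root", {
  # independent route: principal sqrt of the non-symmetric product
  set.seed(34)
  d <- 5
  ra <- matrix(rnorm(40 * d), 40, d)
  rb <- matrix(rnorm(40 * d), 40, d) %*% diag(seq(0.5, 1.5, length.out = d))
  a <- summarize_features(ra)
  b <- summarize_features(rb)
  got <- frechet_distance(a, b)
  sq <- pracma::sqrtm(a$sigma %*% b$sigma)$B
  ref <- sum((a$mu - b$mu)^2) +
    sum(diag(a$sigma + b$sigma - 2 * Re(sq)))
  expect_equal(got, ref, tolerance = 1e-6)
})

test_that("distance properties: identity, symmetry, scale coherence", {
  set.seed(35)
  f1 <- matrix(rnorm(200), 50, 4)
  f2 <- matrix(rnorm(200, sd = 1.3), 50, 4) + 0.5
  a <- summarize_features(f1)
  b <- summarize_features(f2)
  expect_equal(frechet_distance(a, a), 0, tolerance = 1e-10)
  expect_equal(frechet_distance(a, b), frechet_distance(b, a),
               tolerance = 1e-8)
  for (cc in c(2, 5)) {
    ac <- summarize_features(f1 * cc)
    bc <- summarize_features(f2 * cc)
    expect_equal(frechet_distance(ac, bc), cc^2 * frechet_distance(a, b),
                 tolerance = 1e-6)
  }
  bad <- summarize_features(matrix(rnorm(30), 10, 3))
  expect_error(frechet_distance(a, bad), "dimension mismatch")
})

test_that("the projection extractor is deterministic with orthogonal maps", {
  ph <- fixture_phantoms(16)
  for (d in c(64L, 2048L)) {
    ex <- projection_pool_extractor(d)
    f1 <- ex$transform(ph)
    f2 <- projection_pool_extractor(d)$transform(ph)
    expect_identical(dim(f1), c(16L, d))
    expect_identical(f1, f2)
  }
  # isometry: orthonormal rows/columns preserve distances (dim >= pixels);
  # the extractor works on the canonical [0, 1] pixel scale
  ex <- projection_pool_extractor(2048L)
  f <- ex$transform(ph)
  x <- matrix(aperm(unclass(ph) / 255, c(2, 3, 4, 1)), 784, 16)
  d_pix <- sum((x[, 1] - x[, 2])^2)
  d_feat <- sum((f[1, ] - f[2, ])^2)
  expect_equal(d_feat, d_pix, tolerance = 1e-8)
})

test_that("fid is ~0 on identical sets and detects mean shifts exactly", {
  ph <- fixture_phantoms(64)
  ex <- projection_pool_extractor(64)
  expect_lt(suppressMessages(fid(ph, ph, ex)), 1e-3)
  # shifting every feature by v moves the distance by ||v||^2
  v <- rep(2, 64)
  shifted <- structure(list(
    name = "shifted", dim = 64L,
    transform = function(b) sweep(ex$transform(b), 2, v, "+")),
    class = "feature_extractor")
  got <- suppressMessages(fid(ph, ph, ex))
  got_shift <- suppressMessages({
    a <- summarize_features(ex$transform(ph))
    b <- summarize_features(shifted$transform(ph))
    frechet_distance(a, b)
  })
  expect_equal(got_shift, sum(v^2), tolerance = 1e-6)
  expect_lt(got, got_shift)
})

test_that("fid separates phantoms from pure noise at both dimensions", {
  ph <- fixture_phantoms(48)
  noise <- minidiffusion:::with_seed(36, image_batch(
    array(sample(0:255, 48 * 784, replace = TRUE), c(48, 1, 28, 28)),
    "uint8"))
  for (d in c(64L, 2048L)) {
    val <- suppressMessages(fid(ph, noise, projection_pool_extractor(d)))
    expect_gt(val, 1)
  }
})

test_that("fid validates its inputs", {
  ph <- fixture_phantoms(4)
  one <- minidiffusion:::as_batch(unclass(ph)[1, , , , drop = FALSE],
                                  "uint8")
  expect_error(suppressMessages(fid(one, ph)), "at least 2")
  norm <- normalize_images(ph)
  expect_error(suppressMessages(fid(ph, norm)), "pixel domain")
})

test_that("fid_table mirrors the loss-by-dimension layout", {
  ph <- fixture_phantoms(24)
  gen <- list(l1 = fixture_phantoms(24, seed = 8),
              l2 = fixture_phantoms(24, seed = 9),
              huber = fixture_phantoms(24, seed = 10))
  exs <- list(projection_pool_extractor(16), projection_pool_extractor(8))
  tab <- fid_table(ph, gen, extractors = exs)
  expect_identical(names(tab), c("loss", "16", "8"))
  expect_identical(tab$loss, c("l1", "l2", "huber"))
  expect_true(all(as.matrix(tab[, -1]) >= 0))
  # identical sets in every cell give ~0 everywhere
  same <- fid_table(ph, list(a = ph, b = ph), extractors = exs)
  expect_true(all(as.matrix(same[, -1]) < 1e-3))
  # values do not depend on evaluation order
  tab_perm <- fid_table(ph, gen[c(3, 1, 2)], extractors = exs[c(2, 1)])
  for (l in tab$loss) {
    expect_equal(tab_perm[tab_perm$loss == l, "8"],
                 tab[tab$loss == l, "8"], tolerance = 1e-12)
  }
  # CSV serialization
  csv <- tempfile(fileext = ".csv")
  fid_table(ph, gen["l1"], extractors = exs, path = csv)
  expect_identical(names(utils::read.csv(csv, check.names = FALSE)),
                   c("loss", "16", "8"))
})
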