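# Frechet-distance generation-quality evaluation.
#
# The distance between two image sets is computed on Gaussian fits of
# feature embeddings: d^2 = ||mu_a - mu_b||^2 + Tr(Sa + Sb - 2 (Sa Sb)^1/2).
# The trace of the matrix square root is evaluated through the algebraically
# identical symmetric form Tr((Sa^1/2 Sb Sa^1/2)^1/2) using symmetric
# eigendecompositions, with a small diagonal jitter retry if the
# decomposition fails; tiny negative eigenvalues and results are clipped to
# zero and logged.

#' Fit a Gaussian summary to a feature matrix
#'
#' @param features numeric `n x d` matrix, one row per image.
#' @return a `gaussian_summary`: list with `mu` (column means), `sigma`
#'   (sample covariance, `n - 1` denominator, symmetrized) and `n`.
#' @export
#' @examples
#' summarize_features(rbind(c(0, 0), c(2, 2)))$sigma  # all entries 2
summarize_features <- function(features) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < 2L) {
    stop("at least 2 feature rows are required to fit a covariance",
         call. = FALSE)
  }
  sigma <- stats::cov(features)
  structure(list(mu = colMeans(features), sigma = (sigma + t(sigma)) / 2,
                 n = n),
            class = "gaussian_summary")
}

# Tr((Sa Sb)^1/2) for symmetric PSD Sa, Sb via the symmetric product form
trace_sqrt_product <- function(sa, sb, jitter = 1e-6) {
  attempt <- function(sa, sb) {
    ea <- eigen(sa, symmetric = TRUE)
    neg <- ea$values < 0
    if (any(ea$values < -1e-8 * max(abs(ea$values), 1))) {
      log_info("frechet_distance", clipped_eigenvalue = min(ea$values))
    }
    va <- sqrt(pmax(ea$values, 0))
    root_a <- ea$vectors %*% (va * t(ea$vectors))
    m <- root_a %*% sb %*% root_a
    m <- (m + t(m)) / 2
    ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
    sum(sqrt(pmax(ev, 0)))
  }
  out <- tryCatch(attempt(sa, sb), error = function(e) e)
  if (inherits(out, "error")) {
    log_info("frechet_distance", retry_jitter = jitter)
    d <- nrow(sa)
    out <- tryCatch(attempt(sa + jitter * diag(d), sb + jitter * diag(d)),
                    error = function(e) {
                      stop(sprintf(
                        "matrix square root failed after jitter retry: %s",
                        conditionMessage(e)), call. = FALSE)
                    })
  }
  out
}

#' Frechet distance between two Gaussian summaries
#'
#' @param a,b [summarize_features()] objects of equal dimension.
#' @return a non-negative scalar; exact zero for identical summaries.
#' @export
frechet_distance <- function(a, b) {
  stopifnot(inherits(a, "gaussian_summary"), inherits(b, "gaussian_summary"))
  if (length(a$mu) != length(b$mu)) {
    stop(sprintf("dimension mismatch: %d vs %d features",
                 length(a$mu), length(b$mu)), call. = FALSE)
  }
  dmu <- a$mu - b$mu
  val <- sum(dmu * dmu) + sum(diag(a$sigma)) + sum(diag(b$sigma)) -
    2 * trace_sqrt_product(a$sigma, b$sigma)
  if (val < 0) {
    if (val < -1e-6) log_info("frechet_distance", clipped_negative = val)
    val <- 0
  }
  val
}

#' Deterministic projection feature extractor
#'
#' The built-in, download-free extractor: images are flattened and mapped
#' through a fixed-seed random orthogonal projection (orthonormal rows when
#' `dim` is below the pixel count, orthonormal columns — an isometric
#' embedding — when above, as for `dim = 2048` on 28x28 images). The
#' projection is rebuilt deterministically from the seed for each input
#' pixel count, so identical inputs always give identical features on any
#' platform. Pixels are mapped to the canonical `[0, 1]` scale before
#' projection, so feature magnitudes are independent of the storage
#' domain.
#'
#' The conventional FID dimensions 64 and 2048 correspond to the pooling
#' widths of Inception-v3 evaluators; this extractor reproduces the protocol
#' shape (a d-dimensional embedding per image) with no network weights.
#'
#' @param dim feature dimension (e.g. 64 or 2048).
#' @param seed projection seed. Fixed default; change it only to study
#'   extractor sensitivity.
#' @return a `feature_extractor`: list with `name`, `dim` and `transform`
#'   (a function from an [image_batch()] to an `n x dim` matrix).
#' @export
#' @examples
#' ex <- projection_pool_extractor(64)
#' f <- ex$transform(generate_phantoms(phantom_params(8, seed = 1)))
#' dim(f)  # 8 x 64
projection_pool_extractor <- function(dim, seed = 8191L) {
  stopifnot(is.numeric(dim), length(dim) == 1L, dim >= 1)
  dim <- as.integer(dim)
  proj_cache <- new.env(parent = emptyenv())
  projection_for <- function(p) {
    key <- as.character(p)
    if (is.null(proj_cache[[key]])) {
      proj_cache[[key]] <- with_seed(
        derive_seed(seed, paste0("projection-", dim, "-", p)), {
          if (dim <= p) {
            g <- matrix(stats::rnorm(p * dim), p, dim)
            qr.Q(qr(g))            # p x dim, orthonormal columns
          } else {
            g <- matrix(stats::rnorm(dim * p), dim, p)
            t(qr.Q(qr(g)))         # p x dim, orthonormal rows
          }
        })
    }
    proj_cache[[key]]
  }
  transform <- function(batch) {
    x <- unclass(batch)
    stopifnot(length(base::dim(x)) == 4L)
    # canonical [0, 1] pixel scale, so feature (and FID) magnitudes do not
    # depend on which storage domain the batches arrive in
    dom <- attr(batch, "domain")
    if (identical(dom, "uint8")) {
      x <- x / 255
    } else if (identical(dom, "normalized")) {
      x <- (x + 1) / 2
    }
    n <- base::dim(x)[1]
    p <- length(x) / n
    flat <- matrix(aperm(x, c(2, 3, 4, 1)), p, n)
    crossprod(flat, projection_for(p)) # n x dim
  }
  structure(list(name = "projection-pool", dim = dim, seed = as.integer(seed),
                 transform = transform),
            class = "feature_extractor")
}

#' Frechet distance between two image sets
#'
#' Extracts features from both sets with the same extractor, fits Gaussian
#' summaries and returns their Frechet distance. Identical sets give ~0
#' (up to matrix-square-root numerics); the value grows as the feature
#' statistics of the two sets separate.
#'
#' @param real,generated [image_batch()]es with at least 2 images each, in
#'   the same pixel domain.
#' @param extractor a [projection_pool_extractor()]-like extractor.
#' @return non-negative scalar.
#' @export
fid <- function(real, generated, extractor = projection_pool_extractor(64)) {
  stopifnot(inherits(extractor, "feature_extractor"))
  for (nm in c("real", "generated")) {
    v <- get(nm)
    if (dim(v)[1] < 2L) {
      stop(sprintf("`%s` must contain at least 2 images", nm), call. = FALSE)
    }
  }
  if (inherits(real, "image_batch") && inherits(generated, "image_batch") &&
      !identical(batch_domain(real), batch_domain(generated))) {
    stop("`real` and `generated` must share a pixel domain", call. = FALSE)
  }
  a <- summarize_features(extractor$transform(real))
  b <- summarize_features(extractor$transform(generated))
  val <- frechet_distance(a, b)
  log_info("fid", extractor = extractor$name, dim = extractor$dim,
           n_real = a$n, n_generated = b$n, fid = val)
  val
}

#' FID table across losses and feature dimensions
#'
#' Evaluates [fid()] for every combination of a generated set (one per
#' training loss) and a feature extractor, mirroring the customary
#' loss-by-dimension report layout.
#'
#' @param real reference [image_batch()].
#' @param generated_by_loss named list of [image_batch()]es, one per loss.
#' @param extractors list of feature extractors (default dims 2048 and 64).
#' @param path optional CSV output file.
#' @return a data.frame with one row per loss and one column per extractor
#'   dimension.
#' @export
fid_table <- function(real, generated_by_loss,
                      extractors = list(projection_pool_extractor(2048),
                                        projection_pool_extractor(64)),
                      path = NULL) {
  stopifnot(length(generated_by_loss) >= 1L, length(extractors) >= 1L,
            !is.null(names(generated_by_loss)))
  dims <- vapply(extractors, function(e) e$dim, integer(1))
  tab <- matrix(NA_real_, length(generated_by_loss), length(extractors),
                dimnames = list(names(generated_by_loss),
                                as.character(dims)))
  for (i in seq_along(generated_by_loss)) {
    for (j in seq_along(extractors)) {
      tab[i, j] <- suppressMessages(
        fid(real, generated_by_loss[[i]], extractors[[j]]))
    }
  }
  df <- data.frame(loss = rownames(tab), tab, check.names = FALSE,
                   row.names = NULL)
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  df
}
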