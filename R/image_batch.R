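#' Create an image batch
#'
#' The package's image container: a rank-4 numeric array laid out
#' `batch x channel x height x width` carrying an explicit value-domain tag.
#' Two domains exist: `"uint8"` (integers in `[0, 255]`, the storage domain of
#' MedMNIST archives and PNG files) and `"normalized"` (reals in `[-1, 1]`,
#' the domain all diffusion mathematics operates in). Operations that require
#' one domain refuse the other rather than converting silently; use
#' [normalize_images()] / [denormalize_images()] to move between them.
#'
#' A 3-D `n x height x width` array is promoted to a single-channel batch;
#' a 2-D `height x width` matrix to a single-image single-channel batch.
#'
#' @param pixels numeric array of rank 2, 3 or 4.
#' @param domain `"uint8"` or `"normalized"`.
#' @return an `image_batch`: the rank-4 array with a `domain` attribute.
#' @export
#' @examples
#' x <- image_batch(array(0, c(4, 1, 28, 28)), "normalized")
#' batch_domain(x)
image_batch <- function(pixels, domain = c("normalized", "uint8")) {
  domain <- match.arg(domain)
  if (is.matrix(pixels)) dim(pixels) <- c(1L, 1L, nrow(pixels), ncol(pixels))
  if (length(dim(pixels)) == 3L) {
    d <- dim(pixels)
    dim(pixels) <- c(d[1], 1L, d[2], d[3])
  }
  if (length(dim(pixels)) != 4L) {
    stop("`pixels` must be an array of rank 2, 3 or 4", call. = FALSE)
  }
  storage.mode(pixels) <- "double"
  rng <- range(pixels)
  if (domain == "uint8") {
    if (rng[1] < 0 || rng[2] > 255 || any(pixels != round(pixels))) {
      stop("uint8 batches must hold integers in [0, 255]", call. = FALSE)
    }
  } else if (rng[1] < -1 - 1e-9 || rng[2] > 1 + 1e-9) {
    stop("normalized batches must lie in [-1, 1]", call. = FALSE)
  }
  structure(pixels, domain = domain, class = "image_batch")
}

# internal: wrap an array that is already known-valid (e.g. an unclamped
# diffusion state x_t, which may exceed [-1,1]); skips range validation.
as_batch <- function(pixels, domain = "normalized") {
  structure(pixels, domain = domain, class = "image_batch")
}

#' @rdname image_batch
#' @param x an `image_batch`.
#' @export
batch_domain <- function(x) attr(x, "domain") %||% "normalized"

#' @export
print.image_batch <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<image_batch> %d image(s), %d channel(s), %dx%d, domain=%s\n",
              d[1], d[2], d[3], d[4], batch_domain(x)))
  invisible(x)
}

check_normalized <- function(x, arg) {
  if (inherits(x, "image_batch") && batch_domain(x) == "uint8") {
    stop(sprintf(
      "`%s` is in the uint8 domain; call normalize_images() first", arg),
      call. = FALSE)
  }
}

check_same_shape <- function(a, b, na, nb) {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("`%s` and `%s` must have identical shapes (%s vs %s)",
                 na, nb, paste(dim(a), collapse = "x"),
                 paste(dim(b), collapse = "x")), call. = FALSE)
  }
}

#' Convert between uint8 and normalized pixel domains
#'
#' `normalize_images()` maps `[0, 255]` affinely onto `[-1, 1]`
#' (`0 -> -1`, `255 -> 1`). `denormalize_images()` clamps to `[-1, 1]` first,
#' maps back, and rounds half away from zero, so the round trip
#' `denormalize_images(normalize_images(x))` is exact for every uint8 value.
#'
#' @param x an [image_batch()] in the domain being converted from.
#' @return an [image_batch()] in the other domain.
#' @export
normalize_images <- function(x) {
  if (!inherits(x, "image_batch")) x <- image_batch(x, "uint8")
  if (batch_domain(x) != "uint8") {
    stop("`x` is not in the uint8 domain", call. = FALSE)
  }
  y <- unclass(x) / 255 * 2 - 1
  attributes(y) <- list(dim = dim(x))
  image_batch(y, "normalized")
}

#' @rdname normalize_images
#' @export
denormalize_images <- function(x) {
  if (!inherits(x, "image_batch") || batch_domain(x) != "normalized") {
    stop("`x` is not in the normalized domain", call. = FALSE)
  }
  y <- clamp(unclass(x), -1, 1)
  y <- floor((y + 1) / 2 * 255 + 0.5) # round half away from zero (all >= 0)
  attributes(y) <- list(dim = dim(x))
  image_batch(y, "uint8")
}

# draw a standard-normal batch shaped like `like` (normalized domain)
gaussian_like <- function(like) {
  as_batch(array(stats::rnorm(length(like)), dim(like)))
}
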