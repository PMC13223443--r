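# MedMNIST-layout archives, PNG grids, and the synthetic chest-phantom
# generator.
#
# Coordinate convention, used everywhere: images are row-major with the
# origin at the top-left; pixel indices are 0-based in documentation and
# 1-based in R code.

#' Read one split of a MedMNIST-layout NPZ archive
#'
#' The archive must contain `<split>_images` (N x 28 x 28 uint8) and
#' `<split>_labels` members. Images are promoted to an `n x 1 x h x w`
#' uint8 [image_batch()]; labels are returned untouched (they are never
#' consumed by training, which is unconditional, but the reader is faithful
#' to the archive format). Non-28x28 images are accepted with a warning to
#' allow higher-resolution archives.
#'
#' @param path NPZ file.
#' @param split `"train"`, `"val"` or `"test"`.
#' @return list with `images` (uint8 [image_batch()]) and `labels`.
#' @export
read_medmnist_npz <- function(path, split = c("train", "val", "test")) {
  split <- match.arg(split)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  exdir <- tempfile("npz")
  dir.create(exdir)
  on.exit(unlink(exdir, recursive = TRUE))
  members <- utils::unzip(path, exdir = exdir)
  names(members) <- sub("\\.npy$", "", basename(members))
  want <- paste0(split, c("_images", "_labels"))
  if (!all(want %in% names(members))) {
    stop(sprintf(
      "archive %s lacks member(s) %s; expected keys are %s",
      path, paste(setdiff(want, names(members)), collapse = ", "),
      paste(paste0(rep(c("train", "val", "test"), each = 2),
                   c("_images", "_labels")), collapse = ", ")),
      call. = FALSE)
  }
  imgs <- read_npy(members[[want[1]]])
  labels <- read_npy(members[[want[2]]])
  d <- dim(imgs)
  if (length(d) != 3L) {
    stop(sprintf("%s must be a rank-3 N x H x W array", want[1]),
         call. = FALSE)
  }
  if (d[2] != 28L || d[3] != 28L) {
    warning(sprintf("images are %dx%d, not the customary 28x28",
                    d[2], d[3]), call. = FALSE)
  }
  dim(imgs) <- c(d[1], 1L, d[2], d[3])
  list(images = image_batch(imgs, "uint8"), labels = labels)
}

#' Write image splits as a MedMNIST-layout NPZ archive
#'
#' @param path output NPZ file.
#' @param splits named list (`train`/`val`/`test`); each element a list with
#'   `images` (uint8 [image_batch()] or N x H x W array) and optionally
#'   `labels` (defaults to a zero column).
#' @return `path`, invisibly.
#' @export
write_medmnist_npz <- function(path, splits) {
  stopifnot(length(splits) >= 1L, !is.null(names(splits)),
            all(names(splits) %in% c("train", "val", "test")))
  entries <- list()
  for (nm in names(splits)) {
    imgs <- splits[[nm]]$images
    x <- unclass(imgs)
    d <- dim(x)
    if (length(d) == 4L) {
      dim(x) <- c(d[1], d[3], d[4]) # drop the singleton channel
      d <- dim(x)
    }
    labels <- splits[[nm]]$labels %||% matrix(0L, d[1], 1L)
    entries[[paste0(nm, "_images.npy")]] <- npy_bytes(x, "|u1")
    entries[[paste0(nm, "_labels.npy")]] <- npy_bytes(labels, "|u1")
  }
  write_zip(entries, path)
  invisible(path)
}

#' Parameters of the synthetic chest-phantom generator
#'
#' Each knob is an interval from which every phantom draws independently,
#' emulating one axis of the anatomical variability seen across chest
#' radiographs: body scale (body shape / BMI), rotation (posture), lung
#' area fraction (lung volume), brightness (gray value) and integer crop
#' jitter (field of view).
#'
#' @param n number of phantoms.
#' @param seed master seed; each phantom renders from its own derived
#'   sub-stream.
#' @param body_scale_range multiplicative thorax size, within `[0.5, 1.3]`.
#' @param rotation_range_deg posture rotation, within `[-25, 25]` degrees.
#' @param lung_area_range combined lung area as a fraction of the thorax
#'   ellipse, within `[0.05, 0.6]`.
#' @param brightness_range multiplicative intensity, within `[0.5, 1.5]`.
#' @param crop_jitter_px maximum absolute center shift in pixels, `0..4`.
#' @return a `phantom_params` list.
#' @export
phantom_params <- function(n, seed = 0L,
                           body_scale_range = c(0.9, 1.1),
                           rotation_range_deg = c(-8, 8),
                           lung_area_range = c(0.25, 0.40),
                           brightness_range = c(0.85, 1.15),
                           crop_jitter_px = 1L) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1) {
    stop("`n` must be a positive integer", call. = FALSE)
  }
  check_interval <- function(r, nm, lo, hi) {
    if (length(r) != 2L || anyNA(r) || r[1] > r[2] || r[1] < lo ||
        r[2] > hi) {
      stop(sprintf("`%s` must be an interval within [%g, %g]", nm, lo, hi),
           call. = FALSE)
    }
  }
  check_interval(body_scale_range, "body_scale_range", 0.5, 1.3)
  check_interval(rotation_range_deg, "rotation_range_deg", -25, 25)
  check_interval(lung_area_range, "lung_area_range", 0.05, 0.6)
  check_interval(brightness_range, "brightness_range", 0.5, 1.5)
  if (length(crop_jitter_px) != 1L || is.na(crop_jitter_px) ||
      crop_jitter_px < 0 || crop_jitter_px > 4) {
    stop("`crop_jitter_px` must be a single integer in 0..4", call. = FALSE)
  }
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 body_scale_range = as.numeric(body_scale_range),
                 rotation_range_deg = as.numeric(rotation_range_deg),
                 lung_area_range = as.numeric(lung_area_range),
                 brightness_range = as.numeric(brightness_range),
                 crop_jitter_px = as.integer(crop_jitter_px)),
            class = "phantom_params")
}

#' Generate synthetic chest phantoms
#'
#' Renders seeded 28x28 grayscale chest phantoms: a bright elliptical thorax
#' on a dark background, two darker lung fields, faint rib bands, and mild
#' pixel noise, with per-image variability drawn from [phantom_params()].
#' Identical parameters give bitwise-identical batches.
#'
#' The phantoms are intentionally crude: they exist to give the diffusion
#' pipeline a learnable, low-entropy image distribution at desk scale with
#' no download, not to be radiologically plausible.
#'
#' @param params a [phantom_params()].
#' @return a uint8 [image_batch()] of shape `n x 1 x 28 x 28`.
#' @export
#' @examples
#' ph <- generate_phantoms(phantom_params(4, seed = 7))
#' dim(ph)
generate_phantoms <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  size <- 28L
  half <- (size - 1) / 2
  out <- array(0, c(params$n, 1L, size, size))
  for (i in seq_len(params$n)) {
    img <- with_seed(derive_seed(params$seed, sprintf("phantom-%d", i)), {
      scale <- stats::runif(1, params$body_scale_range[1],
                            params$body_scale_range[2])
      theta <- stats::runif(1, params$rotation_range_deg[1],
                            params$rotation_range_deg[2]) * pi / 180
      lungf <- stats::runif(1, params$lung_area_range[1],
                            params$lung_area_range[2])
      bright <- stats::runif(1, params$brightness_range[1],
                             params$brightness_range[2])
      j <- params$crop_jitter_px
      jx <- if (j > 0) sample(-j:j, 1) else 0L
      jy <- if (j > 0) sample(-j:j, 1) else 0L
      phase <- stats::runif(1, 0, 2 * pi)
      xs <- (0:(size - 1)) - half - jx # columns
      ys <- (0:(size - 1)) - half - jy # rows, top-left origin
      X <- matrix(xs, size, size, byrow = TRUE)
      Y <- matrix(ys, size, size)
      xr <- cos(theta) * X + sin(theta) * Y
      yr <- -sin(theta) * X + cos(theta) * Y
      a <- 9 * scale
      b <- 11.5 * scale
      e_th <- (xr / a)^2 + (yr / b)^2
      w_th <- stats::plogis((1 - e_th) / 0.08)
      img <- 18 + (180 * bright - 18) * w_th
      img <- img + 10 * sin(yr * 2 * pi / 4.5 + phase) * w_th # rib bands
      al <- sqrt(lungf * a * b / (2 * 1.55))
      bl <- 1.55 * al
      for (sgn in c(-1, 1)) {
        e_l <- ((xr - sgn * 0.45 * a) / al)^2 + ((yr + 0.08 * b) / bl)^2
        img <- img - (90 * bright) * stats::plogis((1 - e_l) / 0.06)
      }
      img <- img + stats::rnorm(size * size, sd = 3)
      round(clamp(img, 0, 255))
    })
    out[i, 1L, , ] <- img
  }
  image_batch(out, "uint8")
}

#' Write an image batch as a single tiled PNG grid
#'
#' Tiles the batch row-major with `columns` images per row into one
#' lossless 8-bit grayscale PNG; unused trailing cells are black.
#'
#' @param x an [image_batch()] (normalized batches are converted to uint8).
#' @param path output PNG file.
#' @param columns images per row.
#' @return `path`, invisibly.
#' @export
write_image_grid <- function(x, path, columns = 8L) {
  stopifnot(columns >= 1L)
  if (inherits(x, "image_batch") && batch_domain(x) == "normalized") {
    x <- denormalize_images(x)
  }
  d <- dim(x)
  n <- d[1]
  if (n < 1L) stop("`x` must contain at least one image", call. = FALSE)
  h <- d[3]; w <- d[4]
  rows <- ceiling(n / columns)
  canvas <- matrix(0, rows * h, columns * w)
  for (i in seq_len(n)) {
    r <- (i - 1L) %/% columns
    cc <- (i - 1L) %% columns
    canvas[r * h + seq_len(h), cc * w + seq_len(w)] <- x[i, 1L, , ]
  }
  png::writePNG(canvas / 255, path)
  invisible(path)
}

#' Read a tiled PNG grid back into an image batch
#'
#' The inverse of [write_image_grid()] for grids of `image_size`-pixel
#' tiles.
#'
#' @param path PNG file written by [write_image_grid()].
#' @param image_size tile height/width. Default 28.
#' @param n number of images to keep (default: every tile).
#' @return a uint8 [image_batch()].
#' @export
read_image_grid <- function(path, image_size = 28L, n = NULL) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  vals <- round(img * 255)
  rows <- nrow(vals) %/% image_size
  cols <- ncol(vals) %/% image_size
  total <- rows * cols
  n <- n %||% total
  stopifnot(n <= total)
  out <- array(0, c(n, 1L, image_size, image_size))
  for (i in seq_len(n)) {
    r <- (i - 1L) %/% cols
    cc <- (i - 1L) %% cols
    out[i, 1L, , ] <- vals[r * image_size + seq_len(image_size),
                           cc * image_size + seq_len(image_size)]
  }
  image_batch(out, "uint8")
}
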