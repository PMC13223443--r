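test_that("pixel-domain conversion is exact at the endpoints and round-trips", {
  all_vals <- image_batch(array(rep(0:255, 4), c(4, 1, 16, 16)), "uint8")
  norm <- normalize_images(all_vals)
  expect_identical(batch_domain(norm), "normalized")
  expect_equal(min(norm), -1)
  expect_equal(max(norm), 1)
  back <- denormalize_images(norm)
  expect_identical(unclass(back), unclass(all_vals))
  # midpoint symmetry: 127 and 128 straddle zero within one quantum
  n127 <- unclass(normalize_images(image_batch(matrix(127, 1, 1), "uint8")))
  n128 <- unclass(normalize_images(image_batch(matrix(128, 1, 1), "uint8")))
  expect_lt(abs(n127 + n128), 2 / 255)
  expect_lt(n127, 0)
  expect_gt(n128, 0)
  expect_error(normalize_images(norm), "uint8")
  expect_error(denormalize_images(all_vals), "normalized")
})

test_that("phantom generation is deterministic with valid pixel ranges", {
  p <- phantom_params(16, seed = 7)
  a <- generate_phantoms(p)
  b <- generate_phantoms(p)
  expect_identical(unclass(a), unclass(b))
  expect_identical(dim(unclass(a)), c(16L, 1L, 28L, 28L))
  expect_identical(batch_domain(a), "uint8")
  expect_true(all(a >= 0 & a <= 255))
  c2 <- generate_phantoms(phantom_params(16, seed = 8))
  expect_false(identical(unclass(a), unclass(c2)))
})

test_that("phantom parameters reject degenerate ranges", {
  expect_error(phantom_params(0), "positive")
  expect_error(phantom_params(4, body_scale_range = c(1.1, 0.9)),
               "interval")
  expect_error(phantom_params(4, lung_area_range = c(0.01, 0.2)),
               "interval")
  expect_error(phantom_params(4, crop_jitter_px = 9), "0\\.\\.4")
})

test_that("lung fields are darker than the surrounding thorax", {
  n <- 1000
  ph <- unclass(generate_phantoms(phantom_params(n, seed = 11)))
  # fixed central masks; generous margins cover the jitter/rotation ranges
  lung_rows <- 9:17
  lung_cols_l <- 8:11
  lung_cols_r <- 18:21
  medi_cols <- 13:16
  ok <- 0
  for (i in seq_len(n)) {
    img <- ph[i, 1, , ]
    lungs <- mean(c(img[lung_rows, lung_cols_l], img[lung_rows,
                                                     lung_cols_r]))
    medi <- mean(img[lung_rows, medi_cols])
    if (lungs < medi) ok <- ok + 1
  }
  expect_gte(ok / n, 0.95)
})

test_that("widening the brightness range raises across-image variance", {
  narrow <- generate_phantoms(phantom_params(
    500, seed = 12, brightness_range = c(0.99, 1.01)))
  wide <- generate_phantoms(phantom_params(
    500, seed = 12, brightness_range = c(0.7, 1.3)))
  var_narrow <- stats::var(apply(unclass(narrow), 1, mean))
  var_wide <- stats::var(apply(unclass(wide), 1, mean))
  expect_gt(var_wide, var_narrow)
})

test_that("NPZ archives round-trip bitwise through the MedMNIST layout", {
  ph <- fixture_phantoms(10)
  labels <- matrix(as.integer(0:9), 10, 1)
  path <- tempfile(fileext = ".npz")
  write_medmnist_npz(path, list(train = list(images = ph, labels = labels),
                                val = list(images = ph)))
  back <- read_medmnist_npz(path, "train")
  expect_identical(unclass(back$images), unclass(ph))
  expect_identical(as.integer(back$labels), as.integer(labels))
  backv <- read_medmnist_npz(path, "val")
  expect_identical(unclass(backv$images), unclass(ph))
  expect_error(read_medmnist_npz(path, "test"), "test_images")
  expect_error(read_medmnist_npz(tempfile(), "train"), "not found")
})

test_that("non-28x28 archives are accepted with a warning", {
  img <- array(sample(0:255, 5 * 14 * 14, replace = TRUE), c(5, 14, 14))
  path <- tempfile(fileext = ".npz")
  write_medmnist_npz(path, list(train = list(
    images = image_batch(array(img, c(5, 1, 14, 14)), "uint8"))))
  expect_warning(out <- read_medmnist_npz(path, "train"), "28x28")
  expect_identical(dim(unclass(out$images)), c(5L, 1L, 14L, 14L))
})

test_that("NPY serialization handles integer and double payloads", {
  x <- matrix(rnorm(12), 3, 4)
  f <- tempfile(fileext = ".npy")
  writeBin(minidiffusion:::npy_bytes(x), f)
  expect_equal(minidiffusion:::read_npy(f), x)
  xi <- array(sample.int(1000, 24), c(2, 3, 4))
  writeBin(minidiffusion:::npy_bytes(xi, "<i4"), f)
  expect_identical(minidiffusion:::read_npy(f), xi)
})

test_that("image grids tile losslessly and read back exactly", {
  ph <- fixture_phantoms(16)
  path <- tempfile(fileext = ".png")
  write_image_grid(ph, path, columns = 4)
  img <- png::readPNG(path)
  expect_identical(dim(img)[1:2], c(112L, 112L)) # 4 x 28 each side
  back <- read_image_grid(path, image_size = 28, n = 16)
  expect_identical(unclass(back), unclass(ph))
})

test_that("snapshot sequences export one grid per stage", {
  s <- make_linear_schedule(6)
  out <- sample_images(zero_denoiser(), s, n_images = 4, seed = 2,
                       snapshot_after = c(2, 4), image_size = 28)
  dir <- tempfile()
  dir.create(dir)
  files <- character(0)
  for (nm in names(out$snapshots)) {
    f <- file.path(dir, sprintf("snapshot_%s.png", nm))
    write_image_grid(out$snapshots[[nm]], f, columns = 2)
    files <- c(files, f)
  }
  write_image_grid(out$final, file.path(dir, "final.png"), columns = 2)
  expect_length(files, 2)
  expect_true(all(file.exists(files)))
  back <- read_image_grid(files[1], n = 4)
  expect_identical(unclass(back), unclass(out$snapshots[["2"]]))
})
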