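# Minimal NPY (v1.0) and store-only ZIP support for MedMNIST-layout NPZ
# archives. Reading uses base R's built-in unzip; writing emits uncompressed
# ZIP members with a CRC-32 computed in R. Only the dtypes occurring in
# MedMNIST-style archives (and ordinary numeric arrays) are supported.

# ---- CRC-32 -----------------------------------------------------------------

xor32 <- function(a, b) {
  bitwXor(a %% 65536, b %% 65536) +
    bitwXor(a %/% 65536, b %/% 65536) * 65536
}

crc32_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      t <- numeric(256)
      for (n in 0:255) {
        c <- n
        for (k in 1:8) {
          c <- if (c %% 2 == 1) xor32(c %/% 2, 3988292384) else c %/% 2
        }
        t[n + 1] <- c
      }
      tab <<- t
    }
    tab
  }
})

crc32 <- function(data) {
  tab <- crc32_table()
  crc <- 4294967295
  for (b in as.integer(data)) {
    crc <- xor32(tab[bitwXor(crc %% 256, b) + 1], crc %/% 256)
  }
  xor32(crc, 4294967295)
}

# ---- little-endian integer fields -------------------------------------------

le_bytes <- function(x, width) {
  out <- raw(width)
  for (i in seq_len(width)) {
    out[i] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

# ---- NPY --------------------------------------------------------------------

npy_descr <- function(x) {
  if (is.raw(x) || isTRUE(attr(x, "npy_uint8"))) "|u1"
  else if (is.integer(x)) "<i4"
  else "<f8"
}

# serialize a (possibly multi-dimensional) numeric array to NPY v1.0 bytes;
# dtype "|u1" stores rounded values as unsigned bytes
npy_bytes <- function(x, dtype = NULL) {
  d <- dim(x) %||% length(x)
  dtype <- dtype %||% npy_descr(x)
  shape <- if (length(d) == 1L) sprintf("(%d,)", d) else
    sprintf("(%s)", paste(d, collapse = ", "))
  hdr <- sprintf("{'descr': '%s', 'fortran_order': False, 'shape': %s, }",
                 dtype, shape)
  pad <- 64L - ((10L + nchar(hdr) + 1L) %% 64L)
  if (pad == 64L) pad <- 0L
  hdr <- paste0(hdr, strrep(" ", pad), "\n")
  # C order = last index fastest: permute to reversed dims, then column-major
  v <- if (length(d) > 1L) {
    as.vector(aperm(array(as.vector(x), d), rev(seq_along(d))))
  } else {
    as.vector(x)
  }
  payload <- switch(dtype,
    "|u1" = as.raw(round(v)),
    "<i4" = writeBin(as.integer(v), raw(), size = 4L, endian = "little"),
    "<f8" = writeBin(as.numeric(v), raw(), size = 8L, endian = "little"),
    stop(sprintf("unsupported NPY dtype for writing: %s", dtype),
         call. = FALSE))
  c(as.raw(c(0x93L, utf8ToInt("N"), utf8ToInt("U"), utf8ToInt("M"),
             utf8ToInt("P"), utf8ToInt("Y"), 1L, 0L)),
    le_bytes(nchar(hdr), 2L),
    charToRaw(hdr),
    payload)
}

read_npy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 8L)
  if (!identical(magic[1:6], as.raw(c(0x93L, utf8ToInt("N"), utf8ToInt("U"),
                                      utf8ToInt("M"), utf8ToInt("P"),
                                      utf8ToInt("Y"))))) {
    stop(sprintf("%s is not an NPY file", path), call. = FALSE)
  }
  hlen <- if (as.integer(magic[7]) >= 2L) {
    sum(as.integer(readBin(con, "raw", 4L)) * 256^(0:3))
  } else {
    sum(as.integer(readBin(con, "raw", 2L)) * 256^(0:1))
  }
  hdr <- rawToChar(readBin(con, "raw", hlen))
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", hdr)
  fortran <- grepl("'fortran_order':\\s*True", hdr)
  shape_str <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", hdr)
  shape <- as.integer(strsplit(gsub("\\s", "", shape_str), ",")[[1]])
  shape <- shape[!is.na(shape)]
  if (!length(shape)) shape <- integer(0)
  n <- if (length(shape)) prod(shape) else 1L
  v <- switch(descr,
    "|u1" = , "<u1" = readBin(con, "integer", n, size = 1L, signed = FALSE),
    "|i1" = readBin(con, "integer", n, size = 1L, signed = TRUE),
    "<i2" = readBin(con, "integer", n, size = 2L, endian = "little"),
    "<u2" = readBin(con, "integer", n, size = 2L, signed = FALSE,
                    endian = "little"),
    "<i4" = readBin(con, "integer", n, size = 4L, endian = "little"),
    "<f4" = readBin(con, "numeric", n, size = 4L, endian = "little"),
    "<f8" = readBin(con, "numeric", n, size = 8L, endian = "little"),
    stop(sprintf("unsupported NPY dtype: %s", descr), call. = FALSE))
  if (length(shape) <= 1L) return(v)
  if (fortran) {
    array(v, shape)
  } else {
    aperm(array(v, rev(shape)), rev(seq_along(shape)))
  }
}

# ---- ZIP (store only) -------------------------------------------------------

# entries: named list of raw vectors
write_zip <- function(entries, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  offsets <- integer(length(entries))
  crcs <- numeric(length(entries))
  offset <- 0
  for (i in seq_along(entries)) {
    name <- charToRaw(names(entries)[i])
    data <- entries[[i]]
    crcs[i] <- crc32(data)
    offsets[i] <- offset
    local_hdr <- c(as.raw(c(0x50, 0x4b, 0x03, 0x04)),
                   le_bytes(20, 2), le_bytes(0, 2), le_bytes(0, 2),
                   le_bytes(0, 2), le_bytes(33, 2),
                   le_bytes(crcs[i], 4),
                   le_bytes(length(data), 4), le_bytes(length(data), 4),
                   le_bytes(length(name), 2), le_bytes(0, 2),
                   name)
    writeBin(local_hdr, con)
    writeBin(data, con)
    offset <- offset + length(local_hdr) + length(data)
  }
  cd_start <- offset
  cd_size <- 0
  for (i in seq_along(entries)) {
    name <- charToRaw(names(entries)[i])
    data <- entries[[i]]
    cd <- c(as.raw(c(0x50, 0x4b, 0x01, 0x02)),
            le_bytes(20, 2), le_bytes(20, 2), le_bytes(0, 2),
            le_bytes(0, 2), le_bytes(0, 2), le_bytes(33, 2),
            le_bytes(crcs[i], 4),
            le_bytes(length(data), 4), le_bytes(length(data), 4),
            le_bytes(length(name), 2), le_bytes(0, 2), le_bytes(0, 2),
            le_bytes(0, 2), le_bytes(0, 2), le_bytes(0, 4),
            le_bytes(offsets[i], 4),
            name)
    writeBin(cd, con)
    cd_size <- cd_size + length(cd)
  }
  eocd <- c(as.raw(c(0x50, 0x4b, 0x05, 0x06)),
            le_bytes(0, 2), le_bytes(0, 2),
            le_bytes(length(entries), 2), le_bytes(length(entries), 2),
            le_bytes(cd_size, 4), le_bytes(cd_start, 4), le_bytes(0, 2))
  writeBin(eocd, con)
  invisible(path)
}
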