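# NumPy .npy / .npz container support.
#
# Reading .npz relies on R's internal unzip; writing produces a STORED
# (uncompressed) zip archive with a pure-R CRC-32, so round-trips need no
# external zip binary.  Only the dtypes used by MD17-style archives are
# supported: little-endian float64/float32 and integer types up to int64.

npy_crc32_table <- local({
  tab <- integer(256)
  for (i in 0:255) {
    c <- i
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) == 1L) {
        bitwXor(-306674912L, bitwShiftR(bitwAnd(c, -2L), 1))
      } else {
        bitwShiftR(c, 1)
      }
    }
    tab[i + 1L] <- c
  }
  tab
})

npy_crc32 <- function(raw_bytes) {
  crc <- -1L
  b <- as.integer(raw_bytes)
  for (x in b) {
    idx <- bitwAnd(bitwXor(crc, x), 255L) + 1L
    crc <- bitwXor(bitwShiftR(crc, 8), npy_crc32_table[idx])
  }
  bitwXor(crc, -1L)
}

crc32_to_raw_le <- function(crc) {
  u <- as.numeric(crc)
  if (u < 0) u <- u + 2^32
  as.raw(c(u %% 256, (u %/% 256) %% 256, (u %/% 65536) %% 256,
           (u %/% 16777216) %% 256))
}

num_to_raw_le <- function(x, nbytes) {
  out <- raw(nbytes)
  for (k in seq_len(nbytes)) {
    out[k] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

#' Serialize an array to NumPy .npy bytes
#'
#' C-order (row-major) data layout, format version 1.0.  Doubles become
#' `<f8`, integers `<i8`.
#'
#' @param x numeric/integer vector, matrix or array.
#' @return raw vector holding the .npy stream.
#' @keywords internal
npy_serialize <- function(x) {
  dims <- if (is.null(dim(x))) length(x) else dim(x)
  ## R stores column-major; transpose to C order
  arr <- if (length(dims) > 1L) aperm(array(x, dims), rev(seq_along(dims))) else x
  if (is.integer(x)) {
    descr <- "<i8"
    data <- do.call(c, lapply(as.numeric(arr), num_to_raw_le, nbytes = 8))
  } else {
    descr <- "<f8"
    data <- writeBin(as.numeric(arr), raw(), size = 8, endian = "little")
  }
  shape <- if (length(dims) == 1L) sprintf("(%d,)", dims) else
    sprintf("(%s)", paste(dims, collapse = ", "))
  header <- sprintf("{'descr': '%s', 'fortran_order': False, 'shape': %s, }",
                    descr, shape)
  ## pad so that magic(6)+ver(2)+hlen(2)+header is a multiple of 64
  base_len <- 10L + nchar(header) + 1L
  pad <- (64L - base_len %% 64L) %% 64L
  header <- paste0(header, strrep(" ", pad), "\n")
  c(charToRaw("\x93NUMPY"), as.raw(c(1L, 0L)),
    writeBin(nchar(header), raw(), size = 2, endian = "little"),
    charToRaw(header), data)
}

raw_to_num_le <- function(r) {
  sum(as.numeric(r) * 256^(seq_along(r) - 1))
}

#' Parse NumPy .npy bytes into an R array
#' @param bytes raw vector with the .npy stream.
#' @return numeric vector, matrix or array (R column-major layout).
#' @keywords internal
npy_parse <- function(bytes) {
  if (!identical(bytes[1:6], charToRaw("\x93NUMPY")))
    stop("not an .npy stream: bad magic")
  major <- as.integer(bytes[7])
  hdr_off <- if (major >= 2L) 12L else 10L
  hlen <- raw_to_num_le(bytes[9:(hdr_off)])
  header <- rawToChar(bytes[(hdr_off + 1L):(hdr_off + hlen)])
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shape_s <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  dims <- as.integer(strsplit(gsub("\\s", "", shape_s), ",")[[1]])
  dims <- dims[!is.na(dims)]
  n <- if (length(dims)) prod(dims) else 1L
  data_raw <- bytes[(hdr_off + hlen + 1L):length(bytes)]
  size <- as.integer(substring(descr, 3L))
  type <- substring(descr, 2L, 2L)
  read_i8 <- function(r, n) {
    ## int64: combine 32-bit halves (exact up to 2^53)
    halves <- readBin(r, "integer", n = 2L * n, size = 4L, endian = "little")
    lo <- as.numeric(halves[seq(1L, 2L * n, 2L)])
    hi <- as.numeric(halves[seq(2L, 2L * n, 2L)])
    lo[lo < 0] <- lo[lo < 0] + 2^32
    lo + hi * 2^32
  }
  vals <- switch(type,
    f = readBin(data_raw, "double", n = n, size = size, endian = "little"),
    i = if (size == 8L) read_i8(data_raw, n) else
        readBin(data_raw, "integer", n = n, size = size, endian = "little",
                signed = TRUE),
    u = readBin(data_raw, "integer", n = n,
                size = max(size, 2L), endian = "little", signed = FALSE),
    stop("unsupported npy dtype: ", descr))
  if (length(dims) <= 1L) return(vals)
  if (fortran) array(vals, dims) else aperm(array(vals, rev(dims)),
                                            rev(seq_along(dims)))
}

#' Write arrays to a .npz archive
#'
#' Produces a STORED zip container (one .npy member per array) compatible
#' with `numpy.load`.
#'
#' @param arrays named list of numeric arrays.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_npz <- function(arrays, path) {
  stopifnot(length(names(arrays)) == length(arrays))
  con <- file(path, "wb")
  on.exit(close(con))
  offsets <- integer(0)
  centrals <- list()
  offset <- 0L
  for (nm in names(arrays)) {
    fname <- paste0(nm, ".npy")
    data <- npy_serialize(arrays[[nm]])
    crc <- npy_crc32(data)
    fn_raw <- charToRaw(fname)
    local_hdr <- c(as.raw(c(0x50, 0x4b, 0x03, 0x04)),
                   num_to_raw_le(20, 2),          # version needed
                   num_to_raw_le(0, 2),           # flags
                   num_to_raw_le(0, 2),           # method: stored
                   num_to_raw_le(0, 4),           # dos time/date
                   crc32_to_raw_le(crc),
                   num_to_raw_le(length(data), 4),
                   num_to_raw_le(length(data), 4),
                   num_to_raw_le(length(fn_raw), 2),
                   num_to_raw_le(0, 2))
    writeBin(local_hdr, con)
    writeBin(fn_raw, con)
    writeBin(data, con)
    centrals[[nm]] <- c(as.raw(c(0x50, 0x4b, 0x01, 0x02)),
                        num_to_raw_le(20, 2), num_to_raw_le(20, 2),
                        num_to_raw_le(0, 2), num_to_raw_le(0, 2),
                        num_to_raw_le(0, 4),
                        crc32_to_raw_le(crc),
                        num_to_raw_le(length(data), 4),
                        num_to_raw_le(length(data), 4),
                        num_to_raw_le(length(fn_raw), 2),
                        num_to_raw_le(0, 2), num_to_raw_le(0, 2),
                        num_to_raw_le(0, 2), num_to_raw_le(0, 2),
                        num_to_raw_le(0, 4),
                        num_to_raw_le(offset, 4),
                        fn_raw)
    offset <- offset + length(local_hdr) + length(fn_raw) + length(data)
  }
  cd_start <- offset
  for (ce in centrals) writeBin(ce, con)
  cd_size <- sum(vapply(centrals, length, 1L))
  eocd <- c(as.raw(c(0x50, 0x4b, 0x05, 0x06)),
            num_to_raw_le(0, 2), num_to_raw_le(0, 2),
            num_to_raw_le(length(centrals), 2),
            num_to_raw_le(length(centrals), 2),
            num_to_raw_le(cd_size, 4),
            num_to_raw_le(cd_start, 4),
            num_to_raw_le(0, 2))
  writeBin(eocd, con)
  invisible(path)
}

#' Read a .npz archive into a named list of arrays
#' @param path .npz file path.
#' @return named list of arrays (names without the `.npy` suffix).
#' @export
read_npz <- function(path) {
  stopifnot(file.exists(path))
  tmp <- tempfile("npz_")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  files <- utils::unzip(path, exdir = tmp)
  out <- list()
  for (f in files) {
    nm <- sub("\\.npy$", "", basename(f))
    bytes <- readBin(f, "raw", n = file.info(f)$size)
    out[[nm]] <- npy_parse(bytes)
  }
  out
}
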