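# Minimal dependency-free PNG encoder (8-bit grayscale/RGB and 16-bit
# grayscale, no interlacing, filter type 0). Hand-rolled deliberately: no PNG
# package is assumed, and byte-for-byte deterministic output is part of the
# rendering contract. Compression uses memCompress(), whose "gzip" type emits
# an RFC 1950 zlib stream as PNG requires.

.CRC_TABLE <- local({
  tab <- integer(256)
  for (n in 0:255) {
    c <- n
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) == 1L)
        bitwXor(-306674912L, bitwShiftR(c, 1))  # 0xEDB88320
      else bitwShiftR(c, 1)
    }
    tab[n + 1L] <- c
  }
  tab
})

crc32 <- function(bytes) {
  crc <- -1L
  b <- as.integer(bytes)
  for (i in seq_along(b)) {
    crc <- bitwXor(bitwShiftR(crc, 8),
                   .CRC_TABLE[bitwAnd(bitwXor(crc, b[[i]]), 255L) + 1L])
  }
  crc <- bitwXor(crc, -1L)
  x <- as.numeric(crc)
  if (x < 0) x <- x + 4294967296
  x
}

uint32_be <- function(x) {
  as.raw(c(x %/% 16777216, (x %/% 65536) %% 256, (x %/% 256) %% 256, x %% 256))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(uint32_be(length(data)), body, uint32_be(crc32(body)))
}

zlib_compress <- function(bytes) {
  z <- memCompress(bytes, type = "gzip")
  if (length(z) >= 2 && z[[1]] == as.raw(0x78)) return(z)
  # gzip wrapper: strip header/trailer, add zlib framing
  deflate <- z[11:(length(z) - 8)]
  d <- as.numeric(bytes)
  n <- length(d)
  a <- (1 + sum(d)) %% 65521
  bsum <- (n + sum((n - seq_len(n) + 1) * d)) %% 65521
  c(as.raw(c(0x78, 0x01)), deflate, uint32_be(bsum * 65536 + a))
}

#' Write a PNG image
#'
#' @param img For 8-bit output: an integer array `ny x nx` (grayscale) or
#'   `ny x nx x 3` (RGB) with values 0-255. For `bit_depth = 16`: a matrix
#'   with values 0-65535 (grayscale only).
#' @param path Output file.
#' @param bit_depth 8 or 16.
#' @return Invisibly, `path`.
#' @export
write_png <- function(img, path, bit_depth = 8) {
  dims <- dim(img)
  ny <- dims[[1]]; nx <- dims[[2]]
  channels <- if (length(dims) == 3L) dims[[3]] else 1L
  if (!channels %in% c(1L, 3L)) stop("img must have 1 or 3 channels")
  if (bit_depth == 16 && channels != 1L)
    stop("16-bit output supports grayscale only")
  color_type <- if (channels == 3L) 2L else 0L
  v <- round(as.numeric(img))
  maxval <- if (bit_depth == 16) 65535 else 255
  v[v < 0] <- 0; v[v > maxval] <- maxval
  arr <- array(v, dim = c(ny, nx, channels))
  # scanlines: filter byte 0 + interleaved samples, row-major
  rows <- lapply(seq_len(ny), function(r) {
    samp <- as.numeric(t(arr[r, , , drop = TRUE]))
    if (channels == 3L) samp <- as.numeric(rbind(arr[r, , 1],
                                                 arr[r, , 2],
                                                 arr[r, , 3]))
    if (bit_depth == 16) {
      bytes <- as.raw(rbind(samp %/% 256, samp %% 256))
    } else {
      bytes <- as.raw(samp)
    }
    c(as.raw(0), bytes)
  })
  stream <- do.call(c, rows)
  ihdr <- c(uint32_be(nx), uint32_be(ny), as.raw(c(bit_depth, color_type,
                                                   0, 0, 0)))
  out <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", zlib_compress(stream)),
           png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}

# 3x5 bitmap glyphs (row-major bits, '1' = on) for grid labels
.FONT_3x5 <- c(
  A = "010101111101101", B = "110101110101110", C = "011100100100011",
  D = "110101101101110", E = "111100110100111", F = "111100110100100",
  G = "011100101101011", H = "101101111101101", I = "111010010010111",
  J = "001001001101010", K = "101110100110101", L = "100100100100111",
  M = "101111111101101", N = "110101101101101", O = "010101101101010",
  P = "110101110100100", Q = "010101101110011", R = "110101110110101",
  S = "011100010001110", T = "111010010010010", U = "101101101101111",
  V = "101101101101010", W = "101101111111101", X = "101101010101101",
  Y = "101101010010010", Z = "111001010100111",
  `0` = "111101101101111", `1` = "010110010010111", `2` = "111001111100111",
  `3` = "111001011001111", `4` = "101101111001001", `5` = "111100111001111",
  `6` = "111100111101111", `7` = "111001001001001", `8` = "111101111101111",
  `9` = "111101111001111"
)

glyph_matrix <- function(ch) {
  bits <- .FONT_3x5[[ch]]
  if (is.null(bits)) return(matrix(0L, 5, 3))
  matrix(as.integer(strsplit(bits, "")[[1]]), nrow = 5, ncol = 3,
         byrow = TRUE)
}

# stamp `text` into a numeric matrix at (row, col), value `value`
stamp_text <- function(m, text, row, col, value = 255) {
  chars <- strsplit(toupper(text), "")[[1]]
  x <- col
  for (ch in chars) {
    g <- glyph_matrix(ch)
    rr <- row:(row + 4); cc <- x:(x + 2)
    ok_r <- rr >= 1 & rr <= nrow(m)
    ok_c <- cc >= 1 & cc <= ncol(m)
    sub <- g[ok_r, ok_c, drop = FALSE]
    m[rr[ok_r], cc[ok_c]][sub == 1L] <- value
    x <- x + 4L
  }
  m
}
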