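# Minimal BMP decoder (Windows BITMAPINFOHEADER, uncompressed 8/24/32-bit).
# None of the installed imaging packages reads BMP, so the subset that
# microscope software actually exports is decoded here.

read_bmp <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 2L)
  if (!identical(as.integer(magic), c(0x42L, 0x4DL))) { # "BM"
    stop("not a BMP file (bad magic)")
  }
  readBin(con, "integer", 1L, size = 4L, endian = "little")     # file size
  readBin(con, "raw", 4L)                                        # reserved
  data_offset <- readBin(con, "integer", 1L, size = 4L, endian = "little")

  header_size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (header_size < 40L) stop("unsupported BMP header")
  width  <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  height <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  top_down <- height < 0L
  height <- abs(height)
  readBin(con, "integer", 1L, size = 2L, endian = "little")      # planes
  bpp <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  compression <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (compression != 0L) stop("compressed BMP not supported")
  if (!bpp %in% c(8L, 24L, 32L)) {
    stop(sprintf("unsupported BMP bit depth: %d", bpp))
  }
  readBin(con, "raw", header_size - 16L)                         # rest of header

  palette <- NULL
  if (bpp == 8L) {
    n_pal <- (data_offset - 14L - header_size) %/% 4L
    if (n_pal <= 0L) n_pal <- 256L
    pal_raw <- readBin(con, "raw", n_pal * 4L)
    pal <- matrix(as.integer(pal_raw), nrow = 4L) # B, G, R, reserved
    palette <- t(pal[3:1, , drop = FALSE]) / 255  # -> n_pal x 3 (R, G, B)
  }

  seek(con, data_offset)
  bytes_pp <- bpp %/% 8L
  row_bytes <- ((width * bytes_pp + 3L) %/% 4L) * 4L # rows padded to 4 bytes
  data <- readBin(con, "raw", row_bytes * height)
  if (length(data) < row_bytes * height) stop("truncated BMP pixel data")
  rows_px <- matrix(as.integer(data), nrow = row_bytes)[seq_len(width * bytes_pp), ,
                                                        drop = FALSE]
  img <- array(0, c(height, width, 3L))
  for (r in seq_len(height)) {
    out_r <- if (top_down) r else height - r + 1L # BMP rows are bottom-up
    px <- rows_px[, r]
    if (bpp == 8L) {
      img[out_r, , ] <- palette[px + 1L, ]
    } else {
      px <- matrix(px, nrow = bytes_pp) # B, G, R(, A) per pixel
      img[out_r, , 1L] <- px[3L, ] / 255
      img[out_r, , 2L] <- px[2L, ] / 255
      img[out_r, , 3L] <- px[1L, ] / 255
    }
  }
  img
}
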