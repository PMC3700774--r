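# Minimal baseline TIFF support: multi-page, grayscale, uncompressed,
# little-endian, 8- or 16-bit, one strip per page. No installed R package
# reads TIFF in this stack, so the subset needed for movie round-trips is
# implemented here. Big-endian ("MM") and compressed files are rejected with
# informative errors rather than misread.

u16le <- function(x) as.raw(c(x %% 256L, (x %/% 256L) %% 256L))
u32le <- function(x) {
  x <- as.double(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}
rd_u16 <- function(raw, off) {  # off is 1-based
  as.integer(raw[off]) + 256L * as.integer(raw[off + 1])
}
rd_u32 <- function(raw, off) {
  as.double(as.integer(raw[off])) + 256 * as.integer(raw[off + 1]) +
    65536 * as.integer(raw[off + 2]) + 16777216 * as.integer(raw[off + 3])
}

ifd_entry <- function(tag, type, count, value4) {
  c(u16le(tag), u16le(type), u32le(count), value4)
}
short_val <- function(x) c(u16le(x), as.raw(c(0, 0)))

write_tiff_stack <- function(frames, path, bit_depth = 16L) {
  stopifnot(length(dim(frames)) == 3)
  h <- dim(frames)[1]; w <- dim(frames)[2]; nf <- dim(frames)[3]
  bpp <- bit_depth %/% 8L
  dsize <- h * w * bpp
  n_tags <- 9L
  ifd_size <- 2L + n_tags * 12L + 4L
  block <- ifd_size + dsize
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(as.raw(c(0x49, 0x49, 0x2a, 0x00)), u32le(8)), con)
  for (k in seq_len(nf)) {
    ifd_off <- 8 + (k - 1) * block
    data_off <- ifd_off + ifd_size
    next_off <- if (k < nf) ifd_off + block else 0
    ifd <- c(
      u16le(n_tags),
      ifd_entry(256L, 4L, 1L, u32le(w)),          # ImageWidth
      ifd_entry(257L, 4L, 1L, u32le(h)),          # ImageLength
      ifd_entry(258L, 3L, 1L, short_val(bit_depth)),  # BitsPerSample
      ifd_entry(259L, 3L, 1L, short_val(1L)),     # Compression = none
      ifd_entry(262L, 3L, 1L, short_val(1L)),     # Photometric = BlackIsZero
      ifd_entry(273L, 4L, 1L, u32le(data_off)),   # StripOffsets
      ifd_entry(277L, 3L, 1L, short_val(1L)),     # SamplesPerPixel
      ifd_entry(278L, 4L, 1L, u32le(h)),          # RowsPerStrip
      ifd_entry(279L, 4L, 1L, u32le(dsize)),      # StripByteCounts
      u32le(next_off)
    )
    writeBin(ifd, con)
    v <- as.integer(round(as.vector(t(frames[, , k]))))  # row-major
    maxval <- 2^bit_depth - 1
    if (any(v < 0 | v > maxval)) {
      abort_input(sprintf("pixel values outside [0, %d] cannot be written at bit depth %d",
                          maxval, bit_depth))
    }
    if (bit_depth == 8L) {
      writeBin(as.raw(v), con)
    } else {
      bytes <- raw(2L * length(v))
      bytes[seq(1L, by = 2L, length.out = length(v))] <- as.raw(v %% 256L)
      bytes[seq(2L, by = 2L, length.out = length(v))] <- as.raw(v %/% 256L)
      writeBin(bytes, con)
    }
  }
  invisible(path)
}

tiff_parse_error <- function(msg, frame = NULL) {
  abort_input(msg, class = "ciliamotion_error_tiff_parse", frame_index = frame)
}

read_tiff_stack <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("file not found: %s", path))
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8) tiff_parse_error("not a TIFF: file shorter than header")
  if (raw[1] == as.raw(0x4d) && raw[2] == as.raw(0x4d)) {
    tiff_parse_error("big-endian (MM) TIFF not supported; rewrite as little-endian")
  }
  if (!(raw[1] == as.raw(0x49) && raw[2] == as.raw(0x49) && rd_u16(raw, 3) == 42L)) {
    tiff_parse_error("not a TIFF: bad header magic")
  }
  off <- rd_u32(raw, 5)
  frames <- list()
  k <- 0L
  while (off != 0) {
    k <- k + 1L
    if (off + 2 > length(raw)) {
      tiff_parse_error(sprintf("truncated TIFF: IFD of frame %d beyond end of file", k), k)
    }
    n_tags <- rd_u16(raw, off + 1)
    ifd_end <- off + 2 + n_tags * 12 + 4
    if (ifd_end > length(raw)) {
      tiff_parse_error(sprintf("truncated TIFF: IFD of frame %d incomplete", k), k)
    }
    tags <- list()
    for (j in seq_len(n_tags)) {
      e <- off + 2 + (j - 1) * 12 + 1  # 1-based entry start
      tag <- rd_u16(raw, e)
      type <- rd_u16(raw, e + 2)
      count <- rd_u32(raw, e + 4)
      size <- c(1, 1, 2, 4)[type]  # BYTE/ASCII/SHORT/LONG; others unused
      if (is.na(size)) next
      vals <- if (count * size <= 4) {
        vo <- e + 8
        if (type == 3L) vapply(seq_len(count), function(i) as.double(rd_u16(raw, vo + (i - 1) * 2)), 0)
        else if (type == 4L) vapply(seq_len(count), function(i) rd_u32(raw, vo + (i - 1) * 4), 0)
        else as.double(as.integer(raw[vo + seq_len(count) - 1]))
      } else {
        vo <- rd_u32(raw, e + 8) + 1
        if (vo + count * size - 1 > length(raw)) {
          tiff_parse_error(sprintf("truncated TIFF: tag %d data of frame %d beyond end of file", tag, k), k)
        }
        if (type == 3L) vapply(seq_len(count), function(i) as.double(rd_u16(raw, vo + (i - 1) * 2)), 0)
        else if (type == 4L) vapply(seq_len(count), function(i) rd_u32(raw, vo + (i - 1) * 4), 0)
        else as.double(as.integer(raw[vo + seq_len(count) - 1]))
      }
      tags[[as.character(tag)]] <- vals
    }
    g <- function(tag, default = NULL) tags[[as.character(tag)]] %||% default
    w <- g(256); h <- g(257)
    if (is.null(w) || is.null(h)) tiff_parse_error(sprintf("frame %d: missing dimensions", k), k)
    spp <- g(277, 1)
    if (spp != 1) {
      abort_input(paste0("multi-sample (RGB) TIFF not supported: extract a ",
                         "single channel before analysis"),
                  class = "ciliamotion_error_tiff_rgb")
    }
    if (g(259, 1) != 1) tiff_parse_error(sprintf("frame %d: compressed TIFF not supported", k), k)
    bits <- g(258, 1)[1]
    if (!bits %in% c(8, 16)) tiff_parse_error(sprintf("frame %d: %d-bit samples not supported", k, bits), k)
    offs <- g(273); cnts <- g(279)
    if (is.null(offs) || is.null(cnts)) tiff_parse_error(sprintf("frame %d: missing strip layout", k), k)
    if (any(offs + cnts - 1 > length(raw))) {
      tiff_parse_error(sprintf("truncated TIFF: pixel data of frame %d beyond end of file", k), k)
    }
    data <- unlist(lapply(seq_along(offs), function(i) {
      raw[(offs[i] + 1):(offs[i] + cnts[i])]
    }), use.names = FALSE)
    npx <- w * h
    if (length(data) < npx * bits / 8) {
      tiff_parse_error(sprintf("truncated TIFF: frame %d has too few pixel bytes", k), k)
    }
    v <- if (bits == 8) as.integer(data[seq_len(npx)]) else
      readBin(data, "integer", n = npx, size = 2, endian = "little", signed = FALSE)
    frames[[k]] <- list(mat = matrix(v, nrow = h, ncol = w, byrow = TRUE),
                        bits = bits)
    off <- rd_u32(raw, off + 2 + n_tags * 12 + 1)
  }
  if (length(frames) == 0) tiff_parse_error("TIFF contains no frames")
  dims <- vapply(frames, function(f) dim(f$mat), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    tiff_parse_error("frames differ in shape")
  }
  arr <- array(0, dim = c(dims[1, 1], dims[2, 1], length(frames)))
  for (k in seq_along(frames)) arr[, , k] <- frames[[k]]$mat
  list(frames = arr, bit_depth = as.integer(frames[[1]]$bits))
}
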