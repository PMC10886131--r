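# Indexed-palette PNG writer for class masks. No installed package writes
# palette PNGs, so the five fixed chunks are assembled here: the deflate
# stream comes from memCompress (gzip wrapper stripped, zlib header and
# Adler-32 added), chunk CRCs from a compiled CRC-32. Masks read back through
# png::readPNG, which expands the palette to RGB.

# default palette: index 0 background (black), 1 corn (green), 2 weed (red)
voc_palette <- function() {
  matrix(c(0L, 0L, 0L,
           0L, 255L, 0L,
           255L, 0L, 0L), ncol = 3L, byrow = TRUE)
}

u32be <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %/% 16777216, (x %/% 65536) %% 256, (x %/% 256) %% 256, x %% 256))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(u32be(length(data)), body, u32be(cpp_crc32(body)))
}

# memCompress(type = "gzip") emits an RFC 1950 zlib stream (0x78 header,
# Adler-32 trailer), which is exactly the IDAT payload format
zlib_of <- function(raw_data) memCompress(raw_data, type = "gzip")

#' Write a class-index mask as an indexed-palette PNG
#'
#' @param mask integer matrix of palette indices (0-based).
#' @param path output file.
#' @param palette `n x 3` integer matrix of RGB palette entries (0-255); row
#'   `i` colors index `i - 1`. Defaults to black/green/red for
#'   background/corn/weed.
#' @return `path`, invisibly.
#' @export
write_palette_png <- function(mask, path, palette = voc_palette()) {
  mask <- as.matrix(mask)
  if (any(mask < 0) || any(mask >= nrow(palette)))
    rds_format_error("mask contains indices outside the palette")
  H <- nrow(mask); W <- ncol(mask)
  ihdr <- c(u32be(W), u32be(H), as.raw(c(8L, 3L, 0L, 0L, 0L)))
  plte <- as.raw(as.integer(t(palette)))
  # scanlines: filter byte 0 + row of palette indices
  scan <- rbind(rep(0L, H), t(mask))
  raw_data <- as.raw(as.integer(scan))
  idat <- zlib_of(raw_data)
  out <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
           png_chunk("IHDR", ihdr),
           png_chunk("PLTE", plte),
           png_chunk("IDAT", idat),
           png_chunk("IEND", raw(0)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(out, con)
  invisible(path)
}

#' Read a class-index mask PNG
#'
#' Accepts palette PNGs written by [write_palette_png()] (expanded to RGB by
#' libpng and mapped back through the palette) as well as 8-bit grayscale
#' masks holding raw class indices.
#'
#' @param path PNG file.
#' @param palette palette used for the color -> index mapping.
#' @param max_index largest legal class index; anything above raises a format
#'   error.
#' @return integer matrix of class indices.
#' @export
read_mask_png <- function(path, palette = voc_palette(), max_index = 2L) {
  if (!file.exists(path)) rds_io_error(sprintf("mask file not found: %s", path))
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) {
    if (dim(a)[3] == 4L) a <- a[, , 1:3, drop = FALSE] # tolerate alpha
    key <- round(a[, , 1] * 255) * 65536L + round(a[, , 2] * 255) * 256L + round(a[, , 3] * 255)
    pkey <- palette[, 1] * 65536L + palette[, 2] * 256L + palette[, 3]
    idx <- match(as.vector(key), pkey) - 1L
    if (anyNA(idx))
      rds_format_error(sprintf("mask %s contains a color outside the class palette", basename(path)))
    mask <- matrix(idx, nrow(key), ncol(key))
  } else {
    mask <- round(a * 255)
    storage.mode(mask) <- "integer"
  }
  if (any(mask > max_index))
    rds_format_error(sprintf("mask %s contains class index %d > %d",
                             basename(path), max(mask), max_index))
  mask
}
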