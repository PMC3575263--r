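# Raster utilities.
#
# Convention: a raster is a numeric array dim = c(height, width, channels)
# on the 0..255 scale (channels = 1 grayscale, 3 RGB, 4 RGBA). Grayscale
# matrices are accepted anywhere a raster is and treated as 1 channel.
# Pixel coordinates are 0-based, top-left origin; boxes are half-open.

as_raster <- function(x) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  if (!is.array(x) || length(dim(x)) != 3L) {
    ss_validation_error("raster must be a matrix or a height x width x channels array")
  }
  if (any(dim(x) < 1L)) ss_validation_error("raster has a zero-length dimension")
  storage.mode(x) <- "double"
  x
}

raster_width <- function(x) dim(x)[2L]
raster_height <- function(x) dim(x)[1L]
raster_channels <- function(x) if (length(dim(x)) == 3L) dim(x)[3L] else 1L

# [0,1] image (as returned by the png/tiff/jpeg readers) -> 0..255 raster
raster_from_unit <- function(img) {
  x <- as_raster(img)
  round(x * 255)
}

# 0..255 raster -> [0,1] for the image writers
raster_to_unit <- function(x) {
  pmin(pmax(as_raster(x) / 255, 0), 1)
}

# Half-open crop: box [x0, x0+width) x [y0, y0+height), 0-based.
crop_raster <- function(x, x0, y0, width, height) {
  x <- as_raster(x)
  w <- raster_width(x)
  h <- raster_height(x)
  if (x0 < 0 || y0 < 0 || width < 1 || height < 1 ||
      x0 + width > w || y0 + height > h) {
    ss_bounds_error(sprintf(
      "crop box [%d,%d)x[%d,%d) outside raster %dx%d",
      x0, x0 + width, y0, y0 + height, w, h
    ))
  }
  x[(y0 + 1):(y0 + height), (x0 + 1):(x0 + width), , drop = FALSE]
}

# Sparse 1-D resampling weight matrix (n_src x n_out), column-stochastic.
#
# "area": each output cell averages the source interval it covers, with
# fractional weights at the interval ends -- exact block means when the
# scale factor is an integer, the oracle-checkable choice for downsampling.
# "bilinear": linear interpolation between the two nearest source centers.
resample_weights <- function(n_src, n_out, method = c("area", "bilinear")) {
  method <- match.arg(method)
  if (n_out == n_src) return(Matrix::Diagonal(n_src))
  s <- n_src / n_out
  ii <- integer(0); jj <- integer(0); ww <- numeric(0)
  if (method == "area") {
    for (j in seq_len(n_out)) {
      lo <- (j - 1) * s
      hi <- j * s
      i0 <- floor(lo)
      i1 <- ceiling(hi) - 1
      i1 <- min(i1, n_src - 1)
      idx <- i0:i1
      w <- pmin(hi, idx + 1) - pmax(lo, idx)
      keep <- w > 1e-12
      idx <- idx[keep]; w <- w[keep]
      ii <- c(ii, idx + 1L)
      jj <- c(jj, rep.int(j, length(idx)))
      ww <- c(ww, w / sum(w))
    }
  } else {
    for (j in seq_len(n_out)) {
      centre <- (j - 0.5) * s - 0.5
      i0 <- floor(centre)
      frac <- centre - i0
      idx <- c(i0, i0 + 1)
      w <- c(1 - frac, frac)
      keep <- idx >= 0 & idx <= n_src - 1 & w > 1e-12
      idx <- idx[keep]; w <- w[keep]
      ii <- c(ii, idx + 1L)
      jj <- c(jj, rep.int(j, length(idx)))
      ww <- c(ww, w / sum(w))
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = ww, dims = c(n_src, n_out))
}

# Separable resampling to out_width x out_height.
resample_raster <- function(x, out_width, out_height,
                            method = c("area", "bilinear")) {
  method <- match.arg(method)
  x <- as_raster(x)
  if (out_width < 1 || out_height < 1) {
    ss_validation_error("output dimensions must be at least 1x1")
  }
  if (out_width == raster_width(x) && out_height == raster_height(x)) {
    return(x)
  }
  out_width <- as.integer(out_width)
  out_height <- as.integer(out_height)
  wr <- resample_weights(raster_height(x), out_height, method)
  wc <- resample_weights(raster_width(x), out_width, method)
  nc <- raster_channels(x)
  out <- array(0, c(out_height, out_width, nc))
  for (ch in seq_len(nc)) {
    out[, , ch] <- as.matrix(Matrix::t(wr) %*% x[, , ch] %*% wc)
  }
  out
}

# Write a raster as an 8-bit baseline TIFF / PNG / JPEG file.
write_raster_tiff <- function(x, path, compression = "LZW") {
  tiff::writeTIFF(raster_to_unit(round(x)), path, bits.per.sample = 8L,
                  compression = compression)
  invisible(path)
}

write_raster_png <- function(x, path, text = NULL) {
  png::writePNG(raster_to_unit(round(x)), path, text = text)
  invisible(path)
}

encode_raster_jpeg <- function(x, quality) {
  jpeg::writeJPEG(raster_to_unit(round(x)), raw(), quality = quality / 100)
}
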