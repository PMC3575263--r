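# Shared test helpers: small deterministic rasters, independent
# stitch/downsample oracles kept deliberately brute-force.

random_raster <- function(height, width, seed = 1, channels = 3) {
  set.seed(seed)
  array(as.double(sample(0:255, height * width * channels, replace = TRUE)),
        c(height, width, channels))
}

checkerboard <- function(height, width, cell = 1, lo = 0, hi = 255) {
  rows <- matrix(rep(seq_len(height) - 1, width), height)
  cols <- matrix(rep(seq_len(width) - 1, each = height), height)
  plane <- ifelse(((rows %/% cell) + (cols %/% cell)) %% 2 == 0, lo, hi)
  array(rep(plane, 3), c(height, width, 3))
}

# Brute-force area downsample by looping over output pixels; the oracle
# for the package's weighted resampling.
brute_area_downsample <- function(x, out_w, out_h) {
  out_w <- as.integer(out_w); out_h <- as.integer(out_h)
  h <- dim(x)[1]; w <- dim(x)[2]; nc <- dim(x)[3]
  sx <- w / out_w; sy <- h / out_h
  out <- array(0, c(out_h, out_w, nc))
  for (j in seq_len(out_h)) {
    for (i in seq_len(out_w)) {
      x_lo <- (i - 1) * sx; x_hi <- i * sx
      y_lo <- (j - 1) * sy; y_hi <- j * sy
      xs <- floor(x_lo):(ceiling(x_hi) - 1)
      ys <- floor(y_lo):(ceiling(y_hi) - 1)
      wx <- pmin(x_hi, xs + 1) - pmax(x_lo, xs)
      wy <- pmin(y_hi, ys + 1) - pmax(y_lo, ys)
      wgt <- outer(wy, wx)
      for (ch in seq_len(nc)) {
        out[j, i, ch] <- sum(wgt * x[ys + 1, xs + 1, ch]) / sum(wgt)
      }
    }
  }
  out
}

# Reassemble a full level raster from per-tile rasters and their boxes.
stitch_boxes <- function(rasters, boxes, level_w, level_h) {
  out <- array(NA_real_, c(level_h, level_w, 3))
  for (i in seq_along(rasters)) {
    b <- boxes[i, ]
    out[(b$y0 + 1):b$y1, (b$x0 + 1):b$x1, ] <- rasters[[i]]
  }
  out
}

extract_tiles <- function(raster, grid) {
  lapply(seq_len(nrow(grid$tiles)), function(i) {
    t <- grid$tiles[i, ]
    raster[(t$y0 + 1):t$y1, (t$x0 + 1):t$x1, , drop = FALSE]
  })
}

write_png_slide <- function(raster, path = tempfile(fileext = ".png"), text = NULL) {
  png::writePNG(pmin(pmax(raster / 255, 0), 1), path, text = text)
  path
}

write_tiff_slide <- function(raster, path = tempfile(fileext = ".tif")) {
  tiff::writeTIFF(pmin(pmax(raster / 255, 0), 1), path, bits.per.sample = 8L,
                  compression = "LZW")
  path
}
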