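# Snapshot rendering: the publishable JPEG is the centered quarter of
# the slide -- half the width times half the height, taken from the
# middle to maximise the chance of catching the diagnostically relevant
# region -- downsampled to a configured magnification and watermarked at
# the bottom.

#' Snapshot rendering parameters
#'
#' @param magnification Output magnification; `NA` keeps the scan
#'   magnification.
#' @param jpeg_quality JPEG quality, integer 1..100 (default 90).
#' @param watermark_path Optional path to a logo image (PNG with alpha
#'   recommended) composited at the bottom of the snapshot.
#' @return A `snapshot_spec`.
#' @export
snapshot_spec <- function(magnification = NA_real_, jpeg_quality = 90L,
                          watermark_path = NULL) {
  if (jpeg_quality < 1 || jpeg_quality > 100) {
    ss_validation_error("jpeg_quality must be in [1, 100]")
  }
  if (!is.na(magnification) && magnification <= 0) {
    ss_validation_error("magnification must be positive")
  }
  structure(list(magnification = magnification,
                 jpeg_quality = as.integer(jpeg_quality),
                 watermark_path = watermark_path),
            class = "snapshot_spec")
}

#' Centered quarter-area snapshot box
#'
#' The snapshot covers one quarter of the slide area: a centered box of
#' `floor(width/2) x floor(height/2)` pixels, with offsets
#' `x0 = floor((width - box_width) / 2)` (and likewise `y0`), as a
#' half-open box at full resolution.
#'
#' @param slide A `slide_image`, or a length-2 numeric
#'   `c(width, height)`.
#' @return Named integer vector `c(x0, y0, x1, y1)` (half-open).
#' @examples
#' snapshot_box(c(4096, 3072))  # 1024 768 3072 2304
#' @export
snapshot_box <- function(slide) {
  if (inherits(slide, "slide_image")) {
    w <- slide$width_px; h <- slide$height_px
  } else if (is.numeric(slide) && length(slide) == 2L) {
    w <- slide[1]; h <- slide[2]
  } else {
    ss_validation_error("'slide' must be a slide_image or c(width, height)")
  }
  if (w < 2 || h < 2) ss_validation_error("slide must be at least 2x2 pixels")
  bw <- floor(w / 2)
  bh <- floor(h / 2)
  x0 <- floor((w - bw) / 2)
  y0 <- floor((h - bh) / 2)
  c(x0 = as.integer(x0), y0 = as.integer(y0),
    x1 = as.integer(x0 + bw), y1 = as.integer(y0 + bh))
}

#' Alpha-composite a logo onto the bottom of an image
#'
#' The logo is bottom-centered with a margin of 2% of the image height.
#' A logo wider or taller than the image is downscaled (preserving aspect
#' ratio) to fit. Logos without an alpha channel are treated as opaque;
#' a degenerate logo is skipped with a warning. Pixels outside the
#' logo box are untouched and the output dimensions equal the input's.
#'
#' @param image RGB raster (0..255).
#' @param logo RGB or RGBA raster (0..255).
#' @param margin_fraction Bottom margin as a fraction of image height.
#' @return Watermarked raster, same dimensions as `image`.
#' @export
add_watermark <- function(image, logo, margin_fraction = 0.02) {
  image <- as_raster(image)
  if (length(logo) == 0 || any(dim(logo)[1:2] < 1)) {
    warning("degenerate logo skipped")
    return(image)
  }
  logo <- as_raster(logo)
  ih <- raster_height(image); iw <- raster_width(image)
  lh <- raster_height(logo); lw <- raster_width(logo)
  if (lw > iw || lh > ih) {
    scale <- min(iw / lw, ih / lh)
    new_w <- max(1L, as.integer(floor(lw * scale)))
    new_h <- max(1L, as.integer(floor(lh * scale)))
    logo <- resample_raster(logo, new_w, new_h, "area")
    lh <- new_h; lw <- new_w
  }
  margin <- floor(margin_fraction * ih)
  x0 <- floor((iw - lw) / 2)
  y0 <- max(0L, ih - lh - margin)
  rows <- (y0 + 1):(y0 + lh)
  cols <- (x0 + 1):(x0 + lw)
  alpha <- if (raster_channels(logo) >= 4L) logo[, , 4L] / 255 else
    matrix(1, lh, lw)
  out <- image
  for (ch in 1:3) {
    lch <- logo[, , min(ch, raster_channels(logo))]
    out[rows, cols, ch] <- round((1 - alpha) * image[rows, cols, ch] + alpha * lch)
  }
  out
}

#' Render the snapshot of a slide
#'
#' Reads the centered quarter box ([snapshot_box()]) at the spec's
#' magnification, applies the watermark when configured, and encodes the
#' result as JPEG.
#'
#' @param slide A `slide_image`.
#' @param spec A [snapshot_spec()].
#' @return Raw vector of JPEG bytes, with attribute `dims = c(height,
#'   width)` of the encoded raster.
#' @seealso [write_snapshot()]
#' @export
render_snapshot <- function(slide, spec = snapshot_spec()) {
  if (!inherits(spec, "snapshot_spec")) ss_validation_error("'spec' must be a snapshot_spec")
  box <- snapshot_box(slide)
  raster <- read_region(slide, region_request(
    box["x0"], box["y0"], box["x1"] - box["x0"], box["y1"] - box["y0"],
    spec$magnification
  ))
  raster <- round(raster)
  if (!is.null(spec$watermark_path)) {
    logo <- load_logo(spec$watermark_path)
    raster <- add_watermark(raster, logo)
  }
  bytes <- encode_raster_jpeg(raster, spec$jpeg_quality)
  attr(bytes, "dims") <- c(raster_height(raster), raster_width(raster))
  bytes
}

load_logo <- function(path) {
  if (!file.exists(path)) ss_io_error(sprintf("watermark not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                jpg = , jpeg = jpeg::readJPEG(path),
                tif = , tiff = tiff::readTIFF(path),
                ss_validation_error(sprintf("unsupported watermark format: %s", ext)))
  raster_from_unit(img)
}

#' Render a snapshot and write it next to its slide identifier
#'
#' The output filename is the slide identifier: the slide's file stem
#' plus `.jpg`.
#'
#' @param slide A `slide_image`.
#' @param out_dir Output directory (created if absent).
#' @param spec A [snapshot_spec()].
#' @return Path of the written JPEG, invisibly.
#' @export
write_snapshot <- function(slide, out_dir, spec = snapshot_spec()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  bytes <- render_snapshot(slide, spec)
  path <- file.path(out_dir, paste0(slide_stem(slide), ".jpg"))
  writeBin(as.raw(bytes), path)
  invisible(path)
}
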