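# Slide access: a registry of format readers behind one contract --
# report dimensions and scan magnification, extract regions. Shipped
# readers decode plain/multi-page TIFF and PNG; proprietary scanner
# containers (e.g. Hamamatsu NDPI) plug in through the same registry
# without touching the rest of the toolkit.

.reader_registry <- new.env(parent = emptyenv())

#' Register a slide format reader
#'
#' A reader is matched first by magic bytes, then by file extension, and
#' must open the file into an in-memory raster plus metadata. Registering
#' an existing `id` replaces that reader (so a plugin can override the
#' built-ins).
#'
#' @param id Unique reader identifier (e.g. `"tiff"`).
#' @param extensions Character vector of lower-case file extensions.
#' @param match_magic `function(path)` returning `TRUE` if the file
#'   signature belongs to this format.
#' @param open `function(path)` returning a list with elements `raster`
#'   (height x width x channels array, 0..255) and `magnification`
#'   (numeric scalar or `NA` when the container carries no tag). It should
#'   signal an error on corrupt input.
#' @return The reader id, invisibly.
#' @seealso [open_slide()]
#' @export
register_slide_reader <- function(id, extensions, match_magic, open) {
  stopifnot(is.character(id), length(id) == 1L, is.function(match_magic),
            is.function(open))
  assign(id, list(id = id, extensions = tolower(extensions),
                  match_magic = match_magic, open = open),
         envir = .reader_registry)
  invisible(id)
}

#' List registered slide reader ids
#' @return Character vector of reader ids.
#' @export
slide_readers <- function() ls(.reader_registry)

read_magic <- function(path, n = 8L) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n)
}

find_reader <- function(path) {
  ids <- slide_readers()
  magic <- tryCatch(read_magic(path), error = function(e) raw(0))
  for (id in ids) {
    r <- get(id, envir = .reader_registry)
    hit <- tryCatch(isTRUE(r$match_magic(magic)), error = function(e) FALSE)
    if (hit) return(r)
  }
  ext <- tolower(tools::file_ext(path))
  for (id in ids) {
    r <- get(id, envir = .reader_registry)
    if (ext %in% r$extensions) return(r)
  }
  NULL
}

# Built-in readers ---------------------------------------------------------

# A magnification tag, when present, is read from the TIFF ImageDescription
# ("magnification=40", or the Aperio-style "AppMag = 40") or from a PNG
# text chunk named "magnification".
parse_magnification <- function(text) {
  if (length(text) == 0 || all(is.na(text))) return(NA_real_)
  text <- paste(text, collapse = " ")
  m <- regmatches(text, regexec("(?i)(?:magnification\\s*=|AppMag\\s*=)\\s*([0-9.]+)",
                                text, perl = TRUE))[[1]]
  if (length(m) < 2) NA_real_ else as.numeric(m[2])
}

open_tiff_slide <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0) stop("TIFF has no images")
  # pyramidal/multi-page containers: the full-resolution level is the
  # largest page
  areas <- vapply(pages, function(p) prod(dim(p)[1:2]), numeric(1))
  img <- pages[[which.max(areas)]]
  desc <- attr(img, "description")
  mag <- parse_magnification(desc)
  if (length(dim(img)) == 3L && dim(img)[3L] > 3L) img <- img[, , 1:3, drop = FALSE]
  list(raster = raster_from_unit(img), magnification = mag)
}

open_png_slide <- function(path) {
  img <- png::readPNG(path, info = TRUE)
  info <- attr(img, "info")
  mag <- NA_real_
  if (!is.null(info) && !is.null(info$text)) {
    txt <- info$text
    if ("magnification" %in% names(txt)) mag <- suppressWarnings(as.numeric(txt[["magnification"]]))
    if (is.na(mag)) mag <- parse_magnification(unlist(txt))
  }
  if (length(dim(img)) == 3L && dim(img)[3L] > 3L) img <- img[, , 1:3, drop = FALSE]
  list(raster = raster_from_unit(img), magnification = mag)
}

register_builtin_readers <- function() {
  register_slide_reader(
    "tiff", c("tif", "tiff"),
    match_magic = function(magic) {
      length(magic) >= 4 &&
        (identical(magic[1:4], as.raw(c(0x49, 0x49, 0x2a, 0x00))) ||
         identical(magic[1:4], as.raw(c(0x4d, 0x4d, 0x00, 0x2a))))
    },
    open = open_tiff_slide
  )
  register_slide_reader(
    "png", "png",
    match_magic = function(magic) {
      length(magic) >= 8 &&
        identical(magic[1:8], as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)))
    },
    open = open_png_slide
  )
}

# Slide handles ------------------------------------------------------------

new_slide_image <- function(raster, magnification, path, reader_id) {
  raster <- as_raster(raster)
  if (raster_channels(raster) == 1L) {
    raster <- array(rep(raster, 3L), c(dim(raster)[1:2], 3L))
  }
  if (!is.numeric(magnification) || length(magnification) != 1L ||
      is.na(magnification) || magnification <= 0) {
    ss_validation_error("scan magnification must be a positive number")
  }
  structure(
    list(
      width_px = raster_width(raster),
      height_px = raster_height(raster),
      scan_magnification = as.numeric(magnification),
      source_path = path,
      reader_id = reader_id,
      raster = raster
    ),
    class = "slide_image"
  )
}

#' Open a slide image
#'
#' Locates a registered reader by file signature (falling back to the
#' extension), decodes the full-resolution raster and returns a slide
#' handle. The scan magnification comes from container metadata when the
#' reader reports one, otherwise from `default_magnification` (mirroring
#' scanners whose tags are unavailable outside their own SDK).
#'
#' @param path Path to a TIFF or PNG slide (or any format with a
#'   registered reader).
#' @param default_magnification Assumed objective-equivalent scan
#'   magnification when the container has no tag (default 40, i.e. a
#'   "400x" scan).
#' @return A `slide_image`: list with `width_px`, `height_px`,
#'   `scan_magnification`, `source_path`, `reader_id` and the decoded
#'   raster.
#' @examples
#' f <- tempfile(fileext = ".png")
#' png::writePNG(array(runif(48), c(4, 4, 3)), f)
#' sl <- open_slide(f)
#' sl$width_px
#' @export
open_slide <- function(path, default_magnification = 40) {
  if (!file.exists(path)) ss_open_error(sprintf("no such file: %s", path))
  reader <- find_reader(path)
  if (is.null(reader)) {
    ss_open_error(sprintf("no registered reader matches '%s'", path))
  }
  decoded <- tryCatch(
    reader$open(path),
    error = function(e) ss_open_error(sprintf("failed to open '%s': %s",
                                              path, conditionMessage(e)))
  )
  mag <- decoded$magnification
  if (is.null(mag) || is.na(mag)) mag <- default_magnification
  new_slide_image(decoded$raster, mag, path, reader$id)
}

#' Wrap an in-memory raster as a slide
#'
#' Useful for synthetic slides and tests; the handle behaves exactly like
#' one returned by [open_slide()].
#'
#' @param raster Numeric raster (0..255), grayscale or RGB.
#' @param magnification Scan magnification (default 40).
#' @param path Nominal source path recorded on the handle.
#' @return A `slide_image`.
#' @export
slide_from_raster <- function(raster, magnification = 40, path = NA_character_) {
  new_slide_image(raster, magnification, path, "memory")
}

#' @export
print.slide_image <- function(x, ...) {
  cat(sprintf("<slide_image> %d x %d px, scan magnification %gx, reader '%s'\n",
              x$width_px, x$height_px, x$scan_magnification, x$reader_id))
  if (!is.na(x$source_path)) cat("  source:", x$source_path, "\n")
  invisible(x)
}

#' Describe a region of a slide at a target magnification
#'
#' Coordinates are full-resolution pixels, 0-based, top-left origin; the
#' box `[x0, x0+width) x [y0, y0+height)` is half-open. Requesting
#' `magnification` below the scan magnification downsamples the crop by
#' `d = scan_magnification / magnification`.
#'
#' @param x0,y0 Top-left offset in full-resolution pixels.
#' @param width,height Box size in full-resolution pixels.
#' @param magnification Target magnification; `NA` means the scan
#'   magnification (no downsampling).
#' @return A `region_request`.
#' @export
region_request <- function(x0, y0, width, height, magnification = NA_real_) {
  if (width < 1 || height < 1) ss_validation_error("region width/height must be >= 1")
  if (x0 < 0 || y0 < 0) ss_validation_error("region origin must be non-negative")
  if (!is.na(magnification) && magnification <= 0) {
    ss_validation_error("magnification must be positive")
  }
  structure(
    list(x0 = as.integer(x0), y0 = as.integer(y0),
         width = as.integer(width), height = as.integer(height),
         magnification = magnification),
    class = "region_request"
  )
}

#' Extract a region of a slide
#'
#' Crops the requested full-resolution box and, when the requested
#' magnification is below the scan magnification, resamples it by the
#' downsample factor `d = scan_magnification / magnification` to
#' `round(width/d) x round(height/d)` pixels. With `method = "auto"`
#' (the recorded default) area (box) resampling is used for `d >= 2` and
#' bilinear for `1 < d < 2`; `d = 1` returns the crop untouched.
#' Requesting magnification above the scan (`d < 1`) is unsupported.
#'
#' @param slide A `slide_image`.
#' @param req A [region_request()].
#' @param method Resampling method: `"auto"`, `"area"` or `"bilinear"`.
#' @return Numeric RGB raster (0..255) of exactly the output dimensions.
#' @export
read_region <- function(slide, req, method = c("auto", "area", "bilinear")) {
  method <- match.arg(method)
  if (!inherits(slide, "slide_image")) ss_validation_error("'slide' must be a slide_image")
  if (!inherits(req, "region_request")) ss_validation_error("'req' must be a region_request")
  if (req$x0 + req$width > slide$width_px || req$y0 + req$height > slide$height_px) {
    ss_bounds_error(sprintf(
      "region [%d,%d)x[%d,%d) outside slide %dx%d",
      req$x0, req$x0 + req$width, req$y0, req$y0 + req$height,
      slide$width_px, slide$height_px
    ))
  }
  mag <- if (is.na(req$magnification)) slide$scan_magnification else req$magnification
  d <- slide$scan_magnification / mag
  if (d < 1 - 1e-9) {
    ss_abort(sprintf("magnification %g exceeds scan magnification %g (upsampling unsupported)",
                     mag, slide$scan_magnification), "slidesplit_upsample_error")
  }
  crop <- crop_raster(slide$raster, req$x0, req$y0, req$width, req$height)
  if (abs(d - 1) < 1e-9) return(crop)
  out_w <- max(1L, as.integer(round(req$width / d)))
  out_h <- max(1L, as.integer(round(req$height / d)))
  if (method == "auto") method <- if (d >= 2) "area" else "bilinear"
  resample_raster(crop, out_w, out_h, method)
}
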