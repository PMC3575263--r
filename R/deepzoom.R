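# Deep Zoom (DZI) pyramid generation: an XML descriptor plus a folder
# tree of fixed-size, slightly overlapping tiles per power-of-two level,
# the on-disk contract consumed by OpenSeadragon-style web viewers.
# Level max_level is the source raster; each level below halves the
# dimensions with ceiling rounding, down to 1x1 at level 0.

DZI_NS <- "http://schemas.microsoft.com/deepzoom/2008"

#' Compute a Deep Zoom pyramid descriptor
#'
#' `max_level = ceil(log2(max(width, height)))`; level `max_level` has
#' the source dimensions and `dims(l) = ceil(dims(l + 1) / 2)` down to
#' `1 x 1` at level 0.
#'
#' @param width,height Source raster dimensions in pixels.
#' @param tile_size Tile size in pixels (default 254, the Deep Zoom
#'   convention, so that with 1 px overlap interior tiles are 256x256).
#' @param overlap Tile overlap in pixels (default 1).
#' @param format Tile encoding, `"jpg"` or `"png"`.
#' @param jpeg_quality Quality for JPEG tiles (default 85).
#' @return A `pyramid_descriptor`: list with `width`, `height`,
#'   `tile_size`, `overlap`, `format`, `jpeg_quality`, `max_level` and
#'   `level_dims` (a `(max_level + 1) x 2` matrix, row `l + 1` holding
#'   `c(width, height)` of level `l`).
#' @examples
#' compute_pyramid(1000, 800)$max_level  # 10
#' @export
compute_pyramid <- function(width, height, tile_size = 254L, overlap = 1L,
                            format = c("jpg", "png"), jpeg_quality = 85L) {
  format <- match.arg(format)
  if (width < 1 || height < 1) ss_validation_error("dimensions must be >= 1")
  if (tile_size < 1) ss_validation_error("tile_size must be >= 1")
  if (overlap < 0 || overlap >= tile_size) {
    ss_validation_error("overlap must be in [0, tile_size)")
  }
  width <- as.integer(width); height <- as.integer(height)
  max_level <- as.integer(ceiling(log2(max(width, height))))
  if (max_level < 0) max_level <- 0L
  dims <- matrix(0L, nrow = max_level + 1L, ncol = 2L,
                 dimnames = list(NULL, c("width", "height")))
  w <- width; h <- height
  for (l in max_level:0) {
    dims[l + 1L, ] <- c(w, h)
    w <- as.integer(ceiling(w / 2))
    h <- as.integer(ceiling(h / 2))
  }
  structure(
    list(width = width, height = height, tile_size = as.integer(tile_size),
         overlap = as.integer(overlap), format = format,
         jpeg_quality = as.integer(jpeg_quality),
         max_level = max_level, level_dims = dims),
    class = "pyramid_descriptor"
  )
}

#' @export
print.pyramid_descriptor <- function(x, ...) {
  cat(sprintf("<pyramid_descriptor> %dx%d, %d levels (0..%d), tiles %d+%dpx %s\n",
              x$width, x$height, x$max_level + 1L, x$max_level,
              x$tile_size, x$overlap, x$format))
  invisible(x)
}

#' Tiles per level of a pyramid
#'
#' @param desc A `pyramid_descriptor`.
#' @return Data frame with `level`, `cols`, `rows`, `n_tiles`.
#' @export
pyramid_tile_counts <- function(desc) {
  dims <- desc$level_dims
  cols <- as.integer(ceiling(dims[, "width"] / desc$tile_size))
  rows <- as.integer(ceiling(dims[, "height"] / desc$tile_size))
  data.frame(level = 0:desc$max_level, cols = cols, rows = rows,
             n_tiles = cols * rows)
}

#' Address one tile of a pyramid level
#'
#' @param level Pyramid level, 0..`max_level`.
#' @param col,row 0-based tile indices within the level.
#' @return A `tile_address`.
#' @export
tile_address <- function(level, col, row) {
  structure(list(level = as.integer(level), col = as.integer(col),
                 row = as.integer(row)), class = "tile_address")
}

validate_address <- function(desc, addr) {
  if (addr$level < 0 || addr$level > desc$max_level) {
    ss_bounds_error(sprintf("level %d outside 0..%d", addr$level, desc$max_level))
  }
  dims <- desc$level_dims[addr$level + 1L, ]
  ncol_ <- ceiling(dims["width"] / desc$tile_size)
  nrow_ <- ceiling(dims["height"] / desc$tile_size)
  if (addr$col < 0 || addr$col >= ncol_ || addr$row < 0 || addr$row >= nrow_) {
    ss_bounds_error(sprintf("tile (%d, %d) outside level %d grid %dx%d",
                            addr$col, addr$row, addr$level, ncol_, nrow_))
  }
  invisible(TRUE)
}

# Successive ceil-halving from the source with area resampling, rounding
# to 8-bit integers at every level so written tiles and level rasters
# agree bit-for-bit.
level_raster <- function(image, desc, level) {
  image <- round(as_raster(image))
  if (raster_width(image) != desc$width || raster_height(image) != desc$height) {
    ss_validation_error("image dimensions do not match the descriptor")
  }
  for (l in desc$max_level:0) {
    if (l == level) break
    target <- desc$level_dims[l, ] # dims of level l - 1
    image <- round(resample_raster(image, target["width"], target["height"], "area"))
  }
  image
}

tile_box <- function(desc, addr, level_w, level_h) {
  ts <- desc$tile_size; ov <- desc$overlap
  x0 <- max(0L, addr$col * ts - ov)
  y0 <- max(0L, addr$row * ts - ov)
  x1 <- min(level_w, (addr$col + 1L) * ts + ov)
  y1 <- min(level_h, (addr$row + 1L) * ts + ov)
  c(x0 = x0, y0 = y0, x1 = x1, y1 = y1)
}

#' Render one Deep Zoom tile
#'
#' The tile covers `[col * tile_size - overlap, (col + 1) * tile_size +
#' overlap)` intersected with the level bounds (same for rows), cropped
#' from the level raster (the source successively ceil-halved down to
#' the level's dimensions). Interior tiles are therefore
#' `(tile_size + 2 * overlap)` pixels square.
#'
#' @param image Source raster (0..255) with the descriptor's dimensions.
#' @param desc A [compute_pyramid()] descriptor.
#' @param addr A [tile_address()].
#' @return Numeric raster (0..255).
#' @export
render_tile <- function(image, desc, addr) {
  validate_address(desc, addr)
  dims <- desc$level_dims[addr$level + 1L, ]
  lev <- level_raster(image, desc, addr$level)
  box <- tile_box(desc, addr, dims["width"], dims["height"])
  crop_raster(lev, box["x0"], box["y0"], box["x1"] - box["x0"], box["y1"] - box["y0"])
}

#' Write a Deep Zoom pyramid to disk
#'
#' Writes `<name>.dzi` (XML descriptor in the Deep Zoom namespace) and a
#' `<name>_files/<level>/<col>_<row>.<format>` tile tree under
#' `out_dir`. Existing output for the same name is overwritten, making
#' re-publishing idempotent.
#'
#' @param image Source raster (0..255), RGB or grayscale.
#' @param name Basename for the descriptor and tile folder.
#' @param out_dir Output directory (created if absent).
#' @param desc Optional [compute_pyramid()] descriptor; computed from the
#'   image at defaults when `NULL`.
#' @return List with `descriptor` (path to the `.dzi`), `tiles_root` and
#'   `n_tiles` (total tile files written).
#' @export
write_pyramid <- function(image, name, out_dir, desc = NULL) {
  image <- round(as_raster(image))
  if (is.null(desc)) {
    desc <- compute_pyramid(raster_width(image), raster_height(image))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) ss_io_error(sprintf("cannot create '%s'", out_dir))
  files_root <- file.path(out_dir, paste0(name, "_files"))
  unlink(files_root, recursive = TRUE)
  dir.create(files_root, showWarnings = FALSE)

  n_tiles <- 0L
  lev <- level_raster(image, desc, desc$max_level)
  for (l in desc$max_level:0) {
    dims <- desc$level_dims[l + 1L, ]
    if (raster_width(lev) != dims["width"] || raster_height(lev) != dims["height"]) {
      lev <- round(resample_raster(lev, dims["width"], dims["height"], "area"))
    }
    level_dir <- file.path(files_root, l)
    dir.create(level_dir, showWarnings = FALSE)
    ncol_ <- ceiling(dims["width"] / desc$tile_size)
    nrow_ <- ceiling(dims["height"] / desc$tile_size)
    for (row in seq_len(nrow_) - 1L) {
      for (col in seq_len(ncol_) - 1L) {
        box <- tile_box(desc, tile_address(l, col, row), dims["width"], dims["height"])
        tile <- crop_raster(lev, box["x0"], box["y0"],
                            box["x1"] - box["x0"], box["y1"] - box["y0"])
        path <- file.path(level_dir, sprintf("%d_%d.%s", col, row, desc$format))
        ok <- tryCatch({
          if (desc$format == "jpg") {
            writeBin(as.raw(encode_raster_jpeg(tile, desc$jpeg_quality)), path)
          } else {
            write_raster_png(tile, path)
          }
          TRUE
        }, error = function(e) FALSE)
        if (!ok) {
          ss_io_error(sprintf("failed writing tile %d/%d_%d (%d tiles written before abort)",
                              l, col, row, n_tiles))
        }
        n_tiles <- n_tiles + 1L
      }
    }
  }
  dzi_path <- file.path(out_dir, paste0(name, ".dzi"))
  write_dzi(desc, dzi_path)
  list(descriptor = dzi_path, tiles_root = files_root, n_tiles = n_tiles)
}

write_dzi <- function(desc, path) {
  doc <- xml2::xml_new_root(
    "Image",
    TileSize = as.character(desc$tile_size),
    Overlap = as.character(desc$overlap),
    Format = desc$format,
    xmlns = DZI_NS
  )
  xml2::xml_add_child(doc, "Size",
                      Width = as.character(desc$width),
                      Height = as.character(desc$height))
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a Deep Zoom descriptor
#'
#' Parses a `.dzi` XML file back into a `pyramid_descriptor`
#' (round-tripping [write_pyramid()] output).
#'
#' @param path Path to a `.dzi` file.
#' @return A `pyramid_descriptor`.
#' @export
read_dzi <- function(path) {
  doc <- xml2::read_xml(path)
  size <- xml2::xml_find_first(doc, ".//*[local-name() = 'Size']")
  if (inherits(size, "xml_missing")) ss_validation_error("no Size element in DZI")
  compute_pyramid(
    width = as.integer(xml2::xml_attr(size, "Width")),
    height = as.integer(xml2::xml_attr(size, "Height")),
    tile_size = as.integer(xml2::xml_attr(doc, "TileSize")),
    overlap = as.integer(xml2::xml_attr(doc, "Overlap")),
    format = xml2::xml_attr(doc, "Format")
  )
}
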