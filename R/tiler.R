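# Grid splitting: cut a slide into fixed-size tiles at a chosen output
# magnification, name them spreadsheet-style by grid position, write TIFF
# tiles, route empties to a subdirectory and log every verdict.

#' Spreadsheet-style tile name
#'
#' Rows map to bijective base-26 letters (A..Z, AA, AB, ...), columns to
#' 1-based numbers, concatenated: the first row of tiles is A1, A2, A3,
#' ...; the 28th row, second column is AB2.
#'
#' @param row,col 0-based grid indices (vectorised).
#' @return Character vector of names.
#' @seealso [parse_tile_name()]
#' @export
tile_name <- function(row, col) {
  if (any(row < 0) || any(col < 0)) ss_validation_error("row and col must be >= 0")
  letters_for <- function(n) { # n is 1-based; bijective base 26
    out <- ""
    while (n > 0) {
      r <- (n - 1L) %% 26L
      out <- paste0(LETTERS[r + 1L], out)
      n <- (n - 1L) %/% 26L
    }
    out
  }
  paste0(vapply(as.integer(row) + 1L, letters_for, character(1)),
         as.integer(col) + 1L)
}

#' Parse a tile name back to grid indices
#'
#' Inverse of [tile_name()].
#'
#' @param name Character vector of names such as `"A1"` or `"AB2"`.
#' @return Integer matrix with columns `row` and `col` (0-based).
#' @export
parse_tile_name <- function(name) {
  m <- regexec("^([A-Z]+)([0-9]+)$", name)
  parts <- regmatches(name, m)
  bad <- vapply(parts, length, integer(1)) != 3L
  if (any(bad)) ss_validation_error(sprintf("not a tile name: '%s'", name[bad][1]))
  row <- vapply(parts, function(p) {
    chars <- strsplit(p[2], "")[[1]]
    n <- 0
    for (ch in chars) n <- n * 26L + match(ch, LETTERS)
    as.integer(n - 1L)
  }, integer(1))
  col <- vapply(parts, function(p) as.integer(p[3]) - 1L, integer(1))
  cbind(row = row, col = col)
}

#' Compute the tile grid of a slide
#'
#' The slide is first (conceptually) brought to the requested
#' magnification -- level dimensions are the slide dimensions divided by
#' the downsample factor, rounded -- and the level raster is then covered
#' by `ceil(level_width / tile_width)` columns and
#' `ceil(level_height / tile_height)` rows of half-open boxes. Tile
#' dimensions are interpreted at the output magnification. Last-row and
#' last-column tiles are truncated (never padded), so the tiles form an
#' exact partition of the level raster.
#'
#' @param slide A `slide_image`.
#' @param tile_width,tile_height Tile size in pixels at the output
#'   magnification.
#' @param magnification Output magnification; `NA` (default) means the
#'   scan magnification.
#' @return A `tile_grid`: list with `level_width`, `level_height`,
#'   `tile_width`, `tile_height`, `magnification`, `n_rows`, `n_cols` and
#'   a row-major data frame `tiles` (`row`, `col`, `name`, `x0`, `y0`,
#'   `x1`, `y1`, `is_edge`).
#' @examples
#' sl <- slide_from_raster(array(255, c(600, 600, 3)))
#' compute_grid(sl, 300, 300)$tiles$name  # A1 A2 B1 B2
#' @export
compute_grid <- function(slide, tile_width, tile_height, magnification = NA_real_) {
  if (!inherits(slide, "slide_image")) ss_validation_error("'slide' must be a slide_image")
  if (tile_width < 1 || tile_height < 1) {
    ss_validation_error("tile dimensions must be >= 1")
  }
  mag <- if (is.na(magnification)) slide$scan_magnification else magnification
  if (mag <= 0 || mag > slide$scan_magnification + 1e-9) {
    ss_validation_error("magnification must be in (0, scan_magnification]")
  }
  d <- slide$scan_magnification / mag
  level_w <- max(1L, as.integer(round(slide$width_px / d)))
  level_h <- max(1L, as.integer(round(slide$height_px / d)))
  tile_width <- as.integer(tile_width)
  tile_height <- as.integer(tile_height)
  n_cols <- as.integer(ceiling(level_w / tile_width))
  n_rows <- as.integer(ceiling(level_h / tile_height))
  rows <- rep(seq_len(n_rows) - 1L, each = n_cols)
  cols <- rep(seq_len(n_cols) - 1L, times = n_rows)
  x0 <- cols * tile_width
  y0 <- rows * tile_height
  x1 <- pmin(x0 + tile_width, level_w)
  y1 <- pmin(y0 + tile_height, level_h)
  tiles <- data.frame(
    row = rows, col = cols, name = tile_name(rows, cols),
    x0 = x0, y0 = y0, x1 = x1, y1 = y1,
    is_edge = (x1 - x0 < tile_width) | (y1 - y0 < tile_height),
    stringsAsFactors = FALSE
  )
  structure(
    list(level_width = level_w, level_height = level_h,
         tile_width = tile_width, tile_height = tile_height,
         magnification = mag, n_rows = n_rows, n_cols = n_cols,
         tiles = tiles),
    class = "tile_grid"
  )
}

#' @export
print.tile_grid <- function(x, ...) {
  cat(sprintf("<tile_grid> %d x %d tiles of %dx%d px over a %dx%d level at %gx\n",
              x$n_rows, x$n_cols, x$tile_width, x$tile_height,
              x$level_width, x$level_height, x$magnification))
  invisible(x)
}

slide_stem <- function(slide) {
  if (is.na(slide$source_path)) "slide" else
    tools::file_path_sans_ext(basename(slide$source_path))
}

log_line <- function(report) {
  fmt <- function(v) paste(sprintf("%s=%.6g", names(v), v), collapse = ";")
  paste(report$tile_name, report$algorithm, fmt(report$scores),
        fmt(report$thresholds), if (report$is_empty) "empty" else "kept",
        sep = "\t")
}

#' Split a slide into TIFF tiles
#'
#' Extracts the level raster at the grid's magnification, writes each
#' tile as `<name>.tif` into a per-slide directory, and -- when an empty
#' filter is active -- routes tiles classified as empty into an
#' `empty_tiles/` subdirectory instead of discarding them (they are
#' retained for review), writing one tab-separated `log.txt` line per
#' grid cell (`name`, `algorithm`, `scores`, `thresholds`, `verdict`) so
#' thresholds can be tuned from the log.
#'
#' @param slide A `slide_image`.
#' @param grid A [compute_grid()] result for that slide.
#' @param out_dir Output directory; a subdirectory named after the slide
#'   file stem is created inside it.
#' @param empty_filter `"none"` (default), `"intensity"` or
#'   `"compression"`.
#' @param thresholds Optional thresholds object matching the filter;
#'   defaults to [intensity_thresholds()] / [compression_thresholds()].
#' @return A `split_result`: list with `dir`, `written` (tile count in
#'   the root), `empty` (count under `empty_tiles/`), `log` (path or
#'   `NA`), `reports` (list of `emptiness_report`s or `NULL`) and
#'   `tile_paths` (named by tile).
#' @export
split_slide <- function(slide, grid, out_dir,
                        empty_filter = c("none", "intensity", "compression"),
                        thresholds = NULL) {
  if (!is.character(empty_filter) ||
      !all(empty_filter %in% c("none", "intensity", "compression"))) {
    ss_validation_error("empty_filter must be 'none', 'intensity' or 'compression'")
  }
  empty_filter <- match.arg(empty_filter)
  if (!inherits(grid, "tile_grid")) ss_validation_error("'grid' must be a tile_grid")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) ss_io_error(sprintf("cannot create '%s'", out_dir))
  slide_dir <- file.path(out_dir, slide_stem(slide))
  dir.create(slide_dir, showWarnings = FALSE)

  level <- read_region(slide, region_request(0, 0, slide$width_px, slide$height_px,
                                             grid$magnification))
  level <- round(level)
  if (raster_width(level) != grid$level_width ||
      raster_height(level) != grid$level_height) {
    ss_validation_error("grid does not match this slide at its magnification")
  }

  filtering <- empty_filter != "none"
  if (filtering && is.null(thresholds)) {
    thresholds <- switch(empty_filter, intensity = intensity_thresholds(),
                         compression = compression_thresholds())
  }
  if (filtering) dir.create(file.path(slide_dir, "empty_tiles"), showWarnings = FALSE)

  tiles <- grid$tiles
  reports <- if (filtering) vector("list", nrow(tiles)) else NULL
  log_lines <- character(0)
  written <- 0L
  empty <- 0L
  tile_paths <- character(nrow(tiles))
  for (i in seq_len(nrow(tiles))) {
    t <- tiles[i, ]
    raster <- crop_raster(level, t$x0, t$y0, t$x1 - t$x0, t$y1 - t$y0)
    dest <- file.path(slide_dir, paste0(t$name, ".tif"))
    if (filtering) {
      rep_i <- switch(empty_filter,
                      intensity = intensity_emptiness(raster, thresholds, t$name),
                      compression = compression_emptiness(raster, thresholds, t$name))
      reports[[i]] <- rep_i
      log_lines <- c(log_lines, log_line(rep_i))
      if (rep_i$is_empty) {
        dest <- file.path(slide_dir, "empty_tiles", paste0(t$name, ".tif"))
        empty <- empty + 1L
      } else {
        written <- written + 1L
      }
    } else {
      written <- written + 1L
    }
    ok <- tryCatch({ write_raster_tiff(raster, dest); TRUE },
                   error = function(e) FALSE)
    if (!ok) {
      ss_io_error(sprintf(
        "failed writing tile '%s' (%d of %d written before abort)",
        t$name, written + empty - 1L, nrow(tiles)))
    }
    tile_paths[i] <- dest
  }
  log_path <- NA_character_
  if (filtering) {
    log_path <- file.path(slide_dir, "log.txt")
    writeLines(log_lines, log_path)
  }
  names(tile_paths) <- tiles$name
  structure(
    list(dir = slide_dir, written = written, empty = empty,
         log = log_path, reports = reports, tile_paths = tile_paths),
    class = "split_result"
  )
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("<split_result> %s: %d tiles written, %d empty%s\n",
              x$dir, x$written, x$empty,
              if (!is.na(x$log)) sprintf(" (log: %s)", x$log) else ""))
  invisible(x)
}
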