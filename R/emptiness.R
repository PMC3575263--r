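# Empty-tile detection: decide whether a tile carries pathology content
# or only scanner background. Two algorithms, each suited to one imaging
# modality:
#
#  * intensity: fluorescent slides -- background is near-black, so a tile
#    is empty when its mean intensity is low AND too few pixels are lit.
#  * compression: brightfield slides -- background is near-white and
#    hence extremely JPEG-compressible, so a tile is empty when a probe
#    JPEG encoding shrinks it below a ratio threshold.
#
# Neither criterion is perfect on real tissue; verdicts and the scores
# behind them are therefore logged so thresholds can be tuned, and empty
# tiles are retained for review rather than deleted.

#' Thresholds for the intensity emptiness algorithm
#'
#' @param avg_threshold Tile-mean intensity cutoff on the 0..255 scale: a
#'   tile whose mean reaches this is considered lit overall.
#' @param whiteness_threshold Per-pixel cutoff on 0..255: a pixel at or
#'   above it counts as "lit".
#' @param min_lit_fraction Fraction of lit pixels (0..1) that by itself
#'   makes a tile interesting.
#' @return An `intensity_thresholds` object.
#' @export
intensity_thresholds <- function(avg_threshold = 10, whiteness_threshold = 30,
                                 min_lit_fraction = 0.01) {
  if (avg_threshold < 0 || avg_threshold > 255) {
    ss_validation_error("avg_threshold must be in [0, 255]")
  }
  if (whiteness_threshold < 0 || whiteness_threshold > 255) {
    ss_validation_error("whiteness_threshold must be in [0, 255]")
  }
  if (min_lit_fraction < 0 || min_lit_fraction > 1) {
    ss_validation_error("min_lit_fraction must be in [0, 1]")
  }
  structure(list(avg_threshold = avg_threshold,
                 whiteness_threshold = whiteness_threshold,
                 min_lit_fraction = min_lit_fraction),
            class = "intensity_thresholds")
}

#' Thresholds for the compression emptiness algorithm
#'
#' @param probe_quality JPEG quality (1..100) of the in-memory probe
#'   encoding; the written tile is unaffected.
#' @param ratio_threshold Cutoff in (0, 1) on the overhead-corrected
#'   compressed-bytes / raw-bytes ratio; below it the tile is classified
#'   empty.
#' @return A `compression_thresholds` object.
#' @export
compression_thresholds <- function(probe_quality = 75, ratio_threshold = 0.02) {
  if (probe_quality < 1 || probe_quality > 100) {
    ss_validation_error("probe_quality must be in [1, 100]")
  }
  if (ratio_threshold <= 0 || ratio_threshold >= 1) {
    ss_validation_error("ratio_threshold must be in (0, 1)")
  }
  structure(list(probe_quality = probe_quality,
                 ratio_threshold = ratio_threshold),
            class = "compression_thresholds")
}

new_emptiness_report <- function(tile_name, algorithm, scores, thresholds, is_empty) {
  structure(list(tile_name = tile_name, algorithm = algorithm,
                 scores = scores, thresholds = thresholds,
                 is_empty = is_empty),
            class = "emptiness_report")
}

#' @export
print.emptiness_report <- function(x, ...) {
  cat(sprintf("<emptiness_report> %s [%s]: %s (%s)\n",
              if (is.na(x$tile_name)) "tile" else x$tile_name, x$algorithm,
              if (x$is_empty) "EMPTY" else "content",
              paste(sprintf("%s=%.4g", names(x$scores), x$scores), collapse = ", ")))
  invisible(x)
}

tile_intensity <- function(tile) {
  tile <- as_raster(tile)
  nc <- raster_channels(tile)
  if (nc == 1L) return(tile[, , 1L])
  # unweighted channel mean; the target background is near-black
  # fluorescent scans, where luma weighting buys nothing
  apply(tile[, , seq_len(min(nc, 3L)), drop = FALSE], c(1, 2), mean)
}

#' Intensity-based emptiness (fluorescent slides)
#'
#' Per-pixel intensity is the unweighted channel mean on the 0..255
#' scale. A tile is *empty* when its mean intensity falls below
#' `avg_threshold` **and** the fraction of pixels at or above
#' `whiteness_threshold` falls below `min_lit_fraction`; meeting either
#' criterion (a lit average, or sufficiently many lit pixels) marks the
#' tile as carrying content.
#'
#' @param tile RGB or grayscale raster (0..255), at least one pixel.
#' @param thresholds An [intensity_thresholds()] object.
#' @param tile_name Optional name recorded in the report.
#' @return An `emptiness_report` with scores `mean_intensity` and
#'   `lit_fraction`.
#' @examples
#' t <- intensity_thresholds()
#' intensity_emptiness(array(0, c(8, 8, 3)), t)$is_empty    # black -> empty
#' intensity_emptiness(array(255, c(8, 8, 3)), t)$is_empty  # lit -> content
#' @export
intensity_emptiness <- function(tile, thresholds = intensity_thresholds(),
                                tile_name = NA_character_) {
  if (!inherits(thresholds, "intensity_thresholds")) {
    ss_validation_error("'thresholds' must come from intensity_thresholds()")
  }
  inten <- tile_intensity(tile)
  if (length(inten) == 0) ss_validation_error("tile has no pixels")
  mean_intensity <- mean(inten)
  lit_fraction <- mean(inten >= thresholds$whiteness_threshold)
  is_empty <- mean_intensity < thresholds$avg_threshold &&
    lit_fraction < thresholds$min_lit_fraction
  new_emptiness_report(
    tile_name, "intensity",
    scores = c(mean_intensity = mean_intensity, lit_fraction = lit_fraction),
    thresholds = c(avg_threshold = thresholds$avg_threshold,
                   whiteness_threshold = thresholds$whiteness_threshold,
                   min_lit_fraction = thresholds$min_lit_fraction),
    is_empty = is_empty
  )
}

# The JPEG stream carries a fixed header (quantisation + Huffman tables,
# markers) independent of image content. Subtracting it makes the
# compressed/raw ratio comparable across tile sizes; without the
# correction, small edge tiles are dominated by header bytes and a blank
# strip can score above any sensible cutoff. Estimated once per quality
# by encoding a tiny uniform probe image.
.jpeg_overhead_cache <- new.env(parent = emptyenv())

jpeg_overhead_bytes <- function(quality) {
  key <- as.character(quality)
  if (!is.null(.jpeg_overhead_cache[[key]])) return(.jpeg_overhead_cache[[key]])
  probe <- jpeg::writeJPEG(array(1, c(16, 16, 3)), raw(), quality = quality / 100)
  .jpeg_overhead_cache[[key]] <- length(probe)
  length(probe)
}

#' Compression-based emptiness (brightfield slides)
#'
#' Encodes the tile as an in-memory JPEG at `probe_quality` and computes
#' `compression_ratio = max(0, encoded_bytes - overhead) / (width x
#' height x channels)`, where `overhead` is the encoder's fixed
#' header cost at that quality (so the score is tile-size independent).
#' A highly compressible tile is mostly uniform background: the tile is
#' classified empty when the ratio falls below `ratio_threshold`.
#'
#' @param tile RGB or grayscale raster (0..255), at least one pixel.
#' @param thresholds A [compression_thresholds()] object.
#' @param tile_name Optional name recorded in the report.
#' @return An `emptiness_report` with scores `compression_ratio` and
#'   `encoded_bytes`.
#' @export
compression_emptiness <- function(tile, thresholds = compression_thresholds(),
                                  tile_name = NA_character_) {
  if (!inherits(thresholds, "compression_thresholds")) {
    ss_validation_error("'thresholds' must come from compression_thresholds()")
  }
  tile <- as_raster(tile)
  if (length(tile) == 0) ss_validation_error("tile has no pixels")
  bytes <- tryCatch(
    length(encode_raster_jpeg(tile, thresholds$probe_quality)),
    error = function(e) ss_abort(sprintf("JPEG probe encoding failed: %s",
                                         conditionMessage(e)),
                                 "slidesplit_encode_error")
  )
  raw_bytes <- prod(dim(tile))
  ratio <- max(0, bytes - jpeg_overhead_bytes(thresholds$probe_quality)) / raw_bytes
  new_emptiness_report(
    tile_name, "compression",
    scores = c(compression_ratio = ratio, encoded_bytes = bytes),
    thresholds = c(probe_quality = thresholds$probe_quality,
                   ratio_threshold = thresholds$ratio_threshold),
    is_empty = ratio < thresholds$ratio_threshold
  )
}

#' Classify a batch of tiles
#'
#' Applies one emptiness algorithm to each tile independently, preserving
#' order.
#'
#' @param tiles List of rasters.
#' @param algorithm `"intensity"` or `"compression"`.
#' @param thresholds Matching thresholds object; defaults per algorithm.
#' @param names Optional character vector of tile names.
#' @return List of `emptiness_report`s, one per tile.
#' @seealso [reports_as_data_frame()]
#' @export
classify_tiles <- function(tiles, algorithm = c("intensity", "compression"),
                           thresholds = NULL, names = NULL) {
  if (!is.character(algorithm) || !all(algorithm %in% c("intensity", "compression"))) {
    ss_validation_error("algorithm must be 'intensity' or 'compression'")
  }
  algorithm <- match.arg(algorithm)
  if (is.null(thresholds)) {
    thresholds <- switch(algorithm,
                         intensity = intensity_thresholds(),
                         compression = compression_thresholds())
  }
  if (is.null(names)) names <- rep(NA_character_, length(tiles))
  if (length(names) != length(tiles)) {
    ss_validation_error("'names' must match 'tiles' in length")
  }
  fun <- switch(algorithm, intensity = intensity_emptiness,
                compression = compression_emptiness)
  Map(function(tile, nm) fun(tile, thresholds, nm), tiles, names)
}

#' Flatten emptiness reports into a data frame
#'
#' @param reports List of `emptiness_report`s.
#' @return Data frame with one row per report: `tile_name`, `algorithm`,
#'   one column per score, and `is_empty`.
#' @export
reports_as_data_frame <- function(reports) {
  if (length(reports) == 0) {
    return(data.frame(tile_name = character(0), algorithm = character(0),
                      is_empty = logical(0), stringsAsFactors = FALSE))
  }
  score_names <- unique(unlist(lapply(reports, function(r) names(r$scores))))
  rows <- lapply(reports, function(r) {
    row <- data.frame(tile_name = r$tile_name, algorithm = r$algorithm,
                      stringsAsFactors = FALSE)
    for (s in score_names) row[[s]] <- unname(r$scores[s])
    row$is_empty <- r$is_empty
    row
  })
  do.call(rbind, rows)
}
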