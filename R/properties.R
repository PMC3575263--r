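# Java-style .properties files (key=value lines, '#' comments) hold the
# runtime defaults of both tools: "NDPIsplitter.properties" for the
# splitter and "snapshot-creator.properties" for the snapshot workflow.

#' Read a key=value properties file
#'
#' Parses a Java-style properties file: one `key=value` pair per line,
#' blank lines and lines starting with `#` or `!` ignored, whitespace
#' around keys and values trimmed. Later duplicates win.
#'
#' @param path Path to the properties file.
#' @return Named character vector of raw key/value pairs.
#' @seealso [splitter_defaults()], [snapshot_config()]
#' @export
read_properties <- function(path) {
  if (!file.exists(path)) ss_io_error(sprintf("properties file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^[#!]", lines)]
  eq <- regexpr("=", lines, fixed = TRUE)
  bad <- eq < 0
  if (any(bad)) {
    ss_validation_error(sprintf("malformed properties line: '%s'", lines[bad][1]))
  }
  keys <- trimws(substr(lines, 1L, eq - 1L))
  vals <- trimws(substr(lines, eq + 1L, nchar(lines)))
  res <- character(0)
  for (i in seq_along(keys)) res[keys[i]] <- vals[i]
  res
}

prop_num <- function(props, key, default) {
  if (!key %in% names(props)) return(default)
  v <- suppressWarnings(as.numeric(props[[key]]))
  if (is.na(v)) ss_validation_error(sprintf("property '%s' is not numeric: '%s'", key, props[[key]]))
  v
}

prop_chr <- function(props, key, default) {
  if (!key %in% names(props)) default else props[[key]]
}

#' Splitter defaults from NDPIsplitter.properties
#'
#' Reads the splitter's configurable defaults: tile geometry, output
#' magnification, which empty-tile filter to apply and the thresholds of
#' both emptiness algorithms. Missing keys fall back to package defaults.
#'
#' Recognised keys: `tile.width`, `tile.height`, `magnification`,
#' `empty.filter` (`none`, `intensity` or `compression`),
#' `default.magnification` (assumed scan magnification for containers
#' without a magnification tag), `empty.intensity.avg`,
#' `empty.intensity.whiteness`, `empty.intensity.minfraction`,
#' `empty.compression.quality`, `empty.compression.ratio`.
#'
#' @param path Properties file; if missing/nonexistent, all defaults.
#' @return List with elements `tile_width`, `tile_height`, `magnification`
#'   (NA = split at scan magnification), `empty_filter`,
#'   `default_magnification`, `intensity` ([intensity_thresholds()]) and
#'   `compression` ([compression_thresholds()]).
#' @export
splitter_defaults <- function(path = "NDPIsplitter.properties") {
  props <- if (!is.null(path) && file.exists(path)) read_properties(path) else character(0)
  list(
    tile_width = as.integer(prop_num(props, "tile.width", 1024)),
    tile_height = as.integer(prop_num(props, "tile.height", 1024)),
    magnification = prop_num(props, "magnification", NA_real_),
    empty_filter = prop_chr(props, "empty.filter", "none"),
    default_magnification = prop_num(props, "default.magnification", 40),
    intensity = intensity_thresholds(
      avg_threshold = prop_num(props, "empty.intensity.avg", 10),
      whiteness_threshold = prop_num(props, "empty.intensity.whiteness", 30),
      min_lit_fraction = prop_num(props, "empty.intensity.minfraction", 0.01)
    ),
    compression = compression_thresholds(
      probe_quality = prop_num(props, "empty.compression.quality", 75),
      ratio_threshold = prop_num(props, "empty.compression.ratio", 0.02)
    )
  )
}

#' Snapshot/workflow configuration from snapshot-creator.properties
#'
#' Folder paths, record-store location, snapshot magnification and JPEG
#' quality for the batch workflow. Missing keys fall back to defaults
#' rooted at `root`.
#'
#' Recognised keys: `folder.root`, `folder.ndpi.new`,
#' `folder.ndpi.processed`, `folder.ndpi.failed`, `folder.jpeg.processing`,
#' `folder.jpeg.processed`, `folder.jpeg.failed`, `folder.publish`,
#' `store.path`, `snapshot.magnification`, `snapshot.quality`,
#' `watermark.path`, `default.magnification`.
#'
#' @param path Properties file; may be `NULL` for pure defaults.
#' @param root Fallback root directory for folder paths.
#' @return List with `layout` ([folder_layout()]), `store_path`,
#'   `snapshot` ([snapshot_spec()]) and `default_magnification`.
#' @export
snapshot_config <- function(path = "snapshot-creator.properties", root = ".") {
  props <- if (!is.null(path) && file.exists(path)) read_properties(path) else character(0)
  root <- prop_chr(props, "folder.root", root)
  layout <- folder_layout(
    root,
    ndpi_new = prop_chr(props, "folder.ndpi.new", file.path(root, "NDPI-New")),
    ndpi_processed = prop_chr(props, "folder.ndpi.processed", file.path(root, "NDPI-Processed")),
    ndpi_failed = prop_chr(props, "folder.ndpi.failed", file.path(root, "NDPI-Failed")),
    jpeg_processing = prop_chr(props, "folder.jpeg.processing", file.path(root, "JPEG-Snapshot-Processing")),
    jpeg_processed = prop_chr(props, "folder.jpeg.processed", file.path(root, "JPEG-Processed")),
    jpeg_failed = prop_chr(props, "folder.jpeg.failed", file.path(root, "JPEG-Failed")),
    publish_root = prop_chr(props, "folder.publish", file.path(root, "publish"))
  )
  wm <- prop_chr(props, "watermark.path", NA_character_)
  list(
    layout = layout,
    store_path = prop_chr(props, "store.path", file.path(root, "specimens.tsv")),
    snapshot = snapshot_spec(
      magnification = prop_num(props, "snapshot.magnification", NA_real_),
      jpeg_quality = as.integer(prop_num(props, "snapshot.quality", 90)),
      watermark_path = if (is.na(wm)) NULL else wm
    ),
    default_magnification = prop_num(props, "default.magnification", 40)
  )
}
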