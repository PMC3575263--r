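# The nightly archiving pipeline as a folder state machine. Scans land
# in an inbox, are snapshotted and moved to a processed (or failed)
# folder; snapshots are linked to a specimen record store by filename,
# published as Deep Zoom pyramids, and routed to their own processed or
# failed folder, with a notification hook on link failures. Every file
# ends in exactly one terminal folder and a re-run of an already-settled
# batch changes nothing.

#' Folder layout of the batch workflow
#'
#' Seven distinct directories, created on construction if absent. A
#' `notifications.log` file under `root` records fired notifications.
#'
#' @param root Root directory; default subfolder names are created
#'   beneath it.
#' @param ndpi_new,ndpi_processed,ndpi_failed Slide inbox and terminal
#'   folders.
#' @param jpeg_processing,jpeg_processed,jpeg_failed Snapshot queue and
#'   terminal folders.
#' @param publish_root Deep Zoom publishing directory.
#' @return A `folder_layout`.
#' @export
folder_layout <- function(root,
                          ndpi_new = file.path(root, "NDPI-New"),
                          ndpi_processed = file.path(root, "NDPI-Processed"),
                          ndpi_failed = file.path(root, "NDPI-Failed"),
                          jpeg_processing = file.path(root, "JPEG-Snapshot-Processing"),
                          jpeg_processed = file.path(root, "JPEG-Processed"),
                          jpeg_failed = file.path(root, "JPEG-Failed"),
                          publish_root = file.path(root, "publish")) {
  dirs <- c(ndpi_new = ndpi_new, ndpi_processed = ndpi_processed,
            ndpi_failed = ndpi_failed, jpeg_processing = jpeg_processing,
            jpeg_processed = jpeg_processed, jpeg_failed = jpeg_failed,
            publish_root = publish_root)
  if (anyDuplicated(normalizePath(dirs, mustWork = FALSE))) {
    ss_validation_error("the seven workflow folders must be distinct")
  }
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  for (d in dirs) dir.create(d, recursive = TRUE, showWarnings = FALSE)
  structure(c(as.list(dirs), list(root = root,
                                  notifications_log = file.path(root, "notifications.log"))),
            class = "folder_layout")
}

#' File-backed specimen record store
#'
#' A single-file tab-separated store standing in for the biobank
#' database: one row per specimen, keyed by slide identifier, with the
#' path of the linked snapshot (or `NA`). Linking rewrites the file
#' atomically (temp file + rename), so a failed write leaves the store
#' unchanged.
#'
#' @param path Store file; created when it does not exist.
#' @param identifiers Identifiers to seed the store with (ignored when
#'   the file already exists).
#' @return A `specimen_store` handle.
#' @export
specimen_store <- function(path, identifiers = character(0)) {
  if (!file.exists(path)) {
    df <- data.frame(specimen_id = as.character(identifiers),
                     image_path = NA_character_,
                     stringsAsFactors = FALSE)
    store_write(path, df)
  }
  structure(list(path = path), class = "specimen_store")
}

store_read <- function(store) {
  path <- if (inherits(store, "specimen_store")) store$path else store
  if (!file.exists(path)) {
    ss_io_error(sprintf("specimen store unreachable: %s", path))
  }
  utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
}

store_write <- function(path, df) {
  tmp <- tempfile("store", tmpdir = dirname(path))
  utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  if (!file.rename(tmp, path)) {
    unlink(tmp)
    ss_io_error(sprintf("atomic store update failed: %s", path))
  }
  invisible(path)
}

#' Look up a specimen by slide identifier
#'
#' @param store A [specimen_store()].
#' @param identifier Slide identifier (the snapshot file stem).
#' @return The matching one-row data frame, or `NULL` when absent.
#' @export
store_lookup <- function(store, identifier) {
  df <- store_read(store)
  hit <- df[df$specimen_id == identifier, , drop = FALSE]
  if (nrow(hit) == 0) NULL else hit[1, , drop = FALSE]
}

#' Link a snapshot to its specimen record
#'
#' Sets the record's image field to `snapshot_path` when the identifier
#' matches; last write wins, and re-linking the same path is a no-op. On
#' no match the store is left byte-identical.
#'
#' @param store A [specimen_store()].
#' @param identifier Slide identifier; must be non-empty.
#' @param snapshot_path Path recorded on the specimen.
#' @return `"linked"` or `"not_found"`.
#' @export
link_specimen <- function(store, identifier, snapshot_path) {
  if (!is.character(identifier) || !nzchar(identifier)) {
    ss_validation_error("identifier must be a non-empty string")
  }
  df <- store_read(store)
  i <- which(df$specimen_id == identifier)
  if (length(i) == 0) return("not_found")
  if (identical(df$image_path[i[1]], as.character(snapshot_path))) {
    return("linked") # idempotent re-link, no rewrite
  }
  df$image_path[i[1]] <- as.character(snapshot_path)
  store_write(store$path, df)
  "linked"
}

default_notifier <- function(layout) {
  function(identifier, path) {
    line <- sprintf("%s\tlink-failed\t%s\t%s",
                    format(Sys.time(), "%Y-%m-%d %H:%M:%S"), identifier, path)
    cat(line, "\n", sep = "", file = layout$notifications_log, append = TRUE)
  }
}

move_file <- function(from, to_dir) {
  dest <- file.path(to_dir, basename(from))
  if (!file.rename(from, dest)) {
    if (!file.copy(from, dest, overwrite = TRUE)) {
      ss_io_error(sprintf("cannot move '%s' to '%s'", from, to_dir))
    }
    unlink(from)
  }
  dest
}

#' Run one batch of the archiving workflow
#'
#' Stage one: every file in `ndpi_new` is opened and snapshotted; the
#' JPEG (named after the slide's file stem, its identifier) goes into
#' `jpeg_processing` and the slide moves to `ndpi_processed`, or to
#' `ndpi_failed` if opening or rendering fails. Stage two: every JPEG in
#' `jpeg_processing` is looked up in the specimen store by its stem; on
#' a match the record is linked, a Deep Zoom pyramid is published under
#' `publish_root` and the JPEG moves to `jpeg_processed` (or is deleted
#' when `keep_processed_jpeg = FALSE`); on a miss it moves to
#' `jpeg_failed` and the notification hook fires. Per-file errors are
#' contained: one bad file never aborts the batch.
#'
#' @param layout A [folder_layout()].
#' @param store A [specimen_store()].
#' @param spec A [snapshot_spec()] used for stage one.
#' @param notify `function(identifier, path)` called on link failure;
#'   the default appends a line to `notifications.log` under the layout
#'   root.
#' @param default_magnification Scan magnification assumed for slides
#'   whose container carries no tag.
#' @param keep_processed_jpeg Keep processed snapshots (default) or
#'   delete them to save space.
#' @return A `processing_report` data frame: one row per ingested file
#'   with `file`, `stage` (`"slide"` or `"snapshot"`), `outcome`
#'   (`processed`, `open_failed` or `link_failed`), `destination` and
#'   `notified`.
#' @export
run_batch <- function(layout, store, spec = snapshot_spec(), notify = NULL,
                      default_magnification = 40, keep_processed_jpeg = TRUE) {
  if (!inherits(layout, "folder_layout")) ss_validation_error("'layout' must be a folder_layout")
  if (!inherits(store, "specimen_store")) ss_validation_error("'store' must be a specimen_store")
  if (is.null(notify)) notify <- default_notifier(layout)
  rows <- list()

  for (slide_path in list.files(layout$ndpi_new, full.names = TRUE)) {
    res <- tryCatch({
      slide <- open_slide(slide_path, default_magnification)
      write_snapshot(slide, layout$jpeg_processing, spec)
      "ok"
    }, error = function(e) conditionMessage(e))
    if (identical(res, "ok")) {
      dest <- move_file(slide_path, layout$ndpi_processed)
      outcome <- "processed"
    } else {
      dest <- move_file(slide_path, layout$ndpi_failed)
      outcome <- "open_failed"
    }
    rows[[length(rows) + 1L]] <- data.frame(
      file = basename(slide_path), stage = "slide", outcome = outcome,
      destination = dest, notified = FALSE, stringsAsFactors = FALSE)
  }

  for (jpeg_path in list.files(layout$jpeg_processing, pattern = "\\.jpe?g$",
                               ignore.case = TRUE, full.names = TRUE)) {
    id <- tools::file_path_sans_ext(basename(jpeg_path))
    notified <- FALSE
    res <- tryCatch({
      if (is.null(store_lookup(store, id))) {
        list(status = "not_found")
      } else {
        img <- raster_from_unit(jpeg::readJPEG(jpeg_path))
        pub <- write_pyramid(img, id, layout$publish_root)
        list(status = "ok", dzi = pub$descriptor)
      }
    }, error = function(e) list(status = paste("error:", conditionMessage(e))))
    if (identical(res$status, "ok")) {
      if (keep_processed_jpeg) {
        dest <- move_file(jpeg_path, layout$jpeg_processed)
        link_specimen(store, id, dest)
      } else {
        dest <- res$dzi # the record points at the published pyramid
        link_specimen(store, id, dest)
        unlink(jpeg_path)
      }
      outcome <- "processed"
    } else {
      dest <- move_file(jpeg_path, layout$jpeg_failed)
      outcome <- "link_failed"
      notify(id, dest)
      notified <- TRUE
    }
    rows[[length(rows) + 1L]] <- data.frame(
      file = basename(jpeg_path), stage = "snapshot", outcome = outcome,
      destination = dest, notified = notified, stringsAsFactors = FALSE)
  }

  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(file = character(0), stage = character(0),
               outcome = character(0), destination = character(0),
               notified = logical(0), stringsAsFactors = FALSE)
  class(report) <- c("processing_report", class(report))
  report
}

#' Queue a manually corrected snapshot for the next batch
#'
#' After a link failure caused by a wrong filename, the renamed JPEG is
#' put back into the processing queue. The file must decode as a JPEG;
#' queuing the same name twice simply overwrites (one processing per
#' identifier).
#'
#' @param layout A [folder_layout()].
#' @param path Path to the corrected JPEG.
#' @return Path of the queued file, invisibly.
#' @export
reprocess_corrected <- function(layout, path) {
  if (!file.exists(path)) ss_io_error(sprintf("no such file: %s", path))
  ok <- tryCatch({ jpeg::readJPEG(path); TRUE }, error = function(e) FALSE)
  if (!ok) ss_validation_error(sprintf("'%s' is not a decodable JPEG", path))
  dest <- file.path(layout$jpeg_processing, basename(path))
  if (!file.copy(path, dest, overwrite = TRUE)) {
    ss_io_error(sprintf("cannot queue '%s'", path))
  }
  invisible(dest)
}
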