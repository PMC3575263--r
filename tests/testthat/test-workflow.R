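# Folder state machine, specimen store and batch processing.

make_layout <- function() folder_layout(tempfile("wf"))

seed_slides <- function(layout, ids, corrupt = character(0), seed = 60) {
  for (i in seq_along(ids)) {
    fx <- generate_slide(256, 192, "brightfield", n_blobs = 1,
                         seed = seed + i, blob_size_range = c(100, 100))
    write_slide_fixture(fx, file.path(layout$ndpi_new, paste0(ids[i], ".tif")))
  }
  for (id in corrupt) {
    writeBin(as.raw(c(0x49, 0x49, 0x2a, 0x00, 1:20)),
             file.path(layout$ndpi_new, paste0(id, ".tif")))
  }
}

test_that("folder layout creates seven distinct folders", {
  layout <- make_layout()
  dirs <- unlist(layout[c("ndpi_new", "ndpi_processed", "ndpi_failed",
                          "jpeg_processing", "jpeg_processed", "jpeg_failed",
                          "publish_root")])
  expect_length(unique(dirs), 7)
  expect_true(all(dir.exists(dirs)))
  expect_error(folder_layout(tempfile(), ndpi_new = "x", ndpi_processed = "x"),
               class = "slidesplit_validation_error")
})

test_that("specimen linking is idempotent, atomic on miss and last-write-wins", {
  store <- specimen_store(tempfile(fileext = ".tsv"), c("S1", "S2"))
  expect_null(store_lookup(store, "NOPE"))
  expect_equal(store_lookup(store, "S1")$specimen_id, "S1")

  expect_equal(link_specimen(store, "S1", "a.jpg"), "linked")
  expect_equal(store_lookup(store, "S1")$image_path, "a.jpg")
  before <- readBin(store$path, "raw", file.info(store$path)$size)
  expect_equal(link_specimen(store, "S1", "a.jpg"), "linked") # no-op relink
  after <- readBin(store$path, "raw", file.info(store$path)$size)
  expect_identical(before, after)

  expect_equal(link_specimen(store, "MISSING", "b.jpg"), "not_found")
  expect_identical(readBin(store$path, "raw", file.info(store$path)$size), after)

  expect_equal(link_specimen(store, "S1", "b.jpg"), "linked")
  rec <- store_lookup(store, "S1")
  expect_equal(nrow(rec), 1)
  expect_equal(rec$image_path, "b.jpg")

  unreachable <- structure(list(path = tempfile()), class = "specimen_store")
  expect_error(link_specimen(unreachable, "S1", "c.jpg"),
               class = "slidesplit_io_error")
  expect_error(link_specimen(store, "", "c.jpg"),
               class = "slidesplit_validation_error")
})

test_that("a mixed batch routes every file to exactly one terminal folder", {
  layout <- make_layout()
  good <- paste0("S", 1:5)
  seed_slides(layout, c(good, "NOSUCHID"), corrupt = c("BAD1", "BAD2"))
  store <- specimen_store(tempfile(fileext = ".tsv"), good)

  notifications <- character(0)
  report <- run_batch(layout, store,
                      spec = snapshot_spec(magnification = 20),
                      notify = function(id, path) {
                        notifications <<- c(notifications, id)
                      })

  expect_length(list.files(layout$ndpi_new), 0)
  expect_setequal(list.files(layout$ndpi_processed),
                  paste0(c(good, "NOSUCHID"), ".tif"))
  expect_setequal(list.files(layout$ndpi_failed), c("BAD1.tif", "BAD2.tif"))
  expect_setequal(list.files(layout$jpeg_processed), paste0(good, ".jpg"))
  expect_setequal(list.files(layout$jpeg_failed), "NOSUCHID.jpg")
  expect_length(list.files(layout$jpeg_processing), 0)
  expect_equal(notifications, "NOSUCHID")

  # every linked specimen points at a real snapshot; pyramids published
  for (id in good) {
    expect_false(is.na(store_lookup(store, id)$image_path))
    expect_true(file.exists(file.path(layout$publish_root, paste0(id, ".dzi"))))
  }
  expect_false(file.exists(file.path(layout$publish_root, "NOSUCHID.dzi")))

  # each ingested file appears exactly once in the report
  expect_equal(sum(report$stage == "slide"), 8)
  expect_equal(sum(report$outcome == "open_failed"), 2)
  expect_equal(sum(report$outcome == "link_failed"), 1)

  # a re-run of the settled batch changes nothing
  snapshot_tree <- function() {
    files <- sort(list.files(layout$root, recursive = TRUE))
    data.frame(f = files, size = file.info(file.path(layout$root, files))$size)
  }
  tree_before <- snapshot_tree()
  store_before <- readBin(store$path, "raw", file.info(store$path)$size)
  report2 <- run_batch(layout, store, notify = function(id, path) {
    notifications <<- c(notifications, id)
  })
  expect_equal(nrow(report2), 0)
  expect_identical(snapshot_tree(), tree_before)
  expect_identical(readBin(store$path, "raw", file.info(store$path)$size),
                   store_before)
  expect_length(notifications, 1)
})

test_that("corrected snapshots can be re-queued and are deduplicated by name", {
  layout <- make_layout()
  store <- specimen_store(tempfile(fileext = ".tsv"), "S9")

  jpg <- tempfile(fileext = ".jpg")
  writeBin(as.raw(jpeg::writeJPEG(array(0.5, c(32, 32, 3)), raw())), jpg)
  corrected <- file.path(dirname(jpg), "S9.jpg")
  file.copy(jpg, corrected)

  reprocess_corrected(layout, corrected)
  reprocess_corrected(layout, corrected) # duplicate queue: one file
  expect_equal(list.files(layout$jpeg_processing), "S9.jpg")

  notaj <- tempfile(fileext = ".jpg")
  writeLines("not an image", notaj)
  expect_error(reprocess_corrected(layout, notaj),
               class = "slidesplit_validation_error")
  expect_error(reprocess_corrected(layout, tempfile(fileext = ".jpg")),
               class = "slidesplit_io_error")

  report <- run_batch(layout, store)
  expect_equal(report$outcome, "processed")
  expect_equal(store_lookup(store, "S9")$image_path,
               file.path(layout$jpeg_processed, "S9.jpg"))
  expect_true(file.exists(file.path(layout$publish_root, "S9.dzi")))
})

test_that("the default notifier appends to notifications.log", {
  layout <- make_layout()
  seed_slides(layout, "ORPHAN")
  store <- specimen_store(tempfile(fileext = ".tsv"), "OTHER")
  run_batch(layout, store)
  lines <- readLines(layout$notifications_log)
  expect_length(lines, 1)
  expect_match(lines, "ORPHAN")
})
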