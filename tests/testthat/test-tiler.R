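# Grid computation, spreadsheet naming, splitting and logging.

test_that("exact division yields a clean grid with row-major names", {
  sl <- slide_from_raster(array(255, c(600, 600, 3)))
  g <- compute_grid(sl, 300, 300)
  expect_equal(c(g$n_rows, g$n_cols), c(2, 2))
  expect_equal(g$tiles$name, c("A1", "A2", "B1", "B2"))
  expect_false(any(g$tiles$is_edge))
})

test_that("non-divisible levels get truncated edge tiles", {
  sl <- slide_from_raster(array(255, c(500, 700, 3)))
  g <- compute_grid(sl, 300, 300)
  expect_equal(c(g$n_rows, g$n_cols), c(2, 3))
  expect_equal(nrow(g$tiles), 6)
  last_col <- g$tiles[g$tiles$col == 2, ]
  expect_true(all(last_col$x1 - last_col$x0 == 100))
  last_row <- g$tiles[g$tiles$row == 1, ]
  expect_true(all(last_row$y1 - last_row$y0 == 200))
  expect_equal(sum(g$tiles$is_edge), 4) # last row + last column
  # enumerate pixel columns/rows: each level pixel claimed exactly once
  colcover <- integer(700)
  for (i in seq_len(nrow(g$tiles))) {
    t <- g$tiles[i, ]
    if (t$row == 0) colcover[(t$x0 + 1):t$x1] <- colcover[(t$x0 + 1):t$x1] + 1L
  }
  expect_true(all(colcover == 1L))
})

test_that("a tile as large as the level gives a single tile A1", {
  sl <- slide_from_raster(array(0, c(300, 300, 3)))
  g <- compute_grid(sl, 300, 300)
  expect_equal(nrow(g$tiles), 1)
  expect_equal(g$tiles$name, "A1")
  g2 <- compute_grid(sl, 500, 500) # larger than the level is legal
  expect_equal(nrow(g2$tiles), 1)
  expect_error(compute_grid(sl, 0, 300), class = "slidesplit_validation_error")
})

test_that("tile names follow bijective base-26 rows and 1-based columns", {
  expect_equal(tile_name(0, 0), "A1")
  expect_equal(tile_name(0, 2), "A3")
  expect_equal(tile_name(27, 1), "AB2")
  # independent recursive oracle for bijective base-26
  oracle_letters <- function(n) {
    if (n == 0) return("")
    paste0(oracle_letters((n - 1) %/% 26), LETTERS[(n - 1) %% 26 + 1])
  }
  for (row in c(0:60, 675, 676, 702, 703, 18277)) {
    expect_equal(tile_name(row, 4), paste0(oracle_letters(row + 1), 5))
  }
})

test_that("tile names are unique on a grid and round-trip through the parser", {
  sl <- slide_from_raster(array(0, c(64, 64, 3)))
  g <- compute_grid(sl, 2, 2) # 32 x 32 grid crosses the Z -> AA boundary
  expect_false(anyDuplicated(g$tiles$name) > 0)
  parsed <- parse_tile_name(g$tiles$name)
  expect_equal(parsed[, "row"], g$tiles$row)
  expect_equal(parsed[, "col"], g$tiles$col)
  expect_error(parse_tile_name("7B"), class = "slidesplit_validation_error")
})

test_that("tile areas always sum to the level area (fuzzed)", {
  set.seed(42)
  for (k in 1:60) {
    w <- sample(1:900, 1); h <- sample(1:900, 1)
    tw <- sample(1:300, 1); th <- sample(1:300, 1)
    sl <- slide_from_raster(array(0, c(16, 16, 3)))
    sl$width_px <- w; sl$height_px <- h # grid math needs dims only
    g <- compute_grid(sl, tw, th)
    areas <- (g$tiles$x1 - g$tiles$x0) * (g$tiles$y1 - g$tiles$y0)
    expect_equal(sum(areas), w * h)
    expect_true(all(areas > 0))
  }
})

make_split_fixture <- function() {
  # 400x300 brightfield slide, 100px cells: fragments cover 7 of 12 cells
  blobs <- data.frame(x0 = c(0, 0, 100), y0 = c(0, 100, 200),
                      w = c(300, 200, 200), h = c(100, 100, 100))
  generate_slide(400, 300, "brightfield", seed = 5, blobs = blobs)
}

test_that("splitting with the compression filter routes empties and logs all cells", {
  fx <- make_split_fixture()
  sl <- as_slide(fx)
  sl$source_path <- "BC-0042.tif"
  g <- compute_grid(sl, 100, 100)
  truth <- grid_truth(fx, g)
  expect_equal(sum(truth), 7)

  out <- tempfile("split")
  res <- split_slide(sl, g, out, empty_filter = "compression")
  expect_equal(res$written, 7)
  expect_equal(res$empty, 5)
  expect_equal(res$written + res$empty, g$n_rows * g$n_cols)
  expect_equal(basename(res$dir), "BC-0042")
  expect_length(list.files(res$dir, pattern = "\\.tif$"), 7)
  expect_length(list.files(file.path(res$dir, "empty_tiles"), pattern = "\\.tif$"), 5)
  log_lines <- readLines(res$log)
  expect_length(log_lines, 12)
  fields <- strsplit(log_lines, "\t", fixed = TRUE)
  expect_true(all(lengths(fields) == 5))
  verdicts <- vapply(fields, `[[`, "", 5)
  expect_equal(sum(verdicts == "empty"), 5)
  # the log agrees with ground truth tile by tile
  names(verdicts) <- vapply(fields, `[[`, "", 1)
  expect_equal(unname(verdicts[names(truth)] == "kept"), unname(truth))
})

test_that("with the filter off every tile lands in the root and no log is written", {
  fx <- make_split_fixture()
  sl <- as_slide(fx)
  g <- compute_grid(sl, 100, 100)
  out <- tempfile("split")
  res <- split_slide(sl, g, out)
  expect_equal(res$written, 12)
  expect_equal(res$empty, 0)
  expect_true(is.na(res$log))
  expect_length(list.files(res$dir, pattern = "\\.tif$"), 12)
  expect_false(dir.exists(file.path(res$dir, "empty_tiles")))
})

test_that("an all-background slide is routed entirely to empty_tiles", {
  fx <- generate_slide(200, 200, "brightfield", n_blobs = 0, seed = 1,
                       noise_amplitude = 0)
  sl <- as_slide(fx)
  g <- compute_grid(sl, 100, 100)
  res <- split_slide(sl, g, tempfile("split"), empty_filter = "compression")
  expect_equal(res$written, 0)
  expect_equal(res$empty, 4)
})

test_that("written tiles stitch back to the level raster bit-exactly", {
  fx <- make_split_fixture()
  sl <- as_slide(fx)
  g <- compute_grid(sl, 100, 100)
  res <- split_slide(sl, g, tempfile("split"))
  rasters <- lapply(res$tile_paths, function(p) round(tiff::readTIFF(p) * 255))
  stitched <- stitch_boxes(rasters, g$tiles, g$level_width, g$level_height)
  expect_identical(stitched, unclass(fx$raster))
})

test_that("unknown filter ids are rejected", {
  sl <- slide_from_raster(array(0, c(32, 32, 3)))
  g <- compute_grid(sl, 16, 16)
  expect_error(split_slide(sl, g, tempfile(), empty_filter = "magic"),
               class = "slidesplit_validation_error")
})
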