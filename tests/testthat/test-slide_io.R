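# Slide access: reader registry, metadata, region extraction.

test_that("TIFF slides round-trip their dimensions and pixels", {
  src <- random_raster(96, 128, seed = 11)
  path <- write_tiff_slide(src)
  sl <- open_slide(path)
  expect_s3_class(sl, "slide_image")
  expect_equal(sl$width_px, 128)
  expect_equal(sl$height_px, 96)
  expect_equal(sl$reader_id, "tiff")
  expect_equal(sl$raster, src, ignore_attr = TRUE)
})

test_that("multi-page TIFF opens at the largest (full-resolution) page", {
  big <- random_raster(64, 96, seed = 12)
  small <- random_raster(32, 48, seed = 13)
  path <- tempfile(fileext = ".tif")
  tiff::writeTIFF(list(small / 255, big / 255), path, bits.per.sample = 8L,
                  compression = "LZW")
  sl <- open_slide(path)
  expect_equal(c(sl$width_px, sl$height_px), c(96, 64))
  expect_equal(sl$raster, big, ignore_attr = TRUE)
})

test_that("corrupt or unreadable input signals an open failure", {
  bad <- tempfile(fileext = ".tif")
  writeBin(as.raw(c(0x49, 0x49, 0x2a, 0x00, 0xde, 0xad)), bad)
  expect_error(open_slide(bad), class = "slidesplit_open_error")

  png_path <- write_png_slide(random_raster(32, 32, seed = 14))
  bytes <- readBin(png_path, "raw", file.info(png_path)$size)
  truncated <- tempfile(fileext = ".png")
  writeBin(bytes[1:40], truncated)
  expect_error(open_slide(truncated), class = "slidesplit_open_error")

  expect_error(open_slide(tempfile(fileext = ".png")),
               class = "slidesplit_open_error")
  noreader <- tempfile(fileext = ".xyz")
  writeBin(as.raw(1:10), noreader)
  expect_error(open_slide(noreader), class = "slidesplit_open_error")
})

test_that("magnification falls back to the configured default when untagged", {
  path <- write_png_slide(array(255, c(512, 512, 3)))
  cfg <- system.file("extdata", "NDPIsplitter.properties", package = "slidesplit")
  defaults <- splitter_defaults(cfg)
  sl <- open_slide(path, default_magnification = defaults$default_magnification)
  expect_equal(sl$scan_magnification, 40)
})

test_that("a magnification tag in the container wins over the default", {
  path <- write_png_slide(random_raster(32, 32, seed = 15),
                          text = c(magnification = "20"))
  sl <- open_slide(path, default_magnification = 40)
  expect_equal(sl$scan_magnification, 20)
  expect_equal(slidesplit:::parse_magnification("scanner x | AppMag = 40 | foo"), 40)
  expect_equal(slidesplit:::parse_magnification("Magnification=27.5"), 27.5)
})

test_that("full-slide read at scan magnification is the identity", {
  src <- random_raster(60, 80, seed = 16)
  sl <- slide_from_raster(src, magnification = 40)
  out <- read_region(sl, region_request(0, 0, 80, 60))
  expect_identical(out, sl$raster)
})

test_that("constant-color crops survive downsampling unchanged", {
  src <- array(137, c(120, 120, 3))
  sl <- slide_from_raster(src, magnification = 40)
  out <- read_region(sl, region_request(10, 10, 100, 100, magnification = 20))
  expect_equal(dim(out), c(50, 50, 3))
  expect_true(all(out == 137))
})

test_that("area downsampling matches a brute-force block-mean oracle", {
  src <- checkerboard(40, 40)
  sl <- slide_from_raster(src, magnification = 40)
  out <- read_region(sl, region_request(0, 0, 40, 40, magnification = 20))
  expect_equal(out, brute_area_downsample(src, 20, 20))
  expect_true(all(out == 127.5)) # 2x2 blocks of {0, 255} average to mid-gray

  irregular <- random_raster(30, 42, seed = 17)
  sl2 <- slide_from_raster(irregular, magnification = 40)
  out2 <- read_region(sl2, region_request(0, 0, 42, 30, magnification = 12),
                      method = "area")
  d <- 40 / 12
  expect_equal(dim(out2)[1:2], c(round(30 / d), round(42 / d)))
  expect_equal(out2, brute_area_downsample(irregular, round(42 / d), round(30 / d)))
})

test_that("reading a partition of the slide stitches back to one full read", {
  src <- random_raster(45, 67, seed = 18)
  sl <- slide_from_raster(src)
  full <- read_region(sl, region_request(0, 0, 67, 45))
  cuts_x <- c(0, 20, 50, 67)
  cuts_y <- c(0, 13, 45)
  acc <- array(NA_real_, dim(src))
  for (i in 1:(length(cuts_x) - 1)) {
    for (j in 1:(length(cuts_y) - 1)) {
      w <- cuts_x[i + 1] - cuts_x[i]
      h <- cuts_y[j + 1] - cuts_y[j]
      piece <- read_region(sl, region_request(cuts_x[i], cuts_y[j], w, h))
      acc[(cuts_y[j] + 1):cuts_y[j + 1], (cuts_x[i] + 1):cuts_x[i + 1], ] <- piece
    }
  }
  expect_identical(acc, full)
})

test_that("out-of-bounds and upsampling requests are rejected", {
  sl <- slide_from_raster(random_raster(20, 20, seed = 19), magnification = 40)
  expect_error(read_region(sl, region_request(10, 10, 20, 5)),
               class = "slidesplit_bounds_error")
  expect_error(read_region(sl, region_request(0, 0, 10, 10, magnification = 80)),
               class = "slidesplit_upsample_error")
  expect_error(region_request(-1, 0, 5, 5), class = "slidesplit_validation_error")
  expect_error(region_request(0, 0, 0, 5), class = "slidesplit_validation_error")
})

test_that("reader plugins can be registered and take precedence by magic", {
  marker <- as.raw(c(0x4e, 0x44, 0x50, 0x49)) # "NDPI"
  register_slide_reader(
    "toy", "toy",
    match_magic = function(magic) length(magic) >= 4 && identical(magic[1:4], marker),
    open = function(path) list(raster = array(7, c(4, 4, 3)), magnification = 20)
  )
  on.exit(rm("toy", envir = slidesplit:::.reader_registry))
  path <- tempfile(fileext = ".toy")
  writeBin(marker, path)
  sl <- open_slide(path)
  expect_equal(sl$reader_id, "toy")
  expect_equal(sl$scan_magnification, 20)
  expect_true("toy" %in% slide_readers())
})
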