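Package: slidesplit
Title: Splitting, Snapshotting and Deep Zoom Publishing of Whole-Slide Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for desk-scale virtual microscopy archiving: split large
    brightfield or fluorescent slide images into grids of TIFF tiles with
    spreadsheet-style names, filter out empty (background-only) tiles by an
    intensity criterion or a JPEG-compressibility criterion, render centered
    watermarked JPEG snapshots, convert rasters into Deep Zoom (DZI) tile
    pyramids for web viewing, and run a folder-based batch workflow that
    links published snapshots to a specimen record store. Ships plain and
    multi-page TIFF and PNG readers behind a pluggable slide-reader
    registry, plus a deterministic synthetic-slide generator with
    ground-truth occupancy masks for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jpeg,
    png,
    tiff,
    xml2,
    Matrix,
    tools,
    utils,
    stats
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    jsonlite
Config/testthat/edition: 3
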