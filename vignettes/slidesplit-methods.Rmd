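---
title: "slidesplit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{slidesplit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slidesplit)
```

This vignette records how the toolkit's procedures work, which
parameters matter, and the design choices made where more than one
reasonable option existed. It is the companion to the reference
documentation, in the spirit of a methods section.

## Slide access and coordinates

All rasters are numeric arrays `height x width x channels` on the 0..255
scale. Pixel coordinates are 0-based with a top-left origin, and every
box is half-open, `[x0, x1) x [y0, y1)` — a convention chosen once so
that adjacent tiles share an edge but never a pixel, which is what makes
exact partition and bit-exact reassembly provable rather than
approximate.

`open_slide()` goes through a reader registry keyed by file signature
(magic bytes) first and extension second. The shipped readers decode
plain and multi-page TIFF (the largest page is taken as the
full-resolution level, which covers pyramidal containers) and PNG.
Proprietary scanner containers such as Hamamatsu NDPI are deliberately
*not* decoded here — their access normally runs through a licensed,
platform-locked SDK — but a reader for them can be registered with
`register_slide_reader()` and the rest of the toolkit never notices the
difference.

Scan magnification is reader-reported metadata (a `magnification=` or
`AppMag =` token in the TIFF description, or a `magnification` PNG text
chunk); when the container carries no tag, a configurable default (40,
i.e. an objective-equivalent "400x" scan) is assumed. Requesting a
region at magnification `m` yields a downsample factor
`d = scan_magnification / m`; requests above scan magnification are
refused rather than upsampled.

**Resampling.** Downsampling is separable weighted averaging implemented
as two sparse weight matrices (rows and columns). The `"area"` method
gives each output pixel the exact average of the source interval it
covers — for integer `d` this is a plain block mean, which is what makes
it oracle-checkable by brute force — and is used whenever `d >= 2`.
Bilinear interpolation is used for `1 < d < 2`, where box weights would
degenerate towards nearest-neighbour. The choice is recorded per call
(`method` argument) and fixed by default, so pipelines are reproducible.
Outputs are quantised to 8-bit integers only at file-writing boundaries;
two mathematically equal summation orders can disagree by one count when
an exact `x.5` tie meets floating-point rounding, which is why the test
suite checks stitching bit-exactly against the package's own level
rasters but allows a one-count tolerance against independent brute-force
oracles.

## The tile grid

`compute_grid()` covers the level raster with
`ceil(level_w / tile_w) x ceil(level_h / tile_h)` half-open boxes in
row-major order. Two decisions here were genuinely open:

* **Edge tiles are truncated, not padded.** Padding would fabricate
  pixels that downstream analysis software would treat as data;
  truncation keeps the tiles an exact partition, at the cost of
  irregular edge-tile sizes (flagged `is_edge`).
* **Tile dimensions are interpreted at the output magnification**, i.e.
  "300 px tiles at 10x" means 300 px after downsampling — matching how
  a user pairs size and magnification in one breath.

Names map rows to bijective base-26 letters (`A..Z, AA, AB, ...` — no
zero digit, exactly like spreadsheet rows) and columns to 1-based
numbers: the first row of tiles reads `A1, A2, A3, ...`. Beyond 26 rows
the lettering continues `AA, AB, ...`; `parse_tile_name()` inverts the
scheme, and injectivity over any grid is property-tested.

`split_slide()` writes one directory per slide, `<name>.tif` per tile
(8-bit baseline TIFF, LZW), empties under `empty_tiles/` — retained for
review, never deleted, because the emptiness criteria are admitted
heuristics — and, when a filter is active, a `log.txt` with one
tab-separated line per grid cell: name, algorithm, `key=value` scores,
`key=value` thresholds, verdict. The format is designed so thresholds
can be re-tuned offline from the log alone. With the filter off no log
is written (there is no calculation to record).

## Empty-tile detection

Two criteria, each matched to the background statistics of one
modality:

**Intensity (fluorescent).** Per-pixel intensity is the unweighted
channel mean; luma weighting was rejected because the target is
near-black backgrounds where the channel balance is irrelevant. A tile
is *empty* iff it fails **both** content criteria:

```
empty  <=>  mean_intensity < avg_threshold  AND  lit_fraction < min_lit_fraction
```

so either a lit average *or* sufficiently many individually lit pixels
marks content. The conjunction (rather than a disjunction) errs on the
side of keeping tiles, consistent with retaining empties for review.
Defaults: `avg_threshold = 10`, `whiteness_threshold = 30`,
`min_lit_fraction = 0.01`, all on the 0..255 / fraction scales and all
configurable (`NDPIsplitter.properties` keys `empty.intensity.*`).

**Compression (brightfield).** The tile is JPEG-encoded in memory at
`probe_quality = 75` and the byte ratio compared with
`ratio_threshold = 0.02`. Two normalisation decisions:

* the denominator is the *raw* byte count `W·H·C`, and
* the encoder's fixed overhead (quantisation and Huffman tables,
  markers — measured once per quality by encoding a 16x16 uniform
  probe) is subtracted from the numerator.

The subtraction matters: a blank 300x36 edge strip encodes to ~850
bytes of which ~600 are header, and without the correction its naive
ratio (0.026) would exceed any sensible cutoff while a blank 300x300
tile sits at 0.008. With the correction both score below 0.01 and the
threshold is genuinely tile-size independent. The probe is in-memory
only; written tiles remain TIFF.

Monotonicity properties (raising pixel intensities never flips a
content verdict to empty; raising `ratio_threshold` or
`min_lit_fraction` only grows the empty set) follow from the formulas
and are fuzz-tested.

## Snapshot and watermark

The snapshot is the centered quarter of the slide: a
`floor(W/2) x floor(H/2)` box at `(floor((W-w)/2), floor((H-h)/2))`.
"Quarter" is interpreted as quarter *area* (half of each dimension);
the alternative reading — a quarter of each dimension, 1/16 of the area
— was rejected as inconsistent with publishing a representative
overview. Floor-based centering handles odd dimensions
deterministically; the area ratio is exactly 0.25 for even dimensions
and approaches it from below otherwise.

The watermark is alpha-composited bottom-center with a margin of 2% of
the image height (neither placement nor margin has a canonical value;
these are fixed, documented defaults). Oversized logos are downscaled
preserving aspect ratio; degenerate logos are skipped with a warning
rather than failing a batch. Snapshots are encoded at
`jpeg_quality = 90` by default (configurable via
`snapshot-creator.properties`).

## Deep Zoom pyramids

`compute_pyramid()` follows the DZI conventions: `tile_size = 254` and
`overlap = 1` (so interior tiles are 256x256), JPEG tiles at quality 85
for publishing, PNG available where lossless tiles are wanted (the test
suite uses PNG to verify per-level stitching exactly).
`max_level = ceil(log2(max(W, H)))` and dimensions ceil-halve per level
down to 1x1. Each level is produced from the previous (larger) cached
level rather than from the source every time — this matches the
recurrence definition exactly and bounds memory — and is quantised to
8-bit before tiling so tiles and level rasters agree bit-for-bit. The
descriptor XML lives in the `http://schemas.microsoft.com/deepzoom/2008`
namespace and round-trips through `read_dzi()`; only the on-disk
contract is guaranteed, no viewer code ships.

## The batch workflow

`run_batch()` is a two-stage folder state machine over seven distinct
directories. Slides in `NDPI-New` are snapshotted into the JPEG
processing queue and moved to `NDPI-Processed`, or to `NDPI-Failed`
when opening or rendering fails; queued JPEGs are looked up in the
specimen store by their file stem (the slide identifier), published as
Deep Zoom pyramids and moved to `JPEG-Processed`, or to `JPEG-Failed`
with a notification on a failed lookup. Design choices:

* **The record store is an adapter.** The reference backend is a
  single-file TSV updated atomically (temp file + rename), with
  `store_lookup()` / `link_specimen()` as the contract; a SQL-backed
  biobank database slots in behind the same two calls. Linking is
  idempotent and last-write-wins; a failed lookup leaves the store
  byte-identical. The record points at the snapshot's terminal
  location (or at the published `.dzi` when processed JPEGs are
  deleted via `keep_processed_jpeg = FALSE`).
* **Notification is a hook**, `function(identifier, path)`, defaulting
  to an appended line in `notifications.log`; actual e-mail is a
  deployment concern, not a library one.
* **Per-file containment**: every slide/JPEG is processed inside its
  own error handler, so one corrupt file never aborts a batch, and
  every ingested file ends in exactly one terminal folder.
* **Idempotence**: publishing overwrites by name and linking is a
  no-op on an unchanged path, so re-running a settled (or interrupted
  and resumed) batch changes nothing — verified by comparing the whole
  folder tree before and after a re-run.
* **Scheduling is delegated** to the host (`cron`, or the CLI `watch`
  subcommand with `--once` for single runs); there is no internal
  scheduler.

`reprocess_corrected()` covers the manual-repair path: a renamed JPEG is
validated (it must decode) and re-queued, deduplicated by name.

## The synthetic-slide generator

`generate_slide()` emulates the two scanner modalities at desk scale:
brightfield slides are near-white (background `255 - U(0, a)` with noise
bound `a = 2` by default) with pink-toned "tissue" fragments;
fluorescent slides are near-black with bright fragments. Fragment
interiors carry low-frequency sinusoidal shading (random period 23–61
px and phase per fragment) plus per-pixel uniform speckle (±70
brightfield, ±50 fluorescent, clamped so fluorescent fragment pixels
stay at or above intensity 60) — enough incompressible structure for
the JPEG probe to grip, while blank regions stay essentially free.
Identical seed and parameters reproduce raster and mask bit for bit,
and the generator restores the caller's RNG state.

**Fragment geometry is the one deliberately artificial choice.**
Fragments are rounded rectangles (corner radius 30 px) whose edges snap
to a 100 px anchor lattice, rather than free-floating ellipses. The
reason is the interaction between ground truth and the classifiers'
detection limits: a tile counts as occupied from 0.5% mask coverage
(`grid_truth()`), but the compression criterion at its default
threshold only responds from roughly 10% coverage. A free-floating
fragment boundary crossing a tile edge produces arbitrary sliver
overlaps inside that gap, so whether a random fixture agreed with its
own ground truth would be seed lottery. With lattice-snapped edges, the
overlap between a fragment and any tile whose size is a multiple of the
lattice spacing (e.g. the default 300 px tiles) is either zero or at
least one lattice cell minus a rounded corner, about 9 800 px — i.e.
~11% of a 300x300 tile, comfortably above both detection limits. The
agreement between classifiers and ground truth on default fixtures is
therefore a structural property, not sampling luck; the margin (worst
observed content-tile ratio ≈ 0.022 against the 0.02 cutoff) is stable
across seeds.

What the generator does *not* emulate: stain variation, focus blur,
scanner stitching artefacts, tissue folds, or faint sparse content near
the detection thresholds. Passing fixture tests therefore demonstrates
the mechanics — grid bookkeeping, logging, routing, threshold algebra
— on clearly separated data; they do not certify classifier accuracy
on real tissue, where the criteria are known to be imperfect and
empties are retained for human review.

## Problem sizes and numerical notes

The default test slide is 2048x1536 (42 tiles of 300x300): large enough
to exercise multi-level pyramids and edge-tile handling, small enough
for interactive test runs. Property suites use 200 fuzzed grid
geometries up to 220 px, 100 monotonicity cases, 50 fuzzed pyramid
descriptors up to 4096 px, and one fully stitched 330x210 PNG pyramid.
Degenerate inputs are handled explicitly: 1x1 pyramids are a single
level, slides below 2x2 cannot be snapshotted, zero-size tiles and
empty rasters are validation errors, and a tile larger than its level
is legal (one tile). All thresholds and defaults live in the two
properties files so that none of the numbers above is hard-wired for a
user who disagrees with them.
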