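# Deterministic synthetic slides for desk-scale testing: brightfield
# (stained-tissue-like fragments on a near-white background) and
# fluorescent (bright signal on a near-black background), with a
# ground-truth occupancy mask marking every painted pixel.
#
# Fragment geometry is snapped to a coarse anchor lattice (default 100
# px): fragments are rounded rectangles whose edges lie on lattice
# lines. For any tile grid whose tile size is a multiple of the lattice
# spacing, the overlap of a fragment with a tile is then either zero or
# at least one lattice cell (minus a rounded corner), i.e. roughly 10%
# of a 300x300 tile -- so per-tile occupancy is bimodal by construction
# and ground truth cannot straddle the detection limits of the
# emptiness classifiers. Fragment interiors carry low-frequency
# sinusoidal shading plus seeded speckle, giving the JPEG probe
# realistic incompressible structure.

fixture_palette <- list(
  brightfield = list(base = c(193, 128, 158), shade = 30, speckle = 70,
                     clamp = c(0, 255)),
  fluorescent = list(base = c(90, 190, 140), shade = 25, speckle = 50,
                     clamp = c(60, 255))
)

with_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

rounded_rect_mask <- function(w, h, radius) {
  radius <- min(radius, floor(w / 2), floor(h / 2))
  xx <- matrix(rep(seq_len(w) - 0.5, each = h), h)
  yy <- matrix(rep(seq_len(h) - 0.5, times = w), h)
  m <- matrix(TRUE, h, w)
  if (radius > 0) {
    corners <- list(c(radius, radius), c(w - radius, radius),
                    c(radius, h - radius), c(w - radius, h - radius))
    for (cn in corners) {
      inx <- if (cn[1] == radius) xx < radius else xx > w - radius
      iny <- if (cn[2] == radius) yy < radius else yy > h - radius
      corner_zone <- inx & iny
      outside <- (xx - cn[1])^2 + (yy - cn[2])^2 > radius^2
      m[corner_zone & outside] <- FALSE
    }
  }
  m
}

#' Generate a synthetic slide with ground truth
#'
#' Paints `n_blobs` textured tissue-like fragments on a clean background
#' and records the painted pixels in a boolean occupancy mask. Identical
#' `seed` and parameters reproduce the raster and mask bit for bit.
#'
#' Fragments are rounded rectangles with edges snapped to the `anchor`
#' lattice (see the package vignette for why), sized uniformly between
#' `blob_size_range` (rounded to lattice multiples) and placed at seeded
#' random lattice positions; fragments may overlap and merge. The
#' background is uniform white (brightfield) or black (fluorescent) plus
#' seeded additive noise bounded by `noise_amplitude`.
#'
#' @param width,height Slide dimensions in pixels (at least 16).
#' @param mode `"brightfield"` or `"fluorescent"`.
#' @param n_blobs Number of fragments (0 for an empty slide).
#' @param seed Integer seed; the generator never touches the caller's
#'   RNG state.
#' @param noise_amplitude Background noise bound in intensity units
#'   (default 2).
#' @param blob_size_range Fragment side length range in pixels.
#' @param anchor Placement lattice spacing in pixels.
#' @param corner_radius Fragment corner rounding in pixels.
#' @param blobs Optional explicit fragment geometry, a data frame with
#'   columns `x0`, `y0`, `w`, `h` (0-based pixel offsets), overriding
#'   random placement.
#' @return A `synthetic_slide`: list with `raster` (0..255 RGB),
#'   `mask` (logical height x width matrix), `mode`, `seed` and
#'   `params`.
#' @seealso [grid_truth()], [as_slide()]
#' @export
generate_slide <- function(width, height, mode = c("brightfield", "fluorescent"),
                           n_blobs = 8, seed = 1, noise_amplitude = 2,
                           blob_size_range = c(200, 500), anchor = 100,
                           corner_radius = 30, blobs = NULL) {
  mode <- match.arg(mode)
  if (width < 16 || height < 16) ss_validation_error("slide must be at least 16x16")
  if (n_blobs < 0) ss_validation_error("n_blobs must be >= 0")
  pal <- fixture_palette[[mode]]
  width <- as.integer(width); height <- as.integer(height)

  with_seed(seed, {
    bg <- if (mode == "brightfield") 255 else 0
    noise <- round(runif(height * width, 0, noise_amplitude))
    plane <- if (mode == "brightfield") bg - noise else bg + noise
    raster <- array(rep(plane, 3L), c(height, width, 3L))
    mask <- matrix(FALSE, height, width)

    if (is.null(blobs) && n_blobs > 0) {
      lo <- max(1L, round(blob_size_range[1] / anchor))
      hi <- max(lo, round(blob_size_range[2] / anchor))
      avail_w <- floor(width / anchor)
      avail_h <- floor(height / anchor)
      blobs <- data.frame(x0 = integer(0), y0 = integer(0),
                          w = integer(0), h = integer(0))
      for (b in seq_len(n_blobs)) {
        wu <- min(sample(lo:hi, 1L), max(1L, avail_w))
        hu <- min(sample(lo:hi, 1L), max(1L, avail_h))
        xu <- if (avail_w > wu) sample(0:(avail_w - wu), 1L) else 0L
        yu <- if (avail_h > hu) sample(0:(avail_h - hu), 1L) else 0L
        blobs[b, ] <- c(xu, yu, wu, hu) * anchor
      }
      blobs$w <- pmin(blobs$w, width - blobs$x0)
      blobs$h <- pmin(blobs$h, height - blobs$y0)
    }

    if (!is.null(blobs) && nrow(blobs) > 0) {
      for (b in seq_len(nrow(blobs))) {
        x0 <- blobs$x0[b]; y0 <- blobs$y0[b]
        w <- blobs$w[b]; h <- blobs$h[b]
        shape <- rounded_rect_mask(w, h, corner_radius)
        lx <- 2 * pi / runif(1, 23, 61)
        ly <- 2 * pi / runif(1, 23, 61)
        phx <- runif(1, 0, 2 * pi); phy <- runif(1, 0, 2 * pi)
        xx <- matrix(rep(x0 + seq_len(w), each = h), h)
        yy <- matrix(rep(y0 + seq_len(h), times = w), h)
        shading <- pal$shade * sin(lx * xx + phx) * cos(ly * yy + phy)
        n_px <- sum(shape)
        rows <- (y0 + 1):(y0 + h)
        cols <- (x0 + 1):(x0 + w)
        for (ch in 1:3) {
          speckle <- runif(n_px, -pal$speckle, pal$speckle)
          v <- raster[rows, cols, ch]
          v[shape] <- round(pmin(pmax(pal$base[ch] + shading[shape] + speckle,
                                      pal$clamp[1]), pal$clamp[2]))
          raster[rows, cols, ch] <- v
        }
        msub <- mask[rows, cols]
        msub[shape] <- TRUE
        mask[rows, cols] <- msub
      }
    }

    structure(
      list(raster = raster, mask = mask, mode = mode, seed = seed,
           params = list(n_blobs = if (is.null(blobs)) n_blobs else nrow(blobs),
                    noise_amplitude = noise_amplitude,
                         blob_size_range = blob_size_range, anchor = anchor,
                         corner_radius = corner_radius)),
      class = "synthetic_slide"
    )
  })
}

#' @export
print.synthetic_slide <- function(x, ...) {
  cat(sprintf("<synthetic_slide> %s %dx%d, %d fragment(s), seed %d, occupancy %.1f%%\n",
              x$mode, raster_width(x$raster), raster_height(x$raster),
              x$params$n_blobs, x$seed, 100 * mean(x$mask)))
  invisible(x)
}

#' Wrap a synthetic slide as a slide handle
#'
#' @param fixture A [generate_slide()] result.
#' @param magnification Nominal scan magnification (default 40).
#' @return A `slide_image` usable with the whole toolkit.
#' @export
as_slide <- function(fixture, magnification = 40) {
  if (!inherits(fixture, "synthetic_slide")) {
    ss_validation_error("'fixture' must be a synthetic_slide")
  }
  slide_from_raster(fixture$raster, magnification)
}

#' Ground-truth tile occupancy
#'
#' For each tile of a full-resolution grid over the synthetic slide,
#' reports whether the occupancy mask covers at least
#' `min_overlap_fraction` of the tile (default 0.5%).
#'
#' @param fixture A [generate_slide()] result.
#' @param grid A [compute_grid()] result at the slide's full resolution.
#' @param min_overlap_fraction Occupancy cutoff for calling a tile
#'   "contains content".
#' @return Named logical vector, one entry per tile in grid order.
#' @export
grid_truth <- function(fixture, grid, min_overlap_fraction = 0.005) {
  if (!inherits(fixture, "synthetic_slide")) {
    ss_validation_error("'fixture' must be a synthetic_slide")
  }
  if (!inherits(grid, "tile_grid")) ss_validation_error("'grid' must be a tile_grid")
  if (grid$level_width != raster_width(fixture$raster) ||
      grid$level_height != raster_height(fixture$raster)) {
    ss_validation_error("grid must be computed at the slide's full resolution")
  }
  tiles <- grid$tiles
  out <- vapply(seq_len(nrow(tiles)), function(i) {
    t <- tiles[i, ]
    mean(fixture$mask[(t$y0 + 1):t$y1, (t$x0 + 1):t$x1]) >= min_overlap_fraction
  }, logical(1))
  names(out) <- tiles$name
  out
}

#' Write a synthetic slide and its mask to disk
#'
#' @param fixture A [generate_slide()] result.
#' @param path Output TIFF path for the raster.
#' @param mask_path Optional PNG path for the occupancy mask (white =
#'   occupied).
#' @return `path`, invisibly.
#' @export
write_slide_fixture <- function(fixture, path, mask_path = NULL) {
  write_raster_tiff(fixture$raster, path)
  if (!is.null(mask_path)) {
    write_raster_png(matrix(255 * fixture$mask, nrow(fixture$mask)), mask_path)
  }
  invisible(path)
}
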