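#' Tile-selection configuration
#'
#' Controls the mosaic step: tile size, similarity metric, and the
#' percentile of lowest-similarity tiles retained for ratio estimation.
#'
#' @param tile_size Tile side length in pixels. Default 64, standing in for
#'   one to two cell diameters at typical multiplex-imaging resolution; use
#'   [tiles_for_cell_diameter()] to convert a biological size.
#' @param percentile Fraction in `(0, 1]` of tiles (lowest similarity)
#'   combined for estimation. Default 0.01 (the 1st percentile). Small
#'   images with few tiles may need a larger value; at least one tile is
#'   always selected.
#' @param metric Similarity metric scored per tile: `"ssim"` (default;
#'   non-negative in practice and cheap) or `"mi"` (normalized mutual
#'   information).
#' @return An object of class `selection_config`.
#' @export
selection_config <- function(tile_size = 64L, percentile = 0.01,
                             metric = c("ssim", "mi")) {
  metric <- match.arg(metric)
  tile_size <- as.integer(tile_size)
  if (tile_size < 7L)
    stop("`tile_size` must be at least the SSIM window size (7 px)",
         call. = FALSE)
  if (!(percentile > 0 && percentile <= 1))
    stop("`percentile` must be in (0, 1]", call. = FALSE)
  structure(list(tile_size = tile_size, percentile = percentile,
                 metric = metric),
            class = "selection_config")
}

#' Convert a cell-diameter hint to a tile size
#'
#' Mosaic tiles should cover roughly one to two cell diameters so that a
#' tile captures whole cells rather than sub-cellular texture.
#'
#' @param cell_diameter_px Approximate cell diameter in pixels.
#' @param cells_per_tile Diameters per tile side; default 1.5.
#' @return A tile side length in pixels (minimum 8).
#' @export
tiles_for_cell_diameter <- function(cell_diameter_px, cells_per_tile = 1.5) {
  max(8L, as.integer(round(cell_diameter_px * cells_per_tile)))
}

# Tile start/end breaks along one axis. A trailing remainder of at least
# half a tile becomes its own tile; a smaller sliver is merged into the
# previous tile.
.tile_breaks <- function(n, ts) {
  if (n <= ts) return(data.frame(start = 1L, end = n))
  starts <- seq.int(1L, n, by = ts)
  ends <- pmin(starts + ts - 1L, n)
  last <- length(starts)
  if (ends[last] - starts[last] + 1L < ts / 2 && last > 1L) {
    ends[last - 1L] <- n
    starts <- starts[-last]; ends <- ends[-last]
  }
  data.frame(start = starts, end = ends)
}

#' Tile a channel pair and score per-tile similarity
#'
#' Partitions the image into non-overlapping `tile_size x tile_size` tiles
#' (a trailing sliver smaller than half a tile is merged into its
#' neighbour) and computes the configured similarity score between the two
#' channels on each tile. Tiles where both channels are constant have no
#' defined MI score and receive `NA`.
#'
#' @param a,b Numeric matrices of identical dimensions.
#' @param cfg A [selection_config()].
#' @param hist Histogram specification used when `metric = "mi"`.
#' @return An object of class `mosaic_grid`: a list with `tiles` (a tibble
#'   of row, col, pixel bounds and score), `tile_size`, `metric`,
#'   `image_dim`, and `selected` (indices into `tiles`, empty until
#'   [select_low_similarity()] is applied).
#' @export
tile_pair <- function(a, b, cfg = selection_config(), hist = hist_spec()) {
  .check_image(a, "a"); .check_image(b, "b")
  .check_same_shape(a, b)
  d <- dim(a)
  if (any(d < cfg$tile_size))
    warning("image (", paste(d, collapse = "x"),
            ") is smaller than one tile; using a single-tile grid",
            call. = FALSE)
  rb <- .tile_breaks(d[1], cfg$tile_size)
  cb <- .tile_breaks(d[2], cfg$tile_size)
  # one data range for every tile (as when SSIM is run on a fixed-dtype
  # image): keeps scores comparable across tiles, so structureless tiles
  # score as similar rather than spuriously low
  dr <- max(a, b) - min(a, b)
  rows <- list(); idx <- 0L
  for (ri in seq_len(nrow(rb))) for (ci in seq_len(nrow(cb))) {
    idx <- idx + 1L
    ta <- a[rb$start[ri]:rb$end[ri], cb$start[ci]:cb$end[ci], drop = FALSE]
    tb <- b[rb$start[ri]:rb$end[ri], cb$start[ci]:cb$end[ci], drop = FALSE]
    score <- .tile_score(ta, tb, cfg$metric, hist, dr)
    rows[[idx]] <- tibble::tibble(
      tile = idx, row = ri, col = ci,
      y0 = rb$start[ri], y1 = rb$end[ri],
      x0 = cb$start[ci], x1 = cb$end[ci],
      score = score)
  }
  structure(list(tiles = do.call(rbind, rows),
                 tile_size = cfg$tile_size, metric = cfg$metric,
                 image_dim = d, selected = integer(0)),
            class = "mosaic_grid")
}

.tile_score <- function(ta, tb, metric, hist, data_range = NULL) {
  if (metric == "ssim") {
    if (min(dim(ta)) < 7L) return(NA_real_)
    ssim_score(ta, tb, data_range = data_range)
  } else {
    tryCatch(normalized_mi(ta, tb, hist), error = function(e) NA_real_)
  }
}

#' @export
print.mosaic_grid <- function(x, ...) {
  cat("<mosaic_grid> ", nrow(x$tiles), " tiles (nominal ", x$tile_size,
      " px, metric ", x$metric, "), ", length(x$selected), " selected\n",
      sep = "")
  invisible(x)
}

#' Select the lowest-similarity tiles
#'
#' Keeps tiles whose similarity score is at or below the empirical
#' `percentile` quantile (lower interpolation, so boundary ties are
#' included), guaranteeing at least `max(1, ceiling(percentile * T))` tiles
#' for `T` scored tiles. With few tiles the guarantee floor dominates and a
#' warning suggests a larger percentile. Tiles with `NA` scores are never
#' selected (unless every score is `NA`, in which case the first tile is
#' kept so estimation can proceed).
#'
#' @param grid A [tile_pair()] result.
#' @param cfg A [selection_config()].
#' @return The grid with `selected` populated.
#' @export
select_low_similarity <- function(grid, cfg = selection_config()) {
  stopifnot(inherits(grid, "mosaic_grid"))
  sc <- grid$tiles$score
  ok <- which(!is.na(sc))
  if (length(ok) == 0L) {
    grid$selected <- 1L
    warning("no tile has a defined similarity score; keeping tile 1",
            call. = FALSE)
    return(grid)
  }
  tcount <- length(ok)
  n_min <- max(1L, as.integer(ceiling(cfg$percentile * tcount)))
  thr <- stats::quantile(sc[ok], probs = cfg$percentile, type = 1,
                         names = FALSE)
  sel <- ok[sc[ok] <= thr]
  if (length(sel) < n_min)
    sel <- ok[order(sc[ok])][seq_len(n_min)]
  if (tcount < 1 / cfg$percentile)
    warning("only ", tcount, " tiles scored; the ", cfg$percentile,
            " percentile falls below one tile - consider a larger ",
            "percentile or smaller tiles", call. = FALSE)
  grid$selected <- sort(sel)
  grid
}

#' Combine selected tiles into a composite pair
#'
#' Concatenates the selected tiles of each channel into one composite image
#' per channel, used only for mixing-ratio estimation. When all selected
#' tiles share one size and fill a rectangular grid exactly, they are packed
#' row-major into the most-square grid; otherwise equal-height tiles are
#' laid out as a horizontal strip, and unequal tiles are stacked as a single
#' pixel column. No padding is ever introduced, so the composite's pixel
#' multiset — and therefore any histogram-based quantity such as MI —
#' is exactly that of the selected tiles. SSIM is never recomputed on a
#' composite (tile seams would corrupt it).
#'
#' @param a,b The original channel pair.
#' @param grid A grid with `selected` populated.
#' @return `list(a = , b = )` composite matrices.
#' @export
combine_selected <- function(a, b, grid) {
  stopifnot(inherits(grid, "mosaic_grid"))
  if (length(grid$selected) == 0L)
    stop("no tiles selected; run select_low_similarity() first",
         call. = FALSE)
  crop <- function(img, t) img[t$y0:t$y1, t$x0:t$x1, drop = FALSE]
  tl <- grid$tiles[grid$selected, , drop = FALSE]
  ca <- lapply(seq_len(nrow(tl)), function(i) crop(a, tl[i, ]))
  cb <- lapply(seq_len(nrow(tl)), function(i) crop(b, tl[i, ]))
  list(a = .pack_tiles(ca), b = .pack_tiles(cb))
}

.pack_tiles <- function(tiles) {
  k <- length(tiles)
  if (k == 1L) return(tiles[[1]])
  dims <- vapply(tiles, dim, integer(2))
  if (all(dims[1, ] == dims[1, 1]) && all(dims[2, ] == dims[2, 1])) {
    nc <- ceiling(sqrt(k))
    if (k %% nc == 0L) {
      nr <- k %/% nc
      rows <- lapply(seq_len(nr), function(r)
        do.call(cbind, tiles[((r - 1L) * nc + 1L):(r * nc)]))
      return(do.call(rbind, rows))
    }
  }
  if (all(dims[1, ] == dims[1, 1])) return(do.call(cbind, tiles))
  matrix(unlist(lapply(tiles, as.vector)), ncol = 1L)
}

#' Mixing ratios from low-similarity mosaics
#'
#' The full mosaic pipeline for one channel pair: tile, score, select the
#' low-similarity percentile, combine the selected tiles, and estimate the
#' mixing ratio on the composite in both orientations. Estimating only on
#' regions where the two channels share little structure isolates the
#' spectroscopic component of their dependence: genuinely colocalized
#' regions, which would drag the MI minimum toward over-subtraction, are
#' excluded.
#'
#' @param a,b The channel pair (`a` = channel 1, `b` = channel 2).
#' @param cfg A [selection_config()].
#' @param grid Candidate ratio grid, see [alpha_grid()].
#' @param hist Histogram specification.
#' @return A list with `forward` (the `mi_curve` for the ratio of `b`
#'   leaking into `a`, i.e. `alpha[1,2]`), `reverse` (`alpha[2,1]`), and
#'   `grid` (the scored `mosaic_grid` with selection).
#' @export
mosaic_alpha <- function(a, b, cfg = selection_config(),
                         grid = alpha_grid(), hist = hist_spec()) {
  g <- tile_pair(a, b, cfg, hist)
  g <- select_low_similarity(g, cfg)
  comp <- combine_selected(a, b, g)
  list(forward = .estimate_alpha_safe(comp$a, comp$b, grid, hist),
       reverse = .estimate_alpha_safe(comp$b, comp$a, grid, hist),
       grid = g)
}

#' Build a tile selector for iterative demixing
#'
#' Returns a closure suitable as the `selector` argument of
#' [demix_stack()]: given the current pair of channel images it tiles,
#' scores, selects the low-similarity percentile, and returns the composite
#' pair on which the ratios are estimated. Each channel pair gets its own
#' selection, re-scored every iteration.
#'
#' @inheritParams mosaic_alpha
#' @return `function(a, b) -> list(a = , b = )`.
#' @export
mosaic_selector <- function(cfg = selection_config(), hist = hist_spec()) {
  force(cfg); force(hist)
  function(a, b) {
    g <- select_low_similarity(tile_pair(a, b, cfg, hist), cfg)
    combine_selected(a, b, g)
  }
}

#' Per-tile heterogeneity report
#'
#' Estimates the mixing ratios independently on every tile and reports them
#' with the tile's SSIM, giving the quality-control surface for
#' overcorrection risk: when the per-tile ratios are spatially heterogeneous
#' — low-similarity tiles near the true ratio, high-similarity
#' (colocalized) tiles inflated — whole-image MI minimization is being
#' confounded by colocalization.
#'
#' @param a,b The channel pair.
#' @param cfg A [selection_config()]; tiles below 32 px trigger a warning
#'   because MI on very small tiles is unstable.
#' @param grid Candidate ratio grid.
#' @param hist Histogram specification.
#' @return A tibble with one row per tile: `tile`, `row`, `col`, pixel
#'   bounds, `ssim`, `alpha_ab` (ratio of `b` into `a`), `alpha_ba`. Tiles
#'   where estimation fails (e.g. a constant channel) carry `NA` ratios,
#'   not dropped rows.
#' @export
heterogeneity_report <- function(a, b, cfg = selection_config(),
                                 grid = alpha_grid(), hist = hist_spec()) {
  if (cfg$tile_size < 32L)
    warning("tile_size ", cfg$tile_size,
            " px is below 32 px; per-tile MI estimates may be unstable",
            call. = FALSE)
  g <- tile_pair(a, b, selection_config(cfg$tile_size, cfg$percentile,
                                        "ssim"))
  crop <- function(img, t) img[t$y0:t$y1, t$x0:t$x1, drop = FALSE]
  est <- function(t, s) tryCatch(
    estimate_alpha(t, s, grid, hist)$argmin_alpha,
    error = function(e) NA_real_)
  tl <- g$tiles
  ab <- numeric(nrow(tl)); ba <- numeric(nrow(tl))
  for (i in seq_len(nrow(tl))) {
    ta <- crop(a, tl[i, ]); tb <- crop(b, tl[i, ])
    ab[i] <- est(ta, tb)
    ba[i] <- est(tb, ta)
  }
  tibble::tibble(tile = tl$tile, row = tl$row, col = tl$col,
                 y0 = tl$y0, y1 = tl$y1, x0 = tl$x0, x1 = tl$x1,
                 ssim = tl$score, alpha_ab = ab, alpha_ba = ba)
}
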