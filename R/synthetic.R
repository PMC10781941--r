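#' Specification of a synthetic cell phantom
#'
#' Describes a multi-channel phantom of cell-like blobs with a controllable
#' fraction of spatially colocalized signal, additive noise, and a known
#' ground-truth mixing matrix. Phantoms make every stage of the demixing
#' pipeline testable against known truth: colocalization is controlled
#' geometrically (shared blob centres) while crosstalk is applied
#' afterwards with [apply_mixing()], so the two confounded effects can be
#' generated independently.
#'
#' @param shape Image height and width in pixels; default `c(256, 256)`.
#' @param n_channels Number of channels, at least 2.
#' @param n_cells Blobs per channel; default 80 with `cell_radius = 6`,
#'   giving a densely populated tissue-like field at a 256 px scale.
#' @param cell_radius Mean blob radius in pixels (default 6, i.e. ~12 px
#'   cell diameter); per-blob radii are jittered by `radius_jitter`.
#' @param radius_jitter Relative radius jitter (default 0.2).
#' @param coloc_fraction Fraction `rho` in `[0, 1]` of blob centres shared
#'   across all channels. Shared blobs model two markers on one cell:
#'   positions coincide but per-channel amplitudes are drawn independently,
#'   so colocalization is spatial, not intensity-identical. Mirroring real
#'   tissue, where single-positive cells concentrate in distinct zones
#'   rather than salt-and-pepper among double-positive ones, the exclusive
#'   (single-channel) blobs are laid out in a disjoint zone of the field
#'   while shared blobs occupy the rest.
#' @param amplitude Peak blob intensity (arbitrary fluorescence units,
#'   default 1000).
#' @param amp_jitter Relative amplitude jitter per blob per channel
#'   (default 0.3).
#' @param noise_sigma Additive Gaussian (read) noise s.d.; default 0,
#'   modelling a background-subtracted image whose background is
#'   genuinely dark, as in cyclic-immunofluorescence data.
#' @param shot_noise Intensity-dependent noise fraction: each pixel gets
#'   Gaussian noise with s.d. `shot_noise * amplitude * sqrt(I /
#'   amplitude)` (default 0.02, i.e. 2% of peak at full intensity),
#'   emulating photon shot noise.
#' @param poisson If `TRUE`, pixel values are additionally Poisson-resampled.
#'   Off by default to keep phantoms deterministic given the
#'   seed at double precision.
#' @param true_alpha Ground-truth `n x n` mixing matrix (diagonal zero,
#'   entries in `[0, 1)`); default all zero (no crosstalk).
#' @param profile Blob profile: `"gaussian"` (isotropic, s.d. = radius/2.5;
#'   default, avoids aliasing) or `"disk"` (hard-edged).
#' @param seed RNG seed; identical spec + seed gives bit-identical output.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(256L, 256L), n_channels = 2L,
                         n_cells = 80L, cell_radius = 6,
                         radius_jitter = 0.2, coloc_fraction = 0,
                         amplitude = 1000, amp_jitter = 0.3,
                         noise_sigma = 0, shot_noise = 0.02,
                         poisson = FALSE,
                         true_alpha = NULL, profile = c("gaussian", "disk"),
                         seed = 1L) {
  profile <- match.arg(profile)
  n_channels <- as.integer(n_channels)
  if (n_channels < 2L) stop("`n_channels` must be >= 2", call. = FALSE)
  if (!(coloc_fraction >= 0 && coloc_fraction <= 1))
    stop("`coloc_fraction` must be in [0, 1]", call. = FALSE)
  if (cell_radius <= 0) stop("`cell_radius` must be > 0", call. = FALSE)
  if (is.null(true_alpha)) true_alpha <- matrix(0, n_channels, n_channels)
  if (!is.matrix(true_alpha) || !all(dim(true_alpha) == n_channels))
    stop("`true_alpha` must be ", n_channels, "x", n_channels, call. = FALSE)
  if (any(diag(true_alpha) != 0) || any(true_alpha < 0) ||
      any(true_alpha >= 1))
    stop("`true_alpha` needs zero diagonal and entries in [0, 1)",
         call. = FALSE)
  structure(list(shape = as.integer(shape), n_channels = n_channels,
                 n_cells = as.integer(n_cells), cell_radius = cell_radius,
                 radius_jitter = radius_jitter,
                 coloc_fraction = coloc_fraction, amplitude = amplitude,
                 amp_jitter = amp_jitter, noise_sigma = noise_sigma,
                 shot_noise = shot_noise,
                 poisson = poisson, true_alpha = true_alpha,
                 profile = profile, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Run `expr` under a fixed seed without disturbing the caller's RNG state.
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Rejection-sample `n` centres keeping min_sep from `existing` and each
# other, with rows restricted to `ylim`. Errors out when packing is
# infeasible.
.place_centers <- function(n, shape, margin, min_sep, existing,
                           ylim = NULL) {
  if (n == 0L) return(matrix(0, 0, 2))
  if (is.null(ylim)) ylim <- c(1, shape[1])
  ylo <- max(ylim[1], margin); yhi <- min(ylim[2], shape[1] - margin)
  if (yhi <= ylo) { ylo <- ylim[1]; yhi <- ylim[2] }  # very thin zone
  pts <- matrix(0, 0, 2)
  attempts <- 0L
  max_attempts <- 1000L * n
  while (nrow(pts) < n) {
    if (attempts >= max_attempts)
      stop("cannot place ", n, " blobs with separation ", round(min_sep, 1),
           " px in a ", shape[1], "x", shape[2],
           " field: packing infeasible", call. = FALSE)
    attempts <- attempts + 1L
    cand <- c(stats::runif(1, ylo, yhi),
              stats::runif(1, margin, shape[2] - margin))
    all_pts <- rbind(existing, pts)
    if (nrow(all_pts) == 0L ||
        min(sqrt((all_pts[, 1] - cand[1])^2 +
                 (all_pts[, 2] - cand[2])^2)) >= min_sep) {
      pts <- rbind(pts, cand)
    }
  }
  pts
}

# Render one blob additively into img (local window only). Gaussian blobs
# use s.d. = radius / 2.5: a compact core whose halo falls below 1% of
# peak at the minimum centre separation, so adjacent cells do not read as
# spuriously co-occurring signal.
.render_blob <- function(img, cy, cx, r, amp, profile) {
  sigma <- r / 2.5
  half <- ceiling(if (profile == "gaussian") 3.5 * sigma else r)
  ys <- max(1L, floor(cy - half)):min(nrow(img), ceiling(cy + half))
  xs <- max(1L, floor(cx - half)):min(ncol(img), ceiling(cx + half))
  d2 <- outer((ys - cy)^2, (xs - cx)^2, `+`)
  patch <- if (profile == "gaussian") {
    amp * exp(-d2 / (2 * sigma^2))
  } else {
    amp * (d2 <= r^2)
  }
  img[ys, xs] <- img[ys, xs] + patch
  img
}

#' Generate a ground-truth (unmixed) phantom stack
#'
#' Places `floor(coloc_fraction * n_cells)` blob centres shared by all
#' channels and the remainder exclusively per channel. All centres are
#' rejection-sampled to keep a minimum separation of 2.5 cell radii
#' (5 Gaussian s.d. between centres), so exclusive blobs of different
#' channels have disjoint support (at `coloc_fraction = 0` the noiseless
#' channels are spatially disjoint).
#'
#' When both shared and exclusive blobs are present, the exclusive blobs
#' of all channels are interleaved in a single-positive zone (a bottom
#' band of the field sized to hold them, at least a quarter of the image),
#' and the shared blobs occupy the remaining band. This mirrors the zonal
#' organization of real tissue, where single-positive cells concentrate in
#' distinct compartments instead of scattering uniformly among
#' double-positive cells, and is what gives a tiled similarity analysis
#' genuinely dissimilar regions to find.
#'
#' Blobs are rendered with the configured profile, per-blob-per-channel
#' amplitude jitter is applied, noise is added (intensity-dependent shot
#' noise plus optional additive read noise), and intensities are clamped
#' to be non-negative.
#'
#' @param spec A [phantom_spec()].
#' @return An [image_stack()] of the noisy ground-truth channels, with the
#'   noiseless channels attached as `attr(, "noiseless")` (an
#'   `image_stack`) for oracle comparisons.
#' @export
generate_ground_truth <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  .with_seed(spec$seed, {
    sh <- spec$shape
    n_shared <- as.integer(floor(spec$coloc_fraction * spec$n_cells))
    n_excl <- spec$n_cells - n_shared
    min_sep <- 2.5 * spec$cell_radius
    margin <- 2 * spec$cell_radius
    area <- prod(sh)
    apb <- 1.9 * min_sep^2  # comfortable packing area per blob

    if (n_shared > 0L && n_excl > 0L) {
      f <- spec$n_channels * n_excl * apb / area
      f_max <- 1 - 1.15 * n_shared * apb / area
      f <- min(max(f, 0.25), max(f_max, 0.1))
      y_split <- (1 - f) * sh[1]
      # keep shared blobs one separation length clear of the zone boundary
      # so their tails do not bleed into the single-positive zone
      shared_ylim <- c(1, max(1, y_split - min_sep))
      excl_ylim <- c(y_split, sh[1])
    } else {
      shared_ylim <- excl_ylim <- c(1, sh[1])
    }

    shared <- .place_centers(n_shared, sh, margin, min_sep,
                             matrix(0, 0, 2), shared_ylim)
    excl <- list()
    placed <- shared
    for (c in seq_len(spec$n_channels)) {
      e <- .place_centers(n_excl, sh, margin, min_sep, placed, excl_ylim)
      excl[[c]] <- e
      placed <- rbind(placed, e)
    }
    clean <- vector("list", spec$n_channels)
    for (c in seq_len(spec$n_channels)) {
      img <- matrix(0, sh[1], sh[2])
      centers <- rbind(shared, excl[[c]])
      for (k in seq_len(nrow(centers))) {
        r <- spec$cell_radius *
          stats::runif(1, 1 - spec$radius_jitter, 1 + spec$radius_jitter)
        amp <- spec$amplitude *
          stats::runif(1, 1 - spec$amp_jitter, 1 + spec$amp_jitter)
        img <- .render_blob(img, centers[k, 1], centers[k, 2], r, amp,
                            spec$profile)
      }
      clean[[c]] <- img
    }
    noisy <- lapply(clean, function(img) {
      if (spec$poisson) img <- stats::rpois(length(img), img) * 1.0
      sd_px <- sqrt(spec$noise_sigma^2 +
                    (spec$shot_noise * spec$amplitude)^2 *
                      pmax(img, 0) / spec$amplitude)
      img <- img + stats::rnorm(length(img), 0, 1) * sd_px
      matrix(pmax(img, 0), sh[1], sh[2])
    })
    out <- image_stack(noisy)
    attr(out, "noiseless") <- image_stack(clean)
    out
  })
}

#' Apply the forward linear mixing model
#'
#' Produces the measured channels from the true ones:
#' `Img_i = F_i + sum_{j != i} alpha[i, j] * F_j`. All inputs being
#' non-negative, no clamping is needed; total intensity is conserved up to
#' the mixing weights.
#'
#' @param stack The ground-truth [image_stack()].
#' @param alpha `n x n` mixing matrix, zero diagonal, entries `>= 0`.
#' @return The mixed `image_stack`.
#' @export
apply_mixing <- function(stack, alpha) {
  stopifnot(inherits(stack, "image_stack"))
  n <- n_channels(stack)
  if (!is.matrix(alpha) || !all(dim(alpha) == n))
    stop("`alpha` must be ", n, "x", n, call. = FALSE)
  if (any(diag(alpha) != 0) || any(alpha < 0))
    stop("`alpha` needs zero diagonal and non-negative entries",
         call. = FALSE)
  mixed <- lapply(seq_len(n), function(i) {
    acc <- stack[[i]]
    for (j in seq_len(n)[-i]) if (alpha[i, j] != 0)
      acc <- acc + alpha[i, j] * stack[[j]]
    acc
  })
  .restack(mixed, stack)
}

#' Generate a benchmark suite over colocalization and mixing conditions
#'
#' Builds a grid of phantoms crossing colocalization fractions with
#' ground-truth mixing-ratio pairs, with `reps` independent replicates per
#' condition. Seeds are derived deterministically from the base spec's seed
#' so the suite is reproducible case by case.
#'
#' @param rho Numeric vector of colocalization fractions.
#' @param alpha_pairs A list of length-2 numeric vectors `c(a12, a21)`
#'   (ratios of channel 2 into 1 and 1 into 2).
#' @param reps Replicates per condition (default 1).
#' @param base_spec A two-channel [phantom_spec()] providing all other
#'   parameters.
#' @return A list with `manifest` (a tibble: case, rho, a12, a21, rep,
#'   seed) and `cases` (a list of `list(spec, truth, mixed)` in manifest
#'   order).
#' @export
make_benchmark_suite <- function(rho, alpha_pairs, reps = 1L, base_spec) {
  stopifnot(inherits(base_spec, "phantom_spec"), reps >= 1L)
  if (base_spec$n_channels != 2L)
    stop("benchmark suite is defined for two-channel phantoms",
         call. = FALSE)
  if (length(rho) == 0L || length(alpha_pairs) == 0L)
    stop("empty condition grid", call. = FALSE)
  rows <- list(); cases <- list(); case_id <- 0L
  for (r in rho) for (ap in alpha_pairs) for (rep in seq_len(reps)) {
    case_id <- case_id + 1L
    seed <- (base_spec$seed + 7919L * case_id) %% .Machine$integer.max
    sp <- base_spec
    sp$coloc_fraction <- r
    sp$true_alpha <- matrix(c(0, ap[2], ap[1], 0), 2, 2)
    sp$seed <- as.integer(seed)
    truth <- generate_ground_truth(sp)
    mixed <- apply_mixing(truth, sp$true_alpha)
    rows[[case_id]] <- tibble::tibble(case = case_id, rho = r,
                                      a12 = ap[1], a21 = ap[2],
                                      rep = rep, seed = seed)
    cases[[case_id]] <- list(spec = sp, truth = truth, mixed = mixed)
  }
  list(manifest = do.call(rbind, rows), cases = cases)
}
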