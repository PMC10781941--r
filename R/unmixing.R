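#' Candidate grid for the mixing-ratio search
#'
#' The mixing ratio is found by evaluating the mutual information on a
#' uniform grid of candidate ratios, then refining the grid minimum with one
#' three-point parabolic fit. The MI-versus-ratio curves are smooth and
#' unimodal in practice, so grid search plus local refinement is robust and
#' reproducible.
#'
#' @param from,to Grid limits (ratios, dimensionless). Default `[0, 1]`:
#'   crosstalk above 100% of the source channel is not physical.
#' @param step Grid spacing; default 0.01.
#' @return A strictly increasing numeric vector of candidate ratios.
#' @export
alpha_grid <- function(from = 0, to = 1, step = 0.01) {
  if (!(from >= 0 && to > from && step > 0))
    stop("need 0 <= from < to and step > 0", call. = FALSE)
  seq(from, to, by = step)
}

.check_grid <- function(grid) {
  if (length(grid) == 0L) stop("alpha grid is empty", call. = FALSE)
  if (any(grid < 0) || any(diff(grid) <= 0))
    stop("alpha grid must be non-negative and strictly increasing",
         call. = FALSE)
  invisible(grid)
}

#' Estimate a pairwise mixing ratio by MI minimization
#'
#' Scans candidate ratios `a` and evaluates the normalized mutual
#' information between the `source` channel and the residual
#' `target - a * source` (negative residual pixels are clamped to zero
#' before the MI evaluation, since fluorescence is non-negative). The mixing
#' ratio is the minimizer: at the true ratio the leaked copy of `source` has
#' been removed from `target` and the statistical dependence between the two
#' is smallest. The orientation follows the mixing model: the ratio
#' `alpha_ij` of channel `j` leaking into measured channel `i` is estimated
#' with `target` = channel `i` and `source` = channel `j`.
#'
#' Because the clamped subtraction saturates once a leaked component has
#' been fully removed, the MI curve typically has a flat valley extending
#' from the true ratio toward larger candidates. The minimizer is therefore
#' chosen as the *smallest* candidate whose MI lies within
#' `plateau_tol * (max(mi) - min(mi))` of the curve minimum — the
#' least-correction principle: within the statistical resolution of the
#' curve, prefer the weakest correction that explains the data. A strict
#' interior minimum is additionally refined by one parabolic fit through
#' its two grid neighbours.
#'
#' @param target The measured channel containing the leaked signal.
#' @param source The channel whose leakage into `target` is estimated; must
#'   be non-constant.
#' @param grid Candidate ratios, see [alpha_grid()].
#' @param hist Histogram specification for the MI evaluations.
#' @param plateau_tol Fraction of the MI curve's amplitude within which a
#'   candidate counts as tied with the minimum (default 0.05). Zero
#'   recovers the plain first-minimum rule.
#' @param plateau_min Absolute floor (in normalized-MI units, default
#'   0.005) on the tie band: variation below this is treated as
#'   estimation noise, so a curve that is flat to within `plateau_min`
#'   yields the smallest candidate — no measurable crosstalk, no
#'   correction.
#' @return An object of class `mi_curve` with fields `alphas`, `mi`,
#'   `argmin_alpha` (refined), and `grid_argmin`.
#' @examples
#' f1 <- matrix(0, 64, 64); f1[10:20, 10:20] <- 100
#' f2 <- matrix(0, 64, 64); f2[40:50, 40:50] <- 100
#' mixed <- f1 + 0.3 * f2
#' estimate_alpha(mixed, f2)$argmin_alpha  # close to 0.3
#' @export
estimate_alpha <- function(target, source, grid = alpha_grid(),
                           hist = hist_spec(), plateau_tol = 0.05,
                           plateau_min = 0.005) {
  .check_image(target, "target"); .check_image(source, "source")
  .check_same_shape(target, source)
  .check_grid(grid)
  if (min(source) == max(source))
    stop("`source` channel is constant; mixing ratio is unidentifiable",
         call. = FALSE)
  mi <- vapply(grid, function(a) {
    normalized_mi(source, pmax(target - a * source, 0), hist)
  }, numeric(1))
  band <- min(mi) + max(plateau_tol * (max(mi) - min(mi)), plateau_min)
  k <- which(mi <= band)[1]  # smallest candidate within the valley
  a_hat <- grid[k]
  if (k > 1L && k < length(grid) &&
      mi[k] < mi[k - 1L] && mi[k] < mi[k + 1L]) {
    a_hat <- .parabolic_refine(grid[k - 1L], grid[k], grid[k + 1L],
                               mi[k - 1L], mi[k], mi[k + 1L])
  }
  structure(list(alphas = grid, mi = mi,
                 argmin_alpha = a_hat, grid_argmin = grid[k]),
            class = "mi_curve")
}

# estimate_alpha that degrades gracefully on degenerate composites: a
# source with no structure carries no evidence of crosstalk, so the
# least-correction answer is zero.
.estimate_alpha_safe <- function(target, source, grid, hist,
                                 plateau_tol = 0.05) {
  if (min(source) == max(source) || min(target) == max(target))
    return(structure(list(alphas = grid, mi = rep(NA_real_, length(grid)),
                          argmin_alpha = 0, grid_argmin = 0,
                          degenerate = TRUE),
                     class = "mi_curve"))
  estimate_alpha(target, source, grid, hist, plateau_tol)
}

# Vertex of the parabola through three points; falls back to the middle
# point when the fit is degenerate or leaves the bracketing interval.
.parabolic_refine <- function(x0, x1, x2, y0, y1, y2) {
  denom <- (x1 - x0) * (y1 - y2) - (x1 - x2) * (y1 - y0)
  if (denom <= 0) return(x1)  # non-convex or flat: keep grid minimum
  num <- (x1 - x0)^2 * (y1 - y2) - (x1 - x2)^2 * (y1 - y0)
  v <- x1 - 0.5 * num / denom
  if (is.finite(v) && v >= x0 && v <= x2) v else x1
}

#' @export
print.mi_curve <- function(x, ...) {
  cat("<mi_curve> ", length(x$alphas), " candidates on [",
      min(x$alphas), ", ", max(x$alphas), "], argmin alpha = ",
      signif(x$argmin_alpha, 4), " (MI ", signif(min(x$mi), 4), ")\n",
      sep = "")
  invisible(x)
}

#' Mixing-ratio estimate for a stack
#'
#' Holds the matrix of pairwise mixing ratios `alpha[i, j]` (the fraction of
#' channel `j`'s signal leaking into measured channel `i`; diagonal zero),
#' the update step size `gamma`, and iteration provenance.
#'
#' @param alpha Square numeric matrix, diagonal zero, entries in
#'   `[0, alpha_max]`.
#' @param gamma Update step size in `(0, 1]`.
#' @param iterations_run Number of demixing iterations represented.
#' @param alpha_max Cap on individual ratios; estimates at the cap are
#'   suspect (flagged by [demix_stack()] diagnostics).
#' @return An object of class `mixing_estimate`.
#' @export
mixing_estimate <- function(alpha, gamma = 1, iterations_run = 0L,
                            alpha_max = 1) {
  if (!is.matrix(alpha) || nrow(alpha) != ncol(alpha))
    stop("`alpha` must be a square matrix", call. = FALSE)
  if (any(!is.finite(alpha)) || any(alpha < 0))
    stop("`alpha` entries must be finite and >= 0", call. = FALSE)
  if (any(diag(alpha) != 0))
    stop("`alpha` diagonal must be zero", call. = FALSE)
  if (!(gamma > 0 && gamma <= 1))
    stop("`gamma` must be in (0, 1]", call. = FALSE)
  structure(list(alpha = alpha, gamma = gamma,
                 iterations_run = as.integer(iterations_run),
                 alpha_max = alpha_max),
            class = "mixing_estimate")
}

#' @export
print.mixing_estimate <- function(x, ...) {
  cat("<mixing_estimate> ", nrow(x$alpha), " channels, gamma = ", x$gamma,
      ", iterations = ", x$iterations_run, "\n", sep = "")
  print(round(x$alpha, 4))
  invisible(x)
}

#' Demix a two-channel stack in one subtraction step
#'
#' Inverts the linear mixing model for a channel pair by single-step
#' subtraction against the original (not updated) partner channel:
#' `out1 = Img1 - alpha[1,2] * Img2`, `out2 = Img2 - alpha[2,1] * Img1`,
#' with negative pixels clamped to zero.
#'
#' @param stack A two-channel [image_stack()].
#' @param est A [mixing_estimate()] with a 2x2 alpha matrix.
#' @return The demixed two-channel `image_stack`.
#' @export
unmix_pair <- function(stack, est) {
  stopifnot(inherits(stack, "image_stack"), inherits(est, "mixing_estimate"))
  if (n_channels(stack) != 2L || nrow(est$alpha) != 2L)
    stop("unmix_pair() requires exactly 2 channels", call. = FALSE)
  a <- est$alpha
  .restack(list(pmax(stack[[1]] - a[1, 2] * stack[[2]], 0),
                pmax(stack[[2]] - a[2, 1] * stack[[1]], 0)),
           stack)
}

#' Build the per-iteration update matrix
#'
#' Constructs the `n x n` update matrix with ones on the diagonal and
#' `-gamma * alpha[i, j]` off the diagonal. One demixing iteration replaces
#' the channel vector `X` by `P %*% X` (channel-wise linear combination).
#'
#' @param est A [mixing_estimate()].
#' @return The update matrix.
#' @examples
#' est <- mixing_estimate(matrix(c(0, 0.6, 0.2, 0), 2, 2), gamma = 1)
#' build_p_matrix(est)  # [[1, -0.2], [-0.6, 1]]
#' @export
build_p_matrix <- function(est) {
  stopifnot(inherits(est, "mixing_estimate"))
  diag(nrow(est$alpha)) - est$gamma * est$alpha
}

#' Iteration configuration for multi-channel demixing
#'
#' @param gamma Update step size in `(0, 1]`. Default: 1 for two-channel
#'   stacks (single-pass exact subtraction), 0.5 for three or more channels
#'   (damped steps stabilize the coupling between pairs).
#' @param max_iters Maximum iterations. Default: 1 for two channels, 10
#'   otherwise.
#' @param tol Convergence tolerance on the largest per-pair ratio estimated
#'   in a round; default 0.01.
#' @param grid,hist Passed to [estimate_alpha()].
#' @param alpha_max Cap on individual ratios (default 1); capped estimates
#'   are flagged.
#' @return An object of class `demix_config`.
#' @export
demix_config <- function(gamma = NULL, max_iters = NULL, tol = 0.01,
                         grid = alpha_grid(), hist = hist_spec(),
                         alpha_max = 1) {
  .check_grid(grid)
  structure(list(gamma = gamma, max_iters = max_iters, tol = tol,
                 grid = grid, hist = hist, alpha_max = alpha_max),
            class = "demix_config")
}

.resolve_cfg <- function(cfg, n) {
  if (is.null(cfg$gamma)) cfg$gamma <- if (n == 2L) 1 else 0.5
  if (is.null(cfg$max_iters)) cfg$max_iters <- if (n == 2L) 1L else 10L
  if (!(cfg$gamma >= 0 && cfg$gamma <= 1))
    stop("`gamma` must be in [0, 1]", call. = FALSE)
  cfg
}

#' Iteratively demix an n-channel stack
#'
#' Runs the iterative update: at each round, the mixing ratio
#' `alpha[i, j]` is re-estimated for every ordered channel pair from the
#' current stack snapshot (all pairs see the same snapshot; the update is
#' applied simultaneously through the matrix from [build_p_matrix()]), then
#' every channel is replaced by the corresponding linear combination and
#' negatives are clamped to zero. Iteration stops after `max_iters` rounds
#' or once the largest ratio estimated in a round falls below `tol`.
#'
#' When a `selector` is supplied (see [mosaic_selector()]), each pair's
#' ratios are estimated on the composite of that pair's selected
#' low-similarity tiles instead of the whole image, which prevents genuine
#' spatial colocalization from being mistaken for crosstalk. Each pair
#' selects its own tiles independently, re-scored each round.
#'
#' @param stack An [image_stack()] with 2 or more channels.
#' @param cfg A [demix_config()].
#' @param selector Optional `function(a, b)` returning
#'   `list(a = , b = )` composite images on which to estimate the pair's
#'   ratios; `NULL` (default) estimates on the whole image.
#' @return A list with components `stack` (demixed), `estimate` (a
#'   [mixing_estimate()] whose alpha is the cumulative gamma-weighted sum of
#'   per-round ratios), `history` (tibble of per-round per-pair ratios),
#'   `converged` (logical; `FALSE` means `max_iters` was reached with
#'   ratios still above `tol` — returned with a warning flag, not an error)
#'   and `capped` (logical; any ratio hit `alpha_max`).
#' @export
demix_stack <- function(stack, cfg = demix_config(), selector = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  n <- n_channels(stack)
  cfg <- .resolve_cfg(cfg, n)
  X <- as.list(stack)
  eff <- matrix(0, n, n)
  hist_rows <- list()
  converged <- FALSE
  capped <- FALSE
  iters <- 0L

  for (k in seq_len(cfg$max_iters)) {
    A <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
      xi <- X[[i]]; xj <- X[[j]]
      if (min(xi) == max(xi) || min(xj) == max(xj)) next  # degenerate pair
      if (!is.null(selector)) {
        comp <- selector(xi, xj)
        xi <- comp$a; xj <- comp$b
      }
      A[i, j] <- .estimate_alpha_safe(xi, xj, cfg$grid,
                                      cfg$hist)$argmin_alpha
      A[j, i] <- .estimate_alpha_safe(xj, xi, cfg$grid,
                                      cfg$hist)$argmin_alpha
    }
    if (any(A >= cfg$alpha_max)) capped <- TRUE
    A <- pmin(A, cfg$alpha_max)
    iters <- k
    for (ij in which(A != 0)) {
      i <- (ij - 1L) %% n + 1L; j <- (ij - 1L) %/% n + 1L
      hist_rows[[length(hist_rows) + 1L]] <-
        tibble::tibble(iteration = k, i = i, j = j, alpha = A[i, j])
    }
    # apply the simultaneous update, then test convergence
    P <- diag(n) - cfg$gamma * A
    X <- lapply(seq_len(n), function(i) {
      acc <- P[i, i] * X[[i]]
      for (j in seq_len(n)[-i]) if (P[i, j] != 0)
        acc <- acc + P[i, j] * X[[j]]
      pmax(acc, 0)
    })
    eff <- eff + cfg$gamma * A
    if (max(A) < cfg$tol) { converged <- TRUE; break }
  }
  if (!converged && iters == cfg$max_iters && cfg$max_iters > 0L)
    converged <- FALSE

  history <- if (length(hist_rows)) do.call(rbind, hist_rows)
             else tibble::tibble(iteration = integer(), i = integer(),
                                 j = integer(), alpha = numeric())
  list(stack = .restack(X, stack),
       estimate = mixing_estimate(eff, gamma = max(cfg$gamma, 1e-12),
                                  iterations_run = iters,
                                  alpha_max = cfg$alpha_max),
       history = history,
       converged = converged,
       capped = capped)
}
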