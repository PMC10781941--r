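#' Histogram specification for entropy and mutual-information estimates
#'
#' Entropy and mutual information are computed from plug-in estimates on
#' intensity histograms. The specification fixes the number of bins and,
#' optionally, a fixed intensity range. When `range` is `NULL` (the
#' default) each image is binned on its own min--max. Per-image binning
#' makes every histogram quantity invariant to affine rescaling of either
#' channel, which matters during crosstalk estimation: subtracting a scaled
#' copy of one channel shrinks the residual's amplitude, and binning the
#' residual on a scale fixed by the brighter partner would deflate its
#' entropy purely through that shrinkage, biasing the mutual-information
#' minimum toward over-subtraction. Supplying a fixed `range` puts both
#' channels of a pair on one common absolute scale instead.
#'
#' @param bins Number of histogram bins (integer, at least 2). Default 256,
#'   matching the dynamic range of 8-bit data and a common choice for
#'   histogram mutual information on microscopy images.
#' @param range Optional fixed intensity range `c(lo, hi)`. When supplied it
#'   overrides the data-derived range, e.g. `c(0, 65535)` to bin on the full
#'   16-bit scale regardless of content.
#' @return An object of class `hist_spec`.
#' @examples
#' h <- hist_spec(bins = 64)
#' img <- matrix(runif(100), 10, 10)
#' entropy(img, h)
#' @export
hist_spec <- function(bins = 256L, range = NULL) {
  bins <- as.integer(bins)
  if (length(bins) != 1L || is.na(bins) || bins < 2L)
    stop("`bins` must be a single integer >= 2", call. = FALSE)
  if (!is.null(range)) {
    if (length(range) != 2L || !all(is.finite(range)) || range[2] < range[1])
      stop("`range` must be c(lo, hi) with lo <= hi", call. = FALSE)
    range <- as.numeric(range)
  }
  structure(list(bins = bins, range = range), class = "hist_spec")
}

#' @export
print.hist_spec <- function(x, ...) {
  rng <- if (is.null(x$range)) "data-derived (shared over pair)"
         else sprintf("[%g, %g]", x$range[1], x$range[2])
  cat("<hist_spec> bins:", x$bins, " range:", rng, "\n")
  invisible(x)
}

.check_image <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img))
    stop("`", arg, "` must be a numeric matrix", call. = FALSE)
  if (length(img) == 0L)
    stop("`", arg, "` is empty", call. = FALSE)
  if (!all(is.finite(img)))
    stop("`", arg, "` contains non-finite values (NaN/Inf/NA)", call. = FALSE)
  invisible(img)
}

.check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("images must have identical dimensions: ",
         paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"), call. = FALSE)
  invisible(NULL)
}

# Map intensities to bin indices 1..bins over [lo, hi]. Degenerate range
# (constant data) puts everything in bin 1.
.bin_index <- function(x, lo, hi, bins) {
  if (hi <= lo) return(rep.int(1L, length(x)))
  idx <- floor((as.numeric(x) - lo) / (hi - lo) * bins) + 1L
  idx[idx > bins] <- bins  # x == hi lands in the top bin
  as.integer(idx)
}

.range_for <- function(hist, x) {
  if (!is.null(hist$range)) return(hist$range)
  range(x, na.rm = FALSE)
}

.entropy_from_counts <- function(counts) {
  p <- counts[counts > 0L] / sum(counts)
  -sum(p * log2(p))
}

#' Shannon entropy of an image intensity histogram
#'
#' Plug-in entropy \eqn{H = -\sum_i P(i) \log_2 P(i)} of the pixel-intensity
#' histogram, in bits. Empty bins contribute zero (the limit
#' \eqn{p \log p \to 0}).
#'
#' @param img Numeric matrix of pixel intensities (one channel).
#' @param hist A [hist_spec()].
#' @return Entropy in bits, in `[0, log2(bins)]`.
#' @examples
#' entropy(matrix(5, 4, 4))            # constant image: 0 bits
#' entropy(matrix(c(0, 1), 4, 4))      # two equi-probable levels: 1 bit
#' @export
entropy <- function(img, hist = hist_spec()) {
  .check_image(img)
  rng <- .range_for(hist, img)
  idx <- .bin_index(img, rng[1], rng[2], hist$bins)
  .entropy_from_counts(tabulate(idx, nbins = hist$bins))
}

#' Joint entropy of two co-registered channels
#'
#' Plug-in joint entropy \eqn{H = -\sum_{i,j} P(i,j) \log_2 P(i,j)} of the
#' two-dimensional intensity histogram, in bits. Each channel is binned on
#' its own min--max range (or `hist$range` for both when fixed), matching
#' the marginal binning used by [entropy()] so the usual entropy
#' inequalities hold exactly.
#'
#' @param a,b Numeric matrices of identical dimensions.
#' @inheritParams entropy
#' @return Joint entropy in bits; satisfies
#'   `max(H(a), H(b)) <= H(a,b) <= H(a) + H(b)`.
#' @export
joint_entropy <- function(a, b, hist = hist_spec()) {
  .check_image(a, "a"); .check_image(b, "b")
  .check_same_shape(a, b)
  ra <- .range_for(hist, a)
  rb <- .range_for(hist, b)
  ia <- .bin_index(a, ra[1], ra[2], hist$bins)
  ib <- .bin_index(b, rb[1], rb[2], hist$bins)
  .entropy_from_counts(tabulate(ia + (ib - 1L) * hist$bins,
                                nbins = hist$bins * hist$bins))
}

#' Normalized mutual information between two channels
#'
#' Computes \eqn{2\,(H_1 + H_2 - H_{1,2}) / (H_1 + H_2)}, where the
#' marginal and joint entropies are histogram plug-in estimates with each
#' channel binned on its own range (see [hist_spec()]). The result lies in
#' `[0, 1]`: 0 for statistically independent channels, 1 for identical
#' ones. Values outside `[0, 1]` by tiny floating-point margins are
#' clipped.
#'
#' @param a,b Numeric matrices of identical dimensions; at least one must be
#'   non-constant.
#' @inheritParams entropy
#' @return Normalized mutual information in `[0, 1]`.
#' @examples
#' x <- matrix(runif(64 * 64), 64, 64)
#' normalized_mi(x, x)                      # 1: identical
#' normalized_mi(x, matrix(runif(64 * 64), 64, 64))  # near 0: independent
#' @export
normalized_mi <- function(a, b, hist = hist_spec()) {
  .check_image(a, "a"); .check_image(b, "b")
  .check_same_shape(a, b)
  ha <- entropy(a, hist)
  hb <- entropy(b, hist)
  if (ha + hb == 0)
    stop("degenerate pair: both channels are constant", call. = FALSE)
  hab <- joint_entropy(a, b, hist)
  mi <- 2 * (ha + hb - hab) / (ha + hb)
  min(1, max(0, mi))
}

#' Structural similarity index (SSIM) between two channels
#'
#' Mean SSIM over all full sliding windows, with a uniform `win x win`
#' window, stability constants `K1 = 0.01`, `K2 = 0.03`, sample (n-1)
#' variance/covariance normalization, and dynamic range taken as the shared
#' max minus min of the pair (unless `data_range` is given). This matches the
#' default uniform-window formulation in common image-processing libraries.
#'
#' @param a,b Numeric matrices of identical dimensions, each side at least
#'   `win` pixels.
#' @param win Window side length in pixels (odd, default 7).
#' @param K1,K2 SSIM stability constants.
#' @param data_range Dynamic range `L`; default `max(a, b) - min(a, b)`.
#' @return Mean SSIM in `[-1, 1]`; 1 for identical images.
#' @export
ssim_score <- function(a, b, win = 7L, K1 = 0.01, K2 = 0.03,
                       data_range = NULL) {
  .check_image(a, "a"); .check_image(b, "b")
  .check_same_shape(a, b)
  win <- as.integer(win)
  if (any(dim(a) < win))
    stop("image (", paste(dim(a), collapse = "x"),
         ") is smaller than the SSIM window (", win, "x", win, ")",
         call. = FALSE)
  if (is.null(data_range)) data_range <- max(a, b) - min(a, b)
  if (data_range == 0) return(1)  # equal constants everywhere

  n <- win * win
  sa  <- .box_sum(a, win)
  sb  <- .box_sum(b, win)
  saa <- .box_sum(a * a, win)
  sbb <- .box_sum(b * b, win)
  sab <- .box_sum(a * b, win)

  ua <- sa / n
  ub <- sb / n
  # sample (n-1) normalization
  va  <- (saa - sa * sa / n) / (n - 1)
  vb  <- (sbb - sb * sb / n) / (n - 1)
  cab <- (sab - sa * sb / n) / (n - 1)

  C1 <- (K1 * data_range)^2
  C2 <- (K2 * data_range)^2
  s <- ((2 * ua * ub + C1) * (2 * cab + C2)) /
       ((ua * ua + ub * ub + C1) * (va + vb + C2))
  mean(s)
}

# Sum of every full w x w window via an integral image (exact, no padding).
.box_sum <- function(x, w) {
  S <- rbind(0, apply(x, 2L, cumsum))
  S <- cbind(0, t(apply(S, 1L, cumsum)))
  nr <- nrow(x); nc <- ncol(x)
  ri <- seq_len(nr - w + 1L); ci <- seq_len(nc - w + 1L)
  S[ri + w, ci + w, drop = FALSE] - S[ri, ci + w, drop = FALSE] -
    S[ri + w, ci, drop = FALSE] + S[ri, ci, drop = FALSE]
}

#' Pearson correlation between two channels
#'
#' Sample Pearson correlation coefficient over flattened pixel intensities.
#'
#' @param a,b Numeric matrices of identical dimensions, both non-constant.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_score <- function(a, b) {
  .check_image(a, "a"); .check_image(b, "b")
  .check_same_shape(a, b)
  if (stats::var(as.vector(a)) == 0 || stats::var(as.vector(b)) == 0)
    stop("Pearson correlation undefined for a constant channel",
         call. = FALSE)
  stats::cor(as.vector(a), as.vector(b))
}
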