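#' Multi-channel image stack
#'
#' An ordered set of co-registered single-channel images (numeric matrices of
#' identical dimensions), one channel per fluorophore. Channel order is
#' meaningful and preserved by all operations.
#'
#' @param channels A list of numeric matrices with identical dimensions, or a
#'   3-d array with the channel axis first.
#' @param names Optional character vector of channel labels; defaults to
#'   `"ch1"`, `"ch2"`, ...
#' @return An object of class `image_stack`: a named list of matrices.
#' @examples
#' st <- image_stack(list(matrix(runif(16), 4, 4), matrix(runif(16), 4, 4)))
#' n_channels(st)
#' @export
image_stack <- function(channels, names = NULL) {
  if (is.array(channels) && length(dim(channels)) == 3L)
    channels <- lapply(seq_len(dim(channels)[1]),
                       function(i) channels[i, , ])
  if (!is.list(channels) || length(channels) < 2L)
    stop("an image stack needs at least 2 channels", call. = FALSE)
  for (i in seq_along(channels)) .check_image(channels[[i]], paste0("channel ", i))
  d <- dim(channels[[1]])
  for (i in seq_along(channels)[-1])
    if (!identical(dim(channels[[i]]), d))
      stop("channel ", i, " has dimensions ",
           paste(dim(channels[[i]]), collapse = "x"),
           ", expected ", paste(d, collapse = "x"), call. = FALSE)
  if (is.null(names)) names <- paste0("ch", seq_along(channels))
  if (length(names) != length(channels))
    stop("`names` must match the number of channels", call. = FALSE)
  structure(stats::setNames(channels, names), class = "image_stack")
}

#' @rdname image_stack
#' @param x An `image_stack`.
#' @export
n_channels <- function(x) {
  stopifnot(inherits(x, "image_stack"))
  length(x)
}

#' @export
dim.image_stack <- function(x) dim(x[[1]])

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x)
  cat("<image_stack> ", length(x), " channels, ", d[1], " x ", d[2],
      " px\n", sep = "")
  for (nm in names(x))
    cat(sprintf("  %-12s [%.4g, %.4g]\n", nm, min(x[[nm]]), max(x[[nm]])))
  invisible(x)
}

#' @export
as.list.image_stack <- function(x, ...) {
  out <- unclass(x)
  attributes(out) <- list(names = names(out))  # drop auxiliary attributes
  out
}

# internal: rebuild a stack from a plain list, keeping names
.restack <- function(channels, template) {
  image_stack(channels, names = names(template))
}
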