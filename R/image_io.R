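#' Read a multi-channel image stack
#'
#' Reads a multi-page TIFF (one page per channel) or a directory of
#' single-channel TIFF/PNG files (channels in lexicographic filename
#' order). Integer data are read at their raw stored values and promoted to
#' double for computation; the stored dtype is recorded in the metadata.
#' When a JSON sidecar written by [write_stack()] sits next to the file
#' (`<path>.json`), its channel names and intensity scale are applied.
#'
#' @param path Path to a multi-page TIFF or a directory of single-channel
#'   files.
#' @return A list with `stack` (an [image_stack()]) and `metadata` (a list:
#'   `channel_names`, `pixel_dtype`, `scale`, `provenance`, and `alpha` if
#'   the sidecar carries a demixing matrix).
#' @export
read_stack <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(tif|tiff|png)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) < 2L)
      stop("directory must contain at least 2 single-channel images",
           call. = FALSE)
    pages <- lapply(files, .read_one_page)
    sidecar <- .read_sidecar(file.path(path, "stack.json"))
  } else {
    if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
    info <- tiff::readTIFF(path, payload = FALSE, all = TRUE)
    bits <- as.integer(info$bits.per.sample)
    # 32-bit samples are floating point in this writer; 8/16 are unsigned
    is_float <- bits == 32L
    raw <- tiff::readTIFF(path, all = TRUE, as.is = !any(is_float))
    if (!is.list(raw)) raw <- list(raw)
    pages <- lapply(seq_along(raw), function(i)
      list(pixels = .drop_alpha(raw[[i]]),
           dtype = if (is_float[i]) "float32"
                   else paste0("uint", bits[i])))
    sidecar <- .read_sidecar(paste0(path, ".json"))
  }
  dims <- lapply(pages, function(p) dim(p$pixels))
  if (length(unique(dims)) != 1L)
    stop("channels have mixed shapes: ",
         paste(vapply(dims, paste, "", collapse = "x"), collapse = ", "),
         call. = FALSE)
  scale <- if (!is.null(sidecar$scale)) as.numeric(sidecar$scale) else 1
  channels <- lapply(pages, function(p) {
    px <- p$pixels
    storage.mode(px) <- "double"  # integer data promoted for computation
    px * scale
  })
  nm <- sidecar$channel_names %||% paste0("ch", seq_along(channels))
  list(stack = image_stack(channels, names = nm),
       metadata = list(channel_names = nm,
                       pixel_dtype = pages[[1]]$dtype,
                       scale = scale,
                       provenance = sidecar$provenance %||% "",
                       alpha = .sidecar_alpha(sidecar)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.read_sidecar <- function(path) {
  if (!file.exists(path)) return(list())
  jsonlite::fromJSON(path, simplifyMatrix = TRUE)
}

.sidecar_alpha <- function(sidecar) {
  if (is.null(sidecar$alpha)) return(NULL)
  as.matrix(sidecar$alpha)
}

.drop_alpha <- function(m) {
  if (length(dim(m)) == 3L) m[, , 1L] else m
}

.read_one_page <- function(file) {
  if (grepl("\\.png$", file, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("reading PNG requires the 'png' package", call. = FALSE)
    return(list(pixels = .drop_alpha(png::readPNG(file)), dtype = "png"))
  }
  info <- tiff::readTIFF(file, payload = FALSE)
  bits <- as.integer(info$bits.per.sample[1])
  is_float <- bits == 32L
  px <- tiff::readTIFF(file, as.is = !is_float)
  list(pixels = .drop_alpha(px),
       dtype = if (is_float) "float32" else paste0("uint", bits))
}

#' Write a multi-channel image stack
#'
#' Writes a multi-page TIFF (one page per channel, channel order as in the
#' stack) plus a JSON sidecar `<path>.json` holding channel names, dtype,
#' intensity scale, provenance and, when supplied, the demixing matrix.
#'
#' With `dtype = "uint16"` (default) pixel values are rounded to integers
#' and stored as raw counts, which round-trips bit-exactly for
#' integer-valued data; values above 65535 are clamped with a warning. With
#' `dtype = "float32"` values are divided by a power-of-two scale (recorded
#' in the sidecar) so they fit the writer's `[0, 1]` requirement without
#' any decimal rounding; round trips are exact to float32 precision
#' (~1e-7 relative).
#'
#' @param stack An [image_stack()].
#' @param path Output TIFF path.
#' @param dtype `"uint16"` (default) or `"float32"`.
#' @param alpha Optional mixing matrix to record (e.g. the one used to
#'   demix).
#' @param provenance Free-text provenance string.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, dtype = c("uint16", "float32"),
                        alpha = NULL, provenance = "") {
  stopifnot(inherits(stack, "image_stack"))
  dtype <- match.arg(dtype)
  chans <- as.list(stack)
  if (dtype == "uint16") {
    mx <- max(vapply(chans, max, numeric(1)))
    if (mx > 65535) {
      warning("intensities above 65535 clamped during uint16 quantization",
              call. = FALSE)
      chans <- lapply(chans, function(m) pmin(m, 65535))
    }
    pages <- lapply(chans, function(m) round(pmax(m, 0)) / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
    scale <- 1  # integer pages are read back at raw counts
  } else {
    mx <- max(1e-12, vapply(chans, max, numeric(1)))
    scale <- 2^ceiling(log2(mx))
    tiff::writeTIFF(lapply(chans, function(m) pmax(m, 0) / scale), path,
                    bits.per.sample = 32L)
  }
  sidecar <- list(channel_names = names(stack), dtype = dtype,
                  scale = scale, provenance = provenance)
  if (!is.null(alpha)) sidecar$alpha <- alpha
  jsonlite::write_json(sidecar, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}
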