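# Readers and writers: PNG images and class-ID masks, CSV dataset
# manifests, and run checkpoints. All writes are atomic
# (write-temp-then-rename).

#' Write an RGB image as an 8-bit PNG
#'
#' @param img array `(H, W, 3)` with values in `[0, 1]`.
#' @param path destination file.
#' @export
write_image <- function(img, path) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  atomic_write(path, function(tmp) png::writePNG(clamp01(img), tmp))
}

#' Read an RGB image from PNG
#'
#' @param path PNG file.
#' @return array `(H, W, 3)` in `[0, 1]`.
#' @export
read_image <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 2L) x <- array(rep(x, 3L), c(dim(x), 3L))
  if (dim(x)[3] == 4L) x <- x[, , 1:3, drop = FALSE]
  x
}

#' Write a class-ID mask as a single-channel 8-bit PNG
#'
#' Class IDs `0..C-1` are stored as raw byte values; 255 is reserved for the
#' ignore sentinel.
#'
#' @param mask integer matrix `(H, W)` with values in `0..255`.
#' @param path destination file.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.matrix(mask))
  v <- as.integer(mask)
  if (any(v < 0 | v > 255)) stop("mask values must lie in 0..255")
  atomic_write(path, function(tmp) png::writePNG(matrix(v / 255, nrow(mask)), tmp))
}

#' Read a class-ID mask from PNG
#'
#' @param path single-channel 8-bit PNG.
#' @param n_classes if given, values are validated to lie in
#'   `0..n_classes-1` or 255 (ignore).
#' @return integer matrix `(H, W)`.
#' @export
read_mask <- function(path, n_classes = NULL) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L)
    stop("mask ", path, " is multi-channel; expected a single-channel class-ID PNG")
  m <- matrix(as.integer(round(x * 255)), nrow(x))
  if (!is.null(n_classes)) {
    bad <- m[m != IGNORE_LABEL & (m < 0L | m >= n_classes)]
    if (length(bad))
      stop("mask ", path, " contains class IDs outside 0..", n_classes - 1L,
           " (and 255): e.g. ", bad[1])
  }
  m
}

#' Write a dataset manifest CSV
#'
#' @param manifest data frame with at least `path_image`, `path_mask`,
#'   `split` (paths relative to the manifest's directory).
#' @param path destination CSV.
#' @export
write_manifest <- function(manifest, path) {
  atomic_write(path, function(tmp)
    utils::write.csv(manifest, tmp, row.names = FALSE))
}

#' Read a dataset manifest CSV
#'
#' @param path manifest CSV.
#' @return data frame with an attached `root` attribute (the manifest's
#'   directory) used to resolve the relative image/mask paths.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("path_image", "path_mask", "split")
  if (!all(req %in% names(m)))
    stop("manifest must have columns ", paste(req, collapse = ", "))
  attr(m, "root") <- normalizePath(dirname(path))
  m
}

manifest_root <- function(manifest, root = NULL) {
  r <- root %||% attr(manifest, "root")
  if (is.null(r)) stop("manifest has no root directory; pass `root`")
  r
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save a training checkpoint
#'
#' Stores all model parameter structures, the threshold state, optimizer
#' state, configuration and metric history.
#'
#' @param state checkpoint list.
#' @param path destination file.
#' @export
save_checkpoint <- function(state, path) {
  atomic_write(path, function(tmp) saveRDS(state, tmp))
}

#' Load a training checkpoint
#'
#' @param path checkpoint file written by [save_checkpoint()].
#' @export
load_checkpoint <- function(path) readRDS(path)
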