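#' @keywords internal
"_PACKAGE"

# Tensors are base-R arrays. Layout conventions used throughout:
#   image batch      : (H, W, 3,  B)
#   feature map      : (H, W, C,  B)
#   logits / ProbMap : (H, W, C,  B)   C = number of classes
#   LabelMap batch   : (H, W, B) integer, 255 = ignore
IGNORE_LABEL <- 255L

#' Softmax over the class axis of a logits array
#'
#' Numerically stable softmax applied along the third axis of an
#' `(H, W, C, B)` array, turning raw scores into a per-pixel probability
#' distribution over classes.
#'
#' @param logits numeric array `(H, W, C, B)`.
#' @return array of the same shape; at every pixel the class slice sums to 1.
#' @export
prob_softmax <- function(logits) {
  d <- dim(logits)
  stopifnot(length(d) == 4L)
  m <- matrix(aperm(logits, c(1, 2, 4, 3)), ncol = d[3])
  mx <- m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
  z <- exp(m - mx)
  z <- z / rowSums(z)
  aperm(array(z, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
}

#' Per-pixel argmax with deterministic tie-breaking
#'
#' @param p array `(H, W, C, B)`.
#' @return integer array `(H, W, B)` of 0-based class indices; ties resolved
#'   to the lowest class index.
#' @export
prob_argmax <- function(p) {
  d <- dim(p)
  stopifnot(length(d) == 4L)
  # max.col on (pixels x C) with ties.method = "first" gives lowest index
  m <- matrix(aperm(p, c(1, 2, 4, 3)), ncol = d[3])
  array(max.col(m, ties.method = "first") - 1L, dim = d[c(1, 2, 4)])
}

#' Per-pixel maximum class probability
#'
#' @param p array `(H, W, C, B)`.
#' @return numeric array `(H, W, B)` of per-pixel maxima.
#' @export
prob_max <- function(p) {
  d <- dim(p)
  m <- matrix(aperm(p, c(1, 2, 4, 3)), ncol = d[3])
  array(m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))],
        dim = d[c(1, 2, 4)])
}

# coerce single-image (H,W,C) / (H,W) inputs to batch form, remembering
# whether a batch axis was added
as_batch4 <- function(x) {
  if (length(dim(x)) == 3L) x <- array(x, c(dim(x), 1L))
  x
}
as_batch3 <- function(x) {
  if (is.null(dim(x))) stop("expected a matrix or 3-d array label map")
  if (length(dim(x)) == 2L) x <- array(x, c(dim(x), 1L))
  x
}

check_probmap <- function(p, name = "probmap", tol = 1e-5) {
  if (length(dim(p)) != 4L) stop(name, " must be a (H, W, C, B) array")
  if (any(!is.finite(p))) stop(name, " contains non-finite values")
  if (any(p < -tol)) stop(name, " has negative entries")
  s <- rowSums(matrix(aperm(p, c(1, 2, 4, 3)), ncol = dim(p)[3]))
  if (any(abs(s - 1) > 1e-4)) stop(name, " rows do not lie on the simplex")
  invisible(TRUE)
}

#' Atomically write a file
#'
#' Runs `writer(tmp)` against a temporary path in the destination directory
#' and renames it into place, so interrupted runs never leave a truncated
#' file behind.
#'
#' @param path final destination.
#' @param writer function of one argument (the temporary path).
#' @return `path`, invisibly.
#' @export
atomic_write <- function(path, writer) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = paste0(".", basename(path)))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("atomic rename failed for ", path)
  invisible(path)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)
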