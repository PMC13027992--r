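# Training objectives: supervised cross-entropy, hard pseudo-label
# cross-entropy (student and auxiliary teacher), confidence-weighted soft
# KL loss, and their combination into the unsupervised and total losses.
# Each ell_* helper also returns the gradient with respect to the logits so
# the trainer can backpropagate without an autodiff engine.

EPS_LOG <- 1e-8

# softmax CE against integer labels with ignore sentinel; mean over valid
# pixels. Returns loss, d(loss)/d(logits), and the valid-pixel count.
ce_with_grad <- function(logits, labels) {
  logits <- as_batch4(logits); labels <- as_batch3(labels)
  d <- dim(logits)
  if (!identical(dim(labels), d[c(1, 2, 4)]))
    stop("label map shape does not match logits")
  if (any(!is.finite(logits))) stop("non-finite logits")
  lab <- as.vector(labels)
  valid <- lab != IGNORE_LABEL
  if (any(lab[valid] < 0 | lab[valid] >= d[3]))
    stop("label outside 0..C-1 (and not the 255 ignore sentinel)")
  p <- prob_softmax(logits)
  n <- sum(valid)
  if (n == 0)
    return(list(loss = 0, grad = array(0, d), n = 0L))
  pm <- matrix(aperm(p, c(1, 2, 4, 3)), ncol = d[3])  # rows: (H,W,B) linear
  iv <- which(valid)
  picked <- pm[cbind(iv, lab[iv] + 1L)]
  loss <- -mean(log(pmax(picked, EPS_LOG)))
  gm <- matrix(0, nrow(pm), d[3])
  gm[iv, ] <- pm[iv, , drop = FALSE] / n        # d(mean CE)/d(logits) = (p - y)/n
  gm[cbind(iv, lab[iv] + 1L)] <- gm[cbind(iv, lab[iv] + 1L)] - 1 / n
  grad <- aperm(array(gm, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  list(loss = loss, grad = grad, n = as.integer(n))
}

#' Supervised pixel-wise cross-entropy
#'
#' Mean cross-entropy of the student logits against ground-truth labels over
#' pixels not carrying the 255 ignore sentinel; 0 when no pixel is valid.
#'
#' @param logits array `(H, W, C, B)`.
#' @param labels integer array `(H, W, B)` with values in `0..C-1` or 255.
#' @return scalar loss.
#' @export
supervised_ce <- function(logits, labels) {
  ce_with_grad(logits, labels)$loss
}

#' Hard pseudo-label cross-entropy
#'
#' Cross-entropy averaged over the hard pseudo-labeled pixels of a CPF
#' bundle. The same form serves the student (L_hs) and the auxiliary
#' teacher (L_ha) — pass the respective network's logits.
#'
#' @param logits array `(H, W, C, B)`.
#' @param bundle a `pseudo_bundle` from [cpf_step()] computed on the same
#'   batch.
#' @return scalar loss (0 when the bundle has no hard pixels).
#' @export
hard_pseudo_ce <- function(logits, bundle) {
  ce_with_grad(logits, bundle$hard)$loss
}

# soft KL with gradient, weighted by omega and averaged over soft pixels.
# direction "target_first": KL(target || student) — the distillation form;
# "student_first": KL(student || target).
soft_kl_with_grad <- function(logits, bundle, direction = "target_first") {
  logits <- as_batch4(logits)
  d <- dim(logits)
  if (any(!is.finite(logits))) stop("non-finite logits")
  n <- length(bundle$soft_idx)
  if (n == 0) return(list(loss = 0, grad = array(0, d), n = 0L))
  p <- prob_softmax(logits)
  pm <- matrix(aperm(p, c(1, 2, 4, 3)), ncol = d[3])
  q <- bundle$soft_target                       # n x C target rows
  ps <- pm[bundle$soft_idx, , drop = FALSE]
  gm <- matrix(0, nrow(pm), d[3])
  if (direction == "target_first") {
    kl <- rowSums(ifelse(q > 0, q * (log(pmax(q, EPS_LOG)) - log(pmax(ps, EPS_LOG))), 0))
    gm[bundle$soft_idx, ] <- (bundle$omega / n) * (ps - q)
  } else if (direction == "student_first") {
    lr_ <- log(pmax(ps, EPS_LOG)) - log(pmax(q, EPS_LOG))
    kl <- rowSums(ps * lr_)
    gm[bundle$soft_idx, ] <- (bundle$omega / n) * ps * (lr_ - rowSums(ps * lr_))
  } else stop("unknown KL direction: ", direction)
  loss <- sum(bundle$omega * kl) / n
  grad <- aperm(array(gm, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  list(loss = loss, grad = grad, n = as.integer(n))
}

#' Confidence-weighted soft pseudo-label KL loss
#'
#' Mean over soft pixels of `omega * KL(target || softmax(logits))`, where
#' the target is the fused distribution and `omega = max(P)^mu` was fixed at
#' bundle construction. KL is oriented target-first (the conventional
#' distillation form). 0 when the bundle has no soft pixels.
#'
#' @inheritParams hard_pseudo_ce
#' @param direction `"target_first"` (default) for `KL(target || student)`
#'   or `"student_first"` for the reverse orientation.
#' @return scalar loss.
#' @export
soft_kl_loss <- function(logits, bundle, direction = "target_first") {
  soft_kl_with_grad(logits, bundle, direction)$loss
}

#' Combine loss terms into the unsupervised and total losses
#'
#' `L_unsup = L_hs + lambda * L_soft` and `L_total = L_sup + L_unsup`.
#'
#' @param l_sup,l_hs,l_soft component losses.
#' @param lambda soft-label loss weight (default 0.5).
#' @return list with `l_unsup` and `l_total`.
#' @export
total_loss <- function(l_sup, l_hs, l_soft, lambda = 0.5) {
  stopifnot(is.finite(l_sup), is.finite(l_hs), is.finite(l_soft))
  l_unsup <- l_hs + lambda * l_soft
  list(l_unsup = l_unsup, l_total = l_sup + l_unsup)
}
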