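# Multi-source Consistency-guided Pseudo-label Filtering (CPF).
#
# Unlabeled pixels are partitioned by (a) agreement of the branch argmax
# predictions and (b) the confidence of their weighted fusion against
# dynamic per-class thresholds:
#   hard  — all branches agree and fused confidence clears the class
#           threshold; trained with cross-entropy on the one-hot label;
#   soft  — not hard but confident (or top-k filled); trained with a
#           confidence-weighted KL loss against the fused distribution;
#   ignored — everything else (sentinel 255).
# Thresholds follow a momentum update towards the 70th percentile of the
# rolling per-class confidence history, floored at tau_min.

#' Fusion weights over the three prediction branches
#'
#' @param alpha,beta,gamma nonnegative weights for the main-teacher,
#'   auxiliary-teacher and fusion-branch predictions; must sum to 1.
#'   Defaults 0.4/0.3/0.3.
#' @return a `fusion_weights` numeric vector of length 3.
#' @export
fusion_weights <- function(alpha = 0.4, beta = 0.3, gamma = 0.3) {
  w <- c(alpha = alpha, beta = beta, gamma = gamma)
  if (any(w < 0)) stop("fusion weights must be nonnegative")
  if (abs(sum(w) - 1) > 1e-9) stop("fusion weights must sum to 1")
  structure(w, class = "fusion_weights")
}

#' Dynamic per-class threshold state
#'
#' Holds the per-class confidence thresholds `tau`, their rolling
#' confidence histories (a FIFO of at most `window` batches of fused
#' max-confidences per class), and the update hyperparameters.
#'
#' @param n_classes number of classes.
#' @param tau_init initial threshold for every class.
#' @param eta momentum of the threshold update, in `[0, 1]`.
#' @param tau_min threshold floor.
#' @param window history capacity in batches.
#' @param quantile quantile of the history used as the update target
#'   (default 0.7, i.e. the 70th percentile).
#' @return a `threshold_state` list.
#' @export
threshold_state <- function(n_classes, tau_init = 0.5, eta = 0.9,
                            tau_min = 0.5, window = 10L, quantile = 0.7) {
  if (eta < 0 || eta > 1) stop("eta must lie in [0, 1]")
  if (tau_init < 0 || tau_init > 1 || tau_min < 0 || tau_min > 1)
    stop("thresholds must lie in [0, 1]")
  if (quantile <= 0 || quantile >= 1) stop("quantile must lie in (0, 1)")
  structure(list(tau = rep(tau_init, n_classes),
                 S = rep(list(list()), n_classes),
                 eta = eta, tau_min = tau_min,
                 window = as.integer(window), quantile = quantile,
                 n_classes = as.integer(n_classes)),
            class = "threshold_state")
}

#' Weighted fusion of branch probability maps
#'
#' Per-pixel convex combination `alpha*P_T + beta*P_A + gamma*P_F` of the
#' main-teacher, auxiliary-teacher and fusion-branch predictions. Branches
#' may be absent (ablations with fewer prediction sources); the weights of
#' the remaining branches are renormalized to sum to 1.
#'
#' @param p_t,p_a,p_f probability arrays `(H, W, C, B)`; `p_a`/`p_f` may be
#'   `NULL`.
#' @param w a [fusion_weights()] vector.
#' @return the fused probability array, a valid per-pixel distribution.
#' @export
fuse_predictions <- function(p_t, p_a = NULL, p_f = NULL, w = fusion_weights()) {
  w <- fusion_weights(w[1], w[2], w[3])   # re-validate
  maps <- list(p_t, p_a, p_f)
  keep <- !vapply(maps, is.null, logical(1))
  maps <- maps[keep]
  wk <- as.numeric(w)[keep]
  if (sum(wk) <= 0) stop("all active fusion weights are zero")
  wk <- wk / sum(wk)
  ref <- dim(as_batch4(maps[[1]]))
  out <- 0
  for (i in seq_along(maps)) {
    m <- as_batch4(maps[[i]])
    if (!identical(dim(m), ref)) stop("probability map shape mismatch")
    check_probmap(m, sprintf("branch %d", i))
    out <- out + wk[i] * m
  }
  out
}

#' Hard pseudo-label selection
#'
#' A pixel receives the main-teacher label when every branch argmax agrees
#' and the fused confidence exceeds the dynamic threshold of the fused
#' argmax class; otherwise the ignore sentinel 255.
#'
#' @param y_branches list of integer label arrays `(H, W, B)` (the branch
#'   argmaxes, ties broken to the lowest class index).
#' @param p fused probability array `(H, W, C, B)`.
#' @param ts a [threshold_state()].
#' @return integer label array `(H, W, B)` with 255 marking non-hard pixels.
#' @export
select_hard <- function(y_branches, p, ts) {
  p <- as_batch4(p)
  y_branches <- lapply(y_branches, as_batch3)
  consistent <- array(TRUE, dim(y_branches[[1]]))
  for (y in y_branches[-1]) {
    if (!identical(dim(y), dim(y_branches[[1]]))) stop("label map shape mismatch")
    consistent <- consistent & (y == y_branches[[1]])
  }
  conf <- prob_max(p)
  cls <- prob_argmax(p)
  pass <- conf > ts$tau[cls + 1L]
  hard <- array(IGNORE_LABEL, dim(cls))
  sel <- consistent & pass
  hard[sel] <- y_branches[[1]][sel]
  storage.mode(hard) <- "integer"
  hard
}

#' Dynamic threshold update
#'
#' Appends the current batch's fused max-confidences to the per-class
#' histories (keyed by the fused argmax class, FIFO-capped at `window`
#' batches) and moves each threshold towards
#' `max(Q_q(S_c), tau_min)` with momentum `eta`:
#' `tau_c <- eta * tau_c + (1 - eta) * max(Q_q(S_c), tau_min)`.
#' The quantile uses linear interpolation between order statistics
#' (`stats::quantile` type 7). Classes with an empty history use `tau_min`
#' in place of the quantile.
#'
#' @param ts a [threshold_state()].
#' @param p fused probability array `(H, W, C, B)`.
#' @return the updated `threshold_state`.
#' @export
update_thresholds <- function(ts, p) {
  p <- as_batch4(p)
  conf <- as.vector(prob_max(p))
  cls <- as.vector(prob_argmax(p))
  for (c in seq_len(ts$n_classes) - 1L) {
    v <- conf[cls == c]
    if (length(v)) {
      ts$S[[c + 1L]] <- c(ts$S[[c + 1L]], list(v))
      if (length(ts$S[[c + 1L]]) > ts$window)
        ts$S[[c + 1L]] <- ts$S[[c + 1L]][-1L]
    }
    hist <- unlist(ts$S[[c + 1L]], use.names = FALSE)
    target <- if (length(hist))
      max(stats::quantile(hist, ts$quantile, names = FALSE, type = 7), ts$tau_min)
    else ts$tau_min
    ts$tau[c + 1L] <- ts$eta * ts$tau[c + 1L] + (1 - ts$eta) * target
  }
  ts
}

#' Soft pseudo-label selection with top-k density fill
#'
#' Soft candidates are non-hard pixels whose fused confidence clears the
#' class threshold. If, within an image, candidates cover less than
#' `min_density` of the pixels (default 1%), the candidate set is replaced
#' by the `ceiling(k_frac * n_pixels)` most confident non-hard pixels of
#' that image (default top 10%), ties broken by raster order. Soft targets
#' are the full fused distributions; the per-pixel weight is
#' `max(P)^mu`.
#'
#' @param hard integer label array `(H, W, B)` from [select_hard()].
#' @param p fused probability array `(H, W, C, B)`.
#' @param ts a [threshold_state()].
#' @param k_frac fill fraction in `(0, 1]`.
#' @param min_density density trigger in `[0, 1]`.
#' @param mu confidence-weight exponent (>= 0).
#' @return list with `soft_mask` logical `(H, W, B)`, `soft_idx` linear
#'   indices into the batch, `soft_target` matrix `n_soft x C`, and `omega`
#'   numeric weights.
#' @export
select_soft <- function(hard, p, ts, k_frac = 0.10, min_density = 0.01, mu = 1) {
  if (k_frac <= 0 || k_frac > 1) stop("k_frac must lie in (0, 1]")
  if (mu < 0) stop("mu must be nonnegative")
  p <- as_batch4(p); hard <- as_batch3(hard)
  d <- dim(p)
  conf <- prob_max(p)
  cls <- prob_argmax(p)
  n_px <- d[1] * d[2]
  soft <- array(FALSE, dim(hard))
  for (b in seq_len(d[4])) {
    hb <- hard[, , b]
    cb <- conf[, , b]
    non_hard <- (hb == IGNORE_LABEL)
    cand <- non_hard & (cb > ts$tau[cls[, , b] + 1L])
    if (sum(cand) < min_density * n_px) {
      # epsilon guard so ceiling() sees the exact rational k_frac * n_px
      m <- min(ceiling(k_frac * n_px - 1e-9), sum(non_hard))
      if (m > 0) {
        pool <- which(non_hard)
        ord <- pool[order(-cb[pool], pool)]     # confidence desc, raster ties
        cand <- array(FALSE, dim(hb))
        cand[ord[seq_len(m)]] <- TRUE
      } else cand <- array(FALSE, dim(hb))
    }
    soft[, , b] <- cand
  }
  idx <- which(soft)
  pm <- matrix(aperm(p, c(1, 2, 4, 3)), ncol = d[3])  # rows: (H,W,B) linear
  list(soft_mask = soft, soft_idx = idx,
       soft_target = pm[idx, , drop = FALSE],
       omega = as.vector(conf)[idx]^mu)
}

#' One full CPF step
#'
#' Composes the pipeline on a batch of unlabeled predictions: weighted
#' fusion, hard-label selection against the current thresholds, dynamic
#' threshold update with the current batch's confidences, then soft-label
#' selection against the updated thresholds.
#'
#' @inheritParams fuse_predictions
#' @param ts a [threshold_state()].
#' @param mu,k_frac,min_density see [select_soft()].
#' @return list with `bundle` (a `pseudo_bundle`: `hard`, `soft_mask`,
#'   `soft_idx`, `soft_target`, `omega`, `fused`, `diagnostics`) and the
#'   updated `ts`.
#' @export
cpf_step <- function(p_t, p_a = NULL, p_f = NULL, w = fusion_weights(), ts,
                     mu = 1, k_frac = 0.10, min_density = 0.01) {
  fused <- fuse_predictions(p_t, p_a, p_f, w)
  branches <- Filter(Negate(is.null), list(p_t, p_a, p_f))
  y_branches <- lapply(branches, function(x) prob_argmax(as_batch4(x)))
  hard <- select_hard(y_branches, fused, ts)
  ts <- update_thresholds(ts, fused)
  soft <- select_soft(hard, fused, ts, k_frac = k_frac,
                      min_density = min_density, mu = mu)
  n_classes <- dim(fused)[3]
  hard_counts <- tabulate(hard[hard != IGNORE_LABEL] + 1L, nbins = n_classes)
  soft_cls <- prob_argmax(fused)[soft$soft_mask]
  soft_counts <- tabulate(soft_cls + 1L, nbins = n_classes)
  bundle <- structure(list(hard = hard, soft_mask = soft$soft_mask,
                           soft_idx = soft$soft_idx,
                           soft_target = soft$soft_target, omega = soft$omega,
                           fused = fused,
                           diagnostics = list(hard_per_class = hard_counts,
                                              soft_per_class = soft_counts)),
                      class = "pseudo_bundle")
  list(bundle = bundle, ts = ts)
}
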