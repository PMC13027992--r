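# Shared fixtures and independent reference implementations used by the
# unit and acceptance tests. The references are deliberately written as
# plain per-pixel double loops so they share no code path with the
# vectorized implementations they check.

# random probability map: normalized positive entries per pixel
rand_probmap <- function(h, w, c, b = 1L) {
  m <- matrix(stats::rgamma(h * w * b * c, shape = 1), ncol = c)
  m <- m / rowSums(m)
  aperm(array(m, c(h, w, b, c)), c(1, 2, 4, 3))
}

# linear-interpolation percentile between closest order statistics,
# written out from the definition (rank h = q*(n-1), zero-based)
ref_quantile <- function(x, q) {
  x <- sort(x)
  n <- length(x)
  if (n == 1) return(x)
  h <- q * (n - 1)
  lo <- floor(h) + 1
  hi <- min(lo + 1, n)
  x[lo] + (h - floor(h)) * (x[hi] - x[lo])
}

ref_argmax0 <- function(v) which.max(v) - 1L   # lowest index on ties

# per-pixel reference of one full CPF step (fuse -> hard -> threshold
# update -> soft), mirroring the stated pipeline with explicit loops
ref_cpf_step <- function(p_list, w, ts, mu = 1, k_frac = 0.10,
                         min_density = 0.01) {
  w <- w[!vapply(p_list, is.null, logical(1))]
  p_list <- Filter(Negate(is.null), p_list)
  w <- w / sum(w)
  d <- dim(p_list[[1]])
  H <- d[1]; W <- d[2]; C <- d[3]; B <- d[4]
  fused <- array(0, d)
  for (k in seq_along(p_list)) fused <- fused + w[k] * p_list[[k]]
  hard <- array(255L, c(H, W, B))
  conf <- array(0, c(H, W, B)); fcls <- array(0L, c(H, W, B))
  for (b in seq_len(B)) for (i in seq_len(H)) for (j in seq_len(W)) {
    ys <- vapply(p_list, function(p) ref_argmax0(p[i, j, , b]), integer(1))
    conf[i, j, b] <- max(fused[i, j, , b])
    fcls[i, j, b] <- ref_argmax0(fused[i, j, , b])
    if (length(unique(ys)) == 1 && conf[i, j, b] > ts$tau[fcls[i, j, b] + 1])
      hard[i, j, b] <- ys[1]
  }
  # threshold update with the current batch appended
  for (cc in seq_len(C) - 1L) {
    v <- conf[fcls == cc]
    if (length(v)) {
      ts$S[[cc + 1]] <- c(ts$S[[cc + 1]], list(v))
      if (length(ts$S[[cc + 1]]) > ts$window) ts$S[[cc + 1]] <- ts$S[[cc + 1]][-1]
    }
    hist <- unlist(ts$S[[cc + 1]])
    tgt <- if (length(hist)) max(ref_quantile(hist, ts$quantile), ts$tau_min)
           else ts$tau_min
    ts$tau[cc + 1] <- ts$eta * ts$tau[cc + 1] + (1 - ts$eta) * tgt
  }
  soft <- array(FALSE, c(H, W, B))
  for (b in seq_len(B)) {
    cand <- matrix(FALSE, H, W)
    for (i in seq_len(H)) for (j in seq_len(W))
      cand[i, j] <- hard[i, j, b] == 255L &&
        conf[i, j, b] > ts$tau[fcls[i, j, b] + 1]
    if (sum(cand) < min_density * (H * W)) {
      pool <- which(hard[, , b] == 255L)
      m <- min(ceiling(k_frac * (H * W) - 1e-9), length(pool))
      ord <- pool[order(-conf[, , b][pool], pool)]
      cand <- matrix(FALSE, H, W)
      if (m > 0) cand[ord[seq_len(m)]] <- TRUE
    }
    soft[, , b] <- cand
  }
  list(hard = hard, soft = soft, tau = ts$tau, fused = fused,
       conf = conf, fcls = fcls)
}

# brute-force scaled dot-product attention with residual, per batch item
ref_attention <- function(branch, f) {
  d <- dim(f)
  N <- d[1] * d[2]
  out <- array(0, d)
  for (b in seq_len(d[4])) {
    Fm <- matrix(f[, , , b], N, d[3])
    th <- branch$theta; ph <- branch$phi
    Q <- Fm %*% t(th$W) + matrix(th$b, N, length(th$b), byrow = TRUE)
    K <- Fm %*% t(ph$W) + matrix(ph$b, N, length(ph$b), byrow = TRUE)
    R <- matrix(0, N, d[3])
    for (i in seq_len(N)) {
      s <- numeric(N)
      for (j in seq_len(N)) s[j] <- sum(Q[i, ] * K[j, ]) / sqrt(branch$d_k)
      a <- exp(s - max(s)); a <- a / sum(a)
      acc <- numeric(d[3])
      for (j in seq_len(N)) acc <- acc + a[j] * Fm[j, ]
      R[i, ] <- acc + Fm[i, ]
    }
    out[, , , b] <- array(R, d[1:3])
  }
  out
}

# tiny on-disk dataset shared by trainer/io/cli tests (built once per run)
tiny_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "dualseg-tiny")
      if (!dir.exists(dir))
        generate_dataset(20, k = 4, size = 64, seed = 99, out_dir = dir)
      cache <<- read_manifest(file.path(dir, "manifest.csv"))
    }
    cache
  }
})
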