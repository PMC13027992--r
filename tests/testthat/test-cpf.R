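# Consistency-guided pseudo-label filtering

test_that("fused predictions are convex combinations on the simplex", {
  set.seed(10)
  w <- fusion_weights(0.4, 0.3, 0.3)
  p <- rand_probmap(3, 3, 4, 2)
  expect_equal(fuse_predictions(p, p, p, w), p, tolerance = 1e-12)

  p1 <- array(c(1, 0, 0), c(1, 1, 3, 1))
  p2 <- array(c(0, 1, 0), c(1, 1, 3, 1))
  p3 <- array(c(0, 0, 1), c(1, 1, 3, 1))
  expect_equal(as.vector(fuse_predictions(p1, p2, p3, w)), c(0.4, 0.3, 0.3))

  for (i in 1:20) {
    f <- fuse_predictions(rand_probmap(4, 4, 3), rand_probmap(4, 4, 3),
                          rand_probmap(4, 4, 3), w)
    s <- apply(f, c(1, 2, 4), sum)
    expect_true(all(abs(s - 1) < 1e-6))
  }
  expect_error(fusion_weights(0.5, 0.5, 0.5), "sum to 1")
  expect_error(fusion_weights(1.2, -0.1, -0.1), "nonnegative")
  expect_error(fuse_predictions(rand_probmap(2, 2, 3), rand_probmap(3, 2, 3),
                                NULL, w), "mismatch")
})

test_that("hard labels require full branch agreement and threshold clearance", {
  ts <- threshold_state(3, tau_init = 0.7)
  p <- array(c(0.05, 0.05, 0.9), c(1, 1, 3, 1))
  agree <- list(array(2L, c(1, 1, 1)), array(2L, c(1, 1, 1)),
                array(2L, c(1, 1, 1)))
  expect_equal(as.vector(select_hard(agree, p, ts)), 2L)

  disagree <- list(array(2L, c(1, 1, 1)), array(2L, c(1, 1, 1)),
                   array(1L, c(1, 1, 1)))
  expect_equal(as.vector(select_hard(disagree, p, ts)), 255L)

  # below threshold: confident enough branches but weak fusion
  ts2 <- threshold_state(3, tau_init = 0.95)
  expect_equal(as.vector(select_hard(agree, p, ts2)), 255L)
})

test_that("threshold update reproduces the hand-worked quantile example", {
  # Q_0.7 of {0.6 .. 1.0} by linear interpolation at rank 0.7*(5-1) = 2.8
  expect_equal(ref_quantile(c(0.6, 0.7, 0.8, 0.9, 1.0), 0.7), 0.88)
  # run the real update so that the class-0 history ends up being exactly
  # {0.6, 0.7, 0.8, 0.9, 1.0}: preload four values, the batch adds 0.8
  ts <- threshold_state(2, tau_init = 0.5, eta = 0.9, tau_min = 0.5)
  ts$S[[1]] <- list(c(0.6, 0.7, 0.9, 1.0))
  p <- array(c(0.8, 0.2), c(1, 1, 2, 1))
  ts2 <- update_thresholds(ts, p)
  expect_equal(sort(unlist(ts2$S[[1]])), c(0.6, 0.7, 0.8, 0.9, 1.0))
  expect_equal(ts2$tau[1], 0.538, tolerance = 1e-12)
})

test_that("eta = 1 freezes thresholds and the affine recursion contracts geometrically", {
  set.seed(11)
  p <- rand_probmap(4, 4, 3, 2)
  ts <- threshold_state(3, tau_init = 0.6, eta = 1)
  expect_equal(update_thresholds(ts, p)$tau, rep(0.6, 3))

  # constant confidence stream v > tau_min: |tau(t) - v| = eta^t |tau(0) - v|
  v <- 0.9
  pc <- array(0, c(2, 2, 2, 1)); pc[, , 1, ] <- v; pc[, , 2, ] <- 1 - v
  ts <- threshold_state(2, tau_init = 0.5, eta = 0.9, tau_min = 0.5)
  tau0 <- ts$tau[1]
  for (t in 1:12) {
    ts <- update_thresholds(ts, pc)
    expect_equal(abs(ts$tau[1] - v), 0.9^t * abs(tau0 - v), tolerance = 1e-12)
  }
})

test_that("threshold state stays bounded and history capped at the window", {
  set.seed(12)
  ts <- threshold_state(3, tau_init = 0.5, tau_min = 0.5, window = 4L)
  for (i in 1:15) {
    ts <- update_thresholds(ts, rand_probmap(3, 3, 3, 2))
    expect_true(all(ts$tau >= 0.5 - 1e-12 & ts$tau <= 1))
    expect_true(all(lengths(ts$S) >= 0) && all(vapply(ts$S, length, 1L) <= 4L))
  }
  expect_error(threshold_state(3, eta = 1.5), "eta")
})

test_that("soft selection follows the density trigger and exact top-k fill", {
  # 10x10 image, one class dominant; no pixel passes tau -> top-10% fill
  set.seed(13)
  C <- 3
  p <- rand_probmap(10, 10, C)
  p <- 0.5 * p + 0.5 / C          # squash: max prob stays below 0.7
  ts <- threshold_state(C, tau_init = 0.99)
  hard <- array(255L, c(10, 10, 1))
  hard[1, 1, 1] <- 0L             # one hard pixel, never eligible as soft
  s <- select_soft(hard, p, ts, k_frac = 0.10, min_density = 0.01)
  expect_equal(sum(s$soft_mask), 10L)    # ceiling(0.1 * 100)
  expect_false(s$soft_mask[1, 1, 1])
  conf <- prob_max(p)[, , 1]
  pool <- which(hard[, , 1] == 255L)
  expect_setequal(s$soft_idx, pool[order(-conf[pool], pool)][1:10])

  # candidate density 2% >= min_density -> exactly the threshold passers
  p2 <- rand_probmap(10, 10, C)
  ts2 <- threshold_state(C, tau_init = 0.5)
  conf2 <- prob_max(p2)[, , 1]
  q98 <- stats::quantile(conf2, 0.98, names = FALSE)
  ts2$tau[] <- q98                # exactly 2 of 100 pixels above
  hard2 <- array(255L, c(10, 10, 1))
  s2 <- select_soft(hard2, p2, ts2, k_frac = 0.10, min_density = 0.01)
  expect_setequal(s2$soft_idx, which(conf2 > q98))
  expect_error(select_soft(hard2, p2, ts2, k_frac = 0), "k_frac")
})

test_that("cpf_step handles the forced extremes", {
  C <- 4
  # everywhere-confident identical branches: every pixel hard, none soft
  p <- array(0.05 / 3, c(6, 6, C, 2)); p[, , 2, ] <- 0.95
  ts <- threshold_state(C)
  out <- cpf_step(p, p, p, fusion_weights(), ts)
  expect_true(all(out$bundle$hard == 1L))
  expect_length(out$bundle$soft_idx, 0)

  # disjoint argmaxes: zero hard, soft nonempty via top-k fill
  mk <- function(cl) { q <- array(0.1 / (C - 1), c(6, 6, C, 1)); q[, , cl, ] <- 0.9; q }
  out2 <- cpf_step(mk(1), mk(2), mk(3), fusion_weights(), threshold_state(C))
  expect_true(all(out2$bundle$hard == 255L))
  expect_gt(length(out2$bundle$soft_idx), 0)
})

test_that("cpf_step matches the per-pixel brute-force reference", {
  set.seed(14)
  for (i in 1:25) {
    H <- sample(2:8, 1); W <- sample(2:8, 1)
    C <- sample(2:5, 1); B <- sample(1:2, 1)
    ps <- list(rand_probmap(H, W, C, B), rand_probmap(H, W, C, B),
               rand_probmap(H, W, C, B))
    ts <- threshold_state(C, tau_init = runif(1, 0.3, 0.8),
                          eta = runif(1), tau_min = runif(1, 0.3, 0.6))
    ref <- ref_cpf_step(ps, c(0.4, 0.3, 0.3), ts)
    out <- cpf_step(ps[[1]], ps[[2]], ps[[3]], fusion_weights(), ts)
    expect_identical(out$bundle$hard, ref$hard)
    expect_equal(out$ts$tau, ref$tau, tolerance = 1e-9)
    expect_identical(out$bundle$soft_mask, ref$soft)
  }
})

test_that("hard, soft and ignored pixels partition the batch", {
  set.seed(15)
  for (i in 1:10) {
    ps <- replicate(3, rand_probmap(5, 5, 3, 2), simplify = FALSE)
    out <- cpf_step(ps[[1]], ps[[2]], ps[[3]], fusion_weights(),
                    threshold_state(3, tau_init = runif(1, 0.3, 0.7)))
    hard_set <- out$bundle$hard != 255L
    expect_false(any(hard_set & out$bundle$soft_mask))
    # soft targets lie on the simplex; omega in [0, 1]
    if (length(out$bundle$soft_idx)) {
      expect_true(all(abs(rowSums(out$bundle$soft_target) - 1) < 1e-9))
      expect_true(all(out$bundle$omega >= 0 & out$bundle$omega <= 1))
    }
  }
})

test_that("raising a class threshold never increases its hard-pixel count", {
  set.seed(16)
  ps <- replicate(3, rand_probmap(6, 6, 3, 2), simplify = FALSE)
  ys <- lapply(ps, prob_argmax)
  fused <- fuse_predictions(ps[[1]], ps[[2]], ps[[3]], fusion_weights())
  counts <- sapply(seq(0.3, 0.95, by = 0.05), function(tau) {
    ts <- threshold_state(3, tau_init = tau)
    h <- select_hard(ys, fused, ts)
    sum(h != 255L)
  })
  expect_true(all(diff(counts) <= 0))
})
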