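# Training objectives

logits_for <- function(p) log(p)   # softmax(log p) = p for simplex rows

test_that("supervised CE hits its closed-form anchors", {
  # one-hot-correct prediction -> loss 0 (up to the log clamp)
  y <- array(c(0L, 1L, 2L, 1L), c(2, 2, 1))
  p <- array(0, c(2, 2, 3, 1))
  for (i in 1:2) for (j in 1:2) p[i, j, y[i, j, 1] + 1, 1] <- 1
  expect_equal(supervised_ce(logits_for(pmax(p, 1e-12)), y), 0, tolerance = 1e-6)

  # uniform prediction over 4 classes -> ln 4 per pixel
  lu <- array(0, c(3, 3, 4, 2))
  yu <- array(sample(0:3, 18, TRUE), c(3, 3, 2))
  expect_equal(supervised_ce(lu, yu), log(4), tolerance = 1e-12)

  # all-ignored labels -> 0 with zero contributing pixels
  yi <- array(255L, c(3, 3, 2))
  expect_equal(supervised_ce(lu, yi), 0)
  expect_error(supervised_ce(lu, array(7L, c(3, 3, 2))), "255")
})

test_that("hard pseudo-label CE averages over hard pixels only", {
  # 2 hard pixels with student probabilities 0.5 and 0.25 on the label
  C <- 4
  p <- array(1 / C, c(1, 2, C, 1))
  p[1, 1, , 1] <- c(0.5, 0.5 / 3, 0.5 / 3, 0.5 / 3)
  p[1, 2, , 1] <- c(0.25, 0.25, 0.25, 0.25)
  bundle <- list(hard = array(c(0L, 0L), c(1, 2, 1)))
  expect_equal(hard_pseudo_ce(logits_for(p), bundle),
               (log(2) + log(4)) / 2, tolerance = 1e-9)

  bundle_empty <- list(hard = array(255L, c(1, 2, 1)))
  expect_equal(hard_pseudo_ce(logits_for(p), bundle_empty), 0)
})

test_that("soft KL loss matches the worked example and its degenerate cases", {
  # one soft pixel, target (0.5, 0.5), student (0.25, 0.75), mu = 1
  lg <- logits_for(array(c(0.25, 0.75), c(1, 1, 2, 1)))
  bundle <- list(soft_idx = 1L, soft_target = matrix(c(0.5, 0.5), 1),
                 omega = 0.5)
  kl <- 0.5 * log(2) + 0.5 * log(2 / 3)
  expect_equal(kl, 0.14384, tolerance = 1e-4)
  expect_equal(soft_kl_loss(lg, bundle), 0.5 * kl, tolerance = 1e-9)
  expect_equal(soft_kl_loss(lg, bundle), 0.07192, tolerance = 1e-4)

  # student equals target -> 0
  lg2 <- logits_for(array(c(0.5, 0.5), c(1, 1, 2, 1)))
  expect_equal(soft_kl_loss(lg2, bundle), 0, tolerance = 1e-12)

  # mu = 0 makes every weight 1 (bundle built with omega = conf^0)
  bundle1 <- list(soft_idx = 1L, soft_target = matrix(c(0.5, 0.5), 1),
                  omega = max(c(0.25, 0.75))^0)
  expect_equal(soft_kl_loss(lg, bundle1), kl, tolerance = 1e-9)

  # no soft pixels -> 0
  expect_equal(soft_kl_loss(lg, list(soft_idx = integer(0),
                                     soft_target = matrix(0, 0, 2),
                                     omega = numeric(0))), 0)
  # both orientations are nonnegative and vanish iff equal
  expect_gt(soft_kl_loss(lg, bundle, direction = "student_first"), 0)
  expect_equal(soft_kl_loss(lg2, bundle, direction = "student_first"), 0,
               tolerance = 1e-12)
})

test_that("loss combination respects the stated identities", {
  tl <- total_loss(0.3, 0.4, 0.2, lambda = 0.5)
  expect_equal(tl$l_unsup, 0.5)
  expect_equal(tl$l_total, 0.8)
  tl0 <- total_loss(0.3, 0.4, 0, lambda = 0.5)
  expect_equal(tl0$l_unsup, 0.4)
})

test_that("mean-form losses are invariant to duplicating every pixel", {
  set.seed(20)
  lg <- array(rnorm(4 * 4 * 3 * 1), c(4, 4, 3, 1))
  y <- array(sample(c(0:2, 255L), 16, TRUE), c(4, 4, 1))
  dup_l <- array(c(lg, lg), c(4, 4, 3, 2))
  dup_y <- array(c(y, y), c(4, 4, 2))
  expect_equal(supervised_ce(lg, y), supervised_ce(dup_l, dup_y),
               tolerance = 1e-12)
  expect_gte(supervised_ce(lg, y), 0)
})

test_that("loss gradients match finite differences", {
  set.seed(21)
  lg <- array(rnorm(3 * 3 * 3), c(3, 3, 3, 1))
  y <- array(sample(c(0:2, 255L), 9, TRUE), c(3, 3, 1))
  ce <- dualseg:::ce_with_grad(lg, y)
  bundle <- list(soft_idx = c(2L, 5L), soft_target = matrix(c(.2, .3, .5,
                                                              .6, .3, .1),
                                                            2, byrow = TRUE),
                 omega = c(0.8, 0.4))
  for (dirn in c("target_first", "student_first")) {
    sk <- dualseg:::soft_kl_with_grad(lg, bundle, direction = dirn)
    for (i in c(1, 14, 20)) {
      lg2 <- lg; lg2[i] <- lg2[i] + 1e-6
      expect_equal(ce$grad[i],
                   (dualseg:::ce_with_grad(lg2, y)$loss - ce$loss) / 1e-6,
                   tolerance = 1e-3)
      expect_equal(sk$grad[i],
                   (dualseg:::soft_kl_with_grad(lg2, bundle, direction = dirn)$loss -
                      sk$loss) / 1e-6, tolerance = 1e-3)
    }
  }
})
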