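# Training orchestration: EMA contract, gradient isolation, degenerate
# modes, determinism and checkpointing

tiny_cfg <- function(...) {
  cfg <- desk_config(...)
  cfg$optim$epochs <- 2L
  cfg$optim$batch_size <- 4L
  cfg$optim$warmup <- 0L
  cfg$out_dir <- tempfile("run")
  cfg
}

test_that("the EMA update reproduces copy, freeze and interpolation exactly", {
  set.seed(50)
  a <- seg_model("tinycnn-shallow", 3)
  b <- seg_model("tinycnn-shallow", 3)
  expect_equal(ema_update(a, b, rho = 1), a)
  expect_equal(ema_update(a, b, rho = 0)$encoder[[1]]$W, b$encoder[[1]]$W)
  u <- ema_update(a, b, rho = 0.999)
  expect_equal(u$encoder[[2]]$W,
               0.999 * a$encoder[[2]]$W + 0.001 * b$encoder[[2]]$W,
               tolerance = 1e-15)
  # scalar anchor: theta' = 1, theta = 0, rho = 0.999 -> 0.999
  a1 <- a; a1$classifier$b[] <- 1
  b1 <- b; b1$classifier$b[] <- 0
  expect_equal(ema_update(a1, b1, 0.999)$classifier$b[1], 0.999)
  expect_error(ema_update(a, seg_model("tinycnn-deep", 3), 0.5), "congruent")
  expect_error(ema_update(a, b, 1.5), "rho")
})

test_that("main-teacher deltas equal the EMA formula after any train_step", {
  set.seed(51)
  man <- split_semi(tiny_dataset(), 1 / 2, seed = 1)
  lab <- dualseg:::load_split(man, "train-labeled", n_classes = 4)
  unl <- dualseg:::load_split(man, "train-unlabeled", n_classes = 4)
  cfg <- tiny_cfg()
  st <- build_models(cfg)
  ts <- threshold_state(4)
  pre_teacher <- st$models$teacher_main
  out <- train_step(st, list(x = lab$x[, , , 1:4], y = lab$y[, , 1:4]),
                    list(x = unl$x[, , , 1:4]), ts, cfg)
  expected <- ema_update(pre_teacher, out$state$models$student, cfg$optim$ema)
  expect_equal(dualseg:::flatten_params(out$state$models$teacher_main),
               dualseg:::flatten_params(expected), tolerance = 1e-15)

  # rho = 1: teacher parameters bit-identical across steps
  cfg1 <- cfg; cfg1$optim$ema <- 1
  st1 <- build_models(cfg1)
  frozen <- st1$models$teacher_main
  out1 <- train_step(st1, list(x = lab$x[, , , 1:4], y = lab$y[, , 1:4]),
                     list(x = unl$x[, , , 1:4]), ts, cfg1)
  expect_identical(dualseg:::flatten_params(out1$state$models$teacher_main),
                   dualseg:::flatten_params(frozen))
})

test_that("an empty unlabeled batch reduces the step to supervised training", {
  set.seed(52)
  man <- split_semi(tiny_dataset(), 1 / 2, seed = 1)
  lab <- dualseg:::load_split(man, "train-labeled", n_classes = 4)
  cfg <- tiny_cfg()
  st <- build_models(cfg)
  out <- train_step(st, list(x = lab$x[, , , 1:4], y = lab$y[, , 1:4]),
                    list(x = NULL), threshold_state(4), cfg)
  expect_equal(out$report$l_hs, 0)
  expect_equal(out$report$l_soft, 0)
  expect_equal(out$report$l_unsup, 0)
  expect_equal(out$report$l_total, out$report$l_sup)
  expect_error(train_step(st, list(x = NULL), list(x = NULL),
                          threshold_state(4), cfg), "anchor")
})

test_that("loss bookkeeping identities hold on real steps", {
  set.seed(53)
  man <- split_semi(tiny_dataset(), 1 / 2, seed = 1)
  lab <- dualseg:::load_split(man, "train-labeled", n_classes = 4)
  unl <- dualseg:::load_split(man, "train-unlabeled", n_classes = 4)
  cfg <- tiny_cfg()
  st <- build_models(cfg)
  ts <- threshold_state(4)
  for (i in 1:3) {
    out <- train_step(st, list(x = lab$x[, , , 1:4], y = lab$y[, , 1:4]),
                      list(x = unl$x[, , , 1:4]), ts, cfg)
    st <- out$state; ts <- out$ts
    r <- out$report
    expect_equal(r$l_unsup, r$l_hs + cfg$loss$lambda_soft * r$l_soft,
                 tolerance = 1e-9)
    expect_equal(r$l_total, r$l_sup + r$l_unsup, tolerance = 1e-9)
    expect_true(all(c(r$l_sup, r$l_hs, r$l_ha, r$l_soft) >= 0))
  }
})

test_that("supervised-only training runs and logs zero unsupervised terms", {
  set.seed(54)
  man <- split_semi(tiny_dataset(), 1 / 2, seed = 1)
  cfg <- tiny_cfg()
  cfg$model$supervised_only <- TRUE
  f <- fit(man, cfg)
  lg <- utils::read.csv(f$log)
  expect_true(all(lg$l_hs == 0))
  expect_true(all(lg$l_soft == 0))
  expect_true(all(lg$n_soft == 0))
  expect_true(all(lg$l_sup > 0))
})

test_that("training is reproducible from the seed", {
  man <- split_semi(tiny_dataset(), 1 / 2, seed = 1)
  cfg <- tiny_cfg()
  cfg$seed <- 7
  f1 <- fit(man, cfg)
  cfg$out_dir <- tempfile("run")
  f2 <- fit(man, cfg)
  expect_equal(f1$history, f2$history, tolerance = 1e-12)
})

test_that("checkpoints round-trip to the identical evaluation", {
  set.seed(55)
  man <- split_semi(tiny_dataset(), 1 / 2, seed = 1)
  cfg <- tiny_cfg()
  f <- fit(man, cfg)
  ck <- load_checkpoint(f$checkpoint)
  test <- dualseg:::load_split(man, "test", n_classes = 4)
  m <- evaluate_model(ck$best$models$student, test, 4)
  expect_equal(m$miou, ck$best$miou, tolerance = 1e-12)

  # resuming from the checkpoint continues to more epochs
  cfg2 <- cfg
  cfg2$optim$epochs <- 3L
  f2 <- fit(man, cfg2, resume = f$checkpoint)
  expect_equal(nrow(f2$history), 3L)
})

test_that("prediction emits a valid mask for a stored image", {
  set.seed(56)
  man <- tiny_dataset()
  root <- attr(man, "root")
  m <- seg_model("tinycnn-deep", 4)
  msk <- predict_mask(m, file.path(root, man$path_image[1]))
  expect_equal(dim(msk), c(64, 64))
  expect_true(all(msk %in% 0:3))
})
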