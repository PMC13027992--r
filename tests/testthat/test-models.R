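# Segmentation networks and the attention-guided fusion branch

test_that("forward_segment emits aligned logits whose softmax is a ProbMap", {
  set.seed(40)
  m <- seg_model("tinycnn-deep", n_classes = 4)
  x <- array(runif(64 * 64 * 3 * 2), c(64, 64, 3, 2))
  f <- forward_segment(m, x)
  expect_equal(dim(f$logits), c(64, 64, 4, 2))
  p <- prob_softmax(f$logits)
  s <- apply(p, c(1, 2, 4), sum)
  expect_true(all(abs(s - 1) < 1e-6))
  # two calls on the same input are identical (pure forward pass)
  expect_identical(f$logits, forward_segment(m, x)$logits)
  expect_error(forward_segment(m, array(0, c(63, 64, 3, 1))), "divisible")
})

test_that("the deep tap is coarser and wider than the shallow tap", {
  set.seed(41)
  md <- seg_model("tinycnn-deep", 4)
  ms <- seg_model("tinycnn-shallow", 4)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3, 1))
  fd <- forward_segment(md, x)$features
  fs <- forward_segment(ms, x)$features
  expect_gt(dim(fd)[3], dim(fs)[3])      # more channels
  expect_lt(dim(fd)[1], dim(fs)[1])      # smaller spatial size
})

test_that("feature fusion projects, resizes and concatenates main-first", {
  set.seed(42)
  br <- fusion_branch(c_main = 8, c_aux = 4, n_classes = 3)
  f_main <- array(rnorm(16 * 16 * 8 * 2), c(16, 16, 8, 2))
  f_aux <- array(rnorm(8 * 8 * 4 * 2), c(8, 8, 4, 2))
  fu <- fuse_features(br, f_main, f_aux)
  expect_equal(dim(fu$out), c(16, 16, 16, 2))
  # first C1 channels are exactly F_main
  expect_identical(fu$out[, , 1:8, ], f_main)
  expect_error(fuse_features(br, f_main, f_aux[, , , 1, drop = FALSE]),
               "batch")

  # spatially constant aux block stays constant after projection + resize
  f_aux_const <- array(rep(c(1, 2, 3, 4), each = 64), c(8, 8, 4, 1))
  fu2 <- fuse_features(br, f_main[, , , 1, drop = FALSE], f_aux_const)
  up <- fu2$out[, , 9:16, ]
  for (ch in 1:8) expect_lt(diff(range(up[, , ch])), 1e-10)
})

test_that("feature fusion is permutation-equivariant over the batch axis", {
  set.seed(43)
  br <- fusion_branch(6, 3, 3)
  f_main <- array(rnorm(4 * 4 * 6 * 3), c(4, 4, 6, 3))
  f_aux <- array(rnorm(2 * 2 * 3 * 3), c(2, 2, 3, 3))
  fu <- fuse_features(br, f_main, f_aux)$out
  perm <- c(3, 1, 2)
  fu_p <- fuse_features(br, f_main[, , , perm], f_aux[, , , perm])$out
  expect_equal(fu_p, fu[, , , perm], tolerance = 1e-12)
})

test_that("attention refinement matches the double-loop reference", {
  set.seed(44)
  for (n in c(2, 4)) {
    br <- fusion_branch(c_main = 4, c_aux = 2, n_classes = 3, d_k = 2)
    f <- array(rnorm(n * n * 8 * 2), c(n, n, 8, 2))
    out <- attention_refine(br, f)$out
    expect_equal(out, ref_attention(br, f), tolerance = 1e-5)
  }
  # single position: softmax over one element is 1, so output = 2 * input
  br <- fusion_branch(4, 2, 3, d_k = 2)
  f1 <- array(rnorm(8), c(1, 1, 8, 1))
  expect_equal(attention_refine(br, f1)$out, 2 * f1, tolerance = 1e-12)
  expect_error(attention_refine(br, f1 * NA), "finite")
})

test_that("the fusion head is lightweight and emits full-resolution ProbMaps", {
  set.seed(45)
  mc <- dualseg:::BACKBONES[["tinycnn-deep"]]
  c_main <- mc$channels[mc$tap]
  br <- fusion_branch(c_main, 16, n_classes = 4)
  f <- array(rnorm(8 * 8 * 2 * c_main * 1), c(8, 8, 2 * c_main, 1))
  lg <- fusion_head(br, f, c(64, 64))$logits
  expect_equal(dim(lg), c(64, 64, 4, 1))
  p <- prob_softmax(lg)
  expect_true(all(abs(apply(p, c(1, 2, 4), sum) - 1) < 1e-6))
  # head parameters are under 5% of a backbone's
  head_n <- dualseg:::n_params(br$head)
  backbone_n <- dualseg:::n_params(seg_model("tinycnn-deep", 4))
  expect_lt(head_n, 0.05 * backbone_n)
})

test_that("all three branches emit ProbMaps of identical shape", {
  set.seed(46)
  cfg <- desk_config()
  st <- build_models(cfg)
  x <- array(runif(64 * 64 * 3 * 2), c(64, 64, 3, 2))
  ft <- forward_segment(st$models$teacher_main, x)
  fa <- forward_segment(st$models$teacher_aux, x)
  ff <- dualseg:::fusion_forward(st$models$fusion, ft$features, fa$features,
                                 c(64, 64))
  expect_equal(dim(ft$logits), dim(fa$logits))
  expect_equal(dim(ft$logits), dim(ff$logits))
})

test_that("convolution layers agree with finite-difference gradients", {
  set.seed(47)
  x <- array(rnorm(10 * 8 * 3 * 2), c(10, 8, 3, 2))
  ly <- dualseg:::nn_conv(3, 5, k = 3, stride = 2, relu = TRUE)
  fw <- dualseg:::conv_forward(ly, x)
  bk <- dualseg:::conv_backward(ly, fw$cache, 2 * fw$out)
  for (i in c(2, 40)) {
    ly2 <- ly; ly2$W[i] <- ly2$W[i] + 1e-6
    num <- (sum(dualseg:::conv_forward(ly2, x)$out^2) - sum(fw$out^2)) / 1e-6
    expect_equal(bk$dW[i], num, tolerance = 1e-3)
  }
  x2 <- x; x2[11] <- x2[11] + 1e-6
  num <- (sum(dualseg:::conv_forward(ly, x2)$out^2) - sum(fw$out^2)) / 1e-6
  expect_equal(bk$dx[11], num, tolerance = 1e-3)
})
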