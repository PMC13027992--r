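# Student / teacher segmentation networks and the attention-guided
# dual-teacher feature-fusion branch.
#
# Two desk-scale backbones mirror the deep/shallow asymmetry of the
# ResNet-101 / ResNet-50 teacher pairing at a size trainable on a laptop CPU:
#   tinycnn-deep    4 conv stages, strides 2/2/2/1 -> final tap stride 8
#   tinycnn-shallow 3 conv stages, strides 2/2/1   -> penultimate tap stride 4
# The deep tap carries more channels at a coarser grid (global morphology);
# the shallow tap fewer channels at a finer grid (local detail).

BACKBONES <- list(
  "tinycnn-deep"    = list(channels = c(8L, 24L, 48L, 48L), strides = c(2L, 2L, 2L, 1L),
                           tap = 4L),
  "tinycnn-shallow" = list(channels = c(8L, 24L, 24L),      strides = c(2L, 2L, 1L),
                           tap = 2L)
)

#' Build a segmentation network
#'
#' Constructs a small encoder-decoder segmentation model: a stack of strided
#' 3x3 convolution + ReLU stages, a 1x1 classifier convolution, and a
#' bilinear upsample back to input resolution. The designated feature tap is
#' the encoder stage whose activations feed the dual-teacher fusion branch.
#'
#' @param backbone one of `"tinycnn-deep"`, `"tinycnn-shallow"`.
#' @param n_classes number of output classes (including background).
#' @param in_channels input image channels (default 3).
#' @return a `seg_model` list with `$encoder`, `$classifier`, `$tap`,
#'   `$stride` (total downsampling factor at the classifier input).
#' @export
seg_model <- function(backbone = "tinycnn-deep", n_classes = 4L, in_channels = 3L) {
  spec <- BACKBONES[[backbone]]
  if (is.null(spec)) stop("unknown backbone: ", backbone)
  enc <- list()
  cin <- in_channels
  for (i in seq_along(spec$channels)) {
    enc[[i]] <- nn_conv(cin, spec$channels[i], k = 3L, stride = spec$strides[i])
    cin <- spec$channels[i]
  }
  # decoder: deep features upsampled to the first-stage grid, concatenated
  # with the low-level skip features, refined, classified, upsampled to
  # input resolution (thin appendages need the finer grid)
  skip <- 1L
  c_dec <- 24L
  dec <- nn_conv(cin + spec$channels[skip], c_dec, k = 3L)
  cls <- nn_conv(c_dec, n_classes, k = 1L, stride = 1L, relu = FALSE)
  structure(list(backbone = backbone, n_classes = as.integer(n_classes),
                 encoder = enc, skip = skip, decoder = dec, classifier = cls,
                 tap = spec$tap, stride = prod(spec$strides)),
            class = "seg_model")
}

#' Forward pass of a segmentation network
#'
#' @param model a [seg_model()].
#' @param images array `(H, W, 3, B)` (a single `(H, W, 3)` image is
#'   promoted to a batch of one); `H`, `W` must be divisible by the model's
#'   total stride.
#' @param want_cache keep intermediate activations for backpropagation.
#' @return list with `logits` `(H, W, n_classes, B)` aligned with the input,
#'   `features` — the tap-stage activations (`source = "main"` or `"aux"`
#'   depending on use), `taps` — all stage activations, and (optionally)
#'   `cache`.
#' @export
forward_segment <- function(model, images, want_cache = FALSE) {
  images <- as_batch4(images)
  d <- dim(images)
  if (d[1] %% model$stride != 0L || d[2] %% model$stride != 0L)
    stop("input size ", d[1], "x", d[2],
         " is not divisible by the model stride ", model$stride)
  enc <- seq_forward(model$encoder, images)
  sk <- enc$taps[[model$skip]]
  dsk <- dim(sk)
  deep_up <- resize_bilinear(enc$out, dsk[1], dsk[2])
  dec_in <- array(0, c(dsk[1], dsk[2], dim(enc$out)[3] + dsk[3], dsk[4]))
  dec_in[, , seq_len(dim(enc$out)[3]), ] <- deep_up
  dec_in[, , dim(enc$out)[3] + seq_len(dsk[3]), ] <- sk
  dec <- conv_forward(model$decoder, dec_in)
  cls <- conv_forward(model$classifier, dec$out)
  logits <- resize_bilinear(cls$out, d[1], d[2])
  res <- list(logits = logits, features = enc$taps[[model$tap]], taps = enc$taps)
  if (want_cache)
    res$cache <- list(enc = enc$caches, dec = dec$cache, cls = cls$cache,
                      deep_hw = dim(enc$out)[1:2], c_deep = dim(enc$out)[3],
                      skip_hw = dsk[1:2], in_hw = d[1:2])
  res
}

# Backward from d(logits) to parameter gradients; returns a structure
# congruent with the model (dW/db in the W/b slots).
backward_segment <- function(model, cache, dlogits) {
  dcls_out <- resize_bilinear_backward(dlogits, cache$skip_hw[1], cache$skip_hw[2])
  bcls <- conv_backward(model$classifier, cache$cls, dcls_out)
  bdec <- conv_backward(model$decoder, cache$dec, bcls$dx)
  cd <- cache$c_deep
  d_deep <- resize_bilinear_backward(
    bdec$dx[, , seq_len(cd), , drop = FALSE], cache$deep_hw[1], cache$deep_hw[2])
  d_skip <- bdec$dx[, , cd + seq_len(dim(bdec$dx)[3] - cd), , drop = FALSE]
  inject <- stats::setNames(list(d_skip), as.character(model$skip))
  benc <- seq_backward(model$encoder, cache$enc, d_deep, inject = inject)
  g <- model
  g$classifier$W <- bcls$dW; g$classifier$b <- bcls$db
  g$decoder$W <- bdec$dW; g$decoder$b <- bdec$db
  for (i in seq_along(model$encoder)) {
    g$encoder[[i]]$W <- benc$grads[[i]]$dW
    g$encoder[[i]]$b <- benc$grads[[i]]$db
  }
  g
}

# ---- fusion branch ----------------------------------------------------------

#' Build the attention-guided fusion branch
#'
#' The branch fuses the main teacher's deep semantic features with the
#' auxiliary teacher's mid-level structural features: the auxiliary map is
#' channel-projected to the main width by a 1x1 convolution, bilinearly
#' resized to the main grid, and concatenated; a single-head dot-product
#' attention block with residual connection refines the fused map; a
#' lightweight head (3x3 conv + ReLU + 1x1 classifier + bilinear upsample)
#' emits the third prediction branch. The head is deliberately small
#' (well under 5% of a backbone's parameters).
#'
#' @param c_main channels of the main feature tap.
#' @param c_aux channels of the auxiliary feature tap.
#' @param n_classes output classes.
#' @param d_k attention projection width; default `max(8, c_main %/% 4)`.
#' @return a `fusion_branch` list.
#' @export
fusion_branch <- function(c_main, c_aux, n_classes, d_k = NULL) {
  if (is.null(d_k)) d_k <- max(8L, c_main %/% 4L)
  c_fused <- 2L * c_main
  if (d_k > c_fused) stop("d_k must not exceed the fused channel count")
  structure(list(
    c_main = as.integer(c_main), c_aux = as.integer(c_aux),
    c_fused = as.integer(c_fused), d_k = as.integer(d_k),
    proj  = nn_conv(c_aux, c_main, k = 1L, relu = FALSE),
    theta = nn_conv(c_fused, d_k, k = 1L, relu = FALSE),
    phi   = nn_conv(c_fused, d_k, k = 1L, relu = FALSE),
    head  = local({
      # lightweight: 1x1 channel reduction, 3x3 refinement, classifier
      c_red <- max(4L, c_main %/% 5L)
      list(nn_conv(c_fused, c_red, k = 1L),
           nn_conv(c_red, c_red, k = 3L),
           nn_conv(c_red, n_classes, k = 1L, relu = FALSE))
    })
  ), class = "fusion_branch")
}

#' Fuse main and auxiliary teacher feature maps
#'
#' Channel-projects the auxiliary features to the main width with a 1x1
#' convolution, bilinearly resizes them to the main spatial grid, and
#' concatenates along channels (main features first).
#'
#' @param branch a [fusion_branch()] (supplies the projection weights).
#' @param f_main array `(H, W, C1, B)`.
#' @param f_aux array `(H', W', C2, B)`; same batch size.
#' @param want_cache keep activations for backpropagation.
#' @return list with `out` `(H, W, 2*C1, B)` and optionally `cache`.
#' @export
fuse_features <- function(branch, f_main, f_aux, want_cache = FALSE) {
  f_main <- as_batch4(f_main); f_aux <- as_batch4(f_aux)
  dm <- dim(f_main); da <- dim(f_aux)
  if (dm[4] != da[4]) stop("batch size mismatch between main and aux features")
  if (any(!is.finite(f_main)) || any(!is.finite(f_aux)))
    stop("non-finite feature values")
  pr <- conv_forward(branch$proj, f_aux)
  up <- resize_bilinear(pr$out, dm[1], dm[2])
  out <- array(0, c(dm[1], dm[2], branch$c_fused, dm[4]))
  out[, , seq_len(dm[3]), ] <- f_main
  out[, , dm[3] + seq_len(dm[3]), ] <- up
  res <- list(out = out)
  if (want_cache) res$cache <- list(proj = pr$cache, aux_hw = da[1:2],
                                    main_hw = dm[1:2], c1 = dm[3])
  res
}

#' Self-attention refinement of the fused feature map
#'
#' Single-head scaled dot-product attention over spatial positions with the
#' unprojected fused features as values, followed by a residual connection:
#' for query position i, `Fhat_i = sum_j softmax_j(q_i . k_j / sqrt(d_k)) F_j`
#' and the output is `Fhat + F`. Queries/keys come from the 1x1 projections
#' `theta`, `phi`.
#'
#' @param branch a [fusion_branch()].
#' @param f array `(H, W, C, B)` — the fused features.
#' @param want_cache keep activations for backpropagation.
#' @return list with `out` of the same shape and optionally `cache`.
#' @export
attention_refine <- function(branch, f, want_cache = FALSE) {
  f <- as_batch4(f)
  if (any(!is.finite(f))) stop("non-finite feature values")
  d <- dim(f)
  N <- d[1] * d[2]
  q <- conv_forward(branch$theta, f)
  k <- conv_forward(branch$phi, f)
  out <- array(0, d)
  A_list <- vector("list", d[4])
  Fm_list <- vector("list", d[4])
  for (b in seq_len(d[4])) {
    Fm <- matrix(f[, , , b], N, d[3])
    Qm <- matrix(q$out[, , , b], N, branch$d_k)
    Km <- matrix(k$out[, , , b], N, branch$d_k)
    S <- (Qm %*% t(Km)) / sqrt(branch$d_k)
    S <- S - apply(S, 1, max)
    A <- exp(S); A <- A / rowSums(A)
    out[, , , b] <- array(A %*% Fm + Fm, d[1:3])
    A_list[[b]] <- A; Fm_list[[b]] <- Fm
  }
  res <- list(out = out)
  if (want_cache) res$cache <- list(q = q, k = k, A = A_list, Fm = Fm_list,
                                    dims = d)
  res
}

# Backward through attention + residual: returns gradient wrt the fused
# input and parameter grads for theta/phi.
attention_backward <- function(branch, cache, dout) {
  d <- cache$dims
  N <- d[1] * d[2]
  df <- array(0, d)
  dq <- array(0, dim(cache$q$out))
  dk <- array(0, dim(cache$k$out))
  for (b in seq_len(d[4])) {
    A <- cache$A[[b]]; Fm <- cache$Fm[[b]]
    Qm <- matrix(cache$q$out[, , , b], N, branch$d_k)
    Km <- matrix(cache$k$out[, , , b], N, branch$d_k)
    dOut <- matrix(dout[, , , b], N, d[3])
    dA <- dOut %*% t(Fm)
    dFm <- t(A) %*% dOut + dOut            # value path + residual
    dS <- A * (dA - rowSums(A * dA))       # softmax rows backward
    dq[, , , b] <- array((dS %*% Km) / sqrt(branch$d_k), c(d[1], d[2], branch$d_k))
    dk[, , , b] <- array((t(dS) %*% Qm) / sqrt(branch$d_k), c(d[1], d[2], branch$d_k))
    df[, , , b] <- array(dFm, d[1:3])
  }
  bq <- conv_backward(branch$theta, cache$q$cache, dq)
  bk <- conv_backward(branch$phi, cache$k$cache, dk)
  list(dx = df + bq$dx + bk$dx,
       theta = list(dW = bq$dW, db = bq$db),
       phi = list(dW = bk$dW, db = bk$db))
}

#' Lightweight segmentation head of the fusion branch
#'
#' 1x1 channel reduction, 3x3 refinement (both ReLU), 1x1 classifier,
#' bilinear upsample to the target resolution.
#'
#' @param branch a [fusion_branch()].
#' @param f refined fused features `(H', W', 2*C1, B)`.
#' @param out_hw integer length-2 output (input-image) resolution.
#' @param want_cache keep activations for backpropagation.
#' @return list with `logits` `(out_hw, n_classes, B)` and optionally `cache`.
#' @export
fusion_head <- function(branch, f, out_hw, want_cache = FALSE) {
  f <- as_batch4(f)
  h <- seq_forward(branch$head, f)
  logits <- resize_bilinear(h$out, out_hw[1], out_hw[2])
  res <- list(logits = logits)
  if (want_cache) res$cache <- list(head = h$caches, feat_hw = dim(h$out)[1:2])
  res
}

# Full fusion-branch forward: teacher features in, fusion logits out.
fusion_forward <- function(branch, f_main, f_aux, out_hw, want_cache = FALSE) {
  fu <- fuse_features(branch, f_main, f_aux, want_cache = want_cache)
  at <- attention_refine(branch, fu$out, want_cache = want_cache)
  hd <- fusion_head(branch, at$out, out_hw, want_cache = want_cache)
  res <- list(logits = hd$logits)
  if (want_cache) res$cache <- list(fuse = fu$cache, attn = at$cache, head = hd$cache)
  res
}

# Backward from d(fusion logits) to fusion-branch parameter gradients.
# Teacher features are treated as constants (detached).
fusion_backward <- function(branch, cache, dlogits) {
  dh <- resize_bilinear_backward(dlogits, cache$head$feat_hw[1], cache$head$feat_hw[2])
  bh <- seq_backward(branch$head, cache$head$head, dh)
  ba <- attention_backward(branch, cache$attn, bh$dx)
  # gradient into the concatenated map: aux half flows back into proj conv
  c1 <- cache$fuse$c1
  d_up <- ba$dx[, , c1 + seq_len(c1), , drop = FALSE]
  d_pr <- resize_bilinear_backward(d_up, cache$fuse$aux_hw[1], cache$fuse$aux_hw[2])
  bp <- conv_backward(branch$proj, cache$fuse$proj, d_pr)
  g <- branch
  g$proj$W <- bp$dW; g$proj$b <- bp$db
  g$theta$W <- ba$theta$dW; g$theta$b <- ba$theta$db
  g$phi$W <- ba$phi$dW; g$phi$b <- ba$phi$db
  for (i in seq_along(branch$head)) {
    g$head[[i]]$W <- bh$grads[[i]]$dW
    g$head[[i]]$b <- bh$grads[[i]]$db
  }
  g
}
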