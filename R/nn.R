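# Minimal convolutional-network machinery.
#
# There is no deep-learning framework in the dependency set, so the few layer
# types this framework needs (3x3/1x1 convolutions, ReLU, bilinear resize)
# are implemented directly: convolutions as im2col gathers followed by a BLAS
# matrix multiply, bilinear resize as a cached sparse interpolation operator.
# Gradients are hand-derived adjoints of the same operations.

.nn_cache <- new.env(parent = emptyenv())

# im2col gather indices into the padded (Hp x Wp) spatial grid.
# Returns a (k*k) x (Ho*Wo) integer matrix of linear indices (row-major in H).
im2col_idx <- function(Hp, Wp, k, stride) {
  key <- paste("i2c", Hp, Wp, k, stride, sep = "_")
  if (!is.null(.nn_cache[[key]])) return(.nn_cache[[key]])
  Ho <- (Hp - k) %/% stride + 1L
  Wo <- (Wp - k) %/% stride + 1L
  r0 <- rep(seq(0L, by = stride, length.out = Ho), times = Wo)   # ho fastest
  c0 <- rep(seq(0L, by = stride, length.out = Wo), each = Ho)
  kh <- rep(seq_len(k), times = k)
  kw <- rep(seq_len(k), each = k)
  # idx[j, p] = (r0[p] + kh[j]) + (c0[p] + kw[j] - 1) * Hp
  idx <- outer(kh, r0, "+") + (outer(kw, c0, "+") - 1L) * Hp
  storage.mode(idx) <- "integer"
  .nn_cache[[key]] <- idx
  idx
}

# channel-inclusive gather indices into the padded (Hp*Wp*C) volume,
# ordered (kh, kw) fastest then channel — matching the weight-matrix
# column layout — so the gathered matrix needs no transposition.
im2col_idx_full <- function(Hp, Wp, C, k, stride) {
  key <- paste("i2cf", Hp, Wp, C, k, stride, sep = "_")
  if (!is.null(.nn_cache[[key]])) return(.nn_cache[[key]])
  idx <- im2col_idx(Hp, Wp, k, stride)
  k2 <- k * k
  full <- idx[rep(seq_len(k2), C), , drop = FALSE] +
    rep.int((seq_len(C) - 1L) * (Hp * Wp), rep.int(k2, C))
  storage.mode(full) <- "integer"
  .nn_cache[[key]] <- full
  full
}

# Sparse scatter-add (col2im adjoint of the gather): maps the long
# (k2*C*P) gradient stack back onto the padded (Hp*Wp*C) volume.
col2im_operator <- function(Hp, Wp, C, k, stride) {
  key <- paste("c2i", Hp, Wp, C, k, stride, sep = "_")
  if (!is.null(.nn_cache[[key]])) return(.nn_cache[[key]])
  idx <- as.vector(im2col_idx_full(Hp, Wp, C, k, stride))
  op <- Matrix::sparseMatrix(i = idx, j = seq_along(idx), x = 1,
                             dims = c(Hp * Wp * C, length(idx)))
  .nn_cache[[key]] <- op
  op
}

# Sparse bilinear interpolation operator (h_out*w_out) x (h_in*w_in), with
# half-pixel sample centers and edge clamping; each row sums to 1, so a
# spatially constant field maps to the same constant.
resize_operator <- function(h_in, w_in, h_out, w_out) {
  key <- paste("rsz", h_in, w_in, h_out, w_out, sep = "_")
  if (!is.null(.nn_cache[[key]])) return(.nn_cache[[key]])
  src_coord <- function(n_out, n_in) {
    s <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
    pmin(pmax(s, 0), n_in - 1)
  }
  sy <- src_coord(h_out, h_in); sx <- src_coord(w_out, w_in)
  y0 <- floor(sy); x0 <- floor(sx)
  y1 <- pmin(y0 + 1, h_in - 1); x1 <- pmin(x0 + 1, w_in - 1)
  wy <- sy - y0; wx <- sx - x0
  # output pixel (r, c) -> row r + (c-1)*h_out; combine 4 corners
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  grid_r <- rep(seq_len(h_out), times = w_out)
  grid_c <- rep(seq_len(w_out), each = h_out)
  out_i <- grid_r + (grid_c - 1L) * h_out
  for (corner in list(list(y0, 1 - wy, x0, 1 - wx), list(y1, wy, x0, 1 - wx),
                      list(y0, 1 - wy, x1, wx),     list(y1, wy, x1, wx))) {
    yy <- corner[[1]][grid_r]; wyv <- corner[[2]][grid_r]
    xx <- corner[[3]][grid_c]; wxv <- corner[[4]][grid_c]
    rows <- c(rows, out_i)
    cols <- c(cols, (yy + 1) + xx * h_in)
    vals <- c(vals, wyv * wxv)
  }
  op <- Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                             dims = c(h_out * w_out, h_in * w_in))
  .nn_cache[[key]] <- op
  op
}

# Bilinearly resize an (H, W, C, B) array to (h_out, w_out, C, B).
resize_bilinear <- function(x, h_out, w_out) {
  d <- dim(x)
  if (d[1] == h_out && d[2] == w_out) return(x)
  op <- resize_operator(d[1], d[2], h_out, w_out)
  y <- as.matrix(op %*% matrix(x, d[1] * d[2], d[3] * d[4]))
  array(y, c(h_out, w_out, d[3], d[4]))
}

resize_bilinear_backward <- function(dy, h_in, w_in) {
  d <- dim(dy)
  if (d[1] == h_in && d[2] == w_in) return(dy)
  op <- resize_operator(h_in, w_in, d[1], d[2])
  dx <- as.matrix(Matrix::crossprod(op, matrix(dy, d[1] * d[2], d[3] * d[4])))
  array(dx, c(h_in, w_in, d[3], d[4]))
}

# ---- layers -----------------------------------------------------------------

nn_conv <- function(c_in, c_out, k = 3L, stride = 1L, pad = (k - 1L) %/% 2L,
                    relu = TRUE) {
  # He-normal fan-in initialization
  W <- matrix(stats::rnorm(c_out * k * k * c_in, sd = sqrt(2 / (k * k * c_in))),
              nrow = c_out)
  list(type = "conv", k = as.integer(k), stride = as.integer(stride),
       pad = as.integer(pad), c_in = as.integer(c_in), c_out = as.integer(c_out),
       relu = relu, W = W, b = numeric(c_out))
}

conv_forward <- function(layer, x) {
  d <- dim(x)
  if (d[3] != layer$c_in)
    stop("conv expects ", layer$c_in, " input channels, got ", d[3])
  k <- layer$k; s <- layer$stride; p <- layer$pad
  Hp <- d[1] + 2L * p; Wp <- d[2] + 2L * p
  if (Hp < k || Wp < k) stop("input spatially smaller than kernel")
  Ho <- (Hp - k) %/% s + 1L; Wo <- (Wp - k) %/% s + 1L
  if (p > 0L) {
    xp <- array(0, c(Hp, Wp, d[3], d[4]))
    xp[p + seq_len(d[1]), p + seq_len(d[2]), , ] <- x
  } else xp <- x
  idx <- im2col_idx_full(Hp, Wp, d[3], k, s)
  # gather -> (k2*C, P*B) with zero-copy reshapes only
  Gm <- matrix(xp, Hp * Wp * d[3], d[4])[as.vector(idx), , drop = FALSE]
  dim(Gm) <- c(k * k * d[3], Ho * Wo * d[4])
  Y <- layer$W %*% Gm + layer$b
  pre <- array(aperm(array(Y, c(layer$c_out, Ho * Wo, d[4])), c(2, 1, 3)),
               c(Ho, Wo, layer$c_out, d[4]))
  out <- if (layer$relu) pmax(pre, 0) else pre
  list(out = out, cache = list(Gm = Gm, pre = if (layer$relu) pre else NULL,
                               dims = d, Ho = Ho, Wo = Wo))
}

conv_backward <- function(layer, cache, dy) {
  d <- cache$dims; Ho <- cache$Ho; Wo <- cache$Wo
  k <- layer$k; s <- layer$stride; p <- layer$pad
  if (layer$relu) dy <- dy * (cache$pre > 0)
  dYm <- matrix(aperm(array(dy, c(Ho * Wo, layer$c_out, d[4])), c(2, 1, 3)),
                layer$c_out, Ho * Wo * d[4])
  dW <- tcrossprod(dYm, cache$Gm)
  db <- rowSums(dYm)
  dGm <- crossprod(layer$W, dYm)                       # (k2*C) x (P*B)
  Hp <- d[1] + 2L * p; Wp <- d[2] + 2L * p
  # col2im scatter-add as a cached sparse linear operator
  sc <- col2im_operator(Hp, Wp, d[3], k, s)
  dim(dGm) <- c((k * k) * d[3] * Ho * Wo, d[4])
  dxp <- array(as.matrix(sc %*% dGm), c(Hp, Wp, d[3], d[4]))
  dx <- if (p > 0L) dxp[p + seq_len(d[1]), p + seq_len(d[2]), , , drop = FALSE]
        else dxp
  list(dx = dx, dW = dW, db = db)
}

# ---- sequential stack -------------------------------------------------------

seq_forward <- function(layers, x) {
  caches <- vector("list", length(layers))
  taps <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    f <- conv_forward(layers[[i]], x)
    x <- f$out
    caches[[i]] <- f$cache
    taps[[i]] <- x
  }
  list(out = x, caches = caches, taps = taps)
}

# inject: optional named list mapping a stage index (as character) to an
# extra gradient added to that stage's output (skip connections).
seq_backward <- function(layers, caches, dy, inject = NULL) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    if (!is.null(inject) && !is.null(inject[[as.character(i)]]))
      dy <- dy + inject[[as.character(i)]]
    b <- conv_backward(layers[[i]], caches[[i]], dy)
    grads[[i]] <- list(dW = b$dW, db = b$db)
    dy <- b$dx
  }
  list(grads = grads, dx = dy)
}

# ---- parameter bookkeeping --------------------------------------------------

# Walk a nested model structure and apply f(param, ...) to every W/b leaf.
map_params <- function(obj, f) {
  if (is.list(obj)) {
    if (!is.null(obj$type) && obj$type == "conv") {
      obj$W <- f(obj$W); obj$b <- f(obj$b)
      return(obj)
    }
    for (nm in seq_along(obj)) obj[[nm]] <- map_params(obj[[nm]], f)
  }
  obj
}

# Combine two congruent structures leaf-wise: out = f(a_leaf, b_leaf).
combine_params <- function(a, b, f) {
  if (is.list(a)) {
    if (!is.null(a$type) && a$type == "conv") {
      if (is.null(b$type) || !identical(dim(b$W), dim(a$W)))
        stop("parameter structures are not congruent")
      a$W <- f(a$W, b$W); a$b <- f(a$b, b$b)
      return(a)
    }
    for (nm in seq_along(a)) a[[nm]] <- combine_params(a[[nm]], b[[nm]], f)
  }
  a
}

# Flatten every parameter leaf into one numeric vector (diagnostics/tests).
flatten_params <- function(obj) {
  acc <- c()
  walk <- function(o) {
    if (is.list(o)) {
      if (!is.null(o$type) && o$type == "conv") {
        acc <<- c(acc, as.vector(o$W), o$b)
      } else for (e in o) walk(e)
    }
  }
  walk(obj)
  acc
}

n_params <- function(obj) length(flatten_params(obj))

# ---- SGD with momentum ------------------------------------------------------

sgd_state <- function(model) map_params(model, function(p) p * 0)

# grads is a structure congruent with `model` holding dW/db in place of W/b
# (as produced by the *_grads helpers in trainer.R).
sgd_step <- function(model, grads, state, lr, momentum = 0.9, weight_decay = 0) {
  new_state <- combine_params(state, combine_params(grads, model, function(g, p)
    g + weight_decay * p), function(v, g) momentum * v + g)
  model <- combine_params(model, new_state, function(p, v) p - lr * v)
  list(model = model, state = new_state)
}
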