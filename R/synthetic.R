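# Synthetic zooplankton-like microscopy scene generator.
#
# Real zooplankton microscopy collections with pixel-level labels are rare
# and typically private, so the package bundles a deterministic generator
# that emulates their stated properties at desk scale: parametric specimen
# shape families (body aspect ratio x appendage count), diverse poses, thin
# 1-3 px appendages, occasional overlapping individuals with distinct
# classes, small non-biological background particles, mild illumination
# gradients, and a moderately imbalanced class distribution. Every output
# is a pure function of the arguments and the seed.

# Shape families cycle over (body aspect, appendage count) bins so that any
# class count K >= 2 yields classes separable in distribution yet
# overlapping in individual instances.
class_family <- function(class_id) {
  fam <- (class_id - 1L) %% 4L
  switch(fam + 1L,
    list(aspect = c(1.0, 1.4), n_app = c(0L, 2L), app_len = c(0.5, 0.9)),   # round, few
    list(aspect = c(2.6, 3.6), n_app = c(1L, 2L), app_len = c(1.2, 1.8)),   # slender, antennae
    list(aspect = c(1.0, 1.4), n_app = c(5L, 8L), app_len = c(0.5, 0.9)),   # round, many
    list(aspect = c(2.6, 3.6), n_app = c(5L, 8L), app_len = c(0.8, 1.2)))   # slender, many
}

# Draw one specimen specification for a foreground class.
sample_scene_spec <- function(class_id, height, width) {
  fam <- class_family(class_id)
  a <- stats::runif(1, 0.07, 0.20) * min(height, width)      # semi-major axis, px
  aspect <- stats::runif(1, fam$aspect[1], fam$aspect[2])
  b <- a / aspect
  n_app <- if (fam$n_app[2] >= fam$n_app[1])
    sample(fam$n_app[1]:fam$n_app[2], 1L) else fam$n_app[1]
  app_len <- stats::runif(1, fam$app_len[1], fam$app_len[2]) * a
  # species-specific pigmentation: per-class opacity bands, overlapping
  # between neighbouring classes so individual instances remain ambiguous
  oc <- 0.30 + 0.30 * ((class_id - 1L) %% 4L) / 3
  opacity <- stats::runif(1, oc - 0.09, oc + 0.09)
  margin <- a + app_len + 2
  if (2 * margin >= min(height, width))
    margin <- min(height, width) / 2 - 1
  structure(list(
    class_id = as.integer(class_id),
    body = list(cx = stats::runif(1, margin, width - margin),
                cy = stats::runif(1, margin, height - margin),
                a = a, b = b, rot = stats::runif(1, 0, 2 * pi)),
    n_appendages = n_app,
    appendage_width = stats::runif(1, 1, 3),
    appendage_length = app_len,
    texture_level = stats::runif(1, 0.2, 1.0),
    opacity = opacity,
    overlap_partner = NA_integer_
  ), class = "scene_spec")
}

# Anti-aliased support (alpha in [0,1]) of one specimen on the canvas.
# Appendage polylines originate on the body boundary and point outward.
render_specimen <- function(spec, height, width) {
  gx <- matrix(rep(seq_len(width), each = height), height)   # column coord
  gy <- matrix(rep(seq_len(height), times = width), height)  # row coord
  bd <- spec$body
  dx <- gx - bd$cx; dy <- gy - bd$cy
  u <- dx * cos(bd$rot) + dy * sin(bd$rot)
  v <- -dx * sin(bd$rot) + dy * cos(bd$rot)
  q <- sqrt((u / bd$a)^2 + (v / bd$b)^2)
  alpha <- clamp01((1 - q) * min(bd$a, bd$b) + 0.5)
  if (spec$n_appendages > 0) {
    for (i in seq_len(spec$n_appendages)) {
      t0 <- stats::runif(1, 0, 2 * pi)
      # boundary point of the (rotated) ellipse and its outward direction
      bx <- bd$a * cos(t0); by <- bd$b * sin(t0)
      px <- bd$cx + bx * cos(bd$rot) - by * sin(bd$rot)
      py <- bd$cy + bx * sin(bd$rot) + by * cos(bd$rot)
      ang <- atan2(by / bd$b^2, bx / bd$a^2) + bd$rot + stats::runif(1, -0.3, 0.3)
      len <- spec$appendage_length * stats::runif(1, 0.7, 1.0)
      n_seg <- 2L
      for (s in seq_len(n_seg)) {
        qx <- px + cos(ang) * len / n_seg
        qy <- py + sin(ang) * len / n_seg
        alpha <- pmax(alpha, segment_alpha(gx, gy, px, py, qx, qy,
                                           spec$appendage_width))
        px <- qx; py <- qy
        ang <- ang + stats::runif(1, -0.5, 0.5)
      }
    }
  }
  alpha
}

# anti-aliased stroke of width w between (x1,y1)-(x2,y2)
segment_alpha <- function(gx, gy, x1, y1, x2, y2, w) {
  vx <- x2 - x1; vy <- y2 - y1
  L2 <- vx * vx + vy * vy
  t <- if (L2 > 0) clamp01(((gx - x1) * vx + (gy - y1) * vy) / L2) else 0
  dist <- sqrt((gx - (x1 + t * vx))^2 + (gy - (y1 + t * vy))^2)
  clamp01(w / 2 - dist + 0.5)
}

#' Generate one synthetic microscopy scene
#'
#' Renders 1-3 plankton-like specimens (anti-aliased ellipse bodies with
#' thin articulated appendages) on a bright-field background with an
#' illumination gradient, small non-biological speckle particles (labeled
#' background), and sensor noise. With probability `overlap_prob` the scene
#' contains an overlapping pair of specimens with distinct class IDs
#' meeting at a shared boundary.
#'
#' @param class_weights probability vector of length `K` over classes
#'   (entry 1 is background and is ignored for specimen sampling; the
#'   foreground entries are renormalized). Must sum to 1.
#' @param height,width canvas size in pixels, each at least 32.
#' @param seed optional integer; when given, the scene is a pure function
#'   of `(arguments, seed)`.
#' @param overlap_prob probability of an overlapping specimen pair.
#' @return list with `image` `(H, W, 3)` in `[0, 1]`, `mask` integer
#'   `(H, W)` with values in `0..K-1` (0 = background), and `specs` — the
#'   list of `scene_spec` objects rendered.
#' @export
generate_scene <- function(class_weights, height = 64L, width = 64L,
                           seed = NULL, overlap_prob = 0.2) {
  K <- length(class_weights)
  if (K < 2) stop("need at least 2 classes (background + 1 foreground)")
  if (abs(sum(class_weights) - 1) > 1e-9) stop("class_weights must sum to 1")
  if (any(class_weights < 0)) stop("class_weights must be nonnegative")
  if (height < 32 || width < 32)
    stop("canvas ", height, "x", width,
         " too small: the smallest specimen needs at least 32x32")
  if (!is.null(seed)) set.seed(seed)
  fg_w <- class_weights[-1]
  if (sum(fg_w) <= 0) stop("at least one foreground class needs weight > 0")
  fg_w <- fg_w / sum(fg_w)
  draw_class <- function() sample.int(K - 1L, 1L, prob = fg_w)

  n_spec <- sample(1:3, 1L)
  specs <- lapply(seq_len(n_spec), function(i)
    sample_scene_spec(draw_class(), height, width))
  if (stats::runif(1) < overlap_prob) {
    # append an overlapping partner for the first specimen, distinct class
    # when more than one foreground class has mass
    base <- specs[[1]]
    cls <- draw_class()
    if (K > 2 && sum(fg_w > 0) > 1) {
      while (cls == base$class_id) cls <- draw_class()
    }
    partner <- sample_scene_spec(cls, height, width)
    ang <- stats::runif(1, 0, 2 * pi)
    d <- 0.8 * (base$body$a + partner$body$b) / 2 + 0.4 * partner$body$a
    partner$body$cx <- min(max(base$body$cx + d * cos(ang), 2), width - 2)
    partner$body$cy <- min(max(base$body$cy + d * sin(ang), 2), height - 2)
    partner$overlap_partner <- 1L
    specs[[length(specs) + 1L]] <- partner
  }

  alphas <- lapply(specs, render_specimen, height = height, width = width)
  # per-pixel owner = specimen with the highest support (ties: earlier index)
  mask <- matrix(0L, height, width)
  best <- matrix(0, height, width)
  for (i in seq_along(specs)) {
    sel <- alphas[[i]] > 0.5 & alphas[[i]] > best
    mask[sel] <- specs[[i]]$class_id
    best <- pmax(best, alphas[[i]])
  }

  # bright-field background with a mild illumination gradient
  ang <- stats::runif(1, 0, 2 * pi)
  gx <- matrix(rep(seq_len(width), each = height), height) / width - 0.5
  gy <- matrix(rep(seq_len(height), times = width), height) / height - 0.5
  img <- stats::runif(1, 0.75, 0.90) + stats::runif(1, -0.15, 0.15) * (gx * cos(ang) + gy * sin(ang)) * 2
  for (i in seq_along(specs)) {
    base_int <- specs[[i]]$opacity
    tex <- 1 + specs[[i]]$texture_level * 0.5 *
      matrix(stats::rnorm(height * width), height)
    img <- img * (1 - alphas[[i]]) + (base_int * clamp01(tex)) * alphas[[i]]
  }
  # small (<= 5 px) high-contrast non-biological particles, labeled background
  for (s in seq_len(stats::rpois(1, 10))) {
    r <- stats::runif(1, 0.6, 2.2)
    cx <- stats::runif(1, 1, width); cy <- stats::runif(1, 1, height)
    gxx <- matrix(rep(seq_len(width), each = height), height)
    gyy <- matrix(rep(seq_len(height), times = width), height)
    a <- clamp01(r - sqrt((gxx - cx)^2 + (gyy - cy)^2) + 0.5)
    shade <- sample(c(-1, 1), 1) * stats::runif(1, 0.15, 0.3)
    img <- img * (1 - a) + clamp01(img + shade) * a
  }
  img <- clamp01(img + stats::rnorm(height * width, sd = 0.04))
  list(image = array(rep(img, 3L), c(height, width, 3L)),
       mask = mask, specs = specs)
}

#' Generate a synthetic segmentation dataset on disk
#'
#' Writes `n_images` PNG image/mask pairs plus a manifest CSV. Every tenth
#' image is tagged `test` (a fixed 9:1 train/test split independent of any
#' later semi-supervised ratio); the rest form the training pool.
#' Regeneration with identical arguments is byte-identical.
#'
#' @param n_images number of images (>= 10).
#' @param k number of classes including background (default 4).
#' @param size square image size in pixels.
#' @param imbalance `"moderate"` (foreground class weights graded ~220:60,
#'   mirroring natural abundance patterns), `"uniform"`, or a numeric
#'   weight vector of length `k` (entry 1 = background, ignored).
#' @param seed integer seed; the dataset is a pure function of the
#'   arguments and this seed.
#' @param out_dir output directory (created if needed).
#' @param overlap_prob probability of an overlapping pair per scene.
#' @return the manifest data frame (paths relative to `out_dir`; attribute
#'   `root` = `out_dir`), also written to `<out_dir>/manifest.csv`.
#' @export
generate_dataset <- function(n_images, k = 4L, size = 64L,
                             imbalance = "moderate", seed = 1L,
                             out_dir, overlap_prob = 0.2) {
  if (n_images < 10) stop("n_images must be at least 10")
  weights <- dataset_class_weights(k, imbalance)
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  set.seed(seed)
  rows <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    sc <- generate_scene(weights, size, size, overlap_prob = overlap_prob)
    pi_ <- file.path("images", sprintf("img_%04d.png", i))
    pm_ <- file.path("masks", sprintf("img_%04d.png", i))
    write_image(sc$image, file.path(out_dir, pi_))
    write_mask(sc$mask, file.path(out_dir, pm_))
    rows[[i]] <- data.frame(path_image = pi_, path_mask = pm_,
                            split = if (i %% 10 == 0) "test" else "train",
                            k = k, size = size, seed = seed)
  }
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  attr(manifest, "root") <- normalizePath(out_dir)
  manifest
}

dataset_class_weights <- function(k, imbalance) {
  if (is.numeric(imbalance)) {
    if (length(imbalance) != k) stop("numeric imbalance must have length k")
    w <- imbalance
  } else if (identical(imbalance, "moderate")) {
    fg <- seq(220, 60, length.out = k - 1L)
    w <- c(0, fg / sum(fg))
  } else if (identical(imbalance, "uniform")) {
    w <- c(0, rep(1 / (k - 1L), k - 1L))
  } else stop("imbalance must be 'moderate', 'uniform' or a weight vector")
  w / sum(w)
}

#' Tag a manifest with a semi-supervised labeled/unlabeled split
#'
#' Splits the training pool into `train-labeled` and `train-unlabeled`;
#' the test split is untouched and identical across ratios. The ordering is
#' a seeded, class-stratified round-robin over the dominant foreground
#' class of each mask, so (a) splits are nested — the labeled set at ratio
#' 1/2 contains the labeled set at ratio 1/4 under the same seed — and (b)
#' every class present in the pool appears among the labeled images
#' whenever the labeled budget allows.
#'
#' @param manifest a dataset manifest (data frame from
#'   [generate_dataset()] or [read_manifest()]).
#' @param labeled_ratio fraction of the training pool to label; the
#'   canonical protocol uses 1/2, 1/4, 1/8 or 1/16. `floor(ratio * n)`
#'   images are labeled; an error if that is zero.
#' @param seed split seed.
#' @param root dataset root (defaults to the manifest's `root` attribute).
#' @return the manifest with `split` values `train-labeled`,
#'   `train-unlabeled`, `test`.
#' @export
split_semi <- function(manifest, labeled_ratio, seed = 1L, root = NULL) {
  if (labeled_ratio <= 0 || labeled_ratio > 1)
    stop("labeled_ratio must lie in (0, 1]")
  root <- manifest_root(manifest, root)
  is_train <- manifest$split != "test"
  idx_train <- which(is_train)
  n_train <- length(idx_train)
  if (n_train == 0) stop("manifest has no training pool")
  m <- floor(labeled_ratio * n_train)
  if (m < 1)
    stop("labeled_ratio ", labeled_ratio, " yields zero labeled images for a ",
         n_train, "-image training pool")
  # dominant foreground class per training image (0 when purely background)
  dom <- vapply(idx_train, function(i) {
    msk <- read_mask(file.path(root, manifest$path_mask[i]))
    fg <- msk[msk > 0L]
    if (!length(fg)) 0L else as.integer(names(which.max(table(fg))))
  }, integer(1))
  set.seed(seed)
  classes <- sample(unique(dom))                # class visit order
  pools <- lapply(classes, function(cl) sample(idx_train[dom == cl]))
  order_rr <- integer(0)
  while (any(lengths(pools) > 0)) {
    for (j in seq_along(pools)) {
      if (length(pools[[j]])) {
        order_rr <- c(order_rr, pools[[j]][1])
        pools[[j]] <- pools[[j]][-1]
      }
    }
  }
  manifest$split[is_train] <- "train-unlabeled"
  manifest$split[order_rr[seq_len(m)]] <- "train-labeled"
  attr(manifest, "root") <- root
  manifest
}
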