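# Semi-supervised training orchestration: labeled/unlabeled batch
# interleaving, the three prediction branches, CPF, loss assembly,
# optimization of student + auxiliary teacher + fusion branch, and the EMA
# update of the main teacher.
#
# Gradient flow contract: only the student receives L_sup, L_hs and
# L_soft; the auxiliary teacher receives L_ha (plus, optionally, its own
# supervised CE); the fusion branch receives hard-label CE on its own
# logits with teacher features detached; the main teacher is never
# gradient-trained — it is the exponential moving average of the student.

#' Exponential moving average update of the main teacher
#'
#' `theta' <- rho * theta' + (1 - rho) * theta`, applied elementwise to
#' every parameter. `rho = 1` freezes the teacher; `rho = 0` copies the
#' student.
#'
#' @param teacher,student congruent model structures.
#' @param rho EMA coefficient in `[0, 1]` (default 0.999).
#' @return the updated teacher.
#' @export
ema_update <- function(teacher, student, rho = 0.999) {
  if (rho < 0 || rho > 1) stop("rho must lie in [0, 1]")
  combine_params(teacher, student, function(t, s) rho * t + (1 - rho) * s)
}

#' Assemble the model set for a run configuration
#'
#' Builds the student, its EMA main teacher, the heterogeneous auxiliary
#' teacher (when `model$dual_teacher`), and the attention-guided fusion
#' branch (when `model$fusion`). Without a dual teacher, the fusion branch
#' falls back to fusing the main teacher's deep tap with its own mid-level
#' stage.
#'
#' @param cfg validated configuration list.
#' @return list of models plus optimizer states.
#' @export
build_models <- function(cfg) {
  mc <- cfg$model
  student <- seg_model(mc$backbone_main, mc$n_classes)
  teacher_main <- student                     # EMA copy, starts identical
  models <- list(student = student, teacher_main = teacher_main)
  if (isTRUE(mc$dual_teacher) && !isTRUE(mc$supervised_only))
    models$teacher_aux <- seg_model(mc$backbone_aux, mc$n_classes)
  if (isTRUE(mc$fusion) && !isTRUE(mc$supervised_only)) {
    c_main <- BACKBONES[[mc$backbone_main]]$channels[BACKBONES[[mc$backbone_main]]$tap]
    if (!is.null(models$teacher_aux)) {
      sp <- BACKBONES[[mc$backbone_aux]]
      c_aux <- sp$channels[sp$tap]
    } else {
      c_aux <- BACKBONES[[mc$backbone_main]]$channels[2L]   # mid-level stage
    }
    models$fusion <- fusion_branch(c_main, c_aux, mc$n_classes, d_k = mc$d_k)
  }
  opt <- lapply(models[setdiff(names(models), "teacher_main")], sgd_state)
  list(models = models, opt = opt)
}

# horizontal flip (columns) of image batches and label batches
flip_h <- function(x) {
  d <- dim(x)
  idx <- rev(seq_len(d[2]))
  if (length(d) == 4L) x[, idx, , , drop = FALSE] else x[, idx, , drop = FALSE]
}

# weak augmentation: per-image horizontal flip; returns the flip mask so
# labels can be transformed consistently
augment_weak <- function(x, flips = NULL) {
  x <- as_batch4(x)
  B <- dim(x)[4]
  if (is.null(flips)) flips <- stats::runif(B) < 0.5
  for (b in which(flips)) x[, , , b] <- x[, rev(seq_len(dim(x)[2])), , b]
  list(x = x, flips = flips)
}

apply_flips_labels <- function(y, flips) {
  y <- as_batch3(y)
  for (b in which(flips)) y[, , b] <- y[, rev(seq_len(dim(y)[2])), b]
  y
}

# strong augmentation: photometric jitter + Gaussian noise on top of the
# weak view, so pseudo-labels stay spatially aligned
augment_strong <- function(x) {
  x <- as_batch4(x)
  B <- dim(x)[4]
  for (b in seq_len(B)) {
    scale <- stats::runif(1, 0.8, 1.2)
    shift <- stats::runif(1, -0.15, 0.15)
    x[, , , b] <- clamp01((x[, , , b] - 0.5) * scale + 0.5 + shift +
                            stats::rnorm(length(x[, , , b]), sd = 0.05))
  }
  x
}

add_grads <- function(a, b) combine_params(a, b, `+`)

#' One semi-supervised training step
#'
#' Runs the full iteration: supervised CE on the labeled batch; teacher +
#' fusion forward passes on the weakly augmented unlabeled batch; CPF;
#' student hard/soft losses on the strongly augmented unlabeled batch;
#' auxiliary-teacher hard loss; optimizer steps; EMA update of the main
#' teacher. With an empty unlabeled batch the step reduces exactly to
#' supervised training.
#'
#' @param state list from [build_models()] (`models`, `opt`).
#' @param labeled list with `x` `(H, W, 3, B)` and `y` `(H, W, B)`; must be
#'   nonempty (the supervised anchor).
#' @param unlabeled list with `x`, possibly `NULL` or zero images.
#' @param ts a [threshold_state()].
#' @param cfg validated configuration.
#' @return list with updated `state`, `ts`, and a `report` of loss terms
#'   (`l_sup`, `l_hs`, `l_ha`, `l_soft`, `l_unsup`, `l_total`), pixel
#'   counts and the current threshold vector.
#' @export
train_step <- function(state, labeled, unlabeled, ts, cfg) {
  if (is.null(labeled$x) || dim(as_batch4(labeled$x))[4] == 0)
    stop("labeled batch must be nonempty: supervised anchor required")
  models <- state$models; opt <- state$opt
  oc <- cfg$optim
  n_classes <- cfg$model$n_classes
  lx <- as_batch4(labeled$x); ly <- as_batch3(labeled$y)
  if (isTRUE(oc$augment)) {
    wa <- augment_weak(lx)
    lx <- augment_strong(wa$x)
    ly <- apply_flips_labels(ly, wa$flips)
  }
  fs_l <- forward_segment(models$student, lx, want_cache = TRUE)
  sup <- ce_with_grad(fs_l$logits, ly)
  g_student <- backward_segment(models$student, fs_l$cache, sup$grad)

  have_unl <- !is.null(unlabeled$x) && dim(as_batch4(unlabeled$x))[4] > 0 &&
    !isTRUE(cfg$model$supervised_only)
  # The gradient-trained side branches also learn from the labeled batch:
  # the auxiliary teacher via its own supervised CE (aux_supervised), the
  # fusion branch via CE on its prediction from the teachers' features.
  # Once unlabeled batches flow, their pseudo-label losses take over and
  # the labeled passes are skipped (one labeled anchor per step suffices
  # and the saving funds longer schedules).
  g_aux <- NULL; g_fus <- NULL
  l_ha <- 0
  if (!have_unl && !is.null(models$teacher_aux) &&
      isTRUE(cfg$loss$aux_supervised)) {
    fa_l <- forward_segment(models$teacher_aux, lx, want_cache = TRUE)
    sup_a <- ce_with_grad(fa_l$logits, ly)
    g_aux <- backward_segment(models$teacher_aux, fa_l$cache, sup_a$grad)
    l_ha <- l_ha + sup_a$loss
  }
  if (!have_unl && !is.null(models$fusion)) {
    ft_l <- forward_segment(models$teacher_main, lx)
    fa_feat <- if (!is.null(models$teacher_aux)) {
      if (exists("fa_l", inherits = FALSE) && !is.null(g_aux)) fa_l$features
      else forward_segment(models$teacher_aux, lx)$features
    } else ft_l$taps[[2L]]
    fus_l <- fusion_forward(models$fusion, ft_l$features, fa_feat,
                            dim(lx)[1:2], want_cache = TRUE)
    sup_f <- ce_with_grad(fus_l$logits, ly)
    g_fus <- fusion_backward(models$fusion, fus_l$cache, sup_f$grad)
  }

  l_hs <- 0; l_soft <- 0
  n_hard <- 0L; n_soft <- 0L
  bundle <- NULL
  if (have_unl) {
    ux <- as_batch4(unlabeled$x)
    if (isTRUE(oc$augment)) ux <- augment_weak(ux)$x
    d_in <- dim(ux)[1:2]
    ft <- forward_segment(models$teacher_main, ux)
    p_t <- prob_softmax(ft$logits)
    p_a <- NULL; p_f <- NULL
    fa <- NULL; fus <- NULL
    if (!is.null(models$teacher_aux)) {
      fa <- forward_segment(models$teacher_aux, ux, want_cache = TRUE)
      p_a <- prob_softmax(fa$logits)
    }
    if (!is.null(models$fusion)) {
      f_main <- ft$features
      f_aux <- if (!is.null(fa)) fa$features else ft$taps[[2L]]
      fus <- fusion_forward(models$fusion, f_main, f_aux, d_in, want_cache = TRUE)
      p_f <- prob_softmax(fus$logits)
    }
    w <- fusion_weights(cfg$cpf$alpha, cfg$cpf$beta, cfg$cpf$gamma)
    if (isTRUE(cfg$cpf$enabled)) {
      cp <- cpf_step(p_t, p_a, p_f, w, ts, mu = cfg$cpf$mu,
                     k_frac = cfg$cpf$k_frac, min_density = cfg$cpf$min_density)
      bundle <- cp$bundle; ts <- cp$ts
    } else {
      # static-threshold ablation: consistency + fixed tau, no soft labels
      fused <- fuse_predictions(p_t, p_a, p_f, w)
      ys <- lapply(Filter(Negate(is.null), list(p_t, p_a, p_f)), prob_argmax)
      hard <- select_hard(ys, fused, ts)
      bundle <- structure(list(hard = hard, soft_mask = array(FALSE, dim(hard)),
                               soft_idx = integer(0),
                               soft_target = matrix(0, 0, n_classes),
                               omega = numeric(0), fused = fused,
                               diagnostics = list()),
                          class = "pseudo_bundle")
    }
    n_hard <- sum(bundle$hard != IGNORE_LABEL)
    n_soft <- length(bundle$soft_idx)

    sx <- if (isTRUE(oc$augment)) augment_strong(ux) else ux
    fs_u <- forward_segment(models$student, sx, want_cache = TRUE)
    hs <- ce_with_grad(fs_u$logits, bundle$hard)
    sk <- soft_kl_with_grad(fs_u$logits, bundle,
                            direction = cfg$loss$kl_direction)
    l_hs <- hs$loss; l_soft <- sk$loss
    du <- hs$grad + cfg$loss$lambda_soft * sk$grad
    g_student <- add_grads(g_student,
                           backward_segment(models$student, fs_u$cache, du))

    if (!is.null(models$teacher_aux)) {
      ha <- ce_with_grad(fa$logits, bundle$hard)
      l_ha <- l_ha + ha$loss
      g_ha <- backward_segment(models$teacher_aux, fa$cache, ha$grad)
      g_aux <- if (is.null(g_aux)) g_ha else add_grads(g_aux, g_ha)
    }
    if (!is.null(models$fusion) && n_hard > 0) {
      hf <- ce_with_grad(fus$logits, bundle$hard)
      g_hf <- fusion_backward(models$fusion, fus$cache, hf$grad)
      g_fus <- if (is.null(g_fus)) g_hf else add_grads(g_fus, g_hf)
    }
  }
  if (!is.null(g_aux)) {
    st <- sgd_step(models$teacher_aux, g_aux, opt$teacher_aux, oc$lr,
                   oc$momentum, oc$weight_decay)
    models$teacher_aux <- st$model; opt$teacher_aux <- st$state
  }
  if (!is.null(g_fus)) {
    st <- sgd_step(models$fusion, g_fus, opt$fusion, oc$lr,
                   oc$momentum, oc$weight_decay)
    models$fusion <- st$model; opt$fusion <- st$state
  }
  st <- sgd_step(models$student, g_student, opt$student, oc$lr,
                 oc$momentum, oc$weight_decay)
  models$student <- st$model; opt$student <- st$state
  models$teacher_main <- ema_update(models$teacher_main, models$student, oc$ema)

  tl <- total_loss(sup$loss, l_hs, l_soft, cfg$loss$lambda_soft)
  report <- list(l_sup = sup$loss, l_hs = l_hs, l_ha = l_ha, l_soft = l_soft,
                 l_unsup = tl$l_unsup, l_total = tl$l_total,
                 n_sup_px = sup$n, n_hard = n_hard, n_soft = n_soft,
                 tau = ts$tau)
  list(state = list(models = models, opt = opt), ts = ts, report = report)
}

# load every image/mask of the given split tags into memory
load_split <- function(manifest, splits, root = NULL, n_classes = NULL) {
  root <- manifest_root(manifest, root)
  rows <- which(manifest$split %in% splits)
  if (!length(rows)) return(list(x = NULL, y = NULL, n = 0L))
  im1 <- read_image(file.path(root, manifest$path_image[rows[1]]))
  d <- dim(im1)
  x <- array(0, c(d[1], d[2], 3L, length(rows)))
  y <- array(IGNORE_LABEL, c(d[1], d[2], length(rows)))
  for (j in seq_along(rows)) {
    x[, , , j] <- read_image(file.path(root, manifest$path_image[rows[j]]))
    y[, , j] <- read_mask(file.path(root, manifest$path_mask[rows[j]]), n_classes)
  }
  storage.mode(y) <- "integer"
  list(x = x, y = y, n = length(rows))
}

#' Evaluate a segmentation model on a data split
#'
#' @param model a [seg_model()] (typically the student).
#' @param data list with `x`, `y` as produced by the internal loader.
#' @param n_classes class count.
#' @param batch_size evaluation batch size.
#' @return [compute_metrics()] output.
#' @export
evaluate_model <- function(model, data, n_classes, batch_size = 16L) {
  acc <- metric_accumulator(n_classes)
  i <- 1L
  while (i <= data$n) {
    j <- min(i + batch_size - 1L, data$n)
    logits <- forward_segment(model, data$x[, , , i:j, drop = FALSE])$logits
    acc <- accumulate(acc, prob_argmax(prob_softmax(logits)),
                      data$y[, , i:j, drop = FALSE])
    i <- j + 1L
  }
  compute_metrics(acc)
}

#' Train a model on a semi-supervised manifest
#'
#' Runs epochs of [train_step()] with labeled and unlabeled batches drawn
#' in lockstep (the unlabeled pool defines the epoch length; in
#' supervised-only mode the labeled set does). After each epoch the
#' student is evaluated on the test split; the best-mIoU checkpoint and a
#' per-iteration CSV loss log are written to `cfg$out_dir`. Fully seeded:
#' the same configuration and seed reproduce the same history.
#'
#' @param manifest a manifest with `train-labeled`, `train-unlabeled` and
#'   `test` splits (see [split_semi()]).
#' @param cfg validated configuration list.
#' @param root dataset root directory (defaults to the manifest attribute).
#' @param resume path to a checkpoint to continue from.
#' @param quiet suppress per-epoch messages.
#' @return a `dualseg_fit` list: final and best models, threshold state,
#'   metric history, paths of the artifacts written.
#' @export
fit <- function(manifest, cfg, root = NULL, resume = NULL, quiet = TRUE) {
  validate_config(cfg)
  root <- manifest_root(manifest, root)
  n_classes <- cfg$model$n_classes
  labeled <- load_split(manifest, "train-labeled", root, n_classes)
  unlabeled <- load_split(manifest, "train-unlabeled", root, n_classes)
  test <- load_split(manifest, "test", root, n_classes)
  if (labeled$n == 0) stop("manifest has no train-labeled images")
  sup_only <- isTRUE(cfg$model$supervised_only)

  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$out_dir, "train_log.csv")
  ckpt_path <- file.path(cfg$out_dir, "checkpoint.rds")

  if (!is.null(resume)) {
    ck <- load_checkpoint(resume)
    state <- ck$state; ts <- ck$ts
    history <- ck$history; epoch0 <- ck$epoch
    best <- ck$best
    if (!is.null(ck$rng)) assign(".Random.seed", ck$rng, envir = globalenv())
  } else {
    set.seed(cfg$seed)
    state <- build_models(cfg)
    ts <- threshold_state(n_classes, cfg$cpf$tau_init, cfg$cpf$eta,
                          cfg$cpf$tau_min, cfg$cpf$window, cfg$cpf$quantile)
    history <- list(); epoch0 <- 0L
    best <- list(miou = -Inf)
    cat(paste(c("epoch", "step", "l_sup", "l_hs", "l_ha", "l_soft", "l_unsup",
                "l_total", "n_hard", "n_soft",
                paste0("tau_", seq_len(n_classes) - 1L)), collapse = ","),
        "\n", sep = "", file = log_path)
  }

  bs <- cfg$optim$batch_size
  pool_n <- if (sup_only || unlabeled$n == 0) labeled$n else unlabeled$n
  steps_per_epoch <- max(1L, ceiling(pool_n / bs))
  lab_cycle <- integer(0)

  take_batch <- function(data, idx) {
    list(x = data$x[, , , idx, drop = FALSE],
         y = if (!is.null(data$y)) data$y[, , idx, drop = FALSE])
  }

  base_lr <- cfg$optim$lr
  total_steps <- cfg$optim$epochs * steps_per_epoch
  for (epoch in seq_len(cfg$optim$epochs)) {
    if (epoch <= epoch0) next
    unl_order <- if (!sup_only && unlabeled$n > 0) sample(unlabeled$n) else integer(0)
    for (step in seq_len(steps_per_epoch)) {
      if (identical(cfg$optim$lr_schedule, "poly")) {
        t <- (epoch - 1L) * steps_per_epoch + step - 1L
        cfg$optim$lr <- base_lr * (1 - t / total_steps)^0.9
      }
      if (length(lab_cycle) < bs) lab_cycle <- c(lab_cycle, sample(labeled$n))
      li <- lab_cycle[seq_len(min(bs, labeled$n))]
      lab_cycle <- lab_cycle[-seq_len(min(bs, labeled$n))]
      lb <- take_batch(labeled, li)
      ub <- if (length(unl_order) && epoch > (cfg$optim$warmup %||% 0L)) {
        take <- unl_order[seq_len(min(bs, length(unl_order)))]
        unl_order <- unl_order[-seq_len(length(take))]
        take_batch(unlabeled, take)
      } else list(x = NULL)
      out <- train_step(state, lb, ub, ts, cfg)
      state <- out$state; ts <- out$ts
      r <- out$report
      cat(paste(c(epoch, step, sprintf("%.6f", c(r$l_sup, r$l_hs, r$l_ha,
                                                 r$l_soft, r$l_unsup, r$l_total)),
                  r$n_hard, r$n_soft, sprintf("%.4f", r$tau)), collapse = ","),
          "\n", sep = "", file = log_path, append = TRUE)
    }
    ev <- cfg$optim$eval_every %||% 1L
    if (epoch %% ev != 0L && epoch != cfg$optim$epochs) {
      save_checkpoint(list(state = state, ts = ts, cfg = cfg, epoch = epoch,
                           history = history, best = best,
                           rng = get(".Random.seed", envir = globalenv())),
                      ckpt_path)
      next
    }
    m <- evaluate_model(state$models$student, test, n_classes)
    history[[length(history) + 1L]] <-
      data.frame(epoch = epoch, miou = m$miou, dice = m$dice,
                 precision = m$precision, recall = m$recall, f1 = m$f1)
    if (!quiet)
      message(sprintf("epoch %d  test mIoU %.2f  Dice %.2f", epoch, m$miou, m$dice))
    if (m$miou > best$miou)
      best <- list(miou = m$miou, metrics = m, epoch = epoch,
                   models = state$models, ts = ts)
    save_checkpoint(list(state = state, ts = ts, cfg = cfg, epoch = epoch,
                         history = history, best = best,
                         rng = get(".Random.seed", envir = globalenv())),
                    ckpt_path)
  }
  history <- do.call(rbind, history)
  utils::write.csv(history, file.path(cfg$out_dir, "metrics.csv"),
                   row.names = FALSE)
  structure(list(models = state$models, ts = ts, cfg = cfg, history = history,
                 best = best, checkpoint = ckpt_path, log = log_path),
            class = "dualseg_fit")
}

#' Predict a class-ID mask for one image
#'
#' @param model a [seg_model()].
#' @param image `(H, W, 3)` array or a PNG path.
#' @return integer mask matrix `(H, W)`.
#' @export
predict_mask <- function(model, image) {
  if (is.character(image)) image <- read_image(image)
  logits <- forward_segment(model, image)$logits
  prob_argmax(prob_softmax(logits))[, , 1]
}
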