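# Run configuration: nested blocks mirroring the module boundaries
# (data / model / cpf / loss / optim), loaded from YAML with defaults
# filled in and unknown keys rejected.

#' Default run configuration
#'
#' Fusion weights 0.4/0.3/0.3, soft-label weight 0.5, EMA coefficient
#' 0.999, SGD with learning rate 0.001, weight decay 0.0005 and momentum
#' 0.9, quantile 0.7, soft fill top-10% with 1% trigger.
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    out_dir = "runs/dualseg",
    data = list(
      manifest = NULL,         # path to a dataset manifest CSV
      labeled_ratio = 0.25,
      split_seed = 1L,
      input_size = 64L
    ),
    model = list(
      backbone_main = "tinycnn-deep",
      backbone_aux = "tinycnn-shallow",
      n_classes = 4L,
      d_k = NULL,              # NULL = max(8, c_main / 4)
      dual_teacher = TRUE,     # heterogeneous auxiliary teacher (DT)
      fusion = TRUE,           # attention-guided fusion branch (ADF)
      supervised_only = FALSE
    ),
    cpf = list(
      enabled = TRUE,          # dynamic thresholds + soft labels (CPF)
      alpha = 0.4, beta = 0.3, gamma = 0.3,
      eta = 0.9, tau_init = 0.5, tau_min = 0.5,
      quantile = 0.7, window = 10L,
      mu = 1, k_frac = 0.10, min_density = 0.01
    ),
    loss = list(
      lambda_soft = 0.5,
      aux_supervised = TRUE,
      kl_direction = "target_first"
    ),
    optim = list(
      lr = 0.001, weight_decay = 0.0005, momentum = 0.9,
      ema = 0.999, epochs = 20L, batch_size = 8L,
      warmup = 0L,             # supervised-only epochs before pseudo-labeling
      lr_schedule = "constant",# "constant" or "poly" (power 0.9)
      eval_every = 1L,         # test-set evaluation cadence in epochs
      augment = TRUE
    )
  )
}

#' Desk-scale training profile
#'
#' The default configuration scaled to sizes that train in minutes on one
#' CPU: 64x64 inputs, tiny backbones, batch 8, and a learning rate suited
#' to the small networks (0.05; the full-scale profile keeps the classical
#' 0.001 used with large pretrained backbones).
#'
#' @param ... named overrides merged into the profile, e.g.
#'   `desk_config(optim = list(epochs = 5))`.
#' @return nested configuration list.
#' @export
desk_config <- function(...) {
  cfg <- default_config()
  cfg$optim$lr <- 0.02
  cfg$optim$epochs <- 16L
  cfg$optim$warmup <- 5L
  # EMA horizon 1/(1-rho) scaled to the desk step budget (hundreds of
  # steps rather than the tens of thousands of a full-scale schedule)
  cfg$optim$ema <- 0.97
  merge_config(cfg, list(...), path = "")
}

# recursive merge with unknown-key rejection
merge_config <- function(base, override, path = "") {
  for (nm in names(override)) {
    if (!nm %in% names(base))
      stop("unknown configuration key: ", sub("^\\.", "", paste0(path, ".", nm)))
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]])) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]],
                                 paste0(path, ".", nm))
    else base[nm] <- override[nm]   # [ ] keeps explicit NULLs
  }
  base
}

#' Validate a run configuration
#'
#' Checks every field against the module invariants: fusion weights on the
#' simplex, EMA/eta/momentum coefficients in `[0, 1]`, positive learning
#' rate, thresholds in `[0, 1]`, `k_frac` in `(0, 1]`.
#'
#' @param cfg nested configuration list.
#' @return `cfg`, invisibly, or an error.
#' @export
validate_config <- function(cfg) {
  with(cfg$cpf, {
    if (abs(alpha + beta + gamma - 1) > 1e-9)
      stop("cpf: fusion weights alpha+beta+gamma must sum to 1")
    if (any(c(alpha, beta, gamma) < 0)) stop("cpf: fusion weights must be >= 0")
    if (eta < 0 || eta > 1) stop("cpf: eta must lie in [0, 1]")
    if (tau_min < 0 || tau_min > 1 || tau_init < 0 || tau_init > 1)
      stop("cpf: thresholds must lie in [0, 1]")
    if (quantile <= 0 || quantile >= 1) stop("cpf: quantile must lie in (0, 1)")
    if (k_frac <= 0 || k_frac > 1) stop("cpf: k_frac must lie in (0, 1]")
    if (min_density < 0 || min_density > 1) stop("cpf: min_density must lie in [0, 1]")
    if (mu < 0) stop("cpf: mu must be nonnegative")
  })
  with(cfg$optim, {
    if (lr <= 0) stop("optim: lr must be positive")
    if (ema < 0 || ema > 1) stop("optim: ema must lie in [0, 1]")
    if (momentum < 0 || momentum >= 1) stop("optim: momentum must lie in [0, 1)")
    if (batch_size < 1) stop("optim: batch_size must be >= 1")
  })
  if (!cfg$loss$kl_direction %in% c("target_first", "student_first"))
    stop("loss: kl_direction must be 'target_first' or 'student_first'")
  if (!is.null(cfg$model$backbone_main) &&
      !cfg$model$backbone_main %in% names(BACKBONES))
    stop("model: unknown backbone_main")
  if (cfg$model$n_classes < 2) stop("model: n_classes must be >= 2")
  invisible(cfg)
}

#' Load a run configuration from YAML
#'
#' Reads a (possibly partial) YAML file, fills unset fields with
#' [default_config()] values, rejects unknown keys, and validates the
#' result. An empty file yields the full default configuration.
#'
#' @param path YAML file.
#' @return validated configuration list.
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- merge_config(default_config(), user)
  validate_config(cfg)
  cfg
}

#' Save a run configuration to YAML
#'
#' @param cfg configuration list.
#' @param path destination file.
#' @export
save_config <- function(cfg, path) {
  atomic_write(path, function(tmp) yaml::write_yaml(cfg, tmp))
}
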