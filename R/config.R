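# Unified run configuration: one YAML document nesting model, training,
# protocol and synthesis settings plus a root seed that fans out to named
# per-stage generators. Every artifact written by the pipeline embeds the
# config hash and seed for provenance.

#' Default run configuration
#'
#' @return nested list of all configurable settings with their defaults.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    model = list(width_mult = 1, d_model = 512L, conv_kernel = 33L,
                 pool_kernel = 16L, pool_stride = 16L, pair_layers = 4L,
                 id_layers = 4L, n_heads = 8L, ff_dim = 2048L, dropout = 0.1),
    train = list(batch_size = 512L, steps_per_epoch = 256L, adam_beta1 = 0.9,
                 adam_beta2 = 0.98, adam_eps = 1e-9, label_smoothing = 0.1,
                 patience = 3L, max_epochs = 1000L, lr_multiplier = 1,
                 scope_size = 32L, train_count = 2580480L, val_count = 32768L),
    protocol = list(r = 32, t = 0, p = 32, n = 8L, v = 12L, h = NA_integer_),
    synth = list(n_databases = 2L, identities_per_db = c(24L, 16L),
                 rates = c(128, 256), duration_s = 60, drift_rate = 0,
                 easy_noise = TRUE)
  )
}

.check_keys <- function(cfg, ref, path = "") {
  bad <- setdiff(names(cfg), names(ref))
  if (length(bad) > 0)
    stop("unknown config key(s): ", paste0(path, bad, collapse = ", "))
  for (k in names(cfg)) {
    if (is.list(ref[[k]]) && !is.null(names(ref[[k]])))
      .check_keys(cfg[[k]], ref[[k]], paste0(path, k, "."))
  }
}

.merge_cfg <- function(ref, cfg) {
  for (k in names(cfg)) {
    ref[[k]] <- if (is.list(ref[[k]]) && !is.null(names(ref[[k]])))
      .merge_cfg(ref[[k]], cfg[[k]]) else cfg[[k]]
  }
  ref
}

.validate_run_config <- function(cfg) {
  if (cfg$train$batch_size < 1) stop("train.batch_size must be positive")
  if (cfg$train$steps_per_epoch < 1) stop("train.steps_per_epoch must be positive")
  if (cfg$model$dropout < 0 || cfg$model$dropout >= 1)
    stop("model.dropout must be in [0, 1)")
  if (cfg$model$width_mult <= 0) stop("model.width_mult must be positive")
  invisible(cfg)
}

#' Load and validate a run configuration
#'
#' Reads a YAML file, rejects unknown keys, fills defaults and validates.
#'
#' @param path YAML file path; `NULL` returns the defaults.
#' @return validated run config with a `hash` attribute.
#' @export
load_config <- function(path = NULL) {
  ref <- default_run_config()
  cfg <- if (is.null(path)) ref else {
    user <- yaml::read_yaml(path)
    .check_keys(user, ref)
    .merge_cfg(ref, user)
  }
  .validate_run_config(cfg)
  attr(cfg, "hash") <- config_hash(cfg)
  cfg
}

#' Hash of a run configuration
#' @param cfg a run config list.
#' @return character hash.
#' @export
config_hash <- function(cfg) {
  attr(cfg, "hash") <- NULL
  rlang::hash(cfg)
}

#' Dump a run configuration to YAML
#' @param cfg run config list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(cfg, path) {
  attr(cfg, "hash") <- NULL
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' End-to-end smoke run
#'
#' Exercises the whole pipeline in one process: synthesize a 2-database
#' registry, build train/validation datasets, train a desk-scale model, and
#' evaluate it with the voting protocol. All randomness derives from `seed`;
#' the returned report is bit-reproducible. Module invariants (segment
#' standardization, scope uniqueness, distribution normalization) are asserted
#' along the way.
#'
#' @param seed root seed.
#' @param train_count,val_count dataset sizes.
#' @param scope_size training scope size.
#' @param width_mult model width multiplier.
#' @param max_epochs training epoch cap.
#' @param steps_per_epoch,batch_size training step shape.
#' @param lr_multiplier learning-rate multiplier for the desk-scale width.
#' @param out optional path for the JSON report.
#' @return list with `report` (headline metrics), `history`, `config_hash`.
#' @export
end_to_end_smoke <- function(seed = 1L, train_count = 2000L, val_count = 128L,
                             scope_size = 8L, width_mult = 1 / 8,
                             max_epochs = 10L, steps_per_epoch = 32L,
                             batch_size = 32L, lr_multiplier = 12,
                             out = NULL) {
  seeds <- .spawn_seeds(seed, 5L)
  reg <- synth_registry(2L, c(24L, 16L), rates = c(128, 256), seed = seeds[1],
                        duration_s = 40, noise = noise_spec_easy())
  reg <- resample_registry(reg)
  train_ds <- build_dataset(reg, train_count, seed = seeds[2], group = "train",
                            scope_size = scope_size)
  val_ds <- build_dataset(reg, val_count, seed = seeds[3], group = "validation",
                          scope_size = scope_size)
  stopifnot(max(abs(rowMeans(train_ds$query))) < 1e-6)
  model <- model_init(model_config(width_mult = width_mult), seed = seeds[4])
  fit <- train_model(model, train_ds, val_ds,
                     train_config(batch_size = batch_size,
                                  steps_per_epoch = steps_per_epoch,
                                  max_epochs = max_epochs,
                                  lr_multiplier = lr_multiplier,
                                  seed = seeds[5]))
  ev_reg <- synth_registry(1L, scope_size, rates = 128, seed = seeds[1] %% 100000L + 1L,
                           duration_s = 60, noise = noise_spec_easy())
  rep1 <- run_protocol(fit$model, ev_reg,
                       protocol_config(r = 12, t = 0, p = 30, n = 4L, v = 3L,
                                       h = scope_size),
                       seed = seed)
  report <- list(seed = seed,
                 val_id_accuracy = utils::tail(fit$history$val_id_acc, 1),
                 best_val_loss = min(fit$history$val_loss),
                 epochs_run = fit$epochs_run,
                 eval_id_accuracy = rep1[[1]]$id_accuracy,
                 eval_indiv_auc = rep1[[1]]$individual_verification$auc,
                 config_hash = config_hash(list(width_mult = width_mult,
                                                scope_size = scope_size,
                                                seed = seed)))
  if (!is.null(out))
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA)
  list(report = report, history = fit$history, model = fit$model)
}
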