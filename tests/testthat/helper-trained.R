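# One desk-scale trained model shared by the end-to-end checks (training is
# the expensive step; the learning check and the time-separation check use the
# same fitted model).
.trained_cache <- new.env(parent = emptyenv())

desk_training_fixture <- function() {
  if (!is.null(.trained_cache$fit)) return(.trained_cache$fit)
  reg <- resample_registry(synth_registry(2L, c(24L, 16L), rates = c(128, 256),
                                          seed = 101, duration_s = 40,
                                          noise = noise_spec_easy()))
  train_ds <- build_dataset(reg, 2000L, seed = 5, group = "train", scope_size = 8L)
  val_ds <- build_dataset(reg, 64L, seed = 6, group = "validation", scope_size = 8L)
  model <- model_init(model_config(width_mult = 1 / 8, dropout = 0), seed = 2L)
  fit <- train_model(model, train_ds, val_ds,
                     train_config(batch_size = 16L, steps_per_epoch = 50L,
                                  max_epochs = 8L, lr_multiplier = 15,
                                  warmup_steps = 100L, clip_grad = 5,
                                  patience = 3L, seed = 9L))
  fit$train_ds <- train_ds
  fit$val_ds <- val_ds
  .trained_cache$fit <- fit
  fit
}
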