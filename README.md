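# ecgscope

Scope-flexible ECG biometric identification and verification built on a
sequence-pair self-attention model, with a synthetic multi-identity ECG
corpus generator, a blind-segmentation training-data builder, a full training
loop, segment voting, and an ROC/EER evaluation protocol that treats the time
separation between enrollment and classification as a first-class variable.

## The problem and the model

Enrollment registers a person's ECG; classification later asks, for a 3 s
query window `Gq`, whether it matches a claimed identity
(P(q = k), *individual verification*) and which of the `h` enrolled
identities it belongs to (a distribution Pq(k) with sum 1, *closed
identification*). Because a person's ECG changes over time, features computed
independently as `L_k = f(G_k)` and `L_q = f(G_q)` cannot capture the
enrollment-to-query relationship. Here every enrolled/query pair is encoded
*jointly*: each 384-sample standardized segment is expanded by a
conv(512 × 33)/ReLU/maxpool(16/16) front end into 22 tokens of width 512; the
pair forms a 46-token composite sequence
`[clsVE, clsID, enrolled + E_e, query + E_q]` processed by a 4-layer
transformer encoder, and the final hidden states at the two classification
tokens are the pair's verification and identification features
`L_kq = {L_kq(VE), L_kq(ID)}`. A verification head maps `L_kq(VE)` to
P(q = k); the `h` vectors `L_kq(ID)` pass through a second, 4-layer
permutation-equivariant encoder and a shared softmax head to give Pq(k). The
second encoder accepts any `h`, so identities can enroll or leave without
retraining.

Training data are generated by blind segmentation (fixed 384-sample windows
at arbitrary offsets, no R-peak detection) over a multi-database registry:
each example draws a 32-identity scope starting from one uniformly chosen
database, a uniform query identity, and sample-disjoint enrolled/query
windows for the true identity. Optimization is Adam (β1 = 0.9, β2 = 0.98,
ε = 1e-9) under the epoch-indexed rate
`lr(epoch) = 0.000012·e^(2 − 0.03·epoch) + 0.00008`, label smoothing
ε = 0.1 (0.95/0.05 binary targets, 0.903125/0.003125 for 32 classes), and
patience-3 early stopping on validation loss. Long enrollments are exploited
by majority voting over `v` evenly spaced enrollment windows, ties broken by
the largest mean probability.

Everything is implemented from first principles in R (BLAS matrix operations
with an Rcpp/Armadillo attention kernel), including backpropagation, which is
verified against finite differences in the test suite's development history.

## Worked example

```r
library(ecgscope)

# a 2-database synthetic registry: 24 + 16 identities at 128 and 256 Hz
reg <- resample_registry(synth_registry(2, c(24, 16), rates = c(128, 256),
                                        seed = 101, duration_s = 40,
                                        noise = noise_spec_easy()))

train_ds <- build_dataset(reg, 2000, seed = 5, group = "train", scope_size = 8)
val_ds   <- build_dataset(reg, 64,  seed = 6, group = "validation", scope_size = 8)

model <- model_init(model_config(width_mult = 1/8, dropout = 0), seed = 2)
fit <- train_model(model, train_ds, val_ds,
                   train_config(batch_size = 16, steps_per_epoch = 50,
                                max_epochs = 8, lr_multiplier = 15,
                                warmup_steps = 100, clip_grad = 5, seed = 9),
                   verbose = TRUE)
#> epoch 4: train 1.1728 | val 1.1110 | id acc 0.969 | lr 2.38e-03
#> epoch 5: train 0.8685 | val 1.0302 | id acc 0.984 | lr 2.34e-03
#> epoch 7: train 0.8013 | val 1.0510 | id acc 0.953 | lr 2.28e-03

# evaluate on unseen identities: enroll 8 people (12 s each, 3 votes),
# 4 queries per person at time separation 0
ev <- synth_registry(1, 10, 128, seed = 777, duration_s = 60,
                     noise = noise_spec_easy())
rep0 <- run_protocol(fit$model, ev,
                     protocol_config(r = 12, t = 0, p = 30, n = 4, v = 3, h = 8),
                     seed = 3)[[1]]
rep0$id_accuracy                        #> 0.96875
rep0$individual_verification$auc        #> 0.9912109
```

These numbers mean: 31 of the 32 queries were assigned to the right person,
and the verification scores separate genuine from impostor claims with an
area under the ROC of 0.991. With morphology
drift enabled in the generator, re-running the protocol at t = 2 h instead of
t = 0 roughly halves the identification accuracy — the time-separation
phenomenon the evaluation protocol is designed to expose.

A thin command-line surface over the same functions lives in
`inst/cli/ecgscope.R` (`synth`, `preprocess`, `build-dataset`, `train`,
`identify`, `evaluate`, `smoke`).

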