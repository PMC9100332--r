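# Shared fixtures: everything is generated in code at test time.

# small 2-database registry at mixed rates, clean signals
tiny_registry <- function(seed = 101, duration_s = 40, n = c(12L, 8L),
                          drift_rate = 0, noise = noise_spec_easy()) {
  resample_registry(synth_registry(2L, n, rates = c(128, 256), seed = seed,
                                   duration_s = duration_s, noise = noise,
                                   drift_rate = drift_rate))
}

# micro model: full architecture shape, tiny widths, deterministic layers
micro_model <- function(seed = 3L, dropout = 0) {
  model_init(model_config(d_model = 16L, n_heads = 2L, ff_dim = 24L,
                          pair_layers = 2L, id_layers = 2L,
                          ver_widths = c(16L, 8L), id_width = 12L,
                          dropout = dropout),
             seed = seed)
}

# standardized random segments (valid model input)
random_segments <- function(n, seed = 1) {
  set.seed(seed)
  m <- matrix(stats::rnorm(n * 384), n, 384)
  t(apply(m, 1, function(x) (x - mean(x)) / sqrt(mean((x - mean(x))^2))))
}

# pure sinusoid recording helper
sine_recording <- function(freq, fs, dur = 3, id = "sine") {
  tt <- (0:(round(dur * fs) - 1)) / fs
  ecg_recording(sin(2 * pi * freq * tt), fs, id)
}
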