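## Shared fixtures, built once per test run and cached. Everything is
## generated in code with fixed seeds; the RNN fixtures train real (small)
## networks through the package's own training path.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

## Pure model populations at the standard size.
fx_population <- function(kind, seed = 1L) {
  fixture(paste0("pop_", kind, "_", seed), function() {
    kinds <- switch(kind,
      mixed = c(gain = 100, pd_shift = 100, additive = 100),
      setNames(300L, kind))
    build_model_population(kinds, seed = seed)
  })
}

## Deterministic and noisy synthetic sessions with known ground truth.
fx_session <- function(noise = 0) {
  fixture(paste0("session_", noise), function() {
    gt <- synth_ground_truth(c(gain = 6, pd_shift = 6, additive = 6),
                             rate_scale = 2, seed = 3L)
    generate_noisy_session(gt, trials_per_cell = if (noise > 0) 20 else 8,
                           noise = noise, seed = 4L)
  })
}

## Trained interception networks (shared by the dynamics, geometry,
## classification and perturbation tests).
fx_rnn <- function(seed) {
  fixture(paste0("rnn_", seed), function()
    train_rnn(n_steps = 1200, seed = seed))
}

fx_rnn_activity <- function(seed) {
  fixture(paste0("rnn_act_", seed), function()
    rnn_condition_activity(fx_rnn(seed), trials_per_cell = 8, seed = seed))
}

fx_rnn_classification <- function(seed) {
  fixture(paste0("rnn_cls_", seed), function()
    classify_nodes(fx_rnn(seed), activity = fx_rnn_activity(seed),
                   seed = seed))
}

fx_validation_set <- function(n = 200) {
  fixture(paste0("valset_", n), function() rnn_validation_set(n))
}
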