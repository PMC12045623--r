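## Synthetic populations: representational model neurons (gain / PD-shift /
## additive sigmoidal velocity modulation of cosine direction tuning) and
## noisy recorded-style sessions with known ground truth.

sigmoid <- function(x) 1 / (1 + exp(-x))
cosd <- function(x) cospi(x / 180)
sind <- function(x) sinpi(x / 180)

#' Parameters of a representational model neuron
#'
#' Model neurons combine a Gaussian temporal profile (sd 30 bins, peak near
#' bin 100 = movement onset), cosine tuning for reach direction, and one of
#' three sigmoidal target-velocity modulations: multiplicative gain on the
#' cosine amplitude (`gain`), a rotation of the preferred direction of up to
#' 90 degrees (`pd_shift`), or a direction-independent offset (`additive`).
#'
#' @param kind one of `"gain"`, `"pd_shift"`, `"additive"`.
#' @param theta_pd preferred direction, degrees in \[0, 360).
#' @param g gain/offset sigmoid slope in \[0, 1\] (gain and additive kinds).
#' @param s PD-shift sigmoid slope in \[0, 1.5\] (pd_shift kind).
#' @param t_mu peak-time bin of the temporal profile.
#' @return Object of class `model_neuron_params`.
#' @export
model_neuron_params <- function(kind = c("gain", "pd_shift", "additive"),
                                theta_pd, g = NA_real_, s = NA_real_,
                                t_mu = 100) {
  kind <- match.arg(kind)
  if (kind %in% c("gain", "additive")) stopifnot(g >= 0, g <= 1)
  if (kind == "pd_shift") stopifnot(s >= 0, s <= 1.5)
  structure(list(kind = kind, theta_pd = theta_pd %% 360,
                 g = g, s = s, t_mu = t_mu),
            class = "model_neuron_params")
}

temporal_profile <- function(t, t_mu) exp(-(t - t_mu)^2 / (2 * 30^2))

#' Model-neuron firing rate
#'
#' Evaluates the three representational tuning equations on the abstract
#' velocity code `vel` in 1..5 (3 = static target). Rates are unitless and
#' bounded in \[0, 3\] by construction.
#'
#' @param params a [model_neuron_params()].
#' @param t time bin(s) in 1..200 (bin 100 is movement onset).
#' @param vel velocity code(s) in 1..5.
#' @param theta reach direction(s), degrees.
#' @return Numeric rate(s), recycled over the longest argument.
#' @export
model_neuron_rate <- function(params, t, vel, theta) {
  stopifnot(inherits(params, "model_neuron_params"))
  env <- temporal_profile(t, params$t_mu)
  tun <- switch(params$kind,
    gain = sigmoid(params$g * (vel - 3)) * cosd(theta - params$theta_pd) + 1,
    pd_shift = cosd(theta - params$theta_pd -
                      90 * sigmoid(params$s * (vel - 3))) + 1,
    additive = cosd(theta - params$theta_pd) +
      sigmoid(params$g * (vel - 3)) + 1)
  env * tun
}

#' @rdname model_neuron_rate
#' @export
gain_neuron_rate <- function(params, t, vel, theta) {
  stopifnot(params$kind == "gain"); model_neuron_rate(params, t, vel, theta)
}

#' @rdname model_neuron_rate
#' @export
pd_shift_neuron_rate <- function(params, t, vel, theta) {
  stopifnot(params$kind == "pd_shift"); model_neuron_rate(params, t, vel, theta)
}

#' @rdname model_neuron_rate
#' @export
additive_neuron_rate <- function(params, t, vel, theta) {
  stopifnot(params$kind == "additive"); model_neuron_rate(params, t, vel, theta)
}

#' Population activity container
#'
#' A neurons x trials x time-bins firing-rate array with its trial table and
#' bin metadata.
#'
#' @param rates numeric array, neurons x trials x bins; nonnegative.
#' @param trial_table data frame with one row per trial.
#' @param bin_width bin width in ms (or 1 for abstract model-time bins).
#' @param alignment name of the alignment event (e.g. `"MO"`).
#' @param bin_centers bin centers relative to the alignment event.
#' @param neuron_info optional per-neuron data frame (ground-truth labels).
#' @return Object of class `population_activity`.
#' @export
population_activity <- function(rates, trial_table, bin_width = 1,
                                alignment = "MO", bin_centers = NULL,
                                neuron_info = NULL) {
  stopifnot(length(dim(rates)) == 3, dim(rates)[2] == nrow(trial_table),
            all(rates >= 0))
  if (is.null(bin_centers)) bin_centers <- seq_len(dim(rates)[3])
  structure(list(rates = rates, trial_table = trial_table,
                 bin_width = bin_width, alignment = alignment,
                 bin_centers = bin_centers, neuron_info = neuron_info),
            class = "population_activity")
}

#' @export
print.population_activity <- function(x, ...) {
  d <- dim(x$rates)
  cat(sprintf("Population activity: %d neurons x %d trials x %d bins (%g ms bins, aligned to %s)\n",
              d[1], d[2], d[3], x$bin_width, x$alignment))
  if (!is.null(x$neuron_info) && "kind" %in% names(x$neuron_info)) {
    tb <- table(x$neuron_info$kind)
    cat("  neuron kinds:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.population_activity <- function(x) dim(x$rates)

#' Simulate a representational model population
#'
#' Builds the standard simulation: 5 abstract velocity codes (1..5) crossed
#' with 64 reach directions (theta = 360*k/64) for 320 trials of 200 time
#' bins. Preferred directions sit on a deterministic uniform grid within each
#' kind block; `g`, `s` and `t_mu` are drawn per neuron (g ~ U\[0,1\],
#' s ~ U\[0,1.5\], t_mu ~ N(100,10)) and recorded in `neuron_info`.
#'
#' @param kinds named integer vector of neuron counts per kind, e.g.
#'   `c(gain = 300)` or `c(gain = 100, pd_shift = 100, additive = 100)`.
#' @param seed integer RNG seed.
#' @return A [population_activity()] with ground-truth `neuron_info`.
#' @export
build_model_population <- function(kinds = c(gain = 300), seed = 1L) {
  stopifnot(length(kinds) >= 1, all(kinds >= 1),
            all(names(kinds) %in% c("gain", "pd_shift", "additive")))
  set.seed(seed)
  n_total <- sum(kinds)
  vel <- rep(1:5, each = 64)
  theta <- rep(360 * (1:64) / 64, times = 5)
  n_trials <- length(vel)
  n_bins <- 200L
  rates <- array(0, c(n_total, n_trials, n_bins))
  info <- data.frame(neuron = seq_len(n_total), kind = NA_character_,
                     theta_pd = NA_real_, g = NA_real_, s = NA_real_,
                     t_mu = NA_real_)
  idx <- 0L
  for (kind in names(kinds)) {
    nk <- kinds[[kind]]
    pd <- 360 * (seq_len(nk) - 1) / nk
    g <- runif(nk); s <- runif(nk, 0, 1.5); t_mu <- rnorm(nk, 100, 10)
    for (j in seq_len(nk)) {
      p <- model_neuron_params(kind, pd[j], g = if (kind == "pd_shift") NA else g[j],
                               s = if (kind == "pd_shift") s[j] else NA,
                               t_mu = t_mu[j])
      tun <- model_neuron_rate(p, t = 100, vel = vel, theta = theta) /
        temporal_profile(100, t_mu[j])
      rates[idx + j, , ] <- outer(tun, temporal_profile(seq_len(n_bins), t_mu[j]))
      info[idx + j, -1] <- list(kind, pd[j],
                                if (kind == "pd_shift") NA_real_ else g[j],
                                if (kind == "pd_shift") s[j] else NA_real_,
                                t_mu[j])
    }
    idx <- idx + nk
  }
  tt <- data.frame(trial = seq_len(n_trials), vel_code = vel,
                   target_velocity = (vel - 3) * 120,
                   reach_endpoint_angle = theta, sector = assign_sector(theta))
  class(tt) <- c("trial_table", "data.frame")
  population_activity(rates, tt, bin_width = 1, alignment = "MO (bin 100)",
                      neuron_info = info)
}

#' Ground truth for a synthetic recorded session
#'
#' Draws per-neuron tuning-model parameters (in spikes/s) for the three
#' modulation kinds, with baselines chosen so rates stay positive. The
#' sigmoid slope applies to the symmetric velocity code vel/120 in
#' \{-2,...,2\}.
#'
#' @param n_per_kind named counts per kind.
#' @param rate_scale multiplies all rate parameters (SNR knob: Poisson noise
#'   grows as the square root of the rate).
#' @param seed integer RNG seed.
#' @return Data frame with one row per neuron, class `modulation_spec`.
#' @export
synth_ground_truth <- function(n_per_kind = c(gain = 20, pd_shift = 20,
                                              additive = 20),
                               rate_scale = 1, seed = 1L) {
  set.seed(seed)
  kinds <- rep(names(n_per_kind), n_per_kind)
  n <- length(kinds)
  amp <- runif(n, 4, 8)        # cosine amplitude, spikes/s
  mod_amp <- runif(n, 4, 8)    # modulation amplitude, spikes/s
  slope <- runif(n, 0.8, 1.6)  # sigmoid slope per velocity-code unit
  base <- runif(n, 2, 4) + amp + mod_amp  # keeps rates positive
  out <- data.frame(neuron = seq_len(n), kind = kinds,
                    theta_pd = runif(n, 0, 360),
                    amp = amp * rate_scale, mod_amp = mod_amp * rate_scale,
                    slope = slope, base = base * rate_scale)
  class(out) <- c("modulation_spec", "data.frame")
  out
}

## Mean rate (spikes/s) of a session neuron, fitting-model equations with the
## symmetric velocity code.
session_mean_rate <- function(spec_row, theta, vel_deg) {
  vc <- vel_deg / 120
  sg <- sigmoid(spec_row$slope * vc)
  switch(spec_row$kind,
    gain = (spec_row$mod_amp * sg + spec_row$amp) *
      cosd(theta - spec_row$theta_pd) + spec_row$base,
    pd_shift = spec_row$amp * cosd(theta - spec_row$theta_pd - 90 * sg) +
      spec_row$base,
    additive = spec_row$amp * cosd(theta - spec_row$theta_pd) +
      spec_row$mod_amp * sg + spec_row$base)
}

#' Generate a noisy synthetic session
#'
#' Emulates a recorded session over the 5 x 8 condition grid: per-trial mean
#' rates come from the tuning-model equations of the ground-truth table, and
#' trial noise interpolates towards Poisson spike counts in the 200 ms
#' analysis window (rescaled to spikes/s). With `noise = 0` the session is
#' fully deterministic: rates equal the tuning means and endpoint angles sit
#' at the exact sector centers. With `noise > 0` endpoint angles are jittered
#' uniformly within their sector.
#'
#' @param ground_truth a [synth_ground_truth()] data frame.
#' @param trials_per_cell trials per (velocity, sector) cell; must be >= 1.
#' @param noise noise level: 0 = deterministic, 1 = full Poisson noise.
#' @param n_bins time bins spanning the MO +/- 100 ms window.
#' @param seed integer RNG seed.
#' @return A [population_activity()] aligned to movement onset, with the
#'   ground-truth labels in `neuron_info`.
#' @export
generate_noisy_session <- function(ground_truth, trials_per_cell = 15,
                                   noise = 1, n_bins = 20L, seed = 1L) {
  stopifnot(inherits(ground_truth, "modulation_spec"))
  if (trials_per_cell < 1) stop("trials_per_cell must be >= 1")
  tt <- build_trial_table(trials_per_cell, jitter = noise > 0, seed = seed)
  n <- nrow(ground_truth); k <- nrow(tt)
  mu <- matrix(0, n, k)
  for (j in seq_len(n))
    mu[j, ] <- session_mean_rate(ground_truth[j, ], tt$reach_endpoint_angle,
                                 tt$target_velocity)
  if (noise > 0) {
    counts <- matrix(rpois(n * k, pmax(mu, 0) * 0.2), n, k)
    mu <- pmax(mu + noise * (counts / 0.2 - mu), 0)
  }
  rates <- array(mu, c(n, k, n_bins))
  bw <- 200 / n_bins
  centers <- seq(-100 + bw / 2, 100 - bw / 2, by = bw)
  population_activity(rates, tt, bin_width = bw, alignment = "MO",
                      bin_centers = centers,
                      neuron_info = as.data.frame(ground_truth))
}

#' Average rates in a window around the alignment event
#'
#' @param activity a [population_activity()].
#' @param window `c(start, end)` in the units of `bin_centers` (ms for
#'   session data, bins for model populations), inclusive.
#' @return A trials x neurons matrix of window-averaged rates.
#' @export
window_rates <- function(activity, window) {
  stopifnot(inherits(activity, "population_activity"), length(window) == 2)
  sel <- activity$bin_centers >= window[1] & activity$bin_centers <= window[2]
  if (!any(sel)) stop("window contains no bins")
  t(apply(activity$rates[, , sel, drop = FALSE], c(1, 2), mean))
}
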