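## Reproducible end-to-end pipelines tying the synthetic generator, the
## single-neuron statistics, the geometry pipeline and the network suite
## together. Every stochastic stage takes an explicit seed and the
## configuration is returned (and optionally serialized) with the outputs.

write_config <- function(config, output_dir) {
  if (is.null(output_dir)) return(invisible(NULL))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  flat <- vapply(config, function(v) paste(v, collapse = " "), "")
  writeLines(paste(names(flat), flat, sep = " = "),
             file.path(output_dir, "config.txt"))
}

#' Simulated-population geometry pipeline
#'
#' Builds the three pure 300-neuron representational groups and the mixed
#' 100 x 3 group, runs the neural-state geometry on each, and tabulates the
#' PC explained variances (averaged over seeds) and the tilt / rotation /
#' shift metrics.
#'
#' @param seeds integer seeds; the explained-variance table averages over
#'   all of them, the geometry metrics use the first.
#' @param output_dir optional directory for CSV outputs.
#' @return List with `explained_variance` (group x PC, percent),
#'   `geometry` (per-group [geometry_summary()] from the first seed), and
#'   `config`.
#' @export
run_simulated_populations <- function(seeds = 1:20, output_dir = NULL) {
  groups <- list(gain = c(gain = 300), pd_shift = c(pd_shift = 300),
                 additive = c(additive = 300),
                 mixed = c(gain = 100, pd_shift = 100, additive = 100))
  mo_window <- c(50, 150)
  ev <- sapply(names(groups), function(g) {
    rowMeans(vapply(seeds, function(s) {
      ns <- neural_states(build_model_population(groups[[g]], seed = s),
                          mo_window, n_pcs = 3)
      ns$explained_variance[1:3]
    }, numeric(3)))
  })
  ev_table <- data.frame(group = names(groups), PC1 = ev[1, ], PC2 = ev[2, ],
                         PC3 = ev[3, ], row.names = NULL)
  geometry <- lapply(names(groups), function(g)
    geometry_summary(neural_states(build_model_population(groups[[g]],
                                                          seed = seeds[1]),
                                   mo_window, n_pcs = 3)))
  names(geometry) <- names(groups)
  config <- list(pipeline = "simulated_populations", seeds = seeds)
  if (!is.null(output_dir)) {
    write_config(config, output_dir)
    write.csv(ev_table, file.path(output_dir, "explained_variance.csv"),
              row.names = FALSE)
    for (g in names(geometry))
      write.csv(geometry[[g]]$conditions,
                file.path(output_dir, paste0("geometry_", g, ".csv")),
                row.names = FALSE)
  }
  list(explained_variance = ev_table, geometry = geometry, config = config)
}

#' Network ensemble pipeline
#'
#' Trains `n_models` interception networks with different weight seeds, then
#' validates endpoints, classifies node modulation, measures node geometry
#' and connectivity for each, and summarizes the ensemble. A model whose
#' training diverges is recorded and excluded.
#'
#' @param n_models ensemble size.
#' @param n_steps optimizer steps per model.
#' @param variant network variant (see [train_rnn()]).
#' @param trials_per_cell trials per condition cell in the analyses.
#' @param n_validation validation-set size.
#' @param seed base seed; model m uses seed + m.
#' @param output_dir optional directory for CSV outputs.
#' @return List with per-model `models` results and an `ensemble` summary
#'   (endpoint distance, classification fractions, tilt fit), plus `config`
#'   and `failed` seeds.
#' @export
run_rnn_suite <- function(n_models = 3, n_steps = 1500, variant = "main",
                          trials_per_cell = 5, n_validation = 500,
                          seed = 1L, output_dir = NULL) {
  stopifnot(n_models >= 1)
  params <- rnn_params()
  valset <- rnn_validation_set(n_validation, params)
  models <- list(); failed <- integer()
  for (m in seq_len(n_models)) {
    sm <- seed + m
    res <- tryCatch({
      net <- train_rnn(params, n_steps = n_steps, variant = variant,
                       seed = sm)
      act <- rnn_condition_activity(net, trials_per_cell, seed = sm)
      cls <- classify_nodes(net, activity = act, seed = sm)
      lab <- rep(NA_character_, params$n_units)
      for (i in seq_along(cls$active)) {
        l <- cls$labels[[i]]
        on <- c("pd_shift", "gain", "addition")[
          unlist(l[c("pd_shift", "gain", "addition")])]
        if (length(on) == 1) lab[cls$active[i]] <- on
      }
      list(seed = sm, model = net,
           validation = validate_rnn(net, valset),
           classification = cls,
           geometry = node_geometry(net, activity = act, seed = sm),
           connectivity = connectivity_summary(net, lab))
    }, error = function(e) {
      message("model seed ", sm, " failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) failed <- c(failed, sm) else models[[length(models) + 1]] <- res
  }
  if (!length(models)) stop("all models failed")
  frac <- t(vapply(models, function(r) r$classification$fractions, numeric(4)))
  dist <- vapply(models, function(r) r$validation$mean, 1)
  slopes <- vapply(models, function(r) r$geometry$tilt_fit$slope, 1)
  ensemble <- list(
    endpoint_distance = c(mean = mean(dist), sd = sd(dist)),
    fractions_mean = colMeans(frac), fractions_sd = apply(frac, 2, sd),
    tilt_slope = c(mean = mean(slopes), sd = sd(slopes)))
  config <- list(pipeline = "rnn_suite", n_models = n_models,
                 n_steps = n_steps, variant = variant, seed = seed)
  if (!is.null(output_dir)) {
    write_config(config, output_dir)
    write.csv(data.frame(seed = vapply(models, `[[`, 1, "seed"),
                         endpoint = dist, tilt_slope = slopes, frac),
              file.path(output_dir, "rnn_models.csv"), row.names = FALSE)
  }
  list(models = models, ensemble = ensemble, config = config,
       failed = failed)
}

#' Classification-recovery validation harness
#'
#' Generates noisy synthetic sessions with known per-neuron ground truth
#' across a noise grid, classifies every neuron, and reports the confusion
#' between generated and recovered modulation kinds with per-kind
#' sensitivity and specificity.
#'
#' @param noise_levels noise grid (0 = deterministic session).
#' @param n_per_kind neurons per modulation kind.
#' @param trials_per_cell trials per condition cell.
#' @param rate_scale SNR knob of the ground truth.
#' @param seed integer RNG seed.
#' @param output_dir optional directory for CSV outputs.
#' @return List with per-noise-level `confusion` (kind x flag counts),
#'   `metrics` (sensitivity/specificity per kind), `accuracy` (exact flag
#'   recovery), and `config`.
#' @export
run_synthetic_session_recovery <- function(noise_levels = c(0, 0.5, 1),
                                           n_per_kind = c(gain = 10,
                                                          pd_shift = 10,
                                                          additive = 10),
                                           trials_per_cell = 20,
                                           rate_scale = 2, seed = 1L,
                                           output_dir = NULL) {
  gt <- synth_ground_truth(n_per_kind, rate_scale = rate_scale, seed = seed)
  kinds <- c("gain", "pd_shift", "additive")
  flag_of <- c(gain = "gain", pd_shift = "pd_shift", additive = "addition")
  levels_out <- lapply(noise_levels, function(nz) {
    sess <- generate_noisy_session(gt, trials_per_cell, noise = nz,
                                   seed = seed + 1L)
    labs <- lapply(seq_len(nrow(gt)), function(j)
      classify_modulation(sess, j, seed = seed + 2L))
    conf <- sapply(c("gain", "pd_shift", "addition"), function(f)
      tapply(vapply(labs, function(l) isTRUE(l[[f]]), TRUE), gt$kind, sum))
    metrics <- do.call(rbind, lapply(kinds, function(k) {
      own <- gt$kind == k
      flg <- vapply(labs, function(l) isTRUE(l[[flag_of[k]]]), TRUE)
      data.frame(kind = k,
                 sensitivity = mean(flg[own]),
                 specificity = mean(!flg[!own]))
    }))
    exact <- vapply(seq_len(nrow(gt)), function(j) {
      l <- labs[[j]]
      on <- c("gain", "pd_shift", "addition")[
        unlist(l[c("gain", "pd_shift", "addition")])]
      identical(on, unname(flag_of[gt$kind[j]]))
    }, TRUE)
    list(noise = nz, confusion = conf, metrics = metrics,
         accuracy = mean(exact))
  })
  names(levels_out) <- paste0("noise_", noise_levels)
  config <- list(pipeline = "session_recovery", noise = noise_levels,
                 trials_per_cell = trials_per_cell,
                 rate_scale = rate_scale, seed = seed)
  if (!is.null(output_dir)) {
    write_config(config, output_dir)
    acc <- data.frame(noise = noise_levels,
                      accuracy = vapply(levels_out, `[[`, 1, "accuracy"))
    write.csv(acc, file.path(output_dir, "recovery_accuracy.csv"),
              row.names = FALSE)
  }
  list(levels = levels_out, config = config)
}
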