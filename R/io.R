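## Plain-text serialization: population recordings as a rates CSV plus the
## trial table and bin metadata, and network checkpoints as weight CSVs.

#' Write / read a population recording as CSV
#'
#' Serializes a [population_activity()] into a directory of plain-text
#' files: `rates.csv` (one row per neuron x trial, bins as columns),
#' `trials.csv`, `meta.csv`, and `neurons.csv` when ground-truth labels are
#' present.
#'
#' @param activity a [population_activity()].
#' @param dir directory (created if needed).
#' @return `read_population_csv` returns the [population_activity()].
#' @export
write_population_csv <- function(activity, dir) {
  stopifnot(inherits(activity, "population_activity"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(activity$rates)
  flat <- matrix(aperm(activity$rates, c(3, 2, 1)), nrow = d[1] * d[2],
                 byrow = TRUE)
  out <- data.frame(neuron = rep(seq_len(d[1]), each = d[2]),
                    trial = rep(seq_len(d[2]), times = d[1]))
  out <- cbind(out, as.data.frame(flat))
  names(out)[-(1:2)] <- paste0("bin", seq_len(d[3]))
  write.csv(out, file.path(dir, "rates.csv"), row.names = FALSE)
  write.csv(as.data.frame(activity$trial_table),
            file.path(dir, "trials.csv"), row.names = FALSE)
  write.csv(data.frame(bin_width = activity$bin_width,
                       alignment = activity$alignment,
                       bin_center = activity$bin_centers),
            file.path(dir, "meta.csv"), row.names = FALSE)
  if (!is.null(activity$neuron_info))
    write.csv(activity$neuron_info, file.path(dir, "neurons.csv"),
              row.names = FALSE)
  invisible(dir)
}

#' @rdname write_population_csv
#' @export
read_population_csv <- function(dir) {
  rt <- read.csv(file.path(dir, "rates.csv"))
  tt <- read.csv(file.path(dir, "trials.csv"))
  meta <- read.csv(file.path(dir, "meta.csv"))
  n <- max(rt$neuron); k <- max(rt$trial)
  bins <- grep("^bin", names(rt))
  rates <- array(0, c(n, k, length(bins)))
  rates[cbind(rep(rt$neuron, length(bins)),
              rep(rt$trial, length(bins)),
              rep(seq_along(bins), each = nrow(rt)))] <-
    as.numeric(as.matrix(rt[, bins]))
  ninfo <- if (file.exists(file.path(dir, "neurons.csv")))
    read.csv(file.path(dir, "neurons.csv")) else NULL
  class(tt) <- c("trial_table", "data.frame")
  population_activity(rates, tt, bin_width = meta$bin_width[1],
                      alignment = meta$alignment[1],
                      bin_centers = meta$bin_center, neuron_info = ninfo)
}

#' Write / read a trained network checkpoint as CSV
#'
#' @param model a [train_rnn()] model.
#' @param dir directory (created if needed).
#' @return `read_rnn_csv` returns the `trained_rnn`.
#' @export
write_rnn_csv <- function(model, dir) {
  stopifnot(inherits(model, "trained_rnn"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (w in c("J", "B", "W"))
    write.csv(model[[w]], file.path(dir, paste0(w, ".csv")),
              row.names = FALSE)
  p <- model$params
  write.csv(data.frame(field = c(names(p), "variant", "seed"),
                       value = c(vapply(p, as.character, ""),
                                 model$variant, model$seed)),
            file.path(dir, "params.csv"), row.names = FALSE)
  write.csv(data.frame(step = seq_along(model$loss), loss = model$loss,
                       mse = model$mse),
            file.path(dir, "training_log.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_rnn_csv
#' @export
read_rnn_csv <- function(dir) {
  rd <- function(f) unname(as.matrix(read.csv(file.path(dir, f))))
  pv <- read.csv(file.path(dir, "params.csv"), colClasses = "character")
  val <- setNames(pv$value, pv$field)
  params <- rnn_params(
    n_units = as.integer(val[["n_units"]]), tau = as.numeric(val[["tau"]]),
    g = as.numeric(val[["g"]]), alpha = as.numeric(val[["alpha"]]),
    lr = as.numeric(val[["lr"]]), dt = as.numeric(val[["dt"]]),
    sparsity = as.numeric(val[["sparsity"]]),
    j_init_scale = val[["j_init_scale"]],
    b_init_sd = if ("b_init_sd" %in% names(val))
      as.numeric(val[["b_init_sd"]]) else 1 / sqrt(5))
  log <- read.csv(file.path(dir, "training_log.csv"))
  structure(list(J = rd("J.csv"), B = rd("B.csv"), W = rd("W.csv"),
                 loss = log$loss, mse = log$mse, params = params,
                 variant = val[["variant"]],
                 seed = as.integer(val[["seed"]]),
                 input_mask = variant_input_mask(val[["variant"]])),
            class = "trained_rnn")
}
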