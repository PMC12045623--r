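## Population decoding with linear multiclass SVMs: sliding-window temporal
## decoding of reach direction (8-way) and target velocity (5-way), and
## cross-condition transfer decoding.

decode_labels <- function(trial_table, label_kind) {
  switch(label_kind,
    direction = factor(trial_table$sector, levels = 1:8),
    velocity = factor(trial_table$target_velocity),
    stop("label_kind must be 'direction' or 'velocity'"))
}

svm_accuracy <- function(X_train, y_train, X_test, y_test) {
  fit <- e1071::svm(x = X_train, y = droplevels(y_train), kernel = "linear",
                    scale = FALSE)
  mean(as.character(predict(fit, X_test)) == as.character(y_test))
}

#' Sliding-window decoding of trial labels
#'
#' Decodes reach direction (chance 1/8) or target velocity (chance 1/5) from
#' soft-normalized population activity in windows slid along the trial, with
#' a linear multiclass support vector machine under k-fold cross-validation.
#' The cross-validation is repeated with re-randomized folds to give the
#' mean and sd of accuracy per window.
#'
#' @param activity a [population_activity()].
#' @param label_kind `"direction"` or `"velocity"`.
#' @param window window length, ms.
#' @param step window step, ms.
#' @param folds cross-validation folds; every class must have at least this
#'   many trials.
#' @param reps repetitions with re-randomized folds.
#' @param n_pcs if not `NULL`, decode from the first `n_pcs` PCs of the
#'   window activity instead of the full population (used for network nodes).
#' @param seed integer RNG seed.
#' @return Object of class `decoding_result`: data frame `windows` (center,
#'   accuracy, sd), plus `chance` and `label_kind`.
#' @export
sliding_window_decode <- function(activity, label_kind = "direction",
                                  window = 100, step = 50, folds = 10,
                                  reps = 10, n_pcs = NULL, seed = 1L) {
  y <- decode_labels(activity$trial_table, label_kind)
  counts <- table(y)
  if (any(counts < folds))
    stop("class(es) with fewer trials than folds: ",
         paste(names(counts)[counts < folds], collapse = ", "))
  act <- soft_normalize(activity)
  bc <- act$bin_centers
  centers <- seq(min(bc) + window / 2 - act$bin_width / 2,
                 max(bc) - window / 2 + act$bin_width / 2, by = step)
  set.seed(seed)
  res <- lapply(centers, function(ct) {
    X <- window_rates(act, c(ct - window / 2, ct + window / 2))
    if (!is.null(n_pcs)) {
      p <- prcomp(X, center = TRUE, scale. = FALSE)
      X <- p$x[, seq_len(min(n_pcs, ncol(p$x))), drop = FALSE]
    }
    acc <- replicate(reps, {
      fold <- sample(rep_len(seq_len(folds), nrow(X)))
      mean(vapply(seq_len(folds), function(f)
        svm_accuracy(X[fold != f, , drop = FALSE], y[fold != f],
                     X[fold == f, , drop = FALSE], y[fold == f]), 1))
    })
    c(center = ct, accuracy = mean(acc), sd = sd(acc))
  })
  out <- as.data.frame(do.call(rbind, res))
  structure(list(windows = out,
                 chance = 1 / nlevels(droplevels(y)),
                 label_kind = label_kind),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("Sliding-window %s decoding (chance %.3f):\n",
              x$label_kind, x$chance))
  print(transform(x$windows, accuracy = round(accuracy, 3),
                  sd = round(sd, 3)), row.names = FALSE)
  invisible(x)
}

#' Cross-condition transfer decoding
#'
#' Trains a decoder on trials from one condition set and tests it on trials
#' from another, in the peri-movement window, repeating the random
#' train/test draw to obtain an accuracy distribution. For the direction
#' decoder the condition sets are target velocities (e.g. CCW vs CW:
#' train `c(120, 240)`, test `c(-120, -240)`); for the velocity decoder they
#' are reach-direction sectors.
#'
#' @param activity a [population_activity()].
#' @param label_kind `"direction"` or `"velocity"`.
#' @param train_conditions,test_conditions velocity values (direction
#'   decoding) or sector labels (velocity decoding) defining the two sets.
#' @param n_train,n_test trials sampled without replacement per repetition.
#' @param reps repetitions.
#' @param window analysis window around movement onset, ms.
#' @param seed integer RNG seed.
#' @return Object of class `transfer_result` with the accuracy distribution.
#' @export
transfer_decode <- function(activity, label_kind = "direction",
                            train_conditions, test_conditions,
                            n_train = 100, n_test = 100, reps = 1000,
                            window = c(-100, 100), seed = 1L) {
  tt <- activity$trial_table
  cond_var <- if (label_kind == "direction") tt$target_velocity else tt$sector
  y <- decode_labels(tt, label_kind)
  pool_train <- which(cond_var %in% train_conditions)
  pool_test <- which(cond_var %in% test_conditions)
  same <- setequal(train_conditions, test_conditions)
  need <- if (same) n_train + n_test else max(n_train, 0)
  if (length(pool_train) < (if (same) n_train + n_test else n_train))
    stop(sprintf("insufficient training trials: %d available, %d needed",
                 length(pool_train), if (same) n_train + n_test else n_train))
  if (!same && length(pool_test) < n_test)
    stop(sprintf("insufficient test trials: %d available, %d needed",
                 length(pool_test), n_test))
  X <- soft_normalize(window_rates(activity, window))
  set.seed(seed)
  acc <- replicate(reps, {
    if (same) {
      take <- sample(pool_train, n_train + n_test)
      tr <- take[seq_len(n_train)]; te <- take[-seq_len(n_train)]
    } else {
      tr <- sample(pool_train, n_train); te <- sample(pool_test, n_test)
    }
    svm_accuracy(X[tr, , drop = FALSE], y[tr],
                 X[te, , drop = FALSE], y[te])
  })
  structure(list(accuracy = acc,
                 train = train_conditions, test = test_conditions,
                 label_kind = label_kind, reps = reps,
                 chance = 1 / nlevels(droplevels(y))),
            class = "transfer_result")
}

#' @export
print.transfer_result <- function(x, ...) {
  cat(sprintf("Transfer decoding (%s): train {%s} -> test {%s}\n",
              x$label_kind, paste(x$train, collapse = ","),
              paste(x$test, collapse = ",")))
  cat(sprintf("  accuracy %.3f +/- %.3f over %d reps (chance %.3f)\n",
              mean(x$accuracy), sd(x$accuracy), x$reps, x$chance))
  invisible(x)
}

#' Compare two transfer-decoding accuracy distributions
#'
#' Paired one-tailed t-test between repetition-matched accuracy
#' distributions.
#'
#' @param a,b `transfer_result` objects with equal repetition counts.
#' @param alternative passed to [t.test()] (`"less"`: a < b).
#' @return The `htest` object.
#' @export
compare_transfer <- function(a, b, alternative = "less") {
  stopifnot(inherits(a, "transfer_result"), inherits(b, "transfer_result"),
            length(a$accuracy) == length(b$accuracy))
  t.test(a$accuracy, b$accuracy, paired = TRUE, alternative = alternative)
}
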