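## Single-neuron analysis: PSTHs, directional tuning indices, statistical
## classification of target-motion modulation, and nonlinear tuning-model
## fits compared by adjusted R-squared.

#' Peri-stimulus time histogram for one condition cell
#'
#' Condition-averaged firing rate of one neuron in one (velocity, sector)
#' cell, smoothed with a Gaussian kernel (sd 20 ms), with the standard error
#' estimated from 10 bootstrap resamples of trials.
#'
#' @param activity a [population_activity()].
#' @param neuron neuron index.
#' @param target_velocity velocity condition (deg/s) selecting trials.
#' @param sector sector 1..8 selecting trials; `NULL` pools all sectors.
#' @param kernel_sd smoothing kernel sd in ms; 0 disables smoothing.
#' @param n_boot bootstrap resamples for the standard error.
#' @param seed RNG seed for the bootstrap.
#' @return Data frame with `time`, `rate`, `se`.
#' @export
psth <- function(activity, neuron, target_velocity, sector = NULL,
                 kernel_sd = 20, n_boot = 10, seed = 1L) {
  tt <- activity$trial_table
  sel <- tt$target_velocity == target_velocity
  if (!is.null(sector)) sel <- sel & tt$sector == sector
  if (!any(sel)) stop("no trials in the requested condition cell")
  rr <- activity$rates[neuron, sel, , drop = FALSE]
  dim(rr) <- dim(rr)[2:3]                       # trials x bins
  smooth <- function(v) {
    if (kernel_sd <= 0) return(v)
    tms <- activity$bin_centers
    W <- exp(-outer(tms, tms, "-")^2 / (2 * kernel_sd^2))
    as.numeric(W %*% v / rowSums(W))
  }
  m <- smooth(colMeans(rr))
  set.seed(seed)
  bs <- replicate(n_boot, {
    idx <- sample(nrow(rr), replace = TRUE)
    smooth(colMeans(rr[idx, , drop = FALSE]))
  })
  data.frame(time = activity$bin_centers, rate = m,
             se = apply(bs, 1, sd))
}

#' Directional tuning indices
#'
#' Per-condition summary of a neuron's direction tuning in the peri-movement
#' window: the preferred direction (angle of the vector sum of sector-mean
#' rates at the 8 sector centers), the tuning depth (max - min of sector
#' means) and the offset (grand mean rate).
#'
#' @param rates per-trial rates (window-averaged) of one neuron.
#' @param sector sector labels 1..8, same length; all 8 must be populated.
#' @return List with `pd` (degrees; `NA` with `pd_defined = FALSE` when the
#'   resultant vanishes), `depth`, `offset`, `sector_means`.
#' @export
tuning_indices <- function(rates, sector) {
  stopifnot(length(rates) == length(sector))
  missing <- setdiff(1:8, unique(sector))
  if (length(missing))
    stop("empty reach-direction sector(s): ", paste(missing, collapse = ", "))
  m <- tapply(rates, factor(sector, levels = 1:8), mean)
  ctr <- sector_centers()
  ## weighted vector sum of the sector means
  C <- sum(m * cosd(ctr)); S <- sum(m * sind(ctr))
  pd_defined <- sqrt(C^2 + S^2) > 1e-9 * max(sum(abs(m)), 1)
  pd <- if (pd_defined) (atan2(S, C) * 180 / pi) %% 360 else NA_real_
  list(pd = pd, pd_defined = pd_defined,
       depth = max(m) - min(m), offset = mean(rates),
       sector_means = as.numeric(m))
}

## Signed-rank p-value robust to all-zero differences.
safe_signed_rank <- function(x, y) {
  d <- x - y
  if (all(abs(d) < 1e-10)) return(1)
  tryCatch(suppressWarnings(wilcox.test(x, y, paired = TRUE)$p.value),
           error = function(e) 1)
}

#' Classify target-motion modulation of one neuron
#'
#' Applies the statistical criteria for mixed sensorimotor selectivity to one
#' neuron's peri-movement rates across the five target-motion conditions.
#' A unit is flagged `pd_shift` when a Watson-Williams test rejects equality
#' of preferred directions between any moving condition and the static one.
#' The PD samples entering the test are independent estimates from disjoint
#' stratified splits of each condition's trials (each split holds one PD
#' computed from its own sector means), so the test's power is set by the
#' data, not by a resampling count. A unit is flagged `gain` when a
#' two-tailed Wilcoxon signed-rank test on the 8 paired per-sector tuning
#' depths (|sector mean - condition mean|) rejects for any moving condition;
#' `addition` likewise for the per-sector offsets (sector mean rates).
#' Flags may co-occur (mixtures). `none` is `TRUE` only when no flag is set
#' and the unit is not direction-tuned (Kruskal-Wallis across sectors).
#'
#' @param activity a [population_activity()].
#' @param neuron neuron index.
#' @param window analysis window around movement onset, ms.
#' @param alpha significance level per test.
#' @param n_splits disjoint trial splits per condition for the PD samples.
#' @param seed RNG seed for the random split assignment.
#' @return Object of class `modulation_label`: flags plus per-test p-values.
#' @export
classify_modulation <- function(activity, neuron, window = c(-100, 100),
                                alpha = 0.05, n_splits = 5, seed = 1L) {
  classify_modulation_rates(window_rates(activity, window)[, neuron],
                            activity$trial_table, alpha = alpha,
                            n_splits = n_splits, seed = seed)
}

## Core of classify_modulation on precomputed window-averaged rates; shared
## with classify_nodes so the window average is taken once per population.
classify_modulation_rates <- function(rates, tt, alpha = 0.05, n_splits = 5,
                                      seed = 1L) {
  vels <- sort(unique(tt$target_velocity))
  if (!(0 %in% vels) || length(vels) < 2)
    stop("need the static condition plus at least one moving condition")
  cond <- lapply(vels, function(v) which(tt$target_velocity == v))
  names(cond) <- as.character(vels)

  set.seed(seed)
  split_pds <- function(idx) {
    sec <- tt$sector[idx]
    bysec <- split(idx, factor(sec, levels = 1:8))
    if (any(vapply(bysec, length, 1L) == 0))
      stop("empty reach-direction sector in a condition")
    m <- min(n_splits, min(vapply(bysec, length, 1L)))
    ## assign each sector's trials to m disjoint splits
    grp <- lapply(bysec, function(ii)
      split(sample(ii), rep_len(seq_len(m), length(ii))))
    vapply(seq_len(m), function(s) {
      take <- unlist(lapply(grp, `[[`, s))
      sm <- tapply(rates[take], factor(tt$sector[take], levels = 1:8), mean)
      (atan2(sum(sm * sind(sector_centers())),
             sum(sm * cosd(sector_centers()))) * 180 / pi) %% 360
    }, 1)
  }
  sec_means <- lapply(cond, function(idx)
    tapply(rates[idx], factor(tt$sector[idx], levels = 1:8), mean))
  static <- as.character(0)
  moving <- setdiff(names(cond), static)

  pd_static <- split_pds(cond[[static]])
  p_pd <- p_gain <- p_add <- setNames(rep(NA_real_, length(moving)), moving)
  for (v in moving) {
    pdv <- split_pds(cond[[v]])
    p_pd[v] <- if (length(pd_static) < 2 || length(pdv) < 2) NA_real_ else
      watson_williams_test(c(pd_static, pdv),
                           rep(c("s", "m"), c(length(pd_static),
                                              length(pdv))))$p.value
    dev_s <- abs(sec_means[[static]] - mean(sec_means[[static]]))
    dev_v <- abs(sec_means[[v]] - mean(sec_means[[v]]))
    p_gain[v] <- safe_signed_rank(dev_v, dev_s)
    p_add[v] <- safe_signed_rank(sec_means[[v]], sec_means[[static]])
  }
  dir_p <- tryCatch(kruskal.test(rates, factor(tt$sector))$p.value,
                    error = function(e) 1)
  if (is.na(dir_p)) dir_p <- 1
  flags <- list(pd_shift = isTRUE(any(p_pd < alpha, na.rm = TRUE)),
                gain = isTRUE(any(p_gain < alpha, na.rm = TRUE)),
                addition = isTRUE(any(p_add < alpha, na.rm = TRUE)))
  structure(c(flags, list(
    direction_tuned = dir_p < alpha,
    none = !any(unlist(flags)) && !(dir_p < alpha),
    p_pd_shift = p_pd, p_gain = p_gain, p_addition = p_add,
    p_direction = dir_p)), class = "modulation_label")
}

#' @export
print.modulation_label <- function(x, ...) {
  on <- c("pd_shift", "gain", "addition")[unlist(x[c("pd_shift", "gain", "addition")])]
  cat("Modulation:", if (length(on)) paste(on, collapse = " + ")
      else if (x$none) "none" else "direction-tuned only", "\n")
  invisible(x)
}

## ---- tuning-model fits --------------------------------------------------

tuning_model_formulas <- function() {
  list(
    simple   = y ~ a1 * cospi((theta - th_pd) / 180) + c1,
    gain     = y ~ (a1 / (1 + exp(-a2 * vc)) + c2) *
                 cospi((theta - th_pd) / 180) + c1,
    additive = y ~ a1 * cospi((theta - th_pd) / 180) +
                 a3 / (1 + exp(-a2 * vc)) + c1,
    pd_shift = y ~ a1 * cospi((theta - th_pd - a5 / (1 + exp(-a2 * vc))) / 180) + c1,
    full     = y ~ a1 * cospi((theta - th_pd) / 180) +
                 a3o / (1 + exp(-a2 * vc)) +
                 (a3 / (1 + exp(-a2 * vc))) * cospi((theta - th_pd) / 180) +
                 a4 * cospi((theta - th_pd - a5 / (1 + exp(-a2 * vc))) / 180) + c1)
}

tuning_model_start <- function(kind, y, th0) {
  amp <- max(diff(range(y)) / 2, 0.1)
  base <- list(th_pd = th0, c1 = mean(y))
  extra <- switch(kind,
    simple   = list(a1 = amp),
    gain     = list(a1 = amp, a2 = 1, c2 = amp / 2),
    additive = list(a1 = amp, a2 = 1, a3 = amp / 2),
    pd_shift = list(a1 = amp, a2 = 1, a5 = 45),
    full     = list(a1 = amp / 2, a2 = 1, a3o = amp / 4, a3 = amp / 4,
                    a4 = amp / 4, a5 = 45))
  c(extra, base)
}

#' Fit a direction/velocity tuning model to single-trial rates
#'
#' Nonlinear least squares (Levenberg-Marquardt) on single-trial peri-movement
#' rates. Target velocity enters the sigmoidal modulation terms through the
#' symmetric code vel/120 (-2..2 for the standard grid). Fits are multi-started
#' over a grid of 8 initial preferred directions; ties are broken by the lowest
#' residual sum of squares, then by the smallest |a2|.
#'
#' Model forms (vc = vel/120):
#' \describe{
#'   \item{simple}{`a1*cos(theta - pd) + c1`}
#'   \item{gain}{`(a1*sig(a2*vc) + c2)*cos(theta - pd) + c1`}
#'   \item{additive}{`a1*cos(theta - pd) + a3*sig(a2*vc) + c1`}
#'   \item{pd_shift}{`a1*cos(theta - pd - a5*sig(a2*vc)) + c1`}
#'   \item{full}{sum of the additive, gain and shift terms with a common
#'     sigmoid slope and its own coefficients}
#' }
#'
#' @param rates per-trial rates (spikes/s).
#' @param theta per-trial reach directions, degrees.
#' @param vel per-trial target velocities, deg/s.
#' @param model_kind one of `"simple"`, `"gain"`, `"additive"`, `"pd_shift"`,
#'   `"full"`.
#' @return Object of class `tuning_fit` with elements `model_kind`,
#'   `coefficients`, `r2`, `r2_adj`, `n`, `n_params`, `converged`.
#' @export
fit_tuning_model <- function(rates, theta, vel,
                             model_kind = c("simple", "gain", "additive",
                                            "pd_shift", "full")) {
  model_kind <- match.arg(model_kind)
  form <- tuning_model_formulas()[[model_kind]]
  n_params <- c(simple = 3, gain = 5, additive = 5, pd_shift = 5, full = 8)[[model_kind]]
  n <- length(rates)
  if (n < n_params + 2)
    stop("need at least n_params + 2 = ", n_params + 2, " trials")
  dat <- data.frame(y = rates, theta = theta %% 360, vc = vel / 120)
  best <- NULL
  for (th0 in seq(0, 315, by = 45)) {
    fit <- tryCatch(suppressWarnings(minpack.lm::nlsLM(
      form, data = dat, start = tuning_model_start(model_kind, rates, th0),
      control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(resid(fit)^2)
    a2 <- tryCatch(abs(coef(fit)[["a2"]]), error = function(e) 0)
    if (is.null(best) || rss < best$rss - 1e-12 ||
        (abs(rss - best$rss) <= 1e-12 && a2 < best$a2)) {
      best <- list(fit = fit, rss = rss, a2 = a2)
    }
  }
  if (is.null(best)) {
    out <- list(model_kind = model_kind, coefficients = NULL, r2 = NA_real_,
                r2_adj = NA_real_, n = n, n_params = n_params,
                converged = FALSE)
    class(out) <- "tuning_fit"
    return(out)
  }
  sst <- sum((rates - mean(rates))^2)
  r2 <- if (sst > 0) 1 - best$rss / sst else NA_real_
  cf <- coef(best$fit)
  ## canonical form: nonnegative cosine amplitude, th_pd in [0, 360)
  if (model_kind %in% c("simple", "additive", "pd_shift") && cf[["a1"]] < 0) {
    cf[["a1"]] <- -cf[["a1"]]
    cf[["th_pd"]] <- cf[["th_pd"]] + 180
  }
  if (model_kind == "gain" && cf[["a1"]] + 2 * cf[["c2"]] < 0) {
    cf[["a1"]] <- -cf[["a1"]]; cf[["c2"]] <- -cf[["c2"]]
    cf[["th_pd"]] <- cf[["th_pd"]] + 180
  }
  cf[["th_pd"]] <- cf[["th_pd"]] %% 360
  out <- list(model_kind = model_kind, coefficients = cf, r2 = r2,
              r2_adj = 1 - (1 - r2) * (n - 1) / (n - n_params - 1),
              n = n, n_params = n_params, converged = TRUE,
              fitted = fitted(best$fit), residuals = resid(best$fit))
  class(out) <- "tuning_fit"
  out
}

#' @export
print.tuning_fit <- function(x, ...) {
  cat(sprintf("Tuning fit (%s model): n = %d, adj. R^2 = %s\n",
              x$model_kind, x$n,
              ifelse(is.na(x$r2_adj), "NA (not converged)",
                     sprintf("%.3f", x$r2_adj))))
  if (!is.null(x$coefficients)) print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.tuning_fit <- function(object, ...) object$coefficients

#' @export
predict.tuning_fit <- function(object, newdata = NULL, ...) {
  if (is.null(object$coefficients)) stop("fit did not converge")
  if (is.null(newdata)) return(object$fitted)
  stopifnot(all(c("theta", "vel") %in% names(newdata)))
  env <- c(as.list(object$coefficients),
           list(theta = newdata$theta %% 360, vc = newdata$vel / 120))
  eval(tuning_model_formulas()[[object$model_kind]][[3]], env)
}

#' @export
residuals.tuning_fit <- function(object, ...) object$residuals

#' Fit all tuning models to each neuron of a population
#'
#' @param activity a [population_activity()].
#' @param window analysis window around movement onset, ms.
#' @param models model kinds to fit.
#' @param neurons neuron indices (default all).
#' @return Data frame with one row per neuron x model: `neuron`, `model`,
#'   `r2`, `r2_adj`, `converged`.
#' @export
fit_population_tuning <- function(activity, window = c(-100, 100),
                                  models = c("simple", "gain", "additive",
                                             "pd_shift", "full"),
                                  neurons = NULL) {
  X <- window_rates(activity, window)
  if (is.null(neurons)) neurons <- seq_len(ncol(X))
  tt <- activity$trial_table
  out <- do.call(rbind, lapply(neurons, function(j) {
    do.call(rbind, lapply(models, function(m) {
      f <- fit_tuning_model(X[, j], tt$reach_endpoint_angle,
                            tt$target_velocity, m)
      data.frame(neuron = j, model = m, r2 = f$r2, r2_adj = f$r2_adj,
                 converged = f$converged)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Compare tuning-model families across a population
#'
#' Ranks model kinds by their median adjusted R-squared over neurons and
#' tests each pair with a one-tailed Wilcoxon rank-sum test (better family
#' greater).
#'
#' @param fits data frame from [fit_population_tuning()], or a named list of
#'   adjusted R-squared vectors.
#' @return List with `ranking` (model kinds, best first), `medians`, and the
#'   matrix `p_greater` where entry (i, j) tests model i > model j.
#' @export
compare_models <- function(fits) {
  if (is.data.frame(fits))
    fits <- split(fits$r2_adj, fits$model)
  fits <- lapply(fits, function(v) v[is.finite(v)])
  med <- vapply(fits, median, 1)
  ord <- names(sort(med, decreasing = TRUE))
  p <- matrix(NA_real_, length(fits), length(fits),
              dimnames = list(names(fits), names(fits)))
  for (i in names(fits)) for (j in names(fits)) if (i != j)
    p[i, j] <- suppressWarnings(
      wilcox.test(fits[[i]], fits[[j]], alternative = "greater")$p.value)
  list(ranking = ord, medians = med[ord], p_greater = p)
}
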