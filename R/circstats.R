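## Circular statistics needed for preferred-direction analysis. Angles are in
## degrees throughout the package.

#' Circular mean and resultant length
#'
#' @param angles angles in degrees.
#' @param w optional nonnegative weights.
#' @return `circ_mean`: mean angle in degrees in \[0, 360), `NA` when the
#'   resultant vanishes. `circ_r`: mean resultant length in \[0, 1\].
#' @export
circ_mean <- function(angles, w = NULL) {
  if (is.null(w)) w <- rep(1, length(angles))
  C <- sum(w * cosd(angles)); S <- sum(w * sind(angles))
  if (sqrt(C^2 + S^2) < 1e-12 * max(sum(abs(w)), 1)) return(NA_real_)
  (atan2(S, C) * 180 / pi) %% 360
}

#' @rdname circ_mean
#' @export
circ_r <- function(angles, w = NULL) {
  if (is.null(w)) w <- rep(1, length(angles))
  sqrt(sum(w * cosd(angles))^2 + sum(w * sind(angles))^2) / sum(w)
}

## Smallest signed angular difference a - b in (-180, 180].
ang_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

## Maximum-likelihood inverse of the mean resultant length for the von Mises
## concentration (standard piecewise approximation).
a1inv <- function(r) {
  if (r < 0.53) 2 * r + r^3 + 5 * r^5 / 6
  else if (r < 0.85) -0.4 + 1.39 * r + 0.43 / (1 - r)
  else 1 / (r^3 - 4 * r^2 + 3 * r)
}

#' Watson-Williams test for equal circular means
#'
#' One-way test of the hypothesis that k samples of angles share a common
#' mean direction, via the F approximation with the von Mises concentration
#' correction. Degenerate dispersion-free samples (every group concentrated
#' at a single angle) are handled exactly: p = 1 when all group means agree
#' and p = 0 when any differ.
#'
#' @param angles angles in degrees.
#' @param group group labels (coerced to factor), at least 2 groups.
#' @return A list with `statistic` (F), `df`, `p.value`, and per-group means.
#' @export
watson_williams_test <- function(angles, group) {
  group <- as.factor(group)
  stopifnot(length(angles) == length(group), nlevels(group) >= 2)
  k <- nlevels(group)
  n_i <- tabulate(group)
  if (any(n_i < 2)) stop("each group needs at least 2 angles")
  C_i <- tapply(cosd(angles), group, sum)
  S_i <- tapply(sind(angles), group, sum)
  R_i <- sqrt(C_i^2 + S_i^2)
  N <- length(angles)
  R <- sqrt(sum(C_i)^2 + sum(S_i)^2)
  means <- (atan2(S_i, C_i) * 180 / pi) %% 360
  within <- N - sum(R_i)
  if (within < 1e-9 * N) {
    spread <- max(abs(ang_diff(means, means[1])))
    p <- if (spread < 1e-6) 1 else 0
    return(list(statistic = if (p == 0) Inf else 0,
                df = c(k - 1, N - k), p.value = p, group_means = means))
  }
  rw <- sum(R_i) / N
  kappa <- a1inv(rw)
  corr <- 1 + 3 / (8 * kappa)
  Fstat <- corr * ((N - k) * (sum(R_i) - R)) / ((k - 1) * within)
  Fstat <- max(Fstat, 0)
  list(statistic = Fstat, df = c(k - 1, N - k),
       p.value = pf(Fstat, k - 1, N - k, lower.tail = FALSE),
       group_means = means)
}
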