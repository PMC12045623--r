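## Population neural-state pipeline: normalization, PCA neural states,
## per-condition ellipse geometry (tilt / rotation / shift), tilt-velocity
## regression and PC tuning fits.

#' Soft normalization of firing rates
#'
#' Divides each neuron's rates by its firing-rate range plus five, the
#' standard compression applied before population decoding so that high-rate
#' units do not dominate.
#'
#' @param x a [population_activity()] or a trials x neurons matrix.
#' @return The same type, soft-normalized per neuron.
#' @export
soft_normalize <- function(x) {
  if (inherits(x, "population_activity")) {
    r <- x$rates
    for (j in seq_len(dim(r)[1])) {
      rng <- range(r[j, , ])
      r[j, , ] <- r[j, , ] / (rng[2] - rng[1] + 5)
    }
    x$rates <- r
    return(x)
  }
  x <- as.matrix(x)
  rng <- apply(x, 2, function(v) diff(range(v)))
  sweep(x, 2, rng + 5, "/")
}

#' Single-trial neural states by PCA
#'
#' Averages the population activity in a window around the alignment event,
#' z-scores each neuron across trials, and projects onto principal
#' components. Zero-variance neurons are dropped (with a message).
#'
#' @param activity a [population_activity()].
#' @param window `c(start, end)` around the alignment event (ms for session
#'   data, bins for model populations).
#' @param n_pcs number of PCs to retain.
#' @return Object of class `neural_states`: `states` (trials x n_pcs),
#'   `explained_variance` (percent, all PCs), `window`, `trial_table`,
#'   `dropped` (indices of zero-variance neurons).
#' @export
neural_states <- function(activity, window, n_pcs = 3) {
  X <- window_rates(activity, window)
  if (nrow(X) < n_pcs) stop("fewer trials than requested PCs")
  v <- apply(X, 2, var)
  dropped <- which(v < 1e-14)
  if (length(dropped)) {
    message(length(dropped), " zero-variance neuron(s) dropped before PCA")
    X <- X[, -dropped, drop = FALSE]
  }
  Z <- scale(X)
  p <- prcomp(Z, center = FALSE, scale. = FALSE)
  ev <- 100 * p$sdev^2 / sum(p$sdev^2)
  structure(list(states = p$x[, seq_len(min(n_pcs, ncol(p$x))), drop = FALSE],
                 explained_variance = ev, window = window,
                 trial_table = activity$trial_table, dropped = dropped),
            class = "neural_states")
}

#' @export
print.neural_states <- function(x, ...) {
  cat(sprintf("Neural states: %d trials x %d PCs (EV %s%%; window [%g, %g])\n",
              nrow(x$states), ncol(x$states),
              paste(sprintf("%.1f", head(x$explained_variance, 3)),
                    collapse = ", "),
              x$window[1], x$window[2]))
  invisible(x)
}

#' Fit an ellipse to one velocity condition's states
#'
#' @param states a [neural_states()] object (or trials x 3 matrix with a
#'   `sectors` argument).
#' @param target_velocity condition to select (ignored for matrix input).
#' @param sectors per-point sector labels for matrix input.
#' @return An [fit_ellipse3d()] object.
#' @export
fit_ellipse_condition <- function(states, target_velocity = NULL,
                                  sectors = NULL) {
  if (inherits(states, "neural_states")) {
    sel <- states$trial_table$target_velocity == target_velocity
    fit_ellipse3d(states$states[sel, 1:3, drop = FALSE],
                  sectors = states$trial_table$sector[sel])
  } else {
    fit_ellipse3d(states, sectors = sectors)
  }
}

#' Tilting angle between two ellipses
#'
#' The angle between the plane normals, folded into (-90, 90\]. The sign is
#' taken from the component of the ellipse's normal orthogonal to the
#' reference normal, projected on `sign_axis` (the common tilt axis computed
#' in [geometry_summary()]); without `sign_axis` the magnitude is returned.
#'
#' @param e,ref [fit_ellipse3d()] objects (ref = static condition).
#' @param sign_axis optional unit 3-vector fixing the sign convention.
#' @return Tilting angle in degrees.
#' @export
tilting_angle <- function(e, ref, sign_axis = NULL) {
  n1 <- e$normal; n0 <- ref$normal
  if (sum(n1 * n0) < 0) n1 <- -n1
  ang <- acos(pmin(1, abs(sum(n1 * n0)))) * 180 / pi
  if (is.null(sign_axis)) return(ang)
  u <- n1 - sum(n1 * n0) * n0
  if (sqrt(sum(u^2)) < 1e-12) return(0)
  ang * sign(sum(u * sign_axis))
}

#' Rotation angle between two conditions in the PC1-PC2 plane
#'
#' Circular mean over reach-direction sectors of the angular difference
#' between matched sector centroids, measured about each condition's own
#' centroid center.
#'
#' @param states_e,states_ref trials x >=2 state matrices for the two
#'   conditions (PC1, PC2 in the first two columns).
#' @param sectors_e,sectors_ref per-trial sector labels.
#' @return Rotation angle in degrees in (-180, 180\].
#' @export
rotation_angle <- function(states_e, sectors_e, states_ref, sectors_ref) {
  cen <- function(S, sec) {
    out <- sapply(1:8, function(k) {
      if (!any(sec == k)) return(c(NA, NA))
      colMeans(S[sec == k, 1:2, drop = FALSE])
    })
    t(out)
  }
  ce <- cen(as.matrix(states_e), sectors_e)
  cr <- cen(as.matrix(states_ref), sectors_ref)
  keep <- which(stats::complete.cases(ce) & stats::complete.cases(cr))
  if (length(keep) < length(1:8))
    message("sector(s) missing in one condition skipped: ",
            paste(setdiff(1:8, keep), collapse = ", "))
  me <- colMeans(ce[keep, , drop = FALSE])
  mr <- colMeans(cr[keep, , drop = FALSE])
  a_e <- atan2(ce[keep, 2] - me[2], ce[keep, 1] - me[1]) * 180 / pi
  a_r <- atan2(cr[keep, 2] - mr[2], cr[keep, 1] - mr[1]) * 180 / pi
  d <- ang_diff(a_e, a_r)
  ang_diff(circ_mean(d), 0)
}

#' State shift between two ellipses
#'
#' Root mean squared 3D distance between the two ellipses, sampled at 64
#' matched normalized arc-length parameters. Starting phases are anchored at
#' the ellipse point nearest each condition's sector-1 centroid, and the
#' traversal direction is chosen so the sector-2 centroid follows sector 1.
#'
#' @param e,ref [fit_ellipse3d()] objects.
#' @param anchor_e,anchor_ref optional 3-vectors anchoring the starting
#'   phase (e.g. sector-1 centroids); without them both ellipses start at
#'   their major axes.
#' @param dir_e,dir_ref optional 3-vectors (e.g. sector-2 centroids) fixing
#'   the traversal direction.
#' @param k number of matched samples.
#' @return RMS distance in state units.
#' @export
state_shift <- function(e, ref, anchor_e = NULL, anchor_ref = NULL,
                        dir_e = NULL, dir_ref = NULL, k = 64) {
  par_of <- function(ell, p) {
    q <- as.numeric(crossprod(ell$axes3d, p - ell$center))
    atan2(q[2] / ell$semi_axes[2], q[1] / ell$semi_axes[1])
  }
  setup <- function(ell, anchor, dirpt) {
    phase <- if (is.null(anchor)) 0 else par_of(ell, anchor)
    dir <- 1
    if (!is.null(anchor) && !is.null(dirpt)) {
      d <- (par_of(ell, dirpt) - phase) %% (2 * pi)
      dir <- if (d <= pi) 1 else -1
    }
    ellipse3d_points(ell, k = k, phase_start = phase, direction = dir)
  }
  P1 <- setup(e, anchor_e, dir_e)
  P0 <- setup(ref, anchor_ref, dir_ref)
  sqrt(mean(rowSums((P1 - P0)^2)))
}

#' Linear fit of tilting angle on target velocity
#'
#' @param angles tilting angles (degrees), one per condition.
#' @param velocities signed target velocities (deg/s).
#' @return List with `slope`, `intercept`, `r2` (`NA` when the angles are
#'   constant).
#' @export
fit_tilt_vs_velocity <- function(angles, velocities) {
  if (length(angles) < 3) stop("need at least 3 conditions")
  fit <- lm(angles ~ velocities)
  r2 <- if (var(angles) < 1e-12) NA_real_ else summary(fit)$r.squared
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r2 = r2)
}

#' Direction and velocity tuning of principal components
#'
#' Fits each PC score to the reach-direction model
#' `PC = a1*cos(theta) + a2*sin(theta) + c` (linear least squares) and to the
#' sigmoidal velocity model `PC = a1 / (1 + exp(-a2*vc)) + c` (nonlinear
#' least squares, multi-start over the slope sign), returning the fraction of
#' variance each model explains.
#'
#' @param scores trials x PCs matrix (or [neural_states()]).
#' @param theta per-trial reach direction, degrees.
#' @param vel per-trial target velocity (deg/s on the standard grid, or an
#'   abstract 1..5 code; values beyond 5 in magnitude are scaled by 1/120).
#' @return Data frame, one row per PC: `r2_direction`, `r2_velocity`, and
#'   the direction-model coefficients.
#' @export
fit_pc_tuning <- function(scores, theta, vel) {
  if (inherits(scores, "neural_states")) {
    theta <- scores$trial_table$reach_endpoint_angle
    vel <- scores$trial_table$target_velocity
    scores <- scores$states
  }
  scores <- as.matrix(scores)
  if (nrow(scores) < 10) stop("need at least 10 trials")
  vc <- if (max(abs(vel)) > 5) vel / 120 else vel - 3
  out <- lapply(seq_len(ncol(scores)), function(j) {
    y <- scores[, j]
    dir_fit <- lm(y ~ cosd(theta) + sind(theta))
    r2d <- summary(dir_fit)$r.squared
    r2v <- NA_real_
    for (a2_0 in c(-2, -0.5, 0.5, 2)) {
      f <- tryCatch(suppressWarnings(minpack.lm::nlsLM(
        y ~ a1 / (1 + exp(-a2 * vc)) + c0,
        start = list(a1 = diff(range(y)), a2 = a2_0, c0 = min(y)),
        control = minpack.lm::nls.lm.control(maxiter = 100))),
        error = function(e) NULL)
      if (!is.null(f)) {
        r2 <- 1 - sum(resid(f)^2) / sum((y - mean(y))^2)
        if (is.na(r2v) || r2 > r2v) r2v <- r2
      }
    }
    cf <- coef(dir_fit)
    data.frame(pc = j, r2_direction = r2d, r2_velocity = r2v,
               a1 = unname(cf[2]), a2 = unname(cf[3]), c = unname(cf[1]))
  })
  do.call(rbind, out)
}

#' Rotate all states so the static-condition plane is horizontal
#'
#' Applies the proper rigid rotation taking the static ellipse's normal to
#' the z-axis; pairwise distances, and hence all tilt/rotation/shift
#' metrics, are preserved.
#'
#' @param states trials x 3 matrix (or [neural_states()]).
#' @param static_ellipse the static condition's [fit_ellipse3d()].
#' @return A list: `states` (rotated), `rotation` (3 x 3 orthogonal,
#'   det = +1).
#' @export
align_static_plane <- function(states, static_ellipse) {
  S <- if (inherits(states, "neural_states")) states$states else as.matrix(states)
  n <- static_ellipse$normal
  if (n[3] < 0) n <- -n
  z <- c(0, 0, 1)
  v <- c(n[2] * z[3] - n[3] * z[2], n[3] * z[1] - n[1] * z[3],
         n[1] * z[2] - n[2] * z[1])
  s <- sqrt(sum(v^2)); cth <- sum(n * z)
  R <- if (s < 1e-12) diag(3) else {
    K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3)
    diag(3) + K + K %*% K * ((1 - cth) / s^2)
  }
  list(states = S %*% t(R), rotation = R)
}

#' Ellipse geometry summary across target-motion conditions
#'
#' Runs the full per-condition geometry: fits a 3D ellipse to each velocity
#' condition's states, computes the signed tilting angle, the PC1-PC2
#' rotation angle and the state shift of each moving condition against the
#' static one, and regresses tilt on velocity.
#'
#' The tilt sign convention follows the task's circular geometry: the common
#' tilt axis is the leading principal direction of the normals' components
#' orthogonal to the static normal, oriented so that counterclockwise target
#' motion takes positive sign.
#'
#' @param states a [neural_states()] object with >= 3 PCs.
#' @return Object of class `geometry_summary`: data frame `conditions`
#'   (velocity, tilt, rotation, shift, ellipse R^2), list `ellipses`, and
#'   `tilt_fit` (slope, intercept, r2).
#' @export
geometry_summary <- function(states) {
  stopifnot(inherits(states, "neural_states"))
  tt <- states$trial_table
  vels <- sort(unique(tt$target_velocity))
  if (!(0 %in% vels)) stop("static (0 deg/s) condition required as reference")
  ells <- lapply(vels, function(v) {
    sel <- tt$target_velocity == v
    fit_ellipse3d(states$states[sel, 1:3, drop = FALSE],
                  sectors = tt$sector[sel])
  })
  names(ells) <- as.character(vels)
  ref <- ells[["0"]]
  ## orient normals into the reference hemisphere, collect tilt components
  U <- sapply(ells, function(e) {
    n <- e$normal; if (sum(n * ref$normal) < 0) n <- -n
    n - sum(n * ref$normal) * ref$normal
  })
  moving <- which(vels != 0)
  w <- if (length(moving)) {
    M <- U[, moving, drop = FALSE]
    sv <- svd(M)
    axis <- sv$u[, 1]
    orient <- sum(sign(vels[moving]) * as.numeric(crossprod(axis, M)))
    if (orient < 0) axis <- -axis
    axis
  } else c(1, 0, 0)
  sec1 <- function(v) {
    sel <- tt$target_velocity == v & tt$sector == 1
    if (!any(sel)) return(NULL)
    colMeans(states$states[sel, 1:3, drop = FALSE])
  }
  sec2 <- function(v) {
    sel <- tt$target_velocity == v & tt$sector == 2
    if (!any(sel)) return(NULL)
    colMeans(states$states[sel, 1:3, drop = FALSE])
  }
  rows <- lapply(seq_along(vels), function(i) {
    v <- vels[i]; e <- ells[[i]]
    sel <- tt$target_velocity == v
    sel0 <- tt$target_velocity == 0
    data.frame(
      target_velocity = v,
      tilt = if (v == 0) 0 else tilting_angle(e, ref, sign_axis = w),
      rotation = if (v == 0) 0 else
        rotation_angle(states$states[sel, , drop = FALSE], tt$sector[sel],
                       states$states[sel0, , drop = FALSE], tt$sector[sel0]),
      shift = if (v == 0) 0 else
        state_shift(e, ref, anchor_e = sec1(v), anchor_ref = sec1(0),
                    dir_e = sec2(v), dir_ref = sec2(0)),
      shift_vertical = if (v == 0) 0 else
        abs(sum((e$center - ref$center) * ref$normal)),
      r2_ellipse = e$r2_fit)
  })
  conditions <- do.call(rbind, rows)
  tilt_fit <- fit_tilt_vs_velocity(conditions$tilt, conditions$target_velocity)
  structure(list(conditions = conditions, ellipses = ells,
                 tilt_axis = w, tilt_fit = tilt_fit,
                 explained_variance = states$explained_variance),
            class = "geometry_summary")
}

#' @export
print.geometry_summary <- function(x, ...) {
  cat("Orbital geometry summary\n")
  print(transform(x$conditions,
                  tilt = round(tilt, 2), rotation = round(rotation, 2),
                  shift = round(shift, 3),
                  shift_vertical = round(shift_vertical, 3),
                  r2_ellipse = round(r2_ellipse, 3)),
        row.names = FALSE)
  tf <- x$tilt_fit
  cat(sprintf("tilt = %.4f * vel %+.2f (R^2 = %s)\n", tf$slope, tf$intercept,
              ifelse(is.na(tf$r2), "NA", sprintf("%.2f", tf$r2))))
  invisible(x)
}
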