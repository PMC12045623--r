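## Direct least-squares 3D ellipse fitting: a total-least-squares plane
## (PCA of the point cloud), then the numerically stable ellipse-specific
## direct conic fit of Halir & Flusser in the plane.

## Ellipse-specific direct conic fit in 2D. Returns conic coefficients
## (a, b, c, d, e, f) for ax^2 + bxy + cy^2 + dx + ey + f = 0 with
## 4ac - b^2 > 0 guaranteed by the constraint.
fit_conic_ellipse2d <- function(x, y) {
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  Tm <- -solve(S3, t(S2))
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  ok <- which(Re(4 * ev$vectors[1, ] * ev$vectors[3, ] -
                   ev$vectors[2, ]^2) > 0 & abs(Im(ev$values)) < 1e-8)
  if (!length(ok)) stop("conic fit did not select an ellipse")
  a1 <- Re(ev$vectors[, ok[1]])
  c(a1, Tm %*% a1)
}

## Conic (a,b,c,d,e,f) -> center, semi-axes, orientation (radians).
conic_to_ellipse <- function(k) {
  a <- k[1]; b <- k[2] / 2; c <- k[3]; d <- k[4] / 2; e <- k[5] / 2; f <- k[6]
  M <- matrix(c(a, b, b, c), 2)
  if (det(M) <= 0) stop("degenerate conic")
  ctr <- -solve(M, c(d, e))
  f0 <- f + d * ctr[1] + e * ctr[2]
  eg <- eigen(M, symmetric = TRUE)
  ax2 <- -f0 / eg$values
  if (any(ax2 <= 0)) stop("degenerate conic")
  ord <- order(ax2, decreasing = TRUE)
  list(center = ctr, semi_axes = sqrt(ax2[ord]),
       axes_dir = eg$vectors[, ord, drop = FALSE],
       angle = atan2(eg$vectors[2, ord[1]], eg$vectors[1, ord[1]]))
}

## Distance from 2D points to the ellipse x^2/a^2 + y^2/b^2 = 1 (frame
## coordinates): coarse parameter grid then Newton refinement on the
## squared-distance objective.
ellipse_point_dist2d <- function(px, py, a, b) {
  vapply(seq_along(px), function(i) {
    x <- px[i]; y <- py[i]
    phi <- atan2(y / b, x / a)
    grid <- phi + seq(-pi, pi, length.out = 65)
    d2 <- (x - a * cos(grid))^2 + (y - b * sin(grid))^2
    t <- grid[which.min(d2)]
    for (it in 1:20) {
      ct <- cos(t); st <- sin(t)
      g <- (x - a * ct) * a * st - (y - b * st) * b * ct
      h <- (x - a * ct) * a * ct + a^2 * st^2 +
        (y - b * st) * b * st + b^2 * ct^2
      if (abs(h) < 1e-14) break
      step <- g / h
      t <- t - step
      if (abs(step) < 1e-12) break
    }
    sqrt((x - a * cos(t))^2 + (y - b * sin(t))^2)
  }, 1)
}

#' Fit a 3D ellipse to a condition's neural states
#'
#' Fits the best plane by total least squares (the normal is the direction of
#' least variance of the point cloud), then fits an ellipse-constrained conic
#' to the in-plane coordinates by direct least squares. The fit quality is
#' `r2_fit = 1 - sum(d^2) / sum(|p - centroid|^2)` where d is the 3D distance
#' from each point to the nearest point on the fitted ellipse.
#'
#' @param points numeric matrix, trials x 3 (first three PCs).
#' @param min_sectors minimum number of distinct sectors required when
#'   `sectors` is supplied.
#' @param sectors optional per-point sector labels used only for the coverage
#'   check.
#' @return Object of class `ellipse3d_fit`: `center` (3-vector), `normal`
#'   (unit 3-vector), `semi_axes` (major, minor), `axes3d` (3 x 2 in-plane
#'   unit axes), `angle` (in-plane orientation, radians), `r2_fit`, `n`.
#' @export
fit_ellipse3d <- function(points, sectors = NULL, min_sectors = 5) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3)
  if (nrow(points) < 8) stop("need at least 8 points to fit a 3D ellipse")
  if (!is.null(sectors) && length(unique(sectors)) < min_sectors)
    stop("points span fewer than ", min_sectors, " sectors")
  ctr <- colMeans(points)
  X <- sweep(points, 2, ctr)
  sv <- svd(X)
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1))
    stop("degenerate (collinear) points")
  basis <- sv$v[, 1:2, drop = FALSE]
  normal <- sv$v[, 3]
  Q <- X %*% basis
  k <- fit_conic_ellipse2d(Q[, 1], Q[, 2])
  ell <- conic_to_ellipse(k)
  ## in-plane residuals + out-of-plane residuals
  Qc <- sweep(Q, 2, ell$center)
  Qr <- Qc %*% ell$axes_dir
  d_in <- ellipse_point_dist2d(Qr[, 1], Qr[, 2],
                               ell$semi_axes[1], ell$semi_axes[2])
  d_out <- X %*% normal
  d2 <- d_in^2 + as.numeric(d_out)^2
  r2 <- 1 - sum(d2) / sum(rowSums(X^2))
  structure(list(
    center = as.numeric(ctr + basis %*% ell$center),
    normal = as.numeric(normal),
    semi_axes = ell$semi_axes,
    axes3d = basis %*% ell$axes_dir,
    angle = ell$angle,
    r2_fit = r2, n = nrow(points)), class = "ellipse3d_fit")
}

#' @export
print.ellipse3d_fit <- function(x, ...) {
  cat(sprintf("3D ellipse fit: n = %d, semi-axes (%.3g, %.3g), R^2 = %.3f\n",
              x$n, x$semi_axes[1], x$semi_axes[2], x$r2_fit))
  cat(sprintf("  normal: (%.3f, %.3f, %.3f)\n",
              x$normal[1], x$normal[2], x$normal[3]))
  invisible(x)
}

#' Sample points along a fitted 3D ellipse
#'
#' @param e an [fit_ellipse3d()] result.
#' @param k number of samples.
#' @param phase_start starting parameter angle (radians, in the ellipse's
#'   axis frame).
#' @param direction +1 or -1 traversal direction.
#' @param by_arc_length if `TRUE`, samples are equally spaced in arc length
#'   rather than in parameter angle.
#' @return k x 3 matrix of points.
#' @export
ellipse3d_points <- function(e, k = 64, phase_start = 0, direction = 1,
                             by_arc_length = TRUE) {
  stopifnot(inherits(e, "ellipse3d_fit"))
  if (by_arc_length) {
    dense <- phase_start + direction * seq(0, 2 * pi, length.out = 2049)
    pts <- cbind(e$semi_axes[1] * cos(dense), e$semi_axes[2] * sin(dense))
    seg <- sqrt(rowSums(diff(pts)^2))
    cum <- c(0, cumsum(seg))
    targets <- seq(0, cum[length(cum)], length.out = k + 1)[seq_len(k)]
    phi <- approx(cum, dense, xout = targets)$y
  } else {
    phi <- phase_start + direction * seq(0, 2 * pi, length.out = k + 1)[seq_len(k)]
  }
  P2 <- cbind(e$semi_axes[1] * cos(phi), e$semi_axes[2] * sin(phi))
  sweep(P2 %*% t(e$axes3d), 2, e$center, "+")
}
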