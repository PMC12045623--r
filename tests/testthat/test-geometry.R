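test_that("soft normalization divides by range plus five", {
  x <- matrix(c(rep(10, 5), c(0, 5, 10, 15, 7)), 5, 2)
  out <- soft_normalize(x)
  expect_equal(out[, 1], rep(2, 5))          # zero range: divide by 5
  expect_equal(out[, 2], x[, 2] / 20)        # range 15: divide by 20
  expect_true(all(apply(out, 2, function(v) diff(range(v))) < 1))
})

test_that("neural states are orthogonal PCA scores with valid explained variance", {
  pop <- fx_population("gain")
  ns <- neural_states(pop, c(50, 150), n_pcs = 3)
  ev <- ns$explained_variance
  expect_true(all(diff(ev) <= 1e-9))
  expect_lte(sum(ev), 100 + 1e-6)
  ## PCA scores are uncorrelated
  cv <- cov(ns$states)
  expect_equal(cv[upper.tri(cv)], rep(0, 3), tolerance = 1e-8)
  ## rank-2 input: EV beyond PC2 vanishes
  set.seed(1)
  tt <- build_trial_table(2, seed = 1)
  u <- rnorm(nrow(tt)); v <- rnorm(nrow(tt))
  X <- outer(u, rnorm(12)) + outer(v, rnorm(12)) + 30  # stays positive: no clipping
  act <- population_activity(array(t(pmax(X, 0)), c(12, nrow(tt), 1)),
                             tt, bin_centers = 0)
  ns2 <- neural_states(act, c(-1, 1), n_pcs = 3)
  expect_lt(sum(ns2$explained_variance[-(1:2)]), 1e-8)
})

test_that("3D ellipse fit recovers exact planar ellipses and circles", {
  phi <- seq(0, 2 * pi, length.out = 41)[-41]
  ## circle of radius 2 in the xy-plane
  P <- cbind(2 * cos(phi), 2 * sin(phi), 0)
  f <- fit_ellipse3d(P)
  expect_equal(abs(f$normal[3]), 1, tolerance = 1e-8)
  expect_equal(unname(f$semi_axes), c(2, 2), tolerance = 1e-6)
  expect_equal(f$r2_fit, 1, tolerance = 1e-6)
  ## tilted, translated ellipse
  ax <- c(1, -2, -2) / 3  # cross product of the in-plane axes
  b1 <- c(2, -1, 2) / 3; b2 <- c(-2, -2, 1) / 3
  Q <- t(sapply(phi, function(p) c(5, -3, 1) + 3 * cos(p) * b1 + 1.5 * sin(p) * b2))
  g <- fit_ellipse3d(Q)
  expect_equal(abs(sum(g$normal * ax)), 1, tolerance = 1e-8)
  expect_equal(unname(g$semi_axes), c(3, 1.5), tolerance = 1e-6)
  expect_equal(g$center, c(5, -3, 1), tolerance = 1e-6)
  expect_equal(g$r2_fit, 1, tolerance = 1e-6)
  expect_error(fit_ellipse3d(Q[1:5, ]), "at least 8")
  line <- cbind(1:20, 2 * (1:20), 3 * (1:20))
  expect_error(fit_ellipse3d(line), "collinear")
})

test_that("tilt, rotation and shift metrics behave on constructed geometry", {
  phi <- seq(0, 2 * pi, length.out = 33)[-33]
  P0 <- cbind(2 * cos(phi), sin(phi), 0)
  e0 <- fit_ellipse3d(P0)
  expect_equal(tilting_angle(e0, e0), 0, tolerance = 1e-8)
  ## plane tilted by 30 degrees about x
  R30 <- matrix(c(1, 0, 0, 0, cospi(1/6), sinpi(1/6),
                  0, -sinpi(1/6), cospi(1/6)), 3)
  e30 <- fit_ellipse3d(P0 %*% t(R30))
  expect_equal(tilting_angle(e30, e0), 30, tolerance = 1e-6)
  ## antiparallel normals fold to zero
  eflip <- e0; eflip$normal <- -e0$normal
  expect_equal(tilting_angle(eflip, e0), 0, tolerance = 1e-8)
  ## signed version follows the sign axis (orient the fitted normal first)
  n1 <- e30$normal; if (sum(n1 * e0$normal) < 0) n1 <- -n1
  u_axis <- n1 - sum(n1 * e0$normal) * e0$normal
  expect_equal(tilting_angle(e30, e0, sign_axis = u_axis), 30,
               tolerance = 1e-6)
  expect_equal(tilting_angle(e30, e0, sign_axis = -u_axis), -30,
               tolerance = 1e-6)
  ## translation along the normal: shift equals the distance
  etr <- e0; etr$center <- e0$center + c(0, 0, 0.7)
  expect_equal(state_shift(etr, e0), 0.7, tolerance = 1e-6)
  expect_equal(state_shift(e0, e0), 0, tolerance = 1e-9)
  ## rotation of the state cloud in PC1-PC2 is recovered
  sec <- rep(1:8, each = 4)
  ang <- sec * 45 - 22.5 + runif(32, -10, 10)
  S0 <- cbind(2 * cospi(ang / 180), 2 * sinpi(ang / 180), 0)
  rot <- 20
  Rz <- matrix(c(cospi(rot / 180), sinpi(rot / 180), 0,
                 -sinpi(rot / 180), cospi(rot / 180), 0, 0, 0, 1), 3)
  expect_equal(rotation_angle(S0 %*% t(Rz), sec, S0, sec), 20,
               tolerance = 1e-6)
  expect_equal(rotation_angle(S0, sec, S0, sec), 0, tolerance = 1e-9)
})

test_that("tilt-velocity regression handles exact, constant and short inputs", {
  v <- c(-240, -120, 0, 120, 240)
  f <- fit_tilt_vs_velocity(0.2 * v, v)
  expect_equal(f$slope, 0.2, tolerance = 1e-12)
  expect_equal(f$r2, 1)
  f0 <- fit_tilt_vs_velocity(rep(0, 5), v)
  expect_equal(f0$slope, 0)
  expect_true(is.na(f0$r2))
  expect_error(fit_tilt_vs_velocity(1:2, v[1:2]), "at least 3")
})

test_that("PC tuning fits separate direction from velocity signals", {
  tt <- build_trial_table(3, seed = 21)
  th <- tt$reach_endpoint_angle; vel <- tt$target_velocity
  pc1 <- 2 * cospi(th / 180) + 1
  pc2 <- 3 / (1 + exp(-1.5 * vel / 120)) - 1
  fits <- fit_pc_tuning(cbind(pc1, pc2), th, vel)
  expect_equal(fits$r2_direction[1], 1, tolerance = 1e-9)
  expect_equal(fits$a1[1], 2, tolerance = 1e-9)
  expect_equal(fits$c[1], 1, tolerance = 1e-9)
  expect_lt(fits$r2_direction[2], 0.05)
  expect_gt(fits$r2_velocity[2], 0.999)
  expect_lt(fits$r2_velocity[1], 0.05)
})

test_that("geometry metrics are invariant under the static-plane alignment", {
  pop <- fx_population("pd_shift")
  ns <- neural_states(pop, c(50, 150), n_pcs = 3)
  gs <- geometry_summary(ns)
  al <- align_static_plane(ns$states, gs$ellipses[["0"]])
  ## proper rotation preserving pairwise distances
  expect_equal(det(al$rotation), 1, tolerance = 1e-10)
  set.seed(3)
  i <- sample(nrow(ns$states), 20); j <- sample(nrow(ns$states), 20)
  d0 <- sqrt(rowSums((ns$states[i, ] - ns$states[j, ])^2))
  d1 <- sqrt(rowSums((al$states[i, ] - al$states[j, ])^2))
  expect_equal(d1, d0, tolerance = 1e-10)
  ## static normal maps to the z-axis
  ns2 <- ns; ns2$states <- al$states
  gs2 <- geometry_summary(ns2)
  expect_equal(abs(gs2$ellipses[["0"]]$normal[3]), 1, tolerance = 1e-6)
  ## all metrics unchanged
  expect_equal(abs(gs2$conditions$tilt), abs(gs$conditions$tilt),
               tolerance = 1e-4)
  expect_equal(gs2$conditions$shift, gs$conditions$shift, tolerance = 1e-4)
  ## the PC1-PC2 rotation metric depends weakly on the projection plane
  expect_equal(gs2$conditions$rotation, gs$conditions$rotation,
               tolerance = 0.01)
})

test_that("pure-group geometry reproduces the qualitative orbital pattern", {
  win <- c(50, 150)
  gs_gain <- geometry_summary(neural_states(fx_population("gain"), win))
  gs_add <- geometry_summary(neural_states(fx_population("additive"), win))
  gs_pd <- geometry_summary(neural_states(fx_population("pd_shift"), win))
  ## gain and PD-shift groups: tilt strictly monotone in velocity
  expect_true(all(diff(gs_gain$conditions$tilt) > 0))
  expect_true(all(diff(gs_pd$conditions$tilt) > 0))
  ## additive group: no tilt, vertical shift monotone in |velocity|
  expect_true(all(abs(gs_add$conditions$tilt) < 1))
  sh <- gs_add$conditions
  expect_true(all(diff(sh$shift_vertical[sh$target_velocity >= 0]) > 0))
  expect_true(all(diff(sh$shift_vertical[sh$target_velocity <= 0]) < 0))
  ## gain group has no vertical displacement, unlike the additive group
  expect_lt(max(gs_gain$conditions$shift_vertical),
            min(sh$shift_vertical[sh$target_velocity != 0]))
  ## additive group: rotation about zero for all velocities
  expect_true(all(abs(gs_add$conditions$rotation) < 1))
  ## mirrored velocities tilt with opposite signs (antisymmetry)
  expect_true(all(gs_gain$conditions$tilt[1:2] < 0))
  expect_true(all(gs_gain$conditions$tilt[4:5] > 0))
})
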