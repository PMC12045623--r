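test_that("with no recurrence the units are first-order low-pass filters of the input", {
  params <- rnn_params(n_units = 1, dt = 10, tau = 50)
  J <- matrix(0, 1, 1); B <- matrix(1, 1, 5); W <- matrix(1, 2, 1)
  U <- array(0, c(5, 60, 1)); U[1, , 1] <- 1   # step input on channel 1
  sim <- rnn_forward_cpp(J, B, W, U, 10, 50)
  a <- 10 / 50
  x_exact <- 1 - (1 - a)^(seq_len(60))         # Euler solution of the ODE
  expect_equal(as.numeric(sim$rates[1, , 1]), tanh(x_exact), tolerance = 1e-12)
  ## converges to tanh(1) and stays within the Euler error of the ODE
  expect_equal(sim$rates[1, 60, 1], tanh(1), tolerance = 1e-4)
  x_ode <- 1 - exp(-(seq_len(60)) * 10 / 50)
  expect_lt(max(abs(x_exact - x_ode)), 0.06)
  ## zero input from zero state stays at the fixed point
  U0 <- array(0, c(5, 20, 1))
  sim0 <- rnn_forward_cpp(J, B, W, U0, 10, 50)
  expect_equal(max(abs(sim0$rates)), 0)
  ## rectified tanh bounds rates in [0, 1)
  expect_true(all(sim$rates >= 0 & sim$rates < 1))
})

test_that("network trials encode the interception task geometry", {
  tr <- build_rnn_trial(240, theta0 = 10, delay = 500)
  ## desired output integrates to the interception displacement
  expect_equal(rowSums(tr$target_output) * 0.01, tr$ip, tolerance = 1e-3)
  ## interception point is the target position at touch
  cnd <- trial_condition(240, 10, t_go = 500, t_move_onset = 700,
                         t_touch = 1000)
  expect_equal(tr$endpoint_angle, target_angle_at(cnd, 1000))
  ## the target leads the MO position by vel * movement_time
  expect_equal(neurorbit:::ang_diff(tr$endpoint_angle,
                                    target_angle_at(cnd, 700)),
               240 * 0.3, tolerance = 1e-9)
  ## intention channels live only in [MO-50, MO]; GO is a step
  on <- which(colSums(abs(tr$inputs[1:2, ])) > 0)
  tt_ms <- (on - 1) * 10
  expect_true(all(tt_ms >= 650 & tt_ms <= 700))
  expect_equal(unique(tr$inputs[5, ]), c(0, 1))
  ## static target: interception point equals the onset position
  tr0 <- build_rnn_trial(0, 10, 500)
  expect_equal(tr0$endpoint_angle, 10)
  ## target path stays on the 0.15 circle
  expect_equal(sqrt(colSums(tr$inputs[3:4, ]^2)),
               rep(0.15, ncol(tr$inputs)), tolerance = 1e-12)
})

test_that("training reduces the loss and reaches sub-radius endpoint errors", {
  net <- fx_rnn(101)
  ## untrained readout (W = 0) outputs exactly zero
  blank <- net; blank$W[] <- 0
  sim <- rnn_simulate(blank, fx_validation_set()[1:3])
  expect_equal(max(abs(sim$outputs)), 0)
  v0 <- validate_rnn(blank, fx_validation_set()[1:20])
  expect_equal(v0$mean, 0.15, tolerance = 1e-9)
  ## loss decreases in moving average
  ma <- function(v, k = 100) stats::filter(v, rep(1 / k, k), sides = 1)
  l <- ma(net$loss)
  expect_lt(min(l, na.rm = TRUE) * 5, l[100])
  expect_lt(mean(utils::tail(net$loss, 50)), net$loss[1] / 10)
  val <- validate_rnn(net, fx_validation_set())
  expect_lt(val$mean, 0.015)
  ## determinism: same seed reproduces the same weights
  net2 <- train_rnn(n_steps = 30, seed = 77)
  net3 <- train_rnn(n_steps = 30, seed = 77)
  expect_identical(net2$J, net3$J)
})

test_that("node analyses are reproducible and respect the active-node rule", {
  net <- fx_rnn(101)
  act <- fx_rnn_activity(101)
  expect_equal(dim(act)[1], 200)
  expect_true(all(act$rates >= 0 & act$rates < 1))
  cls <- fx_rnn_classification(101)
  expect_true(all(cls$fractions >= 0 & cls$fractions <= 1))
  expect_gt(cls$n_active, 50)
  ## flat nodes are excluded
  mean_rate <- apply(act$rates, 1, mean)
  expect_true(all(mean_rate[cls$active] > 0.01))
  ## same model, same grid: labels are stable
  cls2 <- classify_nodes(net, activity = act, seed = 101)
  expect_identical(cls$fractions, cls2$fractions)
})

test_that("ablation and connection scaling behave as weight surgery", {
  net <- fx_rnn(101)
  expect_error(ablate(net, integer()), "empty")
  ## ablating everything silences the output
  dead <- ablate(net, seq_len(200))
  sim <- rnn_simulate(dead, fx_validation_set()[1:2])
  expect_equal(max(abs(sim$outputs)), 0)
  ## the original model is untouched
  expect_false(isTRUE(all.equal(dead$J, net$J)))
  ## scaling: factor 1 is the identity; rescaling restores J
  labs <- rep(c("gain", "additive"), each = 100)
  s1 <- scale_connection(net, labs, "gain", "additive", factor = 1)
  expect_identical(s1$J, net$J)
  s2 <- scale_connection(net, labs, "gain", "additive", factor = 1.5)
  s3 <- scale_connection(s2, labs, "gain", "additive", factor = 1 / 1.5)
  expect_equal(s3$J, net$J, tolerance = 1e-12)
  expect_error(scale_connection(net, labs, "unknown", "gain"), "unknown")
})

test_that("connectivity summary handles uniform weights and empty classes", {
  net <- fx_rnn(101)
  uni <- net; uni$J[] <- 0.3
  labs <- rep(c("a", "b"), each = 100)
  cs <- connectivity_summary(uni, labs)
  expect_true(all(abs(cs$matrix - 0.3) < 1e-12))
  expect_gt(cs$omnibus$p.value, 0.99)
  expect_true(all(cs$matrix >= 0))
  labs2 <- c(rep("a", 200))
  cs2 <- connectivity_summary(net, labs2)
  expect_equal(dim(cs2$matrix), c(1, 1))
})

test_that("latent-dynamics comparison detects identity and is rotation-invariant", {
  set.seed(51)
  X <- matrix(rnorm(40 * 60), 40, 60)
  cl <- compare_latent(X, X, n_pcs = 10, n_cc = 5)
  expect_equal(unname(cl$canonical_r), rep(1, 5), tolerance = 1e-8)
  expect_equal(cl$procrustes, 0, tolerance = 1e-10)
  ## independent noise: canonical correlations well below 1, disparity high
  Y <- matrix(rnorm(40 * 60), 40, 60)
  cl2 <- compare_latent(X, Y, n_pcs = 10, n_cc = 5)
  expect_gt(cl2$procrustes, 0.5)
  ## rotation of one matrix leaves the disparity unchanged
  Q <- qr.Q(qr(matrix(rnorm(100), 10)))
  Xr <- prcomp(X)$x[, 1:10] %*% Q
  cl3 <- compare_latent(prcomp(X)$x[, 1:10], Xr, n_pcs = 10, n_cc = 5)
  expect_equal(cl3$procrustes, 0, tolerance = 1e-10)
  expect_error(compare_latent(X, Y[1:20, ]), "mismatch")
})

test_that("network checkpoints round-trip through CSV", {
  net <- train_rnn(n_steps = 10, seed = 61)
  dir <- withr::local_tempdir()
  write_rnn_csv(net, dir)
  back <- read_rnn_csv(dir)
  expect_equal(back$J, net$J, tolerance = 1e-12)
  expect_equal(back$W, net$W, tolerance = 1e-12)
  expect_equal(back$params$tau, net$params$tau)
  expect_equal(back$loss, net$loss, tolerance = 1e-10)
  ## identical behavior after reload
  v1 <- validate_rnn(net, fx_validation_set()[1:5])
  v2 <- validate_rnn(back, fx_validation_set()[1:5])
  expect_equal(v1$distances, v2$distances, tolerance = 1e-12)
})

test_that("input-deprived variants drop the right channels", {
  gm <- train_rnn(n_steps = 10, variant = "GM", seed = 71)
  gt <- train_rnn(n_steps = 10, variant = "GT", seed = 71)
  expect_identical(gm$input_mask, c(TRUE, TRUE, FALSE, FALSE, TRUE))
  expect_identical(gt$input_mask, c(FALSE, FALSE, TRUE, TRUE, TRUE))
  sp <- train_rnn(n_steps = 10, variant = "sparse", seed = 71)
  expect_s3_class(sp, "trained_rnn")
  expect_error(train_rnn(n_steps = 5, variant = "bogus"), "unknown variant")
})
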