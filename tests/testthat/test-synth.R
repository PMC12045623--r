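test_that("model-neuron equations evaluate to their closed-form values", {
  g <- model_neuron_params("gain", theta_pd = 90, g = 1, t_mu = 100)
  ## sigmoid midpoint: static target, preferred direction
  expect_equal(gain_neuron_rate(g, 100, 3, 90), 1.5)
  expect_equal(gain_neuron_rate(g, 100, 3, 270), 0.5)
  expect_equal(gain_neuron_rate(g, 100, 5, 90), 1 / (1 + exp(-2)) + 1)
  p <- model_neuron_params("pd_shift", theta_pd = 0, s = 1.5, t_mu = 100)
  ## vel = 3: effective shift is 45 degrees for any slope
  expect_equal(pd_shift_neuron_rate(p, 100, 3, 45), 2)
  p0 <- model_neuron_params("pd_shift", theta_pd = 0, s = 0, t_mu = 100)
  for (v in 1:5) expect_equal(pd_shift_neuron_rate(p0, 100, v, 45), 2)
  ## s = 1.5, vel = 5: shift = 90 / (1 + e^-3)
  shift <- 90 / (1 + exp(-3))
  expect_equal(pd_shift_neuron_rate(p, 100, 5, shift), 2)
  a <- model_neuron_params("additive", theta_pd = 0, g = 1, t_mu = 100)
  expect_equal(additive_neuron_rate(a, 100, 3, 0), 2.5)
  expect_equal(additive_neuron_rate(a, 100, 1, 0), 1 + 1 / (1 + exp(2)) + 1)
  ## additive tuning depth is velocity-independent
  th <- seq(0, 359)
  for (v in c(1, 5))
    expect_equal(diff(range(additive_neuron_rate(a, 100, v, th))), 2)
})

test_that("model populations have the stated shape, bounds and ground truth", {
  pop <- fx_population("gain")
  expect_equal(dim(pop), c(300, 320, 200))
  expect_true(all(pop$rates >= 0 & pop$rates <= 3))
  expect_equal(sort(unique(pop$trial_table$vel_code)), 1:5)
  expect_equal(length(unique(pop$trial_table$reach_endpoint_angle)), 64)
  expect_equal(pop$neuron_info$theta_pd, 360 * (0:299) / 300)
  tiny <- build_model_population(c(gain = 1), seed = 2)
  expect_equal(dim(tiny), c(1, 320, 200))
})

test_that("pure groups preserve their invariant index across velocities (noiseless)", {
  win <- c(50, 150)
  ## gain: PD identical across velocities
  pop <- fx_population("gain")
  X <- window_rates(pop, win)
  tt <- pop$trial_table
  for (j in c(1, 150)) {
    pds <- sapply(1:5, function(v) {
      sel <- tt$vel_code == v
      tuning_indices(X[sel, j], tt$sector[sel])$pd
    })
    expect_lt(max(abs(neurorbit:::ang_diff(pds, pds[1]))), 1e-6)
  }
  ## additive: depth identical across velocities
  pop <- fx_population("additive")
  X <- window_rates(pop, win)
  tt <- pop$trial_table
  for (j in c(1, 150)) {
    depths <- sapply(1:5, function(v) {
      sel <- tt$vel_code == v
      tuning_indices(X[sel, j], tt$sector[sel])$depth
    })
    expect_equal(max(depths) - min(depths), 0, tolerance = 1e-10)
  }
  ## pd_shift: offset identical across velocities
  pop <- fx_population("pd_shift")
  X <- window_rates(pop, win)
  tt <- pop$trial_table
  for (j in c(1, 150)) {
    offs <- sapply(1:5, function(v) {
      sel <- tt$vel_code == v
      tuning_indices(X[sel, j], tt$sector[sel])$offset
    })
    expect_equal(max(offs) - min(offs), 0, tolerance = 1e-10)
  }
})

test_that("noisy sessions honor the seeding and noise contracts", {
  gt <- synth_ground_truth(c(gain = 3, additive = 3), seed = 5)
  expect_error(generate_noisy_session(gt, trials_per_cell = 0), "trials_per_cell")
  ## noise = 0 reduces to the deterministic tuning mean
  s0 <- generate_noisy_session(gt, trials_per_cell = 2, noise = 0, seed = 6)
  tt <- s0$trial_table
  mu <- neurorbit:::session_mean_rate(gt[1, ], tt$reach_endpoint_angle,
                                      tt$target_velocity)
  expect_equal(as.numeric(window_rates(s0, c(-100, 100))[, 1]), mu,
               tolerance = 1e-12)
  ## two seeds: different rates, identical label distribution
  s1 <- generate_noisy_session(gt, trials_per_cell = 3, noise = 1, seed = 7)
  s2 <- generate_noisy_session(gt, trials_per_cell = 3, noise = 1, seed = 8)
  expect_false(isTRUE(all.equal(s1$rates, s2$rates)))
  expect_equal(table(s1$trial_table$target_velocity, s1$trial_table$sector),
               table(s2$trial_table$target_velocity, s2$trial_table$sector))
  expect_true(all(s1$rates >= 0))
})

test_that("population recordings round-trip through the CSV serialization", {
  gt <- synth_ground_truth(c(gain = 2, pd_shift = 2), seed = 9)
  sess <- generate_noisy_session(gt, trials_per_cell = 1, noise = 1,
                                 n_bins = 4L, seed = 9)
  dir <- withr::local_tempdir()
  write_population_csv(sess, dir)
  back <- read_population_csv(dir)
  expect_equal(back$rates, sess$rates, tolerance = 1e-10)
  expect_equal(back$bin_width, sess$bin_width)
  expect_equal(back$trial_table$sector, sess$trial_table$sector)
  expect_equal(back$neuron_info$kind, sess$neuron_info$kind)
})
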