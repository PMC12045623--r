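test_that("Watson-Williams test agrees with ANOVA for concentrated samples and handles degeneracy", {
  set.seed(42)
  ## concentrated von-Mises-like samples: WW F should approach the linear
  ## ANOVA F on the (unwrapped) angles
  a <- rnorm(40, 0, 2) %% 360
  b <- (15 + rnorm(40, 0, 2)) %% 360
  ww <- watson_williams_test(c(a, b), rep(c("a", "b"), each = 40))
  au <- neurorbit:::ang_diff(a, 0); bu <- neurorbit:::ang_diff(b, 0)
  f_aov <- summary(aov(c(au, bu) ~ rep(c("a", "b"), each = 40)))[[1]]$F[1]
  expect_equal(ww$statistic, f_aov, tolerance = 0.05)
  expect_lt(ww$p.value, 1e-6)
  ## same distribution: no rejection at reasonable alpha
  ww0 <- watson_williams_test(c(a, a + 360), rep(c("a", "b"), each = 40))
  expect_gt(ww0$p.value, 0.99)
  ## degenerate zero-dispersion groups
  expect_equal(watson_williams_test(rep(c(10, 10), each = 5),
                                    rep(c("a", "b"), each = 5))$p.value, 1)
  expect_equal(watson_williams_test(rep(c(10, 60), each = 5),
                                    rep(c("a", "b"), each = 5))$p.value, 0)
  expect_error(watson_williams_test(1:3, c("a", "a", "b")), "at least 2")
})

test_that("tuning indices recover cosine tuning and flag degenerate cases", {
  th <- rep(sector_centers(), each = 5)
  sec <- rep(1:8, each = 5)
  rates <- cospi((th - 90) / 180) + 1
  ti <- tuning_indices(rates, sec)
  expect_equal(ti$pd, 90, tolerance = 1e-8)
  ## depth of cosine sampled at the 8 sector centers, by enumeration
  expect_equal(ti$depth,
               max(cospi((sector_centers() - 90) / 180)) -
                 min(cospi((sector_centers() - 90) / 180)))
  expect_equal(ti$offset, mean(rates))
  ## uniform rates: resultant vanishes, PD undefined
  tu <- tuning_indices(rep(2, 40), sec)
  expect_false(tu$pd_defined)
  expect_true(is.na(tu$pd))
  expect_error(tuning_indices(rates[sec != 3], sec[sec != 3]), "sector")
})

test_that("PSTH is flat for constant input and smoothing preserves the mean", {
  tt <- build_trial_table(trials_per_cell = 3, seed = 2)
  rates <- array(10, c(1, nrow(tt), 20))
  act <- population_activity(rates, tt, bin_width = 10, alignment = "MO",
                             bin_centers = seq(-95, 95, by = 10))
  p <- psth(act, 1, target_velocity = 0, sector = 1)
  expect_equal(p$rate, rep(10, 20))
  expect_equal(p$se, rep(0, 20))
  ## smoothing preserves the mean rate of a structured response
  set.seed(1)
  rates[1, , ] <- rates[1, , ] + matrix(rnorm(nrow(tt) * 20), nrow(tt), 20)
  act2 <- population_activity(pmax(rates, 0), tt, bin_width = 10,
                              alignment = "MO",
                              bin_centers = seq(-95, 95, by = 10))
  raw <- psth(act2, 1, 0, 1, kernel_sd = 0)
  smo <- psth(act2, 1, 0, 1, kernel_sd = 20)
  expect_equal(mean(smo$rate), mean(raw$rate), tolerance = 0.05)
  expect_lt(sd(diff(smo$rate)), sd(diff(raw$rate)))
  expect_error(psth(act, 1, target_velocity = 999), "no trials")
})

test_that("noiseless pure-kind neurons classify exactly as their generating flag", {
  sess <- fx_session(0)
  gt <- sess$neuron_info
  flag_of <- c(gain = "gain", pd_shift = "pd_shift", additive = "addition")
  for (j in seq_len(nrow(gt))) {
    l <- classify_modulation(sess, j, seed = 5)
    on <- c("gain", "pd_shift", "addition")[
      unlist(l[c("gain", "pd_shift", "addition")])]
    expect_identical(on, unname(flag_of[gt$kind[j]]),
                     label = paste("neuron", j, gt$kind[j]))
    expect_false(l$none)
  }
})

test_that("identical condition data yields no modulation flags", {
  ## endpoints at sector centers: every condition holds the same trials
  tt <- build_trial_table(trials_per_cell = 4, jitter = FALSE, seed = 3)
  set.seed(8)
  base <- cospi((tt$reach_endpoint_angle - 40) / 180) * 4 + 10
  rates <- array(rep(base, 8), c(1, nrow(tt), 8))
  act <- population_activity(rates, tt, bin_width = 25, alignment = "MO",
                             bin_centers = seq(-87.5, 87.5, by = 25))
  l <- classify_modulation(act, 1, seed = 4)
  expect_false(l$pd_shift); expect_false(l$gain); expect_false(l$addition)
  expect_true(l$direction_tuned)
  expect_false(l$none)
})

test_that("tuning-model fits recover generating parameters and respect nesting", {
  tt <- build_trial_table(trials_per_cell = 6, seed = 11)
  th <- tt$reach_endpoint_angle; vel <- tt$target_velocity
  vc <- vel / 120
  ## data generated exactly from the gain model
  y <- (5 / (1 + exp(-1.2 * vc)) + 3) * cospi((th - 130) / 180) + 12
  fit <- fit_tuning_model(y, th, vel, "gain")
  expect_true(fit$converged)
  expect_equal(fit$r2, 1, tolerance = 1e-6)
  cf <- coef(fit)
  expect_equal(unname(cf["th_pd"]), 130, tolerance = 0.1)
  expect_equal(unname(cf["c1"]), 12, tolerance = 0.01)
  expect_equal(predict(fit, data.frame(theta = 130, vel = 0)),
               5 / (1 + exp(0)) + 3 + 12, tolerance = 1e-3)
  ## with noise: r2_adj below the unadjusted r2 of the containing model
  set.seed(12)
  yn <- y + rnorm(length(y), 0, 2)
  fits <- lapply(c("simple", "gain", "full"), function(m)
    fit_tuning_model(yn, th, vel, m))
  names(fits) <- c("simple", "gain", "full")
  expect_lte(fits$simple$r2_adj, fits$full$r2 + 1e-8)
  expect_lte(fits$gain$r2_adj, fits$gain$r2)
  ## simple cosine data: the full model keeps up, up to the df penalty
  y0 <- 4 * cospi((th - 45) / 180) + 9
  f_simple <- fit_tuning_model(y0, th, vel, "simple")
  f_full <- fit_tuning_model(y0, th, vel, "full")
  expect_gte(f_full$r2_adj, f_simple$r2_adj - 0.02)
  expect_error(fit_tuning_model(y[1:5], th[1:5], vel[1:5], "gain"),
               "at least")
})

test_that("PD estimates are equivariant under rotation of endpoint angles", {
  tt <- build_trial_table(trials_per_cell = 6, seed = 13)
  th <- tt$reach_endpoint_angle
  set.seed(14)
  y <- 5 * cospi((th - 200) / 180) + 10 + rnorm(nrow(tt), 0, 0.5)
  f0 <- fit_tuning_model(y, th, tt$target_velocity, "simple")
  f1 <- fit_tuning_model(y, th + 70, tt$target_velocity, "simple")
  d <- neurorbit:::ang_diff(coef(f1)[["th_pd"]], coef(f0)[["th_pd"]])
  expect_equal(abs(d), 70, tolerance = 0.5)
})

test_that("model comparison ranks families and is order-invariant", {
  set.seed(15)
  ## identical fit quality: p near 0.5
  x <- runif(60, 0.4, 0.6)
  cmp <- compare_models(list(a = x, b = sample(x)))
  expect_gt(cmp$p_greater["a", "b"], 0.2)
  expect_lt(cmp$p_greater["a", "b"], 0.8)
  ## clearly better family: one-tailed rank-sum significant
  cmp2 <- compare_models(list(full = x + 0.2, simple = x))
  expect_lt(cmp2$p_greater["full", "simple"], 0.01)
  expect_identical(cmp2$ranking[1], "full")
  cmp3 <- compare_models(list(full = rev(x + 0.2), simple = rev(x)))
  expect_equal(cmp2$p_greater, cmp3$p_greater)
})
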