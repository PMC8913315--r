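test_that("mm_velocity evaluates the rate law", {
  expect_equal(mm_velocity(1.81, 30.2e-9, 0.90e-3, 0), 0)
  expect_equal(mm_velocity(1.81, 30.2e-9, 0.90e-3, 0.90e-3),
               1.81 * 30.2e-9 / 2)
  expect_equal(mm_velocity(1.81, 30.2e-9, 0.90e-3, 5e-3), 4.632373e-8,
               tolerance = 1e-6)
  expect_error(mm_velocity(1.81, 30.2e-9, 0, 1e-3),
               class = "xk_invalid_argument")
})

test_that("noiseless data of >= 3 concentrations is recovered exactly", {
  set.seed(17)
  for (i in 1:20) {
    kcat <- runif(1, 0.1, 10)
    km <- 10^runif(1, -5, -2)
    params <- true_parameters(kcat, km)
    cfg <- assay_config(enzyme_conc = 30.2e-9, substrate_dp = 2)
    d <- simulate_rates(params, cfg, replicates = 1,
                        noise = noise_model("none"))
    f <- fit_mm(d)
    expect_true(f$converged)
    expect_lt(abs(f$kcat - kcat) / kcat, 1e-6)
    expect_lt(abs(f$km - km) / km, 1e-6)
  }
})

test_that("fitting requires at least 3 distinct concentrations", {
  cfg <- default_pc_config()
  pts <- data.frame(substrate_conc = rep(c(1e-4, 1e-3), each = 3),
                    velocity = rep(c(1e-9, 5e-9), each = 3),
                    replicate = rep(1:3, 2))
  d <- rate_dataset("x", 2, cfg, pts)
  expect_error(fit_mm(d), class = "xk_insufficient_data")
})

test_that("fitting without an assay configuration is a configuration error", {
  pts <- data.frame(substrate_conc = c(1e-4, 5e-4, 1e-3),
                    velocity = c(1e-9, 3e-9, 5e-9), replicate = 1)
  d <- rate_dataset("x", 2, NULL, pts)
  expect_error(fit_mm(d), class = "xk_config_error")
})

test_that("fitted parameters are invariant to a common velocity/enzyme rescaling", {
  params <- true_parameters(0.82, 70e-6, "TrXyl3A")
  d <- simulate_rates(params, default_tr_config(4),
                      noise = noise_model("multiplicative", 0.03, seed = 2))
  f <- fit_mm(d)
  scaled <- rate_dataset(d$enzyme_label, d$dp,
                         assay_config(enzyme_conc = 26.6e-9 * 1000,
                                      substrate_dp = 4),
                         transform(d$points, velocity = velocity * 1000))
  f_scaled <- fit_mm(scaled)
  expect_equal(f_scaled$kcat, f$kcat, tolerance = 1e-8)
  expect_equal(f_scaled$km, f$km, tolerance = 1e-8)
})

test_that("relative weighting and explicit starts are accepted", {
  params <- true_parameters(0.82, 70e-6)
  d <- simulate_rates(params, default_tr_config(4),
                      noise = noise_model("multiplicative", 0.03, seed = 9))
  f_rel <- fit_mm(d, weighting = "relative")
  expect_true(f_rel$converged)
  expect_lt(abs(f_rel$kcat - 0.82) / 0.82, 0.15)
  f_exp <- fit_mm(d, init = "explicit", start = list(kcat = 1, km = 1e-4))
  expect_true(f_exp$converged)
  expect_equal(f_exp$kcat, fit_mm(d)$kcat, tolerance = 1e-6)
  expect_error(fit_mm(d, init = "explicit"), class = "xk_invalid_argument")
})

test_that("estimation bias shrinks as noise goes to zero", {
  params <- true_parameters(0.82, 70e-6)
  cfg <- default_tr_config(4)
  mean_abs_err <- vapply(c(0.10, 0.03, 0.005), function(cv) {
    errs <- vapply(1:60, function(i) {
      f <- fit_mm(simulate_rates(params, cfg,
                                 noise = noise_model("multiplicative", cv,
                                                     seed = 1000 + i)))
      abs(f$kcat - 0.82) / 0.82
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_true(all(diff(mean_abs_err) < 0))
})

test_that("specificity constant and delta-method SE match the closed form", {
  f <- mm_fit(kcat = 1.81, kcat_se = 0.05, km = 0.90e-3, km_se = 0.06e-3)
  sp <- specificity_constant(f)
  expect_equal(sp$value, 1.81 / 0.90e-3)
  # delta method: value * sqrt((0.05/1.81)^2 + (0.06/0.90)^2)
  expect_equal(sp$se * 1e-3, 0.1451285, tolerance = 1e-6)
  # published-table anchors at 2 significant figures (mM^-1 s^-1)
  expect_equal(round_report(sp$value * 1e-3, 2), 2.0)
  f2 <- mm_fit(kcat = 0.39, kcat_se = 0.01, km = 24e-6, km_se = 5e-6)
  expect_equal(round_report(specificity_constant(f2)$value * 1e-3, 2), 16)
  # the mm_fit invariant: stored specificity equals kcat/km for fits
  expect_equal(f$specificity, f$kcat / f$km, tolerance = 1e-13)
})

test_that("report rounding is round-half-even to significant figures", {
  expect_equal(round_report(16.25, 2), 16)
  expect_equal(round_report(2.011, 2), 2.0)
  expect_equal(round_report(0.8821, 1), 0.9)
  expect_equal(round_report(c(1.4444, 8.55), 2), c(1.4, 8.6))
  expect_error(round_report(1, 0), class = "xk_invalid_argument")
})

test_that("kinetic series require consecutive DPs starting at 2", {
  f <- mm_fit(1, 0.1, 1e-4, 1e-5)
  expect_silent(kinetic_series("x", list(`2` = f, `3` = f)))
  expect_error(kinetic_series("x", list(`3` = f, `4` = f)),
               class = "xk_invalid_argument")
  expect_error(kinetic_series("x", list(`2` = f, `4` = f)),
               class = "xk_invalid_argument")
  s <- kinetic_series("x", list(`2` = f))
  expect_equal(select_k_int(s), 1.0)
})

test_that("a kinetic series tabulates in reporting units", {
  tab <- as.data.frame(pc_series())
  expect_equal(tab$dp, 2:5)
  expect_equal(tab$kcat_per_s, c(1.81, 1.80, 2.05, 1.66))
  expect_equal(tab$km_mM, c(0.90, 1.14, 0.74, 1.21))
  expect_equal(tab$spec_mM_s, c(2.0, 1.6, 2.8, 1.4))
})

test_that("seeded noisy datasets from published parameters are recovered on average", {
  # TrXyl3A / X4 generating parameters; mean fitted kcat over seeded
  # replicates matches the generator truth (0.82 1/s)
  params <- true_parameters(0.82, 70e-6, "TrXyl3A")
  cfg <- default_tr_config(4)
  kcats <- vapply(1:200, function(i) {
    fit_mm(simulate_rates(params, cfg,
                          noise = noise_model("multiplicative", 0.03,
                                              seed = i)))$kcat
  }, numeric(1))
  expect_equal(mean(kcats), 0.82, tolerance = 0.02)
})
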