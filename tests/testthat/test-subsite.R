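ctx <- thermo_context()

test_that("thermo context derives RT and validates constants", {
  expect_equal(ctx$rt, 1.9872e-3 * 303.15)
  expect_equal(ctx$c_w, 0.018)
  expect_error(thermo_context(temperature = -1),
               class = "xk_invalid_argument")
  expect_error(thermo_context(c_w = 0), class = "xk_invalid_argument")
})

test_that("k_int is the maximum kcat across chain lengths", {
  expect_equal(select_k_int(pc_series()), 2.05)
  expect_equal(select_k_int(tr_series()), 0.82)
})

test_that("plus-subsite affinities follow RT ln of the specificity ratio", {
  # TrXyl3A subsite +2 from the published kcat/KM values (16 vs 3.7):
  # the 'typical' ~1 kcal/mol subsite
  a_tr2 <- plus_subsite_affinity(tr_series(), 2, ctx)
  expect_equal(a_tr2, 0.8820966, tolerance = 1e-6)
  expect_equal(round(a_tr2), 1)
  # PcBxl3 subsite +2 is essentially empty
  expect_equal(plus_subsite_affinity(pc_series(), 2, ctx), -0.1344261,
               tolerance = 1e-6)
  # equal specificity constants at adjacent DPs: zero affinity
  s_flat <- series_from_specificities(c(2000, 2000))
  expect_equal(plus_subsite_affinity(s_flat, 2, ctx), 0)
  # missing DP
  expect_error(plus_subsite_affinity(tr_series(), 5, ctx),
               class = "xk_missing_data")
})

test_that("affinity from ratio r is the negative of affinity from 1/r", {
  set.seed(31)
  for (i in 1:10) {
    r <- 10^runif(1, -2, 2)
    s_up <- series_from_specificities(c(1000, 1000 * r))
    s_down <- series_from_specificities(c(1000, 1000 / r))
    expect_equal(plus_subsite_affinity(s_up, 2, ctx),
                 -plus_subsite_affinity(s_down, 2, ctx), tolerance = 1e-12)
  }
})

test_that("affinities do not depend on the specificity-constant unit", {
  # scaling every specificity by 1000 (mM <-> M carrying) changes nothing
  s1 <- series_from_specificities(c(3700, 16000, 12000, 8500))
  s2 <- series_from_specificities(c(3.7, 16, 12, 8.5))
  for (n in 2:4)
    expect_equal(plus_subsite_affinity(s1, n, ctx),
                 plus_subsite_affinity(s2, n, ctx), tolerance = 1e-12)
})

test_that("affinity grows linearly with temperature for a fixed ratio > 1", {
  s <- series_from_specificities(c(1000, 4000))
  temps <- c(283.15, 303.15, 323.15)
  a <- vapply(temps, function(T)
    plus_subsite_affinity(s, 2, thermo_context(temperature = T)), numeric(1))
  expect_true(all(diff(a) > 0))
  expect_equal(a / temps, rep(1.9872e-3 * log(4), 3), tolerance = 1e-12)
})

test_that("active-center affinity sum matches the closed form", {
  expect_equal(active_center_affinity(tr_series(), context = ctx),
               7.489235, tolerance = 1e-6)
  expect_equal(active_center_affinity(pc_series(), context = ctx),
               6.566643, tolerance = 1e-6)
  # the inter-enzyme difference is ~0.9 kcal/mol and convention-free:
  # recomputing with c_w = 1 must give the identical difference
  for (cw in c(0.018, 1.0)) {
    cx <- thermo_context(c_w = cw)
    d <- active_center_affinity(tr_series(), context = cx) -
      active_center_affinity(pc_series(), context = cx)
    expect_equal(d, 0.9225915, tolerance = 1e-6)
  }
})

test_that("profiles collect k_int, the active-center sum and plus subsites", {
  p_pc <- build_profile(pc_series(), ctx)
  p_tr <- build_profile(tr_series(), ctx)
  expect_equal(p_pc$k_int, 2.05)
  expect_equal(unname(p_pc$plus_affinities),
               c(-0.1344261, 0.3371236, -0.4175655), tolerance = 1e-6)
  expect_equal(names(p_pc$plus_affinities), c("+2", "+3", "+4"))
  expect_equal(unname(p_tr$plus_affinities),
               c(0.8820966, -0.1733053, -0.2077387), tolerance = 1e-6)
  # single-DP series: active center defined, no plus subsites
  s2 <- kinetic_series("x", list(`2` = mm_fit(1, 0.1, 1e-3, 1e-4)))
  p2 <- build_profile(s2, ctx)
  expect_length(p2$plus_affinities, 0)
  expect_true(is.finite(p2$active_center_affinity))
  expect_equal(count_subsites(p2), 2L)
})

test_that("reconstruction telescopes back to every input specificity", {
  for (series in list(pc_series(), tr_series())) {
    profile <- build_profile(series, ctx)
    for (n in 2:5) {
      ks <- series$fits[[as.character(n)]]$specificity
      expect_equal(reconstruct_specificity(profile, n), ks,
                   tolerance = 1e-10)
    }
  }
  # property: random series reconstruct too
  set.seed(8)
  for (i in 1:10) {
    specs <- 10^runif(4, 2, 5)
    s <- series_from_specificities(specs, kcats = runif(4, 0.1, 5))
    profile <- build_profile(s, ctx)
    for (n in 2:5)
      expect_equal(reconstruct_specificity(profile, n), specs[n - 1],
                   tolerance = 1e-10)
  }
  expect_error(reconstruct_specificity(build_profile(pc_series(), ctx), 6),
               class = "xk_invalid_argument")
})

test_that("subsite counting is contiguous from the active center", {
  expect_equal(count_subsites(build_profile(pc_series(), ctx)), 2L)
  expect_equal(count_subsites(build_profile(tr_series(), ctx)), 3L)
  # a strong subsite past a gap does not count
  s_gap <- series_from_specificities(c(1000, 500, 5000, 10000))
  expect_equal(count_subsites(build_profile(s_gap, ctx)), 2L)
  s_run <- series_from_specificities(c(1000, 3000, 9000, 9500))
  expect_equal(count_subsites(build_profile(s_run, ctx), threshold = 0.4),
               4L)
})

test_that("bootstrap affinity uncertainty matches the delta-method scale", {
  # zero standard errors give zero uncertainty
  rows <- table2_values()
  s0 <- series_from_table("TrXyl3A")
  s0$fits <- lapply(s0$fits, function(f) {
    f$kcat_se <- 0; f$km_se <- 0; f
  })
  expect_equal(affinity_uncertainty(s0, 2, ctx, n_boot = 200, seed = 1), 0)
  # determinism
  se_a <- affinity_uncertainty(tr_series(), 2, ctx, n_boot = 500, seed = 4)
  se_b <- affinity_uncertainty(tr_series(), 2, ctx, n_boot = 500, seed = 4)
  expect_identical(se_a, se_b)
  # delta-method oracle: RT * sqrt(sum of the four relative variances)
  # = 0.6024 * sqrt((0.01/0.39)^2 + (5/24)^2 + (0.01/0.34)^2 + (10/90)^2)
  se <- affinity_uncertainty(tr_series(), 2, ctx, n_boot = 10000, seed = 2)
  expect_equal(se, 0.1441672, tolerance = 0.10)
  # missing SEs signal
  s_na <- series_from_specificities(c(1000, 2000))
  expect_error(affinity_uncertainty(s_na, 2, ctx, n_boot = 200, seed = 1),
               class = "xk_missing_data")
})
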