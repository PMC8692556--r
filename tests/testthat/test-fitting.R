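test_that("objective and AARD are linked by the N/100 identity", {
  expect_equal(objective_rel(c(1, 2), c(1, 2)), 0)
  expect_equal(objective_rel(2e-6, 1e-6), 0.5)
  expect_equal(aard_percent(2e-6, 1.8e-6), 10)
  set.seed(3)
  ye <- runif(30, 1e-6, 1e-5); yc <- ye * runif(30, 0.5, 1.5)
  expect_equal(aard_percent(ye, yc), 100 * objective_rel(ye, yc) / 30,
               tolerance = 1e-12)
  # permutation invariance
  p <- sample(30)
  expect_equal(aard_percent(ye[p], yc[p]), aard_percent(ye, yc))
  expect_error(objective_rel(1:3, 1:4), "length")
  expect_error(objective_rel(c(1, 0), c(1, 1)), "positive")
})

test_that("information criteria follow the literal small-sample formulas", {
  expect_equal(aic(24, 24, 0), 0)
  # AICc - AIC offsets at N = 24 for the parameter counts in play
  expect_equal(aicc(1e-11, 24, 3) - aic(1e-11, 24, 3), 1.2)
  expect_equal(aicc(1e-11, 24, 4) - aic(1e-11, 24, 4), 40 / 19)
  expect_equal(aicc(1e-11, 24, 5) - aic(1e-11, 24, 5), 60 / 18)
  expect_equal(aicc(1e-11, 24, 6) - aic(1e-11, 24, 6), 84 / 17)
  # correction vanishes in the large-sample limit
  expect_equal(aicc(1, 1e6, 3), aic(1, 1e6, 3), tolerance = 1e-2)
  expect_error(aicc(1, 4, 3), "n > n_params")
  expect_error(aic(0, 24, 3), "positive")
})

test_that("AICc ranking penalises parameters and is order-invariant", {
  d <- fixture_data()
  mk <- function(id, np, sse_scale) {
    y_cal <- d$y2 * (1 + sse_scale * rep(c(0.1, -0.1), 12))
    sccosol:::new_fit_result(id, seq_len(np), d, y_cal, np)
  }
  # equal SSE, 3 vs 6 parameters: the leaner model wins
  r <- rank_models(list(mk("six", 6L, 1), mk("three", 3L, 1)))
  expect_equal(r$model_id[1], "three")
  # permutation of the input list leaves the ranking unchanged
  fits <- list(mk("a", 3L, 1), mk("b", 6L, 0.3), mk("c", 5L, 0.8))
  expect_equal(rank_models(fits)$model_id,
               rank_models(rev(fits))$model_id)
  expect_error(rank_models(fits[1]), "at least two")
})

test_that("refits rank the flexible polynomial above Chrastil by AICc", {
  fits <- study_fits()
  r <- rank_models(list(fits$chrastil, fits$reddy_garlapati))
  expect_equal(r$model_id[1], "reddy_garlapati")
})

test_that("enthalpy bookkeeping matches the printed thermodynamic summary", {
  rep <- enthalpy_report(-4907.2, -4216.6, -7179.9, table5_coeffs(), 323)
  get <- function(tm, sm, col) rep[[col]][rep$total_model == tm & rep$sub_model == sm]
  expect_equal(get("chrastil", "bartle", "dH_total_kJ_mol"), 40.798,
               tolerance = 1e-4)
  expect_equal(get("ref_chrastil", "bartle", "dH_total_kJ_mol"), 35.056,
               tolerance = 1e-4)
  expect_equal(get("chrastil", "bartle", "dH_sub_kJ_mol"), 59.694,
               tolerance = 1e-4)
  expect_equal(get("chrastil", "bartle", "dH_solv_kJ_mol"), -18.896,
               tolerance = 1e-4)
  expect_equal(get("chrastil", "eos", "dH_sub_kJ_mol"), 28.516,
               tolerance = 1e-4)
  # the solvation column is exactly total minus sublimation
  expect_equal(rep$dH_solv_kJ_mol, rep$dH_total_kJ_mol - rep$dH_sub_kJ_mol,
               tolerance = 1e-9)
  expect_equal(enthalpy_report(0, -1, -1)$dH_total_kJ_mol[1], 0)
})

test_that("regression is reproducible and recovers known Chrastil constants", {
  p0 <- c(3.0938, -11.003, -4907.2)
  synth <- generate_synthetic("chrastil", p0, noise_rel = 0)
  fit <- fit_density_model(synth, "chrastil", n_starts = 8, seed = 123)
  expect_lt(max(abs((fit$params - p0) / p0)), 1e-3)
  expect_lt(fit$aard_percent, 1e-4)
  # identical seed, identical result
  fit2 <- fit_density_model(synth, "chrastil", n_starts = 8, seed = 123)
  expect_identical(fit$params, fit2$params)
})

test_that("fit results expose tidy/glance views and isotherm plots", {
  d <- fixture_data()
  fit <- evaluate_density(d, "chrastil", c(3.0938, -11.003, -4907.2))
  td <- tidy(fit)
  expect_equal(td$term, c("kappa", "E1", "E2"))
  expect_equal(td$estimate[3], -4907.2)
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("aard_percent", "aicc", "n_params") %in% names(gl)))
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(plot_mt_consistency(d, c(-8479.4, 1.9629, 14.617)), "ggplot")
})
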