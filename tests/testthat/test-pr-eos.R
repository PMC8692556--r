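test_that("pure-component parameters follow the PR-1976 prescription", {
  p <- pr_pure(304.18, co2())
  expect_equal(p$a, 0.45724 * 8.314^2 * 304.18^2 / 7.38e6, tolerance = 1e-10)
  expect_equal(p$b, 0.07780 * 8.314 * 304.18 / 7.38e6, tolerance = 1e-10)

  # alpha(Tr = 1) = 1 for any omega, exactly 1 when omega = 0
  sp0 <- component_spec(44, 300, 5, 0)
  expect_equal(pr_pure(300, sp0)$a, 0.45724 * 8.314^2 * 300^2 / 5e6,
               tolerance = 1e-12)

  # a decreases with T in the subcritical branch (finite difference at Tr=0.9)
  Tq <- 0.9 * 304.18
  da <- (pr_pure(Tq + 0.01, co2())$a - pr_pure(Tq - 0.01, co2())$a) / 0.02
  expect_lt(da, 0)
})

test_that("vdW2 mixing reduces correctly and matches derivative oracles", {
  a <- c(5.0, 0.396); b <- c(4e-4, 2.67e-5)
  m <- pr_mix_vdw2(c(1, 0), a, b, kij = 0.3, lij = 0.2)
  expect_equal(m$a, a[1]); expect_equal(m$b, b[1])

  # identical species: mixture equals pure at any composition
  m2 <- pr_mix_vdw2(c(0.3, 0.7), c(0.4, 0.4), c(3e-5, 3e-5))
  expect_equal(m2$a, 0.4, tolerance = 1e-12)
  expect_equal(m2$b, 3e-5, tolerance = 1e-12)

  expect_error(pr_mix_vdw2(c(0.5, 0.6), a, b), "sum to 1")

  # a_hat_i = (1/n) d(n^2 a)/dn_i and b_hat_i = d(nb)/dn_i by central diff
  x <- c(0.35, 0.65); kij <- 0.25; lij <- -0.1
  mm <- pr_mix_vdw2(x, a, b, kij, lij)
  h <- 1e-6
  for (i in 1:2) {
    np <- x; nm <- x
    np[i] <- x[i] + h; nm[i] <- x[i] - h
    f2a <- function(nv) sum(nv)^2 * pr_mix_vdw2(nv / sum(nv), a, b, kij, lij)$a
    fnb <- function(nv) sum(nv) * pr_mix_vdw2(nv / sum(nv), a, b, kij, lij)$b
    expect_equal(mm$a_hat[i], (f2a(np) - f2a(nm)) / (2 * h), tolerance = 1e-6)
    expect_equal(mm$b_hat[i], (fnb(np) - fnb(nm)) / (2 * h), tolerance = 1e-6)
  }
})

test_that("compressibility roots honour limits and track the measured density loosely", {
  p <- pr_pure(320, co2())
  expect_equal(pr_solve_z(320, 1, p$a, p$b), 1, tolerance = 1e-6)
  expect_equal(pr_solve_z(320, 1e7, 0, 0), 1, tolerance = 1e-12)

  d <- fixture_data()
  z_pr <- mapply(function(Tk, P) {
    pp <- pr_pure(Tk, co2())
    pr_solve_z(Tk, P * 1e6, pp$a, pp$b)
  }, d$T_K, d$P_MPa)
  z_dat <- d$P_MPa * 1e6 * 44.01e-3 / (d$rho_kg_m3 * 8.314 * d$T_K)
  expect_true(all(abs(z_pr - z_dat) / z_dat < 0.10))
})

test_that("pure fugacity coefficient matches the (Z-1)/P quadrature", {
  expect_equal(pr_phi_pure(320, 1, co2()), 1, tolerance = 1e-6)

  p <- pr_pure(318, co2())
  lnphi_quad <- stats::integrate(function(P) {
    vapply(P, function(pp) (pr_solve_z(318, pp, p$a, p$b) - 1) / pp,
           numeric(1))
  }, 1e-3, 7.38e6, rel.tol = 1e-10, subdivisions = 500L)$value
  expect_equal(log(pr_phi_pure(318, 7.38e6, co2())), lnphi_quad,
               tolerance = 1e-4)
})

test_that("mixture fugacity coefficients reduce to the pure limit", {
  aa <- c(pr_pure(318, clemastine())$a, pr_pure(318, co2())$a)
  bb <- c(pr_pure(318, clemastine())$b, pr_pure(318, co2())$b)
  phi <- pr_phi_mixture(c(0, 1), 318, 15e6, aa, bb, kij = 0.4, lij = 0.3)
  expect_equal(phi[2], pr_phi_pure(318, 15e6, co2()), tolerance = 1e-10)
  expect_equal(pr_phi_mixture(c(0.3, 0.7), 318, 1, aa, bb),
               c(1, 1), tolerance = 1e-5)
})

test_that("mixture fugacity coefficients match the partial-derivative oracle", {
  aa <- c(pr_pure(320, clemastine())$a, pr_pure(320, co2())$a)
  bb <- c(pr_pure(320, clemastine())$b, pr_pure(320, co2())$b)
  states <- random_binary_states(50, seed = 7)
  for (k in seq_len(nrow(states))) {
    st <- states[k, ]
    x <- c(st$x1, 1 - st$x1)
    lnphi <- log(pr_phi_mixture(x, 320, st$P_MPa * 1e6, aa, bb,
                                st$kij, st$lij))
    for (i in 1:2) {
      lo <- lnphi_oracle(i, x, 320, st$P_MPa * 1e6, aa, bb, st$kij, st$lij)
      expect_equal(lnphi[i], lo, tolerance = 1e-4)
    }
  }
})

test_that("Gibbs-Duhem holds along composition perturbations", {
  aa <- c(pr_pure(330, clemastine())$a, pr_pure(330, co2())$a)
  bb <- c(pr_pure(330, clemastine())$b, pr_pure(330, co2())$b)
  for (x1 in c(0.1, 0.3, 0.5)) {
    h <- 1e-6
    lp <- log(pr_phi_mixture(c(x1 + h, 1 - x1 - h), 330, 20e6, aa, bb, 0.3, 0.2))
    lm <- log(pr_phi_mixture(c(x1 - h, 1 - x1 + h), 330, 20e6, aa, bb, 0.3, 0.2))
    d_lnphi <- (lp - lm) / (2 * h)
    expect_lt(abs(sum(c(x1, 1 - x1) * d_lnphi)) / max(abs(d_lnphi)), 1e-6)
  }
})

test_that("sublimation-pressure form and its enthalpy behave as printed", {
  cfs <- table5_coeffs()
  # at 298.15 K the log term vanishes
  expect_equal(psub_from_coeffs(298.15, cfs),
               exp(cfs$beta_over_R + cfs$gamma_over_R / 298.15),
               tolerance = 1e-12)
  expect_equal(psub_from_coeffs(298.15, cfs), 0.626, tolerance = 1e-3)
  # monotone increasing over the experimental range
  ps <- psub_from_coeffs(seq(300, 340, by = 2), cfs)
  expect_true(all(diff(ps) > 0))

  # enthalpy conventions
  c0 <- list(beta_over_R = 0, gamma_over_R = -100, dsubdelta_over_R = 0)
  expect_equal(dhsub_eos(c0, 323), -100 * 8.314)
  expect_equal(dhsub_eos(c0, 323, literal = TRUE), 100 * 8.314)
  expect_equal(dhsub_eos(cfs, 323) / 1000, 28.516, tolerance = 1e-4)
  # linear in T
  expect_equal(dhsub_eos(cfs, 323),
               mean(c(dhsub_eos(cfs, 308), dhsub_eos(cfs, 338))))
})

test_that("EoS solubility is monotone in sublimation pressure and matches the printed chain", {
  cle <- clemastine(); sol <- co2()
  ys <- vapply(c(0.01, 0.05, 0.2), function(ps) {
    y2_pr_eos(308, 27e6, cle, sol, 0.79788, 0.74029, ps)
  }, numeric(1))
  expect_true(all(diff(ys) > 0))

  # full chain with the published temperature-independent constants
  ps308 <- psub_from_coeffs(308, table5_coeffs())
  y <- y2_pr_eos(308, 27e6, cle, sol, 0.79788, 0.74029, ps308)
  expect_gt(y, 5.1e-6 / 1.3)
  expect_lt(y, 5.1e-6 * 1.3)

  expect_error(y2_pr_eos(308, 1e4, cle, sol, 0.5, 0.5, 2e4), "below P")
})

test_that("EoS regression recovers known interaction parameters from clean data", {
  cle <- clemastine(); sol <- co2()
  grid <- fixture_data()[, c("T_K", "P_MPa", "rho_kg_m3")]
  psub <- psub_from_coeffs(grid$T_K, table5_coeffs())
  y0 <- sccosol:::.eos_y2_all(grid, cle, sol, 0.6, 0.55, psub)
  synth <- grid
  synth$y2 <- y0
  fit <- fit_pr_eos(synth, cle, sol, mode = "t_dependent",
                    psub_table = setNames(
                      psub_from_coeffs(unique(grid$T_K), table5_coeffs()),
                      unique(grid$T_K)), n_starts = 6)
  expect_lt(max(abs(fit$per_isotherm$kij - 0.6)), 1e-3)
  expect_lt(max(abs(fit$per_isotherm$lij - 0.55)), 1e-3)
  expect_lt(fit$aard_percent, 0.01)
})
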