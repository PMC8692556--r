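# Shared fixtures and independent numerical oracles.

R_GAS <- 8.314

fixture_data <- function() clemastine_table2()
clemastine <- function() component_clemastine()
co2 <- function() component_co2()

table5_coeffs <- function() {
  list(beta_over_R = 0.27409, gamma_over_R = -221.54,
       dsubdelta_over_R = 11.305)
}

# Independent fugacity-coefficient oracle: the partial-molar-volume route,
# ln phi_i = (1/RT) * int_V^inf [dP/dN_i - RT/V] dV - ln Z, with dP/dN_i by
# central differencing of the total-pressure function at fixed T, V.
lnphi_oracle <- function(i, x, T_K, P_Pa, a, b, kij = 0, lij = 0) {
  mix <- pr_mix_vdw2(x, a, b, kij, lij)
  Z <- pr_solve_z(T_K, P_Pa, mix$a, mix$b)
  V0 <- Z * R_GAS * T_K / P_Pa   # total volume for 1 mol
  p_total <- function(N, Vt) {
    Ntot <- sum(N)
    m <- pr_mix_vdw2(N / Ntot, a, b, kij, lij)
    vm <- Vt / Ntot
    R_GAS * T_K / (vm - m$b) - m$a / (vm^2 + 2 * m$b * vm - m$b^2)
  }
  h <- 1e-6
  integrand <- function(Vt) {
    vapply(Vt, function(vv) {
      Np <- x; Nm <- x
      Np[i] <- x[i] + h; Nm[i] <- x[i] - h
      (p_total(Np, vv) - p_total(Nm, vv)) / (2 * h) - R_GAS * T_K / vv
    }, numeric(1))
  }
  # map V in [V0, Inf) to u in (0, 1] via V = V0/u; the integrand decays
  # like 1/V^2 so the transformed integrand is bounded near u = 0
  I <- stats::integrate(function(u) integrand(V0 / u) * V0 / u^2,
                        0, 1, rel.tol = 1e-9, subdivisions = 500L)$value
  I / (R_GAS * T_K) - log(Z)
}

# Random supercritical binary states (heavy solute + CO2-like solvent).
random_binary_states <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(
    T_K = runif(n, 305, 350),
    P_MPa = runif(n, 9, 30),
    x1 = runif(n, 0.02, 0.6),
    kij = runif(n, -0.2, 0.8),
    lij = runif(n, -0.2, 0.8)
  )
}

# The five study-condition refits are expensive; compute once per run.
.fit_cache <- new.env(parent = emptyenv())
study_fits <- function() {
  if (!exists("fits", envir = .fit_cache)) {
    d <- fixture_data()
    .fit_cache$fits <- list(
      chrastil = fit_density_model(d, "chrastil"),
      reddy_garlapati = fit_density_model(d, "reddy_garlapati"),
      cluster_new = fit_cluster(d, "new"),
      cluster_chen = fit_cluster(d, "chen"),
      eos = fit_pr_eos(d, mode = "t_independent")
    )
  }
  .fit_cache$fits
}
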