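#' Relative-deviation objective and AARD
#'
#' `objective_rel()` is the regression objective used throughout the package,
#' OF = sum_i |y_exp_i - y_cal_i| / y_exp_i. `aard_percent()` is the same
#' quantity expressed as a percentage per point, 100 * OF / N.
#'
#' @param y_exp,y_cal equal-length numeric vectors; `y_exp` strictly positive.
#' @return A scalar.
#' @export
objective_rel <- function(y_exp, y_cal) {
  if (length(y_exp) != length(y_cal)) abort("length mismatch")
  if (any(y_exp <= 0)) abort("experimental values must be positive")
  sum(abs(y_exp - y_cal) / y_exp)
}

#' @rdname objective_rel
#' @export
aard_percent <- function(y_exp, y_cal) {
  100 * objective_rel(y_exp, y_cal) / length(y_exp)
}

#' Akaike information criterion and its small-sample correction
#'
#' AIC = N ln(SSE/N) + 2 Np; AICc = AIC + 2 Np (Np + 1) / (N - Np - 1),
#' with SSE the raw squared-error sum on mole fractions.
#'
#' @param sse squared-error sum (> 0).
#' @param n number of data points.
#' @param n_params number of fitted parameters.
#' @return A scalar.
#' @export
aic <- function(sse, n, n_params) {
  if (sse <= 0) abort("sse must be positive")
  n * log(sse / n) + 2 * n_params
}

#' @rdname aic
#' @export
aicc <- function(sse, n, n_params) {
  if (n <= n_params + 1) abort("AICc requires n > n_params + 1")
  aic(sse, n, n_params) + 2 * n_params * (n_params + 1) / (n - n_params - 1)
}

# Assemble the standard fit-result object from observed/calculated vectors.
new_fit_result <- function(model_id, params, data, y_cal, n_params,
                           seed = NA_integer_, extra = list()) {
  y <- data$y2
  sse <- sum((y - y_cal)^2)
  res <- list(
    model_id = model_id,
    params = params,
    aard_percent = aard_percent(y, y_cal),
    sse = sse,
    r2 = 1 - sse / sum((y - mean(y))^2),
    aic = aic(sse, length(y), n_params),
    aicc = aicc(sse, length(y), n_params),
    n_points = length(y),
    n_params = n_params,
    seed = seed,
    data = tibble::as_tibble(data),
    y_cal = y_cal
  )
  structure(modifyList(res, extra), class = "sccosol_fit")
}

#' @export
print.sccosol_fit <- function(x, ...) {
  cat(sprintf("<sccosol_fit> %s: %d parameters, %d points\n",
              x$model_id, x$n_params, x$n_points))
  cat("  params:", paste(signif(unlist(x$params), 6), collapse = ", "), "\n")
  cat(sprintf("  AARD = %.3f%%, R2 = %.4f, AICc = %.2f\n",
              x$aard_percent, x$r2, x$aicc))
  invisible(x)
}

# Seeded multistart wrapper around Nelder-Mead with optional box penalty.
.multistart <- function(of, starts, lower = NULL, upper = NULL,
                        maxit = 2000) {
  pen_of <- function(p) {
    if (!is.null(lower) && any(p < lower)) return(1e10)
    if (!is.null(upper) && any(p > upper)) return(1e10)
    v <- tryCatch(suppressWarnings(of(p)), error = function(e) Inf)
    if (!is.finite(v)) 1e10 else v
  }
  best <- NULL
  for (s in starts) {
    o <- tryCatch(
      optim(s, pen_of, method = "Nelder-Mead",
            control = list(maxit = maxit, reltol = 1e-12)),
      error = function(e) NULL
    )
    if (is.null(o)) next
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) abort("all optimization starts failed")
  # one restart from the incumbent: Nelder-Mead benefits from a fresh simplex
  o2 <- optim(best$par, pen_of, method = "Nelder-Mead",
              control = list(maxit = maxit, reltol = 1e-12))
  if (o2$value < best$value) best <- o2
  best
}

# Linearised least-squares starting values for each density model.
.density_init <- function(data, model_id, solvent) {
  T_K <- data$T_K; P <- data$P_MPa; rho <- data$rho_kg_m3; y <- data$y2
  rs <- .reduced_state(T_K, P, rho, solvent)
  cf <- function(f) unname(coef(f))
  switch(
    model_id,
    alwi_garlapati = {
      b <- cf(lm(log(y * rs$rho1r * rs$Tr) ~ I(1 / rs$Tr) + rs$rho1r))
      c(b[1], b[2], b[3])
    },
    bartle = {
      b <- cf(lm(log(y * P / .P_REF_MPA) ~ I(1 / T_K) + I(rho - .RHO_REF)))
      c(b[1], b[2], b[3])
    },
    bian = {
      b <- cf(lm(log(y) ~ log(rho) + I(rho * log(rho)) + I(1 / T_K) +
                   I(rho / T_K)))
      c(b[2], b[3], b[4], b[5], b[1])
    },
    chrastil = {
      b <- cf(lm(log(y / (1 - y)) ~ log(rho) + I(1 / T_K)))
      c(b[2] + 1, b[1], b[3])
    },
    ref_chrastil = {
      qq <- .R_GAS * T_K * rho / (solvent$M_g_mol * 1e-3) / .F_REF_PA
      b <- cf(lm(log(y) ~ log(qq) + I(1 / T_K)))
      c(b[2] + 1, b[1], b[3])
    },
    garlapati_madras = {
      b <- cf(lm(log(y) ~ log(rho) + I(rho * log(rho)) + I(1 / T_K) +
                   I(log(rho * T_K))))
      c(b[1], b[2], b[3], b[4], b[5])
    },
    mt = {
      b <- cf(lm(I(T_K * log(y * P)) ~ rho + T_K))
      c(b[1], b[2], b[3])
    },
    sodeifian = {
      b <- cf(lm(log(y) ~ I(P^2 / T_K) + I(log(rho * T_K)) +
                   I(rho * log(rho)) + I(P * log(T_K)) + I(log(rho) / T_K)))
      c(b[1], b[2], b[3], b[4], b[5], b[6])
    },
    reddy_garlapati = {
      b <- cf(lm(y ~ 0 + I(rs$Tr^2) + I(rs$Pr * rs$Tr^2) +
                   I(rs$Pr^2 * rs$Tr^2) + rep(1, length(y)) + rs$Pr +
                   I(rs$Pr^2), weights = 1 / y^2))
      b
    },
    mahesh_garlapati = {
      b <- cf(lm(log(y) ~ I(rs$rho1r * rs$Tr) + I(rs$rho1r * rs$Tr^3)))
      c(b[1], b[2], b[3])
    }
  )
}

#' Fit a density-based correlation to a solubility dataset
#'
#' Minimises the relative-deviation objective (see [objective_rel()]) by
#' seeded multistart Nelder-Mead. Starting values come from a linearised
#' least-squares fit of the model (all ten forms are linear in their
#' parameters in a suitable transform), perturbed multiplicatively for the
#' remaining starts; the result is deterministic for a fixed seed.
#'
#' @param data solubility table with `T_K`, `P_MPa`, `rho_kg_m3`, `y2`.
#' @param model_id one of `density_model_registry()$model_id`.
#' @param solvent solvent [component_spec()]; defaults to CO2.
#' @param seed RNG seed for the multistart perturbations.
#' @param n_starts number of starts (the first is the linearised fit itself).
#' @return A `sccosol_fit` (see [tidy()] / [glance()] methods).
#' @export
#' @examples
#' \donttest{
#' fit_density_model(clemastine_table2(), "chrastil")
#' }
fit_density_model <- function(data, model_id, solvent = component_co2(),
                              seed = 42, n_starts = 32) {
  data <- validate_solubility_data(data)
  init <- .density_init(data, model_id, solvent)
  of <- function(p) objective_rel(data$y2, predict_density(data, model_id, p, solvent))
  set.seed(seed)
  starts <- c(list(init), lapply(seq_len(max(0, n_starts - 1)), function(i) {
    init * (1 + 0.25 * rnorm(length(init))) + 1e-3 * rnorm(length(init))
  }))
  best <- .multistart(of, starts)
  y_cal <- predict_density(data, model_id, best$par, solvent)
  np <- density_model_registry()$n_params[density_model_registry()$model_id == model_id]
  new_fit_result(model_id, best$par, data, y_cal, np, seed,
                 extra = list(objective = best$value))
}

#' Evaluate a density correlation with supplied parameters
#'
#' No fitting: computes predictions and the full metric set for a given
#' parameter vector (e.g. published constants).
#'
#' @inheritParams fit_density_model
#' @param params numeric parameter vector.
#' @return A `sccosol_fit`.
#' @export
evaluate_density <- function(data, model_id, params,
                             solvent = component_co2()) {
  data <- validate_solubility_data(data)
  y_cal <- predict_density(data, model_id, params, solvent)
  np <- density_model_registry()$n_params[density_model_registry()$model_id == model_id]
  new_fit_result(model_id, params, data, y_cal, np)
}

#' Rank fitted models by AICc
#'
#' Ascending AICc; ties broken by fewer parameters, then lower AARD.
#'
#' @param results a list of `sccosol_fit` objects (>= 2).
#' @return A tibble with one row per model in rank order.
#' @export
rank_models <- function(results) {
  if (length(results) < 2) abort("need at least two fit results to rank")
  tab <- purrr::map_dfr(results, function(r) {
    tibble::tibble(model_id = r$model_id, sse = r$sse, n_params = r$n_params,
                   n_points = r$n_points, aard_percent = r$aard_percent,
                   r2 = r$r2, aic = r$aic, aicc = r$aicc)
  })
  dplyr::arrange(tab, .data$aicc, .data$n_params, .data$aard_percent)
}

#' Enthalpy bookkeeping from fitted temperature coefficients
#'
#' Total dissolution enthalpy from the Chrastil (E2) and reformulated
#' Chrastil (F2) temperature coefficients, dH_total = -E2 R (resp. -F2 R);
#' sublimation enthalpy from the Bartle coefficient, dH_sub = -B2 R, and
#' from the EoS sublimation form via [dhsub_eos()] at the mean experimental
#' temperature. Solvation enthalpy is the signed difference
#' dH_solv = dH_total - dH_sub for each pairing. R = 8.314 J/mol/K; all
#' outputs in kJ/mol.
#'
#' @param chrastil_E2,refchrastil_F2,bartle_B2 fitted temperature
#'   coefficients (K).
#' @param eos_coeffs optional sublimation coefficients (see
#'   [psub_from_coeffs()]).
#' @param T_mean_K temperature for the EoS enthalpy (K).
#' @return A tibble with one row per (total, sublimation) pairing.
#' @export
#' @examples
#' enthalpy_report(-4907.2, -4216.6, -7179.9,
#'                 list(beta_over_R = 0.27409, gamma_over_R = -221.54,
#'                      dsubdelta_over_R = 11.305), 323)
enthalpy_report <- function(chrastil_E2, refchrastil_F2, bartle_B2,
                            eos_coeffs = NULL, T_mean_K = 323) {
  totals <- c(chrastil = -chrastil_E2 * .R_GAS / 1000,
              ref_chrastil = -refchrastil_F2 * .R_GAS / 1000)
  subs <- c(bartle = -bartle_B2 * .R_GAS / 1000)
  if (!is.null(eos_coeffs)) {
    subs <- c(subs, eos = dhsub_eos(eos_coeffs, T_mean_K) / 1000)
  }
  grid <- expand.grid(total_model = names(totals), sub_model = names(subs),
                      stringsAsFactors = FALSE)
  tibble::tibble(
    total_model = grid$total_model,
    sub_model = grid$sub_model,
    dH_total_kJ_mol = unname(totals[grid$total_model]),
    dH_sub_kJ_mol = unname(subs[grid$sub_model]),
    dH_solv_kJ_mol = unname(totals[grid$total_model] - subs[grid$sub_model])
  )
}
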