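#' Registry of density-based solubility correlations
#'
#' Ten empirical/semi-empirical correlations expressing the mole-fraction
#' solubility of a solid in supercritical CO2 as a function of temperature,
#' pressure and solvent density. Parameter counts follow the standard forms:
#' 3 (Alwi-Garlapati, Bartle, Chrastil, reformulated Chrastil,
#' Mendez-Santiago-Teja, Mahesh-Garlapati), 5 (Bian, Garlapati-Madras) or
#' 6 (Sodeifian, Reddy-Garlapati).
#'
#' @return A tibble with columns `model_id`, `label`, `n_params`, `needs`.
#' @export
#' @examples
#' density_model_registry()
density_model_registry <- function() {
  tibble::tribble(
    ~model_id,           ~label,                     ~n_params, ~needs,
    "alwi_garlapati",    "Alwi-Garlapati",           3L, "Tr, rho1r",
    "bartle",            "Bartle et al.",            3L, "T, P, rho1",
    "bian",              "Bian et al.",              5L, "T, rho1",
    "chrastil",          "Chrastil",                 3L, "T, rho1",
    "ref_chrastil",      "reformulated Chrastil",    3L, "T, rho1",
    "garlapati_madras",  "Garlapati-Madras",         5L, "T, rho1",
    "mt",                "Mendez-Santiago-Teja",     3L, "T, P, rho1",
    "sodeifian",         "Sodeifian et al.",         6L, "T, P, rho1",
    "reddy_garlapati",   "Reddy-Garlapati",          6L, "Tr, Pr",
    "mahesh_garlapati",  "Mahesh-Garlapati",         3L, "Tr, rho1r"
  )
}

# Reference constants of the Bartle enhancement-factor form and the
# reformulated Chrastil form.
.P_REF_MPA <- 0.1    # MPa
.RHO_REF <- 700      # kg/m^3
.F_REF_PA <- 1e5     # Pa (0.1 MPa reference fugacity)

.reduced_state <- function(T_K, P_MPa, rho_kg_m3, solvent) {
  rhoc <- solvent$rhoc_kg_m3
  if (is.null(rhoc)) abort("solvent spec lacks rhoc_kg_m3 (needed for reduced density)")
  list(Tr = T_K / solvent$Tc_K, Pr = P_MPa / solvent$Pc_MPa,
       rho1r = rho_kg_m3 / rhoc)
}

#' Predict solubility with a density-based correlation
#'
#' Evaluates the named correlation at each row of `data`. Conventions are
#' fixed: pressure in MPa wherever a y2*P product appears (Bartle, MT),
#' density in kg/m^3, reference constants P_ref = 0.1 MPa and
#' rho_ref = 700 kg/m^3 for Bartle, reference fugacity 0.1 MPa for the
#' reformulated Chrastil form, and reduced variables built from the solvent
#' record (CO2: Tc = 304.18 K, Pc = 7.38 MPa, rhoc = 467.6 kg/m^3).
#' No clamping is applied: the Reddy-Garlapati polynomial may return
#' negative values for pathological parameters.
#'
#' @param data data frame with columns `T_K`, `P_MPa`, `rho_kg_m3`.
#' @param model_id one of `density_model_registry()$model_id`.
#' @param params numeric parameter vector of the model's length.
#' @param solvent solvent [component_spec()]; defaults to CO2.
#' @return Numeric vector of predicted mole fractions, one per row.
#' @export
#' @examples
#' predict_density(clemastine_table2(), "chrastil", c(3.0938, -11.003, -4907.2))
predict_density <- function(data, model_id, params, solvent = component_co2()) {
  reg <- density_model_registry()
  if (!model_id %in% reg$model_id) {
    abort(paste0("unknown model_id: ", model_id))
  }
  np <- reg$n_params[reg$model_id == model_id]
  if (length(params) != np) {
    abort(sprintf("model '%s' takes %d parameters, got %d",
                  model_id, np, length(params)))
  }
  T_K <- data$T_K; P <- data$P_MPa; rho <- data$rho_kg_m3
  rs <- .reduced_state(T_K, P, rho, solvent)
  p <- params
  y <- switch(
    model_id,
    alwi_garlapati = exp(p[1] + p[2] / rs$Tr + p[3] * rs$rho1r) /
      (rs$rho1r * rs$Tr),
    bartle = exp(p[1] + p[2] / T_K + p[3] * (rho - .RHO_REF)) *
      .P_REF_MPA / P,
    bian = rho^(p[1] + p[2] * rho) *
      exp(p[3] / T_K + p[4] * rho / T_K + p[5]),
    chrastil = {
      q <- rho^(p[1] - 1) * exp(p[2] + p[3] / T_K)
      q / (1 + q)
    },
    ref_chrastil = {
      qq <- .R_GAS * T_K * rho / (solvent$M_g_mol * 1e-3) / .F_REF_PA
      qq^(p[1] - 1) * exp(p[2] + p[3] / T_K)
    },
    garlapati_madras = exp(p[1] + (p[2] + p[3] * rho) * log(rho) +
                             p[4] / T_K + p[5] * log(rho * T_K)),
    mt = exp((p[1] + p[2] * rho) / T_K + p[3]) / P,
    sodeifian = exp(p[1] + p[2] * P^2 / T_K + p[3] * log(rho * T_K) +
                      p[4] * rho * log(rho) + p[5] * P * log(T_K) +
                      p[6] * log(rho) / T_K),
    reddy_garlapati = (p[1] + p[2] * rs$Pr + p[3] * rs$Pr^2) * rs$Tr^2 +
      (p[4] + p[5] * rs$Pr + p[6] * rs$Pr^2),
    mahesh_garlapati = exp(p[1] + p[2] * rs$rho1r * rs$Tr +
                             p[3] * rs$rho1r * rs$Tr^3)
  )
  if (any(is.infinite(y))) warn("overflow in model exponent; Inf propagated")
  y
}

#' Chrastil mass-concentration form
#'
#' c2 = rho1^kappa * exp(E1 + E2/T). Units of c2 are inherited from the
#' fitted constants (g/L when fitted against g/L data with rho in kg/m^3).
#'
#' @param params Chrastil parameter vector `(kappa, E1, E2)`.
#' @param T_K temperature (K).
#' @param rho_kg_m3 CO2 density (kg/m^3).
#' @return Mass concentration of solute.
#' @export
chrastil_c2 <- function(params, T_K, rho_kg_m3) {
  stopifnot(length(params) == 3)
  rho_kg_m3^params[1] * exp(params[2] + params[3] / T_K)
}
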