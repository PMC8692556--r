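#' Sampling geometry of the solubility measurement
#'
#' The static-cell measurement withdraws a fixed loop volume of saturated
#' supercritical CO2 and flushes it into a collection vial whose final
#' (methanolic) solution volume is known. The loop volume fixes the moles of
#' CO2 sampled; the vial volume converts the assayed concentration to moles
#' of drug.
#'
#' @param loop_volume_m3 sampled ScCO2 volume (m^3); default 600 uL.
#' @param vial_volume_m3 total collected solution volume (m^3); default 5 mL.
#' @return A named list of class `sccosol_geometry`.
#' @export
sampling_geometry <- function(loop_volume_m3 = 6e-7, vial_volume_m3 = 5e-6) {
  if (loop_volume_m3 <= 0 || vial_volume_m3 <= 0) {
    abort("loop and vial volumes must be positive")
  }
  if (loop_volume_m3 > vial_volume_m3) {
    warn("loop volume exceeds vial volume; check the geometry units")
  }
  structure(list(loop_volume_m3 = loop_volume_m3,
                 vial_volume_m3 = vial_volume_m3),
            class = "sccosol_geometry")
}

#' Mole-fraction solubility from an assayed vial concentration
#'
#' Converts the drug concentration measured in the collection vial (g/L)
#' into the equilibrium mole fraction in the fluid phase,
#' y2 = n_drug / (n_drug + n_CO2), with
#' n_drug = Cs * V_vial / M_s and n_CO2 = V_loop * rho1 / M_CO2.
#'
#' @param Cs_g_L drug concentration in the vial (g/L).
#' @param geom a [sampling_geometry()].
#' @param rho1_kg_m3 CO2 density at the sampling state (kg/m^3).
#' @param solute,solvent [component_spec()] records (molar masses used).
#' @return Mole fraction in `[0, 1)`.
#' @export
#' @examples
#' y2_from_vial_concentration(1.56e-3, sampling_geometry(), 769,
#'                            component_clemastine(), component_co2())
y2_from_vial_concentration <- function(Cs_g_L, geom, rho1_kg_m3,
                                       solute, solvent) {
  if (any(Cs_g_L < 0)) abort("Cs must be non-negative")
  if (any(rho1_kg_m3 <= 0)) abort("density must be positive")
  # g/L * m3 = kg * 1e-3; molar masses in g/mol -> work in grams throughout:
  # vial volume m3 -> L is *1e3; rho kg/m3 == g/L.
  n_drug <- Cs_g_L * (geom$vial_volume_m3 * 1e3) / solute$M_g_mol
  n_co2 <- (geom$loop_volume_m3 * 1e3) * rho1_kg_m3 / solvent$M_g_mol
  n_drug / (n_drug + n_co2)
}

#' Solubility in g/L from a mole fraction
#'
#' S = rho1 * (M_s / M_CO2) * y2 / (1 - y2), with the CO2 density read in
#' g/L (numerically identical to kg/m^3).
#'
#' @param y2 mole-fraction solubility, in `[0, 1)`.
#' @param rho1_kg_m3 CO2 density (kg/m^3).
#' @param solute,solvent [component_spec()] records.
#' @return Equilibrium solubility (g/L).
#' @export
s_from_y2 <- function(y2, rho1_kg_m3, solute, solvent) {
  if (any(y2 < 0) || any(y2 >= 1)) abort("y2 must lie in [0, 1)")
  rho1_kg_m3 * (solute$M_g_mol / solvent$M_g_mol) * y2 / (1 - y2)
}

#' @rdname s_from_y2
#' @param S_g_L solubility in g/L (exact algebraic inverse of [s_from_y2()]).
#' @export
y2_from_s <- function(S_g_L, rho1_kg_m3, solute, solvent) {
  if (any(S_g_L < 0)) abort("S must be non-negative")
  r <- S_g_L * solvent$M_g_mol / (solute$M_g_mol * rho1_kg_m3)
  r / (1 + r)
}

#' Unbiased sample standard deviation of repeated measurements
#'
#' @param values numeric vector of repeated y2 measurements (n >= 2).
#' @return The (n - 1)-denominator sample standard deviation.
#' @export
sample_std <- function(values) {
  if (length(values) < 2) abort("at least two repeats are required")
  stats::sd(values)
}

#' Mendez-Santiago-Teja self-consistency diagnostic
#'
#' Under the MT correlation T ln(y2 P) = H1 + H2 rho1 + H3 T, the transform
#' T ln(y2 P) - H3 T collapses all isotherms onto one straight line in
#' density. The diagnostic applies the transform to every measurement and
#' reports the straight-line fit; data generated exactly by the model give
#' slope H2, intercept H1 and R^2 = 1. Pressure enters in MPa.
#'
#' @param data solubility table (see [validate_solubility_data()]).
#' @param H numeric length-3 MT parameter vector `(H1, H2, H3)`, e.g. from
#'   [fit_density_model()] with `model_id = "mt"`.
#' @return A list with `points` (tibble of rho and the transformed variable),
#'   `slope`, `intercept` and `r2`.
#' @export
mt_selfconsistency <- function(data, H) {
  data <- validate_solubility_data(data)
  stopifnot(length(H) == 3)
  if (any(data$y2 * data$P_MPa <= 0)) abort("y2 * P must be positive")
  tl <- data$T_K * log(data$y2 * data$P_MPa) - H[3] * data$T_K
  fit <- lm(tl ~ data$rho_kg_m3)
  pts <- tibble::tibble(rho_kg_m3 = data$rho_kg_m3, T_K = data$T_K,
                        P_MPa = data$P_MPa, mt_transform = tl)
  list(points = pts,
       slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]),
       r2 = summary(fit)$r.squared)
}
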