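#' Component property records
#'
#' A component spec carries the per-species constants every model in the
#' package consumes: molar mass, critical temperature and pressure, acentric
#' factor, and (for solid solutes) the solid molar volume and an optional
#' table of sublimation pressures.
#'
#' @param M_g_mol molar mass (g/mol).
#' @param Tc_K critical temperature (K).
#' @param Pc_MPa critical pressure (MPa).
#' @param omega acentric factor (dimensionless).
#' @param Vsolid_m3_mol solid molar volume (m^3/mol); solutes only.
#' @param psub_Pa optional named list/vector mapping temperature (K, as the
#'   name) to sublimation pressure (Pa).
#' @param rhoc_kg_m3 optional critical density (kg/m^3); needed when the
#'   species serves as the solvent of reduced-density correlations.
#' @param name free-text label.
#'
#' @return An object of class `sccosol_component` (a named list).
#' @export
#' @examples
#' co2 <- component_spec(44.01, 304.18, 7.38, 0.225, rhoc_kg_m3 = 467.6)
component_spec <- function(M_g_mol, Tc_K, Pc_MPa, omega,
                           Vsolid_m3_mol = NULL, psub_Pa = NULL,
                           rhoc_kg_m3 = NULL, name = "") {
  stopifnot(is.numeric(M_g_mol), is.numeric(Tc_K), is.numeric(Pc_MPa))
  if (M_g_mol <= 0 || Tc_K <= 0 || Pc_MPa <= 0) {
    abort("M, Tc and Pc must all be positive.")
  }
  if (!is.null(Vsolid_m3_mol) && Vsolid_m3_mol <= 0) {
    abort("Vsolid_m3_mol must be positive when supplied.")
  }
  if (!is.null(psub_Pa)) {
    psub_Pa <- unlist(psub_Pa)
    if (is.null(names(psub_Pa)) || anyNA(suppressWarnings(as.numeric(names(psub_Pa))))) {
      abort("psub_Pa must be named by temperature in K.")
    }
  }
  structure(
    list(
      name = name, M_g_mol = M_g_mol, Tc_K = Tc_K, Pc_MPa = Pc_MPa,
      omega = omega, Vsolid_m3_mol = Vsolid_m3_mol, psub_Pa = psub_Pa,
      rhoc_kg_m3 = rhoc_kg_m3
    ),
    class = "sccosol_component"
  )
}

#' @export
print.sccosol_component <- function(x, ...) {
  cat("<sccosol_component> ", x$name, "\n", sep = "")
  cat(sprintf("  M = %.3f g/mol, Tc = %.2f K, Pc = %.3f MPa, omega = %.3f\n",
              x$M_g_mol, x$Tc_K, x$Pc_MPa, x$omega))
  if (!is.null(x$Vsolid_m3_mol)) {
    cat(sprintf("  Vsolid = %.4g m3/mol\n", x$Vsolid_m3_mol))
  }
  if (!is.null(x$psub_Pa)) {
    cat("  psub(T):", paste(names(x$psub_Pa), signif(x$psub_Pa, 4),
                            sep = " K -> ", collapse = " Pa, "), "Pa\n")
  }
  invisible(x)
}

#' Read a component spec from JSON
#'
#' @param path path to a JSON file with keys `M_g_mol`, `Tc_K`, `Pc_MPa`,
#'   `omega` and optionally `Vsolid_m3_mol`, `psub_Pa` (a T->Pa map),
#'   `rhoc_kg_m3`, `name`.
#' @return An `sccosol_component`.
#' @export
read_component_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  component_spec(
    M_g_mol = x$M_g_mol, Tc_K = x$Tc_K, Pc_MPa = x$Pc_MPa, omega = x$omega,
    Vsolid_m3_mol = x$Vsolid_m3_mol, psub_Pa = x$psub_Pa,
    rhoc_kg_m3 = x$rhoc_kg_m3, name = x$name %||% ""
  )
}

#' Packaged reference components and dataset
#'
#' `component_clemastine()` and `component_co2()` load the packaged property
#' records of clemastine fumarate (M = 459.96 g/mol, estimated Tc = 901.25 K,
#' Pc = 1.409 MPa, omega = 0.337, solid molar volume 364.764 cm^3/mol, and an
#' estimated sublimation-pressure table) and of carbon dioxide.
#' `clemastine_table2()` loads the packaged 24-point isothermal solubility
#' dataset (308-338 K, 12-27 MPa) measured for clemastine fumarate in
#' supercritical CO2.
#'
#' @return Component specs, or a tibble for `clemastine_table2()`.
#' @export
component_clemastine <- function() {
  read_component_json(system.file("extdata", "clemastine_props.json",
                                  package = "sccosol", mustWork = TRUE))
}

#' @rdname component_clemastine
#' @export
component_co2 <- function() {
  read_component_json(system.file("extdata", "co2_props.json",
                                  package = "sccosol", mustWork = TRUE))
}

#' @rdname component_clemastine
#' @export
clemastine_table2 <- function() {
  read_solubility_csv(system.file("extdata", "clemastine_table2.csv",
                                  package = "sccosol", mustWork = TRUE))
}

#' Read an isothermal solubility dataset from CSV
#'
#' Expects the header `T_K,P_MPa,rho_kg_m3,y2,S_g_L` ('.' decimal separator);
#' `S_g_L` and any extra columns (e.g. `sd_y2`) are optional. Rows are sorted
#' by isotherm then pressure and validated (all states positive, 0 < y2 < 1).
#'
#' @param path path to the CSV file.
#' @return A tibble with one row per measurement.
#' @export
read_solubility_csv <- function(path) {
  dat <- readr::read_csv(path, show_col_types = FALSE)
  validate_solubility_data(dat)
}

#' Validate a solubility table
#'
#' @param data data frame with columns `T_K`, `P_MPa`, `rho_kg_m3`, `y2`.
#' @return The data as a tibble, sorted by (T, P).
#' @export
validate_solubility_data <- function(data) {
  need <- c("T_K", "P_MPa", "rho_kg_m3", "y2")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    abort(paste0("solubility data lacks column(s): ", paste(miss, collapse = ", ")))
  }
  if (nrow(data) < 1) abort("solubility data must have at least one row")
  with(data, {
    if (any(T_K <= 0) || any(P_MPa <= 0) || any(rho_kg_m3 <= 0)) {
      abort("T, P and density must be positive")
    }
    if (any(y2 <= 0) || any(y2 >= 1)) abort("y2 must lie strictly in (0, 1)")
  })
  dplyr::arrange(tibble::as_tibble(data), .data$T_K, .data$P_MPa)
}
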