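#' Normal boiling temperature from the Klincewicz relation
#'
#' Inverts Tc = 50.2 - 0.16 M + 1.41 Tb to Tb = (Tc - 50.2 + 0.16 M)/1.41.
#'
#' @param Tc_K critical temperature (K).
#' @param M_g_mol molar mass (g/mol).
#' @return Normal boiling temperature (K).
#' @export
#' @examples
#' klincewicz_tb(901.25, 459.96)  # ~ 655.8 K
klincewicz_tb <- function(Tc_K, M_g_mol) {
  tb <- (Tc_K - 50.2 + 0.16 * M_g_mol) / 1.41
  if (any(tb <= 0)) abort("nonphysical boiling temperature (<= 0)")
  tb
}

#' @rdname klincewicz_tb
#' @param Tb_K normal boiling temperature (K); forward relation.
#' @export
klincewicz_tc <- function(Tb_K, M_g_mol) 50.2 - 0.16 * M_g_mol + 1.41 * Tb_K

# Lee-Kesler reduced vapor-pressure functions.
.lk_f0 <- function(Tr) 5.92714 - 6.09648 / Tr - 1.28862 * log(Tr) +
  0.169347 * Tr^6
.lk_f1 <- function(Tr) 15.2518 - 15.6875 / Tr - 13.4721 * log(Tr) +
  0.43577 * Tr^6

#' Lee-Kesler vapor/sublimation pressure
#'
#' ln(P/Pc) = f0(Tr) + omega f1(Tr) with the standard Lee-Kesler reduced
#' functions; anchored so that P ~ Pc at T = Tc.
#'
#' @param T_K temperature (K); must satisfy 0 < T <= Tc.
#' @param Tc_K critical temperature (K).
#' @param Pc_Pa critical pressure (Pa).
#' @param omega acentric factor.
#' @return Vapor pressure (Pa).
#' @export
#' @examples
#' lee_kesler_psub(338, 901.25, 1.409e6, 0.337) /
#'   lee_kesler_psub(308, 901.25, 1.409e6, 0.337)  # ~ 11.2
lee_kesler_psub <- function(T_K, Tc_K, Pc_Pa, omega) {
  if (any(T_K <= 0) || any(T_K > Tc_K)) abort("require 0 < T <= Tc")
  Tr <- T_K / Tc_K
  Pc_Pa * exp(.lk_f0(Tr) + omega * .lk_f1(Tr))
}

#' Acentric factor from the Lee-Kesler relations
#'
#' Solves ln(P_atm/Pc) = f0(Tbr) + omega f1(Tbr) at the normal boiling point
#' (1 atm = 101325 Pa) for omega.
#'
#' @param Tb_K normal boiling temperature (K), 0 < Tb < Tc.
#' @param Tc_K critical temperature (K).
#' @param Pc_Pa critical pressure (Pa).
#' @return Acentric factor.
#' @export
lee_kesler_omega <- function(Tb_K, Tc_K, Pc_Pa) {
  if (any(Tb_K <= 0) || any(Tb_K >= Tc_K)) abort("require 0 < Tb < Tc")
  Tbr <- Tb_K / Tc_K
  f1 <- .lk_f1(Tbr)
  if (any(abs(f1) < 1e-6)) abort("degenerate anchor: f1(Tbr) ~ 0")
  (log(101325 / Pc_Pa) - .lk_f0(Tbr)) / f1
}

#' Group-contribution coefficient tables
#'
#' `read_gc_table()` loads a coefficient table from JSON (keys `method_id`,
#' `formula_id`, `property`, `contributions`). Three tables ship with the
#' package: Lydersen-type critical-temperature and critical-pressure
#' increments and Fedors-type molar-volume increments; any user table with a
#' supported `formula_id` can be substituted.
#'
#' @param path path to the JSON table.
#' @return A list of class `sccosol_gc_table`.
#' @export
read_gc_table <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(!is.null(x$formula_id), length(x$contributions) > 0)
  structure(x, class = "sccosol_gc_table")
}

#' @rdname read_gc_table
#' @export
gc_table_tc <- function() {
  read_gc_table(system.file("extdata", "gc_tc_lydersen.json",
                            package = "sccosol", mustWork = TRUE))
}

#' @rdname read_gc_table
#' @export
gc_table_pc <- function() {
  read_gc_table(system.file("extdata", "gc_pc_lydersen.json",
                            package = "sccosol", mustWork = TRUE))
}

#' @rdname read_gc_table
#' @export
gc_table_vol <- function() {
  read_gc_table(system.file("extdata", "gc_vol_fedors.json",
                            package = "sccosol", mustWork = TRUE))
}

#' Group-contribution property estimate
#'
#' Sums count-weighted increments and assembles them with the table's
#' formula: `"tb_ratio"` gives Tc = Tb / (0.567 + S - S^2) (needs `Tb_K`);
#' `"inverse_sq"` gives Pc = 0.101325 M / (0.34 + S)^2 in MPa (needs
#' `M_g_mol`); `"linear_sum"` returns S directly (molar volume, cm^3/mol).
#' The estimate is additive in the group counts.
#'
#' @param counts named integer vector/list of group counts; every label must
#'   exist in the table.
#' @param table a coefficient table (see [read_gc_table()]).
#' @param M_g_mol molar mass, for pressure-type formulas.
#' @param Tb_K normal boiling temperature, for Tc-type formulas.
#' @return The estimated property value.
#' @export
#' @examples
#' gc_estimate(c(CH3 = 2, CH2 = 8), gc_table_vol())  # n-decane, ~195 cm3/mol
gc_estimate <- function(counts, table, M_g_mol = NULL, Tb_K = NULL) {
  counts <- unlist(counts)
  if (length(counts) && any(counts < 0)) abort("group counts must be >= 0")
  unknown <- setdiff(names(counts), names(table$contributions))
  if (length(unknown)) {
    abort(paste0("unknown group label(s): ", paste(unknown, collapse = ", ")))
  }
  S <- if (length(counts)) {
    sum(counts * unlist(table$contributions[names(counts)]))
  } else 0
  switch(
    table$formula_id,
    tb_ratio = {
      if (is.null(Tb_K)) abort("tb_ratio formula needs Tb_K")
      Tb_K / (0.567 + S - S^2)
    },
    inverse_sq = {
      if (is.null(M_g_mol)) abort("inverse_sq formula needs M_g_mol")
      0.101325 * M_g_mol / (0.34 + S)^2
    },
    linear_sum = S,
    abort(paste0("unknown formula_id: ", table$formula_id))
  )
}
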