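#' Pure-component Peng-Robinson parameters
#'
#' a(T) = 0.45724 R^2 Tc^2 / Pc * alpha(T), with the 1976 alpha function
#' alpha = `[1 + m (1 - sqrt(Tr))]^2`, m = 0.37464 + 1.54226 w - 0.26992 w^2,
#' and b = 0.07780 R Tc / Pc. SI units (Pa m^6 mol^-2; m^3 mol^-1).
#'
#' @param T_K temperature (K).
#' @param comp a [component_spec()].
#' @return List with elements `a` and `b`.
#' @export
#' @examples
#' pr_pure(304.18, component_co2())  # a ~ 0.396, b ~ 2.666e-5
pr_pure <- function(T_K, comp) {
  if (any(T_K <= 0)) abort("T must be positive")
  Tc <- comp$Tc_K
  Pc <- comp$Pc_MPa * 1e6
  m <- 0.37464 + 1.54226 * comp$omega - 0.26992 * comp$omega^2
  alpha <- (1 + m * (1 - sqrt(T_K / Tc)))^2
  list(a = 0.45724 * .R_GAS^2 * Tc^2 / Pc * alpha,
       b = 0.07780 * .R_GAS * Tc / Pc)
}

#' Two-parameter van der Waals mixing
#'
#' Quadratic mixing with binary corrections:
#' a_ij = (1 - k_ij) sqrt(a_i a_j), b_ij = (1 - l_ij)(b_i + b_j)/2,
#' a = sum_ij x_i x_j a_ij, b = sum_ij x_i x_j b_ij. Also returns the
#' partial quantities entering the fugacity-coefficient expression,
#' a_hat_i = 2 sum_j x_j a_ij and b_hat_i = 2 sum_j x_j b_ij - b.
#'
#' @param x composition vector (must sum to 1 within 1e-12).
#' @param a,b per-species pure PR parameter vectors.
#' @param kij,lij binary correction matrices (or a scalar, applied to all
#'   unlike pairs; diagonal corrections are zero).
#' @return List `a`, `b`, `a_hat`, `b_hat`.
#' @export
pr_mix_vdw2 <- function(x, a, b, kij = 0, lij = 0) {
  n <- length(x)
  if (abs(sum(x) - 1) > 1e-12) abort("composition must sum to 1")
  kmat <- .as_binary_matrix(kij, n)
  lmat <- .as_binary_matrix(lij, n)
  aij <- (1 - kmat) * sqrt(outer(a, a))
  bij <- (1 - lmat) * outer(b, b, function(u, v) (u + v) / 2)
  amix <- drop(x %*% aij %*% x)
  bmix <- drop(x %*% bij %*% x)
  list(a = amix, b = bmix,
       a_hat = 2 * drop(aij %*% x),
       b_hat = 2 * drop(bij %*% x) - bmix)
}

.as_binary_matrix <- function(k, n) {
  if (is.matrix(k)) return(k)
  m <- matrix(k, n, n)
  diag(m) <- 0
  m
}

# Real roots of z^3 + p2 z^2 + p1 z + p0 = 0 (Cardano / trigonometric form).
.cubic_real_roots <- function(p2, p1, p0) {
  q <- (3 * p1 - p2^2) / 9
  r <- (9 * p2 * p1 - 27 * p0 - 2 * p2^3) / 54
  disc <- q^3 + r^2
  if (disc > 0) {
    s <- sign(r + sqrt(disc)) * abs(r + sqrt(disc))^(1 / 3)
    t <- sign(r - sqrt(disc)) * abs(r - sqrt(disc))^(1 / 3)
    return(s + t - p2 / 3)
  }
  # three real roots
  theta <- acos(max(-1, min(1, r / sqrt(-q^3))))
  2 * sqrt(-q) * cos((theta + c(0, 2, 4) * pi) / 3) - p2 / 3
}

#' Compressibility factor from the PR cubic
#'
#' Solves Z^3 - (1 - B) Z^2 + (A - 3B^2 - 2B) Z - (AB - B^2 - B^3) = 0 with
#' A = aP/(RT)^2, B = bP/RT. When several roots satisfy Z > B the root with
#' the lower total Gibbs energy is returned; supercritical states have a
#' single root in practice.
#'
#' @param T_K temperature (K).
#' @param P_Pa pressure (Pa).
#' @param a,b (mixture) PR parameters, SI units.
#' @return Compressibility factor Z (> B).
#' @export
pr_solve_z <- function(T_K, P_Pa, a, b) {
  if (P_Pa <= 0) abort("P must be positive")
  A <- a * P_Pa / (.R_GAS * T_K)^2
  B <- b * P_Pa / (.R_GAS * T_K)
  z <- .cubic_real_roots(-(1 - B), A - 3 * B^2 - 2 * B, -(A * B - B^2 - B^3))
  z <- z[z > B]
  if (!length(z)) abort("no physical compressibility root (Z > B)")
  if (length(z) == 1) return(z)
  # residual Gibbs energy per mole / RT, same for any root count
  g <- (z - 1) - log(z - B) -
    A / (2 * sqrt(2) * B) * log((z + (1 + sqrt(2)) * B) / (z + (1 - sqrt(2)) * B))
  z[which.min(g)]
}

# ln phi_i for a vdW2 PR mixture; x, a, b vectors; returns vector.
.pr_lnphi <- function(x, T_K, P_Pa, a, b, kij = 0, lij = 0) {
  mix <- pr_mix_vdw2(x, a, b, kij, lij)
  A <- mix$a * P_Pa / (.R_GAS * T_K)^2
  B <- mix$b * P_Pa / (.R_GAS * T_K)
  Z <- pr_solve_z(T_K, P_Pa, mix$a, mix$b)
  kernel <- log((Z + (1 + sqrt(2)) * B) / (Z + (1 - sqrt(2)) * B))
  (mix$b_hat / mix$b) * (Z - 1) - log(Z - B) -
    A / (2 * sqrt(2) * B) * (mix$a_hat / mix$a - mix$b_hat / mix$b) * kernel
}

#' Fugacity coefficient of a pure fluid (PR)
#'
#' @param T_K temperature (K).
#' @param P_Pa pressure (Pa).
#' @param comp a [component_spec()].
#' @return phi (> 0).
#' @export
pr_phi_pure <- function(T_K, P_Pa, comp) {
  pp <- pr_pure(T_K, comp)
  exp(.pr_lnphi(1, T_K, P_Pa, pp$a, pp$b))
}

#' Partial fugacity coefficients in a vdW2 PR mixture
#'
#' Standard PR expression with dimensionless A = aP/(RT)^2, B = bP/RT and the
#' ln[(Z + (1+sqrt(2))B) / (Z + (1-sqrt(2))B)] kernel.
#'
#' @param x composition vector.
#' @param T_K temperature (K).
#' @param P_Pa pressure (Pa).
#' @param a,b per-species pure PR parameter vectors (see [pr_pure()]).
#' @param kij,lij binary corrections (scalar or matrix).
#' @param i optional species index; when given a scalar phi_hat_i is
#'   returned, otherwise the full vector.
#' @return Fugacity coefficient(s).
#' @export
pr_phi_mixture <- function(x, T_K, P_Pa, a, b, kij = 0, lij = 0, i = NULL) {
  phi <- exp(.pr_lnphi(x, T_K, P_Pa, a, b, kij, lij))
  if (is.null(i)) phi else phi[i]
}

#' Sublimation pressure from the three-coefficient form
#'
#' R ln(p_sub) = beta + gamma/T + Delta_sub_delta * ln(T/298.15), with
#' coefficients supplied divided by R and p_sub in Pa (package convention;
#' the beta coefficient absorbs the unit choice during fitting).
#'
#' @param T_K temperature (K).
#' @param coeffs list/vector with `beta_over_R`, `gamma_over_R`,
#'   `dsubdelta_over_R`.
#' @return Sublimation pressure (Pa).
#' @export
psub_from_coeffs <- function(T_K, coeffs) {
  if (any(T_K <= 0)) abort("T must be positive")
  exp(coeffs$beta_over_R + coeffs$gamma_over_R / T_K +
        coeffs$dsubdelta_over_R * log(T_K / 298.15))
}

#' Sublimation enthalpy from the EoS sublimation coefficients
#'
#' The default (paper-consistent) convention returns
#' R * (gamma/R + Delta_sub_delta/R * T) in J/mol; `literal = TRUE` switches
#' to the textbook Clausius-Clapeyron sign, R * (-gamma/R +
#' Delta_sub_delta/R * T).
#'
#' @param coeffs sublimation coefficients (see [psub_from_coeffs()]).
#' @param T_K temperature (K) at which to evaluate.
#' @param literal use the literal derivative-based sign convention.
#' @return Sublimation enthalpy (J/mol).
#' @export
dhsub_eos <- function(coeffs, T_K, literal = FALSE) {
  if (any(T_K <= 0)) abort("T must be positive")
  g <- if (literal) -coeffs$gamma_over_R else coeffs$gamma_over_R
  .R_GAS * (g + coeffs$dsubdelta_over_R * T_K)
}

#' Solid solubility from the PR-EoS equilibrium condition
#'
#' y2 = p_sub * phi_sat / (P * phi_hat_2) * exp[(P - p_sub) v_s / (RT)],
#' with the saturated-solid fugacity coefficient taken as 1 and phi_hat_2
#' evaluated self-consistently at composition (y2, 1 - y2) by fixed-point
#' iteration (start 1e-8, relative tolerance 1e-10, max 200 iterations).
#'
#' @param T_K temperature (K).
#' @param P_Pa pressure (Pa).
#' @param solute,solvent [component_spec()] records (solute needs
#'   `Vsolid_m3_mol`).
#' @param kij,lij binary interaction corrections.
#' @param psub_Pa solute sublimation pressure at `T_K` (Pa); must be < P.
#' @return Converged mole fraction in (0, 1).
#' @export
y2_pr_eos <- function(T_K, P_Pa, solute, solvent, kij, lij, psub_Pa) {
  if (psub_Pa >= P_Pa) abort("sublimation pressure must be below P")
  a <- c(pr_pure(T_K, solute)$a, pr_pure(T_K, solvent)$a)
  b <- c(pr_pure(T_K, solute)$b, pr_pure(T_K, solvent)$b)
  vs <- solute$Vsolid_m3_mol
  if (is.null(vs)) abort("solute spec lacks Vsolid_m3_mol")
  poynting <- exp((P_Pa - psub_Pa) * vs / (.R_GAS * T_K))
  y <- 1e-8
  for (it in seq_len(200)) {
    phi2 <- pr_phi_mixture(c(y, 1 - y), T_K, P_Pa, a, b, kij, lij, i = 1)
    y_new <- psub_Pa / (P_Pa * phi2) * poynting
    if (!is.finite(y_new) || y_new <= 0) {
      abort(sprintf("EoS iteration left (0,1): y = %.3g at step %d", y_new, it))
    }
    if (y_new >= 1) abort("EoS solubility iterate reached y >= 1 (nonphysical)")
    if (abs(y_new - y) <= 1e-10 * y) return(y_new)
    y <- y_new
  }
  abort(sprintf("EoS fixed point did not converge; last iterate %.6g", y))
}
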