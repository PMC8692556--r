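# Fast inner loop: solute fugacity coefficient in a binary (solute, CO2)
# vdW2 PR mixture, scalar arithmetic only.
.phi_solute_binary <- function(y, T_K, P_Pa, a1, a2, b1, b2, kij, lij) {
  x1 <- y; x2 <- 1 - y
  a12 <- (1 - kij) * sqrt(a1 * a2)
  b12 <- (1 - lij) * (b1 + b2) / 2
  am <- x1 * x1 * a1 + 2 * x1 * x2 * a12 + x2 * x2 * a2
  bm <- x1 * x1 * b1 + 2 * x1 * x2 * b12 + x2 * x2 * b2
  ah <- 2 * (x1 * a1 + x2 * a12)
  bh <- 2 * (x1 * b1 + x2 * b12) - bm
  A <- am * P_Pa / (.R_GAS * T_K)^2
  B <- bm * P_Pa / (.R_GAS * T_K)
  Z <- pr_solve_z(T_K, P_Pa, am, bm)
  kernel <- log((Z + (1 + sqrt(2)) * B) / (Z + (1 - sqrt(2)) * B))
  exp((bh / bm) * (Z - 1) - log(Z - B) -
        A / (2 * sqrt(2) * B) * (ah / am - bh / bm) * kernel)
}

# Vector of EoS solubilities over a dataset for given interaction and psub
# per point; warm-started fixed point. Returns NA where iteration fails.
.eos_y2_all <- function(data, solute, solvent, kij, lij, psub_vec) {
  Ts <- unique(data$T_K)
  pures <- lapply(Ts, function(Tk) {
    list(s = pr_pure(Tk, solute), f = pr_pure(Tk, solvent))
  })
  names(pures) <- as.character(Ts)
  vs <- solute$Vsolid_m3_mol
  out <- rep(NA_real_, nrow(data))
  for (i in seq_len(nrow(data))) {
    Tk <- data$T_K[i]; P <- data$P_MPa[i] * 1e6
    ps <- psub_vec[i]
    if (!is.finite(ps) || ps <= 0 || ps >= P) next
    pp <- pures[[as.character(Tk)]]
    poy <- exp((P - ps) * vs / (.R_GAS * Tk))
    y <- 1e-8
    ok <- FALSE
    for (it in seq_len(200)) {
      phi2 <- tryCatch(
        .phi_solute_binary(y, Tk, P, pp$s$a, pp$f$a, pp$s$b, pp$f$b, kij, lij),
        error = function(e) NA_real_
      )
      if (!is.finite(phi2) || phi2 <= 0) break
      y_new <- ps / (P * phi2) * poy
      if (!is.finite(y_new) || y_new <= 0 || y_new >= 1) break
      if (abs(y_new - y) <= 1e-10 * y) { y <- y_new; ok <- TRUE; break }
      y <- y_new
    }
    if (ok) out[i] <- y
  }
  out
}

#' Fit the PR-EoS + vdW2 solid-solubility model
#'
#' Two regression modes. `"t_dependent"` fits one (kij, lij) pair per
#' isotherm with the sublimation pressure taken from a supplied table
#' (default: the solute spec's estimated values). `"t_independent"` co-fits
#' a single (kij, lij) pair plus the three sublimation-pressure coefficients
#' (beta/R, gamma/R, Delta_sub_delta/R of [psub_from_coeffs()]) against all
#' points at once. Both minimise the relative-deviation objective by seeded
#' multistart Nelder-Mead; interaction parameters are bounded to `[-2, 2]`.
#'
#' @param data solubility table.
#' @param solute,solvent [component_spec()] records.
#' @param mode `"t_independent"` (default) or `"t_dependent"`.
#' @param psub_table named vector (T in K -> Pa) for `"t_dependent"` mode;
#'   defaults to `solute$psub_Pa`.
#' @param seed,n_starts multistart control.
#' @return A `sccosol_fit` with extra fields `mode`, `interaction` and (in
#'   temperature-independent mode) `sub_coeffs`; `per_isotherm` holds the
#'   per-temperature parameters and AARD.
#' @export
fit_pr_eos <- function(data, solute = component_clemastine(),
                       solvent = component_co2(),
                       mode = c("t_independent", "t_dependent"),
                       psub_table = NULL, seed = 42, n_starts = 16) {
  mode <- match.arg(mode)
  data <- validate_solubility_data(data)
  set.seed(seed)
  if (mode == "t_dependent") {
    psub_table <- psub_table %||% solute$psub_Pa
    if (is.null(psub_table)) abort("t_dependent mode needs a psub table")
    rows <- list(); pars <- list()
    for (Tk in unique(data$T_K)) {
      iso <- data[data$T_K == Tk, ]
      ps <- unname(psub_table[as.character(Tk)])
      if (is.na(ps)) abort(paste0("no sublimation pressure tabulated at T = ", Tk))
      of <- function(p) {
        y <- .eos_y2_all(iso, solute, solvent, p[1], p[2], rep(ps, nrow(iso)))
        if (anyNA(y)) return(Inf)
        objective_rel(iso$y2, y)
      }
      starts <- c(list(c(0.5, 0.5), c(0, 0)),
                  lapply(seq_len(max(0, n_starts - 2)),
                         function(i) runif(2, -1, 1)))
      best <- .multistart(of, starts, lower = c(-2, -2), upper = c(2, 2))
      y_cal <- .eos_y2_all(iso, solute, solvent, best$par[1], best$par[2],
                           rep(ps, nrow(iso)))
      rows[[as.character(Tk)]] <- tibble::tibble(
        T_K = Tk, kij = best$par[1], lij = best$par[2],
        aard_percent = aard_percent(iso$y2, y_cal)
      )
      pars[[as.character(Tk)]] <- list(par = best$par, psub = ps)
    }
    per_iso <- dplyr::bind_rows(rows)
    y_all <- unlist(lapply(unique(data$T_K), function(Tk) {
      iso <- data[data$T_K == Tk, ]
      p <- pars[[as.character(Tk)]]
      .eos_y2_all(iso, solute, solvent, p$par[1], p$par[2],
                  rep(p$psub, nrow(iso)))
    }))
    # 2 interaction parameters per isotherm
    np <- 2L * length(unique(data$T_K))
    res <- new_fit_result("pr_eos_tdep", lapply(pars, `[[`, "par"), data,
                          y_all, np, seed,
                          extra = list(mode = mode, per_isotherm = per_iso))
    return(res)
  }

  # temperature-independent: theta = (kij, lij, beta/R, gamma/R, ddelta/R)
  sub_init <- c(10, -8000, 10)
  if (!is.null(solute$psub_Pa) && length(solute$psub_Pa) >= 3) {
    Tt <- as.numeric(names(solute$psub_Pa))
    f <- lm(log(as.numeric(solute$psub_Pa)) ~ I(1 / Tt) + I(log(Tt / 298.15)))
    sub_init <- unname(coef(f))
  }
  of <- function(p) {
    ps <- exp(p[3] + p[4] / data$T_K + p[5] * log(data$T_K / 298.15))
    y <- .eos_y2_all(data, solute, solvent, p[1], p[2], ps)
    if (anyNA(y)) return(Inf)
    objective_rel(data$y2, y)
  }
  starts <- c(
    list(c(0.5, 0.5, sub_init), c(0.8, 0.7, sub_init)),
    lapply(seq_len(max(0, n_starts - 2)), function(i) {
      c(runif(2, -1, 1), sub_init * (1 + 0.3 * rnorm(3)))
    })
  )
  lower <- c(-2, -2, -200, -5e4, -500)
  upper <- c(2, 2, 200, 5e4, 500)
  best <- .multistart(of, starts, lower = lower, upper = upper, maxit = 3000)
  p <- best$par
  ps <- exp(p[3] + p[4] / data$T_K + p[5] * log(data$T_K / 298.15))
  y_cal <- .eos_y2_all(data, solute, solvent, p[1], p[2], ps)
  per_iso <- data |>
    dplyr::mutate(y_cal = y_cal) |>
    dplyr::group_by(.data$T_K) |>
    dplyr::summarise(aard_percent = aard_percent(.data$y2, .data$y_cal))
  new_fit_result(
    "pr_eos_tindep",
    setNames(as.list(p), c("kij", "lij", "beta_over_R", "gamma_over_R",
                           "dsubdelta_over_R")),
    data, y_cal, 5L, seed,
    extra = list(
      mode = mode,
      interaction = list(kij = p[1], lij = p[2]),
      sub_coeffs = list(beta_over_R = p[3], gamma_over_R = p[4],
                        dsubdelta_over_R = p[5]),
      per_isotherm = per_iso
    )
  )
}
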