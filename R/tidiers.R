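.param_names <- function(model_id, n) {
  nm <- switch(
    model_id,
    alwi_garlapati = c("A1", "A2", "A3"),
    bartle = c("B1", "B2", "B3"),
    bian = c("D1", "D2", "D3", "D4", "D5"),
    chrastil = c("kappa", "E1", "E2"),
    ref_chrastil = c("kappa_p", "F1", "F2"),
    garlapati_madras = c("G1", "G2", "G3", "G4", "G5"),
    mt = c("H1", "H2", "H3"),
    sodeifian = c("I1", "I2", "I3", "I4", "I5", "I6"),
    reddy_garlapati = c("J1", "J2", "J3", "J4", "J5", "J6"),
    mahesh_garlapati = c("K1", "K2", "K3"),
    NULL
  )
  nm %||% paste0("p", seq_len(n))
}

#' Tidy a fit result
#'
#' @param x a `sccosol_fit`.
#' @param ... unused.
#' @return A tibble with one row per fitted parameter (`term`, `estimate`).
#' @export
tidy.sccosol_fit <- function(x, ...) {
  est <- unlist(x$params)
  nm <- names(est)
  if (is.null(nm) || any(nm == "")) nm <- .param_names(x$model_id, length(est))
  tibble::tibble(term = nm, estimate = unname(est))
}

#' One-row fit summary
#'
#' @param x a `sccosol_fit`.
#' @param ... unused.
#' @return A one-row tibble with AARD, SSE, R2, AIC, AICc, sizes and seed.
#' @export
glance.sccosol_fit <- function(x, ...) {
  tibble::tibble(
    model_id = x$model_id, aard_percent = x$aard_percent, sse = x$sse,
    r2 = x$r2, aic = x$aic, aicc = x$aicc, n_points = x$n_points,
    n_params = x$n_params, seed = x$seed
  )
}

#' Predicted-vs-measured isotherm overlay for a fit
#'
#' @param object a `sccosol_fit` (must carry its data, as produced by the
#'   fitting functions).
#' @param ... unused.
#' @return A ggplot: measured points and model curves versus pressure, one
#'   colour per isotherm.
#' @export
autoplot.sccosol_fit <- function(object, ...) {
  df <- dplyr::mutate(object$data, y_cal = object$y_cal,
                      isotherm = factor(.data$T_K))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$P_MPa, colour = .data$isotherm)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$y2)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$y_cal)) +
    ggplot2::scale_y_continuous(labels = function(v) format(v, scientific = TRUE)) +
    ggplot2::labs(x = "P (MPa)", y = expression(y[2]),
                  colour = "T (K)",
                  title = paste0(object$model_id, "  (AARD ",
                                 sprintf("%.1f", object$aard_percent), "%)")) +
    ggplot2::theme_minimal()
}

#' Self-consistency plot of the MT transform
#'
#' @param data solubility table.
#' @param H MT parameter triple (see [mt_selfconsistency()]).
#' @return A ggplot of the transformed points with the collapsing line.
#' @export
plot_mt_consistency <- function(data, H) {
  mt <- mt_selfconsistency(data, H)
  ggplot2::ggplot(mt$points,
                  ggplot2::aes(x = .data$rho_kg_m3, y = .data$mt_transform)) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$T_K))) +
    ggplot2::geom_abline(slope = mt$slope, intercept = mt$intercept) +
    ggplot2::labs(x = expression(rho[1] ~ (kg ~ m^-3)),
                  y = expression(T ~ ln(y[2] * P) - H[3] * T),
                  colour = "T (K)",
                  subtitle = sprintf("R^2 = %.3f", mt$r2)) +
    ggplot2::theme_minimal()
}
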