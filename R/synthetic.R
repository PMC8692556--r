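#' Generate a synthetic solubility dataset
#'
#' Perturbs model-generated solubilities on a (T, P, rho) grid with
#' multiplicative noise, y2 = y_model * (1 + eps). The default grid is the
#' packaged 24-point clemastine measurement grid (308-338 K, 12-27 MPa) and
#' the default noise is centred Gaussian with 5% relative scale, matching
#' the 1-5% relative standard deviations typical of repeated loop-sampling
#' measurements; uniform noise of the same standard deviation is selectable.
#' Results are clipped to (0, 1); grid points where the model fails are
#' dropped with a warning. Deterministic for a fixed seed.
#'
#' @param model_id density-model identifier (ignored when `predict_fn` is
#'   given).
#' @param params parameter vector for `model_id`.
#' @param grid data frame with `T_K`, `P_MPa`, `rho_kg_m3`; defaults to the
#'   packaged measurement grid.
#' @param noise_rel relative noise scale (>= 0).
#' @param seed RNG seed.
#' @param noise `"gaussian"` or `"uniform"` (equal standard deviation).
#' @param predict_fn optional function(grid) -> y2 overriding the density
#'   model (e.g. an EoS or cluster-model closure).
#' @param solvent solvent [component_spec()].
#' @return A tibble with columns `T_K`, `P_MPa`, `rho_kg_m3`, `y2`.
#' @export
#' @examples
#' generate_synthetic("chrastil", c(3.0938, -11.003, -4907.2),
#'                    noise_rel = 0.05, seed = 1)
generate_synthetic <- function(model_id, params, grid = NULL,
                               noise_rel = 0.05, seed = 1,
                               noise = c("gaussian", "uniform"),
                               predict_fn = NULL,
                               solvent = component_co2()) {
  noise <- match.arg(noise)
  if (noise_rel < 0) abort("noise_rel must be >= 0")
  if (is.null(grid)) {
    grid <- clemastine_table2()[, c("T_K", "P_MPa", "rho_kg_m3")]
  }
  y0 <- if (is.null(predict_fn)) {
    predict_density(grid, model_id, params, solvent)
  } else {
    predict_fn(grid)
  }
  keep <- is.finite(y0) & y0 > 0 & y0 < 1
  if (!all(keep)) {
    warn(sprintf("dropping %d grid point(s) where the model failed",
                 sum(!keep)))
  }
  grid <- grid[keep, , drop = FALSE]
  y0 <- y0[keep]
  set.seed(seed)
  eps <- if (noise == "gaussian") {
    rnorm(length(y0), 0, noise_rel)
  } else {
    runif(length(y0), -sqrt(3) * noise_rel, sqrt(3) * noise_rel)
  }
  y <- pmin(pmax(y0 * (1 + eps), 1e-300), 1 - 1e-12)
  tibble::tibble(T_K = grid$T_K, P_MPa = grid$P_MPa,
                 rho_kg_m3 = grid$rho_kg_m3, y2 = y)
}
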