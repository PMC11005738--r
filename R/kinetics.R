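#' Fit Michaelis-Menten parameters by the double-reciprocal method
#'
#' Ordinary least squares on the Lineweaver-Burk transform
#' `1/v = (KM/Vmax) * (1/S) + 1/Vmax`: the fitted intercept gives `Vmax`, the
#' slope gives `KM`, and `kcat = Vmax / enzyme_conc`. Reciprocal-space
#' regression amplifies noise at low substrate concentrations; see
#' [fit_michaelis_menten()] for a direct nonlinear cross-check.
#'
#' @param data Data frame with positive columns `substrate` (mM) and `rate`
#'   (concentration/s), at least 2 distinct substrate levels.
#' @param enzyme_conc Enzyme concentration used to convert `Vmax` to `kcat`
#'   (same concentration unit as `rate` numerator per second).
#' @return A tibble of class `mm_params`: `KM` (mM), `Vmax`, `kcat` (1/s),
#'   `efficiency` (`kcat/KM`, 1/(mM s)).
#' @examples
#' d <- data.frame(substrate = c(0.1, 0.2, 0.5, 1, 2, 5))
#' d$rate <- 114 * 1e-3 * d$substrate / (0.38 + d$substrate)
#' fit_double_reciprocal(d, enzyme_conc = 1e-3)
#' @export
fit_double_reciprocal <- function(data, enzyme_conc) {
  stopifnot(is.data.frame(data), all(c("substrate", "rate") %in% names(data)))
  s <- data$substrate; v <- data$rate
  if (length(s) != length(v) || any(s <= 0) || any(v <= 0)) {
    abort("substrate and rate must be equal-length positive vectors")
  }
  if (length(unique(s)) < 2) abort("need >= 2 distinct substrate levels")
  if (enzyme_conc <= 0) abort("`enzyme_conc` must be positive")
  fit <- lm(I(1 / v) ~ I(1 / s))
  intercept <- coef(fit)[[1]]
  slope <- coef(fit)[[2]]
  if (intercept <= 0) {
    abort("non-positive fitted Vmax: data curvature or noise defeats the double-reciprocal fit")
  }
  vmax <- 1 / intercept
  km <- slope * vmax
  if (km <= 0) abort("non-positive fitted KM")
  kcat <- vmax / enzyme_conc
  structure(tibble::tibble(KM = km, Vmax = vmax, kcat = kcat,
                           efficiency = catalytic_efficiency(kcat, km)),
            class = c("mm_params", "tbl_df", "tbl", "data.frame"))
}

#' Direct nonlinear Michaelis-Menten fit
#'
#' Cross-check for [fit_double_reciprocal()]: fits
#' `v = Vmax * S / (KM + S)` by nonlinear least squares in rate space, which
#' weights observations evenly instead of inflating low-substrate noise.
#'
#' @inheritParams fit_double_reciprocal
#' @return An `mm_params` tibble.
#' @export
fit_michaelis_menten <- function(data, enzyme_conc) {
  stopifnot(is.data.frame(data), all(c("substrate", "rate") %in% names(data)))
  s <- data$substrate; v <- data$rate
  if (any(s <= 0) || any(v <= 0)) abort("substrate and rate must be positive")
  # start from the double-reciprocal estimate; converges in a few steps
  lb <- fit_double_reciprocal(data, enzyme_conc)
  start <- list(vmax = lb$Vmax, km = lb$KM)
  # scaleOffset makes convergence well-defined on (near-)zero-residual data
  fit <- stats::nls(v ~ vmax * s / (km + s), start = start,
                    control = stats::nls.control(scaleOffset = 1))
  est <- coef(fit)
  if (est[["vmax"]] <= 0 || est[["km"]] <= 0) abort("nonlinear fit did not converge to positive parameters")
  kcat <- est[["vmax"]] / enzyme_conc
  structure(tibble::tibble(KM = est[["km"]], Vmax = est[["vmax"]], kcat = kcat,
                           efficiency = catalytic_efficiency(kcat, est[["km"]])),
            class = c("mm_params", "tbl_df", "tbl", "data.frame"))
}

#' Catalytic efficiency kcat/KM
#'
#' @param kcat Turnover number (1/s).
#' @param KM Michaelis constant (mM).
#' @return `kcat / KM` in 1/(mM s).
#' @examples
#' catalytic_efficiency(114, 0.38) # 300
#' @export
catalytic_efficiency <- function(kcat, KM) {
  if (any(KM <= 0) || any(kcat <= 0)) abort("kcat and KM must be positive")
  kcat / KM
}

#' Fold change between catalytic efficiencies
#'
#' @param eff_new,eff_ref Efficiencies (1/(mM s)); `eff_ref > 0`.
#' @return `eff_new / eff_ref` (reported to 2 decimals in summaries).
#' @examples
#' round(fold_change(1158.20, 300.00), 2) # 3.86
#' @export
fold_change <- function(eff_new, eff_ref) {
  if (any(eff_ref <= 0)) abort("reference efficiency must be positive")
  eff_new / eff_ref
}

#' Simulate initial-rate data from Michaelis-Menten parameters
#'
#' Forward model used for round-trip validation of the kinetics fitters.
#'
#' @param KM Michaelis constant (mM).
#' @param kcat Turnover (1/s).
#' @param enzyme_conc Enzyme concentration.
#' @param substrate Substrate concentrations (mM).
#' @return A tibble with `substrate` and `rate`.
#' @export
mm_rates <- function(KM, kcat, enzyme_conc, substrate) {
  stopifnot(KM > 0, kcat > 0, enzyme_conc > 0, all(substrate > 0))
  vmax <- kcat * enzyme_conc
  tibble::tibble(substrate = substrate, rate = vmax * substrate / (KM + substrate))
}
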