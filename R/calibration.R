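#' Fit a titer-to-signal calibration curve
#'
#' The colorimetric assay signal (Al3+ complexation absorbance, a.u.) rises
#' monotonically but sublinearly with product titer. The curve family is a
#' power law anchored at both ends,
#' `signal(t) = s0 + (s_max - s0) * (t / c_max)^h`,
#' which passes exactly through the zero-titer point `(0, s0)` and the
#' top anchor `(c_max, s_max)`; the exponent `h > 0` is chosen to minimize the
#' squared signal error at the interior points (with a single interior point
#' it is matched exactly, in closed form).
#'
#' @param points A data frame with columns `titer` (mg/L) and `signal` (a.u.),
#'   at least 3 rows with distinct titers, one of them at titer 0.
#' @return An object of class `calibration_curve` with fields `s0`, `s_max`,
#'   `c_max`, `exponent`.
#' @examples
#' fit_calibration(data.frame(titer = c(0, 130, 1500), signal = c(0.01, 0.2, 1.34)))
#' @export
fit_calibration <- function(points) {
  stopifnot(is.data.frame(points), all(c("titer", "signal") %in% names(points)))
  points <- points[order(points$titer), , drop = FALSE]
  t <- points$titer
  s <- points$signal
  if (length(unique(t)) < 3) abort("calibration needs >= 3 points with distinct titers")
  if (min(t) != 0) abort("calibration needs an anchor at titer 0")
  if (any(diff(s) <= 0)) abort("calibration points must be strictly increasing in signal")
  s0 <- s[1]
  c_max <- t[length(t)]
  s_max <- s[length(s)]
  ti <- t[-c(1, length(t))]
  si <- s[-c(1, length(s))]
  # normalized interior residuals: (si - s0)/(s_max - s0) should equal (ti/c_max)^h
  u <- ti / c_max
  v <- (si - s0) / (s_max - s0)
  if (length(ti) == 1) {
    h <- log(v) / log(u)
  } else {
    sse <- function(h) sum((v - u^h)^2)
    # bracket around the log-log regression slope; a naive wide interval is
    # numerically flat at large h and defeats golden-section search
    h0 <- unname(coef(lm(log(v) ~ log(u)))[2])
    if (!is.finite(h0) || h0 <= 0) h0 <- 1
    h <- optimize(sse, h0 * c(0.2, 5))$minimum
  }
  if (!is.finite(h) || h <= 0) abort("calibration fit produced a non-positive exponent")
  structure(list(s0 = s0, s_max = s_max, c_max = c_max, exponent = h),
            class = "calibration_curve")
}

#' Paper-anchored default calibration
#'
#' Curve through (0 mg/L, 0.01 a.u.), (130, 0.2), (1500, 1.34) — the anchors
#' of the naringenin Al3+ assay; exponent ~ 0.796.
#' @return A `calibration_curve`.
#' @export
default_calibration <- function() {
  fit_calibration(data.frame(titer = c(0, 130, 1500), signal = c(0.01, 0.2, 1.34)))
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve> signal = %.4g + %.4g * (titer/%.4g)^%.4g  [%.4g..%.4g a.u.]\n",
    x$s0, x$s_max - x$s0, x$c_max, x$exponent, x$s0, x$s_max))
  invisible(x)
}

#' Map titer to assay signal
#'
#' @param titer Titers in mg/L, in `[0, c_max]` unless `extrapolate = TRUE`.
#' @param curve A `calibration_curve`.
#' @param extrapolate Allow titers beyond `c_max` (the power law extends
#'   naturally); out-of-range input errors otherwise.
#' @return Signals in a.u.
#' @export
signal_from_titer <- function(titer, curve, extrapolate = FALSE) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (any(titer < 0) || (!extrapolate && any(titer > curve$c_max))) {
    abort(sprintf("titer outside calibration range [0, %g] mg/L", curve$c_max))
  }
  curve$s0 + (curve$s_max - curve$s0) * (titer / curve$c_max)^curve$exponent
}

#' Map assay signal to titer
#'
#' Inverse of [signal_from_titer()].
#'
#' @param signal Signals in a.u., in `[s0, s_max]` unless `extrapolate = TRUE`.
#' @inheritParams signal_from_titer
#' @return Titers in mg/L.
#' @export
titer_from_signal <- function(signal, curve, extrapolate = FALSE) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (any(signal < curve$s0) || (!extrapolate && any(signal > curve$s_max))) {
    abort(sprintf("signal outside calibration range [%g, %g] a.u.", curve$s0, curve$s_max))
  }
  curve$c_max * ((signal - curve$s0) / (curve$s_max - curve$s0))^(1 / curve$exponent)
}

#' @export
tidy.calibration_curve <- function(x, ...) {
  tibble::tibble(
    term = c("s0", "s_max", "c_max", "exponent"),
    estimate = c(x$s0, x$s_max, x$c_max, x$exponent),
    unit = c("a.u.", "a.u.", "mg/L", "")
  )
}

#' @export
autoplot.calibration_curve <- function(object, n = 200, ...) {
  grid <- tibble::tibble(
    titer = seq(0, object$c_max, length.out = n),
    signal = signal_from_titer(seq(0, object$c_max, length.out = n), object)
  )
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$titer, y = .data$signal)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "naringenin titer (mg/L)", y = "Al3+ assay signal (a.u.)")
}
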