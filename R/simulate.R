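#' Parameters of the series-bottleneck pathway simulator
#'
#' A four-step linear pathway behaves like resistors in series: steady-state
#' flux is the harmonic combination of per-step capacities, so the weakest
#' step is the bottleneck and raising any other step yields diminishing
#' returns. Each step's capacity is `k_i * s_i`: a per-enzyme rate
#' coefficient times the promoter strength driving it. An optional imbalance
#' penalty models intermediate toxicity: when the strongest upstream capacity
#' exceeds the weakest downstream capacity by more than `toxicity_ratio`, the
#' titer is multiplied by `toxicity_penalty`, which makes over-driving an
#' upstream gene harmful and generates sign-epistasis-like interactions.
#'
#' @param capacity Positive per-enzyme rate coefficients, one per pathway
#'   position (flux units per strength unit).
#' @param yield_factor mg/L of product per unit steady-state flux.
#' @param noise_sd SD of multiplicative lognormal measurement noise
#'   (log-space).
#' @param toxicity_ratio Upstream/downstream capacity imbalance (>= 1)
#'   triggering the penalty.
#' @param toxicity_penalty Multiplicative titer reduction in (0, 1].
#' @param upstream_steps How many leading positions count as "upstream" for
#'   the imbalance check (default 2: TAL and 4CL feed intermediates to CHS
#'   and CHI).
#' @return A list of class `pathway_params`.
#' @export
pathway_params <- function(capacity = c(TAL = 1, `4CL` = 0.8, CHS = 0.6, CHI = 1.2),
                           yield_factor = 30,
                           noise_sd = 0.15,
                           toxicity_ratio = 20,
                           toxicity_penalty = 0.5,
                           upstream_steps = 2) {
  stopifnot(all(capacity > 0), yield_factor > 0, noise_sd >= 0,
            toxicity_ratio >= 1, toxicity_penalty > 0, toxicity_penalty <= 1,
            upstream_steps >= 1, upstream_steps < length(capacity))
  structure(list(capacity = capacity, yield_factor = yield_factor,
                 noise_sd = noise_sd, toxicity_ratio = toxicity_ratio,
                 toxicity_penalty = toxicity_penalty,
                 upstream_steps = as.integer(upstream_steps)),
            class = "pathway_params")
}

# per-row matrix of step capacities k_i * s_i
step_capacities <- function(assignments, spec, params) {
  k <- params$capacity
  if (length(k) != length(spec$positions)) {
    abort("`capacity` length must match the number of pathway positions")
  }
  s <- vapply(seq_along(spec$positions), function(i) {
    alph <- spec$alphabet[[i]]
    st <- alph$strength[match(as.character(assignments[[spec$positions[i]]]), alph$id)]
    if (anyNA(st)) abort(paste0("unresolvable promoter at position ", spec$positions[i]))
    st
  }, numeric(nrow(assignments)))
  if (is.null(dim(s))) s <- matrix(s, nrow = nrow(assignments))
  if (any(s <= 0)) abort("zero promoter strength gives a degenerate pathway")
  sweep(s, 2, k, `*`)
}

#' Steady-state pathway flux of promoter assignments
#'
#' `J = 1 / sum_i 1/(k_i * s_i)`: the harmonic (series-resistance) flux law.
#' J is strictly increasing in every strength and bounded above by every
#' single-step capacity.
#'
#' @param assignments Data frame of promoter assignments (one column per
#'   position).
#' @param spec A `library_spec` carrying promoter strengths.
#' @param params A [pathway_params()].
#' @return Numeric flux, one value per assignment row.
#' @export
steady_flux <- function(assignments, spec, params = pathway_params()) {
  cap <- step_capacities(assignments, spec, params)
  1 / rowSums(1 / cap)
}

#' Expected (noise-free) titer of promoter assignments
#'
#' `yield_factor * J`, multiplied by `toxicity_penalty` for assignments whose
#' upstream/downstream capacity imbalance exceeds `toxicity_ratio`.
#'
#' @inheritParams steady_flux
#' @return Numeric expected titers (mg/L).
#' @export
titer_mean <- function(assignments, spec, params = pathway_params()) {
  cap <- step_capacities(assignments, spec, params)
  flux <- 1 / rowSums(1 / cap)
  up <- seq_len(params$upstream_steps)
  imbalance <- apply(cap[, up, drop = FALSE], 1, max) /
    apply(cap[, -up, drop = FALSE], 1, min)
  penalty <- ifelse(imbalance > params$toxicity_ratio, params$toxicity_penalty, 1)
  params$yield_factor * flux * penalty
}

#' Simulate a promoter-library screen
#'
#' Draws `n` assignments uniformly with replacement from the design space,
#' computes expected titers under the series-bottleneck model, applies
#' multiplicative lognormal measurement noise, and reads out the assay signal
#' through the calibration curve. The emitted schema matches what the
#' curation functions consume.
#'
#' @param spec A `library_spec`.
#' @param params A [pathway_params()].
#' @param n Number of clones to screen.
#' @param seed Integer seed; the dataset is fully reproducible.
#' @param calibration A `calibration_curve` for the signal column.
#' @param plate_size Wells per simulated plate (used for `plate_id`).
#' @return A tibble: `strain_id`, one promoter column per position,
#'   `signal` (a.u.), `titer` (mg/L), `plate_id`.
#' @examples
#' simulate_screen(default_library_spec(), n = 5, seed = 1)
#' @export
simulate_screen <- function(spec, params = pathway_params(), n, seed,
                            calibration = default_calibration(),
                            plate_size = 96) {
  stopifnot(n >= 1)
  ids <- lapply(spec$alphabet, function(a) a$id)
  assignments <- with_seed(seed, {
    cols <- lapply(ids, function(a) a[sample.int(length(a), n, replace = TRUE)])
    names(cols) <- spec$positions
    tibble::as_tibble(cols)
  })
  mu <- titer_mean(assignments, spec, params)
  eps <- with_seed(seed + 1L, rnorm(n, 0, params$noise_sd))
  titer <- mu * exp(eps)
  dplyr::bind_cols(
    tibble::tibble(strain_id = sprintf("S%05d", seq_len(n))),
    assignments,
    tibble::tibble(
      signal = signal_from_titer(titer, calibration, extrapolate = TRUE),
      titer = titer,
      plate_id = sprintf("plate%02d", (seq_len(n) - 1) %/% plate_size + 1)
    )
  )
}

#' Classify pairwise epistasis from a fitness quartet
#'
#' Given fitness (or titer) of wild type `f00`, single mutants `f10`/`f01`,
#' and double mutant `f11`, computes the log-scale interaction
#' `eps = log f11 - log f10 - log f01 + log f00`. If `|eps| <= tol` the pair
#' is additive (`none`). Otherwise each mutation's log-effect is compared
#' across backgrounds: if both effects change sign the pair shows
#' `reciprocal_sign` epistasis, if exactly one does it is `sign`, and if
#' neither does the interaction only modulates magnitude (`magnitude`).
#' Vectorized over quartets; invariant to swapping the two mutation labels
#' and to global rescaling.
#'
#' @param f00,f10,f01,f11 Positive fitness values.
#' @param tol Additivity tolerance in log-units (default 0.05).
#' @return Character vector in
#'   `c("none", "magnitude", "sign", "reciprocal_sign")`.
#' @examples
#' classify_epistasis(1, 2, 3, 6)      # multiplicative: none
#' classify_epistasis(1, 2, 2, 1)      # reciprocal sign
#' classify_epistasis(1, 2, 1.5, 2.2)  # magnitude
#' @export
classify_epistasis <- function(f00, f10, f01, f11, tol = 0.05) {
  if (any(c(f00, f10, f01, f11) <= 0)) {
    abort("log-scale epistasis needs positive fitness values")
  }
  l00 <- log(f00); l10 <- log(f10); l01 <- log(f01); l11 <- log(f11)
  eps <- l11 - l10 - l01 + l00
  dA0 <- l10 - l00; dA1 <- l11 - l01 # effect of mutation A without/with B
  dB0 <- l01 - l00; dB1 <- l11 - l10
  flips <- (sign(dA0) * sign(dA1) < 0) + (sign(dB0) * sign(dB1) < 0)
  ifelse(abs(eps) <= tol, "none",
         ifelse(flips == 2, "reciprocal_sign",
                ifelse(flips == 1, "sign", "magnitude")))
}
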