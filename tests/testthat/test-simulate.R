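one_design <- function(...) {
  v <- c(...)
  tibble::as_tibble(as.list(setNames(v, c("TAL", "4CL", "CHS", "CHI"))))
}

unit_spec <- function() {
  # promoters U1..U4 with strengths 1, 2, 3, 4 at every position
  library_spec(promoter_roster(paste0("U", 1:4), 1:4))
}

test_that("steady flux follows the series-resistance law", {
  spec <- unit_spec()
  p <- pathway_params(capacity = c(1, 1, 1, 1), noise_sd = 0)
  # all step capacities 1 -> J = 1/4
  expect_equal(steady_flux(one_design("U1", "U1", "U1", "U1"), spec, p), 0.25)
  # doubling one step -> J = 1/(3 + 1/2) = 2/7
  expect_equal(steady_flux(one_design("U2", "U1", "U1", "U1"), spec, p), 2 / 7)
  # permutation symmetry with equal parameters
  expect_equal(steady_flux(one_design("U1", "U2", "U1", "U1"), spec, p),
               steady_flux(one_design("U1", "U1", "U2", "U1"), spec, p))
})

test_that("flux is bounded by each step capacity and concave in strength", {
  spec <- unit_spec()
  p <- pathway_params(capacity = c(0.5, 1, 2, 1.5))
  designs <- enumerate_space(spec)
  J <- steady_flux(designs, spec, p)
  caps <- promflux:::step_capacities(designs, spec, p)
  expect_true(all(J <= apply(caps, 1, min) + 1e-12))
  # concavity along one coordinate: second differences of J in s_1 are <= 0
  base <- one_design("U1", "U2", "U2", "U2")
  Js <- vapply(paste0("U", 1:4), function(pr) {
    d <- base; d$TAL <- pr
    steady_flux(d, spec, p)
  }, numeric(1))
  expect_true(all(diff(Js) > 0)) # strictly increasing in strength
  expect_true(all(diff(diff(Js)) < 1e-12)) # diminishing returns
})

test_that("titer applies the toxicity penalty exactly when imbalance trips", {
  spec <- unit_spec()
  p_off <- pathway_params(capacity = c(1, 1, 1, 1), toxicity_penalty = 1)
  p_on <- pathway_params(capacity = c(1, 1, 1, 1), toxicity_ratio = 3,
                         toxicity_penalty = 0.4)
  balanced <- one_design("U2", "U2", "U2", "U2")
  expect_equal(titer_mean(balanced, spec, p_off),
               p_off$yield_factor * steady_flux(balanced, spec, p_off))
  # strong TAL (4) over weak CHS (1): imbalance 4 > ratio 3 -> penalty applies
  skewed <- one_design("U4", "U2", "U1", "U2")
  expect_equal(titer_mean(skewed, spec, p_on),
               p_on$yield_factor * steady_flux(skewed, spec, p_on) * 0.4)
  expect_equal(titer_mean(balanced, spec, p_on),
               p_on$yield_factor * steady_flux(balanced, spec, p_on))
})

test_that("with the penalty active, raising an upstream promoter can lower titer", {
  spec <- library_spec(promoter_roster(paste0("G", 1:3), c(1, 4, 16)))
  p <- pathway_params(capacity = c(1, 1, 1, 1), toxicity_ratio = 8,
                      toxicity_penalty = 0.3)
  # brute-force scan over the full 3^4 grid for a violation of monotonicity
  grid <- enumerate_space(spec)
  titers <- titer_mean(grid, spec, p)
  ids <- spec$alphabet[[1]]$id
  found_drop <- FALSE
  for (i in seq_len(nrow(grid))) {
    j <- match(grid$TAL[i], ids)
    if (j < 3) {
      up <- grid[i, ]
      up$TAL <- ids[j + 1]
      k <- which(grid$TAL == up$TAL & grid$`4CL` == up$`4CL` &
                   grid$CHS == up$CHS & grid$CHI == up$CHI)
      if (titers[k] < titers[i]) found_drop <- TRUE
    }
  }
  expect_true(found_drop)
})

test_that("with toxicity disabled, expected titer is monotone in every strength", {
  spec <- unit_spec()
  p <- quiet_params(capacity = c(1, 0.7, 1.3, 0.9))
  grid <- enumerate_space(spec)
  titers <- titer_mean(grid, spec, p)
  ids <- spec$alphabet[[1]]$id
  for (pos in spec$positions) {
    for (i in seq_len(nrow(grid))) {
      j <- match(grid[[pos]][i], ids)
      if (j < length(ids)) {
        up <- grid[i, ]
        up[[pos]] <- ids[j + 1]
        k <- which(Reduce(`&`, lapply(spec$positions, function(q) grid[[q]] == up[[q]])))
        expect_gte(titers[k], titers[i])
      }
    }
  }
})

test_that("largest marginal gain comes from relieving the bottleneck step", {
  spec <- unit_spec()
  p <- quiet_params(capacity = c(1, 1, 1, 1))
  base <- one_design("U1", "U3", "U3", "U3") # TAL is the bottleneck
  gains <- vapply(spec$positions, function(pos) {
    up <- base
    j <- match(base[[pos]], spec$alphabet[[pos]]$id)
    up[[pos]] <- spec$alphabet[[pos]]$id[j + 1]
    titer_mean(up, spec, p) - titer_mean(base, spec, p)
  }, numeric(1))
  expect_equal(names(which.max(gains)), "TAL")
})

test_that("simulated screens are seeded, noise-free when asked, and calibrated", {
  spec <- default_library_spec()
  d0 <- simulate_screen(spec, quiet_params(), n = 50, seed = 9)
  expect_equal(d0$titer, titer_mean(d0, spec, quiet_params()))
  d1 <- simulate_screen(spec, pathway_params(), n = 50, seed = 9)
  d2 <- simulate_screen(spec, pathway_params(), n = 50, seed = 9)
  expect_equal(d1, d2)
  d3 <- simulate_screen(spec, pathway_params(), n = 50, seed = 10)
  expect_false(identical(d1$titer, d3$titer))
  # signal column equals the calibrated transform of the titer column
  cal <- default_calibration()
  expect_equal(d1$signal, signal_from_titer(d1$titer, cal, extrapolate = TRUE))
})

test_that("log-titer residuals average to zero over a large sample", {
  spec <- default_library_spec()
  p <- pathway_params(noise_sd = 0.15)
  n <- 10000
  d <- simulate_screen(spec, p, n = n, seed = 77)
  mu <- titer_mean(d, spec, p)
  resid <- log(d$titer) - log(mu)
  expect_lt(abs(mean(resid)), 3 * p$noise_sd / sqrt(n))
  expect_equal(sd(resid), p$noise_sd, tolerance = 0.05)
})

test_that("epistasis classifier reproduces hand-worked quartets", {
  expect_equal(classify_epistasis(1, 2, 3, 6), "none") # exactly multiplicative
  expect_equal(classify_epistasis(1, 2, 2, 1), "reciprocal_sign")
  expect_equal(classify_epistasis(1, 2, 1.5, 2.2), "magnitude")
  # one mutation flips sign across backgrounds, the other does not
  expect_equal(classify_epistasis(1, 2, 1.5, 1.8), "sign")
  expect_error(classify_epistasis(0, 1, 1, 1), "positive")
})

test_that("epistasis classification is label- and scale-invariant", {
  withr::with_seed(19, {
    for (rep in 1:50) {
      q <- exp(rnorm(4, 0, 1))
      cls <- classify_epistasis(q[1], q[2], q[3], q[4])
      # swap the two mutation labels: f10 <-> f01
      expect_equal(classify_epistasis(q[1], q[3], q[2], q[4]), cls)
      # rescale all fitness values
      expect_equal(classify_epistasis(10 * q[1], 10 * q[2], 10 * q[3], 10 * q[4]),
                   cls, tolerance = 0)
    }
  })
})

test_that("the simulator's imbalance penalty generates sign epistasis", {
  spec <- library_spec(promoter_roster(c("lo", "mid", "hi"), c(1, 3, 30)))
  p <- pathway_params(capacity = c(1, 1, 1, 1), toxicity_ratio = 10,
                      toxicity_penalty = 0.2, noise_sd = 0)
  # mutation A: TAL lo->hi (trips the imbalance penalty on its own);
  # mutation B: CHS lo->hi (restores balance, letting A pay off)
  f00 <- titer_mean(one_design("lo", "mid", "lo", "mid"), spec, p)
  f10 <- titer_mean(one_design("hi", "mid", "lo", "mid"), spec, p)
  f01 <- titer_mean(one_design("lo", "mid", "hi", "mid"), spec, p)
  f11 <- titer_mean(one_design("hi", "mid", "hi", "mid"), spec, p)
  expect_lt(f10, f00) # strong TAL alone is deleterious
  expect_gt(f11, f01) # but beneficial once CHS is strong
  expect_equal(classify_epistasis(f00, f10, f01, f11), "sign")
})
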