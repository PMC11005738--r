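#' Build a promoter roster
#'
#' A roster is one row per promoter: an id, a fluorescence-derived strength in
#' arbitrary units, and a strength class (`low`/`medium`/`high`). When `class`
#' is omitted it is assigned by terciles of log-strength via
#' [classify_strength()].
#'
#' @param id Character vector of unique promoter labels.
#' @param strength Non-negative numeric activities (arbitrary units).
#' @param class Optional character vector in `c("low","medium","high")`.
#' @return A tibble with columns `id`, `strength`, `strength_class`.
#' @examples
#' promoter_roster(c("Pa", "Pb", "Pc"), c(1, 10, 100))
#' @export
promoter_roster <- function(id, strength, class = NULL) {
  id <- as.character(id)
  if (anyDuplicated(id)) abort("promoter ids must be unique within a roster")
  if (length(strength) != length(id)) abort("`id` and `strength` lengths differ")
  if (any(!is.finite(strength)) || any(strength < 0)) {
    abort("promoter strengths must be finite and >= 0")
  }
  if (is.null(class)) {
    class <- if (length(unique(strength)) < 3) {
      rep("medium", length(strength)) # too few levels for terciles
    } else {
      classify_strength(strength, strength_cutoffs(strength))
    }
  }
  class <- as.character(class)
  bad <- setdiff(unique(class), c("low", "medium", "high"))
  if (length(bad)) abort(paste0("unknown strength class: ", paste(bad, collapse = ", ")))
  tibble::tibble(id = id, strength = strength, strength_class = class)
}

#' Default 12-promoter roster
#'
#' A synthetic stand-in roster of 12 promoters whose strengths are log-spaced
#' across a 211-fold dynamic range (the spread reported for characterized
#' promoter panels used in pathway refactoring). The ids `P01`..`P12` are
#' placeholders, not real promoter names; override the roster to describe a
#' real library.
#'
#' @param n Number of promoters (default 12).
#' @param fold Dynamic range between the strongest and weakest promoter.
#' @return A [promoter_roster()] tibble.
#' @export
default_promoter_roster <- function(n = 12, fold = 211) {
  stopifnot(n >= 2, fold > 1)
  strength <- fold^(seq(0, n - 1) / (n - 1))
  promoter_roster(sprintf("P%02d", seq_len(n)), strength)
}

#' Specify a combinatorial promoter library
#'
#' A library spec is an ordered set of pathway gene positions (default the
#' naringenin pathway order TAL, 4CL, CHS, CHI) plus, for each position, the
#' alphabet of candidate promoters. A single roster may be shared by all
#' positions (the common fully-crossed design) or a named list of rosters may
#' give each position its own alphabet.
#'
#' @param roster A [promoter_roster()] tibble, or a named list of rosters
#'   (names matching `positions`).
#' @param positions Character vector of ordered gene labels.
#' @return An object of class `library_spec` with elements `positions`
#'   (character) and `alphabet` (named list of roster tibbles).
#' @examples
#' spec <- library_spec(default_promoter_roster())
#' space_size(spec)
#' @export
library_spec <- function(roster, positions = c("TAL", "4CL", "CHS", "CHI")) {
  positions <- as.character(positions)
  if (!length(positions) || anyDuplicated(positions)) {
    abort("positions must be a non-empty set of unique gene labels")
  }
  if (is.data.frame(roster)) {
    alphabet <- stats::setNames(rep(list(tibble::as_tibble(roster)), length(positions)), positions)
  } else if (is.list(roster)) {
    if (!setequal(names(roster), positions)) {
      abort("per-position roster list must be named by the positions")
    }
    alphabet <- lapply(roster[positions], tibble::as_tibble)
  } else {
    abort("`roster` must be a data frame or a named list of data frames")
  }
  for (pos in positions) {
    alph <- alphabet[[pos]]
    if (nrow(alph) < 1) abort(paste0("empty promoter alphabet at position ", pos))
    if (anyDuplicated(alph$id)) abort(paste0("duplicate promoter ids at position ", pos))
  }
  structure(list(positions = positions, alphabet = alphabet), class = "library_spec")
}

#' Default 12 x 4 library spec
#'
#' The [default_promoter_roster()] crossed over the four naringenin pathway
#' genes, giving a 12^4 = 20,736 member design space.
#' @return A `library_spec`.
#' @export
default_library_spec <- function() {
  library_spec(default_promoter_roster())
}

#' @export
print.library_spec <- function(x, ...) {
  sizes <- vapply(x$alphabet, nrow, integer(1))
  cat("<library_spec> ", paste(x$positions, collapse = " > "), "\n", sep = "")
  cat("  alphabet sizes: ", paste(sizes, collapse = " x "),
      "  (space size ", format(space_size(x), big.mark = ","), ")\n", sep = "")
  invisible(x)
}

#' Number of designs in a library
#' @param spec A `library_spec`.
#' @return Product of the per-position alphabet sizes.
#' @export
space_size <- function(spec) {
  stopifnot(inherits(spec, "library_spec"))
  prod(vapply(spec$alphabet, nrow, integer(1)))
}

#' Enumerate every promoter assignment in a library
#'
#' Returns the full combinatorial space, one row per assignment, in
#' deterministic lexicographic order: the first position is most significant
#' and, within a position, promoters follow alphabet (roster) order.
#'
#' @param spec A `library_spec`.
#' @return A tibble with one character column per position.
#' @examples
#' nrow(enumerate_space(library_spec(default_promoter_roster(2), c("A", "B"))))
#' @export
enumerate_space <- function(spec) {
  stopifnot(inherits(spec, "library_spec"))
  ids <- lapply(spec$alphabet, function(a) a$id)
  # expand.grid varies the first factor fastest; reverse so position 1 is the
  # most significant digit, then restore column order
  grid <- expand.grid(rev(ids), KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, rev(seq_along(ids)), drop = FALSE]
  names(grid) <- spec$positions
  tibble::as_tibble(grid)
}

#' One-hot encode promoter assignments
#'
#' Encodes each assignment as a block-structured binary vector: one block per
#' pathway position (in spec order), block length equal to that position's
#' alphabet size, exactly one 1 per block at the index of the chosen promoter.
#' Columns are named `"<position>.<promoterId>"`.
#'
#' @param assignments A data frame with one character column per position
#'   (extra columns ignored).
#' @param spec A `library_spec`.
#' @return A numeric matrix with `sum(alphabet sizes)` columns.
#' @examples
#' spec <- default_library_spec()
#' x <- encode_one_hot(enumerate_space(spec)[1:3, ], spec)
#' dim(x)
#' @export
encode_one_hot <- function(assignments, spec) {
  stopifnot(inherits(spec, "library_spec"))
  miss <- setdiff(spec$positions, names(assignments))
  if (length(miss)) {
    abort(paste0("assignments are missing position column(s): ", paste(miss, collapse = ", ")))
  }
  n <- nrow(assignments)
  blocks <- lapply(spec$positions, function(pos) {
    alph <- spec$alphabet[[pos]]$id
    idx <- match(as.character(assignments[[pos]]), alph)
    if (anyNA(idx)) {
      bad <- unique(as.character(assignments[[pos]])[is.na(idx)])
      abort(paste0("unknown promoter id(s) at position ", pos, ": ",
                   paste(bad, collapse = ", ")))
    }
    m <- matrix(0, n, length(alph), dimnames = list(NULL, paste(pos, alph, sep = ".")))
    m[cbind(seq_len(n), idx)] <- 1
    m
  })
  do.call(cbind, blocks)
}

#' Decode a one-hot feature matrix back to promoter assignments
#'
#' Inverse of [encode_one_hot()]. Each block must contain exactly one 1.
#'
#' @param x A one-hot matrix (or vector for a single assignment).
#' @param spec A `library_spec`.
#' @return A tibble of assignments.
#' @export
decode_one_hot <- function(x, spec) {
  stopifnot(inherits(spec, "library_spec"))
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  sizes <- vapply(spec$alphabet, nrow, integer(1))
  if (ncol(x) != sum(sizes)) {
    abort(paste0("feature width ", ncol(x), " does not match library width ", sum(sizes)))
  }
  offset <- 0L
  cols <- lapply(seq_along(spec$positions), function(i) {
    block <- x[, offset + seq_len(sizes[i]), drop = FALSE]
    offset <<- offset + sizes[i]
    ones <- rowSums(block == 1)
    if (any(ones != 1) || any(rowSums(block != 0) != 1)) {
      abort(paste0("malformed one-hot block for position ", spec$positions[i],
                   ": expected exactly one 1 per row"))
    }
    spec$alphabet[[i]]$id[max.col(block)]
  })
  names(cols) <- spec$positions
  tibble::as_tibble(cols)
}

#' Clones needed to cover a combinatorial library
#'
#' Smallest number of uniform independent draws `m` such that the probability
#' of observing every one of `space_size` equally likely designs at least once
#' is at least `coverage_prob`, under the independence approximation
#' `P(m) = (1 - (1 - 1/n)^m)^n` to the coupon-collector coverage probability.
#'
#' @param space_size Number of distinct designs (n >= 1).
#' @param coverage_prob Target probability in (0, 1).
#' @return Integer clone count.
#' @examples
#' coverage_sample_size(12^4, 0.95) # > 267,000
#' coverage_sample_size(2, 0.75)
#' @export
coverage_sample_size <- function(space_size, coverage_prob) {
  if (length(space_size) != 1 || !is.finite(space_size) || space_size < 1 ||
      space_size != floor(space_size)) {
    abort("`space_size` must be a single positive integer")
  }
  if (length(coverage_prob) != 1 || !is.finite(coverage_prob) ||
      coverage_prob <= 0 || coverage_prob >= 1) {
    abort("`coverage_prob` must lie strictly between 0 and 1")
  }
  n <- space_size
  if (n == 1) return(1L)
  # invert (1 - (1 - 1/n)^m)^n >= p: m >= log(1 - p^(1/n)) / log(1 - 1/n);
  # expm1/log1p keep the tail accurate for large n
  target <- -expm1(log(coverage_prob) / n) # 1 - p^(1/n)
  m <- ceiling(log(target) / log1p(-1 / n))
  # guard against edge-of-ceiling rounding
  while (coverage_probability(n, m) < coverage_prob) m <- m + 1
  while (m > 1 && coverage_probability(n, m - 1) >= coverage_prob) m <- m - 1
  as.integer(m)
}

#' Approximate coupon-collector coverage probability
#'
#' Probability that `m` uniform draws from `n` categories observe every
#' category at least once, under the independence approximation
#' `(1 - (1 - 1/n)^m)^n`.
#'
#' @param n Number of categories.
#' @param m Number of draws (vectorized).
#' @return Probabilities in \[0, 1\].
#' @export
coverage_probability <- function(n, m) {
  stopifnot(n >= 1, all(m >= 0))
  if (n == 1) return(as.numeric(m >= 1))
  exp(n * log(-expm1(m * log1p(-1 / n))))
}

#' Tercile cutoffs of log-strength
#'
#' Default cutoffs separating low/medium/high promoter classes: the 1/3 and
#' 2/3 quantiles of log-strength, mapped back to the strength scale.
#'
#' @param strength Positive promoter strengths.
#' @return Numeric length-2 increasing cutoffs.
#' @export
strength_cutoffs <- function(strength) {
  if (any(strength <= 0)) abort("log-strength cutoffs require positive strengths")
  exp(unname(quantile(log(strength), c(1 / 3, 2 / 3))))
}

#' Classify promoter strengths into low/medium/high
#'
#' Boundary values are assigned downward: `strength <= cutoffs[1]` is `low`,
#' `strength <= cutoffs[2]` is `medium`, anything above is `high`.
#'
#' @param strength Non-negative strengths (vectorized).
#' @param cutoffs Strictly increasing length-2 numeric cutoffs.
#' @return Character vector in `c("low","medium","high")`.
#' @export
classify_strength <- function(strength, cutoffs) {
  if (length(cutoffs) != 2 || diff(cutoffs) <= 0) {
    abort("`cutoffs` must be two strictly increasing thresholds")
  }
  if (any(strength < 0)) abort("promoter strength cannot be negative")
  ifelse(strength <= cutoffs[1], "low",
         ifelse(strength <= cutoffs[2], "medium", "high"))
}

#' Dynamic range of a promoter roster
#'
#' Ratio of the strongest to the weakest strength in a roster.
#'
#' @param strength Positive strengths (or a roster tibble).
#' @return A single fold-change.
#' @export
dynamic_range <- function(strength) {
  if (is.data.frame(strength)) strength <- strength$strength
  if (any(strength <= 0)) abort("dynamic range requires positive strengths")
  max(strength) / min(strength)
}
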