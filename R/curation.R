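#' Call screening hits above a signal threshold
#'
#' Keeps the records whose assay signal is strictly greater than the
#' threshold ("higher than" semantics), preserving input order.
#'
#' @param records A data frame with a `signal` column (a.u.).
#' @param threshold Non-negative signal cutoff.
#' @return The hit subset, same columns, original order.
#' @examples
#' call_hits(data.frame(strain_id = 1:3, signal = c(0.25, 0.15, 0.05)), 0.2)
#' @export
call_hits <- function(records, threshold) {
  stopifnot(is.data.frame(records), "signal" %in% names(records))
  if (length(threshold) != 1 || !is.finite(threshold) || threshold < 0) {
    abort("`threshold` must be a single non-negative signal value")
  }
  if (anyNA(records$signal)) {
    who <- if ("strain_id" %in% names(records)) {
      records$strain_id[is.na(records$signal)]
    } else {
      which(is.na(records$signal))
    }
    abort(paste0("records with missing signal: ", paste(who, collapse = ", ")))
  }
  dplyr::filter(tibble::as_tibble(records), .data$signal > threshold)
}

#' Assemble a balanced training set from hits and low-signal background
#'
#' The screening funnel keeps every high-signal hit and pads the set with a
#' seeded uniform sample (without replacement) of low-signal background
#' records so the model also sees poor producers. With 108 hits and 50
#' background records this reproduces a 158-record training set. All records
#' must carry validated titers. Set `per_plate = TRUE` to stratify the
#' background sample evenly across a `plate_id` column instead of sampling
#' from the pooled background.
#'
#' @param hits Data frame of hit records (must include `titer`).
#' @param background_pool Data frame of candidate background records.
#' @param n_background How many background records to draw.
#' @param seed Integer seed for the background sample.
#' @param per_plate Stratify the background draw by `plate_id`.
#' @return A tibble of all hits plus the sampled background, with a
#'   `provenance` column in `c("high_signal_hit", "low_signal_background")`.
#' @export
assemble_balanced_set <- function(hits, background_pool, n_background, seed,
                                  per_plate = FALSE) {
  stopifnot(is.data.frame(hits), is.data.frame(background_pool))
  for (d in list(hits, background_pool)) {
    if (nrow(d) && (!"titer" %in% names(d) || anyNA(d$titer))) {
      abort("all curated records must carry validated titers")
    }
  }
  if (n_background > nrow(background_pool)) {
    abort(sprintf("background pool has %d records, %d requested",
                  nrow(background_pool), n_background))
  }
  pick <- with_seed(seed, {
    if (per_plate) {
      if (!"plate_id" %in% names(background_pool)) {
        abort("`per_plate = TRUE` requires a plate_id column")
      }
      plates <- split(seq_len(nrow(background_pool)), background_pool$plate_id)
      quota <- spread_count(n_background, length(plates))
      unlist(purrr::map2(plates, quota, function(idx, k) {
        if (k > length(idx)) abort("a plate has fewer background records than its quota")
        sample(idx, k)
      }), use.names = FALSE)
    } else {
      sample(nrow(background_pool), n_background)
    }
  })
  out <- dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(hits), provenance = "high_signal_hit"),
    dplyr::mutate(tibble::as_tibble(background_pool)[sort(pick), , drop = FALSE],
                  provenance = "low_signal_background")
  )
  if ("strain_id" %in% names(out) && anyDuplicated(out$strain_id)) {
    abort("curated set contains duplicate strain identifiers")
  }
  out
}

# evenly spread n picks over k groups (first groups get the remainder)
spread_count <- function(n, k) {
  base <- n %/% k
  rep(base, k) + c(rep(1, n %% k), rep(0, k - n %% k))
}

# run code under a local RNG seed without disturbing the global stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Scan titer thresholds for training-set augmentation
#'
#' Second-round screening yields extra high-producer records; adding all of
#' them can unbalance the training set. This scan augments the base set with
#' pool records whose titer strictly exceeds each candidate threshold, scores
#' each augmented set with a user-supplied trainer (a cross-validated error,
#' lower is better), and returns the threshold with the lowest score. Ties go
#' to the largest threshold, i.e. the smallest augmentation.
#'
#' @param base Data frame: the curated training set.
#' @param pool Data frame of candidate augmentation records (must carry
#'   `titer`).
#' @param thresholds Numeric titer cutoffs (mg/L) to scan.
#' @param trainer `function(data, seed)` returning a single numeric score
#'   (e.g. cross-validated RMSE).
#' @param seed Integer seed passed through to the trainer.
#' @return A list with `best_threshold`, `augmented` (the winning set, added
#'   records tagged `provenance = "augmentation"`), and `scores` (a tibble
#'   with `threshold`, `n_added`, `score`).
#' @export
augment_threshold_scan <- function(base, pool, thresholds, trainer, seed) {
  stopifnot(is.data.frame(base), is.data.frame(pool), is.function(trainer))
  if (!length(thresholds)) abort("`thresholds` must be non-empty")
  if (nrow(pool) && (!"titer" %in% names(pool) || anyNA(pool$titer))) {
    abort("augmentation pool records must carry titers")
  }
  base <- tibble::as_tibble(base)
  candidates <- purrr::map(thresholds, function(th) {
    add <- dplyr::filter(tibble::as_tibble(pool), .data$titer > th)
    if (nrow(add)) add$provenance <- "augmentation"
    dplyr::bind_rows(base, add)
  })
  scores <- purrr::imap_dbl(candidates, function(d, i) {
    tryCatch(trainer(d, seed),
             error = function(e) abort(paste0(
               "trainer failed at threshold ", thresholds[i], ": ", conditionMessage(e))))
  })
  n_added <- vapply(candidates, nrow, integer(1)) - nrow(base)
  # minimum score; among ties prefer the largest threshold (least augmentation)
  best_i <- which(scores == min(scores) & thresholds == max(thresholds[scores == min(scores)]))[1]
  list(
    best_threshold = thresholds[best_i],
    augmented = candidates[[best_i]],
    scores = tibble::tibble(threshold = thresholds, n_added = n_added, score = scores)
  )
}
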