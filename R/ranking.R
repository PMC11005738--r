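#' Score every design in the combinatorial space
#'
#' Enumerates the full library, predicts a titer for each assignment with the
#' fitted ensemble, and ranks designs by predicted titer (descending). Ties
#' resolve by lexicographic assignment order (the enumeration order), so the
#' ranking is deterministic across platforms. Scoring is chunked internally
#' to bound memory.
#'
#' @param model A fitted `ensemble_model`.
#' @param spec A `library_spec`; defaults to the one the model was trained
#'   with.
#' @param exclude Optional data frame of assignments to drop from the ranking
#'   (e.g. already-measured strains).
#' @param chunk_size Designs scored per batch.
#' @return A tibble: `rank`, one column per position, `predicted_titer`.
#' @export
score_space <- function(model, spec = model$spec, exclude = NULL,
                        chunk_size = 4096) {
  stopifnot(inherits(model, "ensemble_model"), inherits(spec, "library_spec"))
  designs <- enumerate_space(spec)
  if (!is.null(exclude)) {
    key <- function(d) do.call(paste, c(d[spec$positions], sep = "\r"))
    designs <- designs[!key(designs) %in% key(exclude), , drop = FALSE]
  }
  n <- nrow(designs)
  starts <- seq(1, n, by = chunk_size)
  pred <- numeric(n)
  for (s in starts) {
    i <- s:min(s + chunk_size - 1, n)
    pred[i] <- predict(model, designs[i, , drop = FALSE])
  }
  out <- dplyr::mutate(designs, predicted_titer = pred)
  # descending score; ties keep enumeration (lexicographic) order
  out <- out[order(-out$predicted_titer), , drop = FALSE]
  dplyr::bind_cols(tibble::tibble(rank = seq_len(nrow(out))), out)
}

#' Top-k candidate designs
#'
#' @param scored Output of [score_space()].
#' @param k Number of designs, `1 <= k <= nrow(scored)`.
#' @return The first `k` rows by rank.
#' @export
top_k <- function(scored, k) {
  stopifnot(is.data.frame(scored), "rank" %in% names(scored))
  if (length(k) != 1 || k < 1 || k > nrow(scored)) {
    abort(sprintf("`k` must be in [1, %d]", nrow(scored)))
  }
  scored[order(scored$rank), , drop = FALSE][seq_len(k), , drop = FALSE]
}

#' Enrichment of true top producers among top-ranked designs
#'
#' Validation statistic for synthetic benchmarks: the fraction of the top-k
#' predicted designs whose true titer falls in the true top-q quantile,
#' divided by q. A perfect ranking gives 1/q; a random ranking has
#' expectation ~1; an anti-correlated ranking approaches 0.
#'
#' @param scored Output of [score_space()].
#' @param truth Data frame with the same position columns plus a true `titer`
#'   column, covering every scored assignment.
#' @param k Number of top designs to examine.
#' @param q Top quantile defining "true top producers", in (0, 1).
#' @return The enrichment fold (dimensionless).
#' @export
enrichment_fold <- function(scored, truth, k, q) {
  if (length(q) != 1 || q <= 0 || q >= 1) abort("`q` must lie in (0, 1)")
  pos <- setdiff(names(truth), "titer")
  key <- function(d) do.call(paste, c(d[pos], sep = "\r"))
  true_titer <- truth$titer[match(key(scored), key(truth))]
  if (anyNA(true_titer)) abort("`truth` must cover every scored assignment")
  cutoff <- quantile(truth$titer, 1 - q, type = 1)
  top <- top_k(dplyr::mutate(scored, .true = true_titer), k)
  mean(top$.true > cutoff) / q
}
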