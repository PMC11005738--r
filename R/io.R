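#' Read / write screening tables
#'
#' Screening tables are comma-separated UTF-8 text with a header row. The
#' required columns are `strain_id` plus one `promoter_<position>` column per
#' library position; `signal_au`, `titer_mgL` and `plate_id` are optional and
#' unknown columns are preserved. On read, promoter ids are validated against
#' the library spec when one is supplied. Internally the promoter columns are
#' renamed to the bare position labels and the measurement columns to
#' `signal`/`titer`; [write_screen_table()] reverses the mapping, so a
#' write-then-read round trip is lossless.
#'
#' @param path File path.
#' @param spec Optional `library_spec` used to validate promoter ids.
#' @return A tibble of screen records.
#' @export
read_screen_table <- function(path, spec = NULL) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  required <- "strain_id"
  if (!is.null(spec)) required <- c(required, paste0("promoter_", spec$positions))
  miss <- setdiff(required, names(raw))
  if (length(miss)) {
    abort(paste0("screen table is missing required column(s): ",
                 paste(miss, collapse = ", ")))
  }
  names(raw) <- sub("^promoter_", "", names(raw))
  if ("signal_au" %in% names(raw)) names(raw)[names(raw) == "signal_au"] <- "signal"
  if ("titer_mgL" %in% names(raw)) names(raw)[names(raw) == "titer_mgL"] <- "titer"
  if (!is.null(spec)) {
    for (pos in spec$positions) {
      bad <- which(!raw[[pos]] %in% spec$alphabet[[pos]]$id)
      if (length(bad)) {
        abort(sprintf("unknown promoter id '%s' at position %s (row %d)",
                      raw[[pos]][bad[1]], pos, bad[1]))
      }
    }
  }
  raw
}

#' @rdname read_screen_table
#' @param records A tibble of screen records (position columns named by gene
#'   label, measurements in `signal`/`titer`).
#' @export
write_screen_table <- function(records, path, spec = NULL) {
  out <- tibble::as_tibble(records)
  positions <- if (!is.null(spec)) spec$positions else
    intersect(c("TAL", "4CL", "CHS", "CHI"), names(out))
  for (pos in positions) {
    names(out)[names(out) == pos] <- paste0("promoter_", pos)
  }
  if ("signal" %in% names(out)) names(out)[names(out) == "signal"] <- "signal_au"
  if ("titer" %in% names(out)) names(out)[names(out) == "titer"] <- "titer_mgL"
  readr::write_csv(out, path)
  invisible(path)
}

#' Read / write a library spec as JSON
#'
#' The on-disk form records the ordered positions and, per position, the
#' promoter ids, strengths and strength classes, so feature-matrix column
#' order is reproducible from the file alone.
#'
#' @param path File path.
#' @return A `library_spec` ([read_library_spec()]) or `path`, invisibly.
#' @export
read_library_spec <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rosters <- lapply(obj$alphabet, function(a) {
    promoter_roster(a$id, a$strength, a$strength_class)
  })
  library_spec(rosters, positions = obj$positions)
}

#' @rdname read_library_spec
#' @param spec A `library_spec`.
#' @export
write_library_spec <- function(spec, path) {
  stopifnot(inherits(spec, "library_spec"))
  jsonlite::write_json(
    list(positions = spec$positions,
         alphabet = lapply(spec$alphabet, as.list)),
    path, auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a ranked-design table
#'
#' @param scored Output of [score_space()].
#' @param path File path.
#' @export
write_ranked_designs <- function(scored, path) {
  out <- scored
  names(out)[names(out) == "predicted_titer"] <- "predicted_titer_mgL"
  readr::write_csv(out, path)
  invisible(path)
}

#' Run the simulate-curate-train-rank pipeline
#'
#' End-to-end orchestration over the package functions: simulate (or load) a
#' screen, call hits and assemble a balanced training set, fit the greedy
#' ensemble, and rank the full design space. Artifacts — the config snapshot,
#' curated set, estimator ranking, selection trace, metrics, and top designs
#' — are written as delimited text/JSON under `outdir`.
#'
#' @param spec A `library_spec`.
#' @param outdir Output directory (created if needed).
#' @param seed Master seed for every stochastic stage.
#' @param n_screen Clones to simulate when `screen` is NULL.
#' @param screen Optional pre-loaded screen tibble (e.g. from
#'   [read_screen_table()]); must carry `signal` and `titer`.
#' @param params Simulator [pathway_params()] (used when simulating).
#' @param hit_threshold Signal cutoff for hit calling (a.u.).
#' @param n_background Low-signal background records to add.
#' @param roster Estimator roster.
#' @param cv A [cv_config()]; its seed defaults to `seed`.
#' @param top_n How many top designs to report.
#' @return Invisibly, a list with `model`, `curated`, `scored`, `metrics`,
#'   and `outdir`.
#' @export
run_pipeline <- function(spec, outdir, seed = 1L, n_screen = 500,
                         screen = NULL, params = pathway_params(),
                         hit_threshold = 0.2, n_background = 50,
                         roster = default_roster(seed),
                         cv = cv_config(10, seed), top_n = 5) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }
  log_lines <- c(sprintf("seed: %d", seed),
                 sprintf("R: %s", as.character(getRversion())),
                 sprintf("promflux: %s", as.character(utils::packageVersion("promflux"))))
  screen <- stage("simulate", {
    if (is.null(screen)) simulate_screen(spec, params, n_screen, seed) else screen
  })
  write_screen_table(screen, file.path(outdir, "screen.csv"), spec)
  curated <- stage("curate", {
    hits <- call_hits(screen, hit_threshold)
    background <- dplyr::filter(screen, .data$signal <= hit_threshold)
    assemble_balanced_set(hits, background, min(n_background, nrow(background)),
                          seed = seed)
  })
  write_screen_table(curated, file.path(outdir, "curated.csv"), spec)
  model <- stage("train", fit_ensemble(curated, spec, roster, cv))
  readr::write_csv(model$ranking, file.path(outdir, "estimator_ranking.csv"))
  readr::write_csv(model$trace, file.path(outdir, "selection_trace.csv"))
  metrics <- glance(model)
  scored <- stage("rank", score_space(model, spec))
  write_ranked_designs(top_k(scored, top_n), file.path(outdir, "top_designs.csv"))
  jsonlite::write_json(as.list(metrics), file.path(outdir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  config <- list(
    positions = spec$positions, space_size = space_size(spec), seed = seed,
    n_screen = nrow(screen), hit_threshold = hit_threshold,
    n_background = n_background, cv_folds = cv$folds, cv_seed = cv$seed,
    roster = roster$name, top_n = top_n,
    simulator = params[c("capacity", "yield_factor", "noise_sd",
                         "toxicity_ratio", "toxicity_penalty")]
  )
  jsonlite::write_json(config, file.path(outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(outdir, "run.log"))
  write_library_spec(spec, file.path(outdir, "library_spec.json"))
  invisible(list(model = model, curated = curated, scored = scored,
                 metrics = metrics, outdir = outdir))
}
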