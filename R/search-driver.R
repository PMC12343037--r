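# End-to-end batch search over query structures.

#' Search configuration
#'
#' Collects the tunable parameters of the pipeline with their defaults.
#'
#' @param prescreen_tol Anchor pairwise-distance tolerance, Angstrom
#'   (default 3; strict `<`).
#' @param max_combinations Cap on candidate mappings per structure
#'   (default 2000); above it a uniform random subsample is scored.
#' @param score_threshold Acceptance threshold on the mapping score,
#'   Angstrom (default 1; strict `<`).
#' @param neighbor_window Sequence neighbors on each side of every site
#'   residue used in scoring (default 4). Overrides the window stored on the
#'   seed site when not `NULL`.
#' @param rng_seed Global seed; the per-structure sampling seed is derived
#'   from it and the structure id, so results do not depend on batch
#'   composition or ordering (default 0).
#' @param enforce_seed_order Restrict mappings to those preserving the seed
#'   anchors' sequence-rank order (default `FALSE`).
#' @param fit_atoms `"ca+cb"` or `"ca"`: atoms used in the rigid fit.
#' @param additional_match_radius Acceptance radius for additional residues,
#'   Angstrom (default 2).
#' @param score_formula `"mean_over_n"` or `"sum_over_n"`.
#' @param metrics_enabled Compute per-hit whole-structure metrics
#'   (default `TRUE`).
#' @return A `search_config` list.
#' @export
search_config <- function(prescreen_tol = 3.0, max_combinations = 2000L,
                          score_threshold = 1.0, neighbor_window = NULL,
                          rng_seed = 0L, enforce_seed_order = FALSE,
                          fit_atoms = c("ca+cb", "ca"),
                          additional_match_radius = 2.0,
                          score_formula = c("mean_over_n", "sum_over_n"),
                          metrics_enabled = TRUE) {
  fit_atoms <- match.arg(fit_atoms)
  score_formula <- match.arg(score_formula)
  if (prescreen_tol <= 0 || score_threshold <= 0 || additional_match_radius <= 0) {
    stop("tolerances must be > 0")
  }
  if (max_combinations < 1) stop("max_combinations must be >= 1")
  structure(
    list(prescreen_tol = prescreen_tol,
         max_combinations = as.integer(max_combinations),
         score_threshold = score_threshold,
         neighbor_window = if (is.null(neighbor_window)) NULL else as.integer(neighbor_window),
         rng_seed = as.integer(rng_seed),
         enforce_seed_order = isTRUE(enforce_seed_order),
         fit_atoms = fit_atoms,
         additional_match_radius = additional_match_radius,
         score_formula = score_formula,
         metrics_enabled = isTRUE(metrics_enabled)),
    class = "search_config"
  )
}

apply_config_window <- function(site, config) {
  if (!is.null(config$neighbor_window)) site$neighbor_window <- config$neighbor_window
  site
}

# Full per-structure pipeline returning the hit plus a status code.
search_one_detail <- function(query, site, config) {
  site <- apply_config_window(site, config)
  if (is.character(query)) {
    id <- tools::file_path_sans_ext(basename(query))
    parsed <- tryCatch(parse_structure(query), error = function(e) e)
    if (inherits(parsed, "error")) {
      return(list(hit = NULL, reason = "parse_error", id = id,
                  message = conditionMessage(parsed)))
    }
    query <- parsed
  }
  id <- query$id
  if (n_residues(query) < 3) {
    return(list(hit = NULL, reason = "parse_error", id = id,
                message = "fewer than 3 residues"))
  }
  maps <- enumerate_mappings(query, site, config$enforce_seed_order)
  if (!nrow(maps)) return(list(hit = NULL, reason = "no_candidates", id = id))
  maps <- maps[prescreen(maps, query, site, config$prescreen_tol), , drop = FALSE]
  if (!nrow(maps)) return(list(hit = NULL, reason = "no_prescreen_pass", id = id))
  maps <- cap_mappings(maps, config$max_combinations,
                       derive_seed(config$rng_seed, id))
  scored <- lapply(seq_len(nrow(maps)), function(r) {
    score_mapping(query, site, maps[r, ],
                  match_radius = config$additional_match_radius,
                  fit_atoms = config$fit_atoms,
                  score_formula = config$score_formula)
  })
  best <- select_best(scored, config$score_threshold)
  if (is.null(best)) return(list(hit = NULL, reason = "above_threshold", id = id))
  smp <- NA_real_; sls <- NA_real_
  if (config$metrics_enabled) {
    pairing <- pair_ca(site$seed_structure, query, best$transform)
    smp <- structural_mapping_percentage(pairing, query)
    sls <- local_similarity(pairing, query)
  }
  hit <- structure(
    list(structure_id = id, best = best,
         structural_mapping_percentage = smp,
         structural_local_similarity = sls),
    class = "search_hit"
  )
  list(hit = hit, reason = "accepted", id = id)
}

#' Search one query structure for the seed site
#'
#' Runs the full pipeline — parse, enumerate candidate anchor mappings,
#' pre-screen by pairwise distances, cap, score each survivor, select the
#' best — and, when a mapping is accepted, computes the whole-structure
#' similarity metrics with the winning transform.
#'
#' @param query Path to a PDB/mmCIF file, or a parsed `structure_model`.
#' @param site A `seed_site`.
#' @param config A [search_config()].
#' @param detail If `TRUE`, return a list with elements `hit` (the
#'   `search_hit` or `NULL`) and `reason` (one of `accepted`, `parse_error`,
#'   `no_candidates`, `no_prescreen_pass`, `above_threshold`).
#' @return A `search_hit`, or `NULL` when the structure is not accepted (use
#'   `detail = TRUE` or the [search_batch()] log for the reason code).
#' @export
search_one <- function(query, site, config = search_config(), detail = FALSE) {
  res <- search_one_detail(query, site, config)
  if (detail) res[c("hit", "reason")] else res$hit
}

#' @export
print.search_hit <- function(x, ...) {
  cat("search_hit '", x$structure_id, "': score ", sprintf("%.6f", x$best$score),
      ", n_mapped ", x$best$n_mapped,
      ", mapping pct ", sprintf("%.1f", x$structural_mapping_percentage),
      ", local similarity ", sprintf("%.3f", x$structural_local_similarity),
      "\n", sep = "")
  invisible(x)
}

#' Batch search over many query structures
#'
#' Applies [search_one()] to every path, in parallel when `workers > 1`
#' (forked processes via the parallel package; falls back to serial execution
#' where forking is unavailable). The result is independent of the worker
#' count and of the input ordering: per-structure RNG seeds are derived from
#' the structure id, and hits are sorted by ascending score, then id.
#'
#' @param query_paths Character vector of structure file paths (or a list of
#'   parsed `structure_model`s).
#' @param site A `seed_site`.
#' @param config A [search_config()].
#' @param workers Number of worker processes (default 1).
#' @return List of `search_hit` objects sorted by (score, id), with a
#'   `"log"` attribute: a data frame of per-structure status codes.
#' @export
search_batch <- function(query_paths, site, config = search_config(), workers = 1L) {
  if (!length(query_paths)) stop("no query structures given")
  runner <- function(q) search_one_detail(q, site, config)
  results <- if (workers > 1 && .Platform$OS.type == "unix") {
    parallel::mclapply(query_paths, runner, mc.cores = workers)
  } else {
    lapply(query_paths, runner)
  }
  log <- data.frame(
    structure_id = vapply(results, function(r) r$id, character(1)),
    status = vapply(results, function(r) r$reason, character(1)),
    stringsAsFactors = FALSE
  )
  hits <- Filter(Negate(is.null), lapply(results, function(r) r$hit))
  if (length(hits)) {
    sc <- vapply(hits, function(h) h$best$score, numeric(1))
    ids <- vapply(hits, function(h) h$structure_id, character(1))
    hits <- hits[order(sc, ids)]
  }
  attr(hits, "log") <- log
  hits
}
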