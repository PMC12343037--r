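# Scoring of candidate mappings after rigid superposition.

#' Post-transform distance between a seed residue and a query residue
#'
#' The query residue's atoms are mapped into the seed frame by `t`; the
#' distance is the mean of the C-alpha and C-beta separations when both
#' residues have a C-beta, and the C-alpha separation alone otherwise
#' (glycine or missing atom).
#'
#' @param seed_res,query_res Residue lists as returned by the internal
#'   accessor (`position`, `aa3`, `ca`, optional `cb`).
#' @param t A `rigid_transform` mapping query coordinates onto the seed.
#' @return Distance in Angstrom.
#' @export
residue_distance <- function(seed_res, query_res, t) {
  d_ca <- euclid(seed_res$ca, apply_transform(t, query_res$ca))
  if (!is.null(seed_res$cb) && !is.null(query_res$cb)) {
    d_cb <- euclid(seed_res$cb, apply_transform(t, query_res$cb))
    (d_ca + d_cb) / 2
  } else {
    d_ca
  }
}

# Vectorized residue distances between seed residues (indices si) and query
# residues (indices qi) under transform t; same Ca/Cb mean rule.
residue_distances_idx <- function(seed, si, query, qi, t) {
  qca <- apply_transform(t, query$ca[qi, , drop = FALSE])
  d <- sqrt(rowSums((seed$ca[si, , drop = FALSE] - qca)^2))
  both_cb <- !is.na(seed$cb[si, 1]) & !is.na(query$cb[qi, 1])
  if (any(both_cb)) {
    qcb <- apply_transform(t, query$cb[qi[both_cb], , drop = FALSE])
    dcb <- sqrt(rowSums((seed$cb[si[both_cb], , drop = FALSE] - qcb)^2))
    d[both_cb] <- (d[both_cb] + dcb) / 2
  }
  d
}

#' Match the site's additional residues in a query structure
#'
#' For each additional seed residue, query residues of an accepted type are
#' ranked by their post-transform [residue_distance()]; pairs are assigned
#' greedily by ascending distance, one query residue per seed residue and
#' vice versa, and kept only when the distance is below `match_radius`.
#' An additional residue with no acceptable partner is simply absent from the
#' result (which raises the mapping's score through the divisor).
#'
#' @param query A `structure_model`.
#' @param site A `seed_site`.
#' @param t A `rigid_transform` from the anchor fit.
#' @param match_radius Maximum accepted distance in Angstrom (default 2).
#' @param used_query Query positions already consumed (the anchor mapping);
#'   excluded from candidacy.
#' @return Data frame with columns `seed_position`, `query_position`,
#'   `distance`, `kind = "additional"` (possibly zero rows).
#' @export
match_additional <- function(query, site, t, match_radius = 2.0,
                             used_query = integer()) {
  empty <- data.frame(seed_position = integer(), query_position = integer(),
                      distance = numeric(), kind = character(),
                      stringsAsFactors = FALSE)
  if (!length(site$additional)) return(empty)
  seed <- site$seed_structure
  cand <- NULL
  for (sp in site$additional) {
    qpos <- query$position[query$aa3 %in% allowed_types(site, sp) &
                             !query$position %in% used_query]
    if (!length(qpos)) next
    d <- residue_distances_idx(seed, rep(residue_index(seed, sp), length(qpos)),
                               query, residue_index(query, qpos), t)
    keep <- d < match_radius
    if (any(keep)) {
      cand <- rbind(cand, data.frame(seed_position = sp, query_position = qpos[keep],
                                     distance = d[keep], stringsAsFactors = FALSE))
    }
  }
  if (is.null(cand) || !nrow(cand)) return(empty)
  cand <- cand[order(cand$distance, cand$seed_position, cand$query_position), , drop = FALSE]
  taken_seed <- integer(); taken_query <- integer()
  rows <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    if (cand$seed_position[r] %in% taken_seed || cand$query_position[r] %in% taken_query) next
    rows[r] <- TRUE
    taken_seed <- c(taken_seed, cand$seed_position[r])
    taken_query <- c(taken_query, cand$query_position[r])
  }
  out <- cand[rows, , drop = FALSE]
  out <- out[order(out$seed_position), , drop = FALSE]
  out$kind <- "additional"
  rownames(out) <- NULL
  out
}

#' Collect sequence-neighbor residue pairs around the mapped core
#'
#' For every core pair (seed position s, query position q) and every offset
#' in -w..-1, 1..w, the pair (s + offset, q + offset) is scored by
#' [residue_distance()] when both positions exist, regardless of residue
#' type. Offsets truncated at chain termini are skipped, and a (seed, query)
#' pair arising from several overlapping windows — or already present in the
#' core — is counted once.
#'
#' @param query A `structure_model`.
#' @param site A `seed_site`.
#' @param mapped_core Data frame of anchor and additional matches
#'   (`seed_position`, `query_position`, ...).
#' @param t A `rigid_transform`.
#' @param w Window half-width (non-negative integer).
#' @return Data frame with columns `seed_position`, `query_position`,
#'   `distance`, `kind = "neighbor"`.
#' @export
match_neighbors <- function(query, site, mapped_core, t, w = site$neighbor_window) {
  empty <- data.frame(seed_position = integer(), query_position = integer(),
                      distance = numeric(), kind = character(),
                      stringsAsFactors = FALSE)
  if (w == 0 || !nrow(mapped_core)) return(empty)
  seed <- site$seed_structure
  offs <- setdiff(seq.int(-w, w), 0L)
  sp <- rep(mapped_core$seed_position, each = length(offs)) +
    rep(offs, times = nrow(mapped_core))
  qp <- rep(mapped_core$query_position, each = length(offs)) +
    rep(offs, times = nrow(mapped_core))
  ok <- sp %in% seed$position & qp %in% query$position
  sp <- sp[ok]; qp <- qp[ok]
  if (!length(sp)) return(empty)
  key <- paste(sp, qp)
  core_key <- paste(mapped_core$seed_position, mapped_core$query_position)
  keep <- !duplicated(key) & !key %in% core_key
  sp <- sp[keep]; qp <- qp[keep]
  if (!length(sp)) return(empty)
  o <- order(sp, qp)
  sp <- sp[o]; qp <- qp[o]
  d <- residue_distances_idx(seed, residue_index(seed, sp),
                             query, residue_index(query, qp), t)
  data.frame(seed_position = sp, query_position = qp, distance = d,
             kind = "neighbor", stringsAsFactors = FALSE)
}

#' Score one anchor mapping of a query structure
#'
#' Fits the rigid transform on the anchor C-alpha/C-beta point set, gathers
#' the anchors, the matched additional residues and the sequence neighbors of
#' all of them, and computes
#' `score = mean(distances) / n_mapped` (Angstrom; lower is better). Dividing
#' the average by the number of mapped residues penalizes mappings in which
#' additional site residues are not found in the query.
#'
#' @param query A `structure_model`.
#' @param site A `seed_site`.
#' @param mapping Integer vector of 3 query positions for seed anchors 1..3.
#' @param match_radius Acceptance radius for additional residues (Angstrom).
#' @param fit_atoms `"ca+cb"` (default) fits on C-alpha and C-beta of the
#'   anchors; `"ca"` on C-alpha only.
#' @param score_formula `"mean_over_n"` (default, the literal reading of the
#'   score definition) or `"sum_over_n"` (the plain average).
#' @return A `scored_mapping`: list with `mapping`, `transform`, `mapped`
#'   (data frame of all scored residue pairs), `n_mapped` and `score`.
#' @export
score_mapping <- function(query, site, mapping, match_radius = 2.0,
                          fit_atoms = c("ca+cb", "ca"),
                          score_formula = c("mean_over_n", "sum_over_n")) {
  fit_atoms <- match.arg(fit_atoms)
  score_formula <- match.arg(score_formula)
  mapping <- as.integer(mapping)
  if (length(mapping) != 3) stop("a mapping assigns exactly 3 query positions")
  seed <- site$seed_structure
  pts <- paired_anchor_points(seed, site$anchors, query, mapping, fit_atoms)
  t <- fit_transform(pts$query, pts$seed)
  anchors <- data.frame(
    seed_position = site$anchors,
    query_position = mapping,
    distance = residue_distances_idx(seed, residue_index(seed, site$anchors),
                                     query, residue_index(query, mapping), t),
    kind = "anchor", stringsAsFactors = FALSE
  )
  addl <- match_additional(query, site, t, match_radius, used_query = mapping)
  core <- rbind(anchors, addl)
  nbrs <- match_neighbors(query, site, core, t, site$neighbor_window)
  mapped <- rbind(core, nbrs)
  rownames(mapped) <- NULL
  n <- nrow(mapped)
  avg <- mean(mapped$distance)
  score <- switch(score_formula, mean_over_n = avg / n, sum_over_n = avg)
  structure(
    list(mapping = mapping, transform = t, mapped = mapped,
         n_mapped = n, score = score),
    class = "scored_mapping"
  )
}

#' @export
print.scored_mapping <- function(x, ...) {
  cat("scored_mapping: anchors -> (", paste(x$mapping, collapse = ", "),
      "), n_mapped ", x$n_mapped, ", score ", sprintf("%.6f", x$score),
      " Angstrom\n", sep = "")
  invisible(x)
}

#' Select the best-scoring mapping below the acceptance threshold
#'
#' @param scored List of `scored_mapping` objects.
#' @param threshold Acceptance threshold in Angstrom (default 1; strict `<`).
#' @return The lowest-score mapping if its score is below the threshold,
#'   otherwise `NULL`. Ties are broken by the lexicographically smallest
#'   query position triple.
#' @export
select_best <- function(scored, threshold = 1.0) {
  if (!length(scored)) return(NULL)
  sc <- vapply(scored, function(s) s$score, numeric(1))
  best <- which(sc == min(sc))
  if (length(best) > 1) {
    maps <- t(vapply(scored[best], function(s) s$mapping, integer(3)))
    best <- best[order(maps[, 1], maps[, 2], maps[, 3])[1]]
  }
  if (sc[best] < threshold) scored[[best]] else NULL
}
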