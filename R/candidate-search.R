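#' Enumerate candidate anchor mappings in a query structure
#'
#' Builds the Cartesian product of the per-anchor candidate sets (query
#' residues whose type is accepted for that anchor), excluding assignments
#' that reuse a query residue. The output order is deterministic:
#' lexicographic by the triple of query positions.
#'
#' @param query A `structure_model`.
#' @param site A `seed_site`.
#' @param enforce_seed_order If `TRUE`, keep only mappings whose query
#'   positions follow the same rank order as the seed anchor positions
#'   (the restrictive reading of "sequential combinations"); the permissive
#'   default also finds circularly permuted sites.
#' @return Integer matrix with one row per mapping and columns `q1`, `q2`,
#'   `q3`: the query positions assigned to seed anchors 1..3. Zero rows when
#'   any anchor has no candidate.
#' @export
enumerate_mappings <- function(query, site, enforce_seed_order = FALSE) {
  cands <- lapply(site$anchors, function(p) {
    query$position[query$aa3 %in% allowed_types(site, p)]
  })
  empty <- matrix(integer(), 0, 3, dimnames = list(NULL, c("q1", "q2", "q3")))
  if (any(vapply(cands, length, integer(1)) == 0L)) return(empty)
  g <- expand.grid(q1 = cands[[1]], q2 = cands[[2]], q3 = cands[[3]],
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[g$q1 != g$q2 & g$q1 != g$q3 & g$q2 != g$q3, , drop = FALSE]
  if (enforce_seed_order) {
    target <- rank(site$anchors)
    ok <- apply(g, 1, function(q) all(rank(q) == target))
    g <- g[ok, , drop = FALSE]
  }
  if (!nrow(g)) return(empty)
  g <- g[order(g$q1, g$q2, g$q3), , drop = FALSE]
  m <- as.matrix(g)
  dimnames(m) <- list(NULL, c("q1", "q2", "q3"))
  storage.mode(m) <- "integer"
  m
}

#' Pre-screen anchor mappings by pairwise-distance compatibility
#'
#' A mapping survives only if each of the three query anchor-pair C-alpha
#' distances deviates strictly less than `tolerance` from the corresponding
#' seed distance.
#'
#' @param mapping Integer vector of 3 query positions, or a matrix of
#'   mappings as returned by [enumerate_mappings()].
#' @param query A `structure_model`.
#' @param site A `seed_site`.
#' @param tolerance Maximum allowed absolute deviation in Angstrom
#'   (default 3; the comparison is strict `<`).
#' @return Logical scalar (vector input) or logical vector with one entry per
#'   mapping row (matrix input).
#' @export
prescreen <- function(mapping, query, site, tolerance = 3.0) {
  m <- if (is.matrix(mapping)) mapping else matrix(as.integer(mapping), 1, 3)
  if (ncol(m) != 3) stop("a mapping is an ordered triple of query positions")
  if (!nrow(m)) return(logical(0))
  i1 <- residue_index(query, m[, 1])
  i2 <- residue_index(query, m[, 2])
  i3 <- residue_index(query, m[, 3])
  d12 <- sqrt(rowSums((query$ca[i1, , drop = FALSE] - query$ca[i2, , drop = FALSE])^2))
  d13 <- sqrt(rowSums((query$ca[i1, , drop = FALSE] - query$ca[i3, , drop = FALSE])^2))
  d23 <- sqrt(rowSums((query$ca[i2, , drop = FALSE] - query$ca[i3, , drop = FALSE])^2))
  ok <- abs(d12 - site$anchor_distances[1]) < tolerance &
    abs(d13 - site$anchor_distances[2]) < tolerance &
    abs(d23 - site$anchor_distances[3]) < tolerance
  if (is.matrix(mapping)) ok else ok[1]
}

#' Cap the number of candidate mappings by uniform random subsampling
#'
#' When the number of surviving combinations exceeds `cap` (default 2000), a
#' uniform sample without replacement of size `cap` is drawn, reproducibly
#' for a fixed `rng_seed`. The sampled rows are returned in their original
#' (lexicographic) order so downstream processing stays deterministic.
#'
#' @param mappings Mapping matrix (rows are mappings).
#' @param cap Maximum number of mappings to keep (>= 1).
#' @param rng_seed Integer seed for the subsample.
#' @return Mapping matrix with at most `cap` rows.
#' @export
cap_mappings <- function(mappings, cap = 2000L, rng_seed = 0L) {
  if (cap < 1) stop("cap must be >= 1")
  if (!is.matrix(mappings) || nrow(mappings) <= cap) return(mappings)
  idx <- with_seed(rng_seed, sample.int(nrow(mappings), cap))
  mappings[sort(idx), , drop = FALSE]
}
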