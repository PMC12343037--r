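# Whole-structure similarity metrics computed with the active-site transform.

#' Pair the C-alpha traces of seed and query by dynamic programming
#'
#' After mapping the query C-alphas into the seed frame with the hit's
#' transform, a global alignment of the two residue sequences is computed by
#' dynamic programming that maximizes the number of aligned pairs closer
#' than 2 Angstrom (match reward 1 below the cutoff, 0 otherwise; no gap
#' penalty). Only the sub-cutoff pairs are returned; both index sequences are
#' strictly increasing (no crossings).
#'
#' @param seed,query `structure_model` objects.
#' @param t A `rigid_transform` mapping query coordinates onto the seed.
#' @param cutoff Pairing distance cutoff in Angstrom (default 2).
#' @return A `ca_pairing`: list with `pairs` (data frame `seed_index`,
#'   `query_index`, `distance`), `n_seed`, `n_query`.
#' @export
pair_ca <- function(seed, query, t, cutoff = 2.0) {
  n <- n_residues(seed)
  m <- n_residues(query)
  qca <- apply_transform(t, query$ca)
  # n x m matrix of squared distances via the expansion |a-b|^2 = |a|^2 + |b|^2 - 2ab
  d2 <- outer(rowSums(seed$ca^2), rep(1, m)) +
    outer(rep(1, n), rowSums(qca^2)) - 2 * seed$ca %*% t(qca)
  S <- (d2 < cutoff^2) * 1L
  F <- matrix(0L, n + 1L, m + 1L)
  for (i in seq_len(n)) {
    # F[i+1, j+1] = max(F[i, j] + S[i, j], F[i, j+1], F[i+1, j]); the row-wise
    # cummax resolves the left-neighbor dependence without an inner loop
    F[i + 1L, ] <- cummax(c(0L, pmax(F[i, -(m + 1L)] + S[i, ], F[i, -1L])))
  }
  si <- integer(); qi <- integer()
  i <- n; j <- m
  while (i > 0L && j > 0L) {
    if (F[i + 1L, j + 1L] == F[i, j + 1L]) {
      i <- i - 1L
    } else if (F[i + 1L, j + 1L] == F[i + 1L, j]) {
      j <- j - 1L
    } else {
      if (S[i, j] == 1L) { si <- c(i, si); qi <- c(j, qi) }
      i <- i - 1L; j <- j - 1L
    }
  }
  pairs <- data.frame(seed_index = si, query_index = qi,
                      distance = sqrt(pmax(d2[cbind(si, qi)], 0)))
  structure(list(pairs = pairs, n_seed = n, n_query = m), class = "ca_pairing")
}

#' @export
print.ca_pairing <- function(x, ...) {
  cat("ca_pairing: ", nrow(x$pairs), " pairs < cutoff (seed ", x$n_seed,
      " residues, query ", x$n_query, ")\n", sep = "")
  invisible(x)
}

#' Percentage of query residues aligned to the seed
#'
#' @param pairing A `ca_pairing` from [pair_ca()].
#' @param query The query `structure_model` the pairing was computed for.
#' @return Percentage in \[0, 100\]: 100 x (number of retained pairs) /
#'   (number of query residues).
#' @export
structural_mapping_percentage <- function(pairing, query) {
  100 * nrow(pairing$pairs) / n_residues(query)
}

#' Run-length-weighted local structural similarity
#'
#' Aligned pairs are grouped into maximal runs in which both residue indices
#' advance by one. For each run-length threshold L in {5, 10, 15, 20}, let
#' c_L be the fraction of query residues lying in runs of length >= L; the
#' metric is sum(L * c_L) / (5 + 10 + 15 + 20), a value in \[0, 1\] that
#' rewards long contiguously aligned substructure and ignores parts of the
#' query that diverge from the seed.
#'
#' @param pairing A `ca_pairing`.
#' @param query The query `structure_model`.
#' @param lengths Run-length thresholds (default `c(5, 10, 15, 20)`).
#' @return Fraction in \[0, 1\].
#' @export
local_similarity <- function(pairing, query, lengths = c(5L, 10L, 15L, 20L)) {
  p <- pairing$pairs
  nq <- n_residues(query)
  if (!nrow(p)) return(0)
  new_run <- c(TRUE, diff(p$seed_index) != 1L | diff(p$query_index) != 1L)
  run_len <- as.integer(table(cumsum(new_run)))
  cl <- vapply(lengths, function(L) sum(run_len[run_len >= L]) / nq, numeric(1))
  sum(lengths * cl) / sum(lengths)
}
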