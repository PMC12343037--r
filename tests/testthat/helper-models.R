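# In-code fixtures shared across tests.

# Minimal hand-written PDB content: three residues with CA (+CB except GLY).
tiny_pdb_lines <- function() {
  c(
    "ATOM      1  N   SER A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  SER A   1       1.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CB  SER A   1       1.000   1.500   0.000  1.00  0.00           C",
    "ATOM      4  CA  GLY A   2       4.800   0.000   0.000  1.00  0.00           C",
    "ATOM      5  CA  HIS A   3       8.600   0.000   0.000  1.00  0.00           C",
    "ATOM      6  CB  HIS A   3       8.600   1.500   0.000  1.00  0.00           C",
    "END"
  )
}

write_tiny_pdb <- function(lines = tiny_pdb_lines(), name = "tiny") {
  path <- file.path(withr::local_tempdir(.local_envir = parent.frame()),
                    paste0(name, ".pdb"))
  writeLines(lines, path)
  path
}

# Same three residues as a minimal mmCIF atom_site loop.
tiny_cif_lines <- function() {
  c(
    "data_tiny",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.label_atom_id",
    "_atom_site.label_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_seq_id",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 N  SER A 1 0.000 0.000 0.000 1",
    "ATOM 2 CA SER A 1 1.000 0.000 0.000 1",
    "ATOM 3 CB SER A 1 1.000 1.500 0.000 1",
    "ATOM 4 CA GLY A 2 4.800 0.000 0.000 1",
    "ATOM 5 CA HIS A 3 8.600 0.000 0.000 1",
    "ATOM 6 CB HIS A 3 8.600 1.500 0.000 1",
    "#"
  )
}

# A bare triad model whose pairwise C-alpha distances are d = (d12, d13, d23);
# types default to a catalytic-triad-like set. CB omitted (fit on CA only).
triad_model <- function(d, aa3 = c("CYS", "ASP", "HIS"), id = "triad") {
  x3 <- (d[1]^2 + d[2]^2 - d[3]^2) / (2 * d[1])
  y3 <- sqrt(d[2]^2 - x3^2)
  ca <- rbind(c(0, 0, 0), c(d[1], 0, 0), c(x3, y3, 0))
  structure_model(1:3, aa3, ca, id = id)
}

# Random perturbation of a reference triad that always remains a valid
# triangle (redraws on triangle-inequality violations).
random_valid_triad_distances <- function(base = c(8, 10, 12), sd = 2) {
  repeat {
    d <- base + stats::rnorm(3, 0, sd)
    if (all(d > 0) && d[1] + d[2] > d[3] && d[1] + d[3] > d[2] && d[2] + d[3] > d[1]) {
      return(d)
    }
  }
}

# A deterministic proper rigid motion used by invariance tests.
fixed_rigid_motion <- function(angle = 0.7, axis = c(1, 2, 3), shift = c(4, -2, 9)) {
  axis <- axis / sqrt(sum(axis^2))
  K <- rbind(c(0, -axis[3], axis[2]),
             c(axis[3], 0, -axis[1]),
             c(-axis[2], axis[1], 0))
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  structure(list(rotation = R, translation = shift, rmsd = NA_real_),
            class = "rigid_transform")
}

transform_model <- function(model, rt) {
  model$ca <- apply_transform(rt, model$ca)
  ok <- !is.na(model$cb[, 1])
  if (any(ok)) model$cb[ok, ] <- apply_transform(rt, model$cb[ok, , drop = FALSE])
  model
}

# Independent oracle: best rmsd achievable with k random proper rotations
# (translation handled by centroid alignment), for comparison with the
# closed-form fit.
best_random_rotation_rmsd <- function(moving, fixed, k = 1000L) {
  P <- sweep(as.matrix(moving), 2, colMeans(moving))
  Q <- sweep(as.matrix(fixed), 2, colMeans(fixed))
  bigR <- random_rotations_stacked(k)
  M <- bigR %*% t(P)                         # (3k) x m
  Qt <- t(Q)                                 # 3 x m
  E <- (M - Qt[rep(1:3, k), , drop = FALSE])^2
  ss <- rowsum(rowSums(E), rep(seq_len(k), each = 3))
  sqrt(min(ss) / nrow(P))
}

# k uniform random rotation matrices stacked vertically into a (3k) x 3 matrix
# (quaternion method; consumes the current RNG stream).
random_rotations_stacked <- function(k) {
  q <- matrix(stats::rnorm(4 * k), k, 4)
  q <- q / sqrt(rowSums(q^2))
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  bigR <- matrix(0, 3 * k, 3)
  bigR[seq(1, 3 * k, 3), ] <- cbind(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y))
  bigR[seq(2, 3 * k, 3), ] <- cbind(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x))
  bigR[seq(3, 3 * k, 3), ] <- cbind(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2))
  bigR
}

# Exhaustive oracle for the maximum number of sub-cutoff monotone pairs:
# plain recursion over all monotone pairings, no memoization.
oracle_max_monotone_pairs <- function(S) {
  n <- nrow(S); m <- ncol(S)
  rec <- function(i, j) {
    if (i > n || j > m) return(0L)
    max(rec(i + 1L, j), rec(i, j + 1L), rec(i + 1L, j + 1L) + S[i, j])
  }
  rec(1L, 1L)
}

# Pairwise CA-distance indicator matrix for two models under a transform.
pair_indicator <- function(seed, query, t, cutoff = 2) {
  qca <- apply_transform(t, query$ca)
  n <- nrow(seed$ca); m <- nrow(qca)
  S <- matrix(0L, n, m)
  for (i in seq_len(n)) {
    S[i, ] <- as.integer(sqrt(colSums((t(qca) - seed$ca[i, ])^2)) < cutoff)
  }
  S
}
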