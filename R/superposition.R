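# Rigid-body superposition of anchor atom sets (Kabsch / SVD least squares).

#' Collect the anchor C-alpha/C-beta point set of a structure
#'
#' Points are returned in the fixed slot order Ca1, Cb1, Ca2, Cb2, Ca3, Cb3,
#' omitting C-beta slots for residues that lack one (glycine or missing atom);
#' the slot labels are kept as an attribute so that seed and query point sets
#' can drop C-beta slots pairwise (if either partner lacks a C-beta, both
#' sides omit that slot).
#'
#' @param structure A `structure_model`.
#' @param positions Ordered triple of residue positions.
#' @return k x 3 matrix (3 <= k <= 6) with attribute `slots`, a character
#'   vector like `c("ca1", "cb1", "ca2", ...)`.
#' @export
anchor_point_set <- function(structure, positions) {
  if (length(positions) != 3) stop("exactly three anchor positions are required")
  idx <- residue_index(structure, positions)
  pts <- NULL
  slots <- character()
  for (k in 1:3) {
    pts <- rbind(pts, structure$ca[idx[k], ])
    slots <- c(slots, paste0("ca", k))
    cb <- structure$cb[idx[k], ]
    if (!anyNA(cb)) {
      pts <- rbind(pts, cb)
      slots <- c(slots, paste0("cb", k))
    }
  }
  attr(pts, "slots") <- slots
  pts
}

# Seed/query anchor point sets restricted to slots present on both sides.
paired_anchor_points <- function(seed, seed_positions, query, query_positions,
                                 fit_atoms = c("ca+cb", "ca")) {
  fit_atoms <- match.arg(fit_atoms)
  sp <- anchor_point_set(seed, seed_positions)
  qp <- anchor_point_set(query, query_positions)
  common <- intersect(attr(sp, "slots"), attr(qp, "slots"))
  if (fit_atoms == "ca") common <- common[startsWith(common, "ca")]
  list(seed = sp[match(common, attr(sp, "slots")), , drop = FALSE],
       query = qp[match(common, attr(qp, "slots")), , drop = FALSE])
}

#' Optimal rigid superposition of two paired point sets
#'
#' Computes the proper rotation and translation minimizing the least-squares
#' deviation of `moving` onto `fixed` (Kabsch algorithm: SVD of the
#' cross-covariance with a determinant sign correction, so reflections are
#' never returned), together with the post-fit RMSD.
#'
#' @param moving k x 3 matrix of points to transform (k >= 3).
#' @param fixed k x 3 matrix of target points, paired row-wise with `moving`.
#' @return A `rigid_transform`: list with `rotation` (3 x 3, det +1),
#'   `translation` (length-3) and `rmsd` (Angstrom). Points map as
#'   `rotation %*% p + translation`.
#' @export
fit_transform <- function(moving, fixed) {
  moving <- as.matrix(moving); fixed <- as.matrix(fixed)
  if (nrow(moving) != nrow(fixed) || ncol(moving) != 3 || ncol(fixed) != 3) {
    stop("point sets must be k x 3 matrices of equal length")
  }
  if (nrow(moving) < 3) stop("at least 3 point pairs are required")
  cm <- colMeans(moving)
  cf <- colMeans(fixed)
  P <- sweep(moving, 2, cm)
  Q <- sweep(fixed, 2, cf)
  H <- crossprod(P, Q)                       # 3x3 cross-covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1                         # rank-deficient: pick the proper branch
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- as.numeric(cf - R %*% cm)
  moved <- P %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - Q)^2)))
  structure(list(rotation = R, translation = tr, rmsd = rmsd),
            class = "rigid_transform")
}

#' Apply a rigid transform to a set of points
#'
#' @param t A `rigid_transform`.
#' @param points k x 3 matrix or a single length-3 vector.
#' @return Transformed points, same shape as the input.
#' @export
apply_transform <- function(t, points) {
  if (is.null(dim(points))) {
    as.numeric(t$rotation %*% points + t$translation)
  } else {
    sweep(as.matrix(points) %*% t(t$rotation), 2, t$translation, `+`)
  }
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid_transform: rmsd ", sprintf("%.4f", x$rmsd), " Angstrom, translation (",
      paste(sprintf("%.2f", x$translation), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

# Inverse transform (used by tests and the fixture generator).
invert_transform <- function(t) {
  Rinv <- t(t$rotation)
  structure(list(rotation = Rinv, translation = as.numeric(-Rinv %*% t$translation),
                 rmsd = t$rmsd),
            class = "rigid_transform")
}
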