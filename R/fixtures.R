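# Synthetic fixture generator: pseudo-helical backbones with planted
# active sites and stage-specific decoys, so every pipeline stage is testable
# without downloading real structures.

#' Generate an ideal-helix pseudo-protein backbone
#'
#' C-alpha positions lie on an ideal alpha-helical curve (rise 1.5 Angstrom
#' per residue, radius 2.3 Angstrom, 100 degrees per residue), giving the
#' realistic ~3.8 Angstrom consecutive C-alpha spacing that neighbor scoring
#' sees; each C-beta sits 1.5 Angstrom radially outward from its C-alpha.
#' Residue types are drawn uniformly from the 20 standard codes under
#' `rng_seed`; the coordinates depend only on `n`.
#'
#' @param n Number of residues (>= 3).
#' @param rng_seed Seed for the residue-type draw.
#' @param id Model identifier (default derived from `n` and the seed).
#' @return A `structure_model` with positions 1..n.
#' @export
make_backbone <- function(n, rng_seed = 0L, id = NULL) {
  if (n < 3) stop("a backbone needs at least 3 residues")
  if (is.null(id)) id <- sprintf("bb_n%d_s%d", n, rng_seed)
  i <- seq_len(n) - 1L
  theta <- i * (100 * pi / 180)
  ca <- cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * i)
  cb <- ca + cbind(1.5 * cos(theta), 1.5 * sin(theta), 0)
  aa3 <- with_seed(rng_seed, sample(AA3_STANDARD, n, replace = TRUE))
  m <- structure_model(seq_len(n), aa3, ca, cb, id = id)
  m$cb[m$aa3 == "GLY", ] <- NA_real_  # glycine has no C-beta
  m
}

#' Fixture specification for planted active sites
#'
#' @param n_residues Backbone length (>= 20).
#' @param triad_types Three-letter codes of the planted triad.
#' @param target_distances The three pairwise C-alpha distances of the triad,
#'   Angstrom, order (1-2, 1-3, 2-3); must satisfy the triangle inequality.
#' @param jitter_sigma Gaussian jitter (sd, Angstrom) added to each target
#'   distance when planting.
#' @param decoy_mode `"none"` (a positive), `"wrong_types"` (site geometry
#'   kept, triad types replaced by non-matching ones), `"wrong_geometry"`
#'   (types kept, every pairwise distance displaced by +5 Angstrom, a
#'   guaranteed pre-screen failure at the default 3 Angstrom tolerance), or
#'   `"shifted_site"` (a near-miss: each triad atom displaced 2 Angstrom in a
#'   random direction).
#' @param rng_seed Seed controlling types, jitter and the rigid motion.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_residues = 60L,
                         triad_types = c("CYS", "ASP", "HIS"),
                         target_distances = c(8.0, 10.0, 12.0),
                         jitter_sigma = 0,
                         decoy_mode = c("none", "wrong_types", "wrong_geometry", "shifted_site"),
                         rng_seed = 0L) {
  decoy_mode <- match.arg(decoy_mode)
  if (n_residues < 20) stop("fixture backbones need >= 20 residues")
  if (jitter_sigma < 0) stop("jitter_sigma must be >= 0")
  triad_types <- normalize_aa3(triad_types)
  if (length(triad_types) != 3 || anyNA(triad_types)) stop("triad_types must be 3 standard codes")
  check_triangle(target_distances)
  structure(
    list(n_residues = as.integer(n_residues), triad_types = triad_types,
         target_distances = target_distances, jitter_sigma = jitter_sigma,
         decoy_mode = decoy_mode, rng_seed = as.integer(rng_seed)),
    class = "fixture_spec"
  )
}

check_triangle <- function(d) {
  if (length(d) != 3 || any(d <= 0) ||
      d[1] + d[2] <= d[3] || d[1] + d[3] <= d[2] || d[2] + d[3] <= d[1]) {
    stop("target distances must be positive and satisfy the triangle inequality")
  }
  invisible(d)
}

# Alternate residue types guaranteed disjoint from a given triad.
decoy_types <- function(triad_types) {
  pool <- setdiff(c("ALA", "VAL", "LEU", "PHE", "LYS", "GLU"), triad_types)
  pool[1:3]
}

#' Plant a three-residue active site on a backbone
#'
#' Selects three well-separated sequence positions (n/6, n/2, 5n/6),
#' overwrites their types with the requested triad, and rebuilds their
#' C-alpha/C-beta coordinates so the three pairwise C-alpha distances equal
#' the targets plus Gaussian jitter. Background occurrences of the triad
#' types elsewhere in the chain are resampled from the remaining codes, so a
#' decoy fails exactly the stage it targets (the planted triad is the only
#' candidate mapping). Finally a random proper rigid motion is applied to the
#' whole structure, so superposition is genuinely exercised.
#'
#' @param backbone A `structure_model` from [make_backbone()] (positions
#'   1..n).
#' @param spec A [fixture_spec()].
#' @return List with `model` (the planted `structure_model`) and `positions`
#'   (the three planted sequence positions).
#' @export
plant_site <- function(backbone, spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  n <- n_residues(backbone)
  pos <- sort(unique(round(n * c(1, 3, 5) / 6)))
  if (length(pos) != 3) stop("backbone too short to separate planted positions")
  m <- backbone
  types <- if (spec$decoy_mode == "wrong_types") decoy_types(spec$triad_types) else spec$triad_types

  with_seed(spec$rng_seed + 1L, {
    # scrub accidental triad-type occurrences from the background
    bg <- setdiff(seq_len(n), pos)
    clash <- bg[m$aa3[bg] %in% spec$triad_types]
    if (length(clash)) {
      m$aa3[clash] <- sample(setdiff(AA3_STANDARD, spec$triad_types),
                              length(clash), replace = TRUE)
    }
    m$aa3[pos] <- types

    d <- spec$target_distances
    if (spec$decoy_mode == "wrong_geometry") d <- d + 5
    if (spec$jitter_sigma > 0) d <- d + stats::rnorm(3, 0, spec$jitter_sigma)
    check_triangle(d)
    tri <- triangle_points(d)
    centroid_old <- colMeans(m$ca[pos, ])
    tri <- sweep(tri, 2, colMeans(tri))
    tri <- sweep(tri, 2, centroid_old, `+`)
    m$ca[pos, ] <- tri
    # chiral, non-coplanar C-beta offsets so the anchor fit is well posed
    offs <- rbind(c(0, 0, 1.5), c(0, 1.06, 1.06), c(1.06, 0, 1.06))
    m$cb[pos, ] <- tri + offs
    if (spec$decoy_mode == "shifted_site") {
      for (k in 1:3) {
        u <- stats::rnorm(3); u <- 2.0 * u / sqrt(sum(u^2))
        m$ca[pos[k], ] <- m$ca[pos[k], ] + u
        m$cb[pos[k], ] <- m$cb[pos[k], ] + u
      }
    }
    rt <- random_rigid_transform()
    m$ca <- apply_transform(rt, m$ca)
    ok <- !is.na(m$cb[, 1])
    m$cb[ok, ] <- apply_transform(rt, m$cb[ok, , drop = FALSE])
  })
  list(model = m, positions = pos)
}

# Planar triangle realizing pairwise distances (d12, d13, d23).
triangle_points <- function(d) {
  x3 <- (d[1]^2 + d[2]^2 - d[3]^2) / (2 * d[1])
  y3 <- sqrt(max(d[2]^2 - x3^2, 0))
  rbind(c(0, 0, 0), c(d[1], 0, 0), c(x3, y3, 0))
}

# Uniform random proper rotation (QR of a Gaussian matrix, det corrected)
# plus a translation uniform in [-20, 20]^3. Consumes the current RNG stream.
random_rigid_transform <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  structure(list(rotation = R, translation = stats::runif(3, -20, 20), rmsd = NA_real_),
            class = "rigid_transform")
}

#' Write a structure model as a PDB file
#'
#' Emits standard ATOM records for the C-alpha (and C-beta where present) of
#' every residue, single chain A.
#'
#' @param model A `structure_model`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(model, path) {
  lines <- character()
  serial <- 0L
  for (i in seq_len(n_residues(model))) {
    for (atom in c("CA", "CB")) {
      xyz <- if (atom == "CA") model$ca[i, ] else model$cb[i, ]
      if (anyNA(xyz)) next
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
        serial, atom, model$aa3[i], model$position[i],
        xyz[1], xyz[2], xyz[3], 1.00, 0.00))
    }
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Generate a benchmark set of planted positives and decoys
#'
#' Writes `seed.pdb` (the jitter-free planted seed), `pos_*.pdb` positives at
#' the spec's jitter, decoys cycling through the three decoy modes, and a
#' `manifest.tsv` (columns `file`, `label`, `planted_positions`) usable
#' directly with [search_batch()].
#'
#' @param n_positives,n_decoys Counts (>= 0).
#' @param spec A [fixture_spec()]; per-structure seeds are derived from
#'   `spec$rng_seed`.
#' @param out_dir Output directory (created if needed).
#' @return The manifest data frame, invisibly, with attributes `out_dir` and
#'   `seed_path`.
#' @export
make_benchmark <- function(n_positives, n_decoys, spec, out_dir) {
  stopifnot(inherits(spec, "fixture_spec"), n_positives >= 0, n_decoys >= 0)
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok) stop("cannot create output directory ", out_dir)
  seed_spec <- spec
  seed_spec$jitter_sigma <- 0
  seed_spec$decoy_mode <- "none"
  seed_planted <- plant_site(make_backbone(spec$n_residues, spec$rng_seed), seed_spec)
  seed_path <- file.path(out_dir, "seed.pdb")
  write_pdb(seed_planted$model, seed_path)

  rows <- list()
  emit <- function(fname, label, sp, k) {
    bb <- make_backbone(sp$n_residues, sp$rng_seed)
    planted <- plant_site(bb, sp)
    write_pdb(planted$model, file.path(out_dir, fname))
    data.frame(file = fname, label = label,
               planted_positions = paste(planted$positions, collapse = ";"),
               stringsAsFactors = FALSE)
  }
  for (k in seq_len(n_positives)) {
    sp <- spec; sp$decoy_mode <- "none"; sp$rng_seed <- spec$rng_seed + k
    rows[[length(rows) + 1L]] <- emit(sprintf("pos_%03d.pdb", k), "positive", sp, k)
  }
  modes <- c("wrong_types", "wrong_geometry", "shifted_site")
  for (k in seq_len(n_decoys)) {
    sp <- spec
    sp$decoy_mode <- modes[(k - 1L) %% 3L + 1L]
    sp$rng_seed <- spec$rng_seed + n_positives + k
    rows[[length(rows) + 1L]] <- emit(sprintf("decoy_%03d.pdb", k), sp$decoy_mode, sp, k)
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(file = character(), label = character(),
               planted_positions = character(), stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  attr(manifest, "out_dir") <- out_dir
  attr(manifest, "seed_path") <- seed_path
  invisible(manifest)
}
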