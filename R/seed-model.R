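#' Build the active-site search template from a seed structure
#'
#' The template consists of three anchor residues (used to fit the rigid
#' transform), optional additional residues (used in scoring only), optional
#' per-position substitution rules, and a sequence-neighbor window. When fewer
#' than three anchors are given, the anchor set is completed with the
#' lowest-numbered residues whose C-alpha lies within `radius` of the first
#' anchor's C-alpha (see [auto_complete_anchors()]).
#'
#' @param seed A `structure_model` of the seed protein.
#' @param anchor_positions 1 to 3 residue positions (author numbering).
#' @param additional_positions Residue positions used for ranking only.
#' @param substitutions Named list: names are seed positions, values are
#'   character vectors of accepted three-letter codes at that position. The
#'   seed residue's own type is always accepted and is added if missing.
#' @param neighbor_window Number of sequence neighbors on each side of every
#'   site residue used in scoring (default 4, i.e. positions +-1..4).
#' @param radius Auto-completion search radius in Angstrom (default 10).
#' @return A `seed_site` list with elements `anchors`, `additional`,
#'   `substitutions`, `neighbor_window`, `anchor_distances` (C-alpha distances
#'   for pairs (1,2), (1,3), (2,3)) and `seed_structure`.
#' @export
build_seed_site <- function(seed, anchor_positions, additional_positions = integer(),
                            substitutions = list(), neighbor_window = 4L,
                            radius = 10) {
  stopifnot(inherits(seed, "structure_model"))
  if (n_residues(seed) < 3) stop("seed structure has fewer than 3 residues")
  anchor_positions <- as.integer(anchor_positions)
  additional_positions <- as.integer(additional_positions)
  if (!length(anchor_positions) || length(anchor_positions) > 3) {
    stop("between 1 and 3 anchor positions are required")
  }
  if (neighbor_window < 0) stop("neighbor_window must be >= 0")
  all_pos <- c(anchor_positions, additional_positions)
  residue_index(seed, all_pos)  # errors on unknown positions, naming them
  if (anyDuplicated(all_pos)) {
    stop("duplicate site position(s): ",
         paste(unique(all_pos[duplicated(all_pos)]), collapse = ", "))
  }
  if (length(anchor_positions) < 3) {
    anchor_positions <- auto_complete_anchors(seed, anchor_positions[1], radius,
                                              keep = anchor_positions)
    if (anyDuplicated(c(anchor_positions, additional_positions))) {
      stop("auto-completed anchors collide with additional positions")
    }
  }
  subs <- normalize_substitutions(seed, substitutions)
  ai <- residue_index(seed, anchor_positions)
  d <- c(
    euclid(seed$ca[ai[1], ], seed$ca[ai[2], ]),
    euclid(seed$ca[ai[1], ], seed$ca[ai[3], ]),
    euclid(seed$ca[ai[2], ], seed$ca[ai[3], ])
  )
  structure(
    list(
      anchors = anchor_positions,
      additional = additional_positions,
      substitutions = subs,
      neighbor_window = as.integer(neighbor_window),
      anchor_distances = d,
      seed_structure = seed
    ),
    class = "seed_site"
  )
}

normalize_substitutions <- function(seed, substitutions) {
  if (!length(substitutions)) return(list())
  if (is.null(names(substitutions)) || any(names(substitutions) == "")) {
    stop("substitutions must be a named list keyed by seed position")
  }
  pos <- as.integer(names(substitutions))
  idx <- residue_index(seed, pos)
  out <- lapply(seq_along(substitutions), function(k) {
    aa <- normalize_aa3(substitutions[[k]])
    if (anyNA(aa)) stop("unknown amino-acid code in substitution rule at position ", pos[k])
    unique(c(seed$aa3[idx[k]], aa))
  })
  names(out) <- as.character(pos)
  out
}

#' Complete an anchor triple by radius search around the first anchor
#'
#' Returns the given residue followed by the first two other residues (in
#' ascending sequence position) whose C-alpha lies within `radius` Angstrom of
#' the given residue's C-alpha.
#'
#' @param seed A `structure_model`.
#' @param first_position The user-given anchor position.
#' @param radius Search radius in Angstrom (> 0).
#' @param keep Positions already chosen by the user (kept first, in order);
#'   defaults to `first_position` alone.
#' @return Integer vector of 3 anchor positions.
#' @export
auto_complete_anchors <- function(seed, first_position, radius, keep = first_position) {
  if (radius <= 0) stop("radius must be > 0")
  keep <- as.integer(keep)
  i <- residue_index(seed, first_position)
  d <- sqrt(rowSums((seed$ca - matrix(seed$ca[i, ], n_residues(seed), 3, byrow = TRUE))^2))
  cand <- seed$position[d <= radius & !seed$position %in% keep]
  need <- 3L - length(keep)
  if (length(cand) < need) {
    stop("auto-completion found only ", length(cand), " residue(s) within ",
         radius, " Angstrom of position ", first_position, "; ", need, " needed")
  }
  c(keep, sort(cand)[seq_len(need)])
}

#' Accepted residue types at a site position
#'
#' @param site A `seed_site`.
#' @param seed_position An anchor or additional position of the site.
#' @return Character vector of accepted three-letter codes: the substitution
#'   rule if one exists, otherwise the seed residue's own type.
#' @export
allowed_types <- function(site, seed_position) {
  if (!seed_position %in% c(site$anchors, site$additional)) {
    stop("position ", seed_position, " is not part of the site")
  }
  rule <- site$substitutions[[as.character(seed_position)]]
  if (!is.null(rule)) rule else site$seed_structure$aa3[residue_index(site$seed_structure, seed_position)]
}

#' @export
print.seed_site <- function(x, ...) {
  s <- x$seed_structure
  typ <- function(p) s$aa3[residue_index(s, p)]
  cat("seed_site on '", s$id, "'\n", sep = "")
  cat("  anchors:   ", paste(sprintf("%d%s", x$anchors, vapply(x$anchors, typ, "")),
                             collapse = ", "), "\n", sep = "")
  if (length(x$additional)) {
    cat("  additional:", paste(sprintf("%d%s", x$additional, vapply(x$additional, typ, "")),
                               collapse = ", "), "\n")
  }
  cat("  anchor C-alpha distances (1-2, 1-3, 2-3): ",
      paste(sprintf("%.2f", x$anchor_distances), collapse = ", "), " Angstrom\n", sep = "")
  cat("  neighbor window: +-", x$neighbor_window, "\n", sep = "")
  if (length(x$substitutions)) {
    for (p in names(x$substitutions)) {
      cat("  accepted at ", p, ": ", paste(x$substitutions[[p]], collapse = "/"), "\n", sep = "")
    }
  }
  invisible(x)
}

#' Read a site definition and search options from a JSON config file
#'
#' The config mirrors the command-line interface: fields `anchors`,
#' `additional`, `substitutions` (object mapping position to an array of
#' codes), `neighbor_window`, `radius`, plus any [search_config()] fields.
#'
#' @param path Path to a JSON file.
#' @return Named list of config values.
#' @export
read_site_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(cfg$substitutions)) {
    cfg$substitutions <- lapply(cfg$substitutions, as.character)
  }
  cfg
}
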