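#' Parse a protein structure file into a single-chain coordinate model
#'
#' Reads a PDB or mmCIF file and returns the ordered list of standard amino
#' acids of one chain, keeping the alpha carbon (and, when present, the beta
#' carbon) of each residue. Residues without a C-alpha atom are dropped; only
#' the first model and the first alternate location of each atom are used.
#' Nonstandard residues with a known parent (e.g. selenomethionine) are mapped
#' to the parent standard code; unmappable residues are dropped with a warning.
#'
#' @param path Path to a `.pdb`/`.ent` or `.cif`/`.mmcif` file. The format is
#'   chosen by extension, with a content sniff as fallback.
#' @param chain Optional chain identifier. When `NULL` (default) the first
#'   chain containing a standard residue with a C-alpha atom is used.
#' @return A `structure_model`: a list with elements `id` (file stem),
#'   `source_path`, `position` (author residue numbers, strictly increasing),
#'   `aa3` (three-letter codes), `ca` (n x 3 matrix, Angstrom) and `cb`
#'   (n x 3 matrix with `NA` rows where the residue has no C-beta, e.g.
#'   glycine).
#' @export
parse_structure <- function(path, chain = NULL) {
  if (!file.exists(path)) {
    stop("cannot read structure file: ", path)
  }
  ext <- tolower(tools::file_ext(path))
  lines <- tryCatch(readLines(path, warn = FALSE),
                    error = function(e) stop("cannot read structure file: ", path))
  is_cif <- ext %in% c("cif", "mmcif") ||
    (!ext %in% c("pdb", "ent") && any(grepl("^_atom_site\\.", lines)))
  atoms <- if (is_cif) read_cif_atoms(lines, path) else read_pdb_atoms(lines, path)
  build_structure_model(atoms, path, chain)
}

# Fixed-column PDB ATOM/HETATM reader; stops at the first ENDMDL (model 1 only).
read_pdb_atoms <- function(lines, path) {
  end <- which(startsWith(lines, "ENDMDL"))
  if (length(end)) lines <- lines[seq_len(end[1] - 1L)]
  rec <- substr(lines, 1, 6)
  keep <- rec == "ATOM  " | rec == "HETATM"
  lines <- lines[keep]
  if (!length(lines)) {
    return(data.frame(atom = character(), aa3_raw = character(), chain = character(),
                      position = integer(), icode = character(),
                      x = numeric(), y = numeric(), z = numeric(), altloc = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    atom = trimws(substr(lines, 13, 16)),
    aa3_raw = trimws(substr(lines, 18, 20)),
    chain = trimws(substr(lines, 22, 22)),
    position = suppressWarnings(as.integer(substr(lines, 23, 26))),
    icode = trimws(substr(lines, 27, 27)),
    x = as.numeric(substr(lines, 31, 38)),
    y = as.numeric(substr(lines, 39, 46)),
    z = as.numeric(substr(lines, 47, 54)),
    altloc = trimws(substr(lines, 17, 17)),
    stringsAsFactors = FALSE
  )
}

# Minimal mmCIF atom_site loop reader (whitespace-tokenized rows, as written by
# AlphaFold and most deposition pipelines; quoted fields are not needed here).
read_cif_atoms <- function(lines, path) {
  hdr_idx <- grep("^_atom_site\\.", lines)
  if (!length(hdr_idx)) stop("no atom_site loop found in ", path)
  fields <- sub("^_atom_site\\.", "", trimws(lines[hdr_idx]))
  body_start <- max(hdr_idx) + 1L
  rows <- character()
  for (i in body_start:length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#") || startsWith(ln, "_") || startsWith(ln, "loop_")) break
    rows <- c(rows, ln)
  }
  if (!length(rows)) stop("empty atom_site loop in ", path)
  tok <- strsplit(rows, "[[:space:]]+")
  bad <- vapply(tok, length, integer(1)) != length(fields)
  if (any(bad)) stop("malformed atom_site rows in ", path)
  m <- do.call(rbind, tok)
  colnames(m) <- fields
  get <- function(...) {
    for (f in c(...)) if (f %in% fields) return(m[, f])
    rep(NA_character_, nrow(m))
  }
  model_num <- get("pdbx_PDB_model_num")
  if (!all(is.na(model_num))) {
    first <- model_num[1]
    m <- m[model_num == first, , drop = FALSE]
  }
  get2 <- function(...) {
    for (f in c(...)) if (f %in% fields) return(m[, f])
    rep(NA_character_, nrow(m))
  }
  grp <- get2("group_PDB")
  if (!all(is.na(grp))) m <- m[grp %in% c("ATOM", "HETATM"), , drop = FALSE]
  get3 <- function(...) {
    for (f in c(...)) if (f %in% fields) return(m[, f])
    rep(NA_character_, nrow(m))
  }
  pos <- get3("auth_seq_id", "label_seq_id")
  icode <- get3("pdbx_PDB_ins_code")
  icode[is.na(icode) | icode %in% c("?", ".")] <- ""
  altloc <- get3("label_alt_id")
  altloc[is.na(altloc) | altloc %in% c("?", ".")] <- ""
  data.frame(
    atom = get3("auth_atom_id", "label_atom_id"),
    aa3_raw = get3("auth_comp_id", "label_comp_id"),
    chain = get3("auth_asym_id", "label_asym_id"),
    position = suppressWarnings(as.integer(pos)),
    icode = icode,
    x = as.numeric(get3("Cartn_x")),
    y = as.numeric(get3("Cartn_y")),
    z = as.numeric(get3("Cartn_z")),
    altloc = altloc,
    stringsAsFactors = FALSE
  )
}

# Assemble one chain's residues from an atom table into a structure_model.
build_structure_model <- function(atoms, path, chain = NULL) {
  id <- tools::file_path_sans_ext(basename(path))
  atoms$aa3 <- normalize_aa3(atoms$aa3_raw)
  dropped <- unique(atoms$aa3_raw[is.na(atoms$aa3) & atoms$atom == "CA"])
  if (length(dropped)) {
    warning("dropping unmappable residue type(s) in ", id, ": ",
            paste(dropped, collapse = ", "))
  }
  atoms <- atoms[!is.na(atoms$aa3) & !is.na(atoms$position), , drop = FALSE]
  # first altloc per (chain, residue, atom); in files the primary conformer
  # (blank or "A") is listed first, so keeping the first occurrence suffices
  atoms <- atoms[!duplicated(atoms[c("chain", "position", "atom")]), , drop = FALSE]

  chains_with_ca <- unique(atoms$chain[atoms$atom == "CA"])
  if (is.null(chain)) {
    if (!length(chains_with_ca)) stop("no residues with a C-alpha atom in ", path)
    chain <- chains_with_ca[1]
  } else if (!chain %in% atoms$chain) {
    stop("chain '", chain, "' not found in ", path, "; available chains: ",
         paste(unique(atoms$chain), collapse = ", "))
  }
  atoms <- atoms[atoms$chain == chain, , drop = FALSE]
  if (any(atoms$icode != "")) {
    stop("insertion codes are not supported (file ", path, ", chain ", chain, ")")
  }
  ca <- atoms[atoms$atom == "CA", , drop = FALSE]
  if (!nrow(ca)) stop("no residues with a C-alpha atom in ", path)
  ca <- ca[order(ca$position), , drop = FALSE]
  ca <- ca[!duplicated(ca$position), , drop = FALSE]
  cb <- atoms[atoms$atom == "CB", , drop = FALSE]
  cb_idx <- match(ca$position, cb$position)
  cbm <- cbind(cb$x[cb_idx], cb$y[cb_idx], cb$z[cb_idx])
  structure(
    list(
      id = id,
      source_path = path,
      position = as.integer(ca$position),
      aa3 = ca$aa3,
      ca = unname(cbind(ca$x, ca$y, ca$z)),
      cb = unname(cbm)
    ),
    class = "structure_model"
  )
}

#' Construct a structure model from raw coordinates
#'
#' Builds a minimal in-memory model, the same container [parse_structure()]
#' returns, from vectors of positions, residue types and coordinate matrices.
#' Used by the fixture generator and for coordinate-only seed definitions.
#'
#' @param position Integer author residue numbers, strictly increasing.
#' @param aa3 Three-letter residue codes (standard or mappable).
#' @param ca n x 3 matrix of C-alpha coordinates (Angstrom).
#' @param cb Optional n x 3 matrix of C-beta coordinates; rows of `NA` mark
#'   residues without a C-beta.
#' @param id Model identifier.
#' @param source_path Provenance string recorded on the model.
#' @return A `structure_model`.
#' @export
structure_model <- function(position, aa3, ca, cb = NULL, id = "model",
                            source_path = "<memory>") {
  position <- as.integer(position)
  if (any(diff(position) <= 0)) stop("residue positions must be strictly increasing")
  aa3 <- normalize_aa3(aa3)
  if (anyNA(aa3)) stop("unmappable residue type(s): ",
                       paste(which(is.na(aa3)), collapse = ", "))
  ca <- as.matrix(ca)
  if (nrow(ca) != length(position) || ncol(ca) != 3) stop("ca must be an n x 3 matrix")
  if (is.null(cb)) cb <- matrix(NA_real_, nrow(ca), 3) else cb <- as.matrix(cb)
  if (nrow(cb) != nrow(ca) || ncol(cb) != 3) stop("cb must be an n x 3 matrix")
  structure(
    list(id = id, source_path = source_path, position = position, aa3 = aa3,
         ca = unname(ca), cb = unname(cb)),
    class = "structure_model"
  )
}

#' @export
print.structure_model <- function(x, ...) {
  n_cb <- sum(!is.na(x$cb[, 1]))
  cat("structure_model '", x$id, "': ", length(x$position), " residues (",
      n_cb, " with C-beta), positions ", x$position[1], "..",
      x$position[length(x$position)], "\n", sep = "")
  invisible(x)
}

n_residues <- function(model) length(model$position)

residue_index <- function(model, position) {
  i <- match(position, model$position)
  if (anyNA(i)) {
    stop("position(s) not present in structure '", model$id, "': ",
         paste(position[is.na(i)], collapse = ", "))
  }
  i
}

# Extract one residue as a plain list (position, aa3, ca, cb or NULL).
get_residue <- function(model, position) {
  i <- residue_index(model, position)
  cb <- model$cb[i, ]
  list(position = model$position[i], aa3 = model$aa3[i],
       ca = model$ca[i, ], cb = if (anyNA(cb)) NULL else cb)
}

has_cb <- function(model, position) {
  !is.na(model$cb[residue_index(model, position), 1])
}

#' Write search hits to a tab-separated result file
#'
#' One row per accepted structure, sorted by ascending score. The `mapping`
#' column joins the site mapping (anchors first, then matched additional
#' residues) as `seedpos:querypos` pairs separated by semicolons.
#'
#' @param hits List of `search_hit` objects (may be empty).
#' @param path Output file path.
#' @return Invisibly, the data frame that was written.
#' @export
write_results <- function(hits, path) {
  df <- hits_to_table(hits)
  out <- df
  for (col in c("score", "structural_mapping_percentage", "structural_local_similarity")) {
    out[[col]] <- sprintf("%.6f", df[[col]])
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write results to ", path)
  invisible(df)
}

hits_to_table <- function(hits) {
  if (length(hits)) {
    rows <- lapply(hits, function(h) {
      core <- h$best$mapped[h$best$mapped$kind %in% c("anchor", "additional"), , drop = FALSE]
      data.frame(
        structure_id = h$structure_id,
        mapping = paste(sprintf("%d:%d", core$seed_position, core$query_position),
                        collapse = ";"),
        score = h$best$score,
        n_mapped = h$best$n_mapped,
        structural_mapping_percentage = h$structural_mapping_percentage,
        structural_local_similarity = h$structural_local_similarity,
        stringsAsFactors = FALSE
      )
    })
    df <- do.call(rbind, rows)
    df <- df[order(df$score, df$structure_id), , drop = FALSE]
    rownames(df) <- NULL
    df
  } else {
    data.frame(structure_id = character(), mapping = character(),
               score = numeric(), n_mapped = integer(),
               structural_mapping_percentage = numeric(),
               structural_local_similarity = numeric(),
               stringsAsFactors = FALSE)
  }
}

#' Read a result file written by [write_results()]
#'
#' @param path Path to the TSV file.
#' @return Data frame with the result columns in their native types.
#' @export
read_results <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = c(structure_id = "character", mapping = "character"))
}
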