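# Amino-acid code tables shared across modules.

# The 20 standard three-letter codes, alphabetical.
AA3_STANDARD <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

# Common nonstandard / chemically modified residues mapped to their parent
# standard code. Residues not in this table and not standard are dropped at
# parse time with a warning.
AA3_NONSTANDARD_MAP <- c(
  MSE = "MET",  # selenomethionine
  SEC = "CYS",  # selenocysteine
  PYL = "LYS",  # pyrrolysine
  SEP = "SER",  # phosphoserine
  TPO = "THR",  # phosphothreonine
  PTR = "TYR",  # phosphotyrosine
  CSO = "CYS",  # S-hydroxycysteine
  CSD = "CYS",
  CME = "CYS",
  HYP = "PRO",  # hydroxyproline
  MLY = "LYS",
  M3L = "LYS",
  KCX = "LYS",
  CGU = "GLU",
  PCA = "GLU",
  HIC = "HIS",
  FME = "MET"
)

# Normalize a vector of residue names to standard codes; NA where unmappable.
normalize_aa3 <- function(aa3) {
  aa3 <- toupper(trimws(aa3))
  out <- ifelse(aa3 %in% AA3_STANDARD, aa3, unname(AA3_NONSTANDARD_MAP[aa3]))
  out
}
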