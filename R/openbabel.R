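# Thin wrappers around Open Babel (via ChemmineOB) used by the curation and
# fingerprint modules.  All chemistry I/O is funneled through these so that
# the rest of the package deals only in canonical SMILES strings and plain
# numeric matrices.

# Canonical SMILES, or NA_character_ when Open Babel cannot parse the input.
ob_canonical <- function(smiles, neutralize = FALSE) {
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(NA_character_)
    out <- tryCatch({
      if (neutralize) {
        ChemmineOB::convertFormat(
          "SMI", "CAN", source = s,
          options = data.frame(names = "neutralize", args = ""))
      } else {
        ChemmineOB::convertFormat("SMI", "CAN", source = s)
      }
    }, error = function(e) "")
    out <- sub("\t.*$", "", sub("\n$", "", out))
    if (!nzchar(out)) NA_character_ else out
  }, character(1), USE.NAMES = FALSE)
}

# Count non-hydrogen atoms in a SMILES string.  Bracket atoms count as one
# atom unless they are explicit hydrogens/isotopes ([H], [2H], ...).
ob_heavy_atoms <- function(smiles) {
  vapply(smiles, function(s) {
    brackets <- regmatches(s, gregexpr("\\[[^]]*\\]", s))[[1]]
    n_brk <- sum(!grepl("^\\[[0-9]*H[^a-gi-z]*\\]$", brackets))
    bare <- gsub("\\[[^]]*\\]", "", s)
    organic <- gregexpr("Br|Cl|[BCNOPSFI]|[bcnops]", bare)[[1]]
    n_bare <- if (organic[1] == -1L) 0L else length(organic)
    as.integer(n_brk + n_bare)
  }, integer(1), USE.NAMES = FALSE)
}

ob_mol <- function(smiles) {
  ChemmineOB::forEachMol("SMILES", smiles, identity)
}

# MACCS key bit vector (positions 1..166) for a single SMILES.
ob_maccs_row <- function(smiles) {
  bits <- ChemmineOB::fingerprint_OB(ob_mol(smiles), "MACCS")
  as.integer(bits[seq_len(166)])
}

# Physico-chemical properties needed for drug-likeness profiling.
# Rotatable bonds are counted with the conventional SMARTS definition
# (single, acyclic, non-terminal bonds not adjacent to a triple bond).
ROTOR_SMARTS <- "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]"

ob_properties <- function(smiles) {
  mol <- ob_mol(smiles)
  p <- ChemmineOB::prop_OB(mol)
  rot <- ChemmineOB::smartsSearch_OB(mol, ROTOR_SMARTS, uniqueMatches = TRUE)
  data.frame(
    mw = p$MW,
    alogp = p$logP,
    hbd = p$HBD,
    hba = p$HBA2,
    rotatable_bonds = as.integer(rot)
  )
}
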