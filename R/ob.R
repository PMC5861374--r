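# Internal bridge to Open Babel through the ChemmineOB SWIG bindings.
#
# ChemmineOB's exported helpers (convertFormat, smartsSearchOB) only expose a
# slice of the toolkit: conversion options are passed as GENOPTIONS (so SMILES
# write options such as "i", which drops stereo/isotope marks, cannot be set)
# and SMARTS matches are reported as counts without atom maps. The molecule
# editing API (bond deletion, dummy atoms, reattachment) and atom-mapped SMARTS
# matching used here are available in the ChemmineOB namespace as low-level
# wrappers; this file is the only place that touches them.

.ob_state <- new.env(parent = emptyenv())

ob <- function() {
  if (is.null(.ob_state$ns)) {
    ns <- getNamespace("ChemmineOB")
    # Route Open Babel's warning chatter away from stderr; parse failures are
    # detected from return values, not from the log.
    try({
      lvl <- ns$obMessageLevel_obError_get()
      ns$OBMessageHandler_SetOutputLevel(ns$obErrorLog_get(), lvl)
    }, silent = TRUE)
    .ob_state$ns <- ns
  }
  .ob_state$ns
}

# Parse a single SMILES string into an OBMol. Returns NULL on failure; the
# caller owns the molecule and must release it with ob_free().
ob_parse <- function(smiles) {
  OB <- ob()
  conv <- OB$OBConversion()
  on.exit(OB$delete_OBConversion(conv))
  OB$OBConversion_SetInFormat(conv, "SMI")
  mol <- OB$OBMol()
  ok <- OB$OBConversion_ReadString(conv, mol, smiles)
  if (!isTRUE(ok) || OB$OBMol_NumAtoms(mol) == 0L) {
    OB$delete_OBMol(mol)
    return(NULL)
  }
  mol
}

ob_free <- function(mol) {
  if (!is.null(mol)) ob()$delete_OBMol(mol)
  invisible(NULL)
}

# Canonical SMILES writer. Open Babel's "can" output applies aromatic
# perception (lowercase aromatic atoms); write option "i" removes isotope and
# stereo descriptors, which yields the aromatic non-stereo representation used
# throughout the package.
ob_write_canonical <- function(mol) {
  OB <- ob()
  conv <- OB$OBConversion()
  on.exit(OB$delete_OBConversion(conv))
  OB$OBConversion_SetOutFormat(conv, "CAN")
  OB$OBConversion_AddOption(conv, "i", "OUTOPTIONS", "")
  out <- OB$OBConversion_WriteString(conv, mol)
  sub("[ \t\r\n].*$", "", out)
}

ob_num_heavy <- function(mol) ob()$OBMol_NumHvyAtoms(mol)

# Bond table of a molecule: one row per bond with 1-based begin/end atom
# indices, bond order, and ring membership (Open Babel SSSR perception).
ob_bond_table <- function(mol) {
  OB <- ob()
  nb <- OB$OBMol_NumBonds(mol)
  if (nb == 0L) {
    return(data.frame(bond = integer(), begin = integer(), end = integer(),
                      order = integer(), in_ring = logical()))
  }
  idx <- seq_len(nb) - 1L
  begin <- integer(nb); end <- integer(nb); ord <- integer(nb); ring <- logical(nb)
  for (i in idx) {
    b <- OB$OBMol_GetBond(mol, i)
    begin[i + 1L] <- OB$OBBond_GetBeginAtomIdx(b)
    end[i + 1L] <- OB$OBBond_GetEndAtomIdx(b)
    ord[i + 1L] <- OB$OBBond_GetBondOrder(b)
    ring[i + 1L] <- OB$OBBond_IsInRing(b)
  }
  data.frame(bond = idx, begin = begin, end = end, order = ord, in_ring = ring)
}

ob_atomic_numbers <- function(mol) {
  OB <- ob()
  n <- OB$OBMol_NumAtoms(mol)
  vapply(seq_len(n), function(i) OB$OBAtom_GetAtomicNum(OB$OBMol_GetAtom(mol, i)), integer(1))
}

# Compile a SMARTS pattern; errors on invalid input. Caller frees with
# ob_smarts_free().
ob_smarts <- function(smarts) {
  OB <- ob()
  sp <- OB$OBSmartsPattern()
  if (!isTRUE(OB$OBSmartsPattern_Init(sp, smarts))) {
    OB$delete_OBSmartsPattern(sp)
    stop("invalid SMARTS pattern: ", smarts, call. = FALSE)
  }
  sp
}

ob_smarts_free <- function(sp) {
  if (!is.null(sp)) ob()$delete_OBSmartsPattern(sp)
  invisible(NULL)
}

ob_smarts_num_atoms <- function(sp) ob()$OBSmartsPattern_NumAtoms(sp)

# Unique substructure matches as a list of 1-based atom index vectors.
ob_smarts_matches <- function(sp, mol) {
  OB <- ob()
  if (!isTRUE(OB$OBSmartsPattern_Match(sp, mol))) return(list())
  OB$OBSmartsPattern_GetUMapList(sp)
}

ob_smarts_has_match <- function(sp, mol) {
  isTRUE(ob()$OBSmartsPattern_Match(sp, mol))
}

# Delete the bond with 0-based index `bond`, attach a dummy atom ([*]) to each
# of the two former partners, and return the canonical SMILES of the resulting
# two-fragment molecule ("frag1.frag2"). The molecule is modified in place.
ob_cut_bond <- function(mol, bond) {
  OB <- ob()
  b <- OB$OBMol_GetBond(mol, bond)
  a1 <- OB$OBBond_GetBeginAtomIdx(b)
  a2 <- OB$OBBond_GetEndAtomIdx(b)
  OB$OBMol_DeleteBond(mol, b)
  d1 <- OB$OBMol_NewAtom(mol); OB$OBAtom_SetAtomicNum(d1, 0L)
  d2 <- OB$OBMol_NewAtom(mol); OB$OBAtom_SetAtomicNum(d2, 0L)
  OB$OBMol_AddBond(mol, a1, OB$OBAtom_GetIdx(d1), 1L)
  OB$OBMol_AddBond(mol, a2, OB$OBAtom_GetIdx(d2), 1L)
  ob_write_canonical(mol)
}

# Neighbor atom index of atom `idx` (used for single-degree dummy atoms).
ob_single_neighbor <- function(mol, idx) {
  OB <- ob()
  nb <- OB$OBMol_NumBonds(mol)
  for (i in seq_len(nb) - 1L) {
    b <- OB$OBMol_GetBond(mol, i)
    bi <- OB$OBBond_GetBeginAtomIdx(b)
    ei <- OB$OBBond_GetEndAtomIdx(b)
    if (bi == idx) return(ei)
    if (ei == idx) return(bi)
  }
  NA_integer_
}
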