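#' Canonical aromatic non-stereo SMILES
#'
#' Canonicalizes SMILES strings into the representation used throughout the
#' package and by the deposition files: Open Babel canonical SMILES with
#' aromatic perception applied (lowercase aromatic atoms) and all
#' stereochemical and isotope descriptors removed. The transformation is
#' idempotent.
#'
#' @param smiles character vector of SMILES strings.
#' @param on_error `"error"` (default) stops at the first unparsable string,
#'   naming it and its position; `"na"` returns `NA` for unparsable entries.
#' @return character vector of canonical SMILES, same length as the input.
#' @examples
#' \dontrun{
#' canonicalize_smiles("C1=CC=CC=C1")        # "c1ccccc1"
#' canonicalize_smiles("N[C@@@@H](C)C(=O)O")  # stereo stripped
#' }
#' @export
canonicalize_smiles <- function(smiles, on_error = c("error", "na")) {
  on_error <- match.arg(on_error)
  stopifnot(is.character(smiles))
  out <- character(length(smiles))
  for (i in seq_along(smiles)) {
    mol <- ob_parse(smiles[[i]])
    if (is.null(mol)) {
      if (on_error == "error") {
        stop("unparsable SMILES at position ", i, ": '", smiles[[i]], "'",
             call. = FALSE)
      }
      out[[i]] <- NA_character_
      next
    }
    out[[i]] <- ob_write_canonical(mol)
    ob_free(mol)
  }
  out
}

#' Heavy (non-hydrogen) atom count of SMILES strings
#'
#' @param smiles character vector of SMILES strings; must parse.
#' @return integer vector of heavy-atom counts.
#' @export
smiles_heavy_atoms <- function(smiles) {
  stopifnot(is.character(smiles))
  vapply(seq_along(smiles), function(i) {
    mol <- ob_parse(smiles[[i]])
    if (is.null(mol)) {
      stop("unparsable SMILES at position ", i, ": '", smiles[[i]], "'",
           call. = FALSE)
    }
    n <- ob_num_heavy(mol)
    ob_free(mol)
    as.integer(n)
  }, integer(1))
}

# TRUE when the canonical SMILES describes a single connected structure
# (no "." component separator).
smiles_is_connected <- function(canonical_smiles) {
  !grepl(".", canonical_smiles, fixed = TRUE)
}
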