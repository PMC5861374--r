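#' Substructure filter sets for assay-interference flagging
#'
#' A filter set is a named list of SMARTS substructure patterns; a compound
#' matching any pattern is flagged as an assay-interference candidate.
#' [read_filter_set()] loads one from a file (one SMARTS per line, optionally
#' followed by whitespace and a pattern id; `#` comments).
#' [default_interference_filters()] ships a small set of PAINS-style exemplar
#' substructures (quinones, catechols, rhodanine-like scaffolds, enones,
#' azo and hydrazone motifs). The exemplars are illustrative, for testing the
#' mechanism; production screening should load a curated collection.
#'
#' @param patterns data.frame with columns `pattern_id`, `smarts`.
#' @param name label for the set.
#' @return object of class `filter_set`.
#' @export
filter_set <- function(patterns, name = "custom") {
  stopifnot(is.data.frame(patterns),
            all(c("pattern_id", "smarts") %in% names(patterns)))
  if (anyDuplicated(patterns$pattern_id)) {
    stop("duplicate pattern_id in filter set", call. = FALSE)
  }
  for (i in seq_len(nrow(patterns))) {
    sp <- tryCatch(ob_smarts(patterns$smarts[i]), error = function(e) {
      stop("filter pattern '", patterns$pattern_id[i], "' is not valid SMARTS: ",
           patterns$smarts[i], call. = FALSE)
    })
    ob_smarts_free(sp)
  }
  structure(list(name = name, patterns = patterns), class = "filter_set")
}

#' @rdname filter_set
#' @export
default_interference_filters <- function() {
  filter_set(data.frame(
    pattern_id = c("quinone", "catechol", "rhodanine_like", "ene_one",
                   "azo_aromatic", "hydrazone"),
    smarts = c(
      "[#6]1([#6]=[#6][#6]([#6]=[#6]1)=[OX1])=[OX1]",
      "[OX2H]c1ccccc1[OX2H]",
      "[#6]1[#16][#6](=[SX1,OX1])[#7][#6]1=[OX1]",
      "[CX3]=[CX3][CX3]=[OX1]",
      "c[NX2]=[NX2]c",
      "[NX3][NX2]=[CX3]"
    )), name = "default-exemplars")
}

#' @rdname filter_set
#' @param path path to a filter file.
#' @export
read_filter_set <- function(path) {
  if (!file.exists(path)) stop("filter file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(filter_set(data.frame(pattern_id = character(), smarts = character()),
                      name = basename(path)))
  }
  parts <- strsplit(lines, "[ \t]+")
  smarts <- vapply(parts, `[[`, character(1), 1L)
  ids <- vapply(seq_along(parts), function(i) {
    if (length(parts[[i]]) >= 2L) parts[[i]][[2L]] else paste0("filter", i)
  }, character(1))
  filter_set(data.frame(pattern_id = ids, smarts = smarts),
             name = basename(path))
}

#' Flag compounds matching interference substructures
#'
#' @param compounds data.frame with columns `cid`, `smiles`.
#' @param filters a [filter_set()]; default [default_interference_filters()].
#' @return data.frame with columns `cid`, `flagged` (logical), `matched_ids`
#'   (comma-separated pattern ids, empty when unflagged).
#' @export
flag_compounds <- function(compounds, filters = default_interference_filters()) {
  stopifnot(is.data.frame(compounds),
            all(c("cid", "smiles") %in% names(compounds)),
            inherits(filters, "filter_set"))
  pats <- filters$patterns
  sps <- lapply(pats$smarts, ob_smarts)
  on.exit(for (sp in sps) ob_smarts_free(sp))
  matched <- character(nrow(compounds))
  flagged <- logical(nrow(compounds))
  for (i in seq_len(nrow(compounds))) {
    mol <- ob_parse(compounds$smiles[i])
    if (is.null(mol)) {
      stop("unparsable SMILES for compound ", compounds$cid[i], call. = FALSE)
    }
    hits <- vapply(sps, function(sp) ob_smarts_has_match(sp, mol), logical(1))
    ob_free(mol)
    flagged[i] <- any(hits)
    matched[i] <- paste(pats$pattern_id[hits], collapse = ",")
  }
  data.frame(cid = as.character(compounds$cid), flagged = flagged,
             matched_ids = matched)
}

#' Series without any flagged member
#'
#' @param series_set an `analog_series_set`.
#' @param flags data.frame from [flag_compounds()]; every member compound must
#'   have a flag entry.
#' @return vector of `as_id` values whose members are all unflagged.
#' @export
interference_free_series <- function(series_set, flags) {
  stopifnot(inherits(series_set, "analog_series_set"),
            is.data.frame(flags), all(c("cid", "flagged") %in% names(flags)))
  idx <- match(series_set$members$cid, flags$cid)
  if (anyNA(idx)) {
    stop("member compound(s) without a flag entry: ",
         paste(utils::head(unique(series_set$members$cid[is.na(idx)]), 3),
               collapse = ", "), call. = FALSE)
  }
  member_flag <- flags$flagged[idx]
  bad <- unique(series_set$members$as_id[member_flag])
  ids <- series_set$series$as_id
  ids[!ids %in% bad]
}

#' Write a compound flag table
#'
#' Tab-separated: `cid`, `flag` (yes/no), `matched_ids`.
#'
#' @param flags data.frame from [flag_compounds()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_flag_table <- function(flags, path) {
  rows <- paste(flags$cid, ifelse(flags$flagged, "yes", "no"),
                flags$matched_ids, sep = "\t")
  writeLines(c("cid\tflag\tmatched_ids", rows), path, useBytes = TRUE)
  invisible(path)
}
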