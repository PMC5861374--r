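#' Read a compound table (SMILES file)
#'
#' Reads a two-column tab-separated SMILES file (`SMILES<TAB>id`, UTF-8,
#' optional header detected by a first field equal to `"smiles"` ignoring
#' case). Every structure is canonicalized to aromatic non-stereo SMILES and
#' its heavy-atom count recorded.
#'
#' @param path path to the file.
#' @param on_parse_error `"error"` (default) aborts on the first unparsable
#'   SMILES, naming its line; `"skip"` drops such rows and records them in the
#'   `"skipped"` attribute of the result.
#' @return data.frame with columns `cid`, `smiles` (canonical), `heavy_atoms`,
#'   in file order. Attribute `"skipped"`: data.frame of dropped rows
#'   (`line`, `smiles`, `reason`), present when `on_parse_error = "skip"`.
#' @details Duplicate compound ids are always a fatal error. Disconnected
#'   structures (multi-fragment SMILES) are treated like parse failures, since
#'   a screening compound record must describe one molecule.
#' @export
read_compound_table <- function(path, on_parse_error = c("error", "skip")) {
  on_parse_error <- match.arg(on_parse_error)
  if (!file.exists(path)) stop("compound table not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(structure(data.frame(cid = character(), smiles = character(),
                                heavy_atoms = integer()),
                     skipped = NULL))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  line_no <- seq_along(lines)
  if (tolower(trimws(fields[[1]][1])) %in% c("smiles", "#smiles")) {
    fields <- fields[-1]
    line_no <- line_no[-1]
  }
  bad_shape <- vapply(fields, function(f) length(f) < 2L, logical(1))
  if (any(bad_shape)) {
    stop("compound table row without two tab-separated fields at line ",
         line_no[which(bad_shape)[1]], call. = FALSE)
  }
  raw_smiles <- trimws(vapply(fields, `[[`, character(1), 1L))
  cid <- trimws(vapply(fields, `[[`, character(1), 2L))

  canon <- canonicalize_smiles(raw_smiles, on_error = "na")
  failed <- is.na(canon)
  disconnected <- !failed & !smiles_is_connected(canon)
  reason <- ifelse(failed, "unparsable SMILES", "disconnected structure")
  drop <- failed | disconnected
  if (any(drop) && on_parse_error == "error") {
    i <- which(drop)[1]
    stop(reason[i], " at line ", line_no[i], ": '", raw_smiles[i], "'",
         call. = FALSE)
  }
  skipped <- NULL
  if (any(drop)) {
    skipped <- data.frame(line = line_no[drop], smiles = raw_smiles[drop],
                          reason = reason[drop])
    message("read_compound_table: skipped ", sum(drop), " row(s)")
  }
  cid <- cid[!drop]; canon <- canon[!drop]
  if (anyDuplicated(cid)) {
    stop("duplicate compound id(s): ",
         paste(unique(cid[duplicated(cid)]), collapse = ", "), call. = FALSE)
  }
  out <- data.frame(cid = cid, smiles = canon,
                    heavy_atoms = smiles_heavy_atoms(canon))
  attr(out, "skipped") <- skipped
  out
}

#' Sparse ternary compound-by-assay outcome store
#'
#' Container for compound--assay screening outcomes. Each `(cid, assay_id)`
#' pair carries at most one definite outcome (`"active"` or `"inactive"`);
#' pairs absent from the table are untested. Assay metadata records the assay
#' type (`"primary"` or `"confirmatory"`) and an optional target identifier.
#'
#' @param outcomes data.frame with columns `cid`, `assay_id`, `outcome`.
#' @param assays data.frame with columns `assay_id`, `assay_type`, `target_id`
#'   (`NA` allowed). Defaults to the assays seen in `outcomes`, typed primary.
#' @param compounds character vector of known compound ids; defaults to the
#'   compounds seen in `outcomes`.
#' @return object of class `activity_matrix`.
#' @export
activity_matrix <- function(outcomes, assays = NULL, compounds = NULL) {
  stopifnot(is.data.frame(outcomes),
            all(c("cid", "assay_id", "outcome") %in% names(outcomes)))
  outcomes <- data.frame(cid = as.character(outcomes$cid),
                         assay_id = as.character(outcomes$assay_id),
                         outcome = tolower(as.character(outcomes$outcome)))
  if (!all(outcomes$outcome %in% c("active", "inactive"))) {
    stop("outcomes must be 'active' or 'inactive'", call. = FALSE)
  }
  if (is.null(assays)) {
    assays <- data.frame(assay_id = unique(outcomes$assay_id),
                         assay_type = "primary", target_id = NA_character_)
  }
  stopifnot(all(c("assay_id", "assay_type") %in% names(assays)))
  assays <- data.frame(assay_id = as.character(assays$assay_id),
                       assay_type = as.character(assays$assay_type),
                       target_id = if ("target_id" %in% names(assays))
                         as.character(assays$target_id) else NA_character_)
  if (anyDuplicated(assays$assay_id)) {
    stop("duplicate assay_id in assay metadata", call. = FALSE)
  }
  if (!all(assays$assay_type %in% c("primary", "confirmatory"))) {
    stop("assay_type must be 'primary' or 'confirmatory'", call. = FALSE)
  }
  if (is.null(compounds)) compounds <- unique(outcomes$cid)
  compounds <- as.character(compounds)
  if (!all(outcomes$cid %in% compounds)) {
    stop("outcome row references unknown compound id", call. = FALSE)
  }
  if (!all(outcomes$assay_id %in% assays$assay_id)) {
    stop("outcome row references unknown assay id", call. = FALSE)
  }
  key <- paste(outcomes$cid, outcomes$assay_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("multiple outcomes for the same (cid, assay_id) pair: ",
         sub("\r", " / ", key[duplicated(key)][1]), call. = FALSE)
  }
  structure(list(outcomes = outcomes, assays = assays, compounds = compounds,
                 log = list(dropped_outcomes = 0L, deduplicated = 0L)),
            class = "activity_matrix")
}

#' @export
print.activity_matrix <- function(x, ...) {
  cat("<activity_matrix> ", length(x$compounds), " compounds, ",
      nrow(x$assays), " assays (",
      sum(x$assays$assay_type == "primary"), " primary), ",
      nrow(x$outcomes), " outcomes\n", sep = "")
  invisible(x)
}

#' Read a compound--assay outcome table
#'
#' Reads a five-column tab-separated table: `cid`, `assay_id`, `assay_type`,
#' `outcome`, `target_id` (last column may be empty). An optional header is
#' detected by a first field equal to `"cid"` ignoring case. Outcome tokens
#' are matched case-insensitively; rows whose outcome is neither `active` nor
#' `inactive` (e.g. `inconclusive`) are dropped and counted, because hit rates
#' are defined over assays with a definite outcome. Identical duplicate rows
#' are deduplicated with a count; contradictory outcomes for the same
#' `(cid, assay_id)` pair are a fatal error.
#'
#' @param path path to the file.
#' @return `activity_matrix`; its `log` element reports `dropped_outcomes`
#'   (indefinite-outcome rows) and `deduplicated` (identical duplicates).
#' @export
read_activity_table <- function(path) {
  if (!file.exists(path)) stop("activity table not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("activity table is empty: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (tolower(trimws(fields[[1]][1])) == "cid") fields <- fields[-1]
  n_col <- vapply(fields, length, integer(1))
  if (any(n_col < 4L)) {
    stop("activity table row with fewer than 4 tab-separated fields", call. = FALSE)
  }
  get_col <- function(k, default = NA_character_) {
    vapply(fields, function(f) if (length(f) >= k) trimws(f[[k]]) else default,
           character(1))
  }
  df <- data.frame(cid = get_col(1), assay_id = get_col(2),
                   assay_type = tolower(get_col(3)),
                   outcome = tolower(get_col(4)),
                   target_id = get_col(5))
  df$target_id[!nzchar(df$target_id) | is.na(df$target_id)] <- NA_character_

  bad_type <- !df$assay_type %in% c("primary", "confirmatory")
  if (any(bad_type)) {
    stop("unknown assay_type token: '", df$assay_type[which(bad_type)[1]], "'",
         call. = FALSE)
  }
  definite <- df$outcome %in% c("active", "inactive")
  dropped <- sum(!definite)
  df <- df[definite, , drop = FALSE]
  if (nrow(df) == 0L) stop("no rows with definite outcomes in ", path, call. = FALSE)

  # assay metadata must be consistent across rows
  meta <- unique(df[c("assay_id", "assay_type", "target_id")])
  if (anyDuplicated(meta$assay_id)) {
    bad <- meta$assay_id[duplicated(meta$assay_id)][1]
    stop("conflicting assay metadata for assay ", bad, call. = FALSE)
  }

  full_key <- paste(df$cid, df$assay_id, df$outcome, sep = "\r")
  dup_identical <- duplicated(full_key)
  deduplicated <- sum(dup_identical)
  df <- df[!dup_identical, , drop = FALSE]
  pair_key <- paste(df$cid, df$assay_id, sep = "\r")
  if (anyDuplicated(pair_key)) {
    bad <- strsplit(pair_key[duplicated(pair_key)][1], "\r", fixed = TRUE)[[1]]
    stop("conflicting outcomes (both active and inactive) for compound ",
         bad[1], " in assay ", bad[2], call. = FALSE)
  }

  m <- activity_matrix(df[c("cid", "assay_id", "outcome")], assays = meta)
  m$log$dropped_outcomes <- dropped
  m$log$deduplicated <- deduplicated
  if (dropped > 0L) {
    message("read_activity_table: dropped ", dropped,
            " row(s) without definite outcome")
  }
  m
}

#' Write an activity matrix back to the five-column table format
#'
#' @param matrix an `activity_matrix`.
#' @param path output path.
#' @param header write a header line (default TRUE).
#' @return `path`, invisibly.
#' @export
write_activity_table <- function(matrix, path, header = TRUE) {
  stopifnot(inherits(matrix, "activity_matrix"))
  idx <- match(matrix$outcomes$assay_id, matrix$assays$assay_id)
  rows <- paste(matrix$outcomes$cid, matrix$outcomes$assay_id,
                matrix$assays$assay_type[idx], matrix$outcomes$outcome,
                ifelse(is.na(matrix$assays$target_id[idx]), "",
                       matrix$assays$target_id[idx]),
                sep = "\t")
  if (header) rows <- c("cid\tassay_id\tassay_type\toutcome\ttarget_id", rows)
  writeLines(rows, path, useBytes = TRUE)
  invisible(path)
}

#' Assay sets of a compound
#'
#' `tested_assays()` returns the assays in which a compound has a definite
#' outcome; `active_assays()` those in which it was active.
#'
#' @param matrix an `activity_matrix`.
#' @param cid compound id (length 1).
#' @param assay_type `"primary"`, `"confirmatory"`, or `"all"`.
#' @return character vector of assay ids.
#' @export
tested_assays <- function(matrix, cid, assay_type = "all") {
  assay_sets_for(matrix, cid, assay_type, active_only = FALSE)
}

#' @rdname tested_assays
#' @export
active_assays <- function(matrix, cid, assay_type = "all") {
  assay_sets_for(matrix, cid, assay_type, active_only = TRUE)
}

assay_sets_for <- function(matrix, cid, assay_type, active_only) {
  stopifnot(inherits(matrix, "activity_matrix"), length(cid) == 1L)
  o <- matrix$outcomes[matrix$outcomes$cid == cid, , drop = FALSE]
  if (active_only) o <- o[o$outcome == "active", , drop = FALSE]
  ids <- o$assay_id
  if (assay_type != "all") {
    keep <- matrix$assays$assay_id[matrix$assays$assay_type == assay_type]
    ids <- ids[ids %in% keep]
  }
  ids
}
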