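# Two-file open-access deposition format: AS.txt (one row per analog series)
# and AS_SupportingInformation.txt (one row per compound-series membership).
# Tab-separated, comma-separated list fields, percentages with two decimals.

AS_HEADER <- c("AS_ID", "Rank", "MMS_core", "AS_HR [%]", "Assay_OV [%]",
               "Inconsistent_activity [%]", "CID", "AromaticNon-StereoSMILES")
SUPPORT_HEADER <- c("CID", "AromaticNon-StereoSMILES", "AS_ID", "Rank",
                    "MMS_core", "#primary_assays", "#active_primary_assays",
                    "Hit_rate(%)", "Target_ID", "Interference CPD")

#' Write the two-file analog-series deposition
#'
#' Emits `AS.txt` (one row per series, ordered by consensus rank) and
#' `AS_SupportingInformation.txt` (one row per compound-series membership)
#' into `out_dir`. Columns are tab-separated; member id and SMILES lists are
#' comma-separated without spaces; percentages carry two decimals.
#'
#' @param series_set an `analog_series_set` from [build_series()].
#' @param ranked data.frame from [rank_series()] covering every series.
#' @param compounds data.frame (`cid`, `smiles`) covering every member.
#' @param matrix `activity_matrix` supplying per-compound primary-assay counts
#'   and active-target ids.
#' @param flags data.frame from [flag_compounds()] covering every member.
#' @param out_dir output directory (created if absent).
#' @return character vector of the two file paths, invisibly.
#' @export
write_deposition <- function(series_set, ranked, compounds, matrix, flags,
                             out_dir) {
  stopifnot(inherits(series_set, "analog_series_set"),
            inherits(matrix, "activity_matrix"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  members <- series_set$members
  series <- series_set$series

  midx <- match(series$as_id, ranked$as_id)
  if (anyNA(midx)) {
    stop("series without metrics/rank: as_id ",
         series$as_id[which(is.na(midx))[1]], call. = FALSE)
  }
  smiles_of <- function(cids) {
    i <- match(cids, compounds$cid)
    if (anyNA(i)) stop("member compound without structure record: ",
                       cids[which(is.na(i))[1]], call. = FALSE)
    compounds$smiles[i]
  }
  stats <- compute_hit_rates(matrix)
  sidx <- match(members$cid, stats$cid)
  if (anyNA(sidx)) {
    stop("member compound without activity stats: ",
         members$cid[which(is.na(sidx))[1]], call. = FALSE)
  }
  fidx <- match(members$cid, flags$cid)
  if (anyNA(fidx)) {
    stop("member compound without interference flag: ",
         members$cid[which(is.na(fidx))[1]], call. = FALSE)
  }

  # active target ids per compound (primary or confirmatory, definite active)
  o <- matrix$outcomes[matrix$outcomes$outcome == "active", , drop = FALSE]
  tgt <- matrix$assays$target_id[match(o$assay_id, matrix$assays$assay_id)]
  keep <- !is.na(tgt)
  tgt_by_cid <- split(tgt[keep], o$cid[keep])
  targets_of <- function(cid) {
    t <- tgt_by_cid[[cid]]
    if (is.null(t)) "" else paste(sort(unique(t)), collapse = ",")
  }

  by_series <- split(members, members$as_id)
  ord <- order(ranked$consensus_rank[midx])
  as_rows <- vapply(ord, function(i) {
    s <- series[i, ]; r <- ranked[midx[i], ]
    m <- by_series[[as.character(s$as_id)]]
    paste(s$as_id, r$consensus_rank, s$core_smiles,
          sprintf("%.2f", r$cumulative_hr_percent),
          sprintf("%.2f", r$assay_overlap_percent),
          sprintf("%.2f", r$inconsistent_activity_percent),
          paste(m$cid, collapse = ","),
          paste(smiles_of(m$cid), collapse = ","), sep = "\t")
  }, character(1))
  as_path <- file.path(out_dir, "AS.txt")
  writeLines(c(paste(AS_HEADER, collapse = "\t"), as_rows), as_path,
             useBytes = TRUE)

  rank_of <- ranked$consensus_rank[midx][match(members$as_id, series$as_id)]
  core_of <- series$core_smiles[match(members$as_id, series$as_id)]
  sup <- data.frame(cid = members$cid, as_id = members$as_id,
                    rank = rank_of, core = core_of,
                    n_tested = stats$n_tested_primary[sidx],
                    n_active = stats$n_active_primary[sidx],
                    hr = stats$hr_percent[sidx],
                    flagged = flags$flagged[fidx])
  sup <- sup[order(sup$rank, sup$cid, method = "radix"), , drop = FALSE]
  sup_rows <- paste(sup$cid, smiles_of(sup$cid), sup$as_id, sup$rank, sup$core,
                    sup$n_tested, sup$n_active, sprintf("%.2f", sup$hr),
                    vapply(sup$cid, targets_of, character(1)),
                    ifelse(sup$flagged, "yes", "no"), sep = "\t")
  sup_path <- file.path(out_dir, "AS_SupportingInformation.txt")
  writeLines(c(paste(SUPPORT_HEADER, collapse = "\t"), sup_rows), sup_path,
             useBytes = TRUE)
  invisible(c(as_path, sup_path))
}

split_list_field <- function(x) {
  out <- strsplit(x, ",", fixed = TRUE)[[1]]
  trimws(out)
}

#' Read and cross-check a two-file deposition
#'
#' Parses `AS.txt` and `AS_SupportingInformation.txt`, checks the headers
#' against the expected column labels (tolerating surrounding whitespace) and
#' enforces referential integrity: the two files must describe the same
#' series-id set, and every member id listed in a series row must have a
#' support row for that series. A nine-column support file is accepted as
#' format version 1 (no interference column; flags read as `NA`). Readers
#' accept LF or CRLF line endings, spaces after list commas, and
#' case-insensitive yes/no/true/false/1/0 interference values.
#'
#' @param as_path path to `AS.txt`.
#' @param support_path path to `AS_SupportingInformation.txt`.
#' @return object of class `deposition`: list with data.frames `series`
#'   (typed columns plus list-columns `cids`, `member_smiles`) and `support`.
#' @export
read_deposition <- function(as_path, support_path) {
  for (p in c(as_path, support_path)) {
    if (!file.exists(p)) stop("deposition file not found: ", p, call. = FALSE)
  }
  read_rows <- function(path) {
    lines <- gsub("\r$", "", readLines(path, encoding = "UTF-8", warn = FALSE))
    lines <- lines[nzchar(lines)]
    strsplit(lines, "\t", fixed = TRUE)
  }
  as_rows <- read_rows(as_path)
  if (length(as_rows) == 0L) stop("empty AS file: ", as_path, call. = FALSE)
  got <- trimws(as_rows[[1]])
  if (!identical(got, AS_HEADER)) {
    stop("AS header mismatch.\n  expected: ",
         paste(AS_HEADER, collapse = " | "), "\n  found:    ",
         paste(got, collapse = " | "), call. = FALSE)
  }
  as_body <- as_rows[-1]
  for (i in seq_along(as_body)) {
    if (length(as_body[[i]]) != length(AS_HEADER)) {
      stop("malformed AS row at line ", i + 1L, " of ", as_path,
           " (", length(as_body[[i]]), " fields)", call. = FALSE)
    }
  }
  series <- data.frame(
    as_id = vapply(as_body, function(f) as.integer(f[1]), integer(1)),
    rank = vapply(as_body, function(f) as.integer(f[2]), integer(1)),
    core_smiles = vapply(as_body, `[[`, character(1), 3L),
    as_hr = vapply(as_body, function(f) as.numeric(f[4]), numeric(1)),
    assay_ov = vapply(as_body, function(f) as.numeric(f[5]), numeric(1)),
    inconsistent = vapply(as_body, function(f) as.numeric(f[6]), numeric(1)))
  series$cids <- lapply(as_body, function(f) split_list_field(f[7]))
  series$member_smiles <- lapply(as_body, function(f) split_list_field(f[8]))

  sup_rows <- read_rows(support_path)
  if (length(sup_rows) == 0L) stop("empty support file: ", support_path, call. = FALSE)
  got <- trimws(sup_rows[[1]])
  version <- if (identical(got, SUPPORT_HEADER)) 2L
             else if (identical(got, SUPPORT_HEADER[1:9])) 1L
             else stop("support header mismatch.\n  expected: ",
                       paste(SUPPORT_HEADER, collapse = " | "), "\n  found:    ",
                       paste(got, collapse = " | "), call. = FALSE)
  n_col <- if (version == 2L) 10L else 9L
  sup_body <- sup_rows[-1]
  for (i in seq_along(sup_body)) {
    if (!length(sup_body[[i]]) %in% c(n_col, n_col - 1L)) {
      stop("malformed support row at line ", i + 1L, " of ", support_path,
           " (", length(sup_body[[i]]), " fields)", call. = FALSE)
    }
    # a trailing empty Target_ID may drop the final tab-separated field count
    if (length(sup_body[[i]]) == n_col - 1L) {
      sup_body[[i]] <- append(sup_body[[i]], "", after = 8L)
    }
  }
  norm_flag <- function(x) {
    x <- tolower(trimws(x))
    ifelse(x %in% c("yes", "true", "1"), "yes",
           ifelse(x %in% c("no", "false", "0"), "no", NA_character_))
  }
  support <- data.frame(
    cid = vapply(sup_body, `[[`, character(1), 1L),
    smiles = vapply(sup_body, `[[`, character(1), 2L),
    as_id = vapply(sup_body, function(f) as.integer(f[3]), integer(1)),
    rank = vapply(sup_body, function(f) as.integer(f[4]), integer(1)),
    core_smiles = vapply(sup_body, `[[`, character(1), 5L),
    n_primary = vapply(sup_body, function(f) as.integer(f[6]), integer(1)),
    n_active_primary = vapply(sup_body, function(f) as.integer(f[7]), integer(1)),
    hit_rate = vapply(sup_body, function(f) as.numeric(f[8]), numeric(1)),
    target_id = vapply(sup_body, function(f) gsub(", ", ",", f[9]), character(1)),
    interference = if (version == 2L)
      norm_flag(vapply(sup_body, `[[`, character(1), 10L))
    else NA_character_)

  pair <- paste(support$cid, support$as_id)
  if (anyDuplicated(pair)) {
    stop("duplicate (CID, AS_ID) support row: ", pair[duplicated(pair)][1],
         call. = FALSE)
  }
  missing_in_sup <- setdiff(series$as_id, support$as_id)
  missing_in_as <- setdiff(support$as_id, series$as_id)
  if (length(missing_in_sup) || length(missing_in_as)) {
    stop("AS_ID sets differ between files; only in AS.txt: {",
         paste(missing_in_sup, collapse = ","), "}, only in support: {",
         paste(missing_in_as, collapse = ","), "}", call. = FALSE)
  }
  for (i in seq_len(nrow(series))) {
    want <- paste(series$cids[[i]], series$as_id[i])
    absent <- setdiff(want, pair)
    if (length(absent)) {
      stop("support row missing for (CID, AS_ID): ", absent[1], call. = FALSE)
    }
  }
  structure(list(series = series, support = support, version = version),
            class = "deposition")
}

#' @export
print.deposition <- function(x, ...) {
  cat("<deposition v", x$version, "> ", nrow(x$series), " series, ",
      nrow(x$support), " membership rows\n", sep = "")
  invisible(x)
}

#' Validate a deposition and summarize its contents
#'
#' Produces the summary statistics of a parsed deposition (series count,
#' membership counts, compounds in multiple series, member counts per series,
#' hit-rate distribution, interference-free series) and lists internal
#' consistency violations: percentages out of range, member-list length
#' mismatches, non-positive ranks, active counts exceeding tested counts, and
#' per-compound hit rates that disagree with `100 * active / tested` beyond
#' `tolerance`.
#'
#' @param dep a `deposition` from [read_deposition()].
#' @param tolerance absolute tolerance on percentage comparisons
#'   (default 0.05, absorbing two-decimal serialization rounding).
#' @return object of class `deposition_report`: list with `summary` (named
#'   list) and `violations` (data.frame `kind`, `detail`).
#' @export
validate_deposition <- function(dep, tolerance = 0.05) {
  stopifnot(inherits(dep, "deposition"))
  v <- list()
  bad <- function(kind, detail) v[[length(v) + 1L]] <<- data.frame(kind = kind,
                                                                   detail = detail)
  s <- dep$series; sup <- dep$support
  if (nrow(s) == 0L) {
    warning("deposition contains zero series", call. = FALSE)
  }
  for (i in seq_len(nrow(s))) {
    nc <- length(s$cids[[i]]); ns <- length(s$member_smiles[[i]])
    if (nc != ns) bad("member_list_mismatch",
                      sprintf("AS %d: %d CIDs vs %d SMILES", s$as_id[i], nc, ns))
    if (nc < 2L) bad("too_few_members", sprintf("AS %d: %d member(s)", s$as_id[i], nc))
    if (anyDuplicated(s$cids[[i]])) bad("duplicate_member",
                                        sprintf("AS %d", s$as_id[i]))
  }
  for (col in c("as_hr", "assay_ov", "inconsistent")) {
    out <- which(is.na(s[[col]]) | s[[col]] < 0 | s[[col]] > 100)
    for (i in out) bad("percent_out_of_range",
                       sprintf("AS %d: %s = %s", s$as_id[i], col, s[[col]][i]))
  }
  if (nrow(s) > 0L && (anyNA(s$rank) || any(s$rank < 1L))) bad("bad_rank", "AS.txt")
  over <- which(sup$n_active_primary > sup$n_primary)
  for (i in over) bad("active_exceeds_tested",
                      sprintf("CID %s in AS %d", sup$cid[i], sup$as_id[i]))
  recomputed <- ifelse(sup$n_primary > 0L,
                       100 * sup$n_active_primary / sup$n_primary, NA_real_)
  off <- which(!is.na(recomputed) & abs(recomputed - sup$hit_rate) > tolerance)
  for (i in off) bad("hit_rate_mismatch",
                     sprintf("CID %s in AS %d: stated %.2f, recomputed %.4f",
                             sup$cid[i], sup$as_id[i], sup$hit_rate[i],
                             recomputed[i]))

  n_members <- lengths(s$cids)
  cid_series <- unique(sup[c("cid", "as_id")])
  per_cid <- table(cid_series$cid)
  flag_by_series <- tapply(sup$interference, sup$as_id,
                           function(x) all(!is.na(x)) && all(x == "no"))
  summary <- list(
    n_series = nrow(s),
    n_memberships = nrow(sup),
    n_unique_compounds = length(unique(sup$cid)),
    n_multi_series_compounds = sum(per_cid >= 2L),
    members_min = if (nrow(s)) min(n_members) else NA_integer_,
    members_max = if (nrow(s)) max(n_members) else NA_integer_,
    as_hr_min = if (nrow(s)) min(s$as_hr) else NA_real_,
    as_hr_max = if (nrow(s)) max(s$as_hr) else NA_real_,
    as_hr_median = if (nrow(s)) stats::median(s$as_hr) else NA_real_,
    n_interference_free_series = sum(unlist(flag_by_series)),
    n_violations = length(v))
  violations <- if (length(v)) do.call(rbind, v)
                else data.frame(kind = character(), detail = character())
  structure(list(summary = summary, violations = violations),
            class = "deposition_report")
}

#' @export
print.deposition_report <- function(x, ...) {
  cat("Deposition validation report\n")
  for (k in names(x$summary)) {
    val <- x$summary[[k]]
    if (is.numeric(val)) val <- format(val, digits = 6)
    cat(sprintf("  %-28s %s\n", k, val))
  }
  if (nrow(x$violations)) {
    cat("Violations:\n")
    for (i in seq_len(nrow(x$violations))) {
      cat("  [", x$violations$kind[i], "] ", x$violations$detail[i], "\n",
          sep = "")
    }
  } else {
    cat("  no violations\n")
  }
  invisible(x)
}
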