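#' Run the full analog-series pipeline
#'
#' Orchestrates the end-to-end analysis: read compounds and activity, compute
#' per-compound hit rates, apply the cascade selection, extract analog series
#' from the selected compounds, compute and rank the series parameters, flag
#' interference candidates, and write the two-file deposition plus series,
#' metrics and flag tables and a JSON run manifest into `out_dir`. The
#' pipeline is deterministic: identical inputs and configuration produce
#' byte-identical outputs.
#'
#' While a run is in progress a `RUN.partial` marker file exists in
#' `out_dir`; it is removed on success, so its presence marks partial output
#' from a failed run.
#'
#' @param compound_file SMILES file (`SMILES<TAB>id`).
#' @param activity_file five-column activity table (see
#'   [read_activity_table()]).
#' @param out_dir output directory (created if absent).
#' @param selection a [selection_config()].
#' @param policy a [fragmentation_policy()].
#' @param filters a [filter_set()], a path to a filter file, or `NULL` for
#'   the default exemplar set.
#' @param tolerance percentage tolerance forwarded to deposition validation.
#' @return invisibly, a list with the per-stage results (`stats`, `selection`,
#'   `series`, `ranked`, `flags`, `report`) and the `manifest`.
#' @export
run_analog_pipeline <- function(compound_file, activity_file, out_dir,
                                selection = selection_config(),
                                policy = fragmentation_policy(),
                                filters = NULL, tolerance = 0.05) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  marker <- file.path(out_dir, "RUN.partial")
  file.create(marker)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  if (is.null(filters)) filters <- default_interference_filters()
  if (is.character(filters)) filters <- stage("flag", read_filter_set(filters))

  compounds <- stage("read", read_compound_table(compound_file))
  matrix <- stage("read", read_activity_table(activity_file))

  stats <- stage("select", compute_hit_rates(matrix))
  sel <- stage("select", cascade_select(stats, selection))
  conf_frac <- tryCatch(confirmatory_consistency(sel$selected, stats),
                        error = function(e) NA_real_)
  selected <- compounds[compounds$cid %in% sel$selected, , drop = FALSE]

  series <- stage("extract", build_series(selected, policy))
  write_series_table(series, file.path(out_dir, "series.tsv"))

  n_series <- nrow(series$series)
  ranked <- NULL
  flags <- flag_compounds(compounds[compounds$cid %in% series$members$cid, ,
                                    drop = FALSE], filters)
  write_flag_table(flags, file.path(out_dir, "flags.tsv"))
  if (n_series > 0L) {
    metrics <- stage("metrics", series_metrics(series, matrix))
    ranked <- stage("metrics", rank_series(metrics))
    write_metrics_table(ranked, file.path(out_dir, "metrics.tsv"))
    stage("write-deposition",
          write_deposition(series, ranked, compounds, matrix, flags, out_dir))
  } else {
    writeLines(paste(AS_HEADER, collapse = "\t"),
               file.path(out_dir, "AS.txt"))
    writeLines(paste(SUPPORT_HEADER, collapse = "\t"),
               file.path(out_dir, "AS_SupportingInformation.txt"))
  }

  dep <- stage("validate", read_deposition(
    file.path(out_dir, "AS.txt"),
    file.path(out_dir, "AS_SupportingInformation.txt")))
  report <- suppressWarnings(validate_deposition(dep, tolerance = tolerance))

  ifree <- interference_free_series(series, flags)
  manifest <- list(
    inputs = list(compound_file = compound_file,
                  activity_file = activity_file),
    n_compounds = nrow(compounds),
    selection = sel$report,
    confirmatory_active_fraction = conf_frac,
    policy = list(bond_rule = policy$bond_rule,
                  n_retro_patterns = if (is.null(policy$retro_patterns)) 0L
                                     else nrow(policy$retro_patterns),
                  retro_pattern_checksum = pattern_checksum(policy$retro_patterns),
                  max_substituent_heavy_atoms = policy$max_substituent_heavy_atoms,
                  require_substituent_smaller_than_core =
                    policy$require_substituent_smaller_than_core,
                  allow_hydrogen_substituent = policy$allow_hydrogen_substituent),
    filters = list(name = filters$name,
                   n_patterns = nrow(filters$patterns),
                   checksum = pattern_checksum(filters$patterns)),
    n_series = n_series,
    n_memberships = nrow(series$members),
    n_unique_member_compounds = length(unique(series$members$cid)),
    n_interference_free_series = length(ifree),
    validation = report$summary)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  file.remove(marker)
  invisible(list(stats = stats, selection = sel, series = series,
                 ranked = ranked, flags = flags, report = report,
                 manifest = manifest))
}

# md5 of a pattern table (id + SMARTS lines), recorded in the run manifest so
# a run can be reproduced with the exact rule set
pattern_checksum <- function(patterns) {
  if (is.null(patterns) || nrow(patterns) == 0L) return(NA_character_)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(patterns$pattern_id, patterns$smarts, sep = "\t"), tmp,
             useBytes = TRUE)
  unname(tools::md5sum(tmp))
}
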