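# Builders for small hand-written fixtures.

# Activity matrix from named lists: tested[[cid]] = assay ids with a definite
# outcome, active[[cid]] = subset that is active.
mk_matrix <- function(tested, active, assay_type = "primary",
                      targets = NULL) {
  rows <- list()
  for (cid in names(tested)) {
    for (a in tested[[cid]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        cid = cid, assay_id = as.character(a),
        outcome = if (a %in% active[[cid]]) "active" else "inactive")
    }
  }
  outcomes <- do.call(rbind, rows)
  assay_ids <- unique(outcomes$assay_id)
  assays <- data.frame(assay_id = assay_ids,
                       assay_type = rep_len(assay_type, length(assay_ids)),
                       target_id = if (is.null(targets)) NA_character_
                                   else targets[assay_ids])
  activity_matrix(outcomes, assays = assays)
}

write_tsv_lines <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path, useBytes = TRUE)
  path
}

# Small random synthetic library + panel for property tests.
small_synthetic <- function(seed, n_series = 3L, decoys = 4L, ...) {
  cfg <- synthetic_config(n_series = n_series, decoy_compounds = decoys,
                          seed = seed, ...)
  lib <- generate_library(cfg)
  sim <- simulate_assays(lib, cfg)
  list(cfg = cfg, lib = lib, sim = sim)
}

# core -> sorted member-cid set map from an analog_series_set
series_map <- function(series_set) {
  core_of <- series_set$series$core_smiles[
    match(series_set$members$as_id, series_set$series$as_id)]
  lapply(split(series_set$members$cid, core_of),
         function(x) sort(unique(x)))
}

# Full deposition fixture: extract series from a synthetic library, score,
# rank, flag, and write the two files into a temp dir.
make_deposition <- function(seed, n_series = 4L, decoys = 2L, ...) {
  s <- small_synthetic(seed, n_series = n_series, decoys = decoys, ...)
  bs <- build_series(s$lib$compounds,
                     fragmentation_policy(bond_rule = "all_acyclic"))
  ranked <- rank_series(series_metrics(bs, s$sim$matrix))
  flags <- flag_compounds(
    s$lib$compounds[s$lib$compounds$cid %in% bs$members$cid, ])
  dir <- tempfile("dep")
  paths <- write_deposition(bs, ranked, s$lib$compounds, s$sim$matrix, flags,
                            dir)
  list(synth = s, bs = bs, ranked = ranked, flags = flags, dir = dir,
       as_path = paths[1], sup_path = paths[2])
}

mixture_stats <- function(n, seed) {
  # bimodal HR mixture over heavily and lightly tested compounds
  set.seed(seed)
  n_tested <- sample(c(100L, 300L, 500L), n, replace = TRUE)
  hr <- ifelse(stats::runif(n) < 0.7, stats::rbeta(n, 1, 60),
               stats::rbeta(n, 2, 20)) * 100
  n_active <- round(hr / 100 * n_tested)
  data.frame(cid = sprintf("M%04d", seq_len(n)),
             n_tested_primary = n_tested, n_active_primary = n_active,
             hr_percent = 100 * n_active / n_tested,
             n_tested_confirmatory = 0L, n_active_confirmatory = 0L)
}
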