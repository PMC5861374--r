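# Synthetic analog libraries and simulated assay panels with known ground
# truth, so every pipeline stage is testable without external screening data.

default_core_templates <- function() {
  c(phenyl = "[*]c1ccccc1",
    biphenyl = "[*]c1ccc(-c2ccccc2)cc1",
    benzamide = "[*]NC(=O)c1ccccc1",
    indolyl = "[*]c1c[nH]c2ccccc12",
    piperidinylphenyl = "[*]N1CCC(c2ccccc2)CC1")
}

default_r_groups <- function() {
  c("[*]C", "[*]CC", "[*]CCC", "[*]C(C)C", "[*]CCCC", "[*]CC(C)C",
    "[*]C(C)CC", "[*]C(C)(C)C", "[*]CCCCC", "[*]CC(C)(C)C", "[*]C(C)CCC",
    "[*]F", "[*]Cl", "[*]Br", "[*]I",
    "[*]O", "[*]OC", "[*]OCC", "[*]OC(C)C", "[*]OCCC", "[*]OCCO",
    "[*]N", "[*]NC", "[*]N(C)C", "[*]NCC", "[*]NCCC",
    "[*]C#N", "[*]C(F)(F)F", "[*]OC(F)(F)F",
    "[*]C(=O)O", "[*]C(=O)OC", "[*]C(=O)C", "[*]C(=O)N", "[*]C(=O)NC",
    "[*]C=O", "[*]CO", "[*]CCO", "[*]CCCO", "[*]CN", "[*]CCN", "[*]CC#N",
    "[*]S", "[*]SC", "[*]SCC", "[*]S(=O)C", "[*]S(=O)(=O)C",
    "[*]C=C", "[*]CC=C", "[*]C#C", "[*]CC#C",
    "[*]C1CC1", "[*]CC1CC1", "[*]C1CCC1", "[*]C1CCCC1",
    "[*]CF", "[*]CCF", "[*]C(F)F", "[*]CCl", "[*]CCCl", "[*]CBr",
    "[*]COC", "[*]CCOC", "[*]NC(=O)C", "[*]OCC=C")
}

# Decoy scaffolds: none of their single cuts can reproduce a default series
# template core (no monosubstituted-benzene attachment), which is also
# re-checked at generation time.
default_decoy_templates <- function() {
  c("[*]c1ccc(C)cc1", "[*]c1ccc(F)cc1", "[*]c1ccc(OC)cc1",
    "[*]c1ccc(Cl)cc1", "[*]c1ccccn1", "[*]c1cccnc1", "[*]c1ccncc1",
    "[*]c1ccc2ccccc2c1", "[*]c1ccco1", "[*]c1cccs1",
    "[*]C1CCCCC1", "[*]C1CCOCC1")
}

#' Configuration of the synthetic screening-data generator
#'
#' Describes the study conditions emulated by [generate_library()] and
#' [simulate_assays()]: analog series of 2--17 members built from shared
#' single-attachment cores with one-site R-group variation, per-series union
#' assay sets of 261--592 primary assays (so per-compound testing frequencies
#' land in the hundreds), and series-level activity with controllable
#' cumulative hit rate, assay overlap and inconsistency. Member counts are
#' drawn as `2 + Poisson(0.5)` truncated to `members_range`, giving the small,
#' right-skewed series sizes (mean about 2.5 members) typical of analog
#' series mined from screening collections.
#'
#' @param n_series number of planted analog series.
#' @param members_range inclusive member-count range per series (default 2--17).
#' @param core_templates named character vector of scaffold SMILES, each with
#'   one `[*]` attachment; templates are assigned round-robin.
#' @param r_groups character vector of substituent SMILES with one `[*]`
#'   attachment (small fragments, well under the 13-heavy-atom cap).
#' @param n_assays size of the primary assay panel (default 650, so the
#'   261--592 per-series union range fits).
#' @param assays_per_series range of the per-series union assay count
#'   (default 261--592).
#' @param target_cumulative_hr,target_overlap,target_inconsistency series-level
#'   activity targets as fractions (defaults 0.06 / 0.70 / 0.05; the hit-rate
#'   default sits at the middle of the high-hit-rate regime the pipeline is
#'   meant to isolate).
#' @param decoy_compounds number of non-analog singleton compounds.
#' @param decoy_hit_rate per-assay activity probability of decoys
#'   (default 0.005, i.e. background screening hit rates well below 1%).
#' @param n_confirmatory_assays size of the confirmatory panel.
#' @param confirmatory_active_prob probability that a compound with primary
#'   activity is also active in at least one confirmatory assay (default 0.9).
#' @param seed integer seed; every random draw of both generator stages flows
#'   from it.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_series = 20L,
                             members_range = c(2L, 17L),
                             core_templates = default_core_templates(),
                             r_groups = default_r_groups(),
                             n_assays = 650L,
                             assays_per_series = c(261L, 592L),
                             target_cumulative_hr = 0.06,
                             target_overlap = 0.70,
                             target_inconsistency = 0.05,
                             decoy_compounds = 10L,
                             decoy_hit_rate = 0.005,
                             n_confirmatory_assays = 50L,
                             confirmatory_active_prob = 0.9,
                             seed = 1L) {
  stopifnot(n_series >= 0, length(members_range) == 2L,
            members_range[1] >= 2L, members_range[1] <= members_range[2],
            n_assays >= 1, length(assays_per_series) == 2L,
            assays_per_series[1] >= 1,
            assays_per_series[1] <= assays_per_series[2],
            target_cumulative_hr >= 0, target_cumulative_hr <= 1,
            target_overlap >= 0, target_overlap <= 1,
            target_inconsistency >= 0, target_inconsistency <= 1,
            decoy_compounds >= 0, decoy_hit_rate >= 0, decoy_hit_rate <= 1,
            confirmatory_active_prob >= 0, confirmatory_active_prob <= 1)
  if (target_inconsistency > 0 && target_overlap == 0) {
    stop("infeasible targets: inconsistent activity is defined over shared ",
         "assays, so target_inconsistency > 0 requires target_overlap > 0",
         call. = FALSE)
  }
  if (length(r_groups) < members_range[1]) {
    stop("need at least as many r_groups as the minimum series size",
         call. = FALSE)
  }
  structure(list(n_series = as.integer(n_series),
                 members_range = as.integer(members_range),
                 core_templates = core_templates, r_groups = r_groups,
                 n_assays = as.integer(n_assays),
                 assays_per_series = as.integer(assays_per_series),
                 target_cumulative_hr = target_cumulative_hr,
                 target_overlap = target_overlap,
                 target_inconsistency = target_inconsistency,
                 decoy_compounds = as.integer(decoy_compounds),
                 decoy_hit_rate = decoy_hit_rate,
                 n_confirmatory_assays = as.integer(n_confirmatory_assays),
                 confirmatory_active_prob = confirmatory_active_prob,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# sample() without the scalar-x surprise
resample <- function(x, n) x[sample.int(length(x), n)]

#' Generate a synthetic analog library
#'
#' Builds `n_series` analog series by attaching distinct R-groups to core
#' templates (round-robin over the templates; R-groups never reused within a
#' template, and always strictly smaller than their core so that every planted
#' member is recoverable by fragmentation), plus singleton decoy compounds
#' from separate scaffolds verified not to share any cut core with the series
#' templates. Deterministic for a fixed config (same seed gives byte-identical
#' compound tables).
#'
#' @param config a [synthetic_config()].
#' @return list with `compounds` (data.frame `cid`, `smiles`, `heavy_atoms`)
#'   and `truth` (per-series core, member cids and substituents; decoy cids;
#'   the config).
#' @export
generate_library <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, generate_library_impl(config))
}

generate_library_impl <- function(config) {
  templates <- canonicalize_smiles(unname(config$core_templates))
  rgroups <- canonicalize_smiles(unname(config$r_groups))
  if (anyDuplicated(rgroups)) {
    stop("r_groups contain duplicates after canonicalization", call. = FALSE)
  }
  tmpl_heavy <- smiles_heavy_atoms(templates) - 1L   # exclude the attachment
  rg_heavy <- smiles_heavy_atoms(rgroups) - 1L

  counter <- 0L
  next_cid <- function() {
    counter <<- counter + 1L
    sprintf("SYN%05d", counter)
  }
  used <- lapply(templates, function(x) character(0))
  series_truth <- vector("list", config$n_series)
  comp_rows <- list()
  seen_smiles <- character(0)

  for (s in seq_len(config$n_series)) {
    ti <- ((s - 1L) %% length(templates)) + 1L
    tmpl <- templates[ti]
    avail <- rgroups[rg_heavy < tmpl_heavy[ti] & !rgroups %in% used[[ti]]]
    k <- min(config$members_range[2], length(avail),
             max(config$members_range[1], 2L + stats::rpois(1L, 0.5)))
    if (k < 2L) {
      stop("r_groups exhausted for template ", tmpl,
           "; supply more r_groups or fewer series", call. = FALSE)
    }
    chosen <- character(0)
    cids <- character(0)
    pool <- resample(avail, length(avail))
    for (r in pool) {
      if (length(chosen) == k) break
      smi <- tryCatch(reattach_fragments(tmpl, r), error = function(e) NULL)
      if (is.null(smi)) {
        message("generate_library: skipped invalid attachment ", tmpl,
                " + ", r)
        next
      }
      if (smi %in% seen_smiles) next   # cross-template structure collision
      seen_smiles <- c(seen_smiles, smi)
      chosen <- c(chosen, r)
      cid <- next_cid()
      cids <- c(cids, cid)
      comp_rows[[length(comp_rows) + 1L]] <- data.frame(cid = cid, smiles = smi)
    }
    if (length(chosen) < 2L) {
      stop("could not assemble at least 2 members for template ", tmpl,
           call. = FALSE)
    }
    used[[ti]] <- c(used[[ti]], chosen)
    series_truth[[s]] <- list(as_id_true = s, core_smiles = tmpl,
                              cids = cids, substituents = chosen)
  }

  decoy_templates <- canonicalize_smiles(default_decoy_templates())
  planted_cores <- templates
  decoy_cids <- character(0)
  acyclic <- fragmentation_policy(bond_rule = "all_acyclic",
                                  require_substituent_smaller_than_core = FALSE,
                                  allow_hydrogen_substituent = FALSE)
  for (d in seq_len(config$decoy_compounds)) {
    tmpl <- decoy_templates[((d - 1L) %% length(decoy_templates)) + 1L]
    ok <- FALSE
    for (attempt in seq_len(20L)) {
      r <- resample(rgroups, 1L)
      smi <- tryCatch(reattach_fragments(tmpl, r), error = function(e) NULL)
      if (is.null(smi) || smi %in% seen_smiles) next
      cores <- unique(enumerate_cuts(smi, acyclic)$core_smiles)
      if (any(cores %in% planted_cores)) next
      ok <- TRUE
      break
    }
    seen_smiles <- c(seen_smiles, smi)
    if (!ok) stop("could not place decoy on template ", tmpl, call. = FALSE)
    cid <- next_cid()
    decoy_cids <- c(decoy_cids, cid)
    comp_rows[[length(comp_rows) + 1L]] <- data.frame(cid = cid, smiles = smi)
  }

  compounds <- do.call(rbind, comp_rows)
  if (anyDuplicated(compounds$smiles)) {
    stop("generated library contains duplicate structures", call. = FALSE)
  }
  compounds$heavy_atoms <- smiles_heavy_atoms(compounds$smiles)
  list(compounds = compounds,
       truth = list(series = series_truth, decoys = decoy_cids,
                    config = config))
}

#' Simulate an assay panel over a synthetic library
#'
#' For each planted series, draws a union set of primary assays, designates a
#' shared subset tested by every member (size `ceil(target_overlap * U)`),
#' distributes the remaining union assays over proper member subsets, and
#' chooses `ceil(target_cumulative_hr * U)` union assays as active-in-series,
#' of which `round(target_inconsistency * |shared|)` shared assays receive
#' mixed active/inactive member outcomes. Decoys are tested at the same
#' frequency with independent low-rate activity. Compounds with primary
#' activity are additionally tested in confirmatory assays and come out active
#' there with probability `confirmatory_active_prob`. The ground truth records
#' the realized (integer-granular) parameter values next to the targets.
#'
#' @param library result of [generate_library()].
#' @param config the same [synthetic_config()]; infeasible target
#'   combinations (a mixed-activity budget exceeding the active budget) are a
#'   fatal error.
#' @return list with `matrix` (an `activity_matrix`) and `truth` (the library
#'   ground truth completed with realized per-series `hr`, `overlap`,
#'   `inconsistency` percentages and the underlying counts).
#' @export
simulate_assays <- function(library, config = library$truth$config) {
  stopifnot(is.list(library), !is.null(library$truth),
            inherits(config, "synthetic_config"))
  withr::with_seed(config$seed + 1L, simulate_assays_impl(library, config))
}

simulate_assays_impl <- function(library, config) {
  primary_ids <- sprintf("PA%04d", seq_len(config$n_assays))
  conf_ids <- if (config$n_confirmatory_assays > 0L)
    sprintf("CA%03d", seq_len(config$n_confirmatory_assays)) else character(0)
  target_pool <- sprintf("T%03d", seq_len(max(1L, round(config$n_assays / 3))))
  # about 70% of primary assays carry a specified target annotation
  primary_targets <- rep(NA_character_, config$n_assays)
  specified <- stats::runif(config$n_assays) < 0.7
  primary_targets[specified] <-
    target_pool[sample.int(length(target_pool), sum(specified), replace = TRUE)]

  out <- list()
  emit <- function(cids, assay, outcome) {
    out[[length(out) + 1L]] <<- data.frame(cid = cids, assay_id = assay,
                                           outcome = outcome)
  }

  truth <- library$truth
  u_max <- min(config$assays_per_series[2], config$n_assays)
  u_min <- min(config$assays_per_series[1], u_max)
  for (s in seq_along(truth$series)) {
    ser <- truth$series[[s]]
    members <- ser$cids
    k <- length(members)
    U <- sample(seq.int(u_min, u_max), 1L)
    union_set <- resample(primary_ids, U)
    nS <- ceiling(config$target_overlap * U)
    shared <- if (nS > 0L) union_set[seq_len(nS)] else character(0)
    nonshared <- if (nS < U) union_set[seq.int(nS + 1L, U)] else character(0)
    nInc <- round(config$target_inconsistency * nS)
    nAct <- ceiling(config$target_cumulative_hr * U)
    if (nAct > U) nAct <- U
    if (nInc > nAct) {
      stop("infeasible targets for series ", ser$as_id_true, ": ", nInc,
           " mixed shared assays required but only ", nAct,
           " active union assays budgeted; lower target_inconsistency or ",
           "raise target_cumulative_hr", call. = FALSE)
    }
    mixed <- if (nInc > 0L) resample(shared, nInc) else character(0)
    rest_act <- resample(setdiff(union_set, mixed), nAct - nInc)
    act_set <- c(mixed, rest_act)

    for (a in shared) {
      if (a %in% mixed) {
        n_on <- sample.int(k - 1L, 1L)
        on <- resample(members, n_on)
        emit(on, a, "active")
        emit(setdiff(members, on), a, "inactive")
      } else if (a %in% act_set) {
        emit(members, a, "active")
      } else {
        emit(members, a, "inactive")
      }
    }
    for (a in nonshared) {
      testers <- resample(members, sample.int(k - 1L, 1L))
      emit(testers, a, if (a %in% act_set) "active" else "inactive")
    }
    truth$series[[s]]$n_union_assays <- U
    truth$series[[s]]$n_shared_assays <- nS
    truth$series[[s]]$n_active_union_assays <- nAct
    truth$series[[s]]$n_inconsistent_assays <- nInc
    truth$series[[s]]$realized_hr_percent <- 100 * nAct / U
    truth$series[[s]]$realized_overlap_percent <- 100 * nS / U
    truth$series[[s]]$realized_inconsistency_percent <-
      if (nS > 0L) 100 * nInc / nS else 0
  }

  for (cid in truth$decoys) {
    nT <- sample(seq.int(u_min, u_max), 1L)
    tested <- resample(primary_ids, nT)
    act <- stats::runif(nT) < config$decoy_hit_rate
    if (any(act)) emit(cid, tested[act], "active")
    if (any(!act)) emit(cid, tested[!act], "inactive")
  }

  outcomes <- do.call(rbind, out)

  # confirmatory follow-up for compounds with primary activity
  if (length(conf_ids) > 0L) {
    active_cids <- unique(outcomes$cid[outcomes$outcome == "active"])
    for (cid in active_cids) {
      nC <- sample.int(min(8L, length(conf_ids)), 1L)
      tested <- resample(conf_ids, nC)
      if (stats::runif(1L) < config$confirmatory_active_prob) {
        emit(cid, tested[1L], "active")
        if (nC > 1L) emit(cid, tested[-1L], "inactive")
      } else {
        emit(cid, tested, "inactive")
      }
    }
    outcomes <- do.call(rbind, out)
  }

  assays <- rbind(
    data.frame(assay_id = primary_ids, assay_type = "primary",
               target_id = primary_targets),
    if (length(conf_ids) > 0L)
      data.frame(assay_id = conf_ids, assay_type = "confirmatory",
                 target_id = NA_character_))
  matrix <- activity_matrix(outcomes, assays = assays,
                            compounds = library$compounds$cid)
  list(matrix = matrix, truth = truth)
}

#' Write a synthetic data set to disk
#'
#' Emits the compound SMILES file, the activity table, and a ground-truth
#' JSON into `out_dir`.
#'
#' @param library result of [generate_library()].
#' @param simulated result of [simulate_assays()].
#' @param out_dir output directory.
#' @return paths of the three files, invisibly.
#' @export
write_synthetic_dataset <- function(library, simulated, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  cmp_path <- file.path(out_dir, "compounds.smi")
  writeLines(c("smiles\tcid",
               paste(library$compounds$smiles, library$compounds$cid,
                     sep = "\t")), cmp_path, useBytes = TRUE)
  act_path <- file.path(out_dir, "activity.tsv")
  write_activity_table(simulated$matrix, act_path)
  truth_path <- file.path(out_dir, "ground_truth.json")
  truth <- simulated$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(cmp_path, act_path, truth_path))
}
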