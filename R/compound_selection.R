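#' Per-compound assay hit rates
#'
#' Computes, for every compound in the matrix, the number of primary assays
#' with a definite outcome, the number of those in which it was active, the
#' hit rate (HR, percent active among tested primary assays), and the
#' corresponding confirmatory-assay counts. Compounds never tested in a
#' primary assay get `hr_percent = NA`.
#'
#' @param matrix an `activity_matrix`.
#' @return data.frame with columns `cid`, `n_tested_primary`,
#'   `n_active_primary`, `hr_percent`, `n_tested_confirmatory`,
#'   `n_active_confirmatory`; one row per compound known to the matrix.
#' @export
compute_hit_rates <- function(matrix) {
  stopifnot(inherits(matrix, "activity_matrix"))
  o <- matrix$outcomes
  type <- matrix$assays$assay_type[match(o$assay_id, matrix$assays$assay_id)]
  cids <- matrix$compounds
  count_by <- function(sel) {
    t <- table(factor(o$cid[sel], levels = cids))
    as.integer(t)
  }
  prim <- type == "primary"
  conf <- type == "confirmatory"
  act <- o$outcome == "active"
  out <- data.frame(
    cid = cids,
    n_tested_primary = count_by(prim),
    n_active_primary = count_by(prim & act),
    n_tested_confirmatory = count_by(conf),
    n_active_confirmatory = count_by(conf & act)
  )
  out$hr_percent <- ifelse(out$n_tested_primary > 0L,
                           100 * out$n_active_primary / out$n_tested_primary,
                           NA_real_)
  out[c("cid", "n_tested_primary", "n_active_primary", "hr_percent",
        "n_tested_confirmatory", "n_active_confirmatory")]
}

#' Median and third quartile of the hit-rate distribution
#'
#' Quantiles are computed with the linear-interpolation convention
#' (`stats::quantile` type 7) over compounds with a defined hit rate.
#'
#' @param stats data.frame from [compute_hit_rates()].
#' @return named numeric vector `c(median = ..., q3 = ...)`.
#' @export
hr_quantiles <- function(stats) {
  hr <- stats$hr_percent
  hr <- hr[!is.na(hr)]
  if (length(hr) == 0L) stop("no compounds with a defined hit rate", call. = FALSE)
  q <- stats::quantile(hr, probs = c(0.5, 0.75), type = 7, names = FALSE)
  c(median = q[1], q3 = q[2])
}

#' Selection thresholds for the hit-rate cascade
#'
#' Configures [cascade_select()]. Stage A keeps compounds tested in strictly
#' more than `min_primary_assays` primary assays. Stage B keeps compounds with
#' HR strictly above a threshold that is either the third quartile of the
#' stage-A survivors' HR distribution (`stage1 = "q3"`) or a fixed percentage.
#' Stage C keeps compounds with HR strictly above the median of the stage-B
#' survivors (`stage2 = "median"`) or a fixed percentage. The data-derived
#' rules mirror the selection procedure; the fixed numbers mirror its realized
#' thresholds (1.0 and 1.8 on the public screening corpus).
#'
#' @param min_primary_assays stage-A count threshold (strict `>`; default 257).
#' @param stage1 `"q3"` or a fixed HR percentage.
#' @param stage2 `"median"` or a fixed HR percentage.
#' @return object of class `selection_config`.
#' @export
selection_config <- function(min_primary_assays = 257, stage1 = "q3",
                             stage2 = "median") {
  stopifnot(is.numeric(min_primary_assays), min_primary_assays >= 0)
  check_rule <- function(x, allowed) {
    if (is.character(x)) {
      if (!x %in% allowed) stop("stage rule must be '", allowed,
                                "' or a number", call. = FALSE)
    } else if (!(is.numeric(x) && length(x) == 1L && x >= 0)) {
      stop("stage threshold must be a non-negative number", call. = FALSE)
    }
    x
  }
  structure(list(min_primary_assays = min_primary_assays,
                 stage1 = check_rule(stage1, "q3"),
                 stage2 = check_rule(stage2, "median")),
            class = "selection_config")
}

#' Quantile-cascade selection of extensively tested, frequently active compounds
#'
#' Applies the three-stage cascade configured by [selection_config()]:
#' testing-frequency filter, then two successive hit-rate filters whose
#' thresholds may be derived from the surviving distribution (third quartile,
#' then median) or fixed. All comparisons are strict (`>`).
#'
#' @param stats data.frame from [compute_hit_rates()].
#' @param config a `selection_config`.
#' @return list with `selected` (character vector of compound ids surviving
#'   stage C) and `report` (per-stage threshold, rule mode, survivor count,
#'   survivor median HR).
#' @export
cascade_select <- function(stats, config = selection_config()) {
  stopifnot(is.data.frame(stats), nrow(stats) > 0,
            inherits(config, "selection_config"))
  stage_report <- function(name, mode, threshold, survivors) {
    list(stage = name, rule = mode, threshold = unname(threshold),
         n_survivors = nrow(survivors),
         median_hr = if (nrow(survivors)) unname(stats::median(survivors$hr_percent)) else NA_real_)
  }
  a <- stats[!is.na(stats$n_tested_primary) &
               stats$n_tested_primary > config$min_primary_assays, , drop = FALSE]
  if (nrow(a) == 0L) stop("stage A left no survivors", call. = FALSE)
  a <- a[!is.na(a$hr_percent), , drop = FALSE]
  if (nrow(a) == 0L) stop("stage A left no survivors with defined HR", call. = FALSE)

  if (identical(config$stage1, "q3")) {
    t1 <- hr_quantiles(a)[["q3"]]; mode1 <- "q3-of-distribution"
  } else {
    t1 <- config$stage1; mode1 <- "fixed"
  }
  b <- a[a$hr_percent > t1, , drop = FALSE]
  if (nrow(b) == 0L) stop("stage B left no survivors", call. = FALSE)

  if (identical(config$stage2, "median")) {
    t2 <- unname(stats::median(b$hr_percent)); mode2 <- "median-of-remaining"
  } else {
    t2 <- config$stage2; mode2 <- "fixed"
  }
  cc <- b[b$hr_percent > t2, , drop = FALSE]
  if (nrow(cc) == 0L) stop("stage C left no survivors", call. = FALSE)

  list(selected = cc$cid,
       report = list(
         stage_a = stage_report("A", "min-primary-assays",
                                config$min_primary_assays, a),
         stage_b = stage_report("B", mode1, t1, b),
         stage_c = stage_report("C", mode2, t2, cc)
       ))
}

#' Fraction of selected compounds also active in confirmatory assays
#'
#' Computes the proportion of the selected compounds that were active in at
#' least one confirmatory assay. Compounds never tested in a confirmatory
#' assay stay in the denominator, so the value is conservative.
#'
#' @param selected character vector of selected compound ids.
#' @param stats data.frame from [compute_hit_rates()] (or an
#'   `activity_matrix`, from which the stats are computed).
#' @return fraction in `[0, 1]`.
#' @export
confirmatory_consistency <- function(selected, stats) {
  if (length(selected) == 0L) stop("empty selection", call. = FALSE)
  if (inherits(stats, "activity_matrix")) stats <- compute_hit_rates(stats)
  idx <- match(selected, stats$cid)
  if (anyNA(idx)) {
    stop("selected compound(s) missing from stats: ",
         paste(utils::head(selected[is.na(idx)], 3), collapse = ", "),
         call. = FALSE)
  }
  mean(stats$n_active_confirmatory[idx] >= 1L)
}
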