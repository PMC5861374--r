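#' Series-level activity parameters
#'
#' Three parameters characterize an analog series against an assay panel:
#'
#' * **Cumulative series hit rate** — unique assays in which one or more
#'   members were active, divided by the union of unique assays in which the
#'   members were tested (percent). The denominator is the union of tested
#'   assays; the intersection is separately captured as the shared-assay set.
#' * **Assay overlap** — shared assays (tested by every member) relative to
#'   the union of tested assays (percent).
#' * **Inconsistent activity** — proportion of shared assays in which some
#'   members were active and others inactive (percent). A series without
#'   shared assays gets 0 with a note, so that ranking stays total.
#'
#' `cumulative_hit_rate()`, `assay_overlap()` and `inconsistent_activity()`
#' compute one parameter for one member set; [series_metrics()] computes all
#' three (plus the underlying assay counts) for every series of a set.
#'
#' @param cids character vector of member compound ids (at least 2).
#' @param matrix an `activity_matrix`.
#' @param assay_type assay scope: `"primary"` (default), `"confirmatory"`, or
#'   `"all"`.
#' @return a percentage in `[0, 100]`.
#' @name series-parameters
NULL

member_sets <- function(cids, matrix, assay_type) {
  stopifnot(inherits(matrix, "activity_matrix"), length(cids) >= 1L)
  o <- matrix$outcomes[matrix$outcomes$cid %in% cids, , drop = FALSE]
  if (assay_type != "all") {
    keep <- matrix$assays$assay_id[matrix$assays$assay_type == assay_type]
    o <- o[o$assay_id %in% keep, , drop = FALSE]
  }
  tested <- split(o$assay_id, factor(o$cid, levels = cids))
  active <- split(o$assay_id[o$outcome == "active"],
                  factor(o$cid[o$outcome == "active"], levels = cids))
  list(tested = tested, active = active)
}

#' @rdname series-parameters
#' @export
cumulative_hit_rate <- function(cids, matrix, assay_type = "primary") {
  s <- member_sets(cids, matrix, assay_type)
  u <- unique(unlist(s$tested, use.names = FALSE))
  if (length(u) == 0L) {
    stop("series members tested in no assay (zero denominator)", call. = FALSE)
  }
  a <- unique(unlist(s$active, use.names = FALSE))
  100 * length(a) / length(u)
}

#' @rdname series-parameters
#' @export
assay_overlap <- function(cids, matrix, assay_type = "primary") {
  s <- member_sets(cids, matrix, assay_type)
  u <- unique(unlist(s$tested, use.names = FALSE))
  if (length(u) == 0L) {
    stop("series members tested in no assay (zero union)", call. = FALSE)
  }
  shared <- Reduce(intersect, s$tested)
  100 * length(shared) / length(u)
}

#' @rdname series-parameters
#' @export
inconsistent_activity <- function(cids, matrix, assay_type = "primary") {
  s <- member_sets(cids, matrix, assay_type)
  shared <- Reduce(intersect, s$tested)
  if (length(shared) == 0L) return(0)
  active_any <- shared %in% unique(unlist(s$active, use.names = FALSE))
  # inactive by some member: member tested in the shared assay without being
  # active there; shared assays are tested by every member, so a member is
  # inactive there iff the assay is missing from its active set
  inactive_any <- vapply(shared, function(a) {
    any(vapply(seq_along(s$tested), function(i) !a %in% s$active[[i]],
               logical(1)))
  }, logical(1))
  100 * sum(active_any & inactive_any) / length(shared)
}

#' Compute all series parameters for a series set
#'
#' @param series_set an `analog_series_set` from [build_series()].
#' @param matrix an `activity_matrix`.
#' @param assay_type assay scope (see [series-parameters]); default
#'   `"primary"`, matching the scope over which compound hit rates are
#'   defined.
#' @return data.frame with one row per series: `as_id`, `n_members`,
#'   `cumulative_hr_percent`, `assay_overlap_percent`,
#'   `inconsistent_activity_percent`, `n_union_assays`, `n_shared_assays`,
#'   `n_active_union_assays`.
#' @export
series_metrics <- function(series_set, matrix, assay_type = "primary") {
  stopifnot(inherits(series_set, "analog_series_set"))
  by_series <- split(series_set$members$cid, series_set$members$as_id)
  ids <- series_set$series$as_id
  rows <- lapply(ids, function(id) {
    cids <- unique(by_series[[as.character(id)]])
    s <- member_sets(cids, matrix, assay_type)
    if (any(lengths(s$tested) == 0L)) {
      stop("series ", id, " has member(s) tested in no ", assay_type,
           " assay", call. = FALSE)
    }
    u <- unique(unlist(s$tested, use.names = FALSE))
    a <- unique(unlist(s$active, use.names = FALSE))
    shared <- Reduce(intersect, s$tested)
    n_inc <- if (length(shared) == 0L) 0L else {
      active_any <- shared %in% a
      inactive_any <- vapply(shared, function(aa) {
        any(vapply(seq_along(s$tested), function(i) !aa %in% s$active[[i]],
                   logical(1)))
      }, logical(1))
      sum(active_any & inactive_any)
    }
    data.frame(
      as_id = id, n_members = length(cids),
      cumulative_hr_percent = 100 * length(a) / length(u),
      assay_overlap_percent = 100 * length(shared) / length(u),
      inconsistent_activity_percent =
        if (length(shared) == 0L) 0 else 100 * n_inc / length(shared),
      n_union_assays = length(u), n_shared_assays = length(shared),
      n_active_union_assays = length(a))
  })
  do.call(rbind, rows)
}

#' Rank fusion of series parameters
#'
#' Ranks series separately by the three parameters — cumulative hit rate
#' descending, assay overlap descending, inconsistent activity ascending
#' (best = 1, ties get the average rank within the tied block) — sums the
#' three ranks, and assigns the consensus rank by ordering on the smallest
#' rank sum, ties broken by `as_id`. Consensus ranks are a permutation of
#' `1..N`.
#'
#' @param metrics data.frame from [series_metrics()] (any data.frame with
#'   `as_id` and the three `_percent` columns works).
#' @return the input with columns `rank_hr`, `rank_overlap`,
#'   `rank_inconsistency`, `rank_sum`, `consensus_rank` appended, in the
#'   input's row order.
#' @export
rank_series <- function(metrics) {
  stopifnot(is.data.frame(metrics))
  if (nrow(metrics) == 0L) stop("no series to rank", call. = FALSE)
  need <- c("as_id", "cumulative_hr_percent", "assay_overlap_percent",
            "inconsistent_activity_percent")
  if (!all(need %in% names(metrics))) {
    stop("metrics must contain: ", paste(need, collapse = ", "), call. = FALSE)
  }
  out <- metrics
  out$rank_hr <- rank(-out$cumulative_hr_percent, ties.method = "average")
  out$rank_overlap <- rank(-out$assay_overlap_percent, ties.method = "average")
  out$rank_inconsistency <- rank(out$inconsistent_activity_percent,
                                 ties.method = "average")
  out$rank_sum <- out$rank_hr + out$rank_overlap + out$rank_inconsistency
  ord <- order(out$rank_sum, out$as_id)
  out$consensus_rank[ord] <- seq_len(nrow(out))
  out
}

#' Write a series-metrics table
#'
#' Tab-separated: `as_id`, `AS_HR`, `Assay_OV`, `Inconsistent_activity`,
#' `rank_sum`, `consensus_rank`; percentages with two decimals.
#'
#' @param ranked data.frame from [rank_series()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metrics_table <- function(ranked, path) {
  stopifnot(all(c("as_id", "rank_sum", "consensus_rank") %in% names(ranked)))
  rows <- paste(ranked$as_id,
                sprintf("%.2f", ranked$cumulative_hr_percent),
                sprintf("%.2f", ranked$assay_overlap_percent),
                sprintf("%.2f", ranked$inconsistent_activity_percent),
                ranked$rank_sum, ranked$consensus_rank, sep = "\t")
  writeLines(c("as_id\tAS_HR\tAssay_OV\tInconsistent_activity\trank_sum\tconsensus_rank",
               rows), path, useBytes = TRUE)
  invisible(path)
}
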