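test_that("a minimal deposition has the expected shape", {
  m <- mk_matrix(tested = list(A = c("1", "2"), B = c("1", "2")),
                 active = list(A = "1", B = "1"))
  bs <- structure(list(
    series = data.frame(as_id = 1L, core_smiles = "*c1ccccc1", n_members = 2L),
    members = data.frame(as_id = 1L, cid = c("A", "B"),
                         substituent_smiles = c("*C", "*CC"))),
    class = "analog_series_set")
  ranked <- rank_series(series_metrics(bs, m))
  cmp <- data.frame(cid = c("A", "B"),
                    smiles = c("Cc1ccccc1", "CCc1ccccc1"))
  flags <- data.frame(cid = c("A", "B"), flagged = c(FALSE, TRUE),
                      matched_ids = c("", "x"))
  dir <- tempfile()
  write_deposition(bs, ranked, cmp, m, flags, dir)
  as_lines <- readLines(file.path(dir, "AS.txt"))
  sup_lines <- readLines(file.path(dir, "AS_SupportingInformation.txt"))
  expect_length(as_lines, 2L)       # header + one series
  expect_length(sup_lines, 3L)      # header + one row per membership
  expect_match(as_lines[2], "^1\t1\t\\*c1ccccc1\t50\\.00\t100\\.00\t0\\.00\tA,B\t")
  expect_match(sup_lines[3], "\tyes$")   # flagged member
})

test_that("a compound in two series yields one support row per membership", {
  d <- make_deposition(5)
  dep <- read_deposition(d$as_path, d$sup_path)
  multi <- names(which(table(unique(dep$support[c("cid", "as_id")])$cid) >= 2))
  expect_gt(length(multi), 0L)
  cid <- multi[1]
  in_series <- vapply(seq_len(nrow(dep$series)),
                      function(i) cid %in% dep$series$cids[[i]], logical(1))
  expect_equal(sum(dep$support$cid == cid), sum(in_series))
})

test_that("write then read is the identity on all fields", {
  d <- make_deposition(6, n_series = 5L)
  dep <- read_deposition(d$as_path, d$sup_path)
  expect_equal(nrow(dep$series), nrow(d$bs$series))
  ord <- match(dep$series$as_id, d$ranked$as_id)
  expect_equal(dep$series$rank, d$ranked$consensus_rank[ord])
  expect_equal(dep$series$as_hr,
               round(d$ranked$cumulative_hr_percent[ord], 2))
  expect_equal(dep$series$assay_ov,
               round(d$ranked$assay_overlap_percent[ord], 2))
  expect_equal(dep$series$inconsistent,
               round(d$ranked$inconsistent_activity_percent[ord], 2))
  core_ord <- match(dep$series$as_id, d$bs$series$as_id)
  expect_equal(dep$series$core_smiles, d$bs$series$core_smiles[core_ord])
  # membership lists agree with the extracted series
  for (i in seq_len(nrow(dep$series))) {
    want <- sort(d$bs$members$cid[d$bs$members$as_id == dep$series$as_id[i]])
    expect_equal(sort(dep$series$cids[[i]]), want)
    expect_length(dep$series$member_smiles[[i]],
                  length(dep$series$cids[[i]]))
  }
  # support hit rates equal the recomputed compound statistics
  stats <- compute_hit_rates(d$synth$sim$matrix)
  idx <- match(dep$support$cid, stats$cid)
  expect_equal(dep$support$n_primary, stats$n_tested_primary[idx])
  expect_equal(dep$support$n_active_primary, stats$n_active_primary[idx])
  expect_equal(dep$support$hit_rate, round(stats$hr_percent[idx], 2))
})

test_that("reader rejects malformed and inconsistent files", {
  d <- make_deposition(7)
  # header mismatch
  lines <- readLines(d$as_path)
  bad <- tempfile()
  writeLines(c(sub("AS_ID", "SERIES", lines[1]), lines[-1]), bad)
  expect_error(read_deposition(bad, d$sup_path), "header mismatch")
  # truncated data line
  bad2 <- tempfile()
  writeLines(c(lines[1], substr(lines[2], 1, 12)), bad2)
  expect_error(read_deposition(bad2, d$sup_path), "line 2")
  # missing membership row
  sup <- readLines(d$sup_path)
  bad3 <- tempfile()
  writeLines(sup[-2], bad3)
  expect_error(read_deposition(d$as_path, bad3), "support row missing")
})

test_that("reader tolerates CRLF, comma spaces, and the 9-column version 1", {
  d <- make_deposition(8)
  as_crlf <- tempfile()
  writeBin(charToRaw(paste0(paste(readLines(d$as_path), collapse = "\r\n"),
                            "\r\n")), as_crlf)
  sup_lines <- readLines(d$sup_path)
  sup9 <- tempfile()
  drop_last <- function(x) sub("\t[^\t]*$", "", x)
  writeLines(vapply(sup_lines, drop_last, character(1)), sup9)
  dep <- read_deposition(as_crlf, sup9)
  expect_equal(dep$version, 1L)
  expect_true(all(is.na(dep$support$interference)))
})

test_that("validator summarizes and detects internal inconsistencies", {
  d <- make_deposition(9, n_series = 5L)
  dep <- read_deposition(d$as_path, d$sup_path)
  rep <- validate_deposition(dep)
  expect_equal(rep$summary$n_violations, 0L)
  expect_equal(rep$summary$n_series, nrow(d$bs$series))
  expect_equal(rep$summary$n_memberships, nrow(d$bs$members))
  expect_equal(rep$summary$n_unique_compounds,
               length(unique(d$bs$members$cid)))
  tab <- table(unique(d$bs$members[c("cid", "as_id")])$cid)
  expect_equal(rep$summary$n_multi_series_compounds, sum(tab >= 2))
  expect_equal(rep$summary$members_min, min(d$bs$series$n_members))
  expect_equal(rep$summary$members_max, max(d$bs$series$n_members))
  expect_equal(rep$summary$as_hr_median,
               stats::median(round(d$ranked$cumulative_hr_percent, 2)))
  free <- interference_free_series(d$bs, d$flags)
  expect_equal(rep$summary$n_interference_free_series, length(free))
  # validator totals are invariant to support row order
  dep_shuffled <- dep
  set.seed(2)
  dep_shuffled$support <- dep$support[sample(nrow(dep$support)), ]
  expect_equal(validate_deposition(dep_shuffled)$summary, rep$summary)
  # corrupt one hit rate beyond tolerance
  dep_bad <- dep
  dep_bad$support$hit_rate[1] <- dep_bad$support$hit_rate[1] + 1
  rep_bad <- validate_deposition(dep_bad)
  expect_true("hit_rate_mismatch" %in% rep_bad$violations$kind)
})

test_that("a header-only deposition validates to zero series with a warning", {
  as_p <- tempfile(); sup_p <- tempfile()
  writeLines(paste(analogseries:::AS_HEADER, collapse = "\t"), as_p)
  writeLines(paste(analogseries:::SUPPORT_HEADER, collapse = "\t"), sup_p)
  dep <- read_deposition(as_p, sup_p)
  expect_warning(rep <- validate_deposition(dep), "zero series")
  expect_equal(rep$summary$n_series, 0L)
})
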