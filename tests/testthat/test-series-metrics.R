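# Hand-worked two-member panel: tested(A)={1,2,3}, tested(B)={2,3,4},
# active(A)={2}, active(B)={2,3}. Union {1,2,3,4}, active union {2,3},
# shared {2,3}; assay 2 all-active, assay 3 mixed (A inactive, B active).
worked_matrix <- function() {
  mk_matrix(tested = list(A = c("1", "2", "3"), B = c("2", "3", "4")),
            active = list(A = "2", B = c("2", "3")))
}

test_that("the three series parameters reproduce hand set arithmetic", {
  m <- worked_matrix()
  expect_equal(cumulative_hit_rate(c("A", "B"), m), 50.0)
  expect_equal(assay_overlap(c("A", "B"), m), 50.0)
  expect_equal(inconsistent_activity(c("A", "B"), m), 50.0)
})

test_that("parameter edge cases behave per definition", {
  none <- mk_matrix(tested = list(A = c("1", "2"), B = c("1", "2")),
                    active = list(A = character(0), B = character(0)))
  expect_equal(cumulative_hit_rate(c("A", "B"), none), 0.0)
  expect_equal(inconsistent_activity(c("A", "B"), none), 0.0)

  all_active <- mk_matrix(tested = list(A = c("1", "2"), B = c("2", "3")),
                          active = list(A = c("1", "2"), B = c("2", "3")))
  expect_equal(cumulative_hit_rate(c("A", "B"), all_active), 100.0)

  same <- mk_matrix(tested = list(A = c("1", "2"), B = c("1", "2")),
                    active = list(A = "1", B = "1"))
  expect_equal(assay_overlap(c("A", "B"), same), 100.0)
  expect_equal(inconsistent_activity(c("A", "B"), same), 0.0)

  disjoint <- mk_matrix(tested = list(A = c("1", "2"), B = c("3", "4")),
                        active = list(A = "1", B = character(0)))
  expect_equal(assay_overlap(c("A", "B"), disjoint), 50.0 * 0)
  # no shared assays: inconsistency defined as 0, not an error
  expect_equal(inconsistent_activity(c("A", "B"), disjoint), 0.0)

  one_shared <- mk_matrix(tested = list(A = "1", B = "1"),
                          active = list(A = "1", B = character(0)))
  expect_equal(inconsistent_activity(c("A", "B"), one_shared), 100.0)

  empty <- mk_matrix(tested = list(A = "1", Z = "1"),
                     active = list(A = "1", Z = character(0)))
  expect_error(cumulative_hit_rate(c("B", "C"), empty), "zero denominator")
})

test_that("series_metrics aggregates counts consistently with the parameters", {
  s <- small_synthetic(12, n_series = 3L, decoys = 2L)
  bs <- build_series(s$lib$compounds,
                     fragmentation_policy(bond_rule = "all_acyclic"))
  met <- series_metrics(bs, s$sim$matrix)
  by_series <- split(bs$members$cid, bs$members$as_id)
  for (i in seq_len(nrow(met))) {
    cids <- unique(by_series[[as.character(met$as_id[i])]])
    expect_equal(met$cumulative_hr_percent[i],
                 cumulative_hit_rate(cids, s$sim$matrix))
    expect_equal(met$assay_overlap_percent[i],
                 assay_overlap(cids, s$sim$matrix))
    expect_equal(met$inconsistent_activity_percent[i],
                 inconsistent_activity(cids, s$sim$matrix))
    expect_lte(met$n_shared_assays[i], met$n_union_assays[i])
    expect_lte(met$n_active_union_assays[i], met$n_union_assays[i])
    # every member's own activity is a lower bound on the cumulative rate
    for (cid in cids) {
      lb <- 100 * length(active_assays(s$sim$matrix, cid, "primary")) /
        met$n_union_assays[i]
      expect_gte(met$cumulative_hr_percent[i], lb - 1e-9)
    }
  }
})

test_that("adding an assay tested and active by all members moves metrics monotonically", {
  base <- list(tested = list(A = c("1", "2", "3"), B = c("2", "3", "4")),
               active = list(A = "2", B = c("2", "4")))
  m0 <- mk_matrix(base$tested, base$active)
  m1 <- mk_matrix(lapply(base$tested, c, "9"), lapply(base$active, c, "9"))
  cids <- c("A", "B")
  expect_gte(cumulative_hit_rate(cids, m1), cumulative_hit_rate(cids, m0))
  expect_gte(assay_overlap(cids, m1), assay_overlap(cids, m0))
  expect_lte(inconsistent_activity(cids, m1), inconsistent_activity(cids, m0))
})

test_that("rank fusion follows the stated conventions on a hand-ranked example", {
  met <- data.frame(as_id = 1:3,
                    cumulative_hr_percent = c(10, 20, 10),
                    assay_overlap_percent = c(80, 60, 80),
                    inconsistent_activity_percent = c(5, 5, 50))
  r <- rank_series(met)
  expect_equal(r$rank_hr, c(2.5, 1, 2.5))
  expect_equal(r$rank_overlap, c(1.5, 3, 1.5))
  expect_equal(r$rank_inconsistency, c(1.5, 1.5, 3))
  expect_equal(r$rank_sum, c(5.5, 5.5, 7))
  # tied rank sums resolve by series id
  expect_equal(r$consensus_rank, c(1L, 2L, 3L))

  single <- rank_series(data.frame(as_id = 7, cumulative_hr_percent = 1,
                                   assay_overlap_percent = 1,
                                   inconsistent_activity_percent = 1))
  expect_equal(single$rank_sum, 3)
  expect_equal(single$consensus_rank, 1L)
  expect_error(rank_series(met[0, ]), "no series")
})

test_that("consensus ranks are a permutation and stable under relabeling", {
  set.seed(14)
  for (rep in 1:10) {
    n <- sample(2:40, 1)
    met <- data.frame(as_id = seq_len(n),
                      cumulative_hr_percent = stats::runif(n, 0, 40),
                      assay_overlap_percent = stats::runif(n, 0, 100),
                      inconsistent_activity_percent =
                        sample(c(0, 5, 5, 20), n, replace = TRUE))
    r <- rank_series(met)
    expect_setequal(r$consensus_rank, seq_len(n))
    # relabeling ids with an order-preserving map permutes output consistently
    met2 <- met[sample(n), ]
    r2 <- rank_series(met2)
    expect_equal(r2$consensus_rank[match(met$as_id, met2$as_id)],
                 r$consensus_rank)
  }
  # duplicating a series' metric vector lands it adjacent in consensus order
  met <- data.frame(as_id = 1:4,
                    cumulative_hr_percent = c(30, 10, 30, 5),
                    assay_overlap_percent = c(90, 50, 90, 20),
                    inconsistent_activity_percent = c(2, 8, 2, 30))
  r <- rank_series(met)
  dup <- sort(r$consensus_rank[r$as_id %in% c(1, 3)])
  expect_equal(diff(dup), 1L)
})

test_that("metrics on planted member sets equal the generator's realized values", {
  s <- small_synthetic(23, n_series = 5L, decoys = 0L)
  for (ser in s$sim$truth$series) {
    expect_equal(cumulative_hit_rate(ser$cids, s$sim$matrix),
                 ser$realized_hr_percent)
    expect_equal(assay_overlap(ser$cids, s$sim$matrix),
                 ser$realized_overlap_percent)
    expect_equal(inconsistent_activity(ser$cids, s$sim$matrix),
                 ser$realized_inconsistency_percent)
  }
})
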