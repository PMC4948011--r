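test_that("filter thresholds are inclusive at the printed boundary values", {
  boundary <- anchor_hits(query_id = "b", target_chrom = "B01",
                          target_start = 0, target_end = 200,
                          identity = 0.80, coverage = 0.75,
                          aligned_length = 200, match_bp = 160,
                          mismatch_bp = 40)
  expect_equal(nrow(filter_hits(boundary, policy_presets("tocds_peg"))), 1)

  # marker-on-own-genome policy: 98% identity / 200 matching / <=50 mismatching;
  # identity below threshold is rejected whatever the other fields say
  h <- anchor_hits(query_id = "m", target_chrom = "B01",
                   target_start = 0, target_end = 260, identity = 0.97,
                   coverage = 0.99, aligned_length = 260,
                   match_bp = 250, mismatch_bp = 10)
  expect_equal(nrow(filter_hits(h, policy_presets("pem_peg"))), 0)
})

test_that("filtering an empty table is legal and filtering is idempotent", {
  expect_equal(nrow(filter_hits(anchor_hits(), policy_presets("egm_tog"))), 0)
  hits <- random_hits(100, seed = 7)
  for (preset in names(policy_presets())) {
    p <- policy_presets(preset)
    once <- filter_hits(hits, p)
    expect_identical(filter_hits(once, p), once)
  }
})

test_that("filter output equals the per-record predicate oracle", {
  hits <- random_hits(200, seed = 11)
  for (preset in names(policy_presets())) {
    p <- policy_presets(preset)
    expect_identical(as.data.frame(filter_hits(hits, p)),
                     as.data.frame(oracle_filter(hits, p)),
                     label = preset)
  }
})

test_that("best hit ranks match bp before identity and coverage", {
  two <- anchor_hits(query_id = "q", target_chrom = c("B01", "B02"),
                     target_start = c(0, 0), target_end = c(400, 400),
                     identity = c(0.85, 0.99), coverage = c(0.8, 0.99),
                     aligned_length = 400, match_bp = c(300, 250),
                     mismatch_bp = c(100, 150))
  expect_equal(select_best_hit(two)$match_bp, 300)

  single <- two[1, ]
  expect_identical(as.data.frame(select_best_hit(single)),
                   as.data.frame(single))
  expect_error(select_best_hit(anchor_hits()), "at least one hit")
})

test_that("fully tied hits break deterministically to the lowest chromosome", {
  tied <- anchor_hits(query_id = "q", target_chrom = c("P02", "P01"),
                      target_start = 100, target_end = 500,
                      identity = 0.9, coverage = 0.9,
                      aligned_length = 400, match_bp = 360, mismatch_bp = 40)
  expect_equal(select_best_hit(tied)$target_chrom, "P01")
})

test_that("each query appears exactly once after table-wide deduplication", {
  hits <- random_hits(300, seed = 3)
  hits$query_id <- sample(sprintf("q%02d", 1:40), nrow(hits), replace = TRUE)
  uniq <- select_best_hits(hits)
  expect_equal(sort(unique(hits$query_id)), sort(uniq$query_id))
  expect_equal(anyDuplicated(uniq$query_id), 0L)
})

test_that("co-location links intervals whose gap is within the tolerance", {
  h <- anchor_hits(query_id = c("A", "B"), target_chrom = "B01",
                   target_start = c(1000, 1320), target_end = c(1300, 1600),
                   identity = 0.9, coverage = 0.9, aligned_length = 300,
                   match_bp = 270, mismatch_bp = 30)
  g <- find_colocated_queries(h, tolerance_bp = 25)  # gap 20 <= 25
  expect_equal(nrow(g), 1)
  expect_equal(g$member_query_ids[[1]], c("A", "B"))

  h$target_start[2] <- 1330  # gap 30 > 25
  expect_equal(nrow(find_colocated_queries(h, tolerance_bp = 25)), 0)
  expect_error(find_colocated_queries(h, tolerance_bp = -1), "non-negative")
})

test_that("co-location groups equal the O(n^2) union-find oracle", {
  for (seed in 1:6) {
    hits <- random_hits(120, seed, n_chrom = 2, chrom_len = 2e4)
    for (tol in c(0, 25, 50)) {
      got <- find_colocated_queries(hits, tolerance_bp = tol)
      got_sets <- lapply(got$member_query_ids, sort)
      want_sets <- oracle_colocate(hits, tol)
      key <- function(x) paste(vapply(x, paste, "", collapse = ","))
      expect_setequal(key(got_sets), key(want_sets))
    }
  }
})

test_that("co-location grouping is invariant to input order and counts reconcile", {
  hits <- random_hits(150, seed = 21, n_chrom = 2, chrom_len = 3e4)
  g1 <- find_colocated_queries(hits, 25)
  g2 <- find_colocated_queries(hits[sample(nrow(hits)), ], 25)
  key <- function(g) sort(vapply(g$member_query_ids, paste, "", collapse = ","))
  expect_equal(key(g1), key(g2))
  grouped <- unlist(g1$member_query_ids)
  expect_equal(length(grouped) + (nrow(hits) - length(grouped)), nrow(hits))
  expect_equal(sum(g1$n_members), length(grouped))
})
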