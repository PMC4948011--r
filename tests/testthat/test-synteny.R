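colinear_hits <- function(n = 10, q0 = 0, t0 = 0, spacing = 1e5,
                          reversed = FALSE, qc = "A01", tc = "B01") {
  q <- q0 + seq_len(n) * spacing
  t <- t0 + seq_len(n) * spacing
  if (reversed) q <- rev(q)
  anchor_hits(query_id = sprintf("%s_%s_%d", qc, tc, seq_len(n)),
              query_chrom = qc, query_start = q, query_end = q + 1000,
              target_chrom = tc, target_start = t, target_end = t + 1000,
              strand = if (reversed) "-" else "+", identity = 0.9,
              coverage = 0.9, aligned_length = 1000, match_bp = 900,
              mismatch_bp = 100)
}

test_that("chromosome orthology follows the anchor plurality", {
  h <- rbind(colinear_hits(10, qc = "P01", tc = "T01"),
             colinear_hits(2, qc = "P01", tc = "T08"),
             colinear_hits(5, qc = "P02", tc = "T08"))
  orth <- assign_chromosome_orthology(h)
  expect_equal(unname(orth$map["T01"]), "P01")
  expect_equal(unname(orth$map["T08"]), "P02")
  expect_equal(orth$same_chromosome_fraction, 15 / 17)

  empty <- assign_chromosome_orthology(anchor_hits())
  expect_equal(length(empty$map), 0)
})

test_that("orthology is recovered exactly from a simulated pair with noise", {
  cfg <- sim_config(seed = 5)
  sim <- simulate_genome_pair(cfg)
  hits <- select_best_hits(filter_hits(sim$hits, policy_presets("tocds_peg")))
  orth <- assign_chromosome_orthology(hits)
  expect_equal(unname(orth$map[sprintf("B%02d", 1:12)]), sprintf("A%02d", 1:12))
})

test_that("colinear anchors chain into one block with the right orientation", {
  fwd <- chain_anchors(colinear_hits(10))
  expect_equal(nrow(fwd), 1)
  expect_equal(fwd$orientation, "+")
  expect_equal(fwd$n_anchors, 10L)

  rev <- chain_anchors(colinear_hits(10, reversed = TRUE))
  expect_equal(nrow(rev), 1)
  expect_equal(rev$orientation, "-")
})

test_that("an oversized gap splits the chain into the planted runs", {
  params <- chain_params(max_gap_bp = 1e6, max_gap_query = 1e6)
  h <- rbind(colinear_hits(10),
             colinear_hits(10, q0 = 3.1e6, t0 = 3.1e6))  # 2x max_gap apart
  blocks <- chain_anchors(h, params)
  expect_equal(nrow(blocks), 2)
  expect_equal(sort(vapply(blocks$anchor_idx, length, 1L)), c(10L, 10L))
  members <- lapply(blocks$anchor_idx, function(i) sort(h$query_id[i]))
  expect_setequal(vapply(members, paste, "", collapse = ","),
                  c(paste(sort(h$query_id[1:10]), collapse = ","),
                    paste(sort(h$query_id[11:20]), collapse = ",")))
})

test_that("every anchor lands in exactly one block or the dropped set", {
  for (seed in c(1, 9)) {
    sim <- simulate_genome_pair(sim_config(seed = seed))
    hits <- select_best_hits(filter_hits(sim$hits, policy_presets("tocds_peg")))
    blocks <- chain_anchors(hits)
    in_blocks <- unlist(blocks$anchor_idx)
    expect_equal(anyDuplicated(in_blocks), 0L)
    expect_setequal(c(in_blocks, attr(blocks, "dropped_idx")),
                    seq_len(nrow(hits)))
    # block membership respects the minimum anchor count
    expect_true(all(blocks$n_anchors >= 3))
    # anchors of a block share its chromosome pair and monotone query order
    for (i in seq_len(nrow(blocks))) {
      idx <- blocks$anchor_idx[[i]]
      expect_true(all(hits$query_chrom[idx] == blocks$query_chrom[i]))
      ord <- order((hits$target_start + hits$target_end)[idx])
      qmid <- (hits$query_start + hits$query_end)[idx][ord] / 2
      if (blocks$orientation[i] == "+") expect_true(all(diff(qmid) >= 0))
      else expect_true(all(diff(qmid) <= 0))
    }
    break
  }
})

test_that("a large opposite-orientation block is called as an inversion", {
  hits <- regular_inversion_hits(inv_lo = 10e6, inv_hi = 11.2e6)
  params <- chain_params()
  calls <- call_rearrangements(chain_anchors(hits, params),
                               assign_chromosome_orthology(hits), params,
                               hits = hits)
  expect_equal(calls$kind, "inversion")
  expect_equal(calls$orientation, "-")
  expect_gt(calls$span_bp, 1e6)
})

test_that("the minimum-span rule gates sub-threshold inversions", {
  hits <- regular_inversion_hits(inv_lo = 10e6, inv_hi = 10.4e6)
  orth <- assign_chromosome_orthology(hits)
  strict <- chain_params(min_span_bp = 5e5)
  relaxed <- chain_params(min_span_bp = 3e5)
  expect_equal(nrow(call_rearrangements(chain_anchors(hits, strict), orth,
                                        strict, hits = hits)), 0)
  relaxed_calls <- call_rearrangements(chain_anchors(hits, relaxed), orth,
                                       relaxed, hits = hits)
  expect_equal(relaxed_calls$kind, "inversion")
})

test_that("decreasing the span threshold never removes a call", {
  sim <- simulate_genome_pair(sim_config(seed = 13))
  hits <- select_best_hits(filter_hits(sim$hits, policy_presets("tocds_peg")))
  orth <- assign_chromosome_orthology(hits)
  spans <- c(2e6, 1e6, 5e5, 3e5)
  prev <- NULL
  for (ms in spans) {
    p <- chain_params(min_span_bp = ms)
    calls <- call_rearrangements(chain_anchors(hits, p), orth, p, hits = hits)
    key <- paste(calls$kind, calls$query_chrom, calls$target_chrom)
    if (!is.null(prev)) expect_true(all(prev %in% key))
    prev <- key
  }
})

test_that("planted inversions and translocations are all recovered without noise", {
  cfg <- sim_config(n_inversions = 5, n_translocations = 3,
                    n_transpositions = 0, n_duplications = 0,
                    noise = FALSE, seed = 17)
  res <- run_synteny_pipeline(simulate_genome_pair(cfg))
  expect_equal(res$score$recall, 1)
  expect_equal(res$score$precision, 1)
  expect_equal(sum(res$calls$kind == "inversion"), 5)
  expect_equal(sum(res$calls$kind == "translocation"), 6)  # two arms per event
})

test_that("calls are kind-stable under swapping query and target genomes", {
  cfg <- sim_config(n_inversions = 2, n_translocations = 1,
                    n_transpositions = 0, n_duplications = 0,
                    noise = FALSE, seed = 23)
  sim <- simulate_genome_pair(cfg)
  fwd <- run_synteny_pipeline(sim)
  swapped <- sim$hits
  names(swapped)[match(c("query_chrom", "query_start", "query_end",
                         "target_chrom", "target_start", "target_end"),
                       names(swapped))] <-
    c("target_chrom", "target_start", "target_end",
      "query_chrom", "query_start", "query_end")
  swapped <- validate_anchor_hits(swapped)
  rev <- run_synteny_pipeline(list(hits = swapped, truth = sim$truth))
  expect_equal(sort(table(fwd$calls$kind)), sort(table(rev$calls$kind)))
})

test_that("dot-plot points are anchor midpoints with called anchors highlighted", {
  h <- colinear_hits(3)
  dp <- dotplot(h)
  expect_equal(nrow(dp$points), 3)
  expect_equal(dp$points$x, (h$target_start + h$target_end) / 2)
  expect_equal(dp$points$y, (h$query_start + h$query_end) / 2)

  hits <- regular_inversion_hits(inv_lo = 10e6, inv_hi = 11.2e6)
  params <- chain_params()
  blocks <- chain_anchors(hits, params)
  calls <- call_rearrangements(blocks, assign_chromosome_orthology(hits),
                               params, hits = hits)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  dp2 <- dotplot(hits, blocks = blocks, calls = calls, tsv = tsv)
  marked <- dp2$points[!is.na(dp2$points$highlight), ]
  expect_true(all(marked$highlight == "inversion"))
  # highlighted points trace the inverted segment: negative local slope
  ord <- order(marked$x)
  expect_true(all(diff(marked$y[ord]) < 0))
  expect_true(file.exists(tsv))
  expect_equal(nrow(readr::read_tsv(tsv, show_col_types = FALSE)),
               nrow(dp2$points))
})
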