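# Independent brute-force oracles and fixture generators shared by the
# test files. The oracles deliberately re-derive each predicate from the
# rules, one record or one pair at a time, without touching the package's
# vectorized/interval-tree code paths.

# random anchor hit table spanning the filter thresholds, boundary values
# included
random_hits <- function(n, seed, n_chrom = 3, chrom_len = 1e6) {
  withr::with_seed(seed, {
    len <- round(runif(n, 50, 1500))
    start <- round(runif(n, 0, chrom_len - max(len)))
    ident <- sample(c(runif(n, 0.5, 1), 0.80, 0.98, 0.75), n)
    covg <- sample(c(runif(n, 0.1, 1), 0.75, 0.40), n)
    match <- pmin(len, round(ident * len) + sample(-5:5, n, replace = TRUE))
    match <- pmax(0, match)
    anchor_hits(
      query_id = sprintf("q%04d", seq_len(n)),
      query_chrom = sample(sprintf("A%02d", seq_len(n_chrom)), n, TRUE),
      query_start = start, query_end = start + len,
      target_chrom = sample(sprintf("B%02d", seq_len(n_chrom)), n, TRUE),
      target_start = start, target_end = start + len,
      strand = sample(c("+", "-"), n, TRUE),
      identity = ident, coverage = covg,
      aligned_length = len, match_bp = match, mismatch_bp = len - match
    )
  })
}

# per-record filter predicate, written directly from the threshold rules
# (record-at-a-time over plain vectors, independent of the package's
# vectorized path)
oracle_filter <- function(hits, policy) {
  ident <- hits$identity; covg <- hits$coverage
  alen <- hits$aligned_length; mb <- hits$match_bp; mm <- hits$mismatch_bp
  chk <- function(val, thr, cmp) {
    if (is.null(thr)) return(TRUE)
    if (is.na(val)) return(FALSE)
    cmp(val, thr)
  }
  keep <- vapply(seq_len(nrow(hits)), function(i) {
    chk(ident[i], policy$min_identity, `>=`) &&
      chk(covg[i], policy$min_coverage, `>=`) &&
      chk(alen[i], policy$min_aligned_length, `>=`) &&
      chk(mb[i], policy$min_match_bp, `>=`) &&
      chk(mm[i], policy$max_mismatch_bp, `<=`)
  }, logical(1))
  hits[keep, ]
}

# O(n^2) pairwise predicate + union-find colocation oracle; the pairwise
# gap predicate is evaluated for every (i, j) pair
oracle_colocate <- function(hits, tolerance_bp) {
  n <- nrow(hits)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  tc <- hits$target_chrom; ts <- hits$target_start; te <- hits$target_end
  if (n >= 2) {
    for (i in 1:(n - 1)) {
      j <- (i + 1):n
      gap <- pmax(ts[i], ts[j]) - pmin(te[i], te[j])
      linked <- j[tc[j] == tc[i] & gap <= tolerance_bp]
      for (jj in linked) {
        ri <- find(i); rj <- find(jj)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  comps <- split(hits$query_id, roots)
  comps <- comps[lengths(comps) >= 2]
  unname(lapply(comps, sort))
}

# physical QTL fixtures
mk_pqtl <- function(id, chrom, start, end, trait = "fruit_weight",
                    species = "speciesA", pve = 15) {
  tibble::tibble(qtl_id = id, trait = trait, species = species,
                 chrom = chrom, start_bp = start, end_bp = end,
                 peak_bp = (start + end) / 2, pve = pve)
}

random_pqtl <- function(n, species, seed, n_chrom = 4, chrom_len = 3e7) {
  traits <- unique(unlist(default_trait_groups()$groups))
  withr::with_seed(seed, {
    w <- runif(n, 2e5, 3e6)
    s <- runif(n, 0, chrom_len - max(w))
    mk_pqtl(sprintf("%s_%03d", species, seq_len(n)),
            sample(sprintf("B%02d", seq_len(n_chrom)), n, TRUE),
            s, s + w, trait = sample(traits, n, TRUE), species = species,
            pve = runif(n, 0, 30))
  })
}

# all-pairs orthologous-QTL oracle from the stated predicate
oracle_pairs <- function(qa, qb, traits, proximity_bp) {
  out <- list()
  for (i in seq_len(nrow(qa))) {
    for (j in seq_len(nrow(qb))) {
      if (qa$chrom[i] != qb$chrom[j]) next
      if (!traits_related(traits, qa$trait[i], qb$trait[j])) next
      gap <- max(qa$start_bp[i], qb$start_bp[j]) -
        min(qa$end_bp[i], qb$end_bp[j])
      if (gap > proximity_bp) next
      out[[length(out) + 1]] <- c(qa$qtl_id[i], qb$qtl_id[j])
    }
  }
  out
}

# connected components of the gap<=merge_gap interval graph (union-find)
oracle_clusters <- function(q, merge_gap_bp) {
  n <- nrow(q)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  if (n >= 2) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        if (q$chrom[i] != q$chrom[j]) next
        gap <- max(q$start_bp[i], q$start_bp[j]) -
          min(q$end_bp[i], q$end_bp[j])
        if (gap <= merge_gap_bp) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[ri] <- rj
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  comps <- split(q$qtl_id, roots)
  unname(lapply(comps, sort))
}

# regular colinear anchor scaffold with an optional planted inversion,
# used by the span-threshold and dot-plot tests
regular_inversion_hits <- function(chrom_len = 20e6, spacing = 5e4,
                                   inv_lo = 10e6, inv_hi = 10.4e6,
                                   anchor_len = 1000) {
  q <- seq(0, chrom_len - spacing, by = spacing)
  t <- q
  inv <- q >= inv_lo & q < inv_hi
  t[inv] <- inv_lo + inv_hi - (q[inv] + anchor_len)
  anchor_hits(
    query_id = sprintf("a%04d", seq_along(q)), query_chrom = "A01",
    query_start = q, query_end = q + anchor_len,
    target_chrom = "B01", target_start = t, target_end = t + anchor_len,
    strand = ifelse(inv, "-", "+"), identity = 0.95, coverage = 0.9,
    aligned_length = anchor_len, match_bp = anchor_len - 50, mismatch_bp = 50
  )
}

run_synteny_pipeline <- function(sim, params = chain_params()) {
  hits <- select_best_hits(filter_hits(sim$hits, policy_presets("tocds_peg")))
  orth <- assign_chromosome_orthology(hits)
  blocks <- chain_anchors(hits, params)
  calls <- call_rearrangements(blocks, orth, params, hits = hits)
  list(hits = hits, orthology = orth, blocks = blocks, calls = calls,
       score = score_rearrangement_calls(calls, sim$truth))
}

# small GMAP-style GFF3 content, n mRNA records, `drop_identity` of them
# missing the identity attribute
gmap_gff3_lines <- function(n = 1, drop_identity = integer()) {
  vapply(seq_len(n), function(i) {
    attrs <- sprintf(
      "ID=q%d.mrna1;Name=q%d;coverage=80.0;matches=%d;mismatches=50", i, i,
      900 + i)
    if (!i %in% drop_identity) attrs <- paste0(attrs, ";identity=95.0")
    sprintf("B01\tgmap\tmRNA\t%d\t%d\t.\t+\t.\t%s",
            1001 + (i - 1) * 2000, 2000 + (i - 1) * 2000, attrs)
  }, "")
}
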