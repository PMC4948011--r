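test_that("the major-QTL threshold is inclusive at PVE = 10", {
  q <- mk_pqtl(c("a", "b", "c"), "B01", 1e6, 2e6, pve = c(10.0, 9.9, 25))
  expect_equal(filter_major(q)$qtl_id, c("a", "c"))
  expect_equal(nrow(filter_major(q[0, ])), 0)
})

test_that("orthologous pairs require overlap-or-proximity and related traits", {
  traits <- default_trait_groups()
  a <- mk_pqtl("egA", "B01", 10e6, 12e6, trait = "fruit_length")
  b <- mk_pqtl("peB", "B01", 11.5e6, 14e6, trait = "fruit_length",
               species = "speciesB")
  expect_equal(nrow(find_orthologous_pairs(a, b, traits)), 1)

  unrelated <- mk_pqtl("peC", "B01", 11.5e6, 14e6, trait = "plant_height",
                       species = "speciesB")
  expect_equal(nrow(find_orthologous_pairs(a, unrelated, traits)), 0)

  # related but different trait names within one group still pair
  cousin <- mk_pqtl("peD", "B01", 13e6, 14e6, trait = "fruit_shape",
                    species = "speciesB")
  got <- find_orthologous_pairs(a, cousin, traits, proximity_bp = 1e6)
  expect_equal(got$gap_bp, 1e6)

  far <- mk_pqtl("peE", "B01", 13.1e6, 14e6, trait = "fruit_shape",
                 species = "speciesB")
  expect_equal(nrow(find_orthologous_pairs(a, far, traits,
                                           proximity_bp = 1e6)), 0)
})

test_that("QTL with traits missing from the equivalence table are skipped", {
  traits <- trait_equivalence(list(c("fruit_weight", "fruit_length")))
  a <- mk_pqtl(c("a1", "a2"), "B01", 1e6, 2e6,
               trait = c("fruit_weight", "mystery_trait"))
  b <- mk_pqtl("b1", "B01", 1.5e6, 2.5e6, trait = "fruit_length",
               species = "speciesB")
  expect_warning(pairs <- find_orthologous_pairs(a, b, traits), "skipped")
  expect_equal(nrow(pairs), 1)
  expect_equal(attr(pairs, "n_skipped_unknown_trait"), 1L)
})

test_that("pair detection equals the all-pairs predicate oracle", {
  traits <- default_trait_groups()
  for (seed in 1:10) {
    qa <- random_pqtl(50, "eg", seed)
    qb <- random_pqtl(50, "pe", seed + 100)
    got <- find_orthologous_pairs(qa, qb, traits, proximity_bp = 1e6)
    want <- oracle_pairs(qa, qb, traits, proximity_bp = 1e6)
    expect_setequal(paste(got$qtl_a, got$qtl_b),
                    vapply(want, paste, "", collapse = " "))
  }
})

test_that("increasing the proximity never removes a pair", {
  traits <- default_trait_groups()
  qa <- random_pqtl(40, "eg", 3)
  qb <- random_pqtl(40, "pe", 4)
  prev <- NULL
  for (prox in c(1e5, 5e5, 1e6, 5e6)) {
    got <- find_orthologous_pairs(qa, qb, traits, proximity_bp = prox)
    key <- paste(got$qtl_a, got$qtl_b)
    if (!is.null(prev)) expect_true(all(prev %in% key))
    prev <- key
  }
})

test_that("clusters are the connected components of the interval graph", {
  for (seed in 1:10) {
    q <- rbind(random_pqtl(30, "eg", seed), random_pqtl(30, "pe", seed + 200))
    got <- cluster_qtl(q, merge_gap_bp = 1e6, min_members = 1)
    members <- c(got$members_a, got$members_b)
    got_sets <- lapply(seq_len(nrow(got)), function(i)
      sort(c(got$members_a[[i]], got$members_b[[i]])))
    want_sets <- oracle_clusters(q, merge_gap_bp = 1e6)
    expect_setequal(vapply(got_sets, paste, "", collapse = ","),
                    vapply(want_sets, paste, "", collapse = ","))
    # cluster intervals are the hulls of their members
    for (i in seq_len(nrow(got))) {
      ids <- c(got$members_a[[i]], got$members_b[[i]])
      expect_equal(got$start_bp[i], min(q$start_bp[q$qtl_id %in% ids]))
      expect_equal(got$end_bp[i], max(q$end_bp[q$qtl_id %in% ids]))
    }
  }
})

test_that("two-species clusters are flagged orthologous, gaps split clusters", {
  q <- rbind(
    mk_pqtl(c("e1", "e2"), "B01", c(10e6, 10.5e6), c(11e6, 11.5e6)),
    mk_pqtl("p1", "B01", 10.8e6, 12e6, species = "speciesB"),
    mk_pqtl("e3", "B01", 20e6, 21e6)
  )
  cl <- cluster_qtl(q, merge_gap_bp = 1e6, min_members = 1)
  expect_equal(nrow(cl), 2)
  expect_equal(cl$orthologous, c(TRUE, FALSE))
  expect_equal(sum(cl$n_members), nrow(q))
  expect_equal(cl$members_a[[1]], c("e1", "e2"))
  expect_equal(cl$members_b[[1]], "p1")
})

test_that("every emitted pair co-clusters and member counts reconcile", {
  traits <- default_trait_groups()
  qa <- random_pqtl(40, "eg", 15)
  qb <- random_pqtl(40, "pe", 16)
  pairs <- find_orthologous_pairs(qa, qb, traits, proximity_bp = 0)
  cl <- cluster_qtl(rbind(qa, qb), merge_gap_bp = 0, min_members = 1)
  clus_of <- function(id) which(vapply(seq_len(nrow(cl)), function(i)
    id %in% c(cl$members_a[[i]], cl$members_b[[i]]), logical(1)))
  for (i in seq_len(nrow(pairs))) {
    expect_equal(clus_of(pairs$qtl_a[i]), clus_of(pairs$qtl_b[i]))
  }
  expect_equal(sum(cl$n_members), 80)
})

test_that("the planted 8 + 6 cluster structure is recovered exactly", {
  sim <- simulate_orthologous_qtl(n_shared = 8, n_single = 6, seed = 9)
  q <- rbind(filter_major(sim$qtl_a), filter_major(sim$qtl_b))
  cl <- cluster_qtl(q, merge_gap_bp = 1e6)
  expect_equal(nrow(cl), 14)
  expect_equal(sum(cl$orthologous), 8)
  expect_equal(sum(!cl$orthologous), 6)
  pairs <- find_orthologous_pairs(sim$qtl_a, sim$qtl_b, sim$traits,
                                  proximity_bp = 1e6)
  # pairs arise only at the shared loci
  shared_chroms <- sim$truth$chrom[sim$truth$type == "shared"]
  expect_true(all(pairs$chrom %in% shared_chroms))
})
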