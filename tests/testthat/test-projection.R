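mk_anchor <- function(id, lg, cM, chrom, bp) {
  tibble::tibble(marker_id = id, linkage_group = lg, cM = cM,
                 target_chrom = chrom, target_bp = bp)
}

mk_qtl <- function(peak, lo, hi, pve = 15, lg = "LG01", env = NULL) {
  tibble::tibble(qtl_id = "q", trait = "fruit_weight", linkage_group = lg,
                 peak_cM = peak, ci_lo_cM = lo, ci_hi_cM = hi, pve = pve,
                 env_cis = list(env))
}

test_that("the local rate is |delta bp| / delta cM with fatal degenerate pairs", {
  a1 <- mk_anchor("m1", "LG01", 10, "B01", 1e6)
  a2 <- mk_anchor("m2", "LG01", 20, "B01", 3e6)
  expect_equal(local_rate(a1, a2), 2e5)
  expect_equal(local_rate(a2, a1), 2e5)  # orientation-free

  expect_error(local_rate(a1, mk_anchor("m3", "LG01", 10, "B01", 2e6)),
               "co-segregating")
  expect_error(local_rate(a1, mk_anchor("m4", "LG01", 15, "B02", 2e6)),
               "different target chromosomes")
  expect_error(local_rate(a1, mk_anchor("m5", "LG02", 15, "B01", 2e6)),
               "linkage groups")
})

test_that("local rates equal a finite-difference oracle on random monotone maps", {
  withr::with_seed(31, {
    for (rep in 1:5) {
      cM <- sort(runif(12, 0, 100))
      bp <- cumsum(runif(12, 1e4, 5e5))
      a <- mk_anchor(sprintf("m%d", 1:12), "LG01", cM, "B01", bp)
      for (i in 1:11) {
        expect_equal(local_rate(a[i, ], a[i + 1, ]),
                     abs(diff(bp[i:(i + 1)])) / diff(cM[i:(i + 1)]))
      }
    }
  })
})

test_that("per-environment CIs average element-wise", {
  two <- mk_qtl(16, 10, 20, env = data.frame(lo = c(10, 14), hi = c(20, 26)))
  expect_equal(average_environment_ci(two), c(lo = 12, hi = 23))

  one <- mk_qtl(7, 5, 9, env = data.frame(lo = 5, hi = 9))
  expect_equal(average_environment_ci(one), c(lo = 5, hi = 9))

  three <- mk_qtl(3, 0, 6, env = data.frame(lo = c(0, 2, 4), hi = c(2, 4, 6)))
  expect_equal(average_environment_ci(three), c(lo = 2, hi = 4))

  none <- mk_qtl(16, 10, 20)
  expect_equal(average_environment_ci(none), c(lo = 10, hi = 20))
})

test_that("projection through a linear scaffold is exact in both modes", {
  a <- rbind(mk_anchor("m1", "LG01", 0, "B01", 0),
             mk_anchor("m2", "LG01", 10, "B01", 2e6))
  q <- mk_qtl(5, 3, 7)
  for (mode in c("local_rate", "piecewise")) {
    p <- project_qtl(q, a, mode = mode)
    expect_equal(p$peak_bp, 1e6)
    expect_equal(p$start_bp, 6e5)
    expect_equal(p$end_bp, 1.4e6)
    expect_false(p$extrapolated)
    expect_equal(p$status, "ok")
  }
})

test_that("piecewise projection interpolates each bound through the scaffold", {
  a <- rbind(mk_anchor("m1", "LG01", 0, "B01", 0),
             mk_anchor("m2", "LG01", 10, "B01", 1e6),
             mk_anchor("m3", "LG01", 20, "B01", 5e6))
  p <- project_qtl(mk_qtl(15, 8, 18), a, mode = "piecewise")
  expect_equal(p$start_bp, 8e5)
  expect_equal(p$peak_bp, 3e6)
  expect_equal(p$end_bp, 4.2e6)
})

test_that("peaks outside the anchored range are extrapolated and flagged", {
  a <- rbind(mk_anchor("m1", "LG01", 0, "B01", 0),
             mk_anchor("m2", "LG01", 20, "B01", 4e6))
  p <- project_qtl(mk_qtl(25, 23, 27), a)
  expect_true(p$extrapolated)
  expect_equal(p$peak_bp, 5e6)  # terminal interval rate of 2e5 bp/cM
  fewer <- project_qtl(mk_qtl(5, 3, 7), a[1, ])
  expect_equal(fewer$status, "fewer-than-2-usable-anchors")
  expect_true(is.na(fewer$peak_bp))
})

test_that("projection restricted to anchor positions reproduces the anchors", {
  cfg <- sim_config(rate_function = "sigmoid", seed = 2)
  mq <- simulate_map_and_qtl(cfg)
  a <- mq$anchors[mq$anchors$linkage_group == "LG03", ]
  for (i in c(1, 10, 25, nrow(a))) {
    q <- mk_qtl(a$cM[i], a$cM[i], a$cM[i], lg = "LG03")
    p <- project_qtl(q, mq$anchors, mode = "piecewise")
    expect_equal(p$peak_bp, a$target_bp[i], tolerance = 1e-9)
  }
})

test_that("piecewise projection is monotone over a monotone scaffold", {
  cfg <- sim_config(rate_function = "sigmoid", seed = 4)
  mq <- simulate_map_and_qtl(cfg)
  peaks <- seq(2, 98, by = 2)
  bp <- vapply(peaks, function(pk) {
    project_qtl(mk_qtl(pk, pk, pk, lg = "LG01"), mq$anchors,
                mode = "piecewise")$peak_bp
  }, 1)
  expect_true(all(diff(bp) >= 0))
})

test_that("the physical CI width equals the cM width times the local rate", {
  withr::with_seed(8, {
    a <- mk_anchor(sprintf("m%d", 1:20), "LG01",
                   sort(runif(20, 0, 100)), "B01",
                   cumsum(runif(20, 1e5, 2e6)))
    for (i in 1:10) {
      peak <- runif(1, 5, 95)
      w <- runif(1, 2, 12)
      q <- mk_qtl(peak, peak - w / 2, peak + w / 2)
      p <- project_qtl(q, a, mode = "local_rate")
      scaf <- projection_scaffold(a, "LG01")$anchors
      k <- min(max(findInterval(peak, scaf$cM), 1), nrow(scaf) - 1)
      rate <- local_rate(scaf[k, ], scaf[k + 1, ])
      expect_equal(p$end_bp - p$start_bp, w * rate, tolerance = 1e-9)
    }
  })
})

test_that("anchors on a minority chromosome are excluded before projection", {
  a <- rbind(mk_anchor(sprintf("m%d", 1:8), "LG01", seq(0, 70, by = 10),
                       "B01", seq(0, 70, by = 10) * 2e5),
             mk_anchor("t1", "LG01", 35, "B07", 9e9))
  scaf <- projection_scaffold(a, "LG01")
  expect_equal(scaf$chrom, "B01")
  expect_equal(scaf$excluded_chrom, "t1")
  p <- project_qtl(mk_qtl(35, 30, 40), a)
  expect_equal(p$peak_bp, 35 * 2e5)
})

test_that("sigmoid-map piecewise error stays below the anchor spacing", {
  cfg <- sim_config(rate_function = "sigmoid", n_qtl_per_lg = 9, seed = 6)
  mq <- simulate_map_and_qtl(cfg)
  errs <- vapply(seq_len(nrow(mq$qtls)), function(i) {
    p <- project_qtl(mq$qtls[i, ], mq$anchors, mode = "piecewise")
    abs(p$peak_bp - mq$truth$peak_bp[i])
  }, 1)
  # anchors every ~2 cM; local physical spacing bounded by the steepest
  # interval of the sigmoid
  spacing <- max(diff(sort(mq$anchors$target_bp[mq$anchors$linkage_group == "LG01"])))
  expect_gte(mean(errs < spacing), 0.95)
})
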