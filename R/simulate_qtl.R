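#' Default trait relatedness groups
#'
#' A compact trait taxonomy for fruit crops, grouping traits that expert
#' screening would treat as related when comparing QTL across species:
#' fruit size and shape; fruit/peduncle attachment and flowering time;
#' anthocyanin pigmentation; plant architecture; prickliness.
#'
#' @return A [trait_equivalence()] object.
#' @export
default_trait_groups <- function() {
  trait_equivalence(list(
    c("fruit_weight", "fruit_length", "fruit_diameter", "fruit_shape"),
    c("peduncle_length", "flowering_time", "fruit_number"),
    c("anthocyanin_fruit", "anthocyanin_leaf", "anthocyanin_stem"),
    c("plant_height", "plant_width"),
    c("prickliness_leaf", "prickliness_stem")
  ))
}

sim_trait_pool <- function() {
  unique(unlist(default_trait_groups()$groups))
}

# monotone cM -> bp function per linkage group; the sigmoid shape mimics
# centromeric recombination suppression (many bp per cM mid-chromosome)
cM_to_bp_fun <- function(rate_function, chrom_length, cM_length) {
  if (rate_function == "linear") {
    function(cM) cM / cM_length * chrom_length
  } else {
    k <- 8
    g <- function(x) 1 / (1 + exp(-k * (x - 0.5)))
    g0 <- g(0); g1 <- g(1)
    function(cM) chrom_length * (g(cM / cM_length) - g0) / (g1 - g0)
  }
}

#' Simulate a genetic map, marker anchors and QTL with physical truth
#'
#' For each linkage group a monotone cM-to-bp function is generated
#' (linear, or sigmoid to mimic suppressed centromeric recombination),
#' markers are placed evenly along the map and anchored at their true
#' physical positions, and QTL are placed with their true physical peak
#' and confidence interval recorded. Per-environment CIs are produced by
#' jittering the true CI symmetrically in two environments, so their
#' average equals the true CI exactly. A second species' QTL set shares a
#' locus and a related trait with the first species for a
#' `fraction_orthologous` of its QTL.
#'
#' @param config a [sim_config()].
#' @return List with `map` (genetic map tibble), `anchors` (marker-anchor
#'   tibble), `qtls` (QTL records with `env_cis`), `truth` (true physical
#'   peak/CI per QTL) and `chrom_lengths` (named vector).
#' @export
simulate_map_and_qtl <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed + 1L, simulate_map_and_qtl_impl(config))
}

simulate_map_and_qtl_impl <- function(cfg) {
  traits <- sim_trait_pool()
  maps <- list(); anchors <- list(); qtls <- list(); truth <- list()
  for (k in seq_len(cfg$n_chrom)) {
    lg <- sprintf("LG%02d", k)
    tc <- t_chrom_name(k)
    Lc <- cfg$chrom_length_bp[k]
    f <- cM_to_bp_fun(cfg$rate_function, Lc, cfg$cM_length)
    cM <- seq(0, cfg$cM_length, length.out = cfg$markers_per_lg)
    ids <- sprintf("mk_%s_%03d", lg, seq_along(cM))
    maps[[k]] <- tibble(marker_id = ids, linkage_group = lg, cM = cM)
    anchors[[k]] <- tibble(marker_id = ids, linkage_group = lg, cM = cM,
                           target_chrom = tc, target_bp = f(cM))
    if (cfg$n_qtl_per_lg > 0) {
      for (q in seq_len(cfg$n_qtl_per_lg)) {
        peak <- stats::runif(1, 0.15, 0.85) * cfg$cM_length
        w <- draw_span(cfg$ci_width_cM)
        lo <- max(0, peak - w / 2)
        hi <- min(cfg$cM_length, peak + w / 2)
        d <- stats::runif(1, 0.5, 2)
        qtls[[length(qtls) + 1]] <- tibble(
          qtl_id = sprintf("qtl_%s_%d", lg, q),
          trait = sample(traits, 1),
          linkage_group = lg, peak_cM = peak,
          ci_lo_cM = lo, ci_hi_cM = hi,
          pve = stats::runif(1, cfg$pve_range[1], cfg$pve_range[2]),
          env_cis = list(data.frame(lo = c(lo + d, lo - d),
                                    hi = c(hi - d, hi + d)))
        )
        truth[[length(truth) + 1]] <- tibble(
          qtl_id = sprintf("qtl_%s_%d", lg, q),
          chrom = tc, peak_bp = f(peak),
          start_bp = f(lo), end_bp = f(hi))
      }
    }
  }
  list(map = bind_rows(maps), anchors = bind_rows(anchors),
       qtls = bind_rows(qtls), truth = bind_rows(truth),
       chrom_lengths = stats::setNames(cfg$chrom_length_bp,
                                       t_chrom_name(seq_len(cfg$n_chrom))))
}

#' Simulate two species' physical QTL with a planted cluster structure
#'
#' Plants well-separated QTL cluster loci on a shared reference genome:
#' `n_shared` loci carry QTL of both species with related traits
#' (orthologous clusters) and `n_single` loci carry co-localized QTL of
#' species A only — mirroring the observed structure of eight orthologous
#' and six single-species clusters. All planted QTL are major
#' (PVE at or above 10).
#'
#' @param n_shared number of two-species cluster loci.
#' @param n_single number of species-A-only cluster loci.
#' @param n_chrom,chrom_length_bp reference genome shape.
#' @param seed integer seed.
#' @return List with `qtl_a`, `qtl_b` (physical QTL tibbles), `traits`
#'   (a [trait_equivalence()]) and `truth` (locus table with
#'   `type` = `"shared"` / `"single"`).
#' @export
simulate_orthologous_qtl <- function(n_shared = 8, n_single = 6,
                                     n_chrom = 12, chrom_length_bp = 25e6,
                                     seed = 1) {
  withr::with_seed(seed, {
    traits <- default_trait_groups()
    n_loci <- n_shared + n_single
    chrom <- rep(seq_len(n_chrom), length.out = n_loci)
    slot <- stats::ave(chrom, chrom, FUN = seq_along)  # occurrence index per chrom
    center <- ifelse(slot == 1,
                     stats::runif(n_loci, 0.10, 0.35),
                     stats::runif(n_loci, 0.60, 0.90)) * chrom_length_bp
    type <- sample(rep(c("shared", "single"), c(n_shared, n_single)))
    qa <- list(); qb <- list(); truth <- list()
    for (i in seq_len(n_loci)) {
      grp <- traits$groups[[sample(length(traits$groups), 1)]]
      tc <- t_chrom_name(chrom[i])
      mk <- function(species, prefix, n_members) {
        w <- stats::runif(n_members, 5e5, 2e6)
        off <- stats::runif(n_members, -2e5, 2e5)
        tibble(
          qtl_id = sprintf("%s_loc%02d_%d", prefix, i, seq_len(n_members)),
          trait = sample(grp, n_members, replace = TRUE),
          species = species, chrom = tc,
          start_bp = pmax(0, center[i] + off - w / 2),
          end_bp = center[i] + off + w / 2,
          peak_bp = center[i] + off,
          pve = stats::runif(n_members, 10, 25)
        )
      }
      qa[[i]] <- mk("speciesA", "egq", sample(2:3, 1))
      if (type[i] == "shared") {
        qb[[i]] <- mk("speciesB", "peq", sample(1:2, 1))
      }
      truth[[i]] <- tibble(locus = i, chrom = tc, center_bp = center[i],
                           type = type[i])
    }
    list(qtl_a = bind_rows(qa), qtl_b = bind_rows(qb),
         traits = traits, truth = bind_rows(truth))
  })
}
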