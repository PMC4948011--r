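#' Trait equivalence tables
#'
#' QTL from two species are comparable only when they influence related
#' traits; relatedness is an explicit expert-supplied table, never string
#' matching. The table is a list of trait groups (character vectors);
#' two traits are related iff they share a group (symmetric closure is
#' applied at load time, and a trait is always related to itself).
#'
#' @param groups list of character vectors, each one group of related
#'   traits.
#' @return An object of class `"trait_equivalence"`.
#' @export
trait_equivalence <- function(groups) {
  stopifnot(is.list(groups))
  groups <- lapply(groups, as.character)
  structure(list(groups = groups), class = "trait_equivalence")
}

#' @rdname trait_equivalence
#' @param path YAML file whose top level is a list of trait groups.
#' @export
read_trait_equivalence <- function(path) {
  trait_equivalence(yaml::read_yaml(path))
}

#' @rdname trait_equivalence
#' @param traits a `trait_equivalence` object.
#' @param a,b character vectors of trait names (recycled).
#' @return `traits_related()`: logical vector.
#' @export
traits_related <- function(traits, a, b) {
  stopifnot(inherits(traits, "trait_equivalence"))
  if (length(a) == 0 || length(b) == 0) return(logical(0))
  mapply(function(x, y) {
    if (is.na(x) || is.na(y)) return(FALSE)
    if (x == y) return(TRUE)
    any(vapply(traits$groups, function(g) x %in% g && y %in% g, logical(1)))
  }, a, b, USE.NAMES = FALSE)
}

trait_known <- function(traits, x) {
  x %in% unlist(traits$groups)
}

#' Retain major QTL by explained variance
#'
#' Keeps QTL whose percentage of phenotypic variance explained (PVE)
#' reaches the threshold; the comparison is inclusive, so PVE exactly 10
#' is a major QTL under the default.
#'
#' @param qtls physical QTL tibble with a `pve` column.
#' @param threshold PVE threshold in percent (default 10).
#' @return The retained rows, order preserved.
#' @export
filter_major <- function(qtls, threshold = 10) {
  qtls[!is.na(qtls$pve) & qtls$pve >= threshold, ]
}

#' Find orthologous QTL pairs between two species
#'
#' A pair is emitted when two physical QTL lie on the same reference
#' chromosome, influence related traits, and their confidence intervals
#' overlap or lie within `proximity_bp` of each other. QTL whose trait is
#' absent from the equivalence table are skipped with a warning; the count
#' is attached as attribute `n_skipped_unknown_trait`.
#'
#' @param qtls_a,qtls_b physical QTL tibbles of the two species, on the
#'   same reference coordinate system.
#' @param traits a [trait_equivalence()].
#' @param proximity_bp maximum gap between CIs (default 1 Mb).
#' @return Tibble of pairs ordered by (chrom, start): `qtl_a`, `qtl_b`,
#'   `chrom`, `trait_a`, `trait_b`, `gap_bp`.
#' @export
find_orthologous_pairs <- function(qtls_a, qtls_b, traits,
                                   proximity_bp = 1e6) {
  stopifnot(inherits(traits, "trait_equivalence"))
  skipped <- 0L
  drop_unknown <- function(q, label) {
    known <- trait_known(traits, q$trait)
    if (any(!known)) {
      warning(sum(!known), " ", label,
              " QTL with trait absent from the equivalence table skipped",
              call. = FALSE)
      skipped <<- skipped + sum(!known)
    }
    q[known, ]
  }
  qa <- drop_unknown(qtls_a, "species-A")
  qb <- drop_unknown(qtls_b, "species-B")
  out <- tibble(qtl_a = character(), qtl_b = character(), chrom = character(),
                trait_a = character(), trait_b = character(), gap_bp = numeric())
  if (nrow(qa) > 0 && nrow(qb) > 0) {
    gra <- GenomicRanges::GRanges(qa$chrom,
                                  IRanges::IRanges(qa$start_bp + 1, qa$end_bp))
    grb <- GenomicRanges::GRanges(qb$chrom,
                                  IRanges::IRanges(qb$start_bp + 1, qb$end_bp))
    ov <- GenomicRanges::findOverlaps(gra, grb, maxgap = proximity_bp)
    i <- S4Vectors::queryHits(ov)
    j <- S4Vectors::subjectHits(ov)
    related <- traits_related(traits, qa$trait[i], qb$trait[j])
    i <- i[related]; j <- j[related]
    if (length(i) > 0) {
      gap <- pmax(0, pmax(qa$start_bp[i], qb$start_bp[j]) -
                    pmin(qa$end_bp[i], qb$end_bp[j]))
      out <- tibble(qtl_a = qa$qtl_id[i], qtl_b = qb$qtl_id[j],
                    chrom = qa$chrom[i],
                    trait_a = qa$trait[i], trait_b = qb$trait[j],
                    gap_bp = gap)
      key_start <- pmin(qa$start_bp[i], qb$start_bp[j])
      out <- out[order(out$chrom, key_start, out$qtl_a, out$qtl_b), ]
    }
  }
  attr(out, "n_skipped_unknown_trait") <- skipped
  out
}

#' Cluster co-localized QTL into orthology clusters
#'
#' Single-linkage merge of physical QTL intervals on one reference genome:
#' intervals with gap at most `merge_gap_bp` join one cluster (connected
#' components of the within-gap overlap graph). Clusters are labelled with
#' the union of member traits; clusters holding QTL of both species are
#' flagged `orthologous`, and one-species clusters are retained as
#' first-class results (they mark regions with a QTL cluster in one
#' species and no counterpart in the other).
#'
#' @param qtls physical QTL tibble with a `species` column (both species
#'   concatenated; see [project_qtl_table()]).
#' @param merge_gap_bp maximum gap joining two intervals (default 1 Mb).
#' @param min_members minimum member count for a reported cluster
#'   (default 2).
#' @return Tibble of clusters: `cluster_id`, `chrom`, `start_bp`,
#'   `end_bp`, `n_members`, `n_species`, `orthologous`, `traits`,
#'   list-columns `members_a` / `members_b` (QTL ids per species).
#' @export
cluster_qtl <- function(qtls, merge_gap_bp = 1e6, min_members = 2) {
  empty <- tibble(cluster_id = character(), chrom = character(),
                  start_bp = numeric(), end_bp = numeric(),
                  n_members = integer(), n_species = integer(),
                  orthologous = logical(), traits = character(),
                  members_a = list(), members_b = list())
  q <- qtls[!is.na(qtls$start_bp), ]
  if (nrow(q) == 0) return(empty)
  species <- sort(unique(q$species))
  gr <- GenomicRanges::GRanges(q$chrom, IRanges::IRanges(q$start_bp + 1, q$end_bp))
  red <- GenomicRanges::reduce(gr, min.gapwidth = merge_gap_bp + 1)
  ov <- GenomicRanges::findOverlaps(gr, red)
  comp <- integer(nrow(q))
  comp[S4Vectors::queryHits(ov)] <- S4Vectors::subjectHits(ov)
  rows <- list()
  for (k in sort(unique(comp))) {
    members <- which(comp == k)
    if (length(members) < min_members) next
    m <- q[members, ]
    rows[[length(rows) + 1]] <- tibble(
      chrom = m$chrom[1],
      start_bp = min(m$start_bp), end_bp = max(m$end_bp),
      n_members = nrow(m),
      n_species = length(unique(m$species)),
      orthologous = length(unique(m$species)) > 1,
      traits = paste(sort(unique(m$trait)), collapse = ";"),
      members_a = list(sort(m$qtl_id[m$species == species[1]])),
      members_b = list(sort(m$qtl_id[m$species != species[1]]))
    )
  }
  if (length(rows) == 0) return(empty)
  out <- bind_rows(rows) %>% arrange(.data$chrom, .data$start_bp)
  mutate(out, cluster_id = sprintf("clu_%03d", row_number()), .before = 1)
}

#' Write orthology clusters as TSV
#'
#' Flat serialization of [cluster_qtl()] output (member id lists joined
#' with commas), mirroring a supplementary-table layout: chromosome,
#' interval, member ids per species, traits.
#'
#' @param clusters cluster tibble.
#' @param path output path.
#' @export
write_clusters_tsv <- function(clusters, path) {
  flat <- mutate(clusters,
                 members_a = vapply(.data$members_a, paste, "", collapse = ","),
                 members_b = vapply(.data$members_b, paste, "", collapse = ","),
                 across(c("start_bp", "end_bp"), format_bp))
  readr::write_tsv(flat, path, progress = FALSE)
  invisible(path)
}
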