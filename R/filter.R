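#' Filter anchor hits by an alignment quality policy
#'
#' Retains exactly the hits meeting every threshold present in the policy:
#' `identity >= min_identity`, `coverage >= min_coverage`,
#' `aligned_length >= min_aligned_length`, `match_bp >= min_match_bp`,
#' `mismatch_bp <= max_mismatch_bp`. All comparisons are inclusive, so a
#' hit exactly at a printed cut-off passes. Hits with `NA` in a field the
#' policy thresholds are dropped (the quantity cannot be verified). Input
#' order is preserved and the operation is idempotent.
#'
#' @param hits anchor hit tibble.
#' @param policy a [filter_policy()].
#' @return The retained hits, same columns, original order.
#' @examples
#' h <- anchor_hits(query_id = c("a", "b"), target_chrom = "P01",
#'                  target_start = c(0, 100), target_end = c(300, 400),
#'                  identity = c(0.80, 0.79), coverage = 0.9,
#'                  aligned_length = 300)
#' filter_hits(h, policy_presets("tocds_peg"))  # keeps only "a"
#' @export
filter_hits <- function(hits, policy) {
  stopifnot(inherits(policy, "filter_policy"))
  hits <- validate_anchor_hits(hits)
  if (nrow(hits) == 0) return(hits)
  keep <- rep(TRUE, nrow(hits))
  ge <- function(x, thr) !is.na(x) & x >= thr
  le <- function(x, thr) !is.na(x) & x <= thr
  if (!is.null(policy$min_identity)) keep <- keep & ge(hits$identity, policy$min_identity)
  if (!is.null(policy$min_coverage)) keep <- keep & ge(hits$coverage, policy$min_coverage)
  if (!is.null(policy$min_aligned_length)) keep <- keep & ge(hits$aligned_length, policy$min_aligned_length)
  if (!is.null(policy$min_match_bp)) keep <- keep & ge(hits$match_bp, policy$min_match_bp)
  if (!is.null(policy$max_mismatch_bp)) keep <- keep & le(hits$mismatch_bp, policy$max_mismatch_bp)
  hits[keep, ]
}

# ranking key shared by the single-query and table-wide best-hit selectors:
# highest match_bp, then identity, then coverage; deterministic positional
# tie-break on (target_chrom, target_start). NA ranks lowest.
best_hit_order <- function(hits) {
  order(-replace(hits$match_bp, is.na(hits$match_bp), -Inf),
        -replace(hits$identity, is.na(hits$identity), -Inf),
        -replace(hits$coverage, is.na(hits$coverage), -Inf),
        hits$target_chrom, hits$target_start)
}

#' Select the single best hit of one query
#'
#' Resolves a multi-hit query to a single copy: the hit with the highest
#' matching bp, then identity, then coverage (strict lexicographic
#' priority). Full ties are broken deterministically by lowest target
#' chromosome name, then lowest target start.
#'
#' @param hits anchor hit tibble, all rows sharing one `query_id`.
#' @return A one-row anchor hit tibble.
#' @seealso [select_best_hits()] for whole-table deduplication.
#' @export
select_best_hit <- function(hits) {
  hits <- validate_anchor_hits(hits)
  if (nrow(hits) == 0) stop("select_best_hit() requires at least one hit", call. = FALSE)
  if (length(unique(hits$query_id)) != 1) {
    stop("select_best_hit() expects hits of a single query", call. = FALSE)
  }
  hits[best_hit_order(hits)[1], ]
}

#' Deduplicate a hit table to one best hit per query
#'
#' Applies the [select_best_hit()] ranking within every `query_id`; after
#' this each query appears exactly once.
#'
#' @param hits anchor hit tibble.
#' @return Anchor hit tibble with unique `query_id`s, ordered by
#'   (`target_chrom`, `target_start`).
#' @export
select_best_hits <- function(hits) {
  hits <- validate_anchor_hits(hits)
  if (nrow(hits) == 0) return(hits)
  hits <- hits[best_hit_order(hits), ]
  hits <- hits[!duplicated(hits$query_id), ]
  arrange(hits, .data$target_chrom, .data$target_start)
}

#' Detect groups of distinct queries co-located at one target locus
#'
#' Two hits are linked when they lie on the same target chromosome and
#' their intervals overlap or lie within `tolerance_bp` of each other (gap
#' distance between interval hulls, so partial alignments are included).
#' Groups are the connected components of this relation; singletons are
#' not reported. Queries in multi-member groups are the "non-unique match"
#' tallies of the screening step.
#'
#' @param hits anchor hit tibble with one hit per query (run
#'   [select_best_hits()] first).
#' @param tolerance_bp non-negative integer, the co-location confidence
#'   interval (default 25 bp; the CDS screening recipe uses 50 bp).
#' @return Tibble with one row per group: `group_id`, `target_chrom`,
#'   `anchor_start`, `anchor_end`, `n_members`, and list-column
#'   `member_query_ids`.
#' @export
find_colocated_queries <- function(hits, tolerance_bp = 25) {
  if (tolerance_bp < 0) stop("tolerance_bp must be non-negative", call. = FALSE)
  hits <- validate_anchor_hits(hits)
  if (nrow(hits) == 0) {
    return(tibble(group_id = integer(), target_chrom = character(),
                  anchor_start = numeric(), anchor_end = numeric(),
                  n_members = integer(), member_query_ids = list()))
  }
  # single-linkage components of the gap<=tolerance relation on intervals
  # are exactly the merged runs of IRanges::reduce with
  # min.gapwidth = tolerance + 1, computed per chromosome
  out <- vector("list", 0)
  gid <- 0L
  for (chrom in sort(unique(hits$target_chrom))) {
    h <- hits[hits$target_chrom == chrom, ]
    ir <- IRanges::IRanges(start = h$target_start + 1, end = h$target_end)
    red <- IRanges::reduce(ir, min.gapwidth = tolerance_bp + 1)
    ov <- IRanges::findOverlaps(ir, red)
    comp <- integer(nrow(h))
    comp[S4Vectors::queryHits(ov)] <- S4Vectors::subjectHits(ov)
    sizes <- tabulate(comp, nbins = length(red))
    for (k in which(sizes >= 2)) {
      gid <- gid + 1L
      members <- which(comp == k)
      out[[length(out) + 1]] <- tibble(
        group_id = gid, target_chrom = chrom,
        anchor_start = min(h$target_start[members]),
        anchor_end = max(h$target_end[members]),
        n_members = length(members),
        member_query_ids = list(sort(h$query_id[members]))
      )
    }
  }
  if (length(out) == 0) {
    return(tibble(group_id = integer(), target_chrom = character(),
                  anchor_start = numeric(), anchor_end = numeric(),
                  n_members = integer(), member_query_ids = list()))
  }
  bind_rows(out)
}
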