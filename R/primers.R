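#' Validate a marker anchor from a forward/reverse primer pair
#'
#' Conserved-ortholog (COSII-style) markers are defined by a primer pair
#' and an expected amplicon length. Short primers align at many loci, so a
#' marker is anchored only when a forward and a reverse primer hit lie on
#' the same target chromosome, on opposite strands (standard PCR geometry;
#' can be disabled), and at an outer-edge-to-outer-edge distance within a
#' slack of the expected amplicon length. Among valid combinations the one
#' whose span is closest to the expected length wins.
#'
#' @param marker_id marker identifier for the synthesized anchor.
#' @param fwd_hits,rev_hits anchor hit tibbles for the forward and reverse
#'   primer (possibly many decoy seed matches each).
#' @param expected_length_bp expected amplicon length (> 0).
#' @param slack allowed span deviation: a fraction of `expected_length_bp`
#'   when `< 1` (default 0.25, i.e. +-25%), otherwise absolute bp.
#' @param require_opposite_strand logical; demand fwd/rev on opposite
#'   strands (default `TRUE`).
#' @return A list with `hit` (one-row anchor hit tibble spanning the pair,
#'   or `NULL`) and `reason` (`NA` on success, else one of
#'   `"no-common-chrom"`, `"strand-incompatible"`, `"no-span-match"`).
#' @examples
#' fwd <- anchor_hits(query_id = "m1_F", target_chrom = "P01",
#'                    target_start = 1000, target_end = 1020, strand = "+")
#' rev <- anchor_hits(query_id = "m1_R", target_chrom = "P01",
#'                    target_start = 2480, target_end = 2500, strand = "-")
#' pair_primers("m1", fwd, rev, expected_length_bp = 1500)$hit
#' @export
pair_primers <- function(marker_id, fwd_hits, rev_hits, expected_length_bp,
                         slack = 0.25, require_opposite_strand = TRUE) {
  if (expected_length_bp <= 0) {
    stop("expected_length_bp must be positive", call. = FALSE)
  }
  fwd_hits <- validate_anchor_hits(fwd_hits)
  rev_hits <- validate_anchor_hits(rev_hits)
  slack_bp <- if (slack < 1) slack * expected_length_bp else slack
  fail <- function(reason) list(hit = NULL, reason = reason)
  if (nrow(fwd_hits) == 0 || nrow(rev_hits) == 0 ||
      length(intersect(fwd_hits$target_chrom, rev_hits$target_chrom)) == 0) {
    return(fail("no-common-chrom"))
  }
  cand <- merge(
    data.frame(i = seq_len(nrow(fwd_hits)), chrom = fwd_hits$target_chrom),
    data.frame(j = seq_len(nrow(rev_hits)), chrom = rev_hits$target_chrom),
    by = "chrom"
  )
  if (require_opposite_strand) {
    ok_strand <- fwd_hits$strand[cand$i] != rev_hits$strand[cand$j]
    if (!any(ok_strand)) return(fail("strand-incompatible"))
    cand <- cand[ok_strand, ]
  }
  span_start <- pmin(fwd_hits$target_start[cand$i], rev_hits$target_start[cand$j])
  span_end <- pmax(fwd_hits$target_end[cand$i], rev_hits$target_end[cand$j])
  span <- span_end - span_start
  dev <- abs(span - expected_length_bp)
  ok <- dev <= slack_bp
  if (!any(ok)) return(fail("no-span-match"))
  best <- which(ok)[order(dev[ok], cand$chrom[ok], span_start[ok])][1]
  i <- cand$i[best]; j <- cand$j[best]
  stopifnot(abs((span_end[best] - span_start[best]) - expected_length_bp) <= slack_bp)
  hit <- anchor_hits(
    query_id = marker_id,
    query_chrom = NA_character_, query_start = NA_real_, query_end = NA_real_,
    target_chrom = cand$chrom[best],
    target_start = span_start[best], target_end = span_end[best],
    strand = fwd_hits$strand[i],
    identity = min(fwd_hits$identity[i], rev_hits$identity[j]),
    coverage = min(fwd_hits$coverage[i], rev_hits$coverage[j]),
    aligned_length = span[best],
    match_bp = sum(fwd_hits$match_bp[i], rev_hits$match_bp[j], na.rm = TRUE),
    mismatch_bp = sum(fwd_hits$mismatch_bp[i], rev_hits$mismatch_bp[j], na.rm = TRUE)
  )
  list(hit = hit, reason = NA_character_)
}
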