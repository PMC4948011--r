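#' Anchor hit tables
#'
#' An *anchor hit* is one filtered alignment of a query sequence (a CDS, a
#' genetic-map marker, or a primer) to a position on a target genome. Hits
#' are stored as plain tibbles with a fixed column set so that every stage
#' of the pipeline can exchange them; [anchor_hits()] builds such a tibble
#' from vectors and [validate_anchor_hits()] checks the invariants
#' (half-open target interval, fractions in \[0, 1\],
#' `match_bp <= aligned_length`).
#'
#' Coordinates are 0-based half-open. `query_start`/`query_end` are base
#' pairs for sequence queries but centiMorgan-scaled units when the query
#' axis is a genetic map; `strand` is the orientation of the alignment on
#' the target (query orientation is undefined for map markers).
#'
#' @param query_id character, query sequence identifiers.
#' @param query_chrom character, source chromosome / linkage group of the
#'   query (`NA` for unplaced queries).
#' @param query_start,query_end numeric, query coordinates (0-based
#'   half-open when known).
#' @param target_chrom character, target chromosome.
#' @param target_start,target_end numeric bp, target interval (0-based
#'   half-open, `target_start < target_end`).
#' @param strand `"+"` or `"-"`, target alignment orientation.
#' @param identity,coverage fractions in \[0, 1\] (`NA` when the source
#'   format does not report them).
#' @param aligned_length,match_bp,mismatch_bp integers bp.
#' @return A tibble with one row per hit and the columns listed above.
#' @examples
#' anchor_hits(
#'   query_id = "Solyc01g005000", query_chrom = "T01",
#'   query_start = 0, query_end = 1200,
#'   target_chrom = "P01", target_start = 150000, target_end = 151250,
#'   strand = "+", identity = 0.91, coverage = 0.88,
#'   aligned_length = 1250, match_bp = 1140, mismatch_bp = 110
#' )
#' @export
anchor_hits <- function(query_id = character(), query_chrom = NA_character_,
                        query_start = NA_real_, query_end = NA_real_,
                        target_chrom = character(), target_start = numeric(),
                        target_end = numeric(), strand = "+",
                        identity = NA_real_, coverage = NA_real_,
                        aligned_length = NA_real_, match_bp = NA_real_,
                        mismatch_bp = NA_real_) {
  hits <- tibble(
    query_id = as.character(query_id),
    query_chrom = as.character(query_chrom),
    query_start = as.numeric(query_start),
    query_end = as.numeric(query_end),
    target_chrom = as.character(target_chrom),
    target_start = as.numeric(target_start),
    target_end = as.numeric(target_end),
    strand = as.character(strand),
    identity = as.numeric(identity),
    coverage = as.numeric(coverage),
    aligned_length = as.numeric(aligned_length),
    match_bp = as.numeric(match_bp),
    mismatch_bp = as.numeric(mismatch_bp)
  )
  validate_anchor_hits(hits)
}

anchor_hit_columns <- c(
  "query_id", "query_chrom", "query_start", "query_end",
  "target_chrom", "target_start", "target_end", "strand",
  "identity", "coverage", "aligned_length", "match_bp", "mismatch_bp"
)

#' @rdname anchor_hits
#' @param hits a data frame of anchor hits.
#' @export
validate_anchor_hits <- function(hits) {
  missing <- setdiff(anchor_hit_columns, names(hits))
  if (length(missing) > 0) {
    stop("anchor hit table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  hits <- as_tibble(hits)[, anchor_hit_columns]
  if (nrow(hits) == 0) return(hits)
  if (any(hits$target_start >= hits$target_end)) {
    stop("target intervals must satisfy target_start < target_end (0-based half-open)",
         call. = FALSE)
  }
  frac_bad <- function(x) any(!is.na(x) & (x < 0 | x > 1))
  if (frac_bad(hits$identity) || frac_bad(hits$coverage)) {
    stop("identity and coverage must be fractions in [0, 1]", call. = FALSE)
  }
  bad_match <- !is.na(hits$match_bp) & !is.na(hits$aligned_length) &
    hits$match_bp > hits$aligned_length
  if (any(bad_match)) {
    stop("match_bp must not exceed aligned_length", call. = FALSE)
  }
  if (!all(hits$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'", call. = FALSE)
  }
  hits
}

empty_anchor_hits <- function() {
  anchor_hits()
}

#' Alignment filter policies
#'
#' A filter policy bundles the per-dataset alignment thresholds applied to
#' anchor hits: minimum identity, minimum coverage, minimum alignment
#' length, minimum matching bp and maximum mismatching bp. Any threshold
#' may be absent (`NULL`), in which case it is not applied. All thresholds
#' are inclusive (`>=` / `<=`), so a hit sitting exactly on a printed
#' cut-off is retained.
#'
#' @param min_identity,min_coverage minimum identity / coverage. Interpreted
#'   according to `units`: fractions in \[0, 1\] (default) or percentages.
#' @param min_aligned_length minimum alignment length in bp.
#' @param min_match_bp minimum number of matching bp.
#' @param max_mismatch_bp maximum number of mismatching bp.
#' @param units `"fraction"` or `"percent"`; how `min_identity` and
#'   `min_coverage` are expressed. Stored internally as fractions.
#' @return A list of class `"filter_policy"`.
#' @seealso [policy_presets()] for the six shipped per-dataset policies,
#'   [read_filter_policies()] to load policies from YAML.
#' @examples
#' filter_policy(min_identity = 80, min_coverage = 75,
#'               min_aligned_length = 200, units = "percent")
#' @export
filter_policy <- function(min_identity = NULL, min_coverage = NULL,
                          min_aligned_length = NULL, min_match_bp = NULL,
                          max_mismatch_bp = NULL,
                          units = c("fraction", "percent")) {
  units <- match.arg(units)
  scale <- if (units == "percent") 100 else 1
  p <- list(
    min_identity = if (!is.null(min_identity)) min_identity / scale,
    min_coverage = if (!is.null(min_coverage)) min_coverage / scale,
    min_aligned_length = min_aligned_length,
    min_match_bp = min_match_bp,
    max_mismatch_bp = max_mismatch_bp
  )
  for (f in c("min_identity", "min_coverage")) {
    v <- p[[f]]
    if (!is.null(v) && (v < 0 || v > 1)) {
      stop(f, " must lie in [0, 1] after unit normalization", call. = FALSE)
    }
  }
  for (f in c("min_aligned_length", "min_match_bp", "max_mismatch_bp")) {
    v <- p[[f]]
    if (!is.null(v) && v < 0) stop(f, " must be non-negative", call. = FALSE)
  }
  structure(p, class = "filter_policy")
}

#' Shipped per-dataset filter policies
#'
#' The six alignment filters used for the Solanaceae dataset comparisons,
#' named by query/target pair: tomato CDS on the pepper genome
#' (`tocds_peg`), pepper CDS on the tomato genome (`pecds_tog`), pepper map
#' markers on the pepper genome (`pem_peg`), eggplant map markers on the
#' eggplant draft (`egm_egg`) and on the tomato / pepper genomes
#' (`egm_tog`, `egm_peg`).
#'
#' * `tocds_peg`, `pecds_tog`: identity >= 80%, coverage >= 75%, aligned
#'   length >= 200 bp.
#' * `pem_peg`: identity >= 98%, matching bp >= 200, mismatching bp <= 50.
#' * `egm_egg`: identity >= 75%, matching bp >= 100, mismatching bp <= 50.
#' * `egm_tog`, `egm_peg`: identity >= 75%, coverage >= 40%, aligned
#'   length >= 200 bp.
#'
#' @param name optional preset name; when omitted the full named list is
#'   returned.
#' @return A `filter_policy` (when `name` is given) or a named list of all
#'   six presets.
#' @export
policy_presets <- function(name = NULL) {
  presets <- list(
    tocds_peg = filter_policy(min_identity = 0.80, min_coverage = 0.75,
                              min_aligned_length = 200),
    pecds_tog = filter_policy(min_identity = 0.80, min_coverage = 0.75,
                              min_aligned_length = 200),
    pem_peg = filter_policy(min_identity = 0.98, min_match_bp = 200,
                            max_mismatch_bp = 50),
    egm_egg = filter_policy(min_identity = 0.75, min_match_bp = 100,
                            max_mismatch_bp = 50),
    egm_tog = filter_policy(min_identity = 0.75, min_coverage = 0.40,
                            min_aligned_length = 200),
    egm_peg = filter_policy(min_identity = 0.75, min_coverage = 0.40,
                            min_aligned_length = 200)
  )
  if (is.null(name)) return(presets)
  if (!name %in% names(presets)) {
    stop("unknown policy preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  }
  presets[[name]]
}

#' Read filter policies from a YAML file
#'
#' The YAML file maps policy names to threshold blocks; each block may carry
#' a `units` key (`fraction` or `percent`) governing how its identity and
#' coverage thresholds are read.
#'
#' @param path path to a YAML file.
#' @return Named list of `filter_policy` objects.
#' @export
read_filter_policies <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(block) {
    units <- block$units %||% "fraction"
    filter_policy(
      min_identity = block$min_identity,
      min_coverage = block$min_coverage,
      min_aligned_length = block$min_aligned_length,
      min_match_bp = block$min_match_bp,
      max_mismatch_bp = block$max_mismatch_bp,
      units = units
    )
  })
}

`%||%` <- function(x, y) if (is.null(x)) y else x
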