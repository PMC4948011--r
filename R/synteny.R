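#' Chaining parameters for synteny blocks
#'
#' @param max_gap_bp maximum gap between consecutive anchors of one block,
#'   applied on both genomes (default 3 Mb, matched to CDS-anchor densities
#'   of ~1 anchor / 150 kb).
#' @param min_anchors minimum anchors per retained block (default 3).
#' @param min_span_bp minimum target-genome span for a rearrangement call
#'   (default 0.5 Mb).
#' @param max_gap_query maximum gap on the query axis; defaults to
#'   `max_gap_bp`. Set this separately (in cM-scaled units) when the query
#'   axis is a genetic map, in which case `min_span_bp` still applies to
#'   the physical target genome only.
#' @param dup_overlap reciprocal query-overlap fraction for duplication
#'   calls (default 0.5).
#' @return A list of class `"chain_params"`.
#' @export
chain_params <- function(max_gap_bp = 3e6, min_anchors = 3,
                         min_span_bp = 5e5, max_gap_query = max_gap_bp,
                         dup_overlap = 0.5) {
  stopifnot(max_gap_bp > 0, min_anchors > 0, min_span_bp > 0,
            max_gap_query > 0, dup_overlap > 0, dup_overlap <= 1)
  structure(list(max_gap_bp = max_gap_bp, min_anchors = min_anchors,
                 min_span_bp = min_span_bp, max_gap_query = max_gap_query,
                 dup_overlap = dup_overlap),
            class = "chain_params")
}

#' Assign chromosome orthology by anchor plurality
#'
#' For each target chromosome, the orthologous query chromosome is the one
#' contributing the plurality of anchors. Also reports the full per-pair
#' anchor count table and the fraction of anchors lying on their plurality
#' (orthologous) chromosome — the "same chromosome" fraction.
#'
#' @param hits anchor hit tibble with known `query_chrom`.
#' @return List with `map` (named character vector, target chromosome ->
#'   query chromosome), `counts` (tibble query_chrom / target_chrom /
#'   n), and `same_chromosome_fraction`.
#' @export
assign_chromosome_orthology <- function(hits) {
  hits <- validate_anchor_hits(hits)
  hits <- hits[!is.na(hits$query_chrom), ]
  if (nrow(hits) == 0) {
    return(list(map = stats::setNames(character(), character()),
                counts = tibble(query_chrom = character(),
                                target_chrom = character(), n = integer()),
                same_chromosome_fraction = NA_real_))
  }
  counts <- hits %>%
    dplyr::count(.data$query_chrom, .data$target_chrom, name = "n") %>%
    arrange(.data$target_chrom, dplyr::desc(.data$n), .data$query_chrom)
  top <- counts[!duplicated(counts$target_chrom), ]
  map <- stats::setNames(top$query_chrom, top$target_chrom)
  on_ortho <- map[hits$target_chrom] == hits$query_chrom
  list(map = map, counts = counts,
       same_chromosome_fraction = mean(on_ortho, na.rm = TRUE))
}

#' Chain anchors into orientation-consistent synteny blocks
#'
#' Greedy single-linkage chaining per (query chromosome, target
#' chromosome) pair: anchors are sorted by target position and the current
#' block is extended while the next anchor lies within the allowed gap on
#' both genomes and continues the block's query-order direction
#' (increasing for `+` blocks, decreasing for `-`). A direction change or
#' an oversized gap starts a new block. Blocks with fewer than
#' `min_anchors` anchors are dropped; their anchor row indices are
#' attached as attribute `dropped_idx`, so every input anchor is in
#' exactly one block or in the dropped set.
#'
#' @param hits anchor hit tibble (unique per query; see
#'   [select_best_hits()]) with numeric query coordinates.
#' @param params a [chain_params()].
#' @return Tibble of blocks: `block_id`, `query_chrom`, `query_start`,
#'   `query_end`, `target_chrom`, `target_start`, `target_end`,
#'   `orientation`, `n_anchors`, plus list-column `anchor_idx` holding row
#'   indices into `hits`.
#' @export
chain_anchors <- function(hits, params = chain_params()) {
  stopifnot(inherits(params, "chain_params"))
  hits <- validate_anchor_hits(hits)
  empty <- tibble(block_id = character(), query_chrom = character(),
                  query_start = numeric(), query_end = numeric(),
                  target_chrom = character(), target_start = numeric(),
                  target_end = numeric(), orientation = character(),
                  n_anchors = integer(), anchor_idx = list())
  if (nrow(hits) == 0) {
    attr(empty, "dropped_idx") <- integer()
    return(empty)
  }
  usable <- which(!is.na(hits$query_chrom) & !is.na(hits$query_start))
  q_mid <- (hits$query_start + hits$query_end) / 2
  t_mid <- (hits$target_start + hits$target_end) / 2
  pair_key <- paste(hits$query_chrom, hits$target_chrom, sep = "\r")
  blocks <- list()
  dropped <- setdiff(seq_len(nrow(hits)), usable)
  for (key in sort(unique(pair_key[usable]))) {
    idx <- usable[pair_key[usable] == key]
    idx <- idx[order(t_mid[idx], q_mid[idx])]
    runs <- chain_one_pair(q_mid[idx], t_mid[idx],
                           params$max_gap_query, params$max_gap_bp)
    for (run in runs) {
      members <- idx[run$members]
      if (length(members) < params$min_anchors) {
        dropped <- c(dropped, members)
        next
      }
      blocks[[length(blocks) + 1]] <- tibble(
        query_chrom = hits$query_chrom[members][1],
        query_start = min(hits$query_start[members]),
        query_end = max(hits$query_end[members]),
        target_chrom = hits$target_chrom[members][1],
        target_start = min(hits$target_start[members]),
        target_end = max(hits$target_end[members]),
        orientation = run$orientation,
        n_anchors = length(members),
        anchor_idx = list(members)
      )
    }
  }
  if (length(blocks) == 0) {
    attr(empty, "dropped_idx") <- sort(dropped)
    return(empty)
  }
  out <- bind_rows(blocks) %>%
    arrange(.data$target_chrom, .data$target_start, .data$query_chrom)
  out <- mutate(out, block_id = sprintf("blk_%04d", row_number()),
                .before = 1)
  attr(out, "dropped_idx") <- sort(dropped)
  out
}

# core greedy scan over one chromosome pair; q and t are anchor midpoints
# already sorted by t. Returns a list of runs (member positions within the
# sorted vector + orientation).
chain_one_pair <- function(q, t, max_gap_q, max_gap_t) {
  n <- length(q)
  runs <- list()
  start <- 1L
  dir <- 0L
  if (n == 1) return(list(list(members = 1L, orientation = "+")))
  flush <- function(runs, start, end, dir) {
    runs[[length(runs) + 1]] <- list(
      members = start:end,
      orientation = if (dir < 0) "-" else "+"
    )
    runs
  }
  for (i in 2:n) {
    step <- q[i] - q[i - 1]
    gap_ok <- (t[i] - t[i - 1]) <= max_gap_t && abs(step) <= max_gap_q
    sdir <- sign(step)
    dir_ok <- dir == 0L || sdir == 0 || sdir == dir
    if (gap_ok && dir_ok) {
      if (dir == 0L && sdir != 0) dir <- as.integer(sdir)
    } else {
      runs <- flush(runs, start, i - 1L, dir)
      start <- i
      dir <- 0L
    }
  }
  flush(runs, start, n, dir)
}

# Coalesce target-adjacent blocks of one chromosome pair that are
# orientation-compatible and continue the query progression. Repairs block
# splits caused by isolated spurious anchors or positional jitter before
# rearrangement classification; chain-level output is left untouched.
# When anchor query midpoints (`qm`) are available, the continuation test
# is retried with each piece's second-extreme anchor, so a single stray
# anchor absorbed at a block boundary cannot block the repair.
coalesce_blocks <- function(blocks, params, qm = NULL) {
  if (nrow(blocks) <= 1) return(blocks)
  # query must continue in the block direction: forward gap bounded by
  # max_gap_query, backward overlap bounded by a small jitter-scale
  # allowance (so e.g. duplicated copies retracing the same query
  # interval are never merged)
  backstep <- 0.05 * params$max_gap_query
  step_ok <- function(delta) {
    delta <= params$max_gap_query && delta >= -backstep
  }
  edge_candidates <- function(block, side) {
    # extreme and second-extreme anchor query positions on one edge
    hull <- if (side == "hi") block$query_end else block$query_start
    if (is.null(qm)) return(hull)
    q <- sort(qm[block$anchor_idx[[1]]], decreasing = (side == "hi"))
    unique(c(hull, q[seq_len(min(2, length(q)))]))
  }
  query_continues <- function(cur, nxt) {
    if (cur$orientation == "+") {
      ends <- edge_candidates(cur, "hi")
      starts <- edge_candidates(nxt, "lo")
      any(outer(starts, ends, `-`) >= -backstep &
            outer(starts, ends, `-`) <= params$max_gap_query)
    } else {
      ends <- edge_candidates(cur, "lo")
      starts <- edge_candidates(nxt, "hi")
      any(outer(ends, starts, `-`) >= -backstep &
            outer(ends, starts, `-`) <= params$max_gap_query)
    }
  }
  out <- list()
  for (key in unique(paste(blocks$query_chrom, blocks$target_chrom, sep = "\r"))) {
    b <- blocks[paste(blocks$query_chrom, blocks$target_chrom, sep = "\r") == key, ]
    b <- b[order(b$target_start), ]
    cur <- b[1, ]
    for (i in seq_len(nrow(b))[-1]) {
      nxt <- b[i, ]
      gap_t <- nxt$target_start - cur$target_end
      compatible <- nxt$orientation == cur$orientation &&
        gap_t <= params$max_gap_bp &&
        query_continues(cur, nxt)
      if (compatible) {
        cur$query_start <- min(cur$query_start, nxt$query_start)
        cur$query_end <- max(cur$query_end, nxt$query_end)
        cur$target_start <- min(cur$target_start, nxt$target_start)
        cur$target_end <- max(cur$target_end, nxt$target_end)
        cur$n_anchors <- cur$n_anchors + nxt$n_anchors
        cur$anchor_idx <- list(c(cur$anchor_idx[[1]], nxt$anchor_idx[[1]]))
        cur$block_id <- paste(cur$block_id, nxt$block_id, sep = "+")
      } else {
        out[[length(out) + 1]] <- cur
        cur <- nxt
      }
    }
    out[[length(out) + 1]] <- cur
  }
  bind_rows(out) %>% arrange(.data$target_chrom, .data$target_start)
}
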