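#' Call chromosomal rearrangements from synteny blocks
#'
#' Classifies structural differences between the two genomes from the
#' chained blocks, using the chromosome orthology map from
#' [assign_chromosome_orthology()]:
#'
#' * **translocation** — a block whose query chromosome differs from the
#'   orthologous partner of its target chromosome;
#' * **inversion** — orthologous chromosome pair, but block orientation
#'   opposite to the anchor-weighted dominant orientation of that pair;
#' * **transposition** — orthologous pair and dominant orientation, but
#'   the block is displaced out of rank order relative to the other blocks
#'   of the pair (it falls outside the anchor-weighted longest
#'   order-consistent subsequence of block midpoints, i.e. it has jumped
#'   past at least one full block);
#' * **duplication** — two or more blocks whose query intervals
#'   reciprocally overlap by at least `dup_overlap` map to disjoint
#'   target intervals. Blocks in a duplication group are not additionally
#'   classified under the other rules (a dispersed copy would otherwise
#'   always masquerade as a translocation).
#'
#' Before classification, target-adjacent blocks of a pair that are
#' orientation-compatible and continue the query progression are
#' coalesced, so single stray anchors that split a run do not fragment
#' calls. Only calls whose target span reaches `params$min_span_bp`
#' (default 0.5 Mb) are reported. When `hits` is supplied, each call's
#' breakpoints are refined to the midpoints between the outermost block
#' anchors and their nearest retained neighbours outside the block, an
#' unbiased estimate of the true span; otherwise the anchor hull is used.
#'
#' @param blocks block tibble from [chain_anchors()].
#' @param orthology result of [assign_chromosome_orthology()] (or its
#'   `map` component).
#' @param params a [chain_params()].
#' @param hits optional anchor hit tibble the blocks were chained from,
#'   used for breakpoint refinement.
#' @return Tibble of calls: `kind`, `query_chrom`, `query_start`,
#'   `query_end`, `target_chrom`, `target_start`, `target_end`, `span_bp`,
#'   `n_anchors`, `orientation`, `block_ids`.
#' @export
call_rearrangements <- function(blocks, orthology, params = chain_params(),
                                hits = NULL) {
  stopifnot(inherits(params, "chain_params"))
  map <- if (is.list(orthology) && !is.null(orthology$map)) orthology$map else orthology
  empty <- tibble(kind = character(), query_chrom = character(),
                  query_start = numeric(), query_end = numeric(),
                  target_chrom = character(), target_start = numeric(),
                  target_end = numeric(), span_bp = numeric(),
                  n_anchors = integer(), orientation = character(),
                  block_ids = character())
  if (nrow(blocks) == 0) return(empty)
  qm_pre <- if (!is.null(hits)) (hits$query_start + hits$query_end) / 2
  b <- coalesce_blocks(blocks, params, qm = qm_pre)
  b$span_bp <- refined_spans(b, hits)
  b$t_mid <- (b$target_start + b$target_end) / 2
  b$q_mid <- (b$query_start + b$query_end) / 2
  qm <- if (!is.null(hits)) (hits$query_start + hits$query_end) / 2

  # anchor-weighted dominant orientation per chromosome pair
  dom <- b %>%
    group_by(.data$query_chrom, .data$target_chrom) %>%
    summarise(dominant = if (sum(.data$n_anchors[.data$orientation == "-"]) >
                             sum(.data$n_anchors[.data$orientation == "+"])) "-" else "+",
              .groups = "drop")
  b <- left_join(b, dom, by = c("query_chrom", "target_chrom"))

  dup_groups <- duplication_groups(b, params, qm)
  in_dup <- unlist(dup_groups)

  calls <- list()
  emit <- function(kind, rows) {
    tibble(
      kind = kind,
      query_chrom = paste(unique(rows$query_chrom), collapse = ","),
      query_start = min(rows$query_start), query_end = max(rows$query_end),
      target_chrom = paste(unique(rows$target_chrom), collapse = ","),
      target_start = min(rows$target_start), target_end = max(rows$target_end),
      span_bp = max(rows$span_bp), n_anchors = sum(rows$n_anchors),
      orientation = paste(unique(rows$orientation), collapse = ","),
      block_ids = paste(rows$block_id, collapse = ",")
    )
  }
  for (grp in dup_groups) {
    rows <- b[grp, ]
    if (max(rows$span_bp) >= params$min_span_bp) {
      calls[[length(calls) + 1]] <- emit("duplication", rows)
    }
  }

  for (i in seq_len(nrow(b))) {
    if (i %in% in_dup) next
    tc <- b$target_chrom[i]
    if (!tc %in% names(map)) next
    if (b$span_bp[i] < params$min_span_bp) next
    if (b$query_chrom[i] != map[[tc]]) {
      calls[[length(calls) + 1]] <- emit("translocation", b[i, ])
    } else if (b$orientation[i] != b$dominant[i]) {
      calls[[length(calls) + 1]] <- emit("inversion", b[i, ])
    }
  }

  # transpositions: a cut-and-paste within a chromosome leaves the moved
  # block's query interval nested inside the query hull of the (larger)
  # host block of the same chromosome pair — which has a hole exactly
  # there — while the two occupy disjoint target intervals
  for (tc in names(map)) {
    qc <- map[[tc]]
    sel <- which(b$target_chrom == tc & b$query_chrom == qc)
    if (length(sel) < 2) next
    for (i in sel) {
      if (i %in% in_dup) next
      if (b$span_bp[i] < params$min_span_bp) next
      if (b$orientation[i] != b$dominant[i]) next  # already an inversion
      hosts <- setdiff(sel, i)
      expected <- if (b$dominant[i] == "+") 1 else -1
      displaced <- vapply(hosts, function(j) {
        if (b$n_anchors[j] < b$n_anchors[i]) return(FALSE)
        t_disjoint <- b$target_start[j] >= b$target_end[i] ||
          b$target_end[j] <= b$target_start[i]
        if (!t_disjoint) return(FALSE)
        # (a) nested: the host hull covers the moved query interval
        if (b$query_start[j] <= b$query_start[i] &&
            b$query_end[j] >= b$query_end[i]) return(TRUE)
        # (b) disjoint-interval order violation vs the dominant direction
        q_disjoint <- b$query_start[j] >= b$query_end[i] ||
          b$query_end[j] <= b$query_start[i]
        if (!q_disjoint) return(FALSE)
        sign_t <- sign(b$target_start[i] - b$target_start[j])
        sign_q <- sign(b$query_start[i] - b$query_start[j])
        sign_q * sign_t != expected
      }, logical(1))
      if (any(displaced)) {
        calls[[length(calls) + 1]] <- emit("transposition", b[i, ])
      }
    }
  }

  if (length(calls) == 0) return(empty)
  bind_rows(calls) %>%
    arrange(.data$kind, .data$target_chrom, .data$target_start)
}

# unbiased breakpoint estimate: extend each block hull to the midpoint
# towards the nearest retained anchor outside the block on the same target
# chromosome; at chromosome ends the hull edge is kept
refined_spans <- function(b, hits) {
  span <- b$target_end - b$target_start
  if (is.null(hits) || nrow(b) == 0) return(span)
  for (tc in unique(b$target_chrom)) {
    rows <- which(b$target_chrom == tc)
    mids <- sort((hits$target_start + hits$target_end)[hits$target_chrom == tc] / 2)
    for (i in rows) {
      left <- mids[mids < b$target_start[i]]
      right <- mids[mids > b$target_end[i]]
      lo <- if (length(left)) (max(left) + b$target_start[i]) / 2 else b$target_start[i]
      hi <- if (length(right)) (min(right) + b$target_end[i]) / 2 else b$target_end[i]
      span[i] <- hi - lo
    }
  }
  span
}

# connected pair-groups of duplication-compatible blocks. Two blocks are
# copies of one query segment when (i) they share a query chromosome and
# orientation, (ii) their query hulls overlap by >= dup_overlap of the
# smaller hull, (iii) their target intervals are disjoint, and (iv) the
# copies interleave: the larger block has anchors strictly inside the
# smaller block's query interval (a transposed segment also satisfies
# i-iii against its host block, but the host has a coverage hole exactly
# there, so interleaving separates the two signatures; `qm` carries the
# anchor query midpoints, and without it the interleaving check is
# skipped).
duplication_groups <- function(b, params, qm = NULL) {
  n <- nrow(b)
  if (n < 2) return(list())
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  linked <- rep(FALSE, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (b$query_chrom[i] != b$query_chrom[j]) next
      if (b$orientation[i] != b$orientation[j]) next
      ov <- min(b$query_end[i], b$query_end[j]) -
        max(b$query_start[i], b$query_start[j])
      if (ov <= 0) next
      li <- b$query_end[i] - b$query_start[i]
      lj <- b$query_end[j] - b$query_start[j]
      if (ov < params$dup_overlap * min(li, lj)) next
      disjoint <- b$target_chrom[i] != b$target_chrom[j] ||
        b$target_start[j] >= b$target_end[i] ||
        b$target_start[i] >= b$target_end[j]
      if (!disjoint) next
      if (!is.null(qm)) {
        small <- if (b$n_anchors[i] <= b$n_anchors[j]) i else j
        big <- if (small == i) j else i
        margin <- max(0.05 * (b$query_end[small] - b$query_start[small]), 2e4)
        inner_lo <- b$query_start[small] + margin
        inner_hi <- b$query_end[small] - margin
        big_qm <- qm[b$anchor_idx[[big]]]
        if (!any(big_qm > inner_lo & big_qm < inner_hi)) next
      }
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
      linked[i] <- linked[j] <- TRUE
    }
  }
  if (!any(linked)) return(list())
  roots <- vapply(seq_len(n), find, 1L)
  split(which(linked), roots[linked])
}

# anchor-weighted longest monotone subsequence; returns indices kept.
# O(n^2), n = blocks per chromosome pair (small). Deterministic: among
# equal-weight solutions the earlier predecessor wins.
weighted_lis <- function(x, w, increasing = TRUE) {
  n <- length(x)
  if (n == 0) return(integer())
  if (!increasing) x <- -x
  best <- w
  prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1)) {
      if (x[j] <= x[i] && best[j] + w[i] > best[i]) {
        best[i] <- best[j] + w[i]
        prev[i] <- j
      }
    }
  }
  end <- which.max(best)
  keep <- integer()
  while (!is.na(end)) {
    keep <- c(end, keep)
    end <- prev[end]
  }
  keep
}

#' Score rearrangement calls against simulator ground truth
#'
#' Matches each truth event to calls of the same kind on the right
#' chromosome(s) with overlapping coordinates (target interval for
#' inversions / translocations / transpositions, query interval for
#' duplications). Recall is the fraction of truth events with a matching
#' call; precision is the fraction of calls matching some truth event.
#'
#' @param calls call tibble from [call_rearrangements()].
#' @param truth truth tibble from [simulate_genome_pair()].
#' @return List with `recall`, `precision`, `n_truth`, `n_calls`,
#'   per-event logical `truth_found` and per-call logical `call_matched`.
#' @export
score_rearrangement_calls <- function(calls, truth) {
  overlaps <- function(a_lo, a_hi, b_lo, b_hi) a_lo < b_hi & b_lo < a_hi
  match_one <- function(ev, cl) {
    if (cl$kind != ev$kind) return(FALSE)
    if (ev$kind == "duplication") {
      return(ev$query_chrom %in% strsplit(cl$query_chrom, ",")[[1]] &&
               overlaps(cl$query_start, cl$query_end, ev$query_start, ev$query_end))
    }
    if (ev$kind == "translocation") {
      qc <- strsplit(ev$query_chrom, ",")[[1]]
      tc <- strsplit(ev$target_chrom, ",")[[1]]
      return(cl$query_chrom %in% qc && cl$target_chrom %in% tc &&
               overlaps(cl$target_start, cl$target_end,
                        ev$target_start, ev$target_end))
    }
    cl$target_chrom == ev$target_chrom &&
      overlaps(cl$target_start, cl$target_end, ev$target_start, ev$target_end)
  }
  n_truth <- nrow(truth)
  n_calls <- nrow(calls)
  truth_found <- logical(n_truth)
  call_matched <- logical(n_calls)
  if (n_truth > 0 && n_calls > 0) {
    for (e in seq_len(n_truth)) {
      for (c in seq_len(n_calls)) {
        if (match_one(truth[e, ], calls[c, ])) {
          truth_found[e] <- TRUE
          call_matched[c] <- TRUE
        }
      }
    }
  }
  list(recall = if (n_truth) mean(truth_found) else NA_real_,
       precision = if (n_calls) mean(call_matched) else NA_real_,
       n_truth = n_truth, n_calls = n_calls,
       truth_found = truth_found, call_matched = call_matched)
}
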