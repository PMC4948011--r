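#' Simulation configuration
#'
#' Parameters of the synthetic genome-pair / map / QTL generator. The
#' defaults describe a desk-scale stand-in for a Solanaceae genome
#' comparison: two genomes of 12 chromosomes of 25 Mb each, 400 anchors
#' per chromosome (one per ~62 kb, the density of a CDS-anchor set), and
#' per history 2–4 inversions, 1–2 reciprocal translocations, 0–1
#' transpositions and 0–1 dispersed duplications with spans of 1–3 Mb.
#' Inversions, transpositions and duplications are placed in the proximal
#' 5–55% of their chromosome and translocation breakpoints in the distal
#' 60–90% (the distal arm-swap geometry of the classic pepper/tomato
#' P01/T08 exchange), so events are spatially disjoint and independently
#' detectable. Duplications copy the segment's anchors to one position on
#' each of two other chromosomes — a dispersed duplicative transposition,
#' leaving the extra off-diagonal dot-plot runs that a segmental
#' duplication produces between chromosome pairs.
#'
#' Anchor identity and coverage are Beta-distributed above the standard
#' CDS filter thresholds; a contaminant fraction with sub-threshold
#' quality is added on top so the alignment filter is exercised. Noise
#' applied after the event history: anchors deleted at
#' `missing_anchor_rate`, uniform spurious (but filter-passing) hits added
#' at `spurious_hit_rate`, paralogous extra hits of existing queries at
#' `paralog_rate`, and target positions jittered by up to
#' `positional_jitter_bp`.
#'
#' @param n_chrom number of chromosomes (default 12).
#' @param chrom_length_bp chromosome length(s) in bp (recycled).
#' @param anchors_per_chrom anchors placed per chromosome.
#' @param n_inversions,n_translocations,n_transpositions,n_duplications
#'   event counts; a length-2 vector is an inclusive range sampled per
#'   history.
#' @param event_span_bp length-2 range of event spans in bp.
#' @param min_displacement_bp minimum transposition displacement.
#' @param spurious_hit_rate,missing_anchor_rate,paralog_rate rates in
#'   \[0, 1\].
#' @param positional_jitter_bp maximum absolute target-position jitter.
#' @param contaminant_rate fraction of extra sub-quality hits.
#' @param markers_per_lg,cM_length genetic-map markers per linkage group
#'   and map length in cM.
#' @param rate_function `"linear"` or `"sigmoid"` cM-to-bp shape;
#'   `"sigmoid"` mimics centromeric recombination suppression (physical
#'   distance per cM peaks mid-chromosome).
#' @param n_qtl_per_lg QTL simulated per linkage group.
#' @param ci_width_cM,pve_range length-2 ranges for QTL confidence-interval
#'   widths (cM) and PVE (percent).
#' @param fraction_orthologous fraction of second-species QTL sharing a
#'   locus and related trait with the first species.
#' @param noise logical; `FALSE` zeroes every noise and contaminant rate.
#' @param seed integer seed; all randomness flows from it.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_chrom = 12, chrom_length_bp = 25e6,
                       anchors_per_chrom = 400,
                       n_inversions = c(2, 4), n_translocations = c(1, 2),
                       n_transpositions = c(0, 1), n_duplications = c(0, 1),
                       event_span_bp = c(1e6, 3e6),
                       min_displacement_bp = 5e6,
                       spurious_hit_rate = 0.05, missing_anchor_rate = 0.05,
                       paralog_rate = 0.01, positional_jitter_bp = 5000,
                       contaminant_rate = 0.10,
                       markers_per_lg = 50, cM_length = 100,
                       rate_function = c("linear", "sigmoid"),
                       n_qtl_per_lg = 2, ci_width_cM = c(4, 12),
                       pve_range = c(2, 25), fraction_orthologous = 0.5,
                       noise = TRUE, seed = 1) {
  rate_function <- match.arg(rate_function)
  if (!noise) {
    spurious_hit_rate <- missing_anchor_rate <- paralog_rate <- 0
    positional_jitter_bp <- 0
    contaminant_rate <- 0
  }
  cfg <- list(
    n_chrom = n_chrom,
    chrom_length_bp = rep_len(chrom_length_bp, n_chrom),
    anchors_per_chrom = anchors_per_chrom,
    n_inversions = n_inversions, n_translocations = n_translocations,
    n_transpositions = n_transpositions, n_duplications = n_duplications,
    event_span_bp = event_span_bp,
    min_displacement_bp = min_displacement_bp,
    spurious_hit_rate = spurious_hit_rate,
    missing_anchor_rate = missing_anchor_rate,
    paralog_rate = paralog_rate,
    positional_jitter_bp = positional_jitter_bp,
    contaminant_rate = contaminant_rate,
    markers_per_lg = markers_per_lg, cM_length = cM_length,
    rate_function = rate_function,
    n_qtl_per_lg = n_qtl_per_lg, ci_width_cM = ci_width_cM,
    pve_range = pve_range, fraction_orthologous = fraction_orthologous,
    seed = seed
  )
  rates <- c(cfg$spurious_hit_rate, cfg$missing_anchor_rate, cfg$paralog_rate,
             cfg$contaminant_rate, cfg$fraction_orthologous)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]", call. = FALSE)
  if (any(cfg$event_span_bp < 1)) stop("event spans must be >= 1 bp", call. = FALSE)
  if (max(cfg$event_span_bp) > 0.5 * min(cfg$chrom_length_bp)) {
    stop("event span exceeds half the chromosome length", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

draw_count <- function(x) if (length(x) == 2) sample(seq(x[1], x[2]), 1) else x
draw_span <- function(x) stats::runif(1, x[1], x[2])

q_chrom_name <- function(i) sprintf("A%02d", i)
t_chrom_name <- function(i) sprintf("B%02d", i)

# reflection of a half-open interval inside [s, e)
reflect_interval <- function(start, end, s, e) {
  list(start = s + e - end, end = s + e - start)
}

#' Simulate an anchored genome pair with known rearrangements
#'
#' Places anchors uniformly on query genome A (chromosomes `A01`…), then
#' derives their target-genome coordinates (chromosomes `B01`…) by
#' applying a sampled rearrangement history: inversions reflect order and
#' strand within the interval, reciprocal translocations exchange distal
#' arms, transpositions cut-and-paste a segment along its chromosome, and
#' duplications copy a segment's anchors to two separated positions on
#' another chromosome. Noise (deletions, spurious hits, paralogous extra
#' hits, positional jitter, sub-quality contaminants) is applied last.
#' Fully reproducible from `config$seed`.
#'
#' @param config a [sim_config()].
#' @return List with `hits` (anchor hit tibble), `truth` (one row per
#'   planted event: `kind`, query/target chromosomes and intervals),
#'   `genome` (per-chromosome pairing and lengths) and `counts` (exact
#'   bookkeeping: placed, duplication copies, deleted, spurious, paralog,
#'   contaminant).
#' @export
simulate_genome_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_genome_pair_impl(config))
}

simulate_genome_pair_impl <- function(cfg) {
  n <- cfg$n_chrom
  L <- cfg$chrom_length_bp
  span_rng <- cfg$event_span_bp

  counts <- c(inversion = draw_count(cfg$n_inversions),
              translocation = draw_count(cfg$n_translocations),
              transposition = draw_count(cfg$n_transpositions),
              duplication = draw_count(cfg$n_duplications))
  need <- counts[["inversion"]] + 2 * counts[["translocation"]] +
    counts[["transposition"]] + counts[["duplication"]]
  if (need > n) stop("event counts require more chromosomes than available",
                     call. = FALSE)
  pool <- sample(n)
  take <- function(k) {
    got <- pool[seq_len(k)]
    pool <<- pool[-seq_len(k)]
    got
  }

  events <- list()
  for (i in seq_len(counts[["inversion"]])) {
    c1 <- take(1); w <- draw_span(span_rng)
    s <- stats::runif(1, 0.05 * L[c1], 0.55 * L[c1] - w)
    events[[length(events) + 1]] <- list(kind = "inversion", chrom = c1,
                                         s = s, e = s + w)
  }
  for (i in seq_len(counts[["translocation"]])) {
    cc <- take(2)
    b1 <- stats::runif(1, 0.60 * L[cc[1]], 0.90 * L[cc[1]])
    b2 <- stats::runif(1, 0.60 * L[cc[2]], 0.90 * L[cc[2]])
    events[[length(events) + 1]] <- list(kind = "translocation",
                                         c1 = cc[1], c2 = cc[2],
                                         b1 = b1, b2 = b2)
  }
  for (i in seq_len(counts[["transposition"]])) {
    c1 <- take(1); w <- draw_span(span_rng)
    repeat {
      s <- stats::runif(1, 0.05 * L[c1], 0.55 * L[c1] - w)
      d <- stats::runif(1, 0.05 * L[c1], 0.55 * L[c1])
      if (d <= s - cfg$min_displacement_bp ||
          d >= s + w + cfg$min_displacement_bp) break
    }
    events[[length(events) + 1]] <- list(kind = "transposition", chrom = c1,
                                         s = s, e = s + w, d = d)
  }
  for (i in seq_len(counts[["duplication"]])) {
    c1 <- take(1); w <- draw_span(span_rng)
    s <- stats::runif(1, 0.05 * L[c1], 0.55 * L[c1] - w)
    transloc_chroms <- unlist(lapply(events, function(e)
      if (e$kind == "translocation") c(e$c1, e$c2) else integer()))
    dest_ok <- setdiff(seq_len(n), c(c1, transloc_chroms))
    cc <- sample(dest_ok, 2)
    d1 <- stats::runif(1, 0.60 * L[cc[1]], 0.90 * L[cc[1]] - w)
    d2 <- stats::runif(1, 0.60 * L[cc[2]], 0.90 * L[cc[2]] - w)
    events[[length(events) + 1]] <- list(kind = "duplication", chrom = c1,
                                         s = s, e = s + w,
                                         dest1 = cc[1], dest2 = cc[2],
                                         d1 = d1, d2 = d2)
  }

  # anchors on genome A
  per_chrom <- lapply(seq_len(n), function(c1) {
    pos <- sort(stats::runif(cfg$anchors_per_chrom, 0, L[c1] - 2500))
    len <- round(stats::runif(cfg$anchors_per_chrom, 500, 2000))
    tibble(
      query_id = sprintf("g_%s_%04d", q_chrom_name(c1), seq_along(pos)),
      query_chrom = q_chrom_name(c1),
      query_start = round(pos), query_end = round(pos) + len,
      chrom_i = c1,
      target_chrom = t_chrom_name(c1),
      target_start = round(pos), target_end = round(pos) + len,
      strand = "+"
    )
  })
  hits <- bind_rows(per_chrom)
  n_placed <- nrow(hits)

  truth <- list()
  extra_copies <- list()
  n_dup_copies <- 0L
  mid <- function(h) (h$target_start + h$target_end) / 2
  for (ev in events) {
    if (ev$kind == "inversion") {
      tc <- t_chrom_name(ev$chrom)
      sel <- hits$target_chrom == tc & mid(hits) >= ev$s & mid(hits) < ev$e
      r <- reflect_interval(hits$target_start[sel], hits$target_end[sel],
                            ev$s, ev$e)
      hits$target_start[sel] <- r$start
      hits$target_end[sel] <- r$end
      hits$strand[sel] <- ifelse(hits$strand[sel] == "+", "-", "+")
      truth[[length(truth) + 1]] <- tibble(
        kind = "inversion",
        query_chrom = q_chrom_name(ev$chrom),
        query_start = ev$s, query_end = ev$e,
        target_chrom = tc, target_start = ev$s, target_end = ev$e)
    } else if (ev$kind == "translocation") {
      t1 <- t_chrom_name(ev$c1); t2 <- t_chrom_name(ev$c2)
      s1 <- hits$target_chrom == t1 & mid(hits) >= ev$b1
      s2 <- hits$target_chrom == t2 & mid(hits) >= ev$b2
      hits$target_chrom[s1] <- t2
      hits$target_start[s1] <- hits$target_start[s1] - ev$b1 + ev$b2
      hits$target_end[s1] <- hits$target_end[s1] - ev$b1 + ev$b2
      hits$target_chrom[s2] <- t1
      hits$target_start[s2] <- hits$target_start[s2] - ev$b2 + ev$b1
      hits$target_end[s2] <- hits$target_end[s2] - ev$b2 + ev$b1
      truth[[length(truth) + 1]] <- tibble(
        kind = "translocation",
        query_chrom = paste(q_chrom_name(ev$c1), q_chrom_name(ev$c2), sep = ","),
        query_start = min(ev$b1, ev$b2),
        query_end = max(L[ev$c1], L[ev$c2]),
        target_chrom = paste(t1, t2, sep = ","),
        target_start = min(ev$b1, ev$b2),
        target_end = max(L[ev$c1], L[ev$c2]))
    } else if (ev$kind == "transposition") {
      tc <- t_chrom_name(ev$chrom)
      w <- ev$e - ev$s
      m <- mid(hits)
      on_c <- hits$target_chrom == tc
      seg <- on_c & m >= ev$s & m < ev$e
      if (ev$d > ev$e) {
        between <- on_c & m >= ev$e & m < ev$d
        shift_seg <- ev$d - ev$e
        shift_btw <- -w
        dest_lo <- ev$d - w
      } else {
        between <- on_c & m >= ev$d & m < ev$s
        shift_seg <- ev$d - ev$s
        shift_btw <- w
        dest_lo <- ev$d
      }
      hits$target_start[seg] <- hits$target_start[seg] + shift_seg
      hits$target_end[seg] <- hits$target_end[seg] + shift_seg
      hits$target_start[between] <- hits$target_start[between] + shift_btw
      hits$target_end[between] <- hits$target_end[between] + shift_btw
      truth[[length(truth) + 1]] <- tibble(
        kind = "transposition",
        query_chrom = q_chrom_name(ev$chrom),
        query_start = ev$s, query_end = ev$e,
        target_chrom = tc, target_start = dest_lo, target_end = dest_lo + w)
    } else if (ev$kind == "duplication") {
      m <- mid(hits)
      sel <- which(hits$target_chrom == t_chrom_name(ev$chrom) &
                     m >= ev$s & m < ev$e)
      copy1 <- hits[sel, ]
      copy2 <- hits[sel, ]
      copy1$target_chrom <- t_chrom_name(ev$dest1)
      copy1$target_start <- copy1$target_start - ev$s + ev$d1
      copy1$target_end <- copy1$target_end - ev$s + ev$d1
      copy2$target_chrom <- t_chrom_name(ev$dest2)
      copy2$target_start <- copy2$target_start - ev$s + ev$d2
      copy2$target_end <- copy2$target_end - ev$s + ev$d2
      hits <- hits[-sel, ]
      n_dup_copies <- n_dup_copies + length(sel)
      extra_copies[[length(extra_copies) + 1]] <- bind_rows(copy1, copy2)
      truth[[length(truth) + 1]] <- tibble(
        kind = "duplication",
        query_chrom = q_chrom_name(ev$chrom),
        query_start = ev$s, query_end = ev$e,
        target_chrom = paste(t_chrom_name(ev$dest1), t_chrom_name(ev$dest2),
                             sep = ","),
        target_start = min(ev$d1, ev$d2),
        target_end = max(ev$d1, ev$d2) + (ev$e - ev$s))
    }
  }
  hits <- bind_rows(hits, extra_copies)

  # noise: deletions, paralogs, spurious, contaminants, jitter
  del <- stats::runif(nrow(hits)) < cfg$missing_anchor_rate
  n_deleted <- sum(del)
  hits <- hits[!del, ]

  par_sel <- which(stats::runif(nrow(hits)) < cfg$paralog_rate)
  if (length(par_sel) > 0) {
    par <- hits[par_sel, ]
    pc <- sample(n, nrow(par), replace = TRUE)
    plen <- par$target_end - par$target_start
    ppos <- round(stats::runif(nrow(par)) * (L[pc] - plen - 1))
    par$target_chrom <- t_chrom_name(pc)
    par$target_start <- ppos
    par$target_end <- ppos + plen
    hits <- bind_rows(hits, par)
  }
  n_paralog <- length(par_sel)

  n_spur <- round(cfg$spurious_hit_rate * n_placed)
  if (n_spur > 0) {
    qc <- sample(n, n_spur, replace = TRUE)
    tc <- sample(n, n_spur, replace = TRUE)
    slen <- round(stats::runif(n_spur, 500, 2000))
    spur <- tibble(
      query_id = sprintf("spur_%05d", seq_len(n_spur)),
      query_chrom = q_chrom_name(qc),
      query_start = round(stats::runif(n_spur) * (L[qc] - slen - 1)),
      query_end = NA_real_, chrom_i = NA_integer_,
      target_chrom = t_chrom_name(tc),
      target_start = round(stats::runif(n_spur) * (L[tc] - slen - 1)),
      target_end = NA_real_,
      strand = sample(c("+", "-"), n_spur, replace = TRUE)
    )
    spur$query_end <- spur$query_start + slen
    spur$target_end <- spur$target_start + slen
    hits <- bind_rows(hits, spur)
  }

  # anchor quality: Beta-distributed above the CDS filter thresholds
  nh <- nrow(hits)
  hits$identity <- pmax(stats::rbeta(nh, 46, 4), 0.82)
  hits$coverage <- pmax(stats::rbeta(nh, 22, 3), 0.78)
  hits$aligned_length <- hits$query_end - hits$query_start
  hits$match_bp <- round(hits$identity * hits$aligned_length)
  hits$mismatch_bp <- hits$aligned_length - hits$match_bp

  n_cont <- round(cfg$contaminant_rate * n_placed)
  if (n_cont > 0) {
    qc <- sample(n, n_cont, replace = TRUE)
    tc <- sample(n, n_cont, replace = TRUE)
    clen <- round(stats::runif(n_cont, 300, 1500))
    ident <- stats::runif(n_cont, 0.40, 0.75)
    cont <- tibble(
      query_id = sprintf("cont_%05d", seq_len(n_cont)),
      query_chrom = q_chrom_name(qc),
      query_start = round(stats::runif(n_cont) * (L[qc] - clen - 1)),
      query_end = NA_real_, chrom_i = NA_integer_,
      target_chrom = t_chrom_name(tc),
      target_start = round(stats::runif(n_cont) * (L[tc] - clen - 1)),
      target_end = NA_real_,
      strand = sample(c("+", "-"), n_cont, replace = TRUE),
      identity = ident,
      coverage = stats::runif(n_cont, 0.20, 0.70),
      aligned_length = clen,
      match_bp = round(ident * clen),
      mismatch_bp = clen - round(ident * clen)
    )
    cont$query_end <- cont$query_start + clen
    cont$target_end <- cont$target_start + clen
    hits <- bind_rows(hits, cont)
  }

  if (cfg$positional_jitter_bp > 0) {
    j <- stats::runif(nrow(hits), -cfg$positional_jitter_bp,
                      cfg$positional_jitter_bp)
    hits$target_start <- pmax(0, round(hits$target_start + j))
    hits$target_end <- hits$target_start +
      (hits$aligned_length)
  }

  hits$chrom_i <- NULL
  hits <- validate_anchor_hits(hits)
  truth <- if (length(truth)) bind_rows(truth) else
    tibble(kind = character(), query_chrom = character(),
           query_start = numeric(), query_end = numeric(),
           target_chrom = character(), target_start = numeric(),
           target_end = numeric())
  genome <- tibble(query_chrom = q_chrom_name(seq_len(n)),
                   target_chrom = t_chrom_name(seq_len(n)),
                   length_bp = L)
  list(hits = hits, truth = truth, genome = genome,
       counts = list(n_placed = n_placed, n_dup_copies = n_dup_copies,
                     n_deleted = n_deleted, n_spurious = n_spur,
                     n_paralog = n_paralog, n_contaminant = n_cont,
                     n_output = nrow(hits)))
}
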