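#' Local genetic-to-physical rate between two neighbouring marker anchors
#'
#' The local conversion rate is the ratio of physical to genetic distance,
#' `|delta bp| / delta cM`, between two markers anchored on the same
#' target chromosome. Co-segregating pairs (`delta cM = 0`) are unusable,
#' and pairs whose anchors land on different chromosomes span a
#' rearrangement; both are errors.
#'
#' @param a1,a2 one-row marker-anchor tibbles with columns
#'   `linkage_group`, `cM`, `target_chrom`, `target_bp`.
#' @return The local rate in bp per cM.
#' @examples
#' a1 <- tibble::tibble(marker_id = "m1", linkage_group = "LG1", cM = 10,
#'                      target_chrom = "P01", target_bp = 1e6)
#' a2 <- tibble::tibble(marker_id = "m2", linkage_group = "LG1", cM = 20,
#'                      target_chrom = "P01", target_bp = 3e6)
#' local_rate(a1, a2)  # 200000
#' @export
local_rate <- function(a1, a2) {
  if (a1$linkage_group != a2$linkage_group) {
    stop("anchors lie on different linkage groups", call. = FALSE)
  }
  if (a1$target_chrom != a2$target_chrom) {
    stop("anchors map to different target chromosomes (pair spans a rearrangement)",
         call. = FALSE)
  }
  d_cM <- abs(a2$cM - a1$cM)
  if (d_cM == 0) {
    stop("delta cM is zero: co-segregating marker pair is unusable", call. = FALSE)
  }
  abs(a2$target_bp - a1$target_bp) / d_cM
}

#' Average per-environment confidence intervals of a QTL
#'
#' When a QTL was detected in several environments, the element-wise mean
#' of the per-environment confidence intervals is used for projection
#' (with two environments this is the average of the two CIs; a single
#' environment is returned unchanged). With no per-environment CIs the
#' QTL's overall `ci_lo_cM` / `ci_hi_cM` is used.
#'
#' @param qtl one-row QTL tibble (see [read_qtl_table()]), optionally with
#'   an `env_cis` list-column entry (data frame with `lo` and `hi`).
#' @return Named numeric vector `c(lo, hi)` in cM.
#' @export
average_environment_ci <- function(qtl) {
  cis <- if ("env_cis" %in% names(qtl)) qtl$env_cis[[1]] else NULL
  if (is.null(cis) || nrow(cis) == 0) {
    return(c(lo = qtl$ci_lo_cM, hi = qtl$ci_hi_cM))
  }
  c(lo = mean(cis$lo), hi = mean(cis$hi))
}

#' Build a projection scaffold from marker anchors
#'
#' Restricts a linkage group's anchors to its majority target chromosome
#' (anchors elsewhere sit on translocated segments and are excluded, with
#' a report), orders them by cM, and — for piecewise interpolation —
#' resolves local non-monotonicity (small inversions) by keeping the
#' longest cM/bp order-consistent subsequence so the interpolant stays a
#' function.
#'
#' @param anchors marker-anchor tibble (`marker_id`, `linkage_group`,
#'   `cM`, `target_chrom`, `target_bp`).
#' @param linkage_group which linkage group to scaffold.
#' @return List with `anchors` (the usable scaffold, cM-ordered),
#'   `chrom` (majority target chromosome), `excluded_chrom` and
#'   `excluded_monotone` (marker ids dropped at each step), and
#'   `direction` (+1/-1, bp vs cM).
#' @export
projection_scaffold <- function(anchors, linkage_group) {
  a <- anchors[anchors$linkage_group == linkage_group, ]
  if (nrow(a) == 0) {
    return(list(anchors = a, chrom = NA_character_,
                excluded_chrom = character(), excluded_monotone = character(),
                direction = 1))
  }
  tab <- sort(table(a$target_chrom), decreasing = TRUE)
  chrom <- names(tab)[1]
  excluded <- a$marker_id[a$target_chrom != chrom]
  a <- a[a$target_chrom == chrom, ]
  a <- a[order(a$cM, a$target_bp), ]
  a <- a[!duplicated(a$cM), ]  # co-segregating duplicates carry no rate information
  direction <- if (nrow(a) >= 2 &&
                   stats::cor(a$cM, a$target_bp, method = "kendall") < 0) -1 else 1
  keep <- weighted_lis(direction * a$target_bp, rep(1, nrow(a)), increasing = TRUE)
  excluded_mono <- a$marker_id[-keep]
  list(anchors = a[keep, ], chrom = chrom,
       excluded_chrom = excluded,
       excluded_monotone = if (length(keep) < nrow(a)) excluded_mono else character(),
       direction = direction)
}

#' Project a QTL confidence interval to physical coordinates
#'
#' Converts a genetic-map QTL (peak and LOD confidence interval in cM) to
#' target-genome base pairs using marker anchors on its linkage group.
#' Per-environment CIs are first averaged ([average_environment_ci()]).
#'
#' Two modes:
#' * `"local_rate"` (default): the anchor pair flanking the peak gives a
#'   local bp/cM rate; the peak is placed by linear interpolation within
#'   that pair and the physical CI is the cM CI width multiplied by the
#'   local rate, laid out around the projected peak (preserving the cM
#'   asymmetry of the interval, so its total width is exactly
#'   `(hi_cM - lo_cM) * rate`).
#' * `"piecewise"`: peak and both CI bounds are interpolated
#'   independently through the full monotone anchor scaffold.
#'
#' A peak outside the anchored cM range is extrapolated with the terminal
#' interval's rate and flagged `extrapolated = TRUE`. Physical bounds are
#' clipped to `[0, chrom_length]` when the chromosome length is known.
#'
#' @param qtl one-row QTL tibble.
#' @param anchors marker-anchor tibble (see [projection_scaffold()]).
#' @param mode `"local_rate"` or `"piecewise"`.
#' @param species species label carried into the output.
#' @param chrom_lengths optional named vector of target chromosome
#'   lengths for clipping.
#' @return One-row tibble: `qtl_id`, `trait`, `species`, `chrom`,
#'   `start_bp`, `end_bp`, `peak_bp`, `pve`, `extrapolated`, `status`
#'   (`"ok"` or a reason the QTL is unprojectable, in which case the
#'   coordinate fields are `NA`).
#' @export
project_qtl <- function(qtl, anchors, mode = c("local_rate", "piecewise"),
                        species = NA_character_, chrom_lengths = NULL) {
  mode <- match.arg(mode)
  scaf <- projection_scaffold(anchors, qtl$linkage_group)
  a <- scaf$anchors
  out <- tibble(qtl_id = qtl$qtl_id, trait = qtl$trait, species = species,
                chrom = scaf$chrom, start_bp = NA_real_, end_bp = NA_real_,
                peak_bp = NA_real_, pve = qtl$pve, extrapolated = FALSE,
                status = "ok")
  if (nrow(a) < 2) {
    out$status <- "fewer-than-2-usable-anchors"
    return(out)
  }
  ci <- average_environment_ci(qtl)
  peak <- qtl$peak_cM
  extrapolated <- peak < min(a$cM) || peak > max(a$cM)
  if (mode == "local_rate") {
    # flanking pair around the peak (nearest interior pair outside the range)
    i <- findInterval(peak, a$cM, rightmost.closed = TRUE)
    i <- min(max(i, 1L), nrow(a) - 1L)
    slope <- (a$target_bp[i + 1] - a$target_bp[i]) / (a$cM[i + 1] - a$cM[i])
    peak_bp <- a$target_bp[i] + (peak - a$cM[i]) * slope
    lo_bp <- peak_bp + (ci[["lo"]] - peak) * slope
    hi_bp <- peak_bp + (ci[["hi"]] - peak) * slope
  } else {
    extrapolated <- extrapolated || ci[["lo"]] < min(a$cM) || ci[["hi"]] > max(a$cM)
    peak_bp <- interp_extrap(peak, a$cM, a$target_bp)
    lo_bp <- interp_extrap(ci[["lo"]], a$cM, a$target_bp)
    hi_bp <- interp_extrap(ci[["hi"]], a$cM, a$target_bp)
  }
  bounds <- sort(c(lo_bp, hi_bp))
  if (!is.null(chrom_lengths) && scaf$chrom %in% names(chrom_lengths)) {
    bounds <- pmin(pmax(bounds, 0), chrom_lengths[[scaf$chrom]])
    peak_bp <- min(max(peak_bp, 0), chrom_lengths[[scaf$chrom]])
  } else {
    bounds <- pmax(bounds, 0)
    peak_bp <- max(peak_bp, 0)
  }
  out$start_bp <- bounds[1]
  out$end_bp <- bounds[2]
  out$peak_bp <- peak_bp
  out$extrapolated <- extrapolated
  out
}

# piecewise-linear interpolation with linear extrapolation at the
# terminal intervals' rates
interp_extrap <- function(x, xs, ys) {
  n <- length(xs)
  if (x < xs[1]) return(ys[1] + (x - xs[1]) * (ys[2] - ys[1]) / (xs[2] - xs[1]))
  if (x > xs[n]) return(ys[n] + (x - xs[n]) * (ys[n] - ys[n - 1]) / (xs[n] - xs[n - 1]))
  stats::approx(xs, ys, xout = x, ties = "ordered")$y
}

#' Project a whole QTL table
#'
#' Applies [project_qtl()] to each row; unprojectable QTL are kept with
#' their failure reason in `status`.
#'
#' @inheritParams project_qtl
#' @param qtls QTL tibble.
#' @return Tibble with one row per input QTL.
#' @export
project_qtl_table <- function(qtls, anchors, mode = c("local_rate", "piecewise"),
                              species = NA_character_, chrom_lengths = NULL) {
  mode <- match.arg(mode)
  bind_rows(lapply(seq_len(nrow(qtls)), function(i) {
    project_qtl(qtls[i, ], anchors, mode = mode, species = species,
                chrom_lengths = chrom_lengths)
  }))
}
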