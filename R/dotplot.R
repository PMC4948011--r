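#' Syntenic dot plots per chromosome pair
#'
#' Plots anchor positions with the query genome on the vertical axis and
#' the target genome on the horizontal axis, one panel per retained
#' chromosome pair. Points are anchor midpoints; anchors belonging to
#' called rearrangement blocks are highlighted by call kind. A tidy TSV
#' twin of the plotted points can be written alongside the figure for
#' programmatic checks.
#'
#' @param hits anchor hit tibble.
#' @param blocks optional block tibble; when given, panels are restricted
#'   to chromosome pairs containing at least one block.
#' @param calls optional call tibble from [call_rearrangements()]; its
#'   blocks' anchors are highlighted.
#' @param file optional path for the figure (png/pdf by extension).
#' @param tsv optional path for the tidy point table.
#' @return List with `plot` (a ggplot) and `points` (tibble with columns
#'   `query_chrom`, `target_chrom`, `x`, `y`, `query_id`, `highlight`).
#' @export
dotplot <- function(hits, blocks = NULL, calls = NULL, file = NULL,
                    tsv = NULL) {
  hits <- validate_anchor_hits(hits)
  pts <- tibble(
    query_id = hits$query_id,
    query_chrom = hits$query_chrom,
    target_chrom = hits$target_chrom,
    x = (hits$target_start + hits$target_end) / 2,
    y = (hits$query_start + hits$query_end) / 2,
    highlight = NA_character_
  )
  pts <- pts[!is.na(pts$query_chrom) & !is.na(pts$y), ]
  if (!is.null(blocks) && nrow(blocks) > 0) {
    keys <- unique(paste(blocks$query_chrom, blocks$target_chrom))
    pts <- pts[paste(pts$query_chrom, pts$target_chrom) %in% keys, ]
  }
  if (!is.null(calls) && nrow(calls) > 0 && !is.null(blocks)) {
    for (i in seq_len(nrow(calls))) {
      ids <- strsplit(calls$block_ids[i], ",", fixed = TRUE)[[1]]
      ids <- unlist(strsplit(ids, "+", fixed = TRUE))
      idx <- unlist(blocks$anchor_idx[blocks$block_id %in% ids])
      sel <- pts$query_id %in% hits$query_id[idx] &
        pts$target_chrom %in% strsplit(calls$target_chrom[i], ",")[[1]]
      pts$highlight[sel] <- calls$kind[i]
    }
  }
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$x / 1e6, y = .data$y / 1e6)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$highlight), size = 0.4,
                        na.rm = TRUE) +
    ggplot2::scale_colour_discrete(na.value = "grey40", name = "call") +
    ggplot2::facet_grid(query_chrom ~ target_chrom, scales = "free") +
    ggplot2::labs(x = "target position (Mb)", y = "query position (Mb)") +
    ggplot2::theme_bw(base_size = 8)
  if (!is.null(tsv)) readr::write_tsv(pts, tsv, progress = FALSE)
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 10, height = 10, dpi = 150)
  }
  list(plot = p, points = pts)
}
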