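#' Parse GMAP-style alignment GFF3 into anchor hits
#'
#' Reads the GFF3 emitted by GMAP-like spliced aligners, keeping one anchor
#' hit per top-level alignment feature. GFF3 1-based closed coordinates are
#' converted to the internal 0-based half-open convention and percentage
#' attributes are normalized to fractions. Lines that are not valid
#' 9-column GFF3 and alignment features missing a required attribute are
#' skipped with a warning and counted; the counts are attached to the
#' result as attributes `n_skipped_malformed` and `n_skipped_missing_attr`.
#'
#' @param path path to a GFF3 file.
#' @param dialect currently only `"gmap"`.
#' @param feature_types GFF3 `type` values treated as top-level alignment
#'   features.
#' @param attr_names names of the identity / coverage / matches /
#'   mismatches attributes; GMAP versions differ, so they are configurable.
#' @return Anchor hit tibble (see [anchor_hits()]) with skip-count
#'   attributes.
#' @export
parse_gmap_gff3 <- function(path, dialect = "gmap",
                            feature_types = c("mRNA", "cDNA_match"),
                            attr_names = list(identity = "identity",
                                              coverage = "coverage",
                                              matches = "matches",
                                              mismatches = "mismatches")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("cannot read GFF3 file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  n_malformed <- 0L
  n_missing_attr <- 0L
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9L) {
      warning("skipping malformed GFF3 line ", i, " (",
              length(f), " fields)", call. = FALSE)
      n_malformed <- n_malformed + 1L
      next
    }
    if (!f[3] %in% feature_types) next
    start <- suppressWarnings(as.numeric(f[4]))
    end <- suppressWarnings(as.numeric(f[5]))
    if (is.na(start) || is.na(end) || start > end) {
      warning("skipping GFF3 line ", i, " with invalid coordinates",
              call. = FALSE)
      n_malformed <- n_malformed + 1L
      next
    }
    attrs <- parse_gff3_attributes(f[9])
    ident <- suppressWarnings(as.numeric(attrs[[attr_names$identity]]))
    covg <- suppressWarnings(as.numeric(attrs[[attr_names$coverage]]))
    if (length(ident) == 0 || is.na(ident) ||
        length(covg) == 0 || is.na(covg)) {
      n_missing_attr <- n_missing_attr + 1L
      next
    }
    matches <- suppressWarnings(as.numeric(attrs[[attr_names$matches]]))
    mismatches <- suppressWarnings(as.numeric(attrs[[attr_names$mismatches]]))
    matches <- if (length(matches) == 1 && !is.na(matches)) matches else NA_real_
    mismatches <- if (length(mismatches) == 1 && !is.na(mismatches)) mismatches else NA_real_
    qid <- attrs[["Name"]] %||% attrs[["ID"]] %||% paste0("feature_", i)
    tgt <- parse_gff3_target(attrs[["Target"]])
    aligned <- if (!is.na(matches) && !is.na(mismatches)) {
      matches + mismatches
    } else {
      end - start + 1
    }
    rows[[i]] <- tibble(
      query_id = qid, query_chrom = NA_character_,
      query_start = tgt$start, query_end = tgt$end,
      target_chrom = f[1], target_start = start - 1, target_end = end,
      strand = if (f[7] == "-") "-" else "+",
      identity = ident / 100, coverage = covg / 100,
      aligned_length = aligned, match_bp = matches, mismatch_bp = mismatches
    )
  }
  hits <- bind_rows(rows)
  if (nrow(hits) == 0) hits <- empty_anchor_hits()
  hits <- validate_anchor_hits(hits)
  attr(hits, "n_skipped_malformed") <- n_malformed
  attr(hits, "n_skipped_missing_attr") <- n_missing_attr
  hits
}

parse_gff3_attributes <- function(s) {
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  parts <- parts[nzchar(parts)]
  kv <- strsplit(parts, "=", fixed = TRUE)
  vals <- lapply(kv, function(x) if (length(x) >= 2) utils::URLdecode(x[2]) else "")
  stats::setNames(vals, vapply(kv, `[`, "", 1))
}

parse_gff3_target <- function(target) {
  if (is.null(target)) return(list(start = NA_real_, end = NA_real_))
  f <- strsplit(target, " ", fixed = TRUE)[[1]]
  if (length(f) < 3) return(list(start = NA_real_, end = NA_real_))
  list(start = suppressWarnings(as.numeric(f[2])) - 1,
       end = suppressWarnings(as.numeric(f[3])))
}

#' Parse 12-column tabular BLAST output into anchor hits
#'
#' Reads BLAST outfmt-6 style tables (qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore). Subject coordinates
#' with `sstart > send` yield strand `"-"` with swapped, half-open
#' coordinates. `pident` is divided by 100; `match_bp` is the alignment
#' length minus the reported mismatches. BLAST does not report query
#' coverage, so `coverage` is `NA`. Rows with the wrong column count are
#' skipped with a warning and counted in attribute `n_skipped`.
#'
#' @param path path to a tabular BLAST file.
#' @return Anchor hit tibble with a `n_skipped` attribute.
#' @export
parse_blast_tab <- function(path) {
  if (!file.exists(path)) stop("cannot read BLAST file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  n_skipped <- 0L
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) != 12L) {
      warning("skipping BLAST line ", i, " (", length(f),
              " columns, expected 12)", call. = FALSE)
      n_skipped <- n_skipped + 1L
      next
    }
    num <- suppressWarnings(as.numeric(f[c(3:5, 7:10)]))
    if (any(is.na(num))) {
      warning("skipping BLAST line ", i, " with non-numeric fields",
              call. = FALSE)
      n_skipped <- n_skipped + 1L
      next
    }
    pident <- num[1]; len <- num[2]; mism <- num[3]
    qstart <- num[4]; qend <- num[5]; sstart <- num[6]; send <- num[7]
    minus <- sstart > send
    rows[[i]] <- tibble(
      query_id = f[1], query_chrom = NA_character_,
      query_start = min(qstart, qend) - 1, query_end = max(qstart, qend),
      target_chrom = f[2],
      target_start = min(sstart, send) - 1, target_end = max(sstart, send),
      strand = if (minus) "-" else "+",
      identity = pident / 100, coverage = NA_real_,
      aligned_length = len, match_bp = len - mism, mismatch_bp = mism
    )
  }
  hits <- bind_rows(rows)
  if (nrow(hits) == 0) hits <- empty_anchor_hits()
  hits <- validate_anchor_hits(hits)
  attr(hits, "n_skipped") <- n_skipped
  hits
}

#' Read a genetic map table
#'
#' Expects a delimited text file with a header naming at least `marker_id`,
#' `linkage_group` and `cM`. Markers are returned ordered by
#' (`linkage_group`, `cM`); co-segregating markers (tied cM within a
#' linkage group) are permitted and flagged in the logical `tie` column.
#'
#' @param path path to a TSV/CSV file.
#' @return Tibble with columns `marker_id`, `linkage_group`, `cM`, `tie`.
#' @export
read_genetic_map <- function(path) {
  x <- read_delim_checked(path, c("marker_id", "linkage_group", "cM"))
  if (any(x$cM < 0)) stop("cM positions must be non-negative", call. = FALSE)
  x <- arrange(x, .data$linkage_group, .data$cM)
  x <- x %>%
    group_by(.data$linkage_group) %>%
    mutate(tie = duplicated(.data$cM) | duplicated(.data$cM, fromLast = TRUE)) %>%
    ungroup()
  x
}

#' Read a QTL table
#'
#' Expects a delimited text file with columns `qtl_id`, `trait`,
#' `linkage_group`, `peak_cM`, `ci_lo_cM`, `ci_hi_cM`, `pve`. Optional
#' per-environment confidence intervals are given as paired columns
#' `ci_lo_<env>` / `ci_hi_<env>` (any suffix) and are collected into the
#' list-column `env_cis` (one two-column `lo`/`hi` data frame per QTL).
#' Validation is fatal on `ci_lo_cM > peak_cM`, `peak_cM > ci_hi_cM` or
#' negative `pve`.
#'
#' @param path path to a TSV/CSV file.
#' @return Tibble of QTL records with an `env_cis` list-column.
#' @export
read_qtl_table <- function(path) {
  req <- c("qtl_id", "trait", "linkage_group", "peak_cM",
           "ci_lo_cM", "ci_hi_cM", "pve")
  x <- read_delim_checked(path, req)
  validate_qtl_table(x)
}

#' @rdname read_qtl_table
#' @param qtls a data frame of QTL records.
#' @export
validate_qtl_table <- function(qtls) {
  x <- as_tibble(qtls)
  bad <- x$ci_lo_cM > x$peak_cM | x$peak_cM > x$ci_hi_cM
  if (any(bad)) {
    stop("QTL record(s) violate ci_lo_cM <= peak_cM <= ci_hi_cM: ",
         paste(x$qtl_id[bad], collapse = ", "), call. = FALSE)
  }
  if (any(x$pve < 0)) stop("pve must be non-negative", call. = FALSE)
  if (!"env_cis" %in% names(x)) {
    lo_cols <- grep("^ci_lo_(?!cM$)", names(x), perl = TRUE, value = TRUE)
    envs <- sub("^ci_lo_", "", lo_cols)
    envs <- envs[paste0("ci_hi_", envs) %in% names(x)]
    x$env_cis <- lapply(seq_len(nrow(x)), function(i) {
      if (length(envs) == 0) return(NULL)
      lo <- as.numeric(x[i, paste0("ci_lo_", envs)])
      hi <- as.numeric(x[i, paste0("ci_hi_", envs)])
      keep <- !is.na(lo) & !is.na(hi)
      if (!any(keep)) return(NULL)
      data.frame(lo = lo[keep], hi = hi[keep])
    })
  }
  x
}

read_delim_checked <- function(path, required) {
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  x <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                         progress = FALSE)
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    stop("file ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  x
}

#' Write / read synteny blocks as BED6
#'
#' Blocks are serialized as BED6 (0-based half-open target interval, block
#' id as name, anchor count as score, orientation as strand). The query
#' side of each block travels in three extra columns (`query_chrom`,
#' `query_start`, `query_end`), keeping the file a valid BED6+3.
#'
#' @param blocks block tibble from [chain_anchors()].
#' @param path output path.
#' @return `write_blocks_bed()` returns `path` invisibly;
#'   `read_blocks_bed()` returns a block tibble.
#' @export
write_blocks_bed <- function(blocks, path) {
  bed <- tibble(
    chrom = blocks$target_chrom,
    start = format_bp(blocks$target_start),
    end = format_bp(blocks$target_end),
    name = blocks$block_id,
    score = blocks$n_anchors,
    strand = blocks$orientation,
    query_chrom = blocks$query_chrom,
    query_start = format_bp(blocks$query_start),
    query_end = format_bp(blocks$query_end)
  )
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' @rdname write_blocks_bed
#' @export
read_blocks_bed <- function(path) {
  cols <- c("target_chrom", "target_start", "target_end", "block_id",
            "n_anchors", "orientation", "query_chrom", "query_start",
            "query_end")
  x <- readr::read_tsv(path, col_names = cols, show_col_types = FALSE,
                       progress = FALSE)
  x[, c("block_id", "query_chrom", "query_start", "query_end",
        "target_chrom", "target_start", "target_end", "orientation",
        "n_anchors")]
}

#' Write / read rearrangement calls as TSV
#'
#' Columns: kind, query_chrom, query_start, query_end, target_chrom,
#' target_start, target_end, span_bp, n_anchors, orientation.
#'
#' @param calls call tibble from [call_rearrangements()].
#' @param path output path.
#' @export
write_calls_tsv <- function(calls, path) {
  out <- calls[, c("kind", "query_chrom", "query_start", "query_end",
                   "target_chrom", "target_start", "target_end",
                   "span_bp", "n_anchors", "orientation")]
  out <- mutate(out, across(c("query_start", "query_end", "target_start",
                              "target_end", "span_bp"), format_bp))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_calls_tsv
#' @export
read_calls_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write / read physical QTL as BED6+3
#'
#' BED6 columns (chrom, CI start, CI end, QTL id, PVE as score, `.`
#' strand) followed by `peak_bp`, `trait` and `species`.
#'
#' @param qtls physical QTL tibble (see [project_qtl()]).
#' @param path output path.
#' @export
write_physical_qtl_bed <- function(qtls, path) {
  bed <- tibble(
    chrom = qtls$chrom,
    start = format_bp(qtls$start_bp),
    end = format_bp(qtls$end_bp),
    name = qtls$qtl_id,
    score = qtls$pve,
    strand = ".",
    peak_bp = format_bp(qtls$peak_bp),
    trait = qtls$trait,
    species = qtls$species
  )
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' @rdname write_physical_qtl_bed
#' @export
read_physical_qtl_bed <- function(path) {
  cols <- c("chrom", "start_bp", "end_bp", "qtl_id", "pve", "strand",
            "peak_bp", "trait", "species")
  x <- readr::read_tsv(path, col_names = cols, show_col_types = FALSE,
                       progress = FALSE)
  x[, c("qtl_id", "trait", "species", "chrom", "start_bp", "end_bp",
        "peak_bp", "pve")]
}

#' Write / read anchor hits as TSV
#'
#' Plain TSV with the full internal column set (see [anchor_hits()]);
#' the format the simulator writes and every workflow can read back.
#'
#' @param hits anchor hit tibble.
#' @param path output path.
#' @export
write_hits_tsv <- function(hits, path) {
  hits <- validate_anchor_hits(hits)
  out <- mutate(hits, across(c("query_start", "query_end", "target_start",
                               "target_end", "aligned_length", "match_bp",
                               "mismatch_bp"), format_bp))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_hits_tsv
#' @export
read_hits_tsv <- function(path) {
  x <- read_delim_checked(path, anchor_hit_columns)
  validate_anchor_hits(x)
}

# integer-style formatting for bp columns so serialized files never carry
# scientific notation and round-trip exactly
format_bp <- function(x) {
  out <- format(x, scientific = FALSE, trim = TRUE)
  out[is.na(x)] <- NA_character_
  out
}
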