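#' Run a complete analysis workflow
#'
#' Chains the pipeline stages into one of four workflows and writes all
#' tabular outputs plus a JSON run manifest to `out_dir`:
#'
#' * `cds-synteny`: parse hits -> quality filter -> best hit per query ->
#'   co-location screen -> chain blocks -> call rearrangements -> dot
#'   plot. Inputs: a hits file (GMAP GFF3, tabular BLAST, or hits TSV).
#' * `map-synteny`: as above, but query coordinates are taken from a
#'   genetic map (cM units on the query axis; span thresholds apply to
#'   the physical target genome only).
#' * `qtl-orthology`: project two species' QTL onto the reference genome,
#'   keep major QTL, pair and cluster them.
#' * `simulate-validate`: simulate a genome pair with known events, run
#'   the synteny pipeline on it, and score calls against the truth.
#'
#' The manifest records the package version, seed, parameters, input
#' checksums, per-stage record counts and output files; identical config
#' and seed reproduce byte-identical tabular outputs.
#'
#' @param config a named list, or path to a YAML file with the same
#'   structure. Top-level keys: `workflow`, `inputs`, `params`, `sim`,
#'   `seed`, `out_dir` (unknown keys are rejected before any stage runs).
#' @param out_dir output directory (overrides `config$out_dir`).
#' @param seed seed (overrides `config$seed`).
#' @return Invisibly, a list with the manifest and the main stage results.
#' @export
run_workflow <- function(config, out_dir = NULL, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- validate_run_config(config)
  if (!is.null(out_dir)) config$out_dir <- out_dir
  if (!is.null(seed)) config$seed <- seed
  if (is.null(config$out_dir)) stop("an output directory is required", call. = FALSE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- switch(config$workflow,
    "cds-synteny" = workflow_synteny(config, map_query = FALSE),
    "map-synteny" = workflow_synteny(config, map_query = TRUE),
    "qtl-orthology" = workflow_qtl_orthology(config),
    "simulate-validate" = workflow_simulate_validate(config)
  )
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(res$manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(res)
}

run_config_keys <- list(
  top = c("workflow", "inputs", "params", "sim", "seed", "out_dir"),
  inputs = c("hits", "hits_format", "map", "anchors", "qtl_a", "qtl_b",
             "traits", "species_a", "species_b"),
  params = c("policy", "tolerance_bp", "max_gap_bp", "max_gap_query",
             "min_anchors", "min_span_bp", "dup_overlap", "mode",
             "pve_threshold", "proximity_bp", "merge_gap_bp", "dotplot")
)

validate_run_config <- function(config) {
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), run_config_keys$top)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  workflows <- c("cds-synteny", "map-synteny", "qtl-orthology",
                 "simulate-validate")
  if (is.null(config$workflow) || !config$workflow %in% workflows) {
    stop("config$workflow must be one of: ",
         paste(workflows, collapse = ", "), call. = FALSE)
  }
  for (blk in c("inputs", "params")) {
    unknown <- setdiff(names(config[[blk]]), run_config_keys[[blk]])
    if (length(unknown) > 0) {
      stop("unknown ", blk, " key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
  }
  path_keys <- c("hits", "map", "anchors", "qtl_a", "qtl_b", "traits")
  for (p in config$inputs[intersect(names(config$inputs), path_keys)]) {
    if (is.character(p) && !file.exists(p)) {
      stop("input path does not exist: ", p, call. = FALSE)
    }
  }
  config
}

workflow_params <- function(config, map_query = FALSE) {
  p <- config$params %||% list()
  chain_params(
    max_gap_bp = p$max_gap_bp %||% 3e6,
    min_anchors = p$min_anchors %||% 3,
    min_span_bp = p$min_span_bp %||% 5e5,
    max_gap_query = p$max_gap_query %||%
      (if (map_query) 20 else p$max_gap_bp %||% 3e6),
    dup_overlap = p$dup_overlap %||% 0.5
  )
}

resolve_policy <- function(p) {
  if (is.null(p)) return(policy_presets("tocds_peg"))
  if (is.character(p)) return(policy_presets(p))
  do.call(filter_policy, p)
}

read_hits_any <- function(path, format = NULL) {
  format <- format %||%
    (if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "tsv")
  switch(format,
    gff3 = parse_gmap_gff3(path),
    blast = parse_blast_tab(path),
    tsv = read_hits_tsv(path),
    stop("unknown hits format: ", format, call. = FALSE)
  )
}

input_checksums <- function(config) {
  paths <- Filter(function(p) is.character(p) && file.exists(p),
                  config$inputs)
  if (length(paths) == 0) return(list())
  lapply(paths, function(p) unname(tools::md5sum(p)))
}

synteny_stages <- function(hits, policy, params, tolerance_bp, out_dir,
                           dotplot_file = NULL) {
  filtered <- filter_hits(hits, policy)
  unique_hits <- select_best_hits(filtered)
  groups <- find_colocated_queries(unique_hits, tolerance_bp = tolerance_bp)
  orthology <- assign_chromosome_orthology(unique_hits)
  blocks <- chain_anchors(unique_hits, params)
  calls <- call_rearrangements(blocks, orthology, params, hits = unique_hits)
  write_hits_tsv(unique_hits, file.path(out_dir, "hits_unique.tsv"))
  write_blocks_bed(blocks, file.path(out_dir, "blocks.bed"))
  write_calls_tsv(calls, file.path(out_dir, "calls.tsv"))
  if (nrow(groups) > 0) {
    flat <- mutate(groups,
                   member_query_ids = vapply(.data$member_query_ids,
                                             paste, "", collapse = ","))
    readr::write_tsv(flat, file.path(out_dir, "colocated_groups.tsv"),
                     progress = FALSE)
  }
  dp <- dotplot(unique_hits, blocks = blocks, calls = calls,
                file = dotplot_file,
                tsv = file.path(out_dir, "dotplot_points.tsv"))
  list(
    filtered = filtered, unique_hits = unique_hits, groups = groups,
    orthology = orthology, blocks = blocks, calls = calls, dotplot = dp,
    counts = list(
      input_hits = nrow(hits), filtered = nrow(filtered),
      unique = nrow(unique_hits),
      colocated_group_members = sum(groups$n_members),
      same_chromosome_fraction = orthology$same_chromosome_fraction,
      blocks = nrow(blocks), calls = nrow(calls)
    )
  )
}

workflow_synteny <- function(config, map_query = FALSE) {
  inp <- config$inputs
  if (is.null(inp$hits)) stop("inputs$hits is required", call. = FALSE)
  hits <- read_hits_any(inp$hits, inp$hits_format)
  n_parsed <- nrow(hits)
  if (map_query) {
    if (is.null(inp$map)) stop("inputs$map is required for map-synteny",
                               call. = FALSE)
    gmap <- read_genetic_map(inp$map)
    hits <- hits %>%
      select(-"query_chrom", -"query_start", -"query_end") %>%
      dplyr::inner_join(
        tibble(query_id = gmap$marker_id, query_chrom = gmap$linkage_group,
               query_start = gmap$cM, query_end = gmap$cM + 1e-9),
        by = "query_id") %>%
      select(all_of(anchor_hit_columns))
  }
  p <- config$params %||% list()
  params <- workflow_params(config, map_query)
  res <- synteny_stages(
    hits, resolve_policy(p$policy), params,
    tolerance_bp = p$tolerance_bp %||% 25,
    out_dir = config$out_dir,
    dotplot_file = if (isTRUE(p$dotplot)) file.path(config$out_dir, "dotplot.png")
  )
  res$manifest <- list(
    workflow = config$workflow,
    package_version = as.character(utils::packageVersion("synqtl")),
    seed = config$seed, parameters = c(p, unclass(params)),
    inputs = input_checksums(config), counts = res$counts,
    outputs = c("hits_unique.tsv", "blocks.bed", "calls.tsv",
                "dotplot_points.tsv")
  )
  res
}

workflow_qtl_orthology <- function(config) {
  inp <- config$inputs
  for (f in c("anchors", "qtl_a", "qtl_b")) {
    if (is.null(inp[[f]])) stop("inputs$", f, " is required", call. = FALSE)
  }
  anchors <- read_delim_checked(inp$anchors,
                                c("marker_id", "linkage_group", "cM",
                                  "target_chrom", "target_bp"))
  qa <- read_qtl_table(inp$qtl_a)
  qb <- read_qtl_table(inp$qtl_b)
  traits <- if (is.null(inp$traits)) default_trait_groups() else
    read_trait_equivalence(inp$traits)
  p <- config$params %||% list()
  mode <- p$mode %||% "local_rate"
  pa <- project_qtl_table(qa, anchors, mode = mode,
                          species = inp$species_a %||% "speciesA")
  pb <- project_qtl_table(qb, anchors, mode = mode,
                          species = inp$species_b %||% "speciesB")
  ok_a <- filter_major(pa[pa$status == "ok", ], p$pve_threshold %||% 10)
  ok_b <- filter_major(pb[pb$status == "ok", ], p$pve_threshold %||% 10)
  pairs <- find_orthologous_pairs(ok_a, ok_b, traits,
                                  proximity_bp = p$proximity_bp %||% 1e6)
  clusters <- cluster_qtl(bind_rows(ok_a, ok_b),
                          merge_gap_bp = p$merge_gap_bp %||% 1e6)
  write_physical_qtl_bed(pa[pa$status == "ok", ],
                         file.path(config$out_dir, "physical_qtl_a.bed"))
  write_physical_qtl_bed(pb[pb$status == "ok", ],
                         file.path(config$out_dir, "physical_qtl_b.bed"))
  readr::write_tsv(pairs, file.path(config$out_dir, "orthologous_pairs.tsv"),
                   progress = FALSE)
  write_clusters_tsv(clusters, file.path(config$out_dir, "clusters.tsv"))
  counts <- list(
    qtl_a = nrow(qa), qtl_b = nrow(qb),
    projected_a = sum(pa$status == "ok"), projected_b = sum(pb$status == "ok"),
    major_a = nrow(ok_a), major_b = nrow(ok_b),
    pairs = nrow(pairs), clusters = nrow(clusters),
    orthologous_clusters = sum(clusters$orthologous),
    single_species_clusters = sum(!clusters$orthologous)
  )
  list(projected_a = pa, projected_b = pb, pairs = pairs,
       clusters = clusters, counts = counts,
       manifest = list(
         workflow = config$workflow,
         package_version = as.character(utils::packageVersion("synqtl")),
         seed = config$seed, parameters = p,
         inputs = input_checksums(config), counts = counts,
         outputs = c("physical_qtl_a.bed", "physical_qtl_b.bed",
                     "orthologous_pairs.tsv", "clusters.tsv")
       ))
}

workflow_simulate_validate <- function(config) {
  sim_args <- config$sim %||% list()
  if (!is.null(config$seed)) sim_args$seed <- config$seed
  cfg <- do.call(sim_config, sim_args)
  sim <- simulate_genome_pair(cfg)
  write_hits_tsv(sim$hits, file.path(config$out_dir, "sim_hits.tsv"))
  readr::write_tsv(
    mutate(sim$truth, across(c("query_start", "query_end", "target_start",
                               "target_end"), format_bp)),
    file.path(config$out_dir, "sim_truth.tsv"), progress = FALSE)
  p <- config$params %||% list()
  params <- workflow_params(config)
  res <- synteny_stages(sim$hits, resolve_policy(p$policy), params,
                        tolerance_bp = p$tolerance_bp %||% 25,
                        out_dir = config$out_dir)
  score <- score_rearrangement_calls(res$calls, sim$truth)
  res$score <- score
  res$sim <- sim
  res$manifest <- list(
    workflow = config$workflow,
    package_version = as.character(utils::packageVersion("synqtl")),
    seed = cfg$seed, parameters = c(p, unclass(params)),
    counts = c(res$counts, sim$counts),
    validation = list(recall = score$recall, precision = score$precision,
                      n_truth = score$n_truth, n_calls = score$n_calls),
    outputs = c("sim_hits.tsv", "sim_truth.tsv", "hits_unique.tsv",
                "blocks.bed", "calls.tsv", "dotplot_points.tsv")
  )
  res
}
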