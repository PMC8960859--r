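# Orchestration: default configuration, per-stage runners over files, and
# the end-to-end driver that writes a run manifest. Results go to files;
# progress messages go to stderr.

#' Default pipeline configuration
#'
#' Every threshold defaults to the published value: the five annotation
#' keywords; Pfam pool rule (score > 0, >= 5 occurrences); clustering
#' identity 0.45 (proteases) / 0.6 (precursors) with size cutoffs 100 / 10;
#' genomic filters rho > 0.3, pAdj < 1e-5, I >= 10 with pooled BH;
#' co-expression filters rho > 0.4, pAdj < 0.05 combined across all strains;
#' 10-kb clustered-protease window. `simulate = TRUE` generates all inputs
#' from [sim_config()] (overridable via the `sim` sublist); otherwise input
#' paths must be supplied.
#'
#' @param ... Named overrides of any default, e.g. `min_size_prot = 5` or
#'   `sim = list(n_genera = 4)`.
#' @return A named list.
#' @export
default_config <- function(...) {
  cfg <- list(
    simulate = TRUE,
    seed = 1L,
    sim = list(),
    keywords = lan_keywords(),
    min_score = 0,
    min_occurrences = 5,
    window = 10000,
    min_identity_pre = 0.6,
    min_identity_prot = 0.45,
    min_size_pre = 10,
    min_size_prot = 100,
    bh_scope = "pooled",
    rho_min = 0.3,
    padj_max = 1e-5,
    min_I = 10,
    coexpr_rho_min = 0.4,
    coexpr_padj_max = 0.05,
    combine = "all",
    # input paths, used when simulate = FALSE
    annotation = NULL, domain_hits = NULL,
    precursor_fasta = NULL, protease_fasta = NULL,
    genomes = NULL, genomic_assignments = NULL, members = NULL,
    strain_counts = NULL, gene_assignments = NULL)
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0) {
    stop_lan("unknown configuration field(s): %s", paste(unknown, collapse = ", "))
  }
  cfg[names(overrides)] <- overrides
  cfg
}

read_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_lan("config must be a list or a YAML path")
  do.call(default_config, config)
}

stage_msg <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

require_input <- function(config, field, stage) {
  path <- config[[field]]
  if (is.null(path) || !file.exists(path)) {
    stop_lan("stage '%s' requires input '%s'%s", stage, field,
             if (is.null(path)) " (not configured)"
             else sprintf(" (missing file: %s)", path))
  }
  path
}

write_sim_inputs <- function(config, dir) {
  sim <- do.call(sim_config, c(config$sim,
                               if (is.null(config$sim$seed))
                                 list(seed = config$seed)))
  inputs <- file.path(dir, "inputs")
  dir.create(inputs, recursive = TRUE, showWarnings = FALSE)
  ann <- simulate_annotation(sim)
  write_annotation(ann$annotation, file.path(inputs, "annotation.tsv"))
  write_domain_hits(ann$hits, file.path(inputs, "domain_hits.tsv"))
  readr::write_tsv(ann$truth, file.path(inputs, "bgc_truth.tsv"))
  seqs <- simulate_sequences(sim)
  write_sequences(seqs$precursors, file.path(inputs, "precursors.fasta"))
  write_sequences(seqs$proteases, file.path(inputs, "proteases.fasta"))
  readr::write_tsv(seqs$truth, file.path(inputs, "family_truth.tsv"))
  gen <- simulate_genomic(sim)
  readr::write_tsv(gen$genomes, file.path(inputs, "genomes.tsv"), na = ".")
  write_group_assignments(gen$assignments,
                          file.path(inputs, "genomic_assignments.tsv"))
  readr::write_tsv(gen$members, file.path(inputs, "members.tsv"))
  readr::write_tsv(gen$truth, file.path(inputs, "pair_truth.tsv"))
  trx <- simulate_transcriptome(sim, gen$truth)
  strain_paths <- character()
  for (nm in names(trx$strains)) {
    p <- file.path(inputs, sprintf("counts_%s.tsv", nm))
    readr::write_tsv(trx$strains[[nm]], p)
    strain_paths[nm] <- p
  }
  write_group_assignments(trx$gene_groups,
                          file.path(inputs, "gene_assignments.tsv"))
  config$annotation <- file.path(inputs, "annotation.tsv")
  config$domain_hits <- file.path(inputs, "domain_hits.tsv")
  config$precursor_fasta <- file.path(inputs, "precursors.fasta")
  config$protease_fasta <- file.path(inputs, "proteases.fasta")
  config$genomes <- file.path(inputs, "genomes.tsv")
  config$genomic_assignments <- file.path(inputs, "genomic_assignments.tsv")
  config$members <- file.path(inputs, "members.tsv")
  config$strain_counts <- as.list(strain_paths)
  config$gene_assignments <- file.path(inputs, "gene_assignments.tsv")
  config
}

#' Run the mining stage over files
#'
#' Reads the annotation and domain-hit tables, selects BGC proteases by
#' keyword, builds the Pfam pool, harvests genome-wide candidate proteases
#' and flags each BGC for a clustered protease within the window. Writes
#' `pfam_pool.tsv`, `selected_proteases.tsv` and `bgc_flags.tsv`.
#'
#' @param config A configuration list (see [default_config()]).
#' @param out_dir Output directory.
#' @return Named list of output paths, invisibly used by [run_pipeline()].
#' @export
run_mine <- function(config, out_dir) {
  config <- read_config(config)
  ann <- read_annotation(require_input(config, "annotation", "mine"))
  hits <- read_domain_hits(require_input(config, "domain_hits", "mine"))
  bgc_prot <- select_bgc_proteases(ann$proteins, config$keywords)
  pool <- build_pfam_pool(dplyr::semi_join(hits, bgc_prot, by = "protein_id"),
                          min_score = config$min_score,
                          min_occurrences = config$min_occurrences)
  selected <- select_genome_proteases(hits, pool, min_score = config$min_score)
  flags <- flag_clustered_proteases(ann$bgcs, ann$proteins,
                                    selected$protein_id,
                                    window = config$window)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(pfam_pool = file.path(out_dir, "pfam_pool.tsv"),
                selected_proteases = file.path(out_dir, "selected_proteases.tsv"),
                bgc_flags = file.path(out_dir, "bgc_flags.tsv"))
  readr::write_tsv(as_tibble(pool), paths$pfam_pool)
  readr::write_tsv(selected, paths$selected_proteases)
  readr::write_tsv(flags, paths$bgc_flags)
  stage_msg("mine", "pool %d Pfams; %d candidate proteases; %d/%d BGCs with clustered protease",
            nrow(pool), nrow(selected), sum(flags$clustered_protease),
            nrow(flags))
  invisible(paths)
}

#' Run the clustering stage over files
#'
#' Clusters precursor and protease FASTA files at their identity thresholds,
#' filters by group size and assigns size-ranked labels. Writes
#' `precursor_groups.tsv` and `protease_groups.tsv`.
#'
#' @inheritParams run_mine
#' @export
run_cluster <- function(config, out_dir) {
  config <- read_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  for (side in c("precursor", "protease")) {
    fasta <- require_input(config,
                           if (side == "precursor") "precursor_fasta"
                           else "protease_fasta", "cluster")
    seqs <- read_sequences(fasta)
    min_id <- if (side == "precursor") config$min_identity_pre
              else config$min_identity_prot
    min_size <- if (side == "precursor") config$min_size_pre
                else config$min_size_prot
    groups <- cluster_members(seqs, kind = side, min_identity = min_id) |>
      filter_groups(min_size = min_size) |>
      name_groups()
    out <- file.path(out_dir, sprintf("%s_groups.tsv", side))
    write_group_assignments(
      dplyr::select(groups, dplyr::all_of(c("member_id", "group_id",
                                            "group_kind"))), out)
    paths[[sprintf("%s_groups", side)]] <- out
    stage_msg("cluster", "%s: %d members in %d groups (min identity %.2f, min size %d)",
              side, nrow(groups), length(unique(groups$group_id)), min_id,
              min_size)
  }
  invisible(paths)
}

#' Run the correlation-network stage over files
#'
#' Builds per-side count matrices from the genomic group assignments,
#' correlates precursor and protease groups within each genus, adjusts
#' p-values, applies the prioritization filters and writes `edges.tsv`,
#' `filtered_edges.tsv`, `volcano.tsv`, `network.graphml` and the count
#' matrices.
#'
#' @inheritParams run_mine
#' @export
run_network <- function(config, out_dir) {
  config <- read_config(config)
  genomes <- readr::read_tsv(require_input(config, "genomes", "network"),
                             na = ".", show_col_types = FALSE)
  assignments <- read_group_assignments(
    require_input(config, "genomic_assignments", "network"))
  members <- readr::read_tsv(require_input(config, "members", "network"),
                             show_col_types = FALSE)
  pre_counts <- build_count_matrix(
    dplyr::filter(assignments, .data$group_kind == "precursor"),
    members, genomes)
  prot_counts <- build_count_matrix(
    dplyr::filter(assignments, .data$group_kind == "protease"),
    members, genomes)
  edges <- correlate_groups(pre_counts, prot_counts, genomes,
                            bh_scope = config$bh_scope)
  kept <- filter_edges(edges, rho_min = config$rho_min,
                       padj_max = config$padj_max, min_I = config$min_I)
  sizes <- assignments |>
    dplyr::count(.data$group_id, name = "size") |>
    dplyr::rename(node = "group_id")
  graph <- assemble_network(kept, node_sizes = sizes)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(pre_counts = file.path(out_dir, "pre_counts.tsv"),
                prot_counts = file.path(out_dir, "prot_counts.tsv"),
                edges = file.path(out_dir, "edges.tsv"),
                filtered_edges = file.path(out_dir, "filtered_edges.tsv"),
                volcano = file.path(out_dir, "volcano.tsv"),
                graphml = file.path(out_dir, "network.graphml"))
  write_count_matrix(pre_counts, paths$pre_counts)
  write_count_matrix(prot_counts, paths$prot_counts)
  write_edges(tidy(edges), paths$edges)
  write_edges(tidy(kept), paths$filtered_edges)
  readr::write_tsv(volcano_table(edges), paths$volcano)
  write_graphml(graph, paths$graphml)
  stage_msg("network", "%d tests, %d prioritized edges (rho > %g, pAdj < %g, I >= %d)",
            nrow(edges), nrow(kept), config$rho_min, config$padj_max,
            config$min_I)
  invisible(paths)
}

#' Run the co-expression stage over files
#'
#' Computes gene TPM per strain, sums it into group TPM, trims to the groups
#' of the genomic network, derives co-expression edges per strain and
#' combines them across strains. Writes per-strain edge tables and
#' `coexpression_edges.tsv`.
#'
#' @inheritParams run_mine
#' @param network_edges Path to the filtered genomic edge table (defaults to
#'   the one written by [run_network()] under the run directory).
#' @export
run_coexpress <- function(config, out_dir, network_edges = NULL) {
  config <- read_config(config)
  network_edges <- network_edges %||%
    file.path(dirname(out_dir), "network", "filtered_edges.tsv")
  if (!file.exists(network_edges)) {
    stop_lan("stage 'coexpress' requires the genomic network edge table (missing file: %s); run the network stage first",
             network_edges)
  }
  net <- read_edges(network_edges)
  gene_assign <- read_group_assignments(
    require_input(config, "gene_assignments", "coexpress"))
  strain_paths <- config$strain_counts
  if (is.null(strain_paths) || length(strain_paths) == 0) {
    stop_lan("stage 'coexpress' requires input 'strain_counts'")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  per_strain <- list()
  paths <- list()
  for (nm in names(strain_paths)) {
    counts <- readr::read_tsv(strain_paths[[nm]], show_col_types = FALSE)
    expr <- tpm(counts)
    grp <- group_tpm(expr, gene_assign)
    grp <- trim_to_network(grp, net)
    per_strain[[nm]] <- coexpression_edges(grp,
                                           rho_min = config$coexpr_rho_min,
                                           padj_max = config$coexpr_padj_max)
    p <- file.path(out_dir, sprintf("coexpression_%s.tsv", nm))
    readr::write_tsv(per_strain[[nm]], p)
    paths[[sprintf("coexpression_%s", nm)]] <- p
  }
  combined <- combine_strains(per_strain, mode = config$combine)
  paths$coexpression_edges <- file.path(out_dir, "coexpression_edges.tsv")
  readr::write_tsv(combined, paths$coexpression_edges)
  stage_msg("coexpress", "%d strain(s); %d combined co-expression edge(s) (mode %s)",
            length(per_strain), nrow(combined), config$combine)
  invisible(paths)
}

#' Run the full workflow and write a manifest
#'
#' Executes mine, cluster, network, coexpress and the evidence intersection
#' in order under `out_dir`, generating all inputs from the synthetic model
#' when `config$simulate` is `TRUE`. A `manifest.json` records the package
#' version, seed, full configuration, per-stage output row counts and the
#' MD5 of every result file; rerunning with an identical configuration
#' produces byte-identical results. Any stage failure aborts with the stage
#' name attached.
#'
#' @param config A configuration list or YAML path (see [default_config()]).
#' @param out_dir Output directory for all artifacts.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- read_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (isTRUE(config$simulate)) {
    config <- write_sim_inputs(config, out_dir)
  }
  stages <- list()
  run_stage <- function(name, fun, ...) {
    paths <- tryCatch(fun(config, file.path(out_dir, name), ...),
                      error = function(e) {
                        stop_lan("stage '%s' failed: %s", name,
                                 conditionMessage(e))
                      })
    stages[[name]] <<- paths
    paths
  }
  run_stage("mine", run_mine)
  run_stage("cluster", run_cluster)
  net_paths <- run_stage("network", run_network)
  coex_paths <- run_stage("coexpress", run_coexpress,
                          network_edges = net_paths$filtered_edges)
  # evidence intersection
  candidates <- intersect_evidence(read_edges(net_paths$filtered_edges),
                                   read_edges_loose(coex_paths$coexpression_edges))
  inter_dir <- file.path(out_dir, "intersect")
  dir.create(inter_dir, showWarnings = FALSE)
  cand_path <- file.path(inter_dir, "candidates.tsv")
  readr::write_tsv(candidates, cand_path)
  stages$intersect <- list(candidates = cand_path)
  stage_msg("intersect", "%d candidate pair(s) supported by both evidence types",
            nrow(dplyr::distinct(candidates, .data$pre_group,
                                 .data$prot_group)))
  # store paths relative to the run directory so manifests of identical runs
  # are byte-identical wherever they land
  relativize <- function(x) {
    if (is.list(x)) return(purrr::map(x, relativize))
    if (is.character(x) && length(x) == 1 && file.exists(x)) {
      root <- paste0(normalizePath(out_dir, winslash = "/"), "/")
      return(sub(root, "", normalizePath(x, winslash = "/"), fixed = TRUE))
    }
    x
  }
  manifest <- list(
    package = "lanticor",
    version = as.character(utils::packageVersion("lanticor")),
    seed = config$seed,
    config = relativize(config),
    stages = purrr::map(stages, function(paths)
      purrr::map(paths, function(p) list(
        file = basename(p),
        rows = if (grepl("\\.tsv$", p))
          nrow(readr::read_tsv(p, show_col_types = FALSE, progress = FALSE))
        else NA,
        md5 = unname(tools::md5sum(p))))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}

# combined co-expression tables carry min_rho/max_p_adj rather than rho/p_adj
read_edges_loose <- function(path) {
  readr::read_tsv(path, na = "NA", show_col_types = FALSE)
}
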