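# Transcriptomic refinement: TPM from gene counts, group-summed TPM,
# trimming to the genomic network, co-expression edges, multi-strain
# combination and the genomic/transcriptomic evidence intersection.

#' Transcripts per million from gene counts
#'
#' Computes TPM for every sample in a long gene-count table:
#' `rate = count / length`, `TPM = 1e6 * rate / sum(rate)` within the
#' sample. A sample with all-zero counts yields an all-zero row; any other
#' row sums to 1e6 up to numerical tolerance.
#'
#' @param counts Long tibble with columns `sample_id`, `gene_id`, `count`
#'   (non-negative, fractional allowed for multi-mapped reads) and `length`
#'   (positive, nucleotides).
#' @return A wide expression tibble: `sample_id` plus one TPM column per
#'   gene, genes in sorted order.
#' @export
tpm <- function(counts) {
  check_columns(counts, c("sample_id", "gene_id", "count", "length"),
                "gene count table")
  if (any(is.na(counts$count) | counts$count < 0)) {
    stop_lan("counts must be non-negative")
  }
  if (any(is.na(counts$length) | counts$length <= 0)) {
    stop_lan("gene lengths must be positive")
  }
  dup <- counts |> dplyr::count(.data$sample_id, .data$gene_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop_lan("more than one row per (sample, gene), e.g. %s / %s",
             dup$sample_id[1], dup$gene_id[1])
  }
  counts |>
    dplyr::mutate(rate = .data$count / .data$length) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(tpm = if (sum(.data$rate) > 0)
      1e6 * .data$rate / sum(.data$rate) else 0) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::all_of(c("sample_id", "gene_id", "tpm"))) |>
    dplyr::arrange(.data$sample_id, .data$gene_id) |>
    tidyr::pivot_wider(names_from = "gene_id", values_from = "tpm",
                       values_fill = 0)
}

#' Sum gene-level TPM into group-level TPM
#'
#' TPM of genes belonging to the same precursor or protease group are summed
#' per sample, producing the samples-by-groups matrix used for co-expression
#' analysis. Genes without an assignment are ignored; empty groups produce
#' no column.
#'
#' @param expression Wide gene-level TPM tibble from [tpm()].
#' @param assignments Assignment tibble mapping `member_id` (gene id) to
#'   `group_id`.
#' @return A wide tibble: `sample_id` plus one column per group.
#' @export
group_tpm <- function(expression, assignments) {
  check_columns(expression, "sample_id", "expression matrix")
  check_columns(assignments, c("member_id", "group_id"), "assignment table")
  long <- tidyr::pivot_longer(expression, -"sample_id",
                              names_to = "member_id", values_to = "tpm")
  long |>
    dplyr::inner_join(
      dplyr::select(assignments, dplyr::all_of(c("member_id", "group_id"))),
      by = "member_id") |>
    dplyr::group_by(.data$sample_id, .data$group_id) |>
    dplyr::summarise(tpm = sum(.data$tpm), .groups = "drop") |>
    dplyr::arrange(.data$sample_id, .data$group_id) |>
    tidyr::pivot_wider(names_from = "group_id", values_from = "tpm",
                       values_fill = 0)
}

#' Trim a group TPM matrix to the groups of the genomic network
#'
#' Restricts the columns of a samples-by-groups matrix to groups that appear
#' in at least one edge of the genomic correlation network. No overlap at
#' all is an error — the refinement would be impossible, which signals
#' mismatched inputs.
#'
#' @param expr_groups Wide group-level TPM tibble from [group_tpm()].
#' @param edges Genomic correlation edges (see [correlate_groups()]).
#' @return The trimmed expression tibble.
#' @export
trim_to_network <- function(expr_groups, edges) {
  check_columns(expr_groups, "sample_id", "expression matrix")
  check_columns(edges, c("pre_group", "prot_group"), "edge table")
  keep <- intersect(names(expr_groups),
                    union(edges$pre_group, edges$prot_group))
  if (length(keep) == 0) {
    stop_lan("no expression group overlaps the correlation network; refinement impossible")
  }
  dplyr::select(expr_groups, dplyr::all_of(c("sample_id", sort(keep))))
}

#' Co-expression edges between precursor and protease groups
#'
#' For every (precursor group, protease group) column pair — recognized by
#' the `Pre_` / `Prot_` label prefixes — computes the Spearman coefficient
#' of the two TPM profiles across samples, the one-sided upper-tail p-value,
#' and a BH adjustment over this test family. With `filter = TRUE` keeps
#' pairs with `rho` strictly above `rho_min` and adjusted p strictly below
#' `padj_max` (published defaults 0.4 and 0.05).
#'
#' @param expr_groups Wide group-level TPM tibble with `Pre_*` and `Prot_*`
#'   columns; at least 3 samples.
#' @param rho_min,padj_max Filter thresholds (defaults 0.4, 0.05).
#' @param filter Keep only passing pairs (default `TRUE`); otherwise return
#'   all tested pairs.
#' @return A tibble with `pre_group`, `prot_group`, `rho`, `p`, `p_adj`,
#'   `n_samples`.
#' @export
coexpression_edges <- function(expr_groups, rho_min = 0.4, padj_max = 0.05,
                               filter = TRUE) {
  check_columns(expr_groups, "sample_id", "expression matrix")
  n <- nrow(expr_groups)
  if (n < 3) stop_lan("co-expression analysis needs at least 3 samples (got %d)", n)
  cols <- setdiff(names(expr_groups), "sample_id")
  pre <- sort(cols[startsWith(cols, "Pre_")])
  prot <- sort(cols[startsWith(cols, "Prot_")])
  if (length(pre) == 0 || length(prot) == 0) {
    stop_lan("expression matrix must contain both Pre_* and Prot_* columns")
  }
  a <- rank_columns(as.matrix(expr_groups[pre]))
  b <- rank_columns(as.matrix(expr_groups[prot]))
  rho <- suppressWarnings(stats::cor(a, b))
  rho[attr(a, "constant"), ] <- NA_real_
  rho[, attr(b, "constant")] <- NA_real_
  out <- tibble(
    pre_group = rep(pre, times = length(prot)),
    prot_group = rep(prot, each = length(pre)),
    rho = as.vector(rho),
    p = one_sided_p(as.vector(rho), n),
    n_samples = n)
  out$p_adj <- NA_real_
  ok <- !is.na(out$p)
  if (any(ok)) out$p_adj[ok] <- bh_adjust(out$p[ok])
  out <- dplyr::select(out, dplyr::all_of(c("pre_group", "prot_group", "rho",
                                            "p", "p_adj", "n_samples")))
  if (filter) {
    out <- dplyr::filter(out, !is.na(.data$rho), .data$rho > rho_min,
                         .data$p_adj < padj_max)
  }
  out
}

#' Combine co-expression edges across strains
#'
#' With `mode = "all"` (default) keeps only (precursor group, protease
#' group) pairs present in the result of every strain — the reading of
#' "correlations presented in the results of all strains"; `mode = "any"`
#' takes the union.
#'
#' @param per_strain A (possibly named) list of co-expression edge tibbles,
#'   one per strain; at least one.
#' @param mode `"all"` (intersection) or `"any"` (union).
#' @return A tibble keyed by `pre_group`, `prot_group` with `n_strains` (how
#'   many strains showed the edge), `min_rho` and `max_p_adj` across the
#'   strains that did.
#' @export
combine_strains <- function(per_strain, mode = c("all", "any")) {
  mode <- match.arg(mode)
  if (!is.list(per_strain) || length(per_strain) == 0 ||
      is.data.frame(per_strain)) {
    stop_lan("per_strain must be a non-empty list of edge tibbles")
  }
  purrr::walk(per_strain, check_columns,
              required = c("pre_group", "prot_group", "rho", "p_adj"),
              what = "co-expression edge table")
  n_strains <- length(per_strain)
  pooled <- dplyr::bind_rows(per_strain, .id = "strain")
  combined <- pooled |>
    dplyr::distinct(.data$strain, .data$pre_group, .data$prot_group,
                    .data$rho, .data$p_adj) |>
    dplyr::group_by(.data$pre_group, .data$prot_group) |>
    dplyr::summarise(n_strains = dplyr::n_distinct(.data$strain),
                     min_rho = min(.data$rho),
                     max_p_adj = max(.data$p_adj), .groups = "drop")
  if (mode == "all") {
    combined <- dplyr::filter(combined, .data$n_strains == !!n_strains)
  }
  dplyr::arrange(combined, .data$pre_group, .data$prot_group)
}

#' Intersect genomic and co-expression evidence
#'
#' Candidate protease groups are the (precursor group, protease group)
#' pairs supported by both the genomic correlation network and the
#' co-expression analysis. Attributes from both sides are retained
#' (suffixes `.genomic` and `.coexpr` on clashing names).
#'
#' @param genomic_edges Filtered genomic edges (see [filter_edges()]); may
#'   contain one row per genus for a pair.
#' @param coexpr_edges Combined co-expression edges (see
#'   [combine_strains()] or [coexpression_edges()]).
#' @return A tibble of candidate pairs, a subset of both inputs.
#' @export
intersect_evidence <- function(genomic_edges, coexpr_edges) {
  check_columns(genomic_edges, c("pre_group", "prot_group"), "genomic edges")
  check_columns(coexpr_edges, c("pre_group", "prot_group"),
                "co-expression edges")
  dplyr::inner_join(genomic_edges, coexpr_edges,
                    by = c("pre_group", "prot_group"),
                    suffix = c(".genomic", ".coexpr"),
                    relationship = "many-to-many") |>
    dplyr::arrange(.data$pre_group, .data$prot_group)
}
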