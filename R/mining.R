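# Mining of candidate lanthipeptide proteases: keyword selection of
# BGC-associated proteases, construction of the Pfam domain pool, genome-wide
# harvest of pool-domain proteins, and the 10-kb clustered-protease check
# around the LanC-like anchor gene.

#' Default protease annotation keywords
#'
#' The five keywords used to pull protease genes out of BGC annotations:
#' peptidase, proteinase, protease, hydrolase and beta-lactamase. Matching is
#' a case-insensitive substring test on the product field.
#'
#' @return A character vector of length five.
#' @export
lan_keywords <- function() {
  c("peptidase", "proteinase", "protease", "hydrolase", "beta-lactamase")
}

#' Select BGC-associated proteases by annotation keyword
#'
#' Restricts a protein table to proteins that (i) belong to a BGC
#' (`bgc_id` set) and (ii) whose `product` annotation contains at least one
#' keyword as a case-insensitive substring.
#'
#' @param proteins A protein tibble (see [read_annotation()]).
#' @param keywords Character vector of keywords; defaults to [lan_keywords()].
#'   An empty keyword list is an error (it would silently select nothing).
#' @return The selected subset of `proteins`, as a tibble.
#' @export
select_bgc_proteases <- function(proteins, keywords = lan_keywords()) {
  check_columns(proteins, c("protein_id", "product", "bgc_id"), "protein table")
  if (length(keywords) == 0) {
    stop_lan("keyword list is empty; refusing to select nothing")
  }
  pattern <- paste(
    vapply(keywords, function(k) stringr::str_escape(k), character(1)),
    collapse = "|")
  proteins |>
    dplyr::filter(!is.na(.data$bgc_id),
                  stringr::str_detect(.data$product,
                                      stringr::regex(pattern, ignore_case = TRUE)))
}

#' Build the protease Pfam domain pool
#'
#' From domain hits on BGC-associated proteases, keeps every Pfam accession
#' with at least `min_occurrences` hits scoring strictly above `min_score`.
#' The published analysis then manually curated the pool; curation is modeled
#' as optional allow/deny lists (`include` forces accessions in, `exclude`
#' removes them) with no invented heuristic.
#'
#' @param hits Domain-hit tibble (`protein_id`, `pfam_acc`, `score`)
#'   restricted to BGC proteases (see [select_bgc_proteases()]).
#' @param min_score Hits must score strictly above this (default 0).
#' @param min_occurrences Minimum number of qualifying hits per accession
#'   (default 5).
#' @param include,exclude Optional character vectors of accessions to force
#'   into / drop from the pool after the automatic rule.
#' @return A tibble of class `lan_pfam_pool` with columns `pfam_acc` and
#'   `n_occurrences`, sorted by decreasing occurrence count.
#' @export
build_pfam_pool <- function(hits, min_score = 0, min_occurrences = 5,
                            include = character(), exclude = character()) {
  check_columns(hits, c("protein_id", "pfam_acc", "score"), "domain-hit table")
  pool <- hits |>
    dplyr::filter(.data$score > min_score) |>
    dplyr::count(.data$pfam_acc, name = "n_occurrences") |>
    dplyr::filter(.data$n_occurrences >= min_occurrences)
  forced <- setdiff(include, pool$pfam_acc)
  if (length(forced) > 0) {
    extra <- hits |>
      dplyr::filter(.data$pfam_acc %in% forced, .data$score > min_score) |>
      dplyr::count(.data$pfam_acc, name = "n_occurrences")
    missing <- setdiff(forced, extra$pfam_acc)
    if (length(missing) > 0) {
      extra <- dplyr::bind_rows(extra, tibble(pfam_acc = missing,
                                              n_occurrences = 0L))
    }
    pool <- dplyr::bind_rows(pool, extra)
  }
  pool <- pool |>
    dplyr::filter(!.data$pfam_acc %in% exclude) |>
    dplyr::arrange(dplyr::desc(.data$n_occurrences), .data$pfam_acc)
  class(pool) <- c("lan_pfam_pool", class(pool))
  pool
}

#' Harvest genome-wide candidate proteases with pool domains
#'
#' A protein anywhere in any genome is selected as a candidate lanthipeptide
#' protease if it carries at least one Pfam domain from the pool with hit
#' score strictly above `min_score`.
#'
#' @param hits Domain-hit tibble over all proteins in all genomes.
#' @param pool A `lan_pfam_pool` (or any tibble with a `pfam_acc` column, or
#'   a plain character vector of accessions).
#' @param min_score Hits must score strictly above this (default 0).
#' @return A tibble with one row per selected protein: `protein_id` and
#'   `n_pool_hits`, the number of qualifying pool-domain hits.
#' @export
select_genome_proteases <- function(hits, pool, min_score = 0) {
  check_columns(hits, c("protein_id", "pfam_acc", "score"), "domain-hit table")
  accs <- if (is.character(pool)) pool else {
    check_columns(pool, "pfam_acc", "Pfam pool")
    pool$pfam_acc
  }
  hits |>
    dplyr::filter(.data$pfam_acc %in% accs, .data$score > min_score) |>
    dplyr::count(.data$protein_id, name = "n_pool_hits")
}

#' Flag BGCs with a clustered protease within a genomic window
#'
#' For each BGC, tests whether any selected protease gene overlaps the
#' closed interval `[anchor_start - window, anchor_end + window]` around the
#' LanC-like anchor gene, on the same genome and contig. Overlap is
#' non-empty interval intersection on 1-based inclusive coordinates. BGCs
#' lacking a clustered protease are the ones expected to rely on proteases
#' encoded elsewhere in the genome.
#'
#' @param bgcs BGC tibble (see [read_annotation()]); `anchor_start` /
#'   `anchor_end` must be set for every row.
#' @param proteins Protein tibble with coordinates.
#' @param protease_ids Character vector of selected protease `protein_id`s
#'   (e.g. from [select_genome_proteases()]).
#' @param window Window size in nucleotides on each side of the anchor gene
#'   (default 10000, i.e. 10 kb up- and downstream).
#' @return A tibble with columns `bgc_id` and `clustered_protease` (logical).
#' @export
flag_clustered_proteases <- function(bgcs, proteins, protease_ids,
                                     window = 10000) {
  check_columns(bgcs, c("bgc_id", "genome_id", "contig",
                        "anchor_start", "anchor_end"), "BGC table")
  check_columns(proteins, c("protein_id", "genome_id", "contig",
                            "start", "end"), "protein table")
  if (nrow(bgcs) == 0) {
    return(tibble(bgc_id = character(), clustered_protease = logical()))
  }
  missing_anchor <- bgcs$bgc_id[is.na(bgcs$anchor_start) | is.na(bgcs$anchor_end)]
  if (length(missing_anchor) > 0) {
    stop_lan("anchor coordinates missing for BGC(s): %s",
             paste(head(missing_anchor, 5), collapse = ", "))
  }
  prot <- dplyr::filter(proteins, .data$protein_id %in% protease_ids)
  hits <- bgcs |>
    dplyr::select(dplyr::all_of(c("bgc_id", "genome_id", "contig",
                                  "anchor_start", "anchor_end"))) |>
    dplyr::inner_join(
      dplyr::select(prot, dplyr::all_of(c("genome_id", "contig",
                                          "start", "end"))),
      by = c("genome_id", "contig"), relationship = "many-to-many") |>
    dplyr::filter(.data$start <= .data$anchor_end + window,
                  .data$end >= .data$anchor_start - window) |>
    dplyr::distinct(.data$bgc_id)
  bgcs |>
    dplyr::distinct(.data$bgc_id) |>
    dplyr::mutate(clustered_protease = .data$bgc_id %in% hits$bgc_id)
}
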