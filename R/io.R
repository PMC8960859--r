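# Readers and writers for the tabular, sequence and network formats the
# workflow touches. All tables are UTF-8 TSV with fixed headers; missing
# optional fields are written as "."; an undefined correlation coefficient is
# written as the literal string "NA" so it survives a round trip explicitly.

ANNOTATION_REQUIRED <- c("genome_id", "genus", "protein_id", "contig",
                         "start", "end", "strand", "product")
ANNOTATION_OPTIONAL <- c("organism", "bgc_id", "bgc_start", "bgc_end",
                         "lan_class", "anchor_start", "anchor_end")
LAN_CLASSES <- c("I", "II", "III", "IV", "unknown")

#' Read a genome annotation table
#'
#' Parses a flat, one-row-per-protein annotation TSV into typed genome,
#' protein and biosynthetic-gene-cluster (BGC) records. Coordinates are
#' 1-based inclusive, GFF-style. BGC fields are repeated on each member
#' protein row; the BGC table is derived by de-duplication. Referential
#' integrity (protein -> genome, BGC -> genome) is validated on read.
#'
#' Required columns: `genome_id`, `genus`, `protein_id`, `contig`, `start`,
#' `end`, `strand`, `product`. Optional: `organism`, `bgc_id`, `bgc_start`,
#' `bgc_end`, `lan_class` (one of I/II/III/IV/unknown), `anchor_start`,
#' `anchor_end` (coordinates of the LanC-like anchor gene). Missing optional
#' values are encoded as `"."`.
#'
#' @param path Path to a TSV file.
#' @return A list of class `lan_annotation` with tibbles `genomes`
#'   (`genome_id`, `genus`, `organism`), `proteins` (one row per protein,
#'   with `bgc_id` where the protein is part of a BGC) and `bgcs`
#'   (`bgc_id`, `genome_id`, `contig`, `start`, `end`, `lan_class`,
#'   `anchor_start`, `anchor_end`).
#' @export
read_annotation <- function(path) {
  raw <- readr::read_tsv(path, na = ".", show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  check_columns(raw, ANNOTATION_REQUIRED, "annotation table")
  for (col in setdiff(ANNOTATION_OPTIONAL, names(raw))) raw[[col]] <- NA_character_
  raw <- dplyr::mutate(raw, dplyr::across(
    dplyr::all_of(c("start", "end", "bgc_start", "bgc_end",
                    "anchor_start", "anchor_end")),
    ~ suppressWarnings(as.integer(.x))))
  validate_annotation_rows(raw)
  as_lan_annotation(raw)
}

validate_annotation_rows <- function(raw) {
  if (nrow(raw) == 0) return(invisible(raw))
  bad <- which(is.na(raw$start) | is.na(raw$end) | raw$start < 1 | raw$end < 1)
  if (length(bad) > 0) {
    stop_lan("annotation row(s) %s: coordinates must be positive integers",
             paste(head(bad, 5), collapse = ", "))
  }
  bad <- which(raw$start > raw$end)
  if (length(bad) > 0) {
    stop_lan("annotation row(s) %s (protein %s): start > end",
             paste(head(bad, 5), collapse = ", "),
             paste(head(raw$protein_id[bad], 5), collapse = ", "))
  }
  if (anyDuplicated(raw$protein_id)) {
    dup <- unique(raw$protein_id[duplicated(raw$protein_id)])
    stop_lan("duplicate protein_id(s): %s", paste(head(dup, 5), collapse = ", "))
  }
  if (any(is.na(raw$genus) | raw$genus == "")) {
    stop_lan("genus must be non-empty for every row (it partitions the analysis)")
  }
  if (!all(raw$strand %in% c("+", "-"))) {
    stop_lan("strand must be '+' or '-'")
  }
  dangling <- raw$protein_id[!is.na(raw$bgc_id) &
                               (is.na(raw$bgc_start) | is.na(raw$bgc_end))]
  if (length(dangling) > 0) {
    stop_lan("bgc_id set but BGC coordinates missing (dangling BGC reference) for protein(s): %s",
             paste(head(dangling, 5), collapse = ", "))
  }
  cls <- raw$lan_class[!is.na(raw$lan_class)]
  if (!all(cls %in% LAN_CLASSES)) {
    stop_lan("lan_class must be one of %s", paste(LAN_CLASSES, collapse = "/"))
  }
  invisible(raw)
}

as_lan_annotation <- function(raw) {
  genomes <- dplyr::distinct(raw, .data$genome_id, .data$genus, .data$organism)
  if (anyDuplicated(genomes$genome_id)) {
    dup <- unique(genomes$genome_id[duplicated(genomes$genome_id)])
    stop_lan("genome_id(s) with conflicting genus/organism: %s",
             paste(head(dup, 5), collapse = ", "))
  }
  proteins <- dplyr::select(raw, dplyr::all_of(c(
    "protein_id", "genome_id", "contig", "start", "end", "strand",
    "product", "bgc_id")))
  bgcs <- raw |>
    dplyr::filter(!is.na(.data$bgc_id)) |>
    dplyr::mutate(lan_class = dplyr::coalesce(.data$lan_class, "unknown")) |>
    dplyr::distinct(.data$bgc_id, .data$genome_id, .data$contig,
                    start = .data$bgc_start, end = .data$bgc_end,
                    .data$lan_class, .data$anchor_start, .data$anchor_end)
  if (anyDuplicated(bgcs$bgc_id)) {
    dup <- unique(bgcs$bgc_id[duplicated(bgcs$bgc_id)])
    stop_lan("bgc_id(s) with conflicting coordinates: %s",
             paste(head(dup, 5), collapse = ", "))
  }
  if (nrow(bgcs) > 0 && any(bgcs$start > bgcs$end)) {
    stop_lan("BGC with start > end: %s",
             paste(bgcs$bgc_id[bgcs$start > bgcs$end], collapse = ", "))
  }
  structure(list(genomes = genomes, proteins = proteins, bgcs = bgcs),
            class = "lan_annotation")
}

#' Write a genome annotation table
#'
#' Inverse of [read_annotation()]: flattens the typed records back into the
#' one-row-per-protein TSV, so that `read_annotation(write_annotation(x))`
#' reproduces `x`.
#'
#' @param annotation A `lan_annotation` list as returned by [read_annotation()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  stopifnot(inherits(annotation, "lan_annotation"))
  bgc_cols <- annotation$bgcs |>
    dplyr::select(dplyr::all_of(c("bgc_id", "lan_class", "anchor_start",
                                  "anchor_end")),
                  bgc_start = "start", bgc_end = "end")
  flat <- annotation$proteins |>
    dplyr::left_join(annotation$genomes, by = "genome_id") |>
    dplyr::left_join(bgc_cols, by = "bgc_id") |>
    dplyr::select(dplyr::all_of(c(ANNOTATION_REQUIRED, ANNOTATION_OPTIONAL)))
  readr::write_tsv(flat, path, na = ".")
  invisible(path)
}

#' Read and write domain-hit tables
#'
#' Domain hits follow the shape of hmmsearch tabular output after parsing:
#' one row per (protein, Pfam accession, hit) with a real-valued bit score.
#' Scores of any sign are kept at the I/O level; filtering happens downstream.
#'
#' @param path TSV path with columns `protein_id`, `pfam_acc`, `score`.
#' @return `read_domain_hits()`: a tibble; `write_domain_hits()`: `path`,
#'   invisibly.
#' @export
read_domain_hits <- function(path) {
  hits <- readr::read_tsv(path, na = ".", show_col_types = FALSE,
                          col_types = readr::cols(
                            protein_id = readr::col_character(),
                            pfam_acc = readr::col_character(),
                            score = readr::col_double()))
  check_columns(hits, c("protein_id", "pfam_acc", "score"), "domain-hit table")
  hits
}

#' @rdname read_domain_hits
#' @param hits A tibble of domain hits.
#' @export
write_domain_hits <- function(hits, path) {
  check_columns(hits, c("protein_id", "pfam_acc", "score"), "domain-hit table")
  readr::write_tsv(hits, path, na = ".")
  invisible(path)
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file of amino-acid sequences.
#' @return A named character vector, one sequence per record. Duplicate ids
#'   are a hard error.
#' @export
read_sequences <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop_lan("duplicate FASTA id(s): %s", paste(head(dup, 5), collapse = ", "))
  }
  setNames(as.character(set), ids)
}

#' Write protein sequences to FASTA
#'
#' @param sequences Named character vector of amino-acid sequences.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(sequences, path) {
  if (is.null(names(sequences)) || anyDuplicated(names(sequences))) {
    stop_lan("sequences must carry unique names")
  }
  Biostrings::writeXStringSet(Biostrings::AAStringSet(sequences), path)
  invisible(path)
}

#' Read and write group-assignment tables
#'
#' A group assignment maps each member (protein or precursor) to exactly one
#' group. Group labels follow the `Pre_<k>` / `Prot_<k>` convention, matching
#' `group_kind` (`precursor` / `protease`).
#'
#' @param path TSV path with columns `member_id`, `group_id`, `group_kind`.
#' @return `read_group_assignments()`: a tibble; the writer returns `path`
#'   invisibly.
#' @export
read_group_assignments <- function(path) {
  x <- readr::read_tsv(path, na = ".", show_col_types = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  check_columns(x, c("member_id", "group_id", "group_kind"), "assignment table")
  validate_assignments(x)
  x
}

validate_assignments <- function(x) {
  if (anyDuplicated(x$member_id)) {
    dup <- unique(x$member_id[duplicated(x$member_id)])
    stop_lan("member(s) assigned to more than one group: %s",
             paste(head(dup, 5), collapse = ", "))
  }
  if (!all(x$group_kind %in% c("precursor", "protease"))) {
    stop_lan("group_kind must be 'precursor' or 'protease'")
  }
  pre_ok <- x$group_kind != "precursor" | startsWith(x$group_id, "Pre_")
  prot_ok <- x$group_kind != "protease" | startsWith(x$group_id, "Prot_")
  if (!all(pre_ok & prot_ok)) {
    stop_lan("group label prefix must match group_kind (Pre_* / Prot_*)")
  }
  invisible(x)
}

#' @rdname read_group_assignments
#' @param assignments A tibble of group assignments.
#' @export
write_group_assignments <- function(assignments, path) {
  check_columns(assignments, c("member_id", "group_id", "group_kind"),
                "assignment table")
  readr::write_tsv(assignments, path, na = ".")
  invisible(path)
}

#' Read and write genomes-by-groups count matrices
#'
#' Wide TSV: first column `genome_id`, remaining columns one per group,
#' holding non-negative integer occurrence counts.
#'
#' @param path TSV path.
#' @return `read_count_matrix()`: a wide tibble; the writer returns `path`
#'   invisibly.
#' @export
read_count_matrix <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  check_columns(x, "genome_id", "count matrix")
  x
}

#' @rdname read_count_matrix
#' @param counts A wide count tibble (`genome_id` + one column per group).
#' @export
write_count_matrix <- function(counts, path) {
  check_columns(counts, "genome_id", "count matrix")
  readr::write_tsv(counts, path)
  invisible(path)
}

#' Read and write samples-by-columns expression (TPM) matrices
#'
#' Wide TSV: first column `sample_id`, remaining columns genes or groups,
#' holding non-negative TPM values.
#'
#' @param path TSV path.
#' @return `read_expression()`: a wide tibble; the writer returns `path`
#'   invisibly.
#' @export
read_expression <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  check_columns(x, "sample_id", "expression matrix")
  x
}

#' @rdname read_expression
#' @param expression A wide expression tibble (`sample_id` + value columns).
#' @export
write_expression <- function(expression, path) {
  check_columns(expression, "sample_id", "expression matrix")
  readr::write_tsv(expression, path)
  invisible(path)
}

EDGE_COLUMNS <- c("genus", "pre_group", "prot_group", "rho", "p", "p_adj",
                  "I", "n")

#' Read and write correlation edge tables
#'
#' One row per tested (genus, precursor group, protease group) pair carrying
#' the Spearman coefficient `rho`, one-sided p-value `p`, BH-adjusted
#' `p_adj`, genome support `I` (genomes containing both groups) and the
#' number of genomes `n` entering the test. An undefined `rho` (constant
#' count vector) is serialized as the literal `NA` rather than dropped.
#'
#' @param path TSV path.
#' @return `read_edges()`: a tibble; the writer returns `path` invisibly.
#' @export
read_edges <- function(path) {
  x <- readr::read_tsv(path, na = "NA", show_col_types = FALSE,
                       col_types = readr::cols(
                         genus = readr::col_character(),
                         pre_group = readr::col_character(),
                         prot_group = readr::col_character(),
                         rho = readr::col_double(),
                         p = readr::col_double(),
                         p_adj = readr::col_double(),
                         I = readr::col_integer(),
                         n = readr::col_integer()))
  check_columns(x, EDGE_COLUMNS, "edge table")
  x
}

#' @rdname read_edges
#' @param edges A tibble of correlation edges.
#' @export
write_edges <- function(edges, path) {
  check_columns(edges, EDGE_COLUMNS, "edge table")
  readr::write_tsv(edges, path, na = "NA")
  invisible(path)
}

#' Export a correlation network to GraphML
#'
#' Writes an [igraph][igraph::igraph-package] network (see
#' [assemble_network()]) to GraphML for import into Cytoscape. Node
#' attribute `size` carries the group member count and edge attribute
#' `weight` the correlation strength rho, matching the convention that node
#' size reflects the number of precursors/proteases in a group and edge
#' width the Spearman coefficient.
#'
#' @param graph An igraph object with vertex attribute `size` and edge
#'   attribute `weight`.
#' @param path Output GraphML path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(graph, path) {
  stopifnot(inherits(graph, "igraph"))
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}
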