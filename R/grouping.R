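# Identity-threshold connected-component grouping of protein sequences.
# This is a desk-scale stand-in for MMseqs2 easy-cluster in connected-
# component mode: identity >= threshold defines an edge, groups are the
# connected components, so chains of pairwise similarity merge remote
# homologs. Identity is computed from an optimal end-to-end (global)
# alignment with match +1, mismatch 0 and linear gap penalty -1, as
# matches / alignment columns. No attempt is made at bit-compatibility with
# MMseqs2's local-alignment identity.

aa_substitution_matrix <- function() {
  m <- matrix(0, nrow = 26, ncol = 26, dimnames = list(LETTERS, LETTERS))
  diag(m) <- 1
  m
}

check_sequences <- function(sequences) {
  if (length(sequences) == 0) stop_lan("no sequences supplied")
  if (any(is.na(sequences) | nchar(sequences) == 0)) {
    stop_lan("empty sequence(s) supplied")
  }
  if (any(!grepl("^[A-Za-z]+$", sequences))) {
    stop_lan("sequences must be plain amino-acid strings (letters only)")
  }
  toupper(sequences)
}

#' Pairwise global-alignment identity of two protein sequences
#'
#' Aligns `a` and `b` end to end (Needleman-Wunsch; match +1, mismatch 0,
#' linear gap -1) and returns the number of identical aligned positions
#' divided by the total number of alignment columns (including gap columns).
#' The measure is symmetric, equals 1 exactly for identical sequences and 0
#' when no positions match.
#'
#' @param a,b Non-empty amino-acid strings.
#' @return A number in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b) {
  a <- check_sequences(a)
  b <- check_sequences(b)
  stopifnot(length(a) == 1, length(b) == 1)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = aa_substitution_matrix(),
    gapOpening = 0, gapExtension = 1)
  alignment_identity(aln, nchar(a), nchar(b))
}

# alignment columns = len(a) + len(b) - aligned pairs: every column consumes
# one residue of each side (a pair) or one residue of one side (a gap)
alignment_identity <- function(aln, len_a, len_b) {
  pairs <- Biostrings::nmatch(aln) + Biostrings::nmismatch(aln)
  as.numeric(Biostrings::nmatch(aln)) / (len_a + len_b - pairs)
}

#' All-vs-all pairwise identities
#'
#' Computes [pairwise_identity()] for every unordered pair of input
#' sequences. Quadratic in the number of sequences; intended for desk-scale
#' collections.
#'
#' @param sequences Named character vector of amino-acid sequences with
#'   unique names.
#' @return A tibble with columns `id1`, `id2`, `identity`, one row per
#'   unordered pair, with `id1 < id2` lexicographically.
#' @export
pairwise_identities <- function(sequences) {
  sequences <- check_sequences(sequences)
  ids <- names(sequences)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop_lan("sequences must carry unique names")
  }
  n <- length(sequences)
  if (n < 2) {
    return(tibble(id1 = character(), id2 = character(), identity = double()))
  }
  ord <- order(ids)
  sequences <- sequences[ord]
  ids <- ids[ord]
  sub <- aa_substitution_matrix()
  rows <- vector("list", n - 1)
  for (j in 2:n) {
    patterns <- Biostrings::AAStringSet(sequences[seq_len(j - 1)])
    aln <- Biostrings::pairwiseAlignment(
      patterns, Biostrings::AAString(sequences[[j]]), type = "global",
      substitutionMatrix = sub, gapOpening = 0, gapExtension = 1)
    rows[[j - 1]] <- tibble(
      id1 = ids[seq_len(j - 1)], id2 = ids[[j]],
      identity = alignment_identity(aln, nchar(sequences[seq_len(j - 1)]),
                                    nchar(sequences[[j]])))
  }
  dplyr::arrange(dplyr::bind_rows(rows), .data$id1, .data$id2)
}

#' Cluster sequences into groups by connected components
#'
#' Builds the identity graph (edge where identity >= `min_identity`) and
#' returns its connected components as group assignments. Every member is
#' assigned to exactly one group; the provisional group key (`cluster`) is
#' the lexicographically smallest member id of the component, which makes
#' the partition and keys invariant to input order. Defaults follow the
#' published thresholds: 0.45 for proteases and 0.6 for precursors.
#'
#' @param sequences Named character vector of amino-acid sequences.
#' @param kind `"protease"` or `"precursor"`; sets the default threshold and
#'   the label prefix used later by [name_groups()].
#' @param min_identity Identity threshold in `(0, 1]`; default 0.45
#'   (protease) or 0.6 (precursor).
#' @param identities Optional precomputed output of [pairwise_identities()],
#'   to avoid re-aligning when clustering the same set at several thresholds.
#' @return A tibble with columns `member_id`, `group_kind`, `cluster`.
#' @export
cluster_members <- function(sequences, kind = c("protease", "precursor"),
                            min_identity = NULL, identities = NULL) {
  kind <- match.arg(kind)
  min_identity <- min_identity %||% switch(kind, protease = 0.45, precursor = 0.6)
  if (!is.numeric(min_identity) || min_identity <= 0 || min_identity > 1) {
    stop_lan("min_identity must lie in (0, 1]")
  }
  sequences <- check_sequences(sequences)
  ids <- sort(names(sequences))
  if (is.null(identities)) identities <- pairwise_identities(sequences)
  edges <- dplyr::filter(identities, .data$identity >= min_identity)
  g <- igraph::graph_from_data_frame(
    edges[c("id1", "id2")], directed = FALSE,
    vertices = data.frame(name = ids))
  comp <- igraph::components(g)$membership
  tibble(member_id = names(comp),
         group_kind = kind,
         cluster = stats::ave(names(comp), comp,
                              FUN = function(x) min(x))) |>
    dplyr::arrange(.data$member_id)
}

group_key_column <- function(assignments) {
  if ("group_id" %in% names(assignments)) "group_id"
  else if ("cluster" %in% names(assignments)) "cluster"
  else stop_lan("assignment table must carry a 'group_id' or 'cluster' column")
}

#' Drop groups below a minimum size
#'
#' Retains members of groups with at least `min_size` members. Published
#' cutoffs: 100 or more members for protease groups, ten or more for
#' precursor groups.
#'
#' @param assignments Assignment tibble from [cluster_members()] or
#'   [name_groups()].
#' @param min_size Minimum group size (>= 1). When `NULL`, inferred from
#'   `group_kind`: 100 for proteases, 10 for precursors.
#' @return The filtered assignment tibble.
#' @export
filter_groups <- function(assignments, min_size = NULL) {
  key <- group_key_column(assignments)
  if (is.null(min_size)) {
    check_columns(assignments, "group_kind", "assignment table")
    kinds <- unique(assignments$group_kind)
    if (length(kinds) != 1) {
      stop_lan("min_size must be given explicitly for mixed-kind tables")
    }
    min_size <- switch(kinds, protease = 100, precursor = 10,
                       stop_lan("unknown group_kind '%s'", kinds))
  }
  if (min_size < 1) stop_lan("min_size must be >= 1")
  assignments |>
    dplyr::group_by(dplyr::across(dplyr::all_of(key))) |>
    dplyr::filter(dplyr::n() >= min_size) |>
    dplyr::ungroup()
}

#' Assign size-ranked group labels
#'
#' Labels groups `Pre_<k>` (precursors) or `Prot_<k>` (proteases) with `k`
#' running from the largest group down; ties in size are broken by the
#' lexicographically smallest member id, so labels are deterministic and
#' independent of input order.
#'
#' @param assignments Assignment tibble with `member_id`, `group_kind` and a
#'   `cluster` key (see [cluster_members()]).
#' @return The tibble with a `group_id` column added (and `cluster` kept).
#' @export
name_groups <- function(assignments) {
  check_columns(assignments, c("member_id", "group_kind", "cluster"),
                "assignment table")
  key <- "cluster"
  if (nrow(assignments) == 0) {
    return(dplyr::mutate(assignments, group_id = character(0)) |>
             dplyr::select(dplyr::all_of(c("member_id", "group_id",
                                           "group_kind", key))))
  }
  kinds <- unique(assignments$group_kind)
  if (length(kinds) != 1) {
    stop_lan("name_groups() expects a single group_kind per table")
  }
  prefix <- switch(kinds, protease = "Prot", precursor = "Pre",
                   stop_lan("unknown group_kind '%s'", kinds))
  ranking <- assignments |>
    dplyr::group_by(dplyr::across(dplyr::all_of(key))) |>
    dplyr::summarise(size = dplyr::n(),
                     first_member = min(.data$member_id), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$size), .data$first_member) |>
    dplyr::mutate(group_id = sprintf("%s_%d", prefix, dplyr::row_number()))
  assignments |>
    dplyr::left_join(ranking[c(key, "group_id")], by = key) |>
    dplyr::select(dplyr::all_of(c("member_id", "group_id", "group_kind", key)))
}
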