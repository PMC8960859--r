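# The statistical core: per-genus Spearman correlation between precursor-
# group and protease-group occurrence counts across genomes, one-sided
# (upper-tail) t-approximation p-values, Benjamini-Hochberg adjustment, and
# the prioritization filters on rho, adjusted p and genome support I.

#' Build a genomes-by-groups occurrence count matrix
#'
#' Counts, for every genome, how many members of each group it contains.
#' Genomes without any member appear as all-zero rows, so the matrix always
#' covers the full genome list and column sums equal group sizes.
#'
#' @param assignments Assignment tibble (`member_id`, `group_id`).
#' @param members Tibble mapping `member_id` to `genome_id`.
#' @param genomes Tibble of genomes (`genome_id`, ...); defines the rows.
#' @return A wide tibble: `genome_id` plus one integer column per group, in
#'   genome order of `genomes` and column order sorted by group label.
#' @export
build_count_matrix <- function(assignments, members, genomes) {
  check_columns(assignments, c("member_id", "group_id"), "assignment table")
  check_columns(members, c("member_id", "genome_id"), "member table")
  check_columns(genomes, "genome_id", "genome table")
  joined <- dplyr::inner_join(assignments, members, by = "member_id")
  if (nrow(joined) < nrow(assignments)) {
    lost <- setdiff(assignments$member_id, members$member_id)
    stop_lan("member(s) without a genome mapping: %s",
             paste(head(lost, 5), collapse = ", "))
  }
  unknown <- setdiff(joined$genome_id, genomes$genome_id)
  if (length(unknown) > 0) {
    stop_lan("member(s) mapped to unknown genome(s): %s",
             paste(head(unknown, 5), collapse = ", "))
  }
  groups <- sort(unique(assignments$group_id))
  wide <- joined |>
    dplyr::count(.data$genome_id, .data$group_id) |>
    tidyr::pivot_wider(names_from = "group_id", values_from = "n",
                       values_fill = 0L)
  out <- dplyr::left_join(dplyr::select(genomes, "genome_id"), wide,
                          by = "genome_id")
  for (g in setdiff(groups, names(out))) out[[g]] <- 0L
  out <- dplyr::select(out, dplyr::all_of(c("genome_id", groups)))
  out[is.na(out)] <- 0L
  out
}

#' Spearman rank correlation coefficient
#'
#' Pearson correlation of average-ranked values (ties receive their mean
#' rank). Undefined — `NA` — when either vector is constant, rather than
#' silently zero: a rank correlation of a constant vector has no meaning and
#' counting it would inflate the test family.
#'
#' @param x,y Equal-length numeric vectors, length >= 2.
#' @return A number in `[-1, 1]`, or `NA` if undefined.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop_lan("x and y must have equal length")
  if (length(x) < 2) stop_lan("need at least two observations")
  rx <- rank(x)
  ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) return(NA_real_)
  stats::cor(rx, ry)
}

#' One-sided p-value for a Spearman coefficient
#'
#' Upper-tail probability of Student's t with `n - 2` degrees of freedom at
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` — a test of positive association,
#' since the workflow looks for co-occurring partners. The limits are
#' clamped: `rho = 1` gives 0 and `rho = -1` gives 1. Negative correlations
#' therefore surface with p near 1.
#'
#' @param rho Spearman coefficient(s) in `[-1, 1]`; `NA` propagates.
#' @param n Number of observations (single value, >= 3).
#' @return p-value(s) in `[0, 1]`.
#' @export
one_sided_p <- function(rho, n) {
  if (length(n) != 1 || is.na(n) || n < 3) {
    stop_lan("n must be a single integer >= 3")
  }
  bad <- which(!is.na(rho) & abs(rho) > 1 + 1e-12)
  if (length(bad) > 0) stop_lan("rho outside [-1, 1]")
  rho <- pmin(pmax(rho, -1), 1)
  p <- rep(NA_real_, length(rho))
  hi <- !is.na(rho) & rho >= 1
  lo <- !is.na(rho) & rho <= -1
  mid <- !is.na(rho) & !hi & !lo
  p[hi] <- 0
  p[lo] <- 1
  if (any(mid)) {
    t <- rho[mid] * sqrt((n - 2) / (1 - rho[mid]^2))
    p[mid] <- stats::pt(t, df = n - 2, lower.tail = FALSE)
  }
  p
}

#' Spearman test of positive association
#'
#' Convenience wrapper combining [spearman_rho()] and [one_sided_p()]. With
#' `exact = TRUE` (available for n <= 8) the p-value is computed by full
#' enumeration of all permutations of `y` — the exact conditional null given
#' the observed tie structure — instead of the t approximation.
#'
#' @param x,y Equal-length numeric vectors.
#' @param exact Use the exact permutation p-value (n <= 8 only).
#' @return A one-row tibble with `rho`, `p` and `n`.
#' @export
spearman_test <- function(x, y, exact = FALSE) {
  rho <- spearman_rho(x, y)
  n <- length(x)
  if (is.na(rho)) return(tibble(rho = NA_real_, p = NA_real_, n = n))
  if (exact) {
    if (n > 8) {
      stop_lan("exact permutation p-value supported for n <= 8 (got n = %d)", n)
    }
    perms <- all_permutations(n)
    ry <- rank(y)
    rhos <- apply(perms, 1, function(idx) spearman_rho(x, y[idx]))
    p <- mean(rhos >= rho - 1e-12)
  } else {
    p <- one_sided_p(rho, n)
  }
  tibble(rho = rho, p = p, n = n)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  for (k in seq_len(n)) {
    rows <- (k - 1) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1] <- k
    out[rows, -1] <- sub + (sub >= k)
  }
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a vector of p-values. Output
#' order matches input order; adjusted values are never below the raw ones.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (no `NA`).
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  check_probability(p, "p-value vector")
  if (anyNA(p)) stop_lan("bh_adjust() does not accept NA p-values")
  stats::p.adjust(p, method = "BH")
}

# columnwise average ranks; constant columns flagged via attribute
rank_columns <- function(m) {
  r <- apply(m, 2, rank)
  if (!is.matrix(r)) r <- matrix(r, ncol = ncol(m), dimnames = dimnames(m))
  constant <- apply(m, 2, function(col) length(unique(col)) == 1)
  attr(r, "constant") <- constant
  r
}

#' Per-genus correlation of precursor and protease groups
#'
#' For each genus and each (precursor group, protease group) pair with both
#' groups present in at least one genome of the genus, computes the Spearman
#' coefficient across the genus' genomes, the one-sided upper-tail p-value,
#' the genome support `I` (genomes containing at least one member of both
#' groups) and the genus size `n`. Pairs where either count vector is
#' constant get an undefined `rho` (`NA`) and take no part in the adjustment
#' or the filters. BH adjustment is applied once over all emitted tests
#' pooled across genera (`bh_scope = "pooled"`, mirroring a single volcano
#' of all genus-level tests), or within each genus (`"per_genus"`).
#'
#' @param pre_counts,prot_counts Wide count tibbles from
#'   [build_count_matrix()]; must cover the same genomes.
#' @param genomes Tibble with `genome_id` and `genus`; defines the partition.
#' @param bh_scope `"pooled"` (default) or `"per_genus"`.
#' @return A tibble of class `lan_corr` with columns `genus`, `pre_group`,
#'   `prot_group`, `rho`, `p`, `p_adj`, `I`, `n`. Genera with fewer than 3
#'   genomes are skipped with a warning (the t approximation needs n >= 3).
#' @export
correlate_groups <- function(pre_counts, prot_counts, genomes,
                             bh_scope = c("pooled", "per_genus")) {
  bh_scope <- match.arg(bh_scope)
  check_columns(pre_counts, "genome_id", "precursor count matrix")
  check_columns(prot_counts, "genome_id", "protease count matrix")
  check_columns(genomes, c("genome_id", "genus"), "genome table")
  if (nrow(genomes) == 0 || all(is.na(genomes$genus))) {
    stop_lan("empty genus partition")
  }
  if (!setequal(pre_counts$genome_id, prot_counts$genome_id) ||
      !all(genomes$genome_id %in% pre_counts$genome_id)) {
    stop_lan("count matrices and genome table must cover the same genomes")
  }
  pre_m <- as.matrix(pre_counts[-match("genome_id", names(pre_counts))])
  rownames(pre_m) <- pre_counts$genome_id
  prot_m <- as.matrix(prot_counts[-match("genome_id", names(prot_counts))])
  rownames(prot_m) <- prot_counts$genome_id

  per_genus <- genomes |>
    dplyr::group_by(.data$genus) |>
    dplyr::summarise(ids = list(.data$genome_id), .groups = "drop")
  pieces <- purrr::pmap(per_genus, function(genus, ids) {
    n <- length(ids)
    if (n < 3) {
      warn(sprintf("skipping genus '%s' with %d genome(s) (< 3)", genus, n))
      return(NULL)
    }
    a <- pre_m[ids, , drop = FALSE]
    b <- prot_m[ids, , drop = FALSE]
    pre_present <- colSums(a > 0) > 0
    prot_present <- colSums(b > 0) > 0
    if (!any(pre_present) || !any(prot_present)) return(NULL)
    a <- a[, pre_present, drop = FALSE]
    b <- b[, prot_present, drop = FALSE]
    ra <- rank_columns(a)
    rb <- rank_columns(b)
    rho <- suppressWarnings(stats::cor(ra, rb))
    rho[attr(ra, "constant"), ] <- NA_real_
    rho[, attr(rb, "constant")] <- NA_real_
    support <- crossprod((a > 0) + 0L, (b > 0) + 0L)
    tibble(genus = genus,
           pre_group = rep(colnames(a), times = ncol(b)),
           prot_group = rep(colnames(b), each = ncol(a)),
           rho = as.vector(rho),
           p = one_sided_p(as.vector(rho), n),
           I = as.integer(as.vector(support)),
           n = n)
  })
  edges <- dplyr::bind_rows(pieces)
  if (nrow(edges) == 0) {
    edges <- tibble(genus = character(), pre_group = character(),
                    prot_group = character(), rho = double(), p = double(),
                    I = integer(), n = integer())
  }
  edges$p_adj <- NA_real_
  ok <- !is.na(edges$p)
  if (any(ok)) {
    if (bh_scope == "pooled") {
      edges$p_adj[ok] <- bh_adjust(edges$p[ok])
    } else {
      edges$p_adj[ok] <- stats::ave(edges$p[ok], edges$genus[ok],
                                    FUN = bh_adjust)
    }
  }
  edges <- dplyr::select(edges, dplyr::all_of(EDGE_COLUMNS))
  new_lan_corr(edges, bh_scope = bh_scope)
}

new_lan_corr <- function(edges, bh_scope = "pooled") {
  structure(edges,
            class = c("lan_corr", class(tibble())),
            bh_scope = bh_scope)
}

#' Prioritize correlation edges
#'
#' Keeps edges with `rho` strictly above `rho_min`, adjusted p strictly
#' below `padj_max` and genome support `I` of at least `min_I` — the
#' published prioritization rule (rho > 0.3, pAdj < 1e-5, I >= 10). Edges
#' with undefined `rho` are dropped.
#'
#' @param edges Edge tibble (see [correlate_groups()]).
#' @param rho_min Strict lower bound on rho (default 0.3).
#' @param padj_max Strict upper bound on adjusted p (default 1e-5).
#' @param min_I Non-strict lower bound on genome support (default 10).
#' @return The filtered edge tibble.
#' @export
filter_edges <- function(edges, rho_min = 0.3, padj_max = 1e-5, min_I = 10) {
  check_columns(edges, c("rho", "p_adj", "I"), "edge table")
  dplyr::filter(edges,
                !is.na(.data$rho),
                .data$rho > rho_min,
                .data$p_adj < padj_max,
                .data$I >= min_I)
}
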