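# Seeded synthetic-data generators emulating the statistical structure the
# correlation analysis assumes: genus-structured genome collections with
# sparse, zero-inflated group occurrence counts, planted precursor-protease
# dependence of tunable strength, independent background groups, mutated
# sequence families for the clustering stage, annotation/domain tables for
# the mining stage, and transcriptome counts with planted co-expression.

.lan_cache <- new.env(parent = emptyenv())

#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generators, with defaults set
#' to the package's reference study conditions. All generators are pure
#' functions of this object, including its `seed`.
#'
#' Count model: each group's per-genome occurrence count is zero-inflated
#' Poisson (`zero_inflation` mass at zero, rate `background_rate` /
#' `planted_rate`). A planted pair's precursor and protease counts are
#' linked through a Gaussian copula whose correlation is calibrated so that
#' the pair's population Spearman correlation on the count scale equals
#' `effect` (0 = independent, 1 = duplicated counts). Planted pairs occur in
#' every genus — a precursor-protease partnership is a property of the two
#' families, recurring wherever both occur — while background groups are
#' each restricted to one home genus, emulating taxonomically restricted
#' gene families.
#'
#' @param n_genera,genomes_per_genus Shape of the genome collection
#'   (default 20 genera of 50 genomes).
#' @param n_planted_pairs Number of dependent precursor-protease group pairs
#'   (default 5).
#' @param n_coexpressed_pairs How many planted pairs are also co-expressed
#'   in the transcriptome (first pairs by index; default 2). The remainder
#'   are genomic-only decoys.
#' @param n_background_pre,n_background_prot Independent background groups
#'   per side (default 50 each), assigned round-robin to home genera.
#' @param effect Target population Spearman correlation of planted pairs,
#'   in `[0, 1]` (default 0.7).
#' @param background_rate,planted_rate Poisson rates of the count marginals
#'   (default 2).
#' @param zero_inflation Extra mass at zero, in `[0, 1]` (default 0.25).
#' @param n_samples,n_strains Transcriptome shape (default 20 samples in
#'   each of 3 strains).
#' @param coexpr_effect Latent correlation of co-expressed pairs' expression
#'   factors (default 0.9; co-transcribed partners correlate strongly).
#' @param genes_per_group Genes per group in the transcriptome (default 3).
#' @param n_expr_background Background groups per side included in the
#'   transcriptome (default 10).
#' @param n_families,family_size,seq_length,mutation_rate Sequence-family
#'   generator: number of families per kind, members per family, consensus
#'   length (aa) and the fraction of positions substituted in each member
#'   (defaults 3, 12, 60, 0.08; each member mutates exactly
#'   `round(seq_length * mutation_rate)` positions, so within-family
#'   identity is at least `1 - 2 * mutation_rate` by construction and
#'   cross-family identity stays <= 0.3).
#' @param n_bgcs,frac_protease_free Annotation generator: number of BGCs
#'   (one per genome) and the fraction planted without any protease gene
#'   within the 10-kb window (defaults 30 and 1/3, the fraction reported
#'   for real lanthipeptide BGC neighborhoods).
#' @param seed Integer seed; every generator derives its randomness from it.
#' @return A list of class `lan_sim_config`.
#' @export
sim_config <- function(n_genera = 20, genomes_per_genus = 50,
                       n_planted_pairs = 5, n_coexpressed_pairs = 2,
                       n_background_pre = 50, n_background_prot = 50,
                       effect = 0.7, background_rate = 2, planted_rate = 2,
                       zero_inflation = 0.25,
                       n_samples = 20, n_strains = 3, coexpr_effect = 0.9,
                       genes_per_group = 3, n_expr_background = 10,
                       n_families = 3, family_size = 12, seq_length = 60,
                       mutation_rate = 0.08,
                       n_bgcs = 30, frac_protease_free = 1/3,
                       seed = 1L) {
  cfg <- as.list(environment())
  ints <- c("n_genera", "genomes_per_genus", "n_planted_pairs",
            "n_coexpressed_pairs", "n_background_pre", "n_background_prot",
            "n_samples", "n_strains", "genes_per_group", "n_expr_background",
            "n_families", "family_size", "seq_length", "n_bgcs")
  for (f in ints) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] < 0 ||
        cfg[[f]] != round(cfg[[f]])) {
      stop_lan("%s must be a single non-negative integer", f)
    }
    cfg[[f]] <- as.integer(cfg[[f]])
  }
  for (f in c("effect", "zero_inflation", "frac_protease_free",
              "mutation_rate", "coexpr_effect")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1) {
      stop_lan("%s must lie in [0, 1]", f)
    }
  }
  if (cfg$background_rate < 0 || cfg$planted_rate <= 0) {
    stop_lan("rates must be positive")
  }
  if (cfg$n_coexpressed_pairs > cfg$n_planted_pairs) {
    stop_lan("n_coexpressed_pairs cannot exceed n_planted_pairs")
  }
  if (cfg$seq_length < 20) stop_lan("per-family consensus length must be >= 20")
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "lan_sim_config")
}

# zero-inflated Poisson quantile function on uniforms
qzip <- function(u, zero_inflation, rate) {
  as.integer(ifelse(u <= zero_inflation, 0L,
                    qpois(pmax((u - zero_inflation) / (1 - zero_inflation), 0),
                          rate)))
}

rzip <- function(n, zero_inflation, rate) {
  qzip(runif(n), zero_inflation, rate)
}

#' Calibrate the copula correlation for a target count-scale Spearman
#'
#' Maps a target population Spearman correlation (`effect`) of a planted
#' pair's zero-inflated Poisson counts to the Gaussian-copula correlation
#' that produces it. The map is built once per (zero-inflation, rate)
#' setting from a fixed-seed Monte-Carlo grid (so it is a deterministic
#' function), made monotone, and inverse-interpolated. Endpoints are exact:
#' 0 maps to independence and 1 to duplicated counts.
#'
#' @param effect Target population Spearman correlation in `[0, 1]`.
#' @param zero_inflation,rate Marginal parameters of the count model.
#' @return The copula correlation in `[0, 1]`.
#' @export
calibrate_effect <- function(effect, zero_inflation, rate) {
  if (effect <= 0) return(0)
  if (effect >= 1) return(1)
  key <- sprintf("copula_%.6f_%.6f", zero_inflation, rate)
  if (is.null(.lan_cache[[key]])) {
    r_grid <- seq(0, 1, by = 0.05)
    rho_grid <- with_seed(7042L, {
      n <- 2e5
      z1 <- rnorm(n)
      z2 <- rnorm(n)
      u1 <- pnorm(z1)
      x <- qzip(u1, zero_inflation, rate)
      vapply(r_grid, function(r) {
        u2 <- pnorm(r * z1 + sqrt(1 - r^2) * z2)
        y <- qzip(u2, zero_inflation, rate)
        spearman_rho(x, y)
      }, numeric(1))
    })
    rho_grid[1] <- 0
    rho_grid[length(rho_grid)] <- 1
    rho_grid <- cummax(rho_grid)
    .lan_cache[[key]] <- list(r = r_grid, rho = rho_grid)
  }
  grid <- .lan_cache[[key]]
  stats::approx(grid$rho, grid$r, xout = effect, rule = 2, ties = "ordered")$y
}

#' Simulate a genus-structured genome collection with planted pairs
#'
#' Generates genomes grouped into genera, planted precursor-protease group
#' pairs whose per-genome counts are rank-correlated at strength `effect`
#' (per-genus independent draws from the calibrated copula), and independent
#' zero-inflated background groups restricted to home genera. Group members
#' are materialized so that [build_count_matrix()] over the returned
#' assignments reproduces the count matrices exactly.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `lan_sim_genomic`: `genomes` (tibble), `counts_pre`
#'   and `counts_prot` (wide count tibbles), `assignments`, `members`
#'   (member -> genome), and `truth` — one row per planted (pair, genus)
#'   with `pre_group`, `prot_group`, `genus`, `pair`, `coexpressed`.
#' @export
simulate_genomic <- function(cfg) {
  stopifnot(inherits(cfg, "lan_sim_config"))
  if (cfg$n_genera < 1 || cfg$genomes_per_genus < 1) {
    stop_lan("need at least one genus and one genome per genus")
  }
  with_seed(cfg$seed, {
    genera <- sprintf("genus%02d", seq_len(cfg$n_genera))
    genomes <- tibble(
      genome_id = sprintf("g%02d_%03d",
                          rep(seq_len(cfg$n_genera), each = cfg$genomes_per_genus),
                          rep(seq_len(cfg$genomes_per_genus), cfg$n_genera)),
      genus = rep(genera, each = cfg$genomes_per_genus),
      organism = NA_character_)
    n_genomes <- nrow(genomes)

    pre_groups <- sprintf("Pre_%d", seq_len(cfg$n_planted_pairs + cfg$n_background_pre))
    prot_groups <- sprintf("Prot_%d", seq_len(cfg$n_planted_pairs + cfg$n_background_prot))
    counts_pre <- matrix(0L, n_genomes, length(pre_groups),
                         dimnames = list(genomes$genome_id, pre_groups))
    counts_prot <- matrix(0L, n_genomes, length(prot_groups),
                          dimnames = list(genomes$genome_id, prot_groups))

    r <- calibrate_effect(cfg$effect, cfg$zero_inflation, cfg$planted_rate)
    for (g in seq_len(cfg$n_genera)) {
      rows <- which(genomes$genus == genera[g])
      for (k in seq_len(cfg$n_planted_pairs)) {
        z1 <- rnorm(length(rows))
        z2 <- r * z1 + sqrt(1 - r^2) * rnorm(length(rows))
        counts_pre[rows, k] <- qzip(pnorm(z1), cfg$zero_inflation, cfg$planted_rate)
        counts_prot[rows, k] <- qzip(pnorm(z2), cfg$zero_inflation, cfg$planted_rate)
      }
    }
    # background groups: independent draws in the home genus only
    add_background <- function(counts, n_bg, offset) {
      if (n_bg == 0) return(counts)
      home <- rep_len(genera, n_bg)
      for (b in seq_len(n_bg)) {
        rows <- which(genomes$genus == home[b])
        counts[rows, offset + b] <- rzip(length(rows), cfg$zero_inflation,
                                         cfg$background_rate)
      }
      counts
    }
    counts_pre <- add_background(counts_pre, cfg$n_background_pre,
                                 cfg$n_planted_pairs)
    counts_prot <- add_background(counts_prot, cfg$n_background_prot,
                                  cfg$n_planted_pairs)

    truth <- if (cfg$n_planted_pairs > 0) {
      tidyr::expand_grid(pair = seq_len(cfg$n_planted_pairs), genus = genera) |>
        dplyr::mutate(pre_group = sprintf("Pre_%d", .data$pair),
                      prot_group = sprintf("Prot_%d", .data$pair),
                      coexpressed = .data$pair <= cfg$n_coexpressed_pairs) |>
        dplyr::select(dplyr::all_of(c("pre_group", "prot_group", "genus",
                                      "pair", "coexpressed")))
    } else {
      tibble(pre_group = character(), prot_group = character(),
             genus = character(), pair = integer(), coexpressed = logical())
    }

    materialize <- function(counts, kind) {
      long <- as_tibble(as.data.frame.table(counts, stringsAsFactors = FALSE),
                        .name_repair = ~ c("genome_id", "group_id", "count")) |>
        dplyr::filter(.data$count > 0)
      if (nrow(long) == 0) {
        return(tibble(member_id = character(), group_id = character(),
                      group_kind = character(), genome_id = character()))
      }
      long |>
        dplyr::mutate(idx = purrr::map(.data$count, seq_len)) |>
        tidyr::unnest("idx") |>
        dplyr::mutate(member_id = sprintf("%s|%s|m%d", .data$genome_id,
                                          .data$group_id, .data$idx),
                      group_kind = kind) |>
        dplyr::select(dplyr::all_of(c("member_id", "group_id", "group_kind",
                                      "genome_id")))
    }
    members_pre <- materialize(counts_pre, "precursor")
    members_prot <- materialize(counts_prot, "protease")
    all_members <- dplyr::bind_rows(members_pre, members_prot)

    structure(list(
      genomes = genomes,
      counts_pre = dplyr::bind_cols(tibble(genome_id = genomes$genome_id),
                                    as_tibble(counts_pre)),
      counts_prot = dplyr::bind_cols(tibble(genome_id = genomes$genome_id),
                                     as_tibble(counts_prot)),
      assignments = dplyr::select(all_members,
                                  dplyr::all_of(c("member_id", "group_id",
                                                  "group_kind"))),
      members = dplyr::select(all_members,
                              dplyr::all_of(c("member_id", "genome_id"))),
      truth = truth), class = "lan_sim_genomic")
  })
}

#' Simulate sequence families for the clustering stage
#'
#' Generates, for each kind (precursor and protease), `n_families` disjoint
#' consensus sequences and `family_size` point-mutated copies of each.
#' Consensi are resampled until mutually dissimilar, and the construction is
#' verified post hoc: minimum within-family identity >= 0.8 (ungapped
#' lower bound) and maximum cross-family consensus alignment identity
#' <= 0.3; violations are an error.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `lan_sim_sequences`: `precursors` and `proteases`
#'   (named character vectors) and `truth` (tibble `member_id`, `family`,
#'   `kind`).
#' @export
simulate_sequences <- function(cfg) {
  stopifnot(inherits(cfg, "lan_sim_config"))
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  with_seed(cfg$seed + 1009L, {
    gen_kind <- function(kind, prefix) {
      consensi <- list()
      for (f in seq_len(cfg$n_families)) {
        for (try in seq_len(200)) {
          cand <- paste(sample(aa, cfg$seq_length, replace = TRUE),
                        collapse = "")
          ok <- all(vapply(consensi, function(c0)
            hamming_identity(cand, c0) <= 0.2, logical(1)))
          if (ok) break
          cand <- NULL
        }
        if (is.null(cand)) {
          stop_lan("could not draw mutually dissimilar consensi at the requested sizes")
        }
        consensi[[f]] <- cand
      }
      members <- list()
      truth <- list()
      for (f in seq_len(cfg$n_families)) {
        cons <- strsplit(consensi[[f]], "")[[1]]
        n_mut <- round(cfg$seq_length * cfg$mutation_rate)
        for (m in seq_len(cfg$family_size)) {
          # exactly n_mut substituted positions per member, so any two
          # members differ in at most 2 * n_mut positions and within-family
          # identity >= 1 - 2 * mutation_rate by construction
          mutate <- sample(cfg$seq_length, n_mut)
          seq <- cons
          if (n_mut > 0) {
            seq[mutate] <- vapply(cons[mutate], function(orig)
              sample(setdiff(aa, orig), 1), character(1))
          }
          id <- sprintf("%s_f%d_m%02d", prefix, f, m)
          members[[id]] <- paste(seq, collapse = "")
          truth[[id]] <- f
        }
      }
      seqs <- unlist(members)
      # post-hoc verification of the identity structure
      fam <- unlist(truth)
      for (f in seq_len(cfg$n_families)) {
        ids <- names(fam)[fam == f]
        for (i in seq_along(ids)) for (j in seq_len(i - 1)) {
          if (hamming_identity(seqs[[ids[i]]], seqs[[ids[j]]]) < 0.8) {
            stop_lan("within-family identity fell below 0.8; lower mutation_rate")
          }
        }
      }
      if (cfg$n_families > 1) {
        cross <- utils::combn(seq_len(cfg$n_families), 2)
        for (k in seq_len(ncol(cross))) {
          if (pairwise_identity(consensi[[cross[1, k]]],
                                consensi[[cross[2, k]]]) > 0.3) {
            stop_lan("cross-family consensus identity above 0.3; increase seq_length")
          }
        }
      }
      list(seqs = seqs,
           truth = tibble(member_id = names(fam), family = unname(fam),
                          kind = kind))
    }
    pre <- gen_kind("precursor", "pre")
    prot <- gen_kind("protease", "prot")
    structure(list(precursors = pre$seqs, proteases = prot$seqs,
                   truth = dplyr::bind_rows(pre$truth, prot$truth)),
              class = "lan_sim_sequences")
  })
}

hamming_identity <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
}

#' Simulate per-strain transcriptome count tables
#'
#' Builds gene-count tables for `n_strains` strains. Genes belong to the
#' planted groups (plus `n_expr_background` background groups per side),
#' `genes_per_group` each. For a co-expressed planted pair, the precursor
#' and protease groups share a per-sample latent expression factor at
#' correlation `coexpr_effect`; decoy pairs (planted genomically but not
#' co-expressed) and background groups get independent factors. Counts are
#' Poisson around length-scaled log-normal rates; lengths are drawn from
#' 300-3000 nt.
#'
#' @param cfg A [sim_config()]; `n_samples >= 3`.
#' @param truth Truth tibble from [simulate_genomic()] (its distinct pairs
#'   and `coexpressed` flags are used).
#' @return A list of class `lan_sim_transcriptome`: `strains` (named list of
#'   long count tibbles with `sample_id`, `gene_id`, `count`, `length`),
#'   `gene_groups` (gene -> group assignment tibble) and `truth` (distinct
#'   pairs with `coexpressed`).
#' @export
simulate_transcriptome <- function(cfg, truth) {
  stopifnot(inherits(cfg, "lan_sim_config"))
  if (cfg$n_samples < 3) stop_lan("n_samples must be >= 3")
  check_columns(truth, c("pre_group", "prot_group", "coexpressed"),
                "truth table")
  pairs <- dplyr::distinct(truth, .data$pre_group, .data$prot_group,
                           .data$coexpressed)
  bg_pre <- sprintf("Pre_bg%d", seq_len(cfg$n_expr_background))
  bg_prot <- sprintf("Prot_bg%d", seq_len(cfg$n_expr_background))
  groups <- tibble(
    group_id = c(pairs$pre_group, pairs$prot_group, bg_pre, bg_prot),
    group_kind = c(rep("precursor", nrow(pairs)), rep("protease", nrow(pairs)),
                   rep("precursor", length(bg_pre)),
                   rep("protease", length(bg_prot)))) |>
    dplyr::distinct()
  gene_groups <- groups |>
    dplyr::mutate(gene = purrr::map(.data$group_id, function(g)
      sprintf("%s|gene%d", g, seq_len(cfg$genes_per_group)))) |>
    tidyr::unnest("gene") |>
    dplyr::select(member_id = "gene", "group_id", "group_kind")

  strains <- with_seed(cfg$seed + 2003L, {
    out <- list()
    for (s in seq_len(cfg$n_strains)) {
      lengths <- sample(300:3000, nrow(gene_groups), replace = TRUE)
      mu <- rnorm(nrow(gene_groups), mean = log(200), sd = 0.5)
      # one latent factor per pair (shared if co-expressed) + per group
      factors <- matrix(rnorm(nrow(groups) * cfg$n_samples),
                        nrow = nrow(groups),
                        dimnames = list(groups$group_id, NULL))
      for (k in seq_len(nrow(pairs))) {
        if (pairs$coexpressed[k]) {
          f_pre <- factors[pairs$pre_group[k], ]
          factors[pairs$prot_group[k], ] <-
            cfg$coexpr_effect * f_pre +
            sqrt(1 - cfg$coexpr_effect^2) * factors[pairs$prot_group[k], ]
        }
      }
      rows <- list()
      for (i in seq_len(nrow(gene_groups))) {
        f <- factors[gene_groups$group_id[i], ]
        lambda <- exp(mu[i] + 1.0 * f + 0.2 * rnorm(cfg$n_samples)) *
          lengths[i] / 1000
        rows[[i]] <- tibble(
          sample_id = sprintf("s%02d", seq_len(cfg$n_samples)),
          gene_id = gene_groups$member_id[i],
          count = rpois(cfg$n_samples, lambda),
          length = lengths[i])
      }
      out[[sprintf("strain%d", s)]] <- dplyr::arrange(
        dplyr::bind_rows(rows), .data$sample_id, .data$gene_id)
    }
    out
  })
  structure(list(strains = strains, gene_groups = gene_groups, truth = pairs),
            class = "lan_sim_transcriptome")
}

#' Simulate an annotation table and domain hits for the mining stage
#'
#' Generates one BGC per genome with a LanC-like anchor gene, BGC-associated
#' protease genes carrying Pfam domains (the sources of the domain pool),
#' distant "hidden" proteases well outside the 10-kb window, and filler
#' proteins. A planted fraction of BGCs (`frac_protease_free`, rounded to a
#' whole number of BGCs) carries no protease gene anywhere within the
#' window, so the fraction of BGCs failing the clustered-protease check
#' equals the planted fraction exactly. The domain-hit table includes
#' low-scoring and rare accessions to exercise the pool rules.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `lan_sim_annotation`: `annotation` (a
#'   `lan_annotation` list), `hits` (domain-hit tibble) and `truth`
#'   (tibble `bgc_id`, `protease_free`).
#' @export
simulate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "lan_sim_config"))
  if (cfg$n_bgcs < 1) stop_lan("n_bgcs must be >= 1")
  pool_pfams <- c("PF00082", "PF05193", "PF01435", "PF10118", "PF00795")
  rare_pfam <- "PF09999"      # too few occurrences to enter the pool
  negative_pfam <- "PF08888"  # only non-positive scores
  protease_products <- c("zinc metallopeptidase", "serine protease",
                         "subtilisin-like proteinase",
                         "metal-dependent hydrolase",
                         "Beta-Lactamase class A")
  other_products <- c("ABC transporter permease", "ribosomal protein L1",
                      "DNA polymerase III subunit", "sigma factor")
  with_seed(cfg$seed + 3001L, {
    n_free <- round(cfg$frac_protease_free * cfg$n_bgcs)
    protease_free <- c(rep(TRUE, n_free), rep(FALSE, cfg$n_bgcs - n_free))
    rows <- list()
    hit_rows <- list()
    add_hit <- function(pid, acc, score) {
      hit_rows[[length(hit_rows) + 1]] <<- tibble(
        protein_id = pid, pfam_acc = acc, score = score)
    }
    for (i in seq_len(cfg$n_bgcs)) {
      genome <- sprintf("ag%03d", i)
      genus <- sprintf("genus%02d", (i - 1) %% max(cfg$n_genera, 1) + 1)
      bgc <- sprintf("bgc%03d", i)
      anchor_start <- sample(60000:140000, 1)
      anchor_end <- anchor_start + 999L
      bgc_start <- anchor_start - 5000L
      bgc_end <- anchor_end + 5000L
      base <- list(genome_id = genome, genus = genus, organism = NA_character_,
                   contig = "c1", strand = "+")
      mk <- function(pid, start, end, product, in_bgc) {
        c(base, list(protein_id = pid, start = start, end = end,
                     product = product,
                     bgc_id = if (in_bgc) bgc else NA_character_,
                     bgc_start = if (in_bgc) bgc_start else NA_integer_,
                     bgc_end = if (in_bgc) bgc_end else NA_integer_,
                     lan_class = if (in_bgc) "III" else NA_character_,
                     anchor_start = if (in_bgc) anchor_start else NA_integer_,
                     anchor_end = if (in_bgc) anchor_end else NA_integer_))
      }
      rows[[length(rows) + 1]] <- mk(
        sprintf("%s_anchor", genome), anchor_start, anchor_end,
        "lanthionine synthetase LanC-like protein", TRUE)
      if (!protease_free[i]) {
        # clustered protease genes inside the BGC, with pool-eligible domains
        n_prot <- sample(1:3, 1)
        for (j in seq_len(n_prot)) {
          pid <- sprintf("%s_bgcprot%d", genome, j)
          start <- bgc_start + 500L + 1500L * j
          rows[[length(rows) + 1]] <- mk(pid, start, start + 900L,
                                         sample(protease_products, 1), TRUE)
          add_hit(pid, sample(pool_pfams, 1), runif(1, 5, 100))
          if (runif(1) < 0.2) add_hit(pid, negative_pfam, runif(1, -10, 0))
        }
      } else {
        # protease-free neighborhood: only non-protease genes in the BGC
        pid <- sprintf("%s_bgcother", genome)
        rows[[length(rows) + 1]] <- mk(pid, bgc_start + 2000L,
                                       bgc_start + 2900L,
                                       sample(other_products, 1), TRUE)
      }
      # hidden proteases far outside the window (> anchor_end + 10 kb)
      for (j in 1:2) {
        pid <- sprintf("%s_hidden%d", genome, j)
        start <- anchor_end + 10000L + 5000L * j
        rows[[length(rows) + 1]] <- mk(pid, start, start + 900L,
                                       sample(protease_products, 1), FALSE)
        add_hit(pid, sample(pool_pfams, 1), runif(1, 2, 50))
      }
      # filler protein without protease annotation or pool domains
      pid <- sprintf("%s_fill", genome)
      rows[[length(rows) + 1]] <- mk(pid, 1000L, 1900L,
                                     sample(other_products, 1), FALSE)
      if (runif(1) < 0.1) add_hit(pid, rare_pfam, runif(1, 1, 10))
    }
    flat <- dplyr::bind_rows(lapply(rows, as_tibble))
    annotation <- as_lan_annotation(flat)
    hits <- dplyr::bind_rows(hit_rows)
    structure(list(annotation = annotation, hits = hits,
                   truth = tibble(bgc_id = sprintf("bgc%03d", seq_len(cfg$n_bgcs)),
                                  protease_free = protease_free)),
              class = "lan_sim_annotation")
  })
}

#' Score edge recovery against a planted truth table
#'
#' Compares prioritized edges with the generator's truth. At `level =
#' "pair"` (default) a planted (precursor group, protease group) partnership
#' counts as recovered if it is significant in at least one genus — the
#' partnership, not its per-genus sighting, is the discovery the workflow
#' reports. `level = "triple"` scores each (pair, genus) sighting
#' separately.
#'
#' @param edges Prioritized edge tibble (see [filter_edges()]).
#' @param truth Truth tibble from [simulate_genomic()].
#' @param level `"pair"` or `"triple"`.
#' @return A one-row tibble: `precision`, `recall`, `tp`, `fp`, `fn`.
#'   Precision is `NA` when nothing was predicted.
#' @export
score_recovery <- function(edges, truth, level = c("pair", "triple")) {
  level <- match.arg(level)
  check_columns(edges, c("pre_group", "prot_group"), "edge table")
  check_columns(truth, c("pre_group", "prot_group"), "truth table")
  keys <- if (level == "pair") c("pre_group", "prot_group")
          else c("pre_group", "prot_group", "genus")
  pred <- dplyr::distinct(edges[keys])
  true <- dplyr::distinct(truth[keys])
  tp <- nrow(dplyr::inner_join(pred, true, by = keys))
  fp <- nrow(pred) - tp
  fn <- nrow(true) - tp
  tibble(precision = if (nrow(pred) > 0) tp / nrow(pred) else NA_real_,
         recall = if (nrow(true) > 0) tp / nrow(true) else NA_real_,
         tp = tp, fp = fp, fn = fn)
}
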