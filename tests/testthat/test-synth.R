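test_that("configuration validates its fields", {
  expect_s3_class(sim_config(), "lan_sim_config")
  expect_error(sim_config(effect = 1.5), "\\[0, 1\\]")
  expect_error(sim_config(n_genera = -1), "non-negative")
  expect_error(sim_config(n_coexpressed_pairs = 9, n_planted_pairs = 2),
               "cannot exceed")
  expect_error(sim_config(seq_length = 10), ">= 20")
})

test_that("generators are pure functions of the configuration", {
  cfg <- sim_config(n_genera = 3, genomes_per_genus = 15, n_planted_pairs = 2,
                    n_background_pre = 5, n_background_prot = 5,
                    n_samples = 6, n_strains = 2, seed = 77)
  g1 <- simulate_genomic(cfg)
  g2 <- simulate_genomic(cfg)
  expect_identical(g1, g2)
  s1 <- simulate_sequences(cfg)
  s2 <- simulate_sequences(cfg)
  expect_identical(s1, s2)
  t1 <- simulate_transcriptome(cfg, g1$truth)
  t2 <- simulate_transcriptome(cfg, g2$truth)
  expect_identical(t1, t2)
  a1 <- simulate_annotation(cfg)
  a2 <- simulate_annotation(cfg)
  expect_identical(a1, a2)
  # generators do not disturb the caller's RNG stream
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(simulate_genomic(cfg)); after <- runif(1)
  expect_identical(before, after)
})

test_that("materialized members reproduce the count matrices exactly", {
  gen <- toy_genomic()
  for (kind in c("precursor", "protease")) {
    counts <- if (kind == "precursor") gen$counts_pre else gen$counts_prot
    rebuilt <- build_count_matrix(
      dplyr::filter(gen$assignments, group_kind == kind),
      gen$members, gen$genomes)
    expect_equal(as.data.frame(rebuilt[names(counts)]),
                 as.data.frame(counts))
  }
})

test_that("effect = 0 gives independent planted counts at large n", {
  gen <- simulate_genomic(sim_config(n_genera = 1, genomes_per_genus = 10000,
                                     n_planted_pairs = 1,
                                     n_coexpressed_pairs = 0,
                                     n_background_pre = 0,
                                     n_background_prot = 0,
                                     effect = 0, seed = 19))
  rho <- spearman_rho(gen$counts_pre$Pre_1, gen$counts_prot$Prot_1)
  expect_lt(abs(rho), 0.03)
})

test_that("effect = 1 duplicates counts up to the copula limit", {
  gen <- simulate_genomic(sim_config(n_genera = 2, genomes_per_genus = 100,
                                     n_planted_pairs = 1,
                                     n_coexpressed_pairs = 0,
                                     effect = 1, seed = 23))
  expect_identical(gen$counts_pre$Pre_1, gen$counts_prot$Prot_1)
  rho <- spearman_rho(gen$counts_pre$Pre_1, gen$counts_prot$Prot_1)
  expect_identical(rho, 1)
})

test_that("planted rank dependence rises monotonically with effect", {
  mean_rho <- vapply(c(0, 0.3, 0.6, 1), function(eff) {
    rhos <- vapply(1:12, function(rep) {
      gen <- simulate_genomic(sim_config(
        n_genera = 1, genomes_per_genus = 120, n_planted_pairs = 1,
        n_coexpressed_pairs = 0, n_background_pre = 0, n_background_prot = 0,
        effect = eff, seed = 500 + rep))
      r <- spearman_rho(gen$counts_pre$Pre_1, gen$counts_prot$Prot_1)
      if (is.na(r)) 0 else r
    }, numeric(1))
    mean(rhos)
  }, numeric(1))
  expect_true(all(diff(mean_rho) > 0))
  # calibration: empirical rho tracks the requested effect
  expect_equal(mean_rho[3], 0.6, tolerance = 0.1)
})

test_that("calibration maps effect to the copula scale monotonically with exact endpoints", {
  expect_identical(calibrate_effect(0, 0.25, 2), 0)
  expect_identical(calibrate_effect(1, 0.25, 2), 1)
  r <- vapply(c(0.2, 0.5, 0.7, 0.9), calibrate_effect, numeric(1),
              zero_inflation = 0.25, rate = 2)
  expect_true(all(diff(r) > 0))
  # counts are tied and zero-inflated, so the copula correlation must exceed
  # the target rank correlation
  expect_true(all(r > c(0.2, 0.5, 0.7, 0.9)))
})

test_that("sequence families respect the planted identity structure", {
  sim <- simulate_sequences(sim_config(seed = 41))
  truth <- dplyr::filter(sim$truth, kind == "precursor")
  seqs <- sim$precursors
  fams <- split(truth$member_id, truth$family)
  for (fam in fams) {
    for (pair in list(c(1, 2), c(1, length(fam)))) {
      expect_gte(pairwise_identity(seqs[[fam[pair[1]]]],
                                   seqs[[fam[pair[2]]]]), 0.8)
    }
  }
  cross <- pairwise_identity(seqs[[fams[[1]][1]]], seqs[[fams[[2]][1]]])
  expect_lte(cross, 0.35)
  # mutation rate 0: members identical to the consensus and to each other
  clones <- simulate_sequences(sim_config(mutation_rate = 0, seed = 41))
  fam1 <- dplyr::filter(clones$truth, kind == "precursor", family == 1)
  expect_equal(length(unique(clones$precursors[fam1$member_id])), 1)
  single <- simulate_sequences(sim_config(n_families = 1, seed = 2))
  cl <- cluster_members(single$precursors, kind = "precursor")
  expect_equal(length(unique(cl$cluster)), 1)
})

test_that("co-expressed pairs correlate in group TPM while decoys do not", {
  detected <- logical(10)
  decoy_hit <- logical(10)
  for (s in 1:10) {
    cfg <- sim_config(n_planted_pairs = 2, n_coexpressed_pairs = 1,
                      n_samples = 20, n_strains = 1, seed = 700 + s)
    gen <- simulate_genomic(cfg)
    trx <- simulate_transcriptome(cfg, gen$truth)
    expr <- group_tpm(tpm(trx$strains[[1]]), trx$gene_groups)
    edges <- coexpression_edges(expr)
    key <- paste(edges$pre_group, edges$prot_group)
    detected[s] <- "Pre_1 Prot_1" %in% key
    decoy_hit[s] <- "Pre_2 Prot_2" %in% key
  }
  expect_gte(sum(detected), 9)
  expect_lte(sum(decoy_hit), 1)
})

test_that("recovery scoring counts pairs and triples against the truth table", {
  truth <- tibble::tibble(pre_group = c("Pre_1", "Pre_1"),
                          prot_group = c("Prot_1", "Prot_1"),
                          genus = c("A", "B"), pair = 1L, coexpressed = TRUE)
  edges <- tibble::tibble(genus = c("A", "C"),
                          pre_group = c("Pre_1", "Pre_9"),
                          prot_group = c("Prot_1", "Prot_9"))
  pair <- score_recovery(edges, truth, "pair")
  expect_equal(pair$recall, 1)
  expect_equal(pair$precision, 0.5)
  triple <- score_recovery(edges, truth, "triple")
  expect_equal(triple$recall, 0.5)   # genus B sighting missed
  expect_equal(triple$tp, 1)
  none <- score_recovery(edges[0, ], truth, "pair")
  expect_true(is.na(none$precision))
  expect_equal(none$recall, 0)
})
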