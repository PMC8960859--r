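test_that("TPM follows the closed-form rate normalization", {
  counts <- tibble::tibble(sample_id = "s1", gene_id = c("a", "b"),
                           count = c(10, 10), length = c(1000L, 2000L))
  expr <- tpm(counts)
  # rates 0.01 and 0.005 -> TPM 2/3e6 and 1/3e6
  expect_equal(unlist(expr[1, c("a", "b")]),
               c(a = 2e6 / 3, b = 1e6 / 3), tolerance = 1e-12)
  expect_equal(sum(expr[1, -1]), 1e6, tolerance = 1e-6)
  zero <- tpm(dplyr::mutate(counts, count = 0))
  expect_equal(unlist(zero[1, -1]), c(a = 0, b = 0))
  expect_error(tpm(dplyr::mutate(counts, count = c(-1, 5))), "non-negative")
  expect_error(tpm(dplyr::mutate(counts, length = c(0L, 10L))), "positive")
})

test_that("TPM rows sum to one million for all non-degenerate synthetic samples", {
  cfg <- sim_config(n_samples = 12, n_strains = 2, seed = 8)
  gen <- simulate_genomic(cfg)
  trx <- simulate_transcriptome(cfg, gen$truth)
  for (strain in trx$strains) {
    expr <- tpm(strain)
    sums <- rowSums(expr[-1])
    nz <- sums > 0
    expect_true(all(abs(sums[nz] - 1e6) / 1e6 < 1e-6))
  }
})

test_that("group TPM sums member genes and drops empty groups", {
  expr <- tibble::tibble(sample_id = c("s1", "s2"),
                         g1 = c(100, 7), g2 = c(50, 3), g3 = c(5, 5))
  assign <- tibble::tibble(member_id = c("g1", "g2"),
                           group_id = "Pre_1", group_kind = "precursor")
  grp <- group_tpm(expr, assign)
  expect_equal(grp$Pre_1, c(150, 10))   # 100 + 50 and 7 + 3
  expect_false("g3" %in% names(grp))    # unassigned gene ignored
  expect_equal(ncol(grp), 2)            # no column for empty groups
  # partial cover: group totals bounded by the row total
  expect_true(all(grp$Pre_1 <= rowSums(expr[-1])))
})

test_that("trimming restricts to network groups and fails on disjoint inputs", {
  expr <- tibble::tibble(sample_id = "s1", Pre_1 = 1, Pre_2 = 2,
                         Prot_1 = 3, Prot_2 = 4, Prot_9 = 5)
  edges <- tibble::tibble(pre_group = "Pre_1", prot_group = "Prot_2")
  trimmed <- trim_to_network(expr, edges)
  expect_named(trimmed, c("sample_id", "Pre_1", "Prot_2"))
  all_edges <- tibble::tibble(pre_group = c("Pre_1", "Pre_2"),
                              prot_group = c("Prot_1", "Prot_2"))
  expect_named(trim_to_network(expr[1:5], all_edges),
               c("sample_id", "Pre_1", "Pre_2", "Prot_1", "Prot_2"))
  disjoint <- tibble::tibble(pre_group = "Pre_77", prot_group = "Prot_88")
  expect_error(trim_to_network(expr, disjoint), "refinement impossible")
})

test_that("co-expression edges apply strict rho and pAdj bounds", {
  n <- 12
  withr::with_seed(4, {
    shared <- sort(runif(n, 10, 1000))
    expr <- tibble::tibble(sample_id = sprintf("s%02d", 1:n),
                           Pre_1 = shared,
                           Prot_1 = shared * 3 + 1,   # identical ranks
                           Prot_2 = runif(n, 10, 1000))
  })
  kept <- coexpression_edges(expr)
  expect_true(all(c("Pre_1") %in% kept$pre_group))
  top <- dplyr::filter(kept, prot_group == "Prot_1")
  expect_equal(top$rho, 1)
  all_pairs <- coexpression_edges(expr, filter = FALSE)
  expect_equal(nrow(all_pairs), 2)
  expect_error(coexpression_edges(expr[1:2, ]), "at least 3 samples")
  # boundary: rho exactly at the threshold is excluded
  fake <- tibble::tibble(pre_group = "Pre_1", prot_group = "Prot_9",
                         rho = 0.4, p = 0.001, p_adj = 0.01, n_samples = 12L)
  expect_equal(nrow(dplyr::filter(fake, rho > 0.4, p_adj < 0.05)), 0)
})

test_that("raw co-expression p-values are calibrated on independent profiles", {
  # pairs sharing a column are dependent tests, so the rejection rate is
  # averaged over replicates before comparison with the nominal level
  n <- 30
  rates <- vapply(1:4, function(rep) {
    expr <- withr::with_seed(17 + rep, {
      e <- tibble::tibble(sample_id = sprintf("s%02d", seq_len(n)))
      for (k in 1:25) e[[sprintf("Pre_%d", k)]] <- runif(n, 1, 1000)
      for (k in 1:20) e[[sprintf("Prot_%d", k)]] <- runif(n, 1, 1000)
      e
    })
    pairs <- coexpression_edges(expr, filter = FALSE)
    stopifnot(nrow(pairs) == 500)
    mean(pairs$p < 0.05)
  }, numeric(1))
  expect_lt(abs(mean(rates) - 0.05), 0.02)
})

test_that("strain combination intersects or unions edge sets", {
  e1 <- tibble::tibble(pre_group = c("Pre_5", "Pre_5"),
                       prot_group = c("Prot_241", "Prot_1365"),
                       rho = c(0.8, 0.5), p_adj = c(0.001, 0.02))
  e2 <- dplyr::filter(e1, prot_group == "Prot_241")
  e3 <- dplyr::mutate(e2, rho = 0.9)
  all3 <- combine_strains(list(a = e1, b = e2, c = e3))
  expect_equal(all3$prot_group, "Prot_241")  # present in 3/3
  expect_equal(all3$min_rho, 0.8)
  any3 <- combine_strains(list(a = e1, b = e2, c = e3), mode = "any")
  expect_setequal(any3$prot_group, c("Prot_241", "Prot_1365"))
  single <- combine_strains(list(e1))
  expect_equal(nrow(single), 2)  # single strain: identity on pairs
  expect_error(combine_strains(e1), "list")
})

test_that("evidence intersection reproduces the candidate-reduction logic", {
  genomic <- tibble::tibble(
    genus = "Streptomyces",
    pre_group = "Pre_5", prot_group = c("Prot_241", "Prot_1365"),
    rho = c(0.8, 0.7), p = 1e-10, p_adj = c(1e-8, 1e-7), I = c(20L, 15L),
    n = 50L)
  coexpr <- tibble::tibble(pre_group = "Pre_5", prot_group = "Prot_241",
                           rho = 0.75, p = 1e-4, p_adj = 0.002,
                           n_samples = 27L)
  cand <- intersect_evidence(genomic, coexpr)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$prot_group, "Prot_241")
  expect_equal(cand$rho.genomic, 0.8)
  expect_equal(cand$rho.coexpr, 0.75)
  # disjoint evidence: no candidates
  expect_equal(nrow(intersect_evidence(
    genomic, dplyr::mutate(coexpr, prot_group = "Prot_9"))), 0)
  # 34 genomic partners, 4 co-expressed: candidates are exactly the 4
  genomic34 <- tibble::tibble(
    genus = "Paenibacillus", pre_group = "Pre_49",
    prot_group = sprintf("Prot_%d", 1:34),
    rho = 0.6, p = 1e-9, p_adj = 1e-7, I = 12L, n = 44L)
  coexpr4 <- tibble::tibble(pre_group = "Pre_49",
                            prot_group = sprintf("Prot_%d", c(3, 7, 19, 28)),
                            rho = 0.6, p = 1e-3, p_adj = 0.01,
                            n_samples = 18L)
  cand <- intersect_evidence(genomic34, coexpr4)
  expect_equal(nrow(cand), 4)
  expect_setequal(cand$prot_group, coexpr4$prot_group)
  expect_true(nrow(cand) <= min(nrow(genomic34), nrow(coexpr4)))
})
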