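test_that("count matrix counts members per genome with zero rows preserved", {
  genomes <- tibble::tibble(genome_id = c("g1", "g2"), genus = "A")
  assignments <- tibble::tibble(member_id = c("m1", "m2", "m3"),
                                group_id = c("Pre_1", "Pre_1", "Pre_2"),
                                group_kind = "precursor")
  members <- tibble::tibble(member_id = c("m1", "m2", "m3"),
                            genome_id = c("g1", "g1", "g1"))
  cm <- build_count_matrix(assignments, members, genomes)
  expect_equal(cm$Pre_1, c(2L, 0L))
  expect_equal(cm$Pre_2, c(1L, 0L))
  # conservation: column sums equal group sizes
  expect_equal(colSums(cm[-1]), c(Pre_1 = 2, Pre_2 = 1))
  empty <- build_count_matrix(assignments[0, ], members[0, ], genomes)
  expect_equal(nrow(empty), 2)
  expect_equal(ncol(empty), 1)
  expect_error(build_count_matrix(assignments,
                                  dplyr::mutate(members, genome_id = "gX"),
                                  genomes), "unknown genome")
})

test_that("spearman_rho reproduces hand-computed rank correlations", {
  expect_identical(spearman_rho(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_identical(spearman_rho(c(1, 2, 3), c(3, 2, 1)), -1)
  # oracle: Pearson on average ranks x = (1, 2.5, 2.5, 4), y = (1, 3, 2, 4)
  expect_equal(brute_spearman(c(1, 2, 2, 4), c(1, 3, 2, 4)),
               4.5 / sqrt(22.5), tolerance = 1e-12)
  expect_equal(spearman_rho(c(1, 2, 2, 4), c(1, 3, 2, 4)), 4.5 / sqrt(22.5),
               tolerance = 1e-12)
  expect_true(is.na(spearman_rho(c(2, 2, 2), c(1, 2, 3))))
  expect_error(spearman_rho(1:3, 1:4), "equal length")
})

test_that("spearman_rho is invariant under strictly monotone transforms", {
  withr::with_seed(5, {
    for (i in 1:30) {
      x <- rpois(25, 3)
      y <- rpois(25, 3)
      r0 <- spearman_rho(x, y)
      if (is.na(r0)) next
      expect_equal(spearman_rho(exp(x), y), r0, tolerance = 1e-12)
      expect_equal(spearman_rho(x, y^3 + 10), r0, tolerance = 1e-12)
      expect_equal(spearman_rho(log1p(x), sqrt(y)), r0, tolerance = 1e-12)
    }
  })
})

test_that("one-sided p follows the upper-tail t approximation with clamped limits", {
  expect_identical(one_sided_p(0, 10), 0.5)
  expect_identical(one_sided_p(1, 10), 0)
  expect_identical(one_sided_p(-1, 10), 1)
  # oracle: numeric t-CDF at t = 0.6 * sqrt(10 / 0.64), df = 10
  t <- 0.6 * sqrt(10 / (1 - 0.36))
  expect_equal(brute_t_upper(t, 10), 0.01958, tolerance = 1e-4)
  expect_equal(one_sided_p(0.6, 12), brute_t_upper(t, 10), tolerance = 1e-10)
  expect_error(one_sided_p(0.5, 2), "n must be")
  # negative association lands near 1
  expect_gt(one_sided_p(-0.8, 20), 0.99)
})

test_that("exact permutation p-value matches enumeration and the t approximation asymptotically", {
  x <- c(3, 1, 4, 1, 5, 9)
  y <- c(2, 7, 1, 8, 2, 8)
  res <- spearman_test(x, y, exact = TRUE)
  # independent enumeration over all 720 permutations
  perms <- asplit(all_permutations(6), 1)
  rhos <- vapply(perms, function(idx) brute_spearman(x, y[idx]), numeric(1))
  expect_equal(res$p, mean(rhos >= res$rho - 1e-12), tolerance = 1e-12)
  expect_error(spearman_test(rnorm(9), rnorm(9), exact = TRUE), "n <= 8")
})

test_that("BH adjustment matches the textbook step-up procedure", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(0.05, 0.05, 0.05)), c(0.05, 0.05, 0.05))
  expect_equal(bh_adjust(0.5), 0.5)
  expect_error(bh_adjust(c(0.1, 1.2)), "outside")
  withr::with_seed(11, {
    for (i in 1:30) {
      p <- runif(sample(1:40, 1))
      adj <- bh_adjust(p)
      expect_equal(adj, brute_bh(p), tolerance = 1e-15)
      expect_true(all(adj >= p))                        # never below raw
      expect_equal(order(adj, p), order(p, adj))        # order preserved
    }
  })
})

test_that("per-genus correlation respects presence, support and pooled BH", {
  genomes <- tibble::tibble(
    genome_id = sprintf("g%02d", 1:40),
    genus = rep(c("A", "B"), each = 20))
  counts <- withr::with_seed(3, as.integer(rpois(40, 2)))
  pre <- tibble::tibble(genome_id = genomes$genome_id, Pre_1 = counts,
                        Pre_2 = c(as.integer(rpois(20, 2)), rep(0L, 20)))
  prot <- tibble::tibble(genome_id = genomes$genome_id, Prot_1 = counts,
                         Prot_2 = as.integer(rpois(40, 2)))
  edges <- tidy(correlate_groups(pre, prot, genomes))
  planted <- dplyr::filter(edges, pre_group == "Pre_1", prot_group == "Prot_1")
  expect_equal(planted$rho, c(1, 1))  # identical vectors in both genera
  expect_equal(planted$I,
               c(sum(counts[1:20] >= 1), sum(counts[21:40] >= 1)))
  expect_equal(unique(planted$n), 20L)
  # Pre_2 absent from genus B: no edge emitted there
  expect_equal(nrow(dplyr::filter(edges, pre_group == "Pre_2", genus == "B")), 0)
  # pooled BH over all defined tests
  ok <- !is.na(edges$p)
  expect_equal(edges$p_adj[ok], brute_bh(edges$p[ok]), tolerance = 1e-12)
  per_genus <- tidy(correlate_groups(pre, prot, genomes,
                                     bh_scope = "per_genus"))
  a <- dplyr::filter(per_genus, genus == "A", !is.na(p))
  expect_equal(a$p_adj, brute_bh(a$p), tolerance = 1e-12)
  expect_error(correlate_groups(pre, prot, genomes[0, ]), "empty genus")
})

test_that("constant count vectors give undefined rho and leave the test family", {
  genomes <- tibble::tibble(genome_id = sprintf("g%d", 1:10), genus = "A")
  pre <- tibble::tibble(genome_id = genomes$genome_id,
                        Pre_1 = rep(2L, 10),
                        Pre_2 = as.integer(c(0, 1, 2, 3, 0, 1, 2, 3, 0, 1)))
  prot <- tibble::tibble(genome_id = genomes$genome_id,
                         Prot_1 = as.integer(c(1, 0, 2, 1, 0, 3, 1, 0, 2, 1)))
  edges <- tidy(correlate_groups(pre, prot, genomes))
  const <- dplyr::filter(edges, pre_group == "Pre_1")
  expect_true(is.na(const$rho) && is.na(const$p) && is.na(const$p_adj))
  expect_equal(sum(!is.na(edges$p)), 1)
  expect_equal(nrow(filter_edges(edges, rho_min = -2, padj_max = 2,
                                 min_I = 0)), 1)
})

test_that("raw p-values are calibrated on independent count columns", {
  gen <- simulate_genomic(sim_config(n_genera = 2, genomes_per_genus = 50,
                                     n_planted_pairs = 0,
                                     n_coexpressed_pairs = 0,
                                     n_background_pre = 40,
                                     n_background_prot = 50, seed = 99))
  edges <- tidy(correlate_groups(gen$counts_pre, gen$counts_prot, gen$genomes))
  p <- edges$p[!is.na(edges$p)]
  expect_gt(length(p), 900)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.02)
})

test_that("prioritization bounds are strict for rho and pAdj, closed for I", {
  base <- tibble::tibble(genus = "A", pre_group = "Pre_1",
                         prot_group = "Prot_1", p = 1e-9, n = 40L)
  edges <- dplyr::bind_rows(
    dplyr::mutate(base, rho = 0.30, p_adj = 1e-7, I = 12L),  # rho at bound
    dplyr::mutate(base, rho = 0.90, p_adj = 1e-7, I = 10L),  # I at bound
    dplyr::mutate(base, rho = 0.90, p_adj = 1e-5, I = 12L),  # pAdj at bound
    dplyr::mutate(base, rho = 0.90, p_adj = 1e-7, I = 9L),
    dplyr::mutate(base, rho = NA_real_, p_adj = NA_real_, I = 12L))
  kept <- filter_edges(edges)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$I, 10L)
})

test_that("network assembly and volcano data behave on edge cases", {
  edges <- tibble::tibble(
    genus = "A", pre_group = "Pre_1", prot_group = c("Prot_1", "Prot_2"),
    rho = c(0.9, 1), p = c(1e-8, 0), p_adj = c(1e-6, 0), I = c(12L, 15L),
    n = 30L)
  g <- assemble_network(edges)
  expect_equal(igraph::vcount(g), 3)  # shared precursor node
  expect_equal(igraph::ecount(g), 2)
  v <- volcano_table(edges)
  expect_equal(v$neg_log10_p_adj[2], 300)  # p_adj = 0 floored at 1e-300
  empty <- assemble_network(edges[0, ])
  expect_equal(igraph::vcount(empty), 0)
  expect_equal(nrow(volcano_table(edges[0, ])), 0)
  p <- autoplot(correlate_groups(
    tibble::tibble(genome_id = sprintf("g%d", 1:6),
                   Pre_1 = as.integer(c(0, 1, 2, 3, 1, 2))),
    tibble::tibble(genome_id = sprintf("g%d", 1:6),
                   Prot_1 = as.integer(c(1, 1, 2, 4, 0, 2))),
    tibble::tibble(genome_id = sprintf("g%d", 1:6), genus = "A")))
  expect_s3_class(p, "ggplot")
})

test_that("tidy and glance summarize a correlation result", {
  gen <- toy_genomic()
  res <- correlate_groups(gen$counts_pre, gen$counts_prot, gen$genomes)
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_false(inherits(td, "lan_corr"))
  expect_named(td, c("genus", "pre_group", "prot_group", "rho", "p", "p_adj",
                     "I", "n"))
  gl <- glance(res)
  expect_equal(gl$n_tests, nrow(td))
  expect_equal(gl$n_genera, 4)
  expect_equal(gl$bh_scope, "pooled")
})
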