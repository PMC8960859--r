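# Small in-code fixtures shared across test files.

toy_annotation_lines <- function() {
  c(paste(c("genome_id", "genus", "protein_id", "contig", "start", "end",
            "strand", "product", "organism", "bgc_id", "bgc_start",
            "bgc_end", "lan_class", "anchor_start", "anchor_end"),
          collapse = "\t"),
    "g1\tStreptomyces\tp1\tc1\t100\t400\t+\tlanthionine synthetase LanC-like protein\t.\tb1\t50\t900\tIII\t100\t400",
    "g1\tStreptomyces\tp2\tc1\t500\t800\t-\tzinc metallopeptidase\t.\tb1\t50\t900\tIII\t100\t400",
    "g2\tPaenibacillus\tp3\tc1\t10\t200\t+\tABC transporter permease\t.\t.\t.\t.\t.\t.\t.")
}

write_toy_annotation <- function(path = withr::local_tempfile(fileext = ".tsv",
                                                              .local_envir = parent.frame())) {
  writeLines(toy_annotation_lines(), path)
  path
}

toy_genomic <- function(seed = 11) {
  simulate_genomic(sim_config(n_genera = 4, genomes_per_genus = 20,
                              n_planted_pairs = 2, n_background_pre = 6,
                              n_background_prot = 6, seed = seed))
}

random_edges <- function(n, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    genus = sample(c("A", "B"), n, replace = TRUE),
    pre_group = sprintf("Pre_%d", sample(5, n, replace = TRUE)),
    prot_group = sprintf("Prot_%d", seq_len(n)),
    rho = round(stats::runif(n, -1, 1), 3),
    p = round(stats::runif(n), 6),
    p_adj = round(stats::runif(n), 6),
    I = sample(0:20, n, replace = TRUE),
    n = 30L))
}
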