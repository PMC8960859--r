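---
title: "Correlational networking of precursor peptides and hidden proteases: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlational networking of precursor peptides and hidden proteases: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lanticor)
library(dplyr)
```

## The statistical model

The workflow rests on one assumption: a protease that matures a given family
of lanthipeptide precursor peptides co-occurs with that family across
genomes, even when its gene sits far outside the biosynthetic gene cluster
(BGC). Occurrence is quantified as a count — how many members of a sequence
group a genome encodes — and association as Spearman's rank correlation
$\rho$, the Pearson correlation of average ranks. Rank correlation is the
right tool here because gene-family counts are sparse, zero-inflated and far
from normal; $\rho$ is invariant to any monotone transform of either margin
and therefore indifferent to how copy numbers scale.

For a precursor group and a protease group with counts $x, y$ over the $n$
genomes of one genus, the package computes

$$\rho = \mathrm{cor}\big(\mathrm{rank}(x), \mathrm{rank}(y)\big), \qquad
  t = \rho\sqrt{\frac{n-2}{1-\rho^2}},$$

and a one-sided upper-tail p-value $P(T_{n-2} \ge t)$. The test is one-sided
because the workflow searches for co-occurring partners; negative
associations surface with $p \approx 1$ and are not discovery targets. At
the clamped limits, $\rho = 1$ maps to $p = 0$ and $\rho = -1$ to $p = 1$;
the $t$ approximation is undefined there, and the clamp is a deliberate
convention. An exact conditional permutation p-value (enumeration of all
$n!$ rank permutations, honoring ties) is available in `spearman_test()` for
$n \le 8$; beyond that the enumeration grows past what interactive use
tolerates and the $t$ approximation is already accurate.

Tests are stratified **by genus**. Closely related genomes inherit gene
content together, and pooling across the tree would manufacture
correlations from shared ancestry alone; within a genus the phylogenetic
signal is much flatter. One edge is emitted per (genus, precursor group,
protease group) with both groups present in at least one genome of the
genus; pairs absent from a genus are not meaningful tests and would only
dilute the multiple-testing correction. A pair whose count vector is
constant within a genus has no defined rank correlation; such tests are
reported with `rho = NA`, excluded from adjustment and filters, and
serialized explicitly as `NA` rather than silently dropped or zeroed —
assigning $\rho = 0$ would inflate the test family with non-tests.

Benjamini–Hochberg adjustment is applied once over **all** genus-level tests
pooled (`bh_scope = "pooled"`). The alternative, adjusting within each
genus, makes small genera anomalously permissive; pooling matches the view
of the analysis as a single volcano of all tested pairs and is the more
conservative reading. Both are available.

Prioritization keeps edges with $\rho > 0.3$, adjusted $p < 10^{-5}$, and
genome support $I \ge 10$, where $I$ counts genomes containing at least one
member of both groups. The bounds are strict for $\rho$ and adjusted $p$
and closed for $I$, mirroring how the thresholds are written
($\rho > 0.3$, pAdj $< 10^{-5}$, $I \ge 10$); the boundary cases are tested
explicitly.

## Mining and grouping

Candidate BGC proteases are proteins inside BGCs whose product annotation
contains one of five keywords (peptidase, proteinase, protease, hydrolase,
beta-lactamase) as a **case-insensitive substring** — annotation
capitalization is wildly inconsistent in public genomes, so case-sensitive
matching would be a silent filter. Matching is applied to the product field
only. Their Pfam domain hits define the protease domain pool: an accession
enters the pool with at least 5 hits scoring strictly above 0. The
published pool was additionally curated by hand; curation is modeled as
explicit allow/deny lists (`include` / `exclude`) rather than an invented
heuristic. Genome-wide candidates are then all proteins with at least one
positive-scoring pool domain. The clustered-protease check asks whether any
candidate overlaps the closed interval extending 10 kb on each side of the
LanC-like anchor gene, on the same contig; overlap is non-empty
intersection of 1-based inclusive intervals.

Grouping is connected-component clustering of the pairwise-identity graph:
an edge joins two sequences with identity at or above the threshold (0.45
for proteases, 0.6 for precursors), and groups are the components, so
chains of pairwise similarity deliberately merge remote homologs. Identity
is computed from an optimal end-to-end alignment with match $+1$, mismatch
$0$ and linear gap $-1$, as matches divided by alignment columns
(`len(a) + len(b) - aligned pairs`). This is a desk-scale stand-in for a
production clustering tool: the production tool's local-alignment identity
with coverage rules is not recoverable bit-exactly from its description,
so the package preserves the algorithmic role (threshold graph + connected
components) with a fully specified, deterministic metric instead. Scoring
ties cannot change the reported identity in the frozen example cases, and
the implementation is checked against an exhaustive alignment enumeration
on short strings. Group labels `Pre_k` / `Prot_k` rank groups by
decreasing size with ties broken by the lexicographically smallest member
id, making labels independent of input order.

## Co-expression refinement

Transcript abundance per gene is TPM: with count $c_i$ and length $l_i$,
$\mathrm{TPM}_i = 10^6 (c_i/l_i) / \sum_j (c_j/l_j)$, so every
non-degenerate sample sums to $10^6$ exactly. TPM of genes in the same
group is summed into a samples-by-groups matrix, trimmed to groups present
in the genomic network (no overlap at all is an error — it means the inputs
do not belong together). Co-expression edges use the same
$\rho$ / one-sided $p$ / BH machinery across samples with thresholds
$\rho > 0.4$, adjusted $p < 0.05$, adjusted **within each strain's test
family**: different strains are separate experiments with separate
matrices, so pooling their p-values would mix families. Combination across
strains defaults to intersection ("present in the results of all strains"),
with union available because the requirement is genuinely ambiguous in
prose. The final candidates are pairs supported by both the genomic network
and the combined co-expression evidence.

## What the synthetic generator emulates

`simulate_genomic()` draws, for each planted precursor-protease pair and
each genus, counts from zero-inflated Poisson marginals (extra mass
`zero_inflation = 0.25` at zero, rate 2 — genomes mostly carry 0–4 copies
of a family) linked by a Gaussian copula. The copula correlation is
calibrated, once per marginal setting via a fixed-seed Monte-Carlo grid, so
that the pair's **population Spearman correlation on the count scale equals
`effect`**; the endpoints are exact (0 = independence, 1 = duplicated
counts). Calibration is empirical because no closed form maps a copula
parameter to the rank correlation of tied, zero-inflated counts. Background
groups are independent and each restricted to a single home genus: real
gene families are taxonomically restricted, and this is what keeps the
tested-pair count far below the full groups-cross product, as the presence
precondition does on real data. Planted pairs, by contrast, occur in every
genus — a precursor-protease partnership is a property of the two families
and recurs wherever both occur.

Defaults (20 genera × 50 genomes, 5 planted pairs at `effect = 0.7`, 50
background groups per side) are the package's reference study conditions,
chosen to mirror the regime the method targets: strong planted
correlations (the real discoveries had $\rho \approx 0.7$–1), genus sizes
large enough for the $t$ approximation, and a test family dominated by null
pairs.

`simulate_sequences()` plants families as point-mutated copies of mutually
dissimilar random consensi. Each member substitutes exactly
`round(seq_length * mutation_rate)` positions, so within-family identity is
at least $1 - 2 \times$ `mutation_rate` $= 0.84$ **by construction**, and
consensi are rejection-sampled to pairwise identity $\le 0.2$ so
cross-family identity stays below 0.3; both properties are re-verified post
hoc and violations are an error, not a warning.

`simulate_transcriptome()` gives each group a per-sample latent expression
factor; a co-expressed pair's two factors share correlation
`coexpr_effect = 0.9` (co-transcribed partners correlate strongly at the
rank level), decoy pairs and background groups get independent factors, and
gene counts are Poisson around length-scaled log-normal rates with lengths
from 300–3000 nt. `simulate_annotation()` plants a configurable fraction of
BGCs (default one third, the share reported for real lanthipeptide
neighborhoods) with no protease gene inside the 10-kb window, so the
window check's failure rate has an exact expected value.

What the generator does **not** emulate: real sequence composition and
domain architecture, phylogenetic structure finer than the genus blocks,
library-composition artifacts in RNA-seq, and correlated annotation errors.
Passing tests therefore demonstrate that the statistics, filters and
plumbing do what they claim under the stated model — not that the
biological discovery rate on real genomes matches.

## Scoring recovery

`score_recovery()` compares prioritized edges with the planted truth at the
**pair** level by default: a planted partnership counts as recovered if it
is significant in at least one genus. The partnership — not its per-genus
sighting — is the unit the workflow reports and takes into refinement, and
per-genus ("triple") recall is intrinsically capped well below 1 in this
regime: at population $\rho = 0.7$ and $n = 50$, an adjusted-p threshold of
$10^{-5}$ requires a sample $\rho$ of roughly 0.62, and the sampling spread
of $\rho$ (Fisher-z scale s.d. $\approx 0.15$) leaves a sizable minority of
per-genus tests below it. Triple-level scoring remains available and is
reported by the module tests for transparency.

## Numerical and design details

* Ranks use midranks for ties everywhere; the rank matrices are correlated
  in one BLAS call per genus, so the per-genus pass scales as ranking plus
  one matrix product.
* Genera with fewer than 3 genomes are skipped with a warning: the $t$
  approximation needs $n \ge 3$, and a two-genome "correlation" carries no
  information.
* Volcano tables floor adjusted p at `1e-300` before $-\log_{10}$ so
  clamped zero p-values stay finite.
* All tables are UTF-8 TSV with fixed headers; missing optional fields are
  `"."`; undefined $\rho$ is the literal string `NA`. Write-then-read is
  the identity on every table type, and this is tested.
* All generator randomness flows from the single config seed through
  isolated RNG scopes, so generators are pure functions of their
  configuration and never disturb the caller's RNG stream; the calibration
  grid uses its own fixed seed so the effect-to-copula map is a
  deterministic function.
* Problem sizes in the test-suite and acceptance runs (desk scale: tens of
  groups, a thousand genomes, 10,000 null tests) were chosen so the whole
  suite completes in about a minute while keeping Monte-Carlo error well
  inside the asserted bands.

## Known limitations

The identity metric is not bit-compatible with production sequence
clustering tools, so group boundaries on real data will differ from a run
of those tools; the correlation machinery downstream is agnostic to this.
Genus stratification damps but does not remove phylogenetic confounding
within genera. The one-sided test gives no route to discovering negative
associations (e.g., mutually exclusive partners). The exact permutation
p-value is limited to $n \le 8$. Extremely strong correlations are reported
with adjusted p clamped to 0 rather than an exact tail value, which is
conservative for ranking but loses resolution among perfect correlations.

## A compact end-to-end run

```{r example, eval = FALSE}
cfg <- sim_config(n_genera = 6, genomes_per_genus = 50, n_planted_pairs = 2,
                  n_coexpressed_pairs = 1, n_background_pre = 10,
                  n_background_prot = 10, seed = 42)
gen <- simulate_genomic(cfg)
res <- correlate_groups(gen$counts_pre, gen$counts_prot, gen$genomes)
kept <- filter_edges(res)
trx <- simulate_transcriptome(cfg, gen$truth)
per_strain <- lapply(trx$strains, function(x)
  coexpression_edges(trim_to_network(group_tpm(tpm(x), trx$gene_groups),
                                     kept)))
intersect_evidence(kept, combine_strains(per_strain)) |>
  distinct(pre_group, prot_group)
```

The same chain, file-to-file with a manifest, is `run_pipeline()`; the
paper-default group-size cutoffs (100/10) are kept as code defaults and
overridden explicitly in desk-scale configurations, where planted families
have 12 members.
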