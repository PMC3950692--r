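---
title: "Methods: chromatin communities and microRNA gene regulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromatin communities and microRNA gene regulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirchromnet)
```

## The analysis

RNAPII-associated ChIA-PET experiments report two things at once: where RNA
polymerase II binds (peaks, with intensities) and which pairs of genomic
anchors are held together in space by RNAPII (duplex interactions).
`mirchromnet` uses both to ask how microRNA genes (MIRs) are transcribed in
three-dimensional chromatin context: which MIRs have promoters, which sit in
chromatin communities with other genes, how miRNA-target pairs distribute
over those communities, and whether family or disease labels co-localize in
the MIR-MIR interactome.

The pipeline has five stages, each a small set of exported functions over
plain data frames:

1. **Promoter annotation** (`assign_tss`, `classify_promoter_sharing`,
   `mark_profile`). MIR TSSs come from a three-tier evidence cascade with
   strict precedence: curated TSS tables, then CAGE tags, then RNAPII peak
   centers, searching a strand-aware 50 kb window upstream of the pre-miRNA
   5' end. A promoter is *shared* when a coding-gene TSS lies within ±2 kb
   (inclusive). Mark profiles count peak centers within ±5 kb of the TSS.
2. **Chromatin network** (`filter_sv_blacklist`, `build_network`,
   `find_communities`). After removing interactions whose anchors overlap a
   structural-variation blacklist, every duplex interaction links the
   entities whose TSS ±2 kb window overlaps anchor A to those on anchor B
   (cross product; entities sharing a single anchor are not linked by that
   interaction alone). An edge is retained when some cell line supports it
   with at least two distinct replicates. Chromatin communities are the
   connected components of the retained graph; the largest is the giant
   community.
3. **MIR interaction models** (`build_mir_network`,
   `assign_interaction_model`). MIR-MIR pairs obey the same replicate rule,
   relaxed to a single replicate for genomic neighbours (same chromosome,
   pre-miRNA gap ≤ 10 kb) because neighbouring contacts are the easiest for
   ChIA-PET to detect and clustered MIRs are co-transcribed. MIRs in the
   network are in the *interaction* model (submodel `mir_mir` when they have
   a MIR-MIR edge); MIRs with promoter RNAPII binding but no interactions
   are *basal*; the rest are *not assigned*.
4. **Community-level target enrichment** (`map_pairs_to_communities`,
   `community_link_network`, `permutation_percent_targeted`,
   `shared_enriched_terms`). Target pairs supported by ≥ 2 prediction
   databases are mapped onto the network; two communities are linked when ≥
   10 mapped pairs join them, tested with an upper-tail hypergeometric test
   and Benjamini-Hochberg control at FDR 0.001. Permutation controls redraw
   same-size random gene sets (10^3 randomizations) and report Mann-Whitney
   p-values and the empirical FDR.
5. **Family/disease co-localization and expression**
   (`group_contact_enrichment`, `disease_concordance`,
   `community_disease_chi2`, `mark_correlation`, `mantel_test`,
   `expression_by_model`). Within-group contact counts are compared against
   nulls that redraw the same number of edges from all pairs of networked
   MIRs; disease-class enrichment per community uses a 1-df chi-square
   against the background class frequency (classes with ≥ 2 member MIRs,
   alpha 0.001); mark-correlation structure is compared between MIR subsets
   with a Mantel test.

All thresholds live in a single `pipeline_config()` object: 50 kb TSS
search, ±2 kb promoter-share and anchor windows, ±5 kb mark window, ≥ 2
replicates (≥ 1 for neighbours within 10 kb), ≥ 2 databases, ≥ 10 pairs per
tested link at FDR 0.001, 10^3 permutations, BH FDR 0.05 for term
enrichment, chi-square alpha 0.001 with ≥ 2 MIRs per class.

## Statistical conventions

* **Coordinates.** Everything internal is 0-based half-open; GFF3 converts
  on read/write. A window "x ± w" is closed at base resolution: a feature
  exactly w away counts. Interval overlap means ≥ 1 shared base, so an
  interval abutting a blacklist region survives filtering.
* **Hypergeometric margins for community links.** The population is all
  mapped between-community pairs, successes are pairs incident to one
  community of the link, draws are pairs incident to the other, and the
  observed count is the pooled (undirected) pair count on the link. The
  source analyses do not pin these margins down; this pair-based convention
  is fixed here and used identically for observed and permuted data.
* **The depletion 2x2 table.** Mapped pairs are crossed by within/between
  status and by whether the pair's MIR endpoint lies in the giant
  community; a zero margin returns p = 1 with a warning rather than an
  error.
* **Empirical FDR.** Always the add-one estimator
  `(1 + #{null >= observed}) / (1 + n_permutations)`, which cannot return
  zero; with 10^3 permutations the smallest attainable value is 1/1001.
* **Mantel test.** Pearson correlation of vectorized upper triangles;
  the null permutes row/column labels of the second matrix jointly; same
  add-one estimator. Matrices smaller than 3x3 are rejected.
* **Ties.** Within the upstream evidence windows, distance ties can only
  occur at identical coordinates; they resolve by higher intensity and then
  smaller coordinate. Rank tests fall back to the normal approximation when
  ties prevent exact p-values.
* **Degenerate inputs.** Comparisons with an empty group, constant
  expression columns, and term-less communities are reported as
  not-applicable (`NA`) rather than errors; an empty MIR edge list is an
  error for the group-contact null, which cannot be formed without edges.

## What the synthetic generator emulates

`simulation_config()` / `simulate_bundle()` produce a complete input bundle
with recoverable ground truth. The defaults are the package's study
conditions and are deliberately fixed:

* **Two cell lines, K562 with 3 and MCF7 with 4 replicates** — the
  replicate structure the ≥ 2-replicate filter is designed for.
* **Half of MIRs intragenic**, placed inside a host gene on the same
  strand; 60% of them share the host promoter exactly and all inherit
  host-correlated activity, emulating co-transcription with the host.
* **Planted communities.** 26 communities over genes and unclustered
  intergenic MIRs; sizes follow a negative binomial (mean 5) except six
  "hub" communities of ≥ 45 members with six MIRs each. Every community is
  wired by a random spanning tree plus 50% extra edges; each planted edge
  is emitted independently per replicate with probability 0.8 (so the
  probability of surviving a 3-replicate cell line's filter is the binomial
  0.896). A fifth of communities are restricted to one cell line,
  emulating cell-specific chromatin architecture.
* **Noise interactions** (30 per replicate in expectation) each appear in
  exactly one replicate, making the replicate filter's effect exact: no
  noise edge can survive. Clustered MIR neighbours are joined by
  single-replicate interactions so only the neighbour rule can recover
  them.
* **Targets.** Each (MIR, gene) pair is a target with probability 0.05,
  multiplied by 5 between the three planted enriched hub pairs and by 0.1
  within a community; database support is drawn from a fixed distribution
  over 1..6 with 65% of pairs reaching the ≥ 2-database filter. The base
  rate is far above genome-scale target densities by design: at a few
  hundred genes it keeps mapped-pair counts in the regime where the ≥ 10
  pair threshold and the hypergeometric test are both exercised.
* **Expression and marks.** Expression is `10 * activity` with lognormal
  noise (sd 0.4 on the log scale); community members draw activity around
  e^2, basal entities around e^0.5, silent entities around e^-1, so the
  interaction > basal > not-assigned expression ordering is planted.
  Active marks (H3K4me3, H3K4me2, H3K9ac, H3K27ac) are emitted at rates
  increasing in activity, repressive marks (H3K27me3, H3K9me3) at rates
  decreasing in it.

Two geometric choices make the planted structure *identifiable* rather than
merely present. First, intergenic gaps are 110-130 kb with 52 kb placement
margins, wider than the 50 kb TSS search window, so no MIR can pick up
another locus' promoter evidence and be teleported onto a foreign promoter.
Second, TSSs of distinct planted communities are always farther apart than
one TSS window plus the widest anchor (> 8 kb), so no single entity window
can touch anchors from two communities and merge planted blocks; host genes
of intragenic MIRs and clustered MIRs are excluded from community sampling
for the same reason. Community MIR members always carry exact curated or
CAGE evidence; the RNAPII tier is exercised by active non-community MIRs.
These margins are what let the recovery test demand *exact* equality with
the planted partition under perfect reproducibility instead of approximate
agreement.

The hub geometry (six large mixed communities carrying the enrichment)
follows a power analysis of the pair-based hypergeometric margins: because
the tested link's own pairs inflate both margins, the signal-to-expectation
ratio is bounded near `5 * 2ab / (a + b)^2` (a, b the hub's shares of
networked MIRs and genes), so detection at FDR 0.001 with a multiplier of 5
needs links whose baseline expectation is already tens of pairs — hence
large hubs, several of them, with balanced MIR/gene composition.

What passing tests on these bundles does **not** show: robustness to real
anchor-calling noise (anchors here always cover their TSSs), to promoter
mis-annotation (community members are exactly annotated by construction),
to genome-scale sparsity of targets, or to biological confounders such as
copy-number effects on expression. The generator is a correctness harness,
not a realism benchmark.

## Worked example

```{r pipeline, eval = FALSE}
cfg <- pipeline_config(random_seed = 1)
bundle <- simulate_bundle(simulation_config(seed = 1))

calls <- assign_tss(bundle$mirs, bundle$curated_tss, bundle$cage_tags,
                    bundle$rnapii_peaks, cfg)
calls <- classify_promoter_sharing(calls, bundle$genes, cfg)
tier_summary(calls)

tss_index <- make_tss_index(bundle$genes, calls)
interactions <- filter_sv_blacklist(bundle$interactions, bundle$blacklist)
network <- build_network(interactions, tss_index, cfg)
communities <- find_communities(network)
communities

pairs <- filter_target_pairs(bundle$targets, cfg)
mapping <- map_pairs_to_communities(pairs, communities)
community_link_network(mapping, communities, cfg)
```

The problem sizes used throughout the test-suite and the acceptance script
are those of the default configuration: a four-chromosome genome with 420
genes and 150 MIRs, roughly 2,500-3,000 duplex interactions across seven
replicates, and about 2,000 target pairs after filtering. The test suite
additionally runs a half-size configuration for oracle comparisons.

## Design choices where the design was open

* **Communities are connected components.** The construction language for
  the network ("connectivity of overlapping anchors", a single giant
  community) is component language; no modularity-optimizing algorithm is
  implied, and components keep every downstream null exactly computable.
  `find_communities` is the single place to swap in an alternative.
* **Anchors are never pre-merged.** Entity pairs are derived per duplex
  interaction and aggregated, so anchor-overlap connectivity emerges at
  the entity level without an anchor-merging heuristic.
* **The RNAPII-tier TSS is the peak center**, matching the center
  convention used everywhere else for peaks.
* **"Neighbours on the genome"** is formalized as a pre-miRNA gap of at
  most 10 kb, the conventional miRNA-cluster distance, and is
  configurable.
* **Indirect MIR-MIR links** join same-community MIRs without a direct
  edge when the edges on the shortest connecting path carry at least two
  distinct (cell line, replicate) sources; the accounting for "independent
  data sets" along a path is not otherwise pinned down, and the shortest
  path makes the criterion deterministic.
* **Interaction-model membership** includes MIRs whose only network
  participation is a neighbour-rule MIR-MIR edge; they have chromatin
  interactions even though the gene-level ≥ 2-replicate graph excludes
  them.
* **Promoter sharing ignores relative strand**; bidirectional-promoter
  structure is reported as the same/opposite-strand stratification of
  `intensity_expression_report`, not as a separate call class.
* **H3K4me3 support is a reported flag**, not a filter: a call is flagged
  when an H3K4me3 peak center lies within the promoter-share window.
  Manual adjudication of intragenic own-promoters is out of scope; the
  flag is the automatic residue of that step.
* **Size-2 components count as communities**; size filters are applied by
  consumers, not by `find_communities`.

## Known limitations

* Connected components cannot split a community bridged by a single
  reproducible spurious contact; with the ≥ 2-replicate filter this
  requires correlated noise, which the generator deliberately never emits.
* The pair-based hypergeometric margins make closely-tied hub pairs
  conservative (their own signal inflates the null expectation); the
  sensitivity re-run at ≥ 5 pairs (`min_pairs = 5`) is the built-in probe
  for threshold dependence.
* Percent-targeted controls depend on the gene universe supplied; with no
  universe given they fall back to genes seen in the network or the target
  table, which understates the control's spread when many genes are
  entirely untargeted.
* With few mark columns the Mantel permutation null is coarse (n! label
  permutations); the reported p cannot fall below 1/(n_permutations + 1)
  regardless.
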