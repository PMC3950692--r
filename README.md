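# mirchromnet

Integrative analysis of RNAPII-associated 3D chromatin interactions
(ChIA-PET) and microRNA gene (MIR) transcription, for regulatory-genomics
analysts working with processed ChIA-PET interaction and peak data.

ChIA-PET against RNA polymerase II yields both binding peaks and *duplex
interactions* — pairs of genomic anchors held together by RNAPII. Genes
whose transcription start sites map onto interacting anchors are
"chromatin linked"; the connected components of the resulting gene-level
graph are **chromatin communities**, interpreted as co-transcribed spatial
modules. `mirchromnet` places microRNA genes into this picture:

- **Tiered promoter annotation.** MIR TSSs by precedence curated > CAGE >
  RNAPII peak, searching the strand-aware 50 kb window upstream of the
  pre-miRNA 5′ end; promoters within ±2 kb of a coding-gene TSS are
  *shared*, otherwise *isolated*. Mark profiles count peak centers within
  ±5 kb of the TSS.
- **Chromatin network and communities.** Anchors are mapped to entities
  via TSS ±2 kb windows; an edge requires recovery by ≥ 2 replicates in
  some cell line (SV-blacklisted anchors removed first); communities are
  connected components, the largest being the giant community.
- **MIR interaction models.** Each MIR is assigned to the *interaction*
  (submodels MIR–MIR / MIR–gene-only), *basal transcription* (promoter
  RNAPII binding, no interactions) or *not assigned* model. MIR–MIR edges
  relax the replicate rule to ≥ 1 for genomic neighbours (gap ≤ 10 kb).
- **Community-level miRNA–target enrichment.** Target pairs supported by
  ≥ 2 prediction databases are mapped onto communities; community pairs
  with ≥ 10 mapped pairs are tested by an upper-tail hypergeometric test
  (population = all mapped between-community pairs, margins = pairs
  incident to each community), BH-controlled at FDR 0.001; a Fisher exact
  test probes within-community target depletion, and permutation controls
  (10³ randomizations, Mann–Whitney, empirical FDR
  `(1 + #{null ≥ obs}) / (1 + n)`) calibrate percent-of-genes-targeted and
  shared enriched GO-style terms.
- **Family/disease co-localization.** Within-family and within-disease
  contact enrichment against nulls that redraw the same number of edges
  from all networked MIR pairs; disease-category concordance of edges; a
  1-df χ² disease-class test per community (classes with ≥ 2 member MIRs,
  α = 0.001).
- **Expression and chromatin marks.** Spearman mark-correlation matrices
  with average-linkage clustering, a seeded Mantel test between MIR
  subsets, RNAPII-intensity-vs-expression reports, and expression
  comparisons across interaction models (one-sided Mann–Whitney).

A seeded synthetic-data generator (`simulate_bundle()`) emulates the study
conditions — two cell lines with 3 and 4 replicates, planted communities
with configurable replicate reproducibility, single-replicate noise
interactions, planted target enrichment between community pairs and
depletion within them — so every stage has a recoverable ground truth.

## Worked example

```r
library(mirchromnet)

cfg <- pipeline_config(random_seed = 1)          # all thresholds in one place
bundle <- simulate_bundle(simulation_config(seed = 1))

calls <- assign_tss(bundle$mirs, bundle$curated_tss, bundle$cage_tags,
                    bundle$rnapii_peaks, cfg)
calls <- classify_promoter_sharing(calls, bundle$genes, cfg)
str(tier_summary(calls))
#> List of 9
#>  $ n_mirs               : int 150
#>  $ n_curated            : int 100
#>  $ n_cage               : int 32
#>  $ n_rnapii             : int 14
#>  $ n_none               : int 4
#>  $ n_with_promoter      : int 146
#>  $ percent_with_promoter: num 97.3
#>  $ n_shared             : int 38
#>  $ percent_shared       : num 25.3
```

146 of 150 MIRs get a promoter (the four without lack both exact evidence
and nearby RNAPII binding); 25.3% share a promoter with a coding gene.

```r
tss_index <- make_tss_index(bundle$genes, calls)
interactions <- filter_sv_blacklist(bundle$interactions, bundle$blacklist)
network <- build_network(interactions, tss_index, cfg)
communities <- find_communities(network)
communities
#> Chromatin communities: 26 
#>   giant community size: 45 
#>   size distribution:
#>  2  3  4  5  6 45 
#>  5  7  2  5  1  6
```

The ≥ 2-replicate filter leaves 455 edges over 340 entities (45 of them
MIRs); the 26 components recover the generator's planted partition — six
large hub communities and twenty small ones.

```r
mapping <- map_pairs_to_communities(filter_target_pairs(bundle$targets, cfg),
                                    communities)
mapping
#> miRNA-target pair mapping: 2241 input, 618 mapped (8 within, 610 between)
#>   within-community share of mapped pairs: 1.3%
head(community_link_network(mapping, communities, cfg), 3)
#>   community_a community_b n_pairs      p_value      q_value significant
#> 1          C3          C6      78 3.055072e-12 4.582608e-11        TRUE
#> 2          C1          C5      76 2.016382e-07 1.512286e-06        TRUE
#> 3          C2          C4      83 7.922552e-07 3.961276e-06        TRUE
```

Only 1.3% of mapped miRNA–target pairs fall within a community — targets
avoid the community "their" MIR is transcribed from — and the three
significant community links are exactly the generator's planted enriched
hub pairs, at q-values far below the 0.001 threshold.

See `vignettes/mirchromnet-methods.Rmd` for the model, conventions
(coordinate system, hypergeometric margins, empirical-FDR estimator), the
generator's design and its limits. A thin command-line wrapper over the
same functions is installed at `inst/cli/mirchromnet.R`
(`Rscript mirchromnet.R simulate --seed 1 --outdir data/` and so on).

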