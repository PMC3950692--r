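test_that("generators are pure functions of (config, seed)", {
  b1 <- simulate_bundle(small_sim_config(seed = 9))
  b2 <- simulate_bundle(small_sim_config(seed = 9))
  for (el in c("genes", "mirs", "interactions", "rnapii_peaks", "expression",
               "targets", "curated_tss", "cage_tags", "terms", "mark_table"))
    expect_identical(b1[[el]], b2[[el]])
  b3 <- simulate_bundle(small_sim_config(seed = 10))
  expect_false(identical(b1$interactions, b3$interactions))
})

test_that("a genome with no MIRs still yields valid genes", {
  g <- generate_genome(small_sim_config(seed = 2, n_mirs = 0L))
  expect_equal(nrow(g$mirs), 0)
  expect_gt(nrow(g$genes), 0)
  expect_silent(validate_intervals(g$genes, "genes"))
  b <- simulate_bundle(small_sim_config(seed = 2, n_mirs = 0L))
  expect_equal(nrow(b$curated_tss), 0)
})

test_that("genome placement respects annotation invariants", {
  g <- generate_genome(small_sim_config(seed = 3))
  expect_silent(validate_mir_hosts(g$mirs, g$genes))
  # genes do not overlap within a chromosome
  for (ch in unique(g$genes$chrom)) {
    gg <- g$genes[g$genes$chrom == ch, ]
    gg <- gg[order(gg$start), ]
    expect_true(all(gg$start[-1] >= gg$end[-nrow(gg)]))
  }
  # clustered MIRs sit within the neighbour window of their cluster mates
  for (cl in unique(stats::na.omit(g$mirs$cluster_id))) {
    mm <- g$mirs[g$mirs$cluster_id %in% cl, ]
    mm <- mm[order(mm$start), ]
    gaps <- mm$start[-1] - mm$end[-nrow(mm)]
    expect_true(all(gaps <= 10000))
    expect_equal(length(unique(mm$strand)), 1)
  }
})

test_that("intragenic fraction follows its binomial design value", {
  cfg <- simulation_config(seed = 5, n_chromosomes = 8L, n_genes = 700L,
                           n_mirs = 1000L, fraction_intragenic = 0.5)
  g <- generate_genome(cfg)
  frac <- mean(g$mirs$context == "intragenic")
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 1000))
})

test_that("degenerate replicate parameters behave exactly", {
  cfg <- small_sim_config(seed = 4, edge_reproducibility = 1,
                          noise_edge_rate = 0)
  genome <- generate_genome(cfg)
  chia <- generate_chia_pet(genome, genome$truth, cfg)
  reps <- list(K562 = paste0("rep", 1:3), MCF7 = paste0("rep", 1:4))
  pe <- chia$planted_edges
  tssof <- c(stats::setNames(genome$genes$tss, genome$genes$gene_id),
             stats::setNames(genome$truth$mir_tss$true_tss,
                             genome$truth$mir_tss$mir_id))
  chromof <- c(stats::setNames(genome$genes$chrom, genome$genes$gene_id),
               stats::setNames(genome$mirs$chrom, genome$mirs$mir_id))
  contains <- function(i, u, v) {
    pu <- tssof[[u]]; pv <- tssof[[v]]
    cu <- chromof[[u]]; cv <- chromof[[v]]
    (i$chrom1 == cu & i$start1 <= pu & i$end1 > pu &
       i$chrom2 == cv & i$start2 <= pv & i$end2 > pv) |
      (i$chrom1 == cv & i$start1 <= pv & i$end1 > pv &
         i$chrom2 == cu & i$start2 <= pu & i$end2 > pu)
  }
  # every planted pair appears in every replicate of its cell line(s):
  # find interactions whose anchors contain the two member TSSs
  hits <- function(u, v, cell, rep) {
    i <- chia$interactions
    any(i$cell_line == cell & i$replicate_id == rep & contains(i, u, v))
  }
  set.seed(1)
  probe <- pe[sample.int(nrow(pe), 25), ]
  for (r in seq_len(nrow(probe))) {
    cells <- if (probe$cell_restriction[r] == "both") names(reps)
             else probe$cell_restriction[r]
    for (cl in cells) for (rp in reps[[cl]])
      expect_true(hits(probe$u[r], probe$v[r], cl, rp))
  }
  # reproducibility 0: no planted interactions at all (clusters aside)
  cfg0 <- small_sim_config(seed = 4, edge_reproducibility = 0,
                           noise_edge_rate = 0, n_clusters = 0L)
  genome0 <- generate_genome(cfg0)
  chia0 <- generate_chia_pet(genome0, genome0$truth, cfg0)
  expect_equal(nrow(chia0$interactions), 0)
})

test_that("replicate recovery matches the binomial closed form", {
  # P(edge seen in >= 2 of 3 replicates) at reproducibility 0.8
  p_expected <- 1 - (0.2^3 + 3 * 0.8 * 0.2^2)
  cfg <- simulation_config(seed = 6, cell_lines = c(K562 = 3L),
                           fraction_cell_specific_communities = 0,
                           noise_edge_rate = 0, n_clusters = 0L)
  genome <- generate_genome(cfg)
  chia <- generate_chia_pet(genome, genome$truth, cfg)
  tssof <- c(stats::setNames(genome$genes$tss, genome$genes$gene_id),
             stats::setNames(genome$truth$mir_tss$true_tss,
                             genome$truth$mir_tss$mir_id))
  chromof <- c(stats::setNames(genome$genes$chrom, genome$genes$gene_id),
               stats::setNames(genome$mirs$chrom, genome$mirs$mir_id))
  pe <- chia$planted_edges
  n_reps <- vapply(seq_len(nrow(pe)), function(r) {
    pu <- tssof[[pe$u[r]]]; pv <- tssof[[pe$v[r]]]
    cu <- chromof[[pe$u[r]]]; cv <- chromof[[pe$v[r]]]
    i <- chia$interactions
    sel <- (i$chrom1 == cu & i$start1 <= pu & i$end1 > pu &
              i$chrom2 == cv & i$start2 <= pv & i$end2 > pv) |
      (i$chrom1 == cv & i$start1 <= pv & i$end1 > pv &
         i$chrom2 == cu & i$start2 <= pu & i$end2 > pu)
    length(unique(i$replicate_id[sel]))
  }, integer(1))
  frac <- mean(n_reps >= 2)
  expect_lt(abs(frac - p_expected),
            3 * sqrt(p_expected * (1 - p_expected) / nrow(pe)))
})

test_that("target generation honours depletion, enrichment and db support", {
  cfg <- small_sim_config(seed = 7, target_self_depletion = 0)
  genome <- generate_genome(cfg)
  tg <- generate_targets(genome, genome$truth, cfg)
  mem <- genome$truth$membership
  cm <- mem$community[match(tg$mir_id, mem$entity_id)]
  cg <- mem$community[match(tg$target_gene_id, mem$entity_id)]
  expect_equal(sum(!is.na(cm) & !is.na(cg) & cm == cg), 0)

  cfg1 <- small_sim_config(seed = 7,
                           target_db_probs = c(1, 0, 0, 0, 0, 0))
  tg1 <- generate_targets(genome, genome$truth, cfg1)
  expect_true(all(tg1$n_databases == 1))
  expect_equal(nrow(filter_target_pairs(tg1, pipeline_config())), 0)
})

test_that("with no planted structure, per-cell target counts are uniform", {
  # enrichment = depletion = 1: counts per (MIR community, gene community)
  # cell consistent with a uniform rate (chi-square GOF, alpha 0.01,
  # not rejected in >= 18 of 20 seeds)
  rejected <- 0L
  for (s in 1:20) {
    cfg <- small_sim_config(seed = 100 + s, n_mirs = 60L,
                            target_between_enrichment = 1,
                            target_self_depletion = 1)
    genome <- generate_genome(cfg)
    tg <- generate_targets(genome, genome$truth, cfg)
    mem <- genome$truth$membership
    mir_c <- mem$community[match(genome$mirs$mir_id, mem$entity_id)]
    gene_c <- mem$community[match(genome$genes$gene_id, mem$entity_id)]
    n_mir <- table(mir_c[!is.na(mir_c)])
    n_gene <- table(gene_c[!is.na(gene_c)])
    # collapse to MIR-community margins: counts of community-to-community
    # pairs per MIR community should be proportional to its MIR count
    cm <- mem$community[match(tg$mir_id, mem$entity_id)]
    cg <- mem$community[match(tg$target_gene_id, mem$entity_id)]
    ok <- !is.na(cm) & !is.na(cg)
    lev <- names(n_mir)[as.integer(n_mir) > 0]
    cells <- table(factor(cm[ok], levels = lev))
    expected_w <- as.numeric(n_mir[lev])
    p <- if (length(lev) < 2) NA_real_ else suppressWarnings(
      stats::chisq.test(as.integer(cells),
                        p = expected_w / sum(expected_w))$p.value)
    if (is.na(p) || p < 0.01) rejected <- rejected + 1L
  }
  expect_lte(rejected, 2L)
})

test_that("expression is a monotone function of activity, with noise as configured", {
  cfg <- small_sim_config(seed = 8, expression_noise_sd = 0)
  genome <- generate_genome(cfg)
  em <- generate_expression_marks(genome, genome$truth, cfg)
  ex <- em$expression[em$expression$cell_line == "K562", ]
  act <- genome$truth$activity[ex$entity_id, "K562"]
  expect_equal(stats::cor(act, ex$value, method = "spearman"), 1)
  em2 <- generate_expression_marks(genome, genome$truth, cfg)
  expect_identical(em$expression, em2$expression)
  expect_identical(em$mark_table, em2$mark_table)

  # default noise keeps MIR activity and RPM strongly rank-correlated
  cfg_n <- small_sim_config(seed = 8)
  genome_n <- generate_genome(cfg_n)
  ok <- 0L
  n_seeds <- 100L
  for (s in seq_len(n_seeds)) {
    cfg_s <- small_sim_config(seed = 8)
    cfg_s$seed <- 5000L + s
    em_s <- generate_expression_marks(genome_n, genome_n$truth, cfg_s)
    ex_s <- em_s$expression[em_s$expression$cell_line == "K562" &
                              em_s$expression$entity_id %in%
                                genome_n$mirs$mir_id, ]
    rho <- stats::cor(genome_n$truth$activity[ex_s$entity_id, "K562"],
                      ex_s$value, method = "spearman")
    if (rho > 0.5) ok <- ok + 1L
  }
  expect_gte(ok, 95L)
})

test_that("written bundles re-read into the same analysis inputs", {
  b <- simulate_bundle(small_sim_config(seed = 12))
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  genes <- read_annotations(file.path(dir, "genes.gff3"), "gene")
  mirs <- read_annotations(file.path(dir, "mirs.gff3"), "mir")
  expect_equal(genes, b$genes, ignore_attr = TRUE)
  expect_equal(mirs, b$mirs, ignore_attr = TRUE)
  expect_equal(read_interactions(file.path(dir, "interactions.bedpe")),
               b$interactions, ignore_attr = TRUE)
  expect_equal(read_targets(file.path(dir, "targets.tsv")), b$targets,
               ignore_attr = TRUE)
  expect_equal(read_bed3(file.path(dir, "blacklist.bed")), b$blacklist,
               ignore_attr = TRUE)
})
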