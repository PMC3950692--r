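mk_comm <- function(membership) {
  # membership: named character vector entity -> community; MIRs start "M"
  mem <- data.frame(entity_id = names(membership),
                    community_id = unname(membership),
                    is_mir = startsWith(names(membership), "M"),
                    stringsAsFactors = FALSE)
  sizes <- table(mem$community_id)
  ord <- order(-as.integer(sizes), names(sizes))
  comms <- data.frame(community_id = names(sizes)[ord],
                      size = as.integer(sizes)[ord],
                      n_mirs = as.integer(tapply(mem$is_mir,
                                                 mem$community_id,
                                                 sum))[ord],
                      is_giant = seq_along(sizes) == 1,
                      stringsAsFactors = FALSE)
  structure(list(membership = mem, communities = comms),
            class = "chromatin_communities")
}

test_that("target pairs are filtered by database support, order preserved", {
  pairs <- data.frame(mir_id = c("M1", "M2", "M3"),
                      target_gene_id = c("g1", "g2", "g3"),
                      n_databases = c(1L, 2L, 5L), stringsAsFactors = FALSE)
  out <- filter_target_pairs(pairs, pipeline_config())
  expect_equal(out$mir_id, c("M2", "M3"))
  at <- transform(pairs, n_databases = 2L)
  expect_equal(filter_target_pairs(at, pipeline_config()), at,
               ignore_attr = TRUE)
})

test_that("pair mapping classifies within/between/unmapped and conserves totals", {
  comm <- mk_comm(c(M1 = "C1", g1 = "C1", M2 = "C1", g2 = "C2", g3 = "C2"))
  pairs <- data.frame(mir_id = c("M1", "M1", "M2", "M9"),
                      target_gene_id = c("g1", "g2", "g3", "g1"),
                      n_databases = 2L, stringsAsFactors = FALSE)
  mp <- map_pairs_to_communities(pairs, comm)
  expect_equal(mp$pairs$status, c("within", "between", "between", "unmapped"))
  expect_equal(mp$pairs$mir_community[2], "C1")
  expect_equal(mp$pairs$target_community[2], "C2")
  expect_equal(mp$n_within + mp$n_between + mp$n_unmapped, mp$n_total_input)
  expect_equal(mp$percent_within, round(100 * 1 / 3, 1))
})

test_that("the depletion test builds the documented 2x2 table and Fisher p", {
  comm <- mk_comm(c(M1 = "C1", g1 = "C1", M2 = "C2", g2 = "C2", g3 = "C1",
                    g4 = "C3"))
  pairs <- data.frame(
    mir_id = c("M1", "M1", "M1", "M2", "M2"),
    target_gene_id = c("g1", "g2", "g4", "g2", "g3"),
    n_databases = 2L, stringsAsFactors = FALSE)
  mp <- map_pairs_to_communities(pairs, comm)
  res <- within_community_depletion_test(mp, comm)
  # giant community is C1 (3 members)
  expect_equal(unname(res$table["giant", "within"]), 1)   # M1-g1
  expect_equal(unname(res$table["giant", "between"]), 2)  # M1-g2, M1-g4
  expect_equal(unname(res$table["other", "within"]), 1)   # M2-g2
  expect_equal(unname(res$table["other", "between"]), 1)  # M2-g3
  expect_equal(res$p_value, stats::fisher.test(res$table)$p.value)
  # degenerate table: no within pairs at all
  mp0 <- map_pairs_to_communities(pairs[c(2, 3, 5), ], comm)
  expect_warning(res0 <- within_community_depletion_test(mp0, comm),
                 "degenerate")
  expect_equal(res0$p_value, 1)
})

test_that("two-sided Fisher p agrees with fixed-margin enumeration", {
  # enumeration oracle over all tables with the observed margins
  fisher_oracle <- function(tab) {
    r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); N <- sum(tab)
    a_range <- max(0, r1 + c1 - N):min(r1, c1)
    probs <- vapply(a_range, function(a)
      choose(c1, a) * choose(N - c1, r1 - a) / choose(N, r1), numeric(1))
    p_obs <- probs[a_range == tab[1, 1]]
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  tab <- matrix(c(1, 9, 11, 3), 2, byrow = TRUE)
  expect_equal(fisher_oracle(tab), stats::fisher.test(tab)$p.value,
               tolerance = 1e-10)
  expect_equal(round(fisher_oracle(tab), 4), 0.0028)
  # symmetry under transposition
  expect_equal(fisher_oracle(t(tab)), fisher_oracle(tab), tolerance = 1e-12)
})

test_that("hypergeometric upper tail matches the combinatorial closed form", {
  # N=20, K=6, n=5, k=5: only C(6,5)C(14,0) of C(20,5) draws qualify
  expect_equal(hyper_upper_p(5, 6, 5, 20), 6 / 15504, tolerance = 1e-12)
  expect_equal(hyper_upper_p(5, 6, 5, 20), hyper_upper_oracle(5, 6, 5, 20),
               tolerance = 1e-12)
  # monotone non-increasing in k
  p_seq <- hyper_upper_p(0:5, 6, 5, 20)
  expect_true(all(diff(p_seq) <= 0))
})

test_that("community links require the minimum pair count and BH control", {
  set.seed(33)
  membership <- c(
    stats::setNames(rep(c("C1", "C2", "C3", "C4"), each = 3),
                    sprintf("M%02d", 1:12)),
    stats::setNames(rep(c("C1", "C2", "C3", "C4"), each = 10),
                    sprintf("g%02d", 1:40)))
  comm <- mk_comm(membership)
  # 12 pairs C1->C2, 9 pairs C3->C4, sprinkle of others
  mk_pairs <- function(mc, gc, n) {
    data.frame(mir_id = sample(names(membership)[membership == mc &
                                                   startsWith(names(membership), "M")],
                               n, replace = TRUE),
               target_gene_id = sample(names(membership)[membership == gc &
                                                           !startsWith(names(membership), "M")],
                                       n, replace = TRUE),
               n_databases = 2L, stringsAsFactors = FALSE)
  }
  pairs <- rbind(mk_pairs("C1", "C2", 12), mk_pairs("C3", "C4", 9),
                 mk_pairs("C1", "C3", 3), mk_pairs("C2", "C4", 2))
  pairs <- pairs[!duplicated(pairs[, 1:2]), ]
  mp <- map_pairs_to_communities(pairs, comm)
  links <- community_link_network(mp, comm, pipeline_config())
  expect_true(all(links$n_pairs >= 10))
  relaxed <- community_link_network(mp, comm, pipeline_config(),
                                    min_pairs = 5)
  expect_gt(nrow(relaxed), nrow(links))
  expect_equal(relaxed$q_value, stats::p.adjust(relaxed$p_value, "BH"),
               tolerance = 1e-12)
  # q monotone in p
  expect_true(all(diff(relaxed$q_value[order(relaxed$p_value)]) >= -1e-12))
  # hypergeometric margins: verify one tested link against the oracle
  bt <- mp$pairs[mp$pairs$status == "between", ]
  a <- pmin(bt$mir_community, bt$target_community)
  b <- pmax(bt$mir_community, bt$target_community)
  inc <- table(c(a, b))
  l1 <- links[1, ]
  expect_equal(l1$p_value,
               hyper_upper_oracle(l1$n_pairs, inc[[l1$community_a]],
                                  inc[[l1$community_b]], nrow(bt)),
               tolerance = 1e-9)
})

test_that("percent-targeted permutation control is seeded and calibrated", {
  set.seed(41)
  membership <- c(
    stats::setNames(rep(paste0("C", 1:10), each = 2), sprintf("M%02d", 1:20)),
    stats::setNames(rep(paste0("C", 1:10), each = 6), sprintf("g%02d", 1:60)))
  comm <- mk_comm(membership)
  universe <- c(sprintf("g%02d", 1:60), sprintf("x%02d", 1:40))
  pairs <- data.frame(
    mir_id = sample(sprintf("M%02d", 1:20), 200, replace = TRUE),
    target_gene_id = sample(universe, 200, replace = TRUE),
    n_databases = 2L, stringsAsFactors = FALSE)
  pairs <- pairs[!duplicated(pairs[, 1:2]), ]
  cfg <- pipeline_config(n_permutations = 200, random_seed = 3)
  ps1 <- permutation_percent_targeted(comm, pairs, cfg, universe)
  ps2 <- permutation_percent_targeted(comm, pairs, cfg, universe)
  expect_identical(ps1$between$null_means, ps2$between$null_means)
  expect_identical(ps1$between$empirical_fdr, ps2$between$empirical_fdr)
  # observed communities are themselves uniform draws: empirical FDR should
  # be unremarkable across seeds (never at the extreme minimum repeatedly)
  fdrs <- vapply(1:10, function(s) {
    cfgs <- pipeline_config(n_permutations = 99, random_seed = 100 + s)
    permutation_percent_targeted(comm, pairs, cfgs,
                                 universe)$between$empirical_fdr
  }, numeric(1))
  expect_gt(mean(fdrs), 0.05)
  expect_lt(mean(fdrs), 0.95)
})

test_that("term enrichment flags extreme sets and counts shared terms", {
  terms <- rbind(
    data.frame(gene_id = sprintf("g%03d", 1:10), term_id = "T1"),
    data.frame(gene_id = sprintf("g%03d", 1:1000),
               term_id = rep(sprintf("B%02d", 1:10), each = 100)))
  enr <- enriched_terms(sprintf("g%03d", 1:10), terms, fdr = 0.05)
  expect_true("T1" %in% enr)
  # shared term counts equal a set-intersection oracle
  membership <- c(stats::setNames(c("C1", "C2"), c("M01", "M02")),
                  stats::setNames(rep(c("C1", "C2"), each = 10),
                                  sprintf("g%03d", 1:20)))
  comm <- mk_comm(membership)
  links <- data.frame(community_a = "C1", community_b = "C2",
                      n_pairs = 10L, p_value = 0.001, q_value = 0.001,
                      significant = TRUE, stringsAsFactors = FALSE)
  terms2 <- rbind(
    data.frame(gene_id = sprintf("g%03d", 1:20), term_id = "SH"),
    data.frame(gene_id = sprintf("g%03d", 101:400),
               term_id = rep(sprintf("B%02d", 1:3), each = 100)))
  out <- shared_enriched_terms(links, comm, terms2,
                               pipeline_config(random_seed = 2),
                               n_permutations = 20)
  e1 <- enriched_terms(sprintf("g%03d", 1:10), terms2, 0.05)
  e2 <- enriched_terms(sprintf("g%03d", 11:20), terms2, 0.05)
  expect_equal(out$per_link$shared_terms, length(intersect(e1, e2)))
  expect_gte(out$per_link$shared_terms, 1)
})

test_that("target expression contrast recovers planted repression", {
  set.seed(51)
  genes <- sprintf("g%03d", 1:200)
  mirs <- sprintf("M%02d", 1:20)
  membership <- c(stats::setNames(rep(paste0("C", 1:10), each = 2), mirs),
                  stats::setNames(rep(paste0("C", 1:10), each = 20), genes))
  comm <- mk_comm(membership)
  targets <- sample(genes, 100)
  pairs <- data.frame(mir_id = sample(mirs, 300, replace = TRUE),
                      target_gene_id = sample(targets, 300, replace = TRUE),
                      n_databases = 2L, stringsAsFactors = FALSE)
  pairs <- pairs[!duplicated(pairs[, 1:2]), ]
  base <- stats::rlnorm(200, 2, 0.3)
  repressed <- base
  repressed[genes %in% targets] <- repressed[genes %in% targets] * 0.5
  expression <- data.frame(entity_id = c(genes, mirs), cell_line = "K562",
                           value = c(repressed, stats::rlnorm(20, 2, 0.3)),
                           stringsAsFactors = FALSE)
  out <- target_expression_contrast(comm, pairs, expression)
  expect_lt(out$mean_target, out$mean_nontarget)
  expect_lt(out$t_p, 0.01)
  # constant expression: correlation not applicable
  const <- transform(expression, value = 1)
  out2 <- target_expression_contrast(comm, pairs, const)
  expect_true(is.na(out2$spearman_rho))
})
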