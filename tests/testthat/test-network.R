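mk_ints <- function(chrom1, s1, e1, chrom2, s2, e2, cell = "K562",
                    rep = "rep1") {
  canonicalize_interactions(data.frame(
    chrom1 = chrom1, start1 = s1, end1 = e1,
    chrom2 = chrom2, start2 = s2, end2 = e2,
    pet_count = 2L, cell_line = cell, replicate_id = rep,
    stringsAsFactors = FALSE))
}

test_that("blacklist filtering uses half-open overlap on either anchor", {
  ints <- mk_ints("chr1", c(100L, 1000L), c(200L, 1100L),
                  "chr1", c(5000L, 6000L), c(5100L, 6100L))
  expect_identical(filter_sv_blacklist(ints, NULL), ints)
  expect_identical(filter_sv_blacklist(ints, data.frame(chrom = character(0),
                                                        start = integer(0),
                                                        end = integer(0))),
                   ints)
  # abutting interval (end == start of anchor) does not overlap
  bl <- data.frame(chrom = "chr1", start = 0L, end = 100L)
  expect_equal(nrow(filter_sv_blacklist(ints, bl)), 2)
  bl2 <- data.frame(chrom = "chr1", start = 0L, end = 101L)
  expect_equal(nrow(filter_sv_blacklist(ints, bl2)), 1)
})

test_that("blacklist filtering matches a brute-force overlap oracle", {
  set.seed(21)
  n <- 300
  s1 <- sample.int(1e5, n); s2 <- sample.int(1e5, n)
  ints <- mk_ints(sample(c("chr1", "chr2"), n, TRUE), s1, s1 + 500L,
                  sample(c("chr1", "chr2"), n, TRUE), s2, s2 + 500L)
  bs <- sample.int(1e5, 30)
  bl <- data.frame(chrom = sample(c("chr1", "chr2"), 30, TRUE),
                   start = bs, end = bs + sample.int(2000, 30))
  got <- filter_sv_blacklist(ints, bl)
  olap <- function(c1, a, b, c2, x, y) c1 == c2 & a < y & x < b
  keep <- vapply(seq_len(n), function(i) {
    hit_a <- any(olap(ints$chrom1[i], ints$start1[i], ints$end1[i],
                      bl$chrom, bl$start, bl$end))
    hit_b <- any(olap(ints$chrom2[i], ints$start2[i], ints$end2[i],
                      bl$chrom, bl$start, bl$end))
    !(hit_a || hit_b)
  }, logical(1))
  expect_equal(got, ints[keep, ], ignore_attr = TRUE)
})

test_that("anchor-to-entity linking is a cross product across anchors", {
  cfg <- pipeline_config()
  ti <- data.frame(entity_id = c("g1", "g2", "m1"), chrom = "chr1",
                   tss = c(1000L, 2600L, 2700L),
                   is_mir = c(FALSE, FALSE, TRUE), stringsAsFactors = FALSE)
  # g1's window [-1000, 3001) overlaps anchor [2500, 3000)
  int1 <- mk_ints("chr1", 2500L, 3000L, "chr1", 100000L, 101000L)
  expect_equal(nrow(link_genes_to_interaction(int1, ti[1, ], cfg)), 0)
  ti2 <- rbind(ti, data.frame(entity_id = "g9", chrom = "chr1",
                              tss = 100500L, is_mir = FALSE))
  pairs <- link_genes_to_interaction(int1, ti2, cfg)
  expect_setequal(paste(pairs$id1, pairs$id2),
                  c("g1 g9", "g2 g9", "g9 m1"))
  # entities on one anchor only produce no pair
  int2 <- mk_ints("chr1", 500L, 3000L, "chr2", 1L, 100L)
  expect_equal(nrow(link_genes_to_interaction(int2, ti, cfg)), 0)
})

test_that("edges require two replicates within one cell line", {
  cfg <- pipeline_config()
  ti <- data.frame(entity_id = c("a", "b"), chrom = "chr1",
                   tss = c(1000L, 50000L), is_mir = FALSE,
                   stringsAsFactors = FALSE)
  one <- mk_ints("chr1", 900L, 1100L, "chr1", 49900L, 50100L)
  net1 <- build_network(one, ti, cfg)
  expect_equal(nrow(net1$edges), 0)
  two <- rbind(one, mk_ints("chr1", 800L, 1200L, "chr1", 49800L, 50200L,
                            rep = "rep2"))
  net2 <- build_network(two, ti, cfg)
  expect_equal(nrow(net2$edges), 1)
  expect_equal(net2$edges$cell_status, "K562-only")
  # two single replicates in different cell lines do not qualify
  split_cells <- rbind(one, mk_ints("chr1", 800L, 1200L, "chr1", 49800L,
                                    50200L, cell = "MCF7"))
  expect_equal(nrow(build_network(split_cells, ti, cfg)$edges), 0)
  # raising the threshold never adds edges
  net3 <- build_network(two, ti, pipeline_config(min_edge_replicates = 3))
  expect_true(all(paste(net3$edges$id1, net3$edges$id2) %in%
                    paste(net2$edges$id1, net2$edges$id2)))
})

test_that("bundle networks equal a brute-force replicate-counting oracle", {
  b <- simulate_bundle(small_sim_config(seed = 15))
  pc <- pipeline_config(random_seed = 15)
  core <- run_pipeline_core(b, pc)
  ints <- core$interactions
  ti <- core$tss_index
  # oracle: per interaction, assign entities by direct coordinate checks
  w <- pc$anchor_tss_window
  pair_support <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(ints))) {
    on_a <- ti$entity_id[ti$chrom == ints$chrom1[i] &
                           ti$tss - w <= ints$end1[i] - 1 &
                           ti$tss + w >= ints$start1[i]]
    on_b <- ti$entity_id[ti$chrom == ints$chrom2[i] &
                           ti$tss - w <= ints$end2[i] - 1 &
                           ti$tss + w >= ints$start2[i]]
    for (u in on_a) for (v in on_b) {
      if (u == v) next
      key <- paste(min(u, v), max(u, v), sep = "|")
      sup <- paste(ints$cell_line[i], ints$replicate_id[i])
      pair_support[[key]] <- union(pair_support[[key]], sup)
    }
  }
  keys <- ls(pair_support)
  qualified <- vapply(keys, function(k) {
    cells <- sub(" .*", "", pair_support[[k]])
    any(table(cells) >= 2)
  }, logical(1))
  expect_setequal(paste(core$network$edges$id1, core$network$edges$id2,
                        sep = "|"),
                  keys[qualified])
})

test_that("community detection equals a DFS oracle on random graphs", {
  set.seed(23)
  for (trial in 1:200) {
    n <- sample(2:200, 1)
    nodes <- sprintf("n%03d", seq_len(n))
    m <- sample(0:(2 * n), 1)
    edges <- unique(data.frame(
      id1 = sample(nodes, m, replace = TRUE),
      id2 = sample(nodes, m, replace = TRUE), stringsAsFactors = FALSE))
    edges <- edges[edges$id1 != edges$id2, , drop = FALSE]
    k <- data.frame(id1 = pmin(edges$id1, edges$id2),
                    id2 = pmax(edges$id1, edges$id2))
    k <- unique(k)
    nn <- sort(unique(c(k$id1, k$id2)))
    net <- structure(list(
      edges = k, nodes = nn,
      node_info = data.frame(entity_id = nn,
                             is_mir = rep(FALSE, length(nn)),
                             stringsAsFactors = FALSE)),
      class = "gene_network")
    comm <- find_communities(net)
    oracle <- dfs_components(net$nodes, k)
    # same partition: compare canonical block signatures
    got <- vapply(split(comm$membership$entity_id,
                        comm$membership$community_id),
                  function(v) paste(sort(v), collapse = ","), "")
    want <- vapply(split(names(oracle), oracle),
                   function(v) paste(sort(v), collapse = ","), "")
    expect_identical(sort(unname(got)), sort(unname(want)))
  }
})

test_that("community bookkeeping matches the membership rules", {
  net <- structure(list(
    edges = data.frame(id1 = c("a", "b", "d"), id2 = c("b", "c", "e")),
    nodes = c("a", "b", "c", "d", "e"),
    node_info = data.frame(entity_id = c("a", "b", "c", "d", "e"),
                           is_mir = c(TRUE, FALSE, FALSE, FALSE, FALSE))),
    class = "gene_network")
  comm <- find_communities(net)
  expect_equal(nrow(comm$communities), 2)
  expect_equal(comm$communities$size, c(3L, 2L))
  expect_equal(comm$communities$is_giant, c(TRUE, FALSE))
  expect_equal(comm$communities$n_mirs, c(1L, 0L))
  empty <- structure(list(edges = data.frame(id1 = character(0),
                                             id2 = character(0)),
                          nodes = character(0),
                          node_info = data.frame(entity_id = character(0),
                                                 is_mir = logical(0))),
                     class = "gene_network")
  expect_equal(nrow(find_communities(empty)$communities), 0)
})

test_that("community partition is invariant to interaction order and orientation", {
  b <- simulate_bundle(small_sim_config(seed = 16))
  pc <- pipeline_config(random_seed = 16)
  core <- run_pipeline_core(b, pc)
  ints <- core$interactions
  set.seed(1)
  shuffled <- ints[sample.int(nrow(ints)), ]
  swapped <- shuffled[, c(4:6, 1:3, 7:9)]
  names(swapped) <- names(shuffled)
  swapped <- canonicalize_interactions(swapped)
  net2 <- build_network(swapped, core$tss_index, pc)
  comm1 <- find_communities(core$network)
  comm2 <- find_communities(net2)
  expect_equal(comm1$membership, comm2$membership)
})

test_that("topology summary reports degrees, comparisons and the log-log slope", {
  # star K_{1,5}
  nodes <- c("hub", paste0("leaf", 1:5))
  net <- structure(list(
    edges = data.frame(id1 = "hub", id2 = paste0("leaf", 1:5)),
    nodes = nodes,
    node_info = data.frame(entity_id = nodes,
                           is_mir = c(TRUE, rep(FALSE, 5)))),
    class = "gene_network")
  comm <- find_communities(net)
  ts <- topology_summary(net, comm)
  expect_equal(ts$degrees$degree[ts$degrees$entity_id == "hub"], 5L)
  expect_true(all(ts$degrees$degree[ts$degrees$entity_id != "hub"] == 1L))
  expect_equal(sum(ts$size_histogram), nrow(comm$communities))
  # all communities contain the MIR -> size comparison not applicable
  expect_true(is.na(ts$mir_community_size_p))
  expect_lt(ts$degree_loglog_slope, 0)
})

test_that("TAD overlap report counts containing TADs and member fractions", {
  mem <- data.frame(entity_id = c("a", "b", "c", "d"),
                    community_id = c("C1", "C1", "C1", "C2"),
                    is_mir = FALSE)
  comm <- structure(list(membership = mem,
                         communities = data.frame(community_id = c("C1", "C2"),
                                                  size = c(3L, 1L),
                                                  n_mirs = 0L,
                                                  is_giant = c(TRUE, FALSE))),
                    class = "chromatin_communities")
  ti <- data.frame(entity_id = c("a", "b", "c", "d"), chrom = "chr1",
                   tss = c(100L, 200L, 5000L, 900L), is_mir = FALSE)
  tads <- data.frame(chrom = "chr1", start = 0L, end = 1000L)
  out <- tad_overlap_report(comm, tads, ti)
  expect_equal(out$n_tads, c(1, 1))
  expect_equal(out$fraction_in_tad, c(2 / 3, 1))
  none <- tad_overlap_report(comm, tads[0, ], ti)
  expect_equal(none$n_tads, c(0, 0))
  expect_equal(none$fraction_in_tad, c(0, 0))
  # random fixture vs naive containment oracle
  set.seed(5)
  ti2 <- data.frame(entity_id = mem$entity_id, chrom = "chr1",
                    tss = sample.int(2000, 4), is_mir = FALSE)
  ts2 <- sort(sample.int(2000, 6))
  tads2 <- data.frame(chrom = "chr1", start = ts2[c(1, 3, 5)],
                      end = ts2[c(2, 4, 6)])
  out2 <- tad_overlap_report(comm, tads2, ti2)
  for (cid in c("C1", "C2")) {
    ids <- mem$entity_id[mem$community_id == cid]
    inside <- vapply(ids, function(e) {
      p <- ti2$tss[ti2$entity_id == e]
      w <- which(tads2$start <= p & p < tads2$end)
      if (length(w) == 0) NA_integer_ else w[1]
    }, integer(1))
    expect_equal(out2$n_tads[out2$community_id == cid],
                 length(unique(inside[!is.na(inside)])))
    expect_equal(out2$fraction_in_tad[out2$community_id == cid],
                 mean(!is.na(inside)))
  }
})
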