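# Shared fixtures and independent oracles.

# Connected components by explicit depth-first search (oracle, independent
# of the igraph-backed implementation).
dfs_components <- function(nodes, edges) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    adj[[edges$id1[i]]] <- c(adj[[edges$id1[i]]], edges$id2[i])
    adj[[edges$id2[i]]] <- c(adj[[edges$id2[i]]], edges$id1[i])
  }
  comp <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  k <- 0L
  for (n in nodes) {
    if (!is.na(comp[[n]])) next
    k <- k + 1L
    stack <- n
    while (length(stack) > 0) {
      v <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (!is.na(comp[[v]])) next
      comp[[v]] <- k
      stack <- c(stack, adj[[v]])
    }
  }
  comp
}

# Upper-tail hypergeometric by direct combinatorial summation (oracle).
hyper_upper_oracle <- function(k, K, n, N) {
  ks <- max(k, 0):min(K, n)
  if (k > min(K, n)) return(0)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# Down-scaled simulation for fast pipeline tests.
small_sim_config <- function(seed = 1L, ...) {
  defaults <- list(seed = seed, n_chromosomes = 2L, chrom_length = 7e6,
                   n_genes = 80L, n_mirs = 30L, n_clusters = 4L,
                   n_planted_communities = 8L, hub_count = 2L,
                   hub_size = 10L, hub_mirs = 2L, noise_edge_rate = 5,
                   n_terms = 15L)
  do.call(simulation_config, utils::modifyList(defaults, list(...)))
}

# Promoter annotation + network construction on a bundle.
run_pipeline_core <- function(bundle, pc) {
  calls <- classify_promoter_sharing(
    assign_tss(bundle$mirs, bundle$curated_tss, bundle$cage_tags,
               bundle$rnapii_peaks, pc), bundle$genes, pc)
  ti <- make_tss_index(bundle$genes, calls)
  ints <- filter_sv_blacklist(bundle$interactions, bundle$blacklist)
  net <- build_network(ints, ti, pc)
  comm <- find_communities(net)
  list(calls = calls, tss_index = ti, interactions = ints, network = net,
       communities = comm)
}

# Random interaction table (canonical layout) for IO round trips.
random_interactions <- function(n, seed = 1L) {
  set.seed(seed)
  s1 <- sample.int(1e6, n)
  s2 <- sample.int(1e6, n)
  x <- data.frame(
    chrom1 = sample(c("chr1", "chr2"), n, replace = TRUE),
    start1 = s1, end1 = s1 + sample.int(5000, n, replace = TRUE),
    chrom2 = sample(c("chr1", "chr2"), n, replace = TRUE),
    start2 = s2, end2 = s2 + sample.int(5000, n, replace = TRUE),
    pet_count = sample.int(20, n, replace = TRUE),
    cell_line = sample(c("K562", "MCF7"), n, replace = TRUE),
    replicate_id = sample(c("rep1", "rep2"), n, replace = TRUE),
    stringsAsFactors = FALSE)
  x
}
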