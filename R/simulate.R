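# Synthetic input bundles with planted structure.
#
# The generator emulates the study conditions of an RNAPII ChIA-PET
# promoter/community analysis: two cell lines (K562 with 3 replicates,
# MCF7 with 4), about half of the MIRs intragenic, planted chromatin
# communities whose edges reappear independently per replicate, noise
# interactions confined to a single replicate, miRNA-target pairs enriched
# between planted community pairs and depleted within communities, and
# expression/mark signals that increase with planted transcriptional
# activity.
#
# Placement geometry is chosen so planted structure is identifiable:
# entity TSSs of different planted communities are kept more than
# (anchor_tss_window + max anchor half-width) * 2 = 8 kb apart, so no TSS
# window can touch anchors of two communities and connected components
# cannot merge planted blocks. Clustered and intragenic MIRs are excluded
# from community sampling for the same reason; they exercise the neighbour
# rule and host co-transcription instead.

# sample() without the scalar-x surprise
resample <- function(x, ...) x[sample.int(length(x), ...)]

#' Simulation configuration
#'
#' Defaults define the generator's study conditions; see the package
#' vignette for the rationale of each value.
#'
#' @param n_chromosomes,chrom_length genome shape (bp per chromosome).
#' @param n_genes,n_mirs feature counts.
#' @param fraction_intragenic fraction of MIRs placed inside a host gene on
#'   the same strand (default 0.5, the approximate intragenic share of
#'   human MIRs).
#' @param n_clusters,cluster_size_range miRNA clusters among intergenic
#'   MIRs (members within 10 kb of each other, same strand).
#' @param n_families,n_disease_categories label vocabularies.
#' @param n_planted_communities number of planted chromatin communities.
#' @param community_size_mean mean planted community size (negative
#'   binomial; the `hub_count` largest are raised to at least `hub_size` so
#'   that enriched community pairs have enough cross pairs).
#' @param hub_count,hub_size,hub_mirs number, minimum size and guaranteed
#'   MIR membership of the large "hub" communities carrying the planted
#'   target enrichment.
#' @param edge_reproducibility probability a planted anchor pair is emitted
#'   in any given replicate.
#' @param noise_edge_rate expected spurious single-replicate interactions
#'   per replicate.
#' @param cell_lines named integer vector of replicate counts.
#' @param fraction_cell_specific_communities share of planted communities
#'   whose edges are restricted to one cell line.
#' @param n_enriched_community_pairs planted community pairs with excess
#'   miRNA-target density (consecutive hub pairs), or `"all"` to enrich
#'   every distinct community pair.
#' @param target_base_rate baseline probability of a (MIR, gene) target
#'   pair.
#' @param target_between_enrichment multiplier on the planted enriched
#'   community pairs.
#' @param target_self_depletion multiplier (< 1) on within-community pairs.
#' @param target_db_probs distribution of the per-pair database support
#'   over 1..6.
#' @param expression_activity_effect slope of log-expression in
#'   log-activity.
#' @param expression_noise_sd lognormal noise on expression.
#' @param curated_fraction,cage_fraction shares of MIRs with curated /
#'   CAGE TSS evidence.
#' @param basal_fraction share of non-community MIRs given promoter RNAPII
#'   peaks without interactions (the basal transcription model).
#' @param n_terms,n_blacklist,n_tads_per_chrom annotation extras.
#' @param seed integer seed; all generators are pure functions of
#'   (config, seed).
#' @return list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_chromosomes = 4L,
                              chrom_length = 17e6,
                              n_genes = 420L,
                              n_mirs = 150L,
                              fraction_intragenic = 0.5,
                              n_clusters = 10L,
                              cluster_size_range = c(2L, 3L),
                              n_families = 20L,
                              n_disease_categories = 10L,
                              n_planted_communities = 26L,
                              community_size_mean = 5,
                              hub_count = 6L,
                              hub_size = 45L,
                              hub_mirs = 6L,
                              edge_reproducibility = 0.8,
                              noise_edge_rate = 30,
                              cell_lines = c(K562 = 3L, MCF7 = 4L),
                              fraction_cell_specific_communities = 0.2,
                              n_enriched_community_pairs = 3L,
                              target_base_rate = 0.05,
                              target_between_enrichment = 5,
                              target_self_depletion = 0.1,
                              target_db_probs = c(0.35, 0.30, 0.17, 0.10,
                                                  0.05, 0.03),
                              expression_activity_effect = 1,
                              expression_noise_sd = 0.4,
                              curated_fraction = 0.55,
                              cage_fraction = 0.2,
                              basal_fraction = 0.5,
                              n_terms = 40L,
                              n_blacklist = 5L,
                              n_tads_per_chrom = 6L,
                              seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "simulation_config"
  probs <- c("fraction_intragenic", "edge_reproducibility",
             "fraction_cell_specific_communities", "curated_fraction",
             "cage_fraction", "basal_fraction", "target_base_rate")
  for (p in probs)
    if (cfg[[p]] < 0 || cfg[[p]] > 1)
      stop("simulation_config: '", p, "' must lie in [0, 1]")
  if (cfg$target_between_enrichment <= 0 || cfg$target_self_depletion < 0)
    stop("simulation_config: target multipliers must be positive (depletion may be 0)")
  if (abs(sum(cfg$target_db_probs) - 1) > 1e-8 || length(cfg$target_db_probs) != 6)
    stop("simulation_config: target_db_probs must be 6 probabilities summing to 1")
  if (cfg$curated_fraction + cfg$cage_fraction > 1)
    stop("simulation_config: curated_fraction + cage_fraction must be <= 1")
  cfg
}

#' Generate the synthetic genome and planted ground truth
#'
#' Places non-overlapping genes with wide intergenic gaps, intergenic MIRs
#' (one per gap, away from gap boundaries), miRNA clusters (members within
#' the neighbour window, same strand) and intragenic MIRs inside host
#' genes on the same strand. Samples the planted community partition over
#' genes and unclustered intergenic MIRs, the planted enriched community
#' pairs, cell-line restrictions, and per-entity transcriptional activity
#' per cell line.
#'
#' @param config a [simulation_config()].
#' @return list `genes, mirs, truth`; `truth` carries `membership`
#'   (entity_id, community), `community_info`, `enriched_pairs`, `activity`
#'   (matrix entities x cell lines), `mir_tss` (true TSS and evidence tier
#'   per MIR), `basal_mirs`, and `active_entities`.
#' @export
generate_genome <- function(config = simulation_config()) {
  with_seed(config$seed + 1L, generate_genome_impl(config))
}

generate_genome_impl <- function(config) {
  n_chr <- config$n_chromosomes
  chroms <- sprintf("chr%d", seq_len(n_chr))
  genes_per_chr <- table(factor(rep_len(seq_len(n_chr), config$n_genes),
                                levels = seq_len(n_chr)))

  genes <- list(); gaps <- list()
  gid <- 0L
  for (c in seq_len(n_chr)) {
    k <- as.integer(genes_per_chr[c])
    if (k == 0) next
    lens <- round(stats::runif(k, 5000, 20000))
    # gaps are wider than the TSS search window plus placement margins, so
    # no MIR can pick up another locus' promoter evidence upstream
    gapw <- round(stats::runif(k, 110000, 130000))
    starts <- cumsum(gapw) + cumsum(c(0, lens[-k]))
    ends <- starts + lens
    if (max(ends) > config$chrom_length - 150000)
      stop("genome too small to place requested features; increase chrom_length")
    ids <- sprintf("GENE%04d", gid + seq_len(k))
    gid <- gid + k
    genes[[c]] <- data.frame(
      gene_id = ids, symbol = paste0("SYM", sub("GENE", "", ids)),
      chrom = chroms[c], start = as.integer(starts), end = as.integer(ends),
      strand = sample(c("+", "-"), k, replace = TRUE),
      stringsAsFactors = FALSE)
    gaps[[c]] <- data.frame(chrom = chroms[c],
                            start = as.integer(starts - gapw),
                            end = as.integer(starts),
                            stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, genes)
  genes$tss <- tss_position(genes$start, genes$end, genes$strand)
  gaps <- do.call(rbind, gaps)

  # ---- MIR placement
  n_intra <- stats::rbinom(1, config$n_mirs, config$fraction_intragenic)
  n_inter <- config$n_mirs - n_intra
  mir_len <- function(n) round(stats::runif(n, 70, 110))

  # clusters take their own wide gaps; one intergenic MIR per other gap
  csizes <- sample(seq(config$cluster_size_range[1], config$cluster_size_range[2]),
                   config$n_clusters, replace = TRUE)
  csizes <- pmin(csizes, n_inter)  # degenerate small n_mirs
  while (sum(csizes) > n_inter && length(csizes) > 0) csizes <- csizes[-length(csizes)]
  wide <- which(gaps$end - gaps$start >= 113000)
  if (length(wide) < length(csizes))
    stop("genome too small: not enough wide gaps for the requested clusters")
  cluster_gaps <- resample(wide, length(csizes))
  n_single <- n_inter - sum(csizes)
  other_gaps <- setdiff(seq_len(nrow(gaps)), cluster_gaps)
  if (length(other_gaps) < n_single)
    stop("genome too small: fewer gaps than intergenic MIRs")
  single_gaps <- resample(other_gaps, n_single)

  mirs <- list(); mir_tss <- list()
  mid <- 0L
  add_mir <- function(chrom, start, len, strand, context, host, cluster, d_up) {
    mid <<- mid + 1L
    id <- sprintf("MIR%04d", mid)
    tss <- if (strand == "+") start - d_up else start + len - 1L + d_up
    mirs[[mid]] <<- data.frame(
      mir_id = id, chrom = chrom, start = as.integer(start),
      end = as.integer(start + len), strand = strand, context = context,
      host_gene_id = host, cluster_id = cluster,
      stringsAsFactors = FALSE)
    mir_tss[[mid]] <<- data.frame(mir_id = id, true_tss = as.integer(tss),
                                  stringsAsFactors = FALSE)
    id
  }

  for (ci in seq_along(csizes)) {
    g <- gaps[cluster_gaps[ci], ]
    strand <- sample(c("+", "-"), 1)
    pos <- g$start + 52000L
    for (m in seq_len(csizes[ci])) {
      len <- mir_len(1)
      add_mir(g$chrom, pos, len, strand, "intergenic", NA_character_,
              sprintf("CL%02d", ci), round(stats::runif(1, 500, 1500)))
      pos <- pos + len + round(stats::runif(1, 1000, 4000))
    }
  }
  for (gi in single_gaps) {
    g <- gaps[gi, ]
    len <- mir_len(1)
    lo <- g$start + 52000L
    hi <- g$end - 52000L - len
    pos <- if (hi > lo) round(stats::runif(1, lo, hi)) else lo
    add_mir(g$chrom, pos, len, sample(c("+", "-"), 1), "intergenic",
            NA_character_, NA_character_, round(stats::runif(1, 500, 1800)))
  }
  hosts <- resample(which(genes$end - genes$start >= 9000), n_intra,
                  replace = TRUE)
  for (h in hosts) {
    len <- mir_len(1)
    lo <- if (genes$strand[h] == "+") genes$start[h] + 6500L else genes$start[h] + 600L
    hi <- if (genes$strand[h] == "+") genes$end[h] - 600L - len else genes$end[h] - 6500L - len
    pos <- round(stats::runif(1, lo, max(lo, hi)))
    co_tss <- stats::runif(1) < 0.6  # co-transcribed with host
    id <- add_mir(genes$chrom[h], pos, len, genes$strand[h], "intragenic",
                  genes$gene_id[h], NA_character_,
                  round(stats::runif(1, 500, 1800)))
    if (co_tss) mir_tss[[mid]]$true_tss <- genes$tss[h]
  }
  if (mid == 0L) {
    mirs <- data.frame(mir_id = character(0), chrom = character(0),
                       start = integer(0), end = integer(0),
                       strand = character(0), context = character(0),
                       host_gene_id = character(0),
                       cluster_id = character(0))
    mir_tss <- data.frame(mir_id = character(0), true_tss = integer(0))
  } else {
    mirs <- do.call(rbind, mirs)
    mir_tss <- do.call(rbind, mir_tss)
  }

  # ---- families and disease categories
  fam_pool <- sprintf("FAM%02d", seq_len(config$n_families))
  fam <- rep(NA_character_, nrow(mirs))
  has_fam <- stats::runif(nrow(mirs)) < 0.6
  fam[has_fam] <- sample(fam_pool, sum(has_fam), replace = TRUE)
  for (cl in unique(stats::na.omit(mirs$cluster_id)))
    fam[mirs$cluster_id %in% cl] <- sample(fam_pool, 1)
  mirs$family_id <- fam
  dis_pool <- sprintf("disease%02d", seq_len(config$n_disease_categories))
  mirs$disease_categories <- vapply(seq_len(nrow(mirs)), function(i) {
    if (stats::runif(1) > 0.5) return(NA_character_)
    n <- 1 + stats::rpois(1, 0.5)
    paste(sort(sample(dis_pool, min(n, length(dis_pool)))), collapse = ",")
  }, character(1))

  # ---- planted communities over genes + unclustered intergenic MIRs.
  # MIR membership is allocated explicitly: hub communities get a fixed
  # quota so planted target enrichment has stable cross-pair counts.
  pool_mirs <- resample(mirs$mir_id[mirs$context == "intergenic" &
                                      is.na(mirs$cluster_id)])
  # host genes of intragenic MIRs are kept out of planted communities:
  # co-TSS MIRs would otherwise inherit community membership through the
  # shared promoter, and all intragenic MIRs inherit host activity, which
  # would blur the planted basal-vs-interaction expression ordering
  pool_genes <- resample(setdiff(genes$gene_id,
                                 stats::na.omit(mirs$host_gene_id)))
  sizes <- 2L + stats::rnbinom(config$n_planted_communities, size = 2,
                               mu = max(config$community_size_mean - 2, 0.1))
  sizes <- sort(sizes, decreasing = TRUE)
  n_hub <- min(config$hub_count, length(sizes))
  sizes[seq_len(n_hub)] <- pmax(sizes[seq_len(n_hub)], config$hub_size)
  n_mir_quota <- integer(length(sizes))
  n_mir_quota[seq_len(n_hub)] <- pmin(config$hub_mirs,
                                      sizes[seq_len(n_hub)] - 1L)
  if (sum(n_mir_quota) > length(pool_mirs)) {
    # not enough intergenic MIRs: fill hub quotas greedily with what exists
    cum <- cumsum(n_mir_quota)
    n_mir_quota <- pmin(n_mir_quota,
                        pmax(0L, length(pool_mirs) - c(0L, cum[-length(cum)])))
  }
  spare <- length(pool_mirs) - sum(n_mir_quota)
  # spread roughly half of the remaining MIRs over the non-hub communities
  if (length(sizes) > n_hub && spare > 0) {
    extra <- stats::rmultinom(1, size = min(spare %/% 2,
                                            sum(sizes[-seq_len(n_hub)] - 1L)),
                              prob = sizes[-seq_len(n_hub)])[, 1]
    extra <- pmin(extra, sizes[-seq_len(n_hub)] - 1L)
    n_mir_quota[-seq_len(n_hub)] <- extra
  }
  n_gene_quota <- sizes - n_mir_quota
  if (sum(n_gene_quota) > length(pool_genes))
    stop("genome too small: planted communities need ", sum(n_gene_quota),
         " genes but only ", length(pool_genes), " are available")
  members <- character(0); community <- character(0)
  mi <- 0L; gi <- 0L
  for (i in seq_along(sizes)) {
    mm <- if (n_mir_quota[i] > 0) pool_mirs[mi + seq_len(n_mir_quota[i])] else character(0)
    gg <- pool_genes[gi + seq_len(n_gene_quota[i])]
    mi <- mi + n_mir_quota[i]; gi <- gi + n_gene_quota[i]
    members <- c(members, mm, gg)
    community <- c(community, rep(sprintf("P%02d", i), sizes[i]))
  }
  membership <- data.frame(entity_id = members, community = community,
                           stringsAsFactors = FALSE)
  n_spec <- round(config$fraction_cell_specific_communities * length(sizes))
  restrict <- rep("both", length(sizes))
  if (n_spec > 0) {
    # restrict the smallest communities, alternating cell lines
    idx <- rev(seq_along(sizes))[seq_len(n_spec)]
    restrict[idx] <- rep_len(names(config$cell_lines), n_spec)
  }
  community_info <- data.frame(community = sprintf("P%02d", seq_along(sizes)),
                               size = sizes, cell_restriction = restrict,
                               stringsAsFactors = FALSE)
  enriched_pairs <- if (identical(config$n_enriched_community_pairs, "all")) {
    # enrichment between every distinct community pair
    cp <- utils::combn(sprintf("P%02d", seq_along(sizes)), 2)
    data.frame(community_a = cp[1, ], community_b = cp[2, ],
               stringsAsFactors = FALSE)
  } else {
    np <- min(config$n_enriched_community_pairs, floor(length(sizes) / 2))
    if (np > 0) {
      data.frame(community_a = sprintf("P%02d", 2 * seq_len(np) - 1),
                 community_b = sprintf("P%02d", 2 * seq_len(np)),
                 stringsAsFactors = FALSE)
    } else data.frame(community_a = character(0), community_b = character(0))
  }

  # ---- TSS evidence tiers: community and cluster MIRs always carry exact
  # curated/CAGE evidence so planted structure is identified by annotation
  must_exact <- mirs$mir_id %in% c(membership$entity_id) |
    !is.na(mirs$cluster_id)
  ev <- rep("rnapii", nrow(mirs))
  r <- stats::runif(nrow(mirs))
  ev[r < config$curated_fraction] <- "curated"
  ev[r >= config$curated_fraction &
       r < config$curated_fraction + config$cage_fraction] <- "cage"
  ev[must_exact & ev == "rnapii"] <-
    sample(c("curated", "cage"), sum(must_exact & ev == "rnapii"),
           replace = TRUE,
           prob = c(config$curated_fraction,
                    max(config$cage_fraction, 1e-9)))
  mir_tss$evidence <- ev

  # ---- activity per entity per cell line
  all_ids <- c(genes$gene_id, mirs$mir_id)
  cells <- names(config$cell_lines)
  activity <- matrix(NA_real_, length(all_ids), length(cells),
                     dimnames = list(all_ids, cells))
  comm_of <- membership$community[match(all_ids, membership$entity_id)]
  restr_of <- community_info$cell_restriction[match(comm_of,
                                                    community_info$community)]
  non_comm_mirs <- setdiff(mirs$mir_id, membership$entity_id)
  basal <- resample(non_comm_mirs,
                  round(config$basal_fraction * length(non_comm_mirs)))
  for (i in seq_along(all_ids)) {
    id <- all_ids[i]
    for (cl in cells) {
      if (!is.na(comm_of[i])) {
        on <- restr_of[i] == "both" || restr_of[i] == cl
        activity[i, cl] <- if (on) exp(stats::rnorm(1, 2, 0.5))
                           else exp(stats::rnorm(1, -1, 0.3))
      } else if (id %in% basal || (!id %in% mirs$mir_id && stats::runif(1) < 0.5)) {
        activity[i, cl] <- exp(stats::rnorm(1, 0.5, 0.5))
      } else {
        activity[i, cl] <- exp(stats::rnorm(1, -1, 0.3))
      }
    }
  }
  # intragenic MIR activity tracks the host gene (co-transcription)
  intra <- which(mirs$context == "intragenic")
  for (i in intra) {
    h <- mirs$host_gene_id[i]
    activity[mirs$mir_id[i], ] <- activity[h, ] * exp(stats::rnorm(1, 0, 0.2))
  }

  truth <- list(membership = membership, community_info = community_info,
                enriched_pairs = enriched_pairs, activity = activity,
                mir_tss = mir_tss, basal_mirs = basal,
                active_entities = all_ids[apply(activity > 0.7, 1, any)])
  list(genes = genes, mirs = mirs, truth = truth)
}

#' Generate duplex interactions and RNAPII peaks
#'
#' Every planted community gets a connecting edge set (random spanning tree
#' plus extra edges); each planted edge is emitted independently per
#' replicate of its community's cell line(s) with probability
#' `edge_reproducibility`, as a duplex interaction whose anchors (width
#' uniform in 500..4000 bp) are centered on the two member TSSs. Noise
#' interactions join random entity pairs and appear in exactly one
#' replicate. Clustered MIR neighbours are joined by single-replicate
#' interactions (recoverable only through the neighbour rule). RNAPII peaks
#' are emitted per replicate at promoters of active entities with intensity
#' increasing in activity.
#'
#' @param genome output of [generate_genome()].
#' @param truth its `truth` element.
#' @param config the [simulation_config()].
#' @return list `interactions` (data.frame in [read_interactions()]
#'   layout), `rnapii_peaks` (data.frame in [read_peaks()] layout, mark
#'   `"RNAPII"`) and `planted_edges` (data.frame `u, v, community,
#'   cell_restriction`: the ground-truth edge list before replicate
#'   emission).
#' @export
generate_chia_pet <- function(genome, truth = genome$truth,
                              config = simulation_config()) {
  with_seed(config$seed + 2L, generate_chia_pet_impl(genome, truth, config))
}

generate_chia_pet_impl <- function(genome, truth, config) {
  genes <- genome$genes; mirs <- genome$mirs
  tss_of <- c(stats::setNames(genes$tss, genes$gene_id),
              stats::setNames(truth$mir_tss$true_tss, truth$mir_tss$mir_id))
  chrom_of <- c(stats::setNames(genes$chrom, genes$gene_id),
                stats::setNames(mirs$chrom, mirs$mir_id))
  cells <- names(config$cell_lines)
  reps <- lapply(cells, function(cl)
    sprintf("rep%d", seq_len(config$cell_lines[[cl]])))
  names(reps) <- cells

  anchor_at <- function(id) {
    w <- round(stats::runif(length(id), 500, 4000))
    ctr <- as.integer(tss_of[id])
    data.frame(chrom = chrom_of[id],
               start = pmax(0L, as.integer(ctr - w %/% 2)),
               end = as.integer(ctr + w %/% 2 + 1L),
               stringsAsFactors = FALSE)
  }
  mk_rows <- function(id1, id2, cell, rep) {
    a <- anchor_at(id1); b <- anchor_at(id2)
    data.frame(chrom1 = a$chrom, start1 = a$start, end1 = a$end,
               chrom2 = b$chrom, start2 = b$start, end2 = b$end,
               pet_count = 2L + stats::rpois(length(id1), 3),
               cell_line = cell, replicate_id = rep,
               stringsAsFactors = FALSE)
  }

  rows <- list()
  planted <- list()
  # planted community edges
  for (k in seq_len(nrow(truth$community_info))) {
    cid <- truth$community_info$community[k]
    restr <- truth$community_info$cell_restriction[k]
    mem <- truth$membership$entity_id[truth$membership$community == cid]
    if (length(mem) < 2) next
    mem <- sample(mem)
    # random spanning tree: connect node i+1 to a uniform earlier node
    parent <- vapply(seq_len(length(mem) - 1), function(i)
      mem[sample.int(i, 1)], "")
    edges <- data.frame(u = mem[-1], v = parent, stringsAsFactors = FALSE)
    n_extra <- round(0.5 * length(mem))
    if (n_extra > 0 && length(mem) >= 3) {
      for (e in seq_len(n_extra)) {
        uv <- sample(mem, 2)
        edges <- rbind(edges, data.frame(u = uv[1], v = uv[2]))
      }
      edges <- unique(data.frame(u = pmin(edges$u, edges$v),
                                 v = pmax(edges$u, edges$v)))
      edges <- edges[edges$u != edges$v, , drop = FALSE]
    }
    use_cells <- if (restr == "both") cells else restr
    planted[[k]] <- data.frame(u = pmin(edges$u, edges$v),
                               v = pmax(edges$u, edges$v),
                               community = cid,
                               cell_restriction = restr,
                               stringsAsFactors = FALSE)
    for (cl in use_cells) {
      for (rp in reps[[cl]]) {
        emit <- stats::runif(nrow(edges)) < config$edge_reproducibility
        if (any(emit))
          rows[[length(rows) + 1L]] <- mk_rows(edges$u[emit], edges$v[emit],
                                               cl, rp)
      }
    }
  }

  # single-replicate interactions joining clustered MIR neighbours
  for (cl_id in unique(stats::na.omit(mirs$cluster_id))) {
    mm <- mirs$mir_id[mirs$cluster_id %in% cl_id]
    mm <- mm[order(mirs$start[match(mm, mirs$mir_id)])]
    if (length(mm) < 2) next
    cell <- sample(cells, 1)
    rp <- sample(reps[[cell]], 1)
    rows[[length(rows) + 1L]] <- mk_rows(mm[-length(mm)], mm[-1], cell, rp)
  }

  # noise edges: each unique to one replicate
  all_ids <- names(tss_of)
  total_reps <- sum(unlist(config$cell_lines))
  n_noise <- stats::rpois(1, config$noise_edge_rate * total_reps)
  if (n_noise > 0) {
    seen <- character(0)
    picked <- 0L
    while (picked < n_noise) {
      uv <- sample(all_ids, 2)
      key <- paste(sort(uv), collapse = "\r")
      if (key %in% seen) next
      seen <- c(seen, key)
      picked <- picked + 1L
      cell <- sample(cells, 1)
      rp <- sample(reps[[cell]], 1)
      rows[[length(rows) + 1L]] <- mk_rows(uv[1], uv[2], cell, rp)
    }
  }
  interactions <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(chrom1 = character(0), start1 = integer(0), end1 = integer(0),
               chrom2 = character(0), start2 = integer(0), end2 = integer(0),
               pet_count = integer(0), cell_line = character(0),
               replicate_id = character(0))
  interactions <- canonicalize_interactions(interactions)

  # RNAPII peaks at promoters of active entities, per cell line/replicate
  peak_rows <- list()
  for (cl in cells) {
    act <- truth$activity[, cl]
    on <- names(act)[act > 0.7]
    for (rp in reps[[cl]]) {
      ctr <- as.integer(tss_of[on]) + round(stats::rnorm(length(on), 0, 100))
      hw <- round(stats::runif(length(on), 200, 1000))
      peak_rows[[length(peak_rows) + 1L]] <- data.frame(
        chrom = chrom_of[on], start = pmax(0L, ctr - hw),
        end = ctr + hw + 1L, center = ctr,
        intensity = round(10 * act[on] * exp(stats::rnorm(length(on), 0, 0.3)), 2),
        mark = "RNAPII", cell_line = cl, replicate_id = rp,
        stringsAsFactors = FALSE)
    }
  }
  rnapii_peaks <- do.call(rbind, peak_rows)
  rownames(rnapii_peaks) <- NULL
  planted_edges <- if (length(planted) > 0) do.call(rbind, planted) else
    data.frame(u = character(0), v = character(0), community = character(0),
               cell_restriction = character(0))
  rownames(planted_edges) <- NULL
  list(interactions = interactions, rnapii_peaks = rnapii_peaks,
       planted_edges = planted_edges)
}

#' Generate miRNA-target pairs with planted enrichment
#'
#' Every (MIR, gene) pair is a target pair with probability
#' `target_base_rate`, multiplied by `target_between_enrichment` when the
#' two planted communities form a planted enriched pair and by
#' `target_self_depletion` when MIR and gene share a planted community.
#' Database support is drawn from `target_db_probs` over 1..6.
#'
#' @inheritParams generate_chia_pet
#' @return data.frame `mir_id, target_gene_id, n_databases`.
#' @export
generate_targets <- function(genome, truth = genome$truth,
                             config = simulation_config()) {
  with_seed(config$seed + 3L, {
    mirs <- genome$mirs$mir_id
    genes <- genome$genes$gene_id
    cm <- truth$membership$community[match(mirs, truth$membership$entity_id)]
    cg <- truth$membership$community[match(genes, truth$membership$entity_id)]
    ep <- paste(truth$enriched_pairs$community_a,
                truth$enriched_pairs$community_b, sep = "\r")
    grid <- expand.grid(mi = seq_along(mirs), gi = seq_along(genes))
    a <- cm[grid$mi]; b <- cg[grid$gi]
    key <- paste(pmin(a, b), pmax(a, b), sep = "\r")
    mult <- rep(1, nrow(grid))
    mult[!is.na(a) & !is.na(b) & a == b] <- config$target_self_depletion
    mult[!is.na(a) & !is.na(b) & a != b & key %in% ep] <-
      config$target_between_enrichment
    p <- pmin(1, config$target_base_rate * mult)
    hit <- stats::runif(nrow(grid)) < p
    data.frame(mir_id = mirs[grid$mi[hit]],
               target_gene_id = genes[grid$gi[hit]],
               n_databases = sample(1:6, sum(hit), replace = TRUE,
                                    prob = config$target_db_probs),
               stringsAsFactors = FALSE)
  })
}

#' Generate expression tables and chromatin-mark peaks
#'
#' Expression is a monotone (power) function of planted activity with
#' lognormal noise: `value = 10 * activity^effect * exp(noise)` (FPKM for
#' genes, RPM for MIRs). Active marks (H3K4me3, H3K4me2, H3K9ac, H3K27ac)
#' are emitted as peaks around active promoters at a Poisson rate
#' increasing in activity; repressive marks (H3K27me3, H3K9me3) at a rate
#' decreasing in activity. The
#' returned mark count table counts peak centers within
#' `mark_profile_window` of each MIR's true TSS (computed directly, not via
#' [mark_profile()]).
#'
#' @inheritParams generate_chia_pet
#' @param mark_profile_window bp window used for the returned count table.
#' @return list `expression` (data.frame `entity_id, cell_line, value`),
#'   `mark_peaks` (peak data.frame), `mark_table` (matrix MIRs x marks).
#' @export
generate_expression_marks <- function(genome, truth = genome$truth,
                                      config = simulation_config(),
                                      mark_profile_window = 5000L) {
  with_seed(config$seed + 4L, {
    act <- truth$activity
    cells <- colnames(act)
    expression <- do.call(rbind, lapply(cells, function(cl) {
      data.frame(entity_id = rownames(act), cell_line = cl,
                 value = round(10 * act[, cl] ^ config$expression_activity_effect *
                                 exp(stats::rnorm(nrow(act), 0,
                                                  config$expression_noise_sd)), 4),
                 stringsAsFactors = FALSE)
    }))
    rownames(expression) <- NULL

    tss_of <- c(stats::setNames(genome$genes$tss, genome$genes$gene_id),
                stats::setNames(truth$mir_tss$true_tss, truth$mir_tss$mir_id))
    chrom_of <- c(stats::setNames(genome$genes$chrom, genome$genes$gene_id),
                  stats::setNames(genome$mirs$chrom, genome$mirs$mir_id))
    a1 <- act[, 1]
    marks <- c(H3K4me3 = 3, H3K4me2 = 2.5, H3K9ac = 2, H3K27ac = 2,
               H3K27me3 = 2, H3K9me3 = 1.5)
    repressive <- c("H3K27me3", "H3K9me3")
    peak_rows <- list()
    for (m in names(marks)) {
      lambda <- if (m %in% repressive) marks[[m]] / (1 + a1) else
        marks[[m]] * a1 / (1 + a1) * 2
      n <- stats::rpois(length(a1), lambda)
      ids <- rep(names(a1), n)
      if (length(ids) == 0) next
      ctr <- as.integer(tss_of[ids]) +
        round(stats::rnorm(length(ids), 0, 2000))
      hw <- round(stats::runif(length(ids), 150, 600))
      peak_rows[[m]] <- data.frame(
        chrom = chrom_of[ids], start = pmax(0L, ctr - hw), end = ctr + hw + 1L,
        center = pmax(0L, ctr), intensity = round(stats::rlnorm(length(ids), 1, 0.4), 2),
        mark = m, cell_line = cells[1], replicate_id = "rep1",
        stringsAsFactors = FALSE)
      peak_rows[[m]]$center <- pmax(peak_rows[[m]]$start,
                                    pmin(peak_rows[[m]]$center,
                                         peak_rows[[m]]$end - 1L))
    }
    mark_peaks <- do.call(rbind, peak_rows)
    rownames(mark_peaks) <- NULL

    mir_ids <- genome$mirs$mir_id
    mark_table <- matrix(0L, length(mir_ids), length(marks),
                         dimnames = list(mir_ids, names(marks)))
    for (m in names(marks)) {
      pk <- mark_peaks[mark_peaks$mark == m, , drop = FALSE]
      for (i in seq_along(mir_ids)) {
        tt <- tss_of[mir_ids[i]]
        mark_table[i, m] <- sum(pk$chrom == chrom_of[mir_ids[i]] &
                                  abs(pk$center - tt) <= mark_profile_window)
      }
    }
    list(expression = expression, mark_peaks = mark_peaks,
         mark_table = mark_table)
  })
}

#' Generate a complete synthetic input bundle
#'
#' Orchestrates [generate_genome()], [generate_chia_pet()],
#' [generate_targets()] and [generate_expression_marks()], and adds the
#' annotation extras: curated TSS table and CAGE tags realising the
#' per-MIR evidence tiers, GO-style term annotations (a theme term per
#' planted community, shared across planted enriched pairs, over random
#' background terms), an SV blacklist placed in the feature-free tail of
#' each chromosome, and TAD intervals tiling the feature-bearing region.
#'
#' @param config a [simulation_config()].
#' @return list of class `"sim_bundle"` with elements `genes, mirs,
#'   curated_tss, cage_tags, interactions, rnapii_peaks, mark_peaks,
#'   expression, mark_table, targets, terms, blacklist, tads, truth,
#'   config`.
#' @export
simulate_bundle <- function(config = simulation_config()) {
  genome <- generate_genome(config)
  chia <- generate_chia_pet(genome, genome$truth, config)
  targets <- generate_targets(genome, genome$truth, config)
  em <- generate_expression_marks(genome, genome$truth, config)
  extras <- with_seed(config$seed + 5L, {
    mt <- genome$truth$mir_tss
    curated <- mt[mt$evidence == "curated", c("mir_id", "true_tss")]
    names(curated) <- c("mir_id", "tss")
    cage_m <- mt[mt$evidence == "cage", , drop = FALSE]
    cage <- data.frame(
      chrom = genome$mirs$chrom[match(cage_m$mir_id, genome$mirs$mir_id)],
      pos = cage_m$true_tss,
      score = round(stats::rlnorm(nrow(cage_m), 2, 0.5), 2),
      stringsAsFactors = FALSE)
    # terms: community theme terms (shared across enriched pairs) + noise
    mem <- genome$truth$membership
    ep <- genome$truth$enriched_pairs
    theme_of <- stats::setNames(sprintf("T%03d", seq_len(nrow(genome$truth$community_info))),
                                genome$truth$community_info$community)
    for (i in seq_len(nrow(ep)))
      theme_of[ep$community_b[i]] <- theme_of[ep$community_a[i]]
    gene_ids <- genome$genes$gene_id
    term_rows <- list()
    for (cid in names(theme_of)) {
      g <- intersect(mem$entity_id[mem$community == cid], gene_ids)
      g <- g[stats::runif(length(g)) < 0.7]
      if (length(g) > 0)
        term_rows[[length(term_rows) + 1L]] <-
          data.frame(gene_id = g, term_id = theme_of[[cid]])
    }
    for (t in seq_len(config$n_terms)) {
      g <- gene_ids[stats::runif(length(gene_ids)) < 0.08]
      if (length(g) > 0)
        term_rows[[length(term_rows) + 1L]] <-
          data.frame(gene_id = g, term_id = sprintf("B%03d", t))
    }
    terms <- unique(do.call(rbind, term_rows))
    # blacklist in the reserved feature-free chromosome tails
    chroms <- sprintf("chr%d", seq_len(config$n_chromosomes))
    bl_chr <- sample(chroms, config$n_blacklist, replace = TRUE)
    bl_start <- round(stats::runif(config$n_blacklist,
                                   config$chrom_length - 140000,
                                   config$chrom_length - 20000))
    blacklist <- data.frame(chrom = bl_chr, start = as.integer(bl_start),
                            end = as.integer(bl_start +
                                               round(stats::runif(config$n_blacklist,
                                                                  2000, 10000))),
                            stringsAsFactors = FALSE)
    # TADs tile the feature-bearing region
    tad_rows <- list()
    for (ch in chroms) {
      lim <- max(genome$genes$end[genome$genes$chrom == ch])
      bounds <- sort(c(0, round(stats::runif(config$n_tads_per_chrom - 1,
                                             0, lim)), lim))
      tad_rows[[ch]] <- data.frame(chrom = ch,
                                   start = as.integer(bounds[-length(bounds)]),
                                   end = as.integer(bounds[-1]),
                                   stringsAsFactors = FALSE)
    }
    tads <- do.call(rbind, tad_rows)
    tads <- tads[tads$end > tads$start, , drop = FALSE]
    rownames(tads) <- NULL
    list(curated_tss = curated, cage_tags = cage, terms = terms,
         blacklist = blacklist, tads = tads)
  })
  structure(c(list(genes = genome$genes, mirs = genome$mirs,
                   interactions = chia$interactions,
                   rnapii_peaks = chia$rnapii_peaks,
                   planted_edges = chia$planted_edges,
                   mark_peaks = em$mark_peaks,
                   expression = em$expression, mark_table = em$mark_table,
                   targets = targets, truth = genome$truth, config = config),
              extras),
            class = "sim_bundle")
}

#' Write a synthetic bundle to disk in the pipeline's input formats
#'
#' @param bundle a `sim_bundle`.
#' @param dir output directory (created if missing).
#' @return `dir` invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_annotations(bundle$genes, p("genes.gff3"), "gene")
  write_annotations(bundle$mirs, p("mirs.gff3"), "mir")
  write_interactions(bundle$interactions, p("interactions.bedpe"))
  write_peaks(bundle$rnapii_peaks, p("rnapii_peaks.bed"))
  write_peaks(bundle$mark_peaks, p("mark_peaks.bed"))
  write_tsv_strict(bundle$expression, p("expression.tsv"))
  write_tsv_strict(bundle$targets, p("targets.tsv"))
  write_tsv_strict(bundle$curated_tss, p("curated_tss.tsv"))
  write_tsv_strict(bundle$cage_tags, p("cage_tags.tsv"))
  write_tsv_strict(bundle$terms, p("terms.tsv"))
  write_bed3(bundle$blacklist, p("blacklist.bed"))
  write_bed3(bundle$tads, p("tads.bed"))
  jsonlite::write_json(list(
    membership = bundle$truth$membership,
    community_info = bundle$truth$community_info,
    enriched_pairs = bundle$truth$enriched_pairs,
    basal_mirs = bundle$truth$basal_mirs),
    p("ground_truth.json"))
  yaml::write_yaml(unclass(bundle$config), p("sim_config.yaml"))
  invisible(dir)
}
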