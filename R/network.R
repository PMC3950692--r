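#' Remove interactions near structural variations
#'
#' Drops every duplex interaction with at least one anchor overlapping
#' (>= 1 bp, half-open semantics) a blacklist interval; input order is
#' preserved. Any padding of the blacklist is the caller's responsibility.
#'
#' @param interactions interaction data.frame ([read_interactions()]).
#' @param blacklist data.frame `chrom, start, end` (possibly empty).
#' @return Filtered interaction data.frame.
#' @export
filter_sv_blacklist <- function(interactions, blacklist) {
  if (nrow(interactions) == 0 || is.null(blacklist) || nrow(blacklist) == 0)
    return(interactions)
  hit_a <- overlaps_any0(data.frame(chrom = interactions$chrom1,
                                    start = interactions$start1,
                                    end = interactions$end1), blacklist)
  hit_b <- overlaps_any0(data.frame(chrom = interactions$chrom2,
                                    start = interactions$start2,
                                    end = interactions$end2), blacklist)
  out <- interactions[!(hit_a | hit_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' TSS index over genes and promoter-bearing MIRs
#'
#' The node universe of the chromatin network: protein-coding genes plus
#' every MIR with an assigned promoter, each with its TSS position.
#'
#' @param genes gene annotation data.frame.
#' @param promoter_calls promoter calls from [assign_tss()]; rows without a
#'   TSS are excluded.
#' @return data.frame `entity_id, chrom, tss, is_mir`.
#' @export
make_tss_index <- function(genes, promoter_calls) {
  g <- data.frame(entity_id = genes$gene_id, chrom = genes$chrom,
                  tss = genes$tss, is_mir = FALSE, stringsAsFactors = FALSE)
  pc <- promoter_calls[!is.na(promoter_calls$tss), , drop = FALSE]
  m <- data.frame(entity_id = pc$mir_id, chrom = pc$chrom, tss = pc$tss,
                  is_mir = TRUE, stringsAsFactors = FALSE)
  out <- rbind(g, m)
  if (anyDuplicated(out$entity_id)) stop("duplicate entity ids in TSS index")
  rownames(out) <- NULL
  out
}

# Map every entity TSS window onto the A and B anchors of every
# interaction. Returns a data.frame (interaction, entity, side).
anchor_assignments <- function(interactions, tss_index, config) {
  if (nrow(interactions) == 0 || nrow(tss_index) == 0)
    return(data.frame(interaction = integer(0), entity = character(0),
                      side = character(0)))
  win <- as_granges0(window_interval0(tss_index$chrom, tss_index$tss,
                                      config$anchor_tss_window))
  res <- lapply(c(a = 1L, b = 2L), function(side) {
    anc <- as_granges0(data.frame(
      chrom = interactions[[paste0("chrom", side)]],
      start = interactions[[paste0("start", side)]],
      end = interactions[[paste0("end", side)]]))
    h <- suppressWarnings(
      GenomicRanges::findOverlaps(win, anc, ignore.strand = TRUE))
    data.frame(interaction = S4Vectors::subjectHits(h),
               entity = tss_index$entity_id[S4Vectors::queryHits(h)],
               stringsAsFactors = FALSE)
  })
  res$a$side <- rep("a", nrow(res$a))
  res$b$side <- rep("b", nrow(res$b))
  rbind(res$a, res$b)
}

#' Entity pairs linked by one duplex interaction
#'
#' Entities whose TSS window (`anchor_tss_window` bp each side, inclusive)
#' overlaps anchor A are paired with those on anchor B (cross product,
#' self-pairs removed). Entities sharing a single anchor are not paired by
#' that interaction alone.
#'
#' @param interaction a single-row interaction data.frame.
#' @param tss_index from [make_tss_index()].
#' @inheritParams assign_tss
#' @return data.frame `id1, id2` with `id1 < id2`.
#' @export
link_genes_to_interaction <- function(interaction, tss_index,
                                      config = pipeline_config()) {
  stopifnot(nrow(interaction) == 1)
  asg <- anchor_assignments(interaction, tss_index, config)
  cross_anchor_pairs(asg$entity[asg$side == "a"], asg$entity[asg$side == "b"])
}

cross_anchor_pairs <- function(ents_a, ents_b) {
  if (length(ents_a) == 0 || length(ents_b) == 0)
    return(data.frame(id1 = character(0), id2 = character(0)))
  p <- expand.grid(x = ents_a, y = ents_b, stringsAsFactors = FALSE)
  p <- p[p$x != p$y, , drop = FALSE]
  out <- data.frame(id1 = pmin(p$x, p$y), id2 = pmax(p$x, p$y),
                    stringsAsFactors = FALSE)
  out <- unique(out)
  rownames(out) <- NULL
  out
}

#' Build the replicate-filtered gene-level chromatin network
#'
#' Each duplex interaction yields entity pairs via
#' [link_genes_to_interaction()]; a pair becomes an edge when, in at least
#' one cell line, it is supported by `min_edge_replicates` distinct
#' replicates. The per-edge `cell_status` names the cell lines individually
#' meeting the threshold (`"common"` when more than one does).
#'
#' @param interactions blacklist-filtered interaction data.frame.
#' @param tss_index from [make_tss_index()].
#' @inheritParams assign_tss
#' @return An object of class `"gene_network"`: list with `edges`
#'   (data.frame `id1, id2, n_support, cell_status` plus list-column
#'   `support` of `"cell|replicate"` strings), `nodes`, and `node_info`
#'   (the TSS index rows for the nodes).
#' @export
build_network <- function(interactions, tss_index, config = pipeline_config()) {
  asg <- anchor_assignments(interactions, tss_index, config)
  # per interaction: cross product of its A and B entity sets
  pairs_list <- list()
  if (nrow(asg) > 0) {
    by_int <- split(asg, asg$interaction)
    pairs_list <- lapply(names(by_int), function(k) {
      s <- by_int[[k]]
      p <- cross_anchor_pairs(s$entity[s$side == "a"], s$entity[s$side == "b"])
      if (nrow(p) == 0) return(NULL)
      i <- as.integer(k)
      p$cell_line <- interactions$cell_line[i]
      p$replicate_id <- interactions$replicate_id[i]
      p
    })
  }
  raw <- do.call(rbind, pairs_list)
  edges <- aggregate_edge_support(raw, config)
  nodes <- sort(unique(c(edges$id1, edges$id2)))
  structure(list(edges = edges, nodes = nodes,
                 node_info = tss_index[match(nodes, tss_index$entity_id), ,
                                       drop = FALSE],
                 config = config),
            class = "gene_network")
}

# raw: data.frame id1,id2,cell_line,replicate_id (one row per supporting
# duplex interaction). Applies the per-cell-line replicate filter.
aggregate_edge_support <- function(raw, config,
                                   min_replicates = config$min_edge_replicates) {
  empty <- data.frame(id1 = character(0), id2 = character(0),
                      n_support = integer(0), cell_status = character(0))
  empty$support <- list()
  if (is.null(raw) || nrow(raw) == 0) return(empty)
  key <- paste(raw$id1, raw$id2, sep = "\r")
  sup <- tapply(paste(raw$cell_line, raw$replicate_id, sep = "|"), key,
                function(v) sort(unique(v)), simplify = FALSE)
  keys <- names(sup)
  qualifying <- lapply(sup, function(v) {
    cells <- sub("\\|.*", "", v)
    names(which(table(cells) >= min_replicates))
  })
  keep <- vapply(qualifying, function(q) length(q) > 0, logical(1))
  keys <- keys[keep]
  if (length(keys) == 0) return(empty)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- data.frame(id1 = vapply(parts, `[`, "", 1),
                    id2 = vapply(parts, `[`, "", 2),
                    n_support = vapply(sup[keep], length, integer(1)),
                    cell_status = vapply(qualifying[keep], function(q)
                      if (length(q) > 1) "common" else paste0(q, "-only"), ""),
                    stringsAsFactors = FALSE)
  out$support <- unname(sup[keep])
  out <- out[order(out$id1, out$id2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.gene_network <- function(x, ...) {
  cat("Gene-level chromatin interaction network\n")
  cat("  nodes:", length(x$nodes),
      sprintf("(%d MIRs)", sum(x$node_info$is_mir)), "\n")
  cat("  edges:", nrow(x$edges), "\n")
  if (nrow(x$edges) > 0) print(table(x$edges$cell_status))
  invisible(x)
}

#' Partition the network into chromatin communities
#'
#' Communities are the connected components of the retained-edge graph;
#' edgeless entities are not network nodes and belong to no community.
#' Communities are numbered by decreasing size (ties by smallest member
#' id); the largest is flagged as the giant community.
#'
#' @param network a `gene_network`.
#' @return An object of class `"chromatin_communities"`: list with
#'   `membership` (data.frame `entity_id, community_id, is_mir`) and
#'   `communities` (data.frame `community_id, size, n_mirs, is_giant`).
#' @export
find_communities <- function(network) {
  if (nrow(network$edges) == 0) {
    return(structure(list(
      membership = data.frame(entity_id = character(0),
                              community_id = character(0), is_mir = logical(0)),
      communities = data.frame(community_id = character(0), size = integer(0),
                               n_mirs = integer(0), is_giant = logical(0))),
      class = "chromatin_communities"))
  }
  g <- igraph::graph_from_data_frame(network$edges[, c("id1", "id2")],
                                     directed = FALSE,
                                     vertices = network$nodes)
  comp <- igraph::components(g)
  member <- split(names(comp$membership), comp$membership)
  minid <- vapply(member, min, "")
  ord <- order(-comp$csize, minid)
  ids <- sprintf("C%d", seq_along(ord))
  is_mir <- network$node_info$is_mir[match(names(comp$membership),
                                           network$node_info$entity_id)]
  n_mirs_by <- vapply(member, function(v)
    sum(is_mir[match(v, names(comp$membership))]), integer(1))
  membership <- data.frame(
    entity_id = names(comp$membership),
    community_id = ids[match(comp$membership, ord)],
    is_mir = is_mir, stringsAsFactors = FALSE)
  membership <- membership[order(membership$community_id, membership$entity_id), ]
  rownames(membership) <- NULL
  communities <- data.frame(
    community_id = ids,
    size = comp$csize[ord],
    n_mirs = n_mirs_by[ord],
    is_giant = seq_along(ord) == 1L,
    stringsAsFactors = FALSE)
  structure(list(membership = membership, communities = communities),
            class = "chromatin_communities")
}

#' @export
print.chromatin_communities <- function(x, ...) {
  cat("Chromatin communities:", nrow(x$communities), "\n")
  if (nrow(x$communities) > 0) {
    cat("  giant community size:", x$communities$size[1], "\n")
    cat("  size distribution:\n")
    print(utils::head(table(x$communities$size), 10))
  }
  invisible(x)
}

#' Topological summary of the network and its communities
#'
#' Reports the community-size histogram, per-node degrees, a one-sided
#' Mann-Whitney comparison of MIR vs coding-gene degrees (alternative: MIR
#' degrees greater), a Wilcoxon rank-sum comparison of MIR-containing vs
#' MIR-free community sizes, and the least-squares slope of log frequency
#' vs log degree over the degree histogram (descriptive scale-freeness
#' check). Comparisons lacking two non-empty groups are reported as `NA`.
#'
#' @param network a `gene_network`.
#' @param communities a `chromatin_communities`.
#' @return list with `size_histogram`, `degrees`, `mir_vs_gene_degree_p`,
#'   `mir_community_size_p`, `degree_loglog_slope`.
#' @export
topology_summary <- function(network, communities) {
  deg_tab <- table(c(network$edges$id1, network$edges$id2))
  degrees <- data.frame(entity_id = names(deg_tab),
                        degree = as.integer(deg_tab),
                        stringsAsFactors = FALSE)
  degrees$is_mir <- network$node_info$is_mir[match(degrees$entity_id,
                                                   network$node_info$entity_id)]
  size_histogram <- table(communities$communities$size)

  mir_deg <- degrees$degree[degrees$is_mir]
  gene_deg <- degrees$degree[!degrees$is_mir]
  mir_vs_gene_degree_p <- if (length(mir_deg) > 0 && length(gene_deg) > 0) {
    suppressWarnings(
      stats::wilcox.test(mir_deg, gene_deg,
                         alternative = "greater")$p.value)
  } else NA_real_

  has_mir <- communities$communities$n_mirs > 0
  mir_community_size_p <- if (any(has_mir) && any(!has_mir)) {
    suppressWarnings(
      stats::wilcox.test(communities$communities$size[has_mir],
                         communities$communities$size[!has_mir])$p.value)
  } else NA_real_

  dh <- table(degrees$degree)
  degree_loglog_slope <- if (length(dh) >= 2) {
    unname(stats::coef(stats::lm(log(as.integer(dh)) ~
                                   log(as.integer(names(dh)))))[2])
  } else NA_real_

  list(size_histogram = size_histogram, degrees = degrees,
       mir_vs_gene_degree_p = mir_vs_gene_degree_p,
       mir_community_size_p = mir_community_size_p,
       degree_loglog_slope = degree_loglog_slope)
}

#' TAD overlap report per community
#'
#' For each community: the number of distinct TADs containing at least one
#' member TSS, and the fraction of members whose TSS falls inside any TAD
#' (TSS position contained in the half-open TAD interval).
#'
#' @param communities a `chromatin_communities`.
#' @param tads data.frame `chrom, start, end` of precomputed TAD intervals.
#' @param tss_index from [make_tss_index()].
#' @return data.frame `community_id, n_tads, fraction_in_tad`.
#' @export
tad_overlap_report <- function(communities, tads, tss_index) {
  mem <- communities$membership
  if (nrow(mem) == 0)
    return(data.frame(community_id = character(0), n_tads = integer(0),
                      fraction_in_tad = numeric(0)))
  pos <- tss_index[match(mem$entity_id, tss_index$entity_id), , drop = FALSE]
  tad_of <- rep(NA_integer_, nrow(mem))
  if (!is.null(tads) && nrow(tads) > 0) {
    pts <- as_granges0(data.frame(chrom = pos$chrom, start = pos$tss,
                                  end = pos$tss + 1L))
    h <- GenomicRanges::findOverlaps(pts, as_granges0(tads),
                                     ignore.strand = TRUE, select = "first")
    tad_of <- as.integer(h)
  }
  agg <- lapply(split(tad_of, mem$community_id), function(v) {
    c(n_tads = length(unique(v[!is.na(v)])),
      fraction_in_tad = mean(!is.na(v)))
  })
  out <- data.frame(community_id = names(agg),
                    n_tads = vapply(agg, `[[`, numeric(1), "n_tads"),
                    fraction_in_tad = vapply(agg, `[[`, numeric(1),
                                             "fraction_in_tad"),
                    stringsAsFactors = FALSE)
  out <- out[match(communities$communities$community_id, out$community_id), ]
  rownames(out) <- NULL
  out
}
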