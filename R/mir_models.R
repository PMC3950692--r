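#' Build the MIR-MIR interactome
#'
#' Direct edges join MIR pairs co-anchored by shared duplex interactions and
#' are retained when supported by `min_edge_replicates` distinct replicates
#' in some cell line, or -- for genomic neighbours (same chromosome,
#' pre-miRNA gap at most `neighbor_max_gap` bp) -- by
#' `neighbor_min_replicates`. Indirect edges join MIR pairs that share a
#' chromatin community but no direct edge, and are retained when the edges
#' of the path connecting them carry at least two distinct
#' (cell line, replicate) sources in total.
#'
#' @param interactions blacklist-filtered interaction data.frame.
#' @param mirs MIR annotation data.frame.
#' @param tss_index from [make_tss_index()].
#' @param network optional precomputed [build_network()] result; built from
#'   `interactions` when `NULL`.
#' @param communities optional precomputed [find_communities()] result.
#' @inheritParams assign_tss
#' @return data.frame of MIR edges: `mir1, mir2, linkage (direct/indirect),
#'   n_support, cell_status, via_neighbor_rule, intrachromosomal` plus
#'   list-column `support`.
#' @export
build_mir_network <- function(interactions, mirs, tss_index,
                              network = NULL, communities = NULL,
                              config = pipeline_config()) {
  is_mir <- tss_index$entity_id %in% mirs$mir_id
  mir_index <- tss_index[is_mir, , drop = FALSE]

  # ---- direct edges: MIR-MIR pairs from shared duplex interactions
  asg <- anchor_assignments(interactions, tss_index, config)
  asg <- asg[asg$entity %in% mir_index$entity_id, , drop = FALSE]
  raw <- NULL
  if (nrow(asg) > 0) {
    by_int <- split(asg, asg$interaction)
    raw <- do.call(rbind, lapply(names(by_int), function(k) {
      s <- by_int[[k]]
      p <- cross_anchor_pairs(s$entity[s$side == "a"], s$entity[s$side == "b"])
      if (nrow(p) == 0) return(NULL)
      i <- as.integer(k)
      p$cell_line <- interactions$cell_line[i]
      p$replicate_id <- interactions$replicate_id[i]
      p
    }))
  }
  direct <- direct_mir_edges(raw, mirs, config)

  # ---- indirect edges: same community, no direct edge, path support >= 2
  if (is.null(network)) network <- build_network(interactions, tss_index, config)
  if (is.null(communities)) communities <- find_communities(network)
  indirect <- indirect_mir_edges(network, communities, mirs,
                                 existing = direct, config = config)

  out <- rbind(direct, indirect)
  if (nrow(out) > 0) {
    out <- out[order(out$linkage, out$mir1, out$mir2), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

empty_mir_edges <- function() {
  out <- data.frame(mir1 = character(0), mir2 = character(0),
                    linkage = character(0), n_support = integer(0),
                    cell_status = character(0), via_neighbor_rule = logical(0),
                    intrachromosomal = logical(0))
  out$support <- list()
  out
}

mirs_are_neighbors <- function(mir1, mir2, mirs, config) {
  i <- match(mir1, mirs$mir_id)
  j <- match(mir2, mirs$mir_id)
  same <- mirs$chrom[i] == mirs$chrom[j]
  gap <- interval_gap0(mirs$start[i], mirs$end[i], mirs$start[j], mirs$end[j])
  same & gap <= config$neighbor_max_gap
}

direct_mir_edges <- function(raw, mirs, config) {
  if (is.null(raw) || nrow(raw) == 0) return(empty_mir_edges())
  key <- paste(raw$id1, raw$id2, sep = "\r")
  sup <- tapply(paste(raw$cell_line, raw$replicate_id, sep = "|"), key,
                function(v) sort(unique(v)), simplify = FALSE)
  parts <- strsplit(names(sup), "\r", fixed = TRUE)
  mir1 <- vapply(parts, `[`, "", 1)
  mir2 <- vapply(parts, `[`, "", 2)
  neighbor <- mirs_are_neighbors(mir1, mir2, mirs, config)
  general_cells <- lapply(sup, function(v) {
    cells <- sub("\\|.*", "", v)
    names(which(table(cells) >= config$min_edge_replicates))
  })
  neighbor_cells <- lapply(sup, function(v) {
    cells <- sub("\\|.*", "", v)
    names(which(table(cells) >= config$neighbor_min_replicates))
  })
  meets_general <- vapply(general_cells, function(q) length(q) > 0, logical(1))
  meets_neighbor <- neighbor & vapply(neighbor_cells, function(q) length(q) > 0,
                                      logical(1))
  keep <- meets_general | meets_neighbor
  if (!any(keep)) return(empty_mir_edges())
  qual <- neighbor_cells
  qual[meets_general] <- general_cells[meets_general]
  qual <- qual[keep]
  i <- match(mir1[keep], mirs$mir_id)
  j <- match(mir2[keep], mirs$mir_id)
  out <- data.frame(
    mir1 = mir1[keep], mir2 = mir2[keep], linkage = "direct",
    n_support = vapply(sup[keep], length, integer(1)),
    cell_status = vapply(qual, function(q)
      if (length(q) > 1) "common" else paste0(q, "-only"), ""),
    via_neighbor_rule = (neighbor & !meets_general)[keep],
    intrachromosomal = mirs$chrom[i] == mirs$chrom[j],
    stringsAsFactors = FALSE)
  out$support <- unname(sup[keep])
  out
}

indirect_mir_edges <- function(network, communities, mirs, existing, config) {
  mem <- communities$membership
  mir_mem <- mem[mem$is_mir, , drop = FALSE]
  multi <- names(which(table(mir_mem$community_id) >= 2))
  if (length(multi) == 0 || nrow(network$edges) == 0) return(empty_mir_edges())
  g <- igraph::graph_from_data_frame(network$edges[, c("id1", "id2")],
                                     directed = FALSE, vertices = network$nodes)
  edge_support <- network$edges$support
  have_direct <- paste(existing$mir1, existing$mir2, sep = "\r")
  rows <- list()
  for (cid in multi) {
    ms <- sort(mir_mem$entity_id[mir_mem$community_id == cid])
    for (a in seq_len(length(ms) - 1)) {
      for (b in seq((a + 1), length(ms))) {
        m1 <- ms[a]; m2 <- ms[b]
        if (paste(m1, m2, sep = "\r") %in% have_direct) next
        sp <- suppressWarnings(
          igraph::shortest_paths(g, from = m1, to = m2, output = "epath"))
        ep <- sp$epath[[1]]
        if (length(ep) == 0) next
        eidx <- as.integer(ep)
        sup <- sort(unique(unlist(edge_support[eidx])))
        if (length(sup) < 2) next
        cells <- unique(sub("\\|.*", "", sup))
        i <- match(m1, mirs$mir_id); j <- match(m2, mirs$mir_id)
        rows[[length(rows) + 1L]] <- data.frame(
          mir1 = m1, mir2 = m2, linkage = "indirect",
          n_support = length(sup),
          cell_status = if (length(cells) > 1) "common"
                        else paste0(cells, "-only"),
          via_neighbor_rule = FALSE,
          intrachromosomal = mirs$chrom[i] == mirs$chrom[j],
          support = I(list(sup)), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) return(empty_mir_edges())
  do.call(rbind, rows)
}

#' Assign MIRs to chromatin interaction models
#'
#' A MIR is in the interaction model when it participates in the chromatin
#' network (as a network node or through a MIR-MIR edge, including
#' neighbour-rule edges); otherwise it is in the basal transcription model
#' when at least one RNAPII peak center lies within `anchor_tss_window` bp
#' of its TSS; otherwise (including MIRs without a promoter call) it is not
#' assigned. Interaction-model MIRs carry the submodel `mir_mir` when they
#' have at least one MIR-MIR edge, else `mir_gene_only`.
#'
#' @param mirs MIR annotation data.frame.
#' @param promoter_calls from [assign_tss()].
#' @param rnapii_peaks RNAPII peak data.frame (cell lines pooled).
#' @param network a `gene_network`.
#' @param mir_edges from [build_mir_network()].
#' @inheritParams assign_tss
#' @return data.frame `mir_id, model, submodel` partitioning all MIRs.
#' @export
assign_interaction_model <- function(mirs, promoter_calls, rnapii_peaks,
                                     network, mir_edges,
                                     config = pipeline_config()) {
  edged <- unique(c(mir_edges$mir1, mir_edges$mir2))
  in_net <- mirs$mir_id %in% network$nodes | mirs$mir_id %in% edged
  tss <- promoter_calls$tss[match(mirs$mir_id, promoter_calls$mir_id)]
  chrom <- promoter_calls$chrom[match(mirs$mir_id, promoter_calls$mir_id)]
  w <- config$anchor_tss_window
  by_chrom <- split(seq_len(nrow(rnapii_peaks)), rnapii_peaks$chrom)
  has_peak <- vapply(seq_len(nrow(mirs)), function(i) {
    if (is.na(tss[i])) return(FALSE)
    j <- by_chrom[[chrom[i]]]
    !is.null(j) && any(abs(rnapii_peaks$center[j] - tss[i]) <= w)
  }, logical(1))
  model <- ifelse(in_net, "interaction",
                  ifelse(has_peak, "basal", "not_assigned"))
  submodel <- ifelse(model != "interaction", NA_character_,
                     ifelse(mirs$mir_id %in% edged, "mir_mir",
                            "mir_gene_only"))
  data.frame(mir_id = mirs$mir_id, model = model, submodel = submodel,
             stringsAsFactors = FALSE)
}

#' Cell-line specificity of MIR-MIR edges
#'
#' Counts and whole-number percentages of edges specific to each cell line
#' and common to several, with the total edge count as denominator.
#'
#' @param edges MIR edge data.frame.
#' @return data.frame `cell_status, n, percent`.
#' @export
cell_specificity_summary <- function(edges) {
  tab <- table(edges$cell_status)
  data.frame(cell_status = names(tab), n = as.integer(tab),
             percent = percent_of(as.integer(tab), nrow(edges), 0),
             stringsAsFactors = FALSE)
}

#' Fraction of MIR-MIR edges within miRNA clusters
#'
#' Share of edges whose two MIRs carry the same non-null `cluster_id`,
#' reported to one decimal percent.
#'
#' @param edges MIR edge data.frame.
#' @param mirs MIR annotation data.frame with `cluster_id`.
#' @return list `n_within_cluster, n_edges, percent`.
#' @export
cluster_membership_fraction <- function(edges, mirs) {
  c1 <- mirs$cluster_id[match(edges$mir1, mirs$mir_id)]
  c2 <- mirs$cluster_id[match(edges$mir2, mirs$mir_id)]
  within <- !is.na(c1) & !is.na(c2) & c1 == c2
  list(n_within_cluster = sum(within), n_edges = nrow(edges),
       percent = percent_of(sum(within), nrow(edges), 1))
}
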