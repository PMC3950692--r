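#' Permutation enrichment of within-group MIR-MIR contacts
#'
#' For each MIR family (single membership) or disease category (multiple
#' memberships allowed): the observed number of interactome edges joining
#' two group members, against a null that redraws the same number of edges
#' uniformly without replacement from all unordered pairs of MIRs present
#' in the interactome. Groups with fewer than two networked members are
#' excluded. The empirical FDR per group is
#' `(1 + #\{null >= observed\}) / (1 + n_permutations)`.
#'
#' @param edges MIR edge data.frame ([build_mir_network()]); must be
#'   non-empty.
#' @param group_map data.frame `mir_id, group_id` (one row per membership).
#' @inheritParams assign_tss
#' @return data.frame `group_id, n_members, observed, null_mean,
#'   empirical_fdr`.
#' @export
group_contact_enrichment <- function(edges, group_map,
                                     config = pipeline_config()) {
  if (nrow(edges) == 0) stop("empty MIR edge list")
  mirs <- sort(unique(c(edges$mir1, edges$mir2)))
  m <- length(mirs)
  if (m < 2) stop("need at least two networked MIRs")
  gm <- group_map[group_map$mir_id %in% mirs, , drop = FALSE]
  members <- split(gm$mir_id, gm$group_id)
  members <- members[vapply(members, function(v)
    length(unique(v)) >= 2, logical(1))]
  if (length(members) == 0)
    return(data.frame(group_id = character(0), n_members = integer(0),
                      observed = integer(0), null_mean = numeric(0),
                      empirical_fdr = numeric(0)))

  # all unordered pairs of networked MIRs, as indices into `mirs`
  pair_i <- rep(seq_len(m - 1), times = (m - 1):1)
  pair_j <- unlist(lapply(seq_len(m - 1), function(i) (i + 1):m))
  n_pairs_total <- length(pair_i)
  # group label(s) of every pair whose two endpoints share that group
  memb_idx <- lapply(members, function(v) which(mirs %in% unique(v)))
  in_group <- lapply(memb_idx, function(ix) {
    f <- logical(m); f[ix] <- TRUE
    which(f[pair_i] & f[pair_j])
  })
  pair_groups <- rep(list(character(0)), n_pairs_total)
  for (g in names(in_group)) {
    for (p in in_group[[g]]) pair_groups[[p]] <- c(pair_groups[[p]], g)
  }

  e1 <- match(edges$mir1, mirs)
  e2 <- match(edges$mir2, mirs)
  edge_pair <- (e1 - 1) * m - (e1 - 1) * e1 / 2 + (e2 - e1)  # index in pair list
  n_edges <- length(unique(edge_pair))
  obs_groups <- unlist(pair_groups[unique(edge_pair)])
  observed <- vapply(names(members), function(g)
    sum(obs_groups == g), integer(1))

  null_counts <- matrix(0L, config$n_permutations, length(members),
                        dimnames = list(NULL, names(members)))
  with_seed(config$random_seed, {
    for (r in seq_len(config$n_permutations)) {
      idx <- sample.int(n_pairs_total, n_edges)
      gl <- unlist(pair_groups[idx])
      if (length(gl) > 0) {
        tb <- table(gl)
        null_counts[r, names(tb)] <- as.integer(tb)
      }
    }
  })
  data.frame(
    group_id = names(members),
    n_members = vapply(members, function(v) length(unique(v)), integer(1)),
    observed = observed,
    null_mean = colMeans(null_counts),
    empirical_fdr = vapply(seq_along(members), function(k)
      empirical_fdr(observed[k], null_counts[, k]), numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Disease-category concordance of MIR-MIR edges
#'
#' Among edges whose both MIRs carry at least one disease category, the
#' count and whole-number percentage sharing at least one category, plus a
#' per-category tally of edges in which both MIRs carry that category.
#'
#' @param edges MIR edge data.frame.
#' @param disease_map data.frame `mir_id, category` (one row per label).
#' @return list `n_both_annotated, n_sharing, percent, per_category`.
#' @export
disease_concordance <- function(edges, disease_map) {
  labels <- split(disease_map$category, disease_map$mir_id)
  l1 <- labels[edges$mir1]
  l2 <- labels[edges$mir2]
  both <- lengths(l1) > 0 & lengths(l2) > 0
  sharing <- mapply(function(a, b) length(intersect(a, b)) > 0, l1, l2) & both
  cats <- sort(unique(disease_map$category))
  per_category <- data.frame(
    category = cats,
    n_edges = vapply(cats, function(cc)
      sum(mapply(function(a, b) cc %in% a && cc %in% b, l1, l2)), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  list(n_both_annotated = sum(both), n_sharing = sum(sharing),
       percent = percent_of(sum(sharing), sum(both), 0),
       per_category = per_category)
}

#' Disease-class enrichment per community
#'
#' For each (community, disease class) with at least `chi2_min_mirs` member
#' MIRs carrying the class: a 1-degree-of-freedom chi-square comparison of
#' the observed class count among the community's disease-annotated MIRs
#' against the expectation under the background class frequency over all
#' networked disease-annotated MIRs. Classes with zero background frequency
#' are flagged untestable.
#'
#' @param communities a `chromatin_communities`.
#' @param disease_map data.frame `mir_id, category`.
#' @inheritParams assign_tss
#' @return data.frame `community_id, disease_class, n_class, n_annotated,
#'   expected, chi2, p_value, significant`.
#' @export
community_disease_chi2 <- function(communities, disease_map,
                                   config = pipeline_config()) {
  mem <- communities$membership
  mir_mem <- mem[mem$is_mir, , drop = FALSE]
  ann <- disease_map[disease_map$mir_id %in% mir_mem$entity_id, , drop = FALSE]
  bg_mirs <- unique(ann$mir_id)
  empty <- data.frame(community_id = character(0), disease_class = character(0),
                      n_class = integer(0), n_annotated = integer(0),
                      expected = numeric(0), chi2 = numeric(0),
                      p_value = numeric(0), significant = logical(0))
  if (length(bg_mirs) == 0) return(empty)
  bg_freq <- vapply(split(ann$mir_id, ann$category),
                    function(v) length(unique(v)) / length(bg_mirs),
                    numeric(1))
  rows <- list()
  for (cid in unique(mir_mem$community_id)) {
    cm <- mir_mem$entity_id[mir_mem$community_id == cid]
    cm_ann <- intersect(cm, bg_mirs)
    n_ann <- length(cm_ann)
    if (n_ann == 0) next
    sub <- ann[ann$mir_id %in% cm_ann, , drop = FALSE]
    counts <- vapply(split(sub$mir_id, sub$category),
                     function(v) length(unique(v)), integer(1))
    counts <- counts[counts >= config$chi2_min_mirs]
    for (cls in names(counts)) {
      f <- bg_freq[[cls]]
      x <- counts[[cls]]
      if (f <= 0 || f >= 1) {
        rows[[length(rows) + 1L]] <- data.frame(
          community_id = cid, disease_class = cls, n_class = x,
          n_annotated = n_ann, expected = n_ann * f, chi2 = NA_real_,
          p_value = NA_real_, significant = NA, stringsAsFactors = FALSE)
        next
      }
      e1 <- n_ann * f
      e2 <- n_ann * (1 - f)
      chi2 <- (x - e1)^2 / e1 + ((n_ann - x) - e2)^2 / e2
      p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        community_id = cid, disease_class = cls, n_class = x,
        n_annotated = n_ann, expected = e1, chi2 = chi2, p_value = p,
        significant = p < config$chi2_alpha, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
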