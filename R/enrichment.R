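#' Filter miRNA-target pairs by database support
#'
#' Keeps pairs supported by at least `min_target_databases` prediction
#' databases, preserving input order.
#'
#' @param pairs target-pair data.frame ([read_targets()]).
#' @inheritParams assign_tss
#' @return Filtered data.frame.
#' @export
filter_target_pairs <- function(pairs, config = pipeline_config()) {
  out <- pairs[pairs$n_databases >= config$min_target_databases, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map miRNA-target pairs onto chromatin communities
#'
#' A pair is mapped when both its MIR and its target gene are network nodes;
#' it is `within` when they share a community, `between` otherwise.
#'
#' @param pairs filtered target-pair data.frame.
#' @param communities a `chromatin_communities`.
#' @return An object of class `"pair_mapping"`: list with `pairs` (input
#'   plus `status, mir_community, target_community`), totals
#'   (`n_total_input, n_mapped, n_within, n_between, n_unmapped`) and
#'   `percent_within` (one decimal, of mapped pairs).
#' @export
map_pairs_to_communities <- function(pairs, communities) {
  mem <- communities$membership
  cm <- mem$community_id[match(pairs$mir_id, mem$entity_id)]
  cg <- mem$community_id[match(pairs$target_gene_id, mem$entity_id)]
  status <- ifelse(is.na(cm) | is.na(cg), "unmapped",
                   ifelse(cm == cg, "within", "between"))
  out <- pairs
  out$status <- status
  out$mir_community <- cm
  out$target_community <- cg
  n_within <- sum(status == "within")
  n_between <- sum(status == "between")
  structure(list(pairs = out,
                 n_total_input = nrow(pairs),
                 n_mapped = n_within + n_between,
                 n_within = n_within,
                 n_between = n_between,
                 n_unmapped = sum(status == "unmapped"),
                 percent_within = percent_of(n_within, n_within + n_between, 1)),
            class = "pair_mapping")
}

#' @export
print.pair_mapping <- function(x, ...) {
  cat(sprintf("miRNA-target pair mapping: %d input, %d mapped (%d within, %d between)\n",
              x$n_total_input, x$n_mapped, x$n_within, x$n_between))
  cat(sprintf("  within-community share of mapped pairs: %.1f%%\n",
              x$percent_within))
  invisible(x)
}

#' Within-community target depletion test
#'
#' Builds a 2x2 table of mapped pairs, crossing within/between status with
#' whether the pair's MIR endpoint lies in the giant community, and applies
#' a two-sided Fisher exact test. The table convention (MIR endpoint decides
#' giant membership) is fixed and documented; a zero margin yields p = 1
#' with a warning.
#'
#' @param mapping a `pair_mapping`.
#' @param communities a `chromatin_communities`.
#' @return list with `table` (2x2) and `p_value`.
#' @export
within_community_depletion_test <- function(mapping, communities) {
  giant <- communities$communities$community_id[communities$communities$is_giant]
  mp <- mapping$pairs[mapping$pairs$status %in% c("within", "between"), ,
                      drop = FALSE]
  tab <- matrix(c(sum(mp$status == "within" & mp$mir_community %in% giant),
                  sum(mp$status == "between" & mp$mir_community %in% giant),
                  sum(mp$status == "within" & !mp$mir_community %in% giant),
                  sum(mp$status == "between" & !mp$mir_community %in% giant)),
                nrow = 2, byrow = TRUE,
                dimnames = list(giant = c("giant", "other"),
                                status = c("within", "between")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("degenerate 2x2 table (zero margin); p = 1")
    return(list(table = tab, p_value = 1))
  }
  list(table = tab, p_value = stats::fisher.test(tab)$p.value)
}

#' Community-community miRNA-target link network
#'
#' Pools both directions of mapped between-community pairs into unordered
#' community links, tests every link carrying at least
#' `min_community_pairs` pairs with an upper-tail hypergeometric test
#' (population N = all mapped between-community pairs, successes K = pairs
#' incident to one community, draws n = pairs incident to the other,
#' observed k = pairs on the link), and controls the tested family by
#' Benjamini-Hochberg at `community_link_fdr`.
#'
#' @param mapping a `pair_mapping`.
#' @param communities a `chromatin_communities`.
#' @param min_pairs overrides `config$min_community_pairs` (e.g. 5 for the
#'   sensitivity re-run).
#' @inheritParams assign_tss
#' @return data.frame `community_a, community_b, n_pairs, p_value, q_value,
#'   significant` (one row per tested link).
#' @export
community_link_network <- function(mapping, communities,
                                   config = pipeline_config(),
                                   min_pairs = config$min_community_pairs) {
  bt <- mapping$pairs[mapping$pairs$status == "between", , drop = FALSE]
  if (nrow(bt) == 0) {
    warning("no between-community pairs to test")
    return(data.frame(community_a = character(0), community_b = character(0),
                      n_pairs = integer(0), p_value = numeric(0),
                      q_value = numeric(0), significant = logical(0)))
  }
  a <- pmin(bt$mir_community, bt$target_community)
  b <- pmax(bt$mir_community, bt$target_community)
  link_key <- paste(a, b, sep = "\r")
  n_pairs <- table(link_key)
  incident <- table(c(a, b))  # pairs incident to each community
  N <- nrow(bt)
  keys <- names(n_pairs)[as.integer(n_pairs) >= min_pairs]
  if (length(keys) == 0) {
    warning("no community pair reaches the minimum mapped-pair count")
    return(data.frame(community_a = character(0), community_b = character(0),
                      n_pairs = integer(0), p_value = numeric(0),
                      q_value = numeric(0), significant = logical(0)))
  }
  parts <- strsplit(keys, "\r", fixed = TRUE)
  ca <- vapply(parts, `[`, "", 1)
  cb <- vapply(parts, `[`, "", 2)
  k <- as.integer(n_pairs[keys])
  K <- as.integer(incident[ca])
  n <- as.integer(incident[cb])
  p <- hyper_upper_p(k, K, n, N)
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(community_a = ca, community_b = cb, n_pairs = k,
                    p_value = p, q_value = q,
                    significant = q <= config$community_link_fdr,
                    stringsAsFactors = FALSE)
  out <- out[order(out$q_value, out$p_value, out$community_a), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Permutation control for percent-of-genes-targeted
#'
#' For each community, the observed percentage of member protein-coding
#' genes targeted by MIRs of other communities (`between`) or of the same
#' community (`within`). The null redraws, for every community, the same
#' number of genes uniformly from all networked protein-coding genes and
#' recomputes both percentages; the replicate statistic is the mean
#' percentage across communities. Reports a Mann-Whitney p (observed
#' per-community percentages vs the pooled null) and the empirical FDR
#' `(1 + #\{null mean >= observed mean\}) / (1 + n_permutations)`.
#'
#' @param communities a `chromatin_communities`.
#' @param pairs filtered target-pair data.frame.
#' @param gene_universe character vector of all annotated protein-coding
#'   gene ids from which the random control draws; defaults to the union
#'   of networked genes and all target genes in `pairs`.
#' @inheritParams assign_tss
#' @return list of class `"permutation_summary"` with elements `between`
#'   and `within`, each holding `observed_percents, observed_mean,
#'   null_means, mw_p, empirical_fdr`, plus `n_permutations` and `seed`.
#' @export
permutation_percent_targeted <- function(communities, pairs,
                                         config = pipeline_config(),
                                         gene_universe = NULL) {
  if (config$n_permutations < 1) stop("n_permutations must be >= 1")
  mem <- communities$membership
  genes <- mem[!mem$is_mir, , drop = FALSE]
  mirs <- mem[mem$is_mir, , drop = FALSE]
  if (nrow(genes) == 0 || nrow(mirs) == 0)
    stop("need both genes and MIRs in the network")
  if (is.null(gene_universe))
    gene_universe <- unique(c(genes$entity_id, pairs$target_gene_id))
  # per universe gene, the set of communities of networked MIRs targeting it
  tp <- pairs[pairs$mir_id %in% mirs$entity_id, , drop = FALSE]
  tp$mir_comm <- mem$community_id[match(tp$mir_id, mem$entity_id)]
  targeting <- split(tp$mir_comm, tp$target_gene_id)
  uni_comms <- lapply(gene_universe, function(g) unique(targeting[[g]]))
  names(uni_comms) <- gene_universe

  pct_one <- function(gene_set, comm) {
    cs <- uni_comms[gene_set]
    c(between = 100 * mean(vapply(cs, function(v)
        any(v != comm), logical(1))),
      within = 100 * mean(vapply(cs, function(v) comm %in% v, logical(1))))
  }
  comm_ids <- communities$communities$community_id
  comm_genes <- split(genes$entity_id, genes$community_id)
  comm_ids <- comm_ids[comm_ids %in% names(comm_genes)]

  obs_mat <- vapply(comm_ids, function(cid)
    pct_one(comm_genes[[cid]], cid), numeric(2))
  obs <- data.frame(community_id = comm_ids, between = obs_mat["between", ],
                    within = obs_mat["within", ], stringsAsFactors = FALSE,
                    row.names = NULL)
  null_between <- numeric(config$n_permutations)
  null_within <- numeric(config$n_permutations)
  null_pool_between <- vector("list", config$n_permutations)
  null_pool_within <- vector("list", config$n_permutations)
  with_seed(config$random_seed, {
    for (r in seq_len(config$n_permutations)) {
      pr <- vapply(comm_ids, function(cid)
        pct_one(resample(gene_universe, length(comm_genes[[cid]])), cid),
        numeric(2))
      null_between[r] <- mean(pr["between", ])
      null_within[r] <- mean(pr["within", ])
      null_pool_between[[r]] <- pr["between", ]
      null_pool_within[[r]] <- pr["within", ]
    }
  })
  mk <- function(observed, null_means, null_pool) {
    list(observed_percents = observed,
         observed_mean = mean(observed),
         null_means = as.numeric(null_means),
         mw_p = suppressWarnings(
           stats::wilcox.test(observed, unlist(null_pool))$p.value),
         empirical_fdr = empirical_fdr(mean(observed), as.numeric(null_means)))
  }
  structure(list(between = mk(obs$between, null_between, null_pool_between),
                 within = mk(obs$within, null_within, null_pool_within),
                 observed_table = obs,
                 n_permutations = config$n_permutations,
                 seed = config$random_seed),
            class = "permutation_summary")
}

#' @export
print.permutation_summary <- function(x, ...) {
  cat("Permutation control (", x$n_permutations, " randomizations)\n", sep = "")
  for (v in c("between", "within")) {
    cat(sprintf("  %-8s observed mean %.2f%%, null mean %.2f%%, MW p %.3g, empirical FDR %.3g\n",
                v, x[[v]]$observed_mean, mean(x[[v]]$null_means),
                x[[v]]$mw_p, x[[v]]$empirical_fdr))
  }
  invisible(x)
}

#' Per-community enriched terms
#'
#' Upper-tail hypergeometric enrichment of each term among a gene set,
#' against the universe of all annotated genes, BH-controlled.
#'
#' @param gene_set character vector of gene ids.
#' @param terms data.frame `gene_id, term_id`.
#' @param fdr BH threshold.
#' @return Character vector of enriched term ids.
#' @export
enriched_terms <- function(gene_set, terms, fdr = 0.05) {
  universe <- unique(terms$gene_id)
  gs <- intersect(gene_set, universe)
  if (length(gs) == 0) return(character(0))
  term_genes <- split(terms$gene_id, terms$term_id)
  k <- vapply(term_genes, function(g) length(intersect(g, gs)), integer(1))
  K <- vapply(term_genes, function(g) length(unique(g)), integer(1))
  p <- hyper_upper_p(k, K, length(gs), length(universe))
  q <- stats::p.adjust(p, method = "BH")
  names(term_genes)[k > 0 & q <= fdr]
}

#' Shared enriched terms across linked communities
#'
#' For every community link, counts GO-style terms enriched (hypergeometric,
#' BH at `term_enrichment_fdr`) in both communities. The permutation control
#' redraws same-size random gene sets per community from the annotated
#' universe and recomputes the shared counts; a Mann-Whitney p compares the
#' observed and null count distributions.
#'
#' @param link_network data.frame from [community_link_network()] (its
#'   significant rows are used; if none is flagged, all tested rows).
#' @param communities a `chromatin_communities`.
#' @param terms data.frame `gene_id, term_id`.
#' @inheritParams assign_tss
#' @param n_permutations permutation count (defaults to the configured
#'   value).
#' @return list with `per_link` (data.frame `community_a, community_b,
#'   shared_terms`), `null_shared` (matrix permutations x links), `mw_p`,
#'   `seed`.
#' @export
shared_enriched_terms <- function(link_network, communities, terms,
                                  config = pipeline_config(),
                                  n_permutations = config$n_permutations) {
  links <- link_network[link_network$significant, , drop = FALSE]
  if (nrow(links) == 0) links <- link_network
  if (nrow(links) == 0)
    return(list(per_link = data.frame(community_a = character(0),
                                      community_b = character(0),
                                      shared_terms = integer(0)),
                null_shared = NULL, mw_p = NA_real_,
                seed = config$random_seed))
  mem <- communities$membership
  used <- unique(c(links$community_a, links$community_b))
  sets <- lapply(used, function(cid)
    mem$entity_id[mem$community_id == cid & !mem$is_mir])
  names(sets) <- used
  universe <- unique(terms$gene_id)
  enr <- lapply(sets, enriched_terms, terms = terms,
                fdr = config$term_enrichment_fdr)
  shared <- mapply(function(a, b) length(intersect(enr[[a]], enr[[b]])),
                   links$community_a, links$community_b)
  sizes <- vapply(sets, function(s) length(intersect(s, universe)), integer(1))
  null_shared <- matrix(NA_integer_, n_permutations, nrow(links))
  with_seed(config$random_seed, {
    for (r in seq_len(n_permutations)) {
      rand_enr <- lapply(sizes, function(sz)
        enriched_terms(sample(universe, sz), terms,
                       fdr = config$term_enrichment_fdr))
      names(rand_enr) <- used
      null_shared[r, ] <- mapply(function(a, b)
        length(intersect(rand_enr[[a]], rand_enr[[b]])),
        links$community_a, links$community_b)
    }
  })
  mw_p <- if (stats::sd(c(shared, null_shared)) == 0) NA_real_ else
    suppressWarnings(
      stats::wilcox.test(shared, as.numeric(null_shared))$p.value)
  list(per_link = data.frame(community_a = links$community_a,
                             community_b = links$community_b,
                             shared_terms = as.integer(shared),
                             stringsAsFactors = FALSE),
       null_shared = null_shared, mw_p = mw_p, seed = config$random_seed)
}

#' Expression contrast between targets and non-targets
#'
#' Within networked protein-coding genes, compares expression of genes that
#' are miRNA targets against non-targets (Student's t-test, group means) and
#' reports the Spearman correlation between each MIR's expression and the
#' mean expression of its targets, per cell line.
#'
#' @param communities a `chromatin_communities`.
#' @param pairs filtered target-pair data.frame.
#' @param expression expression data.frame ([read_expression()]).
#' @return data.frame per cell line: `cell_line, spearman_rho, mean_target,
#'   mean_nontarget, t_p` (`NA` where a stratum is empty or degenerate).
#' @export
target_expression_contrast <- function(communities, pairs, expression) {
  mem <- communities$membership
  genes <- mem$entity_id[!mem$is_mir]
  mirs <- mem$entity_id[mem$is_mir]
  targets <- unique(pairs$target_gene_id)
  out <- lapply(sort(unique(expression$cell_line)), function(cl) {
    ex <- expression[expression$cell_line == cl, , drop = FALSE]
    val <- ex$value[match(genes, ex$entity_id)]
    is_t <- genes %in% targets
    tv <- val[is_t & !is.na(val)]
    nv <- val[!is_t & !is.na(val)]
    t_p <- if (length(tv) >= 2 && length(nv) >= 2 &&
               stats::sd(c(tv, nv)) > 0)
      stats::t.test(tv, nv)$p.value else NA_real_
    mir_ex <- ex$value[match(mirs, ex$entity_id)]
    mean_target_ex <- vapply(mirs, function(m) {
      tg <- pairs$target_gene_id[pairs$mir_id == m]
      v <- ex$value[match(tg, ex$entity_id)]
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }, numeric(1))
    ok <- !is.na(mir_ex) & !is.na(mean_target_ex)
    rho <- if (sum(ok) >= 3 && stats::sd(mir_ex[ok]) > 0 &&
               stats::sd(mean_target_ex[ok]) > 0)
      stats::cor(mir_ex[ok], mean_target_ex[ok], method = "spearman")
    else NA_real_
    data.frame(cell_line = cl, spearman_rho = rho,
               mean_target = if (length(tv)) mean(tv) else NA_real_,
               mean_nontarget = if (length(nv)) mean(nv) else NA_real_,
               t_p = t_p, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
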