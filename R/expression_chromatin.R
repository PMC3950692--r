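#' Pairwise Spearman correlation of chromatin marks
#'
#' Spearman rank correlations (ties mid-ranked) between mark columns of a
#' promoter mark-profile matrix, over all MIR rows or an intergenic /
#' intragenic subset. The dendrogram leaf order is computed once on the
#' all-MIRs matrix (average-linkage hierarchical clustering on 1 - rho,
#' columns presented in sorted label order so ties resolve to the smaller
#' label) and reused for subsets so heatmaps stay comparable. Constant
#' columns yield `NA` correlations.
#'
#' @param profile mark-profile matrix from [mark_profile()].
#' @param subset `"all"`, `"intergenic"` or `"intragenic"`.
#' @param mirs MIR annotation data.frame (needed for subsets).
#' @param leaf_order optional mark ordering to reuse; computed from the
#'   full matrix when `NULL`.
#' @return list of class `"mark_correlation"`: `cor` (reordered matrix),
#'   `leaf_order`, `subset`.
#' @export
mark_correlation <- function(profile, subset = c("all", "intergenic",
                                                 "intragenic"),
                             mirs = NULL, leaf_order = NULL) {
  subset <- match.arg(subset)
  if (nrow(profile) < 3 || ncol(profile) < 2)
    stop("mark_correlation: need >= 3 MIR rows and >= 2 mark columns")
  profile <- profile[, sort(colnames(profile)), drop = FALSE]
  if (is.null(leaf_order)) {
    rho_all <- suppressWarnings(stats::cor(profile, method = "spearman"))
    d <- 1 - rho_all
    d[is.na(d)] <- 1
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    leaf_order <- colnames(profile)[hc$order]
  }
  rows <- profile
  if (subset != "all") {
    if (is.null(mirs)) stop("subset correlations need the MIR annotations")
    keep <- rownames(profile) %in% mirs$mir_id[mirs$context == subset]
    rows <- profile[keep, , drop = FALSE]
    if (nrow(rows) < 3) stop("fewer than 3 MIRs in subset '", subset, "'")
  }
  rho <- suppressWarnings(stats::cor(rows, method = "spearman"))
  diag(rho) <- 1
  rho <- rho[leaf_order, leaf_order]
  structure(list(cor = rho, leaf_order = leaf_order, subset = subset),
            class = "mark_correlation")
}

#' Mantel test between two correlation matrices
#'
#' The statistic is the Pearson correlation of the vectorized upper
#' triangles; the null permutes the row/column labels of the second matrix
#' jointly. `p = (1 + #\{permuted r >= observed r\}) / (1 + n_permutations)`.
#'
#' @param m1,m2 square symmetric matrices with identical dimnames and
#'   order, at least 3x3.
#' @param n_permutations permutation count.
#' @param seed RNG seed.
#' @return list `r, p, n_permutations`.
#' @export
mantel_test <- function(m1, m2, n_permutations = 1000, seed = 1L) {
  if (inherits(m1, "mark_correlation")) m1 <- m1$cor
  if (inherits(m2, "mark_correlation")) m2 <- m2$cor
  n <- nrow(m1)
  if (n < 3) stop("mantel_test: matrices must be at least 3x3")
  if (!identical(dim(m1), dim(m2)) ||
      !identical(rownames(m1), rownames(m2)))
    stop("mantel_test: matrices must share labels and order")
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  ut <- upper.tri(m1)
  r_obs <- stats::cor(m1[ut], m2[ut])
  r_perm <- with_seed(seed, vapply(seq_len(n_permutations), function(i) {
    p <- sample.int(n)
    stats::cor(m1[ut], m2[p, p][ut])
  }, numeric(1)))
  list(r = r_obs, p = (1 + sum(r_perm >= r_obs)) / (1 + n_permutations),
       n_permutations = n_permutations)
}

# Summed RNAPII peak intensity (centers within +/- w of each TSS).
promoter_intensity <- function(chrom, tss, peaks, w) {
  by_chrom <- split(seq_len(nrow(peaks)), peaks$chrom)
  vapply(seq_along(tss), function(i) {
    j <- by_chrom[[chrom[i]]]
    if (is.null(j) || is.na(tss[i])) return(NA_real_)
    sum(peaks$intensity[j][abs(peaks$center[j] - tss[i]) <= w])
  }, numeric(1))
}

#' RNAPII intensity vs expression report
#'
#' (a) Spearman correlation between per-MIR promoter RNAPII intensity
#' (summed peak intensity within `anchor_tss_window` bp of the TSS, cell
#' lines pooled) and MIR expression (RPM averaged across cell lines), with
#' quartile-binned mean expression; (b) for intragenic MIRs, Pearson
#' correlation between promoter intensity and host-gene expression (FPKM);
#' (c) Pearson correlation between MIR and nearest-gene promoter
#' intensities, stratified by same vs opposite strand. Strata with fewer
#' than 3 usable pairs are reported as `NA`.
#'
#' @param promoter_calls from [assign_tss()].
#' @param rnapii_peaks RNAPII peak data.frame.
#' @param expression expression data.frame.
#' @param mirs,genes annotation data.frames.
#' @inheritParams assign_tss
#' @return list `intensity_vs_expression` (rho, quartile table),
#'   `host_pearson_r`, `strand_stratified` (data.frame).
#' @export
intensity_expression_report <- function(promoter_calls, rnapii_peaks,
                                        expression, mirs, genes,
                                        config = pipeline_config()) {
  w <- config$anchor_tss_window
  calls <- promoter_calls[!is.na(promoter_calls$tss), , drop = FALSE]
  intensity <- promoter_intensity(calls$chrom, calls$tss, rnapii_peaks, w)
  mean_expr <- tapply(expression$value, expression$entity_id, mean)
  mir_expr <- as.numeric(mean_expr[calls$mir_id])

  ok <- !is.na(intensity) & !is.na(mir_expr)
  if (sum(ok) >= 3 && stats::sd(intensity[ok]) > 0 &&
      stats::sd(mir_expr[ok]) > 0) {
    rho <- stats::cor(intensity[ok], mir_expr[ok], method = "spearman")
    qs <- cut(rank(intensity[ok], ties.method = "first"), 4,
              labels = paste0("Q", 1:4))
    quartiles <- data.frame(quartile = levels(qs),
                            mean_expression = as.numeric(
                              tapply(mir_expr[ok], qs, mean)))
  } else {
    rho <- NA_real_
    quartiles <- NULL
  }

  intra <- mirs[mirs$context == "intragenic", , drop = FALSE]
  ci <- match(intra$mir_id, calls$mir_id)
  host_expr <- as.numeric(mean_expr[intra$host_gene_id])
  ii <- intensity[ci]
  ok2 <- !is.na(ii) & !is.na(host_expr)
  host_r <- if (sum(ok2) >= 3 && stats::sd(ii[ok2]) > 0 &&
                stats::sd(host_expr[ok2]) > 0)
    stats::cor(ii[ok2], host_expr[ok2]) else NA_real_

  gene_int <- promoter_intensity(genes$chrom, genes$tss, rnapii_peaks, w)
  strat <- lapply(c(same = TRUE, opposite = FALSE), function(same) {
    xs <- ys <- numeric(0)
    for (i in seq_len(nrow(calls))) {
      cand <- which(genes$chrom == calls$chrom[i] &
                      abs(genes$tss - calls$tss[i]) <= config$tss_search_window)
      if (length(cand) == 0) next
      j <- cand[which.min(abs(genes$tss[cand] - calls$tss[i]))]
      if ((genes$strand[j] == calls$strand[i]) != same) next
      if (is.na(intensity[i]) || is.na(gene_int[j])) next
      xs <- c(xs, intensity[i]); ys <- c(ys, gene_int[j])
    }
    if (length(xs) >= 3 && stats::sd(xs) > 0 && stats::sd(ys) > 0)
      c(n = length(xs), r = stats::cor(xs, ys))
    else c(n = length(xs), r = NA_real_)
  })
  strand_stratified <- data.frame(
    stratum = names(strat),
    n = vapply(strat, `[[`, numeric(1), "n"),
    pearson_r = vapply(strat, `[[`, numeric(1), "r"),
    row.names = NULL, stringsAsFactors = FALSE)

  list(intensity_vs_expression = list(spearman_rho = rho,
                                      quartiles = quartiles),
       host_pearson_r = host_r,
       strand_stratified = strand_stratified)
}

#' Expression by chromatin interaction model
#'
#' Pairwise one-sided Mann-Whitney tests of MIR expression between the
#' interaction submodels, the basal model and the not-assigned model, in
#' the order interaction/mir_mir > interaction/mir_gene_only > basal >
#' not_assigned (alternative: the earlier group is greater). Empty groups
#' are skipped.
#'
#' @param model_assignments from [assign_interaction_model()].
#' @param expression expression data.frame.
#' @param cell_line cell line whose expression values are compared.
#' @param split_submodels split the interaction model into its `mir_mir`
#'   and `mir_gene_only` submodels (default) or pool them.
#' @return list `medians` (data.frame `group, n, median`) and `pairwise`
#'   (data.frame `group_high, group_low, p_value`).
#' @export
expression_by_model <- function(model_assignments, expression, cell_line,
                                split_submodels = TRUE) {
  ex <- expression[expression$cell_line == cell_line, , drop = FALSE]
  grp <- if (split_submodels) {
    ifelse(model_assignments$model == "interaction",
           paste0("interaction/", model_assignments$submodel),
           model_assignments$model)
  } else model_assignments$model
  val <- ex$value[match(model_assignments$mir_id, ex$entity_id)]
  order_groups <- if (split_submodels) {
    c("interaction/mir_mir", "interaction/mir_gene_only",
      "basal", "not_assigned")
  } else c("interaction", "basal", "not_assigned")
  groups <- lapply(order_groups, function(g) val[grp == g & !is.na(val)])
  names(groups) <- order_groups
  groups <- groups[lengths(groups) > 0]
  if (length(groups) < 2) stop("need at least two populated models")
  medians <- data.frame(group = names(groups),
                        n = lengths(groups),
                        median = vapply(groups, stats::median, numeric(1)),
                        row.names = NULL, stringsAsFactors = FALSE)
  combs <- utils::combn(names(groups), 2)
  pairwise <- data.frame(
    group_high = combs[1, ], group_low = combs[2, ],
    p_value = apply(combs, 2, function(gg)
      suppressWarnings(
        stats::wilcox.test(groups[[gg[1]]], groups[[gg[2]]],
                           alternative = "greater")$p.value)),
    stringsAsFactors = FALSE)
  list(medians = medians, pairwise = pairwise)
}
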