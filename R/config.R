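#' Pipeline configuration
#'
#' Single home for every numeric threshold used by the pipeline. Defaults
#' follow the analysis conventions of RNAPII ChIA-PET promoter/community
#' studies: a 50 kb upstream TSS search window, +/- 2 kb windows for
#' promoter sharing and anchor-to-TSS mapping, +/- 5 kb mark profiling,
#' a >=2-replicate filter for chromatin edges (relaxed to >=1 replicate for
#' genomic neighbours within 10 kb), >=2 prediction databases per
#' miRNA-target pair, >=10 mapped pairs per tested community link at FDR
#' 0.001, 10^3 permutations for empirical nulls, BH FDR 0.05 for term
#' enrichment, and a chi-square disease-class test at alpha 0.001 on
#' categories with >=2 MIRs.
#'
#' @param tss_search_window bp searched upstream of the pre-miRNA 5' end for
#'   CAGE- and RNAPII-tier TSS evidence.
#' @param promoter_share_window bp around a gene TSS within which a MIR TSS
#'   is called a shared promoter (inclusive).
#' @param anchor_tss_window bp around a TSS used when mapping entities onto
#'   interaction anchors (inclusive at base resolution).
#' @param mark_profile_window bp around a TSS within which peak centers are
#'   counted for mark profiles (inclusive).
#' @param min_edge_replicates minimum distinct replicates (within one cell
#'   line) supporting a retained chromatin edge.
#' @param neighbor_min_replicates relaxed replicate minimum for MIR pairs
#'   that are genomic neighbours.
#' @param neighbor_max_gap bp; maximum gap between pre-miRNAs still counted
#'   as genomic neighbours.
#' @param min_target_databases minimum prediction databases supporting a
#'   retained miRNA-target pair.
#' @param min_community_pairs minimum mapped pairs between two communities
#'   for the link to be tested.
#' @param community_link_fdr BH FDR threshold for significant community
#'   links.
#' @param n_permutations permutation count for empirical nulls.
#' @param term_enrichment_fdr BH FDR threshold for term enrichment.
#' @param chi2_min_mirs minimum MIRs of a disease class in a community for
#'   the class to be testable there.
#' @param chi2_alpha significance level for the disease-class chi-square
#'   test.
#' @param random_seed integer seed used by seeded operations.
#' @return A validated list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(tss_search_window = 50000L,
                            promoter_share_window = 2000L,
                            anchor_tss_window = 2000L,
                            mark_profile_window = 5000L,
                            min_edge_replicates = 2L,
                            neighbor_min_replicates = 1L,
                            neighbor_max_gap = 10000L,
                            min_target_databases = 2L,
                            min_community_pairs = 10L,
                            community_link_fdr = 0.001,
                            n_permutations = 1000L,
                            term_enrichment_fdr = 0.05,
                            chi2_min_mirs = 2L,
                            chi2_alpha = 0.001,
                            random_seed = 1L) {
  cfg <- list(
    tss_search_window = as.integer(tss_search_window),
    promoter_share_window = as.integer(promoter_share_window),
    anchor_tss_window = as.integer(anchor_tss_window),
    mark_profile_window = as.integer(mark_profile_window),
    min_edge_replicates = as.integer(min_edge_replicates),
    neighbor_min_replicates = as.integer(neighbor_min_replicates),
    neighbor_max_gap = as.integer(neighbor_max_gap),
    min_target_databases = as.integer(min_target_databases),
    min_community_pairs = as.integer(min_community_pairs),
    community_link_fdr = as.numeric(community_link_fdr),
    n_permutations = as.integer(n_permutations),
    term_enrichment_fdr = as.numeric(term_enrichment_fdr),
    chi2_min_mirs = as.integer(chi2_min_mirs),
    chi2_alpha = as.numeric(chi2_alpha),
    random_seed = as.integer(random_seed)
  )
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  windows <- c("tss_search_window", "promoter_share_window",
               "anchor_tss_window", "mark_profile_window", "neighbor_max_gap")
  for (w in windows) {
    if (!is.finite(cfg[[w]]) || cfg[[w]] <= 0L)
      stop("pipeline_config: '", w, "' must be a positive number of bp")
  }
  counts <- c("min_edge_replicates", "neighbor_min_replicates",
              "min_target_databases", "min_community_pairs",
              "n_permutations", "chi2_min_mirs")
  for (k in counts) {
    if (!is.finite(cfg[[k]]) || cfg[[k]] < 1L)
      stop("pipeline_config: '", k, "' must be >= 1")
  }
  rates <- c("community_link_fdr", "term_enrichment_fdr", "chi2_alpha")
  for (r in rates) {
    if (!is.finite(cfg[[r]]) || cfg[[r]] <= 0 || cfg[[r]] >= 1)
      stop("pipeline_config: '", r, "' must lie in (0, 1)")
  }
  invisible(cfg)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Pipeline configuration:\n")
  for (k in names(x)) cat(sprintf("  %-24s %s\n", k, format(x[[k]])))
  invisible(x)
}

#' Read or write a pipeline configuration as YAML
#'
#' Unknown keys in the file are rejected so typos cannot silently fall back
#' to defaults.
#'
#' @param path YAML file path.
#' @return `read_pipeline_config()` returns a `pipeline_config`;
#'   `write_pipeline_config()` returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  stopifnot(file.exists(path))
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0)
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' @rdname read_pipeline_config
#' @param config a `pipeline_config` object.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
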