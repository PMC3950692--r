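#' Percentage at a printed precision
#'
#' Shared reporting convention for all count-based percentages: the ratio is
#' scaled to percent and rounded to the requested number of decimal digits
#' (0 for whole-number percentages such as cell-line specificity and disease
#' concordance, 1 for fractions such as within-cluster or within-community
#' shares).
#'
#' @param numerator,denominator counts.
#' @param digits decimal digits kept.
#' @return Numeric percentage; `NA` when the denominator is 0.
#' @export
percent_of <- function(numerator, denominator, digits = 0) {
  out <- round(100 * numerator / denominator, digits)
  out[rep_len(denominator == 0, length(out))] <- NA_real_
  out
}

#' Promoter evidence-tier summary
#'
#' Tier counts are a partition of the MIR set: curated + cage + rnapii +
#' none equals the number of annotated MIRs, and the promoter total is the
#' sum of the three evidence tiers.
#'
#' @param calls promoter-call data.frame from [assign_tss()].
#' @return list with per-tier counts, `n_with_promoter` (tier sum) and
#'   `percent_with_promoter` (one decimal).
#' @export
tier_summary <- function(calls) {
  tiers <- c("curated", "cage", "rnapii", "none")
  counts <- vapply(tiers, function(t) sum(calls$evidence_tier == t), integer(1))
  n_prom <- sum(counts[c("curated", "cage", "rnapii")])
  list(n_mirs = nrow(calls),
       n_curated = counts[["curated"]],
       n_cage = counts[["cage"]],
       n_rnapii = counts[["rnapii"]],
       n_none = counts[["none"]],
       n_with_promoter = n_prom,
       percent_with_promoter = percent_of(n_prom, nrow(calls), 1),
       n_shared = sum(calls$promoter_class == "shared"),
       percent_shared = percent_of(sum(calls$promoter_class == "shared"),
                                   nrow(calls), 1))
}
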