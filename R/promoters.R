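#' Assign TSSs to MIRs by the tiered evidence cascade
#'
#' Evidence precedence is curated > CAGE > RNAPII > none. Curated calls take
#' the curated position as-is. For the CAGE and RNAPII tiers the candidate
#' closest to the pre-miRNA 5' end, strand-aware upstream within
#' `tss_search_window` bp (distance 0 allowed, the window boundary
#' included), wins; distance ties are broken by higher score/intensity, then
#' by smaller genomic coordinate. The RNAPII-tier TSS is the peak center.
#'
#' @param mirs MIR annotation data.frame ([read_annotations()]).
#' @param curated_tss data.frame `mir_id, tss` or `NULL`.
#' @param cage_tags data.frame `chrom, pos` (optional `score`) or `NULL`.
#' @param rnapii_peaks peak data.frame ([read_peaks()]) or `NULL`;
#'   replicates and cell lines are pooled.
#' @param config [pipeline_config()].
#' @return data.frame of promoter calls: `mir_id, chrom, strand, tss,
#'   evidence_tier, promoter_class, shared_gene_ids`. `promoter_class` is
#'   `"unassigned"` until [classify_promoter_sharing()] is applied.
#' @export
assign_tss <- function(mirs, curated_tss = NULL, cage_tags = NULL,
                       rnapii_peaks = NULL, config = pipeline_config()) {
  if (nrow(mirs) > 0 && any(!mirs$strand %in% c("+", "-")))
    stop("assign_tss: MIR strand must be '+' or '-' (upstream is undefined)")
  fp <- if (nrow(mirs) > 0) tss_position(mirs$start, mirs$end, mirs$strand) else integer(0)
  w <- config$tss_search_window

  tss <- rep(NA_integer_, nrow(mirs))
  tier <- rep("none", nrow(mirs))

  if (!is.null(curated_tss) && nrow(curated_tss) > 0) {
    idx <- match(mirs$mir_id, curated_tss$mir_id)
    hit <- !is.na(idx)
    tss[hit] <- as.integer(curated_tss$tss[idx[hit]])
    tier[hit] <- "curated"
  }

  pick_nearest <- function(pos, score, mir_i) {
    # candidates upstream of the 5' end of MIR mir_i within the window
    d <- if (mirs$strand[mir_i] == "+") fp[mir_i] - pos else pos - fp[mir_i]
    ok <- d >= 0 & d <= w
    if (!any(ok)) return(NA_integer_)
    pos <- pos[ok]; score <- score[ok]; d <- d[ok]
    ord <- order(d, -score, pos)
    pos[ord[1]]
  }

  if (!is.null(cage_tags) && nrow(cage_tags) > 0) {
    score <- if ("score" %in% names(cage_tags)) cage_tags$score else rep(1, nrow(cage_tags))
    by_chrom <- split(seq_len(nrow(cage_tags)), cage_tags$chrom)
    for (i in which(tier == "none")) {
      j <- by_chrom[[mirs$chrom[i]]]
      if (is.null(j)) next
      p <- pick_nearest(cage_tags$pos[j], score[j], i)
      if (!is.na(p)) { tss[i] <- p; tier[i] <- "cage" }
    }
  }

  if (!is.null(rnapii_peaks) && nrow(rnapii_peaks) > 0) {
    by_chrom <- split(seq_len(nrow(rnapii_peaks)), rnapii_peaks$chrom)
    for (i in which(tier == "none")) {
      j <- by_chrom[[mirs$chrom[i]]]
      if (is.null(j)) next
      p <- pick_nearest(rnapii_peaks$center[j], rnapii_peaks$intensity[j], i)
      if (!is.na(p)) { tss[i] <- p; tier[i] <- "rnapii" }
    }
  }

  data.frame(mir_id = mirs$mir_id, chrom = mirs$chrom, strand = mirs$strand,
             tss = tss, evidence_tier = tier,
             promoter_class = ifelse(tier == "none", "unassigned", "isolated"),
             shared_gene_ids = "", stringsAsFactors = FALSE)
}

#' Classify MIR promoters as shared or isolated
#'
#' A MIR promoter is shared when at least one protein-coding gene TSS lies
#' within `promoter_share_window` bp of the MIR TSS (inclusive boundary,
#' same chromosome, strand ignored); otherwise it is isolated. MIRs without
#' a TSS stay unassigned.
#'
#' @param calls promoter calls from [assign_tss()].
#' @param genes gene annotation data.frame.
#' @inheritParams assign_tss
#' @return The calls with `promoter_class` and `shared_gene_ids` (comma
#'   separated, sorted) filled in.
#' @export
classify_promoter_sharing <- function(calls, genes, config = pipeline_config()) {
  w <- config$promoter_share_window
  by_chrom <- split(seq_len(nrow(genes)), genes$chrom)
  for (i in which(!is.na(calls$tss))) {
    j <- by_chrom[[calls$chrom[i]]]
    hits <- if (is.null(j)) character(0) else
      genes$gene_id[j][abs(genes$tss[j] - calls$tss[i]) <= w]
    if (length(hits) > 0) {
      calls$promoter_class[i] <- "shared"
      calls$shared_gene_ids[i] <- paste(sort(hits), collapse = ",")
    } else {
      calls$promoter_class[i] <- "isolated"
      calls$shared_gene_ids[i] <- ""
    }
  }
  calls
}

#' Flag promoter calls supported by H3K4me3
#'
#' A call is H3K4me3-supported when at least one H3K4me3 peak center lies
#' within the promoter-share window of its TSS. The flag is reported only;
#' it is never used as a filter.
#'
#' @param calls promoter calls with TSSs.
#' @param peaks peak data.frame; only rows with `mark == "H3K4me3"` are
#'   used.
#' @inheritParams assign_tss
#' @return The calls with a logical `h3k4me3_supported` column.
#' @export
flag_h3k4me3_support <- function(calls, peaks, config = pipeline_config()) {
  k4 <- peaks[peaks$mark == "H3K4me3", , drop = FALSE]
  w <- config$promoter_share_window
  by_chrom <- split(seq_len(nrow(k4)), k4$chrom)
  flag <- rep(FALSE, nrow(calls))
  for (i in which(!is.na(calls$tss))) {
    j <- by_chrom[[calls$chrom[i]]]
    if (!is.null(j)) flag[i] <- any(abs(k4$center[j] - calls$tss[i]) <= w)
  }
  calls$h3k4me3_supported <- flag
  calls
}

#' Chromatin-mark profile around MIR promoters
#'
#' For every MIR with an assigned TSS, counts the peaks (or tags) of each
#' mark whose center lies within `mark_profile_window` bp of the TSS
#' (inclusive). Replicates of the same mark are pooled by summation.
#'
#' @param calls promoter calls (rows without a TSS are dropped).
#' @param peaks peak data.frame covering one or more marks.
#' @param marks marks to profile; defaults to all marks present. Requesting
#'   a mark absent from `peaks` is an error.
#' @inheritParams assign_tss
#' @return Integer matrix, rows = MIRs with promoters (rownames mir_id),
#'   columns = marks.
#' @export
mark_profile <- function(calls, peaks, marks = NULL,
                         config = pipeline_config()) {
  present <- unique(peaks$mark)
  if (is.null(marks)) marks <- sort(present)
  unknown <- setdiff(marks, present)
  if (length(unknown) > 0)
    stop("mark_profile: unknown mark(s): ", paste(unknown, collapse = ", "))
  rows <- calls[!is.na(calls$tss), , drop = FALSE]
  w <- config$mark_profile_window
  out <- matrix(0L, nrow = nrow(rows), ncol = length(marks),
                dimnames = list(rows$mir_id, marks))
  for (m in marks) {
    pk <- peaks[peaks$mark == m, , drop = FALSE]
    by_chrom <- split(seq_len(nrow(pk)), pk$chrom)
    for (i in seq_len(nrow(rows))) {
      j <- by_chrom[[rows$chrom[i]]]
      if (!is.null(j))
        out[i, m] <- sum(abs(pk$center[j] - rows$tss[i]) <= w)
    }
  }
  out
}
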