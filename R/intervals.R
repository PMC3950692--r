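# Coordinate conventions: every interval in this package is 0-based
# half-open [start, end). GFF3 (1-based inclusive) is converted on read and
# write. A window "x +/- w" is closed at base resolution, i.e. a feature
# exactly w away still counts; as an interval it is [x - w, x + w + 1).

#' Validate a data frame of genomic intervals
#'
#' Checks the shared interval invariants: non-empty chromosome names,
#' `0 <= start < end`, and strand in `+`, `-`, `.` when a strand column is
#' present.
#'
#' @param x data.frame with columns `chrom`, `start`, `end` (and optionally
#'   `strand`).
#' @param what label used in error messages.
#' @return `x` invisibly; stops on the first violated invariant.
#' @export
validate_intervals <- function(x, what = "interval") {
  stopifnot(is.data.frame(x))
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0)
    stop(what, ": missing columns: ", paste(miss, collapse = ", "))
  if (nrow(x) == 0) return(invisible(x))
  if (any(is.na(x$chrom) | !nzchar(as.character(x$chrom))))
    stop(what, ": empty chromosome name")
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad) > 0)
    stop(what, ": invalid coordinates (need 0 <= start < end) at row ", bad[1])
  if ("strand" %in% names(x)) {
    if (any(!x$strand %in% c("+", "-", ".")))
      stop(what, ": strand must be one of '+', '-', '.'")
  }
  invisible(x)
}

#' Strand-aware TSS / 5' end of an interval
#'
#' On `+` the TSS is `start`; on `-` it is `end - 1` (the last covered
#' base). Used both for gene TSSs and for pre-miRNA 5' ends.
#'
#' @param start,end 0-based half-open coordinates.
#' @param strand `"+"` or `"-"`.
#' @return Integer vector of positions.
#' @export
tss_position <- function(start, end, strand) {
  if (any(!strand %in% c("+", "-")))
    stop("strand must be '+' or '-' to define a TSS/5' end")
  ifelse(strand == "+", start, end - 1L)
}

# 0-based half-open data.frame -> GRanges (1-based closed).
as_granges0 <- function(x) {
  strand <- if ("strand" %in% names(x)) x$strand else "*"
  GenomicRanges::GRanges(
    seqnames = as.character(x$chrom),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = strand
  )
}

# For each row of `query`, TRUE iff it overlaps (>= 1 bp, half-open
# semantics) any row of `subject`. Both are 0-based half-open interval
# data.frames.
overlaps_any0 <- function(query, subject) {
  if (nrow(query) == 0) return(logical(0))
  if (nrow(subject) == 0) return(rep(FALSE, nrow(query)))
  IRanges::overlapsAny(as_granges0(query), as_granges0(subject),
                       ignore.strand = TRUE)
}

# Closed window [x - w, x + w] at base resolution as a half-open interval.
window_interval0 <- function(chrom, x, w) {
  data.frame(chrom = as.character(chrom),
             start = pmax(0L, as.integer(x) - as.integer(w)),
             end = as.integer(x) + as.integer(w) + 1L,
             stringsAsFactors = FALSE)
}

# Gap in bp between two 0-based half-open intervals on the same chromosome
# (0 when they overlap or abut).
interval_gap0 <- function(start1, end1, start2, end2) {
  pmax(0L, pmax(start1, start2) - pmin(end1, end2))
}
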