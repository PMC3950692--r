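# File dialects
#
# * GFF3: 1-based inclusive on disk, converted to the package's 0-based
#   half-open convention on read (and back on write); parsed with
#   rtracklayer.
# * BED / BEDPE-like: 0-based half-open on disk, headerless, '#' comments.
# * TSV: tab-separated, '#' comments, header row required; coordinates in
#   TSV annotation tables are 0-based half-open.

read_tsv_strict <- function(path, required = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                         stringsAsFactors = FALSE, check.names = FALSE,
                         quote = "")
  miss <- setdiff(required, names(x))
  if (length(miss) > 0)
    stop(path, ": missing required columns: ", paste(miss, collapse = ", "))
  x
}

write_tsv_strict <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "NA")
  invisible(path)
}

#' Read gene or MIR annotations
#'
#' Reads GFF3 (`.gff`/`.gff3`, 1-based inclusive, converted on read) or the
#' package's TSV dialect (0-based half-open). Gene records carry
#' `gene_id, symbol, chrom, start, end, strand, tss`; MIR records carry
#' `mir_id, chrom, start, end, strand, context, host_gene_id, cluster_id,
#' family_id, disease_categories` (comma-separated labels, `NA` for none).
#'
#' @param path GFF3 or TSV file.
#' @param kind `"gene"` or `"mir"`.
#' @return data.frame of validated records; the `tss` column of genes (and
#'   the implicit 5' end of MIRs) is strand-aware.
#' @export
read_annotations <- function(path, kind = c("gene", "mir")) {
  kind <- match.arg(kind)
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    x <- gff3_to_df(path, kind)
  } else {
    required <- if (kind == "gene") {
      c("gene_id", "symbol", "chrom", "start", "end", "strand")
    } else {
      c("mir_id", "chrom", "start", "end", "strand", "context",
        "host_gene_id", "cluster_id", "family_id", "disease_categories")
    }
    x <- read_tsv_strict(path, required)[, required, drop = FALSE]
    x$start <- as.integer(x$start)
    x$end <- as.integer(x$end)
  }
  if (nrow(x) == 0) return(finalize_annotations(x, kind))
  finalize_annotations(x, kind)
}

gff3_to_df <- function(path, kind) {
  gr <- rtracklayer::import(path, format = "gff3")
  m <- as.data.frame(gr, stringsAsFactors = FALSE)
  get_attr <- function(nm) {
    if (nm %in% names(m)) as.character(m[[nm]]) else rep(NA_character_, nrow(m))
  }
  base <- data.frame(
    chrom = as.character(m$seqnames),
    start = as.integer(m$start) - 1L,  # 1-based inclusive -> 0-based half-open
    end = as.integer(m$end),
    strand = as.character(m$strand),
    stringsAsFactors = FALSE
  )
  if (kind == "gene") {
    cbind(data.frame(gene_id = get_attr("ID"),
                     symbol = get_attr("Name"), stringsAsFactors = FALSE),
          base)
  } else {
    cbind(data.frame(mir_id = get_attr("ID"), stringsAsFactors = FALSE),
          base,
          data.frame(context = get_attr("context"),
                     host_gene_id = get_attr("host_gene_id"),
                     cluster_id = get_attr("cluster_id"),
                     family_id = get_attr("family_id"),
                     disease_categories = get_attr("disease_categories"),
                     stringsAsFactors = FALSE))
  }
}

finalize_annotations <- function(x, kind) {
  validate_intervals(x, what = paste0(kind, " annotations"))
  if (nrow(x) > 0 && any(!x$strand %in% c("+", "-")))
    stop(kind, " annotations: strand must be '+' or '-'")
  if (kind == "gene") {
    if (nrow(x) > 0 && anyDuplicated(x$gene_id))
      stop("gene annotations: duplicated gene_id")
    x$tss <- if (nrow(x) > 0) tss_position(x$start, x$end, x$strand) else integer(0)
  } else {
    if (nrow(x) > 0) {
      if (anyDuplicated(x$mir_id)) stop("mir annotations: duplicated mir_id")
      x$host_gene_id[!is.na(x$host_gene_id) & x$host_gene_id == ""] <- NA
      if (any(!x$context %in% c("intergenic", "intragenic")))
        stop("mir annotations: context must be 'intergenic' or 'intragenic'")
      bad <- which((x$context == "intragenic") != !is.na(x$host_gene_id))
      if (length(bad) > 0)
        stop("mir annotations: context/host_gene_id mismatch at row ", bad[1],
             " (intragenic MIRs and only those carry a host gene)")
    }
  }
  rownames(x) <- NULL
  x
}

#' @rdname read_annotations
#' @param x annotation data.frame as returned by [read_annotations()].
#' @export
write_annotations <- function(x, path, kind = c("gene", "mir")) {
  kind <- match.arg(kind)
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    gr <- as_granges0(x)
    if (kind == "gene") {
      S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        source = "mirchromnet", type = "gene",
        ID = x$gene_id, Name = x$symbol)
    } else {
      S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        source = "mirchromnet", type = "miRNA_primary_transcript",
        ID = x$mir_id, context = x$context,
        host_gene_id = x$host_gene_id, cluster_id = x$cluster_id,
        family_id = x$family_id,
        disease_categories = x$disease_categories)
    }
    rtracklayer::export(gr, path, format = "gff3")
  } else {
    drop <- intersect("tss", names(x))
    write_tsv_strict(x[, setdiff(names(x), drop), drop = FALSE], path)
  }
  invisible(path)
}

#' Check intragenic MIRs against their host genes
#'
#' Every intragenic MIR must lie within its host gene's interval on the
#' same strand; a host id that does not resolve to a gene is an error.
#'
#' @param mirs,genes annotation data.frames.
#' @return `mirs` invisibly.
#' @export
validate_mir_hosts <- function(mirs, genes) {
  intra <- mirs[mirs$context == "intragenic", , drop = FALSE]
  if (nrow(intra) == 0) return(invisible(mirs))
  idx <- match(intra$host_gene_id, genes$gene_id)
  if (anyNA(idx))
    stop("intragenic MIR with unresolvable host gene: ",
         intra$mir_id[which(is.na(idx))[1]])
  h <- genes[idx, , drop = FALSE]
  ok <- intra$chrom == h$chrom & intra$strand == h$strand &
    intra$start >= h$start & intra$end <= h$end
  if (any(!ok))
    stop("intragenic MIR not contained in host gene on the same strand: ",
         intra$mir_id[which(!ok)[1]])
  invisible(mirs)
}

#' Read or write duplex ChIA-PET interactions
#'
#' BEDPE-like dialect: headerless, '#' comments, nine tab-separated columns
#' `chrom1 start1 end1 chrom2 start2 end2 pet_count cell_line replicate_id`
#' with 0-based half-open anchors. On read, anchors are put in canonical
#' order (lexicographic by chromosome, then start, then end) and identical
#' records within one (cell line, replicate) are collapsed with their PET
#' counts summed; identical records in different replicates stay separate.
#'
#' @param path file path.
#' @return data.frame with columns `chrom1, start1, end1, chrom2, start2,
#'   end2, pet_count, cell_line, replicate_id`.
#' @export
read_interactions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cols <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
            "pet_count", "cell_line", "replicate_id")
  x <- utils::read.table(path, header = FALSE, sep = "\t", comment.char = "#",
                         stringsAsFactors = FALSE, quote = "",
                         col.names = cols,
                         colClasses = c("character", "integer", "integer",
                                        "character", "integer", "integer",
                                        "integer", "character", "character"))
  canonicalize_interactions(x)
}

canonicalize_interactions <- function(x) {
  if (nrow(x) == 0) return(x)
  validate_intervals(data.frame(chrom = x$chrom1, start = x$start1, end = x$end1),
                     "interaction anchor A")
  validate_intervals(data.frame(chrom = x$chrom2, start = x$start2, end = x$end2),
                     "interaction anchor B")
  if (any(x$pet_count < 1)) stop("interactions: pet_count must be >= 1")
  swap <- x$chrom2 < x$chrom1 |
    (x$chrom2 == x$chrom1 & (x$start2 < x$start1 |
                               (x$start2 == x$start1 & x$end2 < x$end1)))
  if (any(swap)) {
    tmp <- x[swap, c("chrom1", "start1", "end1")]
    x[swap, c("chrom1", "start1", "end1")] <- x[swap, c("chrom2", "start2", "end2")]
    x[swap, c("chrom2", "start2", "end2")] <- tmp
  }
  key <- paste(x$chrom1, x$start1, x$end1, x$chrom2, x$start2, x$end2,
               x$cell_line, x$replicate_id, sep = "\r")
  if (anyDuplicated(key)) {
    pet <- tapply(x$pet_count, key, sum)
    keep <- !duplicated(key)
    x <- x[keep, , drop = FALSE]
    x$pet_count <- as.integer(pet[key[keep]])
  }
  rownames(x) <- NULL
  x
}

#' @rdname read_interactions
#' @param x interaction data.frame.
#' @export
write_interactions <- function(x, path) {
  cols <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
            "pet_count", "cell_line", "replicate_id")
  utils::write.table(x[, cols, drop = FALSE], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read or write peak files
#'
#' BED-like dialect: headerless, '#' comments, columns
#' `chrom start end name score strand [summit_offset]`. The peak center is
#' `start + summit_offset` when the seventh column is present, otherwise the
#' integer midpoint `floor((start + end) / 2)`; `score` is the (non-negative)
#' binding intensity, 0 when absent.
#'
#' @param path BED file.
#' @param mark mark name attached to every peak (e.g. `"RNAPII"`,
#'   `"H3K4me3"`).
#' @param cell_line,replicate_id labels attached to every peak.
#' @return data.frame with columns `chrom, start, end, center, intensity,
#'   mark, cell_line, replicate_id`.
#' @export
read_peaks <- function(path, mark, cell_line, replicate_id) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- utils::read.table(path, header = FALSE, sep = "\t", comment.char = "#",
                         stringsAsFactors = FALSE, quote = "", fill = FALSE)
  if (ncol(x) < 3) stop(path, ": BED needs at least 3 columns")
  out <- data.frame(chrom = as.character(x[[1]]),
                    start = as.integer(x[[2]]),
                    end = as.integer(x[[3]]),
                    stringsAsFactors = FALSE)
  validate_intervals(out, "peaks")
  intensity <- if (ncol(x) >= 5) as.numeric(x[[5]]) else rep(0, nrow(x))
  if (any(intensity < 0)) stop(path, ": negative peak score")
  center <- if (ncol(x) >= 7) out$start + as.integer(x[[7]])
            else (out$start + out$end) %/% 2L
  if (nrow(out) > 0 && any(center < out$start | center >= out$end))
    stop(path, ": peak summit outside its interval")
  out$center <- as.integer(center)
  out$intensity <- intensity
  out$mark <- mark
  out$cell_line <- cell_line
  out$replicate_id <- replicate_id
  out
}

#' @rdname read_peaks
#' @param x peak data.frame.
#' @export
write_peaks <- function(x, path) {
  bed <- data.frame(x$chrom, x$start, x$end,
                    name = if (nrow(x) > 0) paste0("peak", seq_len(nrow(x))) else character(0),
                    score = x$intensity, strand = ".",
                    summit = x$center - x$start)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read simple BED3 intervals (blacklist, TADs)
#'
#' @param path BED file (headerless, '#' comments, first three columns
#'   used).
#' @return data.frame with columns `chrom, start, end`.
#' @export
read_bed3 <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- tryCatch(
    utils::read.table(path, header = FALSE, sep = "\t", comment.char = "#",
                      stringsAsFactors = FALSE, quote = ""),
    error = function(e) NULL)
  if (is.null(first) || nrow(first) == 0)
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0)))
  out <- data.frame(chrom = as.character(first[[1]]),
                    start = as.integer(first[[2]]),
                    end = as.integer(first[[3]]), stringsAsFactors = FALSE)
  validate_intervals(out, "BED intervals")
  out
}

#' @rdname read_bed3
#' @param x interval data.frame.
#' @export
write_bed3 <- function(x, path) {
  utils::write.table(x[, c("chrom", "start", "end"), drop = FALSE], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read expression, target-pair, term and TSS-evidence tables
#'
#' All are TSVs with a header. Expression: `entity_id, cell_line, value`
#' (FPKM for genes, RPM for MIRs; values must be non-negative). Targets:
#' `mir_id, target_gene_id, n_databases` with unique pairs. Terms:
#' `gene_id, term_id`. Curated TSS: `mir_id, tss`. CAGE tags:
#' `chrom, pos, strand, score`.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_expression <- function(path) {
  x <- read_tsv_strict(path, c("entity_id", "cell_line", "value"))
  x$value <- as.numeric(x$value)
  if (any(!is.finite(x$value) | x$value < 0))
    stop(path, ": expression values must be finite and >= 0")
  x
}

#' @rdname read_expression
#' @export
read_targets <- function(path) {
  x <- read_tsv_strict(path, c("mir_id", "target_gene_id", "n_databases"))
  x$n_databases <- as.integer(x$n_databases)
  if (any(x$n_databases < 1)) stop(path, ": n_databases must be >= 1")
  if (anyDuplicated(x[, c("mir_id", "target_gene_id")]))
    stop(path, ": duplicated (mir_id, target_gene_id) pair")
  x
}

#' @rdname read_expression
#' @export
read_terms <- function(path) {
  read_tsv_strict(path, c("gene_id", "term_id"))
}

#' @rdname read_expression
#' @export
read_curated_tss <- function(path) {
  x <- read_tsv_strict(path, c("mir_id", "tss"))
  x$tss <- as.integer(x$tss)
  x
}

#' @rdname read_expression
#' @export
read_cage_tags <- function(path) {
  x <- read_tsv_strict(path, c("chrom", "pos"))
  x$pos <- as.integer(x$pos)
  if (!"score" %in% names(x)) x$score <- 1
  x$score <- as.numeric(x$score)
  x
}

# Split comma-separated disease labels into a list of character vectors.
split_labels <- function(x) {
  out <- strsplit(ifelse(is.na(x) | x == "", "", x), ",", fixed = TRUE)
  lapply(out, function(v) v[nzchar(v)])
}
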