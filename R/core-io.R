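## Core domain containers and file I/O.
##
## Internal coordinate convention: every genomic position is 0-based, and
## single positions (TSS, TLS, TES) denote the base itself.  File formats
## keep their native conventions (GFF3 1-based inclusive, BED-like tables
## 0-based half-open); conversion happens exactly once, at the I/O boundary.
## "Upstream"/"downstream" and transcript-leader (TL) lengths are always
## measured in transcript orientation so one code path serves both strands.

#' Validate a genome annotation table
#'
#' Checks the invariants of the annotation container: unique gene ids,
#' strand in `{+,-}` and, in transcript orientation,
#' `canonical TSS <= TLS <= TES`.
#'
#' @param ann A data.frame with columns `gene_id`, `chrom`, `strand`,
#'   `tss` (canonical transcription start site), `tls` (translation start
#'   site, first CDS base), `tes` (transcript end site) and `class`
#'   (`mRNA`, `snoRNA`, `rRNA`, `tRNA` or `other`), all positions 0-based.
#' @return The validated annotation, invisibly.
#' @export
validate_annotation <- function(ann) {
  need <- c("gene_id", "chrom", "strand", "tss", "tls", "tes", "class")
  miss <- setdiff(need, names(ann))
  if (length(miss)) stop("annotation lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(ann$gene_id)) {
    stop("duplicate gene_id in annotation: ",
         paste(unique(ann$gene_id[duplicated(ann$gene_id)]), collapse = ", "))
  }
  if (!all(ann$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  up_ok <- tx_offset(ann$tls, ann$tss, ann$strand) >= 0
  dn_ok <- tx_offset(ann$tes, ann$tls, ann$strand) >= 0
  if (!all(up_ok & dn_ok)) {
    bad <- ann$gene_id[!(up_ok & dn_ok)]
    stop("annotation order TSS <= TLS <= TES violated for: ",
         paste(bad, collapse = ", "))
  }
  invisible(ann)
}

#' Read a gene annotation from GFF3
#'
#' Reads gene records from a GFF3 file (1-based inclusive coordinates) and
#' converts them to the package's 0-based internal convention.  The
#' translation start site is carried in a `tls` attribute (1-based genomic
#' position of the first CDS base) and the gene class in a `biotype`
#' attribute; both are written by [write_annotation()], making the pair an
#' exact inverse on valid files.
#'
#' @param path Path to a GFF3 file.
#' @return A validated annotation data.frame (see [validate_annotation()]).
#' @export
read_annotation <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) stop("failed to parse GFF3 '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  gr <- gr[gr$type == "gene"]
  if (length(gr) == 0L) stop("no gene records in ", path)
  md <- S4Vectors::mcols(gr)
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*")) stop("unstranded gene record in ", path)
  start0 <- GenomicRanges::start(gr) - 1L   # 0-based first base
  end0 <- GenomicRanges::end(gr) - 1L       # 0-based last base
  tls1 <- suppressWarnings(as.integer(as.character(md$tls)))
  if (any(is.na(tls1))) stop("gene record without integer 'tls' attribute in ", path)
  ann <- data.frame(
    gene_id = as.character(md$ID),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = strand,
    tss = ifelse(strand == "+", start0, end0),
    tls = tls1 - 1L,
    tes = ifelse(strand == "+", end0, start0),
    class = as.character(md$biotype %||% rep("mRNA", length(gr))),
    stringsAsFactors = FALSE
  )
  validate_annotation(ann)
  ann
}

#' Write a gene annotation to GFF3
#'
#' @param ann Annotation data.frame (0-based internal convention).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  validate_annotation(ann)
  gr <- GenomicRanges::GRanges(
    seqnames = ann$chrom,
    ranges = IRanges::IRanges(
      start = pmin(ann$tss, ann$tes) + 1L,
      end = pmax(ann$tss, ann$tes) + 1L
    ),
    strand = ann$strand
  )
  gr$type <- "gene"
  gr$ID <- ann$gene_id
  gr$biotype <- ann$class
  gr$tls <- as.character(ann$tls + 1L)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read aligned reads from a BED-like TSV
#'
#' Ingests pre-aligned stranded read intervals with columns
#' `chrom,start,end,strand,sample_id` (0-based half-open, BED convention).
#' Records with an empty or inverted interval are rejected rather than
#' fatal; the number of rejects is attached as attribute `"rejects"` and
#' logged.
#'
#' @param path Path to a tab-separated file with a header line.
#' @return A data.frame of validated reads with a per-sample tally attached
#'   as attribute `"tally"`.
#' @export
read_alignments <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "strand", "sample_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("alignment table lacks columns: ", paste(miss, collapse = ", "))
  df <- df[, need]
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  ok <- !is.na(df$start) & !is.na(df$end) & df$start >= 0L & df$start < df$end &
    df$strand %in% c("+", "-")
  n_rej <- sum(!ok)
  if (n_rej > 0) log_msg("read_alignments: rejected ", n_rej, " malformed records")
  df <- df[ok, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "rejects") <- n_rej
  attr(df, "tally") <- table(df$sample_id)
  df
}

#' Write aligned reads to a BED-like TSV
#'
#' @param reads Data.frame with columns `chrom,start,end,strand,sample_id`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignments <- function(reads, path) {
  utils::write.table(
    reads[, c("chrom", "start", "end", "strand", "sample_id")],
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Write a result table as TSV
#'
#' Writes any homogeneous record table with a header and a stable column
#' order.  Floating-point fields are serialised with 15 significant digits
#' so a write/read cycle round-trips within 1e-6.
#'
#' @param records A data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  out <- records
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
      out[[j]] <- formatC(out[[j]], digits = 15, format = "g")
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a result table written by [write_results_table()]
#'
#' @param path Path to the TSV file.
#' @return A data.frame.
#' @export
read_results_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
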