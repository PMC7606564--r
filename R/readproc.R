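## Read processing: adapter trimming, read-class partition, a small
## mismatch-tolerant mapper for toy genomes, and 5'-UTR-window feature
## counting.

ADAPTER_REGEX <- "C[ACGTN]{6}AGATCG"

#' Trim sequencing adapters from raw reads
#'
#' Removes the maximal 5' run of G/N (the CTP-tailing artifact), then
#' locates the first occurrence of the 3' adapter motif
#' `C` + 6 arbitrary bases + `AGATCG` and removes it together with
#' everything downstream.  Reads without the adapter motif are kept
#' full-length and flagged.  Trimmed inserts shorter than `min_len`
#' are classified `discarded`.
#'
#' @param seqs Character vector of uppercase reads over `ACGTN`.
#' @param min_len Minimum insert length to keep (default 12 nt).
#' @return A data.frame with columns `seq` (insert), `length`,
#'   `adapter_found` and `class` (`small` 12-17 nt, `normal` >= 18 nt, or
#'   `discarded`).
#' @export
trim_reads <- function(seqs, min_len = 12L) {
  if (any(grepl("[^ACGTN]", seqs))) stop("reads must be over the ACGTN alphabet")
  ins <- sub("^[GN]+", "", seqs)
  m <- regexpr(ADAPTER_REGEX, ins)
  found <- m != -1L
  ins[found] <- substr(ins[found], 1L, m[found] - 1L)
  len <- nchar(ins)
  cls <- ifelse(len < min_len, "discarded",
         ifelse(len <= 17L, "small", "normal"))
  data.frame(seq = ins, length = len, adapter_found = found, class = cls,
             stringsAsFactors = FALSE)
}

#' Classify trimmed reads
#'
#' Reads matching the spike-in reference (up to `max_mismatch` mismatches
#' against its prefix of matching length) are classified `spike_in` first;
#' the remainder partition by length into `small` (12-17 nt), `normal`
#' (>= 18 nt) and `discarded` (< 12 nt).  The partition is exhaustive and
#' exclusive.
#'
#' @param trimmed Output of [trim_reads()].
#' @param spike_seq Spike-in reference sequence
#'   (default [spike_in_sequence()]).
#' @param max_mismatch Mismatch allowance for the spike-in match.
#' @return `trimmed` with an updated `class` column and a class tally
#'   attached as attribute `"tally"`.
#' @export
classify_reads <- function(trimmed, spike_seq = spike_in_sequence(),
                           max_mismatch = 2L) {
  hamming_prefix <- function(s) {
    k <- nchar(s)
    if (k < 12L || k > nchar(spike_seq)) return(Inf)
    sum(utf8ToInt(s) != utf8ToInt(substr(spike_seq, 1L, k)))
  }
  ok_len <- trimmed$length >= 12L
  mm <- rep(Inf, nrow(trimmed))
  mm[ok_len] <- vapply(trimmed$seq[ok_len], hamming_prefix, numeric(1))
  cls <- trimmed$class
  cls[mm <= max_mismatch] <- "spike_in"
  trimmed$class <- cls
  attr(trimmed, "tally") <-
    table(factor(cls, levels = c("spike_in", "small", "normal", "discarded")))
  trimmed
}

## Brute-force mismatch profile of one read against one chromosome strand:
## returns the number of mismatches at every start position.
mismatch_profile <- function(read_chars, chrom_chars) {
  g <- length(chrom_chars); w <- length(read_chars)
  np <- g - w + 1L
  if (np < 1L) return(integer(0))
  mism <- integer(np)
  for (j in seq_len(w)) {
    mism <- mism + (chrom_chars[j:(j + np - 1L)] != read_chars[j])
  }
  mism
}

#' Map reads to a toy genome
#'
#' Exhaustive alignment of each read against both strands of every
#' chromosome, keeping hits with at most `max_mismatch` mismatches.  A
#' unique best-stratum hit is reported; ties are resolved by assigning the
#' read to one of the tied locations at random (seeded) and counting it as
#' multimapped.  Reads with no hit are counted as unmapped.
#'
#' @param seqs Character vector of read sequences (5'->3').
#' @param genome Named character vector of chromosome sequences.
#' @param max_mismatch Mismatch allowance (default 2).
#' @param sample_id Sample label recorded on the alignments.
#' @param seed Seed for multimapper tie-breaking.
#' @return A list with `alignments` (BED-like data.frame), `n_unmapped`
#'   and `n_multimapped`.
#' @export
map_reads <- function(seqs, genome, max_mismatch = 2L, sample_id = "S1",
                      seed = 1L) {
  set.seed(stage_seed(seed, "map"))
  chrom_fwd <- lapply(genome, function(s) strsplit(s, "")[[1]])
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  hits_one <- function(read) {
    fwd <- strsplit(read, "")[[1]]
    rc <- rev(unname(comp[fwd]))
    w <- length(fwd)
    chrom <- character(0); start <- integer(0); strand <- character(0)
    mm <- integer(0)
    for (cn in names(genome)) {
      g <- chrom_fwd[[cn]]
      for (str in c("+", "-")) {
        prof <- mismatch_profile(if (str == "+") fwd else rc, g)
        idx <- which(prof <= max_mismatch)
        if (!length(idx)) next
        chrom <- c(chrom, rep(cn, length(idx)))
        start <- c(start, idx - 1L)
        strand <- c(strand, rep(str, length(idx)))
        mm <- c(mm, prof[idx])
      }
    }
    if (!length(start)) return(NULL)
    keep <- mm == min(mm)
    list(chrom = chrom[keep], start = start[keep], strand = strand[keep],
         width = w)
  }
  out <- vector("list", length(seqs))
  n_un <- 0L; n_multi <- 0L
  for (i in seq_along(seqs)) {
    h <- hits_one(seqs[i])
    if (is.null(h)) { n_un <- n_un + 1L; next }
    j <- 1L
    if (length(h$start) > 1L) {
      n_multi <- n_multi + 1L
      j <- sample.int(length(h$start), 1L)
    }
    out[[i]] <- data.frame(chrom = h$chrom[j], start = h$start[j],
                           end = h$start[j] + h$width, strand = h$strand[j],
                           sample_id = sample_id, stringsAsFactors = FALSE)
  }
  alignments <- do.call(rbind, out)
  if (is.null(alignments)) {
    alignments <- data.frame(chrom = character(0), start = integer(0),
                             end = integer(0), strand = character(0),
                             sample_id = character(0))
  }
  rownames(alignments) <- NULL
  list(alignments = alignments, n_unmapped = n_un, n_multimapped = n_multi)
}

#' Map small (12-17 nt) reads with zero mismatches
#'
#' @inheritParams map_reads
#' @return As [map_reads()], with `max_mismatch = 0`.
#' @export
map_small_reads <- function(seqs, genome, sample_id = "S1", seed = 1L) {
  map_reads(seqs, genome, max_mismatch = 0L, sample_id = sample_id, seed = seed)
}

#' Count read 5'-ends in gene 5'-UTR windows
#'
#' A read is assigned to a gene when its 5'-end lies within the window
#' `[TLS - upstream, TLS + downstream]` in transcript orientation
#' (boundaries inclusive; defaults -120/+65 with the translation start as
#' 0) on the matching strand.  Reads whose 5'-end falls in an rRNA or tRNA
#' annotation are tallied separately and excluded from the mRNA matrix.
#' Where windows overlap, a read is counted for every overlapping gene.
#'
#' @param reads BED-like read data.frame (`chrom,start,end,strand,sample_id`).
#' @param annotation Validated annotation data.frame.
#' @param upstream Window extent upstream of the TLS (nt, default 120).
#' @param downstream Window extent downstream of the TLS (nt, default 65).
#' @return A list with `counts` (integer matrix, mRNA features x samples),
#'   `rrna_trna` (per-sample tally of rRNA/tRNA-assigned reads) and
#'   `n_unassigned`.
#' @export
count_features <- function(reads, annotation, upstream = 120L,
                           downstream = 65L) {
  validate_annotation(annotation)
  samples <- sort(unique(reads$sample_id))
  f5 <- read_five_prime(reads$start, reads$end, reads$strand)
  is_rt <- annotation$class %in% c("rRNA", "tRNA")
  mr <- annotation[!is_rt, , drop = FALSE]
  counts <- matrix(0L, nrow = nrow(mr), ncol = length(samples),
                   dimnames = list(mr$gene_id, samples))
  assigned <- rep(FALSE, nrow(reads))
  rt_tally <- stats::setNames(integer(length(samples)), samples)

  for (i in seq_len(nrow(annotation))) {
    g <- annotation[i, ]
    off <- tx_offset(f5, g$tls, g$strand)  # position relative to TLS
    hit <- reads$chrom == g$chrom & reads$strand == g$strand &
      off >= -upstream & off <= downstream
    if (!any(hit)) next
    if (is_rt[i]) {
      tt <- table(reads$sample_id[hit])
      rt_tally[names(tt)] <- rt_tally[names(tt)] + as.integer(tt)
      assigned <- assigned | hit
    } else {
      tt <- table(reads$sample_id[hit])
      counts[g$gene_id, names(tt)] <-
        counts[g$gene_id, names(tt)] + as.integer(tt)
      assigned <- assigned | hit
    }
  }
  list(counts = counts, rrna_trna = rt_tally,
       n_unassigned = sum(!assigned))
}
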