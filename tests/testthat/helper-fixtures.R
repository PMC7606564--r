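## Shared fixtures: built in code, deterministic.

## A tiny three-gene annotation on two strands.
tiny_annotation <- function() {
  data.frame(
    gene_id = c("gA", "gB", "gC"),
    chrom = c("chr1", "chr1", "chr2"),
    strand = c("+", "-", "+"),
    tss = c(100L, 980L, 60L),
    tls = c(150L, 930L, 100L),
    tes = c(400L, 700L, 300L),
    class = c("mRNA", "mRNA", "mRNA"),
    stringsAsFactors = FALSE
  )
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## One read as a BED-like row.
bed_read <- function(chrom, start, end, strand, sample_id) {
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             strand = strand, sample_id = sample_id, stringsAsFactors = FALSE)
}

## Reads whose 5' ends sit at given genomic positions (length 30).
reads_at <- function(pos, strand, sample_id, chrom = "chr1", len = 30L) {
  strand <- rep(strand, length.out = length(pos))
  start <- ifelse(strand == "+", pos, pos - len + 1L)
  data.frame(chrom = chrom, start = as.integer(start),
             end = as.integer(start + len), strand = strand,
             sample_id = sample_id, stringsAsFactors = FALSE)
}

## Mirror a simulated dataset: reverse-complement the genome, flip strands
## and reflect all coordinates.
mirror_dataset <- function(sim, reads) {
  L <- nchar(sim$genome)
  flip <- function(s) ifelse(s == "+", "-", "+")
  genome <- vapply(sim$genome, function(g) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(g)))
  }, character(1))
  ann <- sim$annotation
  ann$tss <- L - 1L - ann$tss
  ann$tls <- L - 1L - ann$tls
  ann$tes <- L - 1L - ann$tes
  ann$strand <- flip(ann$strand)
  rd <- reads
  new_start <- L - rd$end
  rd$end <- L - rd$start
  rd$start <- new_start
  rd$strand <- flip(rd$strand)
  list(genome = genome, annotation = ann, reads = rd)
}

## Transcript-oriented sequence window around a genomic position:
## offsets `lo..hi` in transcript orientation (negative = upstream).
oriented_window <- function(genome, chrom, pos, strand, lo, hi) {
  if (strand == "+") {
    substring(genome[chrom], pos + lo + 1L, pos + hi + 1L)
  } else {
    s <- substring(genome[chrom], pos - hi + 1L, pos - lo + 1L)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
}
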