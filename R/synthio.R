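## Synthetic NAD captureSeq data with planted ground truth.
##
## The generator emulates the statistical structure the downstream analysis
## assumes: a small fraction (~1-5%) of each gene's transcripts carry an NAD
## cap; NAD transcripts initiate at a gene-specific NAD TSS distinct from
## the canonical one, frequently embedded in a YAAG core promoter (pyrimidine
## at -1, A at +1 = the NAD incorporation site, A at +2, G at +3); ADPRC
## treatment (the "S" library) captures NAD 5'-ends efficiently while the
## -ADPRC control ("N") sees only unspecific background binding; NAD
## transcripts are more often 3'-truncated; and decapping enzymes active in
## a strain deplete NAD transcripts with transcript-leader-class-dependent
## preference, which is what makes TL-shift and hierarchy signatures
## plantable.

#' Simulation configuration
#'
#' Builds the configuration object consumed by [make_genome()] and
#' [simulate_reads()].  Defaults encode the study conditions the analysis is
#' designed for; see the methods vignette for the rationale behind each
#' value.
#'
#' @param n_genes Number of genes on the toy chromosome.
#' @param utr_length Range (min, max) of canonical 5'-UTR lengths in nt.
#' @param cds_length Range of transcribed lengths downstream of the TLS, nt.
#' @param yaag_fraction Fraction of NAD TSSs carrying the full YAAG motif
#'   (all NAD TSSs initiate on an A, the incorporation site).
#' @param nad_fraction Range of planted per-gene NAD-capping fractions
#'   \eqn{\rho} for non-null genes.
#' @param null_fraction Fraction of genes with \eqn{\rho = 0} (true
#'   negatives for enrichment calling).
#' @param nad_offset Range of the magnitude (nt) of the NAD-TSS offset from
#'   the canonical TSS in single-variant mode.
#' @param nad_variants 1 (one NAD TSS per gene, distal or proximal) or 2
#'   (each gene carries a distal and a proximal NAD TL variant; used to
#'   study decapping hierarchies).
#' @param capture_efficiency Probability `c` that an NAD 5'-end is captured
#'   in the +ADPRC library.
#' @param background_rate Probability `b` of unspecific capture of any
#'   transcript (both libraries).
#' @param reads_per_gene Transcript draws per gene per library before
#'   capture; the sequencing depth dial.
#' @param expr_sdlog Log-normal sd of per-gene expression multipliers.
#' @param n_reps Biological replicates per group.
#' @param jitter_prob Probability that a read 5'-end is jittered by one nt
#'   (split evenly between -1 and +1).
#' @param stop_prob Per-nucleotide geometric stop probability of the 3'
#'   truncation process for canonical-capped transcripts.
#' @param truncation_factor Multiplier on `stop_prob` for NAD transcripts
#'   (1 = no NAD-linked truncation bias).
#' @param small_rna_fraction Fraction of additional 12-17 nt small-RNA reads
#'   emitted per library (relative to normal reads), FASTQ mode only.
#' @param spike_in_copies Copies of the spike-in control per library,
#'   FASTQ mode only.
#' @param survival Named list, per decapping enzyme, of survival
#'   probabilities `c(proximal=, distal=)` for NAD transcripts of each TL
#'   class when the enzyme is active.
#' @param strains Named list mapping strain name to the character vector of
#'   active (non-deleted) decapping enzymes.
#' @param seed Integer global seed; every stage derives its own stream via
#'   [stage_seed()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 60L,
                       utr_length = c(40L, 80L),
                       cds_length = c(200L, 500L),
                       yaag_fraction = 0.8,
                       nad_fraction = c(0.01, 0.05),
                       null_fraction = 0.7,
                       nad_offset = c(10L, 40L),
                       nad_variants = 1L,
                       capture_efficiency = 0.5,
                       background_rate = 0.002,
                       reads_per_gene = 4000L,
                       expr_sdlog = 0.5,
                       n_reps = 3L,
                       jitter_prob = 0.2,
                       stop_prob = 0.001,
                       truncation_factor = 3,
                       small_rna_fraction = 0.05,
                       spike_in_copies = 300L,
                       survival = list(
                         Rai1 = c(proximal = 1.00, distal = 0.05),
                         Npy1 = c(proximal = 0.15, distal = 0.15),
                         Dxo1 = c(proximal = 0.60, distal = 0.60)
                       ),
                       strains = list(
                         WT = c("Rai1", "Dxo1", "Npy1"),
                         triple_ko = character(0)
                       ),
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), utr_length = as.integer(utr_length),
    cds_length = as.integer(cds_length), yaag_fraction = yaag_fraction,
    nad_fraction = nad_fraction, null_fraction = null_fraction,
    nad_offset = as.integer(nad_offset), nad_variants = as.integer(nad_variants),
    capture_efficiency = capture_efficiency, background_rate = background_rate,
    reads_per_gene = as.integer(reads_per_gene), expr_sdlog = expr_sdlog,
    n_reps = as.integer(n_reps), jitter_prob = jitter_prob,
    stop_prob = stop_prob, truncation_factor = truncation_factor,
    small_rna_fraction = small_rna_fraction,
    spike_in_copies = as.integer(spike_in_copies),
    survival = survival, strains = strains, seed = as.integer(seed)
  )
  probs <- c(cfg$yaag_fraction, cfg$nad_fraction, cfg$null_fraction,
             cfg$capture_efficiency, cfg$background_rate, cfg$jitter_prob,
             cfg$stop_prob, unlist(cfg$survival))
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  if (cfg$reads_per_gene <= 0L) stop("reads_per_gene must be positive")
  if (!cfg$nad_variants %in% c(1L, 2L)) stop("nad_variants must be 1 or 2")
  class(cfg) <- "sim_config"
  cfg
}

## Complement of a single base vector.
comp_base <- function(b) c(A = "T", C = "G", G = "C", T = "A", N = "N")[b]

## Write `base` at genomic position `pos` (0-based) of `chars` as seen in
## transcript orientation on `strand`.
set_tx_base <- function(chars, pos, strand, base) {
  chars[pos + 1L] <- ifelse(strand == "+", base, comp_base(base))
  chars
}

#' Generate a toy genome, annotation and planted truth
#'
#' Lays out `n_genes` genes on a single chromosome (random strands), assigns
#' each a canonical TSS, TLS and TES, plants one (or two) NAD TSSs per gene
#' with the configured offset geometry, writes the YAAG core motif around
#' NAD TSSs of flagged genes, and records everything in a truth table.
#' All NAD TSSs initiate on an A (the NAD incorporation site).
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `genome` (named character vector of
#'   chromosome sequences), `annotation` (see [validate_annotation()]),
#'   `truth` (per-gene planted parameters) and `config`.
#' @export
make_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "genome"))
  n <- config$n_genes
  ## sample() with a length-1 vector would expand it to 1:x
  sample_range <- function(lo, hi, n) {
    vals <- lo:hi
    vals[sample.int(length(vals), n, replace = TRUE)]
  }
  pad_up <- 140L; pad_dn <- 60L
  utr <- sample_range(config$utr_length[1], config$utr_length[2], n)
  cds <- sample_range(config$cds_length[1], config$cds_length[2], n)
  blk <- pad_up + utr + cds + pad_dn
  offs <- cumsum(c(0L, blk[-n]))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  glen <- sum(blk)

  tss <- ifelse(strand == "+", offs + pad_up, offs + blk - 1L - pad_up)
  tls <- tx_shift(tss, utr, strand)
  tes <- tx_shift(tls, cds - 1L, strand)

  rho <- stats::runif(n, config$nad_fraction[1], config$nad_fraction[2])
  is_null <- stats::runif(n) < config$null_fraction
  rho[is_null] <- 0
  has_yaag <- stats::runif(n) < config$yaag_fraction
  expr <- stats::rlnorm(n, meanlog = 0, sdlog = config$expr_sdlog)

  if (config$nad_variants == 1L) {
    tl_class <- sample(c("proximal", "distal"), n, replace = TRUE)
    mag <- sample_range(config$nad_offset[1], config$nad_offset[2], n)
    mag <- ifelse(tl_class == "proximal", pmin(mag, utr - 5L), mag)
    tl_nad <- ifelse(tl_class == "distal", utr + mag, utr - mag)
    nad_tss_dist <- ifelse(tl_class == "distal", tx_shift(tls, -tl_nad, strand), NA)
    nad_tss_prox <- ifelse(tl_class == "proximal", tx_shift(tls, -tl_nad, strand), NA)
    tl_dist <- ifelse(tl_class == "distal", tl_nad, NA)
    tl_prox <- ifelse(tl_class == "proximal", tl_nad, NA)
    w_dist <- ifelse(tl_class == "distal", 1, 0)
  } else {
    tl_class <- rep("both", n)
    tl_dist <- utr + sample_range(30L, 40L, n)
    tl_prox <- sample_range(5L, 15L, n)
    nad_tss_dist <- tx_shift(tls, -tl_dist, strand)
    nad_tss_prox <- tx_shift(tls, -tl_prox, strand)
    w_dist <- rep(0.5, n)
  }

  chars <- sample(c("A", "C", "G", "T"), glen, replace = TRUE)
  plant <- function(chars, pos, strand, yaag) {
    ## +1 is always A (NAD incorporation site); YAAG adds Y at -1, A at +2,
    ## G at +3, all in transcript orientation.
    ok <- !is.na(pos)
    p <- pos[ok]; s <- strand[ok]; y <- yaag[ok]
    chars <- set_tx_base(chars, p, s, "A")
    if (any(y)) {
      py <- sample(c("C", "T"), sum(y), replace = TRUE)
      chars <- set_tx_base(chars, tx_shift(p[y], -1L, s[y]), s[y], py)
      chars <- set_tx_base(chars, tx_shift(p[y], 1L, s[y]), s[y], "A")
      chars <- set_tx_base(chars, tx_shift(p[y], 2L, s[y]), s[y], "G")
    }
    chars
  }
  chars <- plant(chars, nad_tss_dist, strand, has_yaag)
  chars <- plant(chars, nad_tss_prox, strand, has_yaag)

  gene_id <- sprintf("g%03d", seq_len(n))
  annotation <- data.frame(
    gene_id = gene_id, chrom = "chrS", strand = strand,
    tss = as.integer(tss), tls = as.integer(tls), tes = as.integer(tes),
    class = "mRNA", stringsAsFactors = FALSE
  )
  validate_annotation(annotation)
  truth <- data.frame(
    gene_id = gene_id, strand = strand, chrom = "chrS",
    tss = as.integer(tss), tls = as.integer(tls), tes = as.integer(tes),
    utr_len = utr, rho = rho, has_yaag = has_yaag, expr = expr,
    tl_class = tl_class,
    nad_tss_prox = as.integer(nad_tss_prox),
    nad_tss_dist = as.integer(nad_tss_dist),
    tl_prox = as.numeric(tl_prox), tl_dist = as.numeric(tl_dist),
    w_dist = w_dist, stringsAsFactors = FALSE
  )
  list(genome = stats::setNames(paste(chars, collapse = ""), "chrS"),
       annotation = annotation, truth = truth, config = config)
}

#' Effective NAD fraction per gene and variant under a strain's enzymes
#'
#' \eqn{\rho' = \rho \, w_v \prod_e s_{e,\mathrm{TL}}} over the enzymes
#' active in the strain, for each TL variant `v`.
#'
#' @param truth Truth table from [make_genome()].
#' @param config The [sim_config()].
#' @param strain Strain name (must be listed in `config$strains`).
#' @return A data.frame with columns `gene_id`, `rho_prox`, `rho_dist` and
#'   their sum `rho_eff`.
#' @export
effective_nad_fraction <- function(truth, config, strain) {
  if (!strain %in% names(config$strains)) {
    stop("unknown strain '", strain, "'; known: ",
         paste(names(config$strains), collapse = ", "))
  }
  active <- config$strains[[strain]]
  surv <- function(class) {
    s <- rep(1, nrow(truth))
    for (e in active) s <- s * config$survival[[e]][[class]]
    s
  }
  rho_dist <- truth$rho * truth$w_dist * surv("distal")
  rho_dist[is.na(truth$nad_tss_dist)] <- 0
  rho_prox <- truth$rho * (1 - truth$w_dist) * surv("proximal")
  rho_prox[is.na(truth$nad_tss_prox)] <- 0
  data.frame(gene_id = truth$gene_id, rho_prox = rho_prox,
             rho_dist = rho_dist, rho_eff = rho_prox + rho_dist,
             stringsAsFactors = FALSE)
}

## Expand a per-(gene x origin) capture count table into read coordinates.
emit_reads <- function(idx, counts, origin, sim, config, sample_id) {
  truth <- sim$truth
  keep <- counts > 0L
  idx <- rep(idx[keep], counts[keep])
  org <- rep(origin[keep], counts[keep])
  n <- length(idx)
  if (n == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      sample_id = character(0), gene_id = character(0),
                      origin = character(0), stringsAsFactors = FALSE))
  }
  strand <- truth$strand[idx]
  tss0 <- ifelse(org == "nad_dist", truth$nad_tss_dist[idx],
          ifelse(org == "nad_prox", truth$nad_tss_prox[idx], truth$tss[idx]))
  jit <- sample(c(-1L, 0L, 1L), n, replace = TRUE,
                prob = c(config$jitter_prob / 2, 1 - config$jitter_prob,
                         config$jitter_prob / 2))
  f5 <- tx_shift(tss0, jit, strand)
  span <- tx_offset(truth$tes[idx], f5, strand) + 1L
  q <- config$stop_prob * ifelse(org == "bg", 1, config$truncation_factor)
  len <- pmin(span, 1L + stats::rgeom(n, q))
  len <- pmax(len, 18L)  # shorter fragments fall into the small-RNA class
  start <- ifelse(strand == "+", f5, f5 + 1L - len)
  end <- ifelse(strand == "+", f5 + len, f5 + 1L)
  data.frame(chrom = truth$chrom[idx], start = as.integer(start),
             end = as.integer(end), strand = strand,
             sample_id = sample_id, gene_id = truth$gene_id[idx],
             origin = org, stringsAsFactors = FALSE)
}

#' Simulate paired S/N capture libraries for one strain
#'
#' For each gene and replicate, `reads_per_gene * expr` transcript copies
#' are drawn; each is NAD-capped with the strain's effective probability
#' \eqn{\rho'} (see [effective_nad_fraction()]).  The +ADPRC ("S") library
#' captures NAD transcripts with probability `capture_efficiency` and any
#' transcript with `background_rate`; the -ADPRC ("N") control captures
#' with `background_rate` only.  Read 5'-ends sit at the originating TSS
#' (NAD or canonical) with one-nucleotide jitter; 3'-ends follow a
#' geometric truncation process with a `truncation_factor`-fold higher
#' per-nucleotide stop probability for NAD transcripts.
#'
#' @param sim Output of [make_genome()].
#' @param strain Strain name present in `config$strains`.
#' @param groups Library groups to emit; any of `"S"`, `"N"`,
#'   `"T"` (transcriptome: all-cap sampling, one replicate).
#' @param config Optional config overriding `sim$config`.
#' @return A list with `reads` (BED-like data.frame, one row per read, with
#'   bookkeeping columns `gene_id` and `origin`), `samples` (sample sheet)
#'   and `manifest` (per-sample emitted totals and all parameters).
#' @export
simulate_reads <- function(sim, strain, groups = c("S", "N"), config = NULL) {
  config <- config %||% sim$config
  rho <- effective_nad_fraction(sim$truth, config, strain)
  set.seed(stage_seed(config$seed, paste0("reads:", strain)))
  truth <- sim$truth
  n <- nrow(truth)
  draws <- as.integer(round(config$reads_per_gene * truth$expr))
  cc <- config$capture_efficiency
  b <- config$background_rate

  out <- list(); samples <- list(); k <- 0L
  for (grp in groups) {
    reps <- if (grp == "T") 1L else config$n_reps
    for (r in seq_len(reps)) {
      sid <- paste(strain, grp, r, sep = "_")
      n_dist <- stats::rbinom(n, draws, rho$rho_dist)
      n_prox <- stats::rbinom(n, draws, rho$rho_prox)
      n_can <- draws - n_dist - n_prox
      if (grp == "S") {
        cap_dist <- stats::rbinom(n, n_dist, cc + (1 - cc) * b)
        cap_prox <- stats::rbinom(n, n_prox, cc + (1 - cc) * b)
        cap_bg <- stats::rbinom(n, n_can, b)
      } else if (grp == "N") {
        cap_dist <- stats::rbinom(n, n_dist, b)
        cap_prox <- stats::rbinom(n, n_prox, b)
        cap_bg <- stats::rbinom(n, n_can, b)
      } else {  # transcriptome: uniform sampling of all transcripts
        cap_dist <- stats::rbinom(n, n_dist, 0.2)
        cap_prox <- stats::rbinom(n, n_prox, 0.2)
        cap_bg <- stats::rbinom(n, n_can, 0.2)
      }
      df <- rbind(
        emit_reads(seq_len(n), cap_dist, rep("nad_dist", n), sim, config, sid),
        emit_reads(seq_len(n), cap_prox, rep("nad_prox", n), sim, config, sid),
        emit_reads(seq_len(n), cap_bg, rep("bg", n), sim, config, sid)
      )
      k <- k + 1L
      out[[k]] <- df
      samples[[k]] <- data.frame(
        sample_id = sid, strain = strain, group = grp, replicate = r,
        library_kind = if (grp == "T") "transcriptome" else "unfragmented",
        stringsAsFactors = FALSE
      )
    }
  }
  reads <- do.call(rbind, out)
  rownames(reads) <- NULL
  samples <- do.call(rbind, samples)
  manifest <- list(
    strain = strain, groups = groups,
    emitted = as.list(table(reads$sample_id)),
    total_reads = nrow(reads),
    seed = config$seed,
    parameters = config[setdiff(names(config), c("strains", "survival"))],
    strains = config$strains, survival = config$survival
  )
  list(reads = reads, samples = samples, manifest = manifest)
}

#' Simulate libraries for several strains at once
#'
#' @param sim Output of [make_genome()].
#' @param strains Character vector of strain names (default: all configured).
#' @param groups Passed to [simulate_reads()].
#' @return A list with combined `reads`, `samples` and per-strain manifests.
#' @export
simulate_experiment <- function(sim, strains = names(sim$config$strains),
                                groups = c("S", "N")) {
  res <- lapply(strains, function(s) simulate_reads(sim, s, groups))
  list(
    reads = do.call(rbind, lapply(res, `[[`, "reads")),
    samples = do.call(rbind, lapply(res, `[[`, "samples")),
    manifests = stats::setNames(lapply(res, `[[`, "manifest"), strains)
  )
}

## Spike-in control sequence (synthetic; fixed so classification is testable).
spike_in_sequence <- function() {
  "ATGCCGTTAGACCTGAAGCTTGACCGGTATTCACGGAGTC"
}

#' Extract read insert sequences from the toy genome
#'
#' @param reads BED-like read data.frame.
#' @param genome Named character vector of chromosome sequences.
#' @return Character vector of oriented insert sequences.
#' @export
read_sequences <- function(reads, genome) {
  seqs <- substring(genome[reads$chrom], reads$start + 1L, reads$end)
  rc <- reads$strand == "-"
  if (any(rc)) {
    seqs[rc] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs[rc]))
    )
  }
  unname(seqs)
}

#' Wrap insert sequences in sequencing adapters
#'
#' Each record becomes: a 5' G-run (length `3 + Poisson(2)`, emulating the
#' CTP-tailing artifact), the insert, then the 3' adapter
#' `C` + 6 random bases + `AGATCG`, then random filler.  This is the exact
#' inverse of [trim_reads()] for inserts that neither start with G/N nor
#' contain the adapter motif internally.
#'
#' @param inserts Character vector of insert sequences.
#' @param seed Integer seed.
#' @return A data.frame with columns `read_id`, `seq`, `qual`.
#' @export
add_adapters <- function(inserts, seed = 1L) {
  set.seed(stage_seed(seed, "adapters"))
  n <- length(inserts)
  g_run <- vapply(3L + stats::rpois(n, 2), function(k)
    strrep("G", k), character(1))
  rand_seq <- function(k) paste(sample(c("A", "C", "G", "T"), k,
                                       replace = TRUE), collapse = "")
  assemble <- function(ins, g5) {
    ## resample the random spacer until the intended adapter is the first
    ## motif occurrence, so trimming inverts the construction exactly
    for (try in 1:20) {
      s <- paste0(g5, ins, "C", rand_seq(6), "AGATCG",
                  rand_seq(stats::rpois(1, 3)))
      core <- sub("^[GN]+", "", s)
      if (regexpr(ADAPTER_REGEX, core) == nchar(sub("^[GN]+", "", ins)) + 1L ||
          grepl(ADAPTER_REGEX, ins)) {
        return(s)
      }
    }
    s
  }
  seq <- vapply(seq_len(n), function(i) assemble(inserts[i], g_run[i]),
                character(1))
  data.frame(
    read_id = sprintf("r%06d", seq_len(n)),
    seq = seq,
    qual = vapply(nchar(seq), function(k) strrep("I", k), character(1)),
    stringsAsFactors = FALSE
  )
}

#' Write simulated outputs to a directory
#'
#' Writes `genome.fasta`, `genes.gff3`, `alignments.bed.tsv`, `truth.tsv`,
#' `samples.tsv` and `manifest.yaml`.
#'
#' @param sim Output of [make_genome()].
#' @param expt Output of [simulate_experiment()] or [simulate_reads()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, expt, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sim$genome), file.path(dir, "genome.fasta")
  )
  write_annotation(sim$annotation, file.path(dir, "genes.gff3"))
  write_alignments(expt$reads, file.path(dir, "alignments.bed.tsv"))
  write_results_table(sim$truth, file.path(dir, "truth.tsv"))
  write_results_table(expt$samples, file.path(dir, "samples.tsv"))
  manifest <- expt$manifests %||% list(run = expt$manifest)
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Emit FASTQ libraries for simulated samples
#'
#' Converts the aligned reads of each sample into raw sequencing reads:
#' insert sequences are taken from the genome, supplemented with 12-17 nt
#' small RNAs (5' prefixes of randomly chosen reads of the same sample, at
#' `small_rna_fraction` of the normal-read count) and `spike_in_copies`
#' prefixes of the spike-in control, then wrapped in adapters by
#' [add_adapters()] and written as one FASTQ file per sample.
#'
#' @param sim Output of [make_genome()].
#' @param run Output of [simulate_reads()] (or a compatible list with
#'   `reads` and `samples`).
#' @param dir Output directory.
#' @param config Optional config overriding `sim$config`.
#' @return Named character vector of FASTQ paths, invisibly.
#' @export
simulate_fastq <- function(sim, run, dir, config = NULL) {
  config <- config %||% sim$config
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  spike <- spike_in_sequence()
  for (sid in unique(run$reads$sample_id)) {
    set.seed(stage_seed(config$seed, paste0("fastq:", sid)))
    rr <- run$reads[run$reads$sample_id == sid, ]
    inserts <- read_sequences(rr, sim$genome)
    n_small <- round(config$small_rna_fraction * length(inserts))
    if (n_small > 0) {
      src <- sample.int(length(inserts), n_small, replace = TRUE)
      slen <- sample(12:17, n_small, replace = TRUE)
      inserts <- c(inserts, substr(inserts[src], 1L, slen))
    }
    if (config$spike_in_copies > 0) {
      splen <- sample(20:nchar(spike), config$spike_in_copies, replace = TRUE)
      inserts <- c(inserts, substr(rep(spike, config$spike_in_copies), 1L, splen))
    }
    inserts <- inserts[sample.int(length(inserts))]
    fq <- add_adapters(inserts, seed = stage_seed(config$seed,
                                                  paste0("adapters:", sid)))
    path <- file.path(dir, paste0("reads_", sid, ".fastq"))
    dna <- Biostrings::DNAStringSet(fq$seq)
    names(dna) <- fq$read_id
    Biostrings::writeXStringSet(dna, path, format = "fastq",
                                qualities = Biostrings::BStringSet(fq$qual))
    paths[sid] <- path
  }
  invisible(paths)
}
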