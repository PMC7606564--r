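## Transcription-start-site analyses: cluster detection in the 5'-UTR
## window, the weighted linear-by-linear trend test for alternative TSS
## usage, sharp-A TSS calling, promoter position-frequency matrices, TSS
## shift classification against a reference, and the transcript-leader
## length index (TLI) between strains.

#' Benjamini-Hochberg FDR
#'
#' Standard step-up BH adjustment (monotone-enforced).
#'
#' @param p Numeric vector of p-values in [0, 1]; `NA` entries propagate.
#' @return Adjusted values in [0, 1].
#' @export
bh_fdr <- function(p) {
  if (any(is.nan(p))) stop("NaN p-value passed to bh_fdr")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Collect per-gene read transcript-leader positions
#'
#' For each gene, selects reads on the matching chromosome and strand whose
#' 5'-end lies within the TSS scan window — the 5'-UTR plus `upstream` nt
#' of upstream extension — and records the transcript-leader length of the
#' 5'-end (distance upstream of the TLS, in transcript orientation).
#'
#' @param reads BED-like read data.frame.
#' @param annotation Validated annotation.
#' @param upstream Upstream extension beyond the canonical TSS (default 50).
#' @return A data.frame `gene_id`, `sample_id`, `tl` (one row per read).
#' @export
collect_read_tls <- function(reads, annotation, upstream = 50L) {
  f5 <- read_five_prime(reads$start, reads$end, reads$strand)
  out <- vector("list", nrow(annotation))
  for (i in seq_len(nrow(annotation))) {
    g <- annotation[i, ]
    utr <- tx_offset(g$tls, g$tss, g$strand)
    rel <- tl_length(f5, g$tls, g$strand)
    hit <- reads$chrom == g$chrom & reads$strand == g$strand &
      rel >= 0L & rel <= utr + upstream
    if (!any(hit)) next
    out[[i]] <- data.frame(gene_id = g$gene_id,
                           sample_id = reads$sample_id[hit],
                           tl = rel[hit], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(gene_id = character(0), sample_id = character(0),
                      tl = integer(0))
  }
  res
}

#' Detect TSS clusters by greedy sliding window
#'
#' Iteratively places an 18-nt window at the transcript-leader position
#' maximising the contained read-start count (S and N pooled), records a
#' cluster whose representative is the modal position inside the window
#' (ties: smallest TL), removes those reads, and repeats until no window
#' holds at least `min_reads` starts.  Clusters are returned sorted by TL
#' length ascending, with per-group counts.
#'
#' @param tl Integer vector of read-start TL lengths (one per read).
#' @param group Group label per read (e.g. `"S"`/`"N"`).
#' @param groups Group levels for the count columns.
#' @param window Window width in nt (default 18).
#' @param min_reads Minimum starts for a cluster (default 2).
#' @return A data.frame `tl` (representative TL length) plus one
#'   `count_<group>` column per group level.
#' @export
detect_tss_clusters <- function(tl, group, groups = c("S", "N"),
                                window = 18L, min_reads = 2L) {
  empty <- function() {
    out <- data.frame(tl = integer(0))
    for (g in groups) out[[paste0("count_", g)]] <- integer(0)
    out
  }
  if (length(tl) == 0L) return(empty())
  maxtl <- max(tl)
  ## per-position start counts, per group
  pos_counts <- matrix(0L, nrow = maxtl + 1L, ncol = length(groups),
                       dimnames = list(NULL, groups))
  for (g in groups) {
    t <- tabulate(tl[group == g] + 1L, nbins = maxtl + 1L)
    pos_counts[, g] <- t
  }
  total <- rowSums(pos_counts)
  win_sum <- function(v) {
    ## sum of v over windows [i, i+window-1]
    cs <- cumsum(c(0L, v))
    np <- max(1L, length(v) - window + 1L)
    cs[pmin(length(v), seq_len(np) + window - 1L) + 1L] - cs[seq_len(np)]
  }
  clusters <- list()
  repeat {
    ws <- win_sum(total)
    best <- which.max(ws)            # ties: smallest TL (which.max picks first)
    if (ws[best] < min_reads) break
    span <- best:min(length(total), best + window - 1L)
    seg <- total[span]
    rep_tl <- span[which.max(seg)] - 1L   # modal position, ties smallest TL
    cnt <- colSums(pos_counts[span, , drop = FALSE])
    clusters[[length(clusters) + 1L]] <-
      c(list(tl = rep_tl), as.list(cnt))
    pos_counts[span, ] <- 0L
    total[span] <- 0L
  }
  if (!length(clusters)) return(empty())
  out <- do.call(rbind, lapply(clusters, function(cl) {
    df <- data.frame(tl = cl$tl)
    for (g in groups) df[[paste0("count_", g)]] <- as.integer(cl[[g]])
    df
  }))
  out[order(out$tl), , drop = FALSE]
}

#' Weighted linear-by-linear trend test on a 2 x n TSS cluster table
#'
#' The bottom row is first scaled to the top row's total (rounded), so
#' library depth cannot masquerade as trend.  The table is then treated as
#' `n_obs` individual observations with row score X (2 for the top row, 1
#' for the bottom) and column score Y = the cluster's transcript-leader
#' length.  The weighted Pearson correlation `r = cov(X,Y)/(sd_X sd_Y)`
#' (population moments) gives the statistic `M^2 = (n_obs - 1) r^2`, which
#' is referred to the upper tail of a chi-squared distribution with one
#' degree of freedom.  Tables with fewer than `n_min` observations, a
#' single cluster, or zero variance in either margin are flagged
#' untestable (`p = NA`) rather than raising an error.
#'
#' @param top_counts,bottom_counts Integer cluster counts (top row = the
#'   group scored 2, e.g. +ADPRC S; bottom row scored 1, e.g. -ADPRC N).
#' @param tl Cluster transcript-leader lengths (column scores).
#' @param n_min Minimum total observations (default 30).
#' @param normalize Scale the bottom row to the top row's total first
#'   (default TRUE).
#' @return A list: `n_obs`, `r`, `m2`, `p`, `testable`.
#' @export
linear_trend_test <- function(top_counts, bottom_counts, tl, n_min = 30L,
                              normalize = TRUE) {
  stopifnot(length(top_counts) == length(tl),
            length(bottom_counts) == length(tl))
  untestable <- list(n_obs = NA_integer_, r = NA_real_, m2 = NA_real_,
                     p = NA_real_, testable = FALSE)
  s <- as.numeric(top_counts); b <- as.numeric(bottom_counts)
  if (normalize && sum(b) > 0 && sum(s) > 0) {
    b <- round(b * sum(s) / sum(b))
  }
  n_obs <- sum(s) + sum(b)
  untestable$n_obs <- as.integer(n_obs)
  if (n_obs < n_min || length(tl) < 2L) return(untestable)
  w <- c(s, b)
  x <- c(rep(2, length(tl)), rep(1, length(tl)))
  y <- c(tl, tl)
  W <- sum(w)
  mx <- sum(w * x) / W; my <- sum(w * y) / W
  vx <- sum(w * (x - mx)^2) / W; vy <- sum(w * (y - my)^2) / W
  if (vx == 0 || vy == 0) return(untestable)
  r <- sum(w * (x - mx) * (y - my)) / W / sqrt(vx * vy)
  m2 <- (n_obs - 1) * r^2
  list(n_obs = as.integer(n_obs), r = r, m2 = m2,
       p = stats::pchisq(m2, df = 1, lower.tail = FALSE), testable = TRUE)
}

#' Genome-wide alternative-TSS trend analysis
#'
#' Runs cluster detection and the trend test for every gene and adjusts
#' p-values by BH.
#'
#' @param reads BED-like reads (S and N samples).
#' @param meta Sample sheet mapping `sample_id` to `group`.
#' @param annotation Validated annotation.
#' @param upstream,window,min_reads,n_min Analysis parameters (defaults
#'   50, 18, 2, 30).
#' @return A data.frame `gene_id`, `n_clusters`, `n_obs`, `r`, `m2`, `p`,
#'   `fdr`, `testable`.
#' @export
trend_test_genes <- function(reads, meta, annotation, upstream = 50L,
                             window = 18L, min_reads = 2L, n_min = 30L) {
  grp <- meta$group[match(reads$sample_id, meta$sample_id)]
  tls <- collect_read_tls(reads, annotation, upstream = upstream)
  tls$group <- meta$group[match(tls$sample_id, meta$sample_id)]
  by_gene <- split(tls, tls$gene_id)
  rows <- lapply(annotation$gene_id, function(gid) {
    d <- by_gene[[gid]]
    if (is.null(d)) {
      return(data.frame(gene_id = gid, n_clusters = 0L, n_obs = 0L,
                        r = NA_real_, m2 = NA_real_, p = NA_real_,
                        testable = FALSE))
    }
    cl <- detect_tss_clusters(d$tl, d$group, groups = c("S", "N"),
                              window = window, min_reads = min_reads)
    tt <- linear_trend_test(cl$count_S, cl$count_N, cl$tl, n_min = n_min)
    data.frame(gene_id = gid, n_clusters = nrow(cl),
               n_obs = tt$n_obs %||% NA_integer_, r = tt$r, m2 = tt$m2,
               p = tt$p, testable = tt$testable)
  })
  out <- do.call(rbind, rows)
  out$fdr <- NA_real_
  ok <- !is.na(out$p)
  out$fdr[ok] <- bh_fdr(out$p[ok])
  out
}

## Base at 0-based genomic position, read in transcript orientation.
genome_base <- function(genome, chrom, pos, strand) {
  b <- substring(genome[chrom], pos + 1L, pos + 1L)
  ifelse(strand == "+", b, unname(comp_base(b)))
}

#' Call sharp-A TSSs
#'
#' For each gene, the TSS is the modal read 5'-end position within the
#' scan window (ties broken towards the position with the larger count one
#' nucleotide downstream).  The sharp value is the start count at the TSS
#' (+1) divided by the count one nucleotide upstream (-1; floored at 1 to
#' avoid division by zero).  A sharp-A call requires the TSS base to be an
#' A and the sharp value to exceed `sharp_min`.
#'
#' @param reads BED-like reads (typically the S group).
#' @param annotation Validated annotation.
#' @param genome Named character vector of chromosome sequences.
#' @param upstream Scan-window upstream extension (default 50).
#' @param min_reads Minimum starts in the window to attempt a call.
#' @param sharp_min Sharp-value threshold (strict; default 4).
#' @return A data.frame `gene_id`, `tss_pos` (genomic), `tl`, `base`,
#'   `sharp_value`, `is_sharp_a`.
#' @export
call_sharp_a <- function(reads, annotation, genome, upstream = 50L,
                         min_reads = 5L, sharp_min = 4) {
  f5 <- read_five_prime(reads$start, reads$end, reads$strand)
  rows <- lapply(seq_len(nrow(annotation)), function(i) {
    g <- annotation[i, ]
    utr <- tx_offset(g$tls, g$tss, g$strand)
    rel <- tl_length(f5, g$tls, g$strand)
    hit <- reads$chrom == g$chrom & reads$strand == g$strand &
      rel >= 0L & rel <= utr + upstream
    if (sum(hit) < min_reads) return(NULL)
    cnt <- table(rel[hit])
    top <- max(cnt)
    cand <- as.integer(names(cnt)[cnt == top])
    if (length(cand) > 1L) {
      ## tie-break: larger count at the next downstream position (+2)
      dn <- vapply(cand, function(x) {
        v <- cnt[as.character(x - 1L)]   # one nt downstream = smaller TL
        if (is.na(v)) 0L else as.integer(v)
      }, integer(1))
      cand <- cand[order(-dn, cand)][1]
    }
    tl0 <- cand[1]
    c_plus1 <- as.integer(cnt[as.character(tl0)])
    c_minus1 <- cnt[as.character(tl0 + 1L)]  # one nt upstream = larger TL
    c_minus1 <- if (is.na(c_minus1)) 0L else as.integer(c_minus1)
    sharp <- c_plus1 / max(1L, c_minus1)
    pos <- tx_shift(g$tls, -tl0, g$strand)  # TL lengths count upstream
    base <- genome_base(genome, g$chrom, pos, g$strand)
    data.frame(gene_id = g$gene_id, tss_pos = pos, tl = tl0, base = base,
               sharp_value = sharp,
               is_sharp_a = base == "A" && sharp > sharp_min,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(0), tss_pos = integer(0),
                      tl = integer(0), base = character(0),
                      sharp_value = numeric(0), is_sharp_a = logical(0))
  }
  out
}

#' Promoter position-frequency matrix around called TSSs
#'
#' Extracts the -10..+10 window (21 positions, transcript orientation)
#' around each supplied TSS, builds a position frequency matrix with a
#' pseudo-count per base, and computes the per-position information
#' content `IC = 2 - H` (bits).  Genes whose window leaves the chromosome
#' are skipped with a log entry.
#'
#' @param calls Data.frame with `tss_pos` and `gene_id` (e.g. from
#'   [call_sharp_a()]), joined with annotation strand/chrom via
#'   `annotation`.
#' @param annotation Validated annotation.
#' @param genome Named character vector of chromosome sequences.
#' @param flank Half-window (default 10).
#' @param pseudo Pseudo-count per base (default 0.25).
#' @param ic_min IC threshold for reporting a consensus base (default 0.5).
#' @return A list: `pfm` (4 x 21 column-stochastic matrix), `ic` (bits),
#'   `consensus` (character; `"."` where IC <= `ic_min`), `n_sites`.
#' @export
promoter_matrix <- function(calls, annotation, genome, flank = 10L,
                            pseudo = 0.25, ic_min = 0.5) {
  ann <- annotation[match(calls$gene_id, annotation$gene_id), ]
  wins <- character(0)
  for (i in seq_len(nrow(calls))) {
    chrom <- ann$chrom[i]; strand <- ann$strand[i]; pos <- calls$tss_pos[i]
    lo <- pos - flank; hi <- pos + flank
    if (lo < 0L || hi >= nchar(genome[chrom])) {
      log_msg("promoter_matrix: window off contig for ", calls$gene_id[i])
      next
    }
    s <- substring(genome[chrom], lo + 1L, hi + 1L)
    if (strand == "-") {
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    wins <- c(wins, s)
  }
  if (!length(wins)) stop("no usable promoter windows")
  mat <- do.call(rbind, strsplit(wins, ""))
  bases <- c("A", "C", "G", "T")
  pfm <- apply(mat, 2, function(col) {
    cnt <- table(factor(col, levels = bases)) + pseudo
    as.numeric(cnt / sum(cnt))
  })
  rownames(pfm) <- bases
  colnames(pfm) <- as.character(-flank:flank)
  ic <- apply(pfm, 2, function(p) 2 + sum(p * log2(p)))
  cons <- ifelse(ic > ic_min, bases[apply(pfm, 2, which.max)], ".")
  list(pfm = pfm, ic = ic, consensus = paste(cons, collapse = ""),
       n_sites = length(wins))
}

#' Select promoter-analysis gene sets from enrichment records
#'
#' `"topK_enriched"` takes the `k` features with the highest fold change;
#' `"background"` takes the `k` most abundant features with
#' `fc_down <= FC <= fc_up` (not significantly enriched either way).
#'
#' @param enrich Enrichment table from [enrichment_test()].
#' @param selection `"topK_enriched"` or `"background"`.
#' @param k Set size (default 25).
#' @param fc_up,fc_down Background band (defaults 1.414, 0.707).
#' @return Character vector of feature ids.
#' @export
select_promoter_set <- function(enrich, selection = c("topK_enriched", "background"),
                                k = 25L, fc_up = 1.414, fc_down = 0.707) {
  selection <- match.arg(selection)
  if (selection == "topK_enriched") {
    e <- enrich[enrich$verdict == "enriched", ]
    e <- e[order(-e$fc), ]
  } else {
    e <- enrich[enrich$fc >= fc_down & enrich$fc <= fc_up, ]
    e <- e[order(-e$nbm), ]
  }
  utils::head(e$feature_id, k)
}

#' Classify TSS shifts of the capture library against a reference
#'
#' Per gene, the shift is the difference of modal transcript-leader lengths
#' between the S-group read starts and the reference (positive = distal,
#' i.e. a longer leader).  Against a read-level reference (e.g. the
#' N-group starts as an all-cap proxy) significance comes from an unpaired
#' two-sided rank-sum test of the TL lengths; against a point reference
#' (a user-supplied canonical TSS) from a two-sided sign test.  p-values
#' are BH-adjusted across genes; a gene is called `distal` when
#' `delta > shift_min` and `fdr < fdr_max`, `proximal` when
#' `delta < -shift_min`, else `none`.
#'
#' @param reads BED-like reads.
#' @param meta Sample sheet (`sample_id`, `group`).
#' @param annotation Validated annotation.
#' @param reference `"N"` (compare against N-group starts) or
#'   `"canonical"` (compare against the annotated canonical TSS).
#' @param upstream Scan-window extension (default 50).
#' @param min_reads Minimum reads per compared set (default 5).
#' @param shift_min Shift threshold in nt (default 10).
#' @param fdr_max FDR threshold (default 0.1).
#' @return A data.frame `gene_id`, `delta`, `n_s`, `n_ref`, `p`, `fdr`,
#'   `direction`.
#' @export
tss_shift_vs_reference <- function(reads, meta, annotation,
                                   reference = c("N", "canonical"),
                                   upstream = 50L, min_reads = 5L,
                                   shift_min = 10, fdr_max = 0.1) {
  reference <- match.arg(reference)
  tls <- collect_read_tls(reads, annotation, upstream = upstream)
  tls$group <- meta$group[match(tls$sample_id, meta$sample_id)]
  by_gene <- split(tls, tls$gene_id)
  rows <- lapply(annotation$gene_id, function(gid) {
    d <- by_gene[[gid]]
    if (is.null(d)) return(NULL)
    s <- d$tl[d$group == "S"]
    if (length(s) < min_reads) return(NULL)
    if (reference == "N") {
      ref <- d$tl[d$group == "N"]
      if (length(ref) < min_reads) return(NULL)
      delta <- modal_value(s) - modal_value(ref)
      p <- suppressWarnings(
        stats::wilcox.test(s, ref, exact = FALSE)$p.value)
      if (is.na(p)) p <- 1  # degenerate all-tie comparison
      n_ref <- length(ref)
    } else {
      g <- annotation[annotation$gene_id == gid, ]
      ref_tl <- tx_offset(g$tls, g$tss, g$strand)
      delta <- modal_value(s) - ref_tl
      nz <- s != ref_tl
      p <- if (any(nz)) {
        stats::binom.test(sum(s[nz] > ref_tl), sum(nz))$p.value
      } else 1
      n_ref <- 1L
    }
    data.frame(gene_id = gid, delta = delta, n_s = length(s), n_ref = n_ref,
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(gene_id = character(0), delta = numeric(0),
                      n_s = integer(0), n_ref = integer(0), p = numeric(0),
                      fdr = numeric(0), direction = character(0)))
  }
  out$fdr <- bh_fdr(out$p)
  out$direction <- ifelse(out$delta > shift_min & out$fdr < fdr_max, "distal",
                   ifelse(out$delta < -shift_min & out$fdr < fdr_max,
                          "proximal", "none"))
  out
}

#' Transcript-leader length index between two strains
#'
#' For each gene, `TLI = (mu_B - mu_A) / W`, where `mu` is the
#' read-count-weighted mean transcript-leader length of the strain's
#' S-group starts in the scan window and `W` is the scanned window length
#' (5'-UTR + `upstream`).  Positive TLI means strain B initiates at more
#' distal (longer-leader) positions.  Significance comes from the weighted
#' trend test applied to the pooled A-vs-B TSS cluster table (strain B in
#' the row scored 2), BH-adjusted across genes; `direction` is `distal`
#' when `TLI > tli_min` and `fdr < fdr_max`, `proximal` when
#' `TLI < -tli_min`, else `none`.
#'
#' @param reads_a,reads_b S-group reads of strains A and B.
#' @param annotation Validated annotation.
#' @param upstream,window,min_reads,n_min Cluster/trend parameters.
#' @param tli_min TLI threshold (default 0.1).
#' @param fdr_max FDR threshold (default 0.1).
#' @return A data.frame `gene_id`, `tli`, `n_a`, `n_b`, `p`, `fdr`,
#'   `direction`.
#' @export
compute_tli <- function(reads_a, reads_b, annotation, upstream = 50L,
                        window = 18L, min_reads = 2L, n_min = 30L,
                        tli_min = 0.1, fdr_max = 0.1) {
  tls_a <- collect_read_tls(reads_a, annotation, upstream = upstream)
  tls_b <- collect_read_tls(reads_b, annotation, upstream = upstream)
  by_a <- split(tls_a$tl, tls_a$gene_id)
  by_b <- split(tls_b$tl, tls_b$gene_id)
  rows <- lapply(seq_len(nrow(annotation)), function(i) {
    g <- annotation[i, ]
    a <- by_a[[g$gene_id]]; b <- by_b[[g$gene_id]]
    if (is.null(a) || is.null(b)) return(NULL)
    W <- tx_offset(g$tls, g$tss, g$strand) + upstream
    tli <- (mean(b) - mean(a)) / W
    cl <- detect_tss_clusters(
      c(a, b), c(rep("A", length(a)), rep("B", length(b))),
      groups = c("B", "A"), window = window, min_reads = min_reads
    )
    tt <- linear_trend_test(cl$count_B, cl$count_A, cl$tl, n_min = n_min)
    data.frame(gene_id = g$gene_id, tli = tli, n_a = length(a),
               n_b = length(b), p = tt$p, testable = tt$testable,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(gene_id = character(0), tli = numeric(0),
                      n_a = integer(0), n_b = integer(0), p = numeric(0),
                      testable = logical(0), fdr = numeric(0),
                      direction = character(0)))
  }
  out$fdr <- NA_real_
  ok <- !is.na(out$p)
  out$fdr[ok] <- bh_fdr(out$p[ok])
  out$direction <- ifelse(
    !is.na(out$fdr) & out$fdr < fdr_max & out$tli > tli_min, "distal",
    ifelse(!is.na(out$fdr) & out$fdr < fdr_max & out$tli < -tli_min,
           "proximal", "none"))
  out
}
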