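## S-vs-N enrichment statistics, TPM normalisation, NAD-modification-ratio
## estimators and small-RNA cluster assembly.
##
## The enrichment test is a self-contained negative-binomial Wald test
## (median-of-ratios size factors, method-of-moments dispersion floored at
## 0.01, pseudo-count 0.5 on group means for the fold change).  It keeps
## the published decision thresholds: a feature is called enriched when
## FC > 1.414, NBM > 1 and p < 0.05, and depleted when FC < 0.707 with the
## same NBM and p gates (strict inequalities).

#' Median-of-ratios size factors
#'
#' Each sample's factor is the median across features of the ratio of its
#' count to the geometric-mean pseudo-reference, computed over features
#' with nonzero counts in every sample.
#'
#' @param counts Non-negative integer matrix, features x samples.
#' @return Named numeric vector of positive size factors.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) == 1L) return(stats::setNames(1, colnames(counts)))
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(all_pos)) {
    stop("no feature has nonzero counts in all samples; ",
         "consider adding a pseudo-count")
  }
  lg <- log(counts[all_pos, , drop = FALSE])
  ref <- rowMeans(lg)
  sf <- apply(lg, 2, function(x) exp(stats::median(x - ref)))
  sf
}

#' Negative-binomial Wald enrichment test (S vs N)
#'
#' Per feature: `NBM` is the mean of size-factor-normalised counts over all
#' samples; `FC` is the ratio of group means with pseudo-count 0.5; the
#' p-value comes from a Wald test of `log FC` with variance
#' `sum_g (1/(n_g mu_g) + alpha/n_g)` under an NB model whose dispersion
#' `alpha` is estimated by the method of moments within groups, pooled
#' across features (median) and floored at 0.01.  All-zero features get
#' `p = 1` and verdict `ns`.
#'
#' @param counts Integer matrix, features x samples.
#' @param meta Sample sheet data.frame with `sample_id` and `group` columns;
#'   `group` distinguishes the two conditions (by default `"S"` vs `"N"`,
#'   but any two labels work, e.g. two strains for differential
#'   expression).
#' @param group_levels Length-2 character: numerator and denominator group.
#' @param fc_up,fc_down,nbm_min,alpha Decision thresholds (defaults 1.414,
#'   0.707, 1, 0.05).
#' @param dispersion_floor Lower bound on the pooled dispersion estimate.
#' @return A data.frame of enrichment records: `feature_id`, `nbm`, `fc`,
#'   `log2fc`, `p_value`, `fdr`, `verdict`.
#' @export
enrichment_test <- function(counts, meta, group_levels = c("S", "N"),
                            fc_up = 1.414, fc_down = 0.707, nbm_min = 1,
                            alpha = 0.05, dispersion_floor = 0.01) {
  counts <- as.matrix(counts)
  meta <- meta[match(colnames(counts), meta$sample_id), , drop = FALSE]
  if (any(is.na(meta$sample_id))) stop("meta lacks some count-matrix samples")
  gi <- lapply(group_levels, function(g) which(meta$group == g))
  if (any(vapply(gi, length, 1L) < 2L)) {
    stop("need >= 2 replicates per group for dispersion estimation")
  }
  sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  nbm <- rowMeans(norm[, unlist(gi), drop = FALSE])

  mu <- vapply(gi, function(ix) rowMeans(norm[, ix, drop = FALSE]),
               numeric(nrow(norm)))
  vv <- vapply(gi, function(ix) apply(norm[, ix, drop = FALSE], 1, stats::var),
               numeric(nrow(norm)))
  nrep <- vapply(gi, length, 1L)

  ## method-of-moments NB dispersion: per-feature within-group estimates
  ## are pooled to a common (median) value, since with few replicates the
  ## per-feature estimator is mostly rectified noise; floored below
  disp_g <- (vv - mu) / mu^2
  disp_g[!is.finite(disp_g)] <- NA
  disp_feat <- apply(disp_g, 1, function(x) mean(pmax(x, 0), na.rm = TRUE))
  disp <- stats::median(disp_feat, na.rm = TRUE)
  if (!is.finite(disp)) disp <- 0
  disp <- max(disp, dispersion_floor)

  ps <- 0.5
  fc <- (mu[, 1] + ps) / (mu[, 2] + ps)
  se2 <- (1 / (nrep[1] * (mu[, 1] + ps)) + disp / nrep[1]) +
         (1 / (nrep[2] * (mu[, 2] + ps)) + disp / nrep[2])
  z <- log(fc) / sqrt(se2)
  p <- 2 * stats::pnorm(-abs(z))
  all_zero <- rowSums(counts) == 0
  p[all_zero] <- 1
  fdr <- bh_fdr(p)

  verdict <- rep("ns", nrow(counts))
  verdict[fc > fc_up & nbm > nbm_min & p < alpha] <- "enriched"
  verdict[fc < fc_down & nbm > nbm_min & p < alpha] <- "depleted"
  verdict[all_zero] <- "ns"
  data.frame(
    feature_id = rownames(counts), nbm = nbm, fc = fc, log2fc = log2(fc),
    p_value = p, fdr = fdr, verdict = verdict,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Transcripts-per-million normalisation
#'
#' @param counts Integer matrix, features x samples.
#' @param feature_lengths Positive lengths (nt) matching the rows.
#' @return Matrix of TPM values; every column sums to 1e6.
#' @export
tpm <- function(counts, feature_lengths) {
  counts <- as.matrix(counts)
  if (any(feature_lengths <= 0)) stop("feature lengths must be positive")
  rate <- counts / feature_lengths
  sweep(rate, 2, colSums(rate), "/") * 1e6
}

#' TPM-integrated NAD-modification ratio
#'
#' Distributes a total NAD amount `k` (an external, e.g. mass-spectrometric,
#' scalar on a relative scale) over features proportionally to
#' `TPM_NAD / TPM_all`: `ratio = k * TPM_NAD / TPM_all`, clipped to [0, 1].
#' Features with `TPM_all = 0` are omitted with a log entry.
#'
#' @param k Positive scalar: relative total NAD-RNA amount.
#' @param tpm_nad Named numeric vector: per-feature TPM in the capture
#'   (+ADPRC) library.
#' @param tpm_all Named numeric vector: per-feature TPM in the
#'   transcriptome (all-cap) library.
#' @return A data.frame `feature_id`, `ratio`, `method`.
#' @export
nad_ratio_tpm <- function(k, tpm_nad, tpm_all) {
  if (k <= 0) stop("k must be positive")
  ids <- intersect(names(tpm_nad), names(tpm_all))
  tn <- tpm_nad[ids]; ta <- tpm_all[ids]
  drop <- ta == 0
  if (any(drop)) {
    log_msg("nad_ratio_tpm: omitting ", sum(drop), " features with TPM_all = 0")
  }
  ids <- ids[!drop]
  ratio <- pmin(pmax(k * tn[!drop] / ta[!drop], 0), 1)
  data.frame(feature_id = ids, ratio = unname(ratio), method = "tpm_integration",
             stringsAsFactors = FALSE)
}

#' qRT-PCR NAD-modification ratio
#'
#' `(S - background) / (S + noncap)`, clipped to [0, 1]; the inputs are the
#' fully treated (+ADPRC), unspecific-binding background (-ADPRC) and
#' non-NAD-cap signals, all on a common normalised scale.
#'
#' @param s_signal,bg_signal,noncap_signal Non-negative numeric vectors.
#' @return Numeric ratio vector; `NA` where the denominator is 0.
#' @export
nad_ratio_qpcr <- function(s_signal, bg_signal, noncap_signal) {
  if (any(c(s_signal, bg_signal, noncap_signal) < 0)) {
    stop("signals must be non-negative")
  }
  den <- s_signal + noncap_signal
  ratio <- ifelse(den == 0, NA_real_,
                  pmin(pmax((s_signal - bg_signal) / den, 0), 1))
  ratio
}

## Ungapped identity of two sequences over offsets -3..+3, relative to the
## shorter length.
pair_identity <- function(a, b, max_offset = 3L) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  la <- length(ca); lb <- length(cb)
  best <- 0
  for (off in -max_offset:max_offset) {
    ia <- max(1L, 1L + off); ib <- max(1L, 1L - off)
    n <- min(la - ia + 1L, lb - ib + 1L)
    if (n <= 0L) next
    matches <- sum(ca[ia:(ia + n - 1L)] == cb[ib:(ib + n - 1L)])
    best <- max(best, matches / min(la, lb))
  }
  best
}

#' Assemble small-RNA clusters
#'
#' Greedy clustering of 12-17 nt reads by descending total abundance: a
#' read joins the first existing cluster whose seed it matches at >= 60%
#' ungapped identity (best offset within +/-3 nt, relative to the shorter
#' length), on the same strand, and whose seed copy number differs by at
#' most a factor of `max_copy_ratio`; otherwise it seeds a new cluster.
#' Cluster enrichment is total S copies / total N copies; `Inf` (N = 0) is
#' reported as is and flagged.
#'
#' @param seqs Character vector of distinct small-RNA sequences.
#' @param strand Strand per sequence.
#' @param copies_s,copies_n Copy numbers per sequence in the S and N groups.
#' @param min_identity Identity threshold (default 0.6).
#' @param max_copy_ratio Maximum seed/member copy ratio (default 50).
#' @param fc_up Enrichment call threshold (default 1.414).
#' @return A data.frame, one row per cluster: `cluster_id`, `seed`,
#'   `strand`, `n_members`, `copies_s`, `copies_n`, `enrichment`,
#'   `enriched`, `infinite_enrichment`.
#' @export
cluster_small_rnas <- function(seqs, strand, copies_s, copies_n,
                               min_identity = 0.6, max_copy_ratio = 50,
                               fc_up = 1.414) {
  stopifnot(length(seqs) == length(strand),
            length(seqs) == length(copies_s),
            length(seqs) == length(copies_n))
  total <- copies_s + copies_n
  ord <- order(-total)
  clusters <- list()
  for (i in ord) {
    placed <- FALSE
    for (k in seq_along(clusters)) {
      cl <- clusters[[k]]
      if (strand[i] != cl$strand) next
      ratio <- max(cl$seed_copies, total[i]) / max(1e-9, min(cl$seed_copies, total[i]))
      if (ratio > max_copy_ratio) next
      if (pair_identity(seqs[i], cl$seed) >= min_identity) {
        cl$members <- c(cl$members, i)
        cl$copies_s <- cl$copies_s + copies_s[i]
        cl$copies_n <- cl$copies_n + copies_n[i]
        clusters[[k]] <- cl
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      clusters[[length(clusters) + 1L]] <- list(
        seed = seqs[i], strand = strand[i], seed_copies = total[i],
        members = i, copies_s = copies_s[i], copies_n = copies_n[i]
      )
    }
  }
  do.call(rbind, lapply(seq_along(clusters), function(k) {
    cl <- clusters[[k]]
    enr <- if (cl$copies_n > 0) cl$copies_s / cl$copies_n else Inf
    data.frame(
      cluster_id = sprintf("cl%03d", k), seed = cl$seed, strand = cl$strand,
      n_members = length(cl$members), copies_s = cl$copies_s,
      copies_n = cl$copies_n, enrichment = enr,
      enriched = is.finite(enr) && enr > fc_up || !is.finite(enr),
      infinite_enrichment = !is.finite(enr),
      stringsAsFactors = FALSE
    )
  }))
}
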