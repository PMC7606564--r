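## Per-read 5'/3' geometry: 2D TSS x TES histograms, full-length read
## fractions, and the S-vs-N truncation contrast.

#' Build per-gene 2D TSS x TES read histograms
#'
#' For every read assigned to a gene (5'-end within the gene's transcribed
#' span plus `upstream` nt), records the pair (tss, tes) of its 5'- and
#' 3'-end positions relative to the canonical TSS in transcript
#' orientation, and accumulates a sparse histogram with unit bins per gene
#' and group.
#'
#' @param reads BED-like read data.frame.
#' @param meta Sample sheet (`sample_id`, `group`).
#' @param annotation Validated annotation.
#' @param upstream Allowance upstream of the canonical TSS (default 50).
#' @return A data.frame `gene_id`, `group`, `tss`, `tes`, `count`.
#' @export
build_2d_profile <- function(reads, meta, annotation, upstream = 50L) {
  f5 <- read_five_prime(reads$start, reads$end, reads$strand)
  f3 <- read_three_prime(reads$start, reads$end, reads$strand)
  grp <- meta$group[match(reads$sample_id, meta$sample_id)]
  out <- vector("list", nrow(annotation))
  for (i in seq_len(nrow(annotation))) {
    g <- annotation[i, ]
    tss_rel <- tx_offset(f5, g$tss, g$strand)
    tes_rel <- tx_offset(f3, g$tss, g$strand)
    span <- tx_offset(g$tes, g$tss, g$strand)
    hit <- reads$chrom == g$chrom & reads$strand == g$strand &
      tss_rel >= -upstream & tss_rel <= span & tes_rel <= span + upstream
    if (!any(hit)) next
    tab <- stats::aggregate(
      list(count = rep(1L, sum(hit))),
      by = list(group = grp[hit], tss = tss_rel[hit], tes = tes_rel[hit]),
      FUN = sum
    )
    tab$gene_id <- g$gene_id
    out[[i]] <- tab[, c("gene_id", "group", "tss", "tes", "count")]
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(gene_id = character(0), group = character(0),
                      tss = integer(0), tes = integer(0), count = integer(0))
  }
  res
}

#' Full-length read fractions per gene and group
#'
#' A read is full-length when its 5'-end lies within `tol` nt of the
#' group's dominant (modal) TSS and its 3'-end within `tol` nt of the
#' annotated TES.  The reported `fraction` is the proportion of
#' full-length reads among reads sharing the dominant TSS
#' (`full_length / at_dominant`): conditioning on an identical 5'-end
#' isolates 3' truncation from TSS-usage differences between the groups.
#' The unconditional proportion is available as `full_length / total`.
#' Groups with no reads for a gene are omitted.
#'
#' @param profile 2D histogram from [build_2d_profile()].
#' @param annotation Validated annotation.
#' @param tol Agreement tolerance in nt (default 3).
#' @return A data.frame `gene_id`, `group`, `full_length`, `at_dominant`,
#'   `total`, `fraction`.
#' @export
full_length_fraction <- function(profile, annotation, tol = 3L) {
  if (nrow(profile) == 0L) {
    return(data.frame(gene_id = character(0), group = character(0),
                      full_length = integer(0), at_dominant = integer(0),
                      total = integer(0), fraction = numeric(0)))
  }
  span <- tx_offset(annotation$tes, annotation$tss, annotation$strand)
  names(span) <- annotation$gene_id
  parts <- split(profile, list(profile$gene_id, profile$group), drop = TRUE)
  rows <- lapply(parts, function(d) {
    total <- sum(d$count)
    tss_tab <- tapply(d$count, d$tss, sum)
    dom_tss <- as.integer(names(tss_tab)[which.max(tss_tab)])
    at_dom <- sum(d$count[abs(d$tss - dom_tss) <= tol])
    fl <- sum(d$count[abs(d$tss - dom_tss) <= tol &
                        abs(d$tes - span[d$gene_id[1]]) <= tol])
    data.frame(gene_id = d$gene_id[1], group = d$group[1],
               full_length = fl, at_dominant = at_dom, total = total,
               fraction = fl / at_dom, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$gene_id, out$group), ]
}

#' Truncation contrast normalised to non-enriched species
#'
#' For each gene with at least `min_reads` reads in both groups, forms the
#' per-gene ratio of full-length fractions `S/N`; the contrast `R` is the
#' median of these ratios over the enriched gene set divided by the median
#' over the non-enriched set.  Working per gene before aggregating cancels
#' gene-to-gene differences in transcript length (longer genes have
#' intrinsically lower full-length probability) that would otherwise leak
#' into a pooled ratio through group-specific gene weighting.  `R < 1`
#' indicates NAD-linked 3' truncation beyond what library handling
#' explains.  With an empty non-enriched set the unnormalised ratio is
#' returned with a warning.
#'
#' @param fractions Output of [full_length_fraction()].
#' @param enriched_ids,nonenriched_ids Character vectors of gene ids.
#' @param min_reads Minimum reads per gene and group (default 10).
#' @return A list: `R`, `ratio_enriched`, `ratio_nonenriched`,
#'   `n_enriched`, `n_nonenriched` (genes actually used).
#' @export
truncation_contrast <- function(fractions, enriched_ids, nonenriched_ids,
                                min_reads = 10L) {
  gene_ratios <- function(ids) {
    d <- fractions[fractions$gene_id %in% ids & fractions$at_dominant >= min_reads, ]
    s <- d[d$group == "S", ]; n <- d[d$group == "N", ]
    i <- match(s$gene_id, n$gene_id)
    ok <- !is.na(i) & n$fraction[i] > 0
    s$fraction[ok] / n$fraction[i][ok]
  }
  re <- gene_ratios(enriched_ids)
  if (!length(nonenriched_ids)) {
    warning("empty non-enriched set; returning unnormalised ratio")
    return(list(R = stats::median(re), ratio_enriched = stats::median(re),
                ratio_nonenriched = NA_real_, n_enriched = length(re),
                n_nonenriched = 0L))
  }
  rn <- gene_ratios(nonenriched_ids)
  list(R = stats::median(re) / stats::median(rn),
       ratio_enriched = stats::median(re),
       ratio_nonenriched = stats::median(rn),
       n_enriched = length(re), n_nonenriched = length(rn))
}
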