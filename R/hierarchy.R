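## Decapping-enzyme hierarchy inference over a knockout-strain lattice.
##
## Starting from the strain in which all decapping enzymes are deleted,
## enzymes are "reintroduced" one at a time.  A species supports the
## ordered path (first = e1, second = e2) when reintroducing e1 shifts its
## transcript leader (TLI beyond threshold at FDR < threshold: e1 removes a
## subset of TL variants) and reintroducing e2 then removes it from the
## enriched fraction, or at least halves its enrichment (e2 decaps the
## remaining variants).  Paths are scored by the number of such resolved
## species; no probabilistic model is fitted.

#' Species with a TL shift between two strains
#'
#' @param tli_table Output of [compute_tli()] for background strain vs the
#'   strain with one more enzyme.
#' @param tli_min TLI magnitude threshold (default 0.1).
#' @param fdr_max FDR threshold (default 0.1).
#' @return A data.frame `gene_id`, `tli`, `direction` for species passing
#'   both thresholds.
#' @export
tl_shift_species <- function(tli_table, tli_min = 0.1, fdr_max = 0.1) {
  if (nrow(tli_table) == 0L) {
    return(data.frame(gene_id = character(0), tli = numeric(0),
                      direction = character(0)))
  }
  keep <- !is.na(tli_table$fdr) & tli_table$fdr < fdr_max &
    abs(tli_table$tli) > tli_min
  d <- tli_table[keep, c("gene_id", "tli")]
  d$direction <- ifelse(d$tli > 0, "distal", "proximal")
  rownames(d) <- NULL
  d
}

#' Species resolved by the second enzyme
#'
#' Of the shifted species, keeps those that are enriched after the first
#' reintroduction but either lose the enriched verdict after the second or
#' show a fold-change drop of at least `r_min`.
#'
#' @param shifted Output of [tl_shift_species()].
#' @param enrich_one Enrichment table ([enrichment_test()]) for the strain
#'   with the first enzyme reintroduced.
#' @param enrich_two Enrichment table for the strain with both enzymes.
#' @param r_min Fold-change drop factor counting as "significantly
#'   reduced" (default 2).
#' @return Subset of `shifted` with an added `resolved_by` column
#'   (`"lost"` or `"reduced"`).
#' @export
resolved_species <- function(shifted, enrich_one, enrich_two, r_min = 2) {
  if (nrow(shifted) == 0L) {
    shifted$resolved_by <- character(0)
    return(shifted)
  }
  i1 <- match(shifted$gene_id, enrich_one$feature_id)
  i2 <- match(shifted$gene_id, enrich_two$feature_id)
  enr1 <- !is.na(i1) & enrich_one$verdict[i1] == "enriched"
  enr2 <- !is.na(i2) & enrich_two$verdict[i2] == "enriched"
  fc1 <- enrich_one$fc[i1]; fc2 <- enrich_two$fc[i2]
  fc2[is.na(fc2)] <- Inf
  lost <- enr1 & !enr2
  reduced <- enr1 & enr2 & (fc1 / fc2 >= r_min)
  out <- shifted[lost | reduced, , drop = FALSE]
  out$resolved_by <- ifelse(lost[lost | reduced], "lost", "reduced")
  rownames(out) <- NULL
  out
}

## Canonical key of a strain by its active enzyme set.
strain_key <- function(active) {
  if (!length(active)) "none" else paste(sort(active), collapse = "+")
}

#' Enumerate and score all ordered enzyme-reintroduction paths
#'
#' For every ordered pair of distinct enzymes (e1, e2), counts species
#' shifted upon reintroduction of e1 into the all-deleted background
#' (split by shift direction) and, of those, species resolved upon
#' additional reintroduction of e2.  Paths whose strains are missing from
#' the supplied tables are omitted with a warning.
#'
#' @param tli_list Named list: for each enzyme `e`, the [compute_tli()]
#'   table comparing the all-deleted strain (A) with the strain where only
#'   `e` is active (B).
#' @param enrich_list Named list of enrichment tables keyed by active
#'   enzyme set (`"e1"`, `"e1+e2"` with alphabetical order, via
#'   [strain_key()]).
#' @param enzymes Character vector of enzyme names.
#' @param tli_min,fdr_max,r_min Thresholds (defaults 0.1, 0.1, 2).
#' @return A data.frame, one row per ordered path: `first`, `second`,
#'   `n_shifted`, `n_distal`, `n_proximal`, `n_resolved`.
#' @export
enumerate_paths <- function(tli_list, enrich_list,
                            enzymes = c("Rai1", "Dxo1", "Npy1"),
                            tli_min = 0.1, fdr_max = 0.1, r_min = 2) {
  rows <- list()
  for (e1 in enzymes) for (e2 in setdiff(enzymes, e1)) {
    k1 <- strain_key(e1); k12 <- strain_key(c(e1, e2))
    if (is.null(tli_list[[e1]]) || is.null(enrich_list[[k1]]) ||
        is.null(enrich_list[[k12]])) {
      warning("missing tables for path ", e1, " -> ", e2, "; omitted")
      next
    }
    shifted <- tl_shift_species(tli_list[[e1]], tli_min = tli_min,
                                fdr_max = fdr_max)
    res <- resolved_species(shifted, enrich_list[[k1]], enrich_list[[k12]],
                            r_min = r_min)
    rows[[length(rows) + 1L]] <- data.frame(
      first = e1, second = e2, n_shifted = nrow(shifted),
      n_distal = sum(shifted$direction == "distal"),
      n_proximal = sum(shifted$direction == "proximal"),
      n_resolved = nrow(res), stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(first = character(0), second = character(0),
                      n_shifted = integer(0), n_distal = integer(0),
                      n_proximal = integer(0), n_resolved = integer(0))
  }
  out
}

#' Run the full hierarchy analysis on simulated strains
#'
#' Convenience wrapper: simulates (or accepts) per-strain read sets for the
#' all-deleted background, each single-enzyme strain and each two-enzyme
#' strain, computes the TLI tables and enrichment tables, and scores all
#' ordered paths.
#'
#' @param sim Output of [make_genome()]; its config must define strains for
#'   every needed active-enzyme set (see [hierarchy_strain_set()]).
#' @param enzymes Enzyme names (default the three configured ones).
#' @param tli_fdr FDR threshold for the shift step (default 0.1).
#' @param r_min Fold-change drop factor (default 2).
#' @return A list: `paths` (scored path table), `tli` (per-enzyme TLI
#'   tables), `enrich` (per-strain enrichment tables).
#' @export
hierarchy_analysis <- function(sim, enzymes = c("Rai1", "Dxo1", "Npy1"),
                               tli_fdr = 0.1, r_min = 2) {
  config <- sim$config
  need <- c("none", vapply(enzymes, strain_key, character(1)),
            unlist(lapply(enzymes, function(e1)
              lapply(setdiff(enzymes, e1), function(e2) strain_key(c(e1, e2))))))
  need <- unique(need)
  have <- vapply(config$strains, strain_key, character(1))
  missing <- setdiff(need, have)
  if (length(missing)) {
    stop("config lacks strains for active sets: ", paste(missing, collapse = ", "))
  }
  name_of <- function(key) names(config$strains)[match(key, have)]

  sim_data <- list()
  for (key in need) {
    nm <- name_of(key)
    run <- simulate_reads(sim, nm, groups = c("S", "N"))
    cm <- count_features(run$reads, sim$annotation)
    sim_data[[key]] <- list(
      s_reads = run$reads[grepl("_S_", run$reads$sample_id), ],
      enrich = enrichment_test(cm$counts, run$samples)
    )
  }
  tli_list <- lapply(stats::setNames(enzymes, enzymes), function(e) {
    compute_tli(sim_data[["none"]]$s_reads, sim_data[[strain_key(e)]]$s_reads,
                sim$annotation, fdr_max = tli_fdr)
  })
  enrich_list <- lapply(sim_data, `[[`, "enrich")
  paths <- enumerate_paths(tli_list, enrich_list, enzymes = enzymes,
                           fdr_max = tli_fdr, r_min = r_min)
  list(paths = paths, tli = tli_list, enrich = enrich_list)
}

#' Strain lattice covering all single and double enzyme reintroductions
#'
#' @param enzymes Enzyme names.
#' @return Named list of active-enzyme sets suitable for
#'   `sim_config(strains = ...)`: the all-deleted background, the three
#'   single-enzyme strains and the three two-enzyme strains.
#' @export
hierarchy_strain_set <- function(enzymes = c("Rai1", "Dxo1", "Npy1")) {
  sets <- list(triple_ko = character(0))
  for (e in enzymes) sets[[paste0("only_", e)]] <- e
  combs <- utils::combn(enzymes, 2, simplify = FALSE)
  for (cc in combs) sets[[paste(cc, collapse = "_")]] <- cc
  sets
}
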