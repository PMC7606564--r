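make_meta <- function(ids, groups) {
  data.frame(sample_id = ids, group = groups, stringsAsFactors = FALSE)
}

test_that("size factors recover depth scaling and match an external oracle", {
  set.seed(41)
  base <- matrix(rnbinom(5 * 3, mu = 50, size = 10), nrow = 5,
                 dimnames = list(paste0("f", 1:5), c("a", "b", "c")))
  doubled <- base
  doubled[, "b"] <- base[, "b"] * 2L
  sf <- size_factors(doubled)
  expect_equal(unname(sf["b"] / sf["a"]),
               2 * unname(size_factors(base)["b"] / size_factors(base)["a"]),
               tolerance = 1e-8)

  expect_equal(unname(size_factors(base[, 1, drop = FALSE])), 1)

  ## independent oracle: DESeq2's median-of-ratios implementation
  skip_if_not_installed("DESeq2")
  expect_equal(unname(size_factors(base)),
               unname(DESeq2::estimateSizeFactorsForMatrix(base)),
               tolerance = 1e-8)

  zero <- base
  zero[, 1] <- 0L
  zero[1, ] <- 0L
  expect_error(size_factors(zero * 0L), "pseudo-count")
})

test_that("enrichment verdicts follow the published thresholds exactly", {
  ids <- c("S1", "S2", "S3", "N1", "N2", "N3")
  meta <- make_meta(ids, rep(c("S", "N"), each = 3))

  ## identical S and N columns: FC = 1, ns
  cts <- matrix(rep(c(100L, 40L), each = 6), nrow = 2, byrow = TRUE,
                dimnames = list(c("f1", "f2"), ids))
  enr <- enrichment_test(cts, meta)
  expect_equal(enr$fc, c(1, 1))
  expect_equal(enr$verdict, c("ns", "ns"))

  ## strong planted enrichment is called (embedded among null features so
  ## median-of-ratios normalisation is anchored)
  set.seed(46)
  null_block <- matrix(rpois(10 * 6, 50), nrow = 10,
                       dimnames = list(paste0("n", 1:10), ids))
  cts2 <- rbind(f1 = c(100L, 110L, 90L, 10L, 9L, 11L), null_block)
  enr2 <- enrichment_test(cts2, meta)
  i1 <- which(enr2$feature_id == "f1")
  expect_equal(enr2$verdict[i1], "enriched")
  expect_gt(enr2$fc[i1], 5)
  expect_lt(enr2$p_value[i1], 1e-6)

  ## at moderate signal the Wald p agrees with an exact rate-ratio
  ## (conditional binomial) oracle within an order of magnitude
  cts4 <- rbind(f1 = c(20L, 18L, 22L, 12L, 10L, 11L), null_block)
  enr4 <- enrichment_test(cts4, meta)
  i1 <- which(enr4$feature_id == "f1")
  oracle_p <- stats::binom.test(sum(cts4[1, 1:3]), sum(cts4[1, ]),
                                p = 0.5)$p.value
  expect_lt(abs(log10(enr4$p_value[i1]) - log10(oracle_p)), 1)

  ## all-zero feature: p = 1, ns
  cts3 <- rbind(f1 = rep(0L, 6), f2 = c(30L, 28L, 31L, 10L, 12L, 9L))
  colnames(cts3) <- ids
  enr3 <- enrichment_test(cts3, meta)
  expect_equal(enr3$p_value[1], 1)
  expect_equal(enr3$verdict[1], "ns")

  expect_error(enrichment_test(cts2[, c(1, 4)],
                               make_meta(ids[c(1, 4)], c("S", "N"))),
               ">= 2 replicates")
})

test_that("fold-change gate is strict at 1.414", {
  ids <- c("S1", "S2", "S3", "N1", "N2", "N3")
  meta <- make_meta(ids, rep(c("S", "N"), each = 3))
  ## large counts at a true ratio just under the gate: tiny p, FC ~ 1.40
  n_val <- 20000L
  s_val <- as.integer(round(n_val * 1.40))
  cts <- rbind(f1 = c(rep(s_val, 3), rep(n_val, 3)),
               f2 = c(rep(1000L, 6)))
  colnames(cts) <- ids
  enr <- enrichment_test(cts, meta)
  i <- which(enr$feature_id == "f1")
  expect_lt(enr$p_value[i], 0.05)
  expect_lt(enr$fc[i], 1.414)
  expect_equal(enr$verdict[i], "ns")
})

test_that("type-I error of the enrichment test is near nominal on null data", {
  set.seed(47)
  ids <- c("S1", "S2", "S3", "N1", "N2", "N3")
  meta <- make_meta(ids, rep(c("S", "N"), each = 3))
  ## null counts at the coverage the -ADPRC background produces
  ps <- unlist(lapply(1:6, function(rep) {
    mu <- stats::runif(400, 4, 15)
    cts <- matrix(stats::rpois(400 * 6, rep(mu, 6)), nrow = 400,
                  dimnames = list(sprintf("f%03d", 1:400), ids))
    enrichment_test(cts, meta)$p_value
  }))
  expect_gt(mean(ps < 0.05), 0.02)
  expect_lt(mean(ps < 0.05), 0.08)
})

test_that("TPM columns sum to one million with length normalisation", {
  one <- matrix(c(7L, 3L), nrow = 1, dimnames = list("f1", c("a", "b")))
  expect_equal(unname(tpm(one, 500)[1, ]), c(1e6, 1e6))

  two <- matrix(c(10L, 10L), nrow = 2, dimnames = list(c("f1", "f2"), "a"))
  tt <- tpm(two, c(1000, 2000))
  expect_equal(unname(tt["f1", 1] / tt["f2", 1]), 2)

  set.seed(42)
  rnd <- matrix(rpois(20, 30), nrow = 10,
                dimnames = list(paste0("f", 1:10), c("a", "b")))
  expect_equal(unname(colSums(tpm(rnd, sample(200:900, 10)))), c(1e6, 1e6),
               tolerance = 1e-9)
  expect_error(tpm(rnd, c(0, rep(100, 9))), "positive")
})

test_that("TPM-integrated NAD ratios scale linearly and clip to [0, 1]", {
  tn <- c(g1 = 100, g2 = 200, g3 = 0)
  ta <- c(g1 = 100, g2 = 100, g3 = 50)
  r <- nad_ratio_tpm(0.03, tn, ta)
  expect_equal(r$ratio[r$feature_id == "g1"], 0.03)
  expect_equal(r$ratio[r$feature_id == "g2"], 0.06)
  r2 <- nad_ratio_tpm(0.02, tn, ta)
  expect_equal(r2$ratio[r2$feature_id == "g2"], 0.04)
  expect_error(nad_ratio_tpm(0, tn, ta), "positive")
  ## features with zero all-cap TPM are omitted
  ta0 <- c(g1 = 100, g2 = 0)
  expect_false("g2" %in% suppressMessages(
    nad_ratio_tpm(0.03, tn[1:2], ta0))$feature_id)
})

test_that("NAD ratios are invariant to library depth rescaling", {
  set.seed(43)
  cts <- matrix(rpois(40, 100), nrow = 20,
                dimnames = list(sprintf("g%02d", 1:20), c("S1", "T1")))
  lens <- rep(186, 20)
  t1 <- tpm(cts, lens)
  r1 <- nad_ratio_tpm(0.05, t1[, "S1"], t1[, "T1"])
  cts2 <- cts
  cts2[, "S1"] <- cts2[, "S1"] * 7L
  t2 <- tpm(cts2, lens)
  r2 <- nad_ratio_tpm(0.05, t2[, "S1"], t2[, "T1"])
  expect_equal(r1$ratio, r2$ratio, tolerance = 1e-12)
})

test_that("qPCR ratio follows the capture-minus-background formula", {
  expect_equal(nad_ratio_qpcr(10, 2, 88), 8 / 98)
  expect_equal(nad_ratio_qpcr(5, 0, 95), 0.05)
  expect_equal(nad_ratio_qpcr(3, 7, 90), 0)      # background exceeds signal
  expect_true(is.na(nad_ratio_qpcr(0, 0, 0)))    # undefined denominator
  expect_error(nad_ratio_qpcr(-1, 0, 1), "non-negative")
})

test_that("small-RNA clustering respects identity, strand and copy rules", {
  ## identical sequences merge into one cluster
  cl1 <- cluster_small_rnas(c("ACGTACGTACGT", "ACGTACGTACGT"),
                            c("+", "+"), c(30, 20), c(10, 5))
  expect_equal(nrow(cl1), 1L)
  expect_equal(cl1$copies_s, 50)
  expect_equal(cl1$enrichment, 50 / 15)

  ## 7/12 identity (58%) falls below the 60% threshold
  a <- "AAAAAAAAAAAA"
  b <- "CCCCCAAAAAAA"   # 7 matches of 12 at zero offset
  expect_equal(nrow(cluster_small_rnas(c(a, b), c("+", "+"),
                                       c(10, 10), c(1, 1))), 2L)

  ## same sequence, opposite strands: separate
  expect_equal(nrow(cluster_small_rnas(c(a, a), c("+", "-"),
                                       c(10, 10), c(1, 1))), 2L)

  ## copy-number ratio of 100 exceeds the max of 50: separate
  expect_equal(nrow(cluster_small_rnas(c(a, a), c("+", "+"),
                                       c(990, 9), c(10, 1))), 2L)

  ## N = 0 is reported as infinite enrichment, flagged
  cl0 <- cluster_small_rnas("ACGTACGTACGT", "+", 25, 0)
  expect_true(cl0$infinite_enrichment)
  expect_true(cl0$enriched)
})

test_that("BH adjustment is monotone and matches the step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 4)), rep(1, 4))
  expect_error(bh_fdr(c(0.1, NaN)), "NaN")

  brute_bh <- function(p) {
    n <- length(p)
    o <- order(p)
    adj <- p[o] * n / seq_len(n)
    adj <- rev(cummin(rev(adj)))
    out <- numeric(n)
    out[o] <- pmin(adj, 1)
    out
  }
  set.seed(44)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))
    expect_equal(bh_fdr(p), brute_bh(p), tolerance = 1e-12)
    expect_true(all(diff(bh_fdr(p)[order(p)]) >= -1e-12))
  }
})
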