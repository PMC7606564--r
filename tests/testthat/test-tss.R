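## Independent re-implementation of the greedy cluster search, kept
## deliberately naive: scan every window start, take the best, delete,
## repeat.
oracle_clusters <- function(tl, group, window = 18L, min_reads = 2L) {
  df <- data.frame(tl = tl, group = group)
  out <- NULL
  repeat {
    if (nrow(df) == 0) break
    starts <- 0:max(df$tl)
    sums <- vapply(starts, function(s)
      sum(df$tl >= s & df$tl <= s + window - 1L), integer(1))
    if (max(sums) < min_reads) break
    s <- starts[which.max(sums)]
    inside <- df$tl >= s & df$tl <= s + window - 1L
    tab <- table(df$tl[inside])
    rep_tl <- min(as.integer(names(tab)[tab == max(tab)]))
    out <- rbind(out, data.frame(
      tl = rep_tl,
      count_S = sum(inside & df$group == "S"),
      count_N = sum(inside & df$group == "N")))
    df <- df[!inside, , drop = FALSE]
  }
  if (is.null(out)) return(out)
  out[order(out$tl), ]
}

test_that("greedy TSS cluster detection matches a naive oracle", {
  ## degenerate: all starts at one position
  cl <- detect_tss_clusters(rep(37L, 10), rep(c("S", "N"), 5))
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$tl, 37L)
  expect_equal(cl$count_S + cl$count_N, 10L)

  ## two spikes 40 nt apart: two clusters, sorted by TL
  tl <- c(rep(20L, 30), rep(60L, 20))
  grp <- rep("S", 50)
  cl2 <- detect_tss_clusters(tl, grp)
  expect_equal(cl2$tl, c(20L, 60L))
  expect_equal(cl2$count_S, c(30L, 20L))

  ## random scatter: equality with the oracle across many draws
  set.seed(51)
  for (i in 1:60) {
    n <- sample(4:60, 1)
    tl <- sample(0:70, n, replace = TRUE)
    grp <- sample(c("S", "N"), n, replace = TRUE)
    got <- detect_tss_clusters(tl, grp)
    want <- oracle_clusters(tl, grp)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      rownames(got) <- rownames(want) <- NULL
      expect_equal(got, want)
    }
  }
})

## Trend statistic by brute-force per-observation expansion.
oracle_trend <- function(s, b, tl, normalize = TRUE) {
  if (normalize && sum(b) > 0 && sum(s) > 0) b <- round(b * sum(s) / sum(b))
  x <- c(rep(2, sum(s)), rep(1, sum(b)))
  y <- c(rep(tl, s), rep(tl, b))
  n <- length(x)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NULL)
  r <- stats::cor(x, y)
  m2 <- (n - 1) * r^2
  list(n = n, r = r, m2 = m2, p = stats::pchisq(m2, 1, lower.tail = FALSE))
}

test_that("trend test equals the per-observation expansion", {
  ## independence: r = 0, p = 1
  t1 <- linear_trend_test(c(5, 5), c(5, 5), c(50, 100), n_min = 10)
  expect_equal(t1$r, 0)
  expect_equal(t1$m2, 0)
  expect_equal(t1$p, 1)

  ## perfect segregation of 30 observations: |r| = 1, M2 = 29
  t2 <- linear_trend_test(c(15, 0), c(0, 15), c(50, 100))
  expect_equal(abs(t2$r), 1, tolerance = 1e-12)
  expect_equal(t2$m2, 29, tolerance = 1e-9)
  expect_equal(t2$p, stats::pchisq(29, 1, lower.tail = FALSE))

  ## mixed table equals the expansion to machine precision
  t3 <- linear_trend_test(c(10, 5), c(5, 10), c(40, 90), n_min = 10)
  o3 <- oracle_trend(c(10, 5), c(5, 10), c(40, 90))
  expect_equal(t3$r, o3$r, tolerance = 1e-12)
  expect_equal(t3$m2, o3$m2, tolerance = 1e-12)
})

test_that("trend test gates and degenerate tables are flagged untestable", {
  expect_false(linear_trend_test(c(10, 4), c(8, 6), c(30, 60))$testable)  # n < 30
  expect_false(linear_trend_test(c(40), c(35), c(50))$testable)           # 1 cluster
  expect_false(linear_trend_test(c(20, 20), c(0, 0), c(30, 60),
                                 normalize = FALSE)$testable)             # no N row
})

test_that("sharp-A calls follow the base and sharp-value rules", {
  ## synthetic gene on the plus strand with controlled base identities
  chars <- rep("T", 400)
  ann <- data.frame(gene_id = "g1", chrom = "c1", strand = "+",
                    tss = 100L, tls = 160L, tes = 350L, class = "mRNA",
                    stringsAsFactors = FALSE)
  mk_genome <- function(base_at_tss) {
    ch <- chars
    ch[121] <- base_at_tss   # genomic position 120, 0-based
    c(c1 = paste(ch, collapse = ""))
  }
  mk_reads <- function(n_at, n_up) {
    rbind(reads_at(rep(120L, n_at), "+", "S1", chrom = "c1"),
          if (n_up > 0) reads_at(rep(119L, n_up), "+", "S1", chrom = "c1"))
  }
  ## 40 starts at +1 vs 5 at -1: sharp 8, A: called
  c1 <- call_sharp_a(mk_reads(40, 5), ann, mk_genome("A"))
  expect_equal(c1$sharp_value, 8)
  expect_equal(c1$tss_pos, 120L)
  expect_true(c1$is_sharp_a)
  ## sharp value 3 fails the > 4 rule even on an A
  c2 <- call_sharp_a(mk_reads(12, 4), ann, mk_genome("A"))
  expect_equal(c2$sharp_value, 3)
  expect_false(c2$is_sharp_a)
  ## G with sharp 10: base rule fails
  c3 <- call_sharp_a(mk_reads(40, 4), ann, mk_genome("G"))
  expect_equal(c3$base, "G")
  expect_false(c3$is_sharp_a)
  ## zero upstream count: denominator floored at 1
  c4 <- call_sharp_a(mk_reads(40, 0), ann, mk_genome("A"))
  expect_equal(c4$sharp_value, 40)
})

test_that("promoter matrices quantify planted and absent information", {
  ## 25 identical windows: near-maximal IC, consensus AAG at +1..+3
  win <- paste0(strrep("T", 10), "AAG", strrep("A", 8))
  chars <- strsplit(strrep(win, 30), "")[[1]]
  genome <- c(c1 = paste(chars, collapse = ""))
  calls <- data.frame(gene_id = sprintf("g%02d", 1:25),
                      tss_pos = 21 * (0:24) + 10L)
  ann <- data.frame(gene_id = calls$gene_id, chrom = "c1", strand = "+",
                    tss = calls$tss_pos, tls = calls$tss_pos + 30L,
                    tes = calls$tss_pos + 100L, class = "mRNA",
                    stringsAsFactors = FALSE)
  pm <- promoter_matrix(calls, ann, genome)
  expect_gt(min(pm$ic), 1.7)
  expect_equal(substr(pm$consensus, 11, 13), "AAG")

  ## uniform random windows: IC stays near zero
  set.seed(52)
  genome_rnd <- c(c1 = random_dna(1000 * 21))
  calls_rnd <- data.frame(gene_id = sprintf("r%04d", 1:1000),
                          tss_pos = 21 * (0:999) + 10L)
  ann_rnd <- data.frame(gene_id = calls_rnd$gene_id, chrom = "c1",
                        strand = "+", tss = calls_rnd$tss_pos,
                        tls = calls_rnd$tss_pos + 30L,
                        tes = calls_rnd$tss_pos + 100L, class = "mRNA",
                        stringsAsFactors = FALSE)
  pm_rnd <- promoter_matrix(calls_rnd, ann_rnd, genome_rnd)
  expect_lt(max(pm_rnd$ic), 0.2)
  expect_equal(unname(colSums(pm_rnd$pfm)), rep(1, 21), tolerance = 1e-12)
})

test_that("TSS shifts classify direction against both reference kinds", {
  ann <- tiny_annotation()[1, ]
  meta <- data.frame(sample_id = c("S1", "N1"), group = c("S", "N"),
                     stringsAsFactors = FALSE)
  ## identical distributions: delta 0, direction none
  r_same <- rbind(reads_at(rep(110L, 50), "+", "S1"),
                  reads_at(rep(110L, 50), "+", "N1"))
  sh <- tss_shift_vs_reference(r_same, meta, ann, reference = "N")
  expect_equal(sh$delta, 0)
  expect_equal(sh$direction, "none")

  ## S initiates 30 nt upstream of the N reference: distal
  r_shift <- rbind(reads_at(rep(80L, 50), "+", "S1"),
                   reads_at(rep(110L, 50), "+", "N1"))
  sh2 <- tss_shift_vs_reference(r_shift, meta, ann, reference = "N")
  expect_equal(sh2$delta, 30)
  expect_equal(sh2$direction, "distal")

  ## against the annotated canonical TSS (point reference, sign test)
  sh3 <- tss_shift_vs_reference(r_shift, meta, ann, reference = "canonical")
  expect_equal(sh3$delta, 70 - 50)   # TL 70 vs canonical TL 50
  expect_equal(sh3$direction, "distal")
})

test_that("TLI is antisymmetric and scales shift over window length", {
  ann <- tiny_annotation()[1, ]   # utr 50, window W = 100
  a <- reads_at(rep(c(100L, 110L), each = 40), "+", "A1")
  b <- reads_at(rep(c(80L, 90L), each = 40), "+", "B1")   # 20 nt upstream
  tli_ab <- compute_tli(a, b, ann)
  tli_ba <- compute_tli(b, a, ann)
  expect_equal(tli_ab$tli, 20 / 100)
  expect_equal(tli_ab$tli, -tli_ba$tli)
  expect_equal(tli_ab$direction, "distal")
  expect_equal(tli_ba$direction, "proximal")

  same <- compute_tli(a, a, ann)
  expect_equal(same$tli, 0)
  expect_equal(same$direction, "none")
})

test_that("trend p-values are uniform under a simulated null", {
  set.seed(53)
  ps <- replicate(400, {
    k <- sample(4:6, 1)
    pos <- sample(0:120, k)
    pr <- as.numeric(stats::rgamma(k, 1)); pr <- pr / sum(pr)
    s <- sample(pos, 150, TRUE, pr)
    n <- sample(pos, 150, TRUE, pr)
    cl <- detect_tss_clusters(c(s, n), rep(c("S", "N"), each = 150))
    linear_trend_test(cl$count_S, cl$count_N, cl$tl)$p
  })
  ps <- ps[!is.na(ps)]
  expect_lt(suppressWarnings(stats::ks.test(ps, "punif")$statistic), 0.08)
})
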