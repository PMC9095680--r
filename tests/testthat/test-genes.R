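test_that("variant-to-gene assignment uses an inclusive flanking window", {
  genes <- data.frame(chrom = "1", start = c(1000000L, 1900000L),
                      end = c(1100000L, 2000000L), name = c("g1", "g2"))
  pos <- c(1000000L - 500000L,      # exactly at the window edge: assigned
           1500000L,                # inside both windows: assigned to both
           5000000L)                # 3 Mb past g2: unassigned
  s <- sumstats(data.frame(snp = c("a", "b", "c"), chrom = "1", pos = pos,
                           a1 = "A", a2 = "G", z = 1, p = 0.3, n = 100), "t")
  asg <- assign_snps(genes, s, window_kb = 500)
  expect_true("a" %in% asg$g1)
  expect_true("b" %in% asg$g1 && "b" %in% asg$g2)
  expect_false("c" %in% unlist(asg))
})

test_that("gene test matches chi-square closed forms", {
  expect_equal(gene_test(3)$p_gene, pchisq(9, 1, lower.tail = FALSE),
               tolerance = 1e-9)
  z <- c(1.3, -0.2, 2.4, 0.7)
  expect_equal(gene_test(z, diag(4))$p_gene,
               pchisq(sum(z^2), 4, lower.tail = FALSE), tolerance = 1e-9)
  # two perfectly correlated variants: null 2*chi2_1
  g <- gene_test(c(2, 2), matrix(1, 2, 2))
  expect_equal(g$stat, 8)
  expect_equal(g$p_gene, pchisq(4, 1, lower.tail = FALSE), tolerance = 1e-9)
})

test_that("gene test tail matches Monte-Carlo under correlated nulls", {
  set.seed(13)
  for (k in 1:6) {
    m <- sample(2:8, 1)
    R <- random_corr(m, seed = 100 + k)
    U <- chol(R)
    zs <- crossprod(U, matrix(rnorm(m * 20000), m))
    stat <- qchisq(0.9, df = m) * mean(diag(R))  # a moderate threshold
    p_num <- pleioscan:::weighted_chisq_tail(
      stat, eigen(R, symmetric = TRUE, only.values = TRUE)$values)
    p_mc <- mean(colSums(zs^2) > stat)
    mc_se <- sqrt(p_mc * (1 - p_mc) / 20000)
    expect_lt(abs(p_num - p_mc), 3 * mc_se + 1e-4)
  }
})

test_that("binomial enrichment is exact and monotone", {
  expect_equal(binomial_enrichment(c("a", "b"), c("a", "b"), 4)$p_binom, 0.25)
  expect_equal(binomial_enrichment(c("a", "b"), c("a", "x", "y"), 4)$p_binom,
               0.875)
  # no overlap: p = 1 (whole support)
  expect_equal(binomial_enrichment(c("a"), c("x", "y"), 10)$p_binom, 1)
  # monotone decreasing in k_both at fixed k_trait
  G <- 1000
  disease <- sprintf("d%d", 1:100)
  ps <- vapply(0:5, function(k) {
    trait <- c(disease[seq_len(k)], sprintf("x%d", seq_len(5 - k)))
    binomial_enrichment(disease, trait, G)$p_binom
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_error(binomial_enrichment(c("a"), character(0), 10), "empty")
})

test_that("weighted Stouffer combination matches the closed form", {
  st <- stouffer_combine(pnorm(-4), pnorm(-3))
  expect_equal(st$combined_z, 7 / sqrt(2), tolerance = 1e-9)
  st2 <- stouffer_combine(pnorm(-5), pnorm(-c(2, 3)))
  expect_equal(st2$combined_z, 15 / sqrt(6), tolerance = 1e-9)
  st3 <- stouffer_combine(0.5, c(0.5, 0.5, 0.5))
  expect_equal(st3$combined_z, 0)
  expect_equal(st3$combined_p, 0.5)
  # disease weight equals the number of included proteins: equal pull
  expect_equal(st2$w_disease, 2)
  expect_error(stouffer_combine(0, 0.5), "strictly")
  expect_error(stouffer_combine(0.5, 1), "strictly")
})

test_that("the combined analysis declares (n_traits + 1) x G tests", {
  # the 15-protein / 18,236-gene configuration gives the printed 291,776
  expect_equal((15 + 1) * 18236, 291776)
  d_scan <- data.frame(gene = c("g1", "g2"), n_snps = 2, stat = c(40, 1),
                       p_gene = c(1e-9, 0.7), p_bh = c(2e-9, 0.7))
  p_scan <- list(
    p1 = data.frame(gene = c("g1", "g2"), n_snps = 2, stat = c(30, 2),
                    p_gene = c(1e-7, 0.5), p_bh = c(2e-7, 0.5)),
    p2 = data.frame(gene = c("g1", "g2"), n_snps = 2, stat = c(3, 2),
                    p_gene = c(0.2, 0.5), p_bh = c(0.3, 0.5)))
  out <- combined_gene_analysis(d_scan, p_scan, G = 18236)
  expect_equal(attr(out, "n_tests"), 3 * 18236)
  expect_equal(nrow(out), 1L)           # only g1 passes the gate
  expect_equal(out$n_proteins, 1L)      # only p1 contributes
  st <- stouffer_combine(1e-9, 1e-7)
  expect_equal(out$combined_p, st$combined_p, tolerance = 1e-12)
})

test_that("gene scan flags known strong genes in simulated data", {
  fx <- planted_locus_pair(6, shared = TRUE, seed = 51)
  genes <- data.frame(chrom = fx$loci$chrom,
                      start = fx$loci$start, end = fx$loci$end,
                      name = sprintf("gene%d", seq_len(nrow(fx$loci))))
  scan <- gene_scan(fx$s1, genes, fx$blocks, window_kb = 0)
  expect_equal(nrow(scan), 6L)
  expect_true(all(scan$p_gene < 0.01))  # planted z = 8 at variant 10 of 50
  # bonferroni significance implies BH significance
  bonf <- scan$p_gene <= 0.05 / nrow(scan)
  expect_true(all(scan$p_bh[bonf] <= 0.05))
})
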