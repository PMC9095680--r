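make_block <- function(R, chrom = "1", pos0 = 1000L, prefix = "rs") {
  m <- nrow(R)
  ld_block(data.frame(snp = sprintf("%s%d", prefix, seq_len(m)),
                      chrom = chrom, pos = pos0 + (seq_len(m) - 1L) * 1000L,
                      a1 = "A", a2 = "G", freq = 0.3), R)
}

test_that("ld scores sum squared within-block correlations", {
  # identity block: every score 1
  b1 <- make_block(diag(4))
  expect_equal(ld_scores(list(b1))$ld_score, rep(1, 4))
  # 2-SNP block at r = 0.5: both scores 1.25
  b2 <- make_block(matrix(c(1, .5, .5, 1), 2), prefix = "q")
  expect_equal(ld_scores(list(b2))$ld_score, c(1.25, 1.25))
  # 3-SNP block, r12 = 1, others 0: scores 2, 2, 1
  R3 <- diag(3); R3[1, 2] <- R3[2, 1] <- 1
  b3 <- make_block(R3, prefix = "w")
  expect_equal(ld_scores(list(b3))$ld_score, c(2, 2, 1))
  # every variant in its own block scores >= 1
  expect_true(all(ld_scores(list(b1, b2, b3))$ld_score >= 1 - 1e-8))
  # non-disjoint blocks rejected
  expect_error(ld_scores(list(b1, b1)), "disjoint")
})

test_that("ld_block validates its correlation matrix", {
  snps <- data.frame(snp = c("a", "b"), chrom = "1", pos = c(1L, 2L))
  expect_error(ld_block(snps, matrix(c(1, .5, .4, 1), 2)), "symmetric")
  expect_error(ld_block(snps, matrix(c(2, 0, 0, 1), 2)), "diagonal")
  expect_error(ld_block(snps, matrix(c(1, 1.5, 1.5, 1), 2)), "eigenvalue")
})

test_that("clumping follows the greedy smallest-p rule", {
  # spec scenario: r2(1,2) = 0.5, other pairs 0.05; SNP2 removed by SNP1
  r <- sqrt(c(0.5, 0.05, 0.05))
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- r[1]
  R[1, 3] <- R[3, 1] <- r[2]
  R[2, 3] <- R[3, 2] <- r[3]
  b <- make_block(R)
  s <- toy_sumstats(c(5.73, 4.42, 3.29))  # p approx 1e-8, 1e-5, 1e-3
  expect_equal(sort(clump(s, list(b))), c("rs1", "rs3"))

  # mutually uncorrelated: everything kept
  s4 <- toy_sumstats(c(1, 2, 3, 4))
  expect_setequal(clump(s4, list(make_block(diag(4)))), s4$data$snp)

  # perfect proxies with tied p: exactly one kept, tie broken by position
  Rp <- matrix(c(1, 1, 1, 1), 2)
  bp <- make_block(Rp)
  sp <- toy_sumstats(c(3.72, -3.72))
  expect_equal(clump(sp, list(bp)), "rs1")

  # variants absent from the reference index themselves
  s_extra <- toy_sumstats(c(1, 2, 3))
  s_extra$data$snp[3] <- "not_in_ref"
  kept <- clump(s_extra, list(make_block(Rp)))
  expect_true("not_in_ref" %in% kept)
})

test_that("clump matches the brute-force greedy oracle on random instances", {
  set.seed(42)
  for (rep in 1:200) {
    m <- sample(3:50, 1)
    b <- make_block(random_corr(m, seed = rep))
    R <- b$R   # named copy shared by implementation and oracle
    # random p-values with occasional ties; window sometimes binding
    p <- round(runif(m), sample(c(2, 6), 1))
    p[p == 0] <- 0.5
    window_kb <- sample(c(2, 5, 10000), 1)
    r2_max <- runif(1, 0.05, 0.8)
    d <- b$snps
    d$p <- p
    s <- sumstats(data.frame(d[c("snp", "chrom", "pos", "a1", "a2")],
                             z = qnorm(p / 2), p = p, n = 1000), "t")
    got <- clump(s, list(b), r2_max = r2_max, window_kb = window_kb)
    want <- clump_oracle(s$data, function(i, j) R[i, j]^2,
                         r2_max, window_kb * 1000)
    expect_equal(got, want, info = paste("instance", rep))
    # pairwise validity: no kept pair both linked and within the window
    if (length(got) > 1) {
      pos <- d$pos[match(got, d$snp)]
      for (i in seq_along(got)) for (j in seq_along(got)) {
        if (i < j)
          expect_false(R[got[i], got[j]]^2 >= r2_max &&
                         abs(pos[i] - pos[j]) <= window_kb * 1000)
      }
    }
    # every removed variant is linked to a kept index with <= its p
    removed <- setdiff(d$snp, got)
    for (snp in removed) {
      culprit <- vapply(got, function(k)
        R[k, snp]^2 >= r2_max &&
          abs(d$pos[d$snp == k] - d$pos[d$snp == snp]) <= window_kb * 1000 &&
          p[d$snp == k] <= p[d$snp == snp], logical(1))
      expect_true(any(culprit), info = snp)
    }
  }
})

test_that("ld blocks survive a write/read round trip", {
  spec <- arch_spec(n_blocks = 2, snps_per_block = 5, ld_decay = 0.6, seed = 3)
  blocks <- simulate_ld(spec)
  dir <- withr::local_tempdir()
  write_ld_blocks(blocks, dir)
  back <- read_ld_blocks(dir)
  expect_equal(length(back), 2L)
  expect_equal(back[[1]]$snps$snp, blocks[[1]]$snps$snp)
  expect_equal(unname(back[[1]]$R), unname(blocks[[1]]$R), tolerance = 1e-12)
})
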