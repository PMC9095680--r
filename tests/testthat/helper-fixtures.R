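# shared fixtures and independent oracles used across test files

# small hand-built sumstats
toy_sumstats <- function(z = c(1.5, -2.0, 0.3), trait = "toy") {
  m <- length(z)
  sumstats(data.frame(
    snp = sprintf("rs%d", seq_len(m)), chrom = "1",
    pos = seq_len(m) * 1000L, a1 = "A", a2 = "G",
    z = z, p = 2 * pnorm(-abs(z)), n = 10000), trait)
}

# brute-force greedy clumping oracle: literal restatement of the procedure
# with an explicit pairwise r2 lookup, independent of the package's block
# bookkeeping
clump_oracle <- function(d, r2_lookup, r2_max, window_bp) {
  remaining <- d[order(d$p, d$chrom, d$pos, d$snp), , drop = FALSE]
  kept <- character(0)
  while (nrow(remaining) > 0L) {
    idx <- remaining[1L, ]
    kept <- c(kept, idx$snp)
    drop <- logical(nrow(remaining))
    for (i in seq_len(nrow(remaining))) {
      r2 <- r2_lookup(idx$snp, remaining$snp[i])
      drop[i] <- r2 >= r2_max &&
        remaining$chrom[i] == idx$chrom &&
        abs(remaining$pos[i] - idx$pos) <= window_bp
    }
    drop[1L] <- TRUE
    remaining <- remaining[!drop, , drop = FALSE]
  }
  kept
}

# random positive-definite correlation matrix
random_corr <- function(m, seed) {
  set.seed(seed)
  A <- matrix(rnorm(m * (m + 2)), m + 2, m)
  C <- cov2cor(crossprod(A))
  C
}

# build a pair of traits with one causal variant per AR(1) locus, either at
# the same position (shared) or 30 variants apart (r ~ 0.9^30 < 0.1)
planted_locus_pair <- function(n_loci, shared, seed, z0 = 8, n = 50000,
                               snps_per_block = 50, ld_decay = 0.9) {
  spec <- arch_spec(n_blocks = n_loci, snps_per_block = snps_per_block,
                    ld_decay = ld_decay, seed = seed)
  blocks <- simulate_ld(spec)
  U <- chol(blocks[[1L]]$R)
  set.seed(seed + 1L)
  snps_all <- do.call(rbind, lapply(blocks, `[[`, "snps"))
  z1 <- z2 <- numeric(0)
  for (b in blocks) {
    m <- nrow(b$snps)
    j <- 10L
    k <- if (shared) j else 40L
    z1 <- c(z1, b$R[, j] * z0 + drop(crossprod(U, rnorm(m))))
    z2 <- c(z2, b$R[, k] * z0 + drop(crossprod(U, rnorm(m))))
  }
  mk <- function(z, id)
    sumstats(data.frame(snp = snps_all$snp, chrom = snps_all$chrom,
                        pos = snps_all$pos, a1 = "A", a2 = "G", z = z,
                        p = 2 * pnorm(-abs(z)), n = n, maf = snps_all$freq),
             id)
  loci <- do.call(rbind, lapply(blocks, function(b)
    data.frame(chrom = b$interval$chrom, start = b$interval$start,
               end = b$interval$end, name = b$name)))
  list(s1 = mk(z1, "t1"), s2 = mk(z2, "t2"), loci = loci, blocks = blocks)
}

# one LCV-scale simulated pair; independent variants so LD scores are 1
lcv_sim <- function(topology, seed, rg = 0.5, m_blocks = 400, h2 = 0.3,
                    n = 50000) {
  spec <- arch_spec(n_blocks = m_blocks, snps_per_block = 50, ld_decay = 0,
                    n_causal_frac = 0.05, h2_trait1 = h2, h2_trait2 = h2,
                    n1 = n, n2 = n, topology = topology, rg_target = rg,
                    seed = seed)
  blocks <- simulate_ld(spec)
  list(sim = simulate_pair(spec, blocks), scores = ld_scores(blocks))
}
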