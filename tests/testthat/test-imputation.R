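two_snp_block <- function(r, prefix = "rs") {
  ld_block(data.frame(snp = paste0(prefix, 1:2), chrom = "1",
                      pos = c(1000L, 2000L), a1 = "A", a2 = "G", freq = 0.3),
           matrix(c(1, r, r, 1), 2))
}

test_that("scalar imputation follows the conditional-expectation formula", {
  # perfect proxy: value passes through, quality 1
  b1 <- two_snp_block(1 - 1e-12)
  out1 <- impute_block(c(rs1 = 2.4), b1, "rs2", ridge = 0)
  expect_equal(out1$z_imputed, 2.4, tolerance = 1e-6)
  expect_equal(out1$r2_pred, 1, tolerance = 1e-6)
  # r = 0.5: z halves, quality 0.25
  b2 <- two_snp_block(0.5)
  out2 <- impute_block(c(rs1 = 2.0), b2, "rs2", ridge = 0)
  expect_equal(out2$z_imputed, 1.0)
  expect_equal(out2$r2_pred, 0.25)
  # r = 0.9: z = 1.8, quality 0.81 (survives the 0.6 filter)
  b3 <- two_snp_block(0.9)
  out3 <- impute_block(c(rs1 = 2.0), b3, "rs2", ridge = 0)
  expect_equal(out3$z_imputed, 1.8)
  expect_equal(out3$r2_pred, 0.81)
  expect_gt(out3$r2_pred, 0.6)
})

test_that("singular typed-typed matrices error at ridge 0, and quality shrinks with ridge", {
  R <- matrix(1, 3, 3)  # two perfectly correlated typed variants
  R[3, 1:2] <- R[1:2, 3] <- 0.5
  b <- ld_block(data.frame(snp = c("a", "b", "c"), chrom = "1",
                           pos = 1:3 * 1000L, a1 = "A", a2 = "G", freq = 0.3), R)
  expect_error(impute_block(c(a = 1, b = 1), b, "c", ridge = 0))
  # r2_pred non-increasing in ridge
  b2 <- two_snp_block(0.8)
  ridges <- c(0, 0.05, 0.1, 0.5)
  r2s <- vapply(ridges, function(l)
    impute_block(c(rs1 = 2), b2, "rs2", ridge = l)$r2_pred, numeric(1))
  expect_true(all(diff(r2s) <= 1e-12))
})

test_that("whole-sumstats imputation masks, filters and restores the frame", {
  spec <- arch_spec(n_blocks = 10, snps_per_block = 30, ld_decay = 0.9,
                    h2_trait1 = 0.3, n1 = 20000, topology = "null", seed = 17)
  blocks <- simulate_ld(spec)
  sim <- simulate_pair(spec, blocks)
  s <- sim$s1

  # fully typed input, no ambiguous variants: output equals input frame
  full <- impute_sumstats(s, blocks)
  expect_setequal(full$data$snp, s$data$snp)
  expect_equal(full$data$z[match(s$data$snp, full$data$snp)], s$data$z)

  # weak-LD target gets imputed then dropped by the quality filter
  b_weak <- two_snp_block(0.5, prefix = "w")
  s_weak <- sumstats(data.frame(snp = "w1", chrom = "1", pos = 1000L,
                                a1 = "A", a2 = "G", z = 2, p = 0.0455,
                                n = 1000), "w")
  out_weak <- impute_sumstats(s_weak, list(b_weak), ridge = 0)
  expect_false("w2" %in% out_weak$data$snp)
  out_weak2 <- impute_sumstats(s_weak, list(b_weak), ridge = 0, r2_min = 0.2)
  expect_true("w2" %in% out_weak2$data$snp)

  # ambiguous typed variant is re-imputed from its neighbours
  s_amb <- s
  victim <- s_amb$data$snp[5]
  s_amb$data$a1[5] <- "A"; s_amb$data$a2[5] <- "T"
  out_amb <- impute_sumstats(s_amb, blocks)
  expect_true(victim %in% out_amb$data$snp)
  expect_equal(unname(out_amb$source[victim]), "imputed")
  r_neighbors <- 0.9  # AR(1) adjacency
  expect_lt(abs(out_amb$data$z[out_amb$data$snp == victim] -
                  s$data$z[s$data$snp == victim]), 3)

  # imputed rows carry back-derived beta/se consistent with z
  imp_rows <- out_amb$data[out_amb$source[out_amb$data$snp] == "imputed", ]
  expect_equal(imp_rows$beta / imp_rows$se, imp_rows$z, tolerance = 1e-10)
})

test_that("masking experiment: imputation error matches 1 - r2_pred", {
  spec <- arch_spec(n_blocks = 20, snps_per_block = 40, ld_decay = 0.9,
                    h2_trait1 = 0, n1 = 10000, topology = "null", seed = 29)
  blocks <- simulate_ld(spec)
  err <- c(); pred <- c()
  for (rep in 1:20) {
    spec$seed <- 29 + rep
    sim <- simulate_pair(spec, blocks)
    s <- sim$s1
    set.seed(rep)
    mask <- sample(s$data$snp, round(0.1 * nrow(s$data)))
    s_obs <- s
    s_obs$data <- s_obs$data[!s_obs$data$snp %in% mask, ]
    out <- impute_sumstats(s_obs, blocks, r2_min = 0, ridge = 0)
    got <- out$data[match(mask, out$data$snp), ]
    truth <- s$data$z[match(mask, s$data$snp)]
    err <- c(err, (got$z - truth)^2)
    pred <- c(pred, 1 - got$info)
  }
  # under the null z ~ MVN(0, R), so with ridge 0 the prediction error
  # variance is exactly 1 - r2_pred; compare means within Monte-Carlo noise
  mc_se <- sd(err) / sqrt(length(err))
  expect_lt(abs(mean(err) - mean(pred)), 4 * mc_se)
})
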