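# a reference with enough variants and spread in LD scores for regression
h2_fixture <- function(seed = 7, n_blocks = 40, decay = 0.9) {
  spec <- arch_spec(n_blocks = n_blocks, snps_per_block = 50,
                    ld_decay = decay, seed = seed)
  blocks <- simulate_ld(spec)
  list(blocks = blocks, scores = ld_scores(blocks))
}

noiseless_sumstats <- function(scores, n, h2, intercept = 1) {
  m <- nrow(scores)
  chi2 <- intercept + n * h2 * scores$ld_score / m
  sumstats(data.frame(snp = scores$snp, chrom = "1",
                      pos = seq_len(m) * 1000L, a1 = "A", a2 = "G",
                      z = sqrt(chi2), p = 2 * pnorm(-sqrt(chi2)), n = n), "x")
}

test_that("the regression recovers a noiseless linear system exactly", {
  fx <- h2_fixture()
  s <- noiseless_sumstats(fx$scores, n = 10000, h2 = 0.2)
  h <- ldsc_h2(s, fx$scores)
  expect_equal(h$h2_obs, 0.2, tolerance = 1e-10)
  expect_equal(h$intercept, 1, tolerance = 1e-10)
  # all chi-square exactly 1: zero heritability, unit intercept
  s0 <- noiseless_sumstats(fx$scores, n = 10000, h2 = 0)
  h0 <- ldsc_h2(s0, fx$scores)
  expect_equal(h0$h2_obs, 0, tolerance = 1e-10)
  expect_equal(h0$intercept, 1, tolerance = 1e-10)
})

test_that("doubling N with the same z halves the heritability estimate", {
  fx <- h2_fixture()
  s <- noiseless_sumstats(fx$scores, n = 10000, h2 = 0.2)
  s2 <- s
  s2$data$n <- 20000
  h1 <- ldsc_h2(s, fx$scores)
  h2 <- ldsc_h2(s2, fx$scores)
  expect_equal(h2$h2_obs, h1$h2_obs / 2, tolerance = 1e-8)
})

test_that("estimates fall within 2 jackknife SE of simulated truth", {
  fx <- h2_fixture(seed = 1, n_blocks = 100)
  hits <- 0L
  for (seed in 1:20) {
    spec <- arch_spec(n_blocks = 100, snps_per_block = 50, ld_decay = 0.9,
                      h2_trait1 = 0.3, n1 = 20000,
                      topology = "shared_latent", rg_target = 0.5,
                      seed = seed)
    sim <- simulate_pair(spec, fx$blocks)
    h <- ldsc_h2(sim$s1, fx$scores)
    hits <- hits + (abs(h$h2_obs - 0.3) < 2 * h$se)
  }
  expect_gte(hits, 17L)  # nominal 95% coverage, small-sample slack
})

test_that("liability conversion matches the closed form and a numerical oracle", {
  h <- structure(list(trait_id = "d", h2_obs = 0.1, se = 0.02, z_h2 = 5,
                      p_one_sided = 1e-7, intercept = 1, intercept_se = 0.01,
                      m_snps = 1000), class = "h2_estimate")
  # K = P = 0.5: factor pi/2 since phi(0)^2 = 1/(2 pi)
  out <- liability_scale(h, 0.5, 0.5)
  expect_equal(out$h2_liability, 0.1 * pi / 2, tolerance = 1e-12)
  expect_equal(out$liability_se, 0.02 * pi / 2, tolerance = 1e-12)
  # K = P = 0.15, h2 = 0.05: compare against the threshold found by
  # numerically inverting the upper normal tail (independent of qnorm)
  h$h2_obs <- 0.05
  out2 <- liability_scale(h, 0.15, 0.15)
  t_num <- uniroot(function(t)
    integrate(dnorm, t, Inf)$value - 0.15, c(-10, 10), tol = 1e-12)$root
  fac_num <- 0.15^2 * 0.85^2 / (0.15 * 0.85 * dnorm(t_num)^2)
  expect_equal(out2$h2_liability, 0.05 * fac_num, tolerance = 1e-8)
  # the transform is the identity only when the factor is 1
  expect_false(isTRUE(all.equal(out2$h2_liability, 0.05)))
  expect_error(liability_scale(h, 0, 0.5), "strictly")
  expect_error(liability_scale(h, 0.5, 1), "strictly")
})

test_that("the panel filter applies the Z and h2 windows and resolves duplicates", {
  mk <- function(id, h2, z, name = id)
    structure(list(trait_id = id, h2_obs = h2, se = h2 / z, z_h2 = z,
                   p_one_sided = pnorm(z, lower.tail = FALSE),
                   intercept = 1, intercept_se = 0.01, m_snps = 1000),
              class = "h2_estimate")
  ests <- list(mk("a", 0.3, 1.64),           # boundary: excluded (strict >)
               mk("b", 1.2, 3),              # h2 above 1: excluded
               mk("c", 0.3, 2.1),            # kept but duplicate of d
               mk("d", 0.4, 3.4),            # kept, larger Z wins
               mk("e", 0.2, 5),              # kept
               mk("f", -0.1, 2))             # h2 <= 0: excluded
  out <- filter_panel(ests, names = c("a", "b", "dup", "dup", "e", "f"))
  expect_setequal(out$trait_id, c("d", "e"))
  expect_equal(attr(out, "n_input"), 6L)
  expect_equal(attr(out, "n_pass_filters"), 3L)
})

test_that("genetic correlation behaves under identity, sign flip and null", {
  fx <- h2_fixture(seed = 2, n_blocks = 100)
  spec <- arch_spec(n_blocks = 100, snps_per_block = 50, ld_decay = 0.9,
                    h2_trait1 = 0.4, h2_trait2 = 0.4, n1 = 20000, n2 = 20000,
                    topology = "shared_latent", rg_target = 0.5, seed = 11)
  sim <- simulate_pair(spec, fx$blocks)
  # trait against itself: rg = 1 exactly (identical fits cancel)
  rg_self <- ldsc_rg(sim$s1, sim$s1, fx$scores)
  expect_lt(abs(rg_self$rg - 1), 1e-3)
  # all signs of one trait flipped: rg negates
  flipped <- sim$s1
  flipped$data$z <- -flipped$data$z
  rg_flip <- ldsc_rg(flipped, sim$s1, fx$scores)
  expect_equal(rg_flip$rg, -rg_self$rg, tolerance = 1e-10)
  # target recovery
  rg <- ldsc_rg(sim$s1, sim$s2, fx$scores)
  expect_lt(abs(rg$rg - 0.5), 2 * rg$se)
  # null pair: rg near zero
  spec0 <- arch_spec(n_blocks = 100, snps_per_block = 50, ld_decay = 0.9,
                     h2_trait1 = 0.4, h2_trait2 = 0.4, n1 = 20000,
                     n2 = 20000, topology = "null", seed = 12)
  sim0 <- simulate_pair(spec0, fx$blocks)
  rg0 <- ldsc_rg(sim0$s1, sim0$s2, fx$scores)
  expect_lt(abs(rg0$rg), 3 * rg0$se)
})
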