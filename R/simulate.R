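#' Specify a synthetic GWAS architecture
#'
#' Collects the generative parameters for a pair (or panel) of traits with
#' block-diagonal LD: AR(1) LD within blocks, point-normal polygenic effects,
#' and a latent-factor cross-trait structure that spans pure null, shared
#' aetiology, and fully/partially causal topologies.
#'
#' The cross-trait model is the latent-variable one: standardized per-variant
#' effects are `beta_t = q_t * sqrt(h2_t) * pi + gamma_t`, where `pi` is a
#' shared (point-normal, hence kurtotic) latent effect vector and `gamma_t`
#' trait-specific residual polygenicity. The latent loadings `q1`, `q2`
#' determine both the genetic correlation (`rg = q1*q2`) and the causal
#' topology: `causal_1to2` corresponds to `q1 = 1` (trait 1 is the latent
#' factor, so its genetic component fully mediates the correlation),
#' `shared_latent` to symmetric loadings `q1 = q2 = sqrt(rg_target)`, and
#' `mixed` to user-chosen asymmetric loadings.
#'
#' @param n_blocks number of LD-independent blocks.
#' @param snps_per_block variants per block.
#' @param ld_decay AR(1) correlation parameter in `[0, 1)`; adjacent variants
#'   correlate at `ld_decay`, next-adjacent at `ld_decay^2`, ...
#' @param n_causal_frac fraction of variants carrying nonzero effects.
#' @param h2_trait1,h2_trait2 SNP heritabilities in `[0, 1)`.
#' @param n1,n2 GWAS sample sizes.
#' @param topology one of `"null"`, `"shared_latent"`, `"causal_1to2"`,
#'   `"causal_2to1"`, `"mixed"`.
#' @param q1,q2 latent loadings (only consulted for `topology = "mixed"`;
#'   other topologies derive them from `rg_target`).
#' @param rg_target target genetic correlation in `[-1, 1]`.
#' @param cis_block optional `list(block =, effect =)` adding one large
#'   standardized effect at the centre of the given block for trait 2 — a
#'   cis-pQTL-like local signal.
#' @param prevalence optional population prevalence for a liability-threshold
#'   binary trait 1 (the disease); heritabilities stay on the observed scale.
#' @param sample_prev sample prevalence recorded for liability conversion
#'   (default 0.5, a balanced case-control design).
#' @param flip_fraction fraction of trait-2 records emitted with swapped
#'   allele labels (and negated z), to exercise harmonization.
#' @param seed integer seed; generation is deterministic given the spec.
#' @return An object of class `arch_spec` (a validated list).
#' @export
arch_spec <- function(n_blocks = 40, snps_per_block = 50, ld_decay = 0.9,
                      n_causal_frac = 0.2, h2_trait1 = 0.1, h2_trait2 = 0.1,
                      n1 = 20000, n2 = 20000,
                      topology = c("null", "shared_latent", "causal_1to2",
                                   "causal_2to1", "mixed"),
                      q1 = NULL, q2 = NULL, rg_target = 0,
                      cis_block = NULL, prevalence = NULL, sample_prev = 0.5,
                      flip_fraction = 0, seed = 1L) {
  topology <- match.arg(topology)
  stopifnot(n_blocks >= 1, snps_per_block >= 1,
            ld_decay >= 0, ld_decay < 1,
            n_causal_frac > 0, n_causal_frac <= 1,
            h2_trait1 >= 0, h2_trait1 < 1, h2_trait2 >= 0, h2_trait2 < 1,
            n1 > 0, n2 > 0, abs(rg_target) <= 1,
            flip_fraction >= 0, flip_fraction <= 1)
  if (!is.null(prevalence) && (prevalence <= 0 || prevalence >= 1))
    stop("prevalence must lie in (0, 1)")
  a <- sqrt(abs(rg_target))
  sgn <- if (rg_target < 0) -1 else 1
  loadings <- switch(topology,
    null          = c(0, 0),
    shared_latent = c(a, sgn * a),
    causal_1to2   = c(1, rg_target),
    causal_2to1   = c(rg_target, 1),
    mixed         = {
      if (is.null(q1) || is.null(q2))
        stop("topology 'mixed' requires explicit q1 and q2")
      c(q1, q2)
    })
  if (any(abs(loadings) > 1)) stop("latent loadings must lie in [-1, 1]")
  structure(list(n_blocks = as.integer(n_blocks),
                 snps_per_block = as.integer(snps_per_block),
                 ld_decay = ld_decay, n_causal_frac = n_causal_frac,
                 h2_trait1 = h2_trait1, h2_trait2 = h2_trait2,
                 n1 = n1, n2 = n2, topology = topology,
                 q1 = loadings[1L], q2 = loadings[2L],
                 rg_target = rg_target, cis_block = cis_block,
                 prevalence = prevalence, sample_prev = sample_prev,
                 flip_fraction = flip_fraction, seed = as.integer(seed)),
            class = "arch_spec")
}

#' Simulate an AR(1) block-LD reference
#'
#' Builds `n_blocks` LD blocks whose correlation between variants j and k is
#' `ld_decay^|j - k|` — positive-definite by construction. Variants are laid
#' out on chromosome 1 at 1 kb spacing with 1 Mb gaps between blocks, so
#' whole blocks sit well inside a 10 Mb clumping window while remaining
#' LD-independent of each other.
#'
#' @param spec an [arch_spec].
#' @return List of [ld_block] objects; reference allele frequencies are drawn
#'   deterministically from the spec seed and stored in the block variant
#'   index (column `freq`).
#' @export
simulate_ld <- function(spec) {
  m <- spec$snps_per_block
  idx <- seq_len(m)
  R <- spec$ld_decay^abs(outer(idx, idx, "-"))
  set.seed(spec$seed)
  blocks <- vector("list", spec$n_blocks)
  for (b in seq_len(spec$n_blocks)) {
    start <- (b - 1L) * (m * 1000L + 1000000L) + 1L
    snps <- data.frame(
      snp = sprintf("rs%d_%d", b, idx),
      chrom = "1",
      pos = start + (idx - 1L) * 1000L,
      a1 = "A", a2 = "G",
      freq = round(stats::runif(m, 0.05, 0.5), 4),
      stringsAsFactors = FALSE)
    blocks[[b]] <- ld_block(snps, R, name = sprintf("block_%04d", b))
  }
  attr(blocks, "uniform_R") <- TRUE
  attr(blocks, "ld_decay") <- spec$ld_decay
  blocks
}

# draw a point-normal effect vector over M snps: nonzero on a random
# n_causal_frac subset, rescaled so sum(beta^2) is exactly `target_var`.
point_normal <- function(m, frac, target_var) {
  beta <- numeric(m)
  if (target_var <= 0) return(beta)
  k <- max(1L, round(m * frac))
  causal <- sample.int(m, k)
  raw <- stats::rnorm(k)
  beta[causal] <- raw * sqrt(target_var / sum(raw^2))
  beta
}

# z = sqrt(N) R beta + chol(R)' eps, block by block
marginal_z <- function(beta, blocks, n, chol_R = NULL) {
  m_b <- vapply(blocks, function(b) nrow(b$snps), integer(1))
  z <- numeric(sum(m_b))
  offset <- 0L
  for (i in seq_along(blocks)) {
    m <- m_b[i]
    rows <- offset + seq_len(m)
    eps <- stats::rnorm(m)
    if (!is.null(chol_R)) {
      z[rows] <- sqrt(n) * drop(blocks[[i]]$R %*% beta[rows]) +
        drop(crossprod(chol_R, eps))
    } else {
      z[rows] <- sqrt(n) * beta[rows] + eps
    }
    offset <- offset + m
  }
  z
}

sumstats_from_z <- function(z, blocks, n, trait_id, note) {
  snps <- do.call(rbind, lapply(blocks, `[[`, "snps"))
  d <- data.frame(snp = snps$snp, chrom = snps$chrom, pos = snps$pos,
                  a1 = snps$a1, a2 = snps$a2,
                  z = z, p = pmax(2 * stats::pnorm(-abs(z)),
                                  .Machine$double.xmin), n = n,
                  maf = snps$freq, stringsAsFactors = FALSE)
  sumstats(d, trait_id = trait_id, provenance = note)
}

#' Simulate a pair of trait GWASs with known cross-trait truth
#'
#' Draws standardized per-variant effects under the spec's latent topology and
#' then marginal association Z scores per block as
#' `z ~ MVN(sqrt(N) R beta, R)` — exactly the sufficient statistics the
#' summary-data pipeline consumes. Trait noise is independent between traits
#' (no sample overlap).
#'
#' @param spec an [arch_spec].
#' @param blocks LD reference from [simulate_ld()] with matching dimensions.
#' @return List with elements `s1`, `s2` ([sumstats]) and `truth` (a list
#'   carrying true heritabilities, genetic correlation, a causal-label
#'   analogue of the genetic causality proportion, per-variant true effects,
#'   and any liability parameters).
#' @export
simulate_pair <- function(spec, blocks = NULL) {
  if (is.null(blocks)) blocks <- simulate_ld(spec)
  m_total <- sum(vapply(blocks, function(b) nrow(b$snps), integer(1)))
  set.seed(spec$seed + 1000L)
  h1 <- spec$h2_trait1; h2 <- spec$h2_trait2
  q1 <- spec$q1; q2 <- spec$q2
  pi_vec <- point_normal(m_total, spec$n_causal_frac, 1)
  beta1 <- q1 * sqrt(h1) * pi_vec +
    point_normal(m_total, spec$n_causal_frac, (1 - q1^2) * h1)
  beta2 <- q2 * sqrt(h2) * pi_vec +
    point_normal(m_total, spec$n_causal_frac, (1 - q2^2) * h2)
  if (!is.null(spec$cis_block)) {
    m_b <- spec$snps_per_block
    pos <- (spec$cis_block$block - 1L) * m_b + ceiling(m_b / 2)
    beta2[pos] <- beta2[pos] + spec$cis_block$effect
  }
  identity_ld <- isTRUE(attr(blocks, "uniform_R")) &&
    attr(blocks, "ld_decay") == 0
  chol_R <- if (identity_ld) NULL else chol(blocks[[1L]]$R)
  z1 <- marginal_z(beta1, blocks, spec$n1, chol_R)
  z2 <- marginal_z(beta2, blocks, spec$n2, chol_R)
  s1 <- sumstats_from_z(z1, blocks, spec$n1, "trait1",
                        sprintf("simulated: topology=%s h2=%g", spec$topology, h1))
  s2 <- sumstats_from_z(z2, blocks, spec$n2, "trait2",
                        sprintf("simulated: topology=%s h2=%g", spec$topology, h2))
  if (spec$flip_fraction > 0) {
    nf <- round(spec$flip_fraction * m_total)
    fl <- sample.int(m_total, nf)
    d <- s2$data
    tmp <- d$a1[fl]; d$a1[fl] <- d$a2[fl]; d$a2[fl] <- tmp
    d$z[fl] <- -d$z[fl]
    s2 <- sumstats(d, s2$trait_id, s2$provenance)
  }
  gcp_label <- switch(spec$topology,
                      causal_1to2 = 1, causal_2to1 = -1,
                      shared_latent = 0, null = 0,
                      mixed = NA_real_)
  truth <- list(h2_trait1 = h1, h2_trait2 = h2,
                rg = q1 * q2, q1 = q1, q2 = q2,
                gcp_label = gcp_label,
                beta1 = beta1, beta2 = beta2,
                prevalence = spec$prevalence,
                sample_prev = if (is.null(spec$prevalence)) NULL
                              else spec$sample_prev)
  list(s1 = s1, s2 = s2, truth = truth)
}

#' Simulate a disease-plus-protein-panel set of GWASs
#'
#' Generates one disease trait and `n_traits` molecular traits over a shared
#' LD reference. A `shared_fraction` of the panel loads on the disease's
#' latent genetic factor (genetic correlation `rg_target` with the disease);
#' the rest are genetically independent of it. Each trait is deterministic
#' given `(seed, trait index)`.
#'
#' @param base an [arch_spec]; `h2_trait1`/`n1` describe the disease,
#'   `n2` the panel sample size, `rg_target` the shared-trait correlation.
#' @param n_traits number of panel traits.
#' @param h2_range length-2 interval from which panel heritabilities are
#'   drawn uniformly.
#' @param shared_fraction fraction of panel traits sharing the disease's
#'   latent factor.
#' @return List with `disease` ([sumstats]), `panel` (named list of
#'   [sumstats]), `blocks`, and `truth` (data.frame: trait, h2, shared, rg).
#' @export
simulate_panel <- function(base, n_traits, h2_range = c(0.1, 0.5),
                           shared_fraction = 0) {
  stopifnot(n_traits >= 1)
  blocks <- simulate_ld(base)
  m_total <- sum(vapply(blocks, function(b) nrow(b$snps), integer(1)))
  identity_ld <- isTRUE(attr(blocks, "uniform_R")) &&
    attr(blocks, "ld_decay") == 0
  chol_R <- if (identity_ld) NULL else chol(blocks[[1L]]$R)
  a <- sqrt(abs(base$rg_target))
  sgn <- if (base$rg_target < 0) -1 else 1
  set.seed(base$seed + 2000L)
  pi_vec <- point_normal(m_total, base$n_causal_frac, 1)
  h_d <- base$h2_trait1
  beta_d <- a * sqrt(h_d) * pi_vec +
    point_normal(m_total, base$n_causal_frac, (1 - a^2) * h_d)
  z_d <- marginal_z(beta_d, blocks, base$n1, chol_R)
  disease <- sumstats_from_z(z_d, blocks, base$n1, "disease",
                             "simulated disease trait")
  n_shared <- round(shared_fraction * n_traits)
  panel <- vector("list", n_traits)
  truth <- data.frame(trait = character(n_traits), h2 = numeric(n_traits),
                      shared = logical(n_traits), rg = numeric(n_traits),
                      stringsAsFactors = FALSE)
  for (i in seq_len(n_traits)) {
    set.seed(base$seed + 2000L + i)
    h_i <- stats::runif(1, h2_range[1L], h2_range[2L])
    shared <- i <= n_shared
    q_i <- if (shared) sgn * a else 0
    beta_i <- q_i * sqrt(h_i) * pi_vec +
      point_normal(m_total, base$n_causal_frac, (1 - q_i^2) * h_i)
    z_i <- marginal_z(beta_i, blocks, base$n2, chol_R)
    id <- sprintf("protein_%03d", i)
    panel[[i]] <- sumstats_from_z(z_i, blocks, base$n2, id,
                                  sprintf("simulated panel trait (shared=%s)", shared))
    truth$trait[i] <- id
    truth$h2[i] <- h_i
    truth$shared[i] <- shared
    truth$rg[i] <- a * q_i
  }
  names(panel) <- truth$trait
  list(disease = disease, panel = panel, blocks = blocks, truth = truth)
}
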