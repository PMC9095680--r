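# Latent causal variable machinery.
#
# Model: standardized genetic effects alpha_1 = q1 pi + gamma_1,
# alpha_2 = q2 pi + gamma_2 with a shared latent factor pi whose effect
# distribution has excess kurtosis kappa. Then rho = q1 q2 and the excess
# mixed fourth moments satisfy
#   E[alpha_1^3 alpha_2] - 3 rho = kappa rho q1^2,
#   E[alpha_1 alpha_2^3] - 3 rho = kappa rho q2^2.
# Parameterizing the genetic causality proportion x by q1^2 = |rho|^(1-x),
# q2^2 = |rho|^(1+x) (x = 1: trait 1 fully causal for trait 2; x = 0:
# symmetric shared factor), the statistic
#   S(x) = k13 |rho|^x - k31 |rho|^(-x)
# has expectation zero at the true x, which yields a grid estimator with
# block-jackknife inference.

lcv_moments <- function(tot) {
  # tot: named totals of weighted sums
  nm <- function(name) tot[[name]] / tot[["sw"]]
  s1sq <- nm("s11") - 1
  s2sq <- nm("s22") - 1
  s1 <- sqrt(max(s1sq, 1e-12))
  s2 <- sqrt(max(s2sq, 1e-12))
  rho <- nm("s12") / (s1 * s2)
  k13 <- (nm("s31") - 3 * nm("s12")) / (s1^3 * s2) - 3 * rho
  k31 <- (nm("s13") - 3 * nm("s12")) / (s1 * s2^3) - 3 * rho
  c(s1sq = s1sq, s2sq = s2sq, rho = rho, k13 = k13, k31 = k31)
}

lcv_stat <- function(mom, x) {
  ar <- min(max(abs(mom[["rho"]]), 1e-8), 1)
  mom[["k13"]] * ar^x - mom[["k31"]] * ar^(-x)
}

#' Genetic causality proportion by the latent causal variable model
#'
#' Estimates the degree to which the genetic correlation between two traits
#' is mediated by one of them, from marginal association Z scores and LD
#' scores alone. Normalized effect-size second and mixed fourth cross-moments
#' are computed with LD-score-derived weights; under the latent model the
#' moment contrast `S(x)` (see source) is zero at the true causality
#' proportion, and a posterior over a grid of x between -1 and 1 is formed from the
#' jackknife-standardized contrast over the grid. Positive gcp means trait 1 (e.g. the
#' protein) is partially/fully causal for trait 2 (the disease).
#'
#' @param protein,disease harmonized [sumstats] objects (trait 1 and
#'   trait 2); run on non-imputed statistics, since imputation quality
#'   correlates with LD score.
#' @param scores LD score table from [ld_scores()].
#' @param n_jackknife number of contiguous jackknife blocks (default 100).
#' @param grid_step grid resolution for the gcp posterior (default 0.01).
#' @return An object of class `lcv_result`: `gcp`, `gcp_se`, `p_gcp`
#'   (two-sided test of gcp = 0), `rho` and `rho_se` (genetic-correlation
#'   analogue), and the trait pair.
#' @export
lcv_gcp <- function(protein, disease, scores, n_jackknife = 100,
                    grid_step = 0.01) {
  shared <- intersect(protein$data$snp, disease$data$snp)
  d1 <- protein$data[match(shared, protein$data$snp), , drop = FALSE]
  d2 <- disease$data[match(shared, disease$data$snp), , drop = FALSE]
  idx <- match(shared, scores$snp)
  keep <- !is.na(idx)
  d1 <- d1[keep, , drop = FALSE]; d2 <- d2[keep, , drop = FALSE]
  ell <- scores$ld_score[idx[keep]]
  ord <- order(d1$chrom, d1$pos)
  d1 <- d1[ord, , drop = FALSE]; d2 <- d2[ord, , drop = FALSE]
  ell <- ell[ord]
  m <- nrow(d1)
  if (m < n_jackknife * 2L)
    stop("too few shared variants (", m, ") for ", n_jackknife,
         " jackknife blocks")
  z1 <- d1$z; z2 <- d2$z
  w <- 1 / pmax(1, ell)^2
  block <- ceiling(seq_len(m) / (m / n_jackknife))
  block[block > n_jackknife] <- n_jackknife
  parts <- list(sw = w, s11 = w * z1^2, s22 = w * z2^2, s12 = w * z1 * z2,
                s31 = w * z1^3 * z2, s13 = w * z1 * z2^3)
  bsum <- lapply(parts, function(x) as.numeric(rowsum(x, block)))
  tot <- lapply(bsum, sum)
  mom_full <- lcv_moments(tot)
  B <- n_jackknife
  mom_del <- t(vapply(seq_len(B), function(b) {
    lcv_moments(Map(function(total, bs) total - bs[b], tot, bsum))
  }, numeric(5)))
  jk_se <- function(col) {
    v <- mom_del[, col]
    sqrt((B - 1) / B * sum((v - mean(v))^2))
  }
  s1_z <- mom_full[["s1sq"]] / jk_se("s1sq")
  s2_z <- mom_full[["s2sq"]] / jk_se("s2sq")
  if (s1_z < 1.64 || s2_z < 1.64)
    stop(sprintf("non-significant heritability (z = %.2f, %.2f); LCV refused",
                 s1_z, s2_z))
  # like rg, the sampling-noise-inflated estimate is truncated to [-1, 1]
  rho <- max(min(mom_full[["rho"]], 1), -1)
  rho_se <- jk_se("rho")
  if (abs(rho) < 1e-8)
    stop("genetic correlation numerically zero; gcp undefined")
  grid <- seq(-1, 1, by = grid_step)
  ar_full <- min(max(abs(rho), 1e-8), 1)
  ar_del <- pmin(pmax(abs(mom_del[, "rho"]), 1e-8), 1)
  tvals <- vapply(grid, function(x) {
    s_full <- mom_full[["k13"]] * ar_full^x - mom_full[["k31"]] * ar_full^(-x)
    s_del <- mom_del[, "k13"] * ar_del^x - mom_del[, "k31"] * ar_del^(-x)
    se <- sqrt((B - 1) / B * sum((s_del - mean(s_del))^2))
    if (se <= 0) return(0)
    s_full / se
  }, numeric(1))
  loglik <- stats::dt(tvals, df = B - 2, log = TRUE)
  lik <- exp(loglik - max(loglik))
  lik <- lik / sum(lik)
  gcp <- sum(grid * lik)
  gcp_se <- sqrt(sum((grid - gcp)^2 * lik))
  t0 <- tvals[which.min(abs(grid))]
  p_gcp <- 2 * stats::pt(-abs(t0), df = B - 2)
  structure(list(trait_pair = c(protein$trait_id, disease$trait_id),
                 gcp = gcp, gcp_se = gcp_se, p_gcp = p_gcp,
                 rho = rho, rho_se = rho_se, m_snps = m,
                 n_jackknife = B),
            class = "lcv_result")
}

#' @export
print.lcv_result <- function(x, ...) {
  cat(sprintf("<lcv_result> %s -> %s: gcp = %.3f (SE %.3f, P = %.3g); rho = %.3f (SE %.3f)\n",
              x$trait_pair[1L], x$trait_pair[2L], x$gcp, x$gcp_se, x$p_gcp,
              x$rho, x$rho_se))
  invisible(x)
}

#' Gate LCV results on genetic-correlation significance and apply FDR
#'
#' Restricts causality results to trait pairs with a nominally significant
#' genetic correlation (`p_rg < 0.05`, strict), then Benjamini-Hochberg
#' adjusts the gated set's gcp P values; pairs are flagged significant at
#' `fdr_q <= fdr`.
#'
#' @param rg_results list of `rg_estimate` objects (from [ldsc_rg()]), one
#'   per candidate pair, in the same order as `lcv_results`.
#' @param lcv_results list of `lcv_result` objects (or `NULL` entries for
#'   pairs where LCV was not run).
#' @param fdr FDR level (default 0.05).
#' @return data.frame with one row per gated pair: `trait`, `rg`, `se_rg`,
#'   `p_rg`, `gcp`, `se_gcp`, `p_gcp`, `fdr_q`, `sig`.
#' @export
gate_and_correct <- function(rg_results, lcv_results, fdr = 0.05) {
  stopifnot(length(rg_results) == length(lcv_results))
  gated <- which(vapply(rg_results, function(r) r$p_rg < 0.05, logical(1)) &
                   !vapply(lcv_results, is.null, logical(1)))
  if (length(gated) == 0L)
    return(data.frame(trait = character(), rg = numeric(), se_rg = numeric(),
                      p_rg = numeric(), gcp = numeric(), se_gcp = numeric(),
                      p_gcp = numeric(), fdr_q = numeric(), sig = logical()))
  out <- do.call(rbind, lapply(gated, function(i) {
    r <- rg_results[[i]]; l <- lcv_results[[i]]
    data.frame(trait = l$trait_pair[1L], rg = r$rg, se_rg = r$se,
               p_rg = r$p_rg, gcp = l$gcp, se_gcp = l$gcp_se,
               p_gcp = l$p_gcp, stringsAsFactors = FALSE)
  }))
  out$fdr_q <- stats::p.adjust(out$p_gcp, method = "BH")
  out$sig <- out$fdr_q <= fdr
  rownames(out) <- NULL
  out
}
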