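#' Fraction of index variants present in a trait's summary statistics
#'
#' @param index_snps character vector of index (clumped) variant ids.
#' @param s a [sumstats] object.
#' @return Fraction of `index_snps` found in `s`, in `[0, 1]`.
#' @export
overlap_fraction <- function(index_snps, s) {
  if (length(index_snps) == 0L) stop("index_snps must be non-empty")
  mean(index_snps %in% s$data$snp)
}

#' Genome-wide pleiotropy by Z-score correlation over index variants
#'
#' Pearson correlation between the two traits' association Z scores over the
#' intersection of the supplied index (LD-independent) variants, with the
#' traits aligned to the same effect allele beforehand (see [harmonize()]).
#' A significant correlation indicates a concordant (r > 0) or discordant
#' (r < 0) genome-wide polygenic overlap. The two-sided P comes from the
#' t-distribution with n-2 degrees of freedom and the 95% CI from the Fisher
#' z-transform.
#'
#' @param disease,protein harmonized [sumstats] objects.
#' @param index_snps character vector of index variant ids.
#' @return An object of class `pleio_cor`: `r`, `ci95`, `p_two_sided`,
#'   `n_snps`, `overlap_frac`.
#' @export
z_correlation <- function(disease, protein, index_snps) {
  ov <- overlap_fraction(index_snps, protein)
  shared <- intersect(intersect(index_snps, disease$data$snp),
                      protein$data$snp)
  n <- length(shared)
  if (n < 3L) stop("fewer than 3 overlapping index variants")
  z1 <- disease$data$z[match(shared, disease$data$snp)]
  z2 <- protein$data$z[match(shared, protein$data$snp)]
  r <- stats::cor(z1, z2)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  fz <- atanh(r)
  half <- stats::qnorm(0.975) / sqrt(n - 3)
  ci <- tanh(c(fz - half, fz + half))
  structure(list(trait_pair = c(disease$trait_id, protein$trait_id),
                 r = r, ci95 = ci, p_two_sided = p,
                 n_snps = n, overlap_frac = ov),
            class = "pleio_cor")
}

#' @export
print.pleio_cor <- function(x, ...) {
  cat(sprintf("<pleio_cor> %s ~ %s: r = %.4f [%.4f, %.4f], P = %.3g (%d SNPs, overlap %.1f%%)\n",
              x$trait_pair[1L], x$trait_pair[2L], x$r, x$ci95[1L], x$ci95[2L],
              x$p_two_sided, x$n_snps, 100 * x$overlap_frac))
  invisible(x)
}

#' Effective number of independent tests from a trait correlation matrix
#'
#' Spectral-decomposition estimates of the effective test count from the
#' eigenvalues of a trait-by-trait correlation matrix. Two variants are
#' reported: Nyholt's `Meff = 1 + (M - 1) (1 - Var(lambda) / M)` (sample
#' variance with denominator M - 1) and Li & Ji's
#' `Meff = sum_i [ I(lambda_i >= 1) + (lambda_i - floor(lambda_i)) ]`.
#'
#' @param corr_matrix square trait correlation matrix.
#' @return List with `m_nominal`, `m_eff_nyholt`, `m_eff_liji` and the
#'   eigenvalues.
#' @export
matspd <- function(corr_matrix) {
  corr_matrix <- as.matrix(corr_matrix)
  M <- nrow(corr_matrix)
  if (M != ncol(corr_matrix)) stop("correlation matrix must be square")
  if (max(abs(corr_matrix - t(corr_matrix))) > 1e-8)
    stop("correlation matrix must be symmetric")
  lambda <- eigen(corr_matrix, symmetric = TRUE, only.values = TRUE)$values
  if (min(lambda) < -1e-6)
    stop("matrix is not positive semi-definite beyond tolerance")
  lambda <- pmax(lambda, 0)
  m_ny <- 1 + (M - 1) * (1 - stats::var(lambda) / M)
  m_lj <- sum(ifelse(lambda >= 1, 1, 0) + (lambda - floor(lambda)))
  list(m_nominal = M, m_eff_nyholt = m_ny, m_eff_liji = m_lj,
       eigenvalues = lambda)
}

#' Benjamini-Hochberg FDR with an effective test count
#'
#' Step-up BH adjustment in which the nominal number of tests is replaced by
#' an effective (possibly fractional) count `m_eff`:
#' `q_(i) = min_{j >= i} p_(j) * m_eff / j`, capped at 1. With
#' `m_eff = length(pvals)` this reduces to standard BH.
#'
#' @param pvals numeric vector of P values in (0, 1].
#' @param m_eff effective number of independent tests.
#' @return Vector of q-values in the input order.
#' @export
fdr_meff <- function(pvals, m_eff) {
  if (any(pvals <= 0 | pvals > 1)) stop("p-values must lie in (0, 1]")
  n <- length(pvals)
  ord <- order(pvals)
  ranks <- seq_len(n)
  q_sorted <- rev(cummin(rev(pvals[ord] * m_eff / ranks)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(n)
  q[ord] <- q_sorted
  q
}

#' Build the trait-trait correlation matrix for the effective-test estimate
#'
#' Correlation between panel traits computed on the common matrix of index-
#' variant Z scores (pairwise-complete), the input [matspd()] operates on.
#'
#' @param panel named list of [sumstats] objects.
#' @param index_snps index variant ids defining the rows of the Z matrix.
#' @return Trait-by-trait correlation matrix.
#' @export
panel_correlation <- function(panel, index_snps) {
  zmat <- sapply(panel, function(s) {
    z <- s$data$z[match(index_snps, s$data$snp)]
    z
  })
  C <- stats::cor(zmat, use = "pairwise.complete.obs")
  C[is.na(C)] <- 0
  diag(C) <- 1
  C
}
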