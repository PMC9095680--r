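#' Assign variants to genes with a flanking window
#'
#' A variant is assigned to every gene whose boundaries, extended by
#' `window_kb` on each side (inclusive), contain its position;
#' multi-assignment is allowed.
#'
#' @param genes data.frame of gene intervals (`chrom`, `start`, `end`,
#'   `name`; 1-based inclusive, as from [read_bed()]).
#' @param s a [sumstats] object.
#' @param window_kb flanking window in kb (default 500).
#' @return Named list mapping gene name to a character vector of variant ids
#'   (genes with no assigned variant map to an empty vector).
#' @export
assign_snps <- function(genes, s, window_kb = 500) {
  w <- window_kb * 1000
  d <- s$data
  out <- vector("list", nrow(genes))
  names(out) <- genes$name
  for (i in seq_len(nrow(genes))) {
    hit <- d$chrom == genes$chrom[i] &
      d$pos >= genes$start[i] - w & d$pos <= genes$end[i] + w
    out[[i]] <- d$snp[hit]
  }
  out
}

# Saddlepoint (Lugannani-Rice) tail of sum lambda_i chi2_1; used when the
# oscillatory inversion integral fails to converge and for far tails.
saddlepoint_tail <- function(q, lambda) {
  m <- length(lambda)
  if (abs(q - sum(lambda)) < 1e-8 * max(q, 1))
    q <- q * (1 + 1e-6)                       # avoid the removable singularity
  upper <- 1 / (2 * max(lambda)) - 1e-10
  Kp <- function(s) sum(lambda / (1 - 2 * s * lambda))
  if (Kp(upper) < q) return(1e-300)
  shat <- stats::uniroot(function(s) Kp(s) - q, c(-1e4, upper),
                         tol = 1e-12)$root
  K <- -0.5 * sum(log1p(-2 * shat * lambda))
  Kpp <- sum(2 * lambda^2 / (1 - 2 * shat * lambda)^2)
  w <- sign(shat) * sqrt(max(2 * (shat * q - K), 0))
  v <- shat * sqrt(Kpp)
  if (abs(shat) < 1e-8) return(stats::pchisq(q * m / sum(lambda), df = m,
                                             lower.tail = FALSE))
  stats::pnorm(w + log(v / w) / w, lower.tail = FALSE)
}

# Ruben's (1962) expansion of sum lambda_i chi2_1 as a mixture of central
# chi-squares with scale beta = min(lambda): coefficients are non-negative
# and sum to one, so the truncation error is bounded by the unassigned
# mixture mass.
ruben_tail <- function(q, lambda, K = 20000L, tol = 1e-9) {
  m <- length(lambda)
  beta <- min(lambda)
  r <- 1 - beta / lambda
  a <- numeric(K)
  a[1L] <- exp(0.5 * sum(log(beta / lambda)))
  g <- vapply(seq_len(K - 1L), function(k) sum(r^k), numeric(1))
  mass <- a[1L]
  for (k in seq_len(K - 1L)) {
    a[k + 1L] <- sum(a[1:k] * g[k:1]) / (2 * k)
    mass <- mass + a[k + 1L]
    if (1 - mass < tol) {
      a <- a[seq_len(k + 1L)]
      break
    }
  }
  if (1 - mass >= tol) return(NULL)   # spectrum too ill-conditioned
  sum(a * stats::pchisq(q / beta, df = m + 2 * (seq_along(a) - 1L),
                        lower.tail = FALSE))
}

# Upper tail of a weighted sum of independent 1-df chi-squares,
# P(sum lambda_i X_i > q): equal weights reduce to a plain chi-square tail;
# otherwise Ruben's mixture series, with a Lugannani-Rice saddlepoint
# fallback when the eigenvalue spread makes the series converge too slowly.
weighted_chisq_tail <- function(q, lambda) {
  lambda <- lambda[lambda > 1e-10]
  if (length(lambda) == 0L) return(1)
  if (max(lambda) - min(lambda) < 1e-10)
    return(stats::pchisq(q / lambda[1L], df = length(lambda),
                         lower.tail = FALSE))
  tol <- if (length(lambda) > 12L) 1e-5 else 1e-9   # larger genes: cheaper series
  p <- if (min(lambda) / max(lambda) > 1e-4)
    ruben_tail(q, lambda, tol = tol) else NULL
  if (is.null(p) || p < 1e-12) p <- saddlepoint_tail(q, lambda)
  min(max(p, 1e-300), 1)
}

#' Gene-based association test from summary statistics
#'
#' Tests a gene's variants jointly with the sum-of-chi-squares statistic
#' `T = sum_j z_j^2`, whose null distribution under local LD is the weighted
#' chi-square `sum_i lambda_i chi2_1` with `lambda_i` the eigenvalues of the
#' gene's variant correlation matrix. The tail probability is evaluated
#' numerically (Imhof's method). With independent variants this reduces
#' exactly to a chi-square test with one degree of freedom per variant.
#'
#' @param snp_z numeric vector of the gene's variant Z scores.
#' @param block_R correlation matrix restricted to those variants (same
#'   order); defaults to the identity.
#' @return An object of class `gene_result`: `n_snps`, `stat`, `p_gene`,
#'   eigenvalues.
#' @export
gene_test <- function(snp_z, block_R = NULL) {
  m <- length(snp_z)
  if (m < 1L) stop("gene has no variants")
  if (is.null(block_R)) block_R <- diag(m)
  block_R <- as.matrix(block_R)
  if (!all(dim(block_R) == c(m, m)))
    stop("correlation matrix dimension does not match z vector")
  lambda <- eigen(block_R, symmetric = TRUE, only.values = TRUE)$values
  if (min(lambda) < -1e-6)
    stop("gene correlation matrix is not positive semi-definite")
  stat <- sum(snp_z^2)
  p <- weighted_chisq_tail(stat, pmax(lambda, 0))
  structure(list(n_snps = m, stat = stat, p_gene = p,
                 eigenvalues = lambda),
            class = "gene_result")
}

# correlation matrix for an arbitrary set of snps: union of block
# correlations with zero correlation across blocks.
gene_cor_matrix <- function(snp_ids, blocks) {
  m <- length(snp_ids)
  R <- diag(m)
  rownames(R) <- colnames(R) <- snp_ids
  for (b in blocks) {
    here <- intersect(snp_ids, b$snps$snp)
    if (length(here) > 1L)
      R[here, here] <- b$R[here, here]
  }
  R
}

#' Run the gene-based test for every gene of an annotation
#'
#' Convenience wrapper: assigns variants to genes ([assign_snps()]), builds
#' each gene's LD submatrix from the block reference (zero correlation across
#' blocks), and runs [gene_test()].
#'
#' @param s a [sumstats] object.
#' @param genes gene intervals (see [assign_snps()]).
#' @param blocks LD reference (list of [ld_block]).
#' @param window_kb flanking window in kb (default 500).
#' @return data.frame with `gene`, `n_snps`, `stat`, `p_gene` (genes with no
#'   variants omitted), plus `p_bh`, the per-trait Benjamini-Hochberg
#'   adjusted P.
#' @export
gene_scan <- function(s, genes, blocks, window_kb = 500) {
  assign <- assign_snps(genes, s, window_kb = window_kb)
  assign <- assign[lengths(assign) > 0L]
  rows <- lapply(names(assign), function(g) {
    ids <- assign[[g]]
    z <- s$data$z[match(ids, s$data$snp)]
    R <- gene_cor_matrix(ids, blocks)
    gt <- gene_test(z, R)
    data.frame(gene = g, n_snps = gt$n_snps, stat = gt$stat,
               p_gene = gt$p_gene, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bh <- stats::p.adjust(out$p_gene, method = "BH")
  rownames(out) <- NULL
  out
}

#' One-sided binomial enrichment of disease genes among trait genes
#'
#' Tests whether genes associated with the disease are over-represented among
#' the genes associated with a trait: with `k_trait` trait-associated genes
#' of which `k_both` are also disease-associated, and null proportion
#' `p0 = |disease genes| / G`, the one-sided exact binomial P is
#' `P(X >= k_both)` for `X ~ Binomial(k_trait, p0)`.
#'
#' @param disease_sig character vector of disease-associated gene names.
#' @param trait_sig character vector (non-empty) of trait-associated gene
#'   names.
#' @param G total number of genes in the universe.
#' @return List with `k_both`, `k_trait`, `p0`, `p_binom`.
#' @export
binomial_enrichment <- function(disease_sig, trait_sig, G) {
  if (length(trait_sig) == 0L)
    stop("trait gene set is empty; enrichment undefined")
  k_trait <- length(trait_sig)
  k_both <- length(intersect(disease_sig, trait_sig))
  p0 <- length(disease_sig) / G
  if (p0 <= 0 || p0 >= 1) stop("null proportion must lie in (0, 1)")
  p <- stats::pbinom(k_both - 1L, size = k_trait, prob = p0,
                     lower.tail = FALSE)
  list(k_both = k_both, k_trait = k_trait, p0 = p0, p_binom = p)
}

#' Weighted Stouffer combination of disease and protein gene P values
#'
#' Combines one gene's P value from the disease scan with P values from
#' `n_p` included protein scans using Stouffer's Z with weight 1 per protein
#' and weight `n_p` for the disease, so disease and panel contribute equally:
#' `Z_comb = (n_p Z_disease + sum Z_protein) / sqrt(n_p^2 + n_p)` with
#' `Z_i = Phi^-1(1 - p_i)`, and `combined_p = 1 - Phi(Z_comb)`.
#'
#' @param p_disease disease gene P value in (0, 1).
#' @param p_proteins numeric vector of included protein gene P values in
#'   (0, 1); must be non-empty.
#' @return List with `combined_z`, `combined_p`, `w_disease`
#'   (= number of included proteins).
#' @export
stouffer_combine <- function(p_disease, p_proteins) {
  p_all <- c(p_disease, p_proteins)
  if (length(p_proteins) == 0L) stop("no protein P values to combine")
  if (any(p_all <= 0 | p_all >= 1))
    stop("p values must lie strictly in (0, 1) for Stouffer combination")
  n_p <- length(p_proteins)
  z_d <- stats::qnorm(p_disease, lower.tail = FALSE)
  z_p <- stats::qnorm(p_proteins, lower.tail = FALSE)
  z_comb <- (n_p * z_d + sum(z_p)) / sqrt(n_p^2 + n_p)
  list(combined_z = z_comb,
       combined_p = stats::pnorm(z_comb, lower.tail = FALSE),
       w_disease = n_p)
}

#' Combined gene analysis across disease and a set of protein scans
#'
#' For every gene at which the disease's BH-adjusted gene P value and at
#' least one protein's BH-adjusted gene P value are both <= `bh_alpha`,
#' combines the raw gene P values by weighted Stouffer
#' ([stouffer_combine()]); the gene is declared significant at the Bonferroni
#' level `alpha / ((n_traits + 1) * G)`, accounting for one scan per protein
#' plus the disease over all `G` genes.
#'
#' @param disease_scan data.frame from [gene_scan()] for the disease.
#' @param protein_scans named list of [gene_scan()] data.frames.
#' @param G total number of genes in the universe.
#' @param bh_alpha BH gating level (default 0.05).
#' @param alpha family-wise level for the combined threshold (default 0.05).
#' @return data.frame with `gene`, `n_proteins`, `combined_z`, `combined_p`,
#'   `sig`; attribute `n_tests` records the declared
#'   `(n_traits + 1) * G` test count.
#' @export
combined_gene_analysis <- function(disease_scan, protein_scans, G,
                                   bh_alpha = 0.05, alpha = 0.05) {
  n_tests <- (length(protein_scans) + 1) * G
  thr <- alpha / n_tests
  rows <- list()
  d_ok <- disease_scan[disease_scan$p_bh <= bh_alpha, , drop = FALSE]
  for (g in d_ok$gene) {
    p_d <- d_ok$p_gene[d_ok$gene == g]
    p_ps <- c()
    included <- character(0)
    for (tr in names(protein_scans)) {
      sc <- protein_scans[[tr]]
      row <- sc[sc$gene == g, , drop = FALSE]
      if (nrow(row) == 1L && row$p_bh <= bh_alpha) {
        p_ps <- c(p_ps, row$p_gene)
        included <- c(included, tr)
      }
    }
    if (length(p_ps) == 0L) next
    st <- stouffer_combine(p_d, p_ps)
    rows[[length(rows) + 1L]] <-
      data.frame(gene = g, n_proteins = length(p_ps),
                 combined_z = st$combined_z, combined_p = st$combined_p,
                 sig = st$combined_p <= thr, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(gene = character(), n_proteins = integer(),
                         combined_z = numeric(), combined_p = numeric(),
                         sig = logical())
  attr(out, "n_tests") <- n_tests
  attr(out, "threshold") <- thr
  out
}
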