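#' Impute association Z scores within one LD block
#'
#' Conditional-expectation imputation of untyped variants from typed ones
#' using the block correlation matrix: with `S_tt` the typed-typed and
#' `S_ut` the target-typed correlations,
#' `z_imp = S_ut (S_tt + ridge I)^-1 z_typed` and the per-target imputation
#' quality is `r2_pred = diag(S_ut (S_tt + ridge I)^-1 S_tu)`. With
#' `ridge = 0` and a singular typed-typed matrix the numerical error is
#' surfaced rather than silently regularized.
#'
#' @param observed_z named numeric vector of Z scores for typed variants
#'   (names are variant ids present in the block).
#' @param block an [ld_block].
#' @param targets character vector of target variant ids (disjoint from the
#'   typed set).
#' @param ridge ridge regularization added to the typed-typed correlation
#'   (default 0.1).
#' @return data.frame with columns `snp`, `z_imputed`, `r2_pred`.
#' @export
impute_block <- function(observed_z, block, targets, ridge = 0.1) {
  typed <- names(observed_z)
  if (length(intersect(typed, targets)) > 0L)
    stop("typed and target variant sets must be disjoint")
  ids <- block$snps$snp
  if (!all(typed %in% ids) || !all(targets %in% ids))
    stop("typed and target variants must all belong to the block")
  S_tt <- block$R[typed, typed, drop = FALSE] + ridge * diag(length(typed))
  S_ut <- block$R[targets, typed, drop = FALSE]
  W <- solve(S_tt, t(S_ut))            # typed x targets
  z_imp <- drop(crossprod(W, observed_z))
  r2 <- colSums(W * t(S_ut))
  r2 <- pmin(pmax(r2, 0), 1 + 1e-8)
  data.frame(snp = targets, z_imputed = as.numeric(z_imp),
             r2_pred = as.numeric(r2), stringsAsFactors = FALSE)
}

# se back-derived from sample size and reference allele frequency under the
# standardized-genotype approximation: se = 1/sqrt(2 f (1-f) (N + z^2)).
se_from_freq_n <- function(z, n, f) 1 / sqrt(2 * f * (1 - f) * (n + z^2))

#' Impute a summary-statistics set to a common variant frame
#'
#' Reconstructs a complete variant frame (`target_set`, e.g. a HapMap3-like
#' panel covered by the LD reference) for one trait: strand-ambiguous (A/T,
#' G/C) variants are removed before imputation and then re-imputed from their
#' neighbours, each missing variant is imputed per block via [impute_block()],
#' imputed records with predicted quality below `r2_min` are dropped, and
#' effect sizes are back-derived from the imputed Z via a standard error
#' estimated from the study sample size and the reference allele frequency.
#'
#' @param s a [sumstats] object.
#' @param blocks LD reference (list of [ld_block]; variant indexes must carry
#'   a `freq` column for effect-size back-derivation).
#' @param target_set character vector of variant ids defining the common
#'   frame; defaults to every variant indexed by the reference.
#' @param r2_min minimum imputation quality for imputed records
#'   (default 0.6).
#' @param ridge ridge passed to [impute_block()] (default 0.1).
#' @return A [sumstats] object on the target frame with an `info` column
#'   holding the imputation quality (1 for observed records) and provenance
#'   describing the counts; imputed records carry alleles and frequency from
#'   the reference.
#' @export
impute_sumstats <- function(s, blocks, target_set = NULL, r2_min = 0.6,
                            ridge = 0.1) {
  ref_snps <- do.call(rbind, lapply(blocks, `[[`, "snps"))
  if (is.null(target_set)) target_set <- ref_snps$snp
  target_set <- intersect(target_set, ref_snps$snp)
  d <- s$data
  amb <- is_ambiguous(d$a1, d$a2)
  n_amb <- sum(amb)
  d <- d[!amb, , drop = FALSE]
  n_bar <- mean(s$data$n)
  out <- list()
  for (b in blocks) {
    ids <- b$snps$snp
    tgt_here <- intersect(target_set, ids)
    if (length(tgt_here) == 0L) next
    typed_here <- intersect(tgt_here, d$snp)
    miss_here <- setdiff(tgt_here, typed_here)
    if (length(typed_here) > 0L) {
      obs <- d[match(typed_here, d$snp), , drop = FALSE]
      obs$info <- 1
      obs$source <- "observed"
      out[[length(out) + 1L]] <- obs
    }
    if (length(miss_here) > 0L && length(typed_here) > 0L) {
      zt <- stats::setNames(d$z[match(typed_here, d$snp)], typed_here)
      imp <- impute_block(zt, b, miss_here, ridge = ridge)
      imp <- imp[imp$r2_pred >= r2_min, , drop = FALSE]
      if (nrow(imp) > 0L) {
        ref <- b$snps[match(imp$snp, b$snps$snp), , drop = FALSE]
        se <- se_from_freq_n(imp$z_imputed, n_bar, ref$freq)
        rec <- data.frame(snp = imp$snp, chrom = ref$chrom, pos = ref$pos,
                          a1 = ref$a1, a2 = ref$a2,
                          z = imp$z_imputed,
                          p = 2 * stats::pnorm(-abs(imp$z_imputed)),
                          n = n_bar,
                          beta = imp$z_imputed * se, se = se,
                          maf = ref$freq, info = pmin(imp$r2_pred, 1),
                          source = "imputed",
                          stringsAsFactors = FALSE)
        out[[length(out) + 1L]] <- rec
      }
    }
  }
  if (length(out) == 0L) stop("no variants could be placed on the target frame")
  full <- do.call(rbind, lapply(out, function(x) {
    for (col in c("beta", "se", "maf", "info"))
      if (is.null(x[[col]])) x[[col]] <- NA_real_
    x[, c("snp", "chrom", "pos", "a1", "a2", "z", "p", "n",
          "beta", "se", "maf", "info", "source")]
  }))
  n_obs <- sum(full$source == "observed")
  n_imp <- sum(full$source == "imputed")
  src <- full$source
  full$source <- NULL
  res <- sumstats(full, s$trait_id,
                  c(s$provenance,
                    sprintf("impute_sumstats: %d ambiguous removed and re-imputed as targets; %d observed, %d imputed kept (r2 >= %g)",
                            n_amb, n_obs, n_imp, r2_min)))
  res$source <- stats::setNames(src, full$snp)[res$data$snp]
  res
}
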