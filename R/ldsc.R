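# Weighted least squares of y on x (with or without intercept) plus
# delete-a-block jackknife, all via per-block sufficient statistics so the
# B deleted fits cost O(B) after one pass over the data.
wls_jackknife <- function(x, y, w, n_blocks, intercept = TRUE) {
  m <- length(x)
  if (m < n_blocks) stop("fewer SNPs (", m, ") than jackknife blocks (",
                         n_blocks, ")")
  block <- ceiling(seq_along(x) / (m / n_blocks))
  block[block > n_blocks] <- n_blocks
  sw   <- rowsum(w, block)
  swx  <- rowsum(w * x, block)
  swxx <- rowsum(w * x * x, block)
  swy  <- rowsum(w * y, block)
  swxy <- rowsum(w * x * y, block)
  tot <- c(sum(sw), sum(swx), sum(swxx), sum(swy), sum(swxy))
  solve_fit <- function(s) {
    # s = c(sw, swx, swxx, swy, swxy)
    if (intercept) {
      det <- s[1] * s[3] - s[2]^2
      slope <- (s[1] * s[5] - s[2] * s[4]) / det
      inter <- (s[4] - slope * s[2]) / s[1]
    } else {
      slope <- s[5] / s[3]
      inter <- 0
    }
    c(inter, slope)
  }
  full <- solve_fit(tot)
  del <- matrix(0, n_blocks, 2L)
  for (b in seq_len(n_blocks))
    del[b, ] <- solve_fit(tot - c(sw[b], swx[b], swxx[b], swy[b], swxy[b]))
  pseudo_mean <- colMeans(del)
  se <- sqrt((n_blocks - 1) / n_blocks *
               colSums(sweep(del, 2, pseudo_mean)^2))
  list(intercept = full[1L], slope = full[2L],
       intercept_se = se[1L], slope_se = se[2L],
       delete_values = del, n_blocks = n_blocks, block = block)
}

align_scores <- function(s, scores) {
  idx <- match(s$data$snp, scores$snp)
  keep <- !is.na(idx)
  list(d = s$data[keep, , drop = FALSE], ell = scores$ld_score[idx[keep]])
}

#' SNP heritability by LD score regression
#'
#' Regresses per-variant chi-square statistics on `N * l_j / M` (LD score
#' scaled by sample size over variant count) with a free intercept. The slope
#' estimates observed-scale SNP heritability; the intercept captures
#' confounding/overcounting. Weights `1 / (l_j * (1 + N h2 l_j / M)^2)`
#' address heteroskedasticity and LD overcounting and are iterated twice from
#' an unweighted initial fit. Standard errors come from a delete-a-block
#' jackknife over contiguous SNP blocks.
#'
#' @param s a [sumstats] object (`z` and `n` required).
#' @param scores LD score table from [ld_scores()].
#' @param n_blocks_jackknife number of jackknife blocks (default 200).
#' @return An object of class `h2_estimate`: trait id, `h2_obs`, `se`,
#'   `z_h2`, one-sided `p`, `intercept`, `intercept_se`, `m_snps`.
#' @export
ldsc_h2 <- function(s, scores, n_blocks_jackknife = 200) {
  al <- align_scores(s, scores)
  d <- al$d; ell <- al$ell
  m <- nrow(d)
  if (m < 200L) stop("need at least 200 SNPs with LD scores, got ", m)
  n_bar <- mean(d$n)
  x <- n_bar * ell / m
  y <- d$z^2
  h2_cur <- max(0, (mean(y) - 1) / mean(x))
  for (step in 1:2) {
    w <- 1 / (pmax(ell, 1) * (1 + n_bar * h2_cur * ell / m)^2)
    fit <- wls_jackknife(x, y, w, n_blocks_jackknife)
    h2_cur <- max(0, fit$slope)
  }
  se <- fit$slope_se
  z_h2 <- fit$slope / se
  structure(list(trait_id = s$trait_id,
                 h2_obs = fit$slope, se = se, z_h2 = z_h2,
                 p_one_sided = stats::pnorm(z_h2, lower.tail = FALSE),
                 intercept = fit$intercept,
                 intercept_se = fit$intercept_se,
                 m_snps = m,
                 h2_liability = NULL, liability_params = NULL),
            class = "h2_estimate")
}

#' @export
print.h2_estimate <- function(x, ...) {
  cat(sprintf("<h2_estimate> %s: h2_obs = %.4f (SE %.4f, Z = %.2f, one-sided P = %.3g)\n",
              x$trait_id, x$h2_obs, x$se, x$z_h2, x$p_one_sided))
  cat(sprintf("  intercept = %.4f (SE %.4f), %d SNPs\n",
              x$intercept, x$intercept_se, x$m_snps))
  if (!is.null(x$h2_liability))
    cat(sprintf("  liability scale: h2 = %.4f (K = %g, P = %g)\n",
                x$h2_liability, x$liability_params$K, x$liability_params$P))
  invisible(x)
}

#' Convert an observed-scale heritability to the liability scale
#'
#' Applies the standard liability-threshold transform for a case-control
#' trait: `h2_liab = h2_obs * K^2 (1-K)^2 / (P (1-P) phi(Phi^-1(1-K))^2)`,
#' with `K` the population prevalence and `P` the sample (study) prevalence.
#' The standard error scales by the same factor.
#'
#' @param h an `h2_estimate` from [ldsc_h2()].
#' @param K population prevalence in (0, 1).
#' @param P sample prevalence in (0, 1).
#' @return The estimate with `h2_liability` and `liability_params` filled in.
#' @export
liability_scale <- function(h, K, P) {
  if (K <= 0 || K >= 1 || P <= 0 || P >= 1)
    stop("K and P must lie strictly in (0, 1)")
  phi <- stats::dnorm(stats::qnorm(1 - K))
  factor <- K^2 * (1 - K)^2 / (P * (1 - P) * phi^2)
  h$h2_liability <- h$h2_obs * factor
  h$liability_se <- h$se * factor
  h$liability_params <- list(K = K, P = P)
  h
}

#' Filter a panel of heritability estimates for significant polygenicity
#'
#' Retains traits with a nominally significant heritability Z score
#' (`z_h2 > 1.64`, one-sided P < 0.05) and a meaningful estimate
#' (`0 < h2_obs < 1`); among duplicate entries for the same trait name, the
#' one with the largest `z_h2` is kept.
#'
#' @param estimates list of `h2_estimate` objects.
#' @param names optional character vector of trait names used for duplicate
#'   resolution (defaults to each estimate's `trait_id`).
#' @return data.frame of the retained estimates (`trait_id`, `name`,
#'   `h2_obs`, `se`, `z_h2`, `p_one_sided`), with attributes `n_input`,
#'   `n_pass_filters`, `n_unique` recording the counts at each step.
#' @export
filter_panel <- function(estimates, names = NULL) {
  if (is.null(names))
    names <- vapply(estimates, `[[`, character(1), "trait_id")
  tab <- data.frame(
    trait_id = vapply(estimates, `[[`, character(1), "trait_id"),
    name = names,
    h2_obs = vapply(estimates, `[[`, numeric(1), "h2_obs"),
    se = vapply(estimates, `[[`, numeric(1), "se"),
    z_h2 = vapply(estimates, `[[`, numeric(1), "z_h2"),
    p_one_sided = vapply(estimates, `[[`, numeric(1), "p_one_sided"),
    stringsAsFactors = FALSE)
  n_input <- nrow(tab)
  tab <- tab[tab$z_h2 > 1.64 & tab$h2_obs > 0 & tab$h2_obs < 1, , drop = FALSE]
  n_pass <- nrow(tab)
  tab <- tab[order(tab$name, -tab$z_h2), , drop = FALSE]
  tab <- tab[!duplicated(tab$name), , drop = FALSE]
  tab <- tab[order(tab$trait_id), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "n_input") <- n_input
  attr(tab, "n_pass_filters") <- n_pass
  attr(tab, "n_unique") <- nrow(tab)
  tab
}

#' Cross-trait genetic correlation by LD score regression
#'
#' Regresses the per-variant product `z_a * z_b` on
#' `sqrt(N_a N_b) * l_j / M`; the slope estimates the genetic covariance and
#' the intercept absorbs phenotypic correlation among overlapping samples.
#' Two fits are performed — free intercept and intercept constrained to zero.
#' The free fit is reported when its intercept is significant (jackknife
#' two-sided P <= 0.05, evidence of sample overlap); otherwise the
#' constrained fit is reported to reduce the standard error, with
#' `intercept_constrained` recording the choice. `rg = gcov /
#' sqrt(h2_a h2_b)`; its SE comes from jackknifing the full ratio (numerator
#' and both heritabilities re-estimated per deleted block).
#'
#' @param a,b harmonized [sumstats] objects on a shared variant frame.
#' @param scores LD score table from [ld_scores()].
#' @param n_blocks_jackknife number of jackknife blocks (default 200).
#' @return An object of class `rg_estimate`: `rg`, `se`, `p_rg` (two-sided),
#'   `gcov`, `gcov_intercept`, `intercept_constrained`, `h2_a`, `h2_b`,
#'   `m_snps`.
#' @export
ldsc_rg <- function(a, b, scores, n_blocks_jackknife = 200) {
  shared <- intersect(a$data$snp, b$data$snp)
  da <- a$data[match(shared, a$data$snp), , drop = FALSE]
  db <- b$data[match(shared, b$data$snp), , drop = FALSE]
  idx <- match(shared, scores$snp)
  keep <- !is.na(idx)
  da <- da[keep, , drop = FALSE]; db <- db[keep, , drop = FALSE]
  ell <- scores$ld_score[idx[keep]]
  ord <- order(da$chrom, da$pos)
  da <- da[ord, , drop = FALSE]; db <- db[ord, , drop = FALSE]
  ell <- ell[ord]
  m <- nrow(da)
  if (m < 200L) stop("need at least 200 shared SNPs with LD scores, got ", m)
  n1 <- mean(da$n); n2 <- mean(db$n)

  h2_fit <- function(z, n_bar) {
    x <- n_bar * ell / m
    y <- z^2
    h2_cur <- max(0, (mean(y) - 1) / mean(x))
    for (step in 1:2) {
      w <- 1 / (pmax(ell, 1) * (1 + n_bar * h2_cur * ell / m)^2)
      fit <- wls_jackknife(x, y, w, n_blocks_jackknife)
      h2_cur <- max(0, fit$slope)
    }
    fit
  }
  fit_a <- h2_fit(da$z, n1)
  fit_b <- h2_fit(db$z, n2)
  h2_a <- fit_a$slope; h2_b <- fit_b$slope
  if (h2_a <= 0 || h2_b <= 0)
    stop("genetic correlation undefined: non-positive heritability estimate (",
         signif(h2_a, 3), ", ", signif(h2_b, 3), ")")
  x <- sqrt(n1 * n2) * ell / m
  y <- da$z * db$z
  w <- 1 / (pmax(ell, 1) *
              (1 + n1 * h2_a * ell / m) * (1 + n2 * h2_b * ell / m))
  fit_free <- wls_jackknife(x, y, w, n_blocks_jackknife, intercept = TRUE)
  fit_zero <- wls_jackknife(x, y, w, n_blocks_jackknife, intercept = FALSE)
  int_z <- fit_free$intercept / fit_free$intercept_se
  int_p <- 2 * stats::pnorm(-abs(int_z))
  use_free <- int_p <= 0.05
  fit <- if (use_free) fit_free else fit_zero
  # jackknife the ratio rg = gcov / sqrt(h2_a h2_b)
  rg_del <- fit$delete_values[, 2L] /
    sqrt(pmax(fit_a$delete_values[, 2L], 1e-12) *
         pmax(fit_b$delete_values[, 2L], 1e-12))
  rg_full <- fit$slope / sqrt(h2_a * h2_b)
  B <- fit$n_blocks
  rg_se <- sqrt((B - 1) / B * sum((rg_del - mean(rg_del))^2))
  p_rg <- 2 * stats::pnorm(-abs(rg_full / rg_se))
  structure(list(trait_pair = c(a$trait_id, b$trait_id),
                 rg = rg_full, se = rg_se, p_rg = p_rg,
                 gcov = fit$slope,
                 gcov_intercept = fit_free$intercept,
                 gcov_intercept_se = fit_free$intercept_se,
                 gcov_intercept_p = int_p,
                 intercept_constrained = !use_free,
                 h2_a = h2_a, h2_b = h2_b, m_snps = m),
            class = "rg_estimate")
}

#' @export
print.rg_estimate <- function(x, ...) {
  cat(sprintf("<rg_estimate> %s ~ %s: rg = %.3f (SE %.3f, P = %.3g)%s\n",
              x$trait_pair[1L], x$trait_pair[2L], x$rg, x$se, x$p_rg,
              if (x$intercept_constrained) " [intercept constrained to 0]"
              else " [free intercept]"))
  invisible(x)
}
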