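#' Wakefield approximate Bayes factor for one variant
#'
#' Evidence in favour of association from a Z score and its standard error
#' under a normal prior on the effect size with variance `prior_w`:
#' with `V = se^2` and shrinkage `W / (V + W)` written r,
#' `ABF = sqrt(1 - r) * exp(z^2 r / 2)`. `W = 0` gives ABF = 1 for any z (a
#' point-null prior carries no evidence either way).
#'
#' @param z association Z score(s).
#' @param se standard error(s), positive.
#' @param prior_w prior variance W on the effect size (default 0.01, i.e. a
#'   prior SD of 0.1 on the standardized effect).
#' @param log if `TRUE` return log ABF.
#' @return ABF (vectorized over `z`/`se`).
#' @export
wakefield_abf <- function(z, se, prior_w = 0.01, log = FALSE) {
  if (any(se <= 0)) stop("se must be positive")
  if (prior_w < 0) stop("prior_w must be non-negative")
  V <- se^2
  r <- prior_w / (V + prior_w)
  labf <- 0.5 * log1p(-r) + z^2 * r / 2
  if (log) labf else exp(labf)
}

#' Model priors for the four-model regional analysis
#'
#' @param pi0,pi1,pi2,pi3,pi4 prior probabilities of: no association, trait-1
#'   only, trait-2 only, shared variant, two distinct variants. Must sum to 1.
#' @return Numeric vector of class `model_priors`.
#' @export
model_priors <- function(pi0 = 0.6, pi1 = 0.1, pi2 = 0.1, pi3 = 0.1,
                         pi4 = 0.1) {
  p <- c(pi0 = pi0, pi1 = pi1, pi2 = pi2, pi3 = pi3, pi4 = pi4)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop("priors must be non-negative and sum to 1")
  structure(p, class = "model_priors")
}

se_for_abf <- function(d) {
  se <- d$se
  need <- is.na(se)
  if (any(need)) {
    f <- d$maf[need]
    n <- d$n[need]
    se[need] <- ifelse(!is.na(f), se_from_freq_n(d$z[need], n, f),
                       1 / sqrt(n))
  }
  se
}

# regional log Bayes factors for the four association models from per-snp
# log-ABFs of the two traits
regional_log_bf <- function(labf1, labf2) {
  K <- length(labf1)
  lse <- function(x) {
    m <- max(x)
    if (!is.finite(m)) return(m)
    m + log(sum(exp(x - m)))
  }
  lbf1 <- lse(labf1) - log(K)          # M1: mean ABF1
  lbf2 <- lse(labf2) - log(K)          # M2: mean ABF2
  lbf3 <- lse(labf1 + labf2) - log(K)  # M3: mean ABF1*ABF2 (same variant)
  if (K > 1) {
    # M4: mean over ordered distinct pairs of ABF1_i * ABF2_j
    big <- lse(labf1) + lse(labf2)
    same <- lse(labf1 + labf2)
    diff <- big + log1p(-exp(pmin(same - big, 0)))
    lbf4 <- if (is.finite(diff)) diff - log(K) - log(K - 1) else -Inf
  } else lbf4 <- -Inf
  c(lbf1, lbf2, lbf3, lbf4)
}

#' Four-model regional association posteriors for one locus
#'
#' For one LD-independent locus, computes per-variant approximate Bayes
#' factors for both traits and combines them into regional Bayes factors for
#' four models — association to trait 1 only, trait 2 only, both via one
#' shared variant, both via two distinct variants — then posteriors
#' `PPA_m` proportional to `pi_m BF_m` with the null carrying `BF_0 = 1`.
#'
#' @param s1,s2 harmonized [sumstats] objects.
#' @param locus list or one-row data.frame with `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @param priors a [model_priors] vector.
#' @param prior_w Wakefield prior variance (default 0.01).
#' @param call_threshold posterior needed to call a model (default 0.9).
#' @return An object of class `regional_posterior`: `ppa` (PPA1..PPA4),
#'   `null_mass`, `lead_snp` (max joint ABF under the shared model), `call`
#'   (`none`/`trait1`/`trait2`/`shared`/`distinct`), `n_snps`, and the
#'   per-model log Bayes factors.
#' @export
region_posteriors <- function(s1, s2, locus, priors = model_priors(),
                              prior_w = 0.01, call_threshold = 0.9) {
  in_locus <- function(d) d$chrom == as.character(locus$chrom) &
    d$pos >= locus$start & d$pos <= locus$end
  d1 <- s1$data[in_locus(s1$data), , drop = FALSE]
  d2 <- s2$data[in_locus(s2$data), , drop = FALSE]
  shared <- intersect(d1$snp, d2$snp)
  if (length(shared) == 0L) stop("no shared variants in locus")
  d1 <- d1[match(shared, d1$snp), , drop = FALSE]
  d2 <- d2[match(shared, d2$snp), , drop = FALSE]
  labf1 <- wakefield_abf(d1$z, se_for_abf(d1), prior_w, log = TRUE)
  labf2 <- wakefield_abf(d2$z, se_for_abf(d2), prior_w, log = TRUE)
  lbf <- regional_log_bf(labf1, labf2)
  logw <- log(as.numeric(priors)) + c(0, lbf)   # null first
  logw[is.nan(logw)] <- -Inf
  w <- exp(logw - max(logw))
  post <- w / sum(w)
  ppa <- post[-1L]
  names(ppa) <- paste0("PPA", 1:4)
  lead <- shared[which.max(labf1 + labf2)]
  calls <- c("trait1", "trait2", "shared", "distinct")
  call <- if (any(ppa >= call_threshold))
    calls[which.max(ppa)] else "none"
  structure(list(locus = locus, ppa = ppa, null_mass = post[1L],
                 lead_snp = lead, call = call, n_snps = length(shared),
                 log_bf = lbf),
            class = "regional_posterior")
}

#' @export
print.regional_posterior <- function(x, ...) {
  cat(sprintf("<regional_posterior> %s:%d-%d (%d SNPs): PPA = %s; call = %s (lead %s)\n",
              x$locus$chrom, x$locus$start, x$locus$end, x$n_snps,
              paste(sprintf("%.3f", x$ppa), collapse = "/"),
              x$call, x$lead_snp))
  invisible(x)
}

#' Fit regional model priors across loci by EM
#'
#' Maximizes the marginal likelihood `prod_l sum_m pi_m BF_ml` over the
#' prior simplex by expectation-maximization across all loci of a run.
#'
#' @param log_bf_list list of length-4 numeric vectors of per-locus log
#'   Bayes factors (as in the `log_bf` field of [region_posteriors()]).
#' @param max_iter,tol EM controls.
#' @return A [model_priors] vector.
#' @export
fit_region_priors <- function(log_bf_list, max_iter = 200, tol = 1e-8) {
  L <- do.call(rbind, lapply(log_bf_list, function(b) c(0, b)))
  L[is.nan(L) | is.na(L)] <- -Inf
  pi_cur <- rep(1 / 5, 5)
  for (it in seq_len(max_iter)) {
    lw <- sweep(L, 2, log(pmax(pi_cur, 1e-300)), "+")
    mx <- apply(lw, 1, max)
    post <- exp(lw - mx)
    post <- post / rowSums(post)
    pi_new <- colMeans(post)
    if (max(abs(pi_new - pi_cur)) < tol) { pi_cur <- pi_new; break }
    pi_cur <- pi_new
  }
  model_priors(pi_cur[1L], pi_cur[2L], pi_cur[3L], pi_cur[4L], pi_cur[5L])
}

#' Run the regional analysis over a set of loci
#'
#' Computes per-locus log Bayes factors, fits the model priors across loci
#' by EM (unless fixed priors are supplied), and returns the per-locus
#' posteriors.
#'
#' @param s1,s2 harmonized [sumstats] objects.
#' @param loci data.frame of locus intervals (`chrom`, `start`, `end`,
#'   `name`).
#' @param priors fixed [model_priors], or `NULL` (default) to fit them
#'   across loci.
#' @param prior_w Wakefield prior variance.
#' @param call_threshold posterior call threshold (default 0.9).
#' @return List of `regional_posterior` objects (loci with no shared
#'   variants skipped), with the fitted priors as attribute `priors`.
#' @export
regional_scan <- function(s1, s2, loci, priors = NULL, prior_w = 0.01,
                          call_threshold = 0.9) {
  flat <- model_priors(0.2, 0.2, 0.2, 0.2, 0.2)
  first <- lapply(seq_len(nrow(loci)), function(i) {
    tryCatch(region_posteriors(s1, s2, loci[i, ], flat, prior_w,
                               call_threshold),
             error = function(e) NULL)
  })
  first <- Filter(Negate(is.null), first)
  if (length(first) == 0L) return(structure(list(), priors = priors))
  if (is.null(priors))
    priors <- fit_region_priors(lapply(first, `[[`, "log_bf"))
  out <- lapply(first, function(rp) {
    logw <- log(pmax(as.numeric(priors), 1e-300)) + c(0, rp$log_bf)
    w <- exp(logw - max(logw))
    post <- w / sum(w)
    rp$ppa <- stats::setNames(post[-1L], paste0("PPA", 1:4))
    rp$null_mass <- post[1L]
    calls <- c("trait1", "trait2", "shared", "distinct")
    rp$call <- if (any(rp$ppa >= call_threshold))
      calls[which.max(rp$ppa)] else "none"
    rp
  })
  structure(out, priors = priors)
}

#' Proportion of trait-2-affecting loci that are pleiotropic
#'
#' Among loci credibly affecting trait 2 (PPA2 >= `threshold`,
#' PPA3 >= `threshold` or PPA4 >= `threshold`), the fraction that affect both
#' traits through a shared variant (PPA3 >= `threshold`). Returns `NA` when
#' no locus qualifies for the denominator.
#'
#' @param posteriors list of `regional_posterior` objects.
#' @param threshold posterior threshold (default 0.9).
#' @return Proportion in `[0, 1]`, or `NA_real_`.
#' @export
pleiotropy_proportion <- function(posteriors, threshold = 0.9) {
  ppa <- do.call(rbind, lapply(posteriors, `[[`, "ppa"))
  if (is.null(ppa) || nrow(ppa) == 0L) return(NA_real_)
  denom <- sum(ppa[, 2L] >= threshold | ppa[, 3L] >= threshold |
                 ppa[, 4L] >= threshold)
  if (denom == 0L) return(NA_real_)
  sum(ppa[, 3L] >= threshold) / denom
}
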