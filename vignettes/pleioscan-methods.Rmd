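---
title: "Models and methods behind pleioscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pleioscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`pleioscan` studies shared polygenic architecture between a complex disease
and a panel of molecular traits using only GWAS summary statistics. This
vignette describes the statistical models, the choices we made where the
design was genuinely open, and what the synthetic-data generator does and
does not emulate.

## The data model

Every analysis consumes per-variant association records: a signed Z score,
sample size N, alleles, position, and optionally beta/SE, allele frequency
and imputation quality. Under a polygenic model with standardized
per-variant effects $\beta$ (so $\sum_j \beta_j^2 = h^2_{SNP}$ over the M
variants) and local LD correlation matrix $R$, the marginal Z scores of a
block are distributed as

$$z \sim \mathcal{N}\!\left(\sqrt{N}\,R\beta,\; R\right),$$

which implies the LD score regression identity
$E[z_j^2] = 1 + N h^2 \ell_j / M$ with $\ell_j = \sum_k r_{jk}^2$. These
are exactly the sufficient statistics the pipeline consumes, which is why
the simulator draws marginal statistics directly rather than genotypes.

## Heritability screen

`ldsc_h2()` regresses $z_j^2$ on $N\ell_j/M$ with a free intercept.
Weights $1/(\ell_j (1 + N h^2 \ell_j / M)^2)$ counter LD overcounting and
heteroskedasticity; because they depend on the unknown slope, they are
iterated twice from a moment-based initial estimate
$\hat h^2_0 = (\bar{z^2} - 1)\,M/(N\bar\ell)$. We use a moment initializer
rather than an unweighted regression because the regression design is
degenerate when all LD scores are equal (a legitimate configuration for
the simulator), while the moment ratio is always defined. Standard errors
come from a delete-a-block jackknife over 200 contiguous equal-count
variant blocks — the convention for this family of estimators; the
jackknife Z in turn yields the one-sided P used by the panel screen.
Jackknife blocks must span at least the LD correlation length to be
(approximately) independent; with simulated genomes of 50-variant LD
blocks the tests size `n_blocks_jackknife` so that each jackknife block
covers a whole LD block, and users of small references should do the
same. The panel screen (`filter_panel()`) keeps traits with Z > 1.64 and
0 < h² < 1 (both filters applied conjunctively) and the best Z per
duplicated trait.

Case-control traits are converted to the liability scale with the
standard threshold-model transform; K is the population prevalence, P the
sample prevalence, and the SE scales by the same factor. The transform is
validated in the tests against a numerically inverted normal tail rather
than against itself.

## Cross-trait genetic correlation

`ldsc_rg()` regresses $z_{aj} z_{bj}$ on $\sqrt{N_a N_b}\,\ell_j/M$. Two
fits are always produced: free genetic-covariance intercept (absorbing
phenotypic correlation among overlapping samples) and intercept
constrained to zero. The free fit is reported only when its intercept is
significant at P ≤ 0.05 by the jackknife test; otherwise the constrained
fit is reported, trading robustness for a smaller SE when there is no
evidence of sample overlap. The flag `intercept_constrained` records the
choice. The ratio $r_g = \widehat{gcov} / \sqrt{\hat h^2_a \hat h^2_b}$ is
jackknifed as a whole (numerator and both denominators re-estimated per
deleted block), not via the delta method. Like all ratio estimators it is
noisy and upward-biased when the denominators are poorly estimated; with
M ≈ 5000 variants and N = 20,000 the bias is negligible, and we use those
sizes wherever a point estimate of $r_g$ is reported.

## Imputation to a common frame

Panels of traits rarely share a variant frame. `impute_sumstats()`
restores a common frame via the conditional expectation under the block
MVN model, with a ridge term (default 0.1) on the typed-typed correlation
for numerical stability; `ridge = 0` is honoured exactly and surfaces
singularity rather than silently regularizing. Imputed variants with
predicted quality R² < 0.6 are dropped. Strand-ambiguous A/T and G/C
variants cannot be strand-resolved between studies, so they are removed
first and re-imputed from their neighbours like any other missing variant
(the quality filter applies to them too). Effect sizes for imputed records
are back-derived via $se = 1/\sqrt{2f(1-f)(N + z^2)}$ with $f$ the
reference allele frequency — a standard reconstitution that users should
treat as approximate. Imputation borrows strength within blocks only,
consistent with an LD-independent locus partition. Because imputation
quality correlates with LD score, the pipeline runs LD-score-based stages
(heritability, $r_g$, LCV) on the original statistics and all other stages
on the imputed frame.

## Genome-wide pleiotropy

Index variants come from greedy P-value-informed clumping (r² ≥ 0.1
within ±10 Mb removed, ties on P broken by position then identifier for
determinism; variants absent from the LD reference index themselves, as
clumping tools do, to avoid silently discarding signal). The genome-wide
test is the Pearson correlation of the two traits' Z scores across index
variants after allele harmonization; P comes from the t-distribution with
n − 2 df and the CI from the Fisher transform. A trait enters only with
> 60% of index variants present. The multiplicity correction is
Benjamini-Hochberg with an effective test count from the eigenvalues of
the panel's trait-trait correlation matrix, which we compute on the common
index-variant Z matrix (pairwise-complete) since the construction is
otherwise unspecified. Both the Nyholt variance-based and the Li & Ji
integer-part effective counts are reported; the FDR default uses Nyholt,
and with `m_eff` equal to the nominal count the procedure reduces exactly
to standard BH.

## Gene-level pleiotropy

The gene statistic is $T = \sum_j z_j^2$ over the variants assigned to a
gene (±500 kb inclusive window; variants may serve several genes). Its
null under local LD is $\sum_i \lambda_i \chi^2_1$ with $\lambda_i$ the
eigenvalues of the gene's LD submatrix (cross-block correlation set to 0).
We evaluate the tail with Ruben's mixture-of-chi-squares series, whose
truncation error is bounded by the unassigned mixture mass (tolerance
1e-9 for genes of ≤ 12 variants, 1e-5 for larger genes where the series
converges more slowly), falling back to a Lugannani–Rice saddlepoint when
the eigenvalue spread makes the series impractical or in the far tail.
We abandoned characteristic-function inversion with an adaptive
quadrature: it looked converged while carrying errors of order 1e-3
against exact two-eigenvalue cases. The tail is validated against Monte
Carlo throughout the tests.

Gene-level trait pleiotropy is a one-sided exact binomial test: with
$k_{trait}$ trait-associated genes (Bonferroni: $p \le 0.05/G$) of which
$k_{both}$ are also disease-associated, $P(X \ge k_{both})$ for
$X \sim \mathrm{Bin}(k_{trait}, |disease\ genes|/G)$. The combined
analysis Stouffer-combines a gene's disease P with the P values of the
proteins whose BH-adjusted gene P is ≤ 0.05 (gating requires the disease
to pass the same BH level), weighting each protein 1 and the disease by
the number of included proteins so the two sides contribute equally; the
declared test count is $(n_{proteins} + 1) \times G$. The per-gene
protein-inclusion rule uses trait-wide BH ranks; we record this as our
reading of an ambiguous construction, not as the only possible one.

## Regional pleiotropy

Per locus, each variant contributes a Wakefield approximate Bayes factor
$\sqrt{1-r}\exp(z^2 r/2)$, $r = W/(V+W)$, with prior effect variance
W = 0.01 (prior SD 0.1 on the standardized effect; configurable — the
choice matters mainly through the null/alternative balance, not the model
ranking). Regional Bayes factors average per-variant evidence: trait-1
only, trait-2 only, shared variant (mean of products), or two distinct
variants (mean over ordered distinct pairs; defined as 0 for
single-variant loci). Model priors are fitted across all loci of a run by
EM on the marginal likelihood, mirroring how pairwise-GWAS tools fit them;
fixed priors can be supplied for unit testing. A locus is called
pleiotropic at PPA3 ≥ 0.9, and the summary proportion divides the number
of shared-variant loci by the number of loci credibly affecting the
molecular trait under any model. Correlated effect sizes from sample
overlap are not modelled.

## Latent causal variable model

With standardized genetic effects $\alpha_1 = q_1\pi + \gamma_1$,
$\alpha_2 = q_2\pi + \gamma_2$ and a kurtotic latent factor $\pi$
(excess kurtosis $\kappa$), the genetic correlation is $\rho = q_1 q_2$
and the excess mixed fourth moments satisfy
$E[\alpha_1^3\alpha_2] - 3\rho = \kappa\rho q_1^2$ and symmetrically for
$q_2^2$. Parameterizing the genetic causality proportion $x$ through
$q_1^2 = |\rho|^{1-x}$, $q_2^2 = |\rho|^{1+x}$, the contrast
$S(x) = \hat k_{13}|\rho|^{x} - \hat k_{31}|\rho|^{-x}$ has expectation
zero at the true $x$. `lcv_gcp()` estimates the moments from
LD-score-weighted (weights $1/\max(1,\ell)^2$) normalized Z scores,
subtracting the sampling-noise contribution $3\,\widehat{nm}(z_1z_2)$, and
forms a posterior over a grid of $x \in [-1, 1]$ (step 0.01) from the
jackknife-standardized contrast with 100 contiguous blocks; the reported
gcp and SE are the posterior mean and SD, and the P value is the
two-sided t-test of $S(0)$. Positive gcp means trait 1 causes trait 2.
The estimator refuses traits without jackknife-significant heritability
and undefined correlations, and the reported $\rho$ is truncated to
[−1, 1] like any correlation estimate. Identifiability requires a
non-Gaussian effect distribution — with $\kappa = 0$ the contrast is
uninformative — which is why the simulator draws point-normal effects.
Whether the P value should be one- or two-sided is not externally fixed;
we use two-sided. Causality analysis is gated on a nominally significant
genetic correlation (P < 0.05, strict) and BH-corrected within the gated
set, each correction stage-local.

## The synthetic-data generator

`simulate_ld()` builds AR(1) blocks ($R_{jk} = \rho_{LD}^{|j-k|}$,
positive-definite by construction) laid out at 1 kb spacing with 1 Mb
gaps; `simulate_pair()`/`simulate_panel()` draw point-normal effects under
the latent-factor topologies above and then marginal Z scores per block.
Everything is deterministic given the spec seed. Default study conditions
mirror the sizes used by the tests and the acceptance script: M = 2000
(40 × 50) variants at N = 20,000 for heritability recovery, M = 5000 for
genetic-correlation point estimates, M = 20,000 independent variants at
N = 50,000 for LCV, 50-variant AR(0.9) loci with a planted z ≈ 8 causal
variant for the regional model, and null panels of 20 traits over 5000
index variants for FDR calibration — desk-scale versions of a
disease-versus-proteome study that one CPU can re-run in minutes.

What the generator does *not* emulate: realistic allele-frequency and
LD-score spectra (blocks are exchangeable, so LD scores span a narrow
range and regression intercepts are imprecisely extrapolated), imputation
error in the input GWAS, sample overlap between studies, population
stratification, and cross-block LD. Passing tests therefore demonstrate
correctness of the estimators under the stated generative model, not
robustness to every artefact of real GWAS data.

## Numerical and degenerate-input choices

* Positions are 1-based inclusive internally; BED input/output converts at
  the boundary.
* Harmonization resolves alleles by exact match, swap (sign flip), strand
  complement, then complemented swap; unresolvable or (optionally)
  strand-ambiguous variants are dropped from both traits.
* Clumping ties on P are broken by (chromosome, position, identifier).
* `qc_filter()` retains records lacking MAF or INFO — the filter applies
  only where studies reported the information.
* P values of exactly 0 are rejected at the container boundary; the
  simulator floors underflowing two-sided tails at the smallest positive
  double.
* Correlation matrices must be symmetric within 1e-8 with eigenvalues
  ≥ −1e-8; the sum of regional posteriors and the prior simplex are
  enforced to 1e-8.
* Single-variant loci set PPA4 = 0 by convention; an empty pleiotropy
  denominator yields NA rather than 0.

## Known limitations

The gene test is a sum-of-chi-squares model comparable to the "mean"
flavour of standard gene-based tools, not their covariate-conditioned
variants. The LCV moment normalization treats per-variant genetic variance
as homogeneous, which is exact for the simulator's equal-`\ell`
architectures and approximate under strong LD heterogeneity. Regional
posteriors assume at most one causal variant per trait per locus.
Instrument-based Mendelian randomization, partitioned heritability,
multi-ancestry references and genome-build liftover are out of scope.
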