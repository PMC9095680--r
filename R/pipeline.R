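#' Pipeline configuration
#'
#' Collects every tunable threshold of the pleiotropy/causality workflow with
#' the pipeline's defaults: QC (MAF >= 0.01, imputation quality >= 0.9),
#' heritability gating (Z > 1.64, 0 < h2 < 1), imputation quality floor
#' (R2 >= 0.6), clumping (r2 < 0.1 within 10 Mb), panel overlap gate
#' (> 60%), gene window (+/- 500 kb) and Bonferroni level, regional call
#' threshold (PPA3 >= 0.9), genetic-correlation gate (P < 0.05) and
#' stage-local FDR level (0.05).
#'
#' @param maf_min,info_min QC thresholds.
#' @param h2_z_min,h2_window heritability filter.
#' @param impute_r2_min imputation-quality floor.
#' @param clump_r2,clump_kb clumping parameters.
#' @param overlap_min minimum index-variant overlap (strict >).
#' @param gene_window_kb gene flanking window.
#' @param gene_alpha family-wise level for per-trait gene significance.
#' @param ppa_threshold regional posterior call threshold.
#' @param gate_prg genetic-correlation gate for LCV.
#' @param fdr stage-local FDR level.
#' @param seed integer seed recorded with the run.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(maf_min = 0.01, info_min = 0.9,
                            h2_z_min = 1.64, h2_window = c(0, 1),
                            impute_r2_min = 0.6,
                            clump_r2 = 0.1, clump_kb = 10000,
                            overlap_min = 0.6,
                            gene_window_kb = 500, gene_alpha = 0.05,
                            ppa_threshold = 0.9, gate_prg = 0.05,
                            fdr = 0.05, seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full pleiotropy and causality pipeline
#'
#' Orchestrates the whole workflow on in-memory objects: heritability
#' estimation and panel filtering, imputation to the common variant frame,
#' the three pleiotropy stages (genome-wide Z correlation over clumped index
#' variants, gene-level binomial enrichment, regional four-model posteriors),
#' and finally genetic-correlation gating plus LCV causality on the union of
#' pleiotropic traits. LD-score-based stages (heritability, rg, LCV) consume
#' the original summary statistics; all other stages the imputed ones. Each
#' FDR correction is stage-local.
#'
#' @param disease a [sumstats] object for the disease.
#' @param panel named list of [sumstats] objects for the molecular traits.
#' @param blocks LD reference (list of [ld_block]).
#' @param genes gene intervals data.frame (`chrom`, `start`, `end`, `name`).
#' @param loci locus intervals data.frame; defaults to the block intervals.
#' @param cfg a [pipeline_config].
#' @return List of per-stage tables: `h2` (panel estimates + filter),
#'   `index_snps`, `gw` (correlation tests with q-values), `gene`
#'   (enrichment tests), `combined` (combined gene analysis), `regional`
#'   (per trait: pleiotropic locus count, proportion), `pleiotropic_union`,
#'   `causality` (gated rg + LCV table), `log`, and the `config`.
#' @export
run_pipeline <- function(disease, panel, blocks, genes, loci = NULL,
                         cfg = pipeline_config()) {
  log <- character(0)
  say <- function(...) log <<- c(log, sprintf(...))
  scores <- ld_scores(blocks)
  if (is.null(loci)) {
    loci <- do.call(rbind, lapply(blocks, function(b)
      data.frame(chrom = b$interval$chrom, start = b$interval$start,
                 end = b$interval$end, name = b$name)))
  }
  # stage 1: heritability filter on original statistics
  panel <- lapply(panel, qc_filter, maf_min = cfg$maf_min,
                  info_min = cfg$info_min)
  ests <- lapply(panel, function(s)
    tryCatch(ldsc_h2(s, scores), error = function(e) NULL))
  ok <- !vapply(ests, is.null, logical(1))
  h2_tab <- filter_panel(ests[ok])
  keep_traits <- intersect(h2_tab$trait_id, names(panel))
  say("heritability filter: %d of %d traits retained (z > %g, 0 < h2 < 1)",
      length(keep_traits), length(panel), cfg$h2_z_min)
  # stage 2: imputation to the common frame for the non-LDSC stages
  disease_imp <- impute_sumstats(disease, blocks, r2_min = cfg$impute_r2_min)
  panel_imp <- lapply(panel[keep_traits], impute_sumstats, blocks = blocks,
                      r2_min = cfg$impute_r2_min)
  # stage 3a: genome-wide pleiotropy
  index_snps <- clump(disease_imp, blocks, r2_max = cfg$clump_r2,
                      window_kb = cfg$clump_kb)
  say("clumping: %d index variants", length(index_snps))
  gw_rows <- list()
  for (tr in keep_traits) {
    hp <- harmonize(disease_imp, panel_imp[[tr]])
    ov <- overlap_fraction(index_snps, hp$b)
    if (ov <= cfg$overlap_min) next
    pc <- z_correlation(hp$a, hp$b, index_snps)
    gw_rows[[tr]] <- data.frame(trait = tr, r = pc$r, p = pc$p_two_sided,
                                n_snps = pc$n_snps, overlap = ov,
                                stringsAsFactors = FALSE)
  }
  gw <- if (length(gw_rows)) do.call(rbind, gw_rows) else NULL
  gw_hits <- character(0)
  meff <- NULL
  if (!is.null(gw) && nrow(gw) > 0L) {
    C <- panel_correlation(panel_imp[gw$trait], index_snps)
    meff <- matspd(C)
    gw$q <- fdr_meff(gw$p, meff$m_eff_nyholt)
    gw_hits <- gw$trait[gw$q <= cfg$fdr]
    rownames(gw) <- NULL
  }
  say("genome-wide pleiotropy: %d traits tested, %d hits (FDR <= %g)",
      if (is.null(gw)) 0L else nrow(gw), length(gw_hits), cfg$fdr)
  # stage 3b: gene-level pleiotropy
  G <- nrow(genes)
  bonf <- cfg$gene_alpha / G
  disease_genes <- gene_scan(disease_imp, genes, blocks,
                             window_kb = cfg$gene_window_kb)
  disease_sig <- disease_genes$gene[disease_genes$p_gene <= bonf]
  gene_rows <- list()
  protein_scans <- list()
  for (tr in keep_traits) {
    sc <- gene_scan(panel_imp[[tr]], genes, blocks,
                    window_kb = cfg$gene_window_kb)
    protein_scans[[tr]] <- sc
    trait_sig <- sc$gene[sc$p_gene <= bonf]
    if (length(trait_sig) == 0L || length(disease_sig) == 0L) next
    en <- binomial_enrichment(disease_sig, trait_sig, G)
    gene_rows[[tr]] <- data.frame(trait = tr, k_both = en$k_both,
                                  k_trait = en$k_trait, p0 = en$p0,
                                  p_binom = en$p_binom,
                                  stringsAsFactors = FALSE)
  }
  gene_tab <- if (length(gene_rows)) do.call(rbind, gene_rows) else NULL
  gene_hits <- character(0)
  if (!is.null(gene_tab)) {
    gene_tab$fdr_q <- stats::p.adjust(gene_tab$p_binom, method = "BH")
    gene_hits <- gene_tab$trait[gene_tab$fdr_q <= cfg$fdr]
    rownames(gene_tab) <- NULL
  }
  combined <- if (length(gene_hits) > 0L)
    combined_gene_analysis(disease_genes, protein_scans[gene_hits], G,
                           bh_alpha = cfg$fdr) else NULL
  say("gene pleiotropy: %d traits enriched (FDR <= %g) of %s tested",
      length(gene_hits), cfg$fdr,
      if (is.null(gene_tab)) "0" else nrow(gene_tab))
  # stage 3c: regional pleiotropy
  reg_rows <- list()
  for (tr in keep_traits) {
    hp <- harmonize(disease_imp, panel_imp[[tr]])
    rs <- regional_scan(hp$a, hp$b, loci,
                        call_threshold = cfg$ppa_threshold)
    if (length(rs) == 0L) next
    ppa3 <- vapply(rs, function(x) x$ppa[["PPA3"]], numeric(1))
    reg_rows[[tr]] <- data.frame(
      trait = tr, n_loci = length(rs),
      n_pleio = sum(ppa3 >= cfg$ppa_threshold),
      proportion = pleiotropy_proportion(rs, cfg$ppa_threshold),
      stringsAsFactors = FALSE)
  }
  reg_tab <- if (length(reg_rows)) do.call(rbind, reg_rows) else NULL
  reg_hits <- if (is.null(reg_tab)) character(0)
              else reg_tab$trait[reg_tab$n_pleio > 0L]
  if (!is.null(reg_tab)) rownames(reg_tab) <- NULL
  say("regional pleiotropy: %d traits with a PPA3 >= %g locus",
      length(reg_hits), cfg$ppa_threshold)
  # stage 4: causality on the pleiotropic union, original statistics
  union_traits <- sort(unique(c(gw_hits, gene_hits, reg_hits)))
  say("pleiotropic union: %d unique traits", length(union_traits))
  rg_list <- list(); lcv_list <- list()
  for (tr in union_traits) {
    hp <- harmonize(disease, panel[[tr]])
    rg <- tryCatch(ldsc_rg(hp$b, hp$a, scores), error = function(e) NULL)
    if (is.null(rg)) next
    lcv <- if (rg$p_rg < cfg$gate_prg)
      tryCatch(lcv_gcp(hp$b, hp$a, scores), error = function(e) NULL)
    else NULL
    rg_list[tr] <- list(rg)
    lcv_list[tr] <- list(lcv)   # may be NULL: keep list lengths aligned
  }
  causality <- if (length(rg_list))
    gate_and_correct(unname(rg_list), unname(lcv_list), fdr = cfg$fdr)
  else NULL
  say("causality: %d gated pairs, %d significant at FDR <= %g",
      if (is.null(causality)) 0L else nrow(causality),
      if (is.null(causality)) 0L else sum(causality$sig), cfg$fdr)
  list(h2 = h2_tab, index_snps = index_snps, gw = gw, meff = meff,
       gw_hits = gw_hits, gene = gene_tab, gene_hits = gene_hits,
       combined = combined, regional = reg_tab, regional_hits = reg_hits,
       pleiotropic_union = union_traits, causality = causality,
       log = log, config = cfg)
}
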