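COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Construct a summary-statistics object
#'
#' A `sumstats` object holds one trait's per-variant GWAS association records:
#' variant identifier, genomic coordinates, effect/other alleles, a signed
#' association Z score (derived from beta/SE when not supplied directly),
#' two-sided P value and effective sample size, plus optional allele frequency
#' and imputation-quality columns. Records are stored sorted by chromosome and
#' position and variant identifiers must be unique.
#'
#' @param data data.frame with columns `snp`, `chrom`, `pos`, `a1` (effect
#'   allele), `a2` (other allele), `z`, `p`, `n`; optional `beta`, `se`,
#'   `maf`, `info`.
#' @param trait_id character scalar naming the trait.
#' @param provenance character vector of free-text processing notes.
#' @return An object of class `sumstats`.
#' @export
sumstats <- function(data, trait_id, provenance = character()) {
  required <- c("snp", "chrom", "pos", "a1", "a2", "z", "p", "n")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0L)
    stop("sumstats data lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  for (col in c("beta", "se", "maf", "info"))
    if (is.null(data[[col]])) data[[col]] <- NA_real_
  data <- data[, c(required, "beta", "se", "maf", "info")]
  data$snp   <- as.character(data$snp)
  data$chrom <- as.character(data$chrom)
  data$pos   <- as.integer(data$pos)
  if (anyDuplicated(data$snp))
    stop("duplicated snp ids in sumstats: ",
         paste(utils::head(unique(data$snp[duplicated(data$snp)]), 3),
               collapse = ", "))
  bad_p <- !is.na(data$p) & (data$p <= 0 | data$p > 1)
  if (any(bad_p))
    stop("p values must lie in (0, 1]; offending snp: ",
         data$snp[which(bad_p)[1L]])
  if (any(data$a1 == data$a2))
    stop("effect allele equals other allele for snp ",
         data$snp[which(data$a1 == data$a2)[1L]])
  has_bse <- !is.na(data$beta) & !is.na(data$se)
  if (any(has_bse)) {
    rel <- abs(data$z[has_bse] - data$beta[has_bse] / data$se[has_bse]) /
      pmax(abs(data$z[has_bse]), 1)
    if (any(rel > 1e-6))
      stop("z inconsistent with beta/se beyond 1e-6 relative tolerance")
  }
  data <- data[order(data$chrom, data$pos, data$snp), , drop = FALSE]
  rownames(data) <- NULL
  structure(list(trait_id = as.character(trait_id),
                 data = data,
                 provenance = provenance),
            class = "sumstats")
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("<sumstats> trait '%s': %d variants on %d chromosome(s)\n",
              x$trait_id, nrow(x$data), length(unique(x$data$chrom))))
  if (length(x$provenance))
    cat(paste0("  ", x$provenance, collapse = "\n"), "\n")
  invisible(x)
}

n_variants <- function(s) nrow(s$data)

default_column_map <- function() {
  c(snp = "SNP", chrom = "CHR", pos = "BP", a1 = "A1", a2 = "A2",
    z = "Z", beta = "BETA", se = "SE", p = "P", n = "N",
    maf = "MAF", info = "INFO")
}

#' Read GWAS summary statistics from a tab-delimited file
#'
#' Reads a header-bearing tab-delimited association file and returns a
#' [sumstats] object. Z scores are derived as beta/SE when only effect sizes
#' are given; a P column is derived from the two-sided normal tail of Z when
#' absent. Rows whose alleles are not single A/C/G/T bases are dropped and the
#' count recorded in the provenance.
#'
#' @param path file path.
#' @param trait_id trait name; defaults to the file's base name.
#' @param column_map named character vector mapping internal field names
#'   (`snp`, `chrom`, `pos`, `a1`, `a2`, `z`, `beta`, `se`, `p`, `n`, `maf`,
#'   `info`) to header names in the file. Defaults to the conventional
#'   SNP/CHR/BP/A1/A2/Z/BETA/SE/P/N/MAF/INFO header.
#' @return A [sumstats] object.
#' @export
read_sumstats <- function(path, trait_id = NULL, column_map = NULL) {
  cmap <- default_column_map()
  if (!is.null(column_map)) cmap[names(column_map)] <- column_map
  if (is.null(trait_id))
    trait_id <- sub("\\.(tsv|txt|sumstats)(\\.gz)?$", "", basename(path))
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0L) stop("no rows in ", path)
  grab <- function(field) {
    col <- cmap[[field]]
    if (!is.null(col) && col %in% names(raw)) raw[[col]] else NULL
  }
  required <- c("snp", "chrom", "pos", "a1", "a2", "n")
  for (field in required)
    if (is.null(grab(field)))
      stop("required column '", cmap[[field]], "' (", field,
           ") absent from ", path)
  z <- grab("z"); beta <- grab("beta"); se <- grab("se"); p <- grab("p")
  if (is.null(z)) {
    if (is.null(beta) || is.null(se))
      stop("file must provide either a Z column or both BETA and SE: ", path)
    z <- beta / se
  }
  if (is.null(p)) p <- 2 * stats::pnorm(-abs(z))
  d <- data.frame(snp = as.character(grab("snp")),
                  chrom = as.character(grab("chrom")),
                  pos = as.integer(grab("pos")),
                  a1 = toupper(as.character(grab("a1"))),
                  a2 = toupper(as.character(grab("a2"))),
                  z = as.numeric(z),
                  p = as.numeric(p),
                  n = as.numeric(grab("n")),
                  stringsAsFactors = FALSE)
  d$beta <- if (is.null(beta)) NA_real_ else as.numeric(beta)
  d$se   <- if (is.null(se)) NA_real_ else as.numeric(se)
  d$maf  <- if (is.null(grab("maf"))) NA_real_ else as.numeric(grab("maf"))
  d$info <- if (is.null(grab("info"))) NA_real_ else as.numeric(grab("info"))
  ok_allele <- d$a1 %in% names(COMPLEMENT) & d$a2 %in% names(COMPLEMENT)
  n_dropped <- sum(!ok_allele)
  d <- d[ok_allele, , drop = FALSE]
  if (nrow(d) == 0L) stop("zero parseable rows in ", path)
  prov <- sprintf("read %d records from %s (%d rows with unparseable alleles dropped)",
                  nrow(d), basename(path), n_dropped)
  sumstats(d, trait_id = trait_id, provenance = prov)
}

#' Write summary statistics to a tab-delimited file
#'
#' Inverse of [read_sumstats()]: emits the conventional
#' SNP/CHR/BP/A1/A2/Z/BETA/SE/P/N/MAF/INFO header. Optional columns that are
#' entirely missing are omitted.
#'
#' @param s a [sumstats] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(s, path) {
  d <- s$data
  out <- data.frame(SNP = d$snp, CHR = d$chrom, BP = d$pos,
                    A1 = d$a1, A2 = d$a2, Z = d$z, BETA = d$beta, SE = d$se,
                    P = d$p, N = d$n, MAF = d$maf, INFO = d$info,
                    stringsAsFactors = FALSE)
  for (col in c("BETA", "SE", "MAF", "INFO"))
    if (all(is.na(out[[col]]))) out[[col]] <- NULL
  utils::write.table(format(out, digits = 17, trim = TRUE, scientific = NA),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter variants on allele frequency and imputation quality
#'
#' Removes variants with minor allele frequency below `maf_min` or imputation
#' quality below `info_min`. Variants lacking the relevant column are retained
#' (the filter is applied only where the study reported the information).
#'
#' @param s a [sumstats] object.
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param info_min minimum imputation quality (default 0.9).
#' @return Filtered [sumstats]; counts of removed records appended to
#'   provenance.
#' @export
qc_filter <- function(s, maf_min = 0.01, info_min = 0.9) {
  d <- s$data
  drop_maf  <- !is.na(d$maf)  & d$maf  < maf_min
  drop_info <- !is.na(d$info) & d$info < info_min
  keep <- !(drop_maf | drop_info)
  s$data <- d[keep, , drop = FALSE]
  rownames(s$data) <- NULL
  s$provenance <- c(s$provenance,
                    sprintf("qc_filter: removed %d (maf < %g), %d (info < %g); %d retained",
                            sum(drop_maf), maf_min, sum(drop_info & !drop_maf),
                            info_min, sum(keep)))
  s
}

is_ambiguous <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
  (a1 == "G" & a2 == "C") | (a1 == "C" & a2 == "G")
}

#' Harmonize two summary-statistics objects to a shared allele frame
#'
#' Restricts both traits to their shared variant identifiers and aligns the
#' second trait's effect direction to the first trait's effect allele. Allele
#' matching tries the exact pair, then the swapped pair (sign flip), then the
#' strand-complemented pair, then the complemented swapped pair; variants whose
#' alleles cannot be reconciled are dropped from both. Strand-ambiguous (A/T,
#' G/C) variants cannot be strand-resolved and are removed from both when
#' `drop_ambiguous` is set.
#'
#' @param a,b [sumstats] objects sharing variant identifiers.
#' @param drop_ambiguous drop A/T and G/C variants (default `TRUE`).
#' @return A list with elements `a` and `b`, both restricted to the harmonized
#'   variants, with `b`'s `z` and `beta` signs flipped where its effect allele
#'   matched `a`'s other allele.
#' @export
harmonize <- function(a, b, drop_ambiguous = TRUE) {
  shared <- intersect(a$data$snp, b$data$snp)
  if (length(shared) == 0L) stop("no shared snp ids between '", a$trait_id,
                                 "' and '", b$trait_id, "'")
  da <- a$data[match(shared, a$data$snp), , drop = FALSE]
  db <- b$data[match(shared, b$data$snp), , drop = FALSE]
  if (drop_ambiguous) {
    amb <- is_ambiguous(da$a1, da$a2) | is_ambiguous(db$a1, db$a2)
    da <- da[!amb, , drop = FALSE]
    db <- db[!amb, , drop = FALSE]
  }
  rc <- function(x) unname(COMPLEMENT[x])
  same  <- db$a1 == da$a1 & db$a2 == da$a2
  swap  <- db$a1 == da$a2 & db$a2 == da$a1
  csame <- rc(db$a1) == da$a1 & rc(db$a2) == da$a2
  cswap <- rc(db$a1) == da$a2 & rc(db$a2) == da$a1
  flip <- (swap | cswap) & !(same | csame)
  keep <- same | swap | csame | cswap
  da <- da[keep, , drop = FALSE]
  db <- db[keep, , drop = FALSE]
  flip <- flip[keep]
  db$z[flip] <- -db$z[flip]
  db$beta[flip] <- -db$beta[flip]
  db$a1 <- da$a1
  db$a2 <- da$a2
  if (nrow(da) == 0L) stop("no variants survive harmonization")
  note <- sprintf("harmonize vs '%s': %d shared, %d flipped, %d retained",
                  a$trait_id, length(shared), sum(flip), nrow(da))
  out_a <- sumstats(da, a$trait_id, c(a$provenance, note))
  out_b <- sumstats(db, b$trait_id, c(b$provenance, note))
  list(a = out_a, b = out_b)
}

#' Read genomic intervals from a BED file
#'
#' Reads a 3- or 4-column BED file (0-based half-open) and converts to the
#' package's 1-based inclusive convention.
#'
#' @param path BED file path.
#' @param partition if `TRUE`, assert that intervals on a chromosome do not
#'   overlap.
#' @return data.frame with columns `chrom`, `start`, `end`, `name`
#'   (1-based inclusive coordinates).
#' @export
read_bed <- function(path, partition = FALSE) {
  raw <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 3L) stop("BED file needs at least 3 columns: ", path)
  out <- data.frame(chrom = as.character(raw[[1L]]),
                    start = as.integer(raw[[2L]]) + 1L,
                    end = as.integer(raw[[3L]]),
                    name = if (ncol(raw) >= 4L) as.character(raw[[4L]])
                           else sprintf("interval_%d", seq_len(nrow(raw))),
                    stringsAsFactors = FALSE)
  if (any(out$start > out$end)) stop("interval with start > end in ", path)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  if (partition) {
    for (ch in unique(out$chrom)) {
      sub <- out[out$chrom == ch, , drop = FALSE]
      if (nrow(sub) > 1L && any(sub$start[-1L] <= sub$end[-nrow(sub)]))
        stop("overlapping intervals on chromosome ", ch, " in ", path)
    }
  }
  out
}

#' Write genomic intervals to a BED file
#'
#' @param intervals data.frame with `chrom`, `start`, `end`, `name` (1-based
#'   inclusive, as produced by [read_bed()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  utils::write.table(
    data.frame(intervals$chrom, intervals$start - 1L, intervals$end,
               intervals$name),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
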