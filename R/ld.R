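#' Construct an LD block
#'
#' An LD block pairs a genomic interval with an ordered variant index and the
#' dense correlation matrix of those variants in a reference panel. Blocks are
#' the unit of LD in this package: correlation between variants in different
#' blocks is defined to be zero (blocks are LD-independent by construction).
#'
#' @param snps data.frame with columns `snp`, `chrom`, `pos` (and optionally
#'   `a1`, `a2`, `freq`), one row per variant, in matrix order.
#' @param R correlation matrix, `nrow(snps)` square, symmetric with unit
#'   diagonal.
#' @param name block label.
#' @return An object of class `ld_block`.
#' @export
ld_block <- function(snps, R, name = NULL) {
  R <- as.matrix(R)
  m <- nrow(snps)
  if (!all(dim(R) == c(m, m)))
    stop("R dimension does not match number of snps")
  if (max(abs(R - t(R))) > 1e-8) stop("R is not symmetric within 1e-8")
  if (max(abs(diag(R) - 1)) > 1e-8) stop("R diagonal is not 1")
  if (m > 1L && max(abs(R[upper.tri(R)])) > 0) {  # diagonal R is trivially PSD
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8)
      stop("R has eigenvalue below -1e-8; not a valid correlation matrix")
  }
  if (is.null(name))
    name <- sprintf("%s:%d-%d", snps$chrom[1L], min(snps$pos), max(snps$pos))
  dimnames(R) <- list(snps$snp, snps$snp)
  structure(list(name = name,
                 interval = list(chrom = as.character(snps$chrom[1L]),
                                 start = min(snps$pos), end = max(snps$pos)),
                 snps = as.data.frame(snps), R = R),
            class = "ld_block")
}

#' @export
print.ld_block <- function(x, ...) {
  cat(sprintf("<ld_block> %s: %d variants\n", x$name, nrow(x$snps)))
  invisible(x)
}

#' Write LD blocks to a directory of plain-text files
#'
#' Each block is stored as a tab-delimited correlation matrix
#' (`<name>.ld.tsv`) plus a sidecar variant index (`<name>.snps.tsv` with
#' columns snp, chrom, pos), and a `blocks.bed` manifest lists the block
#' intervals.
#'
#' @param blocks list of [ld_block] objects.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_ld_blocks <- function(blocks, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest <- data.frame(chrom = character(), start = integer(),
                         end = integer(), name = character())
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    tag <- sprintf("block_%04d", i)
    utils::write.table(b$snps, file.path(dir, paste0(tag, ".snps.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(format(b$R, digits = 17),
                       file.path(dir, paste0(tag, ".ld.tsv")),
                       sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    manifest <- rbind(manifest,
                      data.frame(chrom = b$interval$chrom,
                                 start = b$interval$start,
                                 end = b$interval$end, name = tag))
  }
  write_bed(manifest, file.path(dir, "blocks.bed"))
  invisible(dir)
}

#' Read LD blocks written by [write_ld_blocks()]
#'
#' @param dir directory containing `blocks.bed` plus per-block
#'   `*.snps.tsv` / `*.ld.tsv` pairs.
#' @return List of [ld_block] objects.
#' @export
read_ld_blocks <- function(dir) {
  manifest <- read_bed(file.path(dir, "blocks.bed"))
  lapply(seq_len(nrow(manifest)), function(i) {
    tag <- manifest$name[i]
    snps <- utils::read.delim(file.path(dir, paste0(tag, ".snps.tsv")),
                              stringsAsFactors = FALSE)
    R <- as.matrix(utils::read.table(file.path(dir, paste0(tag, ".ld.tsv")),
                                     sep = "\t"))
    ld_block(snps, R, name = tag)
  })
}

#' LD scores from a collection of LD blocks
#'
#' The LD score of variant j is the sum of squared correlations with every
#' variant in its block (including itself, so any indexed variant scores at
#' least 1). Variants outside all blocks are absent from the table.
#'
#' @param blocks list of [ld_block] objects with disjoint variant sets.
#' @return data.frame with columns `snp` and `ld_score`.
#' @export
ld_scores <- function(blocks) {
  pieces <- lapply(blocks, function(b)
    data.frame(snp = b$snps$snp, ld_score = colSums(b$R^2),
               stringsAsFactors = FALSE))
  out <- do.call(rbind, pieces)
  if (anyDuplicated(out$snp)) stop("blocks are not disjoint")
  rownames(out) <- NULL
  out
}

# r^2 between one index snp and a set of candidate snps; 0 across blocks.
block_lookup <- function(blocks) {
  snp2block <- integer(0)
  for (i in seq_along(blocks)) {
    ids <- blocks[[i]]$snps$snp
    snp2block[ids] <- i
  }
  snp2block
}

#' P-value-informed LD clumping
#'
#' Greedy index-variant selection: repeatedly take the remaining variant with
#' the smallest P value as an index, then discard every remaining variant
#' whose squared correlation with that index is at least `r2_max` and whose
#' position lies within `window_kb` of it. Ties on P are broken by (chrom,
#' pos) then variant id, so results are deterministic. Variants absent from
#' the LD reference are treated as unlinked and index themselves.
#'
#' @param s a [sumstats] object.
#' @param blocks list of [ld_block] objects (the LD reference).
#' @param r2_max squared-correlation threshold (default 0.1).
#' @param window_kb window half-width in kb (default 10000, i.e. 10 Mb).
#' @return Character vector of retained (index) variant ids, in selection
#'   order.
#' @export
clump <- function(s, blocks, r2_max = 0.1, window_kb = 10000) {
  d <- s$data
  if (nrow(d) == 0L) stop("empty sumstats")
  snp2block <- block_lookup(blocks)
  ord <- order(d$p, d$chrom, d$pos, d$snp)
  d <- d[ord, , drop = FALSE]
  alive <- rep(TRUE, nrow(d))
  keep <- character(0)
  window_bp <- window_kb * 1000
  for (i in seq_len(nrow(d))) {
    if (!alive[i]) next
    idx <- d$snp[i]
    keep <- c(keep, idx)
    bi <- snp2block[idx]
    if (is.na(bi)) next
    b <- blocks[[bi]]
    r2 <- b$R[, idx]^2
    linked <- names(r2)[r2 >= r2_max]
    cand <- which(alive & d$snp %in% linked &
                    d$chrom == d$chrom[i] &
                    abs(d$pos - d$pos[i]) <= window_bp)
    alive[cand] <- FALSE
  }
  keep
}
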