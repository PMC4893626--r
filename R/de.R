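# Differential expression on pooled read counts: replicate prefilter,
# RPKM normalization, Fisher's exact test, BH correction, trichotomous
# calls at FDR <= 0.05 and fold change > 2.

#' Keep genes with at least one read in every replicate
#'
#' Expression-noise prefilter: a gene is retained only if it has a read
#' count of at least 1 in every biological replicate of every group
#' under analysis.
#'
#' @param x a \code{\link{count_matrix}}.
#' @param groups groups whose replicates are checked; default all groups
#'   present.
#' @return The filtered \code{count_matrix}, with an attribute
#'   \code{"removed"} giving the number of genes dropped.  An empty
#'   result triggers a warning, not an error.
#' @export
filter_expressed <- function(x, groups = unique(x$groups)) {
  stopifnot(inherits(x, "count_matrix"))
  samples <- names(x$groups)[x$groups %in% groups]
  if (length(samples) == 0) stop("no samples in the requested groups")
  keep <- rowSums(x$counts[, samples, drop = FALSE] >= 1) == length(samples)
  out <- subset_counts(x, genes = which(keep))
  removed <- sum(!keep)
  message(sprintf("filter_expressed: %d genes in, %d retained, %d removed",
                  length(keep), sum(keep), removed))
  if (sum(keep) == 0) warning("no genes pass the replicate filter")
  attr(out, "removed") <- removed
  out
}

#' Reads per kilobase of exon per million mapped reads
#'
#' @param count read count(s).
#' @param length_bp gene (exon) length in base pairs.
#' @param lib_size total mapped reads of the library.
#' @return \code{1e9 * count / (lib_size * length_bp)}.
#' @examples
#' rpkm(10, 1000, 1e6)  # 10
#' @export
rpkm <- function(count, length_bp, lib_size) {
  if (any(length_bp <= 0)) stop("gene length must be > 0")
  if (any(lib_size <= 0)) stop("library size must be > 0")
  # doubles throughout: integer lib_size * length_bp would overflow
  1e9 * as.numeric(count) / (as.numeric(lib_size) * as.numeric(length_bp))
}

#' Two-sided Fisher's exact test for one gene between two libraries
#'
#' Tests the 2x2 table \code{[[countA, countB], [libA - countA,
#' libB - countB]]}.  The two-sided p-value follows the
#' point-probability rule: the sum of hypergeometric probabilities of
#' all tables (with the same margins) whose probability does not exceed
#' that of the observed table, the convention of standard exact-test
#' implementations.  Vectorized over genes.
#'
#' @param count_a,count_b pooled read counts of the gene in the two
#'   libraries.
#' @param lib_a,lib_b the two library sizes (total mapped reads).
#' @return p-value(s) in (0, 1].
#' @examples
#' fisher_de(3, 0, 3, 3)  # 0.1
#' @export
fisher_de <- function(count_a, count_b, lib_a, lib_b) {
  n <- max(length(count_a), length(count_b))
  count_a <- rep_len(count_a, n); count_b <- rep_len(count_b, n)
  lib_a <- rep_len(lib_a, n); lib_b <- rep_len(lib_b, n)
  if (any(count_a < 0) || any(count_b < 0))
    stop("counts must be non-negative")
  if (any(lib_a < count_a) || any(lib_b < count_b))
    stop("library size smaller than count")
  vapply(seq_len(n), function(i)
    .fisher_2x2(count_a[i], count_b[i], lib_a[i], lib_b[i]),
    numeric(1))
}

# Point-probability two-sided p for [[a, b], [la - a, lb - b]].
# Conditions on the first-row total t = a + b: a ~ Hypergeometric
# drawing t from la white and lb black.  relative tolerance as in
# standard implementations.
.fisher_2x2 <- function(a, b, la, lb) {
  t <- a + b
  if (t == 0) return(1)
  support <- max(0, t - lb):min(t, la)
  d <- stats::dhyper(support, la, lb, t)
  min(1, sum(d[d <= d[support == a] * (1 + 1e-7)]))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; a thin wrapper around
#' \code{\link[stats]{p.adjust}} that tolerates empty input.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return q-values, each in \[p, 1\], invariant to input order.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Per-gene differential expression calls between two groups
#'
#' Replicate counts are pooled (summed) per group, each gene is tested
#' by \code{\link{fisher_de}} against the pooled library sizes, p-values
#' are BH-adjusted across genes, and the log2 fold change is computed
#' from RPKM of the pooled counts with a pseudocount of 0.5 (added for
#' the fold change only, never for the test, so that silenced genes get
#' a finite fold change).  A gene is called \code{up} if q <= fdr and
#' log2FC > lfc, \code{down} if q <= fdr and log2FC < -lfc, otherwise
#' \code{ns}.  The fold-change direction is \code{group_b} relative to
#' \code{group_a} (positive log2FC means higher in \code{group_b}).
#'
#' @param x a \code{\link{count_matrix}} (typically already passed
#'   through \code{\link{filter_expressed}}).
#' @param group_a,group_b group labels of the contrast.
#' @param fdr q-value threshold (default 0.05).
#' @param lfc absolute log2-fold-change threshold (default 1, i.e. fold
#'   change > 2).
#' @return data.frame with columns \code{gene}, \code{contrast},
#'   \code{log2fc}, \code{p}, \code{q}, \code{call}.
#' @export
call_de <- function(x, group_a, group_b, fdr = 0.05, lfc = 1) {
  stopifnot(inherits(x, "count_matrix"))
  sa <- group_samples(x, group_a)
  sb <- group_samples(x, group_b)
  ca <- rowSums(x$counts[, sa, drop = FALSE])
  cb <- rowSums(x$counts[, sb, drop = FALSE])
  la <- sum(x$lib_sizes[sa])
  lb <- sum(x$lib_sizes[sb])
  p <- fisher_de(ca, cb, la, lb)
  q <- bh_fdr(p)
  l2 <- log2(rpkm(cb + 0.5, x$lengths, lb) /
             rpkm(ca + 0.5, x$lengths, la))
  call <- rep("ns", length(p))
  call[q <= fdr & l2 > lfc] <- "up"
  call[q <= fdr & l2 < -lfc] <- "down"
  data.frame(gene = rownames(x$counts),
             contrast = paste0(group_a, ":", group_b),
             log2fc = l2, p = p, q = q, call = call,
             row.names = NULL)
}
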