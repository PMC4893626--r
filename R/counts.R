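#' Read-count matrix with gene lengths, library sizes and sample groups
#'
#' Container for raw RNA-seq read counts per gene per sample, together
#' with the per-gene exon length (bp), the per-sample library size
#' (total mapped reads of the library, which may exceed the column sum
#' because not every mapped read falls in an analyzed gene) and the
#' sample-to-group assignment (e.g. the two diploid parents \code{"R"}
#' and \code{"C"} and the hybrids \code{"F1"} and \code{"F18"}).
#'
#' @param counts integer matrix, genes x samples, with row and column
#'   names.
#' @param lengths numeric vector of gene lengths in bp, named by gene or
#'   in row order.
#' @param groups character vector assigning each sample (column) to a
#'   group, named by sample or in column order.
#' @param lib_sizes numeric vector of total mapped reads per sample;
#'   defaults to the column sums.
#'
#' @return An object of class \code{"count_matrix"}: a list with
#'   elements \code{counts}, \code{lengths}, \code{lib_sizes},
#'   \code{groups}.
#' @export
count_matrix <- function(counts, lengths, groups, lib_sizes = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    stop("'counts' must have gene identifiers as row names")
  if (is.null(colnames(counts)))
    stop("'counts' must have sample identifiers as column names")
  if (any(counts < 0)) stop("counts must be non-negative")
  storage.mode(lengths) <- "double"    # avoid integer overflow downstream
  lengths <- .match_named(lengths, rownames(counts), "lengths")
  if (any(lengths <= 0)) stop("gene lengths must be > 0")
  groups <- .match_named(as.character(groups), colnames(counts), "groups")
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  storage.mode(lib_sizes) <- "double"
  lib_sizes <- .match_named(lib_sizes, colnames(counts), "lib_sizes")
  if (any(lib_sizes <= 0)) stop("library sizes must be > 0")
  if (any(lib_sizes < colSums(counts)))
    stop("library size below column sum for: ",
         paste(colnames(counts)[lib_sizes < colSums(counts)], collapse = ", "))
  structure(list(counts = counts, lengths = lengths,
                 lib_sizes = lib_sizes, groups = groups),
            class = "count_matrix")
}

.match_named <- function(x, ref, what) {
  if (!is.null(names(x))) {
    if (!all(ref %in% names(x)))
      stop("'", what, "' is missing entries for: ",
           paste(setdiff(ref, names(x)), collapse = ", "))
    x <- x[ref]
  } else {
    if (length(x) != length(ref))
      stop("'", what, "' must have length ", length(ref))
    names(x) <- ref
  }
  x
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts), "samples\n")
  cat("groups:", paste(sprintf("%s(%d)", names(table(x$groups)),
                               table(x$groups)), collapse = " "), "\n")
  cat("library sizes:", paste(format(x$lib_sizes, big.mark = ","),
                              collapse = " "), "\n")
  invisible(x)
}

#' Subset a count matrix by gene and/or sample
#'
#' @param x a \code{count_matrix}.
#' @param genes gene identifiers or logical/integer index over rows.
#' @param samples sample identifiers or index over columns.
#' @return A \code{count_matrix} restricted to the selection; library
#'   sizes are kept as-is (they refer to the whole library).
#' @export
subset_counts <- function(x, genes = NULL, samples = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  if (is.null(genes)) genes <- rownames(x$counts)
  if (is.null(samples)) samples <- colnames(x$counts)
  structure(list(counts = x$counts[genes, samples, drop = FALSE],
                 lengths = x$lengths[genes],
                 lib_sizes = x$lib_sizes[samples],
                 groups = x$groups[samples]),
            class = "count_matrix")
}

#' Samples belonging to a group
#' @param x a \code{count_matrix}.
#' @param group group label.
#' @return Character vector of sample names.
#' @export
group_samples <- function(x, group) {
  s <- names(x$groups)[x$groups == group]
  if (length(s) == 0) stop("no samples in group '", group, "'")
  s
}

#' Write / read a count matrix as tab-delimited text
#'
#' The on-disk layout is three plain TSV files: the counts (genes x
#' samples with a header row), a two-column gene-length table and a
#' three-column sample table (sample, group, lib_size).
#'
#' @param x a \code{count_matrix}.
#' @param counts_file,lengths_file,samples_file file paths.
#' @return \code{write_counts} returns the paths invisibly;
#'   \code{read_counts} returns a \code{count_matrix}.
#' @export
write_counts <- function(x, counts_file, lengths_file, samples_file) {
  stopifnot(inherits(x, "count_matrix"))
  utils::write.table(data.frame(gene = rownames(x$counts), x$counts,
                                check.names = FALSE),
                     counts_file, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(gene = rownames(x$counts),
                                length = x$lengths),
                     lengths_file, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample = colnames(x$counts),
                                group = x$groups,
                                lib_size = x$lib_sizes),
                     samples_file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(counts_file, lengths_file, samples_file))
}

#' @rdname write_counts
#' @export
read_counts <- function(counts_file, lengths_file, samples_file) {
  ct <- utils::read.delim(counts_file, check.names = FALSE)
  m <- as.matrix(ct[, -1, drop = FALSE])
  rownames(m) <- ct[[1]]
  len <- utils::read.delim(lengths_file)
  smp <- utils::read.delim(samples_file)
  count_matrix(m,
               lengths = stats::setNames(len$length, len$gene),
               groups = stats::setNames(as.character(smp$group), smp$sample),
               lib_sizes = stats::setNames(smp$lib_size, smp$sample))
}
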