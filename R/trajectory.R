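# Mid-parent value construction and the partition of expression changes
# into genome-merger (hybridization) versus genome-doubling
# (polyploidization) effects, for global expression and for
# homoeologue-bias states.

#' Mid-parent expression values and an MPV pseudo-library
#'
#' The mid-parent value (MPV) of a gene is the average of the two
#' parents' replicate-mean normalized expressions: the additive
#' expectation for the hybrid.  Because the Fisher-test machinery needs
#' integer counts, the function also appends an in-silico MPV
#' pseudo-sample to the count matrix: pooled R counts plus pooled C
#' counts halved and rounded to the nearest integer, with the pooled
#' library sizes likewise averaged.
#'
#' @param x a \code{\link{count_matrix}} containing both parents.
#' @param r_group,c_group parental group labels.
#' @param mpv_group group label given to the pseudo-sample (default
#'   \code{"MPV"}).
#' @return A list with \code{mpv} (named vector of MPV normalized
#'   expression, RPKM units) and \code{counts} (the input
#'   \code{count_matrix} with one added \code{MPV} sample, usable in
#'   \code{\link{call_de}} contrasts against the hybrids).
#' @export
compute_mpv <- function(x, r_group = "R", c_group = "C",
                        mpv_group = "MPV") {
  stopifnot(inherits(x, "count_matrix"))
  sr <- group_samples(x, r_group)
  sc <- group_samples(x, c_group)
  rpkm_mean <- function(s) {
    m <- matrix(unlist(lapply(s, function(j)
      rpkm(x$counts[, j], x$lengths, x$lib_sizes[j]))),
      nrow = nrow(x$counts),
      dimnames = list(rownames(x$counts), s))
    rowMeans(m)
  }
  mpv <- (rpkm_mean(sr) + rpkm_mean(sc)) / 2
  pooled <- round((rowSums(x$counts[, sr, drop = FALSE]) +
                   rowSums(x$counts[, sc, drop = FALSE])) / 2)
  lib <- round((sum(x$lib_sizes[sr]) + sum(x$lib_sizes[sc])) / 2)
  lib <- max(lib, sum(pooled))
  cm <- cbind(x$counts, MPV = as.integer(pooled))
  out <- count_matrix(cm, lengths = x$lengths,
                      groups = c(x$groups, MPV = mpv_group),
                      lib_sizes = c(x$lib_sizes, MPV = lib))
  list(mpv = mpv, counts = out)
}

#' Trajectory class of a gene from three DE calls
#'
#' Partitions each gene's expression history into four classes from the
#' MPV-vs-F1, MPV-vs-F18 and F1-vs-F18 DE calls: \code{no-change} (all
#' three \code{ns}), \code{doubling} (hybridization left expression at
#' the mid-parent level but polyploidization changed it: MPV = F1 and
#' F1 != F18), \code{merger} (expression moved at hybridization and
#' stayed: MPV != F1 and F1 = F18), and \code{other} for every
#' remaining pattern.
#'
#' @param call_mpv_f1,call_mpv_f18,call_f1_f18 DE calls in
#'   \code{c("up","down","ns")}.
#' @return character vector of classes.
#' @examples
#' classify_trajectory("ns", "up", "up")  # "doubling"
#' @export
classify_trajectory <- function(call_mpv_f1, call_mpv_f18, call_f1_f18) {
  n <- max(length(call_mpv_f1), length(call_mpv_f18), length(call_f1_f18))
  a <- rep_len(call_mpv_f1, n); b <- rep_len(call_mpv_f18, n)
  d <- rep_len(call_f1_f18, n)
  ok <- c("up", "down", "ns")
  if (!all(c(a, b, d) %in% ok)) stop("invalid DE call token")
  ifelse(a == "ns" & b == "ns" & d == "ns", "no-change",
    ifelse(a == "ns" & d != "ns", "doubling",
      ifelse(a != "ns" & d == "ns", "merger", "other")))
}

#' Trajectory class of homoeologue-bias states
#'
#' The same four-way partition applied to homoeologue-expression-bias
#' states: the parental R-C divergence state and the progeny states in
#' F1 and F18.  \code{no-change}: all three states equal;
#' \code{doubling}: divergence = F1 state but F18 differs;
#' \code{merger}: F1 differs from the divergence and F18 equals F1;
#' \code{other}: the remainder.
#'
#' @param divergence,state_f1,state_f18 states in
#'   \code{c("R>C", "R=C", "R<C")}.
#' @return character vector of classes.
#' @export
classify_heb_trajectory <- function(divergence, state_f1, state_f18) {
  n <- max(length(divergence), length(state_f1), length(state_f18))
  d <- rep_len(divergence, n); f1 <- rep_len(state_f1, n)
  f18 <- rep_len(state_f18, n)
  stopifnot(all(c(d, f1, f18) %in% .HEB_STATES))
  ifelse(d == f1 & f1 == f18, "no-change",
    ifelse(d == f1 & f1 != f18, "doubling",
      ifelse(d != f1 & f1 == f18, "merger", "other")))
}

#' Full MPV trajectory analysis of a four-group experiment
#'
#' Adds the MPV pseudo-library, runs the three DE contrasts and
#' classifies every gene.
#'
#' @param x a filtered \code{\link{count_matrix}} with groups
#'   \code{r_group}, \code{c_group}, \code{f1}, \code{f18}.
#' @param r_group,c_group,f1,f18 group labels.
#' @param fdr,lfc thresholds passed to \code{\link{call_de}}.
#' @return data.frame per gene: the three calls and \code{class}.
#' @export
trajectory_classify <- function(x, r_group = "R", c_group = "C",
                                f1 = "F1", f18 = "F18",
                                fdr = 0.05, lfc = 1) {
  m <- compute_mpv(x, r_group, c_group)
  de1 <- call_de(m$counts, "MPV", f1, fdr = fdr, lfc = lfc)
  de2 <- call_de(m$counts, "MPV", f18, fdr = fdr, lfc = lfc)
  de3 <- call_de(m$counts, f1, f18, fdr = fdr, lfc = lfc)
  data.frame(gene = de1$gene,
             call_mpv_f1 = de1$call, call_mpv_f18 = de2$call,
             call_f1_f18 = de3$call,
             class = classify_trajectory(de1$call, de2$call, de3$call),
             row.names = NULL)
}
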