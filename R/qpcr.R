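# Homoeologue-specific qPCR quantification: relative expression by the
# 2^-ddCt method, R/C homoeologue ratios and per-tissue bias calls,
# silencing detection from non-amplification.

#' Relative expression by the 2^-ddCt method
#'
#' \code{fold = 2^-((ct_target_sample - ct_ref_sample) -
#' (ct_target_calib - ct_ref_calib))}, assuming perfect doubling per
#' cycle.  A non-detected target CT (\code{NA}) yields \code{NA} with a
#' \code{"below_detection"} attribute rather than a number.
#'
#' @param ct_target_sample,ct_ref_sample target and reference-gene CT
#'   in the sample of interest (cycles).
#' @param ct_target_calib,ct_ref_calib the same in the calibrator
#'   sample.
#' @return fold change(s) (> 0), with attribute \code{below_detection}
#'   marking non-detected targets.
#' @examples
#' ddct(25, 20, 24, 20)  # ddCt = 1 -> fold 0.5
#' @export
ddct <- function(ct_target_sample, ct_ref_sample,
                 ct_target_calib, ct_ref_calib) {
  dd <- (ct_target_sample - ct_ref_sample) -
        (ct_target_calib - ct_ref_calib)
  fold <- 2^(-dd)
  below <- is.na(ct_target_sample)
  if (any(below)) attr(fold, "below_detection") <- below
  fold
}

#' Homoeologue expression ratio and bias call from CT replicates
#'
#' In the default \code{"expression-ratio"} mode the R/C expression
#' ratio is \code{2^(meanCT_C - meanCT_R)} (a lower CT means more
#' transcript), and the bias call is \code{R} when the ratio is
#' significantly above 1 by a two-sided t-test on the replicate
#' CT difference at \code{p_cut}, \code{C} when significantly below,
#' \code{none} otherwise.  The \code{"raw-ct-ratio"} mode instead
#' reports the plain ratio of mean CT values \code{meanCT_R /
#' meanCT_C}, a printed convention of some qPCR reports in which a CT
#' ratio above 1 is read as R bias even though CT and abundance run in
#' opposite directions; both conventions are provided and the
#' discrepancy is documented in the vignette.  A homoeologue that is
#' not detected in any replicate (all \code{NA}) yields the call
#' \code{"silenced-C"} / \code{"silenced-R"} for the missing side.
#'
#' @param ct_r,ct_c technical-replicate CT values of the R and C
#'   homoeologue assays.
#' @param mode \code{"expression-ratio"} (default) or
#'   \code{"raw-ct-ratio"}.
#' @param p_cut significance threshold (default 0.05).
#' @return list with \code{ratio}, \code{bias} (\code{"R"},
#'   \code{"C"}, \code{"none"}, \code{"silenced-R"},
#'   \code{"silenced-C"}) and \code{p}.
#' @export
homoeolog_bias <- function(ct_r, ct_c,
                           mode = c("expression-ratio", "raw-ct-ratio"),
                           p_cut = 0.05) {
  mode <- match.arg(mode)
  r_nd <- all(is.na(ct_r)); c_nd <- all(is.na(ct_c))
  if (r_nd && c_nd) stop("neither homoeologue detected")
  if (r_nd || c_nd) {
    return(list(ratio = if (r_nd) 0 else Inf,
                bias = if (r_nd) "silenced-R" else "silenced-C",
                p = NA_real_))
  }
  ct_r <- ct_r[!is.na(ct_r)]; ct_c <- ct_c[!is.na(ct_c)]
  mr <- mean(ct_r); mc <- mean(ct_c)
  ratio <- if (mode == "expression-ratio") 2^(mc - mr) else mr / mc
  if (length(ct_r) == length(ct_c)) {
    dct <- ct_c - ct_r  # paired replicate difference
    p <- if (stats::sd(dct) == 0) {
      if (mean(dct) == 0) 1 else 0  # replicates in perfect agreement
    } else stats::t.test(dct)$p.value
  } else {
    p <- if (stats::sd(ct_r) == 0 && stats::sd(ct_c) == 0) {
      if (mr == mc) 1 else 0
    } else stats::t.test(ct_r, ct_c)$p.value
  }
  expr_ratio <- 2^(mc - mr)  # bias direction always from expression
  bias <- if (p < p_cut && expr_ratio > 1) "R"
          else if (p < p_cut && expr_ratio < 1) "C" else "none"
  list(ratio = ratio, bias = bias, p = p)
}

#' Analyse a homoeologue-specific CT table
#'
#' Runs \code{\link{ddct}} (against a reference-gene assay and a
#' calibrator sample) and \code{\link{homoeolog_bias}} for every gene x
#' tissue x sample combination of a long-format CT table.
#'
#' @param ct data.frame with columns \code{sample}, \code{tissue},
#'   \code{gene}, \code{assay} (\code{"R"}, \code{"C"} or
#'   \code{"ref"}), \code{rep}, \code{ct} (NA = not detected).
#' @param calibrator sample id used as the ddCt calibrator.
#' @param mode bias mode passed to \code{\link{homoeolog_bias}}.
#' @param p_cut significance threshold.
#' @return data.frame per sample/tissue/gene: mean CTs, per-homoeologue
#'   \code{fold_r}/\code{fold_c} relative to the calibrator,
#'   \code{ratio} and \code{bias}.
#' @export
analyze_qpcr <- function(ct, calibrator,
                         mode = c("expression-ratio", "raw-ct-ratio"),
                         p_cut = 0.05) {
  mode <- match.arg(mode)
  need <- c("sample", "tissue", "gene", "assay", "ct")
  if (!all(need %in% names(ct))) stop("CT table lacks columns: ",
                                      paste(setdiff(need, names(ct)), collapse = ", "))
  if (!calibrator %in% ct$sample) stop("calibrator sample not in table")
  mean_ct <- function(s, t, g, a) {
    v <- ct$ct[ct$sample == s & ct$tissue == t & ct$gene == g & ct$assay == a]
    if (length(v) == 0 || all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  cells <- unique(ct[ct$assay != "ref", c("sample", "tissue", "gene")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    s <- cells$sample[i]; t <- cells$tissue[i]; g <- cells$gene[i]
    ref_s <- mean_ct(s, t, g, "ref")
    ref_c <- mean_ct(calibrator, t, g, "ref")
    r_s <- mean_ct(s, t, g, "R"); c_s <- mean_ct(s, t, g, "C")
    r_cal <- mean_ct(calibrator, t, g, "R")
    c_cal <- mean_ct(calibrator, t, g, "C")
    reps <- function(a) ct$ct[ct$sample == s & ct$tissue == t &
                              ct$gene == g & ct$assay == a]
    hb <- homoeolog_bias(reps("R"), reps("C"), mode = mode, p_cut = p_cut)
    data.frame(sample = s, tissue = t, gene = g,
               ct_r = r_s, ct_c = c_s, ct_ref = ref_s,
               fold_r = as.numeric(ddct(r_s, ref_s, r_cal, ref_c)),
               fold_c = as.numeric(ddct(c_s, ref_s, c_cal, ref_c)),
               ratio = hb$ratio, bias = hb$bias, p = hb$p,
               row.names = NULL)
  })
  do.call(rbind, rows)
}
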