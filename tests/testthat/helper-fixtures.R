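# Shared fixtures: tiny designs and hand-built inputs, all generated
# in code at test time.

# a small but fully featured design
small_design <- function(n_genes = 120, depth = 4e4, seed = 42, ...) {
  sim_design(n_genes = n_genes, depth = depth, seed = seed,
             gene_length_range = c(300, 800), ...)
}

# design with no programmed effects at all (pure null)
null_design <- function(n_genes, depth, seed, nb_dispersion = 0.05) {
  cm <- c(I = 0, II = 0, III = 0, IV = 0, V = 0, VI = 0, VII = 0,
          VIII = 0, IX = 0, X = 0, XI = 0, XII = 0, conserved = 1)
  hm <- c("R=C/R=C" = 1, "R>C/R>C" = 0, "R<C/R<C" = 0, "R>C/R=C" = 0,
          "R<C/R=C" = 0, "R=C/R>C" = 0, "R=C/R<C" = 0, "R<C/R>C" = 0,
          "R>C/R<C" = 0)
  sim_design(n_genes = n_genes, depth = depth, seed = seed,
             nb_dispersion = nb_dispersion,
             category_mix = cm, heb_mix = hm,
             silencing_fraction = 0, novel_fraction = 0)
}

# a count_matrix built by hand: counts per group given as a list of
# per-gene vectors replicated with small offsets
toy_counts <- function(mat, lengths = NULL, lib_sizes = NULL,
                       groups = NULL) {
  if (is.null(lengths)) lengths <- rep(1000, nrow(mat))
  if (is.null(groups)) groups <- sub("_.*", "", colnames(mat))
  count_matrix(mat, lengths = lengths, groups = groups,
               lib_sizes = lib_sizes)
}

# write a minimal SAM file of gap-free reads; reads is a data.frame
# with qname, rname, pos, seq
write_toy_sam <- function(reads, ref_lengths, path = tempfile(fileext = ".sam")) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths),
                   as.integer(ref_lengths)))
  cig <- if (is.null(reads$cigar)) paste0(nchar(reads$seq), "M") else reads$cigar
  body <- paste(reads$qname, 0, reads$rname, reads$pos, 60, cig,
                "*", 0, 0, reads$seq, strrep("I", nchar(reads$seq)),
                sep = "\t")
  writeLines(c(hdr, body), path)
  path
}

# independent two-sided Fisher oracle: enumerate all tables with the
# observed margins via binomial coefficients (no dhyper)
fisher_oracle <- function(a, b, la, lb) {
  t <- a + b
  if (t == 0) return(1)
  support <- max(0, t - lb):min(t, la)
  prob <- vapply(support, function(x)
    exp(lchoose(la, x) + lchoose(lb, t - x) - lchoose(la + lb, t)),
    numeric(1))
  obs <- prob[support == a]
  min(1, sum(prob[prob <= obs * (1 + 1e-7)]))
}
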