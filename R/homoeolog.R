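# Homoeologue-specific analysis: reciprocal-best-hit orthologue pairing
# between the two parental transcriptomes, diagnostic-SNP discovery,
# allele-based read binning from SAM alignments, silencing / novel
# expression calling and the homoeologue-expression-bias (HEB) state
# classifier.

#' Read a 12-column BLAST tabular (outfmt 6) hit file
#'
#' @param path file path.
#' @return data.frame with the standard columns (\code{qseqid},
#'   \code{sseqid}, \code{pident}, \code{length}, \code{mismatch},
#'   \code{gapopen}, \code{qstart}, \code{qend}, \code{sstart},
#'   \code{send}, \code{evalue}, \code{bitscore}).
#' @export
read_blast_tab <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  x <- utils::read.delim(path, header = FALSE, comment.char = "#",
                         stringsAsFactors = FALSE)
  if (ncol(x) != 12) {
    bad <- which(apply(x, 1, function(r) sum(!is.na(r)) != 12))[1]
    stop("malformed BLAST tabular file '", path, "': expected 12 columns",
         if (!is.na(bad)) paste0(" (first bad line: ", bad, ")"))
  }
  names(x) <- cols
  x
}

# Deterministic best hit per query: lowest e-value, ties broken by
# higher alignment length, then lexicographic subject id.
.best_hits <- function(hits) {
  o <- order(hits$qseqid, hits$evalue, -hits$length, hits$sseqid)
  h <- hits[o, ]
  h[!duplicated(h$qseqid), ]
}

#' Reciprocal-best-hit orthologue pairs between two transcriptomes
#'
#' Two transcripts are called orthologues when each is the other's best
#' BLASTN hit, the e-value is at or below \code{evalue_max} and the
#' alignment covers at least \code{min_aln_bp} base pairs.
#'
#' @param hits_rc BLAST tabular hits of the R transcripts (query)
#'   against the C transcripts (subject); a data.frame as returned by
#'   \code{\link{read_blast_tab}} or a file path.
#' @param hits_cr hits of C against R.
#' @param evalue_max e-value cut-off (default 1e-20).
#' @param min_aln_bp minimum alignment length in bp (default 300).
#' @return data.frame with columns \code{r_id}, \code{c_id},
#'   \code{length}, \code{evalue}.
#' @export
find_orthologues <- function(hits_rc, hits_cr,
                             evalue_max = 1e-20, min_aln_bp = 300) {
  if (is.character(hits_rc)) hits_rc <- read_blast_tab(hits_rc)
  if (is.character(hits_cr)) hits_cr <- read_blast_tab(hits_cr)
  br <- .best_hits(hits_rc)
  bc <- .best_hits(hits_cr)
  back <- bc$sseqid[match(br$sseqid, bc$qseqid)]
  recip <- !is.na(back) & back == br$qseqid
  keep <- recip & br$evalue <= evalue_max & br$length >= min_aln_bp
  out <- data.frame(r_id = br$qseqid[keep], c_id = br$sseqid[keep],
                    length = br$length[keep], evalue = br$evalue[keep],
                    row.names = NULL)
  out[order(out$r_id), , drop = FALSE]
}

#' Diagnostic SNPs between the R and C copies of an orthologue pair
#'
#' Globally aligns the two transcript sequences and reports every
#' aligned column where the bases differ (gap columns are skipped).
#' When parental pileup counts are supplied, a candidate site is
#' retained only if, in each parent with coverage of at least
#' \code{min_cov}, the frequency of that parent's expected allele is at
#' least \code{min_concordance}; sites absent from the pileup are
#' dropped with a message.
#'
#' @param r_seq,c_seq the two sequences (character or
#'   \code{Biostrings::DNAString}).
#' @param pair_id identifier recorded with each SNP.
#' @param pileup optional data.frame with columns \code{genome}
#'   (\code{"R"}/\code{"C"}), \code{pos} (1-based position on that
#'   genome's transcript), \code{allele}, \code{count} giving observed
#'   parental allele counts at candidate sites.
#' @param min_concordance minimum expected-allele frequency (default 0.9).
#' @param min_cov minimum coverage for a parent to be checked (default 5).
#' @return data.frame with columns \code{pair_id}, \code{r_pos},
#'   \code{c_pos} (1-based), \code{r_allele}, \code{c_allele}.
#' @export
find_diagnostic_snps <- function(r_seq, c_seq, pair_id = "pair",
                                 pileup = NULL,
                                 min_concordance = 0.9, min_cov = 5) {
  al <- Biostrings::pairwiseAlignment(Biostrings::DNAString(as.character(r_seq)),
                                      Biostrings::DNAString(as.character(c_seq)),
                                      type = "global")
  ra <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  ca <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  rpos <- cumsum(ra != "-")
  cpos <- cumsum(ca != "-")
  cand <- which(ra != "-" & ca != "-" & ra != ca)
  snps <- data.frame(pair_id = rep(pair_id, length(cand)),
                     r_pos = rpos[cand], c_pos = cpos[cand],
                     r_allele = ra[cand], c_allele = ca[cand],
                     row.names = NULL)
  if (is.null(pileup) || nrow(snps) == 0) return(snps)
  ok <- vapply(seq_len(nrow(snps)), function(i) {
    .validate_site(snps[i, ], pileup, min_concordance, min_cov)
  }, logical(1))
  snps[ok, , drop = FALSE]
}

.validate_site <- function(snp, pileup, min_concordance, min_cov) {
  for (g in c("R", "C")) {
    pos <- if (g == "R") snp$r_pos else snp$c_pos
    expected <- if (g == "R") snp$r_allele else snp$c_allele
    rows <- pileup[pileup$genome == g & pileup$pos == pos, , drop = FALSE]
    if (nrow(rows) == 0) {
      message(sprintf("site %s:%d dropped: no %s pileup", snp$pair_id, pos, g))
      return(FALSE)
    }
    cov <- sum(rows$count)
    if (cov >= min_cov) {
      freq <- sum(rows$count[rows$allele == expected]) / cov
      if (freq < min_concordance) return(FALSE)
    }
  }
  TRUE
}

#' Bin hybrid reads into R and C homoeologue-specific bins
#'
#' Reads a SAM alignment of a hybrid library against one reference
#' transcript per orthologue pair and assigns each read by the
#' diagnostic-SNP alleles it carries: a read votes R at every covered
#' diagnostic site showing the R allele and C for the C allele, and is
#' assigned to the majority-vote bin; ties, reads covering no
#' informative site, and reads whose alignment is not a simple
#' gap-free match over a site are \code{ambiguous}.  SAM positions are
#' 1-based per the SAM standard.
#'
#' @param sam path to a SAM (or BAM) file.
#' @param snps data.frame of diagnostic SNPs with columns \code{ref}
#'   (the SAM reference name), \code{pair_id}, \code{pos} (1-based on
#'   the reference), \code{r_allele}, \code{c_allele}.
#' @param sample_id label recorded in the output.
#' @param lib_size total mapped reads used for the per-million columns;
#'   defaults to the number of mapped reads in the file.
#' @param details if TRUE, attach the per-read assignments (read name,
#'   pair, bin) as attribute \code{"assignments"}.
#' @return data.frame per pair: \code{pair_id}, \code{sample},
#'   \code{r_count}, \code{c_count}, \code{ambiguous},
#'   \code{r_per_million}, \code{c_per_million}; reads mapped to
#'   references without diagnostic SNPs are tallied in the
#'   \code{"unpaired"} attribute.
#' @export
bin_reads <- function(sam, snps, sample_id = "sample", lib_size = NULL,
                      details = FALSE) {
  aln <- .read_sam(sam)
  if (is.null(lib_size)) lib_size <- nrow(aln)
  refs <- unique(snps$ref)
  unpaired <- sum(!(aln$rname %in% refs))
  detail <- if (details) vector("list", length(refs))
  res <- lapply(seq_along(refs), function(ri) {
    rf <- refs[ri]
    a <- aln[aln$rname == rf, , drop = FALSE]
    s <- snps[snps$ref == rf, , drop = FALSE]
    pid <- s$pair_id[1]
    if (nrow(a) == 0)
      return(data.frame(pair_id = pid, sample = sample_id,
                        r_count = 0L, c_count = 0L, ambiguous = 0L))
    simple <- grepl("^\\d+M$", a$cigar)
    width <- nchar(a$seq)
    votes_r <- integer(nrow(a)); votes_c <- integer(nrow(a))
    for (k in seq_len(nrow(s))) {
      p <- s$pos[k]
      cov <- simple & a$pos <= p & p <= a$pos + width - 1
      base <- substr(a$seq[cov], p - a$pos[cov] + 1, p - a$pos[cov] + 1)
      votes_r[cov] <- votes_r[cov] + (base == s$r_allele[k])
      votes_c[cov] <- votes_c[cov] + (base == s$c_allele[k])
    }
    # non-simple alignments overlapping any site are ambiguous by
    # construction (they never vote)
    assign <- ifelse(votes_r > votes_c, "R",
                     ifelse(votes_c > votes_r, "C", "ambiguous"))
    if (details)
      detail[[ri]] <<- data.frame(qname = a$qname, pair_id = pid,
                                  bin = assign)
    data.frame(pair_id = pid, sample = sample_id,
               r_count = sum(assign == "R"),
               c_count = sum(assign == "C"),
               ambiguous = sum(assign == "ambiguous"))
  })
  out <- do.call(rbind, res)
  out$r_per_million <- 1e6 * out$r_count / lib_size
  out$c_per_million <- 1e6 * out$c_count / lib_size
  attr(out, "unpaired") <- unpaired
  attr(out, "lib_size") <- lib_size
  if (details) attr(out, "assignments") <- do.call(rbind, detail)
  out
}

# Parse a SAM/BAM file into a data.frame of mapped reads.
.read_sam <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                             indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(what = c("qname", "rname", "pos", "cigar", "seq"))
  x <- Rsamtools::scanBam(path, param = p)[[1]]
  keep <- !is.na(x$pos)
  data.frame(qname = x$qname[keep], rname = as.character(x$rname)[keep],
             pos = x$pos[keep], cigar = x$cigar[keep],
             seq = as.character(x$seq)[keep], row.names = NULL)
}

#' Silencing and novel-expression status of orthologue pairs
#'
#' A homoeologue (or a parental gene) counts as expressed when its
#' normalized value reaches \code{threshold} reads per million mapped
#' reads of its library.  R-silencing: the R homoeologue is silent in
#' the hybrid while parent R expressed the gene (C symmetric).  Novel
#' expression: the gene is expressed in the hybrid while silent in both
#' parents.  The two flags are mutually exclusive by construction.
#'
#' @param hom hybrid homoeologue counts for one hybrid (output of
#'   \code{\link{bin_reads}}, or pooled over its replicates), with
#'   attribute or argument \code{lib_size}.
#' @param counts a \code{\link{count_matrix}} holding the parental
#'   libraries (unfiltered; silent genes must still be present).
#' @param gene_map data.frame mapping \code{pair_id} to the parental
#'   \code{gene} identifier in \code{counts}; defaults to pair_id ==
#'   gene id.
#' @param r_group,c_group parental group labels.
#' @param threshold reads per million (default 10).
#' @param lib_size hybrid library size; defaults to the attribute left
#'   by \code{bin_reads}.
#' @return data.frame per pair with per-million values, per-side
#'   expressed/silent status and logical flags \code{novel},
#'   \code{r_silencing}, \code{c_silencing}.  Pairs whose gene is
#'   missing from the parental counts are skipped with a message.
#' @export
call_expression_status <- function(hom, counts, gene_map = NULL,
                                   r_group = "R", c_group = "C",
                                   threshold = 10, lib_size = NULL) {
  stopifnot(inherits(counts, "count_matrix"))
  if (is.null(lib_size)) lib_size <- attr(hom, "lib_size")
  if (is.null(lib_size)) stop("hybrid library size required")
  genes <- if (is.null(gene_map)) hom$pair_id else
    gene_map$gene[match(hom$pair_id, gene_map$pair_id)]
  present <- genes %in% rownames(counts$counts)
  if (any(!present))
    message(sum(!present), " pair(s) skipped: gene absent from parental counts")
  hom <- hom[present, , drop = FALSE]; genes <- genes[present]
  ppm <- function(group) {
    s <- group_samples(counts, group)
    1e6 * rowSums(counts$counts[genes, s, drop = FALSE]) /
      sum(counts$lib_sizes[s])
  }
  r_parent_pm <- ppm(r_group)
  c_parent_pm <- ppm(c_group)
  r_pm <- 1e6 * hom$r_count / lib_size
  c_pm <- 1e6 * hom$c_count / lib_size
  tot_pm <- 1e6 * (hom$r_count + hom$c_count + hom$ambiguous) / lib_size
  data.frame(pair_id = hom$pair_id, gene = genes,
             r_hybrid_pm = r_pm, c_hybrid_pm = c_pm,
             hybrid_total_pm = tot_pm,
             r_parent_pm = r_parent_pm, c_parent_pm = c_parent_pm,
             novel = tot_pm >= threshold &
               r_parent_pm < threshold & c_parent_pm < threshold,
             r_silencing = r_pm < threshold & r_parent_pm >= threshold,
             c_silencing = c_pm < threshold & c_parent_pm >= threshold,
             row.names = NULL)
}

.HEB_STATES <- c("R>C", "R=C", "R<C")

#' Homoeologue-expression-bias state and transition for one pair
#'
#' The parental state comes from the whole-gene DE call between the two
#' parental libraries (\code{up} = R higher, i.e. \code{R>C}).  The
#' progeny state comes from a two-sided Fisher's exact test of the
#' hybrid's R and C homoeologue bins against equal expectation
#' (margins: each bin against the library's total assigned reads), at
#' \code{p_cut} (default 0.05, no multiplicity correction, mirroring a
#' per-pair significance call).  The transition class is a pure
#' function of the two states: equal states are the parental condition;
#' a biased parental state reverting to \code{R=C} is loss of bias in
#' the progeny; bias arising from \code{R=C} parents, or reversing
#' direction, is novel bias.  Overall bias is \code{R}/\code{C} only
#' when the progeny test is significant; potential bias assigns every
#' pair by whether the normalized R/C ratio exceeds 1 (a ratio of
#' exactly 1 is potential C bias).
#'
#' @param parental_call DE call of the R-vs-C contrast for the pair's
#'   gene (\code{up} = R higher), from \code{\link{call_de}}.
#' @param r_count,c_count hybrid homoeologue bin counts (pooled over
#'   the hybrid's replicates).
#' @param lib_size total assigned reads of the hybrid library (per-pair
#'   Fisher margin); defaults to \code{r_count + c_count} summed is not
#'   known here, so pass the library value from \code{bin_reads}.
#' @param p_cut significance threshold for the progeny test.
#' @return data.frame with \code{parental_state}, \code{progeny_state},
#'   \code{transition} (\code{parental-condition},
#'   \code{no-bias-in-progeny}, \code{novel-bias-in-progeny}),
#'   \code{overall_bias} (\code{R}/\code{C}/\code{none}),
#'   \code{potential_bias} (\code{R}/\code{C}), \code{p_progeny},
#'   \code{no_data} (TRUE when both bins are empty; the state then
#'   defaults to \code{R=C}).
#' @examples
#' classify_heb("up", 400, 100, 1e6)  # parental R>C kept in progeny
#' @export
classify_heb <- function(parental_call, r_count, c_count, lib_size,
                         p_cut = 0.05) {
  n <- max(length(parental_call), length(r_count), length(c_count))
  parental_call <- rep_len(parental_call, n)
  r_count <- rep_len(r_count, n); c_count <- rep_len(c_count, n)
  lib_size <- rep_len(lib_size, n)
  parental_state <- c(up = "R>C", down = "R<C", ns = "R=C")[parental_call]
  if (any(is.na(parental_state))) stop("invalid parental DE call")
  no_data <- r_count + c_count == 0
  p <- fisher_de(r_count, c_count, lib_size, lib_size)
  sig <- !no_data & p < p_cut
  progeny_state <- rep("R=C", n)
  progeny_state[sig & r_count > c_count] <- "R>C"
  progeny_state[sig & r_count < c_count] <- "R<C"
  data.frame(parental_state = unname(parental_state),
             progeny_state = progeny_state,
             transition = heb_transition(parental_state, progeny_state),
             overall_bias = ifelse(sig & r_count > c_count, "R",
                            ifelse(sig & r_count < c_count, "C", "none")),
             potential_bias = ifelse(r_count > c_count, "R", "C"),
             p_progeny = p, no_data = no_data, row.names = NULL)
}

#' Transition class over the 3 x 3 (parental, progeny) state grid
#'
#' @param parental_state,progeny_state states in
#'   \code{c("R>C", "R=C", "R<C")}.
#' @return \code{"parental-condition"} when the states are equal,
#'   \code{"no-bias-in-progeny"} when parental bias reverts to
#'   \code{R=C}, \code{"novel-bias-in-progeny"} when bias arises from
#'   unbiased parents or reverses direction.
#' @export
heb_transition <- function(parental_state, progeny_state) {
  stopifnot(all(parental_state %in% .HEB_STATES),
            all(progeny_state %in% .HEB_STATES))
  ifelse(parental_state == progeny_state, "parental-condition",
         ifelse(progeny_state == "R=C", "no-bias-in-progeny",
                "novel-bias-in-progeny"))
}
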