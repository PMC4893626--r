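# Orthologue pairing, diagnostic SNPs, read binning, expression
# status and the bias-state classifier.

test_that("reciprocal best hits respect thresholds and reciprocity", {
  hit <- function(q, s, len, e) data.frame(
    qseqid = q, sseqid = s, pident = 99, length = len, mismatch = 0,
    gapopen = 0, qstart = 1, qend = len, sstart = 1, send = len,
    evalue = e, bitscore = 2 * len)
  rc <- rbind(hit("rA", "cA", 400, 1e-30),
              hit("rB", "cB", 250, 1e-40),   # too short
              hit("rC", "cC", 500, 1e-25))
  cr <- rbind(hit("cA", "rA", 400, 1e-30),
              hit("cB", "rB", 250, 1e-40),
              hit("cC", "rX", 500, 1e-25))   # reciprocity fails
  p <- find_orthologues(rc, cr)
  expect_equal(p$r_id, "rA")
  expect_equal(p$c_id, "cA")
  # e-value cut-off
  rc2 <- hit("rA", "cA", 400, 1e-10)
  cr2 <- hit("cA", "rA", 400, 1e-10)
  expect_equal(nrow(find_orthologues(rc2, cr2)), 0)
  # deterministic best-hit tie-break: equal e-values resolved by longer
  # alignment
  rc3 <- rbind(hit("rA", "cB", 350, 1e-30), hit("rA", "cA", 400, 1e-30))
  cr3 <- rbind(hit("cA", "rA", 400, 1e-30), hit("cB", "rA", 350, 1e-30))
  expect_equal(find_orthologues(rc3, cr3)$c_id, "cA")
})

test_that("BLAST tabular files round-trip and malformed rows error", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("rA\tcA\t99.0\t400\t4\t0\t1\t400\t1\t400\t1e-30\t700"), f)
  h <- read_blast_tab(f)
  expect_equal(h$qseqid, "rA")
  expect_equal(h$evalue, 1e-30)
  writeLines(c("rA\tcA\t99.0\t400"), f)
  expect_error(read_blast_tab(f), "12 columns")
})

test_that("diagnostic SNPs come from mismatched alignment columns", {
  r <- "ACGTACGTACGTACGTACGT"
  c1 <- "ACGTACGTACGAACGTACGT"  # one substitution at position 12
  s <- find_diagnostic_snps(r, c1, pair_id = "p1")
  expect_equal(nrow(s), 1)
  expect_equal(s$r_pos, 12)
  expect_equal(s$c_pos, 12)
  expect_equal(s$r_allele, "T")
  expect_equal(s$c_allele, "A")
  # identical sequences: no candidates
  expect_equal(nrow(find_diagnostic_snps(r, r)), 0)
})

test_that("pileup validation enforces concordance and coverage", {
  r <- "ACGTACGTACGTACGTACGT"
  c1 <- "ACGTACGTACGAACGTACGT"
  good <- data.frame(genome = c("R", "C"), pos = c(12, 12),
                     allele = c("T", "A"), count = c(20, 18))
  expect_equal(nrow(find_diagnostic_snps(r, c1, pileup = good)), 1)
  # concordance 0.5 in parent R: dropped
  mixed <- rbind(good,
                 data.frame(genome = "R", pos = 12, allele = "G", count = 20))
  expect_equal(nrow(find_diagnostic_snps(r, c1, pileup = mixed)), 0)
  # below min_cov the parent does not veto
  thin <- data.frame(genome = c("R", "R", "C"), pos = c(12, 12, 12),
                     allele = c("T", "G", "A"), count = c(2, 2, 18))
  expect_equal(nrow(find_diagnostic_snps(r, c1, pileup = thin)), 1)
  # missing pileup drops the site with a message
  none <- data.frame(genome = "R", pos = 12, allele = "T", count = 20)
  expect_message(out <- find_diagnostic_snps(r, c1, pileup = none),
                 "no C pileup")
  expect_equal(nrow(out), 0)
})

test_that("read binning votes by diagnostic alleles with tie rules", {
  # reference g1_R, 40 bp, SNPs at 10 (R=A, C=G) and 30 (R=C, C=T)
  snps <- data.frame(ref = "g1_R", pair_id = "g1", pos = c(10L, 30L),
                     r_allele = c("A", "C"), c_allele = c("G", "T"))
  mk <- function(len, at = integer(0), ch = character(0)) {
    v <- rep("T", len); v[at] <- ch; paste(v, collapse = "")
  }
  reads <- data.frame(
    qname = c("rr", "rc", "amb_nosnp", "amb_tie"),
    rname = "g1_R",
    pos = c(5L, 5L, 11L, 5L),
    seq = c(mk(20, 6, "A"),        # covers only SNP 10, R allele
            mk(20, 6, "G"),        # covers only SNP 10, C allele
            mk(19),                # spans 11..29: no SNP covered
            mk(30, c(6, 26), c("A", "T"))))  # R vote at 10, C vote at 30
  sam <- write_toy_sam(reads, c(g1_R = 60L))
  out <- bin_reads(sam, snps, sample_id = "s1")
  expect_equal(out$r_count, 1)
  expect_equal(out$c_count, 1)
  expect_equal(out$ambiguous, 2)
  # conservation: bins sum to the reads mapped to the pair
  expect_equal(out$r_count + out$c_count + out$ambiguous, 4)
  # reads to unknown references are tallied, not dropped silently
  reads2 <- reads[1, ]; reads2$rname <- "gX_R"
  sam2 <- write_toy_sam(rbind(reads, reads2), c(g1_R = 60L, gX_R = 60L))
  out2 <- bin_reads(sam2, snps, sample_id = "s1")
  expect_equal(attr(out2, "unpaired"), 1)
})

test_that("binning on synthetic reads is faithful to the origin", {
  d <- small_design(n_genes = 40, depth = 2e4, seed = 19, snp_rate = 0.02)
  sim <- simulate_experiment(d)
  rd <- generate_reads(sim, "F18_1", tempfile("fid"))
  snps <- sim$snps
  out <- bin_reads(rd$sam, snps, sample_id = "F18_1")
  # conservation per pair: bins partition the reads mapped to the pair
  mapped <- table(rd$origin$gene)
  for (i in seq_len(nrow(out))) {
    p <- out$pair_id[i]
    n <- if (p %in% names(mapped)) as.integer(mapped[[p]]) else 0L
    expect_equal(out$r_count[i] + out$c_count[i] + out$ambiguous[i], n)
  }
  # fidelity is checked read-by-read in the acceptance suite; here a
  # cheap aggregate: assigned bins never exceed true origin totals
  truth <- table(rd$origin$gene, rd$origin$origin)
  for (i in seq_len(nrow(out))) {
    p <- out$pair_id[i]
    if (p %in% rownames(truth)) {
      expect_lte(out$r_count[i], truth[p, "R"])
      expect_lte(out$c_count[i], truth[p, "C"])
    }
  }
})

test_that("expression status flags silencing and novel expression", {
  # three pairs: R-silenced, unremarkable, novel
  hom <- data.frame(pair_id = c("g1", "g2", "g3"), sample = "F1",
                    r_count = c(2L, 500L, 20L), c_count = c(600L, 480L, 20L),
                    ambiguous = c(10L, 20L, 0L))
  attr(hom, "lib_size") <- 1e6
  m <- matrix(c(50L, 52L, 48L,  40L, 41L, 39L,   # g1 in R reps, C reps
                60L, 61L, 59L,  55L, 54L, 56L,
                0L, 0L, 0L,     1L, 0L, 0L),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"),
                              c("R_1", "R_2", "R_3", "C_1", "C_2", "C_3")))
  cm <- toy_counts(m, lib_sizes = rep(1e6, 6))
  st <- call_expression_status(hom, cm)
  expect_equal(st$r_silencing, c(TRUE, FALSE, FALSE))
  expect_equal(st$c_silencing, c(FALSE, FALSE, FALSE))
  expect_equal(st$novel, c(FALSE, FALSE, TRUE))
  # silencing and novelty are mutually exclusive by construction
  expect_false(any(st$novel & (st$r_silencing | st$c_silencing)))
  # unknown gene is skipped with a message
  hom2 <- rbind(hom, data.frame(pair_id = "gZ", sample = "F1",
                                r_count = 1L, c_count = 1L, ambiguous = 0L))
  attr(hom2, "lib_size") <- 1e6
  expect_message(st2 <- call_expression_status(hom2, cm), "skipped")
  expect_equal(nrow(st2), 3)
})

test_that("the bias transition grid partitions into 3/2/4 cells", {
  states <- c("R>C", "R=C", "R<C")
  grid <- expand.grid(par = states, prog = states, stringsAsFactors = FALSE)
  tr <- heb_transition(grid$par, grid$prog)
  expect_equal(sum(tr == "parental-condition"), 3)
  expect_equal(sum(tr == "no-bias-in-progeny"), 2)
  expect_equal(sum(tr == "novel-bias-in-progeny"), 4)
  # the unbiased diagonal cell is the parental condition
  expect_equal(heb_transition("R=C", "R=C"), "parental-condition")
})

test_that("classify_heb reproduces the canonical transitions", {
  lib <- 1e6
  # parental R>C kept, lost, reversed
  expect_equal(classify_heb("up", 400, 100, lib)$transition,
               "parental-condition")
  expect_equal(classify_heb("up", 250, 250, lib)$transition,
               "no-bias-in-progeny")
  expect_equal(classify_heb("up", 100, 400, lib)$transition,
               "novel-bias-in-progeny")
  r <- classify_heb("up", 400, 100, lib)
  expect_equal(r$progeny_state, "R>C")
  expect_equal(r$overall_bias, "R")
  expect_equal(r$potential_bias, "R")
  # equal bins: ratio exactly 1 is potential C bias (ratio > 1 rule)
  expect_equal(classify_heb("ns", 250, 250, lib)$potential_bias, "C")
  # insignificant small difference: overall none, potential follows >1
  r2 <- classify_heb("ns", 26, 25, lib)
  expect_equal(r2$overall_bias, "none")
  expect_equal(r2$potential_bias, "R")
  # zero reads in both bins: unbiased state with the no-data flag
  r3 <- classify_heb("ns", 0, 0, lib)
  expect_equal(r3$progeny_state, "R=C")
  expect_true(r3$no_data)
  expect_error(classify_heb("higher", 1, 1, lib), "invalid")
})
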