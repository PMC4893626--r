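# Synthetic-data generator: genomes, counts, reads, qPCR tables and
# the ground-truth contract.

test_that("design validation rejects degenerate inputs", {
  expect_error(sim_design(n_genes = 0), "n_genes")
  expect_error(sim_design(snp_rate = 1.5))
  expect_error(sim_design(gene_length_range = c(0, 100)), "zero-length")
  expect_error(sim_design(category_mix = c(conserved = 1)), "named over")
  cm <- sim_design()$category_mix
  cm["conserved"] <- cm["conserved"] + 0.1
  expect_error(sim_design(category_mix = cm), "sum to 1")
})

test_that("genome generation respects the SNP rate", {
  # degenerate rates
  d0 <- small_design(n_genes = 10, seed = 1, snp_rate = 0)
  g0 <- generate_genomes(d0)
  expect_equal(nrow(g0$snps), 0)
  expect_equal(as.character(g0$r_seqs), as.character(g0$c_seqs),
               ignore_attr = TRUE)
  d1 <- sim_design(n_genes = 3, snp_rate = 1,
                   gene_length_range = c(100, 100), seed = 2)
  g1 <- generate_genomes(d1)
  expect_equal(as.vector(table(g1$snps$pair_id)), rep(100L, 3))
  expect_true(all(g1$snps$r_allele != g1$snps$c_allele))
  # binomial expectation: 500 genes x 1000 bp x rate 0.01 -> 5000 +/- 3 SD
  d <- sim_design(n_genes = 500, snp_rate = 0.01,
                  gene_length_range = c(1000, 1000), seed = 3)
  g <- generate_genomes(d)
  expected <- 500 * 1000 * 0.01
  sd3 <- 3 * sqrt(500 * 1000 * 0.01 * 0.99)
  expect_lt(abs(nrow(g$snps) - expected), sd3)
})

test_that("counts are seeded-deterministic and conserve library sizes", {
  d <- small_design(n_genes = 60, seed = 9)
  s1 <- simulate_experiment(d)
  s2 <- simulate_experiment(small_design(n_genes = 60, seed = 9))
  expect_identical(s1$counts$counts, s2$counts$counts)
  expect_identical(s1$truth, s2$truth)
  expect_identical(as.character(s1$r_seqs), as.character(s2$r_seqs))
  # per-library conservation: reported library size = column sum
  expect_equal(unname(s1$counts$lib_sizes), unname(colSums(s1$counts$counts)))
  # hybrid counts decompose into the two homoeologue components
  for (smp in names(s1$components))
    expect_equal(unname(rowSums(s1$components[[smp]])),
                 unname(s1$counts$counts[, smp]))
})

test_that("programmed means follow the truth table", {
  d <- small_design(n_genes = 200, depth = 1e5, seed = 21)
  sim <- simulate_experiment(d)
  tr <- sim$truth
  # conserved genes: equal programmed means everywhere
  cons <- !is.na(tr$category_f1) & tr$category_f1 == "conserved" &
          !is.na(tr$category_f18) & tr$category_f18 == "conserved" &
          !tr$r_silencing & !tr$c_silencing
  expect_true(all(abs(tr$mu_r[cons] - tr$mu_c[cons]) < 1e-9))
  expect_true(all(abs(tr$mu_r[cons] - tr$mu_f1[cons]) < 1e-9))
  expect_true(all(abs(tr$mu_r[cons] - tr$mu_f18[cons]) < 1e-9))
  # novel genes have zero parental means
  expect_true(all(tr$mu_r[tr$novel] == 0))
  # silencing: the silenced hybrid component mean is zero
  expect_true(all(tr$p_r_f1[tr$r_silencing] == 0))
  expect_true(all(tr$p_r_f1[tr$c_silencing] == 1))
})

test_that("the Poisson limit recovers a programmed 4-fold parental ratio", {
  # dispersion 0 (Poisson), high depth: the empirical R/C mean ratio of
  # divergent genes with decent expression is within 10% of 4
  d <- sim_design(n_genes = 300, depth = 1e6, nb_dispersion = 0,
                  seed = 33)
  sim <- simulate_experiment(d)
  tr <- sim$truth
  no_mid <- !(tr$category_f1 %in% c("XI", "XII")) &
            !(tr$category_f18 %in% c("XI", "XII"))
  sel <- tr$rel == "R>C" & !is.na(no_mid) & no_mid & tr$mu_c >= 200
  expect_gt(sum(sel), 5)
  r_mean <- rowMeans(sim$counts$counts[sel, group_samples(sim$counts, "R")])
  c_mean <- rowMeans(sim$counts$counts[sel, group_samples(sim$counts, "C")])
  ratio <- mean(r_mean / c_mean)
  expect_lt(abs(ratio - 4) / 4, 0.1)
})

test_that("an unsatisfiable silencing demand reports the genes", {
  d <- small_design(n_genes = 40, seed = 4)
  d$silencing_fraction <- 0.9  # conserved pool cannot supply this
  g <- generate_genomes(d)
  expect_error(generate_counts(d, g), "unsatisfiable mixture")
})

test_that("simulated reads carry their origin and respect mixing", {
  d <- small_design(n_genes = 30, depth = 1.5e4, seed = 8)
  sim <- simulate_experiment(d)
  rd <- generate_reads(sim, "F1_1", tempfile("reads"))
  expect_true(file.exists(rd$sam))
  expect_true(file.exists(rd$fastq))
  comp <- sim$components[["F1_1"]]
  tab <- table(rd$origin$gene, rd$origin$origin)
  # per-gene read counts equal the simulated component counts
  for (g in rownames(tab)) {
    expect_equal(unname(tab[g, "R"]), unname(comp[g, "r"]))
    expect_equal(unname(tab[g, "C"]), unname(comp[g, "c"]))
  }
  # a fully R-silenced pair yields no R-origin reads (mixing 0)
  tr <- sim$truth
  sil <- tr$gene[tr$r_silencing]
  if (length(sil) > 0)
    expect_false(any(rd$origin$gene %in% sil & rd$origin$origin == "R"))
  # read length > gene length errors with the gene name
  d2 <- small_design(n_genes = 5, seed = 8)
  d2$read_length <- 5000L
  sim2 <- simulate_experiment(d2)
  expect_error(generate_reads(sim2, "F1_1", tempfile()), "g0001")
})

test_that("binomial sampling governs read origin at a given mixing", {
  # 1000 reads at mixing 0.7: R-origin count within 3 binomial SD of 700
  d <- sim_design(n_genes = 1, snp_rate = 0.02, n_replicates = 1,
                  gene_length_range = c(1000, 1000), depth = 1000,
                  nb_dispersion = 0, seed = 77)
  sim <- simulate_experiment(d)
  sim$components[["F1_1"]][] <- c(0L, 0L)
  # program the split directly: total 1000 at p_R = 0.7
  set.seed(101)
  r <- rbinom(1, 1000, 0.7)
  sim$components[["F1_1"]][1, ] <- c(as.integer(r), as.integer(1000 - r))
  rd <- generate_reads(sim, "F1_1", tempfile("mix"))
  n_r <- sum(rd$origin$origin == "R")
  expect_lt(abs(n_r - 700), 3 * sqrt(1000 * 0.7 * 0.3))
})

test_that("zero-noise qPCR tables encode programmed expression exactly", {
  d <- small_design(n_genes = 50, seed = 12)
  sim <- simulate_experiment(d)
  ct <- generate_qpcr(sim, noise_sd = 0)
  expect_true(all(c("sample", "tissue", "gene", "assay", "rep", "ct")
                  %in% names(ct)))
  tr <- sim$truth
  g <- ct$gene[1]
  i <- match(g, tr$gene)
  r_ct <- unique(ct$ct[ct$sample == "F1" & ct$tissue == "liver" &
                       ct$gene == g & ct$assay == "R"])
  c_ct <- unique(ct$ct[ct$sample == "F1" & ct$tissue == "liver" &
                       ct$gene == g & ct$assay == "C"])
  # CT difference = log2 of the homoeologue expression ratio
  expect_equal(c_ct - r_ct,
               log2((tr$mu_f1[i] * tr$p_r_f1[i]) /
                    (tr$mu_f1[i] * (1 - tr$p_r_f1[i]))))
  # silenced homoeologue reported as not-detected
  sil <- tr$gene[tr$r_silencing | tr$c_silencing]
  sil <- intersect(sil, unique(sim$snps$pair_id))
  if (length(sil) > 0) {
    ct2 <- generate_qpcr(sim, genes = sil[1], noise_sd = 0)
    side <- if (tr$r_silencing[match(sil[1], tr$gene)]) "R" else "C"
    expect_true(all(is.na(ct2$ct[ct2$assay == side])))
  }
})

test_that("round-tripping a simulation through text files preserves it", {
  d <- small_design(n_genes = 25, seed = 6)
  sim <- simulate_experiment(d)
  dir <- tempfile("simout")
  write_sim(sim, dir)
  x <- read_counts(file.path(dir, "counts.tsv"),
                   file.path(dir, "lengths.tsv"),
                   file.path(dir, "samples.tsv"))
  expect_equal(x$counts, sim$counts$counts)
  expect_equal(x$lengths, sim$counts$lengths)
  expect_equal(x$groups, sim$counts$groups)
  fa <- Biostrings::readDNAStringSet(file.path(dir, "R_transcripts.fasta"))
  expect_equal(as.character(fa), as.character(sim$r_seqs))
  # DE results are identical through the text round-trip (guards
  # against integer arithmetic on file-read library sizes)
  de_mem <- call_de(suppressMessages(filter_expressed(sim$counts)), "C", "R")
  de_file <- call_de(suppressMessages(filter_expressed(x)), "C", "R")
  expect_equal(de_file, de_mem)
})
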