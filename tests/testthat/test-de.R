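# Differential-expression substrate: RPKM, Fisher's exact test, BH
# correction, replicate prefilter and trichotomous calls.

test_that("rpkm matches its closed form and is linear", {
  expect_equal(rpkm(10, 1000, 1e6), 10)
  expect_equal(rpkm(0, 1000, 1e6), 0)
  expect_equal(rpkm(5, 500, 2e6), 5)
  # linearity: doubling the count doubles RPKM, doubling the library
  # halves it
  expect_equal(rpkm(20, 700, 3e6), 2 * rpkm(10, 700, 3e6))
  expect_equal(rpkm(10, 700, 6e6), rpkm(10, 700, 3e6) / 2)
  expect_error(rpkm(10, 0, 1e6), "length")
  expect_error(rpkm(10, 1000, 0), "library")
})

test_that("fisher_de follows the point-probability rule", {
  # 2 * C(3,3)C(3,0)/C(6,3) summed over both extreme tables
  expect_equal(fisher_de(3, 0, 3, 3), 0.1)
  # identical rates: every table is at least as probable
  expect_equal(fisher_de(10, 20, 1000, 2000), 1)
  # symmetry under column swap
  expect_equal(fisher_de(7, 2, 40, 55), fisher_de(2, 7, 55, 40))
  # empty table
  expect_equal(fisher_de(0, 0, 10, 10), 1)
})

test_that("fisher_de agrees with stats::fisher.test across random tables", {
  set.seed(11)
  for (i in 1:60) {
    la <- sample(5:400, 1); lb <- sample(5:400, 1)
    a <- sample(0:la, 1); b <- sample(0:lb, 1)
    ref <- stats::fisher.test(matrix(c(a, la - a, b, lb - b), 2))$p.value
    expect_equal(fisher_de(a, b, la, lb), ref, tolerance = 1e-10)
  }
})

test_that("fisher_de matches the choose()-based enumeration oracle", {
  set.seed(12)
  for (i in 1:60) {
    la <- sample(1:30, 1); lb <- sample(1:30, 1)
    a <- sample(0:la, 1); b <- sample(0:lb, 1)
    expect_equal(fisher_de(a, b, la, lb), fisher_oracle(a, b, la, lb),
                 tolerance = 1e-12)
  }
})

test_that("bh_fdr applies the step-up rule and respects order", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  p <- c(0.002, 0.5, 0.03, 0.9, 0.04)
  o <- sample(seq_along(p))
  expect_equal(bh_fdr(p)[o], bh_fdr(p[o]))  # sort-stability
  expect_true(all(bh_fdr(p) >= p))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("filter_expressed drops genes with any zero replicate", {
  set.seed(3)
  m <- matrix(rpois(10 * 6, 20) + 1L, 10, 6,
              dimnames = list(sprintf("g%02d", 1:10),
                              c("R_1", "R_2", "R_3", "C_1", "C_2", "C_3")))
  x <- toy_counts(m)
  expect_message(f0 <- filter_expressed(x), "0 removed")
  expect_equal(nrow(f0$counts), 10)  # all >= 1: identity
  # exactly 3 violating genes, one with a single zero replicate
  m2 <- m
  m2["g02", "R_2"] <- 0L
  m2["g05", ] <- 0L
  m2["g09", "C_3"] <- 0L
  f <- suppressMessages(filter_expressed(toy_counts(m2)))
  expect_equal(nrow(f$counts), 7)
  expect_equal(attr(f, "removed"), 3)
  expect_false("g02" %in% rownames(f$counts))
  # all genes failing is a warning, not an error
  m3 <- m; m3[, "R_1"] <- 0L
  x3 <- toy_counts(m3, lib_sizes = rep(1e5, 6))
  expect_warning(suppressMessages(filter_expressed(x3)), "no genes")
})

test_that("call_de requires both significance and fold change", {
  # identical pooled counts: ns with log2FC 0
  m <- matrix(c(50L, 60L, 70L, 50L, 60L, 70L), nrow = 1,
              dimnames = list("g1", c(paste0("A_", 1:3), paste0("B_", 1:3))))
  x <- toy_counts(m, lib_sizes = rep(1e5, 6))
  de <- call_de(x, "A", "B")
  expect_equal(de$call, "ns")
  expect_equal(de$log2fc, 0)
  # highly significant but below 2-fold: still ns
  m2 <- matrix(c(4000L, 4000L, 6000L, 6000L), 1,
               dimnames = list("g1", c("A_1", "A_2", "B_1", "B_2")))
  x2 <- toy_counts(m2, lib_sizes = rep(1e6, 4))
  de2 <- call_de(x2, "A", "B")
  expect_lt(de2$q, 0.01)
  expect_lt(abs(de2$log2fc), 1)
  expect_equal(de2$call, "ns")
  # direction: up means group_b higher
  m3 <- matrix(c(100L, 100L, 1000L, 1000L), 1,
               dimnames = list("g1", c("A_1", "A_2", "B_1", "B_2")))
  de3 <- call_de(toy_counts(m3, lib_sizes = rep(1e6, 4)), "A", "B")
  expect_equal(de3$call, "up")
  expect_gt(de3$log2fc, 1)
})

test_that("a programmed strong effect at high depth is called", {
  # simulate a design rich in maternal-dominance genes and check a
  # known 'up' gene in the F1-vs-C contrast
  d <- small_design(n_genes = 150, depth = 8e4, seed = 5)
  sim <- simulate_experiment(d)
  filt <- suppressMessages(filter_expressed(sim$counts))
  de <- call_de(filt, "C", "F1")
  tr <- sim$truth[match(de$gene, sim$truth$gene), ]
  # category X genes: hybrid at the (higher) R parent level, so up vs C
  xg <- which(!is.na(tr$category_f1) & tr$category_f1 == "X" &
              tr$mu_f1 > 50)
  expect_gt(length(xg), 0)
  expect_true(mean(de$call[xg] == "up") >= 0.9)
})
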