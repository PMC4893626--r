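# Synthetic allopolyploid transcriptome generator.  Emulates the
# four-group design of the study system: two diploid parents (maternal
# R, paternal C), their F1 diploid hybrid and a later-generation
# allotetraploid (F18), each with biological replicates; orthologous
# gene pairs carry fixed inter-genome SNPs, and per-gene expression is
# programmed from configurable mixtures of expression-dominance
# categories, homoeologue-bias transitions, silencing and novel
# expression, with the full ground truth recorded.

.HEB_TRANSITION_NAMES <- c(
  "R=C/R=C", "R>C/R>C", "R<C/R<C",
  "R>C/R=C", "R<C/R=C",
  "R=C/R>C", "R=C/R<C", "R<C/R>C", "R>C/R<C")

# parental relation implied by each expression category
.CAT_REL <- c(I = "R>C", II = "R=C", III = "R<C",
              IV = "R<C", V = "R=C", VI = "R>C",
              VII = "R<C", VIII = "R>C", IX = "R<C", X = "R>C",
              XI = "R<C", XII = "R>C", conserved = "R=C")

#' Simulation design for a synthetic allopolyploid experiment
#'
#' Collects all parameters of the generator with validation.  The
#' defaults describe a liver-transcriptome-like experiment: three
#' biological replicates per group, a depth of one million mapped reads
#' per library, negative-binomial biological noise, a predominantly
#' conserved category mix, and a homoeologue-bias transition mix in
#' which the parental condition dominates.
#'
#' @param n_genes number of orthologous gene pairs (>= 1).
#' @param snp_rate per-base probability of a fixed R/C sequence
#'   difference (default 0.01).
#' @param gene_length_range min and max gene length in bp (drawn
#'   uniformly; default c(500, 2000)).
#' @param n_replicates biological replicates per group (default 3).
#' @param depth expected mapped reads per library (default 1e6; the
#'   maternal parent's library is scaled to exactly this expectation
#'   and the other groups follow the same per-gene scale).
#' @param nb_dispersion negative-binomial dispersion shared across
#'   groups (default 0.05); 0 gives Poisson counts.
#' @param fold programmed effect size: any two unequal expression
#'   levels differ by at least this factor, and a biased homoeologue
#'   pair splits \code{fold : 1} (default 4).
#' @param category_mix named proportions over the 12 Roman-numeral
#'   categories plus \code{"conserved"}; must sum to 1.
#' @param heb_mix named proportions over the nine
#'   \code{"parental/progeny"} bias-state transitions (e.g.
#'   \code{"R>C/R=C"}); must sum to 1.  Because a gene's parental
#'   relation is set by its category, the progeny state is drawn from
#'   this mix conditional on the parental state.
#' @param silencing_fraction fraction of genes with one hybrid
#'   homoeologue silenced (split evenly between R and C; default
#'   0.0035).
#' @param novel_fraction fraction of genes silent in both parents but
#'   expressed in the hybrids (default 0.001).
#' @param expr_sdlog log-normal spread of per-gene baseline expression
#'   (default 0.5).
#' @param read_length simulated read length in bp (default 100).
#' @param seed integer random seed driving every stochastic step.
#' @return object of class \code{"sim_design"} (a validated list).
#' @export
sim_design <- function(n_genes = 2000,
                       snp_rate = 0.01,
                       gene_length_range = c(500, 2000),
                       n_replicates = 3,
                       depth = 1e6,
                       nb_dispersion = 0.05,
                       fold = 4,
                       category_mix = NULL,
                       heb_mix = NULL,
                       silencing_fraction = 0.0035,
                       novel_fraction = 0.001,
                       expr_sdlog = 0.5,
                       read_length = 100,
                       seed = 1L) {
  if (is.null(category_mix))
    category_mix <- c(I = 0.03, II = 0.02, III = 0.03,
                      IV = 0.03, V = 0.02, VI = 0.02,
                      VII = 0.02, VIII = 0.02, IX = 0.03, X = 0.04,
                      XI = 0.02, XII = 0.02, conserved = 0.70)
  if (is.null(heb_mix))
    heb_mix <- c("R=C/R=C" = 0.703, "R>C/R>C" = 0.042, "R<C/R<C" = 0.001,
                 "R>C/R=C" = 0.084, "R<C/R=C" = 0.055,
                 "R=C/R>C" = 0.065, "R=C/R<C" = 0.034,
                 "R<C/R>C" = 0.001, "R>C/R<C" = 0.015)
  stopifnot(n_genes >= 1, snp_rate >= 0, snp_rate <= 1,
            depth > 0, n_replicates >= 1, nb_dispersion >= 0,
            fold > 1, length(gene_length_range) == 2)
  if (gene_length_range[1] < 1) stop("zero-length genes are not allowed")
  if (gene_length_range[1] > gene_length_range[2])
    stop("gene_length_range must be increasing")
  if (!setequal(names(category_mix), names(.CAT_REL)))
    stop("category_mix must be named over the 12 categories + 'conserved'")
  if (!setequal(names(heb_mix), .HEB_TRANSITION_NAMES))
    stop("heb_mix must be named over the nine state transitions")
  if (abs(sum(category_mix) - 1) > 1e-9) stop("category_mix must sum to 1")
  if (abs(sum(heb_mix) - 1) > 1e-9) stop("heb_mix must sum to 1")
  if (any(category_mix < 0) || any(heb_mix < 0)) stop("negative proportions")
  stopifnot(silencing_fraction >= 0, novel_fraction >= 0,
            silencing_fraction + novel_fraction <= 1)
  structure(list(n_genes = as.integer(n_genes), snp_rate = snp_rate,
                 gene_length_range = gene_length_range,
                 n_replicates = as.integer(n_replicates), depth = depth,
                 nb_dispersion = nb_dispersion, fold = fold,
                 category_mix = category_mix, heb_mix = heb_mix,
                 silencing_fraction = silencing_fraction,
                 novel_fraction = novel_fraction,
                 expr_sdlog = expr_sdlog,
                 read_length = as.integer(read_length),
                 seed = as.integer(seed)),
            class = "sim_design")
}

# evaluate expr under a deterministic seed, restoring the caller's RNG
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate the paired parental transcriptomes and diagnostic SNPs
#'
#' For each gene an R transcript is drawn at random and the C
#' orthologue is an identical copy except at positions mutated with
#' probability \code{snp_rate}; those positions, with both alleles,
#' form the diagnostic-SNP list.
#'
#' @param design a \code{\link{sim_design}}.
#' @return list with \code{r_seqs}, \code{c_seqs}
#'   (\code{Biostrings::DNAStringSet}, names \code{<gene>_R} /
#'   \code{<gene>_C}), \code{snps} (data.frame \code{pair_id},
#'   \code{ref}, \code{pos}, \code{r_allele}, \code{c_allele}) and
#'   \code{lengths} (named by gene).
#' @export
generate_genomes <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  .with_seed(design$seed, {
    n <- design$n_genes
    ids <- sprintf("g%04d", seq_len(n))
    span <- design$gene_length_range[2] - design$gene_length_range[1] + 1L
    lens <- design$gene_length_range[1] - 1L + sample.int(span, n, replace = TRUE)
    bases <- c("A", "C", "G", "T")
    r_chr <- character(n); c_chr <- character(n)
    snps <- vector("list", n)
    for (i in seq_len(n)) {
      r <- sample(bases, lens[i], replace = TRUE)
      cc <- r
      mut <- which(stats::runif(lens[i]) < design$snp_rate)
      if (length(mut) > 0) {
        for (m in mut) cc[m] <- sample(setdiff(bases, r[m]), 1)
        snps[[i]] <- data.frame(pair_id = ids[i],
                                ref = paste0(ids[i], "_R"),
                                pos = mut, r_allele = r[mut],
                                c_allele = cc[mut])
      }
      r_chr[i] <- paste(r, collapse = "")
      c_chr[i] <- paste(cc, collapse = "")
    }
    snps <- if (all(vapply(snps, is.null, logical(1))))
      data.frame(pair_id = character(), ref = character(),
                 pos = integer(), r_allele = character(),
                 c_allele = character())
    else do.call(rbind, snps[!vapply(snps, is.null, logical(1))])
    list(r_seqs = Biostrings::DNAStringSet(stats::setNames(r_chr, paste0(ids, "_R"))),
         c_seqs = Biostrings::DNAStringSet(stats::setNames(c_chr, paste0(ids, "_C"))),
         snps = snps, lengths = stats::setNames(lens, ids))
  })
}

# draw one value per row from a named proportion vector restricted to
# the allowed names of that row
.draw_conditional <- function(mix, allowed_list) {
  vapply(allowed_list, function(allowed) {
    p <- mix[allowed]
    if (sum(p) <= 0) p <- stats::setNames(rep(1, length(allowed)), allowed)
    sample(allowed, 1, prob = p)
  }, character(1))
}

#' Generate replicate counts for all four groups, with ground truth
#'
#' Per-gene programmed expression: each gene draws a parental relation
#' from the category-mix marginal, then an expression category for each
#' hybrid conditional on that relation, and a homoeologue-bias progeny
#' state for each hybrid from the bias mix conditional on the parental
#' state.  Unequal programmed levels are separated by at least
#' \code{fold}; a biased homoeologue pair splits \code{fold : 1}.
#' Counts are negative-binomial with shared dispersion; a hybrid
#' gene's total is split between its R and C homoeologue components by
#' binomial thinning at the programmed mixing proportion, so the
#' within-sample homoeologue ratio carries only sampling noise (cis-
#' regulated allelic ratios are far more stable than total expression).
#' Silencing and novel-expression genes are taken from the conserved
#' pool; if the pool is too small the design is rejected with the list
#' of genes that could not be assigned.  Reported library sizes equal
#' the column sums, so per-library counts are conserved exactly.
#'
#' @param design a \code{\link{sim_design}}.
#' @param genomes output of \code{\link{generate_genomes}}.
#' @return list with \code{counts} (a \code{\link{count_matrix}}),
#'   \code{components} (per hybrid sample, integer matrices of the R
#'   and C homoeologue read counts) and \code{truth} (per-gene
#'   data.frame: relation, per-hybrid category, per-hybrid progeny
#'   state and transition, mixing proportions, flags and programmed
#'   means).
#' @export
generate_counts <- function(design, genomes) {
  stopifnot(inherits(design, "sim_design"))
  .with_seed(design$seed + 1L, {
    n <- design$n_genes
    ids <- names(genomes$lengths)
    f <- design$fold
    base <- stats::rlnorm(n, meanlog = 0, sdlog = design$expr_sdlog)

    rel_prob <- c("R>C" = 0, "R=C" = 0, "R<C" = 0)
    for (cat in names(design$category_mix))
      rel_prob[.CAT_REL[cat]] <- rel_prob[.CAT_REL[cat]] + design$category_mix[cat]
    rel <- sample(names(rel_prob), n, replace = TRUE, prob = rel_prob)

    cats_by_rel <- split(names(.CAT_REL), .CAT_REL)
    cat_f1 <- .draw_conditional(design$category_mix, cats_by_rel[rel])
    cat_f18 <- .draw_conditional(design$category_mix, cats_by_rel[rel])

    prog_states <- c("R>C", "R=C", "R<C")
    heb_by_par <- lapply(stats::setNames(prog_states, prog_states),
                         function(pa) paste0(pa, "/", prog_states))
    tr_f1 <- .draw_conditional(design$heb_mix, heb_by_par[rel])
    tr_f18 <- .draw_conditional(design$heb_mix, heb_by_par[rel])
    state_f1 <- sub(".*/", "", tr_f1)
    state_f18 <- sub(".*/", "", tr_f18)

    # silencing / novel-expression overrides, drawn from the fully
    # conserved pool so the remaining programme is untouched
    novel <- r_sil <- c_sil <- rep(FALSE, n)
    n_nov <- round(design$novel_fraction * n)
    n_sil <- round(design$silencing_fraction * n)
    eligible <- which(cat_f1 == "conserved" & cat_f18 == "conserved" &
                      state_f1 == "R=C" & state_f18 == "R=C")
    if (length(eligible) < n_nov + n_sil)
      stop("unsatisfiable mixture: ", n_nov + n_sil - length(eligible),
           " silencing/novel gene(s) could not be assigned ",
           "(conserved pool too small); first unassignable genes: ",
           paste(utils::head(ids[setdiff(seq_len(n), eligible)], 5),
                 collapse = ", "))
    pick <- sample(eligible, n_nov + n_sil)
    if (n_nov > 0) novel[pick[seq_len(n_nov)]] <- TRUE
    if (n_sil > 0) {
      sil <- pick[n_nov + seq_len(n_sil)]
      half <- seq_len(ceiling(n_sil / 2))
      r_sil[sil[half]] <- TRUE
      c_sil[sil[-half]] <- TRUE
    }

    # Parental divergence is `fold` except for genes carrying an
    # intermediate (XI/XII) category in either hybrid, which need a
    # mid level separated from both parents by `fold` and therefore a
    # fold^2 parental ratio.  Keeping most effects at `fold` keeps the
    # total programmed mass of each library close, as in real data
    # where differentially expressed genes are a small mass fraction.
    ratio <- ifelse(cat_f1 %in% c("XI", "XII") | cat_f18 %in% c("XI", "XII"),
                    f^2, f)
    w_r <- ifelse(rel == "R>C", ratio, 1)
    w_c <- ifelse(rel == "R<C", ratio, 1)
    hybrid_level <- function(cat) {
      lo <- pmin(w_r, w_c); hi <- pmax(w_r, w_c)
      out <- numeric(n)
      out[cat == "conserved"] <- 1
      out[cat %in% c("VII", "VIII")] <- w_c[cat %in% c("VII", "VIII")]
      out[cat %in% c("IX", "X")] <- w_r[cat %in% c("IX", "X")]
      out[cat %in% c("XI", "XII")] <- sqrt((lo * hi)[cat %in% c("XI", "XII")])
      below <- cat %in% c("I", "II", "III")
      out[below] <- lo[below] / f
      above <- cat %in% c("IV", "V", "VI")
      out[above] <- hi[above] * f
      out
    }
    w_f1 <- hybrid_level(cat_f1)
    w_f18 <- hybrid_level(cat_f18)

    mix_of <- function(state) ifelse(state == "R>C", f / (f + 1),
                               ifelse(state == "R<C", 1 / (f + 1), 0.5))
    p_f1 <- mix_of(state_f1); p_f18 <- mix_of(state_f18)

    # overrides
    w_r[novel] <- 0; w_c[novel] <- 0
    p_f1[r_sil] <- 0; p_f18[r_sil] <- 0
    p_f1[c_sil] <- 1; p_f18[c_sil] <- 1
    state_f1[r_sil] <- "R<C"; state_f18[r_sil] <- "R<C"
    state_f1[c_sil] <- "R>C"; state_f18[c_sil] <- "R>C"
    cat_f1[novel] <- NA; cat_f18[novel] <- NA

    s <- design$depth / sum(base * w_r)
    mu <- cbind(R = base * w_r, C = base * w_c,
                F1 = base * w_f1, F18 = base * w_f18) * s

    nr <- design$n_replicates
    draw <- function(m) {
      if (design$nb_dispersion == 0) stats::rpois(length(m), m)
      else stats::rnbinom(length(m), mu = m, size = 1 / design$nb_dispersion)
    }
    groups <- c("R", "C", "F1", "F18")
    samples <- unlist(lapply(groups, function(g) paste0(g, "_", seq_len(nr))))
    counts <- matrix(0L, n, length(samples),
                     dimnames = list(ids, samples))
    components <- list()
    for (g in groups) {
      for (j in seq_len(nr)) {
        smp <- paste0(g, "_", j)
        tot <- draw(mu[, g])
        counts[, smp] <- as.integer(tot)
        if (g %in% c("F1", "F18")) {
          p <- if (g == "F1") p_f1 else p_f18
          rc <- stats::rbinom(n, tot, p)
          components[[smp]] <- cbind(r = as.integer(rc),
                                     c = as.integer(tot - rc))
          rownames(components[[smp]]) <- ids
        }
      }
    }
    cm <- count_matrix(counts, lengths = genomes$lengths,
                       groups = stats::setNames(rep(groups, each = nr), samples))
    truth <- data.frame(gene = ids, rel = rel,
                        category_f1 = cat_f1, category_f18 = cat_f18,
                        state_f1 = state_f1, state_f18 = state_f18,
                        transition_f1 = heb_transition(rel, state_f1),
                        transition_f18 = heb_transition(rel, state_f18),
                        p_r_f1 = p_f1, p_r_f18 = p_f18,
                        novel = novel, r_silencing = r_sil,
                        c_silencing = c_sil,
                        mu_r = mu[, "R"], mu_c = mu[, "C"],
                        mu_f1 = mu[, "F1"], mu_f18 = mu[, "F18"],
                        row.names = NULL)
    list(counts = cm, components = components, truth = truth)
  })
}

#' Run the full generator
#'
#' @param design a \code{\link{sim_design}}.
#' @return object of class \code{"heb_sim"}: the design, genomes, SNP
#'   list, counts, homoeologue components and truth table.
#' @export
simulate_experiment <- function(design) {
  genomes <- generate_genomes(design)
  cnt <- generate_counts(design, genomes)
  structure(c(list(design = design), genomes, cnt), class = "heb_sim")
}

#' @export
print.heb_sim <- function(x, ...) {
  cat("heb_sim:", x$design$n_genes, "gene pairs,",
      x$design$n_replicates, "replicates/group, depth",
      format(x$design$depth, big.mark = ","), "\n")
  cat("diagnostic SNPs:", nrow(x$snps), "sites on",
      length(unique(x$snps$pair_id)), "genes\n")
  cat("flags:", sum(x$truth$novel), "novel,",
      sum(x$truth$r_silencing), "R-silenced,",
      sum(x$truth$c_silencing), "C-silenced\n")
  invisible(x)
}

#' Idealized homoeologue counts of a simulated hybrid
#'
#' Returns, per SNP-bearing gene pair, the hybrid's true R and C
#' homoeologue read counts pooled over its replicates -- the limit of
#' perfectly informative read binning (no ambiguous reads).  Useful as
#' direct input to \code{\link{classify_heb}}.
#'
#' @param sim a \code{\link{simulate_experiment}} result.
#' @param hybrid \code{"F1"} or \code{"F18"}.
#' @return data.frame in the \code{\link{bin_reads}} layout, with the
#'   pooled library size as attribute \code{"lib_size"}.
#' @export
true_homoeolog_counts <- function(sim, hybrid = c("F1", "F18")) {
  hybrid <- match.arg(hybrid)
  stopifnot(inherits(sim, "heb_sim"))
  smp <- group_samples(sim$counts, hybrid)
  r <- Reduce(`+`, lapply(smp, function(s) sim$components[[s]][, "r"]))
  cc <- Reduce(`+`, lapply(smp, function(s) sim$components[[s]][, "c"]))
  pairs <- unique(sim$snps$pair_id)
  lib <- sum(sim$counts$lib_sizes[smp])
  out <- data.frame(pair_id = pairs, sample = hybrid,
                    r_count = unname(r[pairs]), c_count = unname(cc[pairs]),
                    ambiguous = 0L,
                    r_per_million = unname(1e6 * r[pairs] / lib),
                    c_per_million = unname(1e6 * cc[pairs] / lib),
                    row.names = NULL)
  attr(out, "lib_size") <- lib
  out
}

#' Simulate reads and SAM alignments for hybrid libraries
#'
#' Draws fixed-length reads from each homoeologue of every gene in
#' numbers equal to the simulated component counts, records the true
#' genome of origin in the read name (\code{gene|R|i}), and writes a
#' FASTQ file and a SAM alignment (1-based positions against the R
#' transcript of each pair, which is valid for C-origin reads because
#' the orthologues differ only by substitutions).  No sequencing errors
#' are introduced, so binning truth is exact.
#'
#' @param sim a \code{\link{simulate_experiment}} result.
#' @param sample_id a hybrid sample name (e.g. \code{"F1_1"}).
#' @param dir output directory.
#' @return list with paths \code{fastq} and \code{sam} and the
#'   data.frame \code{origin} (read name, gene, true genome).
#' @export
generate_reads <- function(sim, sample_id, dir) {
  stopifnot(inherits(sim, "heb_sim"))
  if (!sample_id %in% names(sim$components))
    stop("'", sample_id, "' is not a simulated hybrid sample")
  rl <- sim$design$read_length
  short <- names(sim$lengths)[sim$lengths < rl]
  if (length(short) > 0)
    stop("read length ", rl, " exceeds gene length for: ",
         paste(utils::head(short, 5), collapse = ", "))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  comp <- sim$components[[sample_id]]
  r_chr <- as.character(sim$r_seqs)
  c_chr <- as.character(sim$c_seqs)
  .with_seed(sim$design$seed + 2L + match(sample_id, names(sim$components)), {
    ids <- rownames(comp)
    out <- vector("list", length(ids))
    for (i in seq_along(ids)) {
      g <- ids[i]
      L <- sim$lengths[[g]]
      n_r <- comp[g, "r"]; n_c <- comp[g, "c"]
      if (n_r + n_c == 0) next
      origin <- c(rep("R", n_r), rep("C", n_c))
      starts <- sample.int(L - rl + 1, n_r + n_c, replace = TRUE)
      src <- character(n_r + n_c)
      if (n_r > 0)
        src[seq_len(n_r)] <- substring(
          r_chr[[paste0(g, "_R")]],
          starts[seq_len(n_r)], starts[seq_len(n_r)] + rl - 1)
      if (n_c > 0)
        src[n_r + seq_len(n_c)] <- substring(
          c_chr[[paste0(g, "_C")]],
          starts[n_r + seq_len(n_c)], starts[n_r + seq_len(n_c)] + rl - 1)
      out[[i]] <- data.frame(qname = sprintf("%s|%s|%d", g, origin,
                                             seq_len(n_r + n_c)),
                             gene = g, origin = origin, pos = starts,
                             seq = src)
    }
    reads <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
    fastq <- file.path(dir, paste0(sample_id, ".fastq"))
    qual <- strrep("I", rl)
    writeLines(as.vector(rbind(paste0("@", reads$qname), reads$seq,
                               "+", qual)), fastq)
    sam <- file.path(dir, paste0(sample_id, ".sam"))
    hdr <- c("@HD\tVN:1.6\tSO:unknown",
             sprintf("@SQ\tSN:%s_R\tLN:%d", names(sim$lengths),
                     unname(sim$lengths)))
    body <- paste(reads$qname, 0, paste0(reads$gene, "_R"), reads$pos, 60,
                  paste0(rl, "M"), "*", 0, 0, reads$seq, qual, sep = "\t")
    writeLines(c(hdr, body), sam)
    list(fastq = fastq, sam = sam,
         origin = reads[, c("qname", "gene", "origin")])
  })
}

#' Simulate a homoeologue-specific qPCR CT table
#'
#' CT values follow \code{ct = baseline - log2(expression) + noise}
#' with triplicate technical replicates, for each assay gene a pair of
#' homoeologue-specific assays (R and C) plus a reference-gene assay of
#' constant expression, in each tissue and hybrid sample.  A silenced
#' homoeologue (programmed expression 0 under a silencing or novel
#' flag) is reported as not detected (\code{NA}); a non-positive
#' expression without such a flag rejects the design.
#'
#' @param sim a \code{\link{simulate_experiment}} result.
#' @param genes assay genes; default up to 7 SNP-bearing genes.
#' @param tissues tissue labels (default liver, muscle, ovary).
#' @param samples hybrid groups to assay (default F1 and F18).
#' @param baseline CT of one expression unit (default 35).
#' @param noise_sd Gaussian CT noise in cycles (default 0.15; 0 gives
#'   exact identities).
#' @param n_tech technical replicates (default 3).
#' @param ref_level constant expression of the reference assay.
#' @return data.frame with columns \code{sample}, \code{tissue},
#'   \code{gene}, \code{assay} (\code{R}/\code{C}/\code{ref}),
#'   \code{rep}, \code{ct}.
#' @export
generate_qpcr <- function(sim, genes = NULL,
                          tissues = c("liver", "muscle", "ovary"),
                          samples = c("F1", "F18"),
                          baseline = 35, noise_sd = 0.15, n_tech = 3,
                          ref_level = 1000) {
  stopifnot(inherits(sim, "heb_sim"))
  tr <- sim$truth
  if (is.null(genes)) {
    snp_genes <- unique(sim$snps$pair_id)
    genes <- utils::head(snp_genes[!tr$novel[match(snp_genes, tr$gene)]], 7)
  }
  if (!all(genes %in% tr$gene)) stop("unknown assay gene(s)")
  .with_seed(sim$design$seed + 1000L, {
    rows <- list()
    for (s in samples) for (t in tissues) for (g in genes) {
      i <- match(g, tr$gene)
      mu_h <- if (s == "F1") tr$mu_f1[i] else tr$mu_f18[i]
      p <- if (s == "F1") tr$p_r_f1[i] else tr$p_r_f18[i]
      expr <- c(R = mu_h * p, C = mu_h * (1 - p), ref = ref_level)
      for (a in names(expr)) {
        if (expr[a] <= 0) {
          flagged <- tr$novel[i] || tr$r_silencing[i] || tr$c_silencing[i]
          if (!flagged)
            stop("non-positive expression for ", g, " assay ", a,
                 " without a silencing/novel flag")
          ct <- rep(NA_real_, n_tech)  # not-detected sentinel
        } else {
          ct <- baseline - log2(unname(expr[[a]])) +
            if (noise_sd > 0) stats::rnorm(n_tech, 0, noise_sd) else rep(0, n_tech)
        }
        rows[[length(rows) + 1L]] <-
          data.frame(sample = s, tissue = t, gene = g, assay = a,
                     rep = seq_len(n_tech), ct = ct)
      }
    }
    do.call(rbind, rows)
  })
}

#' Write a simulated experiment to plain-text files
#'
#' Writes the parental transcript FASTA files, the tab-delimited count
#' matrix with its companion length and sample tables, the diagnostic
#' SNP list and the truth table.
#'
#' @param sim a \code{\link{simulate_experiment}} result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "heb_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(sim$r_seqs, file.path(dir, "R_transcripts.fasta"))
  Biostrings::writeXStringSet(sim$c_seqs, file.path(dir, "C_transcripts.fasta"))
  write_counts(sim$counts, file.path(dir, "counts.tsv"),
               file.path(dir, "lengths.tsv"), file.path(dir, "samples.tsv"))
  utils::write.table(sim$snps, file.path(dir, "snps.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
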