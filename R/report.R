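# Pipeline orchestration and report tables mirroring the field's
# standard presentation: per-contrast DE summaries, novel/silencing
# counts, the bias-transition table and the merger/doubling trajectory
# table, each with explicit denominators and self-audited percentages.

#' Printed percentage with round-half-up
#'
#' \code{100 * count / denominator}, rounded half-up to \code{decimals}
#' places (the convention of printed report tables, where e.g. 0.625
#' prints as 0.63, not banker's-rounded to 0.62).
#'
#' @param count numerator count.
#' @param denominator total (> 0).
#' @param decimals printed decimal places (default 1).
#' @return numeric percentage(s).
#' @examples
#' percentage(2492, 3540)  # 70.4
#' @export
percentage <- function(count, denominator, decimals = 1) {
  if (any(denominator <= 0)) stop("denominator must be > 0")
  x <- 100 * count / denominator
  floor(x * 10^decimals + 0.5) / 10^decimals
}

#' Pipeline configuration
#'
#' Thresholds used across the pipeline, defaulting to the analysis
#' conventions of the package: FDR 0.05 with fold change > 2 for DE
#' calls, 10 reads per million for expression status, P < 0.05 for the
#' per-pair homoeologue-bias test.
#'
#' @param fdr DE q-value threshold.
#' @param lfc DE absolute log2-fold-change threshold.
#' @param threshold_pm expressed/silent threshold, reads per million.
#' @param heb_p per-pair homoeologue-bias significance threshold.
#' @param evalue_max,min_aln_bp orthologue-pair thresholds.
#' @param min_concordance,min_cov diagnostic-SNP validation thresholds.
#' @return a named list of class \code{"heb_config"}.
#' @export
heb_config <- function(fdr = 0.05, lfc = 1, threshold_pm = 10,
                       heb_p = 0.05, evalue_max = 1e-20, min_aln_bp = 300,
                       min_concordance = 0.9, min_cov = 5) {
  cfg <- list(fdr = fdr, lfc = lfc, threshold_pm = threshold_pm,
              heb_p = heb_p, evalue_max = evalue_max,
              min_aln_bp = min_aln_bp, min_concordance = min_concordance,
              min_cov = min_cov)
  if (any(unlist(cfg) <= 0)) stop("all thresholds must be positive")
  structure(cfg, class = "heb_config")
}

#' Run the full expression pipeline on a four-group experiment
#'
#' Executes: replicate prefilter, all pairwise DE contrasts (parental
#' R-C, each hybrid against each parent, F1-F18 and the mid-parent
#' contrasts), the twelve-category dominance classification for each
#' hybrid, the trajectory partition into merger/doubling effects, and
#' -- when homoeologue bin counts are supplied -- silencing /
#' novel-expression status, the bias-state classifier and the
#' bias-trajectory partition.  Deterministic given fixed inputs.
#'
#' @param counts unfiltered \code{\link{count_matrix}} with groups
#'   \code{"R"}, \code{"C"}, \code{"F1"}, \code{"F18"}.
#' @param hom_f1,hom_f18 optional homoeologue counts per hybrid
#'   (layout of \code{\link{bin_reads}} /
#'   \code{\link{true_homoeolog_counts}}, pooled over replicates, with
#'   a \code{"lib_size"} attribute).
#' @param config a \code{\link{heb_config}}.
#' @return object of class \code{"heb_report"}: per-gene record tables
#'   under \code{$records} and formatted summary tables under
#'   \code{$tables} (all percentages audited against their own counts
#'   and denominators).
#' @export
run_pipeline <- function(counts, hom_f1 = NULL, hom_f18 = NULL,
                         config = heb_config()) {
  stopifnot(inherits(counts, "count_matrix"))
  need <- c("R", "C", "F1", "F18")
  if (!all(need %in% counts$groups))
    stop("pipeline failed at stage 'input': missing group(s): ",
         paste(setdiff(need, counts$groups), collapse = ", "))

  records <- list()
  # expression status runs on unfiltered counts (silent genes needed)
  if (!is.null(hom_f1))
    records$status_f1 <- call_expression_status(hom_f1, counts,
                                                threshold = config$threshold_pm)
  if (!is.null(hom_f18))
    records$status_f18 <- call_expression_status(hom_f18, counts,
                                                 threshold = config$threshold_pm)

  filtered <- filter_expressed(counts)
  de <- function(a, b) call_de(filtered, a, b,
                               fdr = config$fdr, lfc = config$lfc)
  records$de <- list(RC = de("C", "R"),       # up = R higher
                     F1_R = de("R", "F1"), F1_C = de("C", "F1"),
                     F18_R = de("R", "F18"), F18_C = de("C", "F18"),
                     F1_F18 = de("F1", "F18"))
  records$eld_f1 <- eld_classify(records$de$F1_R, records$de$F1_C,
                                 records$de$RC)
  records$eld_f18 <- eld_classify(records$de$F18_R, records$de$F18_C,
                                  records$de$RC)
  records$trajectory <- trajectory_classify(filtered, fdr = config$fdr,
                                            lfc = config$lfc)

  if (!is.null(hom_f1) && !is.null(hom_f18)) {
    heb_one <- function(hom) {
      par_call <- records$de$RC$call[match(hom$pair_id, records$de$RC$gene)]
      keep <- !is.na(par_call)
      h <- hom[keep, , drop = FALSE]
      cbind(pair_id = h$pair_id,
            classify_heb(par_call[keep], h$r_count, h$c_count,
                         attr(hom, "lib_size"), p_cut = config$heb_p))
    }
    records$heb_f1 <- heb_one(hom_f1)
    records$heb_f18 <- heb_one(hom_f18)
    common <- intersect(records$heb_f1$pair_id, records$heb_f18$pair_id)
    i1 <- match(common, records$heb_f1$pair_id)
    i18 <- match(common, records$heb_f18$pair_id)
    records$heb_trajectory <- data.frame(
      pair_id = common,
      divergence = records$heb_f1$parental_state[i1],
      state_f1 = records$heb_f1$progeny_state[i1],
      state_f18 = records$heb_f18$progeny_state[i18],
      class = classify_heb_trajectory(records$heb_f1$parental_state[i1],
                                      records$heb_f1$progeny_state[i1],
                                      records$heb_f18$progeny_state[i18]),
      row.names = NULL)
  }

  structure(list(records = records, config = config,
                 tables = .build_tables(records)),
            class = "heb_report")
}

# percentage() that degrades to NA on an empty denominator, for report
# tables built from (possibly empty) subsets
.pct0 <- function(count, denominator, decimals = 1) {
  if (denominator > 0) percentage(count, denominator, decimals)
  else rep(NA_real_, length(count))
}

# Assemble and audit every summary table from the per-gene records.
.build_tables <- function(records) {
  tables <- list()
  tables$de_summary <- do.call(rbind, lapply(names(records$de), function(nm) {
    d <- records$de[[nm]]
    n <- nrow(d); nde <- sum(d$call != "ns")
    data.frame(contrast = nm, n_genes = n, n_de = nde,
               pct_de = .pct0(nde, n, 2),
               up = sum(d$call == "up"), down = sum(d$call == "down"),
               row.names = NULL)
  }))

  eld_tab <- function(recs) {
    s <- summarize_eld(recs)
    data.frame(category = names(s$counts), count = unname(s$counts),
               pct = .pct0(unname(s$counts), s$n_classified, 1),
               denominator = s$n_classified, row.names = NULL)
  }
  if (!is.null(records$eld_f1)) {
    tables$eld_f1 <- eld_tab(records$eld_f1)
    tables$eld_f18 <- eld_tab(records$eld_f18)
  }

  if (!is.null(records$status_f1)) {
    status_row <- function(st, taxon) {
      n <- nrow(st)
      data.frame(taxon = taxon,
                 novel = sum(st$novel), novel_pct = .pct0(sum(st$novel), n, 2),
                 r_silencing = sum(st$r_silencing),
                 r_silencing_pct = .pct0(sum(st$r_silencing), n, 2),
                 c_silencing = sum(st$c_silencing),
                 c_silencing_pct = .pct0(sum(st$c_silencing), n, 2),
                 denominator = n, row.names = NULL)
    }
    tables$status <- rbind(
      status_row(records$status_f1, "F1"),
      if (!is.null(records$status_f18)) status_row(records$status_f18, "F18"))
  }

  if (!is.null(records$heb_f1)) {
    tables$heb <- .heb_table(records$heb_f1, records$heb_f18)
  }
  if (!is.null(records$trajectory)) {
    tables$trajectory <- .trajectory_table(records$trajectory$class,
                                           "Global gene expression changes")
  }
  if (!is.null(records$heb_trajectory)) {
    tables$heb_trajectory <- .trajectory_table(records$heb_trajectory$class,
                                               "Homoeologue expression bias changes")
  }
  .audit_tables(tables)
  tables
}

# Bias-transition table in the standard layout: nine (parental,
# progeny) rows, the total, and the overall / potential bias rows.
.heb_table <- function(heb_f1, heb_f18) {
  grid <- data.frame(
    parental = c("R=C", "R>C", "R<C", "R>C", "R<C", "R=C", "R=C", "R<C", "R>C"),
    progeny  = c("R=C", "R>C", "R<C", "R=C", "R=C", "R>C", "R<C", "R>C", "R<C"))
  grid$description <- heb_transition(grid$parental, grid$progeny)
  grid$description <- c("parental-condition" = "Parental condition",
                        "no-bias-in-progeny" = "No bias in progeny",
                        "novel-bias-in-progeny" = "Novel bias in progeny"
                        )[grid$description]
  one <- function(h) {
    n <- nrow(h)
    cnt <- vapply(seq_len(nrow(grid)), function(i)
      sum(h$parental_state == grid$parental[i] &
          h$progeny_state == grid$progeny[i]), integer(1))
    extra <- c(`Overall R-biased in progeny` = sum(h$overall_bias == "R"),
               `Overall C-biased in progeny` = sum(h$overall_bias == "C"),
               `Potential R-biased in progeny` = sum(h$potential_bias == "R"),
               `Potential C-biased in progeny` = sum(h$potential_bias == "C"))
    list(n = n, cnt = cnt, extra = extra)
  }
  a <- one(heb_f1); b <- one(heb_f18)
  data.frame(
    parental = c(grid$parental, "Total", rep("", 4)),
    progeny = c(grid$progeny, "", rep("", 4)),
    description = c(grid$description, "Total number of genes",
                    names(a$extra)),
    f1_count = c(a$cnt, a$n, unname(a$extra)),
    f1_pct = c(.pct0(a$cnt, a$n, 1), NA,
               .pct0(unname(a$extra), a$n, 1)),
    f18_count = c(b$cnt, b$n, unname(b$extra)),
    f18_pct = c(.pct0(b$cnt, b$n, 1), NA,
                .pct0(unname(b$extra), b$n, 1)),
    row.names = NULL)
}

.trajectory_table <- function(classes, section) {
  lv <- c("no-change", "doubling", "merger", "other")
  desc <- c("No change", "Change due to genome doubling",
            "Change due to genome merger", "Other")
  n <- length(classes)
  cnt <- vapply(lv, function(l) sum(classes == l), integer(1))
  data.frame(section = section,
             class = c(lv, "total"),
             description = c(desc, "Total"),
             count = c(unname(cnt), n),
             pct = c(.pct0(unname(cnt), n, 1), NA),
             row.names = NULL)
}

# Self-consistency audit: every printed percentage must recompute from
# its own count and denominator.
.audit_tables <- function(tables) {
  chk <- function(count, denom, pct, decimals, where) {
    denom <- rep_len(denom, length(pct))
    use <- !is.na(pct) & denom > 0
    if (!any(use)) return(invisible())
    ok <- abs(pct[use] - percentage(count[use], denom[use], decimals)) < 1e-9
    if (!all(ok))
      stop("report audit failed in ", where, ": percentage mismatch")
  }
  if (!is.null(tables$de_summary))
    chk(tables$de_summary$n_de, tables$de_summary$n_genes,
        tables$de_summary$pct_de, 2, "de_summary")
  for (nm in c("eld_f1", "eld_f18"))
    if (!is.null(tables[[nm]]) && any(tables[[nm]]$denominator > 0))
      chk(tables[[nm]]$count, tables[[nm]]$denominator,
          tables[[nm]]$pct, 1, nm)
  if (!is.null(tables$heb)) {
    h <- tables$heb
    total <- h$f1_count[h$description == "Total number of genes"]
    total18 <- h$f18_count[h$description == "Total number of genes"]
    rows <- !is.na(h$f1_pct)
    chk(h$f1_count[rows], total, h$f1_pct[rows], 1, "heb/f1")
    chk(h$f18_count[rows], total18, h$f18_pct[rows], 1, "heb/f18")
  }
  for (nm in c("trajectory", "heb_trajectory"))
    if (!is.null(tables[[nm]])) {
      t <- tables[[nm]]
      total <- t$count[t$class == "total"]
      if (total > 0)
        chk(t$count[!is.na(t$pct)], total, t$pct[!is.na(t$pct)], 1, nm)
    }
  invisible(TRUE)
}

#' Restrict a pipeline report to a gene subset
#'
#' Recomputes every summary table on the subset only; denominators
#' become the subset sizes.  Unknown identifiers are reported in a
#' warning and excluded.  Classification per gene is unchanged -- only
#' the summaries are recomputed -- mirroring gene-panel reporting such
#' as growth-related gene sets.
#'
#' @param report a \code{\link{run_pipeline}} result.
#' @param genes gene / pair identifiers of the subset.
#' @return a new \code{"heb_report"} restricted to the subset.
#' @export
subset_report <- function(report, genes) {
  stopifnot(inherits(report, "heb_report"))
  known <- unique(c(report$records$eld_f1$gene,
                    report$records$heb_f1$pair_id,
                    report$records$status_f1$pair_id,
                    report$records$trajectory$gene))
  unknown <- setdiff(genes, known)
  if (length(unknown) > 0)
    warning("unknown gene id(s) excluded: ",
            paste(utils::head(unknown, 10), collapse = ", "))
  genes <- setdiff(genes, unknown)
  rec <- report$records
  pick <- function(df, col) {
    if (is.null(df)) return(NULL)
    df[df[[col]] %in% genes, , drop = FALSE]
  }
  rec$de <- lapply(rec$de, pick, col = "gene")
  for (nm in c("eld_f1", "eld_f18", "trajectory"))
    rec[[nm]] <- pick(rec[[nm]], "gene")
  for (nm in c("status_f1", "status_f18", "heb_f1", "heb_f18",
               "heb_trajectory"))
    rec[[nm]] <- pick(rec[[nm]], "pair_id")
  structure(list(records = rec, config = report$config,
                 tables = .build_tables(rec)),
            class = "heb_report")
}

#' @export
print.heb_report <- function(x, ...) {
  cat("== Differential expression ==\n")
  print(x$tables$de_summary, row.names = FALSE)
  if (!is.null(x$tables$eld_f1)) {
    s1 <- summarize_eld(x$records$eld_f1)
    s18 <- summarize_eld(x$records$eld_f18)
    cat("\n== Expression level dominance (classified genes) ==\n")
    cat(sprintf("F1 : %d classified / %d genes; maternal %d, paternal %d\n",
                s1$n_classified, s1$n_total,
                s1$totals["maternal_eld"], s1$totals["paternal_eld"]))
    cat(sprintf("F18: %d classified / %d genes; maternal %d, paternal %d\n",
                s18$n_classified, s18$n_total,
                s18$totals["maternal_eld"], s18$totals["paternal_eld"]))
  }
  if (!is.null(x$tables$status)) {
    cat("\n== Novel expression and silencing ==\n")
    print(x$tables$status, row.names = FALSE)
  }
  if (!is.null(x$tables$heb)) {
    cat("\n== Homoeologue expression bias ==\n")
    print(x$tables$heb, row.names = FALSE)
  }
  if (!is.null(x$tables$trajectory)) {
    cat("\n== Expression trajectories (merger vs doubling) ==\n")
    print(x$tables$trajectory[, -1], row.names = FALSE)
  }
  if (!is.null(x$tables$heb_trajectory)) {
    cat("\n== Bias trajectories ==\n")
    print(x$tables$heb_trajectory[, -1], row.names = FALSE)
  }
  invisible(x)
}
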