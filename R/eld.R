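# Expression level dominance: the twelve-category classification of a
# hybrid's expression relative to its two diploid parents, from the
# triple of pairwise DE calls.

.ELD_CATEGORIES <- c("I", "II", "III", "IV", "V", "VI",
                     "VII", "VIII", "IX", "X", "XI", "XII")

# Decision table keyed by "call_hr/call_hc/call_rc" where call_hr is
# hybrid-vs-maternal-R (up = hybrid higher), call_hc hybrid-vs-paternal-
# C, call_rc the parental contrast (up = R higher than C).
.ELD_TABLE <- c(
  "down/down/up"   = "I",     # below both parents, R > C
  "down/down/ns"   = "II",    # below both parents, R = C
  "down/down/down" = "III",   # below both parents, R < C
  "up/up/down"     = "IV",    # above both parents, R < C
  "up/up/ns"       = "V",     # above both parents, R = C
  "up/up/up"       = "VI",    # above both parents, R > C
  "up/ns/down"     = "VII",   # paternal dominance, expression up
  "down/ns/up"     = "VIII",  # paternal dominance, expression down
  "ns/down/down"   = "IX",    # maternal dominance, expression down
  "ns/up/up"       = "X",     # maternal dominance, expression up
  "up/down/down"   = "XI",    # intermediate (mid-parent), R < C
  "down/up/up"     = "XII",   # intermediate (mid-parent), R > C
  "ns/ns/ns"       = "conserved")

#' Expression-level-dominance category from three DE calls
#'
#' Assigns one of the twelve Roman-numeral expression categories (or
#' \code{conserved} / \code{ambiguous}) from the hybrid-vs-R,
#' hybrid-vs-C and R-vs-C differential expression calls.  Call
#' directions: \code{call_hr = "up"} means the hybrid is higher than
#' the maternal parent R, \code{call_hc} likewise against the paternal
#' parent C, and \code{call_rc = "up"} means R is higher than C.
#'
#' Categories VII/VIII are paternal expression dominance (hybrid at the
#' C level), IX/X maternal dominance (hybrid at the R level), XI/XII
#' intermediate between divergent parents, I-III transgressive-low and
#' IV-VI transgressive-high, with the numeral within each trio fixed by
#' the parental relation.  The all-\code{ns} triple is
#' \code{conserved}; the 14 remaining triples (e.g. hybrid equal to
#' both parents while the parents differ) are \code{ambiguous}.
#'
#' @param call_hr,call_hc,call_rc DE calls in \code{c("up","down","ns")};
#'   vectors are recycled to a common length.
#' @return character vector of categories.
#' @examples
#' classify_eld("up", "ns", "down")  # "VII"
#' @export
classify_eld <- function(call_hr, call_hc, call_rc) {
  n <- max(length(call_hr), length(call_hc), length(call_rc))
  call_hr <- rep_len(call_hr, n); call_hc <- rep_len(call_hc, n)
  call_rc <- rep_len(call_rc, n)
  ok <- c("up", "down", "ns")
  bad <- setdiff(unique(c(call_hr, call_hc, call_rc)), ok)
  if (length(bad) > 0)
    stop("invalid DE call token(s): ", paste(bad, collapse = ", "))
  key <- paste(call_hr, call_hc, call_rc, sep = "/")
  out <- unname(.ELD_TABLE[key])
  out[is.na(out)] <- "ambiguous"
  out
}

#' Classify every gene of a hybrid into expression categories
#'
#' Convenience wrapper joining three \code{\link{call_de}} tables on the
#' gene column.
#'
#' @param de_hr DE table for the hybrid-vs-R contrast, directions as
#'   hybrid relative to R (i.e. \code{call_de(x, "R", hybrid)}).
#' @param de_hc DE table for hybrid-vs-C (\code{call_de(x, "C", hybrid)}).
#' @param de_rc DE table for the parental contrast, direction R relative
#'   to C (\code{call_de(x, "C", "R")}).
#' @return data.frame with \code{gene}, the three calls and
#'   \code{category}.
#' @export
eld_classify <- function(de_hr, de_hc, de_rc) {
  genes <- de_hr$gene
  if (!setequal(genes, de_hc$gene) || !setequal(genes, de_rc$gene))
    stop("the three DE tables must cover the same genes; filter first")
  hc <- de_hc$call[match(genes, de_hc$gene)]
  rc <- de_rc$call[match(genes, de_rc$gene)]
  data.frame(gene = genes,
             call_hr = de_hr$call, call_hc = hc, call_rc = rc,
             category = classify_eld(de_hr$call, hc, rc),
             row.names = NULL)
}

# Category membership of the four directional gene lists.
.ELD_UP_VS_C   <- c("IV", "V", "VI", "X", "XII")   # hybrid above C
.ELD_DOWN_VS_C <- c("I", "II", "III", "IX", "XI")  # hybrid below C
.ELD_UP_VS_R   <- c("IV", "V", "VI", "VII", "XI")  # hybrid above R
.ELD_DOWN_VS_R <- c("I", "II", "III", "VIII", "XII")

#' Summary totals over expression categories
#'
#' Counts per category plus the derived totals: maternal dominance
#' (IX + X), paternal dominance (VII + VIII), upregulated-dominance
#' pair (VII, X), downregulated-dominance pair (VIII, IX),
#' transgressive-up (IV + V + VI), transgressive-down (I + II + III),
#' intermediate (XI + XII), and the four directional memberships
#' (hybrid up/down versus each parent).  Percentages are over the
#' classified genes, i.e. excluding \code{conserved} and
#' \code{ambiguous}; the denominator is reported explicitly.
#'
#' @param records data.frame from \code{\link{eld_classify}} (or any
#'   data.frame with a \code{category} column).
#' @return A list with elements \code{counts} (named vector over all 14
#'   labels), \code{totals}, \code{direction_counts},
#'   \code{n_classified}, \code{n_total}, \code{percent} (per category,
#'   over classified genes).
#' @export
summarize_eld <- function(records) {
  labs <- c(.ELD_CATEGORIES, "conserved", "ambiguous")
  counts <- table(factor(records$category, levels = labs))
  counts <- stats::setNames(as.integer(counts), labs)
  cnt <- function(set) sum(counts[set])
  totals <- c(maternal_eld = cnt(c("IX", "X")),
              paternal_eld = cnt(c("VII", "VIII")),
              eld_up = cnt(c("VII", "X")),
              eld_down = cnt(c("VIII", "IX")),
              transgressive_up = cnt(c("IV", "V", "VI")),
              transgressive_down = cnt(c("I", "II", "III")),
              mid_parent = cnt(c("XI", "XII")))
  direction <- c(up_vs_C = cnt(.ELD_UP_VS_C), down_vs_C = cnt(.ELD_DOWN_VS_C),
                 up_vs_R = cnt(.ELD_UP_VS_R), down_vs_R = cnt(.ELD_DOWN_VS_R))
  n_classified <- sum(counts[.ELD_CATEGORIES])
  pct <- if (n_classified > 0)
    100 * counts[.ELD_CATEGORIES] / n_classified
  else stats::setNames(rep(0, 12), .ELD_CATEGORIES)
  list(counts = counts, totals = totals, direction_counts = direction,
       n_classified = n_classified, n_total = nrow(records),
       percent = pct)
}
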