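#' Construct a labeled 2x2 contingency table
#'
#' Cell layout follows the knockdown-overlap convention:
#' \code{a} = in both sets, \code{b} = first set only, \code{c} = second
#' set only, \code{d} = in neither.
#'
#' @param a,b,c,d Non-negative integer counts.
#' @param row_labels,col_labels Length-2 character vectors naming the two
#'   classifications.
#' @return List of class \code{ContingencyTable2x2}.
#' @export
contingency_2x2 <- function(a, b, c, d,
                            row_labels = c("in_A", "not_A"),
                            col_labels = c("in_B", "not_B")) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0)) stop("negative cell count")
  if (any(cells != round(cells))) stop("cell counts must be integers")
  if (sum(cells) == 0) stop("empty table (N = 0)")
  structure(list(a = a, b = b, c = c, d = d,
                 row_labels = row_labels, col_labels = col_labels),
            class = "ContingencyTable2x2")
}

#' @export
print.ContingencyTable2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2L, 2L,
              dimnames = list(x$col_labels, x$row_labels))
  print(t(m))
  invisible(x)
}

.as_cells <- function(table) {
  if (inherits(table, "ContingencyTable2x2"))
    c(table$a, table$b, table$c, table$d)
  else if (is.matrix(table) && all(dim(table) == 2L))
    c(table[1L, 1L], table[1L, 2L], table[2L, 1L], table[2L, 2L])
  else stop("expected a ContingencyTable2x2 or a 2x2 matrix")
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact p-value under the probability-mass convention: the sum of the
#' hypergeometric probabilities of all tables with the observed margins
#' whose probability does not exceed that of the observed table (with a
#' 1e-7 relative tolerance for floating-point ties). Probabilities are
#' evaluated in log space, so tiny p-values are computed without
#' underflow.
#'
#' @param table A \code{\link{contingency_2x2}} or a 2x2 matrix
#'   \code{rbind(c(a, b), c(c, d))}.
#' @return The two-sided exact p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  cells <- .as_cells(table)
  if (any(cells < 0)) stop("negative cell count")
  a <- cells[1L]; b <- cells[2L]; c <- cells[3L]; d <- cells[4L]
  m <- a + b          # margin of the first row
  n <- c + d
  k <- a + c          # margin of the first column
  support <- max(0L, k - n):min(k, m)
  logp <- stats::dhyper(support, m, n, k, log = TRUE)
  obs <- stats::dhyper(a, m, n, k, log = TRUE)
  min(1, sum(exp(logp[logp <= obs + 1e-7])))
}

#' Cross-product odds ratio with Woolf confidence interval
#'
#' Point estimate \code{(a d) / (b c)} (possibly 0, Inf, or NaN for a
#' doubly degenerate table). The 95\% CI uses the Woolf logit method,
#' \code{exp(log OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))}; when any cell
#' is zero the Haldane-Anscombe 0.5 correction is applied to all cells for
#' the CI only.
#'
#' @inheritParams fisher_exact_2x2
#' @return List with \code{odds_ratio}, \code{ci_low}, \code{ci_high}.
#' @export
odds_ratio_ci <- function(table) {
  cells <- .as_cells(table)
  or <- (cells[1L] * cells[4L]) / (cells[2L] * cells[3L])
  cc <- if (any(cells == 0)) cells + 0.5 else cells
  lor <- log((cc[1L] * cc[4L]) / (cc[2L] * cc[3L]))
  se <- sqrt(sum(1 / cc))
  list(odds_ratio = or,
       ci_low = exp(lor - 1.96 * se),
       ci_high = exp(lor + 1.96 * se))
}

#' Full overlap statistics for a 2x2 table
#' @inheritParams fisher_exact_2x2
#' @return List of class \code{OverlapResult}: the table, the
#'   cross-product \code{odds_ratio} with Woolf \code{ci_low} /
#'   \code{ci_high}, and the two-sided exact \code{fisher_p}.
#' @export
overlap_result <- function(table) {
  if (!inherits(table, "ContingencyTable2x2")) {
    cells <- .as_cells(table)
    table <- contingency_2x2(cells[1L], cells[2L], cells[3L], cells[4L])
  }
  or <- odds_ratio_ci(table)
  structure(list(table = table, odds_ratio = or$odds_ratio,
                 ci_low = or$ci_low, ci_high = or$ci_high,
                 fisher_p = fisher_exact_2x2(table)),
            class = "OverlapResult")
}

#' @export
print.OverlapResult <- function(x, ...) {
  cat(sprintf("OverlapResult: OR = %.3g (95%% CI %.3g-%.3g), Fisher p = %.3g\n",
              x$odds_ratio, x$ci_low, x$ci_high, x$fisher_p))
  invisible(x)
}

#' Build the 2x2 overlap table of two sets within a universe
#'
#' Orientation matches the knockdown-overlap layout:
#' \code{a = |A intersect B|}, \code{b = |A \\ B|}, \code{c = |B \\ A|},
#' \code{d = |universe \\ (A union B)|}. The universe must be supplied
#' explicitly — it is never defaulted to the union, because the \code{d}
#' cell (and hence the odds ratio) depends on it.
#'
#' @param set_a,set_b Character vectors, subsets of \code{universe}
#'   (e.g. A = subtype-specific set, B = knockdown-responsive set).
#' @param universe Character vector of all testable identifiers.
#' @param labels Optional length-2 names for the two sets, used for the
#'   table labels.
#' @return A \code{\link{contingency_2x2}}.
#' @export
build_overlap_table <- function(set_a, set_b, universe,
                                labels = c("A", "B")) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  universe <- unique(universe)
  out_a <- setdiff(set_a, universe); out_b <- setdiff(set_b, universe)
  if (length(out_a) || length(out_b))
    stop("sets must be subsets of the universe; offending ids: ",
         paste(utils::head(c(out_a, out_b), 3L), collapse = ", "))
  a <- length(intersect(set_a, set_b))
  b <- length(setdiff(set_a, set_b))
  c <- length(setdiff(set_b, set_a))
  d <- length(universe) - a - b - c
  contingency_2x2(a, b, c, d,
                  row_labels = paste0(c("in_", "not_"), labels[1L]),
                  col_labels = paste0(c("in_", "not_"), labels[2L]))
}

#' Direction concordance between knockdown response and subtype difference
#'
#' Restricted to isoforms with a nonzero signed change in both inputs,
#' counts isoforms by (knockdown up/down) x (TN up/down) in the layout
#' knockdownUp_tnDown / knockdownDown_tnDown / knockdownUp_tnUp /
#' knockdownDown_tnUp, and computes the accompanying overlap statistics.
#' An odds ratio above 1 indicates that knockdown changes oppose the TN
#' direction.
#'
#' @param kd_changes Named numeric vector of signed knockdown changes per
#'   isoform.
#' @param subtype_changes Named numeric vector of signed TN-vs-ER+ changes
#'   per isoform.
#' @return An \code{\link{overlap_result}} whose table has cells
#'   a = KD up & TN down, b = KD down & TN down, c = KD up & TN up,
#'   d = KD down & TN up.
#' @export
direction_concordance_table <- function(kd_changes, subtype_changes) {
  ids <- intersect(names(kd_changes), names(subtype_changes))
  kd <- sign(kd_changes[ids]); st <- sign(subtype_changes[ids])
  keep <- kd != 0 & st != 0
  kd <- kd[keep]; st <- st[keep]
  if (!length(kd)) stop("no isoform with nonzero change in both inputs")
  tab <- contingency_2x2(sum(kd > 0 & st < 0), sum(kd < 0 & st < 0),
                         sum(kd > 0 & st > 0), sum(kd < 0 & st > 0),
                         row_labels = c("knockdownUp", "knockdownDown"),
                         col_labels = c("tnDown", "tnUp"))
  overlap_result(tab)
}

#' Overlap between binding sites and a gene set
#'
#' A gene is "bound" iff any track interval on its chromosome overlaps the
#' gene span extended by \code{window} bases on each side. The resulting
#' bound/unbound classification is crossed with membership in
#' \code{gene_set} over the supplied universe.
#'
#' @param track An \code{\link{interval_track}} of binding sites.
#' @param models Gene models (used for gene spans; a gene's span covers
#'   all its isoforms).
#' @param gene_set Character vector of gene ids (e.g. knockdown-responsive
#'   genes), subset of \code{universe}.
#' @param universe Character vector of all testable gene ids.
#' @param window Bases added to each side of the gene span (default
#'   25000).
#' @return An \code{\link{overlap_result}} with
#'   a = bound & in set, b = bound only, c = in set only, d = neither.
#' @export
gene_binding_overlap <- function(track, models, gene_set, universe,
                                 window = 25000) {
  by_gene <- group_by_gene(models)
  miss <- setdiff(universe, names(by_gene))
  if (length(miss))
    stop("universe gene(s) absent from models: ",
         paste(utils::head(miss, 3L), collapse = ", "))
  bound <- vapply(universe, function(gid) {
    txs <- by_gene[[gid]]
    spans <- vapply(txs, transcript_span, numeric(2L))
    s <- min(spans[1L, ]) - window
    e <- max(spans[2L, ]) + window
    chrom <- txs[[1L]]$chrom
    any(track$chrom == chrom & track$start < e & track$end > s)
  }, logical(1L))
  tab <- build_overlap_table(universe[bound], intersect(gene_set, universe),
                             universe, labels = c("bound", "set"))
  overlap_result(tab)
}

#' Published knockdown-overlap contingency counts
#'
#' The published 2x2 cell counts relating isoforms responsive to siRNA
#' knockdown of six RNA-processing factors (MAGOH, MAGOHB, PCBP2, THOC1,
#' YBX1, YBX2) in MCF7 cells to (i) subtype-specific isoforms, (ii) ER and
#' PR binding-site proximity, and (iii) the direction of the subtype
#' difference, together with the odds ratios and Fisher p-values as
#' printed (and the precision they were printed at). Used to validate the
#' exact contingency statistics against published values.
#'
#' @return Data frame with columns \code{factor}, \code{comparison},
#'   cells \code{a}-\code{d}, \code{printed_or}, \code{or_tol},
#'   \code{printed_p}, \code{p_tol}.
#' @export
published_overlap_counts <- function() {
  utils::read.delim(system.file("extdata", "knockdown_overlap_counts.tsv",
                                package = "isousage"),
                    stringsAsFactors = FALSE)
}

#' Enrichment of an annotated set among differential genes
#'
#' Thin wrapper: builds the overlap table of the differential set against
#' the annotated set over the universe, then computes the Fisher p and
#' odds ratio. Used e.g. to test whether RNA-processing factors are
#' over-represented among subtype-differential genes.
#'
#' @param de_genes Character vector of differential gene ids.
#' @param annotated_set Character vector of annotated gene ids (e.g.
#'   splicing factors); must intersect the universe.
#' @param universe Character vector of all tested gene ids.
#' @return An \code{\link{overlap_result}}.
#' @export
set_enrichment <- function(de_genes, annotated_set, universe) {
  ann <- intersect(annotated_set, universe)
  if (!length(ann))
    stop("annotated set does not intersect the universe")
  de <- intersect(de_genes, universe)
  overlap_result(build_overlap_table(de, ann, universe,
                                     labels = c("DE", "annotated")))
}
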