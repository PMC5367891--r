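# shared fixture builders and independent oracles

make_tx <- function(id, exons, strand = "+", cds = NULL, gene = "gX") {
  transcript_model(id, gene, "chr1", strand, exons, cds)
}

# brute-force base labeling: every exonic position of a transcript tagged
# 5'UTR / CDS / 3'UTR by scanning positions one by one (independent of the
# interval algebra used by the package)
oracle_base_labels <- function(tx) {
  pos <- unlist(lapply(seq_len(nrow(tx$exons)), function(i)
    seq(tx$exons[i, 1L], tx$exons[i, 2L] - 1L)))
  pos <- sort(pos)
  if (is.null(tx$cds)) return(setNames(rep("exon", length(pos)),
                                       as.character(pos)))
  lab <- ifelse(pos < tx$cds[1L], "left",
                ifelse(pos >= tx$cds[2L], "right", "cds"))
  if (tx$strand == "+") {
    lab[lab == "left"] <- "5utr"; lab[lab == "right"] <- "3utr"
  } else {
    lab[lab == "left"] <- "3utr"; lab[lab == "right"] <- "5utr"
  }
  setNames(lab, as.character(pos))
}

# brute-force two-sided Fisher p by enumerating all margin-preserving tables
oracle_fisher_enum <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  pr <- vapply(support, function(x)
    choose(m, x) * choose(n, k - x) / choose(m + n, k), numeric(1L))
  obs <- pr[match(a, support)]
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# random 2x2 table with N <= n_max (all margins nonzero not required)
random_table <- function(n_max = 60) {
  repeat {
    cells <- as.vector(stats::rmultinom(1L, sample(4:n_max, 1L),
                                        prob = stats::runif(4, 0.05, 1)))
    if (sum(cells) > 0) return(cells)
  }
}

# strand-flipped copy of a transcript (same coordinates)
flip_strand <- function(tx) {
  transcript_model(tx$transcript_id, tx$gene_id, tx$chrom,
                   if (tx$strand == "+") "-" else "+",
                   tx$exons, tx$cds, tx$attributes)
}

# exonic base set of a transcript as an integer vector
exon_bases <- function(tx) {
  unlist(lapply(seq_len(nrow(tx$exons)), function(i)
    seq(tx$exons[i, 1L], tx$exons[i, 2L] - 1L)))
}

tiny_expression <- function(vals, features = NULL, samples = NULL) {
  if (is.null(features)) features <- paste0("t", seq_len(nrow(vals)))
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(vals)))
  expression_matrix(matrix(vals, nrow = length(features),
                           dimnames = list(features, samples)), "raw")
}

two_group_sheet <- function(n_er, n_tn) {
  data.frame(sample_id = c(sprintf("ER%02d", seq_len(n_er)),
                           sprintf("TN%02d", seq_len(n_tn))),
             subtype = factor(rep(c("ERpos", "TN"), c(n_er, n_tn)),
                              levels = c("ERpos", "TN")),
             cohort = "fixture", platform = "rnaseq",
             stringsAsFactors = FALSE)
}
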