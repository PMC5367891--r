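#' @name event_classifier
#' @title Pairwise transcript structure comparison and splice-event calling
#' @description
#' Two transcripts of the same gene can differ in their 5'UTR, internal
#' exon structure, and/or 3'UTR. \code{\link{compare_pair}} partitions the
#' exonic base differences of an isoform pair into those three regions and
#' flags coding consequences; \code{\link{call_splice_events}} resolves the
#' internal structure differences into the classic splice-event taxonomy:
#' exon skipping, intron retention, alternative donor and alternative
#' acceptor, plus alternative first/last exons at the transcript termini.
#' All donor/acceptor and first/last notions are strand-aware (on the plus
#' strand the donor is the genomic start boundary of an intron and the
#' acceptor its end boundary; on the minus strand, reversed).
NULL

.check_pair <- function(tx_a, tx_b) {
  if (tx_a$chrom != tx_b$chrom || tx_a$strand != tx_b$strand)
    stop("transcripts on different chrom/strand: ",
         tx_a$transcript_id, " vs ", tx_b$transcript_id)
}

# label a transcript's exonic intervals as 5'UTR / CDS / 3'UTR using its
# own CDS span, strand-aware; without a CDS the whole exonic region gets
# the CDS-equivalent "exon" label (UTR categories unavailable)
.label_regions <- function(tx) {
  if (is.null(tx$cds)) {
    return(list(five = matrix(numeric(), ncol = 2L), cds = tx$exons,
                three = matrix(numeric(), ncol = 2L), no_cds = TRUE))
  }
  span <- transcript_span(tx)
  left <- matrix(c(span[1L], tx$cds[1L]), ncol = 2L)
  right <- matrix(c(tx$cds[2L], span[2L]), ncol = 2L)
  left_iv <- if (left[1L] < left[2L])
    intersect_intervals(tx$exons, left) else matrix(numeric(), ncol = 2L)
  right_iv <- if (right[1L] < right[2L])
    intersect_intervals(tx$exons, right) else matrix(numeric(), ncol = 2L)
  cds_iv <- intersect_intervals(tx$exons, matrix(tx$cds, ncol = 2L))
  if (tx$strand == "+") list(five = left_iv, cds = cds_iv, three = right_iv,
                             no_cds = FALSE)
  else list(five = right_iv, cds = cds_iv, three = left_iv, no_cds = FALSE)
}

.intervals_equal <- function(a, b) {
  nrow(a) == nrow(b) && (nrow(a) == 0L || all(a == b))
}

#' Compare the structure of two isoforms of one gene
#'
#' Each transcript's exonic bases are labeled 5'UTR / CDS / 3'UTR using its
#' own CDS (strand-aware: the 5'UTR is upstream of the CDS in transcription
#' direction). The symmetric difference of the two exonic base sets is then
#' computed, and \code{differs_<region>} is true iff some differing base
#' carries that region's label in the transcript containing it.
#' \code{coding_change} is true iff some differing base is CDS-labeled in
#' either transcript. \code{differs_exons} is additionally true when the
#' internal splice structure (the intron sets within the common span)
#' differs, so a skipped exon lying entirely in a UTR still counts as an
#' exon difference, while pure terminal-exon-length differences in UTRs
#' fall to the UTR categories.
#'
#' The mutually exclusive \code{primary_category} follows the priority
#' rule: internal-exon difference -> \code{alt_splicing}; else 5'UTR
#' difference -> \code{alt_promoter}; else \code{alt_3utr}.
#'
#' @param tx_a,tx_b \code{TranscriptModel}s of the same gene (same
#'   chromosome and strand).
#' @return List of class \code{StructuralDiff}: flags \code{differs_5utr},
#'   \code{differs_exons}, \code{differs_3utr}, \code{coding_change},
#'   \code{no_cds} (either transcript lacks a CDS), and
#'   \code{primary_category} (\code{alt_splicing}, \code{alt_promoter},
#'   \code{alt_3utr}, or \code{NA} for identical structures).
#' @export
compare_pair <- function(tx_a, tx_b) {
  .check_pair(tx_a, tx_b)
  lab_a <- .label_regions(tx_a)
  lab_b <- .label_regions(tx_b)
  diff_a <- setdiff_intervals(tx_a$exons, tx_b$exons)  # bases only in a
  diff_b <- setdiff_intervals(tx_b$exons, tx_a$exons)
  hit <- function(diff, lab) interval_width(intersect_intervals(diff, lab)) > 0
  differs_5utr <- (nrow(diff_a) > 0 && hit(diff_a, lab_a$five)) ||
                  (nrow(diff_b) > 0 && hit(diff_b, lab_b$five))
  differs_3utr <- (nrow(diff_a) > 0 && hit(diff_a, lab_a$three)) ||
                  (nrow(diff_b) > 0 && hit(diff_b, lab_b$three))
  cds_diff <- (nrow(diff_a) > 0 && hit(diff_a, lab_a$cds)) ||
              (nrow(diff_b) > 0 && hit(diff_b, lab_b$cds))
  # internal splice structure differs iff the bubble analysis finds a
  # non-terminal event; replacing a terminal exon (distinct TSS or 3' end)
  # is a promoter/3'UTR difference, not a splicing one
  ev <- call_splice_events(tx_a, tx_b)
  internal_diff <- any(ev$type %in% c("exon_skipping", "intron_retention",
                                      "alt_donor", "alt_acceptor",
                                      "complex"))
  no_cds <- lab_a$no_cds || lab_b$no_cds
  differs_exons <- internal_diff || (cds_diff && !no_cds)
  coding_change <- cds_diff && !no_cds
  if (no_cds) differs_exons <- differs_exons || cds_diff
  primary <- if (differs_exons) "alt_splicing"
             else if (differs_5utr) "alt_promoter"
             else if (differs_3utr) "alt_3utr"
             else NA_character_
  structure(list(differs_5utr = differs_5utr,
                 differs_exons = differs_exons,
                 differs_3utr = differs_3utr,
                 coding_change = coding_change,
                 no_cds = no_cds,
                 primary_category = primary),
            class = "StructuralDiff")
}

#' @export
print.StructuralDiff <- function(x, ...) {
  cat(sprintf(
    "StructuralDiff: 5'UTR=%s exons=%s 3'UTR=%s coding=%s -> %s%s\n",
    x$differs_5utr, x$differs_exons, x$differs_3utr, x$coding_change,
    ifelse(is.na(x$primary_category), "identical", x$primary_category),
    if (x$no_cds) " [no_cds]" else ""))
  invisible(x)
}

.event_row <- function(type, chrom, strand, start, end, inclusion = NA) {
  data.frame(type = type, chrom = chrom, strand = strand,
             start = start, end = end,
             inclusion_isoform = inclusion, stringsAsFactors = FALSE)
}

# transcription-direction first/last exon, as genomic intervals
.first_exon <- function(tx) {
  if (tx$strand == "+") tx$exons[1L, ] else tx$exons[nrow(tx$exons), ]
}
.last_exon <- function(tx) {
  if (tx$strand == "+") tx$exons[nrow(tx$exons), ] else tx$exons[1L, ]
}
.disjoint <- function(a, b) a[2L] <= b[1L] || b[2L] <= a[1L]

#' Call splice events between two isoforms
#'
#' Bubble algorithm: (1) compute each transcript's intron set (gaps between
#' consecutive exons); (2) within the overlap of the two transcript spans,
#' delimit maximal "bubbles" — regions bounded by splice positions shared
#' by both transcripts (matching in kind: exon start with exon start, exon
#' end with exon end) or by the span-overlap boundaries — inside which the
#' intron structures differ; (3) classify each bubble:
#' \itemize{
#'   \item an intron of one transcript whose boundaries both fall strictly
#'     inside an exon of the other -> \code{intron_retention}
#'     (\code{inclusion_isoform} = the exon-containing transcript);
#'   \item an exon of one transcript absent from the other while a single
#'     intron of the other spans the whole bubble, outer splice sites
#'     shared -> \code{exon_skipping} (\code{inclusion_isoform} = the
#'     exon-carrying transcript);
#'   \item two introns sharing their acceptor but not their donor ->
#'     \code{alt_donor}; sharing the donor but not the acceptor ->
#'     \code{alt_acceptor} (strand-aware);
#'   \item anything else -> \code{complex} (e.g. mutually exclusive
#'     exons), reported but excluded from the four-way fractions.
#' }
#' Differences at the transcript termini involving a distinct
#' (non-overlapping) first or last exon in transcription direction are
#' emitted as \code{alt_first_exon} / \code{alt_last_exon}.
#'
#' @param tx_a,tx_b \code{TranscriptModel}s of the same gene.
#' @return Data frame of events: \code{type}, \code{chrom}, \code{strand},
#'   \code{start}, \code{end} (the variable region, 0-based half-open) and
#'   \code{inclusion_isoform} (transcript carrying the extra exonic
#'   sequence, for skipping/retention; otherwise \code{NA}). Zero rows for
#'   structurally identical transcripts.
#' @export
call_splice_events <- function(tx_a, tx_b) {
  .check_pair(tx_a, tx_b)
  chrom <- tx_a$chrom; strand <- tx_a$strand
  empty <- .event_row(character(), character(), character(),
                      numeric(), numeric(), character())[0, ]
  if (.intervals_equal(tx_a$exons, tx_b$exons)) return(empty)
  span_a <- transcript_span(tx_a); span_b <- transcript_span(tx_b)
  ov <- c(max(span_a[1L], span_b[1L]), min(span_a[2L], span_b[2L]))
  events <- list()
  if (ov[1L] >= ov[2L]) {
    # no overlap at all: a single complex difference spanning both
    return(.event_row("complex", chrom, strand,
                      min(span_a[1L], span_b[1L]),
                      max(span_a[2L], span_b[2L])))
  }
  # terminal events (transcription direction)
  fa <- .first_exon(tx_a); fb <- .first_exon(tx_b)
  la <- .last_exon(tx_a); lb <- .last_exon(tx_b)
  term_iv <- matrix(numeric(), ncol = 2L)
  if (.disjoint(fa, fb)) {
    iv <- c(min(fa[1L], fb[1L]), max(fa[2L], fb[2L]))
    events[[length(events) + 1L]] <-
      .event_row("alt_first_exon", chrom, strand, iv[1L], iv[2L])
    term_iv <- rbind(term_iv, iv)
  }
  if (.disjoint(la, lb)) {
    iv <- c(min(la[1L], lb[1L]), max(la[2L], lb[2L]))
    events[[length(events) + 1L]] <-
      .event_row("alt_last_exon", chrom, strand, iv[1L], iv[2L])
    term_iv <- rbind(term_iv, iv)
  }
  # shared splice positions, kind-matched, within the span overlap
  n_a <- nrow(tx_a$exons); n_b <- nrow(tx_b$exons)
  starts_a <- tx_a$exons[-1L, 1L]; ends_a <- tx_a$exons[-n_a, 2L]
  starts_b <- tx_b$exons[-1L, 1L]; ends_b <- tx_b$exons[-n_b, 2L]
  shared <- c(intersect(starts_a, starts_b), intersect(ends_a, ends_b))
  shared <- shared[shared > ov[1L] & shared < ov[2L]]
  bounds <- sort(unique(c(ov[1L], shared, ov[2L])))
  introns_a <- transcript_introns(tx_a)
  introns_b <- transcript_introns(tx_b)
  within <- function(iv, b1, b2)
    iv[iv[, 1L] >= b1 & iv[, 2L] <= b2, , drop = FALSE]
  crossing <- function(iv, b1, b2)
    iv[iv[, 1L] < b2 & iv[, 2L] > b1 &
       !(iv[, 1L] >= b1 & iv[, 2L] <= b2), , drop = FALSE]
  exons_within <- function(ex, b1, b2)
    ex[ex[, 1L] > b1 & ex[, 2L] < b2, , drop = FALSE]
  overlaps_term <- function(b1, b2)
    nrow(term_iv) > 0 && any(term_iv[, 1L] < b2 & term_iv[, 2L] > b1)
  for (i in seq_len(length(bounds) - 1L)) {
    b1 <- bounds[i]; b2 <- bounds[i + 1L]
    ia <- within(introns_a, b1, b2); ib <- within(introns_b, b1, b2)
    cr <- nrow(crossing(introns_a, b1, b2)) +
          nrow(crossing(introns_b, b1, b2))
    if (cr > 0) {
      # an intron runs through the bubble boundary: this bubble is part of
      # a terminal difference; if that terminal event was already emitted,
      # nothing more to report here
      if (!overlaps_term(b1, b2))
        events[[length(events) + 1L]] <-
          .event_row("complex", chrom, strand, b1, b2)
      next
    }
    if (.intervals_equal(ia, ib)) next
    if (overlaps_term(b1, b2)) next
    ev <- .classify_bubble(ia, ib, tx_a, tx_b, b1, b2, strand,
                           exons_within, chrom)
    events <- c(events, ev)
  }
  if (!length(events)) return(empty)
  out <- do.call(rbind, events)
  rownames(out) <- NULL
  out
}

# classify one bubble given the fully-contained introns of each side
.classify_bubble <- function(ia, ib, tx_a, tx_b, b1, b2, strand,
                             exons_within, chrom) {
  res <- list()
  retention <- function(intr, host, guest_id) {
    # every guest intron must sit strictly inside one host exon
    rows <- list()
    for (k in seq_len(nrow(intr))) {
      s <- intr[k, 1L]; e <- intr[k, 2L]
      inside <- any(host$exons[, 1L] < s & host$exons[, 2L] > e)
      if (!inside) return(NULL)
      rows[[k]] <- .event_row("intron_retention", chrom, strand, s, e,
                              host$transcript_id)
    }
    rows
  }
  if (nrow(ia) == 0L && nrow(ib) > 0L) {
    r <- retention(ib, tx_a, tx_b$transcript_id)
    return(if (is.null(r))
      list(.event_row("complex", chrom, strand, b1, b2)) else r)
  }
  if (nrow(ib) == 0L && nrow(ia) > 0L) {
    r <- retention(ia, tx_b, tx_a$transcript_id)
    return(if (is.null(r))
      list(.event_row("complex", chrom, strand, b1, b2)) else r)
  }
  skipping <- function(intr_one, intr_many, carrier) {
    # one side bridges the whole bubble with a single intron; the carrier
    # has exon(s) inside with flanking introns reaching the boundaries
    if (nrow(intr_one) != 1L) return(NULL)
    if (intr_one[1L, 1L] != b1 || intr_one[1L, 2L] != b2) return(NULL)
    if (nrow(intr_many) < 2L) return(NULL)
    if (min(intr_many[, 1L]) != b1 || max(intr_many[, 2L]) != b2)
      return(NULL)
    ex <- exons_within(carrier$exons, b1, b2)
    if (nrow(ex) != 1L) return(NULL)
    list(.event_row("exon_skipping", chrom, strand, ex[1L, 1L], ex[1L, 2L],
                    carrier$transcript_id))
  }
  r <- skipping(ib, ia, tx_a)
  if (!is.null(r)) return(r)
  r <- skipping(ia, ib, tx_b)
  if (!is.null(r)) return(r)
  if (nrow(ia) == 1L && nrow(ib) == 1L) {
    s1 <- ia[1L, 1L]; e1 <- ia[1L, 2L]
    s2 <- ib[1L, 1L]; e2 <- ib[1L, 2L]
    if (e1 == e2 && s1 != s2) {
      # shared genomic end boundary; the differing start is the donor on
      # the plus strand and the acceptor on the minus strand
      type <- if (strand == "+") "alt_donor" else "alt_acceptor"
      return(list(.event_row(type, chrom, strand, min(s1, s2),
                             max(s1, s2))))
    }
    if (s1 == s2 && e1 != e2) {
      type <- if (strand == "+") "alt_acceptor" else "alt_donor"
      return(list(.event_row(type, chrom, strand, min(e1, e2),
                             max(e1, e2))))
    }
  }
  list(.event_row("complex", chrom, strand, b1, b2))
}

#' Structural annotation and summary of differential isoform pairs
#'
#' For each differentially expressed isoform pair (q below \code{fdr}),
#' computes the structural difference category and the splice events, then
#' aggregates: the fraction of pairs in each mutually exclusive primary
#' category (alternative splicing / alternative promoter / alternative
#' 3'UTR), the fraction of each splice-event type among the four-way
#' taxonomy (skipping, retention, alternative donor, alternative
#' acceptor; terminal and complex events are counted separately), and, for
#' every skipping/retention event, which subtype favours the inclusion
#' isoform, read from the sign of the pair's interaction coefficient.
#'
#' @param pairs \code{IsoformPairResult} data frame from
#'   \code{\link{pairwise_interaction_tests}}.
#' @param models Gene models covering the tested transcripts.
#' @param fdr q-value threshold selecting differential pairs.
#' @return List with \code{n_pairs}; \code{category_counts} /
#'   \code{category_fractions} over primary categories;
#'   \code{event_counts} / \code{event_fractions} over the four splice
#'   event types; \code{n_terminal_events}, \code{n_complex_events};
#'   and \code{inclusion_table}, a 2x2 count matrix (event type x subtype
#'   favouring the inclusion isoform).
#' @export
summarize_pairs <- function(pairs, models, fdr = 0.05) {
  de <- pairs[!is.na(pairs$q) & pairs$q < fdr, , drop = FALSE]
  categories <- c("alt_splicing", "alt_promoter", "alt_3utr")
  ev_types <- c("exon_skipping", "intron_retention", "alt_donor",
                "alt_acceptor")
  cat_counts <- stats::setNames(numeric(3L), categories)
  ev_counts <- stats::setNames(numeric(4L), ev_types)
  n_term <- 0L; n_complex <- 0L
  incl <- matrix(0L, 2L, 2L,
                 dimnames = list(c("exon_skipping", "intron_retention"),
                                 c("ERpos", "TN")))
  for (i in seq_len(nrow(de))) {
    tx_a <- models[[de$iso_a[i]]]; tx_b <- models[[de$iso_b[i]]]
    if (is.null(tx_a) || is.null(tx_b))
      stop("pair references transcripts absent from the models: ",
           de$iso_a[i], " / ", de$iso_b[i])
    sd_ <- compare_pair(tx_a, tx_b)
    if (!is.na(sd_$primary_category))
      cat_counts[sd_$primary_category] <- cat_counts[sd_$primary_category] + 1
    ev <- call_splice_events(tx_a, tx_b)
    for (j in seq_len(nrow(ev))) {
      ty <- ev$type[j]
      if (ty %in% ev_types) {
        ev_counts[ty] <- ev_counts[ty] + 1
        if (ty %in% rownames(incl)) {
          # beta > 0: iso_b relatively favoured in TN
          fav_b <- de$beta[i] > 0
          incl_is_b <- ev$inclusion_isoform[j] == de$iso_b[i]
          subtype <- if (incl_is_b == fav_b) "TN" else "ERpos"
          incl[ty, subtype] <- incl[ty, subtype] + 1L
        }
      } else if (ty %in% c("alt_first_exon", "alt_last_exon")) {
        n_term <- n_term + 1L
      } else n_complex <- n_complex + 1L
    }
  }
  list(n_pairs = nrow(de),
       category_counts = cat_counts,
       category_fractions = if (sum(cat_counts) > 0)
         cat_counts / sum(cat_counts) else cat_counts,
       event_counts = ev_counts,
       event_fractions = if (sum(ev_counts) > 0)
         ev_counts / sum(ev_counts) else ev_counts,
       n_terminal_events = n_term,
       n_complex_events = n_complex,
       inclusion_table = incl)
}

#' Write splice events as BED4
#' @param events Event data frame from \code{\link{call_splice_events}}.
#' @param path Output path. Names are \code{type:inclusion_isoform} (or
#'   just the type when no inclusion isoform applies).
#' @return \code{path}, invisibly.
#' @export
write_events_bed <- function(events, path) {
  nm <- ifelse(is.na(events$inclusion_isoform), events$type,
               paste0(events$type, ":", events$inclusion_isoform))
  write_bed(interval_track(events$chrom, events$start, events$end, nm), path)
}
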