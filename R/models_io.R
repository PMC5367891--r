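#' Construct a transcript model
#'
#' A \code{TranscriptModel} holds the exon/CDS structure of one transcript
#' isoform on a genome. All coordinates are 0-based half-open; conversion
#' from the 1-based closed GTF convention happens only in \code{\link{read_gtf}}
#' and \code{\link{write_gtf}}.
#'
#' @param transcript_id,gene_id Character scalars.
#' @param chrom Chromosome name.
#' @param strand \code{"+"} or \code{"-"}.
#' @param exons Two-column numeric matrix of (start, end) intervals,
#'   0-based half-open. Overlapping or book-ended exons are merged and the
#'   result sorted by start.
#' @param cds Optional length-2 numeric vector: genomic span from the first
#'   to one past the last coding base, or \code{NULL} for non-coding
#'   transcripts. Both endpoints must fall inside exons.
#' @param attributes Named character vector of free-form attributes.
#' @return An object of class \code{TranscriptModel}.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons,
                             cds = NULL, attributes = character()) {
  stopifnot(is.character(transcript_id), length(transcript_id) == 1L,
            is.character(gene_id), length(gene_id) == 1L,
            strand %in% c("+", "-"))
  exons <- matrix(as.numeric(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(exons) == 0L)
    stop("transcript '", transcript_id, "' has zero exons")
  if (any(exons[, 2L] <= exons[, 1L]))
    stop("transcript '", transcript_id, "' has an empty or inverted exon")
  exons <- merge_intervals(exons)
  if (!is.null(cds)) {
    cds <- as.numeric(cds)
    stopifnot(length(cds) == 2L, cds[1L] < cds[2L])
    span <- c(exons[1L, 1L], exons[nrow(exons), 2L])
    if (cds[1L] < span[1L] || cds[2L] > span[2L])
      stop("transcript '", transcript_id, "': CDS outside transcript span")
    # both CDS endpoints must land inside exonic sequence
    if (!point_in_intervals(cds[1L], exons) ||
        !point_in_intervals(cds[2L] - 1, exons))
      stop("transcript '", transcript_id, "': CDS endpoint falls in an intron")
  }
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 chrom = chrom, strand = strand, exons = exons, cds = cds,
                 attributes = attributes),
            class = "TranscriptModel")
}

#' @export
print.TranscriptModel <- function(x, ...) {
  cat(sprintf("TranscriptModel %s (gene %s) %s:%d-%d (%s), %d exon(s)%s\n",
              x$transcript_id, x$gene_id, x$chrom,
              x$exons[1L, 1L], x$exons[nrow(x$exons), 2L], x$strand,
              nrow(x$exons),
              if (is.null(x$cds)) ", non-coding"
              else sprintf(", CDS %d-%d", x$cds[1L], x$cds[2L])))
  invisible(x)
}

#' Transcript genomic span
#' @param tx A \code{TranscriptModel}.
#' @return Length-2 vector (start, end), 0-based half-open.
#' @export
transcript_span <- function(tx) {
  c(tx$exons[1L, 1L], tx$exons[nrow(tx$exons), 2L])
}

#' Introns of a transcript
#' @param tx A \code{TranscriptModel}.
#' @return Two-column matrix of intron intervals (gaps between consecutive
#'   exons), 0-based half-open; zero rows for single-exon transcripts.
#' @export
transcript_introns <- function(tx) {
  n <- nrow(tx$exons)
  if (n < 2L) return(matrix(numeric(), ncol = 2L,
                            dimnames = list(NULL, c("start", "end"))))
  cbind(start = tx$exons[-n, 2L], end = tx$exons[-1L, 1L])
}

# --- small interval helpers (0-based half-open, used across modules) -------

merge_intervals <- function(iv) {
  if (nrow(iv) <= 1L) return(iv)
  iv <- iv[order(iv[, 1L], iv[, 2L]), , drop = FALSE]
  out <- iv[1L, , drop = FALSE]
  for (i in 2L:nrow(iv)) {
    j <- nrow(out)
    if (iv[i, 1L] <= out[j, 2L]) {
      out[j, 2L] <- max(out[j, 2L], iv[i, 2L])
    } else out <- rbind(out, iv[i, , drop = FALSE])
  }
  out
}

point_in_intervals <- function(p, iv) {
  any(p >= iv[, 1L] & p < iv[, 2L])
}

# intersect two sorted disjoint interval sets
intersect_intervals <- function(a, b) {
  out <- matrix(numeric(), ncol = 2L)
  for (i in seq_len(nrow(a))) {
    s <- pmax(a[i, 1L], b[, 1L]); e <- pmin(a[i, 2L], b[, 2L])
    keep <- s < e
    if (any(keep)) out <- rbind(out, cbind(s[keep], e[keep]))
  }
  colnames(out) <- c("start", "end")
  if (nrow(out)) out[order(out[, 1L]), , drop = FALSE] else out
}

# bases of a not in b
setdiff_intervals <- function(a, b) {
  out <- matrix(numeric(), ncol = 2L)
  for (i in seq_len(nrow(a))) {
    segs <- matrix(a[i, ], ncol = 2L)
    for (j in seq_len(nrow(b))) {
      nxt <- matrix(numeric(), ncol = 2L)
      for (k in seq_len(nrow(segs))) {
        s <- segs[k, 1L]; e <- segs[k, 2L]
        bs <- b[j, 1L]; be <- b[j, 2L]
        if (be <= s || bs >= e) { nxt <- rbind(nxt, c(s, e)); next }
        if (bs > s) nxt <- rbind(nxt, c(s, bs))
        if (be < e) nxt <- rbind(nxt, c(be, e))
      }
      segs <- nxt
      if (!nrow(segs)) break
    }
    out <- rbind(out, segs)
  }
  colnames(out) <- c("start", "end")
  if (nrow(out)) out[order(out[, 1L]), , drop = FALSE] else out
}

interval_width <- function(iv) if (nrow(iv)) sum(iv[, 2L] - iv[, 1L]) else 0

# --- expression matrix ------------------------------------------------------

.scale_tags <- c("raw", "quantile_normalized", "log2p1", "centered", "residual")

#' Construct an expression matrix
#'
#' Transcripts (or genes) by samples abundance matrix with a scale tag that
#' tracks which normalization steps have been applied. Raw matrices must be
#' non-negative (FPKM-like); residual- and centered-scale matrices may hold
#' any reals.
#'
#' @param values Numeric matrix with row names (feature ids) and column names
#'   (sample ids).
#' @param scale_tag One of \code{"raw"}, \code{"quantile_normalized"},
#'   \code{"log2p1"}, \code{"centered"}, \code{"residual"}.
#' @return An object of class \code{ExpressionMatrix}.
#' @export
expression_matrix <- function(values, scale_tag = "raw") {
  stopifnot(is.matrix(values), is.numeric(values))
  scale_tag <- match.arg(scale_tag, .scale_tags)
  if ((nrow(values) > 0L && is.null(rownames(values))) ||
      (ncol(values) > 0L && is.null(colnames(values))))
    stop("expression matrix needs row (feature) and column (sample) names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  if (anyNA(values)) stop("expression matrix contains missing values")
  if (scale_tag == "raw" && any(values < 0))
    stop("raw-scale expression matrix contains negative values")
  structure(list(values = values, scale_tag = scale_tag),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d features x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$scale_tag))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
as.matrix.ExpressionMatrix <- function(x, ...) x$values

# internal: accept either a plain matrix or an ExpressionMatrix
em_values <- function(x) if (inherits(x, "ExpressionMatrix")) x$values else x

# --- GTF --------------------------------------------------------------------

.parse_gtf_attr <- function(attr, key) {
  m <- regmatches(attr, regexec(paste0(key, '[ =]+"?([^";]+)"?'), attr))[[1L]]
  if (length(m) < 2L) NA_character_ else m[2L]
}

#' Read gene models from a GTF file
#'
#' Consumes \code{exon} and optional \code{CDS} features carrying
#' \code{gene_id} and \code{transcript_id} attributes. GTF coordinates are
#' 1-based closed and are converted to the internal 0-based half-open
#' convention. Exons of each transcript are merged and sorted; the CDS span
#' is \code{min(CDS starts)} to \code{max(CDS ends)} when CDS features exist.
#'
#' @param path Path to a GTF file.
#' @return Named list of \code{\link{transcript_model}} objects, one per
#'   transcript id, in order of first appearance.
#' @export
read_gtf <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  exn <- list(); cds <- list(); meta <- list()
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 9L)
      stop("malformed GTF line ", i, ": expected 9 tab-separated fields")
    if (!(f[3L] %in% c("exon", "CDS"))) next
    s <- suppressWarnings(as.numeric(f[4L])); e <- suppressWarnings(as.numeric(f[5L]))
    if (is.na(s) || is.na(e) || s > e)
      stop("malformed GTF line ", i, ": bad coordinates")
    tid <- .parse_gtf_attr(f[9L], "transcript_id")
    gid <- .parse_gtf_attr(f[9L], "gene_id")
    if (is.na(tid) || is.na(gid))
      stop("malformed GTF line ", i, ": missing gene_id/transcript_id")
    iv <- c(s - 1, e)  # 1-based closed -> 0-based half-open
    if (f[3L] == "exon") exn[[tid]] <- rbind(exn[[tid]], iv)
    else cds[[tid]] <- rbind(cds[[tid]], iv)
    if (is.null(meta[[tid]]))
      meta[[tid]] <- list(gene_id = gid, chrom = f[1L], strand = f[7L])
  }
  only_cds <- setdiff(names(cds), names(exn))
  if (length(only_cds))
    stop("transcript(s) with zero exons: ", paste(only_cds, collapse = ", "))
  out <- lapply(names(exn), function(tid) {
    m <- meta[[tid]]
    cspan <- if (is.null(cds[[tid]])) NULL
             else c(min(cds[[tid]][, 1L]), max(cds[[tid]][, 2L]))
    transcript_model(tid, m$gene_id, m$chrom, m$strand, exn[[tid]], cspan)
  })
  names(out) <- names(exn)
  out
}

#' Write gene models to a GTF file
#'
#' Emits one \code{exon} line per exon and one \code{CDS} line per
#' CDS-overlapping exon segment, converting back to 1-based closed
#' coordinates. \code{read_gtf(write_gtf(models))} is structurally the
#' identity.
#'
#' @param models List of \code{TranscriptModel} objects.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_gtf <- function(models, path) {
  lines <- character()
  for (tx in models) {
    attr_s <- sprintf('gene_id "%s"; transcript_id "%s";',
                      tx$gene_id, tx$transcript_id)
    for (i in seq_len(nrow(tx$exons)))
      lines <- c(lines, paste(tx$chrom, "isousage", "exon",
                              format(tx$exons[i, 1L] + 1, scientific = FALSE),
                              format(tx$exons[i, 2L], scientific = FALSE),
                              ".", tx$strand, ".", attr_s, sep = "\t"))
    if (!is.null(tx$cds)) {
      segs <- intersect_intervals(tx$exons, matrix(tx$cds, ncol = 2L))
      for (i in seq_len(nrow(segs)))
        lines <- c(lines, paste(tx$chrom, "isousage", "CDS",
                                format(segs[i, 1L] + 1, scientific = FALSE),
                                format(segs[i, 2L], scientific = FALSE),
                                ".", tx$strand, "0", attr_s, sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# --- expression tables ------------------------------------------------------

#' Read a transcript-by-sample expression table
#'
#' Tab-separated, header row of sample ids, first column of transcript ids.
#' Values must be non-negative; duplicate transcript ids and ragged rows are
#' rejected.
#'
#' @param path Path to a TSV file.
#' @return An \code{\link{expression_matrix}} with \code{scale_tag = "raw"}.
#' @export
read_expression_table <- function(path) {
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) != 1L)
    stop("ragged expression table: row(s) ",
         paste(which(nf != nf[1L]), collapse = ", "),
         " have a different number of fields")
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate transcript ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric values in expression table")
  neg <- which(vals < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop(sprintf("negative value at row '%s', column '%s'",
                 ids[neg[1L, 1L]], colnames(vals)[neg[1L, 2L]]))
  rownames(vals) <- ids
  expression_matrix(vals, "raw")
}

#' Write an expression matrix as TSV
#' @param em An \code{ExpressionMatrix} (or plain matrix).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_expression_table <- function(em, path) {
  v <- em_values(em)
  df <- data.frame(transcript_id = rownames(v), v, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# --- sample sheets, BED, gene lists ----------------------------------------

.subtype_levels <- c("ERpos", "TN")

#' Read a sample sheet
#'
#' TSV with columns \code{sample_id}, \code{subtype} (one of \code{ERpos},
#' \code{TN}), \code{cohort}, \code{platform}.
#'
#' @param path Path to the sheet.
#' @return Data frame of sample annotations; \code{subtype} is a factor with
#'   reference level \code{ERpos}.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "subtype", "cohort", "platform")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("sample sheet missing column(s): ",
                         paste(miss, collapse = ", "))
  bad <- setdiff(unique(df$subtype), .subtype_levels)
  if (length(bad))
    stop("unknown subtype label(s) ", paste(bad, collapse = ", "),
         "; accepted labels: ", paste(.subtype_levels, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in sheet")
  df$subtype <- factor(df$subtype, levels = .subtype_levels)
  df
}

#' Write a sample sheet
#' @param annotations Data frame as returned by \code{\link{read_sample_sheet}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_sample_sheet <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a BED4 interval track
#'
#' BED is 0-based half-open, matching the internal convention, so no
#' coordinate shift is applied.
#'
#' @param path Path to a BED file (at least 3 columns; 4th column is the
#'   interval name, defaulted when absent).
#' @return Data frame of class \code{IntervalTrack} with columns
#'   \code{chrom}, \code{start}, \code{end}, \code{name}.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "name")[
                            seq_len(max(utils::count.fields(path, sep = "\t")))],
                          fill = FALSE)
  if (ncol(df) < 3L) stop("BED file needs at least chrom, start, end")
  if (ncol(df) == 3L) df$name <- paste0("interval_", seq_len(nrow(df)))
  interval_track(df$chrom, df$start, df$end, df$name)
}

#' Construct an interval track
#' @param chrom,start,end,name Vectors of equal length; 0-based half-open.
#' @return Data frame of class \code{IntervalTrack}.
#' @export
interval_track <- function(chrom, start, end,
                           name = paste0("interval_", seq_along(chrom))) {
  if (any(start >= end)) stop("interval with start >= end")
  structure(data.frame(chrom = as.character(chrom), start = as.numeric(start),
                       end = as.numeric(end), name = as.character(name),
                       stringsAsFactors = FALSE),
            class = c("IntervalTrack", "data.frame"))
}

#' Write an interval track as BED4
#' @param track An \code{IntervalTrack}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_bed <- function(track, path) {
  utils::write.table(
    data.frame(track$chrom,
               format(track$start, scientific = FALSE, trim = TRUE),
               format(track$end, scientific = FALSE, trim = TRUE),
               track$name),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a plain-text identifier list
#' @param path One identifier per line; blank lines ignored.
#' @return Character vector of unique identifiers.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  unique(x[nzchar(x)])
}

#' Group transcript models by gene
#' @param models List of \code{TranscriptModel}s.
#' @return Named list: gene_id -> list of its transcripts. Grouping is by
#'   exact \code{gene_id} string match.
#' @export
group_by_gene <- function(models) {
  split(models, vapply(models, function(tx) tx$gene_id, character(1L)))
}
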