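#' Storey q-values
#'
#' False discovery rate control with estimation of the null proportion
#' pi0. pi0 is estimated as \code{mean(p > lambda) / (1 - lambda)} over the
#' grid lambda = 0.05, 0.10, ..., 0.95, smoothed by a cubic polynomial in
#' lambda, evaluated at lambda = 0.95 and clamped to (0, 1]. The q-value of
#' the i-th order statistic is \code{min over j >= i of pi0 * m * p_(j) / j};
#' tied p-values share a q-value. With pi0 = 1 this reduces exactly to
#' Benjamini-Hochberg adjusted p-values.
#'
#' @param pvalues Numeric vector of p-values in [0, 1].
#' @param pi0 Optional fixed null proportion; when supplied the lambda
#'   smoothing is skipped (pi0 = 1 gives BH).
#' @return List of class \code{QValueResult} with \code{pvalues},
#'   \code{qvalues} (in input order), \code{pi0} and \code{lambda_grid}.
#' @export
storey_qvalues <- function(pvalues, pi0 = NULL) {
  p <- as.numeric(pvalues)
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1] with no missing values")
  m <- length(p)
  lambda_grid <- seq(0.05, 0.95, by = 0.05)
  if (is.null(pi0)) {
    if (m < 20L) {
      warning("fewer than 20 p-values; falling back to pi0 = 1")
      pi0 <- 1
    } else {
      pi0_l <- vapply(lambda_grid,
                      function(l) mean(p > l) / (1 - l), numeric(1L))
      fit <- stats::lm(pi0_l ~ stats::poly(lambda_grid, 3L))
      pi0 <- stats::predict(fit,
                            newdata = data.frame(lambda_grid = 0.95))[[1L]]
      pi0 <- min(1, max(pi0, 1e-4))
    }
  } else {
    if (pi0 <= 0 || pi0 > 1) stop("pi0 must lie in (0, 1]")
  }
  o <- order(p)
  q_sorted <- rev(cummin(rev(pi0 * m * p[o] / seq_len(m))))
  q <- numeric(m)
  q[o] <- q_sorted
  structure(list(pvalues = p, qvalues = q, pi0 = pi0,
                 lambda_grid = lambda_grid),
            class = "QValueResult")
}

#' @export
print.QValueResult <- function(x, ...) {
  cat(sprintf("QValueResult: m = %d, pi0 = %.3f, %d q < 0.05\n",
              length(x$pvalues), x$pi0, sum(x$qvalues < 0.05)))
  invisible(x)
}

# split a sample sheet into the TN indicator, validating both groups present
.tn_indicator <- function(annotations, sample_ids) {
  idx <- match(sample_ids, annotations$sample_id)
  if (anyNA(idx)) stop("samples absent from annotations: ",
                       paste(sample_ids[is.na(idx)], collapse = ", "))
  st <- annotations$subtype[idx]
  if (length(unique(st)) < 2L)
    stop("both subtypes must be present; found only ",
         paste(unique(as.character(st)), collapse = ""))
  as.numeric(st == "TN")
}

#' Gene-level differential expression by Wilcoxon rank-sum test
#'
#' Two-sided test per row comparing the two subtypes. Exact rank-sum
#' p-values are used when the combined sample size is at most 25 and there
#' are no ties; otherwise the normal approximation with tie correction and
#' continuity correction. Rows constant across all samples get p = 1.
#'
#' @param em Normalized \code{ExpressionMatrix}.
#' @param annotations Sample sheet data frame (see
#'   \code{\link{read_sample_sheet}}).
#' @param qvalues Compute Storey q-values over all rows (default TRUE).
#' @return Data frame with \code{gene_id}, \code{method},
#'   \code{statistic} (W for the ER+ group), \code{p}, \code{q}.
#' @export
wilcoxon_de <- function(em, annotations, qvalues = TRUE) {
  v <- em_values(em)
  tn <- .tn_indicator(annotations, colnames(v))
  res <- t(apply(v, 1L, function(y) {
    if (max(y) == min(y)) return(c(NA_real_, 1))
    x <- y[tn == 0]; z <- y[tn == 1]
    exact <- length(y) <= 25L && !anyDuplicated(y)
    wt <- suppressWarnings(
      stats::wilcox.test(x, z, exact = exact, correct = TRUE))
    c(unname(wt$statistic), wt$p.value)
  }))
  out <- data.frame(gene_id = rownames(v), method = "wilcoxon",
                    statistic = res[, 1L], p = res[, 2L],
                    stringsAsFactors = FALSE, row.names = NULL)
  if (qvalues) out$q <- storey_qvalues(out$p)$qvalues
  out
}

#' Gene-level differential expression by linear model
#'
#' Per-row ordinary least squares of the form
#' \code{y ~ intercept + subtype}, with the subtype effect assessed by
#' t-test. The subtype coefficient is \code{mean(TN) - mean(ERpos)} on the
#' log2 scale (reference level ERpos); for balanced or unbalanced two-group
#' data the p-value equals the classical equal-variance two-sample t-test.
#'
#' @inheritParams wilcoxon_de
#' @return Data frame with \code{gene_id}, \code{method}, \code{statistic}
#'   (the t statistic), \code{beta_subtype}, \code{p}, \code{q}.
#' @export
lm_subtype_de <- function(em, annotations, qvalues = TRUE) {
  v <- em_values(em)
  tn <- .tn_indicator(annotations, colnames(v))
  n1 <- sum(tn == 0); n2 <- sum(tn == 1); n <- n1 + n2
  m1 <- rowMeans(v[, tn == 0, drop = FALSE])
  m2 <- rowMeans(v[, tn == 1, drop = FALSE])
  ss1 <- rowSums((v[, tn == 0, drop = FALSE] - m1)^2)
  ss2 <- rowSums((v[, tn == 1, drop = FALSE] - m2)^2)
  s2 <- (ss1 + ss2) / (n - 2L)
  se <- sqrt(s2 * (1 / n1 + 1 / n2))
  beta <- m2 - m1
  tstat <- ifelse(se > 0, beta / se, ifelse(beta == 0, 0, Inf * sign(beta)))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2L)
  out <- data.frame(gene_id = rownames(v), method = "lm_subtype",
                    statistic = tstat, beta_subtype = beta, p = p,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (qvalues) out$q <- storey_qvalues(out$p)$qvalues
  out
}

# core fixed-effects interaction fit on one gene's isoform block.
# ymat: L x S matrix (isoforms x samples), tn: length-S 0/1 indicator.
# Observations are stacked (sample, isoform) rows; within-sample
# correlation between isoforms is deliberately ignored (the stated model).
.interaction_fit <- function(ymat, tn, tol = 1e-10) {
  L <- nrow(ymat); S <- ncol(ymat); n <- L * S
  y <- as.vector(ymat)                      # column-major: isoforms fastest
  iso <- rep(seq_len(L), S)
  tns <- rep(tn, each = L)
  iso_d <- outer(iso, 2:L, "==") * 1        # treatment dummies, iso 1 ref
  X_red <- cbind(1, tns, iso_d)
  X_full <- cbind(X_red, iso_d * tns)
  fit_full <- stats::.lm.fit(X_full, y)
  fit_red <- stats::.lm.fit(X_red, y)
  rss1 <- sum(fit_full$residuals^2)
  rss0 <- sum(fit_red$residuals^2)
  df1 <- L - 1L
  df2 <- n - 2L * L
  ss_int <- rss0 - rss1
  scale <- max(sum(y^2), 1)
  if (rss1 / scale < tol) {
    if (ss_int / scale < tol) { f <- 0; p <- 1 } else { f <- Inf; p <- 0 }
  } else {
    f <- (ss_int / df1) / (rss1 / df2)
    p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  }
  beta <- fit_full$coefficients
  ids <- rownames(ymat)
  if (is.null(ids)) ids <- paste0("iso", seq_len(L))
  names(beta) <- c("intercept", "subtypeTN",
                   if (L > 1L) paste0("iso_", ids[-1L]),
                   if (L > 1L) paste0("subtypeTN:iso_", ids[-1L]))
  list(F = f, p = p, df1 = df1, df2 = df2, betas = beta)
}

#' Subtype-by-isoform interaction test for one gene
#'
#' Fits the fixed-effects model
#' \code{y ~ intercept + subtype + isoform + subtype:isoform} to the
#' stacked (sample, isoform) observations of one gene and compares it to
#' the no-interaction model by the extra-sum-of-squares F-test with
#' (L - 1, n - 2L) degrees of freedom, where L is the number of isoforms
#' and n = samples x L. A significant interaction indicates
#' subtype-specific isoform usage.
#'
#' @param gene_em \code{ExpressionMatrix} (log scale) restricted to one
#'   gene's isoforms; at least two rows.
#' @param annotations Sample sheet data frame.
#' @return List of class \code{GeneTestResult} with \code{gene_id},
#'   \code{method}, \code{statistic} (F), \code{p}, \code{df}, and
#'   \code{betas} (all full-model coefficients, including the interaction
#'   terms whose signs give which isoform is favoured in which subtype).
#' @export
isoform_interaction_test <- function(gene_em, annotations) {
  v <- em_values(gene_em)
  if (nrow(v) < 2L)
    stop("interaction test needs >= 2 isoforms; got ", nrow(v),
         " (single-isoform genes must be filtered out)")
  tn <- .tn_indicator(annotations, colnames(v))
  fit <- .interaction_fit(v, tn)
  structure(list(gene_id = NA_character_, method = "lm_interaction",
                 statistic = fit$F, p = fit$p,
                 df = c(fit$df1, fit$df2), betas = fit$betas),
            class = "GeneTestResult")
}

#' @export
print.GeneTestResult <- function(x, ...) {
  cat(sprintf("GeneTestResult [%s]: F = %.4g on (%d, %d) df, p = %.4g\n",
              x$method, x$statistic, x$df[1L], x$df[2L], x$p))
  invisible(x)
}

#' Interaction tests for every gene with multiple isoforms
#'
#' Convenience driver: applies \code{\link{isoform_interaction_test}} to
#' each multi-isoform gene and computes Storey q-values over all genes.
#'
#' @param em Log-scale \code{ExpressionMatrix} over all transcripts.
#' @param models Gene models (used only for gene grouping).
#' @param annotations Sample sheet data frame.
#' @param min_detected A transcript enters testing if detected (value > 0)
#'   in at least this many samples.
#' @return Data frame with \code{gene_id}, \code{n_isoforms}, \code{F},
#'   \code{p}, \code{q}.
#' @export
genewise_interaction_tests <- function(em, models, annotations,
                                       min_detected = 2L) {
  v <- em_values(em)
  tn <- .tn_indicator(annotations, colnames(v))
  detected <- rownames(v)[rowSums(v > 0) >= min_detected]
  by_gene <- group_by_gene(models)
  rows <- lapply(names(by_gene), function(gid) {
    ids <- intersect(names(by_gene[[gid]]), detected)
    if (length(ids) < 2L) return(NULL)
    fit <- .interaction_fit(v[ids, , drop = FALSE], tn)
    data.frame(gene_id = gid, n_isoforms = length(ids),
               F = fit$F, p = fit$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no gene with >= 2 detected isoforms")
  out$q <- storey_qvalues(out$p)$qvalues
  rownames(out) <- NULL
  out
}

#' Pairwise subtype-by-isoform interaction tests
#'
#' Tests every unordered isoform pair within each multi-isoform gene with
#' the interaction model restricted to the two isoforms (L = 2). With two
#' isoforms there is a single interaction coefficient whose sign gives the
#' direction: positive means the lexicographically larger isoform
#' (\code{iso_b}) is relatively favoured in TN. q-values are computed over
#' all pairs jointly.
#'
#' @inheritParams genewise_interaction_tests
#' @return Data frame of class \code{IsoformPairResult} rows:
#'   \code{gene_id}, \code{iso_a}, \code{iso_b} (canonical lexicographic
#'   order), \code{F}, \code{p}, \code{q}, \code{beta} (interaction
#'   coefficient), \code{direction} (sign of beta).
#' @export
pairwise_interaction_tests <- function(em, models, annotations,
                                       min_detected = 2L) {
  v <- em_values(em)
  tn <- .tn_indicator(annotations, colnames(v))
  detected <- rownames(v)[rowSums(v > 0) >= min_detected]
  by_gene <- group_by_gene(models)
  rows <- list()
  for (gid in names(by_gene)) {
    ids <- sort(intersect(names(by_gene[[gid]]), detected))
    if (length(ids) < 2L) next
    prs <- utils::combn(ids, 2L)
    for (j in seq_len(ncol(prs))) {
      a <- prs[1L, j]; b <- prs[2L, j]
      fit <- .interaction_fit(v[c(a, b), , drop = FALSE], tn)
      beta <- unname(fit$betas[length(fit$betas)])
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = gid, iso_a = a, iso_b = b,
        F = fit$F, p = fit$p, beta = beta,
        direction = sign(beta), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no multi-isoform gene passed the detection filter")
  out <- do.call(rbind, rows)
  out$q <- storey_qvalues(out$p)$qvalues
  out <- out[, c("gene_id", "iso_a", "iso_b", "F", "p", "q",
                 "beta", "direction")]
  class(out) <- c("IsoformPairResult", "data.frame")
  out
}
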