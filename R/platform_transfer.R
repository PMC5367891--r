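#' Normalize NanoString-style counts with a negative-binomial model
#'
#' Fits a log-link negative-binomial regression to the endogenous probe
#' counts with terms for assay, well, log median negative-control count,
#' log median housekeeping count, and transcript (probe) identity,
#' following the nCounter normalization strategy of modelling technical
#' terms jointly with probe identity. The dispersion theta is estimated by
#' maximum likelihood alternating with the IRLS coefficient updates
#' (\code{MASS::glm.nb}). The per-sample covariates are
#' \code{log(median negative-control count + 1)} and
#' \code{log(median housekeeping count + 1)}, entering with free slopes.
#' The returned expression values are Pearson residuals
#' \code{(observed - fitted) / sqrt(fitted + fitted^2 / theta)}.
#'
#' @param counts Integer matrix, probes x samples (row/column names
#'   required).
#' @param probe_info Data frame with \code{probe_id} and \code{probe_class}
#'   (\code{endogenous}, \code{negative}, \code{housekeeping}).
#' @param sample_info Data frame with \code{sample_id}, \code{assay},
#'   \code{well}.
#' @param residual_type \code{"pearson"} (default) or \code{"deviance"}.
#' @return List with \code{model} (class \code{NanostringModel}:
#'   coefficients, theta, link) and \code{residuals} (an
#'   \code{\link{expression_matrix}} of endogenous-probe residuals,
#'   \code{scale_tag = "residual"}).
#' @export
fit_nanostring_model <- function(counts, probe_info, sample_info,
                                 residual_type = c("pearson", "deviance")) {
  residual_type <- match.arg(residual_type)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  idx <- match(colnames(counts), sample_info$sample_id)
  if (anyNA(idx)) stop("sample_info does not cover all count columns")
  sample_info <- sample_info[idx, , drop = FALSE]
  cls <- probe_info$probe_class[match(rownames(counts),
                                      probe_info$probe_id)]
  if (anyNA(cls)) stop("probe_info does not cover all count rows")
  if (!any(cls == "negative") || !any(cls == "housekeeping"))
    stop("negative-control and housekeeping probes must both be present")
  neg_med <- apply(counts[cls == "negative", , drop = FALSE], 2L,
                   stats::median)
  hk_med <- apply(counts[cls == "housekeeping", , drop = FALSE], 2L,
                  stats::median)
  endo <- counts[cls == "endogenous", , drop = FALSE]
  n_p <- nrow(endo); n_s <- ncol(endo)
  dat <- data.frame(
    y = as.vector(endo),
    probe = factor(rep(rownames(endo), n_s)),
    assay = factor(rep(sample_info$assay, each = n_p)),
    well = factor(rep(sample_info$well, each = n_p)),
    lognc = rep(log(neg_med + 1), each = n_p),
    loghk = rep(log(hk_med + 1), each = n_p))
  # drop terms that are constant across samples (degenerate designs)
  terms <- c("assay", "well", "lognc", "loghk", "probe")
  keep <- vapply(terms, function(t) length(unique(dat[[t]])) > 1L,
                 logical(1L))
  fml <- stats::reformulate(terms[keep], response = "y")
  fit <- suppressWarnings(
    MASS::glm.nb(fml, data = dat,
                 control = stats::glm.control(epsilon = 1e-8, maxit = 100L)))
  if (!fit$converged)
    stop("negative-binomial fit failed to converge after ", fit$iter,
         " iterations (deviance ", format(fit$deviance), ")")
  mu <- stats::fitted(fit)
  theta <- fit$theta
  resid <- if (residual_type == "pearson") {
    (dat$y - mu) / sqrt(mu + mu^2 / theta)
  } else stats::residuals(fit, type = "deviance")
  rmat <- matrix(resid, n_p, n_s,
                 dimnames = list(rownames(endo), colnames(endo)))
  model <- structure(list(coefficients = stats::coef(fit), theta = theta,
                          link = "log", deviance = fit$deviance,
                          formula = fml),
                     class = "NanostringModel")
  list(model = model, residuals = expression_matrix(rmat, "residual"))
}

#' @export
print.NanostringModel <- function(x, ...) {
  cat(sprintf(
    "NanostringModel: %d coefficients, theta = %.3f, link = %s\n",
    length(x$coefficients), x$theta, x$link))
  invisible(x)
}

#' Isoform-ratio concordance between RNA-seq and NanoString
#'
#' For each isoform pair and each shared sample, the log-ratio of isoform A
#' to isoform B is computed on each platform: RNA-seq as
#' \code{log2((FPKM_A + eps) / (FPKM_B + eps))} and NanoString as the
#' difference of normalized residuals. A pair/sample is concordant iff the
#' two values share sign; the per-sample concordance fraction counts
#' concordant pairs among pairs with both values nonzero.
#'
#' @param rnaseq_em Raw-scale RNA-seq \code{ExpressionMatrix}.
#' @param nano_em Residual-scale NanoString \code{ExpressionMatrix} from
#'   \code{\link{fit_nanostring_model}}.
#' @param pairs Data frame with columns \code{iso_a}, \code{iso_b}.
#' @param eps Pseudocount for the RNA-seq ratio (default 1).
#' @return List with \code{per_sample} (named concordance fractions) and
#'   \code{quadrants} (pairs x samples character matrix of sign quadrants,
#'   \code{"++"}, \code{"--"}, \code{"+-"}, \code{"-+"}, or \code{"0"}).
#' @export
platform_concordance <- function(rnaseq_em, nano_em, pairs, eps = 1) {
  rv <- em_values(rnaseq_em); nv <- em_values(nano_em)
  samples <- intersect(colnames(rv), colnames(nv))
  if (!length(samples)) stop("no shared samples between platforms")
  need <- unique(c(pairs$iso_a, pairs$iso_b))
  miss <- setdiff(need, intersect(rownames(rv), rownames(nv)))
  if (length(miss))
    stop("pairs reference transcripts absent from a platform: ",
         paste(utils::head(miss, 3L), collapse = ", "))
  r1 <- log2((rv[pairs$iso_a, samples, drop = FALSE] + eps) /
             (rv[pairs$iso_b, samples, drop = FALSE] + eps))
  r2 <- nv[pairs$iso_a, samples, drop = FALSE] -
        nv[pairs$iso_b, samples, drop = FALSE]
  nonzero <- r1 != 0 & r2 != 0
  conc <- sign(r1) == sign(r2) & nonzero
  per_sample <- colSums(conc) / pmax(colSums(nonzero), 1L)
  quad <- matrix("0", nrow(r1), ncol(r1),
                 dimnames = list(paste(pairs$iso_a, pairs$iso_b, sep = "/"),
                                 samples))
  quad[nonzero] <- paste0(ifelse(r1[nonzero] > 0, "+", "-"),
                          ifelse(r2[nonzero] > 0, "+", "-"))
  list(per_sample = per_sample, quadrants = quad)
}

#' Train an L2-penalized logistic subtype classifier
#'
#' Maximizes the binomial log-likelihood minus
#' \code{lambda/2 * sum(weights^2)} (the intercept is unpenalized) by
#' Newton/IRLS with a fixed start at zero — fully deterministic. Features
#' are standardized internally (the stored centering/scaling is reapplied
#' at prediction time), so \code{l2_strength} acts on a common scale.
#'
#' @param em \code{ExpressionMatrix} of features (rows) by samples
#'   (columns).
#' @param labels Subtype per sample (factor or character, levels
#'   \code{ERpos}/\code{TN}); TN is the positive class.
#' @param l2_strength Ridge penalty lambda (default 1).
#' @param max_iter,tol IRLS iteration cap and convergence tolerance on the
#'   coefficient step.
#' @return List of class \code{ClassifierModel}: \code{features},
#'   \code{weights}, \code{intercept}, \code{l2_strength}, plus the
#'   standardization constants.
#' @export
train_logistic <- function(em, labels, l2_strength = 1,
                           max_iter = 100L, tol = 1e-10) {
  v <- em_values(em)
  y <- as.numeric(factor(as.character(labels),
                         levels = .subtype_levels)) - 1
  if (anyNA(y)) stop("labels must be ERpos or TN")
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (length(y) != ncol(v)) stop("one label per sample column required")
  X <- t(v)
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  p <- ncol(Xs)
  Z <- cbind(1, Xs)
  pen <- diag(c(0, rep(l2_strength, p)), p + 1L)
  beta <- numeric(p + 1L)
  for (it in seq_len(max_iter)) {
    eta <- drop(Z %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(crossprod(Z, y - mu)) - pen %*% beta
    hess <- crossprod(Z * w, Z) + pen
    step <- solve(hess, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  structure(list(features = rownames(v), weights = beta[-1L],
                 intercept = beta[1L], l2_strength = l2_strength,
                 center = ctr, scale = scl, iterations = it),
            class = "ClassifierModel")
}

#' @export
print.ClassifierModel <- function(x, ...) {
  cat(sprintf(
    "ClassifierModel: %d features, lambda = %g, intercept = %.3f\n",
    length(x$features), x$l2_strength, x$intercept))
  invisible(x)
}

# linear predictor of a ClassifierModel on a feature matrix
classifier_scores <- function(model, em) {
  v <- em_values(em)
  miss <- setdiff(model$features, rownames(v))
  if (length(miss))
    stop("feature(s) absent from the matrix: ",
         paste(utils::head(miss, 3L), collapse = ", "))
  X <- t(v[model$features, , drop = FALSE])
  if (length(model$features)) {
    Xs <- sweep(sweep(X, 2L, model$center), 2L, model$scale, "/")
    drop(Xs %*% model$weights) + model$intercept
  } else rep(model$intercept, ncol(v))
}

#' Classify samples and compute the ROC curve
#'
#' Scores are the linear predictor of the trained classifier; the ROC is
#' traced by sweeping a threshold through all distinct scores (TN is the
#' positive class), the AUC computed by the trapezoid rule and
#' cross-checked against the rank (Mann-Whitney) form.
#'
#' @param model A \code{ClassifierModel}.
#' @param em Feature \code{ExpressionMatrix} for the samples to classify.
#' @param labels True subtypes of those samples.
#' @return List of class \code{RocResult}: \code{thresholds}, \code{tpr},
#'   \code{fpr} (non-decreasing along the sweep), \code{auc} (trapezoid),
#'   \code{auc_rank}, and \code{scores}.
#' @export
predict_and_roc <- function(model, em, labels) {
  scores <- classifier_scores(model, em)
  roc_from_scores(scores, labels)
}

#' ROC curve and AUC from raw scores
#' @param scores Numeric classification scores (higher = more TN-like).
#' @param labels True subtypes (\code{ERpos}/\code{TN}).
#' @return A \code{RocResult}; see \code{\link{predict_and_roc}}.
#' @export
roc_from_scores <- function(scores, labels) {
  y <- as.character(labels) == "TN"
  if (!any(y) || all(y)) stop("both classes must be present in labels")
  o <- order(scores, decreasing = TRUE)
  ys <- y[o]
  thr <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(y); n_neg <- sum(!y)
  # cumulative counts at each distinct threshold
  grp <- match(scores[o], thr)
  tp <- cumsum(ys); fp <- cumsum(!ys)
  last <- cumsum(tabulate(grp, length(thr)))
  tpr <- c(0, tp[last] / n_pos)
  fpr <- c(0, fp[last] / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  r <- rank(scores)
  auc_rank <- (sum(r[y]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr,
                 auc = auc, auc_rank = auc_rank, scores = scores),
            class = "RocResult")
}

#' @export
print.RocResult <- function(x, ...) {
  cat(sprintf("RocResult: AUC = %.4f (rank form %.4f), %d thresholds\n",
              x$auc, x$auc_rank, length(x$thresholds)))
  invisible(x)
}
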