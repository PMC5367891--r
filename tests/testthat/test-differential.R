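test_that("wilcoxon gene DE matches exact enumeration on separated groups", {
  # groups {1,2,3} vs {4,5,6}: W = 0 and the exact two-sided p is
  # 2 * (1 / choose(6,3)) = 0.1
  em <- tiny_expression(rbind(c(1, 2, 3, 4, 5, 6)))
  ann <- two_group_sheet(3, 3)
  colnames(em$values) <- ann$sample_id
  res <- wilcoxon_de(em, ann, qvalues = FALSE)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 0.1)
})

test_that("wilcoxon handles identical and constant rows", {
  ann <- two_group_sheet(3, 3)
  em <- tiny_expression(rbind(c(1, 2, 3, 1, 2, 3), rep(5, 6)))
  colnames(em$values) <- ann$sample_id
  res <- wilcoxon_de(em, ann, qvalues = FALSE)
  expect_equal(res$p[1], 1)
  expect_equal(res$p[2], 1)
})

test_that("wilcoxon agrees with wilcox.test across regimes", {
  set.seed(5)
  ann <- two_group_sheet(11, 14)
  v <- matrix(rnorm(25 * 20), 20, 25)
  v[1:5, ] <- round(v[1:5, ])   # force ties -> normal approximation
  rownames(v) <- paste0("t", 1:20); colnames(v) <- ann$sample_id
  em <- expression_matrix(abs(v), "raw")
  res <- wilcoxon_de(em, ann, qvalues = FALSE)
  for (i in seq_len(nrow(v))) {
    y <- em$values[i, ]
    exact <- !anyDuplicated(y)
    ref <- suppressWarnings(
      wilcox.test(y[1:11], y[12:25], exact = exact, correct = TRUE))
    expect_equal(res$p[i], ref$p.value)
  }
})

test_that("wilcoxon type-I error is controlled on null data", {
  set.seed(6)
  ann <- two_group_sheet(11, 14)
  v <- matrix(abs(rnorm(25 * 2000)), 2000, 25,
              dimnames = list(paste0("t", 1:2000), ann$sample_id))
  res <- wilcoxon_de(expression_matrix(v, "raw"), ann, qvalues = FALSE)
  expect_gt(mean(res$p < 0.05), 0.03)
  expect_lt(mean(res$p < 0.05), 0.065)
})

test_that("linear-model DE equals the classical pooled t-test", {
  set.seed(7)
  ann <- two_group_sheet(5, 7)
  v <- matrix(abs(rnorm(12 * 15)), 15, 12,
              dimnames = list(paste0("t", 1:15), ann$sample_id))
  em <- expression_matrix(v, "raw")
  res <- lm_subtype_de(em, ann, qvalues = FALSE)
  for (i in 1:15) {
    ref <- t.test(v[i, 6:12], v[i, 1:5], var.equal = TRUE)
    expect_equal(res$p[i], ref$p.value)
    expect_equal(res$beta_subtype[i],
                 mean(v[i, 6:12]) - mean(v[i, 1:5]))
  }
  expect_true(all(sign(res$beta_subtype) ==
                    sign(rowMeans(v[, 6:12]) - rowMeans(v[, 1:5]))))
})

test_that("linear-model DE recovers planted gene effects", {
  cfg <- sim_config(seed = 22, n_genes = 300, gene_de_fraction = 0.3,
                    gene_de_effect = 2, noise_sd = 0.5, switch_fraction = 0,
                    isoform_count_distribution = c("1" = 1))
  coh <- simulate_cohort(simulate_gene_models(cfg), cfg)
  res <- lm_subtype_de(log2p1(coh$expression), coh$annotations,
                       qvalues = FALSE)
  tr <- coh$truth$genes
  de <- tr$gene_de
  planted <- tr$de_sign[de] * cfg$gene_de_effect
  est <- res$beta_subtype[match(tr$gene_id[de],
                                sub("\\.t1$", "", res$gene_id))]
  # estimates track the planted effect: right sign, small average error
  expect_true(all(sign(est) == sign(planted)))
  expect_lt(mean(abs(est - planted)), 0.35)
})

test_that("interaction beta equals the saturated-model cell-mean contrast", {
  # 2 isoforms x 2 subtypes, cell means [[1,1],[1,3]], no noise
  ann <- two_group_sheet(3, 3)
  v <- rbind(rep(1, 6), c(1, 1, 1, 3, 3, 3))
  rownames(v) <- c("a", "b"); colnames(v) <- ann$sample_id
  res <- isoform_interaction_test(expression_matrix(v, "raw"), ann)
  expect_equal(unname(res$betas["subtypeTN:iso_b"]), 2)
  expect_equal(res$p, 0)           # perfect interaction, zero residual
})

test_that("additive noise-free data give a degenerate zero F", {
  ann <- two_group_sheet(3, 3)
  v <- rbind(c(1, 1, 1, 2, 2, 2), c(3, 3, 3, 4, 4, 4))
  rownames(v) <- c("a", "b"); colnames(v) <- ann$sample_id
  res <- isoform_interaction_test(expression_matrix(v, "raw"), ann)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
})

test_that("interaction F and p match the formula-interface ANOVA oracle", {
  # dual route: the hand-built design matrices must reproduce what the
  # model formula y ~ subtype * isoform gives via lm() + anova(), for
  # both 2- and 3-isoform genes, balanced or not
  set.seed(8)
  for (rep_ in 1:10) {
    L <- sample(2:3, 1)
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    ann <- two_group_sheet(n1, n2)
    v <- matrix(abs(rnorm(L * (n1 + n2))) + 1, L,
                dimnames = list(letters[1:L], ann$sample_id))
    res <- isoform_interaction_test(expression_matrix(v, "raw"), ann)
    df <- data.frame(y = as.vector(v),
                     iso = factor(rep(rownames(v), ncol(v))),
                     tn = factor(rep(as.character(ann$subtype), each = L)))
    a <- anova(lm(y ~ tn + iso, df), lm(y ~ tn * iso, df))
    expect_equal(res$statistic, a$F[2], tolerance = 1e-10)
    expect_equal(res$p, a$`Pr(>F)`[2], tolerance = 1e-10)
    expect_equal(res$df, c(L - 1, (n1 + n2) * L - 2 * L))
  }
})

test_that("the interaction contrast tracks the paired-difference t-test", {
  # the stacked fixed-effects model shares its numerator contrast with
  # the two-sample t-test on per-sample isoform differences; the error
  # terms differ (within-sample covariance is deliberately ignored), so
  # the statistics agree in sign and scale but not identically
  set.seed(12)
  ann <- two_group_sheet(6, 6)
  v <- matrix(abs(rnorm(24)) + 1, 2,
              dimnames = list(c("a", "b"), ann$sample_id))
  res <- isoform_interaction_test(expression_matrix(v, "raw"), ann)
  d <- v[2, ] - v[1, ]
  tt <- t.test(d[ann$subtype == "TN"], d[ann$subtype == "ERpos"],
               var.equal = TRUE)
  expect_equal(unname(res$betas["subtypeTN:iso_b"]),
               unname(diff(rev(tt$estimate))), tolerance = 1e-10)
})

test_that("single-isoform genes are rejected by the interaction test", {
  ann <- two_group_sheet(2, 2)
  v <- matrix(1:4, 1, dimnames = list("a", ann$sample_id))
  expect_error(isoform_interaction_test(expression_matrix(v, "raw"), ann),
               ">= 2 isoforms")
})

test_that("pairwise tests emit all pairs and match the two-isoform test", {
  cfg <- sim_config(seed = 23, n_genes = 12,
                    isoform_count_distribution = c("2" = 0.5, "3" = 0.5),
                    switch_fraction = 0.5)
  mod <- simulate_gene_models(cfg)
  coh <- simulate_cohort(mod, cfg)
  norm <- log2p1(coh$expression)
  pairs <- pairwise_interaction_tests(norm, mod, coh$annotations)
  n_iso <- table(vapply(mod, function(tx) tx$gene_id, ""))
  expect_equal(nrow(pairs), sum(choose(n_iso, 2)))
  expect_true(all(pairs$iso_a < pairs$iso_b))
  # for a 2-isoform gene the pair test is the whole-gene test
  gid2 <- names(n_iso)[n_iso == 2][1]
  ids <- names(mod)[vapply(mod, function(tx) tx$gene_id, "") == gid2]
  whole <- isoform_interaction_test(
    expression_matrix(norm$values[ids, ], "raw"), coh$annotations)
  expect_equal(pairs$F[pairs$gene_id == gid2], whole$statistic)
  # direction is the sign of the planted switch for significant pairs
  sw <- coh$truth$isoforms[coh$truth$isoforms$switch_direction != 0, ]
  for (i in seq_len(nrow(sw))) {
    hit <- pairs[(pairs$iso_a == sw$transcript_id[i] |
                  pairs$iso_b == sw$transcript_id[i]) & pairs$q < 0.05, ]
    if (nrow(hit) == 0) next
    expected_dir <- ifelse(hit$iso_b == sw$transcript_id[i], 1, -1) *
      sw$switch_direction[i]
    expect_equal(hit$direction, expected_dir)
  }
})

test_that("storey q-values reduce to BH at pi0 = 1 and stay monotone", {
  set.seed(9)
  p <- c(runif(80), runif(20)^3)
  qv <- storey_qvalues(p, pi0 = 1)
  expect_equal(qv$qvalues, p.adjust(p, "BH"))
  est <- storey_qvalues(p)
  o <- order(p)
  expect_true(all(diff(est$qvalues[o]) >= -1e-12))
  expect_true(all(est$qvalues <= 1 + 1e-12))
  expect_true(est$pi0 > 0 && est$pi0 <= 1)
})

test_that("equal p-values share their q-value", {
  qv <- storey_qvalues(rep(0.01, 100), pi0 = 1)
  expect_true(all(qv$qvalues == 0.01))
})

test_that("pi0 is estimated near 1 for uniform p-values", {
  set.seed(10)
  qv <- storey_qvalues(runif(10000))
  expect_gte(qv$pi0, 0.9)
  expect_lte(qv$pi0, 1)
})

test_that("q-value input validation and small-m fallback work", {
  expect_error(storey_qvalues(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_warning(qv <- storey_qvalues(runif(10)), "pi0 = 1")
  expect_equal(qv$pi0, 1)
})
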