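test_that("identical transcripts have no structural difference", {
  tx <- make_tx("t1", rbind(c(0, 100), c(200, 300)), "+", c(50, 250))
  tx2 <- tx; tx2$transcript_id <- "t2"
  sd_ <- compare_pair(tx, tx2)
  expect_false(sd_$differs_5utr || sd_$differs_exons || sd_$differs_3utr ||
                 sd_$coding_change)
  expect_true(is.na(sd_$primary_category))
  expect_equal(nrow(call_splice_events(tx, tx2)), 0L)
})

test_that("a 3'UTR-only extension is classified as alt_3utr, non-coding", {
  # plus strand; CDS ends at 250; t2's last exon extends beyond both CDS
  a <- make_tx("t1", rbind(c(0, 100), c(200, 300)), "+", c(50, 250))
  b <- make_tx("t2", rbind(c(0, 100), c(200, 400)), "+", c(50, 250))
  sd_ <- compare_pair(a, b)
  expect_true(sd_$differs_3utr)
  expect_false(sd_$differs_5utr || sd_$differs_exons || sd_$coding_change)
  expect_equal(sd_$primary_category, "alt_3utr")
  # the same construction on the minus strand is a 5'UTR difference
  sd_m <- compare_pair(make_tx("t1", rbind(c(0, 100), c(200, 300)), "-",
                               c(50, 250)),
                       make_tx("t2", rbind(c(0, 100), c(200, 400)), "-",
                               c(50, 250)))
  expect_true(sd_m$differs_5utr)
  expect_equal(sd_m$primary_category, "alt_promoter")
})

test_that("a skipped CDS exon is an exon difference with coding change", {
  a <- make_tx("t1", rbind(c(0, 100), c(200, 300), c(400, 500)), "+",
               c(50, 450))
  b <- make_tx("t2", rbind(c(0, 100), c(400, 500)), "+", c(50, 450))
  sd_ <- compare_pair(a, b)
  expect_true(sd_$differs_exons)
  expect_true(sd_$coding_change)
  expect_equal(sd_$primary_category, "alt_splicing")
  # brute-force base labeling agrees: all differing bases are CDS in t1
  lab <- oracle_base_labels(a)
  diff_bases <- setdiff(exon_bases(a), exon_bases(b))
  expect_true(all(lab[as.character(diff_bases)] == "cds"))
})

test_that("structural flags match the brute-force base labeling oracle", {
  cfg <- sim_config(seed = 31, n_genes = 40,
                    isoform_count_distribution = c("2" = 1))
  mod <- simulate_gene_models(cfg)
  for (g in group_by_gene(mod)) {
    a <- g[[1]]; b <- g[[2]]
    if (is.null(a$cds) || is.null(b$cds)) next
    sd_ <- compare_pair(a, b)
    lab_a <- oracle_base_labels(a); lab_b <- oracle_base_labels(b)
    d_a <- as.character(setdiff(exon_bases(a), exon_bases(b)))
    d_b <- as.character(setdiff(exon_bases(b), exon_bases(a)))
    expect_equal(sd_$differs_5utr,
                 any(lab_a[d_a] == "5utr") || any(lab_b[d_b] == "5utr"))
    expect_equal(sd_$differs_3utr,
                 any(lab_a[d_a] == "3utr") || any(lab_b[d_b] == "3utr"))
    expect_equal(sd_$coding_change,
                 any(lab_a[d_a] == "cds") || any(lab_b[d_b] == "cds"))
  }
})

test_that("canonical exon skipping is called with the right inclusion", {
  a <- make_tx("t1", rbind(c(0, 100), c(200, 300), c(400, 500)), "+")
  b <- make_tx("t2", rbind(c(0, 100), c(400, 500)), "+")
  ev <- call_splice_events(a, b)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$type, "exon_skipping")
  expect_equal(c(ev$start, ev$end), c(200, 300))
  expect_equal(ev$inclusion_isoform, "t1")
  # symmetric call swaps nothing but keeps the inclusion label
  ev2 <- call_splice_events(b, a)
  expect_equal(ev2, ev)
})

test_that("canonical intron retention is called with the right inclusion", {
  a <- make_tx("t1", rbind(c(0, 100), c(200, 300)), "+")
  b <- make_tx("t2", rbind(c(0, 300)), "+")
  ev <- call_splice_events(a, b)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$type, "intron_retention")
  expect_equal(c(ev$start, ev$end), c(100, 200))
  expect_equal(ev$inclusion_isoform, "t2")
})

test_that("alternative donors and acceptors are strand-aware", {
  # shared intron end (acceptor on +), differing start (donor on +)
  a <- make_tx("t1", rbind(c(0, 100), c(200, 300)), "+")
  b <- make_tx("t2", rbind(c(0, 120), c(200, 300)), "+")
  ev <- call_splice_events(a, b)
  expect_equal(ev$type, "alt_donor")
  expect_equal(c(ev$start, ev$end), c(100, 120))
  # identical structures on the minus strand: donor and acceptor swap
  ev_m <- call_splice_events(flip_strand(a), flip_strand(b))
  expect_equal(ev_m$type, "alt_acceptor")
  # shared start, differing end
  c1 <- make_tx("t1", rbind(c(0, 100), c(200, 300)), "+")
  c2 <- make_tx("t2", rbind(c(0, 100), c(240, 300)), "+")
  expect_equal(call_splice_events(c1, c2)$type, "alt_acceptor")
  expect_equal(call_splice_events(flip_strand(c1), flip_strand(c2))$type,
               "alt_donor")
})

test_that("mutually exclusive exons fall into the complex bucket", {
  a <- make_tx("t1", rbind(c(0, 100), c(200, 250), c(400, 500)), "+")
  b <- make_tx("t2", rbind(c(0, 100), c(300, 350), c(400, 500)), "+")
  ev <- call_splice_events(a, b)
  expect_equal(ev$type, "complex")
})

test_that("chrom/strand mismatches are rejected", {
  a <- make_tx("t1", rbind(c(0, 100)), "+")
  b <- make_tx("t2", rbind(c(0, 100)), "-")
  expect_error(compare_pair(a, b), "chrom/strand")
  expect_error(call_splice_events(a, b), "chrom/strand")
})

test_that("event calls covary correctly under strand flip on random pairs", {
  # 500 generated pairs across all variant types: flipping the strand at
  # fixed coordinates must swap donor<->acceptor and first<->last exon
  # events and preserve skipping/retention
  swap <- c(exon_skipping = "exon_skipping",
            intron_retention = "intron_retention",
            alt_donor = "alt_acceptor", alt_acceptor = "alt_donor",
            alt_first_exon = "alt_last_exon",
            alt_last_exon = "alt_first_exon", complex = "complex")
  n_checked <- 0L
  for (seed in 31:34) {
    cfg <- sim_config(seed = seed, n_genes = 125,
                      isoform_count_distribution = c("2" = 1))
    for (g in group_by_gene(simulate_gene_models(cfg))) {
      ev <- call_splice_events(g[[1]], g[[2]])
      ev_f <- call_splice_events(flip_strand(g[[1]]), flip_strand(g[[2]]))
      expect_equal(sort(unname(swap[ev$type])), sort(ev_f$type))
      expect_equal(ev[order(ev$start), c("start", "end")],
                   ev_f[order(ev_f$start), c("start", "end")],
                   ignore_attr = TRUE)
      n_checked <- n_checked + 1L
    }
  }
  expect_gte(n_checked, 500L)
})

test_that("compare_pair is symmetric and events match base differences", {
  cfg <- sim_config(seed = 35, n_genes = 60,
                    isoform_count_distribution = c("2" = 1))
  internal <- c("exon_skipping", "intron_retention", "alt_donor",
                "alt_acceptor")
  for (g in group_by_gene(simulate_gene_models(cfg))) {
    a <- g[[1]]; b <- g[[2]]
    expect_equal(unclass(compare_pair(a, b)), unclass(compare_pair(b, a)))
    ev <- call_splice_events(a, b)
    # for a single internal event the exonic base symmetric difference is
    # exactly the event interval
    if (nrow(ev) == 1L && ev$type %in% internal) {
      sym <- sort(c(setdiff(exon_bases(a), exon_bases(b)),
                    setdiff(exon_bases(b), exon_bases(a))))
      expect_equal(sym, seq(ev$start, ev$end - 1))
    }
  }
})

test_that("pairs without CDS are classified by splice structure only", {
  a <- make_tx("t1", rbind(c(0, 100), c(200, 300)), "+")
  b <- make_tx("t2", rbind(c(0, 300)), "+")
  sd_ <- compare_pair(a, b)
  expect_true(sd_$no_cds)
  expect_true(sd_$differs_exons)
  expect_false(sd_$coding_change)
  expect_equal(sd_$primary_category, "alt_splicing")
})

test_that("summarize_pairs partitions categories and counts inclusions", {
  cfg <- sim_config(seed = 36, n_genes = 80,
                    isoform_count_distribution = c("2" = 1),
                    switch_fraction = 1, switch_effect = 3, noise_sd = 0.3)
  mod <- simulate_gene_models(cfg)
  coh <- simulate_cohort(mod, cfg)
  pairs <- pairwise_interaction_tests(log2p1(coh$expression), mod,
                                      coh$annotations)
  sm <- summarize_pairs(pairs, mod, fdr = 0.05)
  expect_gt(sm$n_pairs, 50)
  expect_equal(sum(sm$category_fractions), 1, tolerance = 1e-12)
  expect_equal(sum(sm$event_fractions), 1, tolerance = 1e-12)
  # symmetric planting: inclusion counts are subtype-balanced within a
  # two-sided binomial 95% bound
  n_incl <- sum(sm$inclusion_table)
  expect_gt(n_incl, 10)
  ci <- qbinom(c(0.025, 0.975), n_incl, 0.5)
  expect_gte(sum(sm$inclusion_table[, "TN"]), ci[1])
  expect_lte(sum(sm$inclusion_table[, "TN"]), ci[2])
})

test_that("an all-skipping cohort yields pure skipping event fractions", {
  probs <- c(exon_skipping = 1, intron_retention = 0, alt_donor = 0,
             alt_acceptor = 0, alt_first_exon = 0, alt_last_exon = 0)
  cfg <- sim_config(seed = 37, n_genes = 30,
                    isoform_count_distribution = c("2" = 1),
                    variant_probs = probs, switch_fraction = 1,
                    switch_effect = 3, noise_sd = 0.3)
  mod <- simulate_gene_models(cfg)
  coh <- simulate_cohort(mod, cfg)
  pairs <- pairwise_interaction_tests(log2p1(coh$expression), mod,
                                      coh$annotations)
  sm <- summarize_pairs(pairs, mod, fdr = 0.05)
  expect_equal(unname(sm$event_fractions["exon_skipping"]), 1)
  expect_equal(sum(sm$event_counts) , sm$n_pairs)
})

test_that("events can be written as BED", {
  a <- make_tx("t1", rbind(c(0, 100), c(200, 300), c(400, 500)), "+")
  b <- make_tx("t2", rbind(c(0, 100), c(400, 500)), "+")
  f <- withr::local_tempfile(fileext = ".bed")
  write_events_bed(call_splice_events(a, b), f)
  expect_match(readLines(f), "exon_skipping:t1")
})
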