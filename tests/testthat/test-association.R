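test_that("one-way ANOVA: hand case, null, two-group t^2 identity", {
  an <- anova_oneway(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(an$statistic, 16)
  expect_equal(an$p, pf(16, 2, 3, lower.tail = FALSE))

  flat <- anova_oneway(list(c(1, 2, 3), c(2, 1, 3)))
  expect_lt(flat$statistic, 1e-10)

  degen <- anova_oneway(list(c(2, 2), c(2, 2)))
  expect_equal(degen$statistic, 0)
  expect_equal(degen$p, 1)

  set.seed(50)
  x <- rnorm(12); y <- rnorm(15, 0.5)
  an2 <- anova_oneway(list(x, y))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(an2$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(an2$p, tt$p.value, tolerance = 1e-10)
})

test_that("contingency test: Fisher enumeration oracle and chi-square branch", {
  ct <- contingency_test(matrix(c(2, 0, 0, 2), 2, 2))
  expect_identical(ct$test, "fisher")
  expect_equal(ct$p, 1 / 3)

  big <- contingency_test(matrix(c(10, 10, 10, 10), 2, 2))
  expect_identical(big$test, "chi2")
  expect_equal(big$statistic, 0)
  expect_equal(big$p, 1)

  # all 2x2 tables with margins <= 12 match the enumeration oracle
  for (a in 0:6) for (b in 0:6) for (cc in 0:6) for (d in 0:6) {
    tab <- matrix(c(a, cc, b, d), 2, 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    p <- contingency_test(tab, method = "fisher")$p
    expect_equal(p, oracle_fisher2x2(tab), tolerance = 1e-12)
    expect_equal(contingency_test(t(tab), method = "fisher")$p, p,
                 tolerance = 1e-12)
  }
  expect_error(contingency_test(matrix(c(0, 0, 1, 2), 2, 2)), "margin")
})

test_that("Pearson correlation: exact lines and the hand 3-point case", {
  x <- c(1, 4, 9)
  expect_equal(pearson_corr(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_corr(x, -x)$r, -1)
  hand <- pearson_corr(c(1, 2, 3), c(1, 3, 2))
  expect_equal(hand$r, 0.5)
  ref <- cor.test(c(1, 2, 3), c(1, 3, 2))
  expect_equal(hand$p, ref$p.value, tolerance = 1e-12)
  expect_error(pearson_corr(c(1, 1, 1), c(1, 2, 3)), "constant")
})

test_that("paired t-test: hand case, sign symmetry, zero-variance error", {
  pt <- paired_t(c(2, 2, 2, 4), c(1, 1, 1, 1))
  expect_equal(pt$statistic, 3)
  expect_equal(pt$df, 3)
  expect_equal(pt$p, 2 * stats::pt(-3, 3))
  sw <- paired_t(c(1, 1, 1, 1), c(2, 2, 2, 4))
  expect_equal(sw$statistic, -3)
  expect_equal(sw$p, pt$p)
  expect_error(paired_t(c(1, 2, 3), c(1, 2, 3)), "zero variance")
})

test_that("AUC: exhaustive pair-counting oracle and complement identity", {
  expect_equal(auc_rank(c(1, 2, 3, 4), c(TRUE, FALSE, TRUE, FALSE)), 0.25)
  expect_equal(auc_rank(c(0.9, 0.8, 0.7, 0.6), c(TRUE, TRUE, FALSE, FALSE)), 1)
  set.seed(51)
  for (i in 1:25) {
    n <- sample(4:30, 1)
    s <- sample(round(rnorm(n), 1))  # rounded to force ties
    pos <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(pos) || all(pos)) next
    a <- auc_rank(s, pos)
    expect_equal(a, oracle_auc(s, pos), tolerance = 1e-12)
    expect_equal(auc_rank(-s, pos), 1 - a, tolerance = 1e-12)
  }
})

test_that("outcome ROC labelling: mean-OS rule, exclusions, error reporting", {
  cl <- data.frame(
    sample_id = paste0("s", 1:6),
    os_days = c(100, 200, 900, 1000, 150, 800),
    event = c(1, 1, 1, 0, 0, 0))
  # mean OS over deceased = 400; positives: s1, s2; negatives: s3, s4, s6;
  # s5 censored before 400 -> excluded
  scores <- setNames(c(5, 4, 1, 2, 3, 0), cl$sample_id)
  roc <- roc_auc_outcome(scores, cl)
  expect_equal(roc$mean_os, 400)
  expect_equal(roc$n_pos, 2)
  expect_equal(roc$n_neg, 3)
  expect_equal(roc$n_excluded, 1)
  expect_equal(roc$auc, 1)  # both positives outscore every negative
  # negation gives the complement
  expect_equal(roc_auc_outcome(-scores, cl)$auc, 0)
  # all deaths at the mean itself and every censoring earlier: no positive
  # can exist, so labelling fails with the summary in the message
  cl_bad <- cl; cl_bad$os_days <- c(500, 500, 100, 90, 80, 70)
  cl_bad$event <- c(1, 1, 0, 0, 0, 0)
  expect_error(roc_auc_outcome(scores, cl_bad), "empty outcome class")
})

test_that("logistic combination: constant factor reduces to single predictor", {
  set.seed(52)
  n <- 200
  a <- rnorm(n)
  y <- rbinom(n, 1, plogis(1.2 * a))
  sc <- combine_predictors(y, a, rep(1, n))
  expect_equal(auc_rank(sc, y == 1), auc_rank(a, y == 1), tolerance = 1e-6)
  # independent predictors: AUC near 1/2
  yperm <- y[sample(n)]
  sc_null <- combine_predictors(yperm, a, rnorm(n))
  expect_lt(abs(auc_rank(sc_null, yperm == 1) - 0.5), 0.15)
  # in-sample: combining cannot do materially worse than the best single factor
  b <- rnorm(n)
  y2 <- rbinom(n, 1, plogis(a + b))
  sc2 <- combine_predictors(y2, a, b)
  best_single <- max(auc_rank(a, y2 == 1), auc_rank(b, y2 == 1))
  expect_gte(auc_rank(sc2, y2 == 1), best_single - 0.01)
  expect_warning(combine_predictors(c(0, 0, 1, 1), c(-2, -1, 1, 2), rnorm(4)),
                 "separation")
})

test_that("mutation frequency comparison finds the planted enrichment", {
  co <- default_cohort()
  sc <- ap_score(co$expression[, names(co$latent)], co$truth)
  labels <- dichotomize_by_median(setNames(sc$ap_score, sc$sample_id))
  res <- compare_mutation_freq(co$mutations, labels)
  expect_true(all(c("IDH1", "TP53", "ATRX", "PTEN", "EGFR") %in% res$gene))
  idh <- res[res$gene == "IDH1", ]
  expect_identical(idh$enriched_in, "low")
  expect_lt(idh$q, 0.05)
  egfr <- res[res$gene == "EGFR", ]
  expect_identical(egfr$enriched_in, "high")
  expect_lt(egfr$q, 0.05)
  # gene mutated everywhere is uninformative: p = 1
  allmut <- data.frame(sample_id = names(labels), gene = "UBIQ",
                       mutated = TRUE)
  res2 <- compare_mutation_freq(allmut, labels)
  expect_equal(res2$p, 1)
})

test_that("CNV comparison: planted direction, Welch p, label swap symmetry", {
  co <- default_cohort()
  sc <- ap_score(co$expression[, names(co$latent)], co$truth)
  labels <- dichotomize_by_median(setNames(sc$ap_score, sc$sample_id))
  res <- compare_cnv(co$cnv, labels)
  egfr <- res[res$gene == "EGFR", ]
  expect_gt(egfr$mean_high - egfr$mean_low, 0)
  cdkn <- res[res$gene == "CDKN2A", ]
  expect_lt(cdkn$mean_high - cdkn$mean_low, 0)
  expect_lt(max(egfr$q, cdkn$q), 0.05)
  swapped <- setNames(ifelse(labels == "high", "low", "high"), names(labels))
  res_sw <- compare_cnv(co$cnv, swapped)
  expect_equal(res_sw$mean_low, res$mean_high)
  expect_equal(res_sw$p, res$p, tolerance = 1e-12)
  # identical groups: p = 1
  flat <- expression_matrix(matrix(1, 1, length(labels),
                                   dimnames = list("g", names(labels))))
  expect_equal(compare_cnv(flat, labels)$p, 1)
})

test_that("score-gene correlation: planted genes, self-correlation, threshold", {
  co <- default_cohort()
  tum <- names(co$latent)
  sc <- ap_score(co$expression[, tum], co$truth)
  ap <- setNames(sc$ap_score, sc$sample_id)
  expr <- co$expression[, tum]
  # at a threshold inside the planted-gene correlation band the sets are
  # exactly the planted genes (single genes carry sigma = 0.7 of noise the
  # 18-gene average does not, so per-gene r sits near 0.4-0.7 here while
  # background genes stay below 0.25)
  res <- correlate_genes_with_score(expr, ap, r_threshold = 0.4)
  expect_setequal(res$positive, co$truth$pos$genes)
  expect_setequal(res$negative, co$truth$neg$genes)
  # the default stricter threshold returns subsets of the planted genes
  res06 <- correlate_genes_with_score(expr, ap)
  expect_true(all(res06$positive %in% co$truth$pos$genes))
  expect_true(all(res06$negative %in% co$truth$neg$genes))
  # the AP score injected as a pseudo-gene correlates perfectly
  expr2 <- expression_matrix(rbind(expr, PSEUDO = ap[colnames(expr)]))
  res2 <- correlate_genes_with_score(expr2, ap)
  expect_equal(unname(res2$r["PSEUDO"]), 1, tolerance = 1e-12)
  # strict threshold 1.0 empties both sets
  res3 <- correlate_genes_with_score(expr, ap, r_threshold = 1.0)
  expect_length(res3$positive, 0)
  expect_length(res3$negative, 0)
})

test_that("immune gene-set report has one row and three statistics per set", {
  co <- default_cohort()
  tum <- names(co$latent)
  sc <- ap_score(co$expression[, tum], co$truth)
  ap <- setNames(sc$ap_score, sc$sample_id)
  cl <- co$clinical
  sets <- list(co$truth$pos,
               gene_set("RANDOM", sprintf("BG%05d", 1:25)))
  rep <- immune_ssgsea_association(co$expression[, tum], sets, ap, cl)
  expect_equal(rep$set, c("POS_TRUTH", "RANDOM"))
  expect_equal(names(rep), c("set", "r", "r_p", "logrank_p"))
  # the POS component dominates the AP score by construction
  expect_gt(rep$r[1], 0.8)
  expect_lt(abs(rep$r[2]), 0.4)
  expect_warning(
    na_rep <- immune_ssgsea_association(
      co$expression[, tum], list(gene_set("MISSING", "NOPE")), ap, cl),
    "no overlap")
  expect_true(is.na(na_rep$r))
})
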