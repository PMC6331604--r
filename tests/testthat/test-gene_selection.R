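make_expr <- function(values, genes, samples) {
  expression_matrix(matrix(values, length(genes), length(samples),
                           byrow = TRUE,
                           dimnames = list(genes, samples)))
}

test_that("differential expression: logFC arithmetic and exact rank-sum p", {
  expr <- make_expr(c(4, 4, 2, 2,
                      1, 2, 4, 5,
                      3, 3, 3, 3), paste0("g", 1:3), paste0("s", 1:4))
  de <- differential_expression(expr, c("s1", "s2"), c("s3", "s4"))
  expect_equal(de$logFC, c(2, -3, 0))
  expect_equal(de$p[3], 1)  # identical values in both groups

  expr2 <- make_expr(c(1, 2, 3, 4, 5, 6), "g", paste0("s", 1:6))
  de2 <- differential_expression(expr2, paste0("s", 1:3), paste0("s", 4:6))
  expect_equal(de2$p, 0.1)  # exact two-sided enumeration over C(6,3) splits
  expect_equal(de2$logFC, -3)

  expect_error(differential_expression(expr, c("s1", "s2"), c("s2", "s3")),
               "overlap")
  expect_error(differential_expression(expr, "s1", c("s2", "s3")),
               "at least 2")
})

test_that("BH adjustment: hand case, oracle equivalence, monotonicity", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(40)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    expect_equal(order(q[order(p)]), seq_along(p))  # order preserved
  }
})

test_that("MAD filter: hand-computed thresholds and constant genes", {
  samples <- paste0("s", 1:5)
  expr <- make_expr(c(1, 2, 3, 4, 100,
                      7, 7, 7, 7, 7), c("var", "const"), samples)
  # var: median 3, abs devs {2,1,0,1,97}, raw MAD 1, scaled 1.4826 > 1.0
  expect_equal(mad_filter(expr), "var")
  expect_equal(mad_filter(expr, selection_config(mad_constant = 1)),
               character(0))  # raw MAD 1 is not > 1.0 (strict)

  expr3 <- make_expr(c(1, 2, 3), "g", paste0("s", 1:3))
  expect_equal(mad_filter(expr3), "g")                       # 1.4826 > 1
  expect_equal(mad_filter(expr3, selection_config(mad_constant = 1)),
               character(0))
})

test_that("same-trend filter keeps concordant nonzero signs only", {
  d1 <- data.frame(gene = c("a", "b", "c", "d"),
                   logFC = c(2, 2, 2, -1), p = 0.01, q = 0.01)
  d2 <- data.frame(gene = c("a", "b", "c", "d"),
                   logFC = c(1.6, -1.6, 0, -0.5), p = 0.01, q = 0.01)
  expect_setequal(same_trend_filter(d1, d2), c("a", "d"))
  d3 <- d2[1:3, ]
  expect_warning(kept <- same_trend_filter(d1, d3), "absent")
  expect_setequal(kept, "a")
})

test_that("per-gene KM filter: null uniformity, power, degenerate genes", {
  set.seed(41)
  n <- 60
  samples <- paste0("s", 1:n)
  times <- rexp(n, 1 / 100)
  events <- rbinom(n, 1, 0.8)
  # genes independent of survival: p roughly uniform
  expr <- expression_matrix(matrix(rnorm(40 * n), 40, n,
                                   dimnames = list(paste0("g", 1:40),
                                                   samples)))
  p <- per_gene_km_filter(expr, times, events)
  expect_length(p, 40)
  expect_true(all(p > 0 & p < 1, na.rm = TRUE))
  expect_gt(mean(p, na.rm = TRUE), 0.25)  # not systematically small

  # a constant gene has no median split and is NA
  expr2 <- rbind(expr, flat = rep(1, n))
  p2 <- per_gene_km_filter(expression_matrix(expr2), times, events)
  expect_true(is.na(p2["flat"]))

  # matches the scalar log-rank route gene by gene
  for (g in paste0("g", 1:5)) {
    hi <- expr[g, ] > median(expr[g, ])
    ref <- logrank_test(times[hi], events[hi], times[!hi], events[!hi])
    expect_equal(unname(p[g]), ref$p, tolerance = 1e-10)
  }
})

test_that("KM filter is powered against a survival-coupled gene", {
  # gene = latent progression driving an exp(1 * latent) hazard, n = 200
  set.seed(42)
  n <- 200
  latent <- rnorm(n)
  t_ev <- rexp(n, (1 / 1000) * exp(latent))
  cens <- pmin(3650, runif(n, 0, 3650))
  times <- pmin(t_ev, cens); events <- as.numeric(t_ev <= cens)
  expr <- expression_matrix(matrix(latent, 1, n,
                                   dimnames = list("lat", paste0("s", 1:n))))
  p <- per_gene_km_filter(expr, times, events)
  expect_lt(p[["lat"]], 0.05)
})

test_that("selection cascade is invariant to gene and sample order", {
  co <- tiny_cohort(seed = 43L, n_genes = 150, n_lgg = 40, n_gbm = 25)
  # strengthen the planted signal so the cascade keeps a signature at this size
  cfg <- selection_config(fdr_max = 0.05, mad_min = 0.5)
  pair <- select_progression_genes(co$expression, co$clinical, cfg)
  g_perm <- sample(rownames(co$expression))
  s_perm <- sample(colnames(co$expression))
  pair2 <- select_progression_genes(co$expression[g_perm, s_perm],
                                    co$clinical, cfg)
  expect_setequal(pair$pos$genes, pair2$pos$genes)
  expect_setequal(pair$neg$genes, pair2$neg$genes)
})

test_that("cascade audit is consistent and flags the empty-signature case", {
  co <- tiny_cohort(seed = 44L, n_genes = 150, n_lgg = 40, n_gbm = 25)
  cfg <- selection_config(fdr_max = 0.05, mad_min = 0.5)
  pair <- select_progression_genes(co$expression, co$clinical, cfg)
  aud <- attr(pair, "audit")
  expect_equal(nrow(aud), nrow(co$expression))
  sel <- aud$de_tumour_nt & aud$de_gbm_lgg & aud$mad & aud$trend & aud$km
  expect_equal(aud$selected, sel)
  expect_setequal(c(pair$pos$genes, pair$neg$genes), aud$gene[aud$selected])

  # null cohort: no shifts, no survival coupling -> empty signature
  null_co <- generate_cohort(synthetic_config(
    n_genes = 150, n_lgg = 40, n_gbm = 25, delta_lgg = 0, delta_gbm = 0,
    beta_surv = 0, seed = 45L))
  err <- tryCatch(select_progression_genes(null_co$expression,
                                           null_co$clinical, cfg),
                  error = function(e) e)
  expect_s3_class(err, "error")
  expect_match(conditionMessage(err), "empty signature")
  expect_s3_class(attr(err, "audit"), "data.frame")
})

test_that("cascade recovers planted genes with few false positives when powered", {
  # within reach of the DE criteria: more normals and a stronger shift than
  # the paper-mirroring defaults (see the acceptance suite for those)
  co <- generate_cohort(synthetic_config(
    n_genes = 400, n_nt = 20, n_lgg = 60, n_gbm = 40,
    delta_lgg = 1.5, delta_gbm = 1.5, sigma = 0.9, seed = 46L))
  pair <- select_progression_genes(co$expression, co$clinical)
  sel <- c(pair$pos$genes, pair$neg$genes)
  truth <- c(co$truth$pos$genes, co$truth$neg$genes)
  expect_gte(sum(truth %in% sel), 16)
  expect_lte(sum(!(sel %in% truth)), 2)
  expect_setequal(intersect(pair$pos$genes, truth),
                  intersect(co$truth$pos$genes, sel))
})
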