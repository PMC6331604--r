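# Non-survival statistics relating the AP score to covariates, mutations,
# copy number, individual genes and immune gene sets.

.assoc_result <- function(name, test, statistic, p, extra = list()) {
  out <- c(list(name = name, test = test, statistic = unname(statistic),
                p = unname(p)), extra)
  structure(out, class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("<%s> %s: statistic = %.4g, p = %.4g\n", x$test, x$name,
              x$statistic, x$p))
  invisible(x)
}

#' One-way analysis of variance
#'
#' F = MS_between / MS_within with p from F(k - 1, n - k). When both the
#' between- and within-group sums of squares are zero the result is F = 0,
#' p = 1.
#'
#' @param groups list of numeric vectors, >= 2 groups of >= 2 values.
#' @return `association_result` with `statistic` = F.
#' @export
anova_oneway <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(lengths(groups) < 2L)) stop("each group needs at least 2 values")
  k <- length(groups)
  n <- sum(lengths(groups))
  grand <- mean(unlist(groups))
  ssb <- sum(lengths(groups) * (vapply(groups, mean, 0) - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  if (ssb == 0 && ssw == 0)
    return(.assoc_result("anova", "anova", 0, 1,
                         list(df1 = k - 1, df2 = n - k)))
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  p <- stats::pf(f, k - 1, n - k, lower.tail = FALSE)
  .assoc_result("anova", "anova", f, p, list(df1 = k - 1, df2 = n - k))
}

# Two-sided Fisher exact p for a 2x2 table: with margins fixed, the top-left
# cell is hypergeometric; the p-value sums the probabilities of all tables no
# more probable than the observed one (with a small relative tolerance for
# floating-point ties).
.fisher2x2_p <- function(tab) {
  m <- sum(tab[1, ])           # row-1 margin
  n <- sum(tab[2, ])
  k <- sum(tab[, 1])           # column-1 margin
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

#' Frequency comparison: chi-square or Fisher's exact test
#'
#' For a 2x2 table with any expected cell below 5, the two-sided Fisher exact
#' test is used (sum of hypergeometric probabilities no larger than the
#' observed table's); otherwise the Pearson chi-square test without
#' continuity correction. `method` can force either test.
#'
#' @param tab matrix of non-negative integer counts (2x2 or RxC).
#' @param method `"auto"` (default), `"chi2"` or `"fisher"`.
#' @return `association_result`; `test` records which test ran.
#' @export
contingency_test <- function(tab, method = c("auto", "chi2", "fisher")) {
  method <- match.arg(method)
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("contingency table has a zero margin")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  use_fisher <- switch(method,
    fisher = TRUE,
    chi2 = FALSE,
    auto = all(dim(tab) == 2L) && any(expected < 5))
  if (use_fisher) {
    if (!all(dim(tab) == 2L))
      stop("Fisher exact test implemented for 2x2 tables only")
    p <- .fisher2x2_p(tab)
    .assoc_result("contingency", "fisher", NA_real_, min(p, 1))
  } else {
    chi2 <- sum((tab - expected)^2 / expected)
    df <- (nrow(tab) - 1) * (ncol(tab) - 1)
    .assoc_result("contingency", "chi2", chi2,
                  stats::pchisq(chi2, df, lower.tail = FALSE),
                  list(df = df))
  }
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return `association_result` with `statistic` = r and `r` field.
#' @export
pearson_corr <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector in correlation")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  n <- length(x)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(t), n - 2)
  }
  .assoc_result("pearson", "pearson", r, p, list(r = unname(r), n = n))
}

#' Paired t-test
#'
#' t = mean(d) / (sd(d) / sqrt(n)) on d = x - y, two-sided p from t(n - 1).
#'
#' @param x,y paired numeric vectors (n >= 2, differences not all equal).
#' @return `association_result` with `statistic` = t and `df`.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  d <- x - y
  if (stats::sd(d) == 0) stop("zero variance of paired differences")
  n <- length(d)
  t <- mean(d) / (stats::sd(d) / sqrt(n))
  .assoc_result("paired_t", "paired_t", t, 2 * stats::pt(-abs(t), n - 1),
                list(df = n - 1, mean_diff = mean(d)))
}

#' Rank-based AUC (Mann-Whitney with tie correction)
#'
#' @param scores numeric vector.
#' @param positive logical vector, TRUE = positive class.
#' @return AUC in \[0, 1\]: the probability a random positive outscores a
#'   random negative (ties count one half).
#' @export
auc_rank <- function(scores, positive) {
  stopifnot(length(scores) == length(positive))
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  if (n_pos == 0L || n_neg == 0L) stop("need both classes for AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Outcome ROC labelling and AUC
#'
#' Implements the mean-overall-survival outcome labelling: with `mean_os`
#' the mean of `os_days` over deceased patients (`event == 1`),
#' * positive = died before `mean_os`,
#' * negative = survived past `mean_os` (any event status),
#' * excluded = censored with follow-up shorter than `mean_os`
#'   (outcome indeterminate).
#' The AUC is the Mann-Whitney statistic of the scores against these labels.
#'
#' @param scores named numeric vector (names = sample ids) or plain vector
#'   aligned to `clinical` rows.
#' @param clinical [cohort_clinical()]-style data.frame with `sample_id`,
#'   `os_days`, `event`.
#' @return list of class `roc_result`: `auc`, `n_pos`, `n_neg`, `mean_os`,
#'   `n_excluded`.
#' @export
roc_auc_outcome <- function(scores, clinical) {
  if (!is.null(names(scores))) {
    clinical <- clinical[match(names(scores), clinical$sample_id), ]
    if (any(is.na(clinical$sample_id)))
      stop("scores name samples absent from the clinical table")
  } else stopifnot(length(scores) == nrow(clinical))
  keep <- !is.na(clinical$os_days) & !is.na(clinical$event)
  scores <- scores[keep]
  clinical <- clinical[keep, ]
  if (!any(clinical$event == 1)) stop("no deaths: mean OS undefined")
  mean_os <- mean(clinical$os_days[clinical$event == 1])
  pos <- clinical$event == 1 & clinical$os_days < mean_os
  neg <- clinical$os_days >= mean_os
  excl <- clinical$event == 0 & clinical$os_days < mean_os
  n_pos <- sum(pos); n_neg <- sum(neg)
  if (n_pos == 0L || n_neg == 0L)
    stop(sprintf("empty outcome class after labelling (pos = %d, neg = %d, excluded = %d, mean OS = %.1f)",
                 n_pos, n_neg, sum(excl), mean_os))
  use <- pos | neg
  structure(list(auc = auc_rank(scores[use], pos[use]), n_pos = n_pos,
                 n_neg = n_neg, mean_os = mean_os, n_excluded = sum(excl)),
            class = "roc_result")
}

#' Combine two predictors through a logistic model
#'
#' Fits outcome ~ factor_a + factor_b by maximum-likelihood logistic
#' regression and returns the linear predictor as the combined score for
#' AUC evaluation. Perfect separation is flagged with a warning; the score
#' from the last iterate is still returned (its ranking, hence AUC, is
#' stable).
#'
#' @param outcome 0/1 (or logical) response.
#' @param factor_a,factor_b numeric predictors.
#' @return numeric combined score, attribute `"separation"` TRUE/FALSE and
#'   attribute `"coefficients"`.
#' @export
combine_predictors <- function(outcome, factor_a, factor_b) {
  y <- as.numeric(outcome)
  stopifnot(all(y %in% c(0, 1)), length(factor_a) == length(y),
            length(factor_b) == length(y))
  df <- data.frame(y = y, a = factor_a, b = factor_b)
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ a + b, family = stats::binomial(), data = df),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (sep) warning("possible perfect separation in logistic combination")
  score <- drop(stats::predict(fit, type = "link"))
  attr(score, "separation") <- sep
  attr(score, "coefficients") <- stats::coef(fit)
  score
}

#' Mutation frequency by AP group
#'
#' Per gene, tests the 2x2 table (mutated x AP group) with
#' [contingency_test()], BH-adjusts across genes and reports which group has
#' the larger mutated fraction.
#'
#' @param mutations [mutation_table()] data.frame.
#' @param ap_labels named character vector of `"high"`/`"low"` labels
#'   (names = sample ids, from [dichotomize_by_median()]).
#' @return data.frame `gene`, `n_mut_high`, `n_mut_low`, `frac_high`,
#'   `frac_low`, `enriched_in`, `test`, `p`, `q`.
#' @export
compare_mutation_freq <- function(mutations, ap_labels) {
  mutations <- mutation_table(mutations)
  stopifnot(!is.null(names(ap_labels)), all(ap_labels %in% c("high", "low")))
  mutations <- mutations[mutations$sample_id %in% names(ap_labels), ]
  genes <- sort(unique(mutations$gene))
  rows <- lapply(genes, function(g) {
    sub <- mutations[mutations$gene == g, ]
    lab <- ap_labels[sub$sample_id]
    if (!any(sub$mutated)) {
      warning("gene ", g, " has no mutated sample, skipped")
      return(NULL)
    }
    n_hi <- sum(lab == "high"); n_lo <- sum(lab == "low")
    m_hi <- sum(sub$mutated & lab == "high")
    m_lo <- sum(sub$mutated & lab == "low")
    tab <- matrix(c(m_hi, n_hi - m_hi, m_lo, n_lo - m_lo), 2, 2)
    if (any(rowSums(tab) == 0)) {
      # mutated in every (or no) sample of both groups: nothing to compare
      res <- list(test = "degenerate", p = 1)
    } else {
      res <- contingency_test(tab)
    }
    data.frame(gene = g, n_mut_high = m_hi, n_mut_low = m_lo,
               frac_high = m_hi / n_hi, frac_low = m_lo / n_lo,
               enriched_in = if (m_hi / n_hi >= m_lo / n_lo) "high" else "low",
               test = res$test, p = res$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no testable genes in mutation table")
  out$q <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}

#' Copy-number comparison by AP group
#'
#' Per gene: group means of the copy-number estimate in the low and high AP
#' groups and a two-sided Welch t-test (group variances not assumed equal),
#' BH-adjusted across genes. Zero variance in both groups yields p = 1 when
#' the means agree.
#'
#' @param cnv gene-by-sample copy-number matrix.
#' @param ap_labels named `"high"`/`"low"` vector as in
#'   [compare_mutation_freq()].
#' @return data.frame `gene`, `mean_low`, `mean_high`, `t`, `p`, `q`.
#' @export
compare_cnv <- function(cnv, ap_labels) {
  cnv <- expression_matrix(cnv)
  stopifnot(!is.null(names(ap_labels)), all(ap_labels %in% c("high", "low")))
  common <- intersect(colnames(cnv), names(ap_labels))
  lab <- ap_labels[common]
  if (sum(lab == "high") < 2L || sum(lab == "low") < 2L)
    stop("each AP group needs at least 2 samples with CNV data")
  hi <- cnv[, common[lab == "high"], drop = FALSE]
  lo <- cnv[, common[lab == "low"], drop = FALSE]
  rows <- lapply(rownames(cnv), function(g) {
    x <- hi[g, ]; y <- lo[g, ]
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      t <- 0; p <- if (mean(x) == mean(y)) 1 else 0
    } else {
      ht <- stats::t.test(x, y, var.equal = FALSE)
      t <- unname(ht$statistic); p <- ht$p.value
    }
    data.frame(gene = g, mean_low = mean(y), mean_high = mean(x), t = t,
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}

#' Genes correlated with the AP score
#'
#' Per gene, Pearson r of expression against the AP score over tumour
#' samples; the positive set collects genes with `r > r_threshold`, the
#' negative set genes with `r < -r_threshold` (strict inequalities).
#' Constant genes are skipped with a warning.
#'
#' @param expr gene-by-sample matrix (tumour samples).
#' @param ap named numeric AP score vector (names = sample ids).
#' @param r_threshold correlation threshold (default 0.6).
#' @return list: `positive`, `negative` (gene vectors), `r` (named vector).
#' @export
correlate_genes_with_score <- function(expr, ap, r_threshold = 0.6) {
  expr <- expression_matrix(expr)
  stopifnot(!is.null(names(ap)))
  common <- intersect(colnames(expr), names(ap))
  if (length(common) < 3L) stop("need at least 3 shared samples")
  e <- expr[, common, drop = FALSE]
  a <- ap[common]
  sds <- apply(e, 1, stats::sd)
  if (any(sds == 0))
    warning(sum(sds == 0), " constant gene(s) skipped")
  e <- e[sds > 0, , drop = FALSE]
  r <- as.numeric(stats::cor(t(e), a))
  names(r) <- rownames(e)
  list(positive = names(r)[r > r_threshold],
       negative = names(r)[r < -r_threshold],
       r = r)
}

#' Immune gene-set association report
#'
#' For each immune marker set: its per-sample ssGSEA score, the Pearson
#' correlation (r and p) with the AP score, and the log-rank p for the
#' median-dichotomized set score against survival — one row per set,
#' the shape of a correlation-and-prognosis table. Sets without overlap are
#' reported as NA rows with a warning.
#'
#' @param expr gene-by-sample matrix (tumour samples with survival).
#' @param immune_sets list of [gene_set()] objects.
#' @param ap named AP score vector.
#' @param clinical clinical table with `sample_id`, `os_days`, `event`.
#' @param config [ssgsea_config()].
#' @return data.frame `set`, `r`, `r_p`, `logrank_p`.
#' @export
immune_ssgsea_association <- function(expr, immune_sets, ap, clinical,
                                      config = ssgsea_config()) {
  expr <- expression_matrix(expr)
  if (inherits(immune_sets, "gene_set")) immune_sets <- list(immune_sets)
  stopifnot(!is.null(names(ap)))
  common <- intersect(intersect(colnames(expr), names(ap)),
                      clinical$sample_id[!is.na(clinical$os_days)])
  e <- expr[, common, drop = FALSE]
  cl <- clinical[match(common, clinical$sample_id), ]
  rows <- lapply(immune_sets, function(s) {
    ov <- suppressWarnings(match_gene_set(s, rownames(e)))
    if (!length(ov)) {
      warning("immune set '", s$name, "' has no overlap, reported as NA")
      return(data.frame(set = s$name, r = NA_real_, r_p = NA_real_,
                        logrank_p = NA_real_, stringsAsFactors = FALSE))
    }
    sc <- ssgsea_matrix(e, list(s), ssgsea_config(config$alpha,
                                                  normalize = FALSE))[1, ]
    pc <- pearson_corr(sc, ap[common])
    lab <- dichotomize_by_median(sc)
    lr <- logrank_test(cl$os_days[lab == "high"], cl$event[lab == "high"],
                       cl$os_days[lab == "low"], cl$event[lab == "low"])
    data.frame(set = s$name, r = pc$r, r_p = pc$p, logrank_p = lr$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
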