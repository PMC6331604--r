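# The five-criterion progression-gene cascade:
#   (i)  differentially expressed, tumour vs normal tissue (BH q < fdr_max)
#   (ii) differentially expressed, GBM vs LGG             (BH q < fdr_max)
#   (iii) highly variable across tumours (scaled MAD > mad_min)
#   (iv) same direction of change in (i) and (ii)
#   (v)  prognostic: per-gene median-split log-rank p < km_p_max
# Kept genes with a positive trend form POS_AP, negative trend NEG_AP.

#' Selection cascade configuration
#'
#' @param fdr_max BH-adjusted p ceiling for the two differential-expression
#'   criteria (default 0.01).
#' @param lfc_min minimum |log2 fold change| required in both comparisons.
#'   Default 0: the published screen imposes an FDR threshold only; set this
#'   (e.g. to 1.5) to additionally require an effect-size floor.
#' @param mad_min variability floor on the scaled MAD (default 1.0).
#' @param mad_constant consistency scaling of the raw MAD (default 1.4826,
#'   the normal-consistency constant).
#' @param km_p_max per-gene log-rank p ceiling (default 0.05).
#' @return list of class `selection_config`.
#' @export
selection_config <- function(fdr_max = 0.01, lfc_min = 0, mad_min = 1.0,
                             mad_constant = 1.4826, km_p_max = 0.05) {
  stopifnot(fdr_max > 0, fdr_max < 1, lfc_min >= 0, mad_min > 0,
            mad_constant > 0, km_p_max > 0, km_p_max < 1)
  structure(list(fdr_max = fdr_max, lfc_min = lfc_min, mad_min = mad_min,
                 mad_constant = mad_constant, km_p_max = km_p_max),
            class = "selection_config")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up: on sorted p-values, q(i) = min_{j >= i} p(j) * m / j, mapped back
#' to input order and clipped at 1.
#'
#' @param pvals numeric vector in \[0, 1\] (NA passed through).
#' @return adjusted q-values in input order.
#' @export
bh_adjust <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1)) stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(pvals))
  p <- pvals[ok]
  m <- length(p)
  if (m) {
    o <- order(p, decreasing = TRUE)
    qq <- pmin(1, cummin(p[o] * m / rev(seq_len(m))))
    q[ok][o] <- qq
  }
  q
}

#' Two-group differential expression
#'
#' Per gene: logFC is the mean log2 difference (group A minus group B) and the
#' p-value comes from the two-sided Wilcoxon rank-sum test — distribution-free
#' and applicable to any normalized log-scale platform. The exact null
#' distribution is used whenever there are no ties and the group-size product
#' is at most `exact_max`; otherwise the normal approximation with continuity
#' correction. q is BH over all genes tested.
#'
#' @param expr gene-by-sample expression matrix.
#' @param samples_a,samples_b disjoint sample-id vectors, each of size >= 2.
#' @param exact_max largest `n_A * n_B` for which the exact Wilcoxon null is
#'   used (default 10000).
#' @return data.frame `gene`, `logFC`, `p`, `q`.
#' @export
differential_expression <- function(expr, samples_a, samples_b,
                                    exact_max = 10000) {
  expr <- expression_matrix(expr)
  samples_a <- as.character(samples_a)
  samples_b <- as.character(samples_b)
  if (length(intersect(samples_a, samples_b)))
    stop("sample groups overlap")
  if (length(samples_a) < 2L || length(samples_b) < 2L)
    stop("each group needs at least 2 samples")
  missing <- setdiff(c(samples_a, samples_b), colnames(expr))
  if (length(missing))
    stop("samples not in matrix: ", paste(missing, collapse = ", "))
  a <- expr[, samples_a, drop = FALSE]
  b <- expr[, samples_b, drop = FALSE]
  lfc <- rowMeans(a) - rowMeans(b)
  exact <- ncol(a) * ncol(b) <= exact_max
  p <- vapply(seq_len(nrow(expr)), function(i) {
    if (stats::sd(c(a[i, ], b[i, ])) == 0) return(1)  # identical everywhere
    suppressWarnings(
      stats::wilcox.test(a[i, ], b[i, ], exact = exact, correct = TRUE)$p.value)
  }, numeric(1))
  data.frame(gene = rownames(expr), logFC = lfc, p = p, q = bh_adjust(p),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Variability (MAD) filter
#'
#' Keeps genes whose scaled median absolute deviation across the given
#' samples exceeds `mad_min` (strict inequality):
#' `mad_constant * median(|x - median(x)|) > mad_min`.
#'
#' @param expr gene-by-sample expression matrix (tumour samples).
#' @param config [selection_config()].
#' @return character vector of passing gene symbols.
#' @export
mad_filter <- function(expr, config = selection_config()) {
  expr <- expression_matrix(expr)
  if (ncol(expr) < 2L) stop("MAD filter needs at least 2 samples")
  m <- apply(expr, 1, function(x) stats::median(abs(x - stats::median(x))))
  rownames(expr)[config$mad_constant * m > config$mad_min]
}

#' Concordant-trend filter
#'
#' Keeps genes whose log fold changes in the tumour-vs-NT and GBM-vs-LGG
#' comparisons have the same (nonzero) sign. Genes missing from either table
#' are excluded with a warning.
#'
#' @param de_tumour_vs_nt,de_gbm_vs_lgg data.frames from
#'   [differential_expression()].
#' @return character vector of concordant gene symbols.
#' @export
same_trend_filter <- function(de_tumour_vs_nt, de_gbm_vs_lgg) {
  common <- intersect(de_tumour_vs_nt$gene, de_gbm_vs_lgg$gene)
  miss <- setdiff(union(de_tumour_vs_nt$gene, de_gbm_vs_lgg$gene), common)
  if (length(miss))
    warning(length(miss), " gene(s) absent from one DE table, excluded")
  s1 <- sign(de_tumour_vs_nt$logFC[match(common, de_tumour_vs_nt$gene)])
  s2 <- sign(de_gbm_vs_lgg$logFC[match(common, de_gbm_vs_lgg$gene)])
  common[s1 != 0 & s1 == s2]
}

# Vectorized per-gene log-rank chi-square for median-split groups.
# member: genes-by-samples logical matrix, TRUE = sample in group 1.
# Returns p per gene (NA when a gene's split is degenerate).
.logrank_bulk_p <- function(times, events, member) {
  n <- length(times)
  ord <- order(times, decreasing = TRUE)   # cumulate to get at-risk counts
  times_s <- times[ord]
  events_s <- events[ord]
  mem_s <- member[, ord, drop = FALSE]
  nk_all <- seq_len(n)                      # at risk at position i (ties below)
  n1_all <- t(apply(mem_s, 1, cumsum))
  # positions by increasing time: at-risk counts at a time t are those at the
  # last position sharing t
  tk <- sort(unique(times_s[events_s == 1]))
  o1 <- e1 <- v <- rep(0, nrow(member))
  for (t in tk) {
    idx <- which(times_s == t)
    pos <- max(idx)                         # includes every sample with time >= t
    nk <- nk_all[pos]
    n1k <- n1_all[, pos]
    ev_idx <- idx[events_s[idx] == 1]
    dk <- length(ev_idx)
    d1k <- if (dk) rowSums(mem_s[, ev_idx, drop = FALSE]) else 0
    o1 <- o1 + d1k
    e1 <- e1 + n1k * dk / nk
    if (nk > 1)
      v <- v + dk * (n1k / nk) * (1 - n1k / nk) * (nk - dk) / (nk - 1)
  }
  chi2 <- ifelse(v > 0, (o1 - e1)^2 / v, NA_real_)
  degenerate <- rowSums(member) == 0 | rowSums(member) == ncol(member)
  p <- stats::pchisq(chi2, 1, lower.tail = FALSE)
  p[degenerate] <- NA_real_
  stats::setNames(p, rownames(member))
}

#' Per-gene prognostic (Kaplan-Meier log-rank) filter
#'
#' For every gene, tumour samples are split at that gene's median expression
#' (ties to the low group) and the two-group log-rank p-value is computed.
#' Genes whose split leaves one side empty get `NA`.
#'
#' @param expr gene-by-sample matrix restricted to samples with survival data.
#' @param times,events survival follow-up and 0/1 status, aligned to
#'   `colnames(expr)`.
#' @return named numeric vector of log-rank p-values (selection keeps
#'   `p < km_p_max`).
#' @export
per_gene_km_filter <- function(expr, times, events) {
  expr <- expression_matrix(expr)
  stopifnot(length(times) == ncol(expr), length(events) == ncol(expr))
  keep <- !is.na(times) & !is.na(events)
  if (sum(keep) < 4L) stop("need at least 4 samples with survival data")
  expr <- expr[, keep, drop = FALSE]
  times <- times[keep]; events <- events[keep]
  med <- apply(expr, 1, stats::median)
  member <- expr > med                      # TRUE = high expression group
  .logrank_bulk_p(times, events, member)
}

#' Run the five-criterion progression-gene selection cascade
#'
#' The cascade is a pure intersection: each criterion is evaluated for every
#' gene, and a gene is selected iff it passes all five. The direction of the
#' concordant trend assigns selected genes to the POS (up with progression)
#' or NEG (down) set.
#'
#' @param expr gene-by-sample log2 expression matrix covering NT, LGG and GBM
#'   samples.
#' @param clinical [cohort_clinical()] table; tumour rows must carry survival.
#' @param config [selection_config()].
#' @return a [gene_set_pair()] with attribute `"audit"`: a data.frame with one
#'   row per gene and logical columns `de_tumour_nt`, `de_gbm_lgg`, `mad`,
#'   `trend`, `km`, `selected`, plus the underlying statistics. If either
#'   final set is empty an "empty signature" error carrying the audit table
#'   (attribute `audit` of the condition) is raised.
#' @export
select_progression_genes <- function(expr, clinical,
                                     config = selection_config()) {
  expr <- expression_matrix(expr)
  clinical <- cohort_clinical(clinical)
  clinical <- clinical[match(colnames(expr), clinical$sample_id), ]
  if (any(is.na(clinical$sample_id)))
    stop("clinical table must cover every expression sample")
  nt <- clinical$sample_id[clinical$tissue_group == "NT"]
  lgg <- clinical$sample_id[clinical$tissue_group == "LGG"]
  gbm <- clinical$sample_id[clinical$tissue_group == "GBM"]
  if (!length(nt) || !length(lgg) || !length(gbm))
    stop("cohort must contain NT, LGG and GBM samples")
  tumour <- c(lgg, gbm)

  de_t_nt <- differential_expression(expr, tumour, nt)
  de_g_l <- differential_expression(expr, gbm, lgg)
  pass_i <- de_t_nt$q < config$fdr_max & abs(de_t_nt$logFC) >= config$lfc_min
  pass_ii <- de_g_l$q < config$fdr_max & abs(de_g_l$logFC) >= config$lfc_min

  mad_pass <- rownames(expr) %in%
    mad_filter(expr[, tumour, drop = FALSE], config)
  trend_pass <- rownames(expr) %in% same_trend_filter(de_t_nt, de_g_l)

  cl_t <- clinical[match(tumour, clinical$sample_id), ]
  km_p <- per_gene_km_filter(expr[, tumour, drop = FALSE],
                             cl_t$os_days, cl_t$event)
  km_pass <- !is.na(km_p) & km_p < config$km_p_max

  audit <- data.frame(
    gene = rownames(expr),
    logFC_tumour_nt = de_t_nt$logFC, q_tumour_nt = de_t_nt$q,
    logFC_gbm_lgg = de_g_l$logFC, q_gbm_lgg = de_g_l$q,
    km_p = unname(km_p),
    de_tumour_nt = pass_i, de_gbm_lgg = pass_ii, mad = mad_pass,
    trend = trend_pass, km = km_pass,
    stringsAsFactors = FALSE, row.names = NULL)
  audit$selected <- with(audit, de_tumour_nt & de_gbm_lgg & mad & trend & km)

  sel <- audit[audit$selected, ]
  pos_genes <- sel$gene[sel$logFC_tumour_nt > 0]
  neg_genes <- sel$gene[sel$logFC_tumour_nt < 0]
  if (!length(pos_genes) || !length(neg_genes)) {
    cond <- simpleError("empty signature: selection cascade kept no POS and/or NEG genes")
    attr(cond, "audit") <- audit
    stop(cond)
  }
  pair <- gene_set_pair(gene_set("POS_AP", sort(pos_genes)),
                        gene_set("NEG_AP", sort(neg_genes)))
  attr(pair, "audit") <- audit
  pair
}
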