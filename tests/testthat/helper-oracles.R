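# Independent oracles used by property and acceptance tests. These are
# deliberately naive (double loops, full enumeration) and share no code with
# the package implementation.

# brute-force ssGSEA: for every position of the decreasing-rank ordering,
# recompute P_in and P_out from scratch with explicit loops
oracle_ssgsea_es <- function(ranks, set_genes, alpha) {
  genes <- names(ranks)
  ord <- order(-ranks, genes, method = "radix")
  genes <- genes[ord]
  r <- ranks[ord]
  in_set <- genes %in% set_genes
  denom_in <- 0
  for (k in seq_along(genes)) if (in_set[k]) denom_in <- denom_in + r[k]^alpha
  n_out <- sum(!in_set)
  es <- 0
  for (i in seq_along(genes)) {
    p_in <- 0; c_out <- 0
    for (k in seq_len(i)) {
      if (in_set[k]) p_in <- p_in + r[k]^alpha / denom_in
      else c_out <- c_out + 1
    }
    es <- es + (p_in - c_out / n_out)
  }
  unname(es)
}

# two-sided Fisher exact p by explicit enumeration of all tables with the
# observed margins, using choose() directly
oracle_fisher2x2 <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  total <- r1 + r2
  support <- max(0, c1 - r2):min(c1, r1)
  prob <- function(a) choose(r1, a) * choose(r2, c1 - a) / choose(total, c1)
  p_obs <- prob(tab[1, 1])
  sum(vapply(support, prob, 0)[vapply(support, prob, 0) <= p_obs * (1 + 1e-7)])
}

# AUC by exhaustive pair counting
oracle_auc <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# BH step-up computed directly from the definition on sorted p-values
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    cand <- p[o][i:m] * m / (i:m)
    q_sorted[i] <- min(1, min(cand))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Kaplan-Meier survival at the event times via the definition, no censoring:
# S(t) = fraction with time > t
oracle_km_no_censor <- function(times) {
  tk <- sort(unique(times))
  vapply(tk, function(t) mean(times > t), 0)
}

# small deterministic three-group cohort used across data-io / pipeline tests
tiny_cohort <- function(seed = 42L, n_genes = 300, n_nt = 5, n_lgg = 30,
                        n_gbm = 20) {
  generate_cohort(synthetic_config(
    n_genes = n_genes, n_nt = n_nt, n_lgg = n_lgg, n_gbm = n_gbm,
    seed = seed))
}

# default-size cohort, built once per test run and memoised
default_cohort <- local({
  cache <- NULL
  function(seed = 101L) {
    if (is.null(cache)) cache <<- generate_cohort(synthetic_config(seed = seed))
    cache
  }
})
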