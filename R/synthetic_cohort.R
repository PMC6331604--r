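# Synthetic glioma cohorts with the statistical structure the analysis
# assumes: three tissue groups (NT / LGG / GBM), a small panel of planted
# monotone progression genes, survival coupled loglinearly to a latent
# progression axis, covariates coupled to that axis through logistic links,
# group-dependent mutation frequencies and copy-number shifts.

#' Synthetic cohort configuration
#'
#' Defaults mirror a TCGA-style astrocytoma training cohort: 5 normal
#' tissues and 240 tumours against an 18-gene planted signature (12 up-,
#' 6 down-regulated with progression).
#'
#' @param n_genes total number of genes (default 2000).
#' @param n_nt,n_lgg,n_gbm samples per tissue group (defaults 5 / 160 / 80).
#' @param n_pos_planted,n_neg_planted planted progression genes (12 / 6).
#' @param delta_lgg log2 shift of planted genes from NT to LGG (default 1.0).
#' @param delta_gbm additional log2 shift from LGG to GBM (default 1.0).
#' @param sigma residual SD of log2 expression (default 0.7).
#' @param beta_surv log-hazard per SD of latent progression (default 1.0).
#' @param baseline_hazard hazard per day at latent 0 (default 1/1000).
#' @param censor_days administrative censoring horizon (default 3650).
#' @param seed integer seed; all draws come from one stream in a fixed order.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 2000, n_nt = 5, n_lgg = 160,
                             n_gbm = 80, n_pos_planted = 12,
                             n_neg_planted = 6, delta_lgg = 1.0,
                             delta_gbm = 1.0, sigma = 0.7, beta_surv = 1.0,
                             baseline_hazard = 1 / 1000, censor_days = 3650,
                             seed = 1L) {
  cfg <- list(n_genes = n_genes, n_nt = n_nt, n_lgg = n_lgg, n_gbm = n_gbm,
              n_pos_planted = n_pos_planted, n_neg_planted = n_neg_planted,
              delta_lgg = delta_lgg, delta_gbm = delta_gbm, sigma = sigma,
              beta_surv = beta_surv, baseline_hazard = baseline_hazard,
              censor_days = censor_days, seed = as.integer(seed))
  pos_counts <- c(cfg$n_genes, cfg$n_nt, cfg$n_lgg, cfg$n_gbm,
                  cfg$n_pos_planted, cfg$n_neg_planted)
  if (any(pos_counts <= 0)) stop("all counts must be positive")
  if (cfg$n_pos_planted + cfg$n_neg_planted >= cfg$n_genes)
    stop("planted gene counts must be smaller than n_genes")
  if (cfg$sigma <= 0 || cfg$baseline_hazard <= 0 || cfg$censor_days <= 0)
    stop("sigma, baseline_hazard and censor_days must be positive")
  if (cfg$delta_lgg < 0 || cfg$delta_gbm < 0)
    stop("progression shifts must be non-negative")
  structure(cfg, class = "synthetic_config")
}

# mutation panel: rate at latent 0 and logistic slope on latent.
# IDH1/TP53/ATRX fall with progression, the rest rise.
.mutation_panel <- data.frame(
  gene = c("IDH1", "TP53", "ATRX", "PTEN", "EGFR", "NF1", "RB1", "PIK3CA"),
  base_rate = c(0.60, 0.45, 0.35, 0.15, 0.20, 0.12, 0.08, 0.10),
  slope = c(-1.5, -1.0, -1.0, 1.2, 1.2, 0.8, 0.8, 0.6),
  stringsAsFactors = FALSE)

# CNV panel: per-SD-of-latent mean copy-number shift (noise SD 0.2 on top)
.cnv_panel <- data.frame(
  gene = c("EGFR", "CDK4", "PDGFRA", "CDKN2A", "CDKN2B", "PTEN"),
  slope = c(0.5, 0.3, 0.2, -0.4, -0.4, -0.3),
  stringsAsFactors = FALSE)

# logistic covariate couplings (slope on standardized latent; intercept sets
# the marginal frequency near latent 0)
.covariate_links <- list(
  idh_wildtype = c(intercept = 0, slope = 2.0),
  mgmt_unmethylated = c(intercept = 0, slope = 1.0),
  grade_iii = c(intercept = 0, slope = 1.5),          # III vs II within LGG
  subtype_aggressive = c(intercept = 0, slope = 1.5)  # ME/CL vs NE/PN
)

.plogis_ <- function(x) 1 / (1 + exp(-x))

# expression matrix for given per-sample group shifts of planted genes
.draw_expression <- function(cfg, baselines, groups, sample_ids) {
  n <- length(groups)
  shift <- matrix(0, cfg$n_genes, n)
  shift_amt <- ifelse(groups == "LGG", cfg$delta_lgg,
                      ifelse(groups == "GBM", cfg$delta_lgg + cfg$delta_gbm, 0))
  pos_idx <- seq_len(cfg$n_pos_planted)
  neg_idx <- cfg$n_pos_planted + seq_len(cfg$n_neg_planted)
  shift[pos_idx, ] <- matrix(shift_amt, length(pos_idx), n, byrow = TRUE)
  shift[neg_idx, ] <- -matrix(shift_amt, length(neg_idx), n, byrow = TRUE)
  vals <- baselines + shift +
    matrix(stats::rnorm(cfg$n_genes * n, 0, cfg$sigma), cfg$n_genes, n)
  expression_matrix(vals, gene_ids = .synth_gene_ids(cfg),
                    sample_ids = sample_ids)
}

.synth_gene_ids <- function(cfg) {
  c(sprintf("POSG%02d", seq_len(cfg$n_pos_planted)),
    sprintf("NEGG%02d", seq_len(cfg$n_neg_planted)),
    sprintf("BG%05d", seq_len(cfg$n_genes - cfg$n_pos_planted -
                                cfg$n_neg_planted)))
}

# latent progression: standardized difference of planted-set means
.compute_latent <- function(cfg, expr, tumour_ids) {
  pos <- sprintf("POSG%02d", seq_len(cfg$n_pos_planted))
  neg <- sprintf("NEGG%02d", seq_len(cfg$n_neg_planted))
  raw <- colMeans(expr[pos, tumour_ids, drop = FALSE]) -
    colMeans(expr[neg, tumour_ids, drop = FALSE])
  as.numeric(scale(raw))
}

.draw_survival <- function(cfg, latent) {
  h <- cfg$baseline_hazard * exp(cfg$beta_surv * latent)
  t_event <- stats::rexp(length(latent), rate = h)
  t_cens <- pmin(cfg$censor_days, stats::runif(length(latent), 0,
                                               cfg$censor_days))
  list(os_days = pmin(t_event, t_cens),
       event = as.numeric(t_event <= t_cens))
}

.draw_covariates <- function(latent) {
  n <- length(latent)
  lk <- .covariate_links
  idh_wt <- stats::rbinom(n, 1, .plogis_(lk$idh_wildtype["intercept"] +
                                           lk$idh_wildtype["slope"] * latent))
  mgmt_un <- stats::rbinom(n, 1, .plogis_(lk$mgmt_unmethylated["intercept"] +
                                            lk$mgmt_unmethylated["slope"] * latent))
  aggressive <- stats::rbinom(n, 1, .plogis_(lk$subtype_aggressive["intercept"] +
                                               lk$subtype_aggressive["slope"] * latent))
  sub1 <- stats::rbinom(n, 1, 0.5)
  subtype <- ifelse(aggressive == 1, ifelse(sub1 == 1, "ME", "CL"),
                    ifelse(sub1 == 1, "NE", "PN"))
  list(idh = ifelse(idh_wt == 1, "wildtype", "mutant"),
       mgmt = ifelse(mgmt_un == 1, "unmethylated", "methylated"),
       subtype = subtype,
       gender = ifelse(stats::rbinom(n, 1, 0.5) == 1, "M", "F"),
       age = round(stats::rnorm(n, 50 + 5 * latent, 12)),
       chemo = ifelse(stats::rbinom(n, 1, 0.7) == 1, "yes", "no"),
       radio = ifelse(stats::rbinom(n, 1, 0.8) == 1, "yes", "no"))
}

.draw_mutations <- function(latent, sample_ids) {
  panel <- .mutation_panel
  recs <- lapply(seq_len(nrow(panel)), function(i) {
    p <- .plogis_(stats::qlogis(panel$base_rate[i]) + panel$slope[i] * latent)
    data.frame(sample_id = sample_ids, gene = panel$gene[i],
               mutated = stats::rbinom(length(latent), 1, p) == 1,
               stringsAsFactors = FALSE)
  })
  mutation_table(do.call(rbind, recs))
}

.draw_cnv <- function(latent, sample_ids) {
  panel <- .cnv_panel
  vals <- t(vapply(seq_len(nrow(panel)), function(i) {
    panel$slope[i] * latent + stats::rnorm(length(latent), 0, 0.2)
  }, numeric(length(latent))))
  expression_matrix(vals, gene_ids = panel$gene, sample_ids = sample_ids)
}

#' Generate a synthetic glioma cohort
#'
#' Draws, in a fixed documented order from a single seeded stream:
#' gene baselines (Uniform(2, 10) log2 units), the expression matrix,
#' survival, covariates, mutations, then CNV. The latent progression axis of
#' a tumour sample is the standardized difference between its planted-POS and
#' planted-NEG mean expression — i.e. the quantity the AP score is designed
#' to track — and drives survival (hazard
#' `baseline_hazard * exp(beta_surv * latent)`), the covariate frequencies,
#' the mutation rates and the CNV shifts.
#'
#' @param config [synthetic_config()].
#' @return list of class `synthetic_cohort`: `expression`, `clinical`,
#'   `truth` (planted [gene_set_pair()]), `mutations`, `cnv`, `latent`
#'   (named, tumour samples only), `config`.
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  set.seed(cfg$seed)
  nt_ids <- sprintf("NT%03d", seq_len(cfg$n_nt))
  lgg_ids <- sprintf("LGG%03d", seq_len(cfg$n_lgg))
  gbm_ids <- sprintf("GBM%03d", seq_len(cfg$n_gbm))
  groups <- rep(c("NT", "LGG", "GBM"), c(cfg$n_nt, cfg$n_lgg, cfg$n_gbm))
  ids <- c(nt_ids, lgg_ids, gbm_ids)

  baselines <- stats::runif(cfg$n_genes, 2, 10)
  expr <- .draw_expression(cfg, baselines, groups, ids)
  tumour_ids <- c(lgg_ids, gbm_ids)
  latent <- stats::setNames(.compute_latent(cfg, expr, tumour_ids), tumour_ids)

  surv <- .draw_survival(cfg, latent)
  cov <- .draw_covariates(latent)
  lk3 <- .covariate_links$grade_iii
  lgg_grade <- ifelse(
    stats::rbinom(cfg$n_lgg, 1,
                  .plogis_(lk3["intercept"] +
                             lk3["slope"] * latent[seq_len(cfg$n_lgg)])) == 1,
    "III", "II")
  nt_na <- rep(NA_character_, cfg$n_nt)
  clinical <- cohort_clinical(data.frame(
    sample_id = ids,
    tissue_group = groups,
    os_days = c(rep(NA_real_, cfg$n_nt), surv$os_days),
    event = c(rep(NA_real_, cfg$n_nt), surv$event),
    age = c(round(stats::rnorm(cfg$n_nt, 45, 12)), cov$age),
    gender = c(ifelse(stats::rbinom(cfg$n_nt, 1, 0.5) == 1, "M", "F"),
               cov$gender),
    grade = c(nt_na, lgg_grade, rep("IV", cfg$n_gbm)),
    idh = c(nt_na, cov$idh),
    mgmt = c(nt_na, cov$mgmt),
    subtype = c(nt_na, cov$subtype),
    chemo = c(nt_na, cov$chemo),
    radio = c(nt_na, cov$radio),
    stringsAsFactors = FALSE))

  mutations <- .draw_mutations(latent, tumour_ids)
  cnv <- .draw_cnv(latent, tumour_ids)
  truth <- gene_set_pair(
    gene_set("POS_TRUTH", sprintf("POSG%02d", seq_len(cfg$n_pos_planted))),
    gene_set("NEG_TRUTH", sprintf("NEGG%02d", seq_len(cfg$n_neg_planted))))
  structure(list(expression = expr, clinical = clinical, truth = truth,
                 mutations = mutations, cnv = cnv, latent = latent,
                 config = cfg),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", nrow(x$expression), " genes x ",
      ncol(x$expression), " samples (",
      sum(x$clinical$tissue_group == "NT"), " NT)\n", sep = "")
  invisible(x)
}

#' Generate paired primary-recurrent cohorts
#'
#' Builds `n_pairs` primary lower-grade tumours and their recurrences. Each
#' recurrent sample's latent progression target equals the primary's planted
#' signal plus `increment` (in units of the planted log2 shift) for
#' `n_shifted` of the pairs; the remaining pairs recur without progression.
#' Expression is regenerated from the shifted signal, so the AP score of a
#' shifted recurrence should exceed its primary.
#'
#' @param config [synthetic_config()] (survival/covariates are not generated
#'   here; only expression matters for the longitudinal comparison).
#' @param n_pairs number of pairs (default 7, >= 2).
#' @param n_shifted how many pairs progress at recurrence (default 6).
#' @param increment log2 shift applied to planted genes of a progressing
#'   recurrence (default `config$delta_gbm`).
#' @return list of class `paired_cohort`: `primary`, `recurrent` (expression
#'   matrices), `pairing` (data.frame `primary_id`, `recurrent_id`,
#'   `shifted`).
#' @export
generate_paired_recurrence <- function(config = synthetic_config(),
                                       n_pairs = 7L, n_shifted = 6L,
                                       increment = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (n_pairs < 2L) stop("need at least 2 pairs")
  if (n_shifted > n_pairs) stop("n_shifted cannot exceed n_pairs")
  cfg <- config
  if (is.null(increment)) increment <- cfg$delta_gbm
  set.seed(cfg$seed + 1L)
  prim_ids <- sprintf("PRI%02d", seq_len(n_pairs))
  rec_ids <- sprintf("REC%02d", seq_len(n_pairs))
  baselines <- stats::runif(cfg$n_genes, 2, 10)
  # primaries are lower-grade tumours
  prim <- .draw_expression(cfg, baselines, rep("LGG", n_pairs), prim_ids)
  shifted <- c(rep(TRUE, n_shifted), rep(FALSE, n_pairs - n_shifted))
  rec <- .draw_expression(cfg, baselines, rep("LGG", n_pairs), rec_ids)
  pos_idx <- seq_len(cfg$n_pos_planted)
  neg_idx <- cfg$n_pos_planted + seq_len(cfg$n_neg_planted)
  rec[pos_idx, shifted] <- rec[pos_idx, shifted] + increment
  rec[neg_idx, shifted] <- rec[neg_idx, shifted] - increment
  structure(list(primary = prim, recurrent = rec,
                 pairing = data.frame(primary_id = prim_ids,
                                      recurrent_id = rec_ids,
                                      shifted = shifted,
                                      stringsAsFactors = FALSE)),
            class = "paired_cohort")
}

#' Write a synthetic cohort to disk
#'
#' Emits the five pipeline inputs: `expression.tsv`, `clinical.tsv`,
#' `mutations.tsv`, `cnv.tsv` and `truth.gmt` (the planted signature).
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             clinical = file.path(dir, "clinical.tsv"),
             mutations = file.path(dir, "mutations.tsv"),
             cnv = file.path(dir, "cnv.tsv"),
             truth = file.path(dir, "truth.gmt"))
  write_expression(cohort$expression, paths["expression"])
  write_clinical(cohort$clinical, paths["clinical"])
  write_mutations(cohort$mutations, paths["mutations"])
  write_cnv(cohort$cnv, paths["cnv"])
  write_gmt(list(cohort$truth$pos, cohort$truth$neg), paths["truth"])
  invisible(paths)
}
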