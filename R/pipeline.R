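# Orchestration: simulate -> select -> score -> evaluate, with TSV reports
# and a machine-readable JSON summary. Also the subgroup evaluation layer
# (global-median dichotomization applied inside every covariate level).

.log_msg <- function(..., logfile = NULL) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " [apscore] ", ...)
  message(msg)
  if (!is.null(logfile)) cat(msg, "\n", file = logfile, append = TRUE)
  invisible(NULL)
}

#' Log-rank comparison of high vs low score groups
#'
#' Convenience wrapper listing the high group first, so HR > 1 means worse
#' survival with a high score.
#'
#' @param labels named `"high"`/`"low"` vector.
#' @param clinical table with `sample_id`, `os_days`, `event`.
#' @return [logrank_test()] result.
#' @export
logrank_high_vs_low <- function(labels, clinical) {
  cl <- clinical[match(names(labels), clinical$sample_id), ]
  keep <- !is.na(cl$os_days) & !is.na(cl$event)
  cl <- cl[keep, ]; labels <- labels[keep]
  hi <- labels == "high"
  logrank_test(cl$os_days[hi], cl$event[hi],
               cl$os_days[!hi], cl$event[!hi])
}

#' Subgroup evaluation of the AP score
#'
#' Applies the cohort-wide median dichotomization of the AP score inside each
#' level of each clinical covariate: per level, the Kaplan-Meier log-rank
#' comparison of the (globally labelled) high vs low patients. Per covariate,
#' a composition test (high/low x level contingency table) and an ANOVA of
#' the AP score across levels.
#'
#' @param ap named AP score vector over tumour samples.
#' @param clinical [cohort_clinical()] table.
#' @param covariates covariate columns to stratify on.
#' @return list: `subgroups` (data.frame `covariate`, `level`, `n_high`,
#'   `n_low`, `chi2`, `p`, `hr`, `note`), `composition` (per-covariate
#'   contingency p), `distribution` (per-covariate ANOVA F and p).
#' @export
evaluate_subgroups <- function(ap, clinical,
                               covariates = c("grade", "idh", "mgmt",
                                              "subtype", "gender")) {
  stopifnot(!is.null(names(ap)))
  labels <- dichotomize_by_median(ap)
  cl <- clinical[match(names(ap), clinical$sample_id), ]
  sub_rows <- list(); comp_rows <- list(); dist_rows <- list()
  for (cov in covariates) {
    vals <- cl[[cov]]
    levels_present <- sort(unique(vals[!is.na(vals)]))
    for (lv in levels_present) {
      in_lv <- !is.na(vals) & vals == lv
      n_hi <- sum(in_lv & labels == "high")
      n_lo <- sum(in_lv & labels == "low")
      row <- data.frame(covariate = cov, level = lv, n_high = n_hi,
                        n_low = n_lo, chi2 = NA_real_, p = NA_real_,
                        hr = NA_real_, note = "", stringsAsFactors = FALSE)
      if (n_hi >= 2 && n_lo >= 2) {
        lr <- tryCatch(
          logrank_high_vs_low(labels[in_lv], cl[in_lv, ]),
          error = function(e) NULL)
        if (!is.null(lr)) {
          row$chi2 <- lr$chi2; row$p <- lr$p; row$hr <- lr$hr
        } else row$note <- "log-rank not estimable"
      } else row$note <- "fewer than 2 per arm"
      sub_rows[[length(sub_rows) + 1L]] <- row
    }
    ok <- !is.na(vals)
    if (length(levels_present) >= 2) {
      tab <- table(labels[ok], vals[ok])
      comp <- tryCatch(contingency_test(as.matrix(tab)),
                       error = function(e) NULL)
      comp_rows[[cov]] <- data.frame(
        covariate = cov,
        test = if (is.null(comp)) NA_character_ else comp$test,
        p = if (is.null(comp)) NA_real_ else comp$p,
        stringsAsFactors = FALSE)
      grps <- split(ap[ok], vals[ok])
      grps <- grps[lengths(grps) >= 2]
      if (length(grps) >= 2) {
        an <- anova_oneway(grps)
        dist_rows[[cov]] <- data.frame(covariate = cov, f = an$statistic,
                                       p = an$p, stringsAsFactors = FALSE)
      }
    }
  }
  list(subgroups = do.call(rbind, sub_rows),
       composition = do.call(rbind, c(comp_rows, list(make.row.names = FALSE))),
       distribution = do.call(rbind, c(dist_rows, list(make.row.names = FALSE))))
}

#' Run the full pipeline on a synthetic or user-provided cohort
#'
#' Stages: (1) simulate (or load) the cohort; (2) select the POS/NEG
#' signature (skipped when `signature` is supplied); (3) AP scoring;
#' (4) evaluation — cohort-wide log-rank and Cox, outcome ROC, subgroup
#' report, mutation and CNV comparisons. Every stage writes TSV into
#' `outdir` and the run ends with `summary.json`. Deterministic given
#' `config$seed`.
#'
#' @param outdir output directory.
#' @param config [synthetic_config()] for the simulated cohort.
#' @param cohort optional pre-built `synthetic_cohort` (overrides simulate).
#' @param signature optional [gene_set_pair()]; when given, selection is
#'   skipped and this signature is scored directly.
#' @param selection [selection_config()].
#' @param scoring [ssgsea_config()].
#' @return invisibly, the summary list (also written as JSON).
#' @export
run_pipeline <- function(outdir, config = synthetic_config(),
                         cohort = NULL, signature = NULL,
                         selection = selection_config(),
                         scoring = ssgsea_config()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(outdir, "run.log")
  summary <- list(seed = config$seed)
  stage <- "simulate"
  result <- tryCatch({
    if (is.null(cohort)) {
      .log_msg("simulate: seed ", config$seed, logfile = logfile)
      cohort <- generate_cohort(config)
    }
    write_cohort(cohort, file.path(outdir, "cohort"))
    cl <- cohort$clinical
    tumour <- cl$sample_id[cl$tissue_group != "NT"]
    .log_msg("cohort: ", nrow(cohort$expression), " genes, ",
             ncol(cohort$expression), " samples", logfile = logfile)

    stage <- "select"
    if (is.null(signature)) {
      pair <- select_progression_genes(cohort$expression, cl, selection)
      utils::write.table(attr(pair, "audit"),
                         file.path(outdir, "selection_audit.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    } else pair <- signature
    write_gmt(list(pair$pos, pair$neg), file.path(outdir, "signature.gmt"))
    summary$signature <- list(n_pos = length(pair$pos$genes),
                              n_neg = length(pair$neg$genes))
    .log_msg("signature: ", length(pair$pos$genes), " POS / ",
             length(pair$neg$genes), " NEG", logfile = logfile)

    stage <- "score"
    scores <- ap_score(cohort$expression[, tumour, drop = FALSE], pair,
                       scoring)
    utils::write.table(scores, file.path(outdir, "ap_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ap <- stats::setNames(scores$ap_score, scores$sample_id)

    stage <- "evaluate"
    labels <- dichotomize_by_median(ap)
    lr <- logrank_high_vs_low(labels, cl)
    cl_t <- cl[match(tumour, cl$sample_id), ]
    cox <- cox_fit(cl_t$os_days, cl_t$event,
                   cbind(high_ap = as.numeric(labels == "high")))
    km_hi <- km_estimate(cl_t$os_days[labels == "high"],
                         cl_t$event[labels == "high"])
    km_lo <- km_estimate(cl_t$os_days[labels == "low"],
                         cl_t$event[labels == "low"])
    roc <- tryCatch(roc_auc_outcome(ap, cl_t), error = function(e) NULL)
    subgroups <- evaluate_subgroups(ap, cl)
    utils::write.table(subgroups$subgroups,
                       file.path(outdir, "subgroup_logrank.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    mut <- compare_mutation_freq(cohort$mutations, labels)
    utils::write.table(mut, file.path(outdir, "mutation_enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cnv <- compare_cnv(cohort$cnv, labels)
    utils::write.table(cnv, file.path(outdir, "cnv_comparison.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    summary$logrank <- list(chi2 = lr$chi2, p = lr$p, hr = lr$hr)
    summary$cox <- as.list(cox$coefficients[1, c("beta", "hr", "se",
                                                 "wald_p")])
    summary$median_survival <- list(high = km_hi$median_survival,
                                    low = km_lo$median_survival)
    if (!is.null(roc))
      summary$roc <- list(auc = roc$auc, n_pos = roc$n_pos,
                          n_neg = roc$n_neg, n_excluded = roc$n_excluded)
    summary$distribution <- subgroups$distribution
    summary$composition <- subgroups$composition
    summary$mutation <- mut
    summary$cnv <- cnv
    summary
  }, error = function(e) {
    manifest <- list(failed_stage = stage, error = conditionMessage(e),
                     partial = summary)
    jsonlite::write_json(manifest, file.path(outdir, "failure.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  jsonlite::write_json(result, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       dataframe = "rows")
  .log_msg("done: ", file.path(outdir, "summary.json"), logfile = logfile)
  invisible(result)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `select-genes`, `score`, `survival`, `run-all`.
#' Used by the `exec/apscore` script; callable directly with a character
#' vector of arguments.
#'
#' @param args character vector, e.g. `c("run-all", "--outdir", "out",
#'   "--seed", "7")`.
#' @return invisibly, the subcommand's result.
#' @export
apscore_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: apscore <command> [options]",
    "  simulate     --outdir DIR [--seed INT]",
    "  select-genes --expression TSV --clinical TSV --outdir DIR",
    "  score        --expression TSV --outdir DIR [--gmt GMT]",
    "  survival     --scores TSV --clinical TSV --outdir DIR",
    "  run-all      --outdir DIR [--seed INT]",
    sep = "\n")
  if (!length(args)) { message(usage); return(invisible(NULL)) }
  cmd <- args[1]
  opts <- list()
  rest <- args[-1]
  while (length(rest)) {
    if (!startsWith(rest[1], "--") || length(rest) < 2)
      stop("malformed option near '", rest[1], "'\n", usage)
    opts[[substring(rest[1], 3)]] <- rest[2]
    rest <- rest[-(1:2)]
  }
  need <- function(k) {
    if (is.null(opts[[k]])) stop("missing required option --", k)
    opts[[k]]
  }
  seed <- as.integer(if (is.null(opts$seed)) 1L else opts$seed)
  switch(cmd,
    "simulate" = {
      cohort <- generate_cohort(synthetic_config(seed = seed))
      invisible(write_cohort(cohort, need("outdir")))
    },
    "select-genes" = {
      expr <- read_expression(need("expression"))
      cl <- read_clinical(need("clinical"))
      pair <- select_progression_genes(expr, cl)
      dir.create(need("outdir"), showWarnings = FALSE, recursive = TRUE)
      write_gmt(list(pair$pos, pair$neg),
                file.path(opts$outdir, "signature.gmt"))
      utils::write.table(attr(pair, "audit"),
                         file.path(opts$outdir, "selection_audit.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      invisible(pair)
    },
    "score" = {
      expr <- read_expression(need("expression"))
      pair <- if (is.null(opts$gmt)) ap_signature() else {
        sets <- read_gmt(opts$gmt)
        gene_set_pair(sets[[1]], sets[[2]])
      }
      scores <- ap_score(expr, pair)
      dir.create(need("outdir"), showWarnings = FALSE, recursive = TRUE)
      utils::write.table(scores, file.path(opts$outdir, "ap_scores.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      invisible(scores)
    },
    "survival" = {
      scores <- .read_tsv(need("scores"))
      cl <- read_clinical(need("clinical"))
      ap <- stats::setNames(scores$ap_score, scores$sample_id)
      labels <- dichotomize_by_median(ap)
      lr <- logrank_high_vs_low(labels, cl)
      dir.create(need("outdir"), showWarnings = FALSE, recursive = TRUE)
      out <- data.frame(chi2 = lr$chi2, p = lr$p, hr = lr$hr, o1 = lr$o1,
                        e1 = lr$e1, o2 = lr$o2, e2 = lr$e2)
      utils::write.table(out, file.path(opts$outdir, "logrank.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      invisible(lr)
    },
    "run-all" = {
      invisible(run_pipeline(need("outdir"),
                             synthetic_config(seed = seed)))
    },
    stop("unknown command '", cmd, "'\n", usage))
}
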