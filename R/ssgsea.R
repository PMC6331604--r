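# Single-sample gene-set enrichment (ssGSEA) and the AP score.
#
# The enrichment score is the accumulated difference between a rank-weighted
# in-set ECDF and the uniform out-of-set ECDF, summed over all positions of
# the sample's decreasing-rank gene ordering:
#   ES = sum_i [ P_in(i) - P_out(i) ],
#   P_in(i)  = sum_{k<=i, k in S} r_k^alpha / sum_{k in S} r_k^alpha
#   P_out(i) = #{k<=i, k not in S} / (N - |S|)
# with r_k the within-sample rank (1..N, ties averaged) of gene k.

#' ssGSEA configuration
#'
#' @param alpha rank-weight exponent applied to within-sample ranks
#'   (default 0.25, the customary single-sample GSEA weight). `alpha = 0`
#'   weights all set genes equally.
#' @param normalize if `TRUE` (default) divide raw scores by the global
#'   (max - min) range over all entries of the score matrix.
#' @return list of class `ssgsea_config`.
#' @export
ssgsea_config <- function(alpha = 0.25, normalize = TRUE) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha >= 0,
            is.logical(normalize), length(normalize) == 1L)
  structure(list(alpha = alpha, normalize = normalize),
            class = "ssgsea_config")
}

#' Within-sample rank transform
#'
#' Ranks 1..N with N the highest expression; ties receive the average rank.
#'
#' @param sample_values numeric vector of one sample's expression (>= 2 genes),
#'   all finite.
#' @return numeric vector of ranks, names preserved.
#' @export
rank_transform <- function(sample_values) {
  if (length(sample_values) < 2L) stop("need at least 2 genes to rank")
  if (!all(is.finite(sample_values))) stop("non-finite expression value")
  rank(sample_values, ties.method = "average")
}

#' Raw ssGSEA enrichment score for one sample and one set
#'
#' @param ranks named numeric vector of within-sample ranks
#'   (see [rank_transform()]).
#' @param set_genes character vector of set member symbols.
#' @param alpha rank-weight exponent.
#' @return raw enrichment score (single number).
#' @export
ssgsea_es <- function(ranks, set_genes, alpha = 0.25) {
  if (is.null(names(ranks))) stop("ranks must be named by gene")
  in_set <- names(ranks) %in% set_genes
  n_in <- sum(in_set)
  if (n_in == 0L) stop("gene set has no overlap with the ranked genes")
  if (n_in == length(ranks)) stop("gene set covers the whole universe")
  # decreasing rank; ties broken by gene symbol so the walk is deterministic
  # and independent of input gene order
  ord <- order(-ranks, names(ranks), method = "radix")
  r <- ranks[ord]
  inS <- in_set[ord]
  w <- ifelse(inS, r^alpha, 0)
  p_in <- cumsum(w) / sum(w)
  p_out <- cumsum(!inS) / (length(r) - n_in)
  sum(p_in - p_out)
}

#' ssGSEA score matrix
#'
#' Scores every gene set against every sample. With `normalize = TRUE` each
#' raw entry is divided by the (max - min) range over *all* entries of the raw
#' matrix, putting all sets and samples on one comparable scale.
#'
#' @param expr gene-by-sample expression matrix.
#' @param gene_sets list of [gene_set()] objects (a single set is accepted).
#' @param config [ssgsea_config()].
#' @return sets-by-samples numeric matrix; attribute `"normalized"` records
#'   whether range normalization was applied.
#' @export
ssgsea_matrix <- function(expr, gene_sets, config = ssgsea_config()) {
  expr <- expression_matrix(expr)
  if (inherits(gene_sets, "gene_set")) gene_sets <- list(gene_sets)
  stopifnot(length(gene_sets) >= 1L, inherits(config, "ssgsea_config"))
  universe <- rownames(expr)
  members <- lapply(gene_sets, match_gene_set, universe = universe)
  empty <- lengths(members) == 0L
  if (any(empty))
    stop("gene set(s) with no overlap: ",
         paste(vapply(gene_sets[empty], function(s) s$name, ""), collapse = ", "))
  es <- matrix(NA_real_, nrow = length(gene_sets), ncol = ncol(expr),
               dimnames = list(vapply(gene_sets, function(s) s$name, ""),
                               colnames(expr)))
  for (j in seq_len(ncol(expr))) {
    r <- rank_transform(expr[, j])
    for (i in seq_along(gene_sets))
      es[i, j] <- ssgsea_es(r, members[[i]], config$alpha)
  }
  if (config$normalize) {
    rng <- max(es) - min(es)
    if (rng == 0) stop("cannot normalize: all enrichment scores are equal")
    es <- es / rng
  }
  attr(es, "normalized") <- config$normalize
  es
}

#' Per-sample AP score
#'
#' Scores the POS and NEG progression sets jointly (one shared normalization
#' range, so their difference lives on a single scale) and returns
#' AP = POS score - NEG score per sample.
#'
#' @param expr gene-by-sample log2 expression matrix.
#' @param pair a [gene_set_pair()].
#' @param config [ssgsea_config()].
#' @return data.frame with columns `sample_id`, `pos_score`, `neg_score`,
#'   `ap_score`; attribute `"normalized"`.
#' @export
ap_score <- function(expr, pair, config = ssgsea_config()) {
  stopifnot(inherits(pair, "gene_set_pair"))
  es <- ssgsea_matrix(expr, list(pair$pos, pair$neg), config)
  out <- data.frame(sample_id = colnames(es),
                    pos_score = es[1, ],
                    neg_score = es[2, ],
                    ap_score = es[1, ] - es[2, ],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "normalized") <- attr(es, "normalized")
  out
}

#' The published 18-gene astrocytoma progression signature
#'
#' Returns the POS/NEG gene-set pair shipped with the package
#' (`inst/extdata/ap_signature.gmt`), for scoring real expression data.
#' Symbols are recorded verbatim as published; a few are atypical and may
#' need mapping to the user's annotation.
#'
#' @return a [gene_set_pair()].
#' @export
ap_signature <- function() {
  path <- system.file("extdata", "ap_signature.gmt", package = "apscore",
                      mustWork = TRUE)
  sets <- read_gmt(path)
  gene_set_pair(sets[["POS_AP"]], sets[["NEG_AP"]])
}
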