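# ---- domain containers ------------------------------------------------------

#' Construct a validated expression matrix
#'
#' An expression matrix is a plain numeric matrix of log2-scale expression with
#' unique gene symbols as rownames and unique sample identifiers as colnames.
#' The same container is used for gene-level copy-number estimates (where 0 is
#' copy-neutral, negative values are deletions and positive values
#' amplifications).
#'
#' @param values numeric matrix, genes in rows, samples in columns.
#' @param gene_ids character vector of unique gene symbols (default: existing
#'   rownames).
#' @param sample_ids character vector of unique sample identifiers (default:
#'   existing colnames).
#' @return the validated matrix with dimnames set.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("expression values must be a numeric matrix")
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("gene and sample identifiers are required")
  if (length(gene_ids) != nrow(values) || length(sample_ids) != ncol(values))
    stop("dimension mismatch between values and identifiers")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (!all(is.finite(values)))
    stop("expression values must all be finite")
  dimnames(values) <- list(as.character(gene_ids), as.character(sample_ids))
  values
}

#' Construct a gene set
#'
#' @param name set name (e.g. "POS_AP").
#' @param genes character vector of member gene symbols; duplicates are an
#'   error, as is an empty set.
#' @return object of class `gene_set` with elements `name` and `genes`.
#' @export
gene_set <- function(name, genes) {
  genes <- as.character(genes)
  if (length(name) != 1L || !nzchar(name)) stop("gene set needs a single non-empty name")
  if (length(genes) == 0L) stop("gene set '", name, "' is empty")
  if (anyDuplicated(genes)) stop("gene set '", name, "' has duplicate members")
  structure(list(name = as.character(name), genes = genes), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("<gene_set> ", x$name, ": ", length(x$genes), " genes\n", sep = "")
  invisible(x)
}

#' Construct the POS/NEG signature pair
#'
#' @param pos,neg `gene_set` objects for the positively and negatively
#'   progression-associated genes. Must be disjoint and non-empty.
#' @return object of class `gene_set_pair`.
#' @export
gene_set_pair <- function(pos, neg) {
  stopifnot(inherits(pos, "gene_set"), inherits(neg, "gene_set"))
  ov <- intersect(pos$genes, neg$genes)
  if (length(ov))
    stop("POS and NEG sets overlap: ", paste(ov, collapse = ", "))
  structure(list(pos = pos, neg = neg), class = "gene_set_pair")
}

#' @export
print.gene_set_pair <- function(x, ...) {
  cat("<gene_set_pair> pos=", x$pos$name, " (", length(x$pos$genes),
      "), neg=", x$neg$name, " (", length(x$neg$genes), ")\n", sep = "")
  invisible(x)
}

# valid category levels for the clinical table
.clinical_levels <- list(
  tissue_group = c("NT", "LGG", "GBM"),
  gender  = c("F", "M"),
  grade   = c("II", "III", "IV"),
  idh     = c("mutant", "wildtype"),
  mgmt    = c("methylated", "unmethylated"),
  subtype = c("CL", "NE", "ME", "PN"),
  chemo   = c("yes", "no"),
  radio   = c("yes", "no")
)

.clinical_columns <- c("sample_id", "tissue_group", "os_days", "event", "age",
                       "gender", "grade", "idh", "mgmt", "subtype", "chemo",
                       "radio")

#' Validate a cohort clinical table
#'
#' Checks the fixed column set, category levels, non-negative survival and
#' 0/1 events. Normal-tissue (NT) rows must carry no survival information.
#'
#' @param df data.frame with columns `sample_id`, `tissue_group`, `os_days`,
#'   `event`, `age`, `gender`, `grade`, `idh`, `mgmt`, `subtype`, `chemo`,
#'   `radio`. `NA` marks missing optional covariates.
#' @return the validated data.frame (character sample ids, numeric survival).
#' @export
cohort_clinical <- function(df) {
  missing_cols <- setdiff(.clinical_columns, names(df))
  if (length(missing_cols))
    stop("clinical table lacks columns: ", paste(missing_cols, collapse = ", "))
  df <- df[, .clinical_columns]
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in clinical table")
  for (col in names(.clinical_levels)) {
    vals <- as.character(df[[col]])
    bad <- !is.na(vals) & !(vals %in% .clinical_levels[[col]])
    if (any(bad))
      stop("invalid ", col, " value(s): ",
           paste(unique(vals[bad]), collapse = ", "))
    df[[col]] <- vals
  }
  if (any(is.na(df$tissue_group))) stop("tissue_group is required for every sample")
  df$os_days <- as.numeric(df$os_days)
  df$event <- suppressWarnings(as.numeric(df$event))
  df$age <- as.numeric(df$age)
  if (any(!is.na(df$os_days) & df$os_days < 0))
    stop("os_days must be non-negative")
  if (any(!is.na(df$event) & !(df$event %in% c(0, 1))))
    stop("event must be 0 or 1")
  nt <- df$tissue_group == "NT"
  if (any(nt & (!is.na(df$os_days) | !is.na(df$event))))
    stop("NT samples must not carry survival data")
  rownames(df) <- NULL
  df
}

#' Validate a mutation table
#'
#' @param df data.frame with columns `sample_id`, `gene`, `mutated`
#'   (logical or 0/1); one record per (sample, gene) pair.
#' @return validated data.frame with logical `mutated`.
#' @export
mutation_table <- function(df) {
  need <- c("sample_id", "gene", "mutated")
  if (!all(need %in% names(df)))
    stop("mutation table needs columns: ", paste(need, collapse = ", "))
  df <- df[, need]
  df$sample_id <- as.character(df$sample_id)
  df$gene <- as.character(df$gene)
  mut <- df$mutated
  if (is.character(mut)) mut <- as.logical(toupper(mut) %in% c("TRUE", "1") |
                                             as.numeric(mut) == 1)
  df$mutated <- as.logical(mut)
  if (any(is.na(df$mutated))) stop("mutated must be TRUE/FALSE or 0/1")
  if (anyDuplicated(df[, c("sample_id", "gene")]))
    stop("duplicate (sample, gene) records in mutation table")
  rownames(df) <- NULL
  df
}

# ---- TSV / GMT readers and writers ------------------------------------------

.read_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    na.strings = "NA", check.names = FALSE,
                    stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Read / write a gene-by-sample numeric matrix as TSV
#'
#' Format: tab-separated, UTF-8, no quoting; first column holds gene symbols,
#' header row holds sample identifiers, body is numeric.
#'
#' @param path file path.
#' @return numeric matrix (see [expression_matrix()]).
#' @export
read_expression <- function(path) {
  df <- .read_tsv(path)
  if (ncol(df) < 2) stop("expression TSV needs a gene column plus >=1 sample")
  genes <- as.character(df[[1]])
  body <- df[, -1, drop = FALSE]
  for (j in seq_along(body)) {
    v <- body[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad))
        stop("non-numeric cell at row ", bad[1], " (gene ", genes[bad[1]],
             "), column '", names(body)[j], "'")
      v <- num
    }
    body[[j]] <- v
  }
  expression_matrix(as.matrix(body), gene_ids = genes,
                    sample_ids = names(body))
}

#' @rdname read_expression
#' @param m numeric gene-by-sample matrix with dimnames.
#' @export
write_expression <- function(m, path) {
  m <- expression_matrix(m)
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write CNV matrices
#'
#' Same genes-in-rows TSV dialect as [read_expression()]; values are
#' gene-level copy-number estimates.
#' @param path file path.
#' @export
read_cnv <- function(path) read_expression(path)

#' @rdname read_cnv
#' @param m CNV matrix.
#' @export
write_cnv <- function(m, path) write_expression(m, path)

#' Read / write gene sets in GMT format
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' members. The description is ignored on read and written as `"na"`.
#'
#' @param path file path.
#' @return list of [gene_set()] objects.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3)
      stop("GMT line ", i, " has fewer than 3 tab-separated fields")
    sets[[i]] <- gene_set(parts[1], parts[-(1:2)])
  }
  names(sets) <- vapply(sets, function(s) s$name, character(1))
  sets
}

#' @rdname read_gmt
#' @param sets list of `gene_set` objects.
#' @export
write_gmt <- function(sets, path) {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  lines <- vapply(sets, function(s) {
    stopifnot(inherits(s, "gene_set"))
    paste(c(s$name, "na", s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read / write clinical, mutation tables
#'
#' Clinical: one sample per row with the fixed headers documented in
#' [cohort_clinical()]. Mutations: long table with `sample_id`, `gene`,
#' `mutated`.
#'
#' @param path file path.
#' @export
read_clinical <- function(path) cohort_clinical(.read_tsv(path))

#' @rdname read_clinical
#' @param df clinical data.frame.
#' @export
write_clinical <- function(df, path) {
  df <- cohort_clinical(df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname read_clinical
#' @export
read_mutations <- function(path) mutation_table(.read_tsv(path))

#' @rdname read_clinical
#' @export
write_mutations <- function(df, path) {
  df <- mutation_table(df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Match a gene set against a matrix universe
#'
#' Gene identity is the literal case-sensitive symbol. Members absent from the
#' matrix are dropped with a warning listing them.
#'
#' @param set a `gene_set`.
#' @param universe character vector of gene symbols present in the data.
#' @return the intersection, in universe order.
#' @export
match_gene_set <- function(set, universe) {
  stopifnot(inherits(set, "gene_set"))
  hit <- set$genes[set$genes %in% universe]
  miss <- setdiff(set$genes, universe)
  if (length(miss))
    warning("gene set '", set$name, "': ", length(miss),
            " symbol(s) not in matrix, dropped: ",
            paste(utils::head(miss, 10), collapse = ", "),
            if (length(miss) > 10) ", ..." else "")
  hit
}
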