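#' @importFrom stats sd
NULL

# Canonical clinical schema: 4 binary + 10 continuous cardiovascular risk factors.
.BINARY_COVARIATES <- c("sex", "renal_failure", "smoker", "diabetes")
.CONTINUOUS_COVARIATES <- c("age", "bmi", "heart_rate", "dbp", "sbp",
                            "glucose", "triglyceride", "creatinine", "hdl", "ldl")

#' Clinical covariate names
#'
#' Names of the covariates a [read_clinical_table()] table must carry:
#' four binary risk factors (coded 0/1) and ten continuous ones.
#'
#' @return A list with elements `binary` and `continuous`.
#' @export
clinical_covariates <- function() {
  list(binary = .BINARY_COVARIATES, continuous = .CONTINUOUS_COVARIATES)
}

#' Construct a validated expression matrix
#'
#' Container for a genes x samples matrix of log2 intensities with per-sample
#' condition ("baseline" or "stimulated") and patient annotations.
#'
#' @param values Numeric matrix, genes in rows, samples in columns; dimnames
#'   required and unique.
#' @param condition Named character vector mapping sample id to
#'   `"baseline"` or `"stimulated"`.
#' @param patient_id Named character vector mapping sample id to a patient id.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `condition`, `patient_id`.
#' @export
expression_matrix <- function(values, condition, patient_id) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  gid <- rownames(values); sid <- colnames(values)
  if (is.null(gid) || is.null(sid))
    stop("`values` must have row (gene) and column (sample) names", call. = FALSE)
  dup <- gid[duplicated(gid)]
  if (length(dup)) stop("duplicate gene id(s): ", paste(unique(dup), collapse = ", "), call. = FALSE)
  dup <- sid[duplicated(sid)]
  if (length(dup)) stop("duplicate sample id(s): ", paste(unique(dup), collapse = ", "), call. = FALSE)
  if (any(!is.finite(values)))
    stop("expression values must all be finite", call. = FALSE)
  missing_ann <- setdiff(sid, intersect(names(condition), names(patient_id)))
  if (length(missing_ann))
    stop("sample(s) lacking condition/patient annotation: ",
         paste(missing_ann, collapse = ", "), call. = FALSE)
  condition <- condition[sid]; patient_id <- as.character(patient_id[sid])
  names(patient_id) <- sid
  bad <- !condition %in% c("baseline", "stimulated")
  if (any(bad))
    stop("condition must be 'baseline' or 'stimulated'; offending sample(s): ",
         paste(sid[bad], collapse = ", "), call. = FALSE)
  key <- paste(patient_id, condition)
  if (anyDuplicated(key))
    stop("more than one sample for (patient, condition): ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  structure(list(values = values, condition = condition, patient_id = patient_id),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (%d baseline, %d stimulated)\n",
              nrow(x$values), ncol(x$values),
              sum(x$condition == "baseline"), sum(x$condition == "stimulated")))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Read a genes x samples expression TSV
#'
#' The TSV holds gene ids in the first column and sample ids in the header.
#' Sample condition and patient annotations come either from a sidecar TSV
#' (columns `sample_id`, `condition`, optionally `patient_id`) or, when no
#' sidecar is given, from sample names following the
#' `<patient>_<condition>` convention. A sidecar wins over the naming
#' convention when both are available.
#'
#' @param path Path to the expression TSV.
#' @param condition_map Optional path to the sidecar annotation TSV.
#' @return An [expression_matrix()] object; row and column order preserved.
#' @export
read_expression_matrix <- function(path, condition_map = NULL) {
  head_fields <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  sample_ids <- head_fields[-1]
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup))
    stop("duplicate sample id(s) in header of ", path, ": ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character", quote = "")
  gene_ids <- raw[[1]]
  vals <- as.matrix(raw[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(vals), nrow = nrow(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)[1, , drop = TRUE]
    stop(sprintf("non-numeric value at gene '%s', sample '%s' in %s",
                 gene_ids[bad[1]], sample_ids[bad[2]], path), call. = FALSE)
  }
  dimnames(num) <- list(gene_ids, sample_ids)

  if (!is.null(condition_map)) {
    ann <- utils::read.table(condition_map, header = TRUE, sep = "\t",
                             check.names = FALSE, colClasses = "character", quote = "")
    if (!all(c("sample_id", "condition") %in% names(ann)))
      stop("annotation sidecar needs columns sample_id, condition", call. = FALSE)
    condition <- stats::setNames(ann$condition, ann$sample_id)
    patient_id <- if ("patient_id" %in% names(ann))
      stats::setNames(ann$patient_id, ann$sample_id)
    else .annotation_from_names(ann$sample_id)$patient_id
  } else {
    parsed <- .annotation_from_names(sample_ids)
    condition <- parsed$condition
    patient_id <- parsed$patient_id
  }
  expression_matrix(num, condition, patient_id)
}

# Parse "<patient>_<condition>" sample names (condition = final underscore field).
.annotation_from_names <- function(sample_ids) {
  pos <- regexpr("_[^_]*$", sample_ids)
  ok <- pos > 0
  if (!all(ok))
    stop("sample name(s) not of the form <patient>_<condition>: ",
         paste(sample_ids[!ok], collapse = ", "), call. = FALSE)
  cond <- substring(sample_ids, pos + 1L)
  pat <- substring(sample_ids, 1L, pos - 1L)
  list(condition = stats::setNames(cond, sample_ids),
       patient_id = stats::setNames(pat, sample_ids))
}

#' Write an expression matrix as TSV (with annotation sidecar)
#'
#' @param expr An `ExpressionMatrix`.
#' @param path Output TSV path.
#' @param annotation_path Optional sidecar path; defaults to
#'   `<path>.annotation.tsv`.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(expr, path,
                                    annotation_path = paste0(path, ".annotation.tsv")) {
  df <- data.frame(gene_id = rownames(expr$values), expr$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  ann <- data.frame(sample_id = colnames(expr$values),
                    condition = unname(expr$condition),
                    patient_id = unname(expr$patient_id),
                    stringsAsFactors = FALSE)
  utils::write.table(ann, annotation_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a clinical risk-factor table
#'
#' One row per patient. Requires a `patient_id` column plus the 14 covariates
#' listed by [clinical_covariates()] (case-insensitive match). Binary columns
#' accept 0/1 or yes/no (any case); missing values are preserved as `NA`.
#'
#' @param path Path to a CSV or TSV file (delimiter sniffed from the header).
#' @return A `data.frame` of class `ClinicalTable` with canonical lower-case
#'   column names.
#' @export
read_clinical_table <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"")
  names(df) <- tolower(names(df))
  required <- c("patient_id", .BINARY_COVARIATES, .CONTINUOUS_COVARIATES)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("clinical table missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df$patient_id <- as.character(df$patient_id)
  if (anyDuplicated(df$patient_id))
    stop("duplicate patient_id(s): ",
         paste(unique(df$patient_id[duplicated(df$patient_id)]), collapse = ", "),
         call. = FALSE)
  for (col in .BINARY_COVARIATES) {
    v <- df[[col]]
    if (is.character(v)) {
      lv <- tolower(trimws(v))
      out <- ifelse(lv %in% c("yes", "1", "true"), 1L,
                    ifelse(lv %in% c("no", "0", "false"), 0L, NA_integer_))
      bad <- !is.na(v) & v != "" & is.na(out)
      if (any(bad))
        stop(sprintf("column '%s': cannot coerce value(s) %s to binary", col,
                     paste(unique(v[bad]), collapse = ", ")), call. = FALSE)
      df[[col]] <- out
    } else {
      if (any(!v %in% c(0, 1, NA)))
        stop(sprintf("column '%s': binary values must be 0/1", col), call. = FALSE)
      df[[col]] <- as.integer(v)
    }
  }
  for (col in .CONTINUOUS_COVARIATES) df[[col]] <- as.numeric(df[[col]])
  for (col in c("dbp", "sbp")) {
    v <- df[[col]]
    if (any(!is.na(v) & v <= 0))
      stop(sprintf("column '%s' must be strictly positive", col), call. = FALSE)
  }
  class(df) <- c("ClinicalTable", "data.frame")
  df
}

#' Write a clinical table
#'
#' @param clin A `ClinicalTable`.
#' @param path Output path; written as TSV.
#' @return `path`, invisibly.
#' @export
write_clinical_table <- function(clin, path) {
  utils::write.table(as.data.frame(clin), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, fields `name`, `description`, then members,
#' tab-separated. Duplicate members within a line are dropped.
#'
#' @param path Path to the GMT file.
#' @return A named list of character vectors of class `GeneSetCollection`,
#'   with the source path in attribute `source`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  nm <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop(sprintf("GMT line %d has fewer than 3 fields", i), call. = FALSE)
    nm[i] <- fields[1]
    sets[[i]] <- unique(fields[-(1:2)])
  }
  if (anyDuplicated(nm))
    stop("duplicate gene-set name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  names(sets) <- nm
  structure(sets, source = path, class = "GeneSetCollection")
}

#' Write a GMT gene-set collection
#'
#' @param sets Named list of character vectors (or `GeneSetCollection`).
#' @param path Output path.
#' @param description Description field written for every set.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write a weighted network as SIF or edge TSV
#'
#' Edges are written in deterministic lexicographic (source, target) order.
#' The TSV dialect has columns `source`, `target`, `weight`, `sign`; the SIF
#' dialect writes `source<TAB>interaction<TAB>target`.
#'
#' @param edges Data frame with columns `source`, `target`, `weight`, and
#'   optionally `sign`; or an igraph graph with a `weight` edge attribute.
#' @param path Output path.
#' @param dialect `"tsv"` or `"sif"`.
#' @param interaction SIF interaction type label.
#' @return `path`, invisibly.
#' @export
write_edge_table <- function(edges, path, dialect = c("tsv", "sif"),
                             interaction = "cor") {
  dialect <- match.arg(dialect)
  if (inherits(edges, "igraph")) {
    el <- igraph::as_edgelist(edges, names = TRUE)
    w <- igraph::E(edges)$weight
    s <- if ("sign" %in% igraph::edge_attr_names(edges)) igraph::E(edges)$sign
         else rep(NA_real_, nrow(el))
    edges <- data.frame(source = el[, 1], target = el[, 2], weight = w, sign = s,
                        stringsAsFactors = FALSE)
  }
  if (!"sign" %in% names(edges)) edges$sign <- rep(NA_real_, nrow(edges))
  ord <- order(edges$source, edges$target, method = "radix")
  edges <- edges[ord, , drop = FALSE]
  if (dialect == "sif") {
    writeLines(paste(edges$source, interaction, edges$target, sep = "\t"),
               path, useBytes = TRUE)
  } else {
    utils::write.table(edges[, c("source", "target", "weight", "sign")], path,
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Read an edge TSV written by [write_edge_table()]
#'
#' @param path Path to the TSV.
#' @return Data frame with columns `source`, `target`, `weight`, `sign`.
#' @export
read_edge_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = c("character", "character", "numeric", "numeric"))
}

#' Summarize a clinical cohort
#'
#' Binary covariates are reported as count and percentage of all patients
#' (2-decimal rounding); continuous covariates as mean and sample standard
#' deviation over non-missing values.
#'
#' @param clin A `ClinicalTable`.
#' @return A list with `n_patients`, a `binary` data frame
#'   (`covariate`, `count`, `percentage`) and a `continuous` data frame
#'   (`covariate`, `mean`, `sd`, `n`).
#' @export
summarize_cohort <- function(clin) {
  if (nrow(clin) == 0) stop("clinical table is empty", call. = FALSE)
  n <- nrow(clin)
  bin <- do.call(rbind, lapply(.BINARY_COVARIATES, function(col) {
    cnt <- sum(clin[[col]] == 1, na.rm = TRUE)
    data.frame(covariate = col, count = cnt,
               percentage = round(100 * cnt / n, 2),
               stringsAsFactors = FALSE)
  }))
  cont <- do.call(rbind, lapply(.CONTINUOUS_COVARIATES, function(col) {
    v <- clin[[col]][!is.na(clin[[col]])]
    data.frame(covariate = col,
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) sd(v) else NA_real_,
               n = length(v), stringsAsFactors = FALSE)
  }))
  list(n_patients = n, binary = bin, continuous = cont)
}
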