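#' Read and write cohort tables
#'
#' A cohort CSV carries one row per patient with the documented header:
#' `patient_id`, the four density columns (`cd3_ct`, `cd3_im`, `cd8_ct`,
#' `cd8_im`, cells/mm^2), the binary covariates (`organ_confined`, `lvi`,
#' `margin`, `intravesical`, `chemo`), `nac_response`, `os_months`,
#' `os_event`, `dfs_months`, `dfs_event`. Extra columns are preserved.
#'
#' @param cohort data.frame as produced by [generate_cohort()].
#' @param path File path.
#' @return `read_cohort()` returns the cohort data.frame; `write_cohort()`
#'   returns `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  .assert(is.data.frame(cohort), "`cohort` must be a data.frame")
  write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  cohort <- read.csv(path, stringsAsFactors = FALSE)
  .assert(all(TIL_COMPARTMENTS %in% names(cohort)),
          "cohort file must contain the four density columns")
  cohort
}

#' Read and write expression matrices, sample labels and gene sets
#'
#' The expression TSV has a `gene_id` first column and one column per
#' sample; labels are a two-column TSV (`sample_id`, `subtype`); gene sets
#' are plain text, one gene ID per line.
#'
#' @param expression Numeric genes x samples matrix.
#' @param labels data.frame with `sample_id` and `subtype` columns.
#' @param gene_set Character vector of gene IDs.
#' @param path File path.
#' @return The readers return the parsed object; the writers return `path`
#'   invisibly.
#' @export
write_expression_matrix <- function(expression, path) {
  .assert(is.matrix(expression) && !is.null(rownames(expression)),
          "`expression` must be a matrix with gene-ID rownames")
  df <- data.frame(gene_id = rownames(expression), expression,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_expression_matrix
#' @export
read_expression_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  .assert("gene_id" %in% names(df), "expression TSV needs a gene_id column")
  m <- as.matrix(df[, setdiff(names(df), "gene_id"), drop = FALSE])
  rownames(m) <- df$gene_id
  m
}

#' @rdname write_expression_matrix
#' @export
write_sample_labels <- function(labels, path) {
  .assert(all(c("sample_id", "subtype") %in% names(labels)),
          "`labels` needs sample_id and subtype columns")
  write.table(labels[, c("sample_id", "subtype")], path, sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_expression_matrix
#' @export
read_sample_labels <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  .assert(all(c("sample_id", "subtype") %in% names(df)),
          "labels TSV needs sample_id and subtype columns")
  df
}

#' @rdname write_expression_matrix
#' @export
write_gene_set <- function(gene_set, path) {
  writeLines(as.character(gene_set), path)
  invisible(path)
}

#' @rdname write_expression_matrix
#' @export
read_gene_set <- function(path) {
  ids <- readLines(path)
  ids[nzchar(ids)]
}

#' Serialize and restore a simulation configuration as JSON
#'
#' @param config A [sim_config()] object.
#' @param path File path.
#' @return `read_sim_config()` returns a `til_sim_config`;
#'   `write_sim_config()` returns `path` invisibly.
#' @export
write_sim_config <- function(config, path) {
  .assert(inherits(config, "til_sim_config"),
          "`config` must be created by sim_config()")
  out <- unclass(config)
  for (nm in c("density_meanlog", "density_sdlog", "true_cutoffs",
               "true_log_hr", "covariate_prevalence", "covariate_log_hr")) {
    out[[nm]] <- as.list(out[[nm]])      # keep names in the JSON objects
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE,
                       digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$density_cor <- if (is.matrix(raw$density_cor)) raw$density_cor
                     else matrix(unlist(raw$density_cor), 4, 4, byrow = TRUE)
  for (nm in c("density_meanlog", "density_sdlog", "true_cutoffs",
               "true_log_hr", "covariate_prevalence", "covariate_log_hr")) {
    raw[[nm]] <- unlist(raw[[nm]])
  }
  do.call(sim_config, raw)
}
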