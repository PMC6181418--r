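#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Step-up false-discovery-rate q-values: sort p ascending, set
#' q(i) = min over j >= i of m * p(j) / j, cap at 1, return in the original
#' order. Delegates to [stats::p.adjust()] after validating the inputs.
#'
#' @param p_values Numeric p-values, each in (0, 1].
#' @return q-values in the input order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04, 0.05)) # all 0.05
#' @export
bh_adjust <- function(p_values) {
  .assert(length(p_values) >= 1, "`p_values` must be non-empty")
  .assert(is.numeric(p_values) && all(is.finite(p_values)) &&
            all(p_values > 0) && all(p_values <= 1),
          "all p-values must lie in (0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Two-group differential expression on a log-scale matrix
#'
#' Per-gene two-sided unequal-variance (Welch) location test between basal
#' and luminal samples, with Benjamini-Hochberg q-values computed across all
#' tested genes. Mean differences are signed basal minus luminal. Genes with
#' zero variance in both groups get p = 1 with a warning.
#'
#' @param expression Numeric genes x samples matrix of log-scale values with
#'   unique rownames (gene IDs) and colnames (sample IDs).
#' @param subtype Character/factor per sample, values "luminal" or "basal",
#'   at least two samples per group.
#' @param gene_set Optional character vector of gene IDs; fills the
#'   `in_set` flag.
#' @return data.frame with columns `gene`, `mean_diff` (basal - luminal),
#'   `statistic`, `p_value`, `q_value`, `in_set`.
#' @export
de_two_group <- function(expression, subtype, gene_set = NULL) {
  .assert(is.matrix(expression) && is.numeric(expression) &&
            nrow(expression) >= 1,
          "`expression` must be a numeric matrix with at least one gene")
  .assert(!is.null(rownames(expression)) &&
            !anyDuplicated(rownames(expression)),
          "`expression` must have unique rownames (gene IDs)")
  .assert(length(subtype) == ncol(expression),
          "`subtype` must have one label per sample")
  .assert(all(subtype %in% c("luminal", "basal")),
          "`subtype` values must be \"luminal\" or \"basal\"")
  basal <- subtype == "basal"
  .assert(sum(basal) >= 2 && sum(!basal) >= 2,
          "each group needs at least 2 samples")

  genes <- rownames(expression)
  stat <- diff <- pv <- numeric(length(genes))
  flat <- character(0)
  for (i in seq_along(genes)) {
    x <- expression[i, basal]
    y <- expression[i, !basal]
    diff[i] <- mean(x) - mean(y)
    if (sd(x) == 0 && sd(y) == 0) {
      stat[i] <- 0
      pv[i] <- 1
      flat <- c(flat, genes[i])
    } else {
      ht <- t.test(x, y, var.equal = FALSE)
      stat[i] <- unname(ht$statistic)
      pv[i] <- ht$p.value
    }
  }
  if (length(flat) > 0) {
    warning(sprintf("zero variance in both groups (p set to 1): %s",
                    paste(flat, collapse = ", ")), call. = FALSE)
  }

  data.frame(gene = genes,
             mean_diff = diff,
             statistic = stat,
             p_value = pv,
             q_value = bh_adjust(pv),
             in_set = if (is.null(gene_set)) NA else genes %in% gene_set,
             stringsAsFactors = FALSE)
}

#' Gene-set summary of a differential-expression result
#'
#' Counts how many members of a gene set (e.g. T-cell cytotoxicity genes)
#' are significant at a q-value threshold, split by direction of the mean
#' difference, and optionally slices the expression matrix for heatmap
#' export (significant members, ordered by mean difference).
#'
#' @param results Output of [de_two_group()].
#' @param gene_set Character vector of member gene IDs (non-empty). IDs
#'   absent from the results are reported in `missing_ids`, not fatal.
#' @param q_threshold Significance threshold on the q-value (default 0.05).
#' @param expression Optional matrix (as in [de_two_group()]) from which the
#'   heatmap slice is taken.
#' @return List with `n_set`, `n_tested`, `missing_ids`, `n_significant`,
#'   `frac_significant`, `n_up_in_basal`, `n_down_in_basal`,
#'   `q_threshold`, and `heatmap_slice` (matrix or `NULL`).
#' @export
geneset_summary <- function(results, gene_set, q_threshold = 0.05,
                            expression = NULL) {
  .assert(is.data.frame(results) &&
            all(c("gene", "mean_diff", "q_value") %in% names(results)),
          "`results` must come from de_two_group()")
  .assert(length(gene_set) >= 1, "`gene_set` must be non-empty")

  missing_ids <- setdiff(gene_set, results$gene)
  member <- results[results$gene %in% gene_set, , drop = FALSE]
  sig <- member[member$q_value < q_threshold, , drop = FALSE]
  sig <- sig[order(-sig$mean_diff), , drop = FALSE]

  slice <- NULL
  if (!is.null(expression) && nrow(sig) > 0) {
    slice <- expression[sig$gene, , drop = FALSE]
  }

  list(n_set = length(gene_set),
       n_tested = nrow(member),
       missing_ids = missing_ids,
       n_significant = nrow(sig),
       frac_significant = if (nrow(member) > 0) nrow(sig) / nrow(member)
                          else NA_real_,
       n_up_in_basal = sum(sig$mean_diff > 0),
       n_down_in_basal = sum(sig$mean_diff < 0),
       q_threshold = q_threshold,
       heatmap_slice = slice)
}
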