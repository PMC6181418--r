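#' Pipeline configuration
#'
#' Bundles everything [run_pipeline()] needs: a cohort source (an in-memory
#' table, a CSV path, or a [sim_config()] to simulate from), the density
#' cutoffs (fixed values or `"optimize"` to run the minimum-p-value scan per
#' compartment), the survival endpoints to analyze, the Cox adjustment set,
#' and the output directory. Exactly one cohort source must be supplied, and
#' cutoffs are either all fixed or all optimized, never both.
#'
#' @param out_dir Output directory (created if absent).
#' @param cohort Optional in-memory cohort data.frame.
#' @param cohort_csv Optional path to a cohort CSV ([read_cohort()] format).
#' @param sim Optional [sim_config()] to simulate the cohort from.
#' @param cutoffs Either the string `"optimize"` or a named numeric vector
#'   of fixed cutoffs for all four compartments (cells/mm^2).
#' @param min_group_frac,correction,n_perm Passed to [optimize_cutpoint()]
#'   when optimizing.
#' @param cutpoint_endpoint Endpoint used for cutoff optimization ("os" or
#'   "dfs"; default "os").
#' @param endpoints Endpoints analyzed downstream (subset of c("os",
#'   "dfs")).
#' @param adjustment Covariate columns of the multivariable Cox adjustment
#'   set.
#' @param alpha Two-sided significance level in (0, 1) recorded with the
#'   outputs.
#' @param seed Integer seed for every stochastic stage of the run.
#' @param expression Optional expression source: an
#'   [expression_sim_config()], or a list with paths `expression_tsv`,
#'   `labels_tsv`, `gene_set`.
#' @return An object of class `til_pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            cohort = NULL, cohort_csv = NULL, sim = NULL,
                            cutoffs = "optimize",
                            min_group_frac = 0.10,
                            correction = "miller_siegmund",
                            n_perm = 999,
                            cutpoint_endpoint = "os",
                            endpoints = c("os", "dfs"),
                            adjustment = TIL_COVARIATES,
                            alpha = 0.05,
                            seed = 1L,
                            expression = NULL) {
  n_sources <- sum(!is.null(cohort), !is.null(cohort_csv), !is.null(sim))
  .assert(n_sources == 1,
          "supply exactly one of `cohort`, `cohort_csv`, `sim`")
  if (!is.null(sim)) {
    .assert(inherits(sim, "til_sim_config"),
            "`sim` must be created by sim_config()")
  }
  if (is.character(cutoffs)) {
    .assert(identical(cutoffs, "optimize"),
            "`cutoffs` must be \"optimize\" or a named numeric vector")
  } else {
    cutoffs <- .named4(cutoffs, "cutoffs")
  }
  .assert(all(endpoints %in% c("os", "dfs")) && length(endpoints) >= 1,
          "`endpoints` must be a subset of c(\"os\", \"dfs\")")
  .assert(cutpoint_endpoint %in% c("os", "dfs"),
          "`cutpoint_endpoint` must be \"os\" or \"dfs\"")
  .assert(alpha > 0 && alpha < 1, "`alpha` must lie in (0, 1)")
  .assert(correction %in% c("miller_siegmund", "permutation", "none"),
          "unknown `correction`")

  structure(list(out_dir = out_dir, cohort = cohort,
                 cohort_csv = cohort_csv, sim = sim, cutoffs = cutoffs,
                 min_group_frac = min_group_frac, correction = correction,
                 n_perm = n_perm, cutpoint_endpoint = cutpoint_endpoint,
                 endpoints = endpoints, adjustment = adjustment,
                 alpha = alpha, seed = as.integer(seed),
                 expression = expression),
            class = "til_pipeline_config")
}

.endpoint_cols <- function(endpoint) {
  list(time = paste0(endpoint, "_months"), event = paste0(endpoint, "_event"))
}

#' Run the full TIL-density / Immunoscore analysis pipeline
#'
#' Executes the end-to-end workflow: acquire the cohort (read or simulate),
#' fix or optimize the per-compartment density cutoffs, dichotomize and
#' assign Immunoscores, export Kaplan-Meier curves and log-rank tests per
#' marker and per Immunoscore grade for each endpoint, fit univariable and
#' multivariable Cox models shaped like the standard reporting tables, run
#' the responder density comparison, optionally run the
#' differential-expression stage, and write a manifest with checksums of
#' every output. A failure in any stage aborts the run naming the stage.
#'
#' @param config A [pipeline_config()] object.
#' @return Invisibly, a list with `out_dir`, the scored `cohort`, the
#'   `cutoffs` used, and `files` (relative paths of all outputs).
#' @export
run_pipeline <- function(config) {
  .assert(inherits(config, "til_pipeline_config"),
          "`config` must be created by pipeline_config()")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  notes <- character(0)
  emit <- function(rel) files <<- c(files, rel)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  outpath <- function(rel) file.path(config$out_dir, rel)

  # -- cohort acquisition ----------------------------------------------------
  cohort <- stage("cohort", {
    if (!is.null(config$sim)) generate_cohort(config$sim)
    else if (!is.null(config$cohort_csv)) read_cohort(config$cohort_csv)
    else config$cohort
  })

  # -- cutoffs ---------------------------------------------------------------
  cutpoints <- NULL
  cutoffs <- stage("cutpoint", {
    if (is.numeric(config$cutoffs)) {
      config$cutoffs
    } else {
      ep <- .endpoint_cols(config$cutpoint_endpoint)
      cutpoints <- lapply(TIL_COMPARTMENTS, function(comp) {
        optimize_cutpoint(cohort[[comp]], cohort[[ep$time]],
                          cohort[[ep$event]],
                          min_group_frac = config$min_group_frac,
                          correction = config$correction,
                          n_perm = config$n_perm, seed = config$seed,
                          compartment = comp,
                          endpoint = config$cutpoint_endpoint)
      })
      names(cutpoints) <- TIL_COMPARTMENTS
      for (comp in TIL_COMPARTMENTS) {
        cp <- cutpoints[[comp]]
        jsonlite::write_json(cp[setdiff(names(cp), "scan")],
                             outpath(sprintf("cutpoint_%s.json", comp)),
                             auto_unbox = TRUE, digits = NA)
        emit(sprintf("cutpoint_%s.json", comp))
        write.table(cp$scan, outpath(sprintf("cutpoint_scan_%s.tsv", comp)),
                    sep = "\t", row.names = FALSE, quote = FALSE)
        emit(sprintf("cutpoint_scan_%s.tsv", comp))
      }
      vapply(cutpoints, function(cp) cp$cutoff, numeric(1))
    }
  })

  # -- scoring ---------------------------------------------------------------
  scored <- stage("score", score_cohort(cohort, cutoffs))
  stage("score", write_cohort(scored, outpath("cohort_scored.csv")))
  emit("cohort_scored.csv")

  # -- cohort summary --------------------------------------------------------
  stage("summary", {
    write.table(summarize_cohort(scored), outpath("cohort_summary.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    emit("cohort_summary.tsv")
  })

  # -- KM curves and log-rank tests ------------------------------------------
  tests <- stage("survival", {
    rows <- list()
    for (endpoint in config$endpoints) {
      ep <- .endpoint_cols(endpoint)
      for (comp in TIL_COMPARTMENTS) {
        call_col <- scored[[paste0("call_", comp)]]
        keep <- !is.na(call_col)
        km <- do.call(rbind, lapply(c("low", "high"), function(lv) {
          sel <- keep & call_col == lv
          if (!any(sel)) return(NULL)
          cbind(group = lv, km_estimate(scored[[ep$time]][sel],
                                        scored[[ep$event]][sel]))
        }))
        rel <- sprintf("km_%s_%s.tsv", comp, endpoint)
        write.table(km, outpath(rel), sep = "\t", row.names = FALSE,
                    quote = FALSE)
        emit(rel)
        lr <- logrank_test(scored[[ep$time]][keep], scored[[ep$event]][keep],
                           call_col[keep])
        rows[[length(rows) + 1]] <-
          data.frame(grouping = comp, endpoint = endpoint, test = "logrank",
                     chi_square = lr$chi_square, df = lr$df,
                     p_value = lr$p_value)
      }
      # Immunoscore grades (complete-case)
      keep <- !is.na(scored$immunoscore)
      if (length(unique(scored$immunoscore[keep])) >= 2) {
        grade <- factor(scored$immunoscore[keep],
                        levels = sort(unique(scored$immunoscore[keep])))
        km <- do.call(rbind, lapply(levels(grade), function(lv) {
          sel <- grade == lv
          cbind(group = paste0("I", lv),
                km_estimate(scored[[ep$time]][keep][sel],
                            scored[[ep$event]][keep][sel]))
        }))
        rel <- sprintf("km_immunoscore_%s.tsv", endpoint)
        write.table(km, outpath(rel), sep = "\t", row.names = FALSE,
                    quote = FALSE)
        emit(rel)
        het <- logrank_test(scored[[ep$time]][keep],
                            scored[[ep$event]][keep], grade)
        trend <- logrank_trend(scored[[ep$time]][keep],
                               scored[[ep$event]][keep], grade)
        rows[[length(rows) + 1]] <-
          data.frame(grouping = "immunoscore", endpoint = endpoint,
                     test = "logrank", chi_square = het$chi_square,
                     df = het$df, p_value = het$p_value)
        rows[[length(rows) + 1]] <-
          data.frame(grouping = "immunoscore", endpoint = endpoint,
                     test = "trend", chi_square = trend$chi_square,
                     df = trend$df, p_value = trend$p_value)
      }
    }
    tests <- do.call(rbind, rows)
    write.table(tests, outpath("survival_tests.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    emit("survival_tests.tsv")
    tests
  })

  # -- Cox tables ------------------------------------------------------------
  stage("cox", {
    adj <- config$adjustment[config$adjustment %in% names(scored)]
    usable <- adj[vapply(adj, function(v) {
      length(unique(scored[[v]][!is.na(scored[[v]])])) >= 2
    }, logical(1))]
    dropped <- setdiff(adj, usable)
    if (length(dropped) > 0) {
      notes <- c(notes, paste("constant adjustment covariates dropped:",
                              paste(dropped, collapse = ", ")))
    }
    for (endpoint in config$endpoints) {
      tab <- cox_table(scored, endpoint = endpoint, adjustment = usable)
      rel <- sprintf("cox_%s.tsv", endpoint)
      write.table(tab, outpath(rel), sep = "\t", row.names = FALSE,
                  quote = FALSE)
      emit(rel)
    }
  })

  # -- responder density comparison ------------------------------------------
  stage("responder", {
    sel <- !is.na(scored$nac_response)
    if (sum(sel) > 0 &&
        length(unique(scored$nac_response[sel])) == 2) {
      cmp <- compare_density_groups(scored$cd8_im[sel],
                                    ifelse(scored$nac_response[sel] == 1,
                                           "responder", "non_responder"))
      jsonlite::write_json(cmp, outpath("responder_cd8_im.json"),
                           auto_unbox = TRUE, digits = NA)
      emit("responder_cd8_im.json")
    } else {
      notes <- c(notes, "responder comparison skipped: one response group")
    }
  })

  # -- differential expression ------------------------------------------------
  if (!is.null(config$expression)) {
    stage("expression", {
      if (inherits(config$expression, "til_expression_sim_config")) {
        sim <- generate_expression(config$expression)
        expr <- sim$expression
        labels <- sim$labels
        gene_set <- sim$gene_set
        write_expression_matrix(expr, outpath("expression.tsv"))
        emit("expression.tsv")
        write_sample_labels(labels, outpath("expression_labels.tsv"))
        emit("expression_labels.tsv")
        write_gene_set(gene_set, outpath("cytotoxicity_gene_set.txt"))
        emit("cytotoxicity_gene_set.txt")
      } else {
        expr <- read_expression_matrix(config$expression$expression_tsv)
        labels <- read_sample_labels(config$expression$labels_tsv)
        gene_set <- read_gene_set(config$expression$gene_set)
      }
      subtype <- labels$subtype[match(colnames(expr), labels$sample_id)]
      de <- de_two_group(expr, subtype, gene_set)
      write.table(de, outpath("de_results.tsv"), sep = "\t",
                  row.names = FALSE, quote = FALSE)
      emit("de_results.tsv")
      summ <- geneset_summary(de, gene_set, q_threshold = config$alpha,
                              expression = expr)
      if (!is.null(summ$heatmap_slice)) {
        write_expression_matrix(summ$heatmap_slice,
                                outpath("heatmap_slice.tsv"))
        emit("heatmap_slice.tsv")
      }
      jsonlite::write_json(summ[setdiff(names(summ), "heatmap_slice")],
                           outpath("de_summary.json"), auto_unbox = TRUE,
                           digits = NA)
      emit("de_summary.json")
    })
  }

  # -- manifest ---------------------------------------------------------------
  stage("manifest", {
    checksums <- tools::md5sum(file.path(config$out_dir, files))
    manifest <- list(
      package = "tilscore",
      version = as.character(packageVersion("tilscore")),
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      seed = config$seed,
      alpha = config$alpha,
      cutoffs = as.list(cutoffs),
      cutoffs_optimized = !is.numeric(config$cutoffs),
      endpoints = config$endpoints,
      notes = notes,
      files = lapply(seq_along(files), function(i) {
        list(path = files[i], md5 = unname(checksums[i]))
      }))
    jsonlite::write_json(manifest, outpath("manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  })

  invisible(list(out_dir = config$out_dir, cohort = scored,
                 cutoffs = cutoffs, cutpoints = cutpoints,
                 tests = tests, files = files))
}

#' Univariable + multivariable Cox table for one endpoint
#'
#' Builds the standard reporting table: each adjustment covariate and each
#' immune marker appears with a univariable hazard ratio (model with that
#' variable alone) and a multivariable one. Clinical covariates take their
#' multivariable estimates from the adjustment-set model; each immune marker
#' (four compartment calls, plus Immunoscore entered as grade indicators
#' against I0 or the lowest observed grade) is adjusted in its own model -
#' one model per marker, never one joint model of all markers.
#'
#' @param scored Cohort scored by [score_cohort()] (needs the `call_*` and
#'   `immunoscore` columns plus outcome columns).
#' @param endpoint "os" or "dfs".
#' @param adjustment Covariate columns of the adjustment set.
#' @return data.frame with columns `variable`, `level`, `uni_hr`,
#'   `uni_ci_lower`, `uni_ci_upper`, `uni_p`, `multi_hr`, `multi_ci_lower`,
#'   `multi_ci_upper`, `multi_p`.
#' @export
cox_table <- function(scored, endpoint = "os",
                      adjustment = TIL_COVARIATES) {
  ep <- .endpoint_cols(endpoint)
  .assert(all(c(ep$time, ep$event) %in% names(scored)),
          sprintf("cohort lacks %s/%s", ep$time, ep$event))
  tm <- scored[[ep$time]]
  ev <- scored[[ep$event]]

  fit_terms <- function(covs, keep) {
    m <- cox_fit(covs[keep, , drop = FALSE], tm[keep], ev[keep])
    m$table
  }
  row_of <- function(tab, term) {
    i <- match(term, tab$term)
    c(hr = tab$hr[i], lo = tab$ci_lower[i], hi = tab$ci_upper[i],
      p = tab$p_value[i])
  }

  complete_adj <- complete.cases(scored[, adjustment, drop = FALSE]) &
    !is.na(tm) & !is.na(ev)
  multi_base <- fit_terms(scored[, adjustment, drop = FALSE], complete_adj)

  rows <- list()
  add_row <- function(variable, level, uni, multi) {
    rows[[length(rows) + 1]] <<- data.frame(
      variable = variable, level = level,
      uni_hr = uni[["hr"]], uni_ci_lower = uni[["lo"]],
      uni_ci_upper = uni[["hi"]], uni_p = uni[["p"]],
      multi_hr = multi[["hr"]], multi_ci_lower = multi[["lo"]],
      multi_ci_upper = multi[["hi"]], multi_p = multi[["p"]])
  }

  for (v in adjustment) {
    keep <- !is.na(scored[[v]]) & !is.na(tm) & !is.na(ev)
    uni <- fit_terms(scored[, v, drop = FALSE], keep)
    add_row(v, "yes vs no", row_of(uni, v), row_of(multi_base, v))
  }

  for (comp in TIL_COMPARTMENTS) {
    call_col <- paste0("call_", comp)
    marker <- data.frame(x = factor(scored[[call_col]],
                                    levels = c("low", "high")))
    names(marker) <- comp
    keep_u <- !is.na(marker[[comp]]) & !is.na(tm) & !is.na(ev)
    uni <- fit_terms(marker, keep_u)
    covs <- cbind(scored[, adjustment, drop = FALSE], marker)
    keep_m <- keep_u & complete_adj
    multi <- fit_terms(covs, keep_m)
    term <- paste0(comp, "high")
    add_row(comp, "high vs low", row_of(uni, term), row_of(multi, term))
  }

  if ("immunoscore" %in% names(scored) &&
      length(unique(scored$immunoscore[!is.na(scored$immunoscore)])) >= 2) {
    grades <- sort(unique(scored$immunoscore[!is.na(scored$immunoscore)]))
    marker <- data.frame(immunoscore = factor(scored$immunoscore,
                                              levels = grades))
    keep_u <- !is.na(marker$immunoscore) & !is.na(tm) & !is.na(ev)
    uni <- fit_terms(marker, keep_u)
    covs <- cbind(scored[, adjustment, drop = FALSE], marker)
    multi <- fit_terms(covs, keep_u & complete_adj)
    for (gr in grades[-1]) {
      term <- paste0("immunoscore", gr)
      add_row("immunoscore", sprintf("I%d vs I%d", gr, grades[1]),
              row_of(uni, term), row_of(multi, term))
    }
  }

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cohort characteristics summary
#'
#' Per-variable counts and percentages (categorical variables, percentages
#' over non-missing denominators) and median (IQR) for continuous variables,
#' with missing counts, in the style of a clinical Table 1.
#'
#' @param cohort Cohort data.frame.
#' @return data.frame with columns `variable`, `level`, `n`, `percent`,
#'   `median`, `iqr`, `n_missing`. Categorical rows carry `n`/`percent`;
#'   continuous rows carry `median`/`iqr`.
#' @export
summarize_cohort <- function(cohort) {
  .assert(is.data.frame(cohort) && nrow(cohort) >= 1,
          "`cohort` must be a non-empty data.frame")
  categorical <- intersect(c(TIL_COVARIATES, "nac_response", "immunoscore",
                             paste0("call_", TIL_COMPARTMENTS),
                             "os_event", "dfs_event"),
                           names(cohort))
  continuous <- intersect(c(TIL_COMPARTMENTS, "os_months", "dfs_months"),
                          names(cohort))
  rows <- list()
  for (v in categorical) {
    x <- cohort[[v]]
    n_miss <- sum(is.na(x))
    x <- x[!is.na(x)]
    if (length(x) == 0) {
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, level = NA_character_, n = 0, percent = NA_real_,
        median = NA_real_, iqr = NA_real_, n_missing = n_miss)
      next
    }
    tab <- table(x)
    for (lv in names(tab)) {
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, level = lv, n = as.integer(tab[[lv]]),
        percent = 100 * tab[[lv]] / length(x),
        median = NA_real_, iqr = NA_real_, n_missing = n_miss)
    }
  }
  for (v in continuous) {
    x <- cohort[[v]]
    n_miss <- sum(is.na(x))
    x <- x[!is.na(x)]
    q <- if (length(x) > 0) quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
         else rep(NA_real_, 3)
    rows[[length(rows) + 1]] <- data.frame(
      variable = v, level = "median (IQR)", n = length(x),
      percent = NA_real_, median = q[2], iqr = q[3] - q[1],
      n_missing = n_miss)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
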