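#' Kaplan-Meier product-limit estimate
#'
#' Wraps [survival::survfit()] and returns the curve as a plain table,
#' including a time-zero row (S(0) = 1) and the Greenwood standard error.
#'
#' @param times Positive follow-up times in months.
#' @param events Event indicators (0 = censored, 1 = event).
#' @return An object of class `km_curve`: data.frame with columns `time`,
#'   `n_risk`, `n_event`, `n_censor`, `survival`, `std_err`.
#' @examples
#' km_estimate(c(1, 2, 3), c(1, 0, 1))
#' @export
km_estimate <- function(times, events) {
  .assert(length(times) >= 1, "at least one sample is required")
  .assert(length(times) == length(events),
          "`times` and `events` must have equal length")
  .assert(all(is.finite(times)) && all(times > 0),
          "`times` must be finite and positive")
  .assert(all(events %in% c(0, 1)), "`events` must be 0/1")

  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "none")
  s <- summary(fit, censored = TRUE)
  out <- data.frame(time = c(0, s$time),
                    n_risk = c(length(times), s$n.risk),
                    n_event = c(0, s$n.event),
                    n_censor = c(0, s$n.censor),
                    survival = c(1, s$surv),
                    std_err = c(0, s$std.err))
  class(out) <- c("km_curve", "data.frame")
  out
}

.logrank_group_counts <- function(prep, group_mat) {
  # per-group at-risk and event counts at each distinct event time
  list(n_g = prep$at_risk %*% group_mat, d_g = prep$ev %*% group_mat)
}

#' k-group log-rank test
#'
#' Standard (unweighted) log-rank test with df = k - 1, hypergeometric
#' variance with tie correction, two-sided p from the upper chi-square tail.
#' Computation is delegated to [survival::survdiff()].
#'
#' @inheritParams km_estimate
#' @param groups Group labels (>= 2 non-empty groups).
#' @return An object of class `logrank_result`: list with `chi_square`,
#'   `df`, `p_value`, `observed` and `expected` per-group event counts,
#'   and `n` per group.
#' @export
logrank_test <- function(times, events, groups) {
  .assert(length(times) == length(events) &&
            length(events) == length(groups),
          "`times`, `events`, `groups` must have equal length")
  .assert(all(is.finite(times)) && all(times > 0),
          "`times` must be finite and positive")
  .assert(all(events %in% c(0, 1)), "`events` must be 0/1")
  g <- factor(groups)
  .assert(nlevels(g) >= 2, "at least two groups are required")
  .assert(sum(events) >= 1, "at least one event is required")

  sd <- survival::survdiff(survival::Surv(times, events) ~ g)
  df <- nlevels(g) - 1
  structure(list(chi_square = unname(sd$chisq),
                 df = df,
                 p_value = pchisq(sd$chisq, df, lower.tail = FALSE),
                 observed = setNames(as.vector(sd$obs), levels(g)),
                 expected = setNames(as.vector(sd$exp), levels(g)),
                 n = setNames(as.vector(table(g)), levels(g))),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.3f on %d df, p = %.4g\n",
              x$chi_square, x$df, x$p_value))
  print(data.frame(n = x$n, observed = x$observed, expected = x$expected))
  invisible(x)
}

#' Trend log-rank test across ordered groups
#'
#' Score test for a monotone hazard trend over ordered groups (e.g.
#' Immunoscore grades I0-I4), using integer scores 0..k-1 by default;
#' df = 1. With two groups it reduces to the ordinary two-group log-rank
#' test.
#'
#' @inheritParams logrank_test
#' @param groups Ordered group labels (factor level order, or supply an
#'   ordered factor).
#' @param scores Optional numeric scores per group level (default 0..k-1).
#' @return A `logrank_result` with `df = 1`.
#' @export
logrank_trend <- function(times, events, groups, scores = NULL) {
  .assert(length(times) == length(events) &&
            length(events) == length(groups),
          "`times`, `events`, `groups` must have equal length")
  .assert(all(is.finite(times)) && all(times > 0),
          "`times` must be finite and positive")
  .assert(all(events %in% c(0, 1)), "`events` must be 0/1")
  g <- factor(groups)
  k <- nlevels(g)
  .assert(k >= 2, "at least two ordered groups are required")
  .assert(sum(events) >= 1, "at least one event is required")
  if (is.null(scores)) scores <- seq_len(k) - 1
  .assert(length(scores) == k, "`scores` must have one value per group")

  prep <- .logrank_prepare(times, events)
  group_mat <- outer(as.integer(g), seq_len(k), "==") * 1  # n x k
  cnt <- .logrank_group_counts(prep, group_mat)

  p_g <- cnt$n_g / prep$n_risk                        # J x k risk fractions
  obs <- as.vector(cnt$d_g %*% scores)
  expct <- prep$d * as.vector(p_g %*% scores)
  u <- sum(obs - expct)
  v <- sum(prep$vfac * (as.vector(p_g %*% scores^2) -
                          as.vector(p_g %*% scores)^2))
  chi <- if (v > 0) u^2 / v else 0

  structure(list(chi_square = chi,
                 df = 1,
                 p_value = pchisq(chi, 1, lower.tail = FALSE),
                 observed = setNames(colSums(cnt$d_g), levels(g)),
                 expected = setNames(colSums(prep$d * p_g), levels(g)),
                 n = setNames(as.vector(table(g)), levels(g))),
            class = "logrank_result")
}

#' Cox proportional-hazards fit
#'
#' Wraps [survival::coxph()] (Efron tie handling by default, Breslow
#' selectable) and returns a per-covariate table of log hazard ratios,
#' hazard ratios, Wald 95% confidence intervals and p-values. Constant
#' covariates raise an error naming the column; non-convergence or likely
#' monotone likelihood (perfect separation) is flagged, not silently
#' returned.
#'
#' @param covariates data.frame or numeric matrix of covariates (n x p,
#'   named columns; factors allowed in a data.frame).
#' @inheritParams km_estimate
#' @param ties Tie-handling method, `"efron"` (default) or `"breslow"`.
#' @return An object of class `cox_model`: list with `table` (term,
#'   log_hr, se, hr, ci_lower, ci_upper, p_value), `n`, `n_events`, `ties`,
#'   `converged`, `messages` and the underlying `fit`.
#' @export
cox_fit <- function(covariates, times, events, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  df <- as.data.frame(covariates)
  .assert(ncol(df) >= 1, "at least one covariate is required")
  .assert(nrow(df) == length(times) && length(times) == length(events),
          "covariates, `times` and `events` must agree in length")
  .assert(all(is.finite(times)) && all(times > 0),
          "`times` must be finite and positive")
  .assert(all(events %in% c(0, 1)), "`events` must be 0/1")
  .assert(sum(events) >= 1, "at least one event is required")
  .assert(nrow(df) > ncol(df), "need more observations than covariates")

  for (nm in names(df)) {
    v <- df[[nm]]
    if (length(unique(v[!is.na(v)])) < 2) {
      stop(sprintf("covariate '%s' is constant", nm), call. = FALSE)
    }
  }

  msgs <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(times, events) ~ ., data = df,
                    ties = ties),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    })

  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  zc <- qnorm(0.975)
  converged <- !any(is.na(beta)) && all(abs(beta) < 15) &&
    !any(grepl("converge|infinite|singular", msgs, ignore.case = TRUE))
  if (!converged) {
    warning("Cox fit flagged: possible non-convergence or monotone likelihood",
            call. = FALSE)
  }

  tab <- data.frame(term = names(beta),
                    log_hr = unname(beta),
                    se = unname(se),
                    hr = exp(unname(beta)),
                    ci_lower = exp(unname(beta) - zc * unname(se)),
                    ci_upper = exp(unname(beta) + zc * unname(se)),
                    p_value = 2 * pnorm(abs(unname(beta) / unname(se)),
                                        lower.tail = FALSE),
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL

  structure(list(table = tab,
                 n = fit$n,
                 n_events = fit$nevent,
                 ties = ties,
                 converged = converged,
                 messages = msgs,
                 fit = fit),
            class = "cox_model")
}

#' @export
print.cox_model <- function(x, ...) {
  cat(sprintf("Cox proportional-hazards model (%s ties), n = %d, events = %d%s\n",
              x$ties, x$n, x$n_events,
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(x$table, digits = 3)
  invisible(x)
}

#' Compare density distributions between two groups
#'
#' Two-sided comparison of a density (or any continuous marker) between two
#' groups, e.g. CD8(IM) density in neoadjuvant-chemotherapy responders versus
#' non-responders. Defaults to the Wilcoxon rank-sum test (density
#' distributions are right-skewed); a Welch t-test is available.
#'
#' @param densities Numeric values; `NA` dropped with its label.
#' @param labels Binary group labels (exactly two levels, both non-empty).
#' @param method `"ranksum"` (default) or `"welch"`.
#' @return List with `statistic`, `p_value`, `method`, `n` (per group) and
#'   the group `levels`.
#' @export
compare_density_groups <- function(densities, labels,
                                   method = c("ranksum", "welch")) {
  method <- match.arg(method)
  keep <- !is.na(densities) & !is.na(labels)
  densities <- densities[keep]
  g <- factor(labels[keep])
  .assert(nlevels(g) == 2, "`labels` must have exactly two levels")
  x <- densities[g == levels(g)[1]]
  y <- densities[g == levels(g)[2]]
  .assert(length(x) >= 1 && length(y) >= 1, "both groups must be non-empty")

  if (method == "ranksum") {
    has_ties <- any(duplicated(c(x, y)))
    ht <- wilcox.test(x, y, exact = !has_ties, correct = TRUE)
  } else {
    ht <- t.test(x, y, var.equal = FALSE)
  }
  list(statistic = unname(ht$statistic),
       p_value = ht$p.value,
       method = method,
       n = setNames(c(length(x), length(y)), levels(g)),
       levels = levels(g))
}
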