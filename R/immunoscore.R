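#' Assign the I0-I4 Immunoscore from four high/low calls
#'
#' The Immunoscore is the number of "high" calls among the four
#' marker-compartment combinations CD3(CT), CD3(IM), CD8(CT), CD8(IM): I4
#' when both markers are high in both the tumor core and the invasive
#' margin, down to I0 when all four are low. A missing call makes the grade
#' undefined (`NA`); it is flagged, never imputed.
#'
#' @param calls Named character vector with entries `cd3_ct`, `cd3_im`,
#'   `cd8_ct`, `cd8_im`, each "high", "low" or `NA`.
#' @param patient_id Optional identifier carried into the result.
#' @return An object of class `immunoscore_grade`: list with `patient_id`,
#'   `grade` (integer 0-4 or `NA`), `calls`, `n_missing_calls`.
#' @examples
#' assign_immunoscore(c(cd3_ct = "high", cd3_im = "high",
#'                      cd8_ct = "high", cd8_im = "high"))$grade # 4
#' @export
assign_immunoscore <- function(calls, patient_id = NA_character_) {
  .assert(all(TIL_COMPARTMENTS %in% names(calls)),
          "`calls` must name all four compartments: cd3_ct, cd3_im, cd8_ct, cd8_im")
  calls <- unlist(calls)[TIL_COMPARTMENTS]
  .assert(all(calls %in% c("high", "low") | is.na(calls)),
          "calls must be \"high\", \"low\" or NA")
  n_missing <- sum(is.na(calls))
  grade <- if (n_missing == 0) sum(calls == "high") else NA_integer_
  structure(list(patient_id = patient_id,
                 grade = as.integer(grade),
                 calls = calls,
                 n_missing_calls = as.integer(n_missing)),
            class = "immunoscore_grade")
}

#' @export
print.immunoscore_grade <- function(x, ...) {
  if (is.na(x$grade)) {
    cat(sprintf("Immunoscore: undefined (%d missing call%s)\n",
                x$n_missing_calls, if (x$n_missing_calls == 1) "" else "s"))
  } else {
    cat(sprintf("Immunoscore: I%d\n", x$grade))
  }
  invisible(x)
}

#' Score a cohort: dichotomize densities and assign Immunoscores
#'
#' Applies [dichotomize()] to each density column at its supplied cutoff and
#' counts "high" calls per patient. Patients with any missing density get an
#' `NA` grade and a positive `n_missing_calls` (complete-case flagging).
#'
#' @param cohort data.frame with the four density columns `cd3_ct`,
#'   `cd3_im`, `cd8_ct`, `cd8_im` (cells/mm^2).
#' @param cutoffs Named numeric vector of cutoffs for all four compartments.
#' @return The cohort with added columns `call_<compartment>` (four
#'   high/low columns), `immunoscore` (integer 0-4 or `NA`) and
#'   `n_missing_calls`.
#' @examples
#' cohort <- data.frame(cd3_ct = 500, cd3_im = 300, cd8_ct = 120, cd8_im = 80)
#' score_cohort(cohort, c(cd3_ct = 490, cd3_im = 290,
#'                        cd8_ct = 116, cd8_im = 70))$immunoscore # 4
#' @export
score_cohort <- function(cohort, cutoffs) {
  .assert(is.data.frame(cohort), "`cohort` must be a data.frame")
  .assert(all(TIL_COMPARTMENTS %in% names(cohort)),
          "`cohort` must contain the four density columns")
  .assert(is.numeric(cutoffs) && all(TIL_COMPARTMENTS %in% names(cutoffs)),
          "`cutoffs` must be numeric and name all four compartments")

  calls <- matrix(NA_character_, nrow(cohort), 4,
                  dimnames = list(NULL, TIL_COMPARTMENTS))
  for (comp in TIL_COMPARTMENTS) {
    calls[, comp] <- dichotomize(cohort[[comp]], cutoffs[[comp]])
  }
  n_missing <- rowSums(is.na(calls))
  n_high <- rowSums(calls == "high", na.rm = TRUE)

  out <- cohort
  for (comp in TIL_COMPARTMENTS) {
    out[[paste0("call_", comp)]] <- calls[, comp]
  }
  out$immunoscore <- ifelse(n_missing == 0, as.integer(n_high), NA_integer_)
  out$n_missing_calls <- as.integer(n_missing)
  out
}
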