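#' Compartment density from per-area lymphocyte counts
#'
#' Converts counts from several non-contiguous fields into a single density
#' in cells/mm^2 by averaging the per-area densities (count/area). Averaging
#' per-area densities, rather than pooling counts over pooled area, is the
#' convention when each selected field is scored independently; with equal
#' areas the two coincide.
#'
#' @param counts Non-negative lymphocyte counts, one per selected area.
#' @param areas_mm2 Positive areas in mm^2, same length as `counts`.
#' @return Mean density in cells/mm^2 (single non-negative number).
#' @examples
#' compute_density(c(100, 200, 300), c(1, 1, 1)) # 200
#' compute_density(c(50, 60, 70), c(0.5, 0.5, 0.5)) # 120
#' @export
compute_density <- function(counts, areas_mm2) {
  .assert(length(counts) >= 1, "at least one area is required")
  .assert(length(counts) == length(areas_mm2),
          "`counts` and `areas_mm2` must have the same length")
  .assert(is.numeric(counts) && all(is.finite(counts)) && all(counts >= 0),
          "`counts` must be finite and non-negative")
  .assert(is.numeric(areas_mm2) && all(is.finite(areas_mm2)) &&
            all(areas_mm2 > 0),
          "`areas_mm2` must be finite and strictly positive")
  mean(counts / areas_mm2)
}

#' Dichotomize a density against a cutoff
#'
#' "high" means strictly greater than the cutoff; values equal to the cutoff
#' are "low" (the convention low <= cutoff < high). Missing densities give a
#' missing call; they are never imputed.
#'
#' @param density Numeric vector of densities in cells/mm^2 (`NA` allowed).
#' @param cutoff Single non-negative cutoff in cells/mm^2.
#' @return Character vector of "high"/"low" calls with `NA` where `density`
#'   is missing.
#' @examples
#' dichotomize(c(70, 70.1, 0), 70) # "low"  "high" "low"
#' @export
dichotomize <- function(density, cutoff) {
  .assert(is.numeric(cutoff) && length(cutoff) == 1 && is.finite(cutoff) &&
            cutoff >= 0, "`cutoff` must be a single non-negative number")
  .assert(is.numeric(density), "`density` must be numeric")
  .assert(all(density >= 0, na.rm = TRUE), "densities must be non-negative")
  ifelse(is.na(density), NA_character_,
         ifelse(density > cutoff, "high", "low"))
}

#' Per-patient compartment densities from long-format area measurements
#'
#' Aggregates a long measurement table (one row per selected area) into the
#' wide per-patient density columns used by the rest of the pipeline. Each
#' (patient, marker, region) group is averaged with [compute_density()].
#' Groups with fewer than `n_areas` measurements are averaged over what
#' exists, with a warning.
#'
#' @param measurements data.frame with columns `patient_id`, `marker` ("CD3"
#'   or "CD8"), `region` ("CT" or "IM"), `count`, `area_mm2`.
#' @param n_areas Expected number of areas per compartment (default 3).
#' @return data.frame with `patient_id` and the four density columns
#'   `cd3_ct`, `cd3_im`, `cd8_ct`, `cd8_im`; compartments never measured for
#'   a patient are `NA`.
#' @export
densities_from_measurements <- function(measurements, n_areas = 3) {
  needed <- c("patient_id", "marker", "region", "count", "area_mm2")
  .assert(is.data.frame(measurements) && all(needed %in% names(measurements)),
          paste("`measurements` must contain columns:",
                paste(needed, collapse = ", ")))
  .assert(all(measurements$marker %in% c("CD3", "CD8")),
          "`marker` must be CD3 or CD8")
  .assert(all(measurements$region %in% c("CT", "IM")),
          "`region` must be CT or IM")

  measurements$compartment <- tolower(paste(measurements$marker,
                                            measurements$region, sep = "_"))
  patients <- unique(measurements$patient_id)
  out <- data.frame(patient_id = patients, stringsAsFactors = FALSE)
  for (comp in TIL_COMPARTMENTS) out[[comp]] <- NA_real_

  short <- character(0)
  for (i in seq_along(patients)) {
    for (comp in TIL_COMPARTMENTS) {
      rows <- measurements$patient_id == patients[i] &
        measurements$compartment == comp
      if (!any(rows)) next
      if (sum(rows) < n_areas) {
        short <- c(short, sprintf("%s/%s", patients[i], comp))
      }
      out[i, comp] <- compute_density(measurements$count[rows],
                                      measurements$area_mm2[rows])
    }
  }
  if (length(short) > 0) {
    warning(sprintf("fewer than %d areas for: %s (averaged available areas)",
                    n_areas, paste(short, collapse = ", ")), call. = FALSE)
  }
  out
}
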