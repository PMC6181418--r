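#' Configuration for a synthetic cystectomy cohort
#'
#' Defines the generative model for [generate_cohort()]: per-compartment TIL
#' densities are correlated log-normals (cells/mm^2), survival follows a
#' Weibull proportional-hazards model whose linear predictor combines
#' dichotomized densities (high = strictly above the true cutoff) and binary
#' clinical covariates, and censoring is administrative at `censor_horizon`
#' months plus an independent uniform early-dropout fraction.
#'
#' Defaults mirror the muscle-invasive bladder cancer setting the package
#' targets: density cutoffs 490/290/116/70 cells/mm^2 for
#' CD3(CT)/CD3(IM)/CD8(CT)/CD8(IM), a strongly protective high-CD8(IM) effect
#' (log HR -1.05, i.e. HR 0.35), covariate prevalences of 70.1% LVI, 10.4%
#' positive margin, 26.1% prior intravesical therapy and 40% perioperative
#' chemotherapy, and a baseline scale chosen so that roughly half of patients
#' at the average linear predictor have died by 36 months.
#'
#' @param seed Integer seed; every random draw of the generator derives from
#'   it, so identical configurations give bit-identical cohorts.
#' @param n_patients Number of patients (>= 20).
#' @param density_meanlog,density_sdlog Named numeric vectors (cd3_ct,
#'   cd3_im, cd8_ct, cd8_im): log-normal location and scale of each
#'   compartment density, on the log cells/mm^2 scale.
#' @param density_cor Either a single cross-compartment correlation in
#'   \[0, 1) applied exchangeably, or a 4x4 symmetric positive-definite
#'   correlation matrix with unit diagonal.
#' @param true_cutoffs Named numeric vector of the true density thresholds
#'   (cells/mm^2) at which the hazard changes.
#' @param true_log_hr Named numeric vector: log hazard ratio applied when a
#'   compartment density strictly exceeds its true cutoff.
#' @param covariate_prevalence Named fractions in \[0, 1\] for the binary
#'   covariates (organ_confined, lvi, margin, intravesical, chemo).
#' @param covariate_log_hr Named log hazard ratios for those covariates.
#' @param baseline_shape,baseline_scale Weibull baseline shape (> 0) and
#'   scale in months (> 0). If `baseline_scale` is `NULL` it is set so the
#'   median survival time at the average linear predictor is 36 months.
#' @param censor_horizon Administrative censoring time in months (> 0).
#' @param dropout_frac Fraction of patients censored early at a Uniform(0,
#'   horizon) time, independent of outcome.
#' @param dfs_coupling Slope linking the linear predictor to the log-odds of
#'   recurrence; recurrence shortens DFS relative to OS.
#' @param recurrence_base_prob Recurrence probability at the average linear
#'   predictor.
#' @param nac_intercept,nac_slope Logistic intercept/slope of the probability
#'   of neoadjuvant-chemotherapy response as a function of log CD8(IM)
#'   density centred at its true cutoff; response is only simulated for
#'   chemotherapy-treated patients.
#' @param missing_frac Fraction of each density column masked to `NA`
#'   (default 0), emulating incomplete staining data.
#'
#' @return An object of class `til_sim_config`.
#' @seealso [generate_cohort()], [generate_null_cohort()]
#' @export
sim_config <- function(seed = 1L,
                       n_patients = 67L,
                       density_meanlog = c(cd3_ct = 6.20, cd3_im = 5.12,
                                           cd8_ct = 4.75, cd8_im = 4.77),
                       density_sdlog = c(cd3_ct = 0.9, cd3_im = 0.9,
                                         cd8_ct = 0.9, cd8_im = 0.9),
                       density_cor = 0.5,
                       true_cutoffs = c(cd3_ct = 490, cd3_im = 290,
                                        cd8_ct = 116, cd8_im = 70),
                       true_log_hr = c(cd3_ct = -0.25, cd3_im = -0.5,
                                       cd8_ct = -0.6, cd8_im = -1.05),
                       covariate_prevalence = c(organ_confined = 0.22,
                                                lvi = 0.701, margin = 0.104,
                                                intravesical = 0.261,
                                                chemo = 0.40),
                       covariate_log_hr = c(organ_confined = -1.5,
                                            lvi = 1.19, margin = 0.93,
                                            intravesical = 0, chemo = -0.97),
                       baseline_shape = 1.2,
                       baseline_scale = NULL,
                       censor_horizon = 60,
                       dropout_frac = 0.10,
                       dfs_coupling = 0.8,
                       recurrence_base_prob = 0.6,
                       nac_intercept = 0,
                       nac_slope = 1,
                       missing_frac = 0) {
  .assert(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
          "`seed` must be a single finite number")
  .assert(is.numeric(n_patients) && length(n_patients) == 1 &&
            n_patients >= 20 && n_patients == round(n_patients),
          "`n_patients` must be an integer >= 20")

  density_meanlog <- .named4(density_meanlog, "density_meanlog")
  density_sdlog <- .named4(density_sdlog, "density_sdlog")
  true_cutoffs <- .named4(true_cutoffs, "true_cutoffs")
  true_log_hr <- .named4(true_log_hr, "true_log_hr")
  .assert(all(density_sdlog > 0), "`density_sdlog` must be positive")
  .assert(all(true_cutoffs > 0), "`true_cutoffs` must be positive")

  density_cor <- .as_cor_matrix(density_cor)

  .assert(all(TIL_COVARIATES %in% names(covariate_prevalence)),
          "`covariate_prevalence` must name all five covariates")
  covariate_prevalence <- covariate_prevalence[TIL_COVARIATES]
  .assert(all(covariate_prevalence >= 0 & covariate_prevalence <= 1),
          "covariate prevalences must lie in [0, 1]")
  .assert(all(TIL_COVARIATES %in% names(covariate_log_hr)),
          "`covariate_log_hr` must name all five covariates")
  covariate_log_hr <- covariate_log_hr[TIL_COVARIATES]

  .assert(baseline_shape > 0, "`baseline_shape` must be > 0")
  .assert(censor_horizon > 0, "`censor_horizon` must be > 0")
  .assert(dropout_frac >= 0 && dropout_frac < 1,
          "`dropout_frac` must lie in [0, 1)")
  .assert(missing_frac >= 0 && missing_frac < 1,
          "`missing_frac` must lie in [0, 1)")
  .assert(recurrence_base_prob > 0 && recurrence_base_prob < 1,
          "`recurrence_base_prob` must lie in (0, 1)")

  if (is.null(baseline_scale)) {
    # median survival 36 months at the centred (mean-zero) linear predictor
    baseline_scale <- 36 / log(2)^(1 / baseline_shape)
  }
  .assert(baseline_scale > 0, "`baseline_scale` must be > 0")

  structure(list(seed = as.integer(seed),
                 n_patients = as.integer(n_patients),
                 density_meanlog = density_meanlog,
                 density_sdlog = density_sdlog,
                 density_cor = density_cor,
                 true_cutoffs = true_cutoffs,
                 true_log_hr = true_log_hr,
                 covariate_prevalence = covariate_prevalence,
                 covariate_log_hr = covariate_log_hr,
                 baseline_shape = baseline_shape,
                 baseline_scale = baseline_scale,
                 censor_horizon = censor_horizon,
                 dropout_frac = dropout_frac,
                 dfs_coupling = dfs_coupling,
                 recurrence_base_prob = recurrence_base_prob,
                 nac_intercept = nac_intercept,
                 nac_slope = nac_slope,
                 missing_frac = missing_frac),
            class = "til_sim_config")
}

.named4 <- function(x, what) {
  .assert(is.numeric(x) && all(TIL_COMPARTMENTS %in% names(x)),
          sprintf("`%s` must be numeric and name cd3_ct, cd3_im, cd8_ct, cd8_im",
                  what))
  x[TIL_COMPARTMENTS]
}

.as_cor_matrix <- function(density_cor) {
  if (is.matrix(density_cor)) {
    m <- density_cor
  } else {
    .assert(is.numeric(density_cor) && length(density_cor) == 1 &&
              density_cor >= 0 && density_cor < 1,
            "scalar `density_cor` must lie in [0, 1)")
    m <- matrix(density_cor, 4, 4)
    diag(m) <- 1
  }
  .assert(nrow(m) == 4 && ncol(m) == 4, "correlation matrix must be 4x4")
  .assert(isTRUE(all.equal(m, t(m))), "correlation matrix must be symmetric")
  .assert(isTRUE(all.equal(unname(diag(m)), rep(1, 4))),
          "correlation matrix must have unit diagonal")
  ch <- tryCatch(chol(m), error = function(e) NULL)
  if (is.null(ch)) stop("correlation matrix must be positive-definite",
                        call. = FALSE)
  dimnames(m) <- list(TIL_COMPARTMENTS, TIL_COMPARTMENTS)
  m
}

# population-average linear predictor under a configuration; subtracting it
# centres the hazard so baseline_scale keeps its intended interpretation
.expected_lp <- function(cfg) {
  p_high <- pnorm((cfg$density_meanlog - log(cfg$true_cutoffs)) /
                    cfg$density_sdlog)
  sum(cfg$true_log_hr * p_high) +
    sum(cfg$covariate_log_hr * cfg$covariate_prevalence)
}

#' Generate a synthetic cohort of cystectomy patients
#'
#' Draws `n_patients` records under the model described in [sim_config()]:
#' correlated log-normal CD3/CD8 densities in tumor core (CT) and invasive
#' margin (IM), Bernoulli clinical covariates, Weibull proportional-hazards
#' overall survival driven by the dichotomized densities and covariates,
#' disease-free survival coupled to OS (DFS <= OS for every patient), and
#' administrative-plus-dropout censoring. A neoadjuvant-chemotherapy response
#' flag is simulated for chemotherapy-treated patients with response
#' probability increasing in CD8(IM) density.
#'
#' @param config A [sim_config()] object.
#' @return A data.frame with one row per patient and columns `patient_id`,
#'   the four density columns (`cd3_ct`, `cd3_im`, `cd8_ct`, `cd8_im`,
#'   cells/mm^2), the binary covariates, `nac_response` (0/1, `NA` for
#'   patients without chemotherapy), `os_months`, `os_event`, `dfs_months`,
#'   `dfs_event`.
#' @examples
#' cohort <- generate_cohort(sim_config(seed = 7, n_patients = 67))
#' stopifnot(nrow(cohort) == 67, all(cohort$dfs_months <= cohort$os_months))
#' @export
generate_cohort <- function(config) {
  .assert(inherits(config, "til_sim_config"),
          "`config` must be created by sim_config()")
  withr::with_seed(config$seed, .generate_cohort_impl(config))
}

#' Generate a null cohort (densities independent of survival)
#'
#' Identical to [generate_cohort()] except that every compartment log hazard
#' ratio is forced to zero, so TIL densities carry no survival information.
#' Used to study the type-I error of outcome-based cutpoint selection.
#'
#' @inheritParams generate_cohort
#' @return As [generate_cohort()].
#' @export
generate_null_cohort <- function(config) {
  .assert(inherits(config, "til_sim_config"),
          "`config` must be created by sim_config()")
  config$true_log_hr[] <- 0
  generate_cohort(config)
}

.generate_cohort_impl <- function(cfg) {
  n <- cfg$n_patients

  z <- matrix(rnorm(n * 4), n, 4) %*% chol(cfg$density_cor)
  logd <- sweep(sweep(z, 2, cfg$density_sdlog, "*"), 2,
                cfg$density_meanlog, "+")
  dens <- exp(logd)
  colnames(dens) <- colnames(logd) <- TIL_COMPARTMENTS

  covs <- vapply(TIL_COVARIATES,
                 function(v) rbinom(n, 1L, cfg$covariate_prevalence[[v]]),
                 integer(n))
  if (n == 1) covs <- matrix(covs, 1, dimnames = list(NULL, TIL_COVARIATES))

  high <- sweep(dens, 2, cfg$true_cutoffs, ">") * 1
  lp <- as.vector(high %*% cfg$true_log_hr + covs %*% cfg$covariate_log_hr) -
    .expected_lp(cfg)

  # inverse-transform sampling from S(t) = exp(-(t/scale)^shape * e^lp)
  u <- runif(n)
  t_os <- cfg$baseline_scale *
    (-log(u) * exp(-lp))^(1 / cfg$baseline_shape)

  dropout <- runif(n) < cfg$dropout_frac
  cens <- ifelse(dropout, runif(n, 0, cfg$censor_horizon), cfg$censor_horizon)

  os_months <- pmin(t_os, cens)
  os_event <- as.integer(t_os <= cens)

  p_rec <- plogis(qlogis(cfg$recurrence_base_prob) + cfg$dfs_coupling * lp)
  recur <- runif(n) < p_rec
  t_dfs <- ifelse(recur, t_os * rbeta(n, 5, 2), t_os)
  dfs_months <- pmin(t_dfs, cens)
  dfs_event <- as.integer(t_dfs <= cens)

  nac_response <- rep(NA_integer_, n)
  p_resp <- plogis(cfg$nac_intercept +
                     cfg$nac_slope * (logd[, "cd8_im"] -
                                        log(cfg$true_cutoffs[["cd8_im"]])))
  resp_draw <- runif(n)
  treated <- covs[, "chemo"] == 1L
  nac_response[treated] <- as.integer(resp_draw[treated] < p_resp[treated])

  if (cfg$missing_frac > 0) {
    for (j in seq_len(ncol(dens))) {
      dens[runif(n) < cfg$missing_frac, j] <- NA_real_
    }
  }

  out <- data.frame(patient_id = sprintf("P%04d", seq_len(n)),
                    dens,
                    covs,
                    nac_response = nac_response,
                    os_months = os_months,
                    os_event = os_event,
                    dfs_months = dfs_months,
                    dfs_event = dfs_event,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Configuration for a synthetic expression matrix
#'
#' Generative model for [generate_expression()]: log-scale expression for
#' `n_genes` genes across `n_luminal` + `n_basal` samples, Gaussian noise
#' around gene-specific baselines, with a designated cytotoxicity gene set
#' shifted upward by `effect_size` in the basal group.
#'
#' @param seed Integer seed.
#' @param n_genes Total number of genes (>= 200).
#' @param n_luminal,n_basal Samples per subtype (defaults 121 and 68, the
#'   sizes of the luminal/basal contrast the stage emulates).
#' @param n_cytotoxicity_genes Size of the shifted T-cell-cytotoxicity gene
#'   set (default 113); must not exceed `n_genes`.
#' @param effect_size Mean log-expression shift of set members in basal
#'   samples.
#' @param noise_sd Within-group Gaussian noise SD (> 0).
#' @param baseline_mean,baseline_sd Distribution of gene-level baseline
#'   log-expression.
#' @return An object of class `til_expression_sim_config`.
#' @export
expression_sim_config <- function(seed = 1L,
                                  n_genes = 500L,
                                  n_luminal = 121L,
                                  n_basal = 68L,
                                  n_cytotoxicity_genes = 113L,
                                  effect_size = 2,
                                  noise_sd = 1,
                                  baseline_mean = 6,
                                  baseline_sd = 1.5) {
  .assert(n_genes >= 200, "`n_genes` must be >= 200")
  .assert(n_luminal >= 2 && n_basal >= 2,
          "each subtype needs at least 2 samples")
  .assert(n_cytotoxicity_genes >= 1 && n_cytotoxicity_genes <= n_genes,
          "`n_cytotoxicity_genes` must lie in [1, n_genes]")
  .assert(noise_sd > 0, "`noise_sd` must be > 0")
  structure(list(seed = as.integer(seed),
                 n_genes = as.integer(n_genes),
                 n_luminal = as.integer(n_luminal),
                 n_basal = as.integer(n_basal),
                 n_cytotoxicity_genes = as.integer(n_cytotoxicity_genes),
                 effect_size = effect_size,
                 noise_sd = noise_sd,
                 baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd),
            class = "til_expression_sim_config")
}

#' Generate a synthetic luminal/basal expression matrix and gene set
#'
#' @param config An [expression_sim_config()] object.
#' @return A list with `expression` (genes x samples numeric matrix of
#'   log-scale values), `labels` (data.frame `sample_id`, `subtype` with
#'   values "luminal"/"basal") and `gene_set` (character vector of the
#'   cytotoxicity member gene IDs).
#' @examples
#' sim <- generate_expression(expression_sim_config(seed = 3))
#' stopifnot(ncol(sim$expression) == 189, length(sim$gene_set) == 113)
#' @export
generate_expression <- function(config) {
  .assert(inherits(config, "til_expression_sim_config"),
          "`config` must be created by expression_sim_config()")
  withr::with_seed(config$seed, {
    g <- config$n_genes
    ids <- sprintf("GENE%05d", seq_len(g))
    n_samp <- config$n_luminal + config$n_basal
    sample_id <- c(sprintf("LUM%03d", seq_len(config$n_luminal)),
                   sprintf("BAS%03d", seq_len(config$n_basal)))
    subtype <- rep(c("luminal", "basal"),
                   c(config$n_luminal, config$n_basal))

    mu <- rnorm(g, config$baseline_mean, config$baseline_sd)
    mat <- mu + matrix(rnorm(g * n_samp, 0, config$noise_sd), g, n_samp)
    dimnames(mat) <- list(ids, sample_id)

    members <- sort(sample(ids, config$n_cytotoxicity_genes))
    mat[members, subtype == "basal"] <-
      mat[members, subtype == "basal"] + config$effect_size

    list(expression = mat,
         labels = data.frame(sample_id = sample_id, subtype = subtype,
                             stringsAsFactors = FALSE),
         gene_set = members)
  })
}
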