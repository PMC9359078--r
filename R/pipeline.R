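#' End-to-end pipeline orchestration
#'
#' File-based pipeline stages mirroring a full analysis: simulate a
#' synthetic registry, prepare stratified counts from raw records,
#' fit the family x prior model grid with PSIS-LOO comparison, delineate
#' catchment areas across thresholds, and analyse membership
#' determinants. Every stage is reproducible under the configuration
#' seed; per-stage seeds are derived deterministically from the stage
#' name so stages can be rerun independently.
#'
#' @name pipeline
NULL

stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) + h) %% .Machine$integer.max
}

#' Pipeline configuration
#'
#' @param outdir Output directory (created if missing).
#' @param buffer_km Buffer radius around the hospital (233 km default,
#'   the 145-mile convention).
#' @param scheme A [period_scheme].
#' @param species_rates Animals per household.
#' @param families,priors Model grid to fit.
#' @param chains,iter,warmup_frac MCMC settings.
#' @param thresholds Exceedance thresholds to report.
#' @param scale_covariates Scale determinant covariates by SD.
#' @param seed Master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(outdir = ".", buffer_km = 233,
                            scheme = period_scheme(),
                            species_rates = default_species_rates(),
                            families = c("poisson", "zip", "nb", "zinb",
                                         "cmp", "zicmp"),
                            priors = c("exchangeable", "car"),
                            chains = 4, iter = 4000, warmup_frac = 0.25,
                            thresholds = c(0.80, 0.85, 0.90, 0.95),
                            scale_covariates = TRUE, seed = 1) {
  stopifnot(all(thresholds > 0 & thresholds < 1))
  structure(list(outdir = outdir, buffer_km = buffer_km, scheme = scheme,
                 species_rates = species_rates, families = families,
                 priors = priors, chains = chains, iter = iter,
                 warmup_frac = warmup_frac, thresholds = thresholds,
                 scale_covariates = scale_covariates,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Simulate a synthetic scenario to files
#'
#' Writes `records.csv`, `tracts.geojson`, `counts.csv` and
#' `truth.json` into `outdir`.
#'
#' @param config A [pipeline_config].
#' @param scenario A [scenario_config] (its own seed is replaced by the
#'   pipeline's derived stage seed for reproducibility under the master
#'   seed).
#' @return Invisibly, the paths written.
#' @export
run_simulate <- function(config, scenario = scenario_config()) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  scenario$seed <- stage_seed(config$seed, "simulate")
  sc <- make_scenario(scenario, config$scheme)
  rec <- make_visit_records(sc$counts, config$scheme,
                            seed = stage_seed(config$seed, "records"))
  paths <- file.path(config$outdir,
                     c("records.csv", "tracts.geojson", "counts.csv",
                       "truth.json"))
  utils::write.csv(transform(rec, cancer = as.integer(cancer)), paths[1],
                   row.names = FALSE, quote = FALSE)
  write_tracts_geojson(sc$graph, paths[2])
  write_counts_csv(sc$counts, paths[3])
  write_truth_json(sc$truth, paths[4])
  message("simulated scenario: ", nrow(sc$counts), " strata, ",
          sum(sc$counts$y_visits), " visits")
  invisible(paths)
}

#' Prepare stratified counts from raw records and geography
#'
#' Buffer filter, deduplication, stratification and expected-count
#' offsets; logs the percentage of records retained by the buffer.
#'
#' @param config A [pipeline_config].
#' @param records Records data frame (or CSV path).
#' @param graph A [tract_graph] (or GeoJSON path plus `hospital`).
#' @param hospital `c(lon, lat)`, used when `graph` is a path.
#' @return List with `counts` and the filtered `graph`; also writes
#'   `prepared_counts.csv` into `outdir`.
#' @export
run_prepare <- function(config, records, graph, hospital = NULL) {
  if (is.character(records)) records <- read_records_csv(records)
  if (is.character(graph)) {
    if (is.null(hospital)) stop("run_prepare: hospital coordinates required")
    graph <- read_tracts_geojson(graph, hospital)
  }
  g <- filter_buffer(graph, config$buffer_km)
  keep <- records$tract_id %in% tract_ids(g)
  message(sprintf("buffer retained %d/%d records (%.1f%%)",
                  sum(keep), nrow(records), 100 * mean(keep)))
  rec <- deduplicate(records[keep, , drop = FALSE])
  counts <- expected_counts(stratify(rec, g, config$scheme,
                                     config$species_rates))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  write_counts_csv(counts, file.path(config$outdir, "prepared_counts.csv"))
  list(counts = counts, graph = g)
}

#' Fit the model grid and compare by PSIS-LOO
#'
#' Loops the configured family x prior grid for one outcome, computes
#' PSIS-LOO for each fit, and writes a ranked comparison table
#' (`comparison_<outcome>.csv`). Individual model failures are logged
#' and the grid continues.
#'
#' @param config A [pipeline_config].
#' @param counts,graph Prepared counts and graph.
#' @param outcome `"visits"` or `"cancer"`.
#' @return List with `fits` (named), `loos` (named), and the comparison
#'   data frame (`comparison`; best model first).
#' @export
run_fit_grid <- function(config, counts, graph,
                         outcome = c("visits", "cancer")) {
  outcome <- match.arg(outcome)
  fits <- list(); loos <- list()
  for (fam in config$families) for (pr in config$priors) {
    key <- paste(fam, pr, sep = "+")
    res <- tryCatch({
      spec <- model_spec(fam, pr, outcome = outcome)
      fit <- fit_spatial_count(counts, graph, spec,
                               chains = config$chains, iter = config$iter,
                               warmup_frac = config$warmup_frac,
                               seed = stage_seed(config$seed, key))
      list(fit = fit, loo = psis_loo(pointwise_loglik(fit, counts, graph)))
    }, error = function(e) {
      message("model ", key, " failed: ", conditionMessage(e))
      NULL
    })
    if (!is.null(res)) {
      fits[[key]] <- res$fit
      loos[[key]] <- res$loo
    }
  }
  if (!length(loos)) stop("run_fit_grid: every model failed")
  cmp <- loo_compare(loos)
  cmp$family <- sub("\\+.*", "", cmp$model)
  cmp$prior <- sub(".*\\+", "", cmp$model)
  cmp$best <- seq_len(nrow(cmp)) == 1
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cmp[, c("family", "prior", "elpd_loo", "se", "elpd_diff",
                           "se_diff", "max_pareto_k", "n_bad_k", "best")],
                   file.path(config$outdir,
                             paste0("comparison_", outcome, ".csv")),
                   row.names = FALSE, quote = FALSE)
  list(fits = fits, loos = loos, comparison = cmp)
}

#' Delineate catchment areas across thresholds
#'
#' Exceedance probabilities, one [catchment_area] per configured
#' threshold with primary/secondary split and coverage; writes a CA CSV
#' per threshold and a `ca_summary_<outcome>.json`.
#'
#' @param config A [pipeline_config].
#' @param fit A `posterior_draws` (missing draws raise an error).
#' @param counts,graph Prepared counts and graph.
#' @return List with `exceedance`, `cas` (by threshold label) and
#'   `summary`.
#' @export
run_delineate <- function(config, fit, counts, graph) {
  if (!inherits(fit, "posterior_draws")) {
    stop("run_delineate: posterior draws required")
  }
  outcome <- fit$spec$outcome
  q <- exceedance(fit)
  cas <- list(); summ <- list()
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  for (th in config$thresholds) {
    lab <- sprintf("%.2f", th)
    ca <- catchment_area(q, graph, th, outcome = outcome)
    cov <- coverage(ca, counts, graph, outcome = outcome)
    cas[[lab]] <- ca
    summ[[lab]] <- list(n_members = cov$n_members,
                        n_primary = length(ca$primary),
                        n_secondary = length(ca$secondary),
                        pct_tracts = cov$pct_tracts_in_ca,
                        pct_records = cov$pct_records_in_ca)
    write_ca_csv(ca, file.path(config$outdir,
                               sprintf("ca_%s_%s.csv", outcome, lab)))
  }
  jsonlite::write_json(summ,
                       file.path(config$outdir,
                                 paste0("ca_summary_", outcome, ".json")),
                       auto_unbox = TRUE, digits = NA)
  list(exceedance = q, cas = cas, summary = summ)
}

#' Determinant analysis of a catchment area
#'
#' Fits the three nested logistic models (distance; + income;
#' + interaction), reports AUC for each, and compares mean income
#' between member and non-member tracts. Writes coefficient and ROC
#' CSVs.
#'
#' @param config A [pipeline_config].
#' @param ca A [catchment_area].
#' @param graph A [tract_graph].
#' @param distance Optional per-tract distance override (km).
#' @return List with `fits` (named: distance, income, interaction),
#'   `aucs`, `rocs`, `group_income` (means/F/p), and the covariates.
#' @export
run_determinants <- function(config, ca, graph, distance = NULL) {
  cov <- prepare_covariates(graph, distance = distance,
                            scale = config$scale_covariates)
  member <- cov$tract_id %in% ca$members
  fits <- list(
    distance = fit_logistic_formula(member, cov, member ~ distance),
    income = fit_logistic_formula(member, cov, member ~ distance + income),
    interaction = fit_logistic(member, cov, interaction = TRUE))
  rocs <- lapply(fits, function(f) {
    roc_auc(stats::fitted(f$glm), member)
  })
  aucs <- vapply(rocs, function(r) r$auc, numeric(1))
  inc <- stats::setNames(graph$tracts$avg_income, tract_ids(graph))
  gi <- compare_group_means(inc[cov$tract_id], member)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  ctab <- do.call(rbind, lapply(names(fits), function(nm) {
    cbind(model = nm, fits[[nm]]$coefficients)
  }))
  utils::write.csv(ctab, file.path(config$outdir, "determinant_coefs.csv"),
                   row.names = FALSE, quote = FALSE)
  rtab <- do.call(rbind, lapply(names(rocs), function(nm) {
    data.frame(model = nm, threshold = rocs[[nm]]$thresholds,
               tpr = rocs[[nm]]$tpr, fpr = rocs[[nm]]$fpr)
  }))
  utils::write.csv(rtab, file.path(config$outdir, "determinant_roc.csv"),
                   row.names = FALSE, quote = FALSE)
  list(fits = fits, aucs = aucs, rocs = rocs, group_income = gi,
       covariates = cov)
}

# nested-model variant of fit_logistic with an explicit formula
fit_logistic_formula <- function(member, covars, form) {
  y <- as.integer(member)
  if (length(unique(y)) < 2) stop("membership is constant")
  df <- data.frame(member = y, distance = covars$distance_km,
                   income = covars$income_k)
  g <- stats::glm(form, family = stats::binomial(), data = df,
                  control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  cf <- summary(g)$coefficients
  an <- stats::anova(g)
  structure(list(coefficients = data.frame(
                   term = rownames(cf), estimate = cf[, 1], se = cf[, 2],
                   or = exp(cf[, 1]),
                   or_lo = exp(cf[, 1] - 1.96 * cf[, 2]),
                   or_hi = exp(cf[, 1] + 1.96 * cf[, 2]), row.names = NULL),
                 seq_deviance = data.frame(term = rownames(an)[-1],
                                           deviance = an$Deviance[-1],
                                           row.names = NULL),
                 null_deviance = g$null.deviance,
                 residual_deviance = g$deviance, glm = g,
                 centers = attr(covars, "centers"),
                 scales = attr(covars, "scales")),
            class = "determinant_fit")
}
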