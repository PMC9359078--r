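#' Synthetic registry scenarios with known ground truth
#'
#' Generates a rectangular grid of square "census tracts" around a
#' hospital, spatially correlated tract effects from the intrinsic CAR
#' distribution, and stratified registry counts from the same
#' zero-inflated count model the pipeline fits -- so every parameter has
#' a known true value and catchment recovery can be scored exactly.
#'
#' @name synthdata
NULL

#' Scenario configuration
#'
#' Defaults describe the package's reference scenario: a 20 x 20 tract
#' grid (400 tracts, 3,200 strata over 2 species x 4 periods), queen
#' adjacency, visit totals on the order of 10^4, CAR precision `tau = 0.25`
#' (marginal tract-effect SD about 1.1: tract relative risks span roughly a
#' factor of ten between well- and poorly-captured tracts, as expected of
#' hospital attendance), species effect log(3) (dogs vs cats), mild period drift, a structural-zero share of about 25%, and
#' negative-binomial dispersion 5 (mild residual overdispersion). Income declines with distance from
#' the hospital.
#'
#' @param grid_rows,grid_cols Grid dimensions (>= 2).
#' @param cell_km Tract cell edge length in km.
#' @param hospital_cell `c(row, col)` of the hospital's tract (default:
#'   the grid centre).
#' @param households_range `c(min, max)` uniform integer household counts.
#' @param income_model List with `base` (USD at the hospital),
#'   `distance_slope` (USD lost per km) and `noise_sd` (USD); incomes are
#'   floored at 10,000.
#' @param tau Intrinsic-CAR precision of the tract effects.
#' @param beta_count,beta_zero Coefficient sets: lists with `intercept`,
#'   `species` (canine vs feline) and `period` (P2--P4 vs P1 contrasts);
#'   `beta_zero` parameterises the structural-zero logit.
#' @param family Likelihood family for the counts.
#' @param dispersion NB shape / CMP decay parameter.
#' @param visit_rate Baseline expected visits per animal per period
#'   (sets the offset scale).
#' @param cancer_frac Thinning probability turning a visit into a cancer
#'   case (the registry-wide cancer/visit ratio is about 0.118).
#' @param species_rates Animals per household, see
#'   [default_species_rates].
#' @param seed Integer seed governing all randomness of the scenario.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(grid_rows = 20, grid_cols = 20, cell_km = 3,
                            hospital_cell = NULL,
                            households_range = c(400, 2500),
                            income_model = list(base = 90000,
                                                distance_slope = 300,
                                                noise_sd = 12000),
                            tau = 0.25,
                            beta_count = list(intercept = 0,
                                              species = log(3),
                                              period = c(0.02, 0.1, 0.3)),
                            beta_zero = list(intercept = -1.1,
                                             species = 0,
                                             period = c(0, 0, 0)),
                            family = "zinb", dispersion = 5,
                            visit_rate = 8e-4, cancer_frac = 0.118,
                            species_rates = default_species_rates(),
                            seed = 20220725) {
  stopifnot(grid_rows >= 2, grid_cols >= 2, tau > 0, cell_km > 0,
            visit_rate > 0, cancer_frac >= 0, cancer_frac <= 1)
  family <- match.arg(family, c("poisson", "zip", "nb", "zinb", "cmp", "zicmp"))
  if (is.null(hospital_cell)) {
    hospital_cell <- c(ceiling(grid_rows / 2), ceiling(grid_cols / 2))
  }
  structure(list(grid_rows = grid_rows, grid_cols = grid_cols,
                 cell_km = cell_km, hospital_cell = hospital_cell,
                 households_range = households_range,
                 income_model = income_model, tau = tau,
                 beta_count = beta_count, beta_zero = beta_zero,
                 family = family, dispersion = dispersion,
                 visit_rate = visit_rate, cancer_frac = cancer_frac,
                 species_rates = species_rates, seed = as.integer(seed)),
            class = "scenario_config")
}

# grid anchored near Davis, CA; local equirectangular cell sizing
GRID_ORIGIN <- c(lon = -121.75, lat = 38.55)

#' Build the synthetic grid geography
#'
#' `rows x cols` square tracts with queen adjacency (built
#' combinatorially from grid indices), uniform household counts, and
#' average income decreasing with distance from the hospital.
#'
#' @param config A [scenario_config].
#' @return A [tract_graph] with polygons attached. Tract ids are
#'   `"r<row>c<col>"`.
#' @export
make_grid_region <- function(config) {
  set.seed(config$seed)
  nr <- config$grid_rows; nc <- config$grid_cols
  dlat <- config$cell_km / 110.574
  dlon <- config$cell_km / (111.320 * cos(GRID_ORIGIN["lat"] * pi / 180))
  id_of <- function(r, c) sprintf("r%02dc%02d", r, c)
  grid <- expand.grid(row = seq_len(nr), col = seq_len(nc),
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$row, grid$col), ]
  lon0 <- unname(GRID_ORIGIN["lon"]); lat0 <- unname(GRID_ORIGIN["lat"])
  cx <- lon0 + (grid$col - 0.5) * dlon
  cy <- lat0 + (grid$row - 0.5) * dlat
  ids <- id_of(grid$row, grid$col)
  polys <- lapply(seq_along(ids), function(i) {
    x0 <- lon0 + (grid$col[i] - 1) * dlon; x1 <- x0 + dlon
    y0 <- lat0 + (grid$row[i] - 1) * dlat; y1 <- y0 + dlat
    cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
  })
  names(polys) <- ids
  hosp <- c(lon0 + (config$hospital_cell[2] - 0.5) * dlon,
            lat0 + (config$hospital_cell[1] - 0.5) * dlat)
  hh <- sample(config$households_range[1]:config$households_range[2],
               length(ids), replace = TRUE)
  dist_km <- haversine_km(cbind(cx, cy),
                          matrix(hosp, length(ids), 2, byrow = TRUE))
  im <- config$income_model
  income <- pmax(10000, im$base - im$distance_slope * dist_km +
                          stats::rnorm(length(ids), 0, im$noise_sd))
  tracts <- data.frame(tract_id = ids, lon = cx, lat = cy,
                       households = as.integer(hh), avg_income = income)
  # queen adjacency from grid indices
  ea <- character(0); eb <- character(0)
  for (dr in 0:1) for (dc in -1:1) {
    if (dr == 0 && dc != 1) next     # enumerate each pair once
    r2 <- grid$row + dr; c2 <- grid$col + dc
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    ea <- c(ea, ids[ok]); eb <- c(eb, id_of(r2[ok], c2[ok]))
  }
  tract_graph(tracts, data.frame(tract_a = ea, tract_b = eb),
              hospital = hosp, polygons = polys)
}

#' Draw from the intrinsic CAR distribution over a tract graph
#'
#' Exact sampling by eigendecomposition of the graph Laplacian
#' `L = D - W`: within each connected component the coefficient on each
#' eigenvector with eigenvalue `lambda_k > 0` is drawn
#' `Normal(0, 1/(tau * lambda_k))` and the null-space coefficient is set
#' to 0, which enforces the per-component sum-to-zero constraint exactly.
#' Isolated tracts get independent `Normal(0, 1/tau)`.
#'
#' @param graph A [tract_graph].
#' @param tau Positive precision.
#' @param seed Optional integer seed.
#' @return Named vector of tract effects (sum approx 0 per component).
#' @export
sample_icar <- function(graph, tau, seed = NULL) {
  stopifnot(tau > 0)
  if (!is.null(seed)) set.seed(seed)
  ids <- tract_ids(graph)
  nu <- stats::setNames(numeric(length(ids)), ids)
  comps <- graph_components(graph)
  ei <- edge_indices(graph)
  for (comp in comps) {
    k <- match(comp, ids)
    if (length(k) == 1) {            # isolated tract
      nu[k] <- stats::rnorm(1, 0, sqrt(1 / tau))
      next
    }
    sub <- ei[ei[, 1] %in% k & ei[, 2] %in% k, , drop = FALSE]
    li <- match(sub[, 1], k); lj <- match(sub[, 2], k)
    n <- length(k)
    L <- matrix(0, n, n)
    for (m in seq_along(li)) {
      L[li[m], lj[m]] <- L[li[m], lj[m]] - 1
      L[lj[m], li[m]] <- L[lj[m], li[m]] - 1
      L[li[m], li[m]] <- L[li[m], li[m]] + 1
      L[lj[m], lj[m]] <- L[lj[m], lj[m]] + 1
    }
    ev <- eigen(L, symmetric = TRUE)
    pos <- ev$values > 1e-8
    z <- stats::rnorm(sum(pos), 0, sqrt(1 / (tau * ev$values[pos])))
    nu[k] <- as.numeric(ev$vectors[, pos, drop = FALSE] %*% z)
  }
  nu
}

# design matrix for the stratified grid: intercept, canine, P2..P4
strata_design <- function(counts, period_labels = NULL) {
  if (is.null(period_labels)) period_labels <- unique(counts$period)
  X <- cbind(1, as.numeric(counts$species == "canine"))
  for (p in period_labels[-1]) X <- cbind(X, as.numeric(counts$period == p))
  colnames(X) <- c("intercept", "canine",
                   paste0("period", period_labels[-1], recycle0 = TRUE))
  X
}

beta_vector <- function(beta, n_period_contrasts) {
  b <- c(beta$intercept, beta$species, beta$period)
  if (length(b) != 2 + n_period_contrasts) {
    stop("coefficient set has wrong length for the period scheme")
  }
  b
}

draw_family <- function(n, mu, family, shape) {
  switch(family,
    poisson = , zip = stats::rpois(n, mu),
    nb = , zinb = stats::rnbinom(n, size = shape, mu = mu),
    cmp = , zicmp = {
      lam <- cmp_mean_to_lambda(mu, shape)
      vapply(lam, function(l) {
        lz <- cmp_lognorm(l, shape)
        jmax <- 10
        repeat {
          j <- 0:jmax
          p <- exp(j * log(l) - shape * lgamma(j + 1) - lz)
          if (sum(p) > 1 - 1e-10 || jmax > 1e4) break
          jmax <- jmax * 2
        }
        sample(j, 1, prob = p)
      }, numeric(1))
    })
}

#' Simulate stratified counts from the generative model
#'
#' For each stratum, `mu = e * exp(eta_count)` with
#' `eta_count = X beta_count + nu_count[tract]`; zero-inflated families
#' additionally draw a structural zero with probability
#' `plogis(X beta_zero + nu_zero[tract])`. Offsets are
#' `e = visit_rate * population`. Cancer cases are binomial thinnings of
#' visits with probability `cancer_frac`, guaranteeing
#' `y_cancer <= y_visits`.
#'
#' @param graph A [tract_graph].
#' @param nu List with `count` and `zero` named tract-effect vectors.
#' @param config A [scenario_config].
#' @param scheme A [period_scheme].
#' @return A `stratified_counts` data frame with `e_visits`/`e_cancer`
#'   filled by [expected_counts] from the realised totals.
#' @export
simulate_counts <- function(graph, nu, config, scheme = period_scheme()) {
  counts <- stratify(
    data.frame(animal_id = character(0), species = character(0),
               year = integer(0), cancer = logical(0),
               tract_id = character(0)),
    graph, scheme, rates = config$species_rates)
  X <- strata_design(counts, scheme$label)
  bC <- beta_vector(config$beta_count, nrow(scheme) - 1)
  e <- config$visit_rate * counts$population
  t_idx <- match(counts$tract_id, tract_ids(graph))
  eta_c <- as.numeric(X %*% bC) + nu$count[t_idx]
  mu <- e * exp(eta_c)
  if (any(!is.finite(mu)) || any(mu > 1e9)) {
    stop("simulate_counts: mean overflow (mu > 1e9); use smaller coefficients")
  }
  n <- nrow(counts)
  y <- draw_family(n, mu, config$family, config$dispersion)
  if (config$family %in% c("zip", "zinb", "zicmp")) {
    bZ <- beta_vector(config$beta_zero, nrow(scheme) - 1)
    pi <- stats::plogis(as.numeric(X %*% bZ) + nu$zero[t_idx])
    y[stats::runif(n) < pi] <- 0L
  }
  counts$y_visits <- as.integer(y)
  counts$y_cancer <- as.integer(stats::rbinom(n, counts$y_visits,
                                              config$cancer_frac))
  expected_counts(counts)
}

#' Expand stratified counts into raw visit records
#'
#' Fabricates one record per counted visit (unique animal ids, years
#' uniform within the period), flags `y_cancer` of them as cancer cases,
#' and adds duplicate same-year visits for a fraction `dup_rate` of
#' animals (cancer animals get a non-cancer extra visit) so that
#' [deduplicate] + [stratify] reproduce the counts exactly.
#'
#' @param counts Stratified counts.
#' @param scheme A [period_scheme].
#' @param dup_rate Fraction of animals given a duplicate same-year visit.
#' @param seed Optional seed.
#' @return Records data frame in shuffled order.
#' @export
make_visit_records <- function(counts, scheme = period_scheme(),
                               dup_rate = 0.15, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tot <- sum(counts$y_visits)
  if (tot == 0) {
    return(data.frame(animal_id = character(0), species = character(0),
                      year = integer(0), cancer = logical(0),
                      tract_id = character(0)))
  }
  rows <- counts[counts$y_visits > 0, ]
  idx <- rep(seq_len(nrow(rows)), rows$y_visits)
  per <- match(rows$period[idx], scheme$label)
  year <- scheme$start[per] +
    floor(stats::runif(tot) * (scheme$end[per] - scheme$start[per] + 1))
  cancer <- unlist(lapply(seq_len(nrow(rows)), function(i) {
    c(rep(TRUE, rows$y_cancer[i]),
      rep(FALSE, rows$y_visits[i] - rows$y_cancer[i]))
  }))
  rec <- data.frame(animal_id = sprintf("A%07d", seq_len(tot)),
                    species = rows$species[idx],
                    year = as.integer(year),
                    cancer = cancer,
                    tract_id = rows$tract_id[idx])
  dup <- rec[stats::runif(tot) < dup_rate, ]
  dup$cancer <- FALSE                 # follow-up visits carry no new diagnosis
  rec <- rbind(rec, dup)
  rec[sample(nrow(rec)), , drop = FALSE]
}

#' Generate a complete synthetic scenario
#'
#' Composes [make_grid_region], [sample_icar] (one draw per model
#' component) and [simulate_counts] under a single seed, and records the
#' ground truth: both tract-effect vectors and the true catchment area
#' `{i : nu_count[i] > 0}`.
#'
#' @param config A [scenario_config].
#' @param scheme A [period_scheme].
#' @return A `ca_scenario` list with elements `graph`, `counts`, `truth`
#'   (fields `nu_count`, `nu_zero`, `true_ca`, `config`).
#' @export
make_scenario <- function(config = scenario_config(),
                          scheme = period_scheme()) {
  graph <- make_grid_region(config)       # seeds at config$seed
  nu_count <- sample_icar(graph, config$tau)
  nu_zero <- sample_icar(graph, config$tau)
  counts <- simulate_counts(graph, list(count = nu_count, zero = nu_zero),
                            config, scheme)
  truth <- list(nu_count = nu_count, nu_zero = nu_zero,
                true_ca = names(nu_count)[nu_count > 0],
                config = config)
  structure(list(graph = graph, counts = counts, truth = truth,
                 scheme = scheme),
            class = "ca_scenario")
}

#' @export
print.ca_scenario <- function(x, ...) {
  cat("ca_scenario:", nrow(x$graph$tracts), "tracts,",
      nrow(x$counts), "strata\n")
  cat("  total visits:", sum(x$counts$y_visits),
      " cancer:", sum(x$counts$y_cancer), "\n")
  cat("  true catchment:", length(x$truth$true_ca), "tracts\n")
  invisible(x)
}

#' Write / read ground truth JSON
#' @param truth Ground-truth list from [make_scenario].
#' @param path JSON file.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(list(nu_count = as.list(truth$nu_count),
                            nu_zero = as.list(truth$nu_zero),
                            true_ca = truth$true_ca,
                            config = unclass(truth$config)),
                       path, auto_unbox = TRUE, digits = NA)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  list(nu_count = unlist(x$nu_count), nu_zero = unlist(x$nu_zero),
       true_ca = as.character(x$true_ca),
       config = do.call(scenario_config, x$config[setdiff(
         names(x$config), character(0))]))
}
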