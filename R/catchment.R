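#' Catchment-area delineation from posterior tract effects
#'
#' A tract belongs to the catchment area (CA) when its posterior
#' exceedance probability -- the probability that its relative risk
#' exceeds the null value RR = 1, equivalently that its tract random
#' effect exceeds 0 -- passes a threshold (0.90 by convention in disease
#' mapping). Member tracts connected to the hospital's tract form the
#' primary area; detached members form the secondary area.
#'
#' @name catchment
NULL

# round half up to `digits` decimals (matches the reporting convention;
# base round() rounds half to even)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Posterior exceedance probabilities per tract
#'
#' `q_i = Pr(nu_i > 0 | data)`, the share of posterior draws in which
#' the tract's random effect (hence its relative risk `exp(nu_i)`)
#' exceeds the null.
#'
#' @param fit A `posterior_draws`.
#' @param effect Which random-effect vector: `"count"` (default; the
#'   count component drives case intensity), `"zero"`, or `"sum"` (their
#'   sum).
#' @return An `exceedance_result`: named vector `q` plus the draw count.
#' @export
exceedance <- function(fit, effect = c("count", "zero", "sum")) {
  effect <- match.arg(effect)
  m <- switch(effect,
    count = nu_draws(fit, "count"),
    zero = nu_draws(fit, "zero"),
    sum = nu_draws(fit, "count") + nu_draws(fit, "zero"))
  structure(list(q = colMeans(m > 0), n_draws = nrow(m), effect = effect),
            class = "exceedance_result")
}

#' Threshold exceedance probabilities into a membership set
#'
#' Members are tracts with `q_i >= threshold` (closed comparison: the
#' threshold is the minimum qualifying value). Memberships are nested:
#' raising the threshold never adds tracts.
#'
#' @param q An `exceedance_result` (or named probability vector).
#' @param threshold Probability in (0, 1); 0.90 by convention.
#' @return Character vector of member tract ids.
#' @export
delineate <- function(q, threshold = 0.90) {
  stopifnot(threshold > 0, threshold < 1)
  qv <- if (inherits(q, "exceedance_result")) q$q else q
  names(qv)[qv >= threshold]
}

#' Split members into primary and secondary areas
#'
#' The primary area is the connected component (within the membership,
#' under the tract adjacency) containing the hospital's tract; all other
#' member tracts are secondary. If the hospital tract is not a member,
#' the largest member component is primary (ties broken by proximity to
#' the hospital).
#'
#' @param members Character vector of member tract ids.
#' @param graph A [tract_graph].
#' @param hosp_tract Hospital tract id (default [hospital_tract]).
#' @return List with `primary` and `secondary` id vectors.
#' @export
split_primary_secondary <- function(members, graph,
                                    hosp_tract = hospital_tract(graph)) {
  if (!length(members)) {
    warning("empty membership set")
    return(list(primary = character(0), secondary = character(0)))
  }
  comps <- graph_components(graph, subset = members)
  hit <- vapply(comps, function(cc) hosp_tract %in% cc, logical(1))
  if (any(hit)) {
    primary <- comps[[which(hit)]]
  } else {
    sizes <- vapply(comps, length, integer(1))
    cand <- which(sizes == max(sizes))
    if (length(cand) > 1) {
      d <- hospital_distances(graph)
      cand <- cand[which.min(vapply(comps[cand],
                                    function(cc) min(d[cc]), numeric(1)))]
    }
    primary <- comps[[cand[1]]]
  }
  list(primary = primary, secondary = setdiff(members, primary))
}

#' Assemble a catchment area object
#'
#' @param q An `exceedance_result`.
#' @param graph A [tract_graph].
#' @param threshold Exceedance threshold.
#' @param outcome Outcome label (e.g. `"cancer"`, `"visits"`).
#' @param period Period label or `"all"`.
#' @return A `catchment_area`: threshold, member/primary/secondary sets,
#'   the exceedance vector and labels.
#' @export
catchment_area <- function(q, graph, threshold = 0.90, outcome = "visits",
                           period = "all") {
  members <- delineate(q, threshold)
  ps <- if (length(members)) {
    split_primary_secondary(members, graph)
  } else list(primary = character(0), secondary = character(0))
  structure(list(threshold = threshold, members = members,
                 primary = ps$primary, secondary = ps$secondary,
                 q = if (inherits(q, "exceedance_result")) q$q else q,
                 outcome = outcome, period = period,
                 universe = tract_ids(graph)),
            class = "catchment_area")
}

#' @export
print.catchment_area <- function(x, ...) {
  cat("catchment_area (", x$outcome, ", period ", x$period, "): ",
      length(x$members), " members at threshold ", x$threshold,
      " (", length(x$primary), " primary, ", length(x$secondary),
      " secondary)\n", sep = "")
  invisible(x)
}

#' Record and tract coverage of a catchment area
#'
#' Percentage of registry records falling in member tracts and
#' percentage of tracts that are members. Reported percentages are
#' rounded half-up to 1 decimal; full precision is retained in
#' `*_raw`.
#'
#' @param ca A [catchment_area] (or character member vector).
#' @param counts Stratified counts.
#' @param graph A [tract_graph].
#' @param outcome `"visits"` or `"cancer"` count column.
#' @return List: `pct_records_in_ca`, `pct_tracts_in_ca`, `n_members`,
#'   plus unrounded `pct_records_raw` / `pct_tracts_raw`.
#' @export
coverage <- function(ca, counts, graph, outcome = c("visits", "cancer")) {
  outcome <- match.arg(outcome)
  members <- if (inherits(ca, "catchment_area")) ca$members else ca
  ycol <- if (outcome == "visits") counts$y_visits else counts$y_cancer
  tot <- sum(ycol)
  inca <- sum(ycol[counts$tract_id %in% members])
  pr <- if (tot > 0) inca / tot * 100 else 0
  pt <- length(members) / length(tract_ids(graph)) * 100
  list(pct_records_in_ca = round_half_up(pr),
       pct_tracts_in_ca = round_half_up(pt),
       n_members = length(members),
       pct_records_raw = pr, pct_tracts_raw = pt)
}

#' Concordance between two catchment areas
#'
#' Percentage of tracts classified identically (member / non-member) by
#' two catchment areas over the same tract universe.
#'
#' @param ca_a,ca_b [catchment_area] objects (or member id vectors, with
#'   `universe` supplied).
#' @param universe Character vector of all tract ids (taken from the CA
#'   objects when omitted; must agree).
#' @return List: `pct_agree`, `n_agree`, `n_total`, `only_a`, `only_b`
#'   (discordant id sets) and `pct_only_a` / `pct_only_b`.
#' @export
concordance <- function(ca_a, ca_b, universe = NULL) {
  mem <- function(x) if (inherits(x, "catchment_area")) x$members else x
  uni <- function(x) if (inherits(x, "catchment_area")) x$universe else NULL
  if (is.null(universe)) {
    universe <- uni(ca_a)
    if (is.null(universe)) stop("concordance: supply the tract universe")
  }
  ub <- uni(ca_b)
  if (!is.null(ub) && !setequal(universe, ub)) {
    stop("concordance: catchment areas use different tract universes")
  }
  a <- intersect(mem(ca_a), universe)
  b <- intersect(mem(ca_b), universe)
  only_a <- setdiff(a, b)
  only_b <- setdiff(b, a)
  n_total <- length(universe)
  n_agree <- n_total - length(only_a) - length(only_b)
  list(pct_agree = round_half_up(n_agree / n_total * 100),
       n_agree = n_agree, n_total = n_total,
       only_a = only_a, only_b = only_b,
       pct_only_a = round_half_up(length(only_a) / n_total * 100),
       pct_only_b = round_half_up(length(only_b) / n_total * 100))
}

#' Catchment recovery against a known truth
#'
#' Sensitivity and specificity of an estimated membership set against a
#' true one (synthetic scenarios).
#'
#' @param members Estimated member ids.
#' @param true_ca True member ids.
#' @param universe All tract ids.
#' @return List with `sensitivity`, `specificity`.
#' @export
ca_recovery <- function(members, true_ca, universe) {
  pos <- intersect(true_ca, universe)
  neg <- setdiff(universe, pos)
  list(sensitivity = length(intersect(members, pos)) / max(1, length(pos)),
       specificity = length(setdiff(neg, members)) / max(1, length(neg)))
}

#' Per-period catchment areas
#'
#' Refits the model on each period's subset of the grid (species remains
#' a fixed effect), delineates at the threshold, and intersects the
#' period memberships into a combined CA. Pairwise concordances between
#' periods are reported.
#'
#' @param counts Stratified counts (full grid, offsets filled).
#' @param graph A [tract_graph].
#' @param spec A [model_spec].
#' @param scheme The [period_scheme].
#' @param threshold Exceedance threshold.
#' @param chains,iter,warmup_frac,seed MCMC settings per period fit.
#' @return List with `per_period` (named list of [catchment_area]),
#'   `combined` (id vector: intersection over periods), and
#'   `concordance` (data frame of pairwise period concordances).
#' @export
per_period_cas <- function(counts, graph, spec, scheme = period_scheme(),
                           threshold = 0.90, chains = 4, iter = 1000,
                           warmup_frac = 0.25, seed = 1) {
  cas <- list()
  for (p in scheme$label) {
    sub <- counts[counts$period == p, , drop = FALSE]
    ecol <- if (spec$outcome == "visits") "e_visits" else "e_cancer"
    ycol <- if (spec$outcome == "visits") "y_visits" else "y_cancer"
    if (sum(sub[[ycol]]) == 0) {
      warning("period ", p, " has all-zero counts; empty CA")
      cas[[p]] <- catchment_area(
        structure(list(q = stats::setNames(rep(0, length(tract_ids(graph))),
                                           tract_ids(graph)),
                       n_draws = 0, effect = "count"),
                  class = "exceedance_result"),
        graph, threshold, outcome = spec$outcome, period = p)
      next
    }
    # recompute offsets within the period so each fit is self-contained
    sub$e_visits <- sum(sub$y_visits) / sum(sub$population) * sub$population
    sub$e_cancer <- sum(sub$y_cancer) / sum(sub$population) * sub$population
    fit <- fit_spatial_count(sub, graph, spec, chains = chains, iter = iter,
                             warmup_frac = warmup_frac, seed = seed)
    cas[[p]] <- catchment_area(exceedance(fit), graph, threshold,
                               outcome = spec$outcome, period = p)
  }
  combined <- Reduce(intersect, lapply(cas, function(x) x$members))
  pairs <- utils::combn(scheme$label, 2)
  conc <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    cc <- concordance(cas[[pairs[1, k]]], cas[[pairs[2, k]]])
    data.frame(period_a = pairs[1, k], period_b = pairs[2, k],
               pct_agree = cc$pct_agree)
  }))
  list(per_period = cas, combined = combined, concordance = conc)
}

#' Write catchment-area CSV (`tract_id,q,member,zone`)
#'
#' `zone` is `primary`, `secondary` or `outside`.
#' @param ca A [catchment_area].
#' @param path Output CSV.
#' @export
write_ca_csv <- function(ca, path) {
  ids <- ca$universe
  zone <- ifelse(ids %in% ca$primary, "primary",
                 ifelse(ids %in% ca$secondary, "secondary", "outside"))
  utils::write.csv(data.frame(tract_id = ids, q = as.numeric(ca$q[ids]),
                              member = as.integer(ids %in% ca$members),
                              zone = zone),
                   path, row.names = FALSE, quote = FALSE)
}
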