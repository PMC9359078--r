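#' Hierarchical Bayesian count models for catchment delineation
#'
#' Six likelihood families (Poisson, NB, CMP, each with an optional
#' zero-inflation component) crossed with two random-effect priors
#' (exchangeable iid Normal, intrinsic CAR over the tract adjacency).
#' The linear predictors are
#' `log(RR) = b0 + b_species + b_period + nu_count[tract]` and, for
#' zero-inflated families,
#' `logit(pi) = g0 + g_species + g_period + nu_zero[tract]`, with
#' `mu = e * RR`. Fitting is by an adaptive Metropolis-within-Gibbs
#' sampler: per-coordinate adaptive random-walk updates for regression
#' coefficients and dispersion, chromatic (graph-coloured) single-site
#' updates for the tract effects, and conjugate Gibbs draws for the
#' precisions.
#'
#' @name spatial_count_model
NULL

FAMILIES <- c("poisson", "zip", "nb", "zinb", "cmp", "zicmp")

#' Model specification
#'
#' @param family Likelihood family, one of `"poisson"`, `"zip"`, `"nb"`,
#'   `"zinb"`, `"cmp"`, `"zicmp"`.
#' @param re_prior `"car"` (intrinsic CAR over the adjacency) or
#'   `"exchangeable"` (iid Normal).
#' @param outcome `"visits"` or `"cancer"`; selects the count column and
#'   its offset.
#' @param share_random_effect If `TRUE`, zero and count components share
#'   one tract-effect vector; default `FALSE` (separate vectors).
#' @return A `model_spec`.
#' @export
model_spec <- function(family = "zinb", re_prior = c("car", "exchangeable"),
                       outcome = c("visits", "cancer"),
                       share_random_effect = FALSE) {
  family <- match.arg(family, FAMILIES)
  re_prior <- match.arg(re_prior)
  outcome <- match.arg(outcome)
  structure(list(family = family, re_prior = re_prior, outcome = outcome,
                 share_random_effect = share_random_effect,
                 zi = family %in% c("zip", "zinb", "zicmp"),
                 has_shape = family %in% c("nb", "zinb", "cmp", "zicmp")),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("model_spec:", x$family, "+", x$re_prior, "prior, outcome =",
      x$outcome, if (x$share_random_effect) "(shared RE)" else "", "\n")
  invisible(x)
}

#' Default (weakly informative) priors
#'
#' `beta ~ Normal(0, 5^2)`, `tau ~ Gamma(1, 0.01)`, NB shape
#' `~ Gamma(0.01, 0.01)` truncated above `1e-4`, CMP decay
#' `~ LogNormal(0, 1)`.
#' @return Named list of prior hyperparameters.
#' @export
default_priors <- function() {
  list(beta_sd = 5, tau_shape = 1, tau_rate = 0.01,
       shape_a = 0.01, shape_b = 0.01, shape_min = 1e-4,
       cmp_meanlog = 0, cmp_sdlog = 1)
}

# greedy graph colouring; tracts in one colour class share no edge
colour_graph <- function(n, nbr) {
  ord <- order(-vapply(nbr, length, integer(1)))
  col <- integer(n)
  for (i in ord) {
    used <- col[nbr[[i]]]
    k <- 1
    while (k %in% used) k <- k + 1
    col[i] <- k
  }
  col
}

# shared data preparation for fit and pointwise log-lik
build_model_data <- function(counts, graph, spec) {
  ids <- tract_ids(graph)
  if (!all(counts$tract_id %in% ids)) {
    stop("counts reference tracts absent from the graph")
  }
  y <- if (spec$outcome == "visits") counts$y_visits else counts$y_cancer
  ecol <- if (spec$outcome == "visits") "e_visits" else "e_cancer"
  if (!ecol %in% names(counts)) {
    stop("counts lack offset column '", ecol, "'; run expected_counts() first")
  }
  e <- counts[[ecol]]
  if (any(e < 0)) stop("negative offsets")
  if (any(y > 0 & e == 0)) stop("positive count with zero offset")
  per_levels <- unique(counts$period)
  X <- strata_design(counts, per_levels)
  t_idx <- match(counts$tract_id, ids)
  list(y = as.numeric(y), e = as.numeric(e), X = X, t_idx = t_idx,
       ids = ids, per_levels = per_levels, n = nrow(counts),
       p = ncol(X))
}

# count-component log-pmf at y (and at 0 for ZI); returns -Inf rows on
# overflow so proposals are rejected rather than erroring mid-chain
make_count_ll <- function(y, e, family, zi) {
  e0 <- e == 0
  y0 <- rep(0L, length(y))
  function(eta, shape) {
    mu <- e * exp(eta)
    bad <- !is.finite(mu) | mu > 1e9
    mu[bad | e0] <- 1          # placeholder, overwritten below
    ll <- switch(family,
      poisson = , zip = stats::dpois(y, mu, log = TRUE),
      nb = , zinb = stats::dnbinom(y, size = shape, mu = mu, log = TRUE),
      cmp = , zicmp = {
        lam <- cmp_mean_to_lambda(mu, shape)
        cmp_logpmf(y, lam, shape)
      })
    ll0 <- NULL
    if (zi) {
      ll0 <- switch(family,
        zip = -mu,
        zinb = stats::dnbinom(y0, size = shape, mu = mu, log = TRUE),
        zicmp = {
          lam <- cmp_mean_to_lambda(mu, shape)
          cmp_logpmf(y0, lam, shape)
        })
      ll0[e0] <- 0
      ll0[bad] <- -Inf
    }
    ll[e0] <- ifelse(y[e0] == 0, 0, -Inf)
    ll[bad] <- -Inf
    list(ll = ll, ll0 = ll0)
  }
}

# zero-inflation mixing given cached count-component pmfs
make_mix <- function(y, zi) {
  z <- y == 0
  function(cll, eta_z) {
    if (!zi) return(cll$ll)
    lpi <- stats::plogis(eta_z, log.p = TRUE)
    lnp <- stats::plogis(-eta_z, log.p = TRUE)
    ll <- lnp + cll$ll
    a <- lpi[z]; b <- lnp[z] + cll$ll0[z]
    m <- pmax(a, b)
    ll[z] <- m + log(exp(a - m) + exp(b - m))
    ll
  }
}

#' Fit a spatial count model by MCMC
#'
#' @param counts Stratified counts on the complete tract grid with
#'   offsets filled (see [stratify], [expected_counts]).
#' @param graph A [tract_graph] (adjacency required for the CAR prior).
#' @param spec A [model_spec].
#' @param chains Number of chains (default 4).
#' @param iter Total iterations per chain, warmup included (default
#'   4000).
#' @param warmup_frac Fraction of iterations discarded as burn-in
#'   (default 0.25).
#' @param seed Integer seed; chain `k` uses `seed + k - 1`. Identical
#'   seeds give identical draws.
#' @param priors See [default_priors].
#' @param verbose Print progress.
#' @return A `posterior_draws` object: per-chain matrices of retained
#'   draws (columns named `b_*`, `zi_b_*`, `tau_nu`, `tau_zi_nu`,
#'   `shape`, `nu[<tract>]`, `zi_nu[<tract>]`) plus metadata. Carries an
#'   `rhat_flag` attribute when any fixed-effect/precision split-R-hat
#'   exceeds 1.05.
#' @export
fit_spatial_count <- function(counts, graph, spec, chains = 4, iter = 4000,
                              warmup_frac = 0.25, seed = 1,
                              priors = default_priors(), verbose = FALSE) {
  md <- build_model_data(counts, graph, spec)
  n <- md$n; p <- md$p; Tn <- length(md$ids)
  zi <- spec$zi
  shared <- zi && spec$share_random_effect
  warmup <- round(iter * warmup_frac)
  keep <- iter - warmup
  if (keep < 1) stop("warmup leaves no retained iterations")

  # adjacency structures
  ei <- edge_indices(graph)
  deg <- as.integer(tract_degrees(graph))
  nbr <- vector("list", Tn)
  for (k in seq_len(Tn)) nbr[[k]] <- integer(0)
  if (nrow(ei)) {
    for (m in seq_len(nrow(ei))) {
      nbr[[ei[m, 1]]] <- c(nbr[[ei[m, 1]]], ei[m, 2])
      nbr[[ei[m, 2]]] <- c(nbr[[ei[m, 2]]], ei[m, 1])
    }
  }
  car <- spec$re_prior == "car"
  colours <- if (car) colour_graph(Tn, nbr) else rep(1L, Tn)
  colour_sets <- split(seq_len(Tn), colours)
  # strata grouped by colour, with tract factor for per-tract sums
  strata_by_colour <- lapply(colour_sets, function(tr) {
    idx <- which(md$t_idx %in% tr)
    list(idx = idx, tr = tr,
         g = factor(md$t_idx[idx], levels = tr))
  })
  comps <- graph_components(graph)
  comp_idx <- lapply(comps, function(cc) match(cc, md$ids))
  big_comps <- comp_idx[vapply(comp_idx, length, integer(1)) >= 2]
  n_iso <- sum(vapply(comp_idx, length, integer(1)) == 1)
  car_df <- if (car) (Tn - n_iso - length(big_comps)) + n_iso else Tn
  iso <- which(deg == 0)
  # prior weight per tract in the single-site quadratic form
  wgt <- if (car) pmax(deg, 1) else rep(1, Tn)

  count_ll_fun <- make_count_ll(md$y, md$e, spec$family, zi)
  mix <- make_mix(md$y, zi)
  X <- md$X
  xcols <- lapply(seq_len(p), function(j) which(X[, j] != 0))

  par_names <- c(paste0("b_", colnames(X)),
                 if (zi) paste0("zi_b_", colnames(X)),
                 "tau_nu",
                 if (zi && !shared) "tau_zi_nu",
                 if (spec$has_shape) "shape",
                 paste0("nu[", md$ids, "]"),
                 if (zi && !shared) paste0("zi_nu[", md$ids, "]"))

  run_chain <- function(chain_id) {
    set.seed(seed + chain_id - 1)
    # initial values: tract effects start at empirical log-SIR estimates
    # (jittered per chain) so chains start near the data-supported mode
    bC <- c(log((sum(md$y) + 0.5) / max(sum(md$e), 1e-12)), rep(0, p - 1))
    bZ <- if (zi) c(stats::qlogis(0.2), rep(0, p - 1)) else NULL
    yt <- as.numeric(rowsum(md$y, md$t_idx)[, 1])
    et <- as.numeric(rowsum(md$e, md$t_idx)[, 1])
    nu0 <- log((yt + 0.5) / pmax(et, 1e-12) / exp(bC[1]))
    nu0 <- nu0 - mean(nu0)
    nuC <- nu0 + stats::rnorm(Tn, 0, 0.1)
    nuZ <- if (zi && !shared) stats::rnorm(Tn, 0, 0.1) else NULL
    tauC <- 1 / max(stats::var(nuC), 1e-4); tauZ <- 1
    shape <- if (spec$has_shape) 2 else NULL
    etaC <- as.numeric(X %*% bC) + nuC[md$t_idx]
    etaZ <- if (zi) as.numeric(X %*% bZ) +
      (if (shared) nuC[md$t_idx] else nuZ[md$t_idx]) else NULL
    cll <- count_ll_fun(etaC, shape)
    oll <- mix(cll, etaZ)
    if (!all(is.finite(oll))) {
      stop("non-finite initial log-likelihood; check counts and offsets")
    }
    # adaptive proposal scales
    sc_bC <- rep(0.1, p); sc_bZ <- rep(0.2, p)
    sc_nuC <- rep(0.5, Tn); sc_nuZ <- rep(0.8, Tn); sc_sh <- 0.3
    sc_scl <- 0.1; sc_sclZ <- 0.1
    acc_bC <- rep(0, p); acc_bZ <- rep(0, p)
    acc_nuC <- rep(0, Tn); acc_nuZ <- rep(0, Tn); acc_sh <- 0
    acc_scl <- 0; acc_sclZ <- 0
    batch <- 50

    out <- matrix(NA_real_, keep, length(par_names),
                  dimnames = list(NULL, par_names))

    for (it in seq_len(iter)) {
      ## -- count-component coefficients (per-coordinate RW) --
      for (j in seq_len(p)) {
        d <- stats::rnorm(1, 0, sc_bC[j])
        idx <- xcols[[j]]
        etaC2 <- etaC; etaC2[idx] <- etaC2[idx] + d * X[idx, j]
        cll2 <- count_ll_fun(etaC2, shape)
        oll2 <- mix(cll2, etaZ)
        lr <- sum(oll2[idx]) - sum(oll[idx]) +
          stats::dnorm(bC[j] + d, 0, priors$beta_sd, log = TRUE) -
          stats::dnorm(bC[j], 0, priors$beta_sd, log = TRUE)
        if (is.finite(lr) && log(stats::runif(1)) < lr) {
          bC[j] <- bC[j] + d; etaC <- etaC2; cll <- cll2; oll <- oll2
          acc_bC[j] <- acc_bC[j] + 1
        }
      }

      ## -- count-component tract effects (chromatic single-site) --
      sC <- numeric(Tn)
      if (car && nrow(ei)) {
        for (k in seq_len(Tn)) sC[k] <- sum(nuC[nbr[[k]]])
      }
      for (cs in strata_by_colour) {
        tr <- cs$tr; idx <- cs$idx
        d <- stats::rnorm(length(tr), 0, sc_nuC[tr])
        nu2 <- nuC[tr] + d
        etaC2 <- etaC[idx] + d[as.integer(cs$g)]
        cll_old <- list(ll = cll$ll[idx], ll0 = cll$ll0[idx])
        cll_new <- local({
          f <- make_count_ll(md$y[idx], md$e[idx], spec$family, zi)
          f(etaC2, shape)
        })
        if (shared) {
          etaZ2 <- etaZ[idx] + d[as.integer(cs$g)]
          mix_s <- make_mix(md$y[idx], zi)
          dll <- rowsum(mix_s(cll_new, etaZ2) -
                        mix_s(cll_old, etaZ[idx]), cs$g)
        } else {
          mix_s <- make_mix(md$y[idx], zi)
          ez <- if (zi) etaZ[idx] else NULL
          dll <- rowsum(mix_s(cll_new, ez) - mix_s(cll_old, ez), cs$g)
        }
        if (car) {
          sk <- if (length(sC)) sC[tr] else 0
          dpr <- -tauC / 2 * (wgt[tr] * (nu2^2 - nuC[tr]^2) -
                               2 * sk * (nu2 - nuC[tr]))
          dpr[tr %in% iso] <- (-tauC / 2 * (nu2^2 - nuC[tr]^2))[tr %in% iso]
        } else {
          dpr <- -tauC / 2 * (nu2^2 - nuC[tr]^2)
        }
        lr <- as.numeric(dll) + dpr
        acc <- is.finite(lr) & log(stats::runif(length(tr))) < lr
        if (any(acc)) {
          nuC[tr[acc]] <- nu2[acc]
          upd <- acc[as.integer(cs$g)]
          etaC[idx[upd]] <- etaC2[upd]
          cll$ll[idx[upd]] <- cll_new$ll[upd]
          if (zi) cll$ll0[idx[upd]] <- cll_new$ll0[upd]
          if (shared) etaZ[idx[upd]] <- etaZ[idx[upd]] + (d[as.integer(cs$g)])[upd]
          acc_nuC[tr[acc]] <- acc_nuC[tr[acc]] + 1
          if (car) {       # refresh neighbour sums for later colours
            for (k in which(acc)) for (nb in nbr[[tr[k]]]) {
              sC[nb] <- sC[nb] + d[k]
            }
          }
        }
      }
      ## -- joint rescaling move: nu -> c * nu (funnel traversal) --
      {
        d <- stats::rnorm(1, 0, sc_scl)
        cc <- exp(d)
        qf0 <- if (car) {
          (if (nrow(ei)) sum((nuC[ei[, 1]] - nuC[ei[, 2]])^2) else 0) +
            sum(nuC[iso]^2)
        } else sum(nuC^2)
        etaC2 <- as.numeric(X %*% bC) + cc * nuC[md$t_idx]
        cll2 <- count_ll_fun(etaC2, shape)
        etaZ2 <- if (shared) as.numeric(X %*% bZ) + cc * nuC[md$t_idx] else etaZ
        oll2 <- mix(cll2, etaZ2)
        lr <- sum(oll2) - sum(mix(cll, etaZ)) -
          tauC / 2 * (cc^2 - 1) * qf0 + car_df * d
        if (is.finite(lr) && log(stats::runif(1)) < lr) {
          nuC <- cc * nuC; etaC <- etaC2; cll <- cll2
          if (shared) etaZ <- etaZ2
          acc_scl <- acc_scl + 1
        }
      }
      # recentre per component (CAR gauge fix), then refresh caches
      if (car && length(big_comps)) {
        shifted <- FALSE
        for (ci in big_comps) {
          m <- mean(nuC[ci])
          if (abs(m) > 0) { nuC[ci] <- nuC[ci] - m; shifted <- TRUE }
        }
        if (shifted) {
          etaC <- as.numeric(X %*% bC) + nuC[md$t_idx]
          if (shared) etaZ <- as.numeric(X %*% bZ) + nuC[md$t_idx]
          cll <- count_ll_fun(etaC, shape)
          oll <- mix(cll, etaZ)
        } else oll <- mix(cll, etaZ)
      } else oll <- mix(cll, etaZ)

      ## -- count-effect precision (conjugate Gibbs) --
      qf <- if (car) {
        (if (nrow(ei)) sum((nuC[ei[, 1]] - nuC[ei[, 2]])^2) else 0) +
          sum(nuC[iso]^2)
      } else sum(nuC^2)
      tauC <- stats::rgamma(1, priors$tau_shape + car_df / 2,
                            priors$tau_rate + qf / 2)

      ## -- zero-component updates --
      if (zi) {
        for (j in seq_len(p)) {
          d <- stats::rnorm(1, 0, sc_bZ[j])
          idx <- xcols[[j]]
          etaZ2 <- etaZ; etaZ2[idx] <- etaZ2[idx] + d * X[idx, j]
          oll2 <- mix(cll, etaZ2)
          lr <- sum(oll2[idx]) - sum(oll[idx]) +
            stats::dnorm(bZ[j] + d, 0, priors$beta_sd, log = TRUE) -
            stats::dnorm(bZ[j], 0, priors$beta_sd, log = TRUE)
          if (is.finite(lr) && log(stats::runif(1)) < lr) {
            bZ[j] <- bZ[j] + d; etaZ <- etaZ2; oll <- oll2
            acc_bZ[j] <- acc_bZ[j] + 1
          }
        }
        if (!shared) {
          sZ <- numeric(Tn)
          if (car && nrow(ei)) {
            for (k in seq_len(Tn)) sZ[k] <- sum(nuZ[nbr[[k]]])
          }
          for (cs in strata_by_colour) {
            tr <- cs$tr; idx <- cs$idx
            d <- stats::rnorm(length(tr), 0, sc_nuZ[tr])
            nu2 <- nuZ[tr] + d
            etaZ2 <- etaZ[idx] + d[as.integer(cs$g)]
            mix_s <- make_mix(md$y[idx], zi)
            cll_s <- list(ll = cll$ll[idx], ll0 = cll$ll0[idx])
            dll <- rowsum(mix_s(cll_s, etaZ2) - mix_s(cll_s, etaZ[idx]), cs$g)
            if (car) {
              dpr <- -tauZ / 2 * (wgt[tr] * (nu2^2 - nuZ[tr]^2) -
                                   2 * sZ[tr] * (nu2 - nuZ[tr]))
              dpr[tr %in% iso] <- (-tauZ / 2 * (nu2^2 - nuZ[tr]^2))[tr %in% iso]
            } else {
              dpr <- -tauZ / 2 * (nu2^2 - nuZ[tr]^2)
            }
            lr <- as.numeric(dll) + dpr
            acc <- is.finite(lr) & log(stats::runif(length(tr))) < lr
            if (any(acc)) {
              nuZ[tr[acc]] <- nu2[acc]
              upd <- acc[as.integer(cs$g)]
              etaZ[idx[upd]] <- etaZ2[upd]
              acc_nuZ[tr[acc]] <- acc_nuZ[tr[acc]] + 1
              if (car) for (k in which(acc)) for (nb in nbr[[tr[k]]]) {
                sZ[nb] <- sZ[nb] + d[k]
              }
            }
          }
          {  # rescaling move for the zero-component effects
            d <- stats::rnorm(1, 0, sc_sclZ)
            cc <- exp(d)
            qf0 <- if (car) {
              (if (nrow(ei)) sum((nuZ[ei[, 1]] - nuZ[ei[, 2]])^2) else 0) +
                sum(nuZ[iso]^2)
            } else sum(nuZ^2)
            etaZ2 <- as.numeric(X %*% bZ) + cc * nuZ[md$t_idx]
            oll2 <- mix(cll, etaZ2)
            lr <- sum(oll2) - sum(mix(cll, etaZ)) -
              tauZ / 2 * (cc^2 - 1) * qf0 + car_df * d
            if (is.finite(lr) && log(stats::runif(1)) < lr) {
              nuZ <- cc * nuZ; etaZ <- etaZ2
              acc_sclZ <- acc_sclZ + 1
            }
          }
          if (car && length(big_comps)) {
            for (ci in big_comps) nuZ[ci] <- nuZ[ci] - mean(nuZ[ci])
            etaZ <- as.numeric(X %*% bZ) + nuZ[md$t_idx]
          }
          oll <- mix(cll, etaZ)
          qfz <- if (car) {
            (if (nrow(ei)) sum((nuZ[ei[, 1]] - nuZ[ei[, 2]])^2) else 0) +
              sum(nuZ[iso]^2)
          } else sum(nuZ^2)
          tauZ <- stats::rgamma(1, priors$tau_shape + car_df / 2,
                                priors$tau_rate + qfz / 2)
        }
      }

      ## -- dispersion --
      if (spec$has_shape) {
        d <- stats::rnorm(1, 0, sc_sh)
        shape2 <- exp(log(shape) + d)
        if (shape2 > priors$shape_min) {
          cll2 <- count_ll_fun(etaC, shape2)
          oll2 <- mix(cll2, etaZ)
          lprior <- function(s) {
            if (spec$family %in% c("nb", "zinb")) {
              stats::dgamma(s, priors$shape_a, priors$shape_b, log = TRUE)
            } else {
              stats::dlnorm(s, priors$cmp_meanlog, priors$cmp_sdlog, log = TRUE)
            }
          }
          lr <- sum(oll2) - sum(oll) + lprior(shape2) - lprior(shape) +
            log(shape2) - log(shape)     # Jacobian of log-scale walk
          if (is.finite(lr) && log(stats::runif(1)) < lr) {
            shape <- shape2; cll <- cll2; oll <- oll2
            acc_sh <- acc_sh + 1
          }
        }
      }

      ## -- adaptation during warmup --
      if (it <= warmup && it %% batch == 0) {
        stepd <- min(0.1, 2 / sqrt(it / batch))
        tune <- function(sc, acc) {
          sc * exp(ifelse(acc / batch > 0.44, stepd, -stepd))
        }
        sc_bC <- tune(sc_bC, acc_bC); acc_bC[] <- 0
        sc_nuC <- tune(sc_nuC, acc_nuC); acc_nuC[] <- 0
        sc_scl <- tune(sc_scl, acc_scl); acc_scl <- 0
        if (zi) { sc_bZ <- tune(sc_bZ, acc_bZ); acc_bZ[] <- 0 }
        if (zi && !shared) {
          sc_nuZ <- tune(sc_nuZ, acc_nuZ); acc_nuZ[] <- 0
          sc_sclZ <- tune(sc_sclZ, acc_sclZ); acc_sclZ <- 0
        }
        if (spec$has_shape) {
          sc_sh <- tune(sc_sh, acc_sh); acc_sh <- 0
        }
      }

      if (it > warmup) {
        out[it - warmup, ] <- c(bC, if (zi) bZ, tauC,
                                if (zi && !shared) tauZ,
                                if (spec$has_shape) shape,
                                nuC, if (zi && !shared) nuZ)
      }
      if (verbose && it %% 500 == 0) {
        message("chain ", chain_id, " iteration ", it, "/", iter)
      }
    }
    out
  }

  draws <- lapply(seq_len(chains), run_chain)
  fit <- structure(list(draws = draws, spec = spec, seed = seed,
                        iter = iter, warmup = warmup, chains = chains,
                        par_names = par_names, tract_ids = md$ids,
                        per_levels = md$per_levels),
                   class = "posterior_draws")
  if (chains >= 2) {
    scal <- grep("^(b_|zi_b_|tau|shape)", par_names, value = TRUE)
    rh <- suppressWarnings(split_rhat(fit, pars = scal))
    if (any(rh > 1.05, na.rm = TRUE)) {
      attr(fit, "rhat_flag") <- TRUE
      warning("split-R-hat > 1.05 for: ",
              paste(names(rh)[which(rh > 1.05)], collapse = ", "))
    }
  }
  fit
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat("posterior_draws:", x$chains, "chains x",
      x$iter - x$warmup, "retained iterations,",
      length(x$par_names), "parameters\n")
  cat("  spec:", x$spec$family, "+", x$spec$re_prior, ", outcome",
      x$spec$outcome, "\n")
  if (isTRUE(attr(x, "rhat_flag"))) cat("  WARNING: R-hat flag set\n")
  invisible(x)
}

#' Stacked draw matrix (all chains)
#' @param fit A `posterior_draws`.
#' @param pars Optional parameter name subset.
#' @return Matrix, total draws by parameters.
#' @export
draw_matrix <- function(fit, pars = NULL) {
  m <- do.call(rbind, fit$draws)
  if (!is.null(pars)) m <- m[, pars, drop = FALSE]
  m
}

#' Tract-effect draws
#' @param fit A `posterior_draws`.
#' @param component `"count"` or `"zero"`.
#' @return Matrix draws x tracts with tract-id column names.
#' @export
nu_draws <- function(fit, component = c("count", "zero")) {
  component <- match.arg(component)
  pre <- if (component == "count") "nu[" else "zi_nu["
  pars <- paste0(pre, fit$tract_ids, "]")
  if (component == "zero" && !all(pars %in% fit$par_names)) {
    if (fit$spec$zi && fit$spec$share_random_effect) {
      pars <- paste0("nu[", fit$tract_ids, "]")   # shared vector
    } else {
      stop("no zero-component tract effects in this fit")
    }
  }
  m <- draw_matrix(fit, pars)
  colnames(m) <- fit$tract_ids
  m
}

#' Posterior summary of the fixed effects and dispersion
#' @param fit A `posterior_draws`.
#' @return Data frame with mean, sd and central 95% interval.
#' @export
fixef_summary <- function(fit) {
  pars <- grep("^(b_|zi_b_|tau|shape)", fit$par_names, value = TRUE)
  m <- draw_matrix(fit, pars)
  data.frame(parameter = pars,
             mean = colMeans(m),
             sd = apply(m, 2, stats::sd),
             q2.5 = apply(m, 2, stats::quantile, 0.025),
             q97.5 = apply(m, 2, stats::quantile, 0.975),
             row.names = NULL)
}

# ---- convergence diagnostics -----------------------------------------

split_chains <- function(fit, par) {
  lapply(fit$draws, function(ch) {
    v <- ch[, par]
    n2 <- floor(length(v) / 2)
    list(v[seq_len(n2)], v[seq_len(n2) + n2])
  }) |> unlist(recursive = FALSE)
}

rhat_one <- function(chs) {
  m <- length(chs); n <- length(chs[[1]])
  means <- vapply(chs, mean, numeric(1))
  vars <- vapply(chs, stats::var, numeric(1))
  W <- mean(vars)
  if (!is.finite(W) || W == 0) return(NaN)
  B <- n * stats::var(means)
  sqrt(((n - 1) / n * W + B / n) / W)
}

ess_one <- function(chs) {
  m <- length(chs); n <- length(chs[[1]])
  W <- mean(vapply(chs, stats::var, numeric(1)))
  if (!is.finite(W) || W == 0) return(NaN)
  var_plus <- (n - 1) / n * W + stats::var(vapply(chs, mean, numeric(1)))
  # chain-averaged biased autocovariances via FFT (zero-padded)
  acov <- vapply(chs, function(v) {
    v <- v - mean(v)
    nf <- stats::nextn(2 * n)
    f <- stats::fft(c(v, rep(0, nf - n)))
    Re(stats::fft(f * Conj(f), inverse = TRUE))[seq_len(n)] / (nf * n)
  }, numeric(n))
  rho <- 1 - (W - rowMeans(acov)) / var_plus
  # Geyer initial monotone positive sequence over lag pairs (from lag 0)
  tau_sum <- 0; prev <- Inf; k <- 0
  while (2 * k + 2 <= n) {
    pair <- rho[2 * k + 1] + rho[2 * k + 2]
    if (!is.finite(pair) || pair < 0) break
    pair <- min(pair, prev); prev <- pair
    tau_sum <- tau_sum + pair
    k <- k + 1
  }
  tau <- max(-1 + 2 * tau_sum, 1e-12)
  ess <- m * n / tau
  min(ess, m * n * log10(m * n))
}

#' Split-R-hat per parameter
#' @param fit A `posterior_draws` with at least 2 chains.
#' @param pars Optional subset of parameter names.
#' @return Named vector of split-R-hat values (`NaN` for zero-variance
#'   parameters, with a warning).
#' @export
split_rhat <- function(fit, pars = NULL) {
  if (fit$chains < 2) stop("split_rhat requires at least 2 chains")
  if (is.null(pars)) pars <- fit$par_names
  out <- vapply(pars, function(p) rhat_one(split_chains(fit, p)), numeric(1))
  if (any(is.nan(out))) {
    warning("zero-variance parameter(s); R-hat reported as NaN")
  }
  out
}

#' MCMC diagnostics: split-R-hat and relative effective sample size
#'
#' @param fit A `posterior_draws` with >= 2 chains.
#' @param pars Optional parameter subset (default: all).
#' @return Data frame with `parameter`, `rhat`, `ess_ratio` (ESS divided
#'   by total retained draws) and a logical `flagged` column marking
#'   `rhat > 1.01`.
#' @export
diagnostics <- function(fit, pars = NULL) {
  if (fit$chains < 2) stop("diagnostics requires at least 2 chains")
  if (is.null(pars)) pars <- fit$par_names
  total <- fit$chains * (fit$iter - fit$warmup)
  rh <- split_rhat(fit, pars)
  es <- vapply(pars, function(p) ess_one(split_chains(fit, p)), numeric(1))
  data.frame(parameter = pars, rhat = unname(rh),
             ess_ratio = unname(es) / total,
             flagged = unname(!is.nan(rh) & rh > 1.01),
             row.names = NULL)
}

# ---- persistence ------------------------------------------------------

#' Save posterior draws as long CSV plus JSON sidecar
#' @param fit A `posterior_draws`.
#' @param csv_path Long-format CSV (`chain,iter,parameter,value`).
#' @param json_path Sidecar with spec, seed and dimensions.
#' @export
write_draws_csv <- function(fit, csv_path, json_path = NULL) {
  long <- do.call(rbind, lapply(seq_along(fit$draws), function(ci) {
    ch <- fit$draws[[ci]]
    data.frame(chain = ci, iter = rep(seq_len(nrow(ch)), ncol(ch)),
               parameter = rep(colnames(ch), each = nrow(ch)),
               value = as.numeric(ch))
  }))
  utils::write.csv(long, csv_path, row.names = FALSE, quote = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(spec = unclass(fit$spec), seed = fit$seed,
                              iter = fit$iter, warmup = fit$warmup,
                              chains = fit$chains,
                              tract_ids = fit$tract_ids,
                              per_levels = fit$per_levels),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}

#' Load posterior draws written by [write_draws_csv]
#' @param csv_path,json_path Paths written by [write_draws_csv].
#' @return A `posterior_draws`.
#' @export
read_draws_csv <- function(csv_path, json_path) {
  long <- utils::read.csv(csv_path)
  meta <- jsonlite::fromJSON(json_path)
  pars <- unique(long$parameter)
  draws <- lapply(sort(unique(long$chain)), function(ci) {
    sub <- long[long$chain == ci, ]
    m <- matrix(NA_real_, max(sub$iter), length(pars),
                dimnames = list(NULL, pars))
    for (p in pars) m[, p] <- sub$value[sub$parameter == p]
    m
  })
  spec <- model_spec(meta$spec$family, meta$spec$re_prior,
                     meta$spec$outcome, meta$spec$share_random_effect)
  structure(list(draws = draws, spec = spec, seed = meta$seed,
                 iter = meta$iter, warmup = meta$warmup,
                 chains = meta$chains, par_names = pars,
                 tract_ids = meta$tract_ids, per_levels = meta$per_levels),
            class = "posterior_draws")
}
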