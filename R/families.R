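#' Count-distribution building blocks
#'
#' Log probability mass functions for the likelihood families used by the
#' catchment models: Poisson, negative binomial (mean--dispersion
#' parameterisation), Conway--Maxwell Poisson (CMP), and their zero-inflated
#' mixtures, plus the intrinsic CAR log-density for the spatial random
#' effects.
#'
#' @name families
NULL

#' Negative binomial log-pmf (mean--dispersion parameterisation)
#'
#' Log-density of the negative binomial with mean `mu` and dispersion
#' (shape) `shape`, i.e. variance `mu + mu^2/shape`. As `shape` grows the
#' distribution approaches Poisson(`mu`).
#'
#' @param y Non-negative integer counts (vectorised).
#' @param mu Positive means (recycled against `y`).
#' @param shape Positive dispersion parameter.
#' @return Log-probabilities, same length as `y`.
#' @export
nb_logpmf <- function(y, mu, shape) {
  stopifnot(is.numeric(y), is.numeric(mu), is.numeric(shape))
  if (any(mu <= 0)) stop("nb_logpmf: 'mu' must be positive")
  if (any(shape <= 0)) stop("nb_logpmf: 'shape' must be positive")
  if (any(y < 0) || any(y != floor(y))) {
    stop("nb_logpmf: 'y' must be non-negative integers")
  }
  stats::dnbinom(y, size = shape, mu = mu, log = TRUE)
}

#' Zero-inflated log-pmf
#'
#' Mixes a base count log-pmf with a point mass at zero:
#' `P(0) = pi + (1 - pi) * f(0)` and `P(y) = (1 - pi) * f(y)` for `y > 0`,
#' computed stably in log space.
#'
#' @param y Non-negative integer counts.
#' @param base_logpmf Either a function `f(y) -> log-pmf` for the base
#'   family, or a numeric vector of base log-pmf values at `y`; in the
#'   latter case `base_logpmf0` (log-pmf at 0) must be supplied.
#' @param pi Structural-zero probabilities in `[0, 1]` (recycled).
#' @param base_logpmf0 Optional base log-pmf evaluated at 0, required when
#'   `base_logpmf` is a vector.
#' @return Log-probabilities.
#' @export
zi_logpmf <- function(y, base_logpmf, pi, base_logpmf0 = NULL) {
  if (any(pi < 0 | pi > 1)) stop("zi_logpmf: 'pi' must lie in [0, 1]")
  if (is.function(base_logpmf)) {
    base_ll <- base_logpmf(y)
    base_ll0 <- base_logpmf(rep(0L, length(y)))
  } else {
    if (is.null(base_logpmf0)) {
      stop("zi_logpmf: 'base_logpmf0' required when base log-pmf is a vector")
    }
    base_ll <- base_logpmf
    base_ll0 <- base_logpmf0
  }
  n <- max(length(y), length(base_ll), length(pi))
  y <- rep_len(y, n); base_ll <- rep_len(base_ll, n)
  base_ll0 <- rep_len(base_ll0, n); pi <- rep_len(pi, n)
  out <- log1p(-pi) + base_ll
  z <- y == 0
  if (any(z)) {
    # log(pi + (1-pi) exp(base0)) via pairwise logsumexp
    a <- log(pi[z])
    b <- log1p(-pi[z]) + base_ll0[z]
    m <- pmax(a, b)
    lz <- m + log(exp(a - m) + exp(b - m))
    lz[pi[z] == 1] <- 0            # all mass at zero
    lz[pi[z] == 0] <- base_ll0[z][pi[z] == 0]
    out[z] <- lz
  }
  out[pi == 1 & y > 0] <- -Inf
  out
}

#' Conway--Maxwell Poisson log normalizing constant
#'
#' `log Z(lambda, nu) = log sum_j lambda^j / (j!)^nu`, with the series
#' truncated once the next term falls below `1e-12` of the running sum
#' (or at `1e5` terms, which raises an error as non-convergent).
#'
#' @param lambda Positive rate parameter.
#' @param nu_cmp Positive decay parameter (`nu_cmp = 1` recovers Poisson).
#' @return Log normalizer (scalar; vectorised over `lambda`).
#' @keywords internal
cmp_lognorm <- function(lambda, nu_cmp) {
  vapply(lambda, function(lam) {
    log_term <- 0       # j = 0 term
    lse <- 0
    for (j in seq_len(1e5)) {
      log_term <- log_term + log(lam) - nu_cmp * log(j)
      m <- max(lse, log_term)
      lse <- m + log(exp(lse - m) + exp(log_term - m))
      if (log_term < lse + log(1e-12) && j > lam^(1 / nu_cmp)) {
        return(lse)
      }
    }
    stop("cmp_lognorm: series did not converge (lambda = ", lam,
         ", nu = ", nu_cmp, ")")
  }, numeric(1))
}

#' Conway--Maxwell Poisson log-pmf
#'
#' `P(y) = lambda^y / (y!)^nu / Z(lambda, nu)`. `nu_cmp = 1` reduces to
#' Poisson; `nu_cmp > 1` is under-dispersed, `nu_cmp < 1` over-dispersed.
#'
#' @inheritParams cmp_lognorm
#' @param y Non-negative integer counts.
#' @return Log-probabilities.
#' @export
cmp_logpmf <- function(y, lambda, nu_cmp) {
  if (any(lambda <= 0)) stop("cmp_logpmf: 'lambda' must be positive")
  if (nu_cmp <= 0) stop("cmp_logpmf: 'nu_cmp' must be positive")
  if (any(y < 0) || any(y != floor(y))) {
    stop("cmp_logpmf: 'y' must be non-negative integers")
  }
  n <- max(length(y), length(lambda))
  y <- rep_len(y, n); lambda <- rep_len(lambda, n)
  y * log(lambda) - nu_cmp * lgamma(y + 1) - cmp_lognorm(lambda, nu_cmp)
}

#' CMP mean
#' @keywords internal
cmp_mean <- function(lambda, nu_cmp) {
  vapply(lambda, function(lam) {
    lz <- cmp_lognorm(lam, nu_cmp)
    j <- 0:2000
    lp <- j * log(lam) - nu_cmp * lgamma(j + 1) - lz
    keep <- lp > -40
    sum(j[keep] * exp(lp[keep]))
  }, numeric(1))
}

#' Solve for the CMP rate that yields a target mean
#'
#' Bisection on `lambda` (the CMP mean is strictly increasing in it),
#' to absolute tolerance `1e-8` on the mean. Used so that the CMP family
#' can be mean-parameterised like the other families (`mu = e * RR`).
#'
#' @param target_mean Positive target mean (vectorised).
#' @param nu_cmp Positive decay parameter.
#' @return `lambda` values.
#' @export
cmp_mean_to_lambda <- function(target_mean, nu_cmp) {
  if (any(target_mean <= 0)) stop("cmp_mean_to_lambda: mean must be positive")
  vapply(target_mean, function(m) {
    lo <- 1e-12
    hi <- max(2, (m + 2)^nu_cmp * 2)
    while (cmp_mean(hi, nu_cmp) < m) hi <- hi * 4
    for (it in seq_len(200)) {
      mid <- (lo + hi) / 2
      fm <- cmp_mean(mid, nu_cmp)
      if (abs(fm - m) < 1e-8) return(mid)
      if (fm < m) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
}

#' Intrinsic CAR log-density (up to a constant)
#'
#' Pairwise-difference form of the intrinsic conditional autoregressive
#' density over a tract graph:
#' `((n - c)/2) log(tau) - (tau/2) * sum_{(i,j) in edges} (nu_i - nu_j)^2`,
#' where `c` is the number of connected components. The density is improper
#' (flat along each component mean); the implied full conditional of
#' `nu_i` is Normal(mean of its neighbours, `1/(m_i tau)`).
#'
#' @param nu Numeric vector of tract effects, named or ordered as
#'   `tract_ids(graph)`.
#' @param graph A [tract_graph].
#' @param tau Positive precision.
#' @return Scalar log-density (improper, up to an additive constant).
#' @export
car_logdensity <- function(nu, graph, tau) {
  stopifnot(tau > 0)
  ids <- tract_ids(graph)
  if (length(nu) != length(ids)) {
    stop("car_logdensity: 'nu' length must equal number of tracts")
  }
  ei <- edge_indices(graph)
  q <- if (nrow(ei)) sum((nu[ei[, 1]] - nu[ei[, 2]])^2) else 0
  n <- length(ids)
  c_comp <- length(graph_components(graph))
  ((n - c_comp) / 2) * log(tau) - (tau / 2) * q
}

# ---- internal vectorised likelihood core ------------------------------

#' Per-observation log-likelihood under a model family
#'
#' Assembles the stratum likelihood: `mu = e * exp(eta_count)`, and for
#' zero-inflated families `pi = plogis(eta_zero)`. Strata with `e = 0`
#' contribute a point mass at zero.
#'
#' @param y Observed counts.
#' @param e Expected-count offsets (non-negative).
#' @param eta_count Count-component linear predictor.
#' @param eta_zero Zero-component linear predictor (ignored for non-ZI
#'   families).
#' @param family One of `"poisson"`, `"zip"`, `"nb"`, `"zinb"`, `"cmp"`,
#'   `"zicmp"`.
#' @param shape NB dispersion or CMP decay parameter (ignored for
#'   Poisson families).
#' @return Vector of log-likelihood contributions.
#' @export
loglik_observation <- function(y, e, eta_count, eta_zero = NULL, family,
                               shape = NULL) {
  family <- match.arg(family, c("poisson", "zip", "nb", "zinb", "cmp", "zicmp"))
  if (any(e < 0)) stop("loglik_observation: offsets 'e' must be non-negative")
  n <- length(y)
  out <- numeric(n)
  pos <- e > 0
  # e = 0 strata: degenerate at zero
  if (any(!pos)) out[!pos] <- ifelse(y[!pos] == 0, 0, -Inf)
  if (!any(pos)) return(out)
  mu <- e[pos] * exp(eta_count[pos])
  if (any(!is.finite(mu)) || any(mu > 1e9)) {
    stop("loglik_observation: mean overflow (mu > 1e9); reduce coefficients")
  }
  base <- switch(family,
    poisson = , zip = list(
      ll = stats::dpois(y[pos], mu, log = TRUE),
      ll0 = -mu),
    nb = , zinb = list(
      ll = nb_logpmf(y[pos], mu, shape),
      ll0 = nb_logpmf(rep(0L, sum(pos)), mu, shape)),
    cmp = , zicmp = {
      lam <- cmp_mean_to_lambda(mu, shape)
      list(ll = cmp_logpmf(y[pos], lam, shape),
           ll0 = cmp_logpmf(rep(0L, sum(pos)), lam, shape))
    })
  if (family %in% c("zip", "zinb", "zicmp")) {
    if (is.null(eta_zero)) stop("loglik_observation: eta_zero required for ZI family")
    pi <- stats::plogis(eta_zero[pos])
    out[pos] <- zi_logpmf(y[pos], base$ll, pi, base_logpmf0 = base$ll0)
  } else {
    out[pos] <- base$ll
  }
  out
}
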