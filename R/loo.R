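#' Approximate leave-one-out cross-validation (PSIS-LOO)
#'
#' Candidate models are compared by the expected log pointwise
#' predictive density (ELPD) estimated by leave-one-out cross-validation
#' with Pareto-smoothed importance sampling: for each observation the
#' importance ratios `1/p(y_i | theta_s)` are tail-smoothed by a
#' generalized Pareto fit before reweighting.
#'
#' @name model_selection
NULL

#' Pointwise log-likelihood matrix
#'
#' Entry `(s, i)` is the log-likelihood of observation `i` (in
#' `counts` row order) under posterior draw `s`.
#'
#' @param fit A `posterior_draws` from [fit_spatial_count].
#' @param counts The stratified counts the model was fitted to.
#' @param graph The [tract_graph].
#' @return Matrix, draws by observations. Attribute `"n_draws"` and
#'   `"spec"` carried along.
#' @export
pointwise_loglik <- function(fit, counts, graph) {
  spec <- fit$spec
  md <- build_model_data(counts, graph, spec)
  if (!identical(md$ids, fit$tract_ids)) {
    stop("pointwise_loglik: counts/graph do not match the fitted tracts")
  }
  m <- draw_matrix(fit)
  S <- nrow(m)
  if (S < 100) warning("fewer than 100 draws; PSIS may be unstable")
  bC <- m[, paste0("b_", colnames(md$X)), drop = FALSE]
  zi <- spec$zi
  if (zi) {
    bZ <- m[, paste0("zi_b_", colnames(md$X)), drop = FALSE]
    nuZcols <- if (spec$share_random_effect) paste0("nu[", md$ids, "]")
               else paste0("zi_nu[", md$ids, "]")
    nuZ <- m[, nuZcols, drop = FALSE]
  }
  nuC <- m[, paste0("nu[", md$ids, "]"), drop = FALSE]
  shape_v <- if (spec$has_shape) m[, "shape"] else rep(NA_real_, S)
  ll <- matrix(NA_real_, S, md$n)
  cllf <- make_count_ll(md$y, md$e, spec$family, zi)
  mixf <- make_mix(md$y, zi)
  for (s in seq_len(S)) {
    etaC <- as.numeric(md$X %*% bC[s, ]) + nuC[s, md$t_idx]
    etaZ <- if (zi) as.numeric(md$X %*% bZ[s, ]) + nuZ[s, md$t_idx] else NULL
    ll[s, ] <- mixf(cllf(etaC, shape_v[s]), etaZ)
  }
  structure(ll, spec = spec)
}

# generalized Pareto fit (Zhang & Stephens 2009 profile/moment hybrid,
# with the usual weak-prior regularisation of k)
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  prior <- 3
  m <- 30 + floor(sqrt(n))
  theta <- 1 / x[n] + (1 - sqrt(m / (seq_len(m) - 0.5))) /
    (prior * x[floor(n / 4 + 0.5)])
  lx <- vapply(theta, function(th) {
    k <- -mean(log1p(-th * x))
    n * (log(th / k) + k - 1)
  }, numeric(1))
  w <- 1 / vapply(seq_len(m), function(j) sum(exp(lx - lx[j])), numeric(1))
  th_hat <- sum(theta * w)
  k <- -mean(log1p(-th_hat * x))
  sigma <- k / th_hat
  k <- (n * k + 10 * 0.5) / (n + 10)     # regularise towards 0.5
  list(k = k, sigma = sigma)
}

gpd_quantile <- function(p, k, sigma) {
  if (abs(k) < 1e-12) -sigma * log1p(-p) else sigma / k * ((1 - p)^(-k) - 1)
}

# Pareto-smoothed importance weights for one observation's log-ratios
psis_weights <- function(lr) {
  S <- length(lr)
  lr <- lr - max(lr)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  if (M < 5 || stats::sd(lr) == 0) {
    return(list(lw = lr, k = NaN))
  }
  ord <- order(lr)
  tail_idx <- ord[(S - M + 1):S]
  cutoff <- exp(lr[ord[S - M]])
  exceed <- exp(lr[tail_idx]) - cutoff
  if (all(exceed <= 0) || stats::sd(exceed) == 0) {
    return(list(lw = lr, k = NaN))
  }
  gf <- gpd_fit(exceed)
  q <- gpd_quantile((seq_len(M) - 0.5) / M, gf$k, gf$sigma)
  smoothed <- log(cutoff + q)
  lw <- lr
  lw[tail_idx] <- pmin(smoothed, max(lr))   # cap at max raw weight
  list(lw = lw, k = gf$k)
}

#' PSIS-LOO from a pointwise log-likelihood matrix
#'
#' @param ll Draws-by-observations log-likelihood matrix (see
#'   [pointwise_loglik]).
#' @return A `loo_result`: `elpd_loo`, `se`, `pointwise` (per-observation
#'   `elpd_i`), and `pareto_k` diagnostics (NaN where the tail is
#'   degenerate, e.g. identical draws).
#' @export
psis_loo <- function(ll) {
  if (!is.matrix(ll) || nrow(ll) < 2) stop("psis_loo: need >= 2 draws")
  if (any(!is.finite(ll))) {
    bad <- which(apply(ll, 2, function(c) any(!is.finite(c))))[1]
    stop("psis_loo: non-finite importance ratio at observation ", bad)
  }
  S <- nrow(ll); N <- ncol(ll)
  elpd_i <- numeric(N); k_i <- numeric(N)
  for (i in seq_len(N)) {
    lli <- ll[, i]
    pw <- psis_weights(-lli)         # ratios r_s = exp(-ll) up to a constant
    lw <- pw$lw - max(pw$lw)
    # elpd_i = log( sum w * exp(ll) / sum w )
    m1 <- max(lw + lli)
    elpd_i[i] <- m1 + log(sum(exp(lw + lli - m1))) -
      (max(lw) + log(sum(exp(lw - max(lw)))))
    k_i[i] <- pw$k
  }
  structure(list(elpd_loo = sum(elpd_i),
                 se = sqrt(N * stats::var(elpd_i)),
                 pointwise = elpd_i, pareto_k = k_i,
                 n_draws = S, n_obs = N),
            class = "loo_result")
}

#' @export
print.loo_result <- function(x, ...) {
  cat("PSIS-LOO: elpd_loo =", round(x$elpd_loo, 1),
      "(se", paste0(round(x$se, 1), ")"), "over", x$n_obs, "observations\n")
  nk <- sum(x$pareto_k > 0.7, na.rm = TRUE)
  if (nk) cat("  ", nk, "observation(s) with pareto_k > 0.7\n")
  invisible(x)
}

#' Rank models by ELPD
#'
#' Sorted by `elpd_loo` descending, with the difference to the best
#' model and its standard error computed from the pointwise paired
#' differences.
#'
#' @param results Named list of `loo_result` objects computed on
#'   identical observations.
#' @return Data frame: `model`, `elpd_loo`, `se`, `elpd_diff`,
#'   `se_diff`, `max_pareto_k`, `n_bad_k` (k > 0.7).
#' @export
loo_compare <- function(results) {
  if (!length(results)) stop("loo_compare: empty input")
  ns <- vapply(results, function(r) r$n_obs, integer(1))
  if (length(unique(ns)) != 1) {
    stop("loo_compare: results computed on different observation sets")
  }
  elpd <- vapply(results, function(r) r$elpd_loo, numeric(1))
  ord <- order(-elpd)
  best <- results[[ord[1]]]
  rows <- lapply(ord, function(j) {
    r <- results[[j]]
    dif <- r$pointwise - best$pointwise
    data.frame(model = names(results)[j],
               elpd_loo = r$elpd_loo, se = r$se,
               elpd_diff = sum(dif),
               se_diff = sqrt(r$n_obs * stats::var(dif)),
               max_pareto_k = suppressWarnings(max(r$pareto_k, na.rm = TRUE)),
               n_bad_k = sum(r$pareto_k > 0.7, na.rm = TRUE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
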