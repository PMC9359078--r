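#' Determinants of catchment-area membership
#'
#' Explains tract membership with distance to the hospital and average
#' household income via binary logistic regression
#' `logit(p) = b0 + b1 distance + b2 income + b3 distance x income`,
#' with sequential deviance, odds ratios, ROC/AUC, and group-mean
#' comparison.
#'
#' @name determinants
NULL

#' Prepare tract-level covariates
#'
#' Income is rescaled to thousands of dollars and both covariates are
#' centred on their means (and, by default, also scaled by their SDs so
#' coefficients are per-SD; disable with `scale = FALSE`). The centring
#' and scaling constants are recorded as attributes so the same
#' transform can be applied to new data.
#'
#' @param graph A [tract_graph].
#' @param distance Optional named per-tract distance vector (km), e.g.
#'   true driving distances; defaults to great-circle
#'   [hospital_distances].
#' @param scale Scale by SD after centring (default `TRUE`).
#' @return Data frame `tract_id`, `distance_km`, `income_k` (transformed),
#'   with attributes `centers` and `scales`. Tracts with missing income
#'   are excluded with a warning.
#' @export
prepare_covariates <- function(graph, distance = NULL, scale = TRUE) {
  ids <- tract_ids(graph)
  d <- if (is.null(distance)) hospital_distances(graph) else distance[ids]
  inc <- stats::setNames(graph$tracts$avg_income, ids) / 1000
  ok <- is.finite(d) & is.finite(inc)
  if (!all(ok)) {
    warning(sum(!ok), " tract(s) with missing covariates excluded")
  }
  d <- d[ok]; inc <- inc[ok]
  centers <- c(distance_km = mean(d), income_k = mean(inc))
  scales <- if (scale) c(distance_km = stats::sd(d), income_k = stats::sd(inc))
            else c(distance_km = 1, income_k = 1)
  out <- data.frame(tract_id = ids[ok],
                    distance_km = (d - centers["distance_km"]) / scales["distance_km"],
                    income_k = (inc - centers["income_k"]) / scales["income_k"],
                    row.names = NULL)
  attr(out, "centers") <- centers
  attr(out, "scales") <- scales
  out
}

#' Logistic regression of membership on covariates
#'
#' Maximum likelihood via iteratively reweighted least squares
#' (`stats::glm`, tolerance `1e-8`, up to 100 iterations), with terms
#' entered in the order distance, income, interaction. Sequential
#' (type-I) deviance contributions follow that order.
#'
#' @param member Logical/0-1 membership indicator per tract.
#' @param covars Covariate data frame from [prepare_covariates] (rows
#'   aligned with `member`).
#' @param interaction Include the distance x income interaction
#'   (default `TRUE`).
#' @return A `determinant_fit`: coefficient table (estimate, SE, OR,
#'   Wald 95% CI), sequential deviance table, null/residual deviance,
#'   the underlying `glm` object, and the centring/scaling constants.
#' @export
fit_logistic <- function(member, covars, interaction = TRUE) {
  y <- as.integer(member)
  if (length(unique(y)) < 2) stop("fit_logistic: membership is constant")
  df <- data.frame(member = y,
                   distance = covars$distance_km,
                   income = covars$income_k)
  form <- if (interaction) member ~ distance + income + distance:income
          else member ~ distance + income
  g <- stats::glm(form, family = stats::binomial(), data = df,
                  control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  if (!g$converged) stop("fit_logistic: IRLS did not converge")
  p <- stats::fitted(g)
  if (any(p > 1 - 1e-10) || any(p < 1e-10)) {
    stop("fit_logistic: (quasi-)complete separation detected")
  }
  cf <- summary(g)$coefficients
  coefs <- data.frame(term = rownames(cf),
                      estimate = cf[, 1], se = cf[, 2],
                      or = exp(cf[, 1]),
                      or_lo = exp(cf[, 1] - 1.96 * cf[, 2]),
                      or_hi = exp(cf[, 1] + 1.96 * cf[, 2]),
                      row.names = NULL)
  an <- stats::anova(g)
  seqdev <- data.frame(term = rownames(an)[-1],
                       deviance = an$Deviance[-1], row.names = NULL)
  structure(list(coefficients = coefs, seq_deviance = seqdev,
                 null_deviance = g$null.deviance,
                 residual_deviance = g$deviance,
                 glm = g,
                 centers = attr(covars, "centers"),
                 scales = attr(covars, "scales")),
            class = "determinant_fit")
}

#' @export
print.determinant_fit <- function(x, ...) {
  cat("determinant_fit (logistic):\n")
  print(x$coefficients, digits = 3)
  cat("null deviance", round(x$null_deviance, 1),
      "-> residual", round(x$residual_deviance, 1), "\n")
  invisible(x)
}

#' Predicted membership probabilities
#'
#' Inverse-logit of the linear predictor. `newdata` must already be on
#' the transformed (centred/scaled) covariate scale used in the fit; a
#' warning is raised when its means look untransformed. Supports
#' covariate grids for profile curves (membership probability against
#' income at fixed distance levels).
#'
#' @param fit A `determinant_fit`.
#' @param newdata Data frame with `distance_km` and `income_k` columns
#'   on the fit's transformed scale.
#' @return Probability vector.
#' @export
predict_proba <- function(fit, newdata) {
  d <- newdata$distance_km; i <- newdata$income_k
  if (length(d) > 10 &&
      (abs(mean(d)) > 3 * max(1, stats::sd(d)) ||
       abs(mean(i)) > 3 * max(1, stats::sd(i)))) {
    warning("covariates look untransformed; apply the fit's centring first")
  }
  stats::predict(fit$glm, newdata = data.frame(distance = d, income = i),
                 type = "response")
}

#' ROC curve and AUC
#'
#' AUC by the rank (Mann--Whitney) statistic with half-credit for ties;
#' curve points at every distinct score.
#'
#' @param scores Predicted scores/probabilities.
#' @param labels 0/1 (or logical) class labels; both classes required.
#' @return A `roc_result`: `thresholds`, `tpr`, `fpr`, `auc`.
#' @export
roc_auc <- function(scores, labels) {
  y <- as.integer(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("roc_auc: both classes must be present")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & y == 1) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & y == 0) / n0, numeric(1))
  structure(list(thresholds = c(Inf, thr), tpr = c(0, tpr), fpr = c(0, fpr),
                 auc = auc),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("ROC: AUC =", round(x$auc, 3), "over",
      length(x$thresholds) - 1, "distinct scores\n")
  invisible(x)
}

#' One-way ANOVA of a tract covariate between membership groups
#'
#' For two groups the F statistic equals the squared two-sample t
#' statistic (equal-variance).
#'
#' @param values Numeric covariate per tract.
#' @param membership Group labels (e.g. in/out of the CA).
#' @return List: `means` (per group), `F`, `p`.
#' @export
compare_group_means <- function(values, membership) {
  g <- factor(membership)
  if (nlevels(g) < 2) stop("compare_group_means: need >= 2 groups")
  if (any(table(g) < 2)) stop("compare_group_means: degenerate group (< 2)")
  fit <- stats::aov(values ~ g)
  an <- summary(fit)[[1]]
  list(means = tapply(values, g, mean),
       F = an[["F value"]][1], p = an[["Pr(>F)"]][1])
}
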