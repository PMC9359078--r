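test_that("covariate preparation centres (and scales) with recorded constants", {
  g <- path_graph(5)
  g$tracts$avg_income <- c(40, 55, 60, 70, 90) * 1000
  cov <- prepare_covariates(g, scale = FALSE)
  expect_lt(abs(mean(cov$distance_km)), 1e-10)
  expect_lt(abs(mean(cov$income_k)), 1e-10)
  expect_equal(unname(attr(cov, "centers")["income_k"]), 63)
  expect_equal(unname(attr(cov, "centers")["distance_km"]),
               mean(hospital_distances(g)))
  # constant covariate centres to zeros
  g$tracts$avg_income <- 50000
  cov2 <- prepare_covariates(g, scale = FALSE)
  expect_true(all(abs(cov2$income_k) < 1e-12))
  # scaling gives unit SDs
  g$tracts$avg_income <- c(40, 55, 60, 70, 90) * 1000
  cov3 <- prepare_covariates(g, scale = TRUE)
  expect_equal(sd(cov3$income_k), 1)
  # user-supplied distances override great-circle ones
  d <- setNames(c(5, 10, 15, 20, 25), tract_ids(g))
  cov4 <- prepare_covariates(g, distance = d, scale = FALSE)
  expect_equal(unname(attr(cov4, "centers")["distance_km"]), 15)
})

test_that("logistic fit reproduces the 2x2 closed form and flags separation", {
  # (a,b,c,d) = (40,10,20,30): OR = 6, SE = sqrt(1/40+1/10+1/20+1/30)
  y <- c(rep(1, 40), rep(0, 10), rep(1, 20), rep(0, 30))
  x <- c(rep(1, 50), rep(0, 50))
  cov <- data.frame(tract_id = as.character(1:100), distance_km = x,
                    income_k = 0)
  attr(cov, "centers") <- c(distance_km = 0, income_k = 0)
  attr(cov, "scales") <- c(distance_km = 1, income_k = 1)
  f <- fit_logistic(y, cov, interaction = FALSE)
  co <- f$coefficients
  expect_equal(co$or[co$term == "distance"], 6.0, tolerance = 1e-6)
  expect_equal(co$se[co$term == "distance"],
               sqrt(1 / 40 + 1 / 10 + 1 / 20 + 1 / 30), tolerance = 1e-6)
  # CIs are Wald intervals on the log scale
  expect_equal(co$or_lo[2], exp(log(6) - 1.96 * co$se[2]), tolerance = 1e-6)
  # perfectly separable data raise a separation error
  ysep <- c(rep(0, 50), rep(1, 50))
  covsep <- cov; covsep$distance_km <- seq(-1, 1, length.out = 100)
  expect_error(suppressWarnings(fit_logistic(ysep, covsep,
                                             interaction = FALSE)),
               "separation")
  expect_error(fit_logistic(rep(1, 100), cov), "constant")
})

test_that("null covariates give null effects; fitted probs match prevalence", {
  set.seed(41)
  n <- 400
  cov <- data.frame(tract_id = as.character(1:n),
                    distance_km = rnorm(n), income_k = rnorm(n))
  attr(cov, "centers") <- c(distance_km = 0, income_k = 0)
  attr(cov, "scales") <- c(distance_km = 1, income_k = 1)
  y <- rep(c(0, 1), n / 2)
  f <- fit_logistic(y, cov)
  co <- f$coefficients
  expect_true(all(abs(co$estimate[-1]) < 3 * co$se[-1]))
  expect_true(all(abs(co$or[-1] - 1) < 0.5))
  # score equation: mean fitted probability equals prevalence
  expect_equal(mean(fitted(f$glm)), mean(y), tolerance = 1e-8)
  # log-likelihood of the fit is no worse than the null model
  expect_lte(f$residual_deviance, f$null_deviance + 1e-8)
})

test_that("prediction uses the inverse logit on the fitted scale", {
  set.seed(42)
  n <- 300
  d <- rnorm(n); i <- rnorm(n)
  p <- plogis(-0.5 - 1.2 * d + 0.8 * i - 0.5 * d * i)
  y <- as.integer(runif(n) < p)
  cov <- data.frame(tract_id = as.character(1:n), distance_km = d,
                    income_k = i)
  attr(cov, "centers") <- c(distance_km = 0, income_k = 0)
  attr(cov, "scales") <- c(distance_km = 1, income_k = 1)
  f <- fit_logistic(y, cov)
  # at the covariate means the probability is inv-logit(b0)
  b0 <- f$coefficients$estimate[1]
  expect_equal(unname(predict_proba(f, data.frame(distance_km = 0,
                                                  income_k = 0))),
               plogis(b0), tolerance = 1e-10)
  # negative interaction: income slope shallower at larger distance
  hi <- predict_proba(f, data.frame(distance_km = 1, income_k = c(0, 1)))
  lo <- predict_proba(f, data.frame(distance_km = -1, income_k = c(0, 1)))
  slope_hi <- qlogis(hi[2]) - qlogis(hi[1])
  slope_lo <- qlogis(lo[2]) - qlogis(lo[1])
  expect_lt(slope_hi, slope_lo)
  # untransformed-looking input triggers a warning
  expect_warning(predict_proba(f, data.frame(distance_km = rep(100, 20),
                                             income_k = rep(70, 20))),
                 "untransformed")
})

test_that("AUC equals the pairwise oracle exactly and behaves at the limits", {
  # perfect separation
  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1))$auc, 1.0)
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")
  # O(n^2) pairwise oracle with half-credit ties, n = 200
  set.seed(51)
  n <- 200
  s <- round(rnorm(n), 1)              # induces ties
  y <- as.integer(runif(n) < plogis(s))
  if (length(unique(y)) == 1) y[1] <- 1 - y[1]
  r <- roc_auc(s, y)
  pos <- s[y == 1]; neg <- s[y == 0]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  expect_identical(r$auc, tot / (length(pos) * length(neg)))
  # invariance under strictly monotone transform of the scores
  expect_equal(roc_auc(exp(s), y)$auc, r$auc)
  # curve is monotone nondecreasing and AUC matches its trapezoidal area
  expect_true(all(diff(r$tpr) >= 0))
  expect_true(all(diff(r$fpr) >= 0))
  fpr <- c(r$fpr, 1); tpr <- c(r$tpr, 1)
  trap <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  expect_equal(trap, r$auc, tolerance = 1e-10)
  # independent scores give AUC near 0.5
  set.seed(52)
  s2 <- rnorm(2000); y2 <- rep(c(0, 1), 1000)
  expect_lt(abs(roc_auc(s2, y2)$auc - 0.5), 0.03)
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(53)
  s <- rnorm(150); y <- as.integer(runif(150) < plogis(2 * s))
  if (length(unique(y)) == 1) y[1] <- 1 - y[1]
  ours <- roc_auc(s, y)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("group-mean ANOVA matches hand computation and the t^2 identity", {
  r <- compare_group_means(c(1, 2, 3, 4, 5, 6),
                           rep(c("in", "out"), each = 3))
  expect_equal(unname(r$F), 13.5, tolerance = 1e-10)
  expect_equal(r$p, 0.0214, tolerance = 5e-3)
  expect_equal(as.numeric(r$means), c(2, 5))
  # identical groups: F ~ 0
  r0 <- compare_group_means(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_lt(r0$F, 1e-10)
  expect_gt(r0$p, 0.99)
  # two-group F equals squared t
  set.seed(61)
  v <- rnorm(40); gl <- rep(c("a", "b"), 20)
  tt <- t.test(v ~ gl, var.equal = TRUE)
  expect_equal(compare_group_means(v, gl)$F, unname(tt$statistic)^2,
               tolerance = 1e-10)
  expect_error(compare_group_means(1:5, c("a", "a", "a", "a", "b")),
               "degenerate")
})
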