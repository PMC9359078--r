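test_that("grid region is deterministic with queen adjacency and income decay", {
  cfg <- scenario_config(grid_rows = 2, grid_cols = 2, seed = 5)
  g <- make_grid_region(cfg)
  expect_equal(nrow(g$tracts), 4)
  expect_true(all(tract_degrees(g) == 3))
  g2 <- make_grid_region(cfg)
  expect_identical(g$tracts, g2$tracts)
  # income decreases with distance on average
  big <- make_grid_region(scenario_config(seed = 5))   # 20x20 = 400 tracts
  d <- hospital_distances(big)
  expect_lt(cor(d, big$tracts$avg_income), 0)
  expect_true(all(big$tracts$avg_income >= 10000))
})

test_that("intrinsic CAR draws are centred with the right pairwise variance", {
  g2 <- path_graph(2)
  set.seed(1)
  draws <- replicate(10000, { nu <- sample_icar(g2, tau = 2); nu[1] - nu[2] })
  # Var(nu1 - nu2) = 1/tau for the two-node path
  expect_equal(var(draws), 1 / 2, tolerance = 0.05)
  nu <- sample_icar(g2, 2, seed = 3)
  expect_lt(abs(sum(nu)), 1e-8)
})

test_that("ICAR covariance matches the Laplacian pseudo-inverse on a 3x3 grid", {
  g <- make_grid_region(scenario_config(grid_rows = 3, grid_cols = 3, seed = 1))
  ids <- tract_ids(g)
  ei <- cbind(match(g$edges$tract_a, ids), match(g$edges$tract_b, ids))
  L <- matrix(0, 9, 9)
  for (m in seq_len(nrow(ei))) {
    i <- ei[m, 1]; j <- ei[m, 2]
    L[i, j] <- L[i, j] - 1; L[j, i] <- L[j, i] - 1
    L[i, i] <- L[i, i] + 1; L[j, j] <- L[j, j] + 1
  }
  tau <- 1.5
  ev <- eigen(L, symmetric = TRUE)
  pos <- ev$values > 1e-8
  target <- ev$vectors[, pos] %*% diag(1 / (tau * ev$values[pos])) %*%
    t(ev$vectors[, pos])
  set.seed(2)
  draws <- t(replicate(10000, sample_icar(g, tau)))
  emp <- cov(draws)
  rel <- norm(emp - target, "F") / norm(target, "F")
  expect_lt(rel, 0.10)
  expect_true(all(abs(rowSums(draws)) < 1e-8))
})

test_that("simulated counts respect the generative moments", {
  g <- make_grid_region(scenario_config(grid_rows = 20, grid_cols = 20,
                                        seed = 6))
  nu0 <- list(count = setNames(numeric(400), tract_ids(g)),
              zero = setNames(numeric(400), tract_ids(g)))
  # pi = 1 everywhere -> all zero counts
  cfg1 <- scenario_config(seed = 6, family = "zip",
                          beta_zero = list(intercept = 40, species = 0,
                                           period = c(0, 0, 0)))
  set.seed(6)
  c1 <- simulate_counts(g, nu0, cfg1)
  expect_true(all(c1$y_visits == 0))
  # poisson, pi = 0, beta = 0: mean of y/e near 1 (CLT over 3200 strata)
  cfg2 <- scenario_config(seed = 6, family = "poisson",
                          beta_count = list(intercept = 0, species = 0,
                                            period = c(0, 0, 0)))
  set.seed(6)
  c2 <- simulate_counts(g, nu0, cfg2)
  e_gen <- cfg2$visit_rate * c2$population
  ratio <- sum(c2$y_visits) / sum(e_gen)
  se <- sqrt(sum(e_gen)) / sum(e_gen)
  expect_lt(abs(ratio - 1), 3 * se)
  # species coefficient log(3) shows up as a ~3x canine/feline total ratio
  cfg3 <- scenario_config(seed = 6, family = "poisson",
                          beta_count = list(intercept = 0, species = log(3),
                                            period = c(0, 0, 0)))
  set.seed(6)
  c3 <- simulate_counts(g, nu0, cfg3)
  tot <- tapply(c3$y_visits, c3$species, sum)
  pop <- tapply(c3$population, c3$species, sum)
  expect_equal(unname((tot["canine"] / pop["canine"]) /
                        (tot["feline"] / pop["feline"])),
               3, tolerance = 0.10)
  # mean-variance relationship of the generated NB counts: residuals
  # standardized by sqrt(mu + mu^2/shape) have unit variance, while
  # Poisson standardization (sqrt(mu)) shows the overdispersion
  cfg4 <- scenario_config(seed = 6, family = "nb", dispersion = 2,
                          beta_count = list(intercept = 0, species = 0,
                                            period = c(0, 0, 0)))
  set.seed(6)
  c4 <- simulate_counts(g, nu0, cfg4)
  mu4 <- cfg4$visit_rate * c4$population     # exact generative mean
  z_nb <- (c4$y_visits - mu4) / sqrt(mu4 + mu4^2 / 2)
  expect_equal(var(z_nb), 1, tolerance = 0.15)
  z_pois <- (c4$y_visits - mu4) / sqrt(mu4)
  expect_gt(var(z_pois), 1.5)
  # overflow guard
  cfg5 <- scenario_config(seed = 6,
                          beta_count = list(intercept = 60, species = 0,
                                            period = c(0, 0, 0)))
  expect_error(simulate_counts(g, nu0, cfg5), "overflow")
})

test_that("scenarios are reproducible with coherent ground truth", {
  cfg <- scenario_config(grid_rows = 5, grid_cols = 5, seed = 99)
  a <- make_scenario(cfg)
  b <- make_scenario(cfg)
  expect_identical(a$counts$y_visits, b$counts$y_visits)
  expect_identical(a$truth$nu_count, b$truth$nu_count)
  # changing the seed changes draws but not structure
  c3 <- make_scenario(scenario_config(grid_rows = 5, grid_cols = 5, seed = 100))
  expect_equal(dim(c3$counts), dim(a$counts))
  expect_false(identical(c3$counts$y_visits, a$counts$y_visits))
  # truth definition and pairing constraints
  expect_setequal(a$truth$true_ca,
                  names(a$truth$nu_count)[a$truth$nu_count > 0])
  expect_true(all(a$counts$y_cancer <= a$counts$y_visits))
  expect_gt(sum(a$counts$y_visits), 0)
  # ground truth round-trips through JSON
  tmp <- tempfile(fileext = ".json")
  write_truth_json(a$truth, tmp)
  tr <- read_truth_json(tmp)
  expect_equal(tr$nu_count, a$truth$nu_count, tolerance = 1e-12)
  expect_setequal(tr$true_ca, a$truth$true_ca)
})

test_that("fabricated visit records reproduce their source counts", {
  sc <- make_scenario(scenario_config(grid_rows = 4, grid_cols = 4, seed = 13))
  rec <- make_visit_records(sc$counts, seed = 13)
  expect_gt(nrow(rec), sum(sc$counts$y_visits))   # duplicates included
  dd <- deduplicate(rec)
  s2 <- stratify(dd, sc$graph)
  key <- function(x) paste(x$tract_id, x$species, x$period)
  m <- match(key(sc$counts), key(s2))
  expect_equal(s2$y_visits[m], sc$counts$y_visits)
  expect_equal(s2$y_cancer[m], sc$counts$y_cancer)
})
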