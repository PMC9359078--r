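test_that("exceedance probabilities are exact draw fractions", {
  ids <- c("a", "b", "c")
  m <- rbind(c(-1, 1, 0.2), c(1, 1, -0.1), c(1, 1, 0.3), c(1, 1, -0.2))
  q <- exceedance(fake_fit(m, ids))
  expect_equal(unname(q$q), c(0.75, 1, 0.5))
  # brute-force loop oracle on a random fixture
  set.seed(8)
  mm <- matrix(rnorm(500 * 20), 500, 20)
  ids20 <- sprintf("t%02d", 1:20)
  qq <- exceedance(fake_fit(mm, ids20))$q
  oracle <- numeric(20)
  for (i in 1:20) {
    cnt <- 0
    for (s in 1:500) if (mm[s, i] > 0) cnt <- cnt + 1
    oracle[i] <- cnt / 500
  }
  expect_identical(unname(qq), oracle)
})

test_that("delineation is a closed threshold and nested across thresholds", {
  q <- setNames(c(0.95, 0.90, 0.89), c("a", "b", "c"))
  expect_setequal(delineate(q, 0.90), c("a", "b"))
  set.seed(14)
  qr <- setNames(runif(100), sprintf("t%03d", 1:100))
  last <- delineate(qr, 0.80)
  for (th in c(0.85, 0.90, 0.95)) {
    cur <- delineate(qr, th)
    expect_true(all(cur %in% last))
    last <- cur
  }
})

test_that("primary/secondary split follows hospital connectivity", {
  # path 1-2-3-4-5, hospital in tract 1
  g <- path_graph(5, hospital = c(0.01, 0))
  ps <- split_primary_secondary(c("1", "2", "4"), g, hosp_tract = "1")
  expect_setequal(ps$primary, c("1", "2"))
  expect_setequal(ps$secondary, "4")
  # all connected: no secondary
  ps2 <- split_primary_secondary(c("1", "2", "3"), g, hosp_tract = "1")
  expect_equal(ps2$secondary, character(0))
  # hospital tract not a member: largest component is primary
  ps3 <- split_primary_secondary(c("3", "4", "5"), g, hosp_tract = "1")
  expect_setequal(ps3$primary, c("3", "4", "5"))
  expect_warning(split_primary_secondary(character(0), g, "1"), "empty")

  # random memberships on a 10x10 grid agree with a component oracle
  gg <- make_grid_region(scenario_config(grid_rows = 10, grid_cols = 10,
                                         seed = 3))
  ht <- hospital_tract(gg)
  set.seed(4)
  for (k in 1:3) {
    mem <- sample(tract_ids(gg), 35)
    ps <- split_primary_secondary(mem, gg, ht)
    comps <- graph_components(gg, subset = mem)
    expect_setequal(c(ps$primary, ps$secondary), mem)
    if (ht %in% mem) {
      expect_setequal(ps$primary,
                      comps[[which(vapply(comps, function(cc) ht %in% cc,
                                          logical(1)))]])
    }
  }
})

test_that("coverage reproduces hand-computed and printed-scale percentages", {
  g <- path_graph(3)
  counts <- data.frame(tract_id = as.character(1:3), species = "canine",
                       period = "P1", y_visits = c(5, 3, 2),
                       y_cancer = c(5, 3, 2), population = 10)
  cov <- coverage("1", counts, g)
  expect_equal(cov$pct_records_in_ca, 50)
  expect_equal(cov$pct_tracts_in_ca, 33.3)
  # all tracts: 100/100
  cov_all <- coverage(as.character(1:3), counts, g)
  expect_equal(cov_all$pct_records_in_ca, 100)
  expect_equal(cov_all$pct_tracts_in_ca, 100)
})

test_that("concordance counts agreement and discordant sets symmetrically", {
  uni <- sprintf("t%02d", 1:10)
  a <- uni[1:5]; b <- uni[3:7]
  ca <- concordance(a, b, universe = uni)
  expect_equal(ca$n_agree, 10 - 2 - 2)
  expect_setequal(ca$only_a, uni[1:2])
  expect_setequal(ca$only_b, uni[6:7])
  cb <- concordance(b, a, universe = uni)
  expect_equal(cb$pct_agree, ca$pct_agree)
  expect_setequal(cb$only_a, ca$only_b)
  # identical and complementary sets
  expect_equal(concordance(a, a, universe = uni)$pct_agree, 100)
  expect_equal(concordance(uni[1:5], uni[6:10], universe = uni)$pct_agree, 0)
})

test_that("catchment areas assemble, print and export", {
  sc <- small_scenario()
  fit <- small_zinb_fit()
  q <- exceedance(fit)
  ca <- catchment_area(q, sc$graph, 0.90, outcome = "visits")
  expect_setequal(c(ca$primary, ca$secondary), ca$members)
  expect_length(intersect(ca$primary, ca$secondary), 0)
  tmp <- tempfile(fileext = ".csv")
  write_ca_csv(ca, tmp)
  out <- read.csv(tmp, colClasses = c(tract_id = "character"))
  expect_equal(nrow(out), length(tract_ids(sc$graph)))
  expect_setequal(out$zone, intersect(c("primary", "secondary", "outside"),
                                      out$zone))
  expect_equal(sum(out$member), length(ca$members))
})

test_that("per-period delineation: identical periods give identical CAs", {
  # replicate one period's data across all four periods
  sc <- make_scenario(scenario_config(grid_rows = 5, grid_cols = 5, seed = 77))
  base <- sc$counts[sc$counts$period == "P1", ]
  counts <- do.call(rbind, lapply(paste0("P", 1:4), function(p) {
    b <- base; b$period <- p; b
  }))
  counts <- expected_counts(counts)
  res <- suppressWarnings(
    per_period_cas(counts, sc$graph, model_spec("poisson", "car"),
                   threshold = 0.90, chains = 2, iter = 300, seed = 5))
  mems <- lapply(res$per_period, function(x) sort(x$members))
  expect_equal(mems[["P2"]], mems[["P1"]])
  expect_equal(mems[["P4"]], mems[["P1"]])
  expect_setequal(res$combined, mems[["P1"]])
  # combined is contained in every period CA; concordances are percentages
  for (p in names(mems)) expect_true(all(res$combined %in% mems[[p]]))
  expect_true(all(res$concordance$pct_agree >= 0 &
                  res$concordance$pct_agree <= 100))
})
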