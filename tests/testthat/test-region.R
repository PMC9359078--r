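test_that("grid adjacency has the expected queen/rook degrees", {
  polys <- square_grid_polys(2, 2)
  tr <- grid_tracts_df(polys)
  rook <- build_adjacency(polys, tr, hospital = c(1, 1), rule = "rook")
  expect_true(all(tract_degrees(rook) == 2))
  queen <- build_adjacency(polys, tr, hospital = c(1, 1), rule = "queen")
  expect_true(all(tract_degrees(queen) == 3))
  # adjacency symmetry is structural: each unordered pair stored once
  e <- queen$edges
  expect_false(any(duplicated(rbind(e, data.frame(tract_a = e$tract_b,
                                                  tract_b = e$tract_a)))))
})

test_that("5x5 rook adjacency matches a brute-force boundary oracle", {
  polys <- square_grid_polys(5, 5)
  g <- build_adjacency(polys, grid_tracts_df(polys), hospital = c(2.5, 2.5),
                       rule = "rook")
  # oracle: two unit squares share a positive-length boundary iff their
  # grid coordinates differ by 1 in exactly one axis
  coord <- do.call(rbind, lapply(names(polys), function(id) {
    as.integer(strsplit(sub("t", "", id), "_")[[1]])
  }))
  oracle_deg <- integer(25)
  for (i in 1:24) for (j in (i + 1):25) {
    d <- abs(coord[i, ] - coord[j, ])
    if (sum(d) == 1) {
      oracle_deg[i] <- oracle_deg[i] + 1
      oracle_deg[j] <- oracle_deg[j] + 1
    }
  }
  expect_equal(unname(tract_degrees(g)[names(polys)]), oracle_deg)
})

test_that("invalid polygons are rejected with the tract id", {
  polys <- square_grid_polys(2, 2)
  polys[["t1_2"]] <- polys[["t1_2"]][1:2, ]   # degenerate
  expect_error(build_adjacency(polys, grid_tracts_df(polys), c(0, 0)), "t1_2")
})

test_that("haversine distance has the right closed forms and oracle", {
  expect_equal(haversine_km(c(12, 40), c(12, 40)), 0)
  # quarter meridian: pi * R / 2
  expect_equal(haversine_km(c(0, 0), c(0, 90)), pi * 6371.0088 / 2,
               tolerance = 1e-9)
  # symmetry + spherical law of cosines oracle on random pairs
  slc <- function(a, b) {
    tr <- pi / 180
    d <- sin(a[2] * tr) * sin(b[2] * tr) +
      cos(a[2] * tr) * cos(b[2] * tr) * cos((b[1] - a[1]) * tr)
    6371.0088 * acos(pmin(1, pmax(-1, d)))
  }
  set.seed(3)
  for (k in 1:20) {
    a <- c(runif(1, -180, 180), runif(1, -80, 80))
    b <- c(runif(1, -180, 180), runif(1, -80, 80))
    expect_equal(haversine_km(a, b), haversine_km(b, a))
    expect_equal(haversine_km(a, b), slc(a, b), tolerance = 1e-6)
  }
  expect_error(haversine_km(c(Inf, 0), c(0, 0)), "finite")
})

test_that("buffer filtering keeps the hospital tract and respects the radius", {
  sc_graph <- make_grid_region(scenario_config(grid_rows = 6, grid_cols = 6,
                                               seed = 1))
  ht <- hospital_tract(sc_graph)
  f <- filter_buffer(sc_graph, 5)
  expect_true(ht %in% tract_ids(f))
  # centroid mode: strict threshold at the radius
  g <- path_graph(2, hospital = c(0, 0))
  g$tracts$lon <- c(0, 233.1 / 111.195)    # ~233.1 km east on the equator
  g$tracts$lat <- c(0, 0)
  kept <- filter_buffer(g, 233)
  expect_equal(tract_ids(kept), "1")
  # idempotence
  f2 <- filter_buffer(f, 5)
  expect_equal(tract_ids(f2), tract_ids(f))
  expect_equal(f2$edges, f$edges)
  g_far <- g; g_far$hospital <- c(50, 50)
  expect_error(filter_buffer(g_far, 1), "no tracts")
})

test_that("polygon mode keeps a tract whose centroid is outside the circle", {
  # long thin tract reaching toward the hospital: centroid far, edge near
  polys <- list(
    home = cbind(c(-0.01, 0.01, 0.01, -0.01), c(-0.01, -0.01, 0.01, 0.01)),
    sliver = cbind(c(0.02, 3, 3, 0.02), c(-0.001, -0.001, 0.001, 0.001)))
  tr <- data.frame(tract_id = c("home", "sliver"), households = 10,
                   avg_income = 50000)
  g <- build_adjacency(polys, tr, hospital = c(0, 0))
  d_centroid <- hospital_distances(g)["sliver"]
  expect_gt(d_centroid, 100)                   # centroid well outside
  f <- filter_buffer(g, 50)                    # ...but boundary inside
  expect_true("sliver" %in% tract_ids(f))
  # centroid mode on the same graph drops it
  g_nopoly <- g; g_nopoly$polygons <- NULL
  expect_false("sliver" %in% tract_ids(filter_buffer(g_nopoly, 50)))
})

test_that("connected components respect subset restriction and match BFS", {
  g <- path_graph(3)
  # two tracts joined only via a tract NOT in the subset: two components
  comps <- graph_components(g, subset = c("1", "3"))
  expect_equal(length(comps), 2)
  expect_equal(graph_components(g, subset = "2"), list("2"))
  expect_error(graph_components(g, subset = "99"), "unknown tract_id")

  # random subsets of a 10x10 grid vs an independent BFS oracle
  sc_graph <- make_grid_region(scenario_config(grid_rows = 10, grid_cols = 10,
                                               seed = 2))
  ids <- tract_ids(sc_graph)
  e <- sc_graph$edges
  bfs_components <- function(subset) {
    adj <- lapply(setNames(subset, subset), function(i) {
      c(e$tract_b[e$tract_a == i & e$tract_b %in% subset],
        e$tract_a[e$tract_b == i & e$tract_a %in% subset])
    })
    seen <- character(0); out <- list()
    for (s in subset) {
      if (s %in% seen) next
      queue <- s; comp <- character(0)
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        if (v %in% comp) next
        comp <- c(comp, v)
        queue <- c(queue, setdiff(adj[[v]], comp))
      }
      seen <- c(seen, comp)
      out[[length(out) + 1]] <- sort(comp)
    }
    out
  }
  set.seed(9)
  for (k in 1:5) {
    subset <- sample(ids, 40)
    got <- lapply(graph_components(sc_graph, subset), sort)
    want <- bfs_components(subset)
    expect_setequal(vapply(got, paste, "", collapse = ","),
                    vapply(want, paste, "", collapse = ","))
    # disjoint cover of the subset
    expect_setequal(unlist(got), subset)
    expect_equal(anyDuplicated(unlist(got)), 0)
  }
})

test_that("GeoJSON and edge-list round trips preserve the graph", {
  g <- make_grid_region(scenario_config(grid_rows = 3, grid_cols = 3, seed = 4))
  tmp <- tempfile(fileext = ".geojson")
  write_tracts_geojson(g, tmp)
  g2 <- read_tracts_geojson(tmp, hospital = g$hospital)
  expect_setequal(tract_ids(g2), tract_ids(g))
  expect_equal(tract_degrees(g2)[tract_ids(g)], tract_degrees(g))
  expect_equal(g2$tracts$households[match(tract_ids(g), g2$tracts$tract_id)],
               g$tracts$households)
  # edge list CSV
  tmp2 <- tempfile(fileext = ".csv")
  write.csv(g$edges, tmp2, row.names = FALSE, quote = FALSE)
  e <- read_adjacency_csv(tmp2)
  expect_equal(nrow(e), nrow(g$edges))
  # summary CSV columns
  s <- tract_summary(g, radius_km = 5)
  expect_named(s, c("tract_id", "degree", "distance_km", "in_buffer"))
})
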