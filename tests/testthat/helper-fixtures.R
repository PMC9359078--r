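# shared fixtures, all generated in code

# axis-aligned unit-square grid polygons named t<r>_<c>
square_grid_polys <- function(rows, cols, cell = 1) {
  polys <- list()
  for (r in seq_len(rows)) for (c in seq_len(cols)) {
    x0 <- (c - 1) * cell; y0 <- (r - 1) * cell
    polys[[sprintf("t%d_%d", r, c)]] <-
      cbind(c(x0, x0 + cell, x0 + cell, x0), c(y0, y0, y0 + cell, y0 + cell))
  }
  polys
}

grid_tracts_df <- function(polys, households = 100, income = 50000) {
  data.frame(tract_id = names(polys),
             households = households, avg_income = income)
}

# small hand-built graph: ids 1..n in a path (or custom edges)
path_graph <- function(n, hospital = c(0, 0)) {
  tracts <- data.frame(tract_id = as.character(seq_len(n)),
                       lon = seq_len(n) * 0.01, lat = 0,
                       households = 100, avg_income = 50000)
  edges <- if (n > 1) {
    data.frame(tract_a = as.character(seq_len(n - 1)),
               tract_b = as.character(seq_len(n - 1) + 1))
  } else NULL
  tract_graph(tracts, edges, hospital = hospital)
}

# cached small synthetic scenario + fit, shared across test files
fixture_env <- new.env(parent = emptyenv())

small_scenario <- function() {
  if (is.null(fixture_env$sc)) {
    fixture_env$sc <- make_scenario(
      scenario_config(grid_rows = 8, grid_cols = 8, seed = 42))
  }
  fixture_env$sc
}

small_zinb_fit <- function() {
  if (is.null(fixture_env$fit)) {
    sc <- small_scenario()
    fixture_env$fit <- suppressWarnings(
      fit_spatial_count(sc$counts, sc$graph, model_spec("zinb", "car"),
                        chains = 2, iter = 800, seed = 7))
  }
  fixture_env$fit
}

# minimal posterior_draws carrier for hand-built nu draws
fake_fit <- function(nu_matrix, tract_ids, chains = 2) {
  colnames(nu_matrix) <- paste0("nu[", tract_ids, "]")
  n <- nrow(nu_matrix)
  half <- split(seq_len(n), rep(seq_len(chains), length.out = n))
  structure(list(draws = lapply(half, function(i) nu_matrix[i, , drop = FALSE]),
                 spec = model_spec("poisson", "exchangeable"),
                 seed = 1, iter = n %/% chains, warmup = 0, chains = chains,
                 par_names = colnames(nu_matrix), tract_ids = tract_ids,
                 per_levels = paste0("P", 1:4)),
            class = "posterior_draws")
}
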