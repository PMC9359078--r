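#' Tract geography
#'
#' A `tract_graph` bundles the census-tract geography used throughout the
#' pipeline: one row per tract (id, centroid, households, average household
#' income), an undirected adjacency edge list, the hospital location, and
#' optionally the tract polygons the adjacency was derived from.
#'
#' @param tracts Data frame with columns `tract_id` (character, unique),
#'   `lon`, `lat` (WGS84 degrees), `households` (non-negative integer),
#'   `avg_income` (USD/year), and optionally `county`.
#' @param edges Data frame with character columns `tract_a`, `tract_b`
#'   (unordered pairs; duplicates and self-loops are rejected).
#' @param hospital Numeric `c(lon, lat)` of the hospital.
#' @param polygons Optional named list (by `tract_id`) of rings; each ring a
#'   two-column `(lon, lat)` matrix.
#' @return An object of class `tract_graph`.
#' @export
tract_graph <- function(tracts, edges = NULL, hospital, polygons = NULL) {
  tracts <- as.data.frame(tracts)
  req <- c("tract_id", "lon", "lat", "households", "avg_income")
  if (!all(req %in% names(tracts))) {
    stop("tract_graph: tracts must have columns ", paste(req, collapse = ", "))
  }
  tracts$tract_id <- as.character(tracts$tract_id)
  if (anyDuplicated(tracts$tract_id)) stop("tract_graph: duplicate tract_id")
  if (any(tracts$households < 0)) stop("tract_graph: households must be >= 0")
  if (any(abs(tracts$lat) > 90)) stop("tract_graph: latitude outside [-90, 90]")
  if (is.null(edges)) {
    edges <- data.frame(tract_a = character(0), tract_b = character(0))
  }
  edges <- as.data.frame(edges)[, c("tract_a", "tract_b")]
  edges$tract_a <- as.character(edges$tract_a)
  edges$tract_b <- as.character(edges$tract_b)
  unknown <- setdiff(c(edges$tract_a, edges$tract_b), tracts$tract_id)
  if (length(unknown)) {
    stop("tract_graph: edges reference unknown tracts: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  if (any(edges$tract_a == edges$tract_b)) stop("tract_graph: self-loop edge")
  # canonical unordered representation, deduplicated
  a <- pmin(edges$tract_a, edges$tract_b)
  b <- pmax(edges$tract_a, edges$tract_b)
  keep <- !duplicated(paste(a, b, sep = "\r"))
  edges <- data.frame(tract_a = a[keep], tract_b = b[keep],
                      stringsAsFactors = FALSE)
  stopifnot(is.numeric(hospital), length(hospital) == 2)
  if (!is.null(polygons)) {
    miss <- setdiff(tracts$tract_id, names(polygons))
    if (length(miss)) stop("tract_graph: polygons missing for some tracts")
  }
  structure(list(tracts = tracts, edges = edges,
                 hospital = as.numeric(hospital), polygons = polygons),
            class = "tract_graph")
}

#' @export
print.tract_graph <- function(x, ...) {
  cat("tract_graph:", nrow(x$tracts), "tracts,", nrow(x$edges), "edges\n")
  cat("  hospital at (", x$hospital[1], ",", x$hospital[2], ")\n")
  deg <- tract_degrees(x)
  cat("  degree: min", min(deg), "median", stats::median(deg), "max", max(deg),
      if (any(deg == 0)) paste0(" (", sum(deg == 0), " isolated)") else "", "\n")
  invisible(x)
}

#' Tract ids in canonical order
#' @param graph A [tract_graph].
#' @export
tract_ids <- function(graph) graph$tracts$tract_id

#' Neighbour count (degree) per tract
#'
#' The `m_i` of the CAR prior: the number of adjacent tracts.
#' @param graph A [tract_graph].
#' @return Named integer vector in `tract_ids(graph)` order.
#' @export
tract_degrees <- function(graph) {
  ids <- tract_ids(graph)
  tab <- table(factor(c(graph$edges$tract_a, graph$edges$tract_b), levels = ids))
  stats::setNames(as.integer(tab), ids)
}

#' Edge list as integer index pairs
#' @keywords internal
edge_indices <- function(graph) {
  ids <- tract_ids(graph)
  cbind(match(graph$edges$tract_a, ids), match(graph$edges$tract_b, ids))
}

#' Great-circle distance in km
#'
#' Haversine formula on the sphere with earth radius 6371.0088 km.
#' Vectorised: `a` and `b` may be vectors `c(lon, lat)` or two-column
#' matrices.
#'
#' @param a,b Coordinates as `c(lon, lat)` degrees, or n-by-2 matrices.
#' @return Distances in km.
#' @export
haversine_km <- function(a, b) {
  R <- 6371.0088
  if (is.null(dim(a))) a <- matrix(a, ncol = 2)
  if (is.null(dim(b))) b <- matrix(b, ncol = 2)
  if (!all(is.finite(a)) || !all(is.finite(b))) {
    stop("haversine_km: coordinates must be finite")
  }
  to_rad <- pi / 180
  lon1 <- a[, 1] * to_rad; lat1 <- a[, 2] * to_rad
  lon2 <- b[, 1] * to_rad; lat2 <- b[, 2] * to_rad
  dlat <- lat2 - lat1; dlon <- lon2 - lon1
  h <- sin(dlat / 2)^2 + cos(lat1) * cos(lat2) * sin(dlon / 2)^2
  h <- pmin(1, h)
  2 * R * asin(sqrt(h))
}

#' Distance from each tract centroid to the hospital
#' @param graph A [tract_graph].
#' @return Named numeric vector (km).
#' @export
hospital_distances <- function(graph) {
  d <- haversine_km(as.matrix(graph$tracts[, c("lon", "lat")]),
                    matrix(graph$hospital, nrow(graph$tracts), 2, byrow = TRUE))
  stats::setNames(d, tract_ids(graph))
}

# ---- polygon adjacency ------------------------------------------------

poly_rings <- function(polygons, id) {
  p <- polygons[[id]]
  if (is.matrix(p)) list(p) else p
}

validate_ring <- function(ring, id) {
  if (!is.matrix(ring) || ncol(ring) != 2 || !all(is.finite(ring))) {
    stop("invalid polygon for tract '", id, "': malformed coordinates")
  }
  # drop closing vertex if repeated
  n <- nrow(ring)
  if (n >= 2 && all(ring[1, ] == ring[n, ])) ring <- ring[-n, , drop = FALSE]
  if (nrow(unique(ring)) < 3) {
    stop("invalid polygon for tract '", id, "': fewer than 3 distinct vertices")
  }
  ring
}

# squared distance from points (n x 2) to segment p1-p2
point_seg_dist2 <- function(pts, p1, p2) {
  v <- p2 - p1
  w1 <- pts[, 1] - p1[1]; w2 <- pts[, 2] - p1[2]
  vv <- sum(v * v)
  t <- if (vv == 0) rep(0, nrow(pts)) else pmin(1, pmax(0, (w1 * v[1] + w2 * v[2]) / vv))
  dx <- w1 - t * v[1]; dy <- w2 - t * v[2]
  dx * dx + dy * dy
}

ring_edges <- function(ring) {
  n <- nrow(ring)
  list(p1 = ring, p2 = ring[c(2:n, 1), , drop = FALSE])
}

# do polygons A and B share at least one boundary point? (queen)
share_point <- function(ringsA, ringsB, tol) {
  tol2 <- tol * tol
  for (ra in ringsA) for (rb in ringsB) {
    ea <- ring_edges(rb)
    for (k in seq_len(nrow(ea$p1))) {
      if (any(point_seg_dist2(ra, ea$p1[k, ], ea$p2[k, ]) <= tol2)) return(TRUE)
    }
    eb <- ring_edges(ra)
    for (k in seq_len(nrow(eb$p1))) {
      if (any(point_seg_dist2(rb, eb$p1[k, ], eb$p2[k, ]) <= tol2)) return(TRUE)
    }
  }
  FALSE
}

# do polygons share a boundary segment of positive length? (rook)
share_segment <- function(ringsA, ringsB, tol) {
  for (ra in ringsA) for (rb in ringsB) {
    ea <- ring_edges(ra); eb <- ring_edges(rb)
    for (i in seq_len(nrow(ea$p1))) {
      a1 <- ea$p1[i, ]; a2 <- ea$p2[i, ]
      va <- a2 - a1; la <- sqrt(sum(va^2))
      if (la < tol) next
      ua <- va / la
      for (j in seq_len(nrow(eb$p1))) {
        b1 <- eb$p1[j, ]; b2 <- eb$p2[j, ]
        # collinearity: both endpoints of b within tol of line through a
        d1 <- abs((b1[1] - a1[1]) * ua[2] - (b1[2] - a1[2]) * ua[1])
        d2 <- abs((b2[1] - a1[1]) * ua[2] - (b2[2] - a1[2]) * ua[1])
        if (d1 > tol || d2 > tol) next
        # overlap of projections onto a's direction
        t1 <- (b1[1] - a1[1]) * ua[1] + (b1[2] - a1[2]) * ua[2]
        t2 <- (b2[1] - a1[1]) * ua[1] + (b2[2] - a1[2]) * ua[2]
        lo <- max(0, min(t1, t2)); hi <- min(la, max(t1, t2))
        if (hi - lo > tol) return(TRUE)
      }
    }
  }
  FALSE
}

#' Build tract adjacency from polygons
#'
#' Queen contiguity (the default, the usual convention for US census
#' tracts) links two tracts that share at least one boundary point; rook
#' contiguity requires a shared boundary segment of positive length.
#' Candidate pairs are pre-filtered by bounding-box overlap.
#'
#' @param polygons Named list (by tract id) of rings: each entry either a
#'   two-column `(lon, lat)` matrix or a list of such matrices.
#' @param tracts Tract attribute data frame (see [tract_graph]); if `lon`
#'   and `lat` are absent they are filled with ring vertex means.
#' @param hospital `c(lon, lat)`.
#' @param rule `"queen"` or `"rook"`.
#' @param tol Coordinate tolerance for point/segment coincidence
#'   (degrees; the default is about 1 mm).
#' @return A [tract_graph] with the derived edges and polygons attached.
#' @export
build_adjacency <- function(polygons, tracts, hospital,
                            rule = c("queen", "rook"), tol = 1e-8) {
  rule <- match.arg(rule)
  ids <- names(polygons)
  if (is.null(ids)) stop("build_adjacency: polygons must be a named list")
  rings <- lapply(ids, function(id) {
    lapply(poly_rings(polygons, id), validate_ring, id = id)
  })
  names(rings) <- ids
  bbox <- t(vapply(rings, function(rs) {
    m <- do.call(rbind, rs)
    c(min(m[, 1]), max(m[, 1]), min(m[, 2]), max(m[, 2]))
  }, numeric(4)))
  n <- length(ids)
  ea <- character(0); eb <- character(0)
  for (i in seq_len(n - 1)) {
    # bbox prefilter (expanded by tol)
    js <- which(bbox[(i + 1):n, 1] <= bbox[i, 2] + tol &
                bbox[(i + 1):n, 2] >= bbox[i, 1] - tol &
                bbox[(i + 1):n, 3] <= bbox[i, 4] + tol &
                bbox[(i + 1):n, 4] >= bbox[i, 3] - tol) + i
    for (j in js) {
      hit <- if (rule == "queen") share_point(rings[[i]], rings[[j]], tol)
             else share_segment(rings[[i]], rings[[j]], tol)
      if (hit) { ea <- c(ea, ids[i]); eb <- c(eb, ids[j]) }
    }
  }
  tracts <- as.data.frame(tracts)
  tracts$tract_id <- as.character(tracts$tract_id)
  if (!all(c("lon", "lat") %in% names(tracts))) {
    cent <- t(vapply(rings[tracts$tract_id], function(rs) {
      m <- do.call(rbind, rs); colMeans(m)
    }, numeric(2)))
    tracts$lon <- cent[, 1]; tracts$lat <- cent[, 2]
  }
  tract_graph(tracts, data.frame(tract_a = ea, tract_b = eb),
              hospital = hospital,
              polygons = lapply(rings, identity))
}

# ---- buffer filtering -------------------------------------------------

point_in_ring <- function(pt, ring) {
  # ray casting
  n <- nrow(ring)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    yi <- ring[i, 2]; yj <- ring[j, 2]
    if ((yi > pt[2]) != (yj > pt[2])) {
      xint <- ring[i, 1] + (pt[2] - yi) / (yj - yi) * (ring[j, 1] - ring[i, 1])
      if (pt[1] < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

#' Tract containing (or nearest to) the hospital
#' @param graph A [tract_graph].
#' @return A tract id.
#' @export
hospital_tract <- function(graph) {
  if (!is.null(graph$polygons)) {
    for (id in tract_ids(graph)) {
      inside <- vapply(poly_rings(graph$polygons, id),
                       function(r) point_in_ring(graph$hospital, r), logical(1))
      if (any(inside)) return(id)
    }
  }
  ids <- tract_ids(graph)
  ids[which.min(hospital_distances(graph))]
}

# minimum great-circle distance from hospital to a tract's boundary,
# sampling each polygon edge at `samples` interior points plus vertices
poly_min_distance <- function(graph, id, samples = 64) {
  rings <- poly_rings(graph$polygons, id)
  dmin <- Inf
  for (r in rings) {
    e <- ring_edges(r)
    for (k in seq_len(nrow(e$p1))) {
      t <- seq(0, 1, length.out = samples + 2)
      pts <- cbind(e$p1[k, 1] + t * (e$p2[k, 1] - e$p1[k, 1]),
                   e$p1[k, 2] + t * (e$p2[k, 2] - e$p1[k, 2]))
      dmin <- min(dmin, min(haversine_km(
        pts, matrix(graph$hospital, nrow(pts), 2, byrow = TRUE))))
    }
  }
  dmin
}

#' Restrict a tract graph to a circular buffer around the hospital
#'
#' Keeps tracts within `radius_km` of the hospital: when polygons are
#' attached a tract is kept if its polygon intersects the buffer circle
#' (boundary sampled at 64 points per edge, or the hospital lies inside
#' the polygon); otherwise a tract is kept if its centroid distance is
#' `<= radius_km`. Edges are restricted to the kept tracts.
#'
#' @param graph A [tract_graph].
#' @param radius_km Positive radius in km.
#' @return Filtered [tract_graph]; attributes `n_kept` / `n_dropped`
#'   record the filtering.
#' @export
filter_buffer <- function(graph, radius_km) {
  stopifnot(radius_km > 0)
  ids <- tract_ids(graph)
  if (!is.null(graph$polygons)) {
    keep <- vapply(ids, function(id) {
      inside <- any(vapply(poly_rings(graph$polygons, id),
                           function(r) point_in_ring(graph$hospital, r),
                           logical(1)))
      inside || poly_min_distance(graph, id) <= radius_km
    }, logical(1))
  } else {
    keep <- hospital_distances(graph) <= radius_km
  }
  if (!any(keep)) stop("filter_buffer: no tracts within buffer")
  kept_ids <- ids[keep]
  edges <- graph$edges[graph$edges$tract_a %in% kept_ids &
                       graph$edges$tract_b %in% kept_ids, ]
  out <- tract_graph(graph$tracts[keep, , drop = FALSE], edges,
                     hospital = graph$hospital,
                     polygons = if (is.null(graph$polygons)) NULL
                                else graph$polygons[kept_ids])
  attr(out, "n_kept") <- sum(keep)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

# ---- connected components --------------------------------------------

as_igraph <- function(graph, subset = NULL) {
  ids <- tract_ids(graph)
  if (!is.null(subset)) {
    unknown <- setdiff(subset, ids)
    if (length(unknown)) {
      stop("unknown tract_id: ", paste(utils::head(unknown, 5), collapse = ", "))
    }
    ids <- intersect(ids, subset)
  }
  e <- graph$edges[graph$edges$tract_a %in% ids & graph$edges$tract_b %in% ids, ]
  igraph::graph_from_data_frame(e, directed = FALSE,
                                vertices = data.frame(name = ids))
}

#' Connected components of (a subset of) the tract graph
#'
#' The graph is restricted to `subset`: an edge counts only if both ends
#' are in the subset.
#'
#' @param graph A [tract_graph].
#' @param subset Optional character vector of tract ids (default: all).
#' @return List of character vectors, one per component, largest first.
#' @export
graph_components <- function(graph, subset = NULL) {
  g <- as_igraph(graph, subset)
  if (igraph::vcount(g) == 0) return(list())
  comp <- igraph::components(g)
  out <- split(names(comp$membership), comp$membership)
  names(out) <- NULL
  out[order(-vapply(out, length, integer(1)))]
}

# ---- I/O ---------------------------------------------------------------

#' Read tracts from a GeoJSON FeatureCollection
#'
#' One Feature per tract with `tract_id`, `households`, `avg_income`
#' properties and Polygon/MultiPolygon geometry. Adjacency is derived with
#' [build_adjacency].
#'
#' @param path GeoJSON file.
#' @param hospital `c(lon, lat)`.
#' @param rule Contiguity rule passed to [build_adjacency].
#' @return A [tract_graph].
#' @export
read_tracts_geojson <- function(path, hospital, rule = "queen") {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("read_tracts_geojson: not a FeatureCollection")
  rows <- list(); polys <- list()
  for (f in gj$features) {
    pr <- f$properties
    if (is.null(pr$tract_id)) stop("read_tracts_geojson: feature missing tract_id")
    id <- as.character(pr$tract_id)
    geom <- f$geometry
    ring_of <- function(coords) {
      do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
    }
    rings <- switch(geom$type,
      Polygon = lapply(geom$coordinates[1], ring_of),
      MultiPolygon = lapply(geom$coordinates, function(pg) ring_of(pg[[1]])),
      stop("read_tracts_geojson: unsupported geometry ", geom$type))
    polys[[id]] <- rings
    rows[[id]] <- data.frame(
      tract_id = id,
      households = as.numeric(pr$households),
      avg_income = as.numeric(pr$avg_income),
      county = if (is.null(pr$county)) NA_character_ else as.character(pr$county),
      stringsAsFactors = FALSE)
  }
  tracts <- do.call(rbind, rows)
  build_adjacency(polys, tracts, hospital, rule = rule)
}

#' Write a tract graph as GeoJSON
#' @param graph A [tract_graph] with polygons attached.
#' @param path Output file.
#' @export
write_tracts_geojson <- function(graph, path) {
  if (is.null(graph$polygons)) stop("write_tracts_geojson: no polygons attached")
  feats <- lapply(seq_len(nrow(graph$tracts)), function(i) {
    tr <- graph$tracts[i, ]
    rings <- poly_rings(graph$polygons, tr$tract_id)
    coords <- lapply(rings, function(r) {
      r <- rbind(r, r[1, ])   # close ring
      lapply(seq_len(nrow(r)), function(k) c(r[k, 1], r[k, 2]))
    })
    list(type = "Feature",
         properties = list(tract_id = tr$tract_id,
                           households = tr$households,
                           avg_income = tr$avg_income),
         geometry = list(type = "MultiPolygon",
                         coordinates = lapply(coords, list)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
}

#' Read an adjacency edge list (CSV with header `tract_a,tract_b`)
#' @param path CSV file.
#' @return Data frame of edges usable by [tract_graph].
#' @export
read_adjacency_csv <- function(path) {
  e <- utils::read.csv(path, colClasses = "character")
  if (!all(c("tract_a", "tract_b") %in% names(e))) {
    stop("read_adjacency_csv: header must be tract_a,tract_b")
  }
  e[, c("tract_a", "tract_b")]
}

#' Per-tract geography summary
#'
#' Writes (or returns) `tract_id,degree,distance_km,in_buffer`.
#'
#' @param graph A [tract_graph].
#' @param radius_km Buffer radius defining `in_buffer` (centroid rule).
#' @param path Optional CSV output path.
#' @return The summary data frame, invisibly when written.
#' @export
tract_summary <- function(graph, radius_km = Inf, path = NULL) {
  d <- hospital_distances(graph)
  out <- data.frame(tract_id = tract_ids(graph),
                    degree = as.integer(tract_degrees(graph)),
                    distance_km = as.numeric(d),
                    in_buffer = as.integer(d <= radius_km))
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    return(invisible(out))
  }
  out
}
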