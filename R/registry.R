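#' Registry processing
#'
#' Turns raw hospital visit records into deduplicated, stratified counts
#' over the tract x species x period grid, with population-based
#' expected-count offsets (standardised-incidence-ratio style).
#'
#' @name registry
NULL

SPECIES_LEVELS <- c("canine", "feline")

#' Default per-household animal rates
#'
#' 1.6 dogs and 1.7 cats per household (state-level averages for
#' California reported by the AVMA).
#' @export
default_species_rates <- function() c(canine = 1.6, feline = 1.7)

#' Study period scheme
#'
#' Ordered, contiguous, non-overlapping year ranges covering the study
#' window. The default is four five-year periods P1--P4 spanning
#' 2000--2019.
#'
#' @param labels Character labels.
#' @param start,end Integer start/end years (inclusive) per period.
#' @return A `period_scheme` data frame.
#' @export
period_scheme <- function(labels = paste0("P", 1:4),
                          start = c(2000, 2005, 2010, 2015),
                          end = c(2004, 2009, 2014, 2019)) {
  stopifnot(length(labels) == length(start), length(start) == length(end))
  o <- order(start)
  labels <- labels[o]; start <- start[o]; end <- end[o]
  if (any(start > end)) stop("period_scheme: start > end")
  if (length(start) > 1 && any(start[-1] != end[-length(end)] + 1)) {
    stop("period_scheme: periods must be contiguous and non-overlapping")
  }
  structure(data.frame(label = labels, start = start, end = end,
                       stringsAsFactors = FALSE),
            class = c("period_scheme", "data.frame"))
}

#' Map years to period labels
#' @param year Integer vector.
#' @param scheme A [period_scheme].
#' @return Character labels.
#' @export
assign_period <- function(year, scheme) {
  idx <- findInterval(year, scheme$start)
  bad <- idx == 0 | year > scheme$end[pmax(idx, 1)]
  if (any(bad)) {
    stop("assign_period: year(s) outside the study window: ",
         paste(utils::head(unique(year[bad]), 5), collapse = ", "))
  }
  scheme$label[idx]
}

#' Validate raw visit records
#' @keywords internal
validate_records <- function(records) {
  records <- as.data.frame(records)
  req <- c("animal_id", "species", "year", "cancer", "tract_id")
  if (!all(req %in% names(records))) {
    stop("records must have columns ", paste(req, collapse = ", "))
  }
  records$animal_id <- as.character(records$animal_id)
  records$tract_id <- as.character(records$tract_id)
  records$species <- as.character(records$species)
  records$cancer <- as.logical(records$cancer)
  bad <- setdiff(unique(records$species), SPECIES_LEVELS)
  if (length(bad)) stop("unknown species: ", paste(bad, collapse = ", "))
  records
}

#' Deduplicate visit records to one per animal-year
#'
#' Only one record of the same animal per calendar year is retained. If
#' any record of that animal-year carries a cancer diagnosis the retained
#' record is a cancer record (the first cancer record in input order);
#' otherwise the first record in input order is kept.
#'
#' @param records Data frame with `animal_id`, `species`, `year`,
#'   `cancer`, `tract_id`.
#' @return Deduplicated records data frame.
#' @export
deduplicate <- function(records) {
  records <- validate_records(records)
  if (nrow(records) == 0) return(records)
  sp_per_animal <- tapply(records$species, records$animal_id,
                          function(s) length(unique(s)))
  if (any(sp_per_animal > 1)) {
    stop("conflicting species for animal id(s): ",
         paste(utils::head(names(sp_per_animal)[sp_per_animal > 1], 5),
               collapse = ", "))
  }
  key <- paste(records$animal_id, records$year, sep = "\r")
  # order: cancer records first within animal-year, stable in input order
  ord <- order(key, !records$cancer, seq_len(nrow(records)))
  r <- records[ord, ]
  keep <- !duplicated(key[ord])
  dropped_tract <- tapply(records$tract_id, key, function(x) length(unique(x)))
  if (any(dropped_tract > 1)) {
    warning(sum(dropped_tract > 1),
            " animal-year(s) had records from multiple tracts; ",
            "the retained record's tract was used")
  }
  out <- r[keep, ]
  # cancer = any record of the animal-year had cancer (guaranteed by ordering)
  rownames(out) <- NULL
  out
}

#' Estimate the animal population of a tract
#'
#' `households * rate[species]`; defaults 1.6 dogs and 1.7 cats per
#' household.
#'
#' @param households Non-negative household counts.
#' @param species `"canine"` or `"feline"` (recycled).
#' @param rates Named rate vector, see [default_species_rates].
#' @return Estimated animal counts.
#' @export
estimate_population <- function(households, species,
                                rates = default_species_rates()) {
  if (any(households < 0)) stop("estimate_population: households must be >= 0")
  if (!all(species %in% names(rates))) {
    stop("estimate_population: unknown species")
  }
  households * unname(rates[species])
}

#' Stratify deduplicated records into the full tract grid
#'
#' Counts visits (all deduplicated records) and cancer cases (the
#' `cancer = TRUE` subset) per tract x species x period stratum, on the
#' complete grid (explicit zero rows), and attaches estimated populations.
#'
#' @param records Deduplicated records (see [deduplicate]).
#' @param graph A [tract_graph] providing the tract universe and
#'   household counts.
#' @param scheme A [period_scheme].
#' @param rates Species rates for [estimate_population].
#' @return A `stratified_counts` data frame with columns `tract_id`,
#'   `species`, `period`, `y_visits`, `y_cancer`, `population` (and,
#'   after [expected_counts], `e_visits`, `e_cancer`).
#' @export
stratify <- function(records, graph, scheme = period_scheme(),
                     rates = default_species_rates()) {
  records <- validate_records(records)
  ids <- tract_ids(graph)
  unknown <- !(records$tract_id %in% ids)
  if (any(unknown)) {
    stop("stratify: ", sum(unknown), " record(s) reference unknown tract_id")
  }
  grid <- expand.grid(tract_id = ids, species = SPECIES_LEVELS,
                      period = scheme$label, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  key_of <- function(t, s, p) paste(t, s, p, sep = "\r")
  gk <- key_of(grid$tract_id, grid$species, grid$period)
  if (nrow(records)) {
    per <- assign_period(records$year, scheme)
    rk <- key_of(records$tract_id, records$species, per)
    tv <- table(factor(rk, levels = gk))
    tc <- table(factor(rk[records$cancer], levels = gk))
    grid$y_visits <- as.integer(tv)
    grid$y_cancer <- as.integer(tc)
  } else {
    grid$y_visits <- 0L
    grid$y_cancer <- 0L
  }
  hh <- stats::setNames(graph$tracts$households, ids)
  grid$population <- estimate_population(hh[grid$tract_id], grid$species, rates)
  rownames(grid) <- NULL
  class(grid) <- c("stratified_counts", "data.frame")
  grid
}

#' Fill expected-count offsets
#'
#' SIR-style offsets: a single global rate (grand total count divided by
#' grand total population) times the stratum population, computed
#' separately for visits and cancer, so that `sum(e) == sum(y)` for each
#' outcome.
#'
#' @param counts A `stratified_counts` data frame (see [stratify]).
#' @return The counts with `e_visits` and `e_cancer` columns filled.
#' @export
expected_counts <- function(counts) {
  tot_pop <- sum(counts$population)
  if (tot_pop <= 0) stop("expected_counts: total population is zero")
  counts$e_visits <- sum(counts$y_visits) / tot_pop * counts$population
  counts$e_cancer <- sum(counts$y_cancer) / tot_pop * counts$population
  counts
}

#' Read raw records CSV (`animal_id,species,year,cancer,tract_id`)
#' @param path CSV file.
#' @return Records data frame.
#' @export
read_records_csv <- function(path) {
  r <- utils::read.csv(path, colClasses = c(animal_id = "character",
                                            tract_id = "character"))
  r$cancer <- r$cancer %in% c(1, "1", "TRUE", TRUE)
  validate_records(r)
}

#' Write stratified counts CSV
#' @param counts Stratified counts.
#' @param path Output CSV.
#' @export
write_counts_csv <- function(counts, path) {
  cols <- intersect(c("tract_id", "species", "period", "y_visits", "y_cancer",
                      "population", "e_visits", "e_cancer"), names(counts))
  utils::write.csv(counts[, cols], path, row.names = FALSE, quote = FALSE)
}

#' Read stratified counts CSV
#' @param path CSV file.
#' @return A `stratified_counts` data frame.
#' @export
read_counts_csv <- function(path) {
  x <- utils::read.csv(path, colClasses = c(tract_id = "character"))
  class(x) <- c("stratified_counts", "data.frame")
  x
}
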