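#' Occurrence record handling
#'
#' Occurrence sets are plain data frames with columns
#' `species, lon, lat, date, source` (decimal-degree WGS84 coordinates,
#' ISO-8601 dates). All distances in this module are great-circle
#' (haversine) distances in kilometres.
#'
#' @param path CSV file with the columns above.
#' @return data frame of occurrence records.
#' @export
read_occurrences <- function(path) {
  occ <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "lon", "lat", "date")
  if (!all(need %in% names(occ)))
    stop("occurrence CSV must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (!"source" %in% names(occ)) occ$source <- NA_character_
  occ
}

.km <- function(lon1, lat1, lon2, lat2)
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2)) / 1000

#' Remove exact duplicate records
#'
#' Collapses rows identical on (species, lon, lat, date) to their first
#' occurrence, preserving input order. Records of the same place on
#' different dates are distinct.
#'
#' @param occ occurrence data frame.
#' @return deduplicated data frame.
#' @export
deduplicate <- function(occ) {
  key <- paste(occ$species, occ$lon, occ$lat, occ$date, sep = "\r")
  occ[!duplicated(key), , drop = FALSE]
}

#' Spatial thinning by minimum pairwise distance
#'
#' Greedy retention in input order: a record is kept iff its great-circle
#' distance to every previously kept record is at least `min_km`. The
#' result is a subset of the input whose pairwise distances are all
#' `>= min_km`; thinning an already-thinned set is the identity. The
#' default radius of 3 km is the conventional correction for spatial
#' autocorrelation in dense citizen-science records. `order = "random"`
#' applies the same rule after a seeded shuffle.
#'
#' @param occ occurrence data frame.
#' @param min_km minimum pairwise distance in km (>= 0).
#' @param order `"input"` (default) or `"random"`.
#' @param seed seed used when `order = "random"`.
#' @return thinned occurrence data frame (original row order).
#' @export
thin_min_distance <- function(occ, min_km = 3, order = c("input", "random"),
                              seed = 1L) {
  stopifnot(min_km >= 0)
  order <- match.arg(order)
  n <- nrow(occ)
  if (n <= 1L || min_km == 0) return(occ)
  ord <- seq_len(n)
  if (order == "random") {
    set.seed(seed)
    ord <- sample.int(n)
  }
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept)) { kept <- i; next }
    d <- .km(occ$lon[kept], occ$lat[kept], occ$lon[i], occ$lat[i])
    if (all(d >= min_km)) kept <- c(kept, i)
  }
  occ[sort(kept), , drop = FALSE]
}

#' Thinning by species-specific foraging flight distance
#'
#' Same greedy minimum-distance semantics as [thin_min_distance()], with
#' the radius taken from per-species movement metadata. Corrects sampling
#' bias at the scale an individual forages over; applied before the
#' home-range buffering step.
#'
#' @param occ occurrence data frame (single species).
#' @param foraging_km radius in km, or a species metadata data frame with
#'   columns `species, foraging_km` from which the radius is looked up.
#' @inheritParams thin_min_distance
#' @export
thin_foraging_distance <- function(occ, foraging_km, order = "input",
                                   seed = 1L) {
  if (is.data.frame(foraging_km)) {
    sp <- unique(occ$species)
    if (length(sp) != 1L)
      stop("foraging-distance thinning expects a single-species set",
           call. = FALSE)
    hit <- match(sp, foraging_km$species)
    if (is.na(hit) || is.na(foraging_km$foraging_km[hit]))
      stop("no foraging distance for species '", sp, "'", call. = FALSE)
    foraging_km <- foraging_km$foraging_km[hit]
  }
  if (foraging_km <= 0)
    stop("foraging distance must be > 0", call. = FALSE)
  thin_min_distance(occ, min_km = foraging_km, order = order, seed = seed)
}

#' Species range as a union of home-range buffers
#'
#' The species range is the union of circles of radius `home_range_km`
#' (the home-range radius: how far an individual is likely to move) around
#' each retained record. Supports point-in-range queries via
#' [range_contains()].
#'
#' @param occ occurrence data frame (retained records).
#' @param home_range_km buffer radius in km (> 0).
#' @return object of class `species_range`.
#' @export
build_range <- function(occ, home_range_km) {
  stopifnot(home_range_km > 0)
  if (nrow(occ) == 0)
    warning("building a range from an empty occurrence set", call. = FALSE)
  structure(list(lon = occ$lon, lat = occ$lat, radius_km = home_range_km,
                 species = if (nrow(occ)) occ$species[1] else NA_character_),
            class = "species_range")
}

#' @rdname build_range
#' @param range a `species_range`.
#' @param lon,lat coordinates of query points.
#' @return `range_contains`: logical vector, `TRUE` where the point lies
#'   within `home_range_km` of any record.
#' @export
range_contains <- function(range, lon, lat) {
  stopifnot(inherits(range, "species_range"))
  n <- length(lon)
  if (!length(range$lon)) return(rep(FALSE, n))
  inside <- rep(FALSE, n)
  for (k in seq_along(range$lon)) {
    todo <- which(!inside)
    if (!length(todo)) break
    d <- .km(lon[todo], lat[todo], range$lon[k], range$lat[k])
    inside[todo[d <= range$radius_km]] <- TRUE
  }
  inside
}

#' @method print species_range
#' @export
print.species_range <- function(x, ...) {
  cat("species_range:", length(x$lon), "buffers of", x$radius_km,
      "km for", x$species, "\n")
  invisible(x)
}

#' Sample background (pseudo-absence) points outside the focal range
#'
#' Draws `n` distinct cell-center locations uniformly at random among the
#' grid's valid cells that lie outside the focal species range. These
#' stand in for absences of the focal species (presence-background
#' design); the conventional default is 10,000 points.
#'
#' @param grid a [predictor_grid()].
#' @param focal_range the focal [build_range()] result.
#' @param n number of points (>= 0).
#' @param seed integer seed.
#' @return data frame `lon, lat, row, col` of sampled cell centers.
#' @export
sample_background <- function(grid, focal_range, n = 10000, seed = 1L) {
  stopifnot(n >= 0)
  cc <- grid_cell_centers(grid)
  ok <- grid$mask[cbind(cc$row, cc$col)] &
    !range_contains(focal_range, cc$lon, cc$lat)
  avail <- which(ok)
  if (!length(avail))
    stop("no valid cells outside the focal range", call. = FALSE)
  if (n > length(avail))
    stop("requested ", n, " background points but only ", length(avail),
         " valid cells lie outside the focal range", call. = FALSE)
  set.seed(seed)
  pick <- sample(avail, n)
  cc[pick, c("lon", "lat", "row", "col")]
}

#' Label sites by interactor range membership
#'
#' Interactor species enter the joint model as presence/absence responses
#' defined by range membership: entry (i, j) is 1 iff site i falls inside
#' interactor j's home-range union.
#'
#' @param sites data frame with `lon`, `lat`.
#' @param ranges named list of `species_range` objects.
#' @return binary matrix, sites x interactors.
#' @export
label_interactors <- function(sites, ranges) {
  out <- vapply(ranges,
                function(r) range_contains(r, sites$lon, sites$lat) + 0L,
                integer(nrow(sites)))
  matrix(out, nrow = nrow(sites), dimnames = list(NULL, names(ranges)))
}

#' Extract predictor values at sites
#'
#' Looks up the grid cell containing each site and returns the sites x
#' predictors design matrix. Sites landing on masked (no-data) or
#' out-of-extent cells are dropped with a message. With
#' `standardize = TRUE` each column is centred and scaled to mean 0, sd 1
#' over the included sites; the constants are stored as attributes
#' `center` / `scale` so map prediction can apply the same transform
#' (and `X * scale + center` round-trips to raw values).
#'
#' @param grid a [predictor_grid()].
#' @param sites data frame with `lon`, `lat`.
#' @param standardize center/scale columns?
#' @return list with `X` (design matrix), `sites` (retained rows),
#'   `dropped` (indices of dropped sites).
#' @export
extract_design <- function(grid, sites, standardize = TRUE) {
  loc <- grid_locate(grid, sites$lon, sites$lat)
  ok <- !is.na(loc$row)
  ok[ok] <- grid$mask[cbind(loc$row[ok], loc$col[ok])]
  if (!any(ok)) stop("all sites fall on masked or out-of-extent cells",
                     call. = FALSE)
  if (any(!ok))
    message(sum(!ok), " site(s) on masked/out-of-extent cells dropped")
  loc <- loc[ok, , drop = FALSE]
  X <- vapply(names(grid$layers),
              function(nm) grid$layers[[nm]][cbind(loc$row, loc$col)],
              numeric(nrow(loc)))
  X <- matrix(X, nrow = nrow(loc),
              dimnames = list(NULL, names(grid$layers)))
  if (standardize) {
    ctr <- colMeans(X)
    scl <- apply(X, 2, stats::sd)
    scl[scl == 0] <- 1
    X <- sweep(sweep(X, 2, ctr), 2, scl, "/")
    attr(X, "center") <- ctr
    attr(X, "scale") <- scl
  }
  list(X = X, sites = sites[ok, , drop = FALSE], dropped = which(!ok))
}

#' Filter records to a date window
#'
#' Keeps records whose date falls in `[start, end]` inclusive. Rows whose
#' date cannot be parsed are rejected with a warning rather than an error
#' (one warning summarising the count).
#'
#' @param occ occurrence data frame.
#' @param start,end window bounds (`Date` or ISO-8601 strings),
#'   `start <= end`.
#' @export
filter_by_date <- function(occ, start, end) {
  start <- as.Date(start); end <- as.Date(end)
  if (start > end) stop("start must be <= end", call. = FALSE)
  d <- suppressWarnings(as.Date(as.character(occ$date)))
  if (any(is.na(d)))
    warning(sum(is.na(d)), " record(s) with unparseable dates dropped",
            call. = FALSE)
  occ[!is.na(d) & d >= start & d <= end, , drop = FALSE]
}

#' Assemble a presence-background site table
#'
#' The head of the modelling pipeline: combines thinned focal presences
#' with background pseudo-absences, labels interactor species by range
#' membership, and extracts the (optionally standardized) design matrix.
#' The focal response column is 1 exactly on presence sites and 0 on
#' background sites.
#'
#' @param grid a [predictor_grid()].
#' @param focal_occ thinned focal occurrence data frame.
#' @param focal_range focal `species_range` (background exclusion zone).
#' @param interactor_ranges named list of interactor `species_range`s
#'   (may be empty).
#' @param n_background number of pseudo-absence points.
#' @param seed integer seed for background sampling.
#' @param standardize standardize the design matrix?
#' @param focal_name focal species column name in `Y`.
#' @return a `site_table` (see [simulate_community()]) with roles
#'   `focal-presence` / `background` and per-stage counts in
#'   `attr(, "counts")`.
#' @export
build_site_table <- function(grid, focal_occ, focal_range,
                             interactor_ranges = list(),
                             n_background = 10000, seed = 1L,
                             standardize = TRUE,
                             focal_name = "focal") {
  bg <- sample_background(grid, focal_range, n_background, seed = seed)
  sites <- data.frame(
    lon = c(focal_occ$lon, bg$lon),
    lat = c(focal_occ$lat, bg$lat),
    role = rep(c("focal-presence", "background"),
               c(nrow(focal_occ), nrow(bg))),
    stringsAsFactors = FALSE)
  des <- extract_design(grid, sites, standardize = standardize)
  sites <- des$sites
  yf <- as.integer(sites$role == "focal-presence")
  Y <- matrix(yf, ncol = 1, dimnames = list(NULL, focal_name))
  if (length(interactor_ranges))
    Y <- cbind(Y, label_interactors(sites, interactor_ranges))
  structure(list(sites = sites, X = des$X, Y = Y,
                 species = colnames(Y)),
            class = "site_table",
            counts = c(presence = nrow(focal_occ),
                       background = nrow(bg),
                       dropped_masked = length(des$dropped)))
}
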