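#' Landscape configuration for synthetic predictor grids
#'
#' Describes a rectangular study extent and the predictor layers to
#' simulate on it. Each predictor is a spatially autocorrelated Gaussian
#' random field; layers flagged `urban` are additionally thresholded to
#' mimic patchy, right-skewed impervious-surface / human-density data.
#'
#' @param extent numeric `c(xmin, xmax, ymin, ymax)` in decimal degrees.
#' @param cell_size cell edge in degrees; the default 0.0004 matches a
#'   ~50 m analysis lattice.
#' @param predictors list of specs, each a list with elements `name`,
#'   `corr_length` (spatial correlation length in cells: the lag at which
#'   field autocorrelation falls to 0.5), `mean`, `sd`, and optional
#'   `urban` flag.
#' @param seed integer seed for field generation.
#' @return object of class `landscape_config`.
#' @export
landscape_config <- function(extent, cell_size = 0.0004, predictors, seed = 1L) {
  stopifnot(length(extent) == 4, extent[2] > extent[1], extent[4] > extent[3])
  if (cell_size <= 0) stop("cell_size must be > 0", call. = FALSE)
  nx <- floor((extent[2] - extent[1]) / cell_size)
  ny <- floor((extent[4] - extent[3]) / cell_size)
  if (nx < 2 || ny < 2)
    stop("degenerate extent: fewer than 2 cells on an axis", call. = FALSE)
  for (p in predictors) {
    if (is.null(p$name) || is.null(p$corr_length) || is.null(p$mean) ||
        is.null(p$sd))
      stop("each predictor spec needs name, corr_length, mean, sd",
           call. = FALSE)
    if (p$corr_length <= 0)
      stop("correlation length must be > 0 (predictor '", p$name, "')",
           call. = FALSE)
    if (p$sd < 0)
      stop("marginal sd must be >= 0 (predictor '", p$name, "')",
           call. = FALSE)
  }
  structure(list(extent = extent, cell_size = cell_size, nx = nx, ny = ny,
                 predictors = predictors, seed = as.integer(seed)),
            class = "landscape_config")
}

# Gaussian-kernel smoothing of white noise on an expanded lattice.
# Kernel sd chosen so the smoothed field's autocorrelation, which is
# Gaussian with scale sqrt(2)*sd, equals 0.5 at lag = corr_length:
# rho(d) = exp(-d^2 / (4 sd^2)),  rho(L) = 0.5  =>  sd = L / (2 sqrt(log 2)).
.gaussian_field <- function(ny, nx, corr_length) {
  s <- corr_length / (2 * sqrt(log(2)))
  half <- max(1L, ceiling(3 * s))
  k <- exp(-((-half):half)^2 / (2 * s^2))
  k <- k / sum(k)
  noise <- matrix(stats::rnorm((ny + 2 * half) * (nx + 2 * half)),
                  ny + 2 * half, nx + 2 * half)
  # band matrices implementing valid-region 1-D convolution on each axis
  conv_band <- function(n, npad) {
    A <- matrix(0, n, npad)
    for (i in seq_len(n)) A[i, i:(i + 2 * half)] <- k
    A
  }
  Ar <- conv_band(ny, ny + 2 * half)
  Ac <- conv_band(nx, nx + 2 * half)
  Ar %*% noise %*% t(Ac)
}

#' Generate a synthetic predictor grid
#'
#' Builds one raster per predictor spec on the common lattice. Fields are
#' smoothed white noise (Gaussian kernel convolution), standardized to the
#' requested marginal mean and sd. `urban` layers are first standardized,
#' then clipped below their 75th percentile and rescaled, producing a
#' right-skewed layer that is exactly zero over most of the extent with
#' contiguous high-value patches.
#'
#' @param config a [landscape_config()].
#' @return a [predictor_grid()] with one layer per spec; deterministic
#'   given the config seed.
#' @export
generate_predictor_grid <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  set.seed(config$seed)
  layers <- list()
  for (p in config$predictors) {
    if (p$sd == 0) {
      layers[[p$name]] <- matrix(p$mean, config$ny, config$nx)
      next
    }
    f <- .gaussian_field(config$ny, config$nx, p$corr_length)
    z <- (f - mean(f)) / stats::sd(f)
    if (isTRUE(p$urban)) {
      q <- stats::quantile(z, 0.75)
      z <- pmax(z - q, 0)
      z <- (z - mean(z)) / stats::sd(z)
    }
    layers[[p$name]] <- z * p$sd + p$mean
  }
  predictor_grid(config$extent[1], config$extent[3], config$cell_size,
                 config$nx, config$ny, layers = layers)
}

#' Ground-truth community parameters
#'
#' Holds the data-generating parameters of a multivariate probit community:
#' per-species intercepts, an environmental coefficient matrix and a
#' residual correlation matrix, plus the movement metadata used by the
#' occurrence-preparation stage and a detection rate for presence-only
#' sampling.
#'
#' @param species character vector of species ids, focal species first.
#' @param alpha numeric vector of intercepts (one per species).
#' @param B species x predictors coefficient matrix with predictor column
#'   names.
#' @param R species x species residual correlation matrix (symmetric, unit
#'   diagonal, positive definite).
#' @param foraging_km,home_range_km per-species distances in km (recycled
#'   if scalar).
#' @param detection_rate probability in (0, 1] that a true presence is
#'   recorded by presence-only sampling.
#' @return object of class `community_truth`.
#' @export
community_truth <- function(species, alpha, B, R,
                            foraging_km = 1, home_range_km = 2,
                            detection_rate = 1) {
  J <- length(species)
  B <- as.matrix(B)
  if (length(alpha) != J || nrow(B) != J)
    stop("alpha and B must have one row/entry per species", call. = FALSE)
  if (!isTRUE(all.equal(dim(R), c(J, J))))
    stop("R must be ", J, "x", J, call. = FALSE)
  if (max(abs(R - t(R))) > 1e-8 || max(abs(diag(R) - 1)) > 1e-8)
    stop("R must be symmetric with unit diagonal", call. = FALSE)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    stop("R is not positive definite", call. = FALSE)
  if (detection_rate <= 0 || detection_rate > 1)
    stop("detection_rate must be in (0, 1]", call. = FALSE)
  structure(list(species = species, alpha = as.numeric(alpha), B = B,
                 R = (R + t(R)) / 2,
                 foraging_km = rep_len(foraging_km, J),
                 home_range_km = rep_len(home_range_km, J),
                 detection_rate = detection_rate),
            class = "community_truth")
}

#' Simulate a multi-species site table from ground truth
#'
#' Samples site locations on the grid's valid cells and draws binary
#' occurrences from the latent-normal model `z = alpha + B x + e`,
#' `e ~ N(0, R)`, `Y = 1[z > 0]`. The true marginal occurrence
#' probabilities `pnorm(alpha + B x)` are retained for testing.
#'
#' Cells are sampled uniformly (with replacement: sites are survey events,
#' so `n_sites` may exceed the number of cells) or, with
#' `effort_bias_layer`, with probability proportional to that layer's value
#' above its minimum — emulating citizen-science effort concentrated near
#' anthropogenic centres.
#'
#' @param grid a [predictor_grid()] whose layer names cover
#'   `colnames(truth$B)`.
#' @param truth a [community_truth()].
#' @param n_sites number of sites (>= 1).
#' @param seed integer seed.
#' @param effort_bias_layer optional layer name for effort-biased sampling.
#' @return object of class `site_table`: list with `sites` (lon/lat/row/
#'   col/role data frame), `X` (sites x predictors, raw scale), `Y`
#'   (sites x species 0/1), `prob` (true marginal probabilities) and
#'   `species`.
#' @export
simulate_community <- function(grid, truth, n_sites, seed = 1L,
                               effort_bias_layer = NULL) {
  stopifnot(inherits(grid, "predictor_grid"),
            inherits(truth, "community_truth"))
  if (n_sites < 1) stop("n_sites must be >= 1", call. = FALSE)
  pred <- colnames(truth$B)
  if (is.null(pred) || !all(pred %in% names(grid$layers)))
    stop("predictor names in truth$B must match grid layers", call. = FALSE)
  Rchol <- chol(truth$R)  # validated PD in community_truth

  set.seed(seed)
  valid <- which(grid$mask)  # column-major cell indices into ny x nx
  w <- NULL
  if (!is.null(effort_bias_layer)) {
    lay <- grid$layers[[effort_bias_layer]]
    if (is.null(lay)) stop("no layer '", effort_bias_layer, "'", call. = FALSE)
    w <- lay[valid] - min(lay[valid]) + 1e-9
  }
  idx <- sample(valid, n_sites, replace = TRUE, prob = w)
  row <- ((idx - 1) %% grid$ny) + 1
  col <- ((idx - 1) %/% grid$ny) + 1
  X <- vapply(pred, function(nm) grid$layers[[nm]][cbind(row, col)],
              numeric(n_sites))
  X <- matrix(X, nrow = n_sites, dimnames = list(NULL, pred))

  J <- length(truth$species)
  mu <- matrix(truth$alpha, n_sites, J, byrow = TRUE) + X %*% t(truth$B)
  E <- matrix(stats::rnorm(n_sites * J), n_sites, J) %*% Rchol
  Z <- mu + E
  Y <- (Z > 0) + 0L
  colnames(Y) <- truth$species
  sites <- data.frame(
    lon = grid$xmin + (col - 0.5) * grid$cell_size,
    lat = grid$ymin + (grid$ny - row + 0.5) * grid$cell_size,
    row = row, col = col, role = "simulated",
    stringsAsFactors = FALSE)
  structure(list(sites = sites, X = X, Y = Y,
                 prob = stats::pnorm(mu), species = truth$species,
                 truth = truth),
            class = "site_table")
}

#' @method print site_table
#' @export
print.site_table <- function(x, ...) {
  cat("site_table:", nrow(x$X), "sites,", ncol(x$X), "predictors,",
      ncol(x$Y), "species\n")
  cat("  species:", paste(colnames(x$Y), collapse = ", "), "\n")
  if ("role" %in% names(x$sites))
    print(table(x$sites$role))
  invisible(x)
}

#' Presence-only subsample of simulated presences
#'
#' Emulates presence-only (citizen-science style) records: each true
#' presence site of a species is recorded independently with probability
#' `truth$detection_rate`; absences are never emitted. Record dates are
#' drawn uniformly from `date_range`.
#'
#' @param sites a `site_table` carrying true `Y`.
#' @param truth the [community_truth()] (supplies the detection rate).
#' @param seed integer seed.
#' @param date_range two `Date`s (or strings) bounding record dates.
#' @return named list of occurrence data frames (one per species) with
#'   columns `species, lon, lat, date, source`.
#' @export
sample_presence_only <- function(sites, truth, seed = 1L,
                                 date_range = c("2016-01-01", "2018-12-31")) {
  stopifnot(inherits(sites, "site_table"))
  rate <- truth$detection_rate
  if (rate <= 0 || rate > 1)
    stop("detection_rate must be in (0, 1]", call. = FALSE)
  d0 <- as.Date(date_range[1]); d1 <- as.Date(date_range[2])
  set.seed(seed)
  out <- list()
  for (sp in truth$species) {
    pres <- which(sites$Y[, sp] == 1)
    keep <- pres[stats::runif(length(pres)) <= rate]
    dates <- if (length(keep))
      d0 + floor(stats::runif(length(keep)) * (as.numeric(d1 - d0) + 1))
    else as.Date(character())
    out[[sp]] <- data.frame(
      species = rep(sp, length(keep)),
      lon = sites$sites$lon[keep], lat = sites$sites$lat[keep],
      date = dates, source = rep("synthetic", length(keep)),
      stringsAsFactors = FALSE)
  }
  out
}
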