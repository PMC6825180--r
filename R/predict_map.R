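#' Probability-of-occurrence surfaces
#'
#' A `probability_surface` is a single-layer [predictor_grid()]-shaped
#' lattice whose unmasked cells hold probabilities in [0, 1]; the mask is
#' propagated from the predictor grid.
#'
#' @name probability_surface
NULL

.as_surface <- function(grid, prob_matrix, provenance) {
  prob_matrix[!grid$mask] <- NA_real_
  structure(
    list(xmin = grid$xmin, ymin = grid$ymin, cell_size = grid$cell_size,
         nx = grid$nx, ny = grid$ny, prob = prob_matrix, mask = grid$mask,
         provenance = provenance),
    class = "probability_surface")
}

#' @method print probability_surface
#' @export
print.probability_surface <- function(x, ...) {
  v <- x$prob[x$mask]
  cat("probability_surface:", x$ny, "x", x$nx, "cells (",
      x$provenance, ")\n")
  cat(sprintf("  range %.3f-%.3f, mean %.3f, %d masked cells\n",
              min(v), max(v), mean(v), sum(!x$mask)))
  invisible(x)
}

# standardize grid layers with the model's training constants and return
# the cells x predictors matrix for unmasked cells
.grid_design <- function(grid, predictors, std) {
  missing <- setdiff(predictors, names(grid$layers))
  if (length(missing))
    stop("grid is missing predictor layer(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  idx <- which(grid$mask)
  X <- vapply(predictors, function(nm) grid$layers[[nm]][idx],
              numeric(length(idx)))
  X <- matrix(X, nrow = length(idx), dimnames = list(NULL, predictors))
  if (!is.null(std$center)) {
    X <- sweep(sweep(X, 2, std$center[predictors]), 2,
               std$scale[predictors], "/")
  }
  list(X = X, idx = idx)
}

#' Map a fitted JSDM to a probability surface
#'
#' Evaluates the grid-wise probit prediction
#' `Mu = pnorm(intercept + B_1 P_1 + ... + B_p P_p)` for one species on
#' every unmasked cell. With `mode = "draws"` (the default) `Mu` is
#' computed per retained posterior draw and averaged — a surface of
#' average probabilities; `mode = "plugin"` plugs in the posterior means.
#' The grid layers are standardized with the constants stored at fitting
#' time; if the model was fitted on an unstandardized design the raw cell
#' values are used.
#'
#' @param post a fitted [jsdm()].
#' @param grid a [predictor_grid()] carrying the model's predictor
#'   layers (raw scale).
#' @param species species name or index.
#' @param mode `"draws"` or `"plugin"`.
#' @return a `probability_surface`.
#' @export
predict_jsdm_map <- function(post, grid, species = 1,
                             mode = c("draws", "plugin")) {
  mode <- match.arg(mode)
  gd <- .grid_design(grid, post$predictors, post$standardization)
  p <- predict(post, newdata = gd$X, species = species, mode = mode)
  m <- matrix(NA_real_, grid$ny, grid$nx)
  m[gd$idx] <- p
  .as_surface(grid, m, paste0("jsdm:", mode))
}

#' Map a replicated SDM to a probability surface
#'
#' Per-cell prediction averaged across the replicate fits.
#'
#' @param model an [fit_replicates()] ensemble (or a single `sdm_fit`,
#'   in which case `spec` must be given).
#' @param grid a [predictor_grid()] with the model's predictor layers.
#' @param std standardization constants (`list(center, scale)`) used at
#'   fitting time, or `NULL` if the design was raw.
#' @param spec [feature_spec()] when `model` is a single `sdm_fit`.
#' @return a `probability_surface`.
#' @export
predict_sdm_map <- function(model, grid, std = NULL, spec = NULL) {
  if (inherits(model, "sdm_fit")) {
    stopifnot(!is.null(spec))
    model <- structure(list(fits = list(model), spec = spec,
                            auc = NA_real_, n_replicates = 1L),
                       class = "sdm_replicates")
  }
  predictors <- names(model$fits[[1]]$knots)
  gd <- .grid_design(grid, predictors, std)
  p <- predict(model, gd$X)
  m <- matrix(NA_real_, grid$ny, grid$nx)
  m[gd$idx] <- p
  .as_surface(grid, m, "sdm:replicate-mean")
}

#' Threshold a probability surface into a binary range map
#'
#' A cell is predicted present iff its probability is greater than or
#' equal to the threshold (ties count as presence, fixed for
#' reproducible sensitivity). Masked cells stay `NA`.
#'
#' @param surface a `probability_surface`.
#' @param threshold probability in [0, 1].
#' @return integer matrix (ny x nx) of 0/1 with `NA` on masked cells.
#' @export
binarize <- function(surface, threshold) {
  stopifnot(inherits(surface, "probability_surface"),
            threshold >= 0, threshold <= 1)
  out <- (surface$prob >= threshold) + 0L
  out[!surface$mask] <- NA_integer_
  out
}

#' Write / read a probability surface
#'
#' `write_surface` emits both an ESRI ASCII grid and (optionally) a CSV
#' of `lon, lat, probability` for unmasked cells; `read_surface` reads
#' the ASCII grid back bit-exactly.
#'
#' @param surface a `probability_surface`.
#' @param path output `.asc` path.
#' @param csv optional CSV path.
#' @export
write_surface <- function(surface, path, csv = NULL) {
  g <- predictor_grid(surface$xmin, surface$ymin, surface$cell_size,
                      surface$nx, surface$ny,
                      layers = list(prob = surface$prob),
                      mask = surface$mask)
  write_ascii_grid(g, "prob", path)
  if (!is.null(csv)) {
    cc <- grid_cell_centers(g)
    ok <- surface$mask[cbind(cc$row, cc$col)]
    utils::write.csv(
      data.frame(lon = cc$lon[ok], lat = cc$lat[ok],
                 probability = surface$prob[cbind(cc$row, cc$col)][ok]),
      csv, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_surface
#' @export
read_surface <- function(path) {
  g <- read_ascii_grids(c(prob = path))
  .as_surface(g, g$layers$prob, provenance = paste0("file:", path))
}
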