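#' Feature specification for the maximum-entropy-style SDM
#'
#' Feature classes follow the MaxEnt convention: L = linear, Q =
#' quadratic, H = hinge, P = pairwise product, T = threshold (step)
#' indicators. Hinge and threshold knots are placed at equally spaced
#' quantiles of each predictor. The regularization multiplier scales the
#' L1 penalty of the fit.
#'
#' @param classes character vector, subset of `c("L","Q","H","P","T")`.
#' @param knots hinge/threshold knots per predictor.
#' @param multiplier positive regularization multiplier.
#' @return object of class `feature_spec`.
#' @export
feature_spec <- function(classes = c("L", "Q", "H"), knots = 10,
                         multiplier = 1) {
  if (length(classes) == 1L && nchar(classes) > 1L)
    classes <- strsplit(classes, "")[[1]]  # compact "LQH" form
  classes <- unique(toupper(classes))
  if (!length(classes) || !all(classes %in% c("L", "Q", "H", "P", "T")))
    stop("classes must be a non-empty subset of L, Q, H, P, T",
         call. = FALSE)
  if (multiplier <= 0) stop("multiplier must be > 0", call. = FALSE)
  structure(list(classes = classes, knots = as.integer(knots),
                 multiplier = multiplier),
            class = "feature_spec")
}

#' @method print feature_spec
#' @export
print.feature_spec <- function(x, ...) {
  cat("feature_spec:", paste(sort(x$classes), collapse = ""),
      "| knots", x$knots, "| multiplier", x$multiplier, "\n")
  invisible(x)
}

#' Expand a design matrix into MaxEnt-style features
#'
#' Deterministic expansion of a (standardized) design matrix. Column
#' names encode provenance, e.g. `Q:bio11` or `H:imp:3`. Hinge features
#' are `max(0, x - k)`; threshold features are `1[x >= k]`; knots are
#' interior quantiles of the training column (stored as an attribute so
#' test data expand identically). Constant predictors keep their L
#' column but have their Q/H/P/T features dropped with a warning.
#'
#' @param X sites x predictors matrix (standardized).
#' @param spec a [feature_spec()].
#' @param knots_list optional precomputed knots (from a previous
#'   expansion) so held-out data use training knots.
#' @return feature matrix with attribute `knots`.
#' @export
build_features <- function(X, spec, knots_list = NULL) {
  X <- as.matrix(X)
  pn <- colnames(X)
  if (is.null(pn)) pn <- paste0("x", seq_len(ncol(X)))
  const <- apply(X, 2, function(v) max(v) - min(v) == 0)
  if (any(const) && length(setdiff(spec$classes, "L")))
    warning("constant predictor(s) ", paste(pn[const], collapse = ", "),
            ": Q/H/P/T features dropped", call. = FALSE)
  if (is.null(knots_list)) {
    qs <- seq(0, 1, length.out = spec$knots + 2L)[-c(1L, spec$knots + 2L)]
    knots_list <- lapply(seq_len(ncol(X)), function(j)
      unique(unname(stats::quantile(X[, j], qs))))
    names(knots_list) <- pn
  }
  cols <- list()
  if ("L" %in% spec$classes)
    for (j in seq_len(ncol(X))) cols[[paste0("L:", pn[j])]] <- X[, j]
  if ("Q" %in% spec$classes)
    for (j in which(!const)) cols[[paste0("Q:", pn[j])]] <- X[, j]^2
  if ("H" %in% spec$classes)
    for (j in which(!const))
      for (ki in seq_along(knots_list[[pn[j]]]))
        cols[[paste0("H:", pn[j], ":", ki)]] <-
          pmax(0, X[, j] - knots_list[[pn[j]]][ki])
  if ("P" %in% spec$classes && ncol(X) >= 2) {
    idx <- which(!const)
    if (length(idx) >= 2)
      for (a in idx[-length(idx)]) for (b in idx[idx > a])
        cols[[paste0("P:", pn[a], ":", pn[b])]] <- X[, a] * X[, b]
  }
  if ("T" %in% spec$classes)
    for (j in which(!const))
      for (ki in seq_along(knots_list[[pn[j]]]))
        cols[[paste0("T:", pn[j], ":", ki)]] <-
          (X[, j] >= knots_list[[pn[j]]][ki]) + 0
  F <- do.call(cbind, cols)
  attr(F, "knots") <- knots_list
  F
}

# multiplier -> glmnet lambda; lambda_base fixes the penalty at
# multiplier 1 (glmnet's objective is mean log-likelihood + lambda*|w|_1)
.sdm_lambda_base <- 0.01

#' Fit the penalized presence-background model
#'
#' Maximizes the Bernoulli log-likelihood of presence (1) vs background
#' (0) minus an L1 penalty proportional to the regularization multiplier
#' — the penalized-likelihood equivalence of maximum-entropy SDM
#' fitting. The optimization is glmnet's coordinate descent, which is
#' deterministic given the data.
#'
#' @param features feature matrix from [build_features()].
#' @param y 0/1 vector (both classes present).
#' @param multiplier regularization multiplier (> 0, or 0 for the
#'   unpenalized fit).
#' @return object of class `sdm_fit` with `weights` (named, including
#'   `(Intercept)`), the knots, and a `predict` method returning
#'   probabilities.
#' @export
fit_penalized <- function(features, y, multiplier = 1) {
  y <- as.numeric(y)
  if (length(unique(y)) < 2)
    stop("both presence and background classes are required",
         call. = FALSE)
  if (multiplier < 0) stop("multiplier must be >= 0", call. = FALSE)
  lam <- multiplier * .sdm_lambda_base
  path <- sort(unique(c(lam, pmax(lam, 1e-4) * c(100, 10, 1))),
               decreasing = TRUE)
  Fm <- as.matrix(features)
  one_col <- ncol(Fm) == 1L  # glmnet needs >= 2 columns; pad with zeros
  if (one_col) Fm <- cbind(Fm, `..pad` = 0)
  fit <- glmnet::glmnet(Fm, y, family = "binomial", lambda = path,
                        standardize = FALSE)
  w <- stats::coef(fit, s = lam, exact = FALSE)
  w <- stats::setNames(as.numeric(w), rownames(w))
  if (one_col) w <- w[names(w) != "..pad"]
  if (any(!is.finite(w))) stop("non-finite weights", call. = FALSE)
  structure(list(weights = w, knots = attr(features, "knots"),
                 multiplier = multiplier,
                 feature_names = colnames(features)),
            class = "sdm_fit")
}

#' @method print sdm_fit
#' @export
print.sdm_fit <- function(x, ...) {
  nz <- sum(x$weights[-1] != 0)
  cat("sdm_fit:", length(x$weights) - 1, "features,", nz, "nonzero,",
      "multiplier", x$multiplier, "\n")
  invisible(x)
}

#' @method coef sdm_fit
#' @export
coef.sdm_fit <- function(object, ...) object$weights

#' @param object an `sdm_fit`.
#' @param newfeatures feature matrix with the training columns.
#' @param ... unused.
#' @rdname fit_penalized
#' @method predict sdm_fit
#' @export
predict.sdm_fit <- function(object, newfeatures, ...) {
  F <- as.matrix(newfeatures)[, object$feature_names, drop = FALSE]
  stats::plogis(drop(F %*% object$weights[-1]) + object$weights[1])
}

# Bernoulli deviance of probabilities p against y
.deviance <- function(p, y) {
  eps <- 1e-12
  -2 * sum(y * log(pmax(p, eps)) + (1 - y) * log(pmax(1 - p, eps)))
}

#' Tune regularization multiplier and feature classes
#'
#' Grid search over regularization multipliers and feature-class
#' combinations, scored by k-fold cross-validated predictive deviance.
#' The default grid is the conventional multipliers
#' (0.25, 0.5, 1, 1.5, 2, 4, 6) by combinations
#' (L, LQ, H, LQH, LQHP, LQHPT).
#'
#' @param X standardized design matrix.
#' @param y 0/1 response.
#' @param multipliers numeric vector of multipliers.
#' @param class_combos list of class vectors (or strings like "LQH").
#' @param folds number of CV folds (>= 2).
#' @param seed fold-assignment seed.
#' @param knots hinge/threshold knots per predictor.
#' @return the winning [feature_spec()]; the full grid with mean CV
#'   deviance is attached as `attr(, "grid")`.
#' @export
tune <- function(X, y, multipliers = c(0.25, 0.5, 1, 1.5, 2, 4, 6),
                 class_combos = list("L", "LQ", "H", "LQH", "LQHP",
                                     "LQHPT"),
                 folds = 5, seed = 1L, knots = 10) {
  if (!length(multipliers) || !length(class_combos))
    stop("empty tuning grid", call. = FALSE)
  if (folds < 2) stop("folds must be >= 2", call. = FALSE)
  combos <- lapply(class_combos, function(cc)
    if (length(cc) == 1L && nchar(cc) > 1L)
      strsplit(cc, "")[[1]] else cc)
  set.seed(seed)
  fold_id <- sample(rep_len(seq_len(folds), length(y)))
  grid <- expand.grid(combo = seq_along(combos),
                      multiplier = multipliers)
  grid$cv_deviance <- NA_real_
  for (g in seq_len(nrow(grid))) {
    spec <- feature_spec(combos[[grid$combo[g]]], knots = knots,
                         multiplier = grid$multiplier[g])
    dev <- 0
    ok <- TRUE
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 2) {
        ok <- FALSE; break
      }
      Ftr <- build_features(X[tr, , drop = FALSE], spec)
      fit <- fit_penalized(Ftr, y[tr], spec$multiplier)
      Fte <- build_features(X[!tr, , drop = FALSE], spec,
                            knots_list = attr(Ftr, "knots"))
      dev <- dev + .deviance(predict(fit, Fte), y[!tr])
    }
    grid$cv_deviance[g] <- if (ok) dev / length(y) else NA_real_
  }
  grid$classes <- vapply(combos[grid$combo],
                         function(cc) paste(sort(cc), collapse = ""), "")
  best <- which.min(grid$cv_deviance)
  out <- feature_spec(combos[[grid$combo[best]]], knots = knots,
                      multiplier = grid$multiplier[best])
  attr(out, "grid") <- grid[, c("classes", "multiplier", "cv_deviance")]
  out
}

#' Per-predictor percent contribution
#'
#' Permutation importance: the drop in training gain (log-likelihood
#' above the null model) when all features derived from one predictor
#' have that predictor's column permuted, averaged over permutations,
#' clipped at zero and normalized to sum to 100.
#'
#' @param model an `sdm_fit`.
#' @param X the raw (standardized) design matrix used for fitting.
#' @param y 0/1 response.
#' @param spec the [feature_spec()] used for fitting.
#' @param permutations number of permutations averaged per predictor.
#' @param seed permutation seed.
#' @return named vector of percentages summing to 100.
#' @export
percent_contribution <- function(model, X, y, spec, permutations = 5,
                                 seed = 1L) {
  X <- as.matrix(X)
  pn <- colnames(X)
  if (is.null(pn)) pn <- paste0("x", seq_len(ncol(X)))
  colnames(X) <- pn
  Ffull <- build_features(X, spec, knots_list = model$knots)
  ll_full <- -0.5 * .deviance(predict(model, Ffull), y)
  set.seed(seed)
  drop_gain <- stats::setNames(numeric(ncol(X)), pn)
  for (j in seq_len(ncol(X))) {
    acc <- 0
    for (r in seq_len(permutations)) {
      Xp <- X
      Xp[, j] <- X[sample.int(nrow(X)), j]
      Fp <- build_features(Xp, spec, knots_list = model$knots)
      acc <- acc + (ll_full + 0.5 * .deviance(predict(model, Fp), y))
    }
    drop_gain[j] <- max(acc / permutations, 0)
  }
  if (sum(drop_gain) == 0) return(drop_gain)  # no predictor matters
  100 * drop_gain / sum(drop_gain)
}

#' Stepwise backward elimination of predictors
#'
#' Iteratively refits the model, dropping (a) the lower-contribution
#' member of any predictor pair correlated at `|r| >=` `corr_threshold`,
#' then (b) the weakest predictor whose percent contribution is at or
#' below `contrib_threshold`, until all retained predictors clear both
#' rules. Defaults follow the conventional |r| < 0.75 and > 1%
#' contribution screen.
#'
#' @param X standardized design matrix with named columns.
#' @param y 0/1 response.
#' @param spec [feature_spec()] used for the working fits.
#' @param contrib_threshold percent-contribution floor (exclusive).
#' @param corr_threshold absolute Pearson correlation ceiling.
#' @param permutations,seed passed to [percent_contribution()].
#' @return character vector of retained predictor names; the elimination
#'   path is attached as `attr(, "path")`.
#' @export
backward_eliminate <- function(X, y, spec = feature_spec("L"),
                               contrib_threshold = 1,
                               corr_threshold = 0.75,
                               permutations = 3, seed = 1L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  keep <- colnames(X)
  path <- character(0)
  repeat {
    if (!length(keep))
      stop("all predictors eliminated; relax the thresholds",
           call. = FALSE)
    Xk <- X[, keep, drop = FALSE]
    F <- build_features(Xk, spec)
    fit <- fit_penalized(F, y, spec$multiplier)
    contrib <- percent_contribution(fit, Xk, y, spec,
                                    permutations = permutations,
                                    seed = seed)
    # correlation rule first: among |r| >= threshold pairs drop the
    # weaker member
    dropped <- NULL
    if (length(keep) > 1) {
      C <- abs(stats::cor(Xk))
      diag(C) <- 0
      hit <- which(C >= corr_threshold, arr.ind = TRUE)
      if (nrow(hit)) {
        pair <- hit[1, ]
        dropped <- keep[pair][which.min(contrib[pair])]
        path <- c(path, paste0(dropped, " (|r| >= ", corr_threshold,
                               " with ", keep[pair][keep[pair] != dropped],
                               ")"))
      }
    }
    if (is.null(dropped)) {
      low <- contrib[contrib <= contrib_threshold]
      if (!length(low)) break
      dropped <- names(low)[which.min(low)]
      path <- c(path, paste0(dropped, " (contribution ",
                             round(min(low), 2), "% <= ",
                             contrib_threshold, "%)"))
    }
    keep <- setdiff(keep, dropped)
    if (!length(keep))
      stop("all predictors eliminated; relax the thresholds",
           call. = FALSE)
  }
  attr(keep, "path") <- path
  keep
}

#' Replicated SDM fit with averaged prediction
#'
#' Fits `n_replicates` models on seeded random subsamples
#' (cross-validation-style resampling: each replicate trains on a random
#' `train_fraction` of the sites and is scored on the rest). The
#' ensemble prediction is the arithmetic mean of per-replicate
#' predictions; per-replicate held-out AUCs are retained for
#' mean +/- sd reporting. The conventional replicate count is 100.
#'
#' @param X standardized design matrix.
#' @param y 0/1 response.
#' @param spec the [feature_spec()] to fit.
#' @param n_replicates number of replicates (>= 1).
#' @param seed resampling seed.
#' @param train_fraction fraction of sites per training subsample
#'   (ignored when `n_replicates = 1`, which fits on all data).
#' @return object of class `sdm_replicates` with the fitted list,
#'   per-replicate AUC, and a `predict` method averaging over
#'   replicates.
#' @export
fit_replicates <- function(X, y, spec, n_replicates = 100, seed = 1L,
                           train_fraction = 0.8) {
  stopifnot(n_replicates >= 1)
  X <- as.matrix(X)
  set.seed(seed)
  fits <- vector("list", n_replicates)
  aucs <- rep(NA_real_, n_replicates)
  for (r in seq_len(n_replicates)) {
    if (n_replicates == 1L) {
      tr <- seq_len(nrow(X))
    } else {
      repeat {
        tr <- sample.int(nrow(X), max(2, round(train_fraction * nrow(X))))
        if (length(unique(y[tr])) == 2) break
      }
    }
    Ftr <- build_features(X[tr, , drop = FALSE], spec)
    fits[[r]] <- fit_penalized(Ftr, y[tr], spec$multiplier)
    te <- setdiff(seq_len(nrow(X)), tr)
    if (length(te) && length(unique(y[te])) == 2) {
      Fte <- build_features(X[te, , drop = FALSE], spec,
                            knots_list = attr(Ftr, "knots"))
      aucs[r] <- auc(predict(fits[[r]], Fte), y[te])
    }
  }
  structure(list(fits = fits, spec = spec, auc = aucs,
                 n_replicates = n_replicates),
            class = "sdm_replicates")
}

#' @method print sdm_replicates
#' @export
print.sdm_replicates <- function(x, ...) {
  cat("sdm_replicates:", x$n_replicates, "replicate fits (",
      paste(sort(x$spec$classes), collapse = ""), ", multiplier",
      x$spec$multiplier, ")\n")
  if (any(!is.na(x$auc)))
    cat(sprintf("  held-out AUC %.3f +/- %.3f\n",
                mean(x$auc, na.rm = TRUE), stats::sd(x$auc, na.rm = TRUE)))
  invisible(x)
}

#' @param object an `sdm_replicates`.
#' @param newdata sites x predictors matrix (raw design scale used in
#'   fitting).
#' @param ... unused.
#' @rdname fit_replicates
#' @method predict sdm_replicates
#' @export
predict.sdm_replicates <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  acc <- numeric(nrow(newdata))
  for (f in object$fits) {
    F <- build_features(newdata, object$spec, knots_list = f$knots)
    acc <- acc + predict(f, F)
  }
  acc / length(object$fits)
}
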