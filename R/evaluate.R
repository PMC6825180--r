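#' Area under the ROC curve
#'
#' The probability that a randomly chosen presence site is scored above a
#' randomly chosen background site, with ties counted half — the
#' rank-statistic (Mann-Whitney) formulation.
#'
#' @param scores numeric per-site scores/probabilities.
#' @param labels 0/1 vector (both classes required).
#' @return AUC in [0, 1].
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("AUC undefined: both classes must be present", call. = FALSE)
  r <- rank(scores)  # average ranks handle ties as half-wins
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Maximum sensitivity-plus-specificity threshold
#'
#' Chooses, among the observed score values, the threshold maximizing
#' sensitivity + specificity under the tie-at-threshold-counts-as-
#' presence rule (`score >= t` predicts presence). Ties in the objective
#' are broken by the lowest qualifying threshold.
#'
#' @inheritParams auc
#' @return the selected threshold, with `sensitivity` and `specificity`
#'   at that threshold as attributes.
#' @export
max_sens_spec_threshold <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("threshold undefined: both classes must be present",
         call. = FALSE)
  cand <- sort(unique(scores))
  # cumulative counts of scores >= each candidate
  pos_ge <- n1 - cumsum(c(0, utils::head(tabulate(
    match(scores[labels == 1], cand), nbins = length(cand)), -1)))
  neg_ge <- n0 - cumsum(c(0, utils::head(tabulate(
    match(scores[labels == 0], cand), nbins = length(cand)), -1)))
  # integer-count objective: exact, so mathematical ties are real ties
  # (fp sums of sens + spec can differ in the last ulp and flip the
  # argmax between tied thresholds)
  obj <- pos_ge * n0 + (n0 - neg_ge) * n1
  best <- which(obj == max(obj))[1]  # lowest qualifying threshold
  structure(cand[best], sensitivity = pos_ge[best] / n1,
            specificity = (n0 - neg_ge[best]) / n0)
}

#' Sensitivity at an evaluation cell size
#'
#' Aggregates a thresholded surface to a coarser lattice and scores the
#' percentage of occurrence records falling in predicted-present coarse
#' cells: `100 * true positives / total occurrences`. A coarse cell is
#' predicted present iff any constituent fine cell is predicted present
#' (`rule = "any"`, the default, under which sensitivity is non-
#' decreasing in cell size); `rule = "mean"` instead compares the mean
#' probability of the coarse cell's unmasked fine cells to the
#' threshold. Conventional evaluation sizes are 0.004, 0.01, 0.02, 0.03
#' and 0.05 degrees.
#'
#' @param surface a `probability_surface`.
#' @param occ occurrence data frame with `lon`, `lat` inside the surface
#'   extent.
#' @param threshold probability threshold.
#' @param cell_size evaluation cell size in degrees (>= the surface's
#'   native resolution).
#' @param rule `"any"` or `"mean"`.
#' @return sensitivity as a percentage in [0, 100].
#' @export
sensitivity_at_resolution <- function(surface, occ, threshold, cell_size,
                                      rule = c("any", "mean")) {
  rule <- match.arg(rule)
  if (cell_size < surface$cell_size - 1e-12)
    stop("evaluation cell size is below the native resolution",
         call. = FALSE)
  if (!nrow(occ)) stop("no occurrence records", call. = FALSE)
  cc_row <- rep(seq_len(surface$ny), surface$nx)
  cc_col <- rep(seq_len(surface$nx), each = surface$ny)
  lon <- surface$xmin + (cc_col - 0.5) * surface$cell_size
  lat <- surface$ymin + (surface$ny - cc_row + 0.5) * surface$cell_size
  # coarse indices relative to the grid origin
  cidx <- function(x, y) {
    paste(floor((x - surface$xmin) / cell_size),
          floor((y - surface$ymin) / cell_size))
  }
  fine_coarse <- cidx(lon, lat)
  pv <- surface$prob[cbind(cc_row, cc_col)]
  ok <- !is.na(pv)
  present <- if (rule == "any") {
    tapply(pv[ok] >= threshold, fine_coarse[ok], any)
  } else {
    tapply(pv[ok], fine_coarse[ok], mean) >= threshold
  }
  occ_coarse <- cidx(occ$lon, occ$lat)
  hit <- present[occ_coarse]
  hit[is.na(hit)] <- FALSE
  100 * mean(hit)
}

#' Evaluation report for one model
#'
#' Bundles AUC, the max-sensitivity-plus-specificity threshold, and
#' (optionally) multi-resolution sensitivities into an `eval_report`
#' comparable across models. A fingerprint of the evaluation labels
#' guards against comparing reports computed on different data.
#'
#' @param model_id character label.
#' @param scores,labels per-site scores and 0/1 labels.
#' @param surface optional `probability_surface` for resolution-based
#'   sensitivity.
#' @param occ optional occurrence data frame (with `surface`).
#' @param cell_sizes evaluation cell sizes in degrees.
#' @param auc_sd optional AUC sd (replicate models).
#' @return object of class `eval_report`.
#' @export
eval_report <- function(model_id, scores, labels, surface = NULL,
                        occ = NULL,
                        cell_sizes = c(0.004, 0.01, 0.02, 0.03, 0.05),
                        auc_sd = NA_real_) {
  a <- auc(scores, labels)
  thr <- max_sens_spec_threshold(scores, labels)
  sens <- NULL
  if (!is.null(surface) && !is.null(occ)) {
    cell_sizes <- cell_sizes[cell_sizes >= surface$cell_size - 1e-12]
    sens <- vapply(cell_sizes, function(cs)
      sensitivity_at_resolution(surface, occ, as.numeric(thr), cs),
      numeric(1))
    names(sens) <- format(cell_sizes)
  }
  structure(list(model_id = model_id, auc = a, auc_sd = auc_sd,
                 threshold = as.numeric(thr),
                 sensitivity = sens,
                 fingerprint = c(n = length(labels),
                                 n_pos = sum(labels == 1),
                                 sum_scores_digest =
                                   signif(sum(as.numeric(labels)), 12))),
            class = "eval_report")
}

#' @method print eval_report
#' @export
print.eval_report <- function(x, ...) {
  cat("eval_report [", x$model_id, "]\n", sep = "")
  cat(sprintf("  AUC %.3f%s | threshold %.3f\n", x$auc,
              if (!is.na(x$auc_sd)) sprintf(" +/- %.3f", x$auc_sd) else "",
              x$threshold))
  if (!is.null(x$sensitivity)) {
    cat("  sensitivity (%) by cell size:\n")
    print(round(x$sensitivity, 2))
  }
  invisible(x)
}

#' Cross-validated model evaluation
#'
#' Repeated seeded random train/validation splits (default 5 splits,
#' 60% training / 40% validation). Each split refits the requested model
#' kind on the training sites and scores held-out AUC and sensitivity
#' (at the training-data max-sens-spec threshold). Splits that lose a
#' response class entirely are redrawn up to a retry cap.
#'
#' @param sites a `site_table`.
#' @param model_kind `"sdm"` or `"jsdm"`.
#' @param folds number of random splits.
#' @param train_fraction fraction of sites used for training.
#' @param seed split seed.
#' @param spec [feature_spec()] for the SDM fits.
#' @param jsdm_args list of arguments passed on to [jsdm()] (run
#'   lengths etc.).
#' @param focal focal species column of `Y` evaluated (default first).
#' @return list with per-fold `auc` and `sensitivity` vectors, their
#'   means, and the fold assignments.
#' @export
cross_validate <- function(sites, model_kind = c("sdm", "jsdm"),
                           folds = 5, train_fraction = 0.6, seed = 1L,
                           spec = feature_spec("LQH", multiplier = 1.5),
                           jsdm_args = list(), focal = 1L) {
  model_kind <- match.arg(model_kind)
  stopifnot(inherits(sites, "site_table"), folds >= 1,
            train_fraction > 0, train_fraction < 1)
  n <- nrow(sites$X)
  yf <- sites$Y[, focal]
  set.seed(seed)
  auc_f <- sens_f <- rep(NA_real_, folds)
  assignments <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- NULL
    for (try in 1:20) {
      cand <- sample.int(n, round(train_fraction * n))
      y_tr <- sites$Y[cand, , drop = FALSE]
      y_te <- sites$Y[-cand, , drop = FALSE]
      need <- if (model_kind == "jsdm") seq_len(ncol(sites$Y)) else focal
      ok <- all(colSums(y_tr[, need, drop = FALSE]) > 0) &&
        all(colSums(y_tr[, need, drop = FALSE]) < nrow(y_tr)) &&
        length(unique(y_te[, focal])) == 2
      if (ok) { tr <- cand; break }
    }
    if (is.null(tr))
      stop("could not draw a split with both classes after 20 tries",
           call. = FALSE)
    assignments[[f]] <- tr
    Xtr <- sites$X[tr, , drop = FALSE]
    Xte <- sites$X[-tr, , drop = FALSE]
    if (model_kind == "sdm") {
      Ftr <- build_features(Xtr, spec)
      fit <- fit_penalized(Ftr, yf[tr], spec$multiplier)
      Fte <- build_features(Xte, spec, knots_list = attr(Ftr, "knots"))
      sc_tr <- predict(fit, Ftr)
      sc_te <- predict(fit, Fte)
    } else {
      args <- c(list(x = Xtr, y = sites$Y[tr, , drop = FALSE],
                     seed = seed + 17L * f), jsdm_args)
      fit <- do.call(jsdm, args)
      sc_tr <- predict(fit, species = focal)
      sc_te <- predict(fit, newdata = Xte, species = focal)
    }
    thr <- as.numeric(max_sens_spec_threshold(sc_tr, yf[tr]))
    auc_f[f] <- auc(sc_te, yf[-tr])
    pos <- yf[-tr] == 1
    sens_f[f] <- 100 * mean(sc_te[pos] >= thr)
  }
  list(model_kind = model_kind, auc = auc_f, sensitivity = sens_f,
       mean_auc = mean(auc_f), mean_sensitivity = mean(sens_f),
       folds = folds, train_fraction = train_fraction,
       assignments = assignments)
}

#' Side-by-side model comparison table
#'
#' Aligns two or more [eval_report()]s computed on the same evaluation
#' data into the classic comparison layout: AUC, selected threshold and
#' sensitivity per evaluation cell size, one column block per model. No
#' winner is declared.
#'
#' @param reports list of `eval_report`s.
#' @return data frame with a `metric` column and one column per model.
#' @export
compare_models <- function(reports) {
  stopifnot(length(reports) >= 2)
  fp <- lapply(reports, function(r) r$fingerprint)
  for (k in 2:length(fp))
    if (!isTRUE(all.equal(fp[[1]], fp[[k]])))
      stop("reports were computed on different evaluation data",
           call. = FALSE)
  cs <- names(reports[[1]]$sensitivity)
  metrics <- c("AUC", "AUC_sd", "Threshold",
               if (length(cs)) paste0("Sensitivity_", cs))
  out <- data.frame(metric = metrics)
  for (r in reports) {
    vals <- c(r$auc, r$auc_sd, r$threshold,
              if (length(cs)) as.numeric(r$sensitivity[cs]))
    out[[r$model_id]] <- vals
  }
  out
}
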