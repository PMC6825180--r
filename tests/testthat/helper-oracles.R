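# Independent oracles and small fixture builders used across the suite.
# Oracles are deliberately naive (brute force / direct iteration) and share
# no code with the package implementations they check.

# AUC by exhaustive pair counting: P(score_pos > score_neg) + 0.5 ties
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# max sens+spec threshold by exhaustive scan over observed values,
# >= convention, lowest qualifying threshold on objective ties
brute_threshold <- function(scores, labels) {
  cand <- sort(unique(scores))
  best_t <- NA; best_obj <- -Inf
  for (t in cand) {
    sens <- mean(scores[labels == 1] >= t)
    spec <- mean(scores[labels == 0] < t)
    if (sens + spec > best_obj + 1e-12) {
      best_obj <- sens + spec; best_t <- t
    }
  }
  best_t
}

# unpenalized logistic regression by direct Newton-Raphson iteration
newton_logistic <- function(X, y, maxit = 100, tol = 1e-10) {
  Xi <- cbind(1, X)
  b <- rep(0, ncol(Xi))
  for (i in seq_len(maxit)) {
    p <- plogis(drop(Xi %*% b))
    W <- p * (1 - p)
    step <- solve(crossprod(Xi, Xi * W), crossprod(Xi, y - p))
    b <- b + step
    if (max(abs(step)) < tol) break
  }
  drop(b)
}

# independent univariate Bayesian probit Gibbs sampler (Albert-Chib
# augmentation via inverse-CDF truncated normals), prior N(0, prior_var)
probit_gibbs_oracle <- function(X, y, iter, burnin, thin,
                                prior_var = 100, seed = 1) {
  set.seed(seed)
  Xi <- cbind(1, X); q <- ncol(Xi); n <- nrow(Xi)
  P <- crossprod(Xi) + diag(1 / prior_var, q)
  Pc <- chol(P)
  beta <- rep(0, q)
  keep <- matrix(NA_real_, (iter - burnin) %/% thin, q)
  k <- 0
  for (t in seq_len(iter)) {
    mu <- drop(Xi %*% beta)
    u <- runif(n)
    lo <- ifelse(y == 1, pnorm(-mu), 0)
    hi <- ifelse(y == 1, 1, pnorm(-mu))
    z <- mu + qnorm(lo + u * (hi - lo))
    ok <- is.finite(z)
    z[!ok] <- mu[!ok] + ifelse(y[!ok] == 1, 6, -6)
    m <- backsolve(Pc, forwardsolve(t(Pc), crossprod(Xi, z)))
    beta <- drop(m + backsolve(Pc, rnorm(q)))
    if (t > burnin && (t - burnin) %% thin == 0) {
      k <- k + 1; keep[k, ] <- beta
    }
  }
  keep
}

# a small landscape with two climate-like layers and one patchy urban
# layer; layers are unit-scale anomalies so truth coefficients read as
# per-sd effects
make_test_grid <- function(seed = 1, n_cells = 30, cell = 0.01,
                           origin = c(34, 31)) {
  cfg <- landscape_config(
    extent = c(origin[1], origin[1] + n_cells * cell,
               origin[2], origin[2] + n_cells * cell),
    cell_size = cell,
    predictors = list(
      list(name = "temp", corr_length = 8, mean = 0, sd = 1),
      list(name = "precip", corr_length = 6, mean = 0, sd = 1),
      list(name = "urban", corr_length = 5, mean = 0, sd = 1,
           urban = TRUE)),
    seed = seed)
  generate_predictor_grid(cfg)
}

# ground truth on that landscape: focal species driven by urbanization
make_test_truth <- function(J = 3, detection_rate = 1) {
  B <- rbind(c(0.3, 0.1, 1.2),
             c(0.5, -0.4, 0.8),
             c(-0.6, 0.5, 0.2))[seq_len(J), , drop = FALSE]
  colnames(B) <- c("temp", "precip", "urban")
  R <- diag(J)
  if (J >= 2) R[1, 2] <- R[2, 1] <- 0.5
  community_truth(paste0("sp", seq_len(J)),
                  alpha = rep(-0.2, J), B = B, R = R,
                  foraging_km = 0.4, home_range_km = 0.8,
                  detection_rate = detection_rate)
}

# standardize a raw matrix the way extract_design does
standardize_cols <- function(X) {
  ctr <- colMeans(X); scl <- apply(X, 2, sd)
  out <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  attr(out, "center") <- ctr; attr(out, "scale") <- scl
  out
}

cli_path <- function() system.file("cli", "sdmjoint.R",
                                   package = "sdmjoint")
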