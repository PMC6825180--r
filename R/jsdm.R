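#' MCMC presets for the joint model
#'
#' `"paper"` is the publication-scale run (5 chains of 1,000,000
#' iterations, burn-in 15,000, thinning 1,000); `"desk"` is a reduced
#' preset (4 chains of 20,000 iterations, burn-in 5,000, thinning 10)
#' sized for interactive use and tests.
#'
#' @param name `"desk"` or `"paper"`.
#' @return list with `chains`, `iter`, `burnin`, `thin`.
#' @export
jsdm_preset <- function(name = c("desk", "paper")) {
  switch(match.arg(name),
         desk  = list(chains = 4L, iter = 20000L, burnin = 5000L,
                      thin = 10L),
         paper = list(chains = 5L, iter = 1000000L, burnin = 15000L,
                      thin = 1000L))
}

#' Fit a multivariate probit joint species distribution model
#'
#' Binary occurrences of J species at n sites are modelled through a
#' latent multivariate normal: `y_ij = 1[z_ij > 0]`,
#' `z_i ~ N(alpha + B x_i, R)` with `R` a correlation matrix. `B` carries
#' each species' environmental response; the off-diagonals of `R` are
#' residual correlations — co-occurrence not explained by the modelled
#' environment. Fitting is by Gibbs sampling: truncated-normal draws of
#' the latent scores (Albert–Chib augmentation), a conjugate
#' multivariate-normal draw of the coefficients, and a parameter-expanded
#' inverse-Wishart draw of the residual covariance rescaled to
#' correlation form. Priors: `alpha, B ~ N(0, prior_scale^2)` elementwise
#' (weakly informative on standardized predictors); expanded covariance
#' `~ IW(I, J + 1)` by default.
#'
#' Chains run sequentially with seeds derived from `seed` by fixed
#' offsets, so fits are reproducible. Draw retention: after burn-in,
#' every `thin`-th sweep, giving `chains * floor((iter - burnin)/thin)`
#' retained draws.
#'
#' @param x a `site_table` (from [build_site_table()] or
#'   [simulate_community()]) or an n x p design matrix.
#' @param y n x J binary response matrix (ignored when `x` is a
#'   `site_table`).
#' @param chains,iter,burnin,thin MCMC run lengths; defaults from
#'   `preset`.
#' @param preset `"desk"` (default) or `"paper"`; see [jsdm_preset()].
#' @param prior_scale prior sd of intercepts and coefficients.
#' @param prior_df degrees of freedom of the expanded inverse-Wishart
#'   prior; default `J + 1`.
#' @param seed master seed.
#' @param fix_residual_identity if `TRUE` the residual correlation is held
#'   at the identity (independent-species probit), a diagnostic switch.
#' @return object of class `jsdm` with components `alpha` (draws x J),
#'   `B` (draws x J x p array), `R` (draws x J x J array), `chain`
#'   (chain index per draw), `species`, `predictors`, the fitted `X`/`Y`,
#'   and the run settings in `$settings`.
#' @export
jsdm <- function(x, y = NULL, chains = NULL, iter = NULL, burnin = NULL,
                 thin = NULL, preset = "desk", prior_scale = 10,
                 prior_df = NULL, seed = 1L,
                 fix_residual_identity = FALSE) {
  if (inherits(x, "site_table")) {
    X <- x$X; Y <- x$Y
  } else {
    X <- as.matrix(x); Y <- as.matrix(y)
  }
  std <- list(center = attr(X, "center"), scale = attr(X, "scale"))
  X <- unname(as.matrix(X)); storage.mode(X) <- "double"
  if (anyNA(X)) stop("X has missing values", call. = FALSE)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("sp", seq_len(ncol(Y)))
  species <- colnames(Y)
  predictors <- if (inherits(x, "site_table")) colnames(x$X)
                else colnames(as.matrix(x))
  if (is.null(predictors)) predictors <- paste0("x", seq_len(ncol(X)))
  if (!all(Y %in% c(0, 1))) stop("Y must be binary", call. = FALSE)
  bad <- species[colSums(Y) == 0 | colSums(Y) == nrow(Y)]
  if (length(bad))
    stop("species with all-0 or all-1 responses (probit unidentifiable): ",
         paste(bad, collapse = ", "), call. = FALSE)

  pre <- jsdm_preset(preset)
  chains <- as.integer(chains %||% pre$chains)
  iter <- as.integer(iter %||% pre$iter)
  burnin <- as.integer(burnin %||% pre$burnin)
  thin <- as.integer(thin %||% pre$thin)
  if (chains < 1L || thin < 1L || burnin < 0L || iter <= burnin)
    stop("need chains >= 1, thin >= 1, 0 <= burnin < iter", call. = FALSE)
  J <- ncol(Y); p <- ncol(X)
  if (is.null(prior_df)) prior_df <- J + 1

  Xi <- cbind(1, X)
  Yi <- Y; storage.mode(Yi) <- "integer"
  keep_per <- (iter - burnin) %/% thin
  alpha <- matrix(NA_real_, chains * keep_per, J)
  Barr <- array(NA_real_, c(chains * keep_per, J, p))
  Rarr <- array(NA_real_, c(chains * keep_per, J, J))
  chain_id <- integer(chains * keep_per)
  for (ch in seq_len(chains)) {
    set.seed(seed + (ch - 1L) * 1009L)
    res <- .jsdm_gibbs_chain(Xi, Yi, iter, burnin, thin,
                             prior_scale^2, prior_df,
                             fix_residual_identity)
    rows <- (ch - 1L) * keep_per + seq_len(keep_per)
    g <- res$gamma  # keep x (p+1)*J, vec(Gamma) with Gamma (p+1) x J
    for (j in seq_len(J)) {
      off <- (j - 1L) * (p + 1L)
      alpha[rows, j] <- g[, off + 1L]
      Barr[rows, j, ] <- g[, off + 1L + seq_len(p), drop = FALSE]
    }
    Rarr[rows, , ] <- array(res$R, c(keep_per, J, J))
    chain_id[rows] <- ch
  }
  .check_R_draws(Rarr)
  dimnames(alpha) <- list(NULL, species)
  dimnames(Barr) <- list(NULL, species, predictors)
  dimnames(Rarr) <- list(NULL, species, species)
  structure(
    list(alpha = alpha, B = Barr, R = Rarr, chain = chain_id,
         species = species, predictors = predictors,
         X = X, Y = Y, standardization = std,
         sites = if (inherits(x, "site_table")) x$sites else NULL,
         settings = list(chains = chains, iter = iter, burnin = burnin,
                         thin = thin, prior_scale = prior_scale,
                         prior_df = prior_df, seed = seed,
                         fix_residual_identity = fix_residual_identity)),
    class = "jsdm")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# every retained R draw must be symmetric, unit-diagonal, PD
.check_R_draws <- function(Rarr) {
  J <- dim(Rarr)[2]
  for (d in seq_len(dim(Rarr)[1])) {
    Rd <- Rarr[d, , ]
    if (J == 1L) Rd <- matrix(Rd, 1, 1)
    if (max(abs(Rd - t(Rd))) > 1e-8 || max(abs(diag(Rd) - 1)) > 1e-8)
      stop("retained R draw ", d, " is not a correlation matrix",
           call. = FALSE)
    ok <- tryCatch({ chol(Rd); TRUE }, error = function(e) FALSE)
    if (!ok) stop("retained R draw ", d, " is not positive definite",
                  call. = FALSE)
  }
  invisible(TRUE)
}

#' @method print jsdm
#' @export
print.jsdm <- function(x, ...) {
  s <- x$settings
  cat("Multivariate probit JSDM\n")
  cat("  species:", length(x$species), " predictors:",
      length(x$predictors), " sites:", nrow(x$X), "\n")
  cat("  draws:", nrow(x$alpha), sprintf("(%d chains x %d kept)",
      s$chains, nrow(x$alpha) %/% s$chains), "\n")
  invisible(x)
}

#' @method coef jsdm
#' @export
coef.jsdm <- function(object, ...) {
  cbind(`(Intercept)` = colMeans(object$alpha),
        apply(object$B, c(2, 3), mean))
}

#' @method summary jsdm
#' @export
summary.jsdm <- function(object, prob = 0.95, ...) {
  lo <- (1 - prob) / 2; hi <- 1 - lo
  summarize <- function(draws, name) {
    data.frame(parameter = name, mean = mean(draws), sd = stats::sd(draws),
               lower = unname(stats::quantile(draws, lo)),
               upper = unname(stats::quantile(draws, hi)),
               stringsAsFactors = FALSE)
  }
  rows <- list()
  for (j in seq_along(object$species)) {
    rows[[length(rows) + 1L]] <-
      summarize(object$alpha[, j],
                paste0("alpha[", object$species[j], "]"))
    for (k in seq_along(object$predictors))
      rows[[length(rows) + 1L]] <-
        summarize(object$B[, j, k],
                  paste0("B[", object$species[j], ",",
                         object$predictors[k], "]"))
  }
  J <- length(object$species)
  if (J > 1)
    for (j in 1:(J - 1)) for (k in (j + 1):J)
      rows[[length(rows) + 1L]] <-
        summarize(object$R[, j, k],
                  paste0("R[", object$species[j], ",",
                         object$species[k], "]"))
  out <- do.call(rbind, rows)
  structure(list(table = out, prob = prob, n_draws = nrow(object$alpha)),
            class = "summary.jsdm")
}

#' @method print summary.jsdm
#' @export
print.summary.jsdm <- function(x, ...) {
  cat("Posterior summary (", x$n_draws, " draws, ",
      round(100 * x$prob), "% intervals)\n", sep = "")
  tab <- x$table
  tab[, -1] <- round(tab[, -1], 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Posterior predicted probability of occurrence
#'
#' Per-site probability `pnorm(alpha_j + B_j . x)` for one species.
#' `mode = "draws"` (default) averages the probability over retained
#' posterior draws; `mode = "plugin"` evaluates it at the posterior means
#' (the two differ by the Jensen gap of the normal CDF).
#'
#' @param object a fitted [jsdm()].
#' @param newdata sites x predictors matrix on the same scale as the
#'   fitted design (i.e. standardized if the fit was); default the fitted
#'   sites.
#' @param species species name or index.
#' @param mode `"draws"` or `"plugin"`.
#' @param ... unused.
#' @return numeric vector of probabilities in [0, 1].
#' @method predict jsdm
#' @export
predict.jsdm <- function(object, newdata = NULL, species = 1,
                         mode = c("draws", "plugin"), ...) {
  mode <- match.arg(mode)
  X <- if (is.null(newdata)) object$X else as.matrix(newdata)
  if (ncol(X) != length(object$predictors))
    stop("newdata must have ", length(object$predictors), " columns",
         call. = FALSE)
  j <- if (is.character(species)) match(species, object$species)
       else as.integer(species)
  if (is.na(j) || j < 1 || j > length(object$species))
    stop("unknown species", call. = FALSE)
  Bj <- matrix(object$B[, j, ], nrow = dim(object$B)[1])
  if (mode == "plugin") {
    eta <- mean(object$alpha[, j]) + drop(X %*% colMeans(Bj))
    return(stats::pnorm(eta))
  }
  # draws mode: average pnorm over draws; loop draws to bound memory
  acc <- numeric(nrow(X))
  nd <- nrow(Bj)
  for (d in seq_len(nd))
    acc <- acc + stats::pnorm(object$alpha[d, j] + drop(X %*% Bj[d, ]))
  acc / nd
}

#' Residual co-occurrence summary
#'
#' Posterior mean and sd of each pair's residual correlation `R_jk` —
#' co-occurrence beyond the modelled environment (the biological-
#' interaction signal).
#'
#' @param post a fitted [jsdm()].
#' @return data frame with one row per unordered species pair:
#'   `species_1, species_2, res_mean, res_sd`.
#' @export
residual_correlation <- function(post) {
  stopifnot(inherits(post, "jsdm"))
  J <- length(post$species)
  rows <- list()
  for (j in seq_len(J)) for (k in seq_len(J)) {
    if (k <= j) next
    d <- post$R[, j, k]
    rows[[length(rows) + 1L]] <- data.frame(
      species_1 = post$species[j], species_2 = post$species[k],
      res_mean = mean(d), res_sd = stats::sd(d),
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(species_1 = character(), species_2 = character(),
                      res_mean = numeric(), res_sd = numeric()))
  do.call(rbind, rows)
}

#' Environmental correlation summary
#'
#' For each retained draw, each species' environmental linear predictor
#' `alpha_j + B_j . x_i` is evaluated over the sites; the environmental
#' correlation of a pair is the Pearson correlation of the two site
#' vectors — similarity of habitat response. Summarized as posterior
#' mean and sd across draws.
#'
#' @param post a fitted [jsdm()].
#' @param newdata optional sites x predictors matrix (same scale as the
#'   fit); default the fitted sites.
#' @return data frame `species_1, species_2, env_mean, env_sd`.
#' @export
environmental_correlation <- function(post, newdata = NULL) {
  stopifnot(inherits(post, "jsdm"))
  X <- if (is.null(newdata)) post$X else as.matrix(newdata)
  if (nrow(X) < 3)
    stop("environmental correlation needs at least 3 sites", call. = FALSE)
  J <- length(post$species); nd <- nrow(post$alpha)
  pairs <- which(upper.tri(diag(J)), arr.ind = TRUE)
  acc <- matrix(NA_real_, nd, nrow(pairs))
  for (d in seq_len(nd)) {
    Bd <- matrix(post$B[d, , ], nrow = J)
    Eta <- sweep(X %*% t(Bd), 2, post$alpha[d, ], "+")
    for (pp in seq_len(nrow(pairs)))
      acc[d, pp] <- stats::cor(Eta[, pairs[pp, 1]], Eta[, pairs[pp, 2]])
  }
  data.frame(species_1 = post$species[pairs[, 1]],
             species_2 = post$species[pairs[, 2]],
             env_mean = colMeans(acc),
             env_sd = if (nd == 1) rep(0, ncol(acc))
                      else apply(acc, 2, stats::sd),
             stringsAsFactors = FALSE)
}

#' Environmental vs residual co-occurrence table
#'
#' Combines [environmental_correlation()] and [residual_correlation()]
#' into the per-pair table behind the classic env-vs-residual
#' co-occurrence scatter.
#'
#' @inheritParams environmental_correlation
#' @return data frame `pair, species_1, species_2, env_mean, env_sd,
#'   res_mean, res_sd`, symmetric in the pair by construction.
#' @export
cooccurrence_summary <- function(post, newdata = NULL) {
  env <- environmental_correlation(post, newdata)
  res <- residual_correlation(post)
  out <- merge(env, res, by = c("species_1", "species_2"), sort = FALSE)
  out <- cbind(pair = paste(out$species_1, out$species_2, sep = ":"), out)
  out
}

#' @description `plot.jsdm` draws the per-pair environmental vs residual
#'   correlation scatter with +/- 1 sd error bars and a 1:1 reference
#'   line.
#' @rdname cooccurrence_summary
#' @param x a fitted [jsdm()].
#' @param focal if given, restrict to pairs involving this species.
#' @param ... passed to `plot`.
#' @method plot jsdm
#' @export
plot.jsdm <- function(x, focal = NULL, ...) {
  cs <- cooccurrence_summary(x)
  if (!is.null(focal))
    cs <- cs[cs$species_1 == focal | cs$species_2 == focal, , drop = FALSE]
  if (!nrow(cs)) stop("no species pairs to plot", call. = FALSE)
  graphics::plot(cs$env_mean, cs$res_mean, xlim = c(-1, 1), ylim = c(-1, 1),
                 xlab = "environmental correlation",
                 ylab = "residual correlation", pch = 19, ...)
  graphics::abline(0, 1, lty = 2)
  graphics::abline(h = 0, v = 0, col = "grey")
  graphics::segments(cs$env_mean - cs$env_sd, cs$res_mean,
                     cs$env_mean + cs$env_sd, cs$res_mean)
  graphics::segments(cs$env_mean, cs$res_mean - cs$res_sd,
                     cs$env_mean, cs$res_mean + cs$res_sd)
  invisible(cs)
}

#' MCMC convergence diagnostics
#'
#' Split-chain potential scale reduction (split-Rhat) and a rank-normal-
#' free effective sample size for every scalar parameter (intercepts,
#' coefficients and residual correlations). Parameters with Rhat above
#' `threshold` are flagged. With a single chain the split halves of that
#' chain are used and the report says so.
#'
#' @param post a fitted [jsdm()].
#' @param threshold flag parameters with Rhat above this (default 1.1).
#' @return data frame `parameter, rhat, ess, flagged` with attribute
#'   `single_chain`.
#' @export
convergence_check <- function(post, threshold = 1.1) {
  stopifnot(inherits(post, "jsdm"))
  draws <- .scalar_draws(post)
  chains <- post$chain
  out <- data.frame(parameter = colnames(draws),
                    rhat = NA_real_, ess = NA_real_)
  for (i in seq_len(ncol(draws))) {
    m <- split(draws[, i], chains)
    out$rhat[i] <- .split_rhat(m)
    out$ess[i] <- .ess(m)
  }
  out$flagged <- !is.na(out$rhat) & out$rhat > threshold
  attr(out, "single_chain") <- length(unique(chains)) == 1L
  out
}

.scalar_draws <- function(post) {
  J <- length(post$species); p <- length(post$predictors)
  cols <- list()
  for (j in seq_len(J)) {
    cols[[paste0("alpha[", post$species[j], "]")]] <- post$alpha[, j]
    for (k in seq_len(p))
      cols[[paste0("B[", post$species[j], ",", post$predictors[k], "]")]] <-
        post$B[, j, k]
  }
  if (J > 1)
    for (j in 1:(J - 1)) for (k in (j + 1):J)
      cols[[paste0("R[", post$species[j], ",", post$species[k], "]")]] <-
        post$R[, j, k]
  do.call(cbind, cols)
}

# split-Rhat: each chain halved, between/within variance ratio
.split_rhat <- function(chain_list) {
  halves <- list()
  for (ch in chain_list) {
    n2 <- length(ch) %/% 2
    if (n2 < 2) return(NA_real_)
    halves[[length(halves) + 1L]] <- ch[seq_len(n2)]
    halves[[length(halves) + 1L]] <- ch[(n2 + 1):(2 * n2)]
  }
  n <- length(halves[[1]])
  mu <- vapply(halves, mean, 0)
  s2 <- vapply(halves, stats::var, 0)
  W <- mean(s2)
  B <- n * stats::var(mu)
  if (W < 1e-12) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# effective sample size via the initial-positive-sequence estimator on
# chain-mean-centred draws
.ess <- function(chain_list) {
  ns <- vapply(chain_list, length, 0L)
  n <- min(ns); m <- length(chain_list)
  if (n < 4) return(NA_real_)
  centred <- lapply(chain_list, function(ch) ch[seq_len(n)] - mean(ch))
  v0 <- mean(vapply(centred, function(x) mean(x^2), 0))
  if (v0 < 1e-12) return(m * n)
  max_lag <- min(n - 2, 200L)
  rho <- numeric(max_lag)
  for (t in seq_len(max_lag)) {
    rho[t] <- mean(vapply(centred, function(x)
      mean(x[1:(n - t)] * x[(1 + t):n]), 0)) / v0
  }
  tau <- 1; t <- 1
  while (t + 1 <= max_lag) {
    pair <- rho[t] + rho[t + 1]
    if (pair < 0) break
    tau <- tau + 2 * pair
    t <- t + 2
  }
  m * n / tau
}
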