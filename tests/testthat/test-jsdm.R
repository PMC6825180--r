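# a hand-built posterior object with fixed draws, for closed-form checks
fake_jsdm <- function(alpha, B, R, X, chain = NULL) {
  nd <- nrow(alpha)
  J <- ncol(alpha); p <- dim(B)[3]
  structure(list(
    alpha = alpha, B = B, R = R,
    chain = chain %||% rep(1L, nd),
    species = colnames(alpha) %||% paste0("s", seq_len(J)),
    predictors = paste0("x", seq_len(p)),
    X = X, Y = NULL, standardization = list(center = NULL, scale = NULL),
    settings = list(chains = length(unique(chain %||% 1L)))),
    class = "jsdm")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("fitting validates responses and run-length accounting", {
  set.seed(1)
  X <- matrix(rnorm(60), 60, 1, dimnames = list(NULL, "x"))
  Y <- cbind(a = rbinom(60, 1, 0.5), b = rep(1L, 60))
  expect_error(jsdm(X, Y, chains = 1, iter = 100, burnin = 10, thin = 1),
               "b")
  Y2 <- cbind(a = c(rep(0L, 30), rep(1L, 30)),
              b = c(rep(1L, 30), rep(0L, 30)))
  fit <- jsdm(X, Y2, chains = 2, iter = 230, burnin = 30, thin = 4,
              seed = 2)
  expect_equal(nrow(fit$alpha), 2 * floor((230 - 30) / 4))
  expect_equal(fit$chain, rep(1:2, each = 50))
  expect_error(jsdm(X, Y2, chains = 1, iter = 10, burnin = 10, thin = 1),
               "burnin")
  # reproducibility under the master seed
  fit2 <- jsdm(X, Y2, chains = 2, iter = 230, burnin = 30, thin = 4,
               seed = 2)
  expect_identical(fit$alpha, fit2$alpha)
  expect_identical(fit$R, fit2$R)
})

test_that("every retained correlation draw is a valid correlation matrix", {
  set.seed(3)
  X <- matrix(rnorm(200), 200, 1, dimnames = list(NULL, "x"))
  mu <- cbind(0.3 * X[, 1], -0.5 * X[, 1], 0.2 * X[, 1])
  Y <- (mu + matrix(rnorm(600), 200, 3) > 0) + 0L
  colnames(Y) <- c("a", "b", "c")
  fit <- jsdm(X, Y, chains = 1, iter = 2000, burnin = 500, thin = 5,
              seed = 4)
  for (d in seq_len(nrow(fit$alpha))) {
    Rd <- fit$R[d, , ]
    expect_equal(Rd, t(Rd))
    expect_equal(unname(diag(Rd)), rep(1, 3))
    expect_gt(min(eigen(Rd, symmetric = TRUE,
                        only.values = TRUE)$values), 0)
  }
})

test_that("with identity residual correlation B matches per-species probit", {
  set.seed(5)
  n <- 600
  X <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("x1", "x2")))
  B <- rbind(c(1, -0.5), c(-0.8, 0.6))
  mu <- X %*% t(B)
  Y <- (mu + matrix(rnorm(n * 2), n, 2) > 0) + 0L
  colnames(Y) <- c("a", "b")
  fit <- jsdm(X, Y, chains = 2, iter = 3000, burnin = 500, thin = 5,
              seed = 6, fix_residual_identity = TRUE)
  expect_true(all(fit$R[, 1, 2] == 0))
  for (j in 1:2) {
    ml <- glm(Y[, j] ~ X, family = binomial("probit"))
    post <- c(mean(fit$alpha[, j]), apply(fit$B[, j, ], 2, mean))
    expect_equal(unname(post), unname(coef(ml)), tolerance = 0.12)
  }
})

test_that("species order permutation permutes the posterior equivariantly", {
  set.seed(7)
  n <- 400
  X <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "x"))
  mu <- cbind(0.8 * X[, 1], -0.6 * X[, 1], 0.1 + 0.3 * X[, 1])
  R <- diag(3); R[1, 3] <- R[3, 1] <- 0.5
  Y <- (mu + matrix(rnorm(n * 3), n, 3) %*% chol(R) > 0) + 0L
  colnames(Y) <- c("a", "b", "c")
  perm <- c(3, 1, 2)
  f1 <- jsdm(X, Y, chains = 2, iter = 3000, burnin = 1000, thin = 5,
             seed = 8)
  f2 <- jsdm(X, Y[, perm], chains = 2, iter = 3000, burnin = 1000,
             thin = 5, seed = 8)
  expect_equal(colMeans(f2$alpha)[colnames(Y)], colMeans(f1$alpha),
               tolerance = 0.1)
  R1 <- apply(f1$R, c(2, 3), mean)
  R2 <- apply(f2$R, c(2, 3), mean)[colnames(Y), colnames(Y)]
  expect_equal(R2, R1, tolerance = 0.12)
})

test_that("residual summary has unit diagonal semantics and symmetry", {
  nd <- 50
  alpha <- matrix(0, nd, 2, dimnames = list(NULL, c("a", "b")))
  B <- array(0, c(nd, 2, 1))
  R <- array(0, c(nd, 2, 2))
  rho <- seq(-0.4, 0.4, length.out = nd)
  for (d in seq_len(nd))
    R[d, , ] <- matrix(c(1, rho[d], rho[d], 1), 2)
  X <- matrix(rnorm(20), 20, 1)
  f <- fake_jsdm(alpha, B, R, X)
  rs <- residual_correlation(f)
  expect_equal(nrow(rs), 1)  # one unordered pair; diagonal excluded
  expect_equal(rs$res_mean, mean(rho))
  expect_equal(rs$res_sd, sd(rho))
  # diagonal of each draw is exactly 1 by construction
  expect_true(all(f$R[, 1, 1] == 1 & f$R[, 2, 2] == 1))
})

test_that("environmental correlation reduces to closed forms", {
  nd <- 4
  X <- matrix(rnorm(15), 5, 3)
  # identical coefficient vectors in every draw -> +1
  alpha <- matrix(0.3, nd, 2, dimnames = list(NULL, c("a", "b")))
  B <- array(rep(c(1, 1, -2, -2, 0.5, 0.5), each = nd), c(nd, 2, 3))
  R <- array(rep(diag(2), each = nd), c(nd, 2, 2))
  f <- fake_jsdm(alpha, B, R, X)
  expect_equal(environmental_correlation(f)$env_mean, 1)
  # negated coefficients with zero intercepts -> -1
  B2 <- B; B2[, 2, ] <- -B[, 1, ]
  f2 <- fake_jsdm(alpha * 0, B2, R, X)
  expect_equal(environmental_correlation(f2)$env_mean, -1)
  # single fixed draw matches a direct Pearson computation
  a3 <- matrix(c(0.2, -0.1), 1, 2, dimnames = list(NULL, c("a", "b")))
  B3 <- array(c(1, 0.3, -0.5, 0.8, 0.2, -0.4), c(1, 2, 3))
  f3 <- fake_jsdm(a3, B3, array(rep(diag(2), 1), c(1, 2, 2)), X)
  eta1 <- 0.2 + X %*% c(B3[1, 1, ])
  eta2 <- -0.1 + X %*% c(B3[1, 2, ])
  expect_equal(environmental_correlation(f3)$env_mean,
               cor(eta1, eta2)[1], tolerance = 1e-12)
  expect_equal(environmental_correlation(f3)$env_sd, 0)
  expect_error(environmental_correlation(f3, X[1:2, , drop = FALSE]),
               "3 sites")
})

test_that("co-occurrence summary joins both parts per pair", {
  nd <- 10
  alpha <- matrix(rnorm(nd * 2, 0, 0.1), nd, 2,
                  dimnames = list(NULL, c("a", "b")))
  B <- array(rnorm(nd * 2 * 2, 0, 0.1), c(nd, 2, 2))
  R <- array(0, c(nd, 2, 2))
  for (d in seq_len(nd)) R[d, , ] <- matrix(c(1, 0.3, 0.3, 1), 2)
  f <- fake_jsdm(alpha, B, R, matrix(rnorm(40), 20, 2))
  cs <- cooccurrence_summary(f)
  expect_named(cs, c("pair", "species_1", "species_2", "env_mean",
                     "env_sd", "res_mean", "res_sd"))
  expect_equal(cs$res_mean, 0.3)
})

test_that("convergence diagnostics separate mixed from unmixed chains", {
  nd <- 1000
  set.seed(9)
  white <- rnorm(2 * nd)
  same <- fake_jsdm(matrix(white, 2 * nd, 1, dimnames = list(NULL, "a")),
                    array(white, c(2 * nd, 1, 1)),
                    array(1, c(2 * nd, 1, 1)),
                    matrix(rnorm(10), 10, 1),
                    chain = rep(1:2, each = nd))
  cc <- convergence_check(same)
  expect_lt(max(cc$rhat), 1.02)
  expect_false(any(cc$flagged))
  # independent draws: ESS within 20% of the draw count
  expect_gt(min(cc$ess), 0.8 * 2 * nd)
  # chains centred at different means are flagged
  shifted <- same
  shifted$alpha[same$chain == 2, 1] <- shifted$alpha[same$chain == 2, 1] + 5
  shifted$B[same$chain == 2, 1, 1] <- shifted$B[same$chain == 2, 1, 1] + 5
  cc2 <- convergence_check(shifted)
  expect_gt(min(cc2$rhat), 2)
  expect_true(all(cc2$flagged))
  # single chain: diagnostics still computable from split halves
  one <- fake_jsdm(matrix(rnorm(nd), nd, 1, dimnames = list(NULL, "a")),
                   array(rnorm(nd), c(nd, 1, 1)),
                   array(1, c(nd, 1, 1)), matrix(rnorm(10), 10, 1))
  cc3 <- convergence_check(one)
  expect_true(attr(cc3, "single_chain"))
})

test_that("posterior methods print, summarize and expose coefficients", {
  set.seed(10)
  X <- matrix(rnorm(150), 150, 1, dimnames = list(NULL, "x"))
  Y <- cbind(a = rbinom(150, 1, pnorm(X[, 1])),
             b = rbinom(150, 1, pnorm(-X[, 1])))
  fit <- jsdm(X, Y, chains = 1, iter = 800, burnin = 200, thin = 3,
              seed = 11)
  expect_output(print(fit), "Multivariate probit JSDM")
  co <- coef(fit)
  expect_equal(dim(co), c(2, 2))
  expect_equal(rownames(co), c("a", "b"))
  s <- summary(fit)
  expect_s3_class(s, "summary.jsdm")
  expect_true(all(c("alpha[a]", "B[a,x]", "R[a,b]") %in%
                  s$table$parameter))
  expect_output(print(s), "Posterior summary")
})
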