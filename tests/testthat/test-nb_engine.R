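test_that("TMM factors behave on symmetric, scaled and unbiased libraries", {
  set.seed(1)
  base <- rpois(200, 100) + 1
  gid <- paste0("g", seq_along(base))
  y <- count_matrix(cbind(s1 = base, s2 = base), gene_ids = gid)
  expect_equal(unname(compute_norm_factors(y)), c(1, 1))
  # pure depth scaling: all M-values are 0, factors stay at ratio 1
  y2 <- count_matrix(cbind(s1 = base, s2 = 2L * base), gene_ids = gid)
  f <- compute_norm_factors(y2)
  expect_equal(unname(f), c(1, 1), tolerance = 1e-12)
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)
  # no composition bias: factors near 1 (Poisson libraries)
  set.seed(3)
  y3 <- count_matrix(matrix(rpois(100 * 6, rep(rlnorm(100, 6, 1), 6)), 100,
                            dimnames = list(paste0("g", 1:100),
                                            paste0("s", 1:6))))
  f3 <- compute_norm_factors(y3)
  expect_true(all(f3 > 0.95 & f3 < 1.05))
  expect_equal(exp(mean(log(f3))), 1, tolerance = 1e-12)
  # agreement with edgeR on overdispersed libraries
  set.seed(3)
  y4 <- matrix(rnbinom(100 * 6, mu = rep(rlnorm(100, 5, 1), 6), size = 20),
               100, dimnames = dimnames(y3))
  f4 <- compute_norm_factors(count_matrix(y4))
  ref <- edgeR::calcNormFactors(edgeR::DGEList(y4))$samples$norm.factors
  expect_equal(unname(f4), ref, tolerance = 1e-6)
  expect_warning(compute_norm_factors(count_matrix(
    matrix(1:3, 3, dimnames = list(letters[1:3], "s1")))), "single sample")
})

test_that("NB GLM score equations give exact closed-form fits", {
  # intercept-only with equal offsets: fitted mean is the sample mean
  for (phi in c(0, 0.1, 1)) {
    f <- fit_nb_glm(c(4, 6, 8, 10), matrix(1, 4, 1), dispersion = phi)
    expect_equal(unname(f$fitted), rep(7, 4), tolerance = 1e-6)
  }
  # balanced two-group: coefficient is the log ratio of group means
  X <- cbind(intercept = 1, group = rep(0:1, each = 3))
  f2 <- fit_nb_glm(c(10, 10, 10, 40, 40, 40), X, dispersion = 0.1)
  expect_equal(unname(f2$coefficients["group"]), log(4), tolerance = 1e-6)
  expect_true(f2$converged)
})

test_that("IRLS deviance matches a brute-force likelihood maximization", {
  set.seed(4)
  y <- rnbinom(6, mu = c(20, 25, 18, 60, 55, 70), size = 10)
  X <- cbind(1, rep(0:1, each = 3))
  off <- rnorm(6, 0, 0.1)
  phi <- 0.1
  f <- fit_nb_glm(y, X, dispersion = phi, offset = off)
  nll <- function(b) -sum(dnbinom(y, size = 1 / phi,
                                  mu = exp(drop(X %*% b) + off), log = TRUE))
  opt <- optim(c(3, 1), nll, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  sat <- sum(dnbinom(y, size = 1 / phi, mu = pmax(y, 1e-10), log = TRUE))
  dev_oracle <- 2 * (sat + opt$value)
  expect_equal(f$deviance, dev_oracle, tolerance = 1e-4)
})

test_that("dispersion estimation recovers known values and handles edge cases", {
  # zero within-cell variance drives the common dispersion to the floor
  y0 <- matrix(rep(c(5, 50, 500), each = 4), 3, 4, byrow = TRUE,
               dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  d0 <- estimate_dispersions(y0, matrix(1, 4, 1))
  expect_lt(d0$common, 2e-6)
  # NB truth 0.1
  set.seed(5)
  mu <- rlnorm(2000, log(100), 1)
  y <- matrix(rnbinom(2000 * 4, mu = rep(mu, 4), size = 10), ncol = 4,
              dimnames = list(paste0("g", 1:2000), paste0("s", 1:4)))
  d <- estimate_dispersions(y, matrix(1, 4, 1))
  expect_gt(d$common, 0.08); expect_lt(d$common, 0.12)
  # Poisson truth
  set.seed(6)
  yp <- matrix(rpois(2000 * 4, rep(mu, 4)), ncol = 4,
               dimnames = dimnames(y))
  dp <- estimate_dispersions(yp, matrix(1, 4, 1))
  expect_lte(dp$common, 1e-3)
  # no replication
  expect_error(estimate_dispersions(y[, 1:2], cbind(1, 0:1)),
               "no replication")
})

test_that("tagwise dispersions shrink monotonically toward common", {
  set.seed(7)
  mu <- rlnorm(300, log(100), 1)
  y <- matrix(rnbinom(300 * 6, mu = rep(mu, 6), size = 1 / 0.1), ncol = 6,
              dimnames = list(paste0("g", 1:300), paste0("s", 1:6)))
  X <- matrix(1, 6, 1)
  d1 <- estimate_dispersions(y, X, prior_df = 1)
  d10 <- estimate_dispersions(y, X, prior_df = 10)
  dInf <- estimate_dispersions(y, X, prior_df = 1e6)
  gap <- function(d) median(abs(log(d$tagwise) - log(d$common)))
  expect_gt(gap(d1), gap(d10))
  expect_gt(gap(d10), gap(dInf))
  expect_equal(dInf$tagwise, rep(dInf$common, 300), tolerance = 0.05)
  expect_true(all(d1$tagwise >= 1e-6 & d1$tagwise <= 10))
})

test_that("LRT is zero for identical models and errors for non-nested ones", {
  set.seed(8)
  y <- matrix(rnbinom(10 * 4, mu = 50, size = 10), 10)
  X <- cbind(1, rep(0:1, each = 2))
  f <- nb_glm_fit(y, design_matrix(X), 0.1)
  t0 <- lrt(f, f, df = 1)
  expect_equal(t0$statistic, rep(0, 10))
  expect_equal(t0$p, rep(1, 10))
  # reparameterization spanning the same space leaves the statistic unchanged
  X2 <- cbind(rep(1:0, each = 2), rep(0:1, each = 2))  # cell-means coding
  r <- nb_glm_fit(y, design_matrix(X[, 1, drop = FALSE]), 0.1)
  s1 <- lrt(f, r, 1)$statistic
  s2 <- lrt(nb_glm_fit(y, design_matrix(X2), 0.1), r, 1)$statistic
  expect_equal(s1, s2, tolerance = 1e-6)
  Xother <- cbind(c(1, 0, 0, 0))
  expect_error(lrt(f, nb_glm_fit(y, design_matrix(Xother), 0.1), 1),
               "not nested")
})

test_that("null LRT p-values are uniform", {
  set.seed(9)
  G <- 2000
  mu <- rlnorm(G, log(150), 1)
  y <- matrix(rnbinom(G * 6, mu = rep(mu, 6), size = 1 / 0.05), ncol = 6,
              dimnames = list(paste0("g", 1:G), paste0("s", 1:6)))
  X <- cbind(1, rep(0:1, each = 3))
  full <- nb_glm_fit(y, design_matrix(X), 0.05)
  red <- nb_glm_fit(y, design_matrix(X[, 1, drop = FALSE]), 0.05)
  p <- lrt(full, red, 1)$p
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 0.04)
})

test_that("fixed-dispersion fits agree with edgeR's GLM on the same data", {
  library(edgeR)
  set.seed(10)
  G <- 200
  mu <- rlnorm(G, log(100), 1)
  fc <- ifelse(seq_len(G) <= 20, 2, 1)
  y <- cbind(matrix(rnbinom(G * 3, mu = rep(mu, 3), size = 10), ncol = 3),
             matrix(rnbinom(G * 3, mu = rep(mu * fc, 3), size = 10), ncol = 3))
  dimnames(y) <- list(paste0("g", 1:G), paste0("s", 1:6))
  X <- cbind(1, rep(0:1, each = 3))
  off <- log(colSums(y))
  phi <- 0.1
  ours <- nb_glm_fit(y, design_matrix(X, off), phi)
  ef <- edgeR::glmFit(y, X, dispersion = phi, offset = off, prior.count = 0)
  expect_equal(unname(ours$beta), unname(ef$coefficients), tolerance = 1e-4)
  lr <- edgeR::glmLRT(ef, coef = 2)
  red <- nb_glm_fit(y, design_matrix(X[, 1, drop = FALSE], off), phi)
  stat <- lrt(ours, red, 1)$statistic
  expect_equal(unname(stat), unname(lr$table$LR), tolerance = 1e-3)
})

test_that("BH adjustment matches the step-up oracle and propagates NaN", {
  expect_equal(bh_adjust(1), 1)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(11)
  p <- runif(97)
  # independent sort-then-cummin oracle
  m <- length(p); o <- order(p, decreasing = TRUE)
  oracle <- pmin(1, cummin(m / (m:1) * p[o]))[order(o)]
  expect_equal(bh_adjust(p), oracle)
  expect_warning(bh_adjust(c(0.5, NaN)), "NaN")
  expect_error(bh_adjust(c(0.5, 2)), "0, 1")
})

test_that("Storey q-values estimate pi0 and reduce to BH when pi0 = 1", {
  r <- storey_qvalue(rep(1, 30))
  expect_equal(r$pi0, 1)
  expect_equal(r$q, rep(1, 30))
  set.seed(12)
  p <- runif(5000)
  r2 <- storey_qvalue(p)
  expect_gte(r2$pi0, 0.9); expect_lte(r2$pi0, 1.0)
  # forced pi0 = 1 equals BH exactly
  r3 <- storey_qvalue(p, pi0 = 1)
  expect_equal(r3$q, bh_adjust(p))
  # with estimated pi0 < 1, q <= BH everywhere; q monotone in p
  p4 <- c(runif(500, 0, 0.01), runif(1500))
  r4 <- storey_qvalue(p4)
  expect_lte(r4$pi0, 1)
  expect_true(all(r4$q <= bh_adjust(p4) + 1e-12))
  expect_true(all(diff(r4$q[order(p4)]) >= -1e-12))
})
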