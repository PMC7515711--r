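## Negative-binomial GLM engine.
##
## Everything here is vectorized across genes: one IRLS iteration updates all
## genes simultaneously, and the per-gene p x p normal equations are solved
## with an element-wise Cholesky whose scalar loops run over matrix entries
## (p <= ~6) while each operation is a length-G vector op.  The NB2
## parameterization is used throughout: Var(y) = mu + phi * mu^2.

PHI_MIN <- 1e-6
PHI_MAX <- 10

#' Construct a design matrix with offsets
#'
#' @param x samples-by-p numeric matrix (full column rank).
#' @param offset per-sample offset on the natural-log scale, typically
#'   `log(library size * normalization factor)`.
#' @return list of class `design_matrix` with elements `x` and `offset`.
#' @export
design_matrix <- function(x, offset = rep(0, nrow(x))) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (qr(x)$rank < ncol(x)) stop("design matrix is not full column rank")
  if (length(offset) == 1L) offset <- rep(offset, nrow(x))
  if (length(offset) != nrow(x) || any(!is.finite(offset)))
    stop("offset must be finite, one value per sample")
  structure(list(x = x, offset = as.numeric(offset)), class = "design_matrix")
}

as_design <- function(design, offset = NULL) {
  if (inherits(design, "design_matrix")) return(design)
  design_matrix(design, offset %||% rep(0, nrow(as.matrix(design))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## NB log-likelihood summed over samples, per gene.  phi may be scalar or
## per-gene; phi == 0 falls back to the Poisson limit.
nb_row_loglik <- function(y, mu, phi) {
  G <- nrow(y)
  if (length(phi) == 1L) phi <- rep(phi, G)
  ll <- matrix(0, G, ncol(y))
  pos <- phi > 0
  if (any(pos))
    ll[pos, ] <- stats::dnbinom(y[pos, , drop = FALSE], size = 1 / phi[pos],
                                mu = mu[pos, , drop = FALSE], log = TRUE)
  if (any(!pos))
    ll[!pos, ] <- stats::dpois(y[!pos, , drop = FALSE],
                               lambda = mu[!pos, , drop = FALSE], log = TRUE)
  rowSums(ll)
}

## Solve G symmetric positive-definite p x p systems A x = b at once.
## A: G x p x p array, b: G x p.  Returns list(x = G x p, logdet = G).
chol_solve_batch <- function(A, b) {
  G <- dim(A)[1L]; p <- dim(A)[2L]
  L <- array(0, dim(A))
  for (j in seq_len(p)) {
    s <- A[, j, j]
    if (j > 1L) for (k in seq_len(j - 1L)) s <- s - L[, j, k]^2
    L[, j, j] <- sqrt(pmax(s, 1e-12))
    if (j < p) for (i in (j + 1L):p) {
      s <- A[, i, j]
      if (j > 1L) for (k in seq_len(j - 1L)) s <- s - L[, i, k] * L[, j, k]
      L[, i, j] <- s / L[, j, j]
    }
  }
  z <- matrix(0, G, p)
  for (i in seq_len(p)) {
    s <- b[, i]
    if (i > 1L) for (k in seq_len(i - 1L)) s <- s - L[, i, k] * z[, k]
    z[, i] <- s / L[, i, i]
  }
  x <- matrix(0, G, p)
  for (i in rev(seq_len(p))) {
    s <- z[, i]
    if (i < p) for (k in (i + 1L):p) s <- s - L[, k, i] * x[, k]
    x[, i] <- s / L[, i, i]
  }
  logdet <- rep(0, G)
  for (j in seq_len(p)) logdet <- logdet + 2 * log(L[, j, j])
  list(x = x, logdet = logdet)
}

## IRLS fit of the NB GLM with log link for all genes at once.
## y: G x S counts; design: design_matrix; phi: scalar or length-G.
## Returns beta (G x p, natural log), mu, deviance, loglik, converged,
## iterations, logdet of X'WX at convergence (for Cox-Reid), boundary flag.
nb_glm_fit <- function(y, design, phi, beta_start = NULL,
                       maxit = 100L, tol = 1e-8) {
  design <- as_design(design)
  X <- design$x
  off <- matrix(design$offset, nrow(y), ncol(y), byrow = TRUE)
  G <- nrow(y); S <- ncol(y); p <- ncol(X)
  if (S - p < 0) stop("more coefficients than samples")
  XtX <- crossprod(X)
  if (is.null(beta_start)) {
    z0 <- log(y + 0.5) - off
    beta <- z0 %*% X %*% chol2inv(chol(XtX))
  } else beta <- beta_start

  ij <- which(upper.tri(matrix(0, p, p), diag = TRUE), arr.ind = TRUE)
  Xprod <- X[, ij[, 1L], drop = FALSE] * X[, ij[, 2L], drop = FALSE]  # S x p(p+1)/2

  sat_ll <- nb_row_loglik(y, pmax(y, 1e-10), phi)
  eta <- pmin(pmax(beta %*% t(X) + off, -30), 30)
  mu <- pmax(exp(eta), 1e-10)
  dev <- 2 * (sat_ll - nb_row_loglik(y, mu, phi))
  converged <- rep(FALSE, G)
  iter <- 0L
  A <- array(0, c(G, p, p))
  logdet <- rep(NA_real_, G)

  while (iter < maxit && !all(converged)) {
    iter <- iter + 1L
    W <- mu / (1 + phi * mu)                     # phi recycles per gene
    z <- (eta - off) + (y - mu) / mu
    Aflat <- W %*% Xprod                         # G x p(p+1)/2
    for (k in seq_len(nrow(ij))) {
      A[, ij[k, 1L], ij[k, 2L]] <- Aflat[, k]
      A[, ij[k, 2L], ij[k, 1L]] <- Aflat[, k]
    }
    Bmat <- (W * z) %*% X                        # G x p
    sol <- chol_solve_batch(A, Bmat)
    beta_prop <- sol$x
    logdet <- sol$logdet
    ## step-halving on genes whose deviance would increase
    step <- rep(1, G)
    delta <- beta_prop - beta
    for (h in seq_len(15L)) {
      beta_new <- beta + step * delta
      eta_new <- pmin(pmax(beta_new %*% t(X) + off, -30), 30)
      mu_new <- pmax(exp(eta_new), 1e-10)
      dev_new <- 2 * (sat_ll - nb_row_loglik(y, mu_new, phi))
      worse <- !is.finite(dev_new) | dev_new > dev + 1e-10
      if (!any(worse)) break
      step[worse] <- step[worse] / 2
    }
    converged <- abs(dev - dev_new) < tol * (abs(dev_new) + 0.1)
    beta <- beta_new; eta <- eta_new; mu <- mu_new; dev <- dev_new
  }
  colnames(beta) <- colnames(X)
  list(beta = beta, mu = mu, deviance = pmax(dev, 0),
       loglik = sat_ll - dev / 2, converged = converged,
       iterations = iter, logdet_xtwx = logdet,
       boundary = rowSums(y) == 0, design = design, phi = phi)
}

#' Fit a negative-binomial GLM to one gene's counts
#'
#' Maximizes the NB2 log-likelihood with log link and per-sample offsets by
#' iteratively reweighted least squares with step-halving; convergence when
#' the relative deviance change drops below `1e-8` (at most 100 iterations).
#'
#' @param counts_row per-sample counts (numeric vector).
#' @param design a [design_matrix()] (or plain samples-by-p matrix).
#' @param dispersion NB dispersion phi in `[0, 10]` (`Var = mu + phi mu^2`).
#' @param offset per-sample offset if `design` is a plain matrix.
#' @return list with `coefficients` (natural-log scale), `fitted`,
#'   `deviance`, `loglik`, `converged`, `iterations`, `boundary`.
#' @examples
#' X <- cbind(1, rep(0:1, each = 2))
#' fit_nb_glm(c(10, 12, 38, 42), X, dispersion = 0.1)$coefficients
#' @export
fit_nb_glm <- function(counts_row, design, dispersion, offset = NULL) {
  if (dispersion < 0 || dispersion > PHI_MAX)
    stop("dispersion must lie in [0, ", PHI_MAX, "]")
  design <- as_design(design, offset)
  f <- nb_glm_fit(matrix(counts_row, 1L), design, dispersion)
  list(coefficients = stats::setNames(drop(f$beta), colnames(design$x)),
       fitted = drop(f$mu), deviance = f$deviance, loglik = f$loglik,
       converged = f$converged, iterations = f$iterations,
       boundary = f$boundary, design = design, phi = dispersion)
}

## Cox-Reid adjusted profile log-likelihood for every gene at one phi.
apl_at <- function(y, design, phi, beta_start = NULL) {
  f <- nb_glm_fit(y, design, phi, beta_start = beta_start, maxit = 50L,
                  tol = 1e-6)
  list(apl = f$loglik - 0.5 * f$logdet_xtwx, beta = f$beta)
}

#' Estimate common and tagwise NB dispersions
#'
#' Uses the Cox-Reid adjusted profile likelihood (APL).  The common
#' dispersion maximizes the summed APL over a log-spaced grid followed by
#' golden-section refinement; tagwise dispersions maximize
#' `APL_g(phi) + w * mean_APL(phi)` with weight `w = prior_df / residual_df`,
#' which shrinks per-gene estimates toward the common value (exactly so as
#' `prior_df` grows).  All estimates are clamped to `[1e-6, 10]`.
#'
#' @param cm counts (a [count_matrix()] or genes-by-samples matrix).
#' @param design a [design_matrix()] (or plain matrix; zero offsets).
#' @param prior_df prior degrees of freedom for tagwise shrinkage
#'   (default 10).
#' @return list of class `dispersion_estimate`: `common`, `tagwise`,
#'   `prior_df`.
#' @export
estimate_dispersions <- function(cm, design, prior_df = 10) {
  y <- unclass(as.matrix(cm))
  design <- as_design(design)
  rdf <- ncol(y) - ncol(design$x)
  if (rdf < 1) stop("no replication: zero residual degrees of freedom")
  grid <- c(PHI_MIN, exp(seq(log(1e-4), log(PHI_MAX), length.out = 17L)))
  apl <- matrix(NA_real_, nrow(y), length(grid))
  beta <- NULL
  for (k in seq_along(grid)) {
    a <- apl_at(y, design, grid[k], beta_start = beta)
    apl[, k] <- a$apl
    beta <- a$beta
  }
  tot <- colSums(apl)
  k0 <- which.max(tot)
  lo <- log(grid[max(1L, k0 - 1L)]); hi <- log(grid[min(length(grid), k0 + 1L)])
  gr <- (sqrt(5) - 1) / 2
  fcache <- function(lphi) sum(apl_at(y, design, exp(lphi), beta_start = beta)$apl)
  a <- lo; b <- hi
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- fcache(c1); f2 <- fcache(c2)
  while (b - a > 0.02) {
    if (f1 < f2) { a <- c1; c1 <- c2; f1 <- f2; c2 <- a + gr * (b - a); f2 <- fcache(c2) }
    else { b <- c2; c2 <- c1; f2 <- f1; c1 <- b - gr * (b - a); f1 <- fcache(c1) }
  }
  common <- min(max(exp((a + b) / 2), PHI_MIN), PHI_MAX)

  w <- prior_df / rdf
  score <- apl + w * matrix(colMeans(apl), nrow(y), length(grid), byrow = TRUE)
  kbest <- max.col(score, ties.method = "first")
  lg <- log(grid)
  tagwise <- exp(lg[kbest])
  ## quadratic refinement in log-phi where an interior maximum exists
  interior <- kbest > 1L & kbest < length(grid)
  if (any(interior)) {
    i <- which(interior)
    km <- kbest[i]
    x1 <- lg[km - 1L]; x2 <- lg[km]; x3 <- lg[km + 1L]
    y1 <- score[cbind(i, km - 1L)]; y2 <- score[cbind(i, km)]
    y3 <- score[cbind(i, km + 1L)]
    denom <- (y1 - 2 * y2 + y3)
    vertex <- x2 - 0.5 * ((x3 - x2) * (y3 - y1)) / ifelse(abs(denom) < 1e-12, Inf, denom)
    vertex[!is.finite(vertex)] <- x2[!is.finite(vertex)]
    tagwise[i] <- exp(pmin(pmax(vertex, x1), x3))
  }
  tagwise <- pmin(pmax(tagwise, PHI_MIN), PHI_MAX)
  structure(list(common = common, tagwise = tagwise, prior_df = prior_df),
            class = "dispersion_estimate")
}

#' Likelihood-ratio test between nested NB GLM fits
#'
#' The statistic is the deviance difference (reduced minus full), clamped at
#' zero, referred to an upper-tail chi-square with `df` degrees of freedom.
#' Both fits must use the same dispersion; the reduced design must be nested
#' in the full design (checked by column-space projection).
#'
#' @param full,reduced fits from [nb_glm_fit()] / [fit_nb_glm()].
#' @param df positive integer degrees of freedom of the test.
#' @return list with `statistic` and `p` (vectors over genes).
#' @export
lrt <- function(full, reduced, df = 1L) {
  Xf <- full$design$x; Xr <- reduced$design$x
  proj <- Xf %*% qr.solve(Xf, Xr)
  if (max(abs(proj - Xr)) > 1e-8)
    stop("reduced design is not nested in the full design")
  stat <- reduced$deviance - full$deviance
  stat[stat < 0] <- 0
  list(statistic = stat, p = stats::pchisq(stat, df = df, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up adjustment, clamped to `[0, 1]`, monotone in p.  NaN
#' inputs propagate with a warning.
#'
#' @param p vector of p-values in `[0, 1]` (NaN allowed).
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(is.nan(p))) warning("NaN p-values propagated")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Storey q-values with smoother-based pi0 estimate
#'
#' pi0 is estimated from `#{p > lambda} / (m (1 - lambda))` on the lambda
#' grid 0.05, 0.10, ..., 0.95, smoothed with a cubic smoothing spline
#' (3 degrees of freedom) and evaluated at the largest lambda, clamped to
#' (0, 1].  Inputs shorter than 20 fall back to pi0 = 1, in which case the
#' q-values equal the Benjamini-Hochberg adjustment.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @param pi0 optionally force pi0 instead of estimating it.
#' @return list with `q` (same length as `p`) and `pi0`.
#' @export
storey_qvalue <- function(p, pi0 = NULL) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (is.null(pi0)) {
    if (m < 20L) pi0 <- 1
    else {
      lambda <- seq(0.05, 0.95, by = 0.05)
      pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
      fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
      pi0 <- stats::predict(fit, x = max(lambda))$y
      pi0 <- min(1, max(pi0, 1e-8))
    }
  }
  ord <- order(p, decreasing = TRUE)
  q <- numeric(m)
  running <- 1
  ranks <- rank(p, ties.method = "max")
  q_raw <- pmin(pi0 * p * m / ranks, 1)
  for (i in ord) {
    running <- min(running, q_raw[i])
    q[i] <- running
  }
  list(q = q, pi0 = pi0)
}

#' Trimmed-mean-of-M-values normalization factors
#'
#' Scaling factors correcting for library composition: pairwise log-ratios
#' (M) against a reference column are doubly trimmed (30% of M each tail,
#' 5% of average log-abundance A each tail) and averaged with asymptotic
#' precision weights.  The reference is the column whose upper quartile of
#' scaled counts is closest to the mean upper quartile.  Factors are
#' normalized to geometric mean 1.
#'
#' @param cm a [count_matrix()] or genes-by-samples matrix with >= 2 samples
#'   and no all-zero column.
#' @return named vector of positive factors, one per sample.
#' @export
compute_norm_factors <- function(cm) {
  y <- unclass(as.matrix(cm))
  libs <- colSums(y)
  if (any(libs == 0)) stop("all-zero column: ", colnames(y)[which(libs == 0)[1L]])
  if (ncol(y) < 2L) {
    warning("single sample: normalization factor set to 1")
    return(stats::setNames(1, colnames(y)))
  }
  uq <- apply(sweep(y, 2L, libs, "/"), 2L, stats::quantile, probs = 0.75)
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(y)), function(j) {
    if (j == ref) return(1)
    tmm_pair(y[, j], y[, ref], libs[j], libs[ref])
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(y))
}

tmm_pair <- function(obs, ref, n_obs, n_ref,
                     logratio_trim = 0.3, sum_trim = 0.05) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  if (!length(obs)) return(1)
  M <- log2((obs / n_obs) / (ref / n_ref))
  A <- 0.5 * log2((obs / n_obs) * (ref / n_ref))
  w <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  n <- length(M)
  loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
  loA <- floor(n * sum_trim) + 1;      hiA <- n + 1 - loA
  rM <- rank(M, ties.method = "first"); rA <- rank(A, ties.method = "first")
  keep2 <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(keep2)) return(1)
  2^(sum(M[keep2] / w[keep2]) / sum(1 / w[keep2]))
}
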