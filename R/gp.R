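#' Median-criterion kernel bandwidth
#'
#' `theta = 1 / (2 * median of all pairwise squared Euclidean row
#' distances)`.
#'
#' @param X numeric design matrix (N x J), N >= 2.
#' @return bandwidth (scalar > 0).
#' @export
median_bandwidth <- function(X) {
  if (nrow(X) < 2L) stop_("need at least 2 rows")
  med <- stats::median(stats::dist(X)^2)
  if (med <= 0) stop_("degenerate design: all rows identical")
  1 / (2 * med)
}

#' Radial basis function kernel matrix
#'
#' `K[i, i'] = exp(-theta * ||x_i - x_i'||^2)`.  A diagonal jitter is the
#' caller's concern (see [ess_sample()]).
#'
#' @param X numeric matrix (N x J).
#' @param theta bandwidth > 0.
#' @return N x N symmetric kernel matrix with unit diagonal.
#' @export
rbf_kernel <- function(X, theta) {
  if (theta <= 0) stop_("theta must be > 0")
  d2 <- as.matrix(stats::dist(X))^2
  K <- exp(-theta * d2)
  dimnames(K) <- NULL
  K
}

## log p(y | f) under the probit link: sum log Phi((2y-1) f)
probit_loglik <- function(f, y) {
  sum(stats::pnorm((2 * y - 1) * f, log.p = TRUE))
}

#' Elliptical slice sampler for the latent GP classifier
#'
#' Draws from `p(f | y) \propto Bernoulli-probit(y | f) * N(f; 0, K)`
#' with the rejection-free elliptical slice scheme: propose
#' `f' = f cos(a) + nu sin(a)` on the ellipse through the current state and
#' a prior draw `nu ~ N(0, K)`, shrinking the angle bracket until the
#' likelihood clears a log-uniform slice.
#'
#' @param K N x N kernel matrix.
#' @param y binary labels (length N).
#' @param n_iter total MCMC iterations.
#' @param burn_in iterations discarded (default half).
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param seed integer seed.
#' @param jitter initial diagonal jitter added before Cholesky; escalated
#'   x10 up to 1e-2 on failure.
#' @param log_lik log-likelihood function `f(f, y)`; the probit by default
#'   (swappable for prior-invariance checks).
#' @return S x N matrix of retained draws, with attribute `loglik`
#'   (post-burn-in trace).
#' @export
ess_sample <- function(K, y, n_iter = 10000, burn_in = floor(n_iter / 2),
                       thin = 10, seed = 1, jitter = 1e-6,
                       log_lik = probit_loglik) {
  N <- nrow(K)
  L <- NULL
  j <- jitter
  while (is.null(L) && j <= 1e-2) {
    L <- tryCatch(chol(K + diag(j, N)), error = function(e) NULL)
    if (is.null(L)) j <- j * 10
  }
  if (is.null(L)) stop_("kernel Cholesky failed even with jitter 1e-2")
  set.seed(seed)
  f <- drop(crossprod(L, stats::rnorm(N)))
  ll <- log_lik(f, y)
  keep <- seq(burn_in + thin, n_iter, by = thin)
  out <- matrix(0, length(keep), N)
  trace <- numeric(n_iter - burn_in)
  s <- 0L
  for (it in seq_len(n_iter)) {
    nu <- drop(crossprod(L, stats::rnorm(N)))
    log_u <- ll + log(stats::runif(1))
    a <- stats::runif(1, 0, 2 * pi)
    a_min <- a - 2 * pi
    a_max <- a
    repeat {
      f_new <- f * cos(a) + nu * sin(a)
      ll_new <- log_lik(f_new, y)
      if (ll_new > log_u) break
      if (a < 0) a_min <- a else a_max <- a
      a <- stats::runif(1, a_min, a_max)
    }
    f <- f_new
    ll <- ll_new
    if (it > burn_in) {
      trace[it - burn_in] <- ll
      if (it %in% keep) {
        s <- s + 1L
        out[s, ] <- f
      }
    }
  }
  attr(out, "loglik") <- trace
  attr(out, "jitter") <- j
  out
}

#' Project latent draws to per-feature effect sizes
#'
#' Each latent draw is mapped through the minimum-norm least-squares
#' solution `beta = pinv(X) f` (Moore-Penrose via SVD, relative singular
#' value cutoff `svd_tol`).  Posterior moments are empirical over draws;
#' the precision is the spectral pseudoinverse of the sample covariance
#' (relative eigenvalue cutoff `eig_tol`) — the covariance is necessarily
#' rank-deficient whenever J exceeds the number of draws, so a
#' pseudoinverse keeps the downstream divergences well-defined.
#'
#' The J x J covariance/precision are never formed here; they are held in
#' factored form (see [posterior_sigma()] / [posterior_lambda()]).
#'
#' @param X design matrix (N x J).
#' @param f_samples S x N matrix of latent draws (S >= 2).
#' @param svd_tol relative SVD cutoff for `pinv(X)`.
#' @param eig_tol relative eigenvalue cutoff for the precision.
#' @return A `dect_posterior`: `beta_samples` (S x J), `mu` (length J),
#'   and the spectral factors `V` (J x r), `evals` (length r) of the
#'   covariance.
#' @export
project_effects <- function(X, f_samples, svd_tol = 1e-10, eig_tol = 1e-8) {
  if (is.null(dim(f_samples))) f_samples <- matrix(f_samples, 1)
  S <- nrow(f_samples)
  if (S < 2L) stop_("need at least 2 draws for a covariance")
  sv <- svd(X)
  keep <- sv$d > svd_tol * max(sv$d)
  ## beta_s = V D^-1 U' f_s for all draws at once: (S x J)
  B <- f_samples %*% sv$u[, keep, drop = FALSE]
  B <- sweep(B, 2, sv$d[keep], "/")
  beta <- B %*% t(sv$v[, keep, drop = FALSE])
  mu <- colMeans(beta)
  Bc <- sweep(beta, 2, mu)
  sc <- svd(Bc, nu = 0)
  ev <- sc$d^2 / (S - 1)
  k2 <- ev > eig_tol * max(ev)
  structure(list(beta_samples = beta, mu = mu,
                 V = sc$v[, k2, drop = FALSE], evals = ev[k2]),
            class = "dect_posterior")
}

#' Build an effect posterior directly from effect draws
#'
#' Same empirical-moment and spectral-factor machinery as
#' [project_effects()], for cases where the effect samples are already in
#' hand (simulation studies, tests).
#'
#' @param beta_samples S x J matrix of effect draws (S >= 2).
#' @param eig_tol relative eigenvalue cutoff for the precision.
#' @return A `dect_posterior`.
#' @export
effect_posterior <- function(beta_samples, eig_tol = 1e-8) {
  S <- nrow(beta_samples)
  if (is.null(S) || S < 2L) stop_("need at least 2 draws")
  mu <- colMeans(beta_samples)
  Bc <- sweep(beta_samples, 2, mu)
  sc <- svd(Bc, nu = 0)
  ev <- sc$d^2 / (S - 1)
  k2 <- ev > eig_tol * max(ev)
  structure(list(beta_samples = beta_samples, mu = mu,
                 V = sc$v[, k2, drop = FALSE], evals = ev[k2]),
            class = "dect_posterior")
}

#' Posterior covariance matrix of the effects
#' @param post a `dect_posterior`.
#' @return J x J matrix `V diag(evals) V'` (small-J use; O(J^2) memory).
#' @export
posterior_sigma <- function(post)
  post$V %*% (t(post$V) * post$evals)

#' Posterior precision (spectral pseudoinverse of the covariance)
#' @param post a `dect_posterior`.
#' @return J x J matrix `V diag(1/evals) V'`.
#' @export
posterior_lambda <- function(post)
  post$V %*% (t(post$V) / post$evals)
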