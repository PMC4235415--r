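#' Model, prior and sampler configuration containers
#'
#' `lmm_spec()` bundles the data for the Gaussian mixed model
#' \eqn{y = X\beta + G u + \epsilon} with \eqn{u \sim N(0, \sigma^2_g I)} and
#' \eqn{\epsilon \sim N(0, \sigma^2_e I)}; `glmm_spec()` the Bernoulli-logit
#' analogue (no residual variance, dispersion fixed at 1). `prior_spec()`
#' holds the default priors: independent \eqn{N(0, 1/0.001)} on each fixed
#' effect and Gamma(1, 1) on each precision \eqn{\tau = 1/\sigma^2}.
#' `mcmc_config()` holds chain settings; the defaults (11,000 iterations,
#' 1000 burn-in, no thinning) are sufficient for convergence on data sets of
#' a few hundred families.
#'
#' @param y numeric (or 0/1 for `glmm_spec`) trait vector.
#' @param X design matrix including the intercept column; must be full
#'   column rank.
#' @param G a [block_decompose()] loading matrix.
#' @param off [family_offsets]; defaults to the offsets stored in `G`.
#' @return A list of class `lmm_spec` / `glmm_spec`.
#' @export
lmm_spec <- function(y, X, G, off = G$offsets) {
  check_spec_dims(y, X, G, off, binary = FALSE)
  structure(list(y = as.numeric(y), X = as.matrix(X), G = G, off = off),
            class = "lmm_spec")
}

#' @rdname lmm_spec
#' @export
glmm_spec <- function(y, X, G, off = G$offsets) {
  check_spec_dims(y, X, G, off, binary = TRUE)
  structure(list(y = as.integer(y), X = as.matrix(X), G = G, off = off),
            class = "glmm_spec")
}

check_spec_dims <- function(y, X, G, off, binary) {
  X <- as.matrix(X)
  stopifnot(inherits(G, "loading_matrix"), inherits(off, "family_offsets"))
  n <- off$N
  if (length(y) != n || nrow(X) != n)
    stop("y, X and offsets disagree on the number of individuals")
  if (binary && !all(y %in% c(0, 1)))
    stop("binary trait must contain only 0 and 1")
  if (qr(X)$rank < ncol(X))
    stop("design matrix X is rank deficient")
  invisible(TRUE)
}

#' @rdname lmm_spec
#' @param beta_mean,beta_precision normal prior mean and precision for each
#'   fixed effect.
#' @param tau_shape,tau_rate Gamma prior shape and rate for the precisions
#'   \eqn{\tau_e} and \eqn{\tau_g}.
#' @export
prior_spec <- function(beta_mean = 0, beta_precision = 0.001,
                       tau_shape = 1, tau_rate = 1) {
  stopifnot(beta_precision > 0, tau_shape > 0, tau_rate > 0)
  structure(list(beta_mean = beta_mean, beta_precision = beta_precision,
                 tau_shape = tau_shape, tau_rate = tau_rate),
            class = "prior_spec")
}

#' @rdname lmm_spec
#' @param n_iter total MCMC iterations.
#' @param burn_in iterations discarded from the start of the chain.
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param seed optional integer seed; seeded runs are bit-reproducible.
#' @export
mcmc_config <- function(n_iter = 11000L, burn_in = 1000L, thin = 1L,
                        seed = NULL) {
  n_iter <- as.integer(n_iter); burn_in <- as.integer(burn_in)
  thin <- as.integer(thin)
  stopifnot(n_iter > 0L, burn_in >= 0L, burn_in < n_iter, thin >= 1L)
  structure(list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                 seed = seed), class = "mcmc_config")
}

#' Gibbs sampler for the Gaussian family mixed model
#'
#' Samples the posterior of \eqn{(\beta, u, \tau_e, \tau_g)} under the
#' independent-effects parameterization \eqn{y = X\beta + G u + \epsilon} by
#' cycling the full conditionals in the fixed order
#' \eqn{\beta \to u \to \tau_e \to \tau_g}:
#' \itemize{
#'   \item \eqn{\beta \mid \cdot} multivariate normal with precision
#'     \eqn{\tau_e X^T X + P_0} (prior precision \eqn{P_0});
#'   \item \eqn{u_f \mid \cdot} per family, normal with precision
#'     \eqn{\tau_e G_f^T G_f + \tau_g I}. Since \eqn{G_f = U_f S_f^{1/2}},
#'     \eqn{G_f^T G_f = S_f} is diagonal and the update is componentwise;
#'   \item \eqn{\tau_e \mid \cdot \sim} Gamma(shape \eqn{a + n/2}, rate
#'     \eqn{b + \|y - X\beta - Gu\|^2/2});
#'   \item \eqn{\tau_g \mid \cdot \sim} Gamma(\eqn{a + N/2},
#'     \eqn{b + u^T u/2}).
#' }
#' The chain starts at the least-squares \eqn{\beta}, \eqn{u = 0},
#' \eqn{\tau_e = \tau_g = 1}. Derived draws \eqn{\sigma^2_g = 1/\tau_g},
#' \eqn{\sigma^2_e = 1/\tau_e} and the narrow-sense heritability
#' \eqn{h^2 = \sigma^2_g / (\sigma^2_g + \sigma^2_e)} are recorded per
#' iteration.
#'
#' @param spec an [lmm_spec()].
#' @param prior a [prior_spec()].
#' @param cfg an [mcmc_config()].
#' @return An `mcmc_draws` matrix (kept iterations by parameters) with
#'   columns for each fixed effect, `tau.g`, `tau.e`, `sigma.g2`,
#'   `sigma.e2` and `herit`.
#' @seealso [summarize_draws()], [fit_reml()]
#' @export
gibbs_lmm <- function(spec, prior = prior_spec(), cfg = mcmc_config()) {
  stopifnot(inherits(spec, "lmm_spec"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  y <- spec$y; X <- spec$X; off <- spec$off
  n <- length(y); p <- ncol(X); N <- off$N
  Gs <- loading_as_matrix(spec$G, sparse = TRUE)
  Gt <- Matrix::t(Gs)
  # G'G per block: diagonal (= the block eigenvalues) for spectral loadings;
  # fall back to a generic blockwise solve otherwise.
  GtG <- as.matrix(Gt %*% Gs)
  diag_GtG <- diag(GtG)
  diagonal_u <- max(abs(GtG - diag(diag_GtG, N))) < 1e-10

  XtX <- crossprod(X)
  P0 <- diag(prior$beta_precision, p)
  P0m <- prior$beta_precision * rep(prior$beta_mean, p)
  a <- prior$tau_shape; b <- prior$tau_rate

  beta <- qr.coef(qr(X), y)
  u <- numeric(N)
  tau_e <- 1; tau_g <- 1
  Gu <- numeric(N)

  kept <- seq.int(cfg$burn_in + 1L, cfg$n_iter, by = cfg$thin)
  cn <- c(colnames(X, do.NULL = FALSE, prefix = "b"),
          "tau.g", "tau.e", "sigma.g2", "sigma.e2", "herit")
  draws <- matrix(NA_real_, length(kept), length(cn),
                  dimnames = list(NULL, cn))
  k <- 0L
  for (it in seq_len(cfg$n_iter)) {
    # beta | .
    prec <- tau_e * XtX + P0
    L <- chol(prec)
    m <- backsolve(L, backsolve(L, tau_e * crossprod(X, y - Gu) + P0m,
                                transpose = TRUE))
    beta <- drop(m + backsolve(L, rnorm(p)))
    r <- y - drop(X %*% beta)
    # u | .
    g <- as.numeric(Gt %*% r)
    if (diagonal_u) {
      pr <- tau_e * diag_GtG + tau_g
      u <- tau_e * g / pr + rnorm(N) / sqrt(pr)
    } else {
      for (f in seq_len(off$n_fam)) {
        idx <- off$offsets[f]:(off$offsets[f + 1L] - 1L)
        Lf <- chol(tau_e * GtG[idx, idx] + diag(tau_g, length(idx)))
        mf <- backsolve(Lf, backsolve(Lf, tau_e * g[idx], transpose = TRUE))
        u[idx] <- mf + backsolve(Lf, rnorm(length(idx)))
      }
    }
    Gu <- as.numeric(Gs %*% u)
    # tau_e | .
    rss <- sum((r - Gu)^2)
    tau_e <- rgamma(1L, shape = a + n / 2, rate = b + rss / 2)
    # tau_g | .
    tau_g <- rgamma(1L, shape = a + N / 2, rate = b + sum(u^2) / 2)

    if (it > cfg$burn_in && (it - cfg$burn_in - 1L) %% cfg$thin == 0L) {
      k <- k + 1L
      sg2 <- 1 / tau_g; se2 <- 1 / tau_e
      draws[k, ] <- c(beta, tau_g, tau_e, sg2, se2, sg2 / (sg2 + se2))
    }
  }
  new_mcmc_draws(draws, cfg, p_fixed = p, model = "gaussian")
}

new_mcmc_draws <- function(draws, cfg, p_fixed, model) {
  structure(draws, class = c("mcmc_draws", "matrix"),
            n_iter = cfg$n_iter, burn_in = cfg$burn_in, thin = cfg$thin,
            seed = cfg$seed, p_fixed = p_fixed, model = model)
}

#' @export
print.mcmc_draws <- function(x, ...) {
  cat(sprintf("MCMC draws: %d kept iterations (%s model), %d parameters\n",
              nrow(x), attr(x, "model"), ncol(x)))
  print(summarize_draws(x))
  invisible(x)
}

#' Posterior summary table
#'
#' Point estimate (PE) = posterior mean, SE = posterior standard deviation,
#' and equal-tailed 95% credible interval (2.5 and 97.5 empirical
#' percentiles) for each sampled or derived parameter.
#'
#' @param draws an `mcmc_draws` object (or any matrix of draws with column
#'   names).
#' @return Data frame with columns `parameter`, `PE`, `SE`, `ci_lower`,
#'   `ci_upper`.
#' @export
summarize_draws <- function(draws) {
  m <- as.matrix(draws)
  if (nrow(m) == 0L) stop("no draws to summarize")
  qs <- apply(m, 2L, quantile, probs = c(0.025, 0.975), names = FALSE)
  data.frame(parameter = colnames(m),
             PE = colMeans(m),
             SE = apply(m, 2L, sd),
             ci_lower = qs[1L, ],
             ci_upper = qs[2L, ],
             row.names = NULL)
}

#' Narrow-sense heritability
#'
#' The proportion of phenotypic variance attributable to additive genetic
#' variance, \eqn{h^2 = \sigma^2_g / (\sigma^2_g + \sigma^2_e)}.
#'
#' @param sigma_g2 additive genetic variance (>= 0).
#' @param sigma_e2 residual variance (>= 0); not both zero.
#' @return Value in `[0, 1]`; vectorized over its arguments.
#' @examples
#' heritability(0.2837, 0.4877)
#' @export
heritability <- function(sigma_g2, sigma_e2) {
  if (any(sigma_g2 < 0) || any(sigma_e2 < 0))
    stop("variance components must be non-negative")
  if (any(sigma_g2 + sigma_e2 == 0))
    stop("heritability undefined when both variance components are zero")
  sigma_g2 / (sigma_g2 + sigma_e2)
}
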