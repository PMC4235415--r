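# Shared fixtures: tiny pedigrees and model objects built in code.

nuclear_ped <- function(fam = "fam1") {
  pedigree(id = paste0(fam, c("_fa", "_mo", "_o1", "_o2")),
           father = c(NA, NA, paste0(fam, "_fa"), paste0(fam, "_fa")),
           mother = c(NA, NA, paste0(fam, "_mo"), paste0(fam, "_mo")),
           sex = c(1, 2, 1, 2), family = fam)
}

# Two nuclear families of four: the 8-individual toy used by the posterior
# quadrature checks.
toy_two_family_ped <- function() {
  a <- as.data.frame(nuclear_ped("famA"))
  b <- as.data.frame(nuclear_ped("famB"))
  ab <- rbind(a, b)
  pedigree(id = ab$id, father = ab$father, mother = ab$mother,
           sex = ab$sex, family = ab$family)
}

loading_from_ped <- function(ped) {
  off <- family_offsets(ped)
  block_decompose(additive_matrix(kinship(ped)), off)
}

# Marginal log posterior (unnormalized) of the precisions for an
# intercept-only Gaussian model: beta and u integrated out analytically,
# y ~ N(0, (1/beta_prec) X X' + sigma_g2 A + sigma_e2 I), Gamma(a, b) priors
# on both precisions. Independent oracle: dense covariance + Cholesky.
log_post_tau <- function(tau_g, tau_e, y, X, A, prior) {
  Sigma <- tcrossprod(X) / prior$beta_precision + A / tau_g +
    diag(length(y)) / tau_e
  L <- chol(Sigma)
  q <- sum(backsolve(L, y, transpose = TRUE)^2)
  ld <- 2 * sum(log(diag(L)))
  -0.5 * (ld + q) +
    (prior$tau_shape - 1) * log(tau_g) - prior$tau_rate * tau_g +
    (prior$tau_shape - 1) * log(tau_e) - prior$tau_rate * tau_e
}

# Posterior means of (sigma_g2, sigma_e2, h2) by 2-D grid integration over
# (tau_g, tau_e) on a log-spaced grid.
quadrature_posterior_means <- function(y, X, A, prior,
                                       tau_lo = 0.02, tau_hi = 60,
                                       n_grid = 220) {
  lt <- seq(log(tau_lo), log(tau_hi), length.out = n_grid)
  tau <- exp(lt)
  lp <- outer(tau, tau, Vectorize(function(tg, te)
    log_post_tau(tg, te, y, X, A, prior)))
  # integrate in log space: weight includes the Jacobian tau_g * tau_e
  lw <- lp + log(tau)[row(lp)] + log(tau)[col(lp)]
  w <- exp(lw - max(lw))
  w <- w / sum(w)
  sg2 <- 1 / tau[row(lp)]
  se2 <- 1 / tau[col(lp)]
  c(sigma_g2 = sum(w * sg2), sigma_e2 = sum(w * se2),
    h2 = sum(w * sg2 / (sg2 + se2)))
}
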