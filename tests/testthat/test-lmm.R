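test_that("heritability ratio is correct and guarded", {
  expect_equal(heritability(0.2837, 0.4877), 0.2837 / (0.2837 + 0.4877))
  expect_equal(heritability(0, 2), 0)
  expect_equal(heritability(2, 0), 1)
  expect_equal(heritability(1, 1), 0.5)
  expect_error(heritability(-1, 1), "non-negative")
  expect_error(heritability(0, 0), "undefined")
})

test_that("posterior summaries implement PE/SE/95% CI conventions", {
  const <- matrix(2.5, 200, 1, dimnames = list(NULL, "theta"))
  sm <- summarize_draws(const)
  expect_equal(sm$PE, 2.5)
  expect_equal(sm$SE, 0)
  expect_equal(c(sm$ci_lower, sm$ci_upper), c(2.5, 2.5))

  m <- matrix(c(1, 2, 3, 4), 4, 1, dimnames = list(NULL, "x"))
  sm2 <- summarize_draws(m)
  expect_equal(sm2$PE, 2.5)
  expect_equal(sm2$SE, sd(1:4))

  # variance components treated as degenerate draws give the published-style
  # heritability point estimate
  h <- heritability(rep(0.2837, 10), rep(0.4877, 10))
  expect_equal(mean(h), 0.3677, tolerance = 1e-4 / 0.3677)

  expect_error(summarize_draws(matrix(numeric(0), 0, 1)), "no draws")
})

test_that("spec constructors validate dimensions and rank", {
  ped <- make_pedigree("nuclear", 2)
  G <- loading_from_ped(ped)
  y <- rnorm(8)
  expect_error(lmm_spec(y[1:4], matrix(1, 8, 1), G), "disagree")
  expect_error(lmm_spec(y, cbind(1, 1:8, 2 * (1:8)), G), "rank deficient")
  expect_error(glmm_spec(rep(2, 8), matrix(1, 8, 1), G), "0 and 1")
  expect_silent(lmm_spec(y, matrix(1, 8, 1), G))
})

test_that("with no genetic component the beta/tau_e posterior matches a
           1-D quadrature oracle", {
  set.seed(301)
  n <- 60L
  ped <- pedigree(id = sprintf("i%02d", 1:n), father = NA, mother = NA,
                  family = "f1")
  off <- family_offsets(ped)
  # zero loading matrix: the polygenic term drops out of the likelihood
  Gz <- block_decompose(matrix(0, n, n), off)
  X <- cbind(1, rnorm(n))
  y <- drop(X %*% c(1, -2)) + rnorm(n, sd = sqrt(0.5))
  spec <- lmm_spec(y, X, Gz)
  pr <- prior_spec()
  dr <- gibbs_lmm(spec, pr, mcmc_config(22000, 2000, seed = 302))

  # oracle: p(tau_e | y) on a grid, beta integrated out analytically
  lt <- seq(log(0.05), log(40), length.out = 400)
  taus <- exp(lt)
  lp <- vapply(taus, function(te) {
    Sigma <- tcrossprod(X) / pr$beta_precision + diag(n) / te
    L <- chol(Sigma)
    -0.5 * (2 * sum(log(diag(L))) +
              sum(backsolve(L, y, transpose = TRUE)^2)) +
      (pr$tau_shape - 1) * log(te) - pr$tau_rate * te + log(te)
  }, numeric(1))
  w <- exp(lp - max(lp)); w <- w / sum(w)
  se2_exact <- sum(w / taus)
  expect_lt(abs(mean(dr[, "sigma.e2"]) - se2_exact), 0.02)

  # beta | tau_e is normal; posterior mean from iterated expectation
  bmeans <- sapply(taus, function(te) {
    P <- te * crossprod(X) + diag(pr$beta_precision, 2)
    solve(P, te * crossprod(X, y))
  })
  b_exact <- drop(bmeans %*% w)
  expect_lt(max(abs(colMeans(dr[, 1:2]) - b_exact)), 0.02)
})

test_that("gibbs sampler recovers variance components on a two-trios design", {
  ped <- make_pedigree("two_trios", 100)
  y <- simulate_gaussian(ped, sigma_g2 = 2, sigma_e2 = 1, seed = 42)
  G <- loading_from_ped(ped)
  spec <- lmm_spec(y, matrix(1, 600, 1), G)
  dr <- gibbs_lmm(spec, cfg = mcmc_config(6000, 1000, seed = 7))
  sm <- summarize_draws(dr)
  sg <- sm[sm$parameter == "sigma.g2", ]
  se <- sm[sm$parameter == "sigma.e2", ]
  expect_lt(abs(sg$PE - 2), 3 * sg$SE)
  expect_lt(abs(se$PE - 1), 3 * se$SE)
  # per-draw identity and positivity
  expect_equal(unname(dr[, "herit"]),
               unname(dr[, "sigma.g2"] /
                        (dr[, "sigma.g2"] + dr[, "sigma.e2"])))
  expect_true(all(dr[, c("sigma.g2", "sigma.e2")] > 0))
})

test_that("seeded chains are bit-reproducible", {
  ped <- make_pedigree("nuclear", 10)
  y <- simulate_gaussian(ped, 1, 1, seed = 1)
  spec <- lmm_spec(y, matrix(1, 40, 1), loading_from_ped(ped))
  d1 <- gibbs_lmm(spec, cfg = mcmc_config(500, 100, seed = 99))
  d2 <- gibbs_lmm(spec, cfg = mcmc_config(500, 100, seed = 99))
  expect_identical(as.matrix(d1), as.matrix(d2))
})
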