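test_that("scenario pedigrees have the designed structure", {
  ped <- make_pedigree("nuclear", 3)
  expect_equal(sum(ped$sampled), 12L)
  expect_equal(length(unique(ped$family)), 3L)

  ped2 <- make_pedigree("two_trios", 2)
  expect_equal(sum(ped2$sampled), 12L)
  expect_equal(sum(!ped2$sampled), 4L)  # two phantom founders per family

  # asymmetric family carries first-, second- and third-degree sampled pairs
  K <- kinship(make_pedigree("asymmetric", 1))
  expect_equal(sum(ped$sampled[ped$family == ped$family[1]]), 4L)
  expect_true(any(abs(K - 0.25) < 1e-12))    # parent-offspring / sibs
  expect_true(any(abs(K - 0.125) < 1e-12))   # avuncular
  expect_true(any(abs(K - 0.0625) < 1e-12))  # first cousins
  expect_equal(nrow(K), 15L)

  comb <- make_pedigree("combination", 5)
  sizes <- table(comb$family[comb$sampled])
  expect_setequal(as.integer(sizes), c(4L, 10L))
  expect_error(make_pedigree("nuclear", 0), "n_fam")
})

test_that("gaussian simulator: independence limit and seeding", {
  ped <- make_pedigree("nuclear", 300)
  y0 <- simulate_gaussian(ped, sigma_g2 = 0, sigma_e2 = 1, seed = 5)
  sib1 <- y0[seq(3, 1200, by = 4)]
  sib2 <- y0[seq(4, 1200, by = 4)]
  # sigma_g2 = 0: sibs uncorrelated; cov SE ~ 1/sqrt(R)
  expect_lt(abs(mean(sib1 * sib2) - mean(sib1) * mean(sib2)),
            3 / sqrt(300))
  expect_identical(y0, simulate_gaussian(ped, 0, 1, seed = 5))
  expect_false(identical(y0, simulate_gaussian(ped, 0, 1, seed = 6)))

  X <- cbind(1, rnorm(1200))
  ym <- simulate_gaussian(ped, 0, 1, X = X, beta = c(10, 2), seed = 5)
  expect_equal(unname(ym - y0), drop(X %*% c(10, 2)))
})

test_that("gaussian simulator covariance matches sigma_e2 I + sigma_g2 A", {
  # many replicate nuclear families = replicate draws of one 4x4 block
  sg2 <- 1; se2 <- 1
  reps <- 20L; nf <- 500L
  sibcov <- fampairs <- numeric(0)
  mats <- vector("list", reps)
  for (r in seq_len(reps)) {
    ped <- make_pedigree("nuclear", nf)
    y <- simulate_gaussian(ped, sg2, se2, seed = 100 + r)
    mats[[r]] <- matrix(y, nrow = 4)  # columns are iid family draws
  }
  Y <- do.call(cbind, mats)
  R <- ncol(Y)
  emp <- tcrossprod(Y) / R
  A4 <- additive_matrix(kinship(make_pedigree("nuclear", 1)))
  target <- se2 * diag(4) + sg2 * unname(A4)
  se <- sqrt((outer(diag(target), diag(target)) + target^2) / R)
  expect_true(all(abs(emp - target) <= 3 * se))
  # the Fig-1-style oracle: sib-sib covariance = 2 k sigma_g2 = 0.5
  expect_lt(abs(emp[3, 4] - 2 * 0.25 * sg2), 3 * se[3, 4])
})

test_that("binary simulator prevalence follows the inverse logit", {
  ped <- make_pedigree("nuclear", 1500)
  n <- 6000L
  X <- matrix(1, n, 1)
  y <- simulate_binary(ped, sigma_g2 = 0, X = X, beta = 0, seed = 9)
  expect_lt(abs(mean(y) - 0.5), 3 * sqrt(0.25 / n))
  y2 <- simulate_binary(ped, sigma_g2 = 0, X = X, beta = -5, seed = 9)
  p <- plogis(-5)
  expect_lt(abs(mean(y2) - p), 3 * sqrt(p * (1 - p) / n))
  expect_identical(y2, simulate_binary(ped, 0, X, -5, seed = 9))
})

test_that("large genetic variance induces within-family case clustering", {
  ped <- make_pedigree("nuclear", 1000)
  X <- matrix(1, 4000, 1)
  sib1 <- sib2 <- integer(0)
  for (s in 21:23) {
    y <- simulate_binary(ped, sigma_g2 = 2, X = X, beta = 0, seed = s)
    ym <- matrix(y, nrow = 4)
    sib1 <- c(sib1, ym[3, ]); sib2 <- c(sib2, ym[4, ])
  }
  within <- mean(sib1 == sib2)
  between <- mean(sib1 == sib2[sample(length(sib2))])
  expect_gt(within, between)
})

test_that("simulator rejects invalid variances", {
  ped <- make_pedigree("nuclear", 1)
  expect_error(simulate_gaussian(ped, -1, 1), "sigma_g2")
  expect_error(simulate_gaussian(ped, 1, -1), "sigma_e2")
})
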