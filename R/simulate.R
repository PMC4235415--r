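#' Generate a scenario pedigree
#'
#' Builds replicated pedigrees for four standard family designs used to
#' evaluate variance-component estimators:
#' \describe{
#'   \item{`nuclear`}{a couple with two offspring; 4 sampled per family.}
#'   \item{`two_trios`}{two parent-offspring trios whose two linked parents
#'     are full siblings (siblinghood encoded by two phantom, unsampled
#'     founder grandparents); 6 sampled per family. First-, second- and
#'     third-degree relative pairs are all present.}
#'   \item{`asymmetric`}{same linkage but the first trio has 1 offspring and
#'     the second 10; 15 sampled per family.}
#'   \item{`combination`}{`n_fam` nuclear families plus `n_fam` extended
#'     families of two linked trios with 3 offspring each (10 sampled per
#'     extended family).}
#' }
#' At `n_fam = 100` the sampled totals are 400, 600, 1500 and 1400.
#'
#' @param scenario one of `"nuclear"`, `"two_trios"`, `"asymmetric"`,
#'   `"combination"`.
#' @param n_fam number of families (per sub-design for `combination`).
#' @return A [pedigree]; phantom grandparents have `sampled = FALSE`.
#' @export
make_pedigree <- function(scenario = c("nuclear", "two_trios", "asymmetric",
                                       "combination"),
                          n_fam = 100L) {
  scenario <- match.arg(scenario)
  n_fam <- as.integer(n_fam)
  if (n_fam < 1L) stop("n_fam must be >= 1")
  build <- switch(scenario,
    nuclear = function(pre, k) nuclear_family(sprintf("%s%03d", pre, k)),
    two_trios = function(pre, k) linked_trios(sprintf("%s%03d", pre, k), 1L, 1L),
    asymmetric = function(pre, k) linked_trios(sprintf("%s%03d", pre, k), 1L, 10L),
    combination = NULL)
  recs <- if (scenario == "combination") {
    c(lapply(seq_len(n_fam), function(k) nuclear_family(sprintf("N%03d", k))),
      lapply(seq_len(n_fam), function(k) linked_trios(sprintf("E%03d", k), 3L, 3L)))
  } else {
    lapply(seq_len(n_fam), function(k) build("F", k))
  }
  recs <- do.call(rbind, recs)
  pedigree(id = recs$id, father = recs$father, mother = recs$mother,
           sex = recs$sex, family = recs$family, sampled = recs$sampled)
}

nuclear_family <- function(fam) {
  data.frame(
    id = paste0(fam, "_", c("fa", "mo", "o1", "o2")),
    father = c(NA, NA, paste0(fam, "_fa"), paste0(fam, "_fa")),
    mother = c(NA, NA, paste0(fam, "_mo"), paste0(fam, "_mo")),
    sex = c(1L, 2L, 1L, 2L), family = fam, sampled = TRUE,
    stringsAsFactors = FALSE)
}

# Two parent-offspring trios linked through a full-sib pair (s1, s2) in the
# parent generation; the siblinghood is carried by phantom founders gf/gm.
linked_trios <- function(fam, n_off1, n_off2) {
  p <- function(x) paste0(fam, "_", x)
  base <- data.frame(
    id = p(c("gf", "gm", "s1", "s2", "sp1", "sp2")),
    father = c(NA, NA, p("gf"), p("gf"), NA, NA),
    mother = c(NA, NA, p("gm"), p("gm"), NA, NA),
    sex = c(1L, 2L, 1L, 1L, 2L, 2L), family = fam,
    sampled = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  off <- function(trio, n) {
    if (n == 0L) return(NULL)
    data.frame(id = p(sprintf("t%do%02d", trio, seq_len(n))),
               father = p(paste0("s", trio)),
               mother = p(paste0("sp", trio)),
               sex = rep_len(c(1L, 2L), n), family = fam, sampled = TRUE,
               stringsAsFactors = FALSE)
  }
  rbind(base, off(1L, n_off1), off(2L, n_off2))
}

#' Default generating variances for a scenario
#'
#' Assumed generating values for the simulation study: `(sigma_g2, sigma_e2)`
#' of (1, 1) for the nuclear and asymmetric designs and (2, 1) for the
#' two-trios and combination designs. These are stated assumptions consistent
#' in magnitude with typical variance-component recovery experiments on these
#' designs, not estimates.
#'
#' @param scenario scenario name as in [make_pedigree()].
#' @return list with `sigma_g2`, `sigma_e2`.
#' @export
scenario_defaults <- function(scenario = c("nuclear", "two_trios",
                                           "asymmetric", "combination")) {
  scenario <- match.arg(scenario)
  switch(scenario,
         nuclear = list(sigma_g2 = 1, sigma_e2 = 1),
         two_trios = list(sigma_g2 = 2, sigma_e2 = 1),
         asymmetric = list(sigma_g2 = 1, sigma_e2 = 1),
         combination = list(sigma_g2 = 2, sigma_e2 = 1))
}

#' Simulate a Gaussian polygenic trait on a pedigree
#'
#' Draws \eqn{Y = X\beta + U D^{1/2} Z} per family block, where \eqn{(U, D)}
#' is the spectral decomposition of the block of
#' \eqn{V = \sigma^2_e I + 2\sigma^2_g K} and \eqn{Z} is i.i.d. standard
#' normal, so that \eqn{Var(Y) = V} exactly.
#'
#' @param ped a [pedigree].
#' @param sigma_g2,sigma_e2 genetic and residual variances (trait units^2).
#' @param X optional design matrix over sampled individuals; with `beta`
#'   absent or `X = NULL` the trait has mean zero.
#' @param beta fixed-effect vector matching `ncol(X)`.
#' @param seed optional integer seed.
#' @return Named numeric vector over sampled individuals.
#' @export
simulate_gaussian <- function(ped, sigma_g2, sigma_e2, X = NULL, beta = NULL,
                              seed = NULL) {
  check_variances(sigma_g2, sigma_e2)
  if (!is.null(seed)) set.seed(seed)
  K <- kinship(ped)
  off <- family_offsets(ped)
  n <- off$N
  y <- numeric(n)
  for (f in seq_len(off$n_fam)) {
    idx <- off$offsets[f]:(off$offsets[f + 1L] - 1L)
    Vf <- sigma_e2 * diag(length(idx)) + 2 * sigma_g2 * K[idx, idx]
    eg <- eigen(Vf, symmetric = TRUE)
    d <- pmax(eg$values, 0)
    z <- rnorm(length(idx))
    y[idx] <- eg$vectors %*% (sqrt(d) * z)
  }
  if (!is.null(X)) {
    X <- as.matrix(X)
    stopifnot(nrow(X) == n, length(beta) == ncol(X))
    y <- y + drop(X %*% beta)
  }
  names(y) <- rownames(K)
  y
}

#' Simulate a binary polygenic trait (logit link)
#'
#' Draws independent effects \eqn{u \sim N(0, \sigma^2_g I)}, forms the
#' linear predictor \eqn{\eta = X\beta + G u} on the log-odds scale with
#' \eqn{G} the per-family loading matrix, and samples
#' \eqn{y_j \sim Bernoulli(logit^{-1}(\eta_j))}. The Bernoulli dispersion is
#' fixed at 1.
#'
#' @inheritParams simulate_gaussian
#' @param X design matrix including an intercept column.
#' @return Named integer vector of 0/1 over sampled individuals.
#' @export
simulate_binary <- function(ped, sigma_g2, X, beta, seed = NULL) {
  check_variances(sigma_g2, 0)
  if (!is.null(seed)) set.seed(seed)
  K <- kinship(ped)
  off <- family_offsets(ped)
  X <- as.matrix(X)
  stopifnot(nrow(X) == off$N, length(beta) == ncol(X))
  G <- block_decompose(additive_matrix(K), off)
  u <- rnorm(off$N, sd = sqrt(sigma_g2))
  eta <- drop(X %*% beta)
  for (f in seq_len(off$n_fam)) {
    idx <- off$offsets[f]:(off$offsets[f + 1L] - 1L)
    eta[idx] <- eta[idx] + drop(G$blocks[[f]] %*% u[idx])
  }
  y <- rbinom(off$N, 1L, plogis(eta))
  names(y) <- rownames(K)
  y
}

check_variances <- function(sigma_g2, sigma_e2) {
  if (!is.finite(sigma_g2) || sigma_g2 < 0)
    stop("sigma_g2 must be a non-negative number")
  if (!is.finite(sigma_e2) || sigma_e2 < 0)
    stop("sigma_e2 must be a non-negative number")
  invisible(TRUE)
}
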