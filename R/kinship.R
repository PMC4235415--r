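#' Kinship matrix from a pedigree
#'
#' Computes the kinship coefficient \eqn{\phi_{ij}} — the probability that two
#' alleles, one drawn at random from each of \eqn{i} and \eqn{j} at the same
#' autosomal locus, are identical by descent — by the standard recursion over
#' a topologically sorted pedigree: founders are non-inbred and mutually
#' unrelated (\eqn{\phi_{ii} = 1/2}), \eqn{\phi_{ii} = (1 + \phi_{fm})/2}
#' where \eqn{f, m} are \eqn{i}'s parents, and
#' \eqn{\phi_{ij} = (\phi_{fj} + \phi_{mj})/2} for any \eqn{j} that is not a
#' descendant of \eqn{i}. Phantom connecting ancestors participate in the
#' recursion; the returned matrix is restricted to sampled individuals.
#' Individuals from different families have kinship zero.
#'
#' @param ped a [pedigree] in construction order (the constructor sorts;
#'   a pedigree whose parents do not precede their children is an error —
#'   the numeric kernel never re-sorts silently).
#' @return Symmetric matrix of kinship coefficients indexed by the sampled
#'   individuals' ids, block-diagonal by family.
#' @seealso [additive_matrix()], [gene_drop_kinship()]
#' @export
kinship <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  fa <- match(ped$father, ped$id)
  mo <- match(ped$mother, ped$id)
  if (any(stats::na.omit(fa - seq_along(fa)) >= 0) ||
      any(stats::na.omit(mo - seq_along(mo)) >= 0))
    stop("pedigree is not topologically sorted (parents must precede children)")
  keep <- which(ped$sampled)
  ns <- length(keep)
  K <- matrix(0, ns, ns, dimnames = list(ped$id[keep], ped$id[keep]))
  pos <- integer(nrow(ped))  # position of each sampled individual in K
  pos[keep] <- seq_len(ns)
  # recursion runs family by family over all members (phantoms included);
  # families are unrelated, so the result is block-diagonal.
  for (members in split(seq_len(nrow(ped)), factor(ped$family,
                                                   unique(ped$family)))) {
    m <- length(members)
    lfa <- match(fa[members], members)
    lmo <- match(mo[members], members)
    phi <- matrix(0, m, m)
    for (i in seq_len(m)) {
      if (is.na(lfa[i])) {
        phi[i, i] <- 0.5
      } else {
        phi[i, i] <- 0.5 * (1 + phi[lfa[i], lmo[i]])
        if (i > 1L) {
          j <- seq_len(i - 1L)
          phi[i, j] <- phi[j, i] <- 0.5 * (phi[lfa[i], j] + phi[lmo[i], j])
        }
      }
    }
    samp <- which(ped$sampled[members])
    K[pos[members[samp]], pos[members[samp]]] <- phi[samp, samp]
  }
  K
}

#' Additive genetic relationship matrix
#'
#' The additive relationship matrix is twice the kinship matrix,
#' \eqn{A = 2K}; under the polygenic model the phenotypic covariance of
#' relatives \eqn{i, j} is \eqn{2 k_{ij} \sigma^2_g}. For a non-inbred
#' individual \eqn{A_{ii} = 1}.
#'
#' @param K kinship matrix as returned by [kinship()].
#' @return The matrix `2 * K`, same dimnames and ordering.
#' @export
additive_matrix <- function(K) {
  stopifnot(is.matrix(K), nrow(K) == ncol(K))
  2 * K
}

#' Monte Carlo kinship by gene dropping
#'
#' Independent check of the recursive kinship computation. Each replicate
#' assigns every founder two unique alleles and transmits one allele per
#' parent to each child down the (topologically sorted) pedigree. The kinship
#' estimate for a pair is the average, over replicates, of the probability
#' that one allele drawn from each is identical by descent (the mean of the
#' four allele-pair identity indicators).
#'
#' Deliberately shares no code with [kinship()]: it is a simulation oracle,
#' suitable for pedigrees of modest size.
#'
#' @param ped a [pedigree].
#' @param n_drop number of gene-dropping replicates.
#' @param seed optional integer seed.
#' @param chunk replicates per vectorized chunk (memory control).
#' @return List with `estimate` (matrix over sampled individuals) and
#'   `n_drop`; the binomial standard error of entry \eqn{\hat\phi} is
#'   about `sqrt(phi * (1 - phi) / n_drop)`.
#' @export
gene_drop_kinship <- function(ped, n_drop = 1e5, seed = NULL, chunk = 5e4) {
  stopifnot(inherits(ped, "pedigree"))
  if (!is.null(seed)) set.seed(seed)
  fa <- match(ped$father, ped$id)
  mo <- match(ped$mother, ped$id)
  if (any(stats::na.omit(fa - seq_along(fa)) >= 0))
    stop("pedigree is not topologically sorted")
  n <- nrow(ped)
  keep <- which(ped$sampled)
  acc <- matrix(0, length(keep), length(keep))
  done <- 0
  while (done < n_drop) {
    R <- min(chunk, n_drop - done)
    a1 <- matrix(0L, R, n)
    a2 <- matrix(0L, R, n)
    lab <- 0L
    for (i in seq_len(n)) {
      if (is.na(fa[i])) {
        a1[, i] <- lab + 1L
        a2[, i] <- lab + 2L
        lab <- lab + 2L
      } else {
        pick_f <- runif(R) < 0.5
        pick_m <- runif(R) < 0.5
        a1[, i] <- ifelse(pick_f, a1[, fa[i]], a2[, fa[i]])
        a2[, i] <- ifelse(pick_m, a1[, mo[i]], a2[, mo[i]])
      }
    }
    for (ii in seq_along(keep)) {
      for (jj in ii:length(keep)) {
        i <- keep[ii]; j <- keep[jj]
        p <- (as.numeric(a1[, i] == a1[, j]) + (a1[, i] == a2[, j]) +
              (a2[, i] == a1[, j]) + (a2[, i] == a2[, j])) / 4
        s <- sum(p)
        acc[ii, jj] <- acc[ii, jj] + s
        if (jj > ii) acc[jj, ii] <- acc[jj, ii] + s
      }
    }
    done <- done + R
  }
  est <- acc / n_drop
  dimnames(est) <- list(ped$id[keep], ped$id[keep])
  list(estimate = est, n_drop = n_drop)
}
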