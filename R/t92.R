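## Tamura (1992) substitution model with equilibrium GC content theta and
## transition/transversion ratio kappa.  States are ordered A, C, G, T
## throughout; stationary frequencies are ((1-theta)/2, theta/2, theta/2,
## (1-theta)/2).  The nonhomogeneous thermometer model attaches one theta to
## every branch (and one to the root) with a single global kappa.

NUC_STATES <- c("A", "C", "G", "T")

#' Stationary distribution of the T92 model
#'
#' @param theta equilibrium GC fraction in (0, 1).
#' @return numeric vector of frequencies for A, C, G, T.
#' @export
t92_stationary <- function(theta) {
  stopifnot(theta > 0, theta < 1)
  c(A = (1 - theta) / 2, C = theta / 2, G = theta / 2, T = (1 - theta) / 2)
}

#' T92 rate matrix
#'
#' Builds the 4x4 generator with off-diagonal rates proportional to
#' `kappa * pi_j` for transitions (A<->G, C<->T) and `pi_j` for
#' transversions, scaled so that the expected substitution rate at the
#' model's own stationary distribution is 1 (branch lengths keep their
#' substitutions/site meaning).
#'
#' @param theta equilibrium GC fraction in (0, 1).
#' @param kappa transition/transversion ratio (> 0).
#' @return 4x4 generator matrix with rows/columns A, C, G, T.
#' @export
t92_generator <- function(theta, kappa) {
  stopifnot(theta > 0, theta < 1, kappa > 0)
  pi <- t92_stationary(theta)
  is_transition <- matrix(FALSE, 4, 4, dimnames = list(NUC_STATES, NUC_STATES))
  is_transition["A", "G"] <- is_transition["G", "A"] <- TRUE
  is_transition["C", "T"] <- is_transition["T", "C"] <- TRUE
  Q <- matrix(rep(pi, each = 4), 4, 4, dimnames = list(NUC_STATES, NUC_STATES))
  Q[is_transition] <- Q[is_transition] * kappa
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  rate <- -sum(pi * diag(Q))
  Q / rate
}

## Closed-form T92 transition probabilities P[parent, child] after branch
## length t substitutions/site (special case of the Tamura-Nei solution with
## purine and pyrimidine contents both 1/2).  Used instead of a matrix
## exponential in the likelihood inner loop.
t92_transition <- function(theta, kappa, t) {
  pi <- t92_stationary(theta)
  beta <- 1 / (kappa * theta * (1 - theta) + 0.5)   # normalizing transversion rate
  alpha <- kappa * beta
  e1 <- exp(-beta * t)
  e2 <- exp(-0.5 * (alpha + beta) * t)
  P <- matrix(0, 4, 4, dimnames = list(NUC_STATES, NUC_STATES))
  piA <- pi[["A"]]; piC <- pi[["C"]]; piG <- pi[["G"]]; piT <- pi[["T"]]
  # transversions
  P["A", "C"] <- P["G", "C"] <- piC * (1 - e1)
  P["A", "T"] <- P["G", "T"] <- piT * (1 - e1)
  P["C", "A"] <- P["T", "A"] <- piA * (1 - e1)
  P["C", "G"] <- P["T", "G"] <- piG * (1 - e1)
  # within purines
  P["A", "G"] <- piG * (1 + e1) - 2 * piG * e2
  P["G", "A"] <- piA * (1 + e1) - 2 * piA * e2
  P["A", "A"] <- piA * (1 + e1) + 2 * piG * e2
  P["G", "G"] <- piG * (1 + e1) + 2 * piA * e2
  # within pyrimidines
  P["C", "T"] <- piT * (1 + e1) - 2 * piT * e2
  P["T", "C"] <- piC * (1 + e1) - 2 * piC * e2
  P["C", "C"] <- piC * (1 + e1) + 2 * piT * e2
  P["T", "T"] <- piT * (1 + e1) + 2 * piC * e2
  P
}

#' Transition probability matrix of a generator
#'
#' Matrix exponential `expm(Q t)` for an arbitrary rate matrix, via
#' eigendecomposition with a Pade ([Matrix::expm()]) fallback when the
#' generator is defective or the reconstruction is inaccurate.
#'
#' @param Q square generator matrix (rows summing to 0).
#' @param t branch length, `t >= 0`.
#' @return stochastic matrix of the same dimension.
#' @export
transition_matrix <- function(Q, t) {
  stopifnot(is.matrix(Q), nrow(Q) == ncol(Q), t >= 0)
  if (t == 0) {
    P <- diag(nrow(Q))
    dimnames(P) <- dimnames(Q)
    return(P)
  }
  P <- NULL
  eg <- tryCatch(eigen(Q), error = function(e) NULL)
  if (!is.null(eg) && !anyNA(eg$values)) {
    Vinv <- tryCatch(solve(eg$vectors), error = function(e) NULL)
    if (!is.null(Vinv)) {
      recon <- Re(eg$vectors %*% (eg$values * Vinv))
      if (max(abs(recon - Q)) < 1e-9 * max(1, max(abs(Q)))) {
        P <- Re(eg$vectors %*% (exp(eg$values * t) * Vinv))
      }
    }
  }
  if (is.null(P)) {
    P <- as.matrix(Matrix::expm(Q * t))
  }
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- dimnames(Q)
  P
}
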