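# Evolutionary dynamics of cultural transmission: the replicator
# equation with mutation, its neutral (equal-fitness) linearisation,
# mutation matrices induced by Bayesian posterior-sampling learners on
# enumerable hypothesis spaces, and the iterated-learning Markov chain.
#
# Orientation convention: Q is COLUMN-stochastic, Q[i, j] = probability
# a learner adopts hypothesis i after learning from a teacher holding
# hypothesis j. The literature is split on this; all functions here
# assume columns sum to one.

#' Total variation distance between two distributions
#'
#' @param p,q probability vectors of equal length.
#' @return `0.5 * sum(abs(p - q))`.
#' @export
tv_distance <- function(p, q) {
  stopifnot(length(p) == length(q))
  0.5 * sum(abs(p - q))
}

check_column_stochastic <- function(Q, tol = 1e-8) {
  if (!is.matrix(Q) || nrow(Q) != ncol(Q)) stop("Q must be a square matrix")
  if (any(Q < -tol) || any(abs(colSums(Q) - 1) > tol)) {
    stop("Q must be column-stochastic (entries >= 0, columns summing to 1)")
  }
}

#' Replicator-with-mutation time derivative
#'
#' Computes `dx_i/dt = sum_j Q[i,j] f_j x_j - phi * x_i`, with mean
#' fitness `phi = sum_j f_j x_j`. The subtraction of `phi * x` keeps the
#' total proportion constant, so the rates always sum to zero. With
#' uniform fitness (`f = 1`) this reduces on the simplex to the linear
#' neutral model `dx/dt = Q x - x`.
#'
#' @param x proportions on the simplex.
#' @param Q column-stochastic mutation matrix.
#' @param f fitness vector (default all ones, the neutral model).
#' @return the rate vector `dx/dt`.
#' @export
replicator_derivative <- function(x, Q, f = rep(1, length(x))) {
  if (length(x) != nrow(Q) || length(f) != length(x)) {
    stop("dimension mismatch between x, f and Q")
  }
  fx <- f * x
  as.numeric(Q %*% fx) - sum(fx) * x
}

#' Integrate the replicator dynamics
#'
#' Numerically integrates [replicator_derivative()] from `x0` with
#' `deSolve::ode` (lsoda) at tight tolerances. Since the exact flow
#' conserves `sum(x) = 1`, trajectory points stay on the simplex up to
#' integration error.
#'
#' @param x0 initial proportions (must sum to 1).
#' @param Q column-stochastic mutation matrix.
#' @param f fitness vector (default uniform: the neutral model).
#' @param t_end integration horizon.
#' @param n_out number of output times (default 101).
#' @param rtol,atol solver tolerances.
#' @return a matrix: column `time` then one column per type.
#' @export
integrate_dynamics <- function(x0, Q, f = rep(1, length(x0)), t_end = 50,
                               n_out = 101, rtol = 1e-12, atol = 1e-14) {
  check_column_stochastic(Q)
  if (any(!is.finite(x0)) || abs(sum(x0) - 1) > 1e-8 || any(x0 < 0)) {
    stop("x0 must be a finite probability vector")
  }
  deriv <- function(t, x, parms) {
    if (any(!is.finite(x))) stop("non-finite state during integration")
    list(replicator_derivative(x, Q, f))
  }
  out <- deSolve::ode(y = x0, times = seq(0, t_end, length.out = n_out),
                      func = deriv, parms = NULL, method = "lsoda",
                      rtol = rtol, atol = atol)
  unclass(out)
}

#' Stationary distribution of a mutation matrix
#'
#' The eigenvector of the column-stochastic `Q` for eigenvalue 1,
#' normalised to a probability vector: the equilibrium of the neutral
#' replicator dynamics and the stationary distribution of the
#' iterated-learning Markov chain. If eigenvalue 1 is degenerate
#' (reducible chain) or other eigenvalues lie on the unit circle
#' (periodic chain), no unique stationary distribution exists and an
#' error is signalled rather than returning an arbitrary vector.
#'
#' @param Q column-stochastic matrix.
#' @param tol numerical tolerance for eigenvalue comparisons.
#' @return a probability vector.
#' @export
stationary_distribution <- function(Q, tol = 1e-8) {
  check_column_stochastic(Q)
  eig <- eigen(Q)
  on_circle <- which(abs(Mod(eig$values) - 1) < tol)
  if (length(on_circle) != 1) {
    stop("no unique stationary distribution: Q is reducible or periodic (",
         length(on_circle), " eigenvalues on the unit circle)")
  }
  v <- Re(eig$vectors[, on_circle])
  v <- v / sum(v)
  if (any(v < -1e-10)) stop("leading eigenvector is not non-negative")
  pmax(v, 0) / sum(pmax(v, 0))
}

#' Simulate the iterated-learning Markov chain
#'
#' Each agent adopts a hypothesis by sampling from the column of `Q`
#' indexed by its teacher's hypothesis. For an ergodic `Q`, the
#' empirical distribution over a long run converges to
#' [stationary_distribution()].
#'
#' @param Q column-stochastic transition matrix.
#' @param steps chain length (including the initial state).
#' @param seed integer seed.
#' @param init initial hypothesis index (default 1).
#' @return an integer vector of hypothesis indices of length `steps`.
#' @export
simulate_markov_chain <- function(Q, steps, seed = NULL, init = 1L) {
  check_column_stochastic(Q)
  cum <- apply(Q, 2, cumsum)
  with_seed(seed, {
    out <- integer(steps)
    out[1] <- init
    u <- stats::runif(steps - 1L)
    for (t in seq_len(steps - 1L)) {
      out[t + 1L] <- findInterval(u[t], cum[, out[t]]) + 1L
    }
    out
  })
}

#' Enumerable hypothesis space: binary partitions of a ring
#'
#' A toy, fully enumerable analogue of colour-category systems: each
#' hypothesis labels the `n_sites` sites of a ring with one of two
#' categories. With `contiguous = TRUE` (default) the space holds the
#' two uniform labellings plus every labelled arc (`n*(n-1) + 2`
#' hypotheses); otherwise all `2^n` labellings. The prior favours
#' simple systems: `prior(h) proportional to exp(-beta * boundaries(h))`
#' where a boundary is an adjacent site pair with different labels.
#' Data are site/label observations with per-site flip noise:
#' `P((s, y) | h) = (1/n) * (1 - eps)` if `h` labels site `s` with `y`,
#' else `(1/n) * eps`.
#'
#' @param n_sites ring size (<= 10 for full enumeration).
#' @param beta prior concentration on few-boundary systems (default 1).
#' @param eps label-flip noise in `(0, 0.5]` intervals sensible;
#'   `eps = 0` gives noiseless likelihoods (default 0.1).
#' @param contiguous restrict to contiguous two-category systems
#'   (default `TRUE`).
#' @return an object of class `hypothesis_space` with fields
#'   `hypotheses` (0/1 matrix, one row per hypothesis), `prior`,
#'   `n_sites`, `beta`, `eps`.
#' @export
ring_space <- function(n_sites, beta = 1, eps = 0.1, contiguous = TRUE) {
  stopifnot(n_sites >= 3, n_sites <= 10, beta >= 0, eps >= 0, eps < 1)
  if (contiguous) {
    rows <- list(rep(0L, n_sites), rep(1L, n_sites))
    for (start in seq_len(n_sites)) {
      for (len in seq_len(n_sites - 1L)) {
        h <- rep(0L, n_sites)
        h[((start - 1L + seq_len(len) - 1L) %% n_sites) + 1L] <- 1L
        rows[[length(rows) + 1L]] <- h
      }
    }
    H <- do.call(rbind, rows)
  } else {
    H <- as.matrix(expand.grid(rep(list(0:1), n_sites)))
    dimnames(H) <- NULL
    storage.mode(H) <- "integer"
  }
  boundaries <- rowSums(H != H[, c(2:n_sites, 1), drop = FALSE])
  w <- exp(-beta * boundaries)
  structure(list(hypotheses = H, prior = w / sum(w), n_sites = n_sites,
                 beta = beta, eps = eps, contiguous = contiguous),
            class = "hypothesis_space")
}

#' @export
print.hypothesis_space <- function(x, ...) {
  cat(sprintf("<hypothesis_space: %d-site ring, %d hypotheses (%s), beta=%g, eps=%g>\n",
              x$n_sites, nrow(x$hypotheses),
              if (x$contiguous) "contiguous" else "all labellings",
              x$beta, x$eps))
  invisible(x)
}

# log-likelihood of each single observation (site, label) under each
# hypothesis: n_outcomes x n_hypotheses, outcomes ordered site-major
# with label 0 then 1
outcome_loglik <- function(space) {
  H <- space$hypotheses
  n <- space$n_sites
  eps <- space$eps
  match0 <- t(H) == 0L # n_sites x n_hyp: TRUE where hypothesis says 0
  p_match <- log1p(-eps) - log(n)
  p_miss <- if (eps > 0) log(eps) - log(n) else -Inf
  rbind_out <- matrix(NA_real_, 2L * n, nrow(H))
  rbind_out[seq_len(n), ] <- ifelse(match0, p_match, p_miss)
  rbind_out[n + seq_len(n), ] <- ifelse(match0, p_miss, p_match)
  rbind_out
}

#' Mutation matrix of a Bayesian posterior-sampling learner
#'
#' Computes `Q[i, j] = sum_d P(adopt i | d) P(d | j)`: the teacher with
#' hypothesis `j` generates a data set `d` of `data_size` independent
#' observations, and the learner adopts hypothesis `i` with its
#' posterior probability given `d` under the space's prior. With
#' `method = "exact"` the sum runs over all `(2 * n_sites)^data_size`
#' data sequences (exact enumeration); `method = "mc"` instead averages
#' posteriors over `mc_samples` simulated data sets per teacher, with
#' Monte-Carlo error of order `1/sqrt(mc_samples)` per entry.
#'
#' A posterior-sampling learner leaves the prior invariant:
#' `Q %*% prior = prior`, so the prior is the stationary distribution
#' of iterated learning.
#'
#' @param space a [ring_space()].
#' @param data_size observations per generation.
#' @param method `"exact"` (default) or `"mc"`.
#' @param mc_samples Monte-Carlo sample count per teacher.
#' @param seed seed for `method = "mc"`.
#' @return a column-stochastic matrix.
#' @export
build_q_matrix <- function(space, data_size, method = c("exact", "mc"),
                           mc_samples = 2000, seed = NULL) {
  method <- match.arg(method)
  stopifnot(data_size >= 0)
  H <- nrow(space$hypotheses)
  if (data_size == 0) {
    return(matrix(space$prior, H, H)) # posterior = prior: every column is the prior
  }
  M <- outcome_loglik(space)
  n_out <- nrow(M)
  if (method == "exact") {
    n_seq <- n_out^data_size
    if (n_seq * H > 5e7) {
      stop("exact enumeration needs ", n_seq, " x ", H,
           " likelihood entries; use method = 'mc'")
    }
    seqs <- as.matrix(expand.grid(rep(list(seq_len(n_out)), data_size)))
    logL <- matrix(0, n_seq, H)
    for (t in seq_len(data_size)) logL <- logL + M[seqs[, t], , drop = FALSE]
    L <- exp(logL) # P(d | h), sequences as rows
    post <- sweep(L, 2, space$prior, `*`)
    rs <- rowSums(post)
    # sequences impossible under every hypothesis (noiseless likelihoods)
    # have zero teacher probability and contribute nothing
    post[rs > 0, ] <- post[rs > 0, , drop = FALSE] / rs[rs > 0]
    post[rs == 0, ] <- 0
    Q <- crossprod(post, L) # Q[i,j] = sum_d P(i|d) P(d|j)
  } else {
    P <- exp(M) # outcome probabilities per hypothesis
    Q <- with_seed(seed, {
      acc <- matrix(0, H, H)
      for (j in seq_len(H)) {
        d <- matrix(sample.int(n_out, data_size * mc_samples, replace = TRUE,
                               prob = P[, j]), mc_samples, data_size)
        logl <- matrix(0, mc_samples, H)
        for (t in seq_len(data_size)) logl <- logl + M[d[, t], , drop = FALSE]
        post <- exp(logl - apply(logl, 1, max)) *
          matrix(space$prior, mc_samples, H, byrow = TRUE)
        acc[, j] <- colMeans(post / rowSums(post))
      }
      acc
    })
  }
  dimnames(Q) <- NULL
  Q
}
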