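# Variational Laplace: Gauss-Newton ascent on the free energy of a nonlinear
# Gaussian observation model with a Gaussian parameter prior and (optionally)
# estimated per-region noise precisions.
#
# The free energy of the Laplace-approximated posterior q = N(mu, Sigma) is
#   F = log p(y | mu, h) - 0.5 (mu - m)' P0 (mu - m)
#       + 0.5 log|Sigma| - 0.5 log|C0|  (+ analogous terms for h),
# i.e. accuracy minus a complexity (KL) penalty.  The E-step takes damped
# Gauss-Newton steps on mu with step-halving until F increases; the M-step
# updates each region's log precision h_r by guarded Newton ascent.

.logdet_chol <- function(M) 2 * sum(log(diag(chol(M))))

# F as a function of residuals, precisions and the current curvature
.vl_free_energy <- function(e, groups, h, quad, logdetSigma,
                            logdetC0, h_mean, h_var, estimate_h) {
  lam <- exp(h)
  L <- 0
  for (r in seq_along(groups)) {
    idx <- groups[[r]]
    ssr <- sum(e[idx]^2)
    L <- L + 0.5 * length(idx) * h[r] - 0.5 * lam[r] * ssr -
      0.5 * length(idx) * log(2 * pi)
  }
  F <- L - 0.5 * quad + 0.5 * logdetSigma - 0.5 * logdetC0
  if (estimate_h) {
    for (r in seq_along(groups)) {
      ssr <- sum(e[groups[[r]]]^2)
      Sh <- 1 / (0.5 * lam[r] * ssr + 1 / h_var)
      F <- F - 0.5 * (h[r] - h_mean)^2 / h_var - 0.5 * log(h_var) +
        0.5 * log(Sh)
    }
  }
  unname(F)
}

#' Invert a nonlinear Gaussian model by variational Laplace
#'
#' Generic engine used by [dcm()]: `g` maps a parameter vector to a predicted
#' data vector; the observation noise is i.i.d. Gaussian within each region
#' (group) with log precision `h_r`, either estimated under a Gaussian
#' hyperprior or fixed.  Gradients are obtained by central finite differences
#' on `g`.
#'
#' @param g Function `theta -> numeric(N)` (non-finite values signal an
#'   invalid parameter point and trigger step-halving).
#' @param y Observed data vector of length N.
#' @param prior_mean,prior_var Named prior mean and (diagonal) variance over
#'   the parameters.
#' @param region_index Integer vector of length N assigning each observation
#'   to a noise group; `NULL` for a single group.
#' @param h_mean,h_var Hyperprior on each group's log noise precision.
#' @param lambda_fixed Fixed noise precisions (one per group); when given the
#'   hyperparameter step is skipped and the hyperprior terms are dropped.
#' @param maxit Maximum Gauss-Newton iterations.
#' @param tol Convergence tolerance on the change in free energy (nats).
#' @param fd_step Central-difference step.
#' @param verbose Print one line per iteration.
#' @return List with posterior `mean`, `cov`, free energy `F`, `n_iter`,
#'   `converged`, log precisions `h` and `lambda`, the accepted-step trace
#'   `F_trace`, and the `fitted` prediction at the posterior mean.
#' @export
vl_invert <- function(g, y, prior_mean, prior_var, region_index = NULL,
                      h_mean = 0, h_var = 1, lambda_fixed = NULL,
                      maxit = 128, tol = 1e-2, fd_step = 1e-3,
                      verbose = FALSE) {
  N <- length(y)
  p <- length(prior_mean)
  stopifnot(length(prior_var) == p, all(prior_var > 0))
  if (is.null(region_index)) region_index <- rep(1L, N)
  groups <- split(seq_len(N), region_index)
  R <- length(groups)
  P0 <- 1 / prior_var
  logdetC0 <- sum(log(prior_var))
  estimate_h <- is.null(lambda_fixed)

  mu <- as.numeric(prior_mean)
  pred <- g(mu)
  if (length(pred) != N || !all(is.finite(pred)))
    stop("prediction at the prior mean is invalid")
  e <- y - pred

  h <- if (estimate_h) {
    vapply(groups, function(idx)
      min(max(log(length(idx) / max(sum(e[idx]^2), 1e-12)), -5), 10),
      numeric(1))
  } else log(rep_len(lambda_fixed, R))

  F_trace <- numeric(0)
  F_curr <- -Inf
  converged <- FALSE
  n_decreasing <- 0
  Sigma <- NULL
  lm <- 0.5  # Levenberg-Marquardt damping, adapted per iteration
  n_failed <- 0
  best <- list(F = -Inf, mu = mu, h = h, Sigma = NULL, pred = pred)

  for (iter in seq_len(maxit)) {
    # central-difference Jacobian at mu
    J <- matrix(0, N, p)
    for (i in seq_len(p)) {
      d <- numeric(p); d[i] <- fd_step
      gp <- g(mu + d); gm <- g(mu - d)
      if (!all(is.finite(gp)) || !all(is.finite(gm)))
        stop("non-finite prediction while differentiating")
      J[, i] <- (gp - gm) / (2 * fd_step)
    }
    lamN <- exp(h)[region_index]
    P <- crossprod(J, J * lamN) + diag(P0, p)
    ch <- tryCatch(chol(P), error = function(e) NULL)
    if (is.null(ch)) {
      P <- P + diag(1e-6 * max(diag(P)), p)
      ch <- chol(P)
    }
    logdetSigma <- -2 * sum(log(diag(ch)))
    Sigma <- chol2inv(ch)
    dmu <- mu - prior_mean
    F_here <- .vl_free_energy(e, groups, h, sum(P0 * dmu^2),
                              logdetSigma, logdetC0, h_mean, h_var,
                              estimate_h)
    grad <- crossprod(J, lamN * e) - P0 * dmu
    # Levenberg-Marquardt damped step (the damping regularizes the search
    # direction only; the posterior covariance stays the undamped inverse)
    Pd <- P + lm * diag(diag(P), p)
    step <- drop(solve(Pd, grad))

    # step-halving on F (curvature frozen at mu)
    accepted <- FALSE
    for (k in 0:16) {
      mu_c <- mu + step / 2^k
      pred_c <- g(mu_c)
      if (!all(is.finite(pred_c))) next
      e_c <- y - pred_c
      dmu_c <- mu_c - prior_mean
      F_c <- .vl_free_energy(e_c, groups, h, sum(P0 * dmu_c^2),
                             logdetSigma, logdetC0, h_mean, h_var,
                             estimate_h)
      if (F_c > F_here) {
        mu <- mu_c; pred <- pred_c; e <- e_c; F_here <- F_c
        accepted <- TRUE
        lm <- if (k == 0) max(lm / 4, 1e-4) else min(lm * 4, 1e4)
        break
      }
    }
    if (!accepted) lm <- min(lm * 8, 1e4)

    # M-step: guarded Newton ascent on each log precision
    if (estimate_h) {
      for (r in seq_len(R)) {
        idx <- groups[[r]]
        ssr <- sum(e[idx]^2)
        for (it in 1:4) {
          lam_r <- exp(h[r])
          gr <- 0.5 * length(idx) - 0.5 * lam_r * ssr -
            (h[r] - h_mean) / h_var
          he <- -0.5 * lam_r * ssr - 1 / h_var
          dh <- -gr / he
          dh <- max(min(dh, 2), -2)
          h[r] <- h[r] + dh
          if (abs(dh) < 1e-6) break
        }
      }
      # refresh the curvature at the new precisions so the reported F is
      # internally consistent (J unchanged)
      lamN <- exp(h)[region_index]
      P <- crossprod(J, J * lamN) + diag(P0, p)
      ch <- tryCatch(chol(P), error = function(e) NULL)
      if (is.null(ch)) {
        P <- P + diag(1e-6 * max(diag(P)), p)
        ch <- chol(P)
      }
      logdetSigma <- -2 * sum(log(diag(ch)))
      Sigma <- chol2inv(ch)
      dmu <- mu - prior_mean
      F_here <- .vl_free_energy(e, groups, h, sum(P0 * dmu^2),
                                logdetSigma, logdetC0, h_mean, h_var,
                                estimate_h)
    }

    if (verbose)
      message(sprintf("iter %3d  F = %.4f  %s", iter, F_here,
                      if (accepted) "" else "(no step)"))
    dF <- F_here - F_curr
    F_trace <- c(F_trace, F_here)
    if (F_here > best$F)
      best <- list(F = F_here, mu = mu, h = h, Sigma = Sigma, pred = pred)
    if (dF < 0) {
      n_decreasing <- n_decreasing + 1
      if (n_decreasing >= 8)
        stop("free energy decreased on 8 consecutive iterations")
      # a small dip after the curvature refresh signals the optimum has
      # been reached to within the numerical consistency of the scheme
      if (iter > 3 && abs(dF) < 50 * tol) { converged <- TRUE; break }
    } else n_decreasing <- 0
    F_curr <- F_here
    n_failed <- if (accepted) 0 else n_failed + 1
    if (iter > 1 && accepted && abs(dF) < tol) { converged <- TRUE; break }
    if (n_failed >= 3) { converged <- abs(dF) < tol; break }
  }

  list(mean = setNames(best$mu, names(prior_mean)), cov = best$Sigma,
       F = best$F, n_iter = length(F_trace), converged = converged,
       h = best$h, lambda = exp(best$h), F_trace = F_trace,
       fitted = best$pred)
}
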