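# The fitting front end: invert a DCM for one session of BOLD data and
# return a classed model object with the usual accessor methods.

# lean prediction closure used inside the optimizer: index-vector parameter
# assembly and a direct call into the compiled integrator (equivalent to
# unpack_params() + predict_bold(), without per-call validation overhead)
.make_dcm_predictor <- function(spec, inputs, hemo_base) {
  map <- param_map(spec)
  idx <- function(type) which(map$type == type)
  lin_nn <- function(r) (map$j[r] - 1L) * 3L + map$i[r]
  lin_b <- function(r) (map$k[r] - 1L) * 9L + (map$j[r] - 1L) * 3L + map$i[r]
  lin_c <- function(r) (map$k[r] - 1L) * 3L + map$i[r]
  i_self <- idx("self"); i_a <- idx("A"); i_b <- idx("B"); i_c <- idx("C")
  i_kappa <- idx("kappa"); i_tau <- idx("tau")
  l_self <- lin_nn(i_self); l_a <- lin_nn(i_a)
  l_b <- lin_b(i_b); l_c <- lin_c(i_c)
  t_tau <- map$i[i_tau]
  k <- .bold_consts(hemo_base)  # depends only on the fixed E0
  uu <- inputs$groups$uu
  group <- inputs$groups$group
  scan_bins <- .scan_bins(inputs)
  dt <- inputs$dt_micro
  n_out <- inputs$n_scans * 3L
  A0 <- matrix(0, 3, 3); B0 <- array(0, c(3, 3, 3)); C0 <- matrix(0, 3, 3)

  function(theta) {
    A <- A0; A[l_self] <- -0.5 * exp(theta[i_self]); A[l_a] <- theta[i_a]
    ev <- eigen(A, only.values = TRUE)$values
    if (any(Re(ev) >= -1e-9)) return(rep(NA_real_, n_out))
    B <- B0; B[l_b] <- theta[i_b]
    C <- C0; C[l_c] <- theta[i_c]
    kap <- hemo_base$kappa * exp(theta[i_kappa])
    tau <- hemo_base$tau
    tau[t_tau] <- tau[t_tau] * exp(theta[i_tau])
    as.numeric(cpp_dcm_integrate(A, B, C, uu, group, dt, kap,
                                 hemo_base$gamma, tau, hemo_base$alpha,
                                 hemo_base$E0, hemo_base$efficacy,
                                 k$k1, k$k2, k$k3, k$V0, scan_bins, FALSE)$y)
  }
}

#' Fit (invert) a dynamic causal model
#'
#' Estimates the free parameters of a bilinear DCM from a BOLD time series by
#' variational Laplace (see [vl_invert()]): Gauss-Newton ascent on the free
#' energy with central-difference gradients through the forward model, a
#' per-region noise precision estimated under a standard-normal log-precision
#' hyperprior, and convergence when the free energy changes by less than
#' `tol` nats.
#'
#' @param y A `bold_series` (or scans x 3 matrix, % signal change).
#' @param inputs A `dcm_inputs` object spanning the same session.
#' @param spec A `dcm_spec` defining the model structure.
#' @param priors A [dcm_priors()]; defaults to the package's shrinkage
#'   priors.
#' @param hemo_base Baseline hemodynamics scaled by the free log-parameters.
#' @param lambda_fixed Optional fixed noise precisions (skips hyperparameter
#'   estimation).
#' @param maxit,tol,fd_step,verbose Passed to [vl_invert()].
#' @return An object of class `dcm`: posterior `mean` and `cov` over the
#'   free parameters, free energy `F`, noise precisions, and the data and
#'   model needed by the methods ([coef()], [summary()], [predict()],
#'   [fitted()], [residuals()], [simulate()], [plot()], [log_evidence()]).
#' @examples
#' \donttest{
#' design <- build_session(seed = 1)
#' inputs <- build_inputs(design, n_scans = 128, truncate = "silent")
#' truth <- reference_params(noise_sd = 0.2)
#' y <- simulate_bold(truth, inputs, seed = 1)
#' fit <- dcm(y, inputs, reference_model())
#' summary(fit)
#' }
#' @export
dcm <- function(y, inputs, spec, priors = dcm_priors(spec),
                hemo_base = hemo_params(), lambda_fixed = NULL, maxit = 64,
                tol = 1e-2, fd_step = 1e-3, verbose = FALSE) {
  Y <- if (inherits(y, "bold_series")) y$y else as.matrix(y)
  stopifnot(inherits(inputs, "dcm_inputs"), inherits(spec, "dcm_spec"),
            ncol(Y) == 3)
  if (nrow(Y) != inputs$n_scans)
    stop("data and inputs span different numbers of scans")
  n_scans <- nrow(Y)
  region_index <- rep(seq_len(3), each = n_scans)
  if (is.null(inputs$groups)) inputs$groups <- .u_groups(inputs$u)

  g <- .make_dcm_predictor(spec, inputs, hemo_base)

  res <- vl_invert(g, as.numeric(Y), priors$mean, priors$var, region_index,
                   h_mean = priors$h_mean, h_var = priors$h_var,
                   lambda_fixed = lambda_fixed, maxit = maxit, tol = tol,
                   fd_step = fd_step, verbose = verbose)

  fitted <- matrix(res$fitted, n_scans, 3, dimnames = list(NULL, .nodes))
  structure(c(res[c("mean", "cov", "F", "n_iter", "converged", "h",
                    "lambda", "F_trace")],
              list(fitted = fitted, y = Y, spec = spec, priors = priors,
                   inputs = inputs, hemo_base = hemo_base,
                   map = priors$map)),
            class = "dcm")
}

#' Log model evidence (free energy) of a fitted DCM
#'
#' Returns the variational free energy, the lower-bound approximation to the
#' log evidence used for model comparison.  For an unconverged fit the value
#' is still returned, with a warning and `converged = FALSE` attached as an
#' attribute.
#' @param fit A fitted `dcm` object.
#' @export
log_evidence <- function(fit) {
  stopifnot(inherits(fit, "dcm"))
  if (!fit$converged)
    warning("inversion did not converge; free energy may be a poor bound")
  structure(fit$F, converged = fit$converged)
}

#' @export
print.dcm <- function(x, ...) {
  cat(sprintf("Fitted DCM (%d free parameters)\n", length(x$mean)))
  cat(sprintf("  free energy F = %.2f nats after %d iterations (%s)\n",
              x$F, x$n_iter,
              if (x$converged) "converged" else "not converged"))
  cat(sprintf("  noise SD (%% signal): %s\n",
              paste(sprintf("%s %.3f", .nodes, 1 / sqrt(x$lambda)),
                    collapse = ", ")))
  invisible(x)
}

#' @export
coef.dcm <- function(object, natural = FALSE, ...) {
  est <- object$mean
  if (natural) {
    sel <- object$map$type == "self"
    est[sel] <- -0.5 * exp(est[sel])
  }
  est
}

#' @export
vcov.dcm <- function(object, ...) {
  v <- object$cov
  dimnames(v) <- list(names(object$mean), names(object$mean))
  v
}

#' @export
summary.dcm <- function(object, ...) {
  sds <- sqrt(diag(object$cov))
  est <- object$mean
  tab <- data.frame(estimate = est, sd = sds,
                    lower = est - 1.96 * sds, upper = est + 1.96 * sds)
  sel <- object$map$type == "self"
  tab$natural <- est
  tab$natural[sel] <- -0.5 * exp(est[sel])
  out <- list(coefficients = tab, F = object$F, converged = object$converged,
              n_iter = object$n_iter, noise_sd = 1 / sqrt(object$lambda))
  class(out) <- "summary.dcm"
  out
}

#' @export
print.summary.dcm <- function(x, digits = 3, ...) {
  cat(sprintf("DCM posterior (F = %.2f nats, %d iterations, %s)\n", x$F,
              x$n_iter, if (x$converged) "converged" else "not converged"))
  print(round(x$coefficients, digits))
  cat(sprintf("Estimated noise SD: %s\n",
              paste(sprintf("%s %.3f", .nodes, x$noise_sd), collapse = ", ")))
  invisible(x)
}

#' @export
fitted.dcm <- function(object, ...) object$fitted

#' @export
residuals.dcm <- function(object, ...) object$y - object$fitted

#' @export
predict.dcm <- function(object, inputs = object$inputs, ...) {
  p <- unpack_params(object$mean, object$spec, object$hemo_base)
  predict_bold(p, inputs)
}

#' @export
simulate.dcm <- function(object, nsim = 1, seed = NULL, ...) {
  p <- unpack_params(object$mean, object$spec, object$hemo_base,
                     noise_sd = 1 / sqrt(object$lambda))
  .with_seed(seed, lapply(seq_len(nsim), function(i)
    simulate_bold(p, object$inputs)))
}

#' @export
plot.dcm <- function(x, ...) {
  old <- par(mfrow = c(3, 1), mar = c(3, 4, 1.5, 1))
  on.exit(par(old))
  t <- (seq_len(nrow(x$y)) - 1) * x$inputs$tr
  for (r in 1:3) {
    matplot(t, cbind(x$y[, r], x$fitted[, r]), type = "l", lty = c(1, 1),
            col = c("grey60", "firebrick"), xlab = "", ylab = "% signal",
            main = .nodes[r], ...)
  }
  invisible(x)
}
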