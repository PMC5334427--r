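# Shrinkage priors over the free parameters of a model.

#' Default priors for a DCM
#'
#' Zero-mean Gaussian shrinkage priors, truncated to the dynamically stable
#' regime (the model class is defined on stable systems; [draw_from_prior()]
#' rejection-samples accordingly, and the inversion rejects unstable points
#' the same way).  Default variances are the conventional weakly-informative
#' unit variance on all neuronal coupling parameters -- off-diagonal A, B, C
#' and the self-connection log-scalings (under `A_ii = -0.5 exp(theta_ii)`,
#' which keeps every decay negative by construction) -- so couplings of the
#' order of 1 Hz are recoverable without material shrinkage, plus tight
#' priors (variance 1/256) on the hemodynamic log-scales and a
#' standard-normal prior on each region's log noise precision.
#'
#' @param spec A `dcm_spec`.
#' @param v_self,v_a,v_b,v_c,v_hemo Prior variances per parameter class
#'   (self log-scaling, off-diagonal A, B, C, hemodynamic log-scales); all
#'   overridable, and recorded in the fit for provenance.
#' @param h_mean,h_var Hyperprior on the region log noise precisions.
#' @return A `dcm_priors` object: named `mean` and `var` vectors over the
#'   free parameters (see [param_map()]), plus the log-precision hyperprior
#'   (`h_mean`, `h_var`).
#' @export
dcm_priors <- function(spec, v_self = 1, v_a = 1, v_b = 1, v_c = 1,
                       v_hemo = 1 / 256, h_mean = 0, h_var = 1) {
  map <- param_map(spec)
  v <- c(self = v_self, A = v_a, B = v_b, C = v_c,
         kappa = v_hemo, tau = v_hemo)[map$type]
  structure(list(mean = setNames(numeric(nrow(map)), map$name),
                 var = setNames(as.numeric(v), map$name),
                 map = map, spec = spec, h_mean = h_mean, h_var = h_var),
            class = "dcm_priors")
}

#' @export
print.dcm_priors <- function(x, ...) {
  cat(sprintf("DCM priors over %d free parameters\n", length(x$mean)))
  tab <- table(x$map$type)
  cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf("  log-precision hyperprior N(%g, %g)\n", x$h_mean, x$h_var))
  invisible(x)
}

#' Draw parameter vectors from the prior
#'
#' By default draws from the stability-truncated prior: Gaussian proposals
#' are rejected until the implied endogenous matrix A has all eigenvalues in
#' the left half-plane, matching the support on which the model (and its
#' inversion) is defined.
#'
#' @param priors A [dcm_priors()].
#' @param n Number of draws.
#' @param seed Optional seed.
#' @param require_stable Rejection-sample to the stable regime.
#' @return n x p matrix of draws (named columns).
#' @export
draw_from_prior <- function(priors, n = 1, seed = NULL,
                            require_stable = TRUE) {
  .with_seed(seed, {
    p <- length(priors$mean)
    one <- function() {
      for (i in 1:1000) {
        d <- rnorm(p, priors$mean, sqrt(priors$var))
        if (!require_stable) return(d)
        A <- unpack_params(d, priors$spec)$A
        if (all(Re(eigen(A, only.values = TRUE)$values) < 0)) return(d)
      }
      stop("could not draw a stable system from the prior")
    }
    draws <- t(vapply(seq_len(n), function(i) one(), numeric(p)))
    colnames(draws) <- names(priors$mean)
    draws
  })
}
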