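# Group-level fixed-effects Bayesian model selection, Occam's window,
# Bayesian parameter averaging, and multiplicity-corrected credible
# intervals.

#' Assemble an evidence table
#'
#' @param fits_by_subject List (one element per subject) of lists of fitted
#'   `dcm` objects, or of named numeric free-energy vectors.  Model order
#'   must agree across subjects.
#' @param ids Optional model identifiers (taken from fit specs or names
#'   otherwise).
#' @param families Optional family label per model.
#' @return An `evidence_table`: subjects x models matrix of free energies
#'   with model ids as column names and `families` attached.
#' @export
evidence_table <- function(fits_by_subject, ids = NULL, families = NULL) {
  rows <- lapply(fits_by_subject, function(s) {
    if (is.numeric(s)) return(s)
    vapply(s, function(f) f$F, numeric(1))
  })
  F <- do.call(rbind, rows)
  if (is.null(ids)) {
    s1 <- fits_by_subject[[1]]
    ids <- if (is.numeric(s1)) names(s1)
           else vapply(s1, function(f) f$spec$id, character(1))
  }
  colnames(F) <- ids
  if (anyNA(F) || any(!is.finite(F))) stop("non-finite free energy in table")
  structure(F, families = families, class = c("evidence_table", "matrix"))
}

#' Fixed-effects Bayesian model selection
#'
#' Sums log evidences over subjects (all subjects assumed to share one
#' generating structure) and converts the group log evidences to posterior
#' model probabilities under a uniform model prior.  Family probabilities
#' are sums of member posteriors.
#'
#' @param ev An [evidence_table()] (or subjects x models matrix of free
#'   energies with model ids as column names).
#' @param families Optional family label per model (overrides the table's).
#' @return A `bms_result`: `posterior_prob` (named, sums to one),
#'   `group_logev`, and `family_prob` when families are given.
#' @export
ffx_bms <- function(ev, families = NULL) {
  F <- unclass(ev)
  if (is.null(dim(F))) F <- matrix(F, nrow = 1)
  stopifnot(nrow(F) >= 1, ncol(F) >= 2)
  if (anyNA(F) || any(!is.finite(F))) stop("non-finite free energy")
  if (is.null(families)) families <- attr(ev, "families")
  group <- colSums(F)
  z <- group - max(group)
  post <- exp(z) / sum(exp(z))
  out <- list(posterior_prob = post, group_logev = group,
              n_subjects = nrow(F))
  if (!is.null(families)) {
    out$family_prob <- vapply(split(post, families), sum, numeric(1))
    out$families <- families
  }
  structure(out, class = "bms_result")
}

#' @export
print.bms_result <- function(x, top = 5, ...) {
  cat(sprintf("Fixed-effects BMS over %d models, %d subject(s)\n",
              length(x$posterior_prob), x$n_subjects))
  ord <- order(x$posterior_prob, decreasing = TRUE)
  show <- head(ord, top)
  for (i in show)
    cat(sprintf("  %-14s p = %.4f  (group logev %.2f)\n",
                names(x$posterior_prob)[i], x$posterior_prob[i],
                x$group_logev[i]))
  if (!is.null(x$family_prob)) {
    cat("  family probabilities:",
        paste(sprintf("%s %.3f", names(x$family_prob), x$family_prob),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Occam's window
#'
#' Models retaining non-negligible posterior probability after model
#' comparison: those with posterior above `threshold` (default 0.01).
#'
#' @param result A `bms_result`.
#' @param threshold Posterior-probability threshold.
#' @return Character vector of model ids in the window, with the
#'   within-window renormalized probabilities attached as attribute
#'   `renormalized` (the raw probabilities remain in `result`).
#' @export
occams_window <- function(result, threshold = 0.01) {
  stopifnot(inherits(result, "bms_result"))
  p <- result$posterior_prob
  keep <- names(p)[p > threshold]
  if (length(keep) == 0) keep <- names(p)[which.max(p)]
  structure(keep, renormalized = p[keep] / sum(p[keep]))
}

#' Bayesian parameter averaging
#'
#' Precision-weighted fixed-effects combination of Gaussian posteriors over
#' a shared parameter set: the combined precision is the sum of the
#' per-session precisions and the combined mean the precision-weighted mean.
#'
#' @param posteriors List of fitted `dcm` objects (or lists with `mean` and
#'   `cov`) over identical parameter vectors.
#' @return A `bpa_result`: combined `mean`, `cov`, per-parameter `sd`.
#' @export
bayesian_parameter_average <- function(posteriors) {
  stopifnot(length(posteriors) >= 1)
  nm <- names(posteriors[[1]]$mean)
  p <- length(nm)
  for (po in posteriors)
    if (!identical(names(po$mean), nm))
      stop("posteriors are over different parameter sets")
  Psum <- matrix(0, p, p)
  Pmu <- numeric(p)
  for (po in posteriors) {
    Pi <- solve(po$cov)
    Psum <- Psum + Pi
    Pmu <- Pmu + Pi %*% po$mean
  }
  cov <- solve(Psum)
  mean <- drop(cov %*% Pmu)
  structure(list(mean = setNames(mean, nm), cov = cov,
                 sd = setNames(sqrt(diag(cov)), nm),
                 n_posteriors = length(posteriors)),
            class = "bpa_result")
}

#' @export
print.bpa_result <- function(x, digits = 3, ...) {
  cat(sprintf("Bayesian parameter average over %d posteriors\n",
              x$n_posteriors))
  print(round(data.frame(mean = x$mean, sd = x$sd), digits))
  invisible(x)
}

# multivariate normal draws via the Cholesky factor
.rmvnorm <- function(n, mean, cov) {
  p <- length(mean)
  ch <- chol(cov + diag(1e-12 * max(diag(cov)), p))
  matrix(rnorm(n * p), n, p) %*% ch + rep(mean, each = n)
}

#' Multiplicity-corrected credible intervals
#'
#' Draws samples from the averaged Gaussian posterior and forms per-parameter
#' empirical intervals at the Bonferroni-corrected simultaneous level: the
#' `(alpha/k)/2` and `1 - (alpha/k)/2` quantiles over `k` tested parameters
#' (13 by default).  Flags parameters whose corrected interval contains
#' zero.
#'
#' @param bpa A `bpa_result` (or any list with `mean` and `cov`).
#' @param k Number of parameters corrected for.
#' @param alpha Simultaneous error level.
#' @param n_samples Posterior draws.
#' @param seed Optional seed.
#' @return Data frame with `mean`, `lower`, `upper`, `contains_zero`.
#' @export
corrected_intervals <- function(bpa, k = 13, alpha = 0.05,
                                n_samples = 1e5, seed = NULL) {
  stopifnot(k >= 1)
  if (n_samples < 1000)
    warning("fewer than 1000 samples gives unstable interval estimates")
  .with_seed(seed, {
    draws <- .rmvnorm(n_samples, bpa$mean, bpa$cov)
    qs <- c((alpha / k) / 2, 1 - (alpha / k) / 2)
    lo <- apply(draws, 2, quantile, qs[1])
    hi <- apply(draws, 2, quantile, qs[2])
    data.frame(mean = bpa$mean, lower = lo, upper = hi,
               contains_zero = lo <= 0 & hi >= 0,
               row.names = names(bpa$mean))
  })
}

#' Markdown report of a model selection
#'
#' Writes a short human-readable report: winning model, Occam's window, and
#' the averaged coupling parameters with corrected intervals.
#'
#' @param bms A `bms_result`.
#' @param bpa Optional `bpa_result` for the winning model.
#' @param intervals Optional output of [corrected_intervals()].
#' @param path Output file.
#' @export
report_markdown <- function(bms, bpa = NULL, intervals = NULL, path) {
  lines <- c("# Model selection report", "",
             sprintf("Fixed-effects BMS over %d models, %d subject(s).",
                     length(bms$posterior_prob), bms$n_subjects), "")
  win <- occams_window(bms)
  lines <- c(lines, "## Occam's window", "",
             sprintf("- `%s`: posterior %.4f (renormalized %.4f)", win,
                     bms$posterior_prob[win], attr(win, "renormalized")), "")
  if (!is.null(bpa)) {
    lines <- c(lines, "## Averaged parameters (winning model)", "",
               "| parameter | mean | sd |", "|---|---|---|",
               sprintf("| %s | %.3f | %.3f |", names(bpa$mean), bpa$mean,
                       bpa$sd), "")
  }
  if (!is.null(intervals)) {
    lines <- c(lines, "## Corrected credible intervals", "",
               "| parameter | lower | upper | contains zero |",
               "|---|---|---|---|",
               sprintf("| %s | %.3f | %.3f | %s |", rownames(intervals),
                       intervals$lower, intervals$upper,
                       ifelse(intervals$contains_zero, "yes", "no")), "")
  }
  writeLines(lines, path)
  invisible(path)
}
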