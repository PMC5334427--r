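# Generative model: bilinear neuronal dynamics plus balloon-Windkessel
# hemodynamics, integrated on the microtime grid and sampled at scan times.

#' Bilinear neuronal derivative
#'
#' Evaluates `dx/dt = (A + sum_i u_i B^(i)) x + C u`.
#'
#' @param x Neuronal state vector (one per node).
#' @param u Input vector (one per input).
#' @param params A [dcm_params()].
#' @export
neural_derivative <- function(x, u, params) {
  if (anyNA(x) || anyNA(u)) stop("NaN in neuronal states or inputs")
  M <- params$A
  for (i in seq_along(u)) M <- M + u[i] * params$B[, , i]
  drop(M %*% x + params$C %*% u)
}

.check_stable <- function(A) {
  if (any(Re(eigen(A, only.values = TRUE)$values) >= 0))
    stop("unstable endogenous matrix A (some Re eig >= 0)")
}

# 0-based bin-boundary indices of the scan times t = (s - 1) * TR
.scan_bins <- function(inputs) {
  bins_per_scan <- round(inputs$tr / inputs$dt_micro)
  as.integer((seq_len(inputs$n_scans) - 1) * bins_per_scan)
}

# distinct input rows and a 0-based per-bin group index (the integrator
# computes one matrix exponential per distinct input vector)
.u_groups <- function(u) {
  key <- do.call(paste, c(as.data.frame(u), sep = ","))
  first <- !duplicated(key)
  list(uu = u[first, , drop = FALSE],
       group = as.integer(match(key, key[first]) - 1L))
}

.integrate <- function(params, inputs, return_states = FALSE) {
  if (is.null(inputs$groups)) inputs$groups <- .u_groups(inputs$u)
  k <- .bold_consts(params$hemo)
  cpp_dcm_integrate(params$A, params$B, params$C, inputs$groups$uu,
                    inputs$groups$group, inputs$dt_micro,
                    params$hemo$kappa, params$hemo$gamma, params$hemo$tau,
                    params$hemo$alpha, params$hemo$E0, params$hemo$efficacy,
                    k$k1, k$k2, k$k3, k$V0, .scan_bins(inputs),
                    return_states)
}

#' Integrate neuronal and hemodynamic state trajectories
#'
#' Neuronal states are advanced with the exact affine (matrix-exponential)
#' update over each microtime bin, exploiting that the inputs are piecewise
#' constant; hemodynamic states by fourth-order Runge-Kutta within each bin.
#' Rejects an unstable endogenous matrix before integrating.
#'
#' @param params A [dcm_params()].
#' @param inputs A `dcm_inputs` object.
#' @return List with `time` (bin boundaries, s), neuronal states `x` and
#'   hemodynamic states `s`, `f`, `v`, `q` (each (T+1) x n), and the
#'   noiseless BOLD `y` at scan times.
#' @export
integrate_states <- function(params, inputs) {
  .check_stable(params$A)
  out <- .integrate(params, inputs, return_states = TRUE)
  out$time <- (0:nrow(inputs$u)) * inputs$dt_micro
  for (nm in c("x", "s", "f", "v", "q", "y")) colnames(out[[nm]]) <- .nodes
  out
}

#' Noiseless BOLD prediction at scan times
#'
#' @param params A [dcm_params()].
#' @param inputs A `dcm_inputs` object.
#' @return A `bold_series`: list with `y` (scans x regions, % signal change)
#'   and `tr`.
#' @export
predict_bold <- function(params, inputs) {
  .check_stable(params$A)
  y <- .integrate(params, inputs)$y
  colnames(y) <- .nodes
  structure(list(y = y, tr = inputs$tr), class = "bold_series")
}

#' Simulate a noisy BOLD series
#'
#' Adds i.i.d. Gaussian noise per scan and region (SD `params$noise_sd`) to
#' the noiseless prediction.
#'
#' @inheritParams predict_bold
#' @param seed Optional seed (caller RNG state restored).
#' @export
simulate_bold <- function(params, inputs, seed = NULL) {
  out <- predict_bold(params, inputs)
  nsd <- rep_len(params$noise_sd, ncol(out$y))
  .with_seed(seed, {
    for (r in seq_len(ncol(out$y)))
      out$y[, r] <- out$y[, r] + rnorm(nrow(out$y), 0, nsd[r])
  })
  out
}

#' @export
print.bold_series <- function(x, ...) {
  cat(sprintf("BOLD series: %d scans x %d regions (TR %g s)\n",
              nrow(x$y), ncol(x$y), x$tr))
  invisible(x)
}

#' @export
plot.bold_series <- function(x, ...) {
  t <- (seq_len(nrow(x$y)) - 1) * x$tr
  matplot(t, x$y, type = "l", lty = 1, xlab = "time (s)",
          ylab = "BOLD (% signal)", ...)
  legend("topright", colnames(x$y), col = seq_len(ncol(x$y)), lty = 1,
         bty = "n")
  invisible(x)
}

#' Write / read a BOLD series (CSV plus JSON sidecar)
#'
#' @param bold A `bold_series`.
#' @param path CSV path (scan x region); sidecar `<path>.json` records the
#'   TR, node names and any extra metadata supplied.
#' @param meta Optional named list merged into the sidecar.
#' @export
write_bold <- function(bold, path, meta = list()) {
  write.table(bold$y, path, sep = ",", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(c(list(tr = bold$tr, nodes = colnames(bold$y)), meta),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_bold
#' @export
read_bold <- function(path) {
  y <- as.matrix(read.table(path, header = TRUE, sep = ","))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  colnames(y) <- meta$nodes
  structure(list(y = y, tr = meta$tr, meta = meta), class = "bold_series")
}
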