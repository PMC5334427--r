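# Nested exogenous inputs on the microtime grid.
#
# The three DCM inputs are cumulative ("nested") boxcars: MOTION is on during
# every experimental block, UNPREDICTABLE during RANDOM and ARBITRARY blocks,
# and ARBITRARY during ARBITRARY blocks only, so pointwise
# ARBITRARY <= UNPREDICTABLE <= MOTION and all inputs are 0 at baseline.

#' Build the nested DCM inputs from a session schedule
#'
#' @param session A `session_design` (see [build_session()]).
#' @param n_scans Number of scans in the acquisition window.
#' @param tr Repetition time in seconds.
#' @param dt_micro Microtime bin width; must divide `tr`.  The default
#'   `tr/16` mirrors common DCM practice.
#' @param truncate What to do when a block extends beyond the scan window:
#'   `"warn"` (default) truncates with a warning, `"silent"` truncates
#'   quietly, `"error"` aborts.
#' @return A `dcm_inputs` object: list with `u` (T x 3 binary matrix on the
#'   microtime grid), `dt_micro`, `names`, `n_scans`, `tr`.
#' @export
build_inputs <- function(session, n_scans = 512, tr = 1.8,
                         dt_micro = tr / 16,
                         truncate = c("warn", "silent", "error")) {
  truncate <- match.arg(truncate)
  stopifnot(inherits(session, "session_design"), n_scans >= 1, tr > 0)
  bins_per_scan <- tr / dt_micro
  if (abs(bins_per_scan - round(bins_per_scan)) > 1e-9)
    stop("dt_micro must divide tr")
  Tm <- n_scans * round(bins_per_scan)
  window <- n_scans * tr
  over <- session$onset + session$duration - window
  if (any(over > 1e-9)) {
    msg <- sprintf(
      "%d block(s) extend past the %d-scan window by up to %.2f s; truncated",
      sum(over > 1e-9), n_scans, max(over))
    if (truncate == "error") stop(msg)
    if (truncate == "warn") warning(msg)
  }
  mids <- (seq_len(Tm) - 0.5) * dt_micro
  u <- matrix(0, Tm, 3, dimnames = list(NULL, .input_names))
  for (b in seq_len(nrow(session))) {
    on <- mids >= session$onset[b] & mids < session$onset[b] +
      session$duration[b]
    u[on, "MOTION"] <- 1
    if (session$condition[b] %in% c("RANDOM", "ARBITRARY"))
      u[on, "UNPREDICTABLE"] <- 1
    if (session$condition[b] == "ARBITRARY")
      u[on, "ARBITRARY"] <- 1
  }
  structure(list(u = u, dt_micro = dt_micro, names = .input_names,
                 n_scans = n_scans, tr = tr, groups = .u_groups(u)),
            class = "dcm_inputs")
}

#' @export
print.dcm_inputs <- function(x, ...) {
  cat(sprintf("DCM inputs: %d microtime bins (dt = %g s), %d scans (TR %g s)\n",
              nrow(x$u), x$dt_micro, x$n_scans, x$tr))
  on <- colSums(x$u) * x$dt_micro
  cat(sprintf("  on-time (s): %s\n",
              paste(sprintf("%s %.1f", colnames(x$u), on), collapse = ", ")))
  invisible(x)
}

#' Recover block onsets and durations from an input set
#'
#' Inverse of [build_inputs()] at microtime resolution: detects boxcar edges
#' of the nested inputs and labels each block by its condition.
#'
#' @param inputs A `dcm_inputs` object.
#' @return A `session_design`-shaped data frame (jitter/baseline unknown).
#' @export
inputs_to_schedule <- function(inputs) {
  u <- inputs$u
  motion <- u[, "MOTION"]
  edges <- diff(c(0, motion, 0))
  starts <- which(edges == 1)
  ends <- which(edges == -1) - 1
  cond <- vapply(seq_along(starts), function(i) {
    mid <- (starts[i] + ends[i]) %/% 2
    if (u[mid, "ARBITRARY"] == 1) "ARBITRARY"
    else if (u[mid, "UNPREDICTABLE"] == 1) "RANDOM"
    else "PREDICTABLE"
  }, character(1))
  structure(
    data.frame(onset = (starts - 1) * inputs$dt_micro,
               duration = (ends - starts + 1) * inputs$dt_micro,
               condition = cond, jitter = NA_real_, baseline = NA_real_,
               stringsAsFactors = FALSE),
    class = c("session_design", "data.frame"))
}

#' Canonical double-gamma hemodynamic response function
#'
#' Used only for GLM-style sanity plots of the boxcar regressors; the DCM
#' itself uses the balloon-Windkessel forward model.
#'
#' @param t Time points in seconds.
#' @param peak1,peak2 Delays of response and undershoot (s).
#' @param ratio Peak-to-undershoot ratio.
#' @export
canonical_hrf <- function(t, peak1 = 6, peak2 = 16, ratio = 1 / 6) {
  h <- stats::dgamma(t, shape = peak1, rate = 1) -
    ratio * stats::dgamma(t, shape = peak2, rate = 1)
  h / max(h)
}

#' Write / read an input set (CSV plus JSON sidecar)
#'
#' The CSV holds the T x 3 binary input matrix; the sidecar records
#' `dt_micro`, `names`, `n_scans` and `tr`.
#' @param inputs A `dcm_inputs` object.
#' @param path CSV path; the sidecar is `<path>.json`.
#' @export
write_inputs <- function(inputs, path) {
  write.table(inputs$u, path, sep = ",", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(dt_micro = inputs$dt_micro, names = inputs$names,
         n_scans = inputs$n_scans, tr = inputs$tr),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_inputs
#' @export
read_inputs <- function(path) {
  u <- as.matrix(read.table(path, header = TRUE, sep = ","))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  colnames(u) <- meta$names
  structure(list(u = u, dt_micro = meta$dt_micro, names = meta$names,
                 n_scans = meta$n_scans, tr = meta$tr),
            class = "dcm_inputs")
}
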