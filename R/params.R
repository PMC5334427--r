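# Numeric parameters of a DCM: bilinear coupling (A, B, C), the
# balloon-Windkessel hemodynamics, and the observation-noise level, plus the
# packing of a model's free parameters into the estimation vector.

#' Balloon-Windkessel hemodynamic parameters
#'
#' Conventional prior means: signal decay kappa = 0.64 1/s, flow feedback
#' gamma = 0.32 1/s, mean transit time tau = 2 s, vessel stiffness
#' alpha = 0.32, resting oxygen extraction E0 = 0.4, neuronal efficacy 1.
#' Values are recycled to one per region.
#'
#' @param kappa,gamma,tau,alpha,E0,efficacy Per-region values (recycled).
#' @param n_regions Number of regions.
#' @return A `hemo_params` list of per-region vectors.
#' @export
hemo_params <- function(kappa = 0.64, gamma = 0.32, tau = 2, alpha = 0.32,
                        E0 = 0.4, efficacy = 1, n_regions = 3) {
  out <- list(kappa = rep_len(kappa, n_regions),
              gamma = rep_len(gamma, n_regions),
              tau = rep_len(tau, n_regions),
              alpha = rep_len(alpha, n_regions),
              E0 = rep_len(E0, n_regions),
              efficacy = rep_len(efficacy, n_regions))
  stopifnot(all(unlist(out) > 0), all(out$alpha < 1), all(out$E0 < 1))
  structure(out, class = "hemo_params")
}

# 3T BOLD observation constants (echo time matching the acquisition, 30 ms)
.bold_consts <- function(hemo, TE = 0.03, nu0 = 80.6, r0 = 110,
                         eps_rho = 0.4, V0 = 0.04) {
  list(k1 = 4.3 * nu0 * hemo$E0 * TE,
       k2 = eps_rho * r0 * hemo$E0 * TE,
       k3 = rep_len(1 - eps_rho, length(hemo$E0)),
       V0 = V0)
}

#' Full numeric parameter set of a DCM
#'
#' @param A 3 x 3 endogenous coupling matrix (Hz), target x source.
#' @param B 3 x 3 x 3 modulatory array (Hz), target x source x input.
#' @param C 3 x 3 driving-input matrix (Hz), node x input.
#' @param hemo A [hemo_params()] object.
#' @param noise_sd Observation noise SD (scalar or per region, BOLD % units).
#' @param spec Optional `dcm_spec`; when given, entries outside the masks
#'   must be zero.
#' @return A `dcm_params` object.
#' @export
dcm_params <- function(A, B = .zero_b(), C = .zero_nm(),
                       hemo = hemo_params(), noise_sd = 0, spec = NULL) {
  stopifnot(identical(dim(A), c(3L, 3L)), identical(dim(B), c(3L, 3L, 3L)),
            identical(dim(C), c(3L, 3L)), all(noise_sd >= 0))
  dimnames(A) <- list(.nodes, .nodes)
  dimnames(B) <- list(.nodes, .nodes, .input_names)
  dimnames(C) <- list(.nodes, .input_names)
  if (!is.null(spec)) {
    offdiag <- spec$a_mask; diag(offdiag) <- 1
    if (any(A[offdiag == 0] != 0) || any(B[spec$b_masks == 0] != 0) ||
        any(C[spec$c_mask == 0] != 0))
      stop("nonzero parameter outside the model's masks")
  }
  structure(list(A = A, B = B, C = C, hemo = hemo,
                 noise_sd = rep_len(noise_sd, 3)),
            class = "dcm_params")
}

#' @export
print.dcm_params <- function(x, ...) {
  cat("DCM parameters (Hz)\nA:\n"); print(round(x$A, 3))
  for (i in .input_names) if (any(x$B[, , i] != 0)) {
    cat(sprintf("B[%s]:\n", i)); print(round(x$B[, , i], 3))
  }
  if (any(x$C != 0)) { cat("C:\n"); print(round(x$C, 3)) }
  cat(sprintf("noise SD: %s\n", paste(round(x$noise_sd, 3), collapse = ", ")))
  invisible(x)
}

# ---- free-parameter packing --------------------------------------------
#
# The estimation vector holds, in order: the three self-connection
# log-scalings theta_ii (A_ii = -0.5 * exp(theta_ii), so stability of the
# decay is structural), the masked off-diagonal A entries, masked B entries,
# masked C entries, then the free hemodynamic parameters (a shared log-scale
# on kappa and one per-region log-scale on the transit time tau).

#' Free-parameter map of a model
#'
#' @param spec A `dcm_spec`.
#' @return Data frame with the name, type and array indices of every free
#'   parameter, in packing order.
#' @export
param_map <- function(spec) {
  rows <- list()
  add <- function(name, type, i = NA, j = NA, k = NA)
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, type = type, i = i, j = j, k = k,
      stringsAsFactors = FALSE)
  for (r in 1:3) add(paste0("self:", .nodes[r]), "self", r, r)
  off <- spec$a_mask; diag(off) <- 0
  for (j in 1:3) for (i in 1:3) if (off[i, j] == 1)
    add(sprintf("A:%s->%s", .nodes[j], .nodes[i]), "A", i, j)
  for (k in 1:3) {
    bm <- spec$b_masks[, , k]
    for (j in 1:3) for (i in 1:3) if (bm[i, j] == 1)
      add(sprintf("B:%s:%s->%s", .input_names[k], .nodes[j], .nodes[i]),
          "B", i, j, k)
  }
  for (k in 1:3) for (i in 1:3) if (spec$c_mask[i, k] == 1)
    add(sprintf("C:%s->%s", .input_names[k], .nodes[i]), "C", i = i, k = k)
  add("hemo:kappa", "kappa")
  for (r in 1:3) add(paste0("hemo:tau:", .nodes[r]), "tau", r)
  do.call(rbind, rows)
}

#' Unpack an estimation vector into numeric DCM parameters
#'
#' @param theta Named or ordered numeric vector matching [param_map()].
#' @param spec The `dcm_spec` the vector belongs to.
#' @param hemo_base Baseline hemodynamics scaled by the free log-parameters.
#' @param noise_sd Carried through to the result.
#' @return A `dcm_params` object.
#' @export
unpack_params <- function(theta, spec, hemo_base = hemo_params(),
                          noise_sd = 0) {
  map <- param_map(spec)
  stopifnot(length(theta) == nrow(map))
  A <- .zero_nn(); B <- .zero_b(); C <- .zero_nm()
  hemo <- hemo_base
  for (p in seq_len(nrow(map))) {
    v <- theta[p]
    switch(map$type[p],
           self  = { A[map$i[p], map$j[p]] <- -0.5 * exp(v) },
           A     = { A[map$i[p], map$j[p]] <- v },
           B     = { B[map$i[p], map$j[p], map$k[p]] <- v },
           C     = { C[map$i[p], map$k[p]] <- v },
           kappa = { hemo$kappa <- hemo_base$kappa * exp(v) },
           tau   = { hemo$tau[map$i[p]] <- hemo_base$tau[map$i[p]] * exp(v) })
  }
  dcm_params(A, B, C, hemo = hemo, noise_sd = noise_sd)
}

#' Pack numeric DCM parameters into an estimation vector
#'
#' Inverse of [unpack_params()]; self-connections map to
#' `log(-A_ii / 0.5)` and free hemodynamic parameters to log-ratios against
#' the baseline.
#' @param params A `dcm_params`.
#' @param spec The governing `dcm_spec`.
#' @param hemo_base Baseline hemodynamics.
#' @export
pack_params <- function(params, spec, hemo_base = hemo_params()) {
  map <- param_map(spec)
  theta <- numeric(nrow(map))
  for (p in seq_len(nrow(map))) {
    theta[p] <- switch(map$type[p],
      self  = log(-params$A[map$i[p], map$j[p]] / 0.5),
      A     = params$A[map$i[p], map$j[p]],
      B     = params$B[map$i[p], map$j[p], map$k[p]],
      C     = params$C[map$i[p], map$k[p]],
      kappa = log(params$hemo$kappa[1] / hemo_base$kappa[1]),
      tau   = log(params$hemo$tau[map$i[p]] / hemo_base$tau[map$i[p]]))
  }
  setNames(theta, map$name)
}
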