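# Model structure: which entries of A, B and C are free.
#
# All models in this package share the three-node visual hierarchy V1, V5,
# PPC with the reciprocal endogenous skeleton V1<->V5 and V5<->PPC (no direct
# V1<->PPC edge) and self-connections on the diagonal.

#' Endogenous connectivity skeleton
#'
#' Reciprocal V1-V5 and V5-PPC connections plus self-connections.
#' @return 3 x 3 binary mask, rows = target, columns = source.
#' @export
endogenous_mask <- function() {
  a <- diag(3)
  dimnames(a) <- list(.nodes, .nodes)
  a["V5", "V1"] <- 1   # V1 -> V5
  a["V1", "V5"] <- 1   # V5 -> V1
  a["PPC", "V5"] <- 1  # V5 -> PPC
  a["V5", "PPC"] <- 1  # PPC -> V5
  a
}

# empty mask helpers
.zero_nn <- function() matrix(0, 3, 3, dimnames = list(.nodes, .nodes))
.zero_nm <- function() matrix(0, 3, 3, dimnames = list(.nodes, .input_names))
.zero_b <- function() {
  array(0, c(3, 3, 3), dimnames = list(.nodes, .nodes, .input_names))
}

#' Specify a DCM structure
#'
#' @param a_mask 3 x 3 binary endogenous mask (target x source); the diagonal
#'   is always treated as present.
#' @param b_masks 3 x 3 x 3 binary array of modulatory effects
#'   (target x source x input).
#' @param c_mask 3 x 3 binary matrix of driving inputs (node x input).
#' @param family Optional family label.
#' @param gain_variant One of `"none"`, `"UNPREDICTABLE"`, `"ARBITRARY"`:
#'   which input (if any) modulates the V5 self-connection (synaptic gain).
#' @return A `dcm_spec` object.
#' @export
dcm_spec <- function(a_mask = endogenous_mask(), b_masks = .zero_b(),
                     c_mask = .zero_nm(), family = NA_character_,
                     gain_variant = c("none", "UNPREDICTABLE", "ARBITRARY")) {
  gain_variant <- match.arg(gain_variant)
  stopifnot(identical(dim(a_mask), c(3L, 3L)),
            identical(dim(b_masks), c(3L, 3L, 3L)),
            identical(dim(c_mask), c(3L, 3L)))
  a_mask <- (a_mask != 0) + 0
  diag(a_mask) <- 1
  b_masks <- (b_masks != 0) + 0
  c_mask <- (c_mask != 0) + 0
  dimnames(a_mask) <- list(.nodes, .nodes)
  dimnames(b_masks) <- list(.nodes, .nodes, .input_names)
  dimnames(c_mask) <- list(.nodes, .input_names)
  if (gain_variant != "none") b_masks["V5", "V5", gain_variant] <- 1
  spec <- structure(list(nodes = .nodes, a_mask = a_mask, b_masks = b_masks,
                         c_mask = c_mask, family = family,
                         gain_variant = gain_variant),
                    class = "dcm_spec")
  spec$id <- spec_id(spec)
  spec
}

#' Stable identifier of a model structure
#'
#' Hex encoding of the concatenated A/B/C mask bits; identical structures map
#' to identical ids across runs and platforms.
#' @param spec A `dcm_spec`.
#' @export
spec_id <- function(spec) {
  bits <- c(spec$a_mask, spec$b_masks, spec$c_mask)
  pad <- (4 - length(bits) %% 4) %% 4
  bits <- c(bits, rep(0, pad))
  nib <- matrix(bits, nrow = 4)
  paste(sprintf("%x", colSums(nib * c(8, 4, 2, 1))), collapse = "")
}

#' @export
print.dcm_spec <- function(x, ...) {
  cat("DCM specification", if (!is.na(x$family))
    sprintf("(family %s, gain %s)", x$family, x$gain_variant), "\n")
  cat("  id:", x$id, "\n")
  edges <- which(x$a_mask == 1 & row(x$a_mask) != col(x$a_mask))
  cat("  endogenous:",
      paste(sprintf("%s->%s", .nodes[col(x$a_mask)[edges]],
                    .nodes[row(x$a_mask)[edges]]), collapse = ", "), "\n")
  for (i in .input_names) {
    bm <- x$b_masks[, , i]
    if (any(bm == 1)) {
      e <- which(bm == 1)
      cat(sprintf("  %s modulates: %s\n", i,
                  paste(sprintf("%s->%s", .nodes[col(bm)[e]],
                                .nodes[row(bm)[e]]), collapse = ", ")))
    }
  }
  drv <- which(x$c_mask == 1)
  if (length(drv))
    cat("  driving:",
        paste(sprintf("%s->%s", .input_names[col(x$c_mask)[drv]],
                      .nodes[row(x$c_mask)[drv]]), collapse = ", "), "\n")
  cat("  free neural parameters:", n_neural_params(x), "\n")
  invisible(x)
}

#' Number of free neural parameters of a model
#'
#' Self-connections (always free) plus masked off-diagonal A, B and C
#' entries.
#' @param spec A `dcm_spec`.
#' @export
n_neural_params <- function(spec) {
  offdiag <- spec$a_mask
  diag(offdiag) <- 0
  as.integer(3 + sum(offdiag) + sum(spec$b_masks) + sum(spec$c_mask))
}
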