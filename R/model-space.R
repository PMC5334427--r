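# Enumeration of the factorial model spaces: three input families crossed
# with all modulatory on/off combinations and three synaptic-gain variants,
# plus the two smaller pre-selection spaces used to fix the driving inputs.

# the four inter-node connections, as (target, source) pairs
.edges <- list(c("V5", "V1"), c("PPC", "V5"), c("V1", "V5"), c("V5", "PPC"))

# family driving-input structures (nested: A within B within C)
.family_c_mask <- function(family) {
  cm <- .zero_nm()
  cm["V1", "MOTION"] <- 1
  cm["PPC", "ARBITRARY"] <- 1
  if (family %in% c("B", "C")) cm["V5", "MOTION"] <- 1
  if (family == "C") {
    cm["V5", "UNPREDICTABLE"] <- 1
    cm["V5", "ARBITRARY"] <- 1
  }
  cm
}

# b_masks with the mandatory MOTION modulation of V1 -> V5 plus the given
# on/off pattern of UNPREDICTABLE/ARBITRARY over the four connections
.b_masks_from_bits <- function(bits) {
  bm <- .zero_b()
  bm["V5", "V1", "MOTION"] <- 1
  k <- 1
  for (input in c("UNPREDICTABLE", "ARBITRARY")) {
    for (e in .edges) {
      if (bits[k] == 1) bm[e[1], e[2], input] <- 1
      k <- k + 1
    }
  }
  bm
}

.new_space <- function(models, description) {
  ids <- vapply(models, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate models in space")
  structure(list(models = models, description = description),
            class = "model_space")
}

#' The main 2304-model space
#'
#' Three driving-input families, each with all `2^8` on/off combinations of
#' the UNPREDICTABLE and ARBITRARY modulations over the four inter-node
#' connections (768 models), each replicated under three mutually exclusive
#' synaptic-gain variants of V5 (no gain modulation, UNPREDICTABLE, or
#' ARBITRARY on the V5 self-connection), giving 2304 models.  Every model
#' carries the MOTION modulation of V1 -> V5.
#'
#' @param gain_variants Include the synaptic-gain replication (default);
#'   `FALSE` returns the 768-model space.
#' @return A `model_space`.
#' @export
build_main_space <- function(gain_variants = TRUE) {
  gains <- if (gain_variants) c("none", "UNPREDICTABLE", "ARBITRARY")
           else "none"
  models <- list()
  for (fam in c("A", "B", "C")) {
    cm <- .family_c_mask(fam)
    for (code in 0:255) {
      bits <- as.integer(intToBits(code))[1:8]
      bm <- .b_masks_from_bits(bits)
      for (g in gains) {
        models[[length(models) + 1L]] <-
          dcm_spec(b_masks = bm, c_mask = cm, family = fam, gain_variant = g)
      }
    }
  }
  .new_space(models, if (gain_variants) "main" else "main-no-gain")
}

#' First pre-selection space (32 models of driving inputs)
#'
#' All combinations of the five candidate driving inputs MOTION -> V1,
#' UNPREDICTABLE -> V5/PPC and ARBITRARY -> V5/PPC.  Every model carries the
#' full modulatory structure (UNPREDICTABLE and ARBITRARY on all four
#' connections, MOTION on V1 -> V5).
#' @return A `model_space` of 32 models.
#' @export
build_preselect1_space <- function() {
  bm <- .b_masks_from_bits(rep(1, 8))
  flags <- rbind(c("V1", "MOTION"), c("V5", "UNPREDICTABLE"),
                 c("V5", "ARBITRARY"), c("PPC", "UNPREDICTABLE"),
                 c("PPC", "ARBITRARY"))
  models <- lapply(0:31, function(code) {
    bits <- as.integer(intToBits(code))[1:5]
    cm <- .zero_nm()
    for (i in 1:5) if (bits[i] == 1) cm[flags[i, 1], flags[i, 2]] <- 1
    dcm_spec(b_masks = bm, c_mask = cm, family = "preselect1")
  })
  .new_space(models, "preselect1")
}

#' Second pre-selection space (winner plus MOTION -> V5/PPC variants)
#'
#' The winning model of the first pre-selection against the three variants
#' that additionally allow MOTION to drive V5, PPC, or both.
#' @param winner A `dcm_spec` (the step-1 winner).
#' @return A `model_space` of 4 models differing only in the MOTION column of
#'   the driving-input mask.
#' @export
build_preselect2_space <- function(winner) {
  stopifnot(inherits(winner, "dcm_spec"))
  models <- lapply(0:3, function(code) {
    bits <- as.integer(intToBits(code))[1:2]
    cm <- winner$c_mask
    if (bits[1] == 1) cm["V5", "MOTION"] <- 1
    if (bits[2] == 1) cm["PPC", "MOTION"] <- 1
    dcm_spec(a_mask = winner$a_mask, b_masks = winner$b_masks, c_mask = cm,
             family = "preselect2")
  })
  .new_space(models, "preselect2")
}

#' Size of the exhaustive model space
#'
#' Number of structurally distinct bilinear DCMs over `n` nodes and `m`
#' inputs when every connection, modulation and driving input may be switched
#' on or off independently: `2^(n*n*(m+1) + m*n)`.
#'
#' @param n Number of nodes.
#' @param m Number of inputs.
#' @return The count, as a double (exact for the sizes of interest).
#' @export
exhaustive_count <- function(n, m) {
  stopifnot(n >= 1, m >= 0)
  2^(n * n * (m + 1) + m * n)
}

#' @export
print.model_space <- function(x, ...) {
  fams <- table(vapply(x$models, `[[`, character(1), "family"))
  cat(sprintf("Model space '%s': %d models\n", x$description,
              length(x$models)))
  cat("  families:", paste(sprintf("%s (%d)", names(fams), fams),
                           collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.model_space <- function(x) length(x$models)

#' Index table of a model space
#'
#' @param space A `model_space`.
#' @return Data frame with `id`, `family`, `gain_variant`, `n_free_params`.
#' @export
space_index <- function(space) {
  data.frame(
    id = vapply(space$models, `[[`, character(1), "id"),
    family = vapply(space$models, `[[`, character(1), "family"),
    gain_variant = vapply(space$models, `[[`, character(1), "gain_variant"),
    n_free_params = vapply(space$models, n_neural_params, integer(1)),
    stringsAsFactors = FALSE)
}

#' Export a model space as JSON-lines plus a CSV index
#'
#' One JSON document per line per model (masks and labels) and a CSV index
#' with id, family, gain variant and free-parameter count.
#' @param space A `model_space`.
#' @param path Base path; writes `<path>.jsonl` and `<path>.csv`.
#' @export
write_model_space <- function(space, path) {
  lines <- vapply(space$models, function(s) {
    jsonlite::toJSON(list(id = s$id, family = s$family,
                          gain_variant = s$gain_variant,
                          a_mask = s$a_mask, b_masks = s$b_masks,
                          c_mask = s$c_mask),
                     auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, paste0(path, ".jsonl"))
  write.table(space_index(space), paste0(path, ".csv"), sep = ",",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
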