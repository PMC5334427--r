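# Reference network used as simulation ground truth, and the synthetic
# cohort generator that exercises the full pipeline.

#' Reference model structure of the motion-predictability network
#'
#' The winning structure of the active response mode: MOTION drives V1 and
#' V5, ARBITRARY perturbs PPC, and all three inputs (MOTION, UNPREDICTABLE,
#' ARBITRARY) modulate the forward connection V1 -> V5; no synaptic-gain
#' modulation.
#' @return A `dcm_spec`.
#' @export
reference_model <- function() {
  bm <- .zero_b()
  bm["V5", "V1", ] <- 1  # all three inputs modulate V1 -> V5
  cm <- .zero_nm()
  cm["V1", "MOTION"] <- 1
  cm["V5", "MOTION"] <- 1
  cm["PPC", "ARBITRARY"] <- 1
  dcm_spec(b_masks = bm, c_mask = cm, family = "B")
}

#' Reference coupling values of the motion-predictability network
#'
#' Group-averaged coupling strengths of the active-mode winning model, used
#' as generating values for synthetic cohorts: the endogenous hierarchy
#' (negative V1 -> V5, strong V5 -> PPC, inhibitory feedback), a strong
#' MOTION drive on V5 with a weak one on V1, a small inhibitory ARBITRARY
#' perturbation of PPC, and modulations of V1 -> V5 by all three inputs
#' (negative for MOTION, increasingly positive with unpredictability).
#'
#' @param noise_sd Observation noise SD carried in the parameter set.
#' @return A `dcm_params` consistent with [reference_model()].
#' @export
reference_params <- function(noise_sd = 0) {
  A <- matrix(c(-0.61, 0.62, 0,
                -0.43, -0.24, -0.59,
                0, 1.05, -0.69),
              3, 3, byrow = TRUE, dimnames = list(.nodes, .nodes))
  B <- .zero_b()
  B["V5", "V1", "MOTION"] <- -0.51
  B["V5", "V1", "UNPREDICTABLE"] <- 0.28
  B["V5", "V1", "ARBITRARY"] <- 0.16
  C <- .zero_nm()
  C["V1", "MOTION"] <- 0.09
  C["V5", "MOTION"] <- 1.02
  C["PPC", "ARBITRARY"] <- -0.10
  dcm_params(A, B, C, noise_sd = noise_sd, spec = reference_model())
}

#' A 16-model subspace around the reference model
#'
#' Driving inputs fixed to the reference structure; the UNPREDICTABLE and
#' ARBITRARY modulations of the two forward connections (V1 -> V5 and
#' V5 -> PPC) are switched on/off in all `2^4` combinations (MOTION on
#' V1 -> V5 stays mandatory).  Contains the reference model.
#' @return A `model_space` of 16 models.
#' @export
forward_modulation_subspace <- function() {
  cm <- reference_model()$c_mask
  models <- lapply(0:15, function(code) {
    bits <- as.integer(intToBits(code))[1:4]
    bm <- .zero_b()
    bm["V5", "V1", "MOTION"] <- 1
    if (bits[1] == 1) bm["V5", "V1", "UNPREDICTABLE"] <- 1
    if (bits[2] == 1) bm["PPC", "V5", "UNPREDICTABLE"] <- 1
    if (bits[3] == 1) bm["V5", "V1", "ARBITRARY"] <- 1
    if (bits[4] == 1) bm["PPC", "V5", "ARBITRARY"] <- 1
    dcm_spec(b_masks = bm, c_mask = cm, family = "B")
  })
  .new_space(models, "forward-modulation-16")
}

#' Simulate a synthetic cohort
#'
#' Each subject gets an independently randomized session schedule, the
#' noiseless BOLD prediction of the generating parameters, and i.i.d.
#' Gaussian scan noise scaled per region to a target signal-to-noise ratio
#' (`SD(signal) / SD(noise)`).
#'
#' @param n_subjects Cohort size.
#' @param params Generating [dcm_params()] (defaults to the reference
#'   values).
#' @param snr Per-region signal-to-noise ratio of the simulated scans.
#' @param n_scans,tr Acquisition window.
#' @param seed Base seed; subject `i` uses `seed * 100 + i` for both the
#'   schedule and the noise.
#' @return List of subjects, each with `y` (`bold_series`), `inputs`,
#'   `design`, `noise_sd` and `seed`.
#' @export
simulate_cohort <- function(n_subjects = 10, params = reference_params(),
                            snr = 3, n_scans = 512, tr = 1.8, seed = 1) {
  stopifnot(n_subjects >= 1)
  lapply(seq_len(n_subjects), function(i) {
    s <- seed * 100 + i
    design <- build_session(seed = s)
    inputs <- build_inputs(design, n_scans = n_scans, tr = tr,
                           truncate = "silent")
    clean <- predict_bold(params, inputs)
    noise_sd <- apply(clean$y, 2, sd) / snr
    p <- params
    p$noise_sd <- noise_sd
    y <- simulate_bold(p, inputs, seed = s)
    list(y = y, inputs = inputs, design = design, noise_sd = noise_sd,
         seed = s)
  })
}
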