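# Shared fixtures, built in code.  Expensive objects are computed once per
# test run and cached across test files.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    assign(key, force(expr), envir = .fixture_cache)
  .fixture_cache[[key]]
}

# a short session design (9 blocks of 12 s) for desk-scale inversion tests
mini_design <- function(seed = 1) {
  set.seed(seed)
  cond <- sample(rep(c("PREDICTABLE", "RANDOM", "ARBITRARY"), 3))
  n <- length(cond)
  onset <- 8 + (seq_len(n) - 1) * 20
  structure(
    data.frame(onset = onset, duration = 12, condition = cond,
               jitter = 0, baseline = 8, stringsAsFactors = FALSE),
    class = c("session_design", "data.frame"))
}

mini_inputs <- function(seed = 1, n_scans = 104, tr = 1.8) {
  build_inputs(mini_design(seed), n_scans = n_scans, tr = tr,
               truncate = "silent")
}

# constant-input object for steady-state checks
constant_inputs <- function(u_row, t_end = 60, dt = 0.1125, tr = 1.8) {
  Tm <- ceiling(t_end / dt / 16) * 16
  u <- matrix(rep(u_row, each = Tm), Tm, 3,
              dimnames = list(NULL, c("MOTION", "UNPREDICTABLE",
                                      "ARBITRARY")))
  structure(list(u = u, dt_micro = dt, names = colnames(u),
                 n_scans = Tm / 16, tr = tr),
            class = "dcm_inputs")
}

# a simple stable parameter set used by forward-model tests
toy_params <- function(noise_sd = 0) {
  A <- matrix(c(-0.5, 0.3, 0,
                0.2, -0.4, -0.2,
                0, 0.4, -0.6), 3, 3, byrow = TRUE)
  C <- matrix(0, 3, 3)
  C[1, 1] <- 0.8
  dcm_params(A, C = C, noise_sd = noise_sd)
}
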