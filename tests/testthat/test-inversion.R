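# Variational-Laplace inversion: analytic oracles, self-consistency,
# parameter recovery and the Occam property of the free energy.

test_that("priors cover exactly the masked parameters and imply stability", {
  spec <- reference_model()
  pr <- dcm_priors(spec)
  expect_length(pr$mean, 17)  # 13 neural + 4 hemodynamic
  expect_equal(sum(pr$map$type %in% c("self", "A", "B", "C")), 13)
  expect_false(any(grepl("B:UNPREDICTABLE:V5->PPC", names(pr$mean))))
  draws <- draw_from_prior(pr, 1000, seed = 17)
  stable <- apply(draws, 1, function(th) {
    A <- unpack_params(th, spec)$A
    all(Re(eigen(A, only.values = TRUE)$values) < 0)
  })
  expect_equal(sum(stable), 1000)
  # the truncation is doing real work: without it, a substantial fraction
  # of unit-variance draws is dynamically unstable
  raw <- draw_from_prior(pr, 500, seed = 18, require_stable = FALSE)
  raw_stable <- apply(raw, 1, function(th) {
    A <- unpack_params(th, spec)$A
    all(Re(eigen(A, only.values = TRUE)$values) < 0)
  })
  expect_lt(mean(raw_stable), 0.85)
  expect_gt(mean(raw_stable), 0.3)
})

test_that("noiseless data generated at the prior mean are self-consistent", {
  spec <- reference_model()
  pr <- dcm_priors(spec)
  inp <- mini_inputs()
  p0 <- unpack_params(pr$mean, spec)
  y <- predict_bold(p0, inp)
  fit <- dcm(y, inp, spec, lambda_fixed = c(100, 100, 100))
  expect_lt(sqrt(sum((fit$mean - pr$mean)^2)), 1e-3)
})

test_that("free energy matches the closed-form linear-Gaussian evidence", {
  set.seed(33)
  n <- 60; p <- 4
  X <- matrix(rnorm(n * p), n, p)
  m0 <- rnorm(p, 0, 0.3)
  v0 <- runif(p, 0.2, 1.5)
  sigma <- 0.4
  theta_true <- rnorm(p, m0, sqrt(v0))
  y <- drop(X %*% theta_true) + rnorm(n, 0, sigma)
  fit <- vl_invert(function(th) drop(X %*% th), y, prior_mean = m0,
                   prior_var = v0, lambda_fixed = 1 / sigma^2, tol = 1e-8)
  # closed form: y ~ N(X m0, sigma^2 I + X C0 X')
  Cy <- sigma^2 * diag(n) + X %*% (v0 * t(X))
  ch <- chol(Cy)
  r <- y - drop(X %*% m0)
  logev <- -0.5 * n * log(2 * pi) - sum(log(diag(ch))) -
    0.5 * sum(backsolve(ch, r, transpose = TRUE)^2)
  expect_lt(abs(fit$F - logev), 1e-3)
  # posterior moments match the conjugate solution
  P <- crossprod(X) / sigma^2 + diag(1 / v0)
  mu <- solve(P, crossprod(X, y) / sigma^2 + m0 / v0)
  expect_equal(unname(fit$mean), drop(mu), tolerance = 1e-6)
})

test_that("accepted Gauss-Newton steps ascend the free energy", {
  fit <- cached("mini_fit", {
    spec <- reference_model()
    truth <- reference_params()
    inp <- mini_inputs(seed = 2)
    clean <- predict_bold(truth, inp)
    p <- truth; p$noise_sd <- apply(clean$y, 2, sd) / 3
    y <- simulate_bold(p, inp, seed = 2)
    dcm(y, inp, spec)
  })
  expect_true(fit$converged)
  # the returned fit is the best iterate; the ascent shows no sustained or
  # large decrease (small terminal wiggle reflects the curvature refresh)
  expect_equal(fit$F, max(fit$F_trace))
  expect_true(all(diff(fit$F_trace) > -0.5))
  expect_gt(fit$F, fit$F_trace[1])
  # complexity (KL) penalty is strictly positive: F below the accuracy term
  T_r <- nrow(fit$y)
  L <- sum(0.5 * T_r * fit$h - 0.5 * fit$lambda *
             colSums((fit$y - fit$fitted)^2)) -
    0.5 * 3 * T_r * log(2 * pi)
  expect_lt(fit$F, L)
})

test_that("log_evidence returns F and flags unconverged fits", {
  fit <- cached("mini_fit", stop("fixture missing"))
  expect_equal(as.numeric(log_evidence(fit)), fit$F)
  bad <- fit; bad$converged <- FALSE
  expect_warning(Fv <- log_evidence(bad), "converge")
  expect_false(attr(Fv, "converged"))
})

test_that("generating parameters are recovered across seeded replicates", {
  spec <- reference_model()
  truth <- reference_params()
  th <- pack_params(truth, spec)
  neural <- which(dcm_priors(spec)$map$type %in% c("self", "A", "B", "C"))
  mods <- c("B:MOTION:V1->V5", "B:UNPREDICTABLE:V1->V5",
            "B:ARBITRARY:V1->V5")
  fits <- cached("recovery_fits", {
    cohort <- simulate_cohort(20, n_scans = 256, seed = 3)
    lapply(cohort, function(s) dcm(s$y, s$inputs, spec, maxit = 96))
  })
  inside <- vapply(fits, function(f) {
    sd <- sqrt(diag(f$cov))
    mean(abs(f$mean[neural] - th[neural]) <= 1.96 * sd[neural])
  }, numeric(1))
  # each generating neural parameter inside the 95% marginal interval in
  # at least 90% of replicates (here: mean coverage across parameters)
  expect_gte(mean(inside), 0.9)
  bias <- rowMeans(vapply(fits, function(f) f$mean[mods] - th[mods],
                          numeric(3)))
  expect_lt(mean(abs(bias)), 0.1)
})

test_that("the free energy penalizes spuriously modulated models", {
  spec <- reference_model()
  spurious <- spec
  bm <- spec$b_masks
  bm["V1", "V5", "UNPREDICTABLE"] <- 1
  bm["V5", "PPC", "UNPREDICTABLE"] <- 1
  bm["V1", "V5", "ARBITRARY"] <- 1
  bm["V5", "PPC", "ARBITRARY"] <- 1
  spurious <- dcm_spec(b_masks = bm, c_mask = spec$c_mask)
  truth <- reference_params()
  dF <- vapply(1:10, function(i) {
    d <- build_session(seed = 400 + i)
    inp <- build_inputs(d, n_scans = 256, truncate = "silent")
    clean <- predict_bold(truth, inp)
    p <- truth; p$noise_sd <- apply(clean$y, 2, sd) / 3
    y <- simulate_bold(p, inp, seed = 400 + i)
    f_true <- dcm(y, inp, spec, maxit = 96)
    f_spur <- dcm(y, inp, spurious, maxit = 96)
    f_true$F - f_spur$F
  }, numeric(1))
  expect_gt(mean(dF), 0)
})

test_that("invalid inputs to the engine are rejected", {
  expect_error(vl_invert(function(th) rep(NaN, 5), rnorm(5), 0, 1),
               "invalid")
  spec <- reference_model()
  inp <- mini_inputs()
  y <- matrix(0, 50, 3)  # wrong number of scans
  expect_error(dcm(y, inp, spec), "different numbers of scans")
})
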