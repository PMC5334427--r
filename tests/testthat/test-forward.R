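# Generative model: bilinear neuronal dynamics and balloon hemodynamics.

test_that("the neuronal derivative evaluates the bilinear equation", {
  p <- toy_params()
  expect_equal(unname(neural_derivative(c(0, 0, 0), c(0, 0, 0), p)),
               c(0, 0, 0))
  # at rest, the derivative is exactly C u
  expect_equal(neural_derivative(c(0, 0, 0), c(1, 0, 0), p),
               drop(p$C %*% c(1, 0, 0)), ignore_attr = TRUE)
  # generic point: (A + sum u_i B_i) x + C u, assembled independently
  p$B[2, 1, 1] <- 0.3
  x <- c(0.5, -0.2, 0.1); u <- c(1, 1, 0)
  M <- p$A + p$B[, , 1] * u[1] + p$B[, , 2] * u[2]
  expect_equal(neural_derivative(x, u, p), drop(M %*% x + p$C %*% u),
               ignore_attr = TRUE)
  expect_error(neural_derivative(c(NA, 0, 0), u, p), "NaN")
})

test_that("constant input drives the states to the analytic steady state", {
  p <- toy_params()
  inp <- constant_inputs(c(1, 0, 0), t_end = 80)
  st <- integrate_states(p, inp)
  x_star <- drop(solve(-p$A) %*% p$C %*% c(1, 0, 0))
  t_settle <- 20 / abs(max(Re(eigen(p$A)$values)))
  late <- st$time >= t_settle
  expect_lt(max(abs(sweep(st$x[late, ], 2, x_star))), 1e-6)
})

test_that("doubling C doubles the neuronal response when B = 0", {
  p <- toy_params()
  p2 <- p; p2$C <- 2 * p$C
  inp <- mini_inputs()
  x1 <- integrate_states(p, inp)$x
  x2 <- integrate_states(p2, inp)$x
  expect_equal(x2, 2 * x1, tolerance = 1e-12)
})

test_that("matrix-exponential neuronal updates match a fine-step RK4 oracle", {
  set.seed(21)
  inp <- mini_inputs()
  u <- inp$u; dt <- inp$dt_micro
  for (rep in 1:20) {
    # random stable system: negative decay plus small couplings
    A <- matrix(rnorm(9, 0, 0.15), 3, 3)
    diag(A) <- -runif(3, 0.4, 0.8)
    if (any(Re(eigen(A)$values) >= 0)) next
    B <- array(rnorm(27, 0, 0.05), c(3, 3, 3))
    C <- matrix(rnorm(9, 0, 0.3), 3, 3)
    p <- dcm_params(A, B, C)
    x_pkg <- integrate_states(p, inp)$x
    # independent oracle: classical RK4 at dt/10 on the bilinear ODE
    x <- c(0, 0, 0)
    h <- dt / 10
    worst <- 0
    for (k in seq_len(200)) {  # first 200 bins are enough to discriminate
      uk <- u[k, ]
      M <- A + uk[1] * B[, , 1] + uk[2] * B[, , 2] + uk[3] * B[, , 3]
      cu <- drop(C %*% uk)
      f <- function(x) drop(M %*% x) + cu
      for (s in 1:10) {
        k1 <- f(x); k2 <- f(x + h / 2 * k1); k3 <- f(x + h / 2 * k2)
        k4 <- f(x + h * k3)
        x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      }
      worst <- max(worst, abs(x - x_pkg[k + 1, ]))
    }
    expect_lt(worst, 1e-8)
  }
})

test_that("without perturbation the full system stays exactly at rest", {
  p <- toy_params()
  p$C[] <- 0
  inp <- mini_inputs()
  st <- integrate_states(p, inp)
  expect_equal(max(abs(st$x)), 0)
  expect_equal(max(abs(st$y)), 0)
  expect_equal(range(st$f), c(1, 1))
})

test_that("regions unreachable from the inputs show no BOLD response", {
  A <- diag(c(-0.5, -0.5, -0.5))  # no inter-node coupling
  C <- matrix(0, 3, 3); C[1, 1] <- 1
  p <- dcm_params(A, C = C)
  y <- predict_bold(p, mini_inputs())$y
  expect_gt(max(abs(y[, "V1"])), 0.1)
  expect_equal(max(abs(y[, c("V5", "PPC")])), 0)
})

test_that("the BOLD impulse response peaks 3-6 s after a brief input", {
  A <- diag(c(-0.5, -0.5, -0.5))
  C <- matrix(0, 3, 3); C[1, 1] <- 1
  p <- dcm_params(A, C = C)
  dt <- 0.1125
  Tm <- 32 * 16
  u <- matrix(0, Tm, 3, dimnames = list(NULL, c("MOTION", "UNPREDICTABLE",
                                                "ARBITRARY")))
  u[seq_len(ceiling(1 / dt)), 1] <- 1  # 1 s bump starting at t = 0
  inp <- structure(list(u = u, dt_micro = dt, names = colnames(u),
                        n_scans = 32, tr = 1.8), class = "dcm_inputs")
  st <- integrate_states(p, inp)
  # BOLD at microtime resolution from the hemodynamic states
  k <- dcmbold:::.bold_consts(p$hemo)
  y_micro <- 100 * k$V0 * (k$k1[1] * (1 - st$q[, 1]) +
                           k$k2[1] * (1 - st$q[, 1] / st$v[, 1]) +
                           k$k3[1] * (1 - st$v[, 1]))
  lag <- st$time[which.max(y_micro)] - st$time[which.max(st$x[, 1])]
  expect_gt(lag, 3)
  expect_lt(lag, 6)
})

test_that("unstable endogenous dynamics are rejected before integration", {
  A <- matrix(c(0.1, 0, 0, 0, -0.5, 0, 0, 0, -0.5), 3, 3)
  p <- dcm_params(A)
  expect_error(predict_bold(p, mini_inputs()), "unstable")
})

test_that("simulated noise matches its nominal level and seed", {
  d <- build_session(seed = 3)
  inp <- build_inputs(d, n_scans = 512, truncate = "silent")
  p <- toy_params(noise_sd = 0.25)
  clean <- predict_bold(p, inp)
  noisy <- simulate_bold(p, inp, seed = 8)
  expect_identical(simulate_bold(p, inp, seed = 8)$y, noisy$y)
  resid_sd <- apply(noisy$y - clean$y, 2, sd)
  expect_true(all(abs(resid_sd - 0.25) / 0.25 < 0.05))
  p0 <- p; p0$noise_sd <- 0
  expect_identical(simulate_bold(p0, inp, seed = 8)$y, clean$y)
})

test_that("parameter packing round-trips through the estimation vector", {
  spec <- reference_model()
  truth <- reference_params()
  th <- pack_params(truth, spec)
  expect_equal(length(th), 17)  # 13 neural + 4 hemodynamic
  back <- unpack_params(th, spec)
  expect_equal(back$A, truth$A, tolerance = 1e-12)
  expect_equal(back$B, truth$B)
  expect_equal(back$C, truth$C)
  # masked-out entries are absent from the free-parameter vector
  expect_false(any(grepl("A:V1->PPC|A:PPC->V1", names(th))))
  expect_equal(n_neural_params(spec), 13)
})

test_that("BOLD series round-trip through CSV + JSON sidecar", {
  p <- toy_params(noise_sd = 0.1)
  b <- simulate_bold(p, mini_inputs(), seed = 2)
  f <- tempfile(fileext = ".csv")
  write_bold(b, f, meta = list(seed = 2))
  back <- read_bold(f)
  expect_equal(back$y, b$y, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$tr, b$tr)
  expect_equal(back$meta$seed, 2)
})
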