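# Ball-motion simulator: exact event times, reflection rules, schedule
# counterbalancing.

test_that("specular reflection matches the closed-form time-to-boundary", {
  geom <- frame_geometry()  # effective play area 22 x 14, speed 6
  blk <- simulate_block("PREDICTABLE", duration = 5, geometry = geom,
                        initial_state = list(position = c(0, 0),
                                             angle = pi / 4))
  # moving at 45 deg from the centre, the top wall (7 deg away) comes first
  t_oracle <- 7 / (6 * sin(pi / 4))
  expect_equal(blk$events$time[1], t_oracle, tolerance = 1e-12)
  expect_equal(blk$events$kind[1], "WALL")
  # outgoing velocity: horizontal component kept, vertical flipped
  after <- blk$trajectory[blk$trajectory$time > t_oracle + 0.02, ][1, ]
  expect_equal(after$vx, 6 * cos(pi / 4), tolerance = 1e-9)
  expect_equal(after$vy, -6 * sin(pi / 4), tolerance = 1e-9)
})

test_that("predictable wall-event times match the boundary oracle on random
           initial conditions", {
  geom <- frame_geometry()
  set.seed(7)
  for (i in 1:100) {
    pos <- c(runif(1, -10, 10), runif(1, -6, 6))
    ang <- runif(1, 0, 2 * pi)
    blk <- simulate_block("PREDICTABLE", duration = 3, geometry = geom,
                          initial_state = list(position = pos, angle = ang))
    v <- 6 * c(cos(ang), sin(ang))
    tx <- if (v[1] > 0) (11 - pos[1]) / v[1] else (-11 - pos[1]) / v[1]
    ty <- if (v[2] > 0) (7 - pos[2]) / v[2] else (-7 - pos[2]) / v[2]
    t1 <- min(tx, ty, na.rm = TRUE)
    if (t1 < 3)
      expect_equal(blk$events$time[1], t1, tolerance = 1e-9)
    else
      expect_equal(nrow(blk$events), 0)
  }
})

test_that("speed is constant and the ball stays inside the play area", {
  geom <- frame_geometry()
  for (cond in c("PREDICTABLE", "RANDOM", "ARBITRARY")) {
    blk <- simulate_block(cond, duration = 30, geometry = geom,
                          hazard_rate = 0.3, seed = 11)
    tr <- blk$trajectory
    expect_equal(sqrt(tr$vx^2 + tr$vy^2), rep(6, nrow(tr)),
                 tolerance = 1e-12)
    tol <- 0.01 * 6  # one 100 Hz sample at full speed
    expect_true(all(abs(tr$x) <= 11 + tol))
    expect_true(all(abs(tr$y) <= 7 + tol))
  }
})

test_that("ARBITRARY with zero hazard reproduces RANDOM exactly", {
  a <- simulate_block("ARBITRARY", 25, hazard_rate = 0, seed = 3)
  r <- simulate_block("RANDOM", 25, hazard_rate = 0, seed = 3)
  expect_identical(a$events, r$events)
  expect_identical(a$trajectory, r$trajectory)
})

test_that("degenerate and invalid block arguments are handled", {
  blk <- simulate_block("PREDICTABLE", 0,
                        initial_state = list(position = c(1, 2), angle = 0))
  expect_equal(nrow(blk$trajectory), 1)
  expect_equal(nrow(blk$events), 0)
  expect_error(simulate_block("PREDICTABLE", 5,
                              initial_state = list(position = c(40, 0))),
               "outside")
})

test_that("session schedules are counterbalanced and reproducible", {
  d <- build_session(seed = 5)
  expect_equal(nrow(d), 30)
  expect_equal(as.integer(table(d$condition)), rep(10L, 3))
  # per-condition multisets: {3, 3, 4} over the three levels, rotated so
  # the session totals per level are equal
  for (col in c("duration", "jitter", "baseline")) {
    per_cond <- tapply(d[[col]], d$condition,
                       function(x) sort(as.integer(table(x))))
    for (tab in per_cond) expect_equal(tab, c(3L, 3L, 4L))
    expect_equal(as.integer(table(d[[col]])), rep(10L, 3))
  }
  expect_equal(mean(d$baseline), 10)  # baselines average exactly 10 s
  expect_true(all(diff(d$onset) > 0))
  # onsets consistent with preceding durations + baselines + jitters
  expect_equal(d$onset,
               cumsum(d$baseline + d$jitter + c(0, head(d$duration, -1))))
  expect_identical(build_session(seed = 5), d)
  expect_error(build_session(n_blocks = 20), "divisible")
})

test_that("direction-change counts behave per condition", {
  expect_equal(count_changes(data.frame(onset_s = numeric(0),
                                        kind = character(0),
                                        condition = character(0),
                                        block = integer(0)))$total,
               c(0, 0, 0))
  d <- build_session(seed = 9)
  ses <- simulate_session(d, hazard_rate = default_hazard(), seed = 9)
  cc <- count_changes(ses$events)
  tot <- setNames(cc$total, cc$condition)
  # identical wall-hit kinematics up to the emergent angle
  expect_lt(abs(tot["PREDICTABLE"] - tot["RANDOM"]) /
              tot["PREDICTABLE"], 0.35)
  expect_gt(tot["ARBITRARY"], tot["PREDICTABLE"])
  # MIDFIELD changes occur only in ARBITRARY blocks
  mids <- ses$events[ses$events$kind == "MIDFIELD", ]
  expect_true(all(mids$condition == "ARBITRARY"))
  # seeded reproducibility of the full event stream
  ses2 <- simulate_session(d, hazard_rate = default_hazard(), seed = 9)
  expect_identical(ses$events, ses2$events)
})

test_that("event and schedule TSV round-trips preserve the data", {
  d <- build_session(seed = 2)
  ses <- simulate_session(d, seed = 2)
  f <- tempfile(fileext = ".tsv")
  write_events_tsv(ses$events, f)
  back <- read_events_tsv(f)
  expect_equal(back$onset_s, ses$events$onset_s)
  expect_equal(back$kind, ses$events$kind)
  f2 <- tempfile(fileext = ".tsv")
  write_schedule_tsv(d, f2)
  d2 <- read_schedule_tsv(f2)
  expect_equal(d2$onset, d$onset)
  expect_equal(d2$duration, d$duration)
  expect_equal(d2$condition, d$condition)
})
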