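# Stimulus simulator: a ball moving at constant speed inside a rectangular
# frame under three predictability regimes, plus the counterbalanced block
# schedule of a two-run session.

#' Frame geometry of the moving-ball display
#'
#' The ball moves inside a rectangular frame; its centre is confined to the
#' effective play area `(width - ball_diameter) x (height - ball_diameter)`.
#'
#' @param width,height Frame size in degrees visual angle.
#' @param ball_diameter Ball diameter in degrees.
#' @param speed Constant ball speed in degrees per second.
#' @return An object of class `frame_geometry`.
#' @export
frame_geometry <- function(width = 24, height = 16, ball_diameter = 2,
                           speed = 6) {
  stopifnot(width > height, height > ball_diameter, ball_diameter > 0,
            speed > 0)
  structure(
    list(width = width, height = height, ball_diameter = ball_diameter,
         speed = speed,
         half_x = (width - ball_diameter) / 2,
         half_y = (height - ball_diameter) / 2),
    class = "frame_geometry")
}

#' @export
print.frame_geometry <- function(x, ...) {
  cat(sprintf("Frame %g x %g deg, ball %g deg, speed %g deg/s\n",
              x$width, x$height, x$ball_diameter, x$speed))
  cat(sprintf("Effective play area: %g x %g deg (centre coordinates)\n",
              2 * x$half_x, 2 * x$half_y))
  invisible(x)
}

.conditions <- c("PREDICTABLE", "RANDOM", "ARBITRARY")

# run code under a temporary RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}

# exact time to the next wall contact along the current direction
.time_to_wall <- function(pos, vel, geom) {
  tx <- if (vel[1] > 1e-12) (geom$half_x - pos[1]) / vel[1]
        else if (vel[1] < -1e-12) (-geom$half_x - pos[1]) / vel[1]
        else Inf
  ty <- if (vel[2] > 1e-12) (geom$half_y - pos[2]) / vel[2]
        else if (vel[2] < -1e-12) (-geom$half_y - pos[2]) / vel[2]
        else Inf
  c(tx = max(tx, 0), ty = max(ty, 0))
}

#' Simulate one block of ball motion
#'
#' Event-driven simulation with exact event times.  Under `PREDICTABLE` the
#' ball reflects specularly from the walls; under `RANDOM` the emergent angle
#' at each wall contact is drawn uniformly over the inward half-plane
#' (excluding a 5-degree grazing band); `ARBITRARY` additionally inserts
#' mid-field direction changes as a Poisson process with rate `hazard_rate`,
#' the new direction drawn uniformly on the circle.
#'
#' @param condition One of `"PREDICTABLE"`, `"RANDOM"`, `"ARBITRARY"`.
#' @param duration Block duration in seconds (0 gives an empty trajectory
#'   holding only the initial state).
#' @param geometry A [frame_geometry()].
#' @param initial_state List with `position` (centre coordinates, degrees) and
#'   optionally `angle` (radians; drawn uniformly when absent).
#' @param hazard_rate Mid-field direction-change rate (1/s); used only for
#'   `ARBITRARY`.  With `hazard_rate = 0` the event stream is identical to
#'   `RANDOM` under the same RNG state.
#' @param sample_hz Trajectory export rate; event times are kept exact.
#' @param seed Optional seed (caller RNG state is restored).
#' @return List with `trajectory` (data frame `time, x, y, vx, vy`), `events`
#'   (data frame `time, kind` with kind `WALL` or `MIDFIELD`) and
#'   `final_state`.
#' @export
simulate_block <- function(condition, duration, geometry = frame_geometry(),
                           initial_state = list(position = c(0, 0)),
                           hazard_rate = 0, sample_hz = 100, seed = NULL) {
  condition <- match.arg(condition, .conditions)
  stopifnot(duration >= 0, hazard_rate >= 0)
  pos <- initial_state$position
  if (abs(pos[1]) > geometry$half_x + 1e-9 ||
      abs(pos[2]) > geometry$half_y + 1e-9)
    stop("initial position outside the effective play area")
  .with_seed(seed, {
    ang <- if (is.null(initial_state$angle)) runif(1, 0, 2 * pi)
           else initial_state$angle
    graze <- 5 * pi / 180
    speed <- geometry$speed

    seg_t <- numeric(0); seg_x <- numeric(0); seg_y <- numeric(0)
    seg_a <- numeric(0)
    ev_t <- numeric(0); ev_k <- character(0)
    t <- 0
    repeat {
      seg_t <- c(seg_t, t); seg_x <- c(seg_x, pos[1]); seg_y <- c(seg_y, pos[2])
      seg_a <- c(seg_a, ang)
      if (t >= duration) break
      vel <- speed * c(cos(ang), sin(ang))
      tw <- .time_to_wall(pos, vel, geometry)
      t_wall <- min(tw)
      t_mid <- if (condition == "ARBITRARY" && hazard_rate > 0)
        rexp(1, hazard_rate) else Inf
      t_next <- min(t_wall, t_mid)
      if (t + t_next >= duration) {
        pos <- pos + vel * (duration - t)
        t <- duration
        next
      }
      pos <- pos + vel * t_next
      t <- t + t_next
      if (t_mid < t_wall) {
        ang <- runif(1, 0, 2 * pi)
        ev_t <- c(ev_t, t); ev_k <- c(ev_k, "MIDFIELD")
      } else {
        corner <- is.finite(tw["tx"]) && is.finite(tw["ty"]) &&
          abs(tw["tx"] - tw["ty"]) < 1e-12
        hit_x <- corner || tw["tx"] < tw["ty"]
        hit_y <- corner || tw["ty"] <= tw["tx"]
        if (hit_x) pos[1] <- sign(vel[1]) * geometry$half_x
        if (hit_y) pos[2] <- sign(vel[2]) * geometry$half_y
        if (condition == "PREDICTABLE") {
          if (corner) ang <- ang + pi
          else if (hit_x) ang <- pi - ang
          else ang <- -ang
        } else {
          if (corner) {
            normal <- atan2(-sign(pos[2]), -sign(pos[1]))
            spread <- pi / 4 - graze
          } else if (hit_x) {
            normal <- if (pos[1] > 0) pi else 0
            spread <- pi / 2 - graze
          } else {
            normal <- if (pos[2] > 0) -pi / 2 else pi / 2
            spread <- pi / 2 - graze
          }
          ang <- normal + runif(1, -spread, spread)
        }
        ang <- ang %% (2 * pi)
        ev_t <- c(ev_t, t); ev_k <- c(ev_k, "WALL")
      }
    }

    trajectory <- NULL
    if (!is.na(sample_hz) && sample_hz > 0) {
      ts <- if (duration > 0) seq(0, duration, by = 1 / sample_hz) else 0
      i <- findInterval(ts, seg_t, rightmost.closed = TRUE)
      i[i < 1] <- 1
      dtl <- ts - seg_t[i]
      vx <- speed * cos(seg_a[i]); vy <- speed * sin(seg_a[i])
      trajectory <- data.frame(
        time = ts, x = seg_x[i] + vx * dtl, y = seg_y[i] + vy * dtl,
        vx = vx, vy = vy)
    }
    list(trajectory = trajectory,
         events = data.frame(time = ev_t, kind = ev_k,
                             stringsAsFactors = FALSE),
         final_state = list(position = pos, angle = ang))
  })
}

# rotate-and-split counterbalancing: k items per condition over 3 levels,
# the remainder assigned cyclically so session totals per level are equal
.counterbalanced <- function(levels, k, rotation) {
  base <- k %/% 3
  extra <- k %% 3
  counts <- rep(base, 3)
  if (extra > 0) {
    idx <- ((rotation - 1 + seq_len(extra) - 1) %% 3) + 1
    counts[idx] <- counts[idx] + 1
  }
  rep(levels, counts)
}

#' Build a counterbalanced session schedule
#'
#' Thirty experimental blocks (ten per predictability condition) in
#' pseudo-random order; block durations, start jitters and preceding baseline
#' gaps are drawn from fixed three-element sets counterbalanced across
#' conditions (the remainder of 10/3 is rotated across conditions so that
#' session totals per level match).  Baselines average exactly 10 s.
#'
#' @param n_blocks Total number of blocks; must be divisible by 3.
#' @param durations,jitters,baselines Three-element value sets (seconds).
#' @param seed Optional seed for the pseudo-random block order.
#' @return A `session_design`: data frame with columns `onset`, `duration`,
#'   `condition`, `jitter`, `baseline` (baseline is the gap preceding the
#'   block; the jitter delays the block start within that gap's tail).
#' @export
build_session <- function(n_blocks = 30,
                          durations = c(20, 20.5, 21.5),
                          jitters = c(0, 0.5, 1.5),
                          baselines = c(8.5, 10, 11.5),
                          seed = NULL) {
  if (n_blocks %% 3 != 0)
    stop("number of blocks must be divisible by the number of conditions")
  stopifnot(length(durations) == 3, length(jitters) == 3,
            length(baselines) == 3)
  k <- n_blocks / 3
  .with_seed(seed, {
    order <- sample(rep(.conditions, k))
    dur <- jit <- bas <- numeric(n_blocks)
    for (ci in seq_along(.conditions)) {
      sel <- which(order == .conditions[ci])
      dur[sel] <- sample(.counterbalanced(durations, k, ci))
      jit[sel] <- sample(.counterbalanced(jitters, k, ci))
      bas[sel] <- sample(.counterbalanced(baselines, k, ci))
    }
    onset <- numeric(n_blocks)
    t <- 0
    for (b in seq_len(n_blocks)) {
      t <- t + bas[b] + jit[b]
      onset[b] <- t
      t <- t + dur[b]
    }
    structure(
      data.frame(onset = onset, duration = dur, condition = order,
                 jitter = jit, baseline = bas, stringsAsFactors = FALSE),
      class = c("session_design", "data.frame"))
  })
}

#' Simulate the ball motion of a whole session
#'
#' Chains [simulate_block()] over a [build_session()] schedule; the ball
#' resumes each block from its position at the end of the previous one (the
#' starting point of the session is the frame centre).
#'
#' @param design A `session_design`.
#' @param geometry A [frame_geometry()].
#' @param hazard_rate Mid-field hazard for `ARBITRARY` blocks (1/s).
#' @param seed Optional seed.
#' @param sample_hz Trajectory export rate; `NA` skips trajectory export
#'   (events only), which is much faster.
#' @return List with `events` (data frame `onset_s, kind, condition, block`)
#'   and, when sampled, `trajectories` (one data frame per block).
#' @export
simulate_session <- function(design, geometry = frame_geometry(),
                             hazard_rate = default_hazard(), seed = NULL,
                             sample_hz = NA) {
  stopifnot(inherits(design, "session_design"))
  .with_seed(seed, {
    state <- list(position = c(0, 0))
    evs <- vector("list", nrow(design))
    trajs <- if (!is.na(sample_hz)) vector("list", nrow(design)) else NULL
    for (b in seq_len(nrow(design))) {
      state$angle <- NULL  # direction re-drawn at each block start
      blk <- simulate_block(design$condition[b], design$duration[b], geometry,
                            initial_state = state, hazard_rate = hazard_rate,
                            sample_hz = sample_hz)
      if (nrow(blk$events) > 0)
        evs[[b]] <- data.frame(onset_s = design$onset[b] + blk$events$time,
                               kind = blk$events$kind,
                               condition = design$condition[b], block = b,
                               stringsAsFactors = FALSE)
      if (!is.null(trajs)) trajs[[b]] <- blk$trajectory
      state <- blk$final_state
    }
    events <- do.call(rbind, evs[!vapply(evs, is.null, logical(1))])
    if (is.null(events))
      events <- data.frame(onset_s = numeric(0), kind = character(0),
                           condition = character(0), block = integer(0))
    out <- list(events = events, design = design)
    if (!is.null(trajs)) out$trajectories <- trajs
    out
  })
}

#' Count direction changes per condition
#'
#' @param events Event data frame as returned by [simulate_session()]
#'   (columns `condition`, `block`; one row per direction change).
#' @return Data frame with per-condition totals and per-block mean/SD.
#' @export
count_changes <- function(events) {
  out <- lapply(.conditions, function(cond) {
    e <- events[events$condition == cond, , drop = FALSE]
    per_block <- if (nrow(e)) table(factor(e$block, levels = unique(e$block)))
                 else integer(0)
    data.frame(condition = cond, total = nrow(e),
               mean_per_block = if (length(per_block)) mean(per_block) else 0,
               sd_per_block = if (length(per_block) > 1) sd(per_block) else NA,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Ratio of ARBITRARY to PREDICTABLE direction changes
#' @param counts Output of [count_changes()].
#' @export
change_ratio <- function(counts) {
  counts$total[counts$condition == "ARBITRARY"] /
    counts$total[counts$condition == "PREDICTABLE"]
}

#' Calibrate the mid-field hazard rate
#'
#' Finds by bisection the `ARBITRARY` hazard rate for which the session-level
#' ratio of `ARBITRARY` to `PREDICTABLE` direction changes matches a target
#' (1.6 by default).  The ratio is averaged over `n_sessions` simulated
#' sessions per candidate rate and is monotone in the hazard.
#'
#' @param target_ratio Target change ratio.
#' @param geometry A [frame_geometry()].
#' @param n_sessions Sessions simulated per bisection step.
#' @param interval Search interval for the hazard (1/s).
#' @param tol Bisection tolerance on the hazard.
#' @param seed Seed; the same session seeds are reused across candidate rates
#'   so the bisected function is deterministic.
#' @return The calibrated hazard rate (1/s).
#' @export
calibrate_hazard <- function(target_ratio = 1.6, geometry = frame_geometry(),
                             n_sessions = 20, interval = c(0.01, 2),
                             tol = 1e-3, seed = 1) {
  ratio_at <- function(h) {
    r <- vapply(seq_len(n_sessions), function(i) {
      des <- build_session(seed = seed * 1000 + i)
      ses <- simulate_session(des, geometry, hazard_rate = h,
                              seed = seed * 1000 + i)
      change_ratio(count_changes(ses$events))
    }, numeric(1))
    mean(r)
  }
  lo <- interval[1]; hi <- interval[2]
  if (ratio_at(lo) > target_ratio || ratio_at(hi) < target_ratio)
    stop("target ratio not bracketed by the hazard interval")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (ratio_at(mid) < target_ratio) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Default ARBITRARY hazard rate
#'
#' The package default mid-field direction-change rate, fixed by running
#' [calibrate_hazard()] with its default settings (target ratio 1.6 under the
#' default geometry and schedule).
#' @export
default_hazard <- function() 0.208

# ---- events / schedule I/O ---------------------------------------------

#' Write / read a direction-change event table (TSV)
#'
#' Three columns: `onset_s`, `kind`, `condition`.
#' @param events Event data frame.
#' @param path File path.
#' @export
write_events_tsv <- function(events, path) {
  write.table(events[, c("onset_s", "kind", "condition")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write / read a block schedule as a BIDS-style events TSV
#'
#' Columns `onset`, `duration`, `trial_type`.
#' @param design A `session_design`.
#' @param path File path.
#' @export
write_schedule_tsv <- function(design, path) {
  write.table(data.frame(onset = design$onset, duration = design$duration,
                         trial_type = design$condition),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule_tsv
#' @export
read_schedule_tsv <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  structure(
    data.frame(onset = d$onset, duration = d$duration,
               condition = d$trial_type, jitter = NA_real_,
               baseline = NA_real_, stringsAsFactors = FALSE),
    class = c("session_design", "data.frame"))
}
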