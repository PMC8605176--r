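# Synthetic foraging + spiking generator with known ground truth.
#
# Trajectories: Ornstein-Uhlenbeck velocity process (smooth heading and
# speed) with reflecting arena boundaries; stationary speed distribution is
# Rayleigh-like and concentrated well below 60 cm/s. Spikes: inhomogeneous
# Poisson by thinning with a rate piecewise-constant per video frame,
# lambda(t) = base_rate[session] * g(speed(t)) * spatial(x, y) * drift(t).
# The rate model is multiplicative so MFR shifts and speed tuning can be
# injected independently.

# deterministic 31-bit stream seed from (seed, cell_id, stream label);
# adding cells never perturbs existing ones
derive_seed <- function(seed, key) {
  M <- 2147483647
  h <- 0
  for (ch in utf8ToInt(paste0(key))) h <- (h * 31 + ch) %% M
  as.integer((seed %% M * 48271 + h * 7919 + 1) %% M)
}

#' Simulate a foraging trajectory
#'
#' Velocity follows a two-component Ornstein-Uhlenbeck process (relaxation
#' time `1/theta`, per-component stationary sd `sigma_v`), giving smoothly
#' varying heading and a Rayleigh-like stationary speed distribution with
#' mean `sigma_v * sqrt(pi/2)` (~17.5 cm/s at the defaults) and negligible
#' mass above 60 cm/s. Positions are integrated at the frame rate and
#' reflected at the arena boundary (for a wall-less platform the platform
#' edge acts as a soft reflecting boundary). Deterministic given `seed`.
#'
#' @param arena An [arena()].
#' @param duration Session length in seconds.
#' @param seed Integer RNG seed.
#' @param frame_rate Samples per second. Default 30.
#' @param theta Velocity relaxation rate, 1/s. Default 0.5.
#' @param sigma_v Per-component stationary velocity sd, cm/s. Default 14.
#' @return A [position_trace()] with `duration * frame_rate` samples.
#' @export
simulate_trajectory <- function(arena, duration, seed, frame_rate = 30,
                                theta = 0.5, sigma_v = 14) {
  stopifnot(duration > 0)
  n <- round(duration * frame_rate)
  dt <- 1 / frame_rate
  a1 <- exp(-theta * dt)
  a2 <- sigma_v * sqrt(1 - a1^2)
  bbox <- arena_bbox(arena)
  circle <- arena$shape == "circle"
  R <- bbox[1] / 2
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, "trajectory"))
  x <- numeric(n); y <- numeric(n)
  if (circle) {
    ang <- runif(1, 0, 2 * pi); rad <- R * sqrt(runif(1)) * 0.95
    px <- R + rad * cos(ang); py <- R + rad * sin(ang)
  } else {
    px <- runif(1, 0.05, 0.95) * bbox[1]
    py <- runif(1, 0.05, 0.95) * bbox[2]
  }
  vx <- rnorm(1, 0, sigma_v); vy <- rnorm(1, 0, sigma_v)
  ex <- rnorm(n); ey <- rnorm(n)
  for (i in seq_len(n)) {
    vx <- a1 * vx + a2 * ex[i]
    vy <- a1 * vy + a2 * ey[i]
    px <- px + vx * dt
    py <- py + vy * dt
    if (circle) {
      dx <- px - R; dy <- py - R
      d <- sqrt(dx^2 + dy^2)
      if (d > R) {  # radial reflection at the wall
        ux <- dx / d; uy <- dy / d
        over <- d - R
        px <- px - 2 * over * ux
        py <- py - 2 * over * uy
        vr <- vx * ux + vy * uy
        vx <- vx - 2 * vr * ux
        vy <- vy - 2 * vr * uy
      }
    } else {
      if (px < 0) { px <- -px; vx <- -vx }
      if (px > bbox[1]) { px <- 2 * bbox[1] - px; vx <- -vx }
      if (py < 0) { py <- -py; vy <- -vy }
      if (py > bbox[2]) { py <- 2 * bbox[2] - py; vy <- -vy }
    }
    x[i] <- px; y[i] <- py
  }
  position_trace(t = (seq_len(n) - 1) / frame_rate, x = x, y = y,
                 frame_rate = frame_rate)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Ground-truth rate model for one simulated cell
#'
#' @param cell_id Character id, stable across the triplet.
#' @param base_rate Named numeric vector `c(pre=, manip=, post=)`,
#'   spikes/s, all > 0 (a cell with all three equal is a "null" cell; one
#'   whose `manip` differs from equal flankers is a "shift" cell).
#' @param speed_shape One of `"flat"`, `"increasing"`, `"decreasing"`,
#'   `"preferred"`.
#' @param preferred_center,preferred_width Center and width (cm/s) of the
#'   preferred-speed bump (used when `speed_shape = "preferred"`).
#' @param spatial_field Optional list `list(center = c(x, y), sigma, peak)`
#'   describing a 2D Gaussian firing field (cm; peak multiplier > 1), or
#'   `NULL` for spatially uniform firing.
#' @return A `cell_truth` object.
#' @export
cell_truth <- function(cell_id, base_rate,
                       speed_shape = c("flat", "increasing", "decreasing",
                                       "preferred"),
                       preferred_center = 30, preferred_width = 8,
                       spatial_field = NULL) {
  speed_shape <- match.arg(speed_shape)
  stopifnot(all(base_rate >= 0),
            all(c("pre", "manip", "post") %in% names(base_rate)))
  label <- if (base_rate[["manip"]] > base_rate[["pre"]]) "increase"
  else if (base_rate[["manip"]] < base_rate[["pre"]]) "decrease"
  else "none"
  structure(list(cell_id = as.character(cell_id),
                 base_rate = base_rate[c("pre", "manip", "post")],
                 speed_shape = speed_shape,
                 preferred_center = preferred_center,
                 preferred_width = preferred_width,
                 spatial_field = spatial_field,
                 label = label,
                 speed_tuned = speed_shape != "flat"),
            class = "cell_truth")
}

# raw (unnormalized) speed gain for a shape; normalized over the session so
# the mean gain is ~1 and base_rate stays the session MFR in expectation
speed_gain_raw <- function(truth, v) {
  switch(truth$speed_shape,
         flat = rep(1, length(v)),
         increasing = 0.25 + 1.5 * pmin(v, 60) / 60,
         decreasing = 1.75 - 1.5 * pmin(v, 60) / 60,
         preferred = 0.25 + 1.5 * exp(-(v - truth$preferred_center)^2 /
                                        (2 * truth$preferred_width^2)))
}

# per-frame rate (spikes/s) for a cell on a trajectory
frame_rates <- function(truth, trace, session_label, rate_mult = NULL) {
  v <- compute_speed(trace, smooth_frames = 1)$v
  g <- speed_gain_raw(truth, v)
  g <- g / mean(g)
  lam <- truth$base_rate[[session_label]] * g
  if (!is.null(truth$spatial_field)) {
    f <- truth$spatial_field
    s <- 1 + (f$peak - 1) * exp(-((trace$x - f$center[1])^2 +
                                    (trace$y - f$center[2])^2) /
                                  (2 * f$sigma^2))
    s <- s / mean(s)
    lam <- lam * s
  }
  if (!is.null(rate_mult)) lam <- lam * rate_mult
  pmax(lam, 0)
}

#' Simulate one cell's spike train by Poisson thinning
#'
#' Generates an inhomogeneous Poisson spike train whose rate is piecewise
#' constant per video frame (33.3 ms at 30 Hz, far below any analysis bin):
#' candidate spikes are drawn homogeneously at the envelope rate
#' `max(lambda)` and accepted with probability `lambda(frame) / envelope`.
#' The RNG stream is derived from `(seed, cell_id, session_label)`, so
#' adding cells or sessions never perturbs existing ones.
#'
#' @param truth A [cell_truth()].
#' @param trace The session's [position_trace()].
#' @param session_label `"pre"`, `"manip"`, or `"post"` (selects the
#'   baseline rate).
#' @param seed Integer master seed.
#' @param rate_mult Optional per-frame multiplier (e.g. a slow drift ramp).
#' @return A [spike_train()].
#' @export
simulate_cell <- function(truth, trace, session_label, seed,
                          rate_mult = NULL) {
  stopifnot(inherits(truth, "cell_truth"))
  lam <- frame_rates(truth, trace, session_label, rate_mult)
  n_frames <- length(lam)
  duration <- n_frames / trace$frame_rate
  env <- max(lam)
  if (env == 0) return(spike_train(numeric(0), truth$cell_id))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, paste0(truth$cell_id, ":", session_label)))
  n_cand <- rpois(1, env * duration)
  tt <- sort(runif(n_cand, 0, duration))
  frame <- pmin(floor(tt * trace$frame_rate) + 1L, n_frames)
  keep <- runif(n_cand) < lam[frame] / env
  spike_train(tt[keep], truth$cell_id)
}

#' Simulator configuration
#'
#' Defaults mirror the study conditions the pipeline is designed for: 200
#' simultaneously tracked cells, 11.5% shifted up by +4.0 spikes/s and 7.5%
#' shifted down by 5.7 spikes/s in the middle session, ~3 spikes/s baselines
#' (decrease cells start 5.7 spikes/s higher so the shifted-down rate is
#' still positive and comparable), 800 s sessions in a 125 cm square arena,
#' and 70% of cells speed tuned (25% increasing, 25% decreasing, 20%
#' preferred).
#'
#' @param n_cells Number of cells. Default 200.
#' @param fraction_increase,fraction_decrease Fractions of cells whose manip
#'   baseline shifts up/down. Defaults 0.115 / 0.075.
#' @param shift_increase,shift_decrease Shift magnitudes, spikes/s. Defaults
#'   4.0 and 5.7.
#' @param base_mean Mean baseline rate, spikes/s. Default 3.
#' @param speed_fractions Named fractions of speed-tuned shapes; remainder
#'   is flat. Default `c(increasing = .25, decreasing = .25, preferred = .2)`.
#' @param arena_pre,arena_manip Arenas for the flanking / middle sessions
#'   (default: same 125 cm square).
#' @param manipulation_type Manipulation family label. Default `"object"`.
#' @param duration Session length, seconds. Default 800.
#' @param drift Slow-drift amplitude: each cell's rate is ramped linearly by
#'   a factor `1 +- drift` across the concatenated triplet (random sign per
#'   cell), emulating representational drift over the recording day.
#'   Default 0 (off).
#' @param seed Master seed. Default 1.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_cells = 200,
                       fraction_increase = 0.115, fraction_decrease = 0.075,
                       shift_increase = 4.0, shift_decrease = 5.7,
                       base_mean = 3,
                       speed_fractions = c(increasing = 0.25,
                                           decreasing = 0.25,
                                           preferred = 0.20),
                       arena_pre = arena("square", 125),
                       arena_manip = arena("square", 125),
                       manipulation_type = "object",
                       duration = 800, drift = 0, seed = 1) {
  stopifnot(fraction_increase >= 0, fraction_decrease >= 0,
            fraction_increase + fraction_decrease <= 1,
            all(speed_fractions >= 0), sum(speed_fractions) <= 1)
  structure(list(n_cells = n_cells,
                 fraction_increase = fraction_increase,
                 fraction_decrease = fraction_decrease,
                 shift_increase = shift_increase,
                 shift_decrease = shift_decrease,
                 base_mean = base_mean,
                 speed_fractions = speed_fractions,
                 arena_pre = arena_pre, arena_manip = arena_manip,
                 manipulation_type = manipulation_type,
                 duration = duration, drift = drift, seed = seed),
            class = "sim_config")
}

#' Generate a full A-B-A' triplet with ground truth
#'
#' Draws per-cell ground truth (baselines, shift labels, speed-tuning
#' shapes), simulates three independent trajectories with identical motion
#' statistics, and thins spikes for every cell in every session. Shift
#' counts are exact: `round(n_cells * fraction)` cells get each label.
#'
#' @param config A [sim_config()].
#' @return List with `triplet` (a `session_triplet`, truncated to `t_max`)
#'   and `truth` (data.frame: cell_id, label, speed_shape, speed_tuned,
#'   base_pre, base_manip, base_post).
#' @param t_max Analysis window passed to [validate_triplet()]. Default 765.
#' @export
generate_triplet <- function(config, t_max = 765) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_cells
  n_inc <- round(n * config$fraction_increase)
  n_dec <- round(n * config$fraction_decrease)
  labels <- c(rep("increase", n_inc), rep("decrease", n_dec),
              rep("none", n - n_inc - n_dec))
  n_shape <- vapply(config$speed_fractions, function(f) round(n * f),
                    numeric(1))
  shapes <- c(rep(names(n_shape), n_shape),
              rep("flat", n - sum(n_shape)))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(config$seed, "truth"))
  shapes <- sample(shapes)  # decorrelate shape from shift label
  ids <- sprintf("cell%03d", seq_len(n))
  base <- pmax(rgamma(n, shape = 4, scale = config$base_mean / 4), 0.5)
  base[labels == "decrease"] <- base[labels == "decrease"] +
    config$shift_decrease
  truths <- lapply(seq_len(n), function(i) {
    b <- base[i]
    bm <- switch(labels[i],
                 increase = b + config$shift_increase,
                 decrease = b - config$shift_decrease,
                 none = b)
    cell_truth(ids[i], c(pre = b, manip = bm, post = b),
               speed_shape = shapes[i],
               preferred_center = runif(1, 15, 45),
               preferred_width = runif(1, 6, 12))
  })
  drift_sign <- sample(c(-1, 1), n, replace = TRUE)
  traces <- lapply(1:3, function(k)
    simulate_trajectory(config$arena_pre, config$duration,
                        seed = derive_seed(config$seed, paste0("traj", k))))
  if (!identical(config$arena_manip, config$arena_pre))
    traces[[2]] <- simulate_trajectory(config$arena_manip, config$duration,
                                       seed = derive_seed(config$seed,
                                                          "traj2"))
  session_labels <- c("pre", "manip", "post")
  conditions <- c("pre", "manipulation", "post")
  nf <- length(traces[[1]]$t)
  sessions <- lapply(1:3, function(k) {
    spikes <- lapply(seq_len(n), function(i) {
      mult <- NULL
      if (config$drift > 0) {
        # global time fraction across the concatenated triplet
        tau <- ((k - 1) * nf + seq_len(nf) - 0.5) / (3 * nf)
        mult <- pmax(1 + drift_sign[i] * config$drift * (2 * tau - 1), 0.05)
      }
      simulate_cell(truths[[i]], traces[[k]], session_labels[k],
                    seed = config$seed, rate_mult = mult)
    })
    names(spikes) <- ids
    session(condition = conditions[k],
            manipulation_type = config$manipulation_type,
            arena = if (k == 2) config$arena_manip else config$arena_pre,
            trace = traces[[k]], spikes = spikes,
            duration = config$duration)
  })
  truth_df <- data.frame(
    cell_id = ids, label = labels, speed_shape = shapes,
    speed_tuned = shapes != "flat",
    base_pre = vapply(truths, function(x) x$base_rate[["pre"]], numeric(1)),
    base_manip = vapply(truths, function(x) x$base_rate[["manip"]],
                        numeric(1)),
    base_post = vapply(truths, function(x) x$base_rate[["post"]], numeric(1)),
    drift_sign = drift_sign,
    stringsAsFactors = FALSE)
  list(triplet = validate_triplet(sessions[[1]], sessions[[2]], sessions[[3]],
                                  t_max = t_max),
       truth = truth_df)
}
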