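# Fixture builders shared across the suite. Everything is generated in code;
# no data files.

# metronomic spike train: one spike every 1/rate s, strictly inside [0, dur)
metronome <- function(rate, dur, phase = 0.5) {
  spike_train(seq(phase / rate, dur - 1e-9, by = 1 / rate), "metro")
}

# sawtooth trace: constant-speed zigzag along the diagonal of a square arena,
# giving full control over speed (cm/s) at 30 Hz
sawtooth_trace <- function(speed_cms, dur, extent = 125, frame_rate = 30) {
  n <- round(dur * frame_rate)
  step <- speed_cms / frame_rate / sqrt(2)    # per-axis step
  period <- 2 * (extent - 2)
  pos1d <- function(s) {
    m <- s %% period
    ifelse(m <= period / 2, 1 + m, 1 + period - m)
  }
  s <- (seq_len(n) - 1) * step
  position_trace(t = (seq_len(n) - 1) / frame_rate,
                 x = pos1d(s), y = pos1d(s), frame_rate = frame_rate)
}

# stationary trace: animal parked at one point
parked_trace <- function(x, y, dur, frame_rate = 30) {
  n <- round(dur * frame_rate)
  position_trace(t = (seq_len(n) - 1) / frame_rate,
                 x = rep(x, n), y = rep(y, n), frame_rate = frame_rate)
}

# minimal session around arbitrary spike trains
toy_session <- function(spikes, condition = "pre", dur = 765,
                        manipulation_type = "object", trace = NULL,
                        extent = 125) {
  if (is.null(trace)) trace <- sawtooth_trace(15, dur, extent)
  if (is.null(names(spikes)))
    names(spikes) <- vapply(spikes, function(s) s$cell_id, character(1))
  session(condition = condition, manipulation_type = manipulation_type,
          arena = arena("square", extent), trace = trace, spikes = spikes,
          duration = dur)
}

# triplet of toy sessions holding per-cell Poisson rates per session;
# shared trajectory statistics, independent spikes
poisson_triplet <- function(rates_pre, rates_manip, rates_post, dur = 800,
                            seed = 1, t_max = 765) {
  ids <- names(rates_pre)
  mk <- function(cond, lab, rates, k) {
    tr <- simulate_trajectory(arena("square", 125), dur,
                              seed = seed * 10 + k)
    spikes <- lapply(ids, function(id) {
      ct <- cell_truth(id, c(pre = rates[[id]], manip = rates[[id]],
                             post = rates[[id]]))
      simulate_cell(ct, tr, "pre", seed = seed * 100 + k)
    })
    names(spikes) <- ids
    session(condition = cond, manipulation_type = "object",
            arena = arena("square", 125), trace = tr, spikes = spikes,
            duration = dur)
  }
  validate_triplet(mk("pre", "pre", rates_pre, 1),
                   mk("manipulation", "manip", rates_manip, 2),
                   mk("post", "post", rates_post, 3),
                   t_max = t_max)
}

# brute-force Kruskal-Wallis H by the rank formula (no tie correction;
# independent of the package implementation)
kw_brute <- function(groups) {
  vals <- unlist(groups)
  N <- length(vals)
  r <- rank(vals)
  idx <- rep(seq_along(groups), vapply(groups, length, integer(1)))
  Rj <- tapply(r, idx, sum)
  nj <- vapply(groups, length, numeric(1))
  12 / (N * (N + 1)) * sum(Rj^2 / nj) - 3 * (N + 1)
}
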