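test_that("speed is the finite difference of position, boxcar optional", {
  # stationary -> all zeros
  expect_true(all(compute_speed(parked_trace(5, 5, 10))$v == 0))
  # straight line at 1 cm/frame -> 30 cm/s everywhere
  n <- 300
  tr <- position_trace((0:(n - 1)) / 30, seq_len(n), rep(1, n))
  expect_equal(compute_speed(tr, smooth_frames = 1)$v, rep(30, n))
  # jittered fixture: unsmoothed speed equals the finite-difference oracle
  set.seed(3)
  xj <- cumsum(rnorm(n)); yj <- cumsum(rnorm(n))
  trj <- position_trace((0:(n - 1)) / 30, xj, yj)
  v <- compute_speed(trj, smooth_frames = 1)$v
  oracle <- c(NA, sqrt(diff(xj)^2 + diff(yj)^2) * 30)
  oracle[1] <- oracle[2]
  expect_equal(v, oracle)
  expect_length(v, n)   # aligned sample-for-sample with the trace
  expect_error(compute_speed(parked_trace(1, 1, 1/30)), ">= 2 samples")
})

test_that("tuning curve is per-speed-bin rate with the stated flavors", {
  expect_length(speed_bin_edges("analysis"), 26)   # 25 bins, 5-55 cm/s
  expect_equal(range(speed_bin_edges("analysis")), c(5, 55))
  expect_equal(diff(speed_bin_edges("display"))[1], 2.5)
  expect_equal(range(speed_bin_edges("display")), c(0, 60))
  # all frames at 10 cm/s, 20 spikes in 4 s -> bin containing 10 = 5 spikes/s
  tr <- sawtooth_trace(10, 4)
  sp <- compute_speed(tr, smooth_frames = 1)
  st <- spike_train(seq(0.1, 3.9, length.out = 20), "c")
  crv <- speed_tuning_curve(st, sp, "analysis", min_occupancy_s = 0.5)
  b <- findInterval(10, crv$edges)
  expect_equal(crv$rate[b], 20 / crv$occupancy_s[b])
  expect_equal(crv$occupancy_s[b], 4, tolerance = 0.1)
  expect_true(all(is.na(crv$rate[-b])))
  # occupancy-weighted mean of defined analysis bins = MFR restricted to
  # frames with speed in [5, 55)
  trs <- simulate_trajectory(arena("square", 125), 765, seed = 5)
  sps <- compute_speed(trs)
  ct <- cell_truth("c", c(pre = 4, manip = 4, post = 4),
                   speed_shape = "preferred")
  sts <- simulate_cell(ct, trs, "pre", seed = 5)
  crv2 <- speed_tuning_curve(sts, sps, "analysis", min_occupancy_s = 0)
  def <- !is.na(crv2$rate)
  expect_equal(sum(crv2$rate[def] * crv2$occupancy_s[def]),
               sum(crv2$spike_counts[def]))
})

test_that("F-test handles constant, perfectly linear, and null curves", {
  mk_curve <- function(rate, occ = rep(10, 25)) {
    edges <- speed_bin_edges("analysis")
    structure(list(edges = edges, centers = (edges[-1] + edges[-26]) / 2,
                   rate = rate, occupancy_s = occ,
                   spike_counts = rate * occ, flavor = "analysis",
                   min_occupancy_s = 1),
              class = "speed_tuning_curve")
  }
  # exactly constant: F = 0, p = 1
  res <- linear_vs_uniform_ftest(mk_curve(rep(3, 25)))
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)
  expect_false(res$perfect_fit)
  # exactly linear, nonzero slope: perfect fit, p = 0
  lin <- linear_vs_uniform_ftest(mk_curve(1 + 0.1 * (1:25)))
  expect_true(lin$perfect_fit)
  expect_equal(lin$p, 0)
  expect_gt(lin$slope, 0)
  # adding a constant changes neither F nor p
  set.seed(9)
  r <- rpois(25, 30) / 10
  a <- linear_vs_uniform_ftest(mk_curve(r))
  b <- linear_vs_uniform_ftest(mk_curve(r + 7))
  expect_equal(a$F, b$F)
  expect_equal(a$p, b$p)
  expect_error(linear_vs_uniform_ftest(mk_curve(c(1, 2, rep(NA, 23)))),
               ">= 3 defined bins")
})

test_that("F-test power rises with the simulated speed-gain slope", {
  tr <- simulate_trajectory(arena("square", 125), 765, seed = 23)
  sp <- compute_speed(tr)
  power_at <- function(scale) {
    rej <- vapply(1:15, function(s) {
      ct <- cell_truth(paste0("g", s), c(pre = 3, manip = 3, post = 3),
                       speed_shape = "increasing")
      lam_flat <- cell_truth(paste0("g", s), c(pre = 3, manip = 3, post = 3))
      # interpolate between flat and full "increasing" gain via rate_mult
      g <- envshift:::frame_rates(ct, tr, "pre") /
        envshift:::frame_rates(lam_flat, tr, "pre")
      mult <- 1 + scale * (g - 1)
      st <- simulate_cell(lam_flat, tr, "pre", seed = 900 + s,
                          rate_mult = mult)
      crv <- speed_tuning_curve(st, sp, "analysis")
      linear_vs_uniform_ftest(crv)$p < 0.05
    }, logical(1))
    mean(rej)
  }
  p <- vapply(c(0, 0.5, 1), power_at, numeric(1))
  expect_lte(p[1], p[2] + 0.15)
  expect_lte(p[2], p[3] + 0.15)
  expect_gt(p[3], 0.8)
})

test_that("any-of-three rule drives the sensitivity classification", {
  g <- generate_triplet(sim_config(n_cells = 40, seed = 31))
  cls <- lapply(g$triplet$cell_roster, function(id)
    classify_speed_cell(g$triplet, id))
  sens <- vapply(cls, `[[`, logical(1), "speed_sensitive")
  pmat <- t(vapply(cls, `[[`, numeric(3), "p"))
  expect_equal(sens, apply(pmat < 0.05, 1, any))
  # recovery: tuned cells detected at high rate; null cells inflated only by
  # the any-of-three union bound (<= 3 * alpha)
  truth <- g$truth$speed_tuned[match(g$triplet$cell_roster, g$truth$cell_id)]
  expect_gt(mean(sens[truth]), 0.85)
  expect_lt(mean(sens[!truth]), 0.4)
})

test_that("tuning-shape categories recover designed shapes", {
  mk_curve <- function(rate) {
    edges <- speed_bin_edges("display")
    structure(list(edges = edges, centers = (edges[-1] + edges[-25]) / 2,
                   rate = rate, occupancy_s = rep(20, 24),
                   spike_counts = rate * 20, flavor = "display",
                   min_occupancy_s = 1),
              class = "speed_tuning_curve")
  }
  expect_equal(categorize_tuning_shape(mk_curve(seq(1, 5, length.out = 24))),
               "increasing")
  expect_equal(categorize_tuning_shape(mk_curve(seq(5, 1, length.out = 24))),
               "decreasing")
  centers <- (speed_bin_edges("display")[-1] +
                speed_bin_edges("display")[-25]) / 2
  bump <- 1 + 4 * exp(-(centers - 30)^2 / (2 * 64))
  expect_equal(categorize_tuning_shape(mk_curve(bump)), "preferred")
  # noisy flat curves are mostly unclassified under the margin rule
  set.seed(13)
  cats <- vapply(1:40, function(i) {
    r <- rpois(24, 60) / 20
    categorize_tuning_shape(mk_curve(r))
  }, character(1))
  expect_gt(mean(cats == "unclassified"), 0.5)
})

test_that("split-half curves match a masking oracle and are stable", {
  g <- generate_triplet(sim_config(n_cells = 6, seed = 37,
                                   fraction_increase = 0,
                                   fraction_decrease = 0))
  id <- g$triplet$cell_roster[1]
  sh <- split_half_curves(g$triplet, id)
  expect_equal(sh$midpoint_s, 3 * 765 / 2)
  # oracle: recount spikes per speed bin in the first half by direct masking
  m <- envshift:::merge_triplet_cell(g$triplet, id)
  sp <- compute_speed(m$trace)
  half_mask <- sp$t < sh$midpoint_s
  edges <- speed_bin_edges("display")
  fb <- findInterval(sp$v, edges, rightmost.closed = TRUE)
  fb[fb < 1 | fb > 24] <- NA
  idx <- envshift:::nearest_sample(
    m$spikes$times[m$spikes$times < sh$midpoint_s], sp$t[half_mask])
  oracle_counts <- tabulate(fb[half_mask][idx], nbins = 24)
  expect_equal(sh$first_half$spike_counts, oracle_counts)
  # time-homogeneous speed-tuned cells: halves correlate strongly (the
  # modulation is stable; flat cells would only correlate noise with noise)
  gt <- generate_triplet(sim_config(
    n_cells = 20, seed = 41, fraction_increase = 0, fraction_decrease = 0,
    speed_fractions = c(increasing = 0.4, decreasing = 0.3,
                        preferred = 0.3)))
  cors <- vapply(gt$triplet$cell_roster, function(cid) {
    s <- split_half_curves(gt$triplet, cid)
    ok <- !is.na(s$first_half$rate) & !is.na(s$second_half$rate)
    cor(s$first_half$rate[ok], s$second_half$rate[ok])
  }, numeric(1))
  expect_gt(mean(cors), 0.8)
  # merged curve built from two identical halves equals either half
  trs <- sawtooth_trace(21, 100)
  sps <- compute_speed(trs, smooth_frames = 1)
  sts <- spike_train(seq(0.05, 99.9, by = 0.5), "c")
  full <- speed_tuning_curve(sts, sps, "display")
  expect_equal(full$rate[!is.na(full$rate)],
               rep(2, sum(!is.na(full$rate))), tolerance = 0.05)
})
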