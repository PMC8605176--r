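test_that("trajectory has the right sample count, stays inside, repeats", {
  a <- arena("square", 125)
  tr <- simulate_trajectory(a, 765, seed = 7)
  expect_length(tr$t, 22950)                 # duration x 30 Hz
  expect_true(all(tr$x >= 0 & tr$x <= 125))
  expect_true(all(tr$y >= 0 & tr$y <= 125))
  tr2 <- simulate_trajectory(a, 765, seed = 7)
  expect_identical(tr$x, tr2$x)
  expect_identical(tr$y, tr2$y)
  # circle containment
  trc <- simulate_trajectory(arena("circle", 110), 100, seed = 3)
  expect_true(all(sqrt((trc$x - 55)^2 + (trc$y - 55)^2) <= 55 + 1e-9))
})

test_that("speed distribution is concentrated below 60 cm/s", {
  frac_fast <- vapply(1:10, function(s) {
    tr <- simulate_trajectory(arena("square", 125), 200, seed = s)
    v <- compute_speed(tr, smooth_frames = 1)$v
    mean(v > 60)
  }, numeric(1))
  expect_true(all(frac_fast < 0.05))
})

test_that("square-arena occupancy covers >= 90% of 3 cm bins at 765 s", {
  tr <- simulate_trajectory(arena("square", 125), 765, seed = 7)
  occ <- compute_occupancy(tr, arena("square", 125))
  expect_gte(mean(occ$occupancy > 0), 0.90)
})

test_that("flat-cell spike counts follow the homogeneous Poisson mean", {
  tr <- simulate_trajectory(arena("square", 125), 765, seed = 2)
  ct <- cell_truth("c", c(pre = 2, manip = 2, post = 2))
  st <- simulate_cell(ct, tr, "pre", seed = 5)
  expect_lt(abs(length(st$times) - 1530), 3 * sqrt(1530))
  expect_identical(st$times, simulate_cell(ct, tr, "pre", seed = 5)$times)
  # zero rate -> empty train
  ct0 <- cell_truth("z", c(pre = 0, manip = 0, post = 0))
  expect_length(simulate_cell(ct0, tr, "pre", seed = 5)$times, 0)
})

test_that("empirical MFR of flat cells converges to base rate", {
  tr <- simulate_trajectory(arena("square", 125), 765, seed = 9)
  rel_err <- vapply(1:20, function(s) {
    ct <- cell_truth(paste0("c", s), c(pre = 3, manip = 3, post = 3))
    st <- simulate_cell(ct, tr, "pre", seed = s)
    abs(length(st$times) / 765 - 3) / 3
  }, numeric(1))
  expect_lt(mean(rel_err), 0.05)
})

test_that("thinning matches the target per-speed-bin rates (chi-square)", {
  tr <- simulate_trajectory(arena("square", 125), 765, seed = 13)
  sp <- compute_speed(tr, smooth_frames = 1)
  dt <- 1 / 30
  edges <- seq(0, 60, by = 5)
  fb <- findInterval(sp$v, edges, rightmost.closed = TRUE)
  fb[fb < 1 | fb > length(edges) - 1] <- NA
  not_rejected <- vapply(1:20, function(s) {
    ct <- cell_truth(paste0("t", s), c(pre = 5, manip = 5, post = 5),
                     speed_shape = "increasing")
    lam <- envshift:::frame_rates(ct, tr, "pre")
    st <- simulate_cell(ct, tr, "pre", seed = 400 + s)
    frame <- pmin(floor(st$times * 30) + 1L, length(lam))
    obs <- tabulate(fb[frame], nbins = length(edges) - 1)
    expct <- vapply(seq_len(length(edges) - 1), function(b)
      sum(lam[which(fb == b)]) * dt, numeric(1))
    keep <- expct >= 5
    chi2 <- sum((obs[keep] - expct[keep])^2 / expct[keep])
    pchisq(chi2, df = sum(keep) - 1, lower.tail = FALSE) >= 0.01
  }, logical(1))
  expect_gte(sum(not_rejected), 18)
})

test_that("increasing-gain cells show positive tuning slopes downstream", {
  tr <- simulate_trajectory(arena("square", 125), 765, seed = 17)
  sp <- compute_speed(tr)
  slopes <- vapply(1:20, function(s) {
    ct <- cell_truth(paste0("i", s), c(pre = 3, manip = 3, post = 3),
                     speed_shape = "increasing")
    st <- simulate_cell(ct, tr, "pre", seed = 700 + s)
    linear_vs_uniform_ftest(speed_tuning_curve(st, sp, "analysis"))$slope
  }, numeric(1))
  expect_true(all(slopes > 0))
})

test_that("triplet generation honors fractions and determinism", {
  cfg <- sim_config(n_cells = 200, seed = 3)
  g <- generate_triplet(cfg)
  expect_equal(sum(g$truth$label == "increase"), 23)
  expect_equal(sum(g$truth$label == "decrease"), 15)
  expect_equal(length(g$triplet$cell_roster), 200)
  # shift structure: flankers equal, manip shifted by the configured amount
  inc <- g$truth[g$truth$label == "increase", ]
  expect_equal(inc$base_manip - inc$base_pre, rep(4.0, 23))
  expect_equal(inc$base_pre, inc$base_post)
  dec <- g$truth[g$truth$label == "decrease", ]
  expect_equal(dec$base_manip - dec$base_pre, rep(-5.7, 15))
  expect_true(all(dec$base_manip > 0))
  # zero fractions -> all none
  g0 <- generate_triplet(sim_config(n_cells = 20, fraction_increase = 0,
                                    fraction_decrease = 0, seed = 3))
  expect_true(all(g0$truth$label == "none"))
  # same config twice -> identical spikes end to end
  g2 <- generate_triplet(cfg)
  expect_identical(g$triplet$manip$spikes$cell005$times,
                   g2$triplet$manip$spikes$cell005$times)
})

test_that("per-cell RNG streams: other cells never perturb a cell's train", {
  tr <- simulate_trajectory(arena("square", 125), 200, seed = 6)
  truths <- lapply(1:3, function(i)
    cell_truth(paste0("c", i), c(pre = 3, manip = 3, post = 3)))
  # cell 2 alone
  alone <- simulate_cell(truths[[2]], tr, "pre", seed = 6)
  # cell 2 simulated between two others, in a session-wide loop
  for (ct in truths) tmp <- simulate_cell(ct, tr, "pre", seed = 6)
  surrounded <- simulate_cell(truths[[2]], tr, "pre", seed = 6)
  expect_identical(alone$times, surrounded$times)
  # distinct cells get distinct streams
  other <- simulate_cell(truths[[1]], tr, "pre", seed = 6)
  expect_false(identical(alone$times, other$times))
})
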