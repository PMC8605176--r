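test_that("occupancy conserves time and matches a histogram oracle", {
  a <- arena("square", 125)
  # 30 samples parked in one bin at 30 Hz -> 1.0 s there, zero elsewhere
  tr <- parked_trace(10, 10, 1)
  occ <- compute_occupancy(tr, a)
  expect_equal(sum(occ$occupancy), 1.0)
  expect_equal(max(occ$occupancy), 1.0)
  expect_equal(sum(occ$occupancy > 0), 1)
  # simulated 765 s trajectory sums to the session duration
  trs <- simulate_trajectory(a, 765, seed = 4)
  occ2 <- compute_occupancy(trs, a)
  expect_equal(sum(occ2$occupancy), 765, tolerance = 1 / 30)
  # brute-force per-bin sample counts / 30
  oracle <- table(factor(floor(trs$y / 3) + 1, levels = 1:42),
                  factor(floor(trs$x / 3) + 1, levels = 1:42)) / 30
  expect_equal(unname(occ2$occupancy), unname(matrix(oracle, 42, 42)),
               tolerance = 1e-12)
  empty <- structure(list(t = numeric(0), x = numeric(0), y = numeric(0),
                          frame_rate = 30, gaps = integer(0)),
                     class = "position_trace")
  expect_error(compute_occupancy(empty, a), "empty")
})

test_that("raw ratemap is spikes over dwell time with unvisited bins masked", {
  a <- arena("square", 125)
  tr <- parked_trace(10, 10, 2)             # 2 s in one bin
  st <- spike_train(seq(0.1, 1.9, length.out = 10), "c")
  rm <- compute_ratemap(st, tr, a)
  expect_equal(rm$rate[rm$visited], 5.0)    # 10 spikes / 2 s
  expect_true(all(is.na(rm$rate[!rm$visited])))
  # zero spikes -> zero rate over the visited mask
  rm0 <- compute_ratemap(spike_train(numeric(0), "c"), tr, a)
  expect_equal(rm0$rate[rm0$visited], 0)
})

test_that("ratemap conservation and MFR identity hold on simulated data", {
  a <- arena("square", 125)
  tr <- simulate_trajectory(a, 765, seed = 8)
  ct <- cell_truth("c", c(pre = 3, manip = 3, post = 3))
  st <- simulate_cell(ct, tr, "pre", seed = 8)
  rm <- compute_ratemap(st, tr, a)
  # sum(rate * occupancy) over visited bins = assigned spikes, exactly
  expect_equal(sum(rm$rate[rm$visited] * rm$occupancy[rm$visited]),
               rm$n_spikes_assigned)
  expect_equal(rm$n_spikes_assigned, length(st$times))
  # occupancy-weighted mean rate = session MFR
  expect_equal(sum(rm$rate[rm$visited] * rm$occupancy[rm$visited]) /
                 sum(rm$occupancy),
               length(st$times) / 765, tolerance = 1e-6)
  # invariance to a global time shift of spikes and trace
  tr_shift <- position_trace(tr$t + 100, tr$x, tr$y, frame_rate = 30)
  rm_shift <- compute_ratemap(spike_train(st$times + 100, "c"), tr_shift, a)
  expect_equal(rm_shift$rate, rm$rate)
})

test_that("masked Gaussian smoothing preserves constants and positivity", {
  a <- arena("square", 30)
  tr <- simulate_trajectory(a, 120, seed = 2)
  ct <- cell_truth("c", c(pre = 5, manip = 5, post = 5))
  st <- simulate_cell(ct, tr, "pre", seed = 3)
  rm <- compute_ratemap(st, tr, a)
  # constant field over the visited mask is returned unchanged
  cst <- rm
  cst$rate[cst$visited] <- 4.2
  smc <- smooth_ratemap(cst)
  expect_equal(smc$rate[smc$visited], rep(4.2, sum(smc$visited)))
  expect_identical(smc$visited, rm$visited)
  sm <- smooth_ratemap(rm)
  expect_true(all(sm$rate[sm$visited] >= 0))
  expect_error(smooth_ratemap(sm), "already smoothed")
})

test_that("smoothing an interior impulse reproduces the kernel weights", {
  # fully visited 21x21 grid built by hand
  n <- 21
  rm <- structure(list(rate = matrix(0, n, n),
                       occupancy = matrix(1, n, n),
                       spike_counts = matrix(0, n, n),
                       visited = matrix(TRUE, n, n),
                       bin_size = 3, smoothed = FALSE,
                       n_spikes_assigned = 0),
                  class = "ratemap")
  rm$rate[11, 11] <- 1
  sm <- smooth_ratemap(rm, kernel_cm = 7)
  # direct convolution oracle: kernel sigma 7/3 cm, radius floor(7/3)=2 bins
  off <- -2:2
  K <- exp(-outer(off^2, off^2, `+`) * 9 / (2 * (7 / 3)^2))
  K <- K / sum(K)
  expect_equal(sm$rate[11, 11], K[3, 3], tolerance = 1e-12)
  expect_equal(sm$rate[11 + 2, 11], K[5, 3], tolerance = 1e-12)
  # impulse at a mask edge: masked renormalization >= unmasked weight
  rm2 <- rm
  rm2$visited[, 1:9] <- FALSE
  rm2$rate[!rm2$visited] <- NA
  rm2$rate[11, 10] <- 1
  sm2 <- smooth_ratemap(rm2, kernel_cm = 7)
  expect_gte(sm2$rate[11, 10], K[3, 3])
})

test_that("display normalization divides by the pooled 95th percentile", {
  set.seed(1)
  mk <- function(vals) {
    n <- 10
    structure(list(rate = matrix(vals, n, n), occupancy = matrix(1, n, n),
                   spike_counts = matrix(0, n, n),
                   visited = matrix(TRUE, n, n), bin_size = 3,
                   smoothed = TRUE, n_spikes_assigned = 0),
              class = "ratemap")
  }
  maps <- list(mk(runif(100, 0, 10)), mk(runif(100, 0, 10)),
               mk(runif(100, 0, 10)))
  nrm <- normalize_for_display(maps)
  pooled <- unlist(lapply(maps, function(m) m$rate))
  q95 <- quantile(pooled, 0.95, names = FALSE)
  expect_equal(attr(nrm, "scale"), q95)
  expect_equal(nrm[[2]], maps[[2]]$rate / q95)
  # ~5% of pooled bins exceed 1.0
  frac_above <- mean(unlist(nrm) > 1)
  expect_equal(frac_above * 300, 15, tolerance = 1.5)
  # identical maps stay identical; all-zero maps return zeros
  nrm2 <- normalize_for_display(list(maps[[1]], maps[[1]], maps[[1]]))
  expect_equal(nrm2[[1]], nrm2[[3]])
  z <- normalize_for_display(list(mk(0), mk(0), mk(0)))
  expect_true(all(z[[1]] == 0))
})
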