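# Linear speed tuning: instantaneous running speed, occupancy-normalized
# speed tuning curves, the uniform-vs-linear F-test for speed sensitivity,
# qualitative shape categories, and split-half stability curves.

#' Instantaneous running speed from a position trace
#'
#' Finite-difference speed at the camera frame rate:
#' `v[i] = ||p[i] - p[i-1]|| * frame_rate`, with `v[1] = v[2]` so the series
#' aligns sample-for-sample with the trace. An optional boxcar smoother
#' (default 5 frames, centered) suppresses tracking jitter; set
#' `smooth_frames = 1` for the raw finite difference.
#'
#' @param trace A [position_trace()] with >= 2 samples.
#' @param smooth_frames Boxcar width in frames (odd; 1 = off). Default 5.
#' @return List of class `speed_series`: `t`, `v` (cm/s, >= 0),
#'   `smooth_frames`.
#' @export
compute_speed <- function(trace, smooth_frames = 5) {
  stopifnot(inherits(trace, "position_trace"))
  n <- length(trace$t)
  if (n < 2) stop("need >= 2 samples to compute speed")
  v <- sqrt(diff(trace$x)^2 + diff(trace$y)^2) * trace$frame_rate
  v <- c(v[1], v)
  if (smooth_frames > 1) {
    k <- rep(1 / smooth_frames, smooth_frames)
    vs <- stats::filter(v, k, sides = 2)
    # boxcar shrinks at the edges: fall back to partial means there
    half <- (smooth_frames - 1) %/% 2
    for (i in which(is.na(vs))) {
      lo <- max(1, i - half); hi <- min(n, i + half)
      vs[i] <- mean(v[lo:hi])
    }
    v <- as.numeric(vs)
  }
  structure(list(t = trace$t, v = v, smooth_frames = smooth_frames),
            class = "speed_series")
}

#' Speed bin edges for a tuning-curve flavor
#'
#' `analysis`: 25 bins of 2 cm/s spanning 5-55 cm/s (used for the F-test);
#' `display`: 24 bins of 2.5 cm/s spanning 0-60 cm/s (used for shape
#' categorization and split-half visualization).
#'
#' @param flavor `"analysis"` or `"display"`.
#' @return Numeric vector of bin edges (cm/s).
#' @export
speed_bin_edges <- function(flavor = c("analysis", "display")) {
  flavor <- match.arg(flavor)
  if (flavor == "analysis") seq(5, 55, by = 2) else seq(0, 60, by = 2.5)
}

#' Occupancy-normalized speed tuning curve
#'
#' Spikes are assigned to the temporally nearest position sample; per speed
#' bin, rate = spikes in frames whose speed falls in the bin / time spent in
#' the bin. Bins are half-open `[lo, hi)` with the top bin closed. Bins with
#' occupancy below `min_occupancy_s` are undefined (`NA`) and excluded from
#' fits; sparsely sampled extreme-speed bins otherwise contribute rate
#' estimates with near-infinite variance.
#'
#' @param spikes A [spike_train()].
#' @param speed A `speed_series` from [compute_speed()].
#' @param flavor `"analysis"` (5-55 cm/s, 2 cm/s) or `"display"`
#'   (0-60 cm/s, 2.5 cm/s).
#' @param min_occupancy_s Minimum seconds of occupancy for a bin to be
#'   defined. Default 1.
#' @return Object of class `speed_tuning_curve`: `edges`, `centers`, `rate`
#'   (spikes/s, `NA` where undefined), `occupancy_s`, `spike_counts`,
#'   `flavor`.
#' @export
speed_tuning_curve <- function(spikes, speed,
                               flavor = c("analysis", "display"),
                               min_occupancy_s = 1) {
  flavor <- match.arg(flavor)
  stopifnot(inherits(spikes, "spike_train"), inherits(speed, "speed_series"))
  edges <- speed_bin_edges(flavor)
  nb <- length(edges) - 1L
  frame_bin <- findInterval(speed$v, edges, rightmost.closed = TRUE)
  frame_bin[frame_bin < 1L | frame_bin > nb] <- NA_integer_
  dt <- 1 / attr_frame_rate(speed)
  occ <- tabulate(frame_bin[!is.na(frame_bin)], nbins = nb) * dt
  idx <- nearest_sample(spikes$times, speed$t)
  sbin <- frame_bin[idx]
  cnt <- tabulate(sbin[!is.na(sbin)], nbins = nb)
  rate <- rep(NA_real_, nb)
  def <- occ >= min_occupancy_s
  rate[def] <- cnt[def] / occ[def]
  if (!any(def)) stop("all speed bins empty/undefined")
  structure(list(edges = edges, centers = (edges[-1] + edges[-(nb + 1)]) / 2,
                 rate = rate, occupancy_s = occ, spike_counts = cnt,
                 flavor = flavor, min_occupancy_s = min_occupancy_s),
            class = "speed_tuning_curve")
}

# speed series carries the trace sampling implicitly via t spacing
attr_frame_rate <- function(speed) {
  dt <- stats::median(diff(speed$t))
  1 / dt
}

#' Uniform-versus-linear F-test on a speed tuning curve
#'
#' Fits the defined bins of an analysis-flavor tuning curve with a uniform
#' function (1 parameter) and a linear function `a + b v` (2 parameters) and
#' compares residual sums of squares with
#' `F = ((RSS0 - RSS1)/1) / (RSS1/(n-2))` on `(1, n-2)` degrees of freedom,
#' `n` = number of defined bins. By default both fits are weighted by bin
#' occupancy: the sampling variance of an occupancy-normalized rate is
#' inversely proportional to the time spent in the bin, so occupancy weights
#' are the correct inverse-variance weights and keep the test's size at its
#' nominal level (unweighted fitting over bins with very unequal occupancy
#' inflates the false positive rate several-fold). Set
#' `weights = "none"` for plain least squares. A perfectly linear curve with
#' nonzero slope (RSS1 = 0) is reported as p = 0 with `perfect_fit = TRUE`;
#' an exactly constant curve gives F = 0, p = 1.
#'
#' @param curve A `speed_tuning_curve` (analysis flavor) with >= 3 defined
#'   bins.
#' @param weights `"occupancy"` (default) or `"none"`.
#' @return List with `F`, `p`, `slope`, `n_bins`, `perfect_fit`.
#' @export
linear_vs_uniform_ftest <- function(curve, weights = c("occupancy", "none")) {
  weights <- match.arg(weights)
  stopifnot(inherits(curve, "speed_tuning_curve"))
  def <- !is.na(curve$rate)
  n <- sum(def)
  if (n < 3) stop("need >= 3 defined bins for the F-test")
  v <- curve$centers[def]
  r <- curve$rate[def]
  w <- if (weights == "occupancy") curve$occupancy_s[def] else rep(1, n)
  mw <- sum(w * r) / sum(w)
  rss0 <- sum(w * (r - mw)^2)
  fit <- stats::lm.wfit(cbind(1, v), r, w)
  rss1 <- sum(w * fit$residuals^2)
  slope <- fit$coefficients[2]
  tol <- .Machine$double.eps^0.75 * max(1, mean(r)^2)
  if (rss0 <= tol)  # exactly constant curve: both fits perfect, no evidence
    return(list(F = 0, p = 1, slope = unname(slope), n_bins = n,
                perfect_fit = FALSE))
  if (rss1 <= tol)  # exactly linear with nonzero slope
    return(list(F = Inf, p = 0, slope = unname(slope), n_bins = n,
                perfect_fit = TRUE))
  Fstat <- (rss0 - rss1) / (rss1 / (n - 2))
  list(F = Fstat, p = stats::pf(Fstat, 1, n - 2, lower.tail = FALSE),
       slope = unname(slope), n_bins = n, perfect_fit = FALSE)
}

# merge three sessions into one concatenated pseudo-session:
# spikes and trace of B shifted by dur(A), C by dur(A)+dur(B)
merge_triplet_cell <- function(trip, cell_id) {
  ss <- list(trip$pre, trip$manip, trip$post)
  offs <- cumsum(c(0, ss[[1]]$duration, ss[[2]]$duration))
  t <- unlist(lapply(seq_along(ss), function(i) ss[[i]]$trace$t + offs[i]))
  x <- unlist(lapply(ss, function(s) s$trace$x))
  y <- unlist(lapply(ss, function(s) s$trace$y))
  st <- unlist(lapply(seq_along(ss), function(i)
    ss[[i]]$spikes[[cell_id]]$times + offs[i]))
  list(trace = position_trace(t, x, y, frame_rate = ss[[1]]$trace$frame_rate),
       spikes = spike_train(st, cell_id),
       total_duration = sum(vapply(ss, `[[`, numeric(1), "duration")))
}

#' Classify a cell's linear speed sensitivity across a triplet
#'
#' A cell possesses linear speed sensitivity when the uniform-vs-linear
#' F-test gives p < `alpha` in at least one of the three sessions (any-of-
#' three rule). The qualitative tuning shape is assigned from the merged
#' three-session display curve via [categorize_tuning_shape()].
#'
#' @param trip A `session_triplet`.
#' @param cell_id Roster cell id.
#' @param alpha Per-session significance threshold. Default 0.05.
#' @param smooth_frames Boxcar width for speed estimation. Default 5.
#' @return List of class `speed_classification`: `cell_id`, `F` and `p`
#'   (named per session), `speed_sensitive`, `category`.
#' @export
classify_speed_cell <- function(trip, cell_id, alpha = 0.05,
                                smooth_frames = 5) {
  stopifnot(inherits(trip, "session_triplet"))
  ss <- list(pre = trip$pre, manip = trip$manip, post = trip$post)
  res <- lapply(ss, function(s) {
    sp <- compute_speed(s$trace, smooth_frames = smooth_frames)
    crv <- speed_tuning_curve(s$spikes[[cell_id]], sp, flavor = "analysis")
    linear_vs_uniform_ftest(crv)
  })
  Fv <- vapply(res, `[[`, numeric(1), "F")
  pv <- vapply(res, `[[`, numeric(1), "p")
  merged <- merge_triplet_cell(trip, cell_id)
  msp <- compute_speed(merged$trace, smooth_frames = smooth_frames)
  mcurve <- speed_tuning_curve(merged$spikes, msp, flavor = "display")
  structure(list(cell_id = cell_id, F = Fv, p = pv,
                 speed_sensitive = any(pv < alpha),
                 category = categorize_tuning_shape(mcurve)),
            class = "speed_classification")
}

#' Qualitative tuning-shape category from a display curve
#'
#' The speed range of defined bins is cut into terciles and the candidate
#' category comes from the tercile holding the curve's peak bin: lowest
#' tercile -> `decreasing`, highest -> `increasing`, middle -> `preferred`.
#' The candidate is confirmed only if the modulation is material: the mean
#' rate of the peak tercile must exceed the mean of the opposite tercile
#' (both opposite terciles, for `preferred`) by a relative margin (default
#' 10%); otherwise the curve is `unclassified`, which is where noisy flat
#' cells land. This is an explicit repo convention for shapes the source
#' analyses treated qualitatively.
#'
#' @param curve A display-flavor `speed_tuning_curve`.
#' @param margin Relative margin the peak tercile's mean rate must exceed
#'   the opposing tercile's by. Default 0.1.
#' @return One of `"increasing"`, `"preferred"`, `"decreasing"`,
#'   `"unclassified"`.
#' @export
categorize_tuning_shape <- function(curve, margin = 0.1) {
  stopifnot(inherits(curve, "speed_tuning_curve"))
  def <- which(!is.na(curve$rate))
  if (length(def) < 3) return("unclassified")
  cen <- curve$centers[def]
  r <- curve$rate[def]
  lo <- min(cen); hi <- max(cen)
  ter <- lo + (hi - lo) * c(1, 2) / 3
  tm <- c(low = mean(r[cen <= ter[1]]),
          mid = mean(r[cen > ter[1] & cen < ter[2]]),
          high = mean(r[cen >= ter[2]]))
  pv <- cen[which.max(r)]
  exceeds <- function(a, b) is.finite(a) && is.finite(b) &&
    a > (1 + margin) * b
  if (pv <= ter[1])
    return(if (exceeds(tm[["low"]], tm[["high"]])) "decreasing"
           else "unclassified")
  if (pv >= ter[2])
    return(if (exceeds(tm[["high"]], tm[["low"]])) "increasing"
           else "unclassified")
  if (exceeds(tm[["mid"]], tm[["low"]]) && exceeds(tm[["mid"]], tm[["high"]]))
    "preferred" else "unclassified"
}

#' Split-half speed tuning curves for a merged triplet
#'
#' All three sessions are concatenated in time; the merged recording is cut
#' at its temporal midpoint and display-flavor tuning curves are built for
#' the first half, the second half, and the whole merged recording — the
#' standard stability visualization for tuning curves.
#'
#' @param trip A `session_triplet`.
#' @param cell_id Roster cell id.
#' @param smooth_frames Boxcar width for speed estimation. Default 5.
#' @return List with `first_half`, `second_half`, `merged` (each a
#'   `speed_tuning_curve`), and `midpoint_s`.
#' @export
split_half_curves <- function(trip, cell_id, smooth_frames = 5) {
  m <- merge_triplet_cell(trip, cell_id)
  mid <- m$total_duration / 2
  sp <- compute_speed(m$trace, smooth_frames = smooth_frames)
  half_curve <- function(lo, hi) {
    keep <- sp$t >= lo & sp$t < hi
    hsp <- structure(list(t = sp$t[keep], v = sp$v[keep],
                          smooth_frames = sp$smooth_frames),
                     class = "speed_series")
    hspk <- spike_train(m$spikes$times[m$spikes$times >= lo &
                                         m$spikes$times < hi], cell_id)
    speed_tuning_curve(hspk, hsp, flavor = "display")
  }
  list(first_half = half_curve(0, mid),
       second_half = half_curve(mid, Inf),
       merged = speed_tuning_curve(m$spikes, sp, flavor = "display"),
       midpoint_s = mid)
}
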