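# Occupancy-normalized 2D firing ratemaps on a 3 cm grid, Gaussian-smoothed
# with masked renormalization so unvisited pixels contribute nothing.

# grid geometry for an arena bounding box: bin edges covering [0, extent]
grid_edges <- function(bbox, bin_size) {
  nx <- ceiling(bbox[1] / bin_size)
  ny <- ceiling(bbox[2] / bin_size)
  list(x = seq(0, nx * bin_size, by = bin_size),
       y = seq(0, ny * bin_size, by = bin_size), nx = nx, ny = ny)
}

bin_index <- function(v, edges) {
  i <- findInterval(v, edges, rightmost.closed = TRUE)
  i[i < 1L | i > length(edges) - 1L] <- NA_integer_
  i
}

#' Spatial occupancy grid
#'
#' Each position sample contributes one frame interval (1 / frame_rate
#' seconds) to the bin containing it, so the grid total equals
#' n_samples / frame_rate. Samples outside the arena bounding box are dropped
#' with a warning.
#'
#' @param trace A [position_trace()].
#' @param arena An [arena()]; its bounding box defines the grid extent.
#' @param bin_size Spatial bin side in cm. Default 3.
#' @return List with `occupancy` (ny x nx matrix, seconds; rows = y bins),
#'   `edges`, `bin_size`, `n_dropped`.
#' @export
compute_occupancy <- function(trace, arena, bin_size = 3) {
  stopifnot(inherits(trace, "position_trace"))
  if (length(trace$t) == 0) stop("empty trace")
  g <- grid_edges(arena_bbox(arena), bin_size)
  ix <- bin_index(trace$x, g$x)
  iy <- bin_index(trace$y, g$y)
  ok <- !is.na(ix) & !is.na(iy)
  if (any(!ok))
    warning(sum(!ok), " out-of-bounds samples dropped from occupancy")
  occ <- matrix(0, nrow = g$ny, ncol = g$nx)
  counts <- table(factor(iy[ok], levels = seq_len(g$ny)),
                  factor(ix[ok], levels = seq_len(g$nx)))
  occ[] <- as.numeric(counts) / trace$frame_rate
  list(occupancy = occ, edges = g, bin_size = bin_size,
       n_dropped = sum(!ok))
}

#' Raw occupancy-normalized ratemap
#'
#' Each spike is assigned to the spatial bin of the temporally nearest
#' position sample; the raw rate in a bin is its spike count divided by the
#' time the animal occupied that bin. Unvisited bins are masked (`NA`) and
#' excluded from all downstream computation. Spikes outside the trace's time
#' span are dropped with a warning.
#'
#' @param spikes A [spike_train()].
#' @param trace A [position_trace()].
#' @param arena An [arena()].
#' @param bin_size Bin side in cm. Default 3.
#' @return Object of class `ratemap`: list with `rate` (ny x nx, spikes/s,
#'   `NA` where unvisited), `occupancy`, `spike_counts`, `visited` (logical
#'   matrix), `bin_size`, `smoothed = FALSE`, `n_spikes_assigned`.
#' @export
compute_ratemap <- function(spikes, trace, arena, bin_size = 3) {
  stopifnot(inherits(spikes, "spike_train"))
  occ <- compute_occupancy(trace, arena, bin_size)
  g <- occ$edges
  st <- spikes$times
  # tolerate spikes within half a frame of the span (nearest-sample rule)
  half <- 0.5 / trace$frame_rate
  in_span <- st >= trace$t[1] - half & st <= trace$t[length(trace$t)] + half
  if (any(!in_span))
    warning(sum(!in_span), " spikes outside trace span dropped")
  st <- st[in_span]
  idx <- nearest_sample(st, trace$t)
  ix <- bin_index(trace$x[idx], g$x)
  iy <- bin_index(trace$y[idx], g$y)
  ok <- !is.na(ix) & !is.na(iy)
  cnt <- matrix(0, nrow = g$ny, ncol = g$nx)
  if (any(ok)) {
    tab <- table(factor(iy[ok], levels = seq_len(g$ny)),
                 factor(ix[ok], levels = seq_len(g$nx)))
    cnt[] <- as.numeric(tab)
  }
  visited <- occ$occupancy > 0
  rate <- matrix(NA_real_, nrow = g$ny, ncol = g$nx)
  rate[visited] <- cnt[visited] / occ$occupancy[visited]
  structure(list(rate = rate, occupancy = occ$occupancy, spike_counts = cnt,
                 visited = visited, bin_size = bin_size, smoothed = FALSE,
                 n_spikes_assigned = sum(cnt[visited])),
            class = "ratemap")
}

# index of nearest element of sorted vector tv for each value in q
nearest_sample <- function(q, tv) {
  i <- findInterval(q, tv, all.inside = TRUE)
  lo <- abs(q - tv[i]) <= abs(tv[pmin(i + 1L, length(tv))] - q)
  ifelse(lo, i, pmin(i + 1L, length(tv)))
}

#' Gaussian smoothing with masked renormalization
#'
#' Smooths a raw ratemap with an isotropic 2D Gaussian kernel. The kernel
#' nominally spans `kernel_cm` (default 7 cm): sigma defaults to
#' `kernel_cm / 3` cm so that +-1.5 sigma covers the stated span, and the
#' kernel support is truncated at a `kernel_cm` half-width. Unvisited bins are
#' excluded from both the numerator and the kernel-weight renormalization
#' (masked normalization), so a constant field is preserved exactly and mass
#' never bleeds in from unvisited pixels. The visited mask is unchanged.
#'
#' @param raw An unsmoothed `ratemap`.
#' @param kernel_cm Nominal kernel span in cm (also the truncation
#'   half-width). Default 7.
#' @param sigma_cm Gaussian sigma in cm. Default `kernel_cm / 3`.
#' @return A `ratemap` with `smoothed = TRUE`.
#' @export
smooth_ratemap <- function(raw, kernel_cm = 7, sigma_cm = kernel_cm / 3) {
  stopifnot(inherits(raw, "ratemap"))
  if (raw$smoothed) stop("ratemap already smoothed")
  bs <- raw$bin_size
  r <- floor(kernel_cm / bs)          # truncation radius in bins
  off <- (-r):r
  d2 <- outer(off^2, off^2, `+`) * bs^2
  K <- exp(-d2 / (2 * sigma_cm^2))
  K <- K / sum(K)
  sm <- masked_convolve(raw$rate, raw$visited, K)
  out <- raw
  out$rate <- sm
  out$smoothed <- TRUE
  out$kernel <- list(kernel_cm = kernel_cm, sigma_cm = sigma_cm,
                     radius_bins = r)
  out
}

# 2D convolution with NA masking: at each visited pixel, weighted mean of
# visited neighbors with weights renormalized over the visited support.
masked_convolve <- function(mat, visited, K) {
  ny <- nrow(mat); nx <- ncol(mat)
  r <- (nrow(K) - 1L) %/% 2L
  vals <- ifelse(visited, mat, 0)
  wsum <- matrix(0, ny, nx)
  vsum <- matrix(0, ny, nx)
  vis <- visited * 1
  for (dy in (-r):r) {
    ys <- max(1, 1 - dy):min(ny, ny - dy)
    yt <- ys + dy
    for (dx in (-r):r) {
      w <- K[dy + r + 1L, dx + r + 1L]
      xs <- max(1, 1 - dx):min(nx, nx - dx)
      xt <- xs + dx
      vsum[yt, xt] <- vsum[yt, xt] + w * vals[ys, xs]
      wsum[yt, xt] <- wsum[yt, xt] + w * vis[ys, xs]
    }
  }
  out <- matrix(NA_real_, ny, nx)
  ok <- visited & wsum > 0
  out[ok] <- vsum[ok] / wsum[ok]
  out
}

#' Cross-session display normalization for a cell's three ratemaps
#'
#' Divides all three smoothed maps by the 95th percentile of the pooled
#' visited-bin rates across the three sessions, so the same color scale is
#' comparable across the triplet. Values may exceed 1. All-zero maps return
#' zeros (divide-by-zero guarded).
#'
#' @param maps List of three `ratemap` objects from one cell's triplet.
#' @return List of three matrices (same shapes, `NA` where unvisited), with
#'   attribute `scale` = the pooled 95th percentile used.
#' @export
normalize_for_display <- function(maps) {
  stopifnot(length(maps) == 3)
  pooled <- unlist(lapply(maps, function(m) m$rate[m$visited]))
  q95 <- stats::quantile(pooled, 0.95, na.rm = TRUE, names = FALSE)
  out <- lapply(maps, function(m) {
    if (q95 > 0) m$rate / q95 else m$rate * 0
  })
  attr(out, "scale") <- q95
  out
}
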