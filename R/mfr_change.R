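# Central classifier: neurons whose mean firing rate (MFR) is systematically
# different in the manipulation session relative to BOTH flanking sessions.
# Each 765 s session is cut into ten equal blocks of 76.5 s; the three groups
# of ten block MFRs are compared with a Kruskal-Wallis omnibus and Scheffe-type
# pairwise post hoc tests on ranks.

#' Block-wise mean firing rates for one session
#'
#' Splits `[0, duration)` into `n_blocks` equal half-open blocks and returns
#' the MFR of each (spike count / block length, spikes/s). With the default
#' 765 s window and 10 blocks, blocks are 76.5 s. The mean of the block MFRs
#' equals the session MFR exactly (equal blocks).
#'
#' @param spikes A [spike_train()] (or bare numeric vector of spike times)
#'   from a session already truncated to `duration`.
#' @param duration Session duration in seconds. Default 765.
#' @param n_blocks Number of equal blocks. Default 10.
#' @return List with `block_rates` (length `n_blocks`), `block_s`
#'   (block length, seconds) and `session_mfr` (spikes/s).
#' @export
block_mfr <- function(spikes, duration = 765, n_blocks = 10) {
  times <- if (inherits(spikes, "spike_train")) spikes$times else
    as.numeric(spikes)
  if (length(times) && max(times) >= duration)
    stop("spike times must lie in [0, duration); truncate the session first")
  block_s <- duration / n_blocks
  edges <- seq(0, duration, length.out = n_blocks + 1)
  counts <- tabulate(findInterval(times, edges, left.open = FALSE,
                                  rightmost.closed = FALSE),
                     nbins = n_blocks)
  rates <- counts / block_s
  list(block_rates = rates, block_s = block_s,
       session_mfr = length(times) / duration)
}

#' Classify a cell's MFR change across an A-B-A' triplet
#'
#' A cell is labeled `increase` when the manipulation session's block MFRs are
#' significantly different from both the pre and the post session's blocks
#' (Scheffe-type pairwise tests at `alpha`, following a Kruskal-Wallis
#' omnibus over the three groups of block MFRs) and the manipulation MFR
#' exceeds the flanker mean; `decrease` likewise with a lower manipulation
#' MFR; `none` otherwise. The pre-vs-post comparison never vetoes a label; it
#' is reported as a quality flag (`pre_post_differs`).
#'
#' @param trip A `session_triplet` (sessions truncated to a common window).
#' @param cell_id Cell to classify; must be in `trip$cell_roster`.
#' @param alpha Significance threshold. Default 0.05.
#' @param n_blocks Blocks per session. Default 10.
#' @return List of class `change_classification`: `cell_id`, `label`,
#'   `H`, `p_omnibus`, `p_manip_pre`, `p_manip_post`, `p_pre_post`,
#'   `delta` (manip MFR - mean(pre, post), spikes/s), `mfr` (named vector),
#'   `blocks` (3 x n_blocks matrix), `pre_post_differs`, `silent`.
#' @export
classify_mfr_change <- function(trip, cell_id, alpha = 0.05, n_blocks = 10) {
  stopifnot(inherits(trip, "session_triplet"))
  if (!cell_id %in% trip$cell_roster)
    stop("cell '", cell_id, "' is not in the triplet roster")
  dur <- trip$pre$duration
  b <- lapply(list(pre = trip$pre, manip = trip$manip, post = trip$post),
              function(s) block_mfr(s$spikes[[cell_id]], duration = dur,
                                    n_blocks = n_blocks))
  mfr <- vapply(b, `[[`, numeric(1), "session_mfr")
  blocks <- do.call(rbind, lapply(b, `[[`, "block_rates"))
  silent <- all(blocks == 0)
  delta <- mfr[["manip"]] - mean(c(mfr[["pre"]], mfr[["post"]]))
  groups <- list(pre = blocks["pre", ], manip = blocks["manip", ],
                 post = blocks["post", ])
  om <- kruskal_wallis(groups)
  ph <- posthoc_pairwise(groups)
  # group order pre=1, manip=2, post=3
  p_mp <- ph$p[ph$i == 1 & ph$j == 2]
  p_mq <- ph$p[ph$i == 2 & ph$j == 3]
  p_pp <- ph$p[ph$i == 1 & ph$j == 3]
  label <- "none"
  if (!silent && p_mp < alpha && p_mq < alpha) {
    if (delta > 0) label <- "increase"
    if (delta < 0) label <- "decrease"
  }
  structure(list(cell_id = cell_id, label = label,
                 H = om$H, p_omnibus = om$p,
                 p_manip_pre = p_mp, p_manip_post = p_mq, p_pre_post = p_pp,
                 delta = unname(delta), mfr = mfr, blocks = blocks,
                 pre_post_differs = p_pp < alpha, silent = silent),
            class = "change_classification")
}

#' Classify every roster cell of a triplet
#'
#' @param trip A `session_triplet`.
#' @inheritParams classify_mfr_change
#' @return data.frame with one row per roster cell: `cell_id`, `label`, `H`,
#'   `p_omnibus`, pairwise p's, `delta`, per-session MFRs.
#' @export
classify_triplet <- function(trip, alpha = 0.05, n_blocks = 10) {
  cls <- lapply(trip$cell_roster, function(id)
    classify_mfr_change(trip, id, alpha = alpha, n_blocks = n_blocks))
  data.frame(cell_id = vapply(cls, `[[`, character(1), "cell_id"),
             label = vapply(cls, `[[`, character(1), "label"),
             H = vapply(cls, `[[`, numeric(1), "H"),
             p_omnibus = vapply(cls, `[[`, numeric(1), "p_omnibus"),
             p_manip_pre = vapply(cls, `[[`, numeric(1), "p_manip_pre"),
             p_manip_post = vapply(cls, `[[`, numeric(1), "p_manip_post"),
             p_pre_post = vapply(cls, `[[`, numeric(1), "p_pre_post"),
             delta = vapply(cls, `[[`, numeric(1), "delta"),
             mfr_pre = vapply(cls, function(x) x$mfr[["pre"]], numeric(1)),
             mfr_manip = vapply(cls, function(x) x$mfr[["manip"]], numeric(1)),
             mfr_post = vapply(cls, function(x) x$mfr[["post"]], numeric(1)),
             stringsAsFactors = FALSE)
}

#' Population summary of MFR-change classifications
#'
#' Counts and percentages (one decimal) of increase / decrease / none cells,
#' overall and within the significant subset, plus the mean |delta| among
#' increases and decreases.
#'
#' @param classifications data.frame from [classify_triplet()] (needs columns
#'   `label` and `delta`), or a character vector of labels (then mean deltas
#'   are `NA`).
#' @param manipulation_type Optional label carried into the summary.
#' @return List with `manipulation_type`, `n_total`, `n_increase`,
#'   `n_decrease`, `n_significant`, `n_none`, `pct_increase`, `pct_decrease`,
#'   `pct_significant`, `pct_none` (percent of all cells, one decimal),
#'   `pct_increase_of_significant`, `pct_decrease_of_significant`,
#'   `mean_delta_increase`, `mean_delta_decrease` (spikes/s; `NA` when the
#'   class is empty).
#' @export
summarize_population <- function(classifications, manipulation_type = NA) {
  if (is.character(classifications))
    classifications <- data.frame(label = classifications,
                                  delta = NA_real_)
  if (nrow(classifications) < 1) stop("need >= 1 classification")
  lab <- classifications$label
  n <- length(lab)
  n_inc <- sum(lab == "increase")
  n_dec <- sum(lab == "decrease")
  n_sig <- n_inc + n_dec
  pct <- function(a, b) if (b > 0) round(100 * a / b, 1) else NA_real_
  mdelta <- function(which) {
    d <- classifications$delta[lab == which]
    if (length(d) == 0 || all(is.na(d))) NA_real_ else mean(abs(d))
  }
  list(manipulation_type = manipulation_type,
       n_total = n, n_increase = n_inc, n_decrease = n_dec,
       n_significant = n_sig, n_none = n - n_sig,
       pct_increase = pct(n_inc, n),
       pct_decrease = pct(n_dec, n),
       pct_significant = pct(n_sig, n),
       pct_none = pct(n - n_sig, n),
       pct_increase_of_significant = pct(n_inc, n_sig),
       pct_decrease_of_significant = pct(n_dec, n_sig),
       mean_delta_increase = mdelta("increase"),
       mean_delta_decrease = mdelta("decrease"))
}
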