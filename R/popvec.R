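# Population vector (PV) MFR correlation analysis: the whole-session MFR
# vector over a fixed cell roster is correlated with every 400 ms binned MFR
# vector, within and across session types, and the four resulting correlation
# distributions are compared with Kruskal-Wallis + Scheffe post hoc tests.

#' Whole-session mean firing rate population vector
#'
#' @param roster Character vector fixing the cell order for the analysis.
#' @param session A `session` truncated to the analysis window; every roster
#'   cell must be present.
#' @return Named numeric vector (spikes/s), one entry per roster cell.
#' @export
whole_session_pv <- function(roster, session) {
  stopifnot(inherits(session, "session"))
  missing <- setdiff(roster, names(session$spikes))
  if (length(missing))
    stop("roster cells missing from session: ",
         paste(missing, collapse = ", "))
  vapply(roster, function(id)
    length(session$spikes[[id]]$times) / session$duration, numeric(1))
}

#' Binned population rate matrix (cells x 400 ms bins)
#'
#' The session is split into `floor(duration / bin_s)` complete half-open
#' bins (1912 bins for 765 s at 0.4 s); the trailing remainder is discarded.
#' Entries are spike counts per bin divided by `bin_s` (spikes/s).
#'
#' @param roster Character vector fixing the cell order.
#' @param session A truncated `session` containing all roster cells.
#' @param bin_s Bin width in seconds. Default 0.4.
#' @return Numeric matrix, rows = roster cells, columns = bins.
#' @export
binned_pv_matrix <- function(roster, session, bin_s = 0.4) {
  stopifnot(inherits(session, "session"))
  missing <- setdiff(roster, names(session$spikes))
  if (length(missing))
    stop("roster cells missing from session: ",
         paste(missing, collapse = ", "))
  nb <- floor(session$duration / bin_s + 1e-9)
  m <- matrix(0, nrow = length(roster), ncol = nb,
              dimnames = list(roster, NULL))
  for (id in roster) {
    st <- session$spikes[[id]]$times
    b <- floor(st / bin_s) + 1L
    b <- b[b >= 1L & b <= nb]
    if (length(b)) m[id, ] <- tabulate(b, nbins = nb) / bin_s
  }
  m
}

#' Correlate a population vector with every binned column
#'
#' Pearson correlation across cells between the whole-session PV and each
#' 400 ms column of the binned matrix. Columns with zero variance (e.g. no
#' spikes from any cell in that bin) have undefined correlation; they are
#' excluded and counted, never imputed.
#'
#' @param pv Named numeric vector from [whole_session_pv()].
#' @param mat Matrix from [binned_pv_matrix()] over the same roster.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return List with `r` (correlations for defined bins), `n_excluded`
#'   (zero-variance bins dropped), `n_bins`.
#' @export
pv_correlations <- function(pv, mat, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!identical(names(pv), rownames(mat)))
    stop("roster mismatch between population vector and binned matrix")
  if (stats::sd(pv) == 0)
    stop("whole-session population vector has zero variance")
  sds <- apply(mat, 2, stats::sd)
  keep <- sds > 0
  r <- as.numeric(stats::cor(pv, mat[, keep, drop = FALSE],
                             method = method))
  list(r = r, n_excluded = sum(!keep), n_bins = ncol(mat))
}

#' All session-type pairings of PV correlations for a set of triplets
#'
#' For each triplet and each (whole-session type, binned type) pairing, the
#' whole-session PV of the first type is correlated with every 400 ms bin of
#' the second type's session. Pairings are pooled across triplets into four
#' labeled distributions: `same_type` (pre x pre, manip x manip, post x
#' post), `pre_x_manip`, `pre_x_post`, `manip_x_post` (each direction
#' pooled).
#'
#' @param triplets List of `session_triplet` objects (a single triplet is
#'   accepted); each uses its own roster.
#' @param bin_s Bin width in seconds. Default 0.4.
#' @param method Correlation type. Default `"pearson"`.
#' @return Named list of four numeric vectors of correlations.
#' @export
pv_correlation_sets <- function(triplets, bin_s = 0.4, method = "pearson") {
  if (inherits(triplets, "session_triplet")) triplets <- list(triplets)
  out <- list(same_type = numeric(0), pre_x_manip = numeric(0),
              pre_x_post = numeric(0), manip_x_post = numeric(0))
  pair_label <- function(a, b) {
    if (a == b) return("same_type")
    key <- paste(sort(c(a, b)), collapse = "_x_")
    switch(key,
           manip_x_pre = "pre_x_manip",
           post_x_pre = "pre_x_post",
           manip_x_post = "manip_x_post")
  }
  for (trip in triplets) {
    roster <- trip$cell_roster
    ss <- list(pre = trip$pre, manip = trip$manip, post = trip$post)
    pvs <- lapply(ss, function(s) whole_session_pv(roster, s))
    mats <- lapply(ss, function(s) binned_pv_matrix(roster, s, bin_s = bin_s))
    for (a in names(ss)) for (b in names(ss)) {
      lab <- pair_label(a, b)
      r <- pv_correlations(pvs[[a]], mats[[b]], method = method)$r
      out[[lab]] <- c(out[[lab]], r)
    }
  }
  out
}

#' Compare the four PV correlation distributions
#'
#' Kruskal-Wallis omnibus across the labeled correlation distributions,
#' followed by Scheffe-type pairwise post hoc comparisons on pooled ranks.
#' Medians summarize effect direction.
#'
#' @param sets Named list of numeric vectors (e.g. from
#'   [pv_correlation_sets()]); each nonempty.
#' @return List of class `pv_correlation_set`: `labels`, `medians`,
#'   `omnibus` (H, p, df), `pairwise` (data.frame with group labels and
#'   family-wise p), `n` per group.
#' @export
compare_correlation_distributions <- function(sets) {
  if (any(vapply(sets, length, integer(1)) == 0))
    stop("every correlation distribution must be nonempty")
  om <- kruskal_wallis(sets)
  ph <- posthoc_pairwise(sets)
  labs <- names(sets)
  ph$group_i <- labs[ph$i]
  ph$group_j <- labs[ph$j]
  structure(list(labels = labs,
                 medians = vapply(sets, stats::median, numeric(1)),
                 omnibus = om,
                 pairwise = ph[, c("group_i", "group_j", "mean_rank_diff",
                                   "p")],
                 n = vapply(sets, length, integer(1))),
            class = "pv_correlation_set")
}

#' @export
print.pv_correlation_set <- function(x, ...) {
  cat("<pv_correlation_set>\n")
  cat(sprintf("  omnibus: H = %.1f, df = %d, p = %.3g\n",
              x$omnibus$H, x$omnibus$df, x$omnibus$p))
  for (i in seq_along(x$labels))
    cat(sprintf("  %-13s median r = %.3f  (n = %d)\n",
                x$labels[i], x$medians[i], x$n[i]))
  invisible(x)
}
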