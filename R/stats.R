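# Shared nonparametric machinery: Kruskal-Wallis omnibus and Scheffe-type
# pairwise comparisons on pooled ranks (the MATLAB multcompare convention
# after kruskalwallis, with tie adjustment).

#' Kruskal-Wallis test on a list of groups
#'
#' Thin wrapper around [stats::kruskal.test()] returning the tie-corrected H
#' statistic and its chi-squared p-value on k-1 degrees of freedom. The
#' degenerate case where every value is identical across all groups is
#' reported as H = 0, p = 1 (the test statistic is undefined there because
#' every observation is tied).
#'
#' @param groups List of >= 2 numeric vectors, each of length >= 2.
#' @return List with `H`, `p`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("need >= 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("each group needs >= 2 values")
  vals <- unlist(groups, use.names = FALSE)
  df <- length(groups) - 1L
  if (length(unique(vals)) == 1L)
    return(list(H = 0, p = 1, df = df))
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  kt <- stats::kruskal.test(vals, g)
  list(H = unname(kt$statistic), p = kt$p.value, df = df)
}

#' Scheffe-type pairwise comparisons on pooled ranks
#'
#' Family-wise corrected pairwise tests following a Kruskal-Wallis omnibus:
#' all observations are ranked jointly (mean ranks for ties), and each pair of
#' groups (i, j) is compared via the standardized mean-rank difference
#' \deqn{t_{ij} = (\bar R_i - \bar R_j) / \sqrt{(N(N+1)/12 - T)(1/n_i + 1/n_j)}}
#' where \eqn{T = \sum (t^3 - t) / (12(N-1))} adjusts for ties. Under the
#' Scheffe criterion the family-wise p-value for a pair is
#' \eqn{P(\chi^2_{k-1} > t_{ij}^2)}, which controls the family-wise error
#' rate for all contrasts simultaneously.
#'
#' @param groups List of >= 2 numeric vectors (each length >= 2).
#' @return data.frame with columns `i`, `j` (group indices), `mean_rank_diff`,
#'   `p` (family-wise corrected).
#' @export
posthoc_pairwise <- function(groups) {
  k <- length(groups)
  if (k < 2) stop("need >= 2 groups")
  n <- vapply(groups, length, integer(1))
  if (any(n < 2)) stop("each group needs >= 2 values")
  vals <- unlist(groups, use.names = FALSE)
  N <- length(vals)
  r <- rank(vals)
  grp <- rep(seq_len(k), n)
  mr <- tapply(r, grp, mean)
  ties <- table(vals)
  tieadj <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tieadj
  pairs <- utils::combn(k, 2)
  out <- data.frame(i = pairs[1, ], j = pairs[2, ])
  out$mean_rank_diff <- mr[out$i] - mr[out$j]
  se <- sqrt(s2 * (1 / n[out$i] + 1 / n[out$j]))
  tsq <- ifelse(se > 0, (out$mean_rank_diff / se)^2, 0)
  out$p <- stats::pchisq(tsq, df = k - 1, lower.tail = FALSE)
  rownames(out) <- NULL
  out
}
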