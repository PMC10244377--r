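## Shared nonparametric tests: Kruskal-Wallis (wrapped), Dunn's all-pairs
## z-test on pooled ranks, Games-Howell pairwise comparisons, BH adjustment.

as_grouped <- function(groups) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("group", "value") %in% names(groups)))
    groups <- split(groups$value, groups$group)
  }
  groups <- lapply(groups, function(v) v[is.finite(v)])
  groups[vapply(groups, length, integer(1)) > 0]
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square reference distribution
#' on k - 1 degrees of freedom (delegates to [stats::kruskal.test()]).
#'
#' @param groups Named list of numeric vectors, or a data.frame with
#'   columns `group` and `value`.
#' @return List with `H`, `df`, `p.value`, `n` and per-group `medians`.
#' @examples
#' kruskal_wallis(list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9)))
#' @export
kruskal_wallis <- function(groups) {
  groups <- as_grouped(groups)
  if (length(groups) < 2) stop("need at least 2 groups")
  if (sum(lengths(groups)) < 3) stop("need at least 3 observations in total")
  vals <- unlist(groups, use.names = FALSE)
  if (length(unique(vals)) == 1) {
    ## every observation tied: no rank variation, H is 0 by convention
    return(list(H = 0, df = length(groups) - 1L, p.value = 1,
                n = length(vals),
                medians = vapply(groups, median, numeric(1))))
  }
  kt <- kruskal.test(groups)
  list(
    H = unname(kt$statistic),
    df = unname(kt$parameter),
    p.value = unname(kt$p.value),
    n = sum(lengths(groups)),
    medians = vapply(groups, median, numeric(1))
  )
}

#' Dunn's all-pairs post hoc test
#'
#' Pairwise z statistics from pooled-rank mean differences with
#' tie-corrected variance, two-sided normal p-values, and (by default)
#' Benjamini-Hochberg adjustment across all pairs.
#'
#' The z statistic for groups i, j is
#' \deqn{z = (\bar R_i - \bar R_j)/\sqrt{(N(N+1)/12 - T)(1/n_i + 1/n_j)}}
#' with tie correction \eqn{T = \sum_t (t^3 - t) / (12 (N - 1))} over tie
#' group sizes t.
#'
#' @param groups Named list of numeric vectors, or a data.frame with
#'   `group` and `value` columns.
#' @param adjust Multiple-testing adjustment method (see
#'   [stats::p.adjust()]); default `"BH"`.
#' @return data.frame with `group1`, `group2`, `z`, `p.value`, `padj`.
#' @export
dunn_all_pairs <- function(groups, adjust = "BH") {
  groups <- as_grouped(groups)
  k <- length(groups)
  if (k < 2) stop("need at least 2 groups")
  small <- lengths(groups) < 2
  if (any(small)) {
    warning("excluding group(s) with <2 observations: ",
            paste(names(groups)[small], collapse = ", "))
    groups <- groups[!small]
    k <- length(groups)
    if (k < 2) stop("fewer than 2 usable groups after exclusion")
  }
  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  ties <- table(x)
  Tcorr <- sum(ties^3 - ties) / (12 * (N - 1))
  v0 <- N * (N + 1) / 12 - Tcorr
  pairs <- utils::combn(names(groups), 2)
  z <- p <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt(v0 * (1 / n[[a]] + 1 / n[[b]]))
    z[j] <- (rbar[[a]] - rbar[[b]]) / se
    p[j] <- 2 * pnorm(-abs(z[j]))
  }
  data.frame(
    group1 = pairs[1, ], group2 = pairs[2, ],
    z = z, p.value = p, padj = p.adjust(p, method = adjust),
    stringsAsFactors = FALSE
  )
}

#' Games-Howell pairwise comparisons
#'
#' Welch-type pairwise statistic on group means with Welch-Satterthwaite
#' degrees of freedom and p-values from the studentized-range distribution
#' with k groups (Tukey-Kramer quantiles). Appropriate for unequal
#' variances and unequal group sizes.
#'
#' @param groups Named list of numeric vectors, or a data.frame with
#'   `group` and `value` columns.
#' @return data.frame with `group1`, `group2`, `t`, `df`, `p.value`.
#' @export
games_howell <- function(groups) {
  groups <- as_grouped(groups)
  k <- length(groups)
  if (k < 2) stop("need at least 2 groups")
  if (any(lengths(groups) < 2)) {
    stop("Games-Howell requires >=2 observations per group")
  }
  m <- vapply(groups, mean, numeric(1))
  v <- vapply(groups, var, numeric(1))
  n <- lengths(groups)
  pairs <- utils::combn(names(groups), 2)
  tt <- df <- p <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se2 <- v[[a]] / n[[a]] + v[[b]] / n[[b]]
    tt[j] <- (m[[a]] - m[[b]]) / sqrt(se2)
    df[j] <- se2^2 / ((v[[a]] / n[[a]])^2 / (n[[a]] - 1) +
                      (v[[b]] / n[[b]])^2 / (n[[b]] - 1))
    p[j] <- ptukey(abs(tt[j]) * sqrt(2), nmeans = k, df = df[j],
                   lower.tail = FALSE)
  }
  data.frame(
    group1 = pairs[1, ], group2 = pairs[2, ],
    t = tt, df = df, p.value = p,
    stringsAsFactors = FALSE
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (delegates to
#' [stats::p.adjust()] with `method = "BH"`); monotone and capped at 1.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  stopifnot(is.numeric(p), all(is.na(p) | (p >= 0 & p <= 1)))
  p.adjust(p, method = "BH")
}
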