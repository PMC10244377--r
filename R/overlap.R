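## Hypergeometric set-overlap statistics (representation factor).

#' Hypergeometric overlap test between two gene lists
#'
#' Given two sets drawn from a finite universe, computes the observed
#' overlap k, the overlap expected under independence
#' (n1 * n2 / N), the representation factor k / expected, and the
#' upper-tail hypergeometric probability P(X >= k). The tail is computed
#' with [stats::phyper()], which works in log space internally and is
#' stable at extreme significance.
#'
#' @param set_a,set_b Character vectors of identifiers; must be subsets of
#'   `universe`.
#' @param universe Character vector: the background universe (deduplicated
#'   internally; must be non-empty).
#' @return List of class `overlap_result` with `n1`, `n2`, `N`, `k`,
#'   `expected`, `representation_factor`, `p.value`.
#' @examples
#' u <- paste0("g", 1:1000)
#' res <- hypergeometric_overlap(u[1:100], u[81:180], u)
#' res$representation_factor
#' @export
hypergeometric_overlap <- function(set_a, set_b, universe) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("universe is empty")
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  out_a <- setdiff(set_a, universe)
  out_b <- setdiff(set_b, universe)
  if (length(out_a) || length(out_b)) {
    stop("elements outside the universe: ",
         paste(head(c(out_a, out_b), 5), collapse = ", "),
         if (length(c(out_a, out_b)) > 5) ", ..." else "")
  }
  n1 <- length(set_a); n2 <- length(set_b); N <- length(universe)
  k <- length(intersect(set_a, set_b))
  expected <- n1 * n2 / N
  ## P(X >= k): phyper gives P(X <= q), so use q = k - 1 upper tail
  p <- if (k == 0) 1.0 else phyper(k - 1, n1, N - n1, n2, lower.tail = FALSE)
  structure(
    list(n1 = n1, n2 = n2, N = N, k = k, expected = expected,
         representation_factor = if (expected > 0) k / expected else NA_real_,
         p.value = p),
    class = "overlap_result"
  )
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "Hypergeometric overlap: k = %d of n1 = %d, n2 = %d (universe %d)\n",
    x$k, x$n1, x$n2, x$N))
  cat(sprintf("  expected %.3f, representation factor %.3f, p = %.4g\n",
              x$expected, x$representation_factor, x$p.value))
  invisible(x)
}
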