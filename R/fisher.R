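#' Fisher's exact test for a 2x2 table
#'
#' Exact two-sided P by summing, at fixed margins, the hypergeometric
#' probabilities of all tables no more probable than the observed one (with
#' the conventional relative tolerance for ties). The odds ratio is the
#' sample odds ratio (a*d)/(b*c); division by zero yields `Inf`/`NaN` with
#' the `or_degenerate` flag set. A zero margin gives P = 1 with the
#' `degenerate` flag.
#'
#' @param a,b,c,d cell counts: `a` and `b` form the first row, `c` and `d`
#'   the second; alternatively pass a 2x2 matrix as `a`
#' @return list with `p`, `odds_ratio`, `table`, `degenerate`,
#'   `or_degenerate`
#' @export
fisher_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == 2))
    d <- a[2, 2]; c <- a[2, 1]; b <- a[1, 2]; a <- a[1, 1]
  }
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers", call. = FALSE)
  tab <- matrix(cells, 2, 2, byrow = TRUE)
  m <- a + b; n <- c + d; k <- a + c
  or <- (a * d) / (b * c)
  or_degenerate <- !is.finite(or)
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0)
    return(list(p = 1, odds_ratio = or, table = tab, degenerate = TRUE,
                or_degenerate = or_degenerate))
  support <- max(0, k - n):min(k, m)
  dens <- dhyper(support, m, n, k)
  obs <- dhyper(a, m, n, k)
  p <- min(1, sum(dens[dens <= obs * (1 + 1e-7)]))
  list(p = p, odds_ratio = or, table = tab, degenerate = FALSE,
       or_degenerate = or_degenerate)
}

# One-sided (enrichment) hypergeometric tail: P(X >= hits) for `hits` of
# `query_size` draws landing in a set of `set_size` among `background_size`.
.hyper_enrichment_p <- function(hits, set_size, background_size, query_size) {
  phyper(hits - 1, set_size, background_size - set_size, query_size,
         lower.tail = FALSE)
}
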