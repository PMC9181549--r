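#' Kimura two-parameter distance between two aligned sequences
#'
#' Computes the K2P substitution distance
#' \deqn{K = -\tfrac{1}{2}\,\ln\big((1 - 2P - Q)\sqrt{1 - 2Q}\big)}
#' where \eqn{P} and \eqn{Q} are the proportions of aligned sites showing a
#' transition (A\eqn{\leftrightarrow}G, C\eqn{\leftrightarrow}T) and a
#' transversion, respectively. Columns containing a gap (`-`) or an
#' ambiguous base are excluded from \eqn{P}, \eqn{Q} and the site count
#' (complete "pairwise deletion").
#'
#' @param a,b aligned nucleotide sequences of equal length: single strings
#'   or character vectors of single bases. Gaps are `-`.
#' @return an object of class `k2p_distance`: a list with elements `P`, `Q`,
#'   `K` (substitutions/site) and `sites_compared`.
#' @details The distance is undefined (saturated) when
#'   \eqn{1 - 2P - Q \le 0} or \eqn{1 - 2Q \le 0}; this is signalled as an
#'   error of class `retroscape_saturation` so callers can count and skip
#'   saturated pairs.
#' @export
#' @examples
#' k2p("AAAA", "AGAA")$K     # -0.5 * log(0.5)
k2p <- function(a, b) {
  if (length(a) == 1L && is.character(a)) a <- s2c(a)
  if (length(b) == 1L && is.character(b)) b <- s2c(b)
  if (length(a) != length(b))
    stop("sequences must be aligned to equal length")
  a <- toupper(a); b <- toupper(b)
  keep <- a %in% DNA_BASES & b %in% DNA_BASES
  n <- sum(keep)
  if (n == 0L) stop("no comparable (gap-free, unambiguous) sites")
  a <- base_codes(a[keep]); b <- base_codes(b[keep])
  diff <- a != b
  transition <- diff & (a %% 2L) == (b %% 2L)
  P <- sum(transition) / n
  Q <- sum(diff & !transition) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    cond <- structure(
      class = c("retroscape_saturation", "error", "condition"),
      list(message = sprintf(
        "K2P distance undefined (saturated): P = %.3f, Q = %.3f", P, Q),
        call = sys.call(-1)))
    stop(cond)
  }
  structure(list(P = P, Q = Q, K = -0.5 * log(w1 * sqrt(w2)),
                 sites_compared = n),
            class = "k2p_distance")
}

#' @export
print.k2p_distance <- function(x, ...) {
  cat(sprintf("K2P distance: K = %.5f (P = %.4f, Q = %.4f, %d sites)\n",
              x$K, x$P, x$Q, x$sites_compared))
  invisible(x)
}

# Expected transition/transversion proportions after evolving a site for
# K substitutions/site under K2P with transition:transversion ratio R.
# Rates: alpha (transition) + 2 beta (transversions) = 1 per unit K,
# alpha = R/(R+1), beta = 1/(2(R+1)).
k2p_expected_pq <- function(K, ts_tv_ratio = 2) {
  R <- ts_tv_ratio
  alpha <- R / (R + 1)
  beta <- 1 / (2 * (R + 1))
  P <- 0.25 + 0.25 * exp(-4 * beta * K) - 0.5 * exp(-2 * (alpha + beta) * K)
  Q <- 0.5 - 0.5 * exp(-4 * beta * K)
  c(P = P, Q = Q)
}
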