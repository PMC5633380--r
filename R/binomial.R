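# Exact binomial machinery for binned enrichment. The two-tailed p-value
# uses the minimum-likelihood construction: sum P(X = k) over every outcome
# no more probable than the observed one. Tail boundaries are located by
# bisection on the two monotone flanks of the unimodal pmf, so a single
# evaluation costs O(log S) rather than O(S); stats::binom.test (which
# enumerates) is the cross-check oracle in the test suite, never the
# implementation.

# Outcomes within this relative factor of the observed probability count as
# "as extreme" (guards against ties lost to floating-point rounding).
.REL_ERR <- 1 + 1e-07

.binom_two_tailed_scalar <- function(s, S, p0) {
  if (p0 <= 0) return(if (s == 0L) 1 else 0)
  if (p0 >= 1) return(if (s == S) 1 else 0)
  d_obs <- dbinom(s, S, p0) * .REL_ERR
  m <- floor((S + 1) * p0)  # mode of the pmf
  if (m > S) m <- S
  if (dbinom(m, S, p0) <= d_obs) return(1)
  if (s < m) {
    left <- pbinom(s, S, p0)
    # smallest b in (m, S] with dbinom(b) <= d_obs (pmf decreasing there)
    lo <- m; hi <- S
    if (dbinom(S, S, p0) > d_obs) return(min(1, left))
    while (hi - lo > 1L) {
      mid <- (lo + hi) %/% 2L
      if (dbinom(mid, S, p0) <= d_obs) hi <- mid else lo <- mid
    }
    # upper tail via lower.tail = FALSE to avoid 1 - (1 - tiny) cancellation
    return(min(1, left + pbinom(hi - 1L, S, p0, lower.tail = FALSE)))
  }
  # s > m: right tail plus the matching left tail
  right <- pbinom(s - 1L, S, p0, lower.tail = FALSE)
  if (dbinom(0L, S, p0) > d_obs) return(min(1, right))
  lo <- 0L; hi <- m  # largest a in [0, m) with dbinom(a) <= d_obs
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (dbinom(mid, S, p0) <= d_obs) lo <- mid else hi <- mid
  }
  min(1, right + pbinom(lo, S, p0))
}

#' Exact two-tailed binomial p-value (minimum-likelihood tails)
#'
#' For observed count `s` out of `S` trials at null success probability
#' `p0`, returns `sum P(X = k)` over all `k` with
#' `P(X = k) <= P(X = s)`, `X ~ Binomial(S, p0)` -- the construction used by
#' [stats::binom.test()]. Vectorized over `s`, `S`, `p0`.
#'
#' @param s Observed successes (0 <= s <= S).
#' @param S Number of trials.
#' @param p0 Null success probability.
#' @return P-values in `[0, 1]`.
#' @export
binomial_pvalue_two_tailed <- function(s, S, p0) {
  stopifnot(all(s >= 0), all(s <= S), all(p0 >= 0), all(p0 <= 1))
  n <- max(length(s), length(S), length(p0))
  s <- rep_len(as.integer(s), n)
  S <- rep_len(as.integer(S), n)
  p0 <- rep_len(p0, n)
  vapply(seq_len(n), function(i) {
    .binom_two_tailed_scalar(s[i], S[i], p0[i])
  }, numeric(1))
}

# Wilson score interval for a binomial proportion (no continuity
# correction); vectorized. Returns list(lower, upper).
.wilson_interval <- function(x, n, confidence = 0.95) {
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  list(lower = pmax(0, center - half), upper = pmin(1, center + half))
}

#' Point fold enrichment of a bin
#'
#' `((s/S) / (c/C))`, the ratio of the bin's share of sample reads to its
#' share of control reads. When the control count is zero a pseudocount
#' replaces it (and is added to `s`) so the fold stays finite while still
#' increasing in `s`; bins with counts in both samples are left untouched.
#'
#' @param s,c Bin counts in sample and control.
#' @param S,C Library totals (`S, C > 0`).
#' @param pseudocount Value used when `c == 0` (default 0.5).
#' @return Fold values, vectorized.
#' @export
fold_enrichment <- function(s, S, c, C, pseudocount = 0.5) {
  stopifnot(all(S > 0), all(C > 0))
  ifelse(c > 0,
         (s / S) / (c / C),
         ((s + pseudocount) / S) / (pseudocount / C))
}

#' Sampling-robust lower bound on the fold enrichment
#'
#' Recomputes the fold with the lower Wilson score confidence limit of the
#' sample proportion and the upper limit of the control proportion: the
#' smallest fold compatible with expected binomial stochastic variation in
#' both read counts at the given confidence. Always at most the point fold;
#' converges to it as counts grow at fixed proportions; zero when `s == 0`.
#'
#' @inheritParams fold_enrichment
#' @param confidence Two-sided confidence level of the score intervals.
#' @return Lower-bound folds, vectorized.
#' @export
robust_fold_lower <- function(s, S, c, C, confidence = 0.95) {
  stopifnot(all(S > 0), all(C > 0))
  lo <- .wilson_interval(s, S, confidence)$lower
  hi <- .wilson_interval(c, C, confidence)$upper
  lo / hi
}
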