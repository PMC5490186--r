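#' Fisher's exact test p-value for a 2x2 table
#'
#' Exact hypergeometric tail probability for the table
#' \preformatted{  | a  b |
#'   | c  d | }
#' with all margins fixed, as used by every statistical gate in the pipeline:
#' the junction background-expression filter, the variant significance gate,
#' the allele-frequency consistency check and the variant-junction
#' association test.
#'
#' `alternative = "greater"` returns \eqn{P(X \ge a)} where `X` is the
#' top-left cell under the hypergeometric null; `"two.sided"` sums the
#' probabilities of all tables no more likely than the observed one (the
#' same convention as [stats::fisher.test()]).
#'
#' @param a,b,c,d Non-negative integer cell counts, row-wise.
#' @param alternative One of `"greater"`, `"less"`, `"two.sided"`.
#' @return A single p-value in \[0, 1\].
#' @examples
#' fisher_exact_p(3, 0, 0, 3)            # 1/20
#' fisher_exact_p(10, 0, 0, 10)          # 1/choose(20, 10)
#' fisher_exact_p(3, 3, 3, 3, "two.sided")
#' @export
fisher_exact_p <- function(a, b, c, d, alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  if (any(c(a, b, c, d) < 0)) stop("cell counts must be non-negative")
  m <- a + b # row 1 total
  n <- c + d # row 2 total
  k <- a + c # column 1 total
  if (m + n == 0L) return(1)
  switch(alternative,
    greater = stats::phyper(a - 1, m, n, k, lower.tail = FALSE),
    less    = stats::phyper(a, m, n, k),
    two.sided = {
      if (k == 0L || k == m + n) return(1)
      x <- max(0L, k - n):min(k, m)
      dens <- stats::dhyper(x, m, n, k)
      sum(dens[dens <= stats::dhyper(a, m, n, k) * (1 + 1e-07)])
    }
  )
}

# vectorised over rows; used internally where many tables are tested at once
fisher_exact_p_vec <- function(a, b, c, d, alternative = "greater") {
  if (length(a) == 0L) return(numeric(0))
  mapply(fisher_exact_p, a, b, c, d, MoreArgs = list(alternative = alternative))
}

#' Benjamini-Hochberg adjustment helper
#'
#' Thin wrapper over [stats::p.adjust()] kept as a named step so the
#' multiple-testing policy of the association stage is explicit.
#' @param p Numeric vector of p-values.
#' @keywords internal
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

# alpha-gate comparison with a tiny absolute slack so tables lying exactly
# on the threshold (e.g. p = 1/20 at alpha 0.05) are not lost to floating-
# point representation of the hypergeometric tail
p_within_alpha <- function(p, alpha) p <= alpha + 1e-12
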