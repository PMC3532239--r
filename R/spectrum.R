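#' Tally the observed sense-strand substitution spectrum
#'
#' Counts qualifying single-base consequence calls by sense-strand
#' substitution type.  Qualifying categories are those that alter coding
#' sense or hit a critical splice junction: missense, nonsense, make-sense,
#' start-loss and critical splice changes.  Synonymous, non-critical splice,
#' deeper intronic and structural calls are excluded, as are calls without a
#' substitution type.
#'
#' @param calls consequence-call data.frame (or a `consequence_set`).
#' @param dataset optional dataset filter (`"phenotypic"`, `"incidental"`,
#'   ...); `NULL` keeps all.
#' @return A `spectrum_tally`: named integer vector over the 12 substitution
#'   types with a `dataset` attribute.
#' @export
tally_spectrum <- function(calls, dataset = NULL) {
  if (inherits(calls, "consequence_set")) calls <- calls$calls
  keep <- calls$category %in% .SPECTRUM_CATEGORIES & !is.na(calls$sense_sub)
  if (!is.null(dataset)) keep <- keep & calls$dataset %in% dataset
  counts <- table(factor(calls$sense_sub[keep],
                         levels = substitution_types()))
  structure(setNames(as.integer(counts), substitution_types()),
            dataset = if (is.null(dataset)) "all" else
              paste(dataset, collapse = "+"),
            class = "spectrum_tally")
}

#' @export
print.spectrum_tally <- function(x, ...) {
  cat("Sense-strand spectrum (", attr(x, "dataset"), "), total ",
      sum(x), " mutation(s)\n", sep = "")
  print(setNames(as.integer(x), names(x)))
  invisible(x)
}

#' Exact binomial tail probability
#'
#' Computes tail probabilities of the binomial distribution by direct
#' summation of the probability mass in log space -- no normal
#' approximation.  `"lower"` is `Pr[X <= k]`, `"upper"` is `Pr[X >= k]`, and
#' `"two.sided"` is twice the smaller tail, capped at 1.
#'
#' @param k observed count, `0 <= k <= n`.
#' @param n number of trials.
#' @param p success probability, in (0, 1).
#' @param tail which tail.
#' @return A probability.
#' @export
#' @examples
#' exact_binomial_tail(2, 10, 0.5)  # 56/1024
exact_binomial_tail <- function(k, n, p,
                                tail = c("lower", "upper", "two.sided")) {
  tail <- match.arg(tail)
  stopifnot(length(k) == 1L, length(n) == 1L, k >= 0, k <= n, n >= 1,
            p > 0, p < 1)
  mass <- function(j) exp(lchoose(n, j) + j * log(p) + (n - j) * log1p(-p))
  lower <- sum(mass(0:k))
  if (tail == "lower") return(min(lower, 1))
  upper <- sum(mass(k:n))
  if (tail == "upper") return(min(upper, 1))
  min(1, 2 * min(lower, upper))
}

#' Strand-asymmetry exact binomial tests
#'
#' For each complementary substitution pair, tests whether the observed
#' sense-strand counts are compatible with the opportunity-derived null.
#' Pairs are keyed by their purine-reference focal type (`A>N` or `G>N`):
#' with `k` the observed count of the focal type, `n = k + k(complement)`
#' and `p` the null probability of the focal type, the reported `P` is the
#' exact lower tail `Pr[X <= k]`, `X ~ Binomial(n, p)`.  Both tails and the
#' two-sided (doubled smaller tail) value are also returned.  Pairs with
#' `n = 0` are marked not testable (`NA`).
#'
#' @param tally a `spectrum_tally` (or named count vector over the 12
#'   types).
#' @param p null probabilities from [null_probabilities()] (named over the
#'   12 types).
#' @return A `strand_test` data.frame, one row per focal type, with columns
#'   `substitution`, `p`, `k`, `n`, `P_lower`, `P_upper`, `P_two_sided`.
#' @export
strand_asymmetry_test <- function(tally, p) {
  focal <- grep("^[AG]>", substitution_types(), value = TRUE)
  rows <- lapply(focal, function(s) {
    sc <- complement_substitution(s)
    k <- as.integer(tally[[s]])
    n <- k + as.integer(tally[[sc]])
    ps <- p[[s]]
    if (is.na(ps) || n == 0L) {
      return(data.frame(substitution = s, p = ps, k = k, n = n,
                        P_lower = NA_real_, P_upper = NA_real_,
                        P_two_sided = NA_real_, stringsAsFactors = FALSE))
    }
    data.frame(substitution = s, p = ps, k = k, n = n,
               P_lower = exact_binomial_tail(k, n, ps, "lower"),
               P_upper = exact_binomial_tail(k, n, ps, "upper"),
               P_two_sided = exact_binomial_tail(k, n, ps, "two.sided"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("strand_test", "data.frame")
  out
}

#' @export
print.strand_test <- function(x, ...) {
  cat("Strand-asymmetry exact binomial tests (lower tail of the",
      "purine-reference type)\n")
  y <- as.data.frame(x)
  y$p <- round(y$p, 4L)
  y$P_lower <- signif(y$P_lower, 3L)
  y$P_upper <- signif(y$P_upper, 3L)
  y$P_two_sided <- signif(y$P_two_sided, 3L)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Sense/antisense observation ratio for one substitution type
#'
#' The ratio of observed sense-strand counts of `s` to its complementary
#' type, reported to one decimal place.
#'
#' @param tally a `spectrum_tally` (or named count vector).
#' @param s substitution type, e.g. `"T>A"`.
#' @return Ratio rounded to one decimal; `NA` when the complementary count
#'   is zero.
#' @export
sense_antisense_ratio <- function(tally, s) {
  sc <- complement_substitution(s)
  denom <- as.numeric(tally[[sc]])
  if (denom == 0) {
    warning("zero antisense count for ", s)
    return(NA_real_)
  }
  round(as.numeric(tally[[s]]) / denom, 1L)
}
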