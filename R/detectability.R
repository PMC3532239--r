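#' Overt-null to other-allele ratio
#'
#' Renders the count of overt null alleles (frameshift, nonsense, critical
#' splice) against all other alleles of a dataset as the ratio
#' `1 : other/overt` (three significant figures) together with the overt
#' fraction of the total.
#'
#' @param overt count of overt null alleles, or a consequence-call
#'   data.frame (in which case `other` is ignored and counts are taken from
#'   the `overt_null` column).
#' @param other count of all other alleles.
#' @return A list with `overt`, `other`, `ratio` (other/overt, 3 s.f.;
#'   `NA` when there are no overt nulls), `ratio_label` (e.g. `"1 : 2.07"`)
#'   and `fraction` (overt / total).
#' @export
#' @examples
#' overt_null_ratios(59, 122)  # 1 : 2.07, 32.6%
overt_null_ratios <- function(overt, other = NULL) {
  if (is.data.frame(overt)) {
    calls <- overt
    overt <- sum(calls$overt_null, na.rm = TRUE)
    other <- nrow(calls) - overt
  }
  stopifnot(overt >= 0, other >= 0)
  total <- overt + other
  ratio <- if (overt == 0) NA_real_ else signif(other / overt, 3L)
  list(overt = as.integer(overt), other = as.integer(other),
       ratio = ratio,
       ratio_label = if (is.na(ratio)) "undefined" else
         paste("1 :", format(ratio)),
       fraction = if (total == 0) NA_real_ else overt / total)
}

#' Estimate the detectable fraction of missense mutations
#'
#' The headline inference: overt null alleles are enriched in the phenotypic
#' mutation set relative to the incidental set because the phenotypic set is
#' conditioned on causing phenotype.  Assuming phenotypically detectable
#' alleles of every class are enriched by the same factor, the enrichment
#' `E = f_p / f_i` of overt-null fractions estimates the reciprocal of the
#' detectable missense fraction: `f_d = 1 / E` (capped at 1 when the
#' "enrichment" runs the wrong way, with a warning).
#'
#' A nonparametric bootstrap (resampling mutation labels with replacement
#' within each dataset) supplies a percentile interval for `f_d`.
#'
#' @param phenotypic numeric `c(overt, total)` for the phenotypic set.
#' @param incidental numeric `c(overt, total)` for the incidental set.
#' @param bootstrap number of bootstrap replicates (0 = none).
#' @param conf confidence level for the percentile interval.
#' @param seed optional seed for the bootstrap.
#' @return A `detectability_estimate` list: the four counts, the fractions
#'   `f_p` and `f_i`, `enrichment` (E), `f_d`, and (with bootstrap) `ci`
#'   and `boot_fd`.  Unrounded values throughout; the print method shows
#'   3-significant-figure renderings alongside.
#' @export
#' @examples
#' estimate_detectability(c(59, 181), c(28, 402))
estimate_detectability <- function(phenotypic, incidental, bootstrap = 0L,
                                   conf = 0.95, seed = NULL) {
  stopifnot(length(phenotypic) == 2L, length(incidental) == 2L,
            phenotypic[2L] > 0, incidental[2L] > 0,
            phenotypic[1L] <= phenotypic[2L],
            incidental[1L] <= incidental[2L])
  f_p <- phenotypic[1L] / phenotypic[2L]
  f_i <- incidental[1L] / incidental[2L]
  if (incidental[1L] == 0) stop("incidental overt-null count is zero: ",
                                "enrichment undefined")
  E <- f_p / f_i
  capped <- E < 1
  if (capped) {
    warning("phenotypic overt fraction below incidental; f_d capped at 1")
  }
  f_d <- min(1, 1 / E)
  out <- list(phenotypic = as.integer(phenotypic),
              incidental = as.integer(incidental),
              f_p = f_p, f_i = f_i, enrichment = E, f_d = f_d,
              capped = capped, conf = conf, ci = NULL, boot_fd = NULL)
  if (bootstrap > 0L) {
    if (!is.null(seed)) set.seed(seed)
    bp <- stats::rbinom(bootstrap, phenotypic[2L], f_p) / phenotypic[2L]
    bi <- stats::rbinom(bootstrap, incidental[2L], f_i) / incidental[2L]
    fd <- ifelse(bi > 0 & bp > 0, pmin(1, bi / bp), NA_real_)
    a <- (1 - conf) / 2
    out$ci <- unname(stats::quantile(fd, c(a, 1 - a), na.rm = TRUE))
    out$boot_fd <- fd
  }
  class(out) <- "detectability_estimate"
  out
}

#' @export
print.detectability_estimate <- function(x, ...) {
  cat("Detectable-missense-fraction estimate from overt-null enrichment\n")
  cat(sprintf("  phenotypic: %d overt / %d total  (%.4f; %s)\n",
              x$phenotypic[1L], x$phenotypic[2L], x$f_p,
              paste0(signif(100 * x$f_p, 3), "%")))
  cat(sprintf("  incidental: %d overt / %d total  (%.4f; %s)\n",
              x$incidental[1L], x$incidental[2L], x$f_i,
              paste0(signif(100 * x$f_i, 3), "%")))
  cat(sprintf("  enrichment E = %.4f  (3 s.f.: %s)\n",
              x$enrichment, format(signif(x$enrichment, 3))))
  cat(sprintf("  detectable missense fraction f_d = %.4f  (%s%%)\n",
              x$f_d, format(signif(100 * x$f_d, 3))))
  if (!is.null(x$ci)) {
    cat(sprintf("  %d%% bootstrap interval: [%.4f, %.4f]\n",
                round(100 * x$conf), x$ci[1L], x$ci[2L]))
  }
  invisible(x)
}

#' @export
confint.detectability_estimate <- function(object, parm, level = 0.95, ...) {
  if (is.null(object$ci)) stop("no bootstrap interval: rerun with bootstrap > 0")
  m <- matrix(object$ci, nrow = 1L,
              dimnames = list("f_d", paste0(100 * c((1 - object$conf) / 2,
                                                    1 - (1 - object$conf) / 2),
                                            " %")))
  m
}

#' Summarise damage scores of a mutation set
#'
#' Damage scores (PolyPhen-2-style, in \[0, 1\]) are consumed as input data.
#' Reports the scored/unscored split, the mean score, and the count at or
#' above the damaging threshold with two fractions: over the full set
#' (scored + unscored, the convention of per-set percentages in screening
#' reports) and over scored entries only.
#'
#' @param scores numeric vector of scores, `NA` = unscored.
#' @param threshold damaging cutoff (default 0.95, the usual
#'   "probably damaging" lower bound).
#' @return A list with `n_total`, `n_scored`, `n_unscored`, `mean_score`,
#'   `n_damaging`, `fraction_of_total`, `fraction_of_scored`.
#' @export
summarize_scores <- function(scores, threshold = 0.95) {
  scores <- as.numeric(scores)
  if (any(!is.na(scores) & (scores < 0 | scores > 1))) {
    stop("scores must lie in [0, 1]")
  }
  n_total <- length(scores)
  scored <- scores[!is.na(scores)]
  n_damaging <- sum(scored >= threshold)
  list(n_total = n_total,
       n_scored = length(scored),
       n_unscored = n_total - length(scored),
       mean_score = if (length(scored)) mean(scored) else NA_real_,
       n_damaging = as.integer(n_damaging),
       fraction_of_total = if (n_total) n_damaging / n_total else NA_real_,
       fraction_of_scored = if (length(scored)) n_damaging / length(scored)
         else NA_real_)
}

#' Specificity bound for a damage classifier
#'
#' If a fraction `f_d` of the mutations with assignable scores is truly
#' capable of causing phenotype, the expected number of damaging mutations is
#' `f_d * n_assignable`, and the specificity of a classifier that labels
#' `n_called_damaging` of them as damaging is at most
#' `expected / n_called_damaging`.  Both the floor and the
#' round-half-to-even rendering of the expectation are reported (counts are
#' integers; the floor variant is the headline value), and specificity is
#' capped at 1 with a warning when the call count falls below the
#' expectation.
#'
#' @param f_d detectable fraction.
#' @param n_assignable mutations with assignable scores.
#' @param n_called_damaging mutations the classifier labels damaging.
#' @return A list with `expected` (floor), `expected_round`,
#'   `specificity` and `specificity_round`.
#' @export
#' @examples
#' specificity_bound(0.213, 317, 125)  # expected 67, ~54% specific
specificity_bound <- function(f_d, n_assignable, n_called_damaging) {
  stopifnot(f_d >= 0, f_d <= 1, n_assignable >= 0, n_called_damaging > 0)
  raw <- f_d * n_assignable
  exp_floor <- floor(raw)
  exp_round <- round(raw)
  spec <- exp_floor / n_called_damaging
  spec_round <- exp_round / n_called_damaging
  if (spec > 1 || spec_round > 1) {
    warning("expected damaging exceeds calls; specificity capped at 1")
    spec <- min(spec, 1)
    spec_round <- min(spec_round, 1)
  }
  list(expected = as.integer(exp_floor),
       expected_round = as.integer(exp_round),
       specificity = spec,
       specificity_round = spec_round)
}
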