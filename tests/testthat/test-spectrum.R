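.calls_df <- function(category, sense_sub, dataset = "phenotypic") {
  data.frame(id = paste0("m", seq_along(category)), gene = "g",
             transcript = "t", category = category, sense_sub = sense_sub,
             codon_from = NA, codon_to = NA, aa_from = NA, aa_to = NA,
             aa_pos = NA, splice_distance = NA, splice_side = NA,
             overt_null = category %in% c("frameshift", "nonsense",
                                          "critical_splice_donor",
                                          "critical_splice_acceptor"),
             dataset = dataset, score = NA_real_, stringsAsFactors = FALSE)
}

test_that("spectrum tallies count qualifying sense-strand changes only", {
  calls <- .calls_df(
    c("missense", "nonsense", "critical_splice_donor", "synonymous",
      "noncritical_splice_donor", "frameshift"),
    c("A>T", "T>A", "T>A", "A>G", "G>A", NA))
  tal <- tally_spectrum(calls)
  expect_equal(tal[["A>T"]], 1L)
  expect_equal(tal[["T>A"]], 2L)
  expect_equal(sum(tal), 3L)  # synonymous, non-critical and indel excluded
  # dataset filter
  calls$dataset <- c("phenotypic", "incidental", "phenotypic", "phenotypic",
                     "phenotypic", "phenotypic")
  expect_equal(sum(tally_spectrum(calls, "phenotypic")), 2L)
})

test_that("a minus-strand missense tallies under its sense type", {
  toy <- toy_plus()
  mir <- mirror_toy(toy$genome, toy$models)
  # sense K2I change (A>T at sense position 5) seen genomically as T>A
  mut <- mirror_mutation(list(id = "m", contig = "chrT", pos = 5, ref = "A",
                              alt = "T"), toy$genome)
  mut$dataset <- "phenotypic"
  out <- classify_batch(as.data.frame(mut, stringsAsFactors = FALSE),
                        mir$models, mir$genome)
  tal <- tally_spectrum(out)
  expect_equal(tal[["A>T"]], 1L)
  expect_equal(sum(tal), 1L)
})

test_that("exact binomial tails agree with direct summation cases", {
  expect_equal(exact_binomial_tail(2, 10, 0.5), 56 / 1024)
  expect_equal(exact_binomial_tail(10, 10, 0.5), 1)
  expect_equal(exact_binomial_tail(0, 10, 0.5, tail = "upper"), 1)
})

test_that("exact binomial tails match the reference implementation for n <= 30", {
  set.seed(1)
  for (i in 1:200) {
    n <- sample(1:30, 1)
    k <- sample(0:n, 1)
    p <- runif(1, 0.05, 0.95)
    expect_equal(exact_binomial_tail(k, n, p), pbinom(k, n, p),
                 tolerance = 1e-12)
    expect_equal(exact_binomial_tail(k, n, p, "upper"),
                 pbinom(k - 1, n, p, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("the lower tail is monotone in k and mirrors under complementation", {
  n <- 40; p <- 0.547
  tails <- vapply(0:n, exact_binomial_tail, 0, n = n, p = p)
  expect_true(all(diff(tails) >= 0))
  for (k in c(0, 7, 20, 33, 40)) {
    lower <- exact_binomial_tail(k, n, p)
    upper <- exact_binomial_tail(k, n, p, "upper")
    # complementing the focal type swaps the tails
    expect_equal(exact_binomial_tail(n - k, n, 1 - p), upper,
                 tolerance = 1e-12)
    # the two tails overlap in exactly the point mass at k
    expect_equal(lower + upper, 1 + dbinom(k, n, p), tolerance = 1e-12)
  }
})

test_that("strand tests on the packaged counts reproduce printed tail values", {
  fx <- load_paper_fixtures()
  p <- null_probabilities(fx$table7)
  tal_p <- setNames(fx$table5$k_phenotypic, fx$table5$substitution)
  st <- strand_asymmetry_test(tal_p, p)
  expect_equal(signif(st$P_lower[st$substitution == "A>T"], 3), 0.00397)
  expect_equal(signif(st$P_lower[st$substitution == "A>G"], 2), 0.00071)
  expect_equal(signif(st$P_lower[st$substitution == "A>C"], 3), 0.0631)
  # the published 0.1202 and 0.6600 were evidently computed with the
  # 4-decimal rounded p column; unrounded p agrees to 3 significant figures
  expect_equal(signif(st$P_lower[st$substitution == "G>A"], 3), 0.120)
  expect_equal(signif(st$P_lower[st$substitution == "G>T"], 3), 0.660)
  # G>C has no observations in the phenotypic set: not testable
  expect_true(is.na(st$P_lower[st$substitution == "G>C"]))
  expect_equal(st$n[st$substitution == "G>C"], 0L)
})

test_that("sense/antisense ratios render to one decimal", {
  fx <- load_paper_fixtures()
  tal <- setNames(fx$table5$k_combined, fx$table5$substitution)
  expect_equal(sense_antisense_ratio(tal, "T>A"), 1.7)  # 103 / 62
  expect_equal(sense_antisense_ratio(c("A>T" = 5, "T>A" = 5), "A>T"), 1.0)
  expect_equal(sense_antisense_ratio(c("A>T" = 0, "T>A" = 5), "A>T"), 0.0)
  expect_warning(r <- sense_antisense_ratio(c("A>T" = 5, "T>A" = 0), "A>T"),
                 "zero")
  expect_true(is.na(r))
})

test_that("182 coding-change types are enumerable from the standard code", {
  types <- enumerate_aa_change_types()
  expect_equal(types$total, 182L)
  expect_equal(unname(types$counts),
               c(150L, 10L, 10L, 6L, 6L))
  expect_true("W>*" %in% types$classes$nonsense)  # TGG>TGA or TGG>TAG
  expect_setequal(sub("^Mstart>", "", types$classes$start_loss),
                  c("I", "L", "V", "K", "T", "R"))
})

test_that("type enumeration is robust to degenerate and reordered codes", {
  expect_equal(enumerate_aa_change_types(c(TTT = "F"))$total, 0L)
  code <- Biostrings::GENETIC_CODE
  set.seed(2)
  shuffled <- code[sample(length(code))]
  expect_equal(enumerate_aa_change_types(shuffled)$total, 182L)
  expect_error(enumerate_aa_change_types(c(XYZ = "F")), "malformed")
})

test_that("amino-acid spectrum comparison agrees with the hypergeometric oracle", {
  # 10 of 100 phenotypic vs 1 of 100 incidental
  mp <- as_aa_change_matrix(c("S>P", "T>I"), c(10L, 90L), "phenotypic")
  mi <- as_aa_change_matrix(c("S>P", "T>I"), c(1L, 99L), "incidental")
  cmp <- compare_aa_spectra(mp, mi)
  row <- cmp[cmp$type == "S>P", ]
  expect_equal(row$p_value, oracle_fisher2x2(10, 90, 1, 99),
               tolerance = 1e-9)
  expect_equal(row$direction, "phenotypic")
  expect_true(row$significant)
  # identical matrices: everything on the diagonal, nothing significant
  same <- compare_aa_spectra(mp, structure(mp, dataset = "incidental"))
  expect_true(all(same$freq_phenotypic == same$freq_incidental))
  expect_true(all(!same$significant))
  expect_true(all(same$direction == "none"))
})

test_that("published deleterious substitution types flag as phenotypic-enriched", {
  # qualitative structure of the observed sets: S>P, L>P, I>N, C>R, Y>D
  # heavily overrepresented among phenotypic changes
  phen <- as_aa_change_matrix(
    c("S>P", "L>P", "I>N", "C>R", "Y>D", "T>I", "V>A"),
    c(16L, 15L, 9L, 9L, 7L, 2L, 2L), "phenotypic")
  inc <- as_aa_change_matrix(
    c("S>P", "L>P", "I>N", "C>R", "Y>D", "T>I", "T>A", "V>A", "E>G"),
    c(4L, 5L, 2L, 2L, 1L, 90L, 80L, 85L, 80L), "incidental")
  cmp <- compare_aa_spectra(phen, inc)
  for (ty in c("S>P", "L>P", "I>N", "C>R", "Y>D")) {
    row <- cmp[cmp$type == ty, ]
    expect_equal(row$direction, "phenotypic")
    expect_true(row$significant)
  }
})
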