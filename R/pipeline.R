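.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full spectrum-analysis pipeline
#'
#' Orchestrates the stages in order: classify mutations, tally the
#' sense-strand spectra per dataset, obtain opportunity counts (enumerated
#' from the transcript set or taken from the packaged genome-wide table),
#' run the strand-asymmetry tests, compare the amino-acid change spectra of
#' the phenotypic and incidental sets, and estimate the detectable missense
#' fraction.  Any stage error aborts with the stage name in the message.
#'
#' @param genome an `enu_genome` or path to a FASTA file.
#' @param transcripts a named list of `transcript_model`s or a path to a
#'   GFF3 / transcript TSV; reduced to one transcript per gene.
#' @param mutations a mutation record data.frame or path to a mutation
#'   TSV.
#' @param window non-critical splice window (bp).
#' @param use_packaged_opportunities use the packaged genome-wide
#'   opportunity counts instead of enumerating the supplied transcript set
#'   (appropriate when the observed mutations come from a full-genome
#'   screen but only a reduced annotation is at hand).
#' @param bootstrap bootstrap replicates for the detectability interval.
#' @param seed seed for the bootstrap.
#' @param out_dir if non-`NULL`, TSV/JSON artifacts are written there.
#' @return An `enu_report` list: `calls` (a `consequence_set`),
#'   `tallies`, `opportunities`, `null_p`, `strand_tests` (per dataset and
#'   combined), `aa_comparison` (or `NULL` if either set has no coding
#'   changes), `detectability` (or `NULL` without both datasets),
#'   `provenance`.
#' @export
run_pipeline <- function(genome, transcripts, mutations, window = 10L,
                         use_packaged_opportunities = FALSE,
                         bootstrap = 1000L, seed = 1L, out_dir = NULL) {
  prov <- list(package = "enuspectra",
               version = as.character(utils::packageVersion("enuspectra")),
               seed = seed, window = window,
               inputs = list())
  if (is.character(genome)) {
    prov$inputs$genome <- c(path = genome, md5 = unname(tools::md5sum(genome)))
    genome <- .stage("load_genome", load_genome(genome))
  }
  if (is.character(transcripts)) {
    prov$inputs$transcripts <- c(path = transcripts,
                                 md5 = unname(tools::md5sum(transcripts)))
    transcripts <- .stage("load_transcripts",
                          load_transcripts(transcripts, genome))
  }
  if (is.character(mutations)) {
    if (!file.exists(mutations)) {
      stop("pipeline stage 'classify' failed: mutation file not found: ",
           mutations, call. = FALSE)
    }
    prov$inputs$mutations <- c(path = mutations,
                               md5 = unname(tools::md5sum(mutations)))
    mutations <- .stage("classify", read_mutation_table(mutations, genome))
  }
  models <- .stage("classify", select_longest_cds(transcripts))
  calls <- .stage("classify",
                  classify_batch(mutations, models, genome, window = window))

  tallies <- .stage("tally", list(
    phenotypic = tally_spectrum(calls, "phenotypic"),
    incidental = tally_spectrum(calls, "incidental"),
    combined = tally_spectrum(calls, c("phenotypic", "incidental"))))

  opp <- .stage("opportunities", {
    if (use_packaged_opportunities) load_paper_fixtures()$table7
    else enumerate_opportunities(models, genome)
  })
  null_p <- .stage("opportunities", null_probabilities(opp))

  strand <- .stage("strand_tests",
                   lapply(tallies, strand_asymmetry_test, p = null_p))

  aa_cmp <- .stage("aa_comparison", {
    mp <- aa_change_matrix(calls, "phenotypic")
    mi <- aa_change_matrix(calls, "incidental")
    if (nrow(mp) && nrow(mi)) compare_aa_spectra(mp, mi) else NULL
  })

  detect <- .stage("detectability", {
    cp <- calls$calls[calls$calls$dataset == "phenotypic", ]
    ci <- calls$calls[calls$calls$dataset == "incidental", ]
    if (nrow(cp) && nrow(ci) && sum(ci$overt_null) > 0) {
      estimate_detectability(c(sum(cp$overt_null), nrow(cp)),
                             c(sum(ci$overt_null), nrow(ci)),
                             bootstrap = bootstrap, seed = seed)
    } else NULL
  })

  report <- structure(list(calls = calls, tallies = tallies,
                           opportunities = opp, null_p = null_p,
                           strand_tests = strand, aa_comparison = aa_cmp,
                           detectability = detect, provenance = prov),
                      class = "enu_report")
  if (!is.null(out_dir)) .write_report(report, out_dir)
  report
}

.write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report$calls$calls, file.path(out_dir, "calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(report$opportunities),
                     file.path(out_dir, "opportunities.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (ds in names(report$strand_tests)) {
    utils::write.table(as.data.frame(report$strand_tests[[ds]]),
                       file.path(out_dir, paste0("strand_", ds, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$aa_comparison)) {
    utils::write.table(as.data.frame(report$aa_comparison),
                       file.path(out_dir, "aa_comparison.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  payload <- list(provenance = report$provenance)
  if (!is.null(report$detectability)) {
    d <- report$detectability
    payload$detectability <- list(
      phenotypic = d$phenotypic, incidental = d$incidental,
      f_p = d$f_p, f_i = d$f_i, enrichment = d$enrichment, f_d = d$f_d,
      ci = d$ci)
  }
  jsonlite::write_json(payload, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' @export
print.enu_report <- function(x, ...) {
  cat("== ENU spectrum report ==\n\n")
  print(x$calls)
  cat("\n")
  print(x$opportunities)
  cat("\nStrand-asymmetry tests (combined):\n")
  print(x$strand_tests$combined)
  if (!is.null(x$detectability)) {
    cat("\n")
    print(x$detectability)
  }
  invisible(x)
}
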