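#' Configuration for in-silico ENU mutagenesis
#'
#' Bundles the parameters of the mutagenesis and screening model.  Defaults
#' reflect the study conditions: each G1 animal carries on the order of 30
#' coding-change mutations (from a genomic load of ~3000 at roughly one
#' mutation per Mbp), substitution-type weights proportional to the combined
#' observed sense-strand spectrum, overt null alleles always detectable,
#' missense detectable with probability 0.213, about 12 screened G3 mice per
#' pedigree (100,000 G3 over 8,000 pedigrees), and a 1/8 chance that a given
#' G1 mutation is homozygous in a given G3 under the backcross scheme
#' (daughter carries it w.p. 1/2, G3 homozygous w.p. 1/4 given that); the
#' intercross scheme halves this to 1/16.
#'
#' @param seed random seed (mandatory: simulations are reproducible).
#' @param coding_mutations_per_g1 Poisson mean of coding-region mutation
#'   events per G1 genome.
#' @param weights named numeric over the 12 sense-strand substitution
#'   types; normalised internally.  Default: the combined phenotypic +
#'   incidental spectrum counts of the packaged tables.
#' @param detect named detection probabilities per consequence class:
#'   `overt_null`, `missense` (also applied to start-loss), `make_sense`,
#'   `noncritical_splice`, `synonymous`.
#' @param pedigrees number of G1 pedigrees screened.
#' @param g3_per_pedigree effective number of screened G3 mice per
#'   pedigree.
#' @param scheme breeding scheme, `"backcross"` (P(hom) = 1/8) or
#'   `"intercross"` (1/16); `p_homozygous` overrides either.
#' @param p_homozygous probability a given G3 is homozygous for a given G1
#'   mutation.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed,
                       coding_mutations_per_g1 = 30,
                       weights = NULL,
                       detect = c(overt_null = 1.0, missense = 0.213,
                                  make_sense = 0.213,
                                  noncritical_splice = 0, synonymous = 0),
                       pedigrees = 50L,
                       g3_per_pedigree = 12L,
                       scheme = c("backcross", "intercross"),
                       p_homozygous = NULL) {
  scheme <- match.arg(scheme)
  if (is.null(weights)) {
    t5 <- load_paper_fixtures()$table5
    weights <- setNames(t5$k_combined, t5$substitution)
  }
  types <- substitution_types()
  stopifnot(setequal(names(weights), types))
  weights <- weights[types]
  if (any(weights < 0)) stop("weights must be non-negative")
  if (sum(weights) <= 0) stop("weights must not all be zero")
  weights <- weights / sum(weights)
  if (is.null(p_homozygous)) {
    p_homozygous <- if (scheme == "backcross") 1 / 8 else 1 / 16
  }
  stopifnot(all(detect >= 0 & detect <= 1), p_homozygous >= 0,
            p_homozygous <= 1, coding_mutations_per_g1 >= 0,
            pedigrees >= 0, g3_per_pedigree >= 0)
  structure(list(seed = as.integer(seed),
                 coding_mutations_per_g1 = coding_mutations_per_g1,
                 weights = weights, detect = detect,
                 pedigrees = as.integer(pedigrees),
                 g3_per_pedigree = as.integer(g3_per_pedigree),
                 scheme = scheme, p_homozygous = p_homozygous),
            class = "sim_config")
}

# per-category detection probability under a config
.detect_prob <- function(category, detect) {
  unname(ifelse(category %in% .OVERT_NULL_CATEGORIES, detect[["overt_null"]],
         ifelse(category %in% c("missense", "start_loss"),
                detect[["missense"]],
         ifelse(category == "make_sense", detect[["make_sense"]],
         ifelse(category %in% c("noncritical_splice_donor",
                                "noncritical_splice_acceptor"),
                detect[["noncritical_splice"]],
         ifelse(category == "synonymous", detect[["synonymous"]], 0))))))
}

#' Simulate coding mutations of G1 genomes
#'
#' Draws ENU-induced coding-region mutation events for a set of G1 animals.
#' Each event first draws a sense-strand substitution type from the
#' configured weights and then a position uniformly among the sites of the
#' transcript set whose sense-strand base matches (CDS positions plus
#' critical splice-junction bases), applying the weights per gene
#' orientation; the aggregate simulated spectrum therefore converges to the
#' weights.  Each event is classified, flagged as phenotype-causing with the
#' per-class detection probability, marked as exposed (rendered homozygous
#' in at least one screened G3) with probability
#' `1 - (1 - p_homozygous)^g3_per_pedigree`, and assigned to the phenotypic
#' set when flagged and exposed, to the incidental set otherwise.
#'
#' @param config a `sim_config` (its `seed` is set before drawing).
#' @param models named list of `transcript_model`s, one per gene.
#' @param genome an `enu_genome`.
#' @param n_g1 number of G1 genomes (defaults to `config$pedigrees`).
#' @return A data.frame with one row per simulated mutation: `g1`, `gene`,
#'   `contig`, `pos`, `ref`, `alt` (genomic alleles), `sense_sub`,
#'   `category`, `detectable`, `exposed`, `dataset`.
#' @export
simulate_g1_genomes <- function(config, models, genome,
                                n_g1 = config$pedigrees) {
  stopifnot(inherits(config, "sim_config"))
  if (length(models) == 0L) stop("empty transcript set")
  set.seed(config$seed)
  sites <- .site_consequences(models, genome)
  .simulate_mutations(config, sites, n_g1)
}

# internal sampler over a precomputed site table
.simulate_mutations <- function(config, sites, n_g1) {
  n_mut <- stats::rpois(n_g1, config$coding_mutations_per_g1)
  total <- sum(n_mut)
  if (total == 0L) {
    return(data.frame(g1 = integer(0), gene = character(0),
                      contig = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      sense_sub = character(0), category = character(0),
                      detectable = logical(0), exposed = logical(0),
                      dataset = character(0), stringsAsFactors = FALSE))
  }
  types <- substitution_types()
  site_sub <- .sub_type(sites$sense_from, sites$sense_to)
  rows_of <- split(seq_len(nrow(sites)), factor(site_sub, levels = types))
  avail <- vapply(rows_of, length, 0L) > 0L
  w <- config$weights
  if (any(!avail & w > 0)) {
    warning("no eligible sites for: ",
            paste(types[!avail & w > 0], collapse = ", "),
            "; their weight is redistributed")
    w[!avail] <- 0
    w <- w / sum(w)
  }
  drawn_type <- sample(types, total, replace = TRUE, prob = w)
  idx <- integer(total)
  for (ty in unique(drawn_type)) {
    sel <- drawn_type == ty
    pool <- rows_of[[ty]]
    idx[sel] <- pool[sample.int(length(pool), sum(sel), replace = TRUE)]
  }
  picked <- sites[idx, ]
  minus <- picked$strand == "-"
  p_detect <- .detect_prob(picked$category, config$detect)
  p_expose <- 1 - (1 - config$p_homozygous)^config$g3_per_pedigree
  detectable <- stats::runif(total) < p_detect
  exposed <- stats::runif(total) < p_expose
  data.frame(
    g1 = rep.int(seq_len(n_g1), n_mut),
    gene = picked$gene, contig = picked$contig, pos = picked$pos,
    ref = ifelse(minus, .complement_bases(picked$sense_from),
                 picked$sense_from),
    alt = ifelse(minus, .complement_bases(picked$sense_to),
                 picked$sense_to),
    sense_sub = .sub_type(picked$sense_from, picked$sense_to),
    category = picked$category,
    detectable = detectable, exposed = exposed,
    dataset = ifelse(detectable & exposed, "phenotypic", "incidental"),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Estimate screen saturation by simulation
#'
#' Saturation is the fraction of genes carrying at least one
#' phenotype-detectable mutation rendered homozygous in at least one
#' screened G3 of the simulated population.  Repeated simulation gives a
#' Monte-Carlo mean and interval.
#'
#' @param config a `sim_config`.
#' @param models,genome transcript set and genome.
#' @param replicates Monte-Carlo replicates.
#' @return A `saturation_estimate` list with `mean`, `sd`, `interval`
#'   (2.5/97.5 percentiles), `per_replicate` and `per_gene` (per-gene hit
#'   frequency across replicates).
#' @export
saturation_estimate <- function(config, models, genome, replicates = 20L) {
  stopifnot(inherits(config, "sim_config"))
  if (length(models) == 0L) stop("empty transcript set")
  set.seed(config$seed)
  sites <- .site_consequences(models, genome)
  genes <- vapply(models, `[[`, "", "gene")
  hits <- matrix(FALSE, nrow = replicates, ncol = length(genes),
                 dimnames = list(NULL, genes))
  for (r in seq_len(replicates)) {
    sim <- .simulate_mutations(config, sites, config$pedigrees)
    hit_genes <- unique(sim$gene[sim$detectable & sim$exposed])
    hits[r, hit_genes] <- TRUE
  }
  sat <- rowMeans(hits)
  structure(list(mean = mean(sat),
                 sd = stats::sd(sat),
                 interval = unname(stats::quantile(sat, c(0.025, 0.975))),
                 per_replicate = sat,
                 per_gene = colMeans(hits)),
            class = "saturation_estimate")
}

#' @export
print.saturation_estimate <- function(x, ...) {
  cat(sprintf("Simulated screen saturation: %.3f (sd %.3f, MC interval %.3f-%.3f, %d replicates)\n",
              x$mean, x$sd, x$interval[1L], x$interval[2L],
              length(x$per_replicate)))
  invisible(x)
}

#' Generate phenotypic/incidental counts under a known detectable fraction
#'
#' Draws one synthetic experiment under the equal-enrichment model the
#' overt-null inference rests on: detectable alleles of every class are
#' enriched in the phenotypic set by the same factor, so the phenotypic
#' overt-null fraction is `f_i / f_d` where `f_i` is the incidental
#' (spectrum-level) overt-null fraction.  Mutations are i.i.d. labelled
#' overt/other within each set.
#'
#' @param true_fd true detectable missense fraction, in (0, 1].
#' @param n_phenotypic,n_incidental set sizes.
#' @param incidental_overt_fraction overt-null fraction of the incidental
#'   set (default the observed 28/402).
#' @return A list of `phenotypic` and `incidental` `c(overt, total)`
#'   count pairs.
#' @export
simulate_detectability_counts <- function(true_fd, n_phenotypic,
                                          n_incidental,
                                          incidental_overt_fraction = 28 / 402) {
  stopifnot(true_fd >= 0, true_fd <= 1)
  f_p <- if (true_fd <= 0) 1 else min(1, incidental_overt_fraction / true_fd)
  list(phenotypic = c(stats::rbinom(1L, n_phenotypic, f_p), n_phenotypic),
       incidental = c(stats::rbinom(1L, n_incidental,
                                    incidental_overt_fraction),
                      n_incidental))
}

#' Parameter-recovery report for the detectability estimator
#'
#' Repeatedly generates synthetic phenotypic/incidental mutation sets with a
#' known detectable missense fraction
#' (see [simulate_detectability_counts()]), runs
#' [estimate_detectability()] on each, and reports the mean estimate, bias,
#' and the coverage of the bootstrap interval.
#'
#' @param true_fd true detectable fraction.
#' @param n_mutations total mutations per replicate experiment.
#' @param phenotypic_share fraction of mutations in the phenotypic set
#'   (default the observed 181/583).
#' @param incidental_overt_fraction see
#'   [simulate_detectability_counts()].
#' @param replicates number of replicate experiments.
#' @param bootstrap bootstrap resamples per replicate (0 disables coverage).
#' @param conf interval level.
#' @param seed random seed.
#' @return A `recovery_report` list with `true_fd`, `mean_estimate`,
#'   `bias`, `sd`, `coverage` (or `NA`), and `estimates`.
#' @export
recover_detectability <- function(true_fd, n_mutations = 20000L,
                                  phenotypic_share = 181 / 583,
                                  incidental_overt_fraction = 28 / 402,
                                  replicates = 200L, bootstrap = 1000L,
                                  conf = 0.95, seed) {
  set.seed(seed)
  n_p <- max(1L, round(phenotypic_share * n_mutations))
  n_i <- max(1L, n_mutations - n_p)
  est <- numeric(replicates)
  covered <- logical(replicates)
  for (r in seq_len(replicates)) {
    cts <- simulate_detectability_counts(true_fd, n_p, n_i,
                                         incidental_overt_fraction)
    if (cts$incidental[1L] == 0L || cts$phenotypic[1L] == 0L) {
      est[r] <- NA_real_
      covered[r] <- NA
      next
    }
    e <- suppressWarnings(
      estimate_detectability(cts$phenotypic, cts$incidental,
                             bootstrap = bootstrap, conf = conf))
    est[r] <- e$f_d
    covered[r] <- if (bootstrap > 0L) {
      true_fd >= e$ci[1L] && true_fd <= e$ci[2L]
    } else NA
  }
  structure(list(true_fd = true_fd,
                 mean_estimate = mean(est, na.rm = TRUE),
                 bias = mean(est, na.rm = TRUE) - true_fd,
                 sd = stats::sd(est, na.rm = TRUE),
                 coverage = if (bootstrap > 0L) mean(covered, na.rm = TRUE)
                   else NA_real_,
                 estimates = est),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Detectability recovery: truth %.3f, mean estimate %.4f (bias %+.4f, sd %.4f)\n",
              x$true_fd, x$mean_estimate, x$bias, x$sd))
  if (!is.na(x$coverage)) {
    cat(sprintf("  bootstrap interval coverage: %.1f%% over %d replicates\n",
                100 * x$coverage, length(x$estimates)))
  }
  invisible(x)
}
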