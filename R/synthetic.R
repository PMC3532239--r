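# Toy data generators.  The toy transcriptome emulates the structural
# features the classifier and enumerator depend on -- multi-exon genes on
# both strands, GT..AG introns, complete ORFs -- and nothing else (no UTRs,
# no repeats, no realistic chromosome structure).

.STOP_CODONS <- c("TAA", "TAG", "TGA")

.random_bases <- function(n, gc = 0.5) {
  sample(.BASES, n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

.random_codons <- function(n, gc = 0.5) {
  out <- character(n)
  i <- 1L
  while (i <= n) {
    cd <- paste(.random_bases(3L, gc), collapse = "")
    if (!cd %in% .STOP_CODONS) {
      out[i] <- cd
      i <- i + 1L
    }
  }
  out
}

#' Generate a toy transcriptome
#'
#' Builds a deterministic (seeded) toy genome with `n_genes` complete coding
#' genes laid head-to-tail on one contig, separated by random spacer.  Each
#' gene has a start codon, in-frame stop, `GT`..`AG` intron dinucleotides,
#' and is placed on the minus strand with probability `p_minus`.  Exons and
#' CDS coincide (no UTRs).  Generated models pass validation as complete.
#'
#' @param n_genes number of genes.
#' @param exons_per_gene integer range `c(min, max)` of exon counts.
#' @param codons_per_gene range of codon counts (including start and stop).
#' @param intron_length range of intron lengths; the minimum is 20 bp so
#'   the critical (1-2) and non-critical (3-10) windows of the two intron
#'   ends never collide.
#' @param p_minus probability a gene goes on the minus strand.
#' @param gc GC content of coding and spacer sequence.
#' @param spacer bases between genes (and before the first / after the
#'   last).
#' @param seed random seed (required: generation is deterministic).
#' @param dir if non-`NULL`, FASTA and GFF3 files are written there.
#' @return A list with `genome` (`enu_genome`), `models` (named list of
#'   validated `transcript_model`s) and, when `dir` is given, `fasta` and
#'   `gff3` paths.
#' @export
make_toy_transcriptome <- function(n_genes = 5L,
                                   exons_per_gene = c(1L, 3L),
                                   codons_per_gene = c(20L, 60L),
                                   intron_length = c(20L, 60L),
                                   p_minus = 0.5, gc = 0.5,
                                   spacer = 30L, seed, dir = NULL) {
  stopifnot(n_genes >= 1L, intron_length[1L] >= 20L,
            codons_per_gene[1L] >= 4L)
  set.seed(seed)
  contig <- "chr1"
  pieces <- character(0)
  offset <- 0L
  models <- list()

  for (g in seq_len(n_genes)) {
    sp <- paste(.random_bases(spacer, gc), collapse = "")
    pieces <- c(pieces, sp)
    offset <- offset + nchar(sp)

    n_cod <- sample(seq(codons_per_gene[1L], codons_per_gene[2L]), 1L)
    coding <- paste0("ATG",
                     paste(.random_codons(n_cod - 2L, gc), collapse = ""),
                     sample(.STOP_CODONS, 1L))
    L <- nchar(coding)
    n_ex <- sample(seq(exons_per_gene[1L], exons_per_gene[2L]), 1L)
    n_ex <- min(n_ex, L %/% 6L)  # every exon at least ~6 bp
    n_ex <- max(n_ex, 1L)
    cuts <- if (n_ex > 1L) {
      sort(sample(seq(6L, L - 6L), n_ex - 1L))
    } else integer(0)
    ex_start_s <- c(1L, cuts + 1L)
    ex_end_s <- c(cuts, L)

    introns <- if (n_ex > 1L) {
      vapply(seq_len(n_ex - 1L), function(i) {
        len <- sample(seq(intron_length[1L], intron_length[2L]), 1L)
        paste0("GT", paste(.random_bases(len - 4L, gc), collapse = ""), "AG")
      }, character(1))
    } else character(0)

    # assemble the gene in sense orientation and track exon sense coords
    gene_seq <- ""
    sense_exons <- matrix(0L, nrow = n_ex, ncol = 2L)
    at <- 0L
    for (i in seq_len(n_ex)) {
      ex_seq <- substr(coding, ex_start_s[i], ex_end_s[i])
      sense_exons[i, ] <- c(at + 1L, at + nchar(ex_seq))
      gene_seq <- paste0(gene_seq, ex_seq)
      at <- at + nchar(ex_seq)
      if (i < n_ex) {
        gene_seq <- paste0(gene_seq, introns[i])
        at <- at + nchar(introns[i])
      }
    }

    strand <- if (stats::runif(1L) < p_minus) "-" else "+"
    Lg <- nchar(gene_seq)
    if (strand == "+") {
      genomic_seq <- gene_seq
      ex_g <- cbind(offset + sense_exons[, 1L], offset + sense_exons[, 2L])
    } else {
      genomic_seq <- .revcomp(gene_seq)
      ex_g <- cbind(offset + Lg - sense_exons[, 2L] + 1L,
                    offset + Lg - sense_exons[, 1L] + 1L)
      ex_g <- ex_g[order(ex_g[, 1L]), , drop = FALSE]
    }
    pieces <- c(pieces, genomic_seq)
    offset <- offset + Lg

    gid <- sprintf("gene%02d", g)
    models[[paste0(gid, ".t1")]] <- transcript_model(
      gene = gid, transcript = paste0(gid, ".t1"), contig = contig,
      strand = strand, exons = ex_g, cds = ex_g, phase = 0L)
  }
  pieces <- c(pieces, paste(.random_bases(spacer, gc), collapse = ""))
  genome <- new_genome(setNames(list(paste(pieces, collapse = "")), contig))
  models <- lapply(models, validate_transcript, genome = genome)

  out <- list(genome = genome, models = models)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    out$fasta <- write_genome_fasta(genome, file.path(dir, "toy.fa"))
    out$gff3 <- write_transcripts_gff3(models, file.path(dir, "toy.gff3"))
  }
  out
}

#' Generate a mutation set with known ground truth
#'
#' Samples mutations whose requested consequence categories are guaranteed:
#' candidate positions are drawn from a full enumeration of the toy
#' transcriptome (coding substitutions, splice windows, deep intron,
#' single-base CDS deletions for frameshifts) and every sampled mutation is
#' re-classified; any disagreement with the request is an error, so the
#' emitted labels are ground truth by construction.
#'
#' @param models named list of `transcript_model`s (one per gene).
#' @param genome an `enu_genome`.
#' @param requests data.frame with columns `category`, `dataset`, `n`.
#'   Category may be any classifiable category or the aliases
#'   `"overt_null"` (nonsense, critical splice or frameshift, sampled
#'   uniformly among achievable kinds) and `"other"` (missense).
#' @param window non-critical splice window used for candidate enumeration
#'   and verification.
#' @param seed random seed.
#' @return A mutation record data.frame (see [read_mutation_table()]) with
#'   an extra `true_category` column.
#' @export
make_mutation_set <- function(models, genome, requests, window = 10L,
                              seed) {
  stopifnot(all(c("category", "dataset", "n") %in% names(requests)))
  set.seed(seed)
  if (sum(requests$n) == 0L) {
    out <- .mutation_record(character(0), character(0), integer(0),
                            character(0), character(0),
                            dataset = character(0),
                            zygosity = character(0), score = numeric(0))
    out$true_category <- character(0)
    return(out)
  }
  cand <- .mutation_candidates(models, genome, window)
  rows <- list()
  counter <- 0L
  for (r in seq_len(nrow(requests))) {
    categ <- requests$category[r]
    n <- requests$n[r]
    if (n == 0L) next
    wanted <- switch(categ,
      overt_null = c("nonsense", "critical_splice_donor",
                     "critical_splice_acceptor", "frameshift"),
      other = "missense",
      categ)
    pool <- cand[cand$category %in% wanted, , drop = FALSE]
    if (nrow(pool) < n) {
      stop("category '", categ, "' unreachable: ", nrow(pool),
           " candidate(s) in the toy genome, ", n, " requested")
    }
    pick <- pool[sample.int(nrow(pool), n), , drop = FALSE]
    pick$dataset <- requests$dataset[r]
    pick$requested <- categ
    rows[[length(rows) + 1L]] <- pick
  }
  sel <- do.call(rbind, rows)
  sel$id <- sprintf("m%05d", seq_len(nrow(sel)))
  # closed loop: the classifier must agree with the generated label
  for (i in seq_len(nrow(sel))) {
    call <- classify_mutation(
      list(id = sel$id[i], contig = sel$contig[i], pos = sel$pos[i],
           ref = sel$ref[i], alt = sel$alt[i]),
      models[[sel$transcript[i]]], genome, window = window)
    if (call$category != sel$category[i]) {
      stop("generator/classifier disagreement at ", sel$contig[i], ":",
           sel$pos[i], " (", sel$category[i], " vs ", call$category, ")")
    }
  }
  out <- .mutation_record(sel$id, sel$contig, sel$pos, sel$ref, sel$alt,
                          dataset = sel$dataset)
  out$true_category <- sel$category
  out
}

# all single-base (and frameshift-deletion) mutation candidates of a toy
# transcriptome, labelled with the category the classifier will assign
.mutation_candidates <- function(models, genome, window = 10L) {
  sites <- .site_consequences(models, genome)
  tx_of_gene <- setNames(vapply(models, `[[`, "", "transcript"),
                         vapply(models, `[[`, "", "gene"))
  strand_of <- setNames(vapply(models, `[[`, "", "strand"),
                        vapply(models, `[[`, "", "transcript"))
  sites$transcript <- tx_of_gene[sites$gene]
  minus <- strand_of[sites$transcript] == "-"
  sites$ref <- ifelse(minus, .complement_bases(sites$sense_from),
                      sites$sense_from)
  sites$alt <- ifelse(minus, .complement_bases(sites$sense_to),
                      sites$sense_to)
  cand <- sites[, c("contig", "pos", "ref", "alt", "category",
                    "transcript")]

  extra <- list()
  for (m in models) {
    # intronic positions beyond the critical two bases
    intr <- .introns(m)
    for (i in seq_len(nrow(intr))) {
      pos <- seq.int(intr[i, 1L], intr[i, 2L])
      for (p in pos) {
        sd <- splice_distance(p, m)
        categ <- if (sd$distance <= 2L) next
        else if (sd$distance <= window) {
          paste0("noncritical_splice_", sd$side)
        } else "deep_intronic"
        ref <- .genome_base(genome, m$contig, p)
        for (alt in setdiff(.BASES, ref)) {
          extra[[length(extra) + 1L]] <- data.frame(
            contig = m$contig, pos = p, ref = ref, alt = alt,
            category = categ, transcript = m$transcript,
            stringsAsFactors = FALSE)
        }
      }
    }
    # single-base deletions inside the CDS -> frameshift
    cds_pos <- sort(.cds_positions(m))
    take <- cds_pos[seq(1L, length(cds_pos), by = 7L)]  # a sparse sample
    for (p in take) {
      extra[[length(extra) + 1L]] <- data.frame(
        contig = m$contig, pos = p,
        ref = .genome_base(genome, m$contig, p), alt = "",
        category = "frameshift", transcript = m$transcript,
        stringsAsFactors = FALSE)
    }
  }
  out <- rbind(cand, do.call(rbind, extra))
  rownames(out) <- NULL
  out
}

#' Load the packaged printed count tables
#'
#' Returns the published count tables shipped with the package: the
#' mutation-type tallies of the phenotypic and incidental sets, the splice
#' mutation distances, the sense-strand substitution counts with their
#' binomial test columns, and the genome-wide opportunity counts.  Fixture
#' integrity is verified against embedded totals (e.g. 167 phenotypic and
#' 358 incidental spectrum mutations; 35,954,982 total opportunities) and a
#' corrupted installation is an error.
#'
#' @return A list with elements `table2` (category counts), `table3`
#'   (splice distances), `table5` (spectrum counts, printed null and tail
#'   probabilities) and `table7` (an `opportunity_table`).
#' @export
load_paper_fixtures <- function() {
  path <- function(f) {
    p <- system.file("extdata", f, package = "enuspectra")
    if (p == "") stop("fixture not found: ", f)
    p
  }
  t2 <- utils::read.delim(path("table2_mutation_types.tsv"),
                          stringsAsFactors = FALSE)
  t3 <- utils::read.delim(path("table3_splice_distances.tsv"),
                          stringsAsFactors = FALSE)
  t5 <- utils::read.delim(path("table5_strand_counts.tsv"),
                          stringsAsFactors = FALSE)
  t7 <- as_opportunity_table(
    utils::read.delim(path("table7_opportunities.tsv"),
                      stringsAsFactors = FALSE))
  ok <- sum(t5$k_phenotypic) == 167L &&
    sum(t5$k_incidental) == 358L &&
    sum(t5$k_combined) == 525L &&
    sum(t7$coding) == 81590532 &&
    sum(t7$splice) == 2090544 &&
    t7$total[t7$substitution == "A>T"] == 8003357 &&
    t7$total[t7$substitution == "T>C"] == 5172489 &&
    sum(t2$phenotypic) == 178L && sum(t2$incidental) == 402L &&
    nrow(t3) == 32L
  if (!ok) stop("packaged count fixtures are corrupted")
  list(table2 = t2, table3 = t3, table5 = t5, table7 = t7)
}
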