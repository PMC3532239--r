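.translate_codon <- function(codon, code = Biostrings::GENETIC_CODE) {
  if (grepl("N", codon, fixed = TRUE)) return(NA_character_)
  unname(code[[codon]])
}

#' Distance of an intronic position from the nearest exon boundary
#'
#' Distances are counted in transcript orientation: position 1 on the donor
#' side is the first intronic base after the upstream exon (the `G` of the
#' canonical `GT`), position 1 on the acceptor side is the last intronic base
#' before the downstream exon (the `G` of `AG`).  The side is whichever exon
#' boundary is nearer; an exact tie resolves to the donor side.
#'
#' @param position 1-based genomic coordinate, intronic for the model.
#' @param model a `transcript_model`.
#' @return A list with `distance` (integer, >= 1), `side` (`"donor"` or
#'   `"acceptor"`) and `intron` (index in transcript orientation).
#' @export
splice_distance <- function(position, model) {
  intr <- .introns(model)
  hit <- which(position >= intr[, 1L] & position <= intr[, 2L])
  if (length(hit) != 1L) {
    stop("position ", position, " is not intronic for transcript ",
         model$transcript)
  }
  d_left <- position - intr[hit, 1L] + 1L
  d_right <- intr[hit, 2L] - position + 1L
  if (model$strand == "+") {
    donor <- d_left; acceptor <- d_right
    intron_index <- hit
  } else {
    donor <- d_right; acceptor <- d_left
    intron_index <- nrow(intr) - hit + 1L
  }
  if (donor <= acceptor) {
    list(distance = as.integer(donor), side = "donor",
         intron = as.integer(intron_index))
  } else {
    list(distance = as.integer(acceptor), side = "acceptor",
         intron = as.integer(intron_index))
  }
}

.empty_call <- function() {
  data.frame(id = NA_character_, gene = NA_character_,
             transcript = NA_character_, category = NA_character_,
             sense_sub = NA_character_, codon_from = NA_character_,
             codon_to = NA_character_, aa_from = NA_character_,
             aa_to = NA_character_, aa_pos = NA_integer_,
             splice_distance = NA_integer_, splice_side = NA_character_,
             overt_null = NA, dataset = NA_character_, score = NA_real_,
             stringsAsFactors = FALSE)
}

#' Classify one mutation against a transcript model
#'
#' Implements the category ladder used throughout the package.  For a
#' single-base substitution: positions at the first two intronic bases of
#' either intron end are critical splice changes; intronic positions 3 to
#' `window` are non-critical splice changes; coding positions are classified
#' by codon substitution into synonymous, missense, nonsense (residue to
#' stop), make-sense (stop to residue) or start-loss (first `ATG` codon
#' altered away from methionine); deeper intronic positions are
#' `deep_intronic` and positions outside the gene span are `intergenic`.
#' Indels and multi-nucleotide substitutions overlapping the CDS are
#' classified structurally as `frameshift` (net length change not a multiple
#' of 3) or `inframe_indel`; they carry no substitution type and are excluded
#' from spectrum tallies.  Codons containing `N` give `unresolvable`.
#'
#' The sense-strand substitution type is the genomic change complemented for
#' minus-strand genes, so spectra are always expressed on the coding strand.
#' The overt-null flag is true exactly for frameshift, nonsense and critical
#' splice categories.
#'
#' @param mutation one mutation record (one-row data.frame or list with
#'   `id`, `contig`, `pos`, `ref`, `alt`, optionally `dataset`, `score`).
#' @param model a `transcript_model`.
#' @param genome an `enu_genome`.
#' @param window non-critical splice window in bp from the exon boundary
#'   (default 10).
#' @param code genetic code (named character vector, codon to one-letter
#'   residue with `*` for stop).
#' @return A one-row data.frame (a consequence call).
#' @export
classify_mutation <- function(mutation, model, genome, window = 10L,
                              code = Biostrings::GENETIC_CODE) {
  mut <- as.list(mutation)
  pos <- as.integer(mut$pos)
  ref <- toupper(mut$ref)
  alt <- toupper(if (is.null(mut$alt) || is.na(mut$alt)) "" else mut$alt)
  if (pos < 1L || pos > attr(genome, "lengths")[[mut$contig]]) {
    stop("mutation ", mut$id, ": position outside contig ", mut$contig)
  }
  g <- genome_fetch(genome, mut$contig, pos, pos + nchar(ref) - 1L)
  if (g != ref) {
    stop("mutation ", mut$id, ": ref allele ", ref,
         " does not match genome (", g, ") at ", mut$contig, ":", pos)
  }

  call <- .empty_call()
  call$id <- as.character(mut$id)
  call$gene <- model$gene
  call$transcript <- model$transcript
  call$dataset <- if (is.null(mut$dataset)) "unlabeled" else mut$dataset
  call$score <- if (is.null(mut$score)) NA_real_ else as.numeric(mut$score)

  if (!identical(model$contig, mut$contig)) {
    call$category <- "intergenic"
    call$overt_null <- FALSE
    return(call)
  }

  span <- .gene_span(model)
  is_snv <- nchar(ref) == 1L && nchar(alt) == 1L

  if (!is_snv) {
    # structural: indel or multi-nucleotide substitution
    rng <- c(pos, pos + nchar(ref) - 1L)
    net <- nchar(alt) - nchar(ref)
    in_cds <- any(rng[2L] >= model$cds[, 1L] & rng[1L] <= model$cds[, 2L])
    if (in_cds) {
      call$category <- if (net %% 3L != 0L) "frameshift" else "inframe_indel"
    } else if (pos < span[1L] || pos > span[2L]) {
      call$category <- "intergenic"
    } else {
      intr <- .introns(model)
      if (nrow(intr) && any(pos >= intr[, 1L] & pos <= intr[, 2L])) {
        sd <- splice_distance(pos, model)
        call$splice_distance <- sd$distance
        call$splice_side <- sd$side
        call$category <- if (sd$distance <= 2L) {
          paste0("critical_splice_", sd$side)
        } else if (sd$distance <= window) {
          paste0("noncritical_splice_", sd$side)
        } else "deep_intronic"
      } else {
        call$category <- "intergenic"  # exonic non-CDS: out of scope, noncoding
      }
    }
    call$overt_null <- call$category %in% .OVERT_NULL_CATEGORIES
    return(call)
  }

  sense_from <- .sense_base(model, ref)
  sense_to <- .sense_base(model, alt)

  if (pos < span[1L] || pos > span[2L]) {
    call$category <- "intergenic"
    call$overt_null <- FALSE
    return(call)
  }

  # ladder: splice windows take precedence, then coding change
  intr <- .introns(model)
  if (nrow(intr) && any(pos >= intr[, 1L] & pos <= intr[, 2L])) {
    sd <- splice_distance(pos, model)
    call$splice_distance <- sd$distance
    call$splice_side <- sd$side
    call$sense_sub <- .sub_type(sense_from, sense_to)
    call$category <- if (sd$distance <= 2L) {
      paste0("critical_splice_", sd$side)
    } else if (sd$distance <= window) {
      paste0("noncritical_splice_", sd$side)
    } else "deep_intronic"
    call$overt_null <- call$category %in% .OVERT_NULL_CATEGORIES
    return(call)
  }

  cds_pos <- .cds_positions(model)
  idx <- match(pos, cds_pos)
  if (is.na(idx)) {
    # exonic but non-coding (UTR): out of scope, treated as noncoding
    call$category <- "intergenic"
    call$overt_null <- FALSE
    return(call)
  }

  codon_i <- (idx - 1L) %/% 3L + 1L
  off <- (idx - 1L) %% 3L + 1L
  s <- sense_cds_seq(model, genome)
  codon <- substr(s, 3L * (codon_i - 1L) + 1L, 3L * codon_i)
  call$sense_sub <- .sub_type(sense_from, sense_to)
  if (grepl("N", codon, fixed = TRUE) || nchar(codon) < 3L) {
    call$category <- "unresolvable"
    call$overt_null <- FALSE
    return(call)
  }
  codon_new <- codon
  substr(codon_new, off, off) <- sense_to
  aa1 <- .translate_codon(codon, code)
  aa2 <- .translate_codon(codon_new, code)
  call$codon_from <- codon
  call$codon_to <- codon_new
  call$aa_from <- aa1
  call$aa_to <- aa2
  call$aa_pos <- codon_i

  call$category <- if (aa1 == aa2) {
    "synonymous"
  } else if (codon_i == 1L && codon == "ATG") {
    "start_loss"
  } else if (aa2 == "*") {
    "nonsense"
  } else if (aa1 == "*") {
    "make_sense"
  } else {
    "missense"
  }
  call$overt_null <- call$category %in% .OVERT_NULL_CATEGORIES
  call
}

#' Classify a batch of mutations
#'
#' Each mutation is assigned to the transcript model whose gene span contains
#' it (the first such model when chosen transcripts overlap); mutations
#' falling in no gene are `intergenic`.  Per-record errors (reference
#' mismatches, out-of-range positions) are collected and reported at the end
#' without aborting the batch.
#'
#' @param mutations mutation record data.frame
#'   (see [read_mutation_table()]).
#' @param models named list of `transcript_model`s, one per gene
#'   (see [select_longest_cds()]).
#' @param genome an `enu_genome`.
#' @param window non-critical splice window (bp).
#' @return An object of class `consequence_set`: a list with `calls` (one
#'   row per successfully classified mutation), `summary` (category by
#'   dataset counts with percentages), `ratios` (per-dataset overt-null to
#'   other ratios) and `errors` (character vector of per-record messages).
#' @export
classify_batch <- function(mutations, models, genome, window = 10L) {
  spans <- do.call(rbind, lapply(models, function(m) {
    sp <- .gene_span(m)
    data.frame(contig = m$contig, start = sp[1L], end = sp[2L],
               stringsAsFactors = FALSE)
  }))
  calls <- vector("list", nrow(mutations))
  errors <- character(0)
  for (i in seq_len(nrow(mutations))) {
    mut <- mutations[i, ]
    hit <- which(spans$contig == mut$contig & mut$pos >= spans$start &
                   mut$pos <= spans$end)
    res <- tryCatch({
      if (length(hit) == 0L) {
        call <- .empty_call()
        call$id <- mut$id
        call$category <- "intergenic"
        call$overt_null <- FALSE
        call$dataset <- mut$dataset
        call$score <- mut$score
        call
      } else {
        classify_mutation(mut, models[[hit[1L]]], genome, window = window)
      }
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      errors <- c(errors, res)
    } else {
      calls[[i]] <- res
    }
  }
  calls <- do.call(rbind, calls[!vapply(calls, is.null, TRUE)])
  if (is.null(calls)) calls <- .empty_call()[0, ]
  out <- list(calls = calls,
              summary = consequence_summary(calls),
              ratios = .overt_ratio_lines(calls),
              errors = errors)
  class(out) <- "consequence_set"
  if (length(errors)) {
    warning(length(errors), " record(s) failed classification; ",
            "see $errors")
  }
  out
}

#' Summarise consequence calls by category and dataset
#'
#' Start-loss calls are folded into missense for the summary (they are listed
#' among missense alleles in per-allele tables), while remaining a distinct
#' category on the calls themselves.
#'
#' @param calls consequence-call data.frame.
#' @return A data.frame of counts and percent-of-total by category and
#'   dataset.
#' @export
consequence_summary <- function(calls) {
  if (nrow(calls) == 0L) {
    return(data.frame(category = character(0), dataset = character(0),
                      n = integer(0), pct = numeric(0)))
  }
  cat_disp <- ifelse(calls$category == "start_loss", "missense",
                     calls$category)
  ds <- ifelse(is.na(calls$dataset), "unlabeled", calls$dataset)
  tab <- as.data.frame(table(category = cat_disp, dataset = ds),
                       stringsAsFactors = FALSE)
  names(tab)[3L] <- "n"
  tab <- tab[tab$n > 0L, ]
  tot <- tapply(tab$n, tab$dataset, sum)
  tab$pct <- round(100 * tab$n / as.numeric(tot[tab$dataset]), 1L)
  rownames(tab) <- NULL
  tab[order(tab$dataset, -tab$n), ]
}

.overt_ratio_lines <- function(calls) {
  ds <- unique(calls$dataset[!is.na(calls$dataset)])
  out <- lapply(ds, function(d) {
    sub <- calls[calls$dataset == d, ]
    overt_null_ratios(sum(sub$overt_null), nrow(sub) - sum(sub$overt_null))
  })
  names(out) <- ds
  out
}

#' @export
print.consequence_set <- function(x, ...) {
  cat("Consequence calls:", nrow(x$calls), "mutation(s)")
  if (length(x$errors)) cat(" (", length(x$errors), " failed)", sep = "")
  cat("\n\n")
  print(x$summary)
  for (d in names(x$ratios)) {
    r <- x$ratios[[d]]
    cat(sprintf("\n%s: overt null : other = %s (%.2f%% of total)\n",
                d, r$ratio_label, 100 * r$fraction))
  }
  invisible(x)
}
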