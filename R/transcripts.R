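#' Construct a transcript model
#'
#' A transcript model records one gene's chosen coding transcript: its exons
#' and CDS as 1-based inclusive genomic intervals, the strand, and the phase
#' of the first CDS base.  All coordinates are genomic; strand orientation is
#' applied when sequence is extracted, never to the stored intervals.
#'
#' @param gene,transcript gene and transcript identifiers.
#' @param contig contig name.
#' @param strand `"+"` or `"-"`.
#' @param exons,cds two-column matrices (start, end) of 1-based inclusive
#'   intervals, or data.frames with `start`/`end` columns.  Rows in ascending
#'   genomic order.
#' @param phase phase of the first CDS base in translation order (0-2).
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(gene, transcript, contig, strand, exons, cds,
                             phase = 0L) {
  stopifnot(strand %in% c("+", "-"), phase %in% 0:2)
  exons <- .as_interval_matrix(exons)
  cds <- .as_interval_matrix(cds)
  m <- structure(
    list(gene = as.character(gene), transcript = as.character(transcript),
         contig = as.character(contig), strand = strand,
         exons = exons, cds = cds, phase = as.integer(phase),
         complete = NA, warnings = character(0)),
    class = "transcript_model")
  .check_transcript_structure(m)
  m
}

.as_interval_matrix <- function(x) {
  if (is.data.frame(x)) x <- cbind(x$start, x$end)
  x <- matrix(as.integer(x), ncol = 2L,
              dimnames = list(NULL, c("start", "end")))
  x[order(x[, 1L]), , drop = FALSE]
}

# hard structural invariants: sorted, non-overlapping exons; CDS within exons
.check_transcript_structure <- function(m) {
  ex <- m$exons
  if (nrow(ex) == 0L) stop("transcript ", m$transcript, ": no exons")
  if (any(ex[, 2L] < ex[, 1L])) {
    stop("transcript ", m$transcript, ": exon end < start")
  }
  if (nrow(ex) > 1L && any(ex[-1L, 1L] <= ex[-nrow(ex), 2L])) {
    stop("transcript ", m$transcript, ": overlapping or unsorted exons")
  }
  for (i in seq_len(nrow(m$cds))) {
    inside <- any(m$cds[i, 1L] >= ex[, 1L] & m$cds[i, 2L] <= ex[, 2L])
    if (!inside) {
      stop("transcript ", m$transcript, ": CDS interval ",
           m$cds[i, 1L], "-", m$cds[i, 2L], " not contained in an exon")
    }
  }
  invisible(m)
}

#' Validate a transcript model against a genome
#'
#' Checks the soft invariants of a complete coding model: the phase-trimmed
#' CDS length is a positive multiple of 3, the sense-strand CDS begins with a
#' start codon and ends with a stop codon.  Violations are recorded as
#' validation warnings on the returned model (and emitted with
#' `warning()` when `quiet = FALSE`) rather than errors; the `complete` flag
#' is set accordingly.
#'
#' @param model a `transcript_model`.
#' @param genome an `enu_genome`, or `NULL` to check lengths only.
#' @param quiet suppress `warning()` emission.
#' @return The model with `complete` and `warnings` filled in.
#' @export
validate_transcript <- function(model, genome = NULL, quiet = TRUE) {
  w <- character(0)
  if (!is.null(genome) && is.null(genome[[model$contig]])) {
    stop("transcript ", model$transcript, ": unknown contig ", model$contig)
  }
  len <- sum(model$cds[, 2L] - model$cds[, 1L] + 1L) - model$phase
  if (len <= 0L || len %% 3L != 0L) {
    w <- c(w, paste0("CDS length ", len,
                     " (after phase trim) is not a positive multiple of 3"))
  }
  if (!is.null(genome) && length(w) == 0L) {
    s <- sense_cds_seq(model, genome)
    if (substr(s, 1L, 3L) != "ATG") {
      w <- c(w, "sense CDS does not begin with ATG")
    }
    last <- substr(s, nchar(s) - 2L, nchar(s))
    if (!last %in% c("TAA", "TAG", "TGA")) {
      w <- c(w, "sense CDS does not end with a stop codon")
    }
  }
  model$warnings <- w
  model$complete <- length(w) == 0L
  if (!quiet && length(w)) {
    warning("transcript ", model$transcript, ": ",
            paste(w, collapse = "; "))
  }
  model
}

#' @export
print.transcript_model <- function(x, ...) {
  cat("Transcript", x$transcript, "(gene", x$gene, ") on", x$contig,
      x$strand, "\n")
  cat("  exons:", nrow(x$exons), " CDS intervals:", nrow(x$cds),
      " CDS length:", sum(x$cds[, 2] - x$cds[, 1] + 1), "bp\n")
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

# --- coordinate machinery ---------------------------------------------------

# genomic positions of the CDS in translation order (phase-trimmed)
.cds_positions <- function(model) {
  pos <- unlist(lapply(seq_len(nrow(model$cds)), function(i) {
    seq.int(model$cds[i, 1L], model$cds[i, 2L])
  }))
  if (model$strand == "-") pos <- rev(pos)
  if (model$phase > 0L) pos <- pos[-seq_len(model$phase)]
  pos
}

#' Sense-strand CDS sequence of a transcript
#'
#' Concatenates the CDS intervals in translation order and complements for
#' minus-strand models, yielding the mRNA-sense coding sequence.
#'
#' @param model a `transcript_model`.
#' @param genome an `enu_genome`.
#' @return A character string.
#' @export
sense_cds_seq <- function(model, genome) {
  pieces <- vapply(seq_len(nrow(model$cds)), function(i) {
    genome_fetch(genome, model$contig, model$cds[i, 1L], model$cds[i, 2L])
  }, character(1))
  s <- paste(pieces, collapse = "")
  if (model$strand == "-") s <- .revcomp(s)
  if (model$phase > 0L) s <- substr(s, model$phase + 1L, nchar(s))
  s
}

# introns as a genomic interval matrix (possibly 0 rows), ascending
.introns <- function(model) {
  ex <- model$exons
  if (nrow(ex) < 2L) {
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("start", "end"))))
  }
  cbind(start = ex[-nrow(ex), 2L] + 1L, end = ex[-1L, 1L] - 1L)
}

.gene_span <- function(model) {
  c(min(model$exons[, 1L]), max(model$exons[, 2L]))
}

# sense-strand identity of the genomic plus-strand base `b` for this model
.sense_base <- function(model, b) {
  if (model$strand == "-") .complement_bases(b) else b
}

# --- loading ----------------------------------------------------------------

#' Load transcript models from GFF3 or a simplified transcript table
#'
#' GFF3 input must link `mRNA` features to `gene` parents and `exon`/`CDS`
#' features to their `mRNA` via `Parent` attributes (1-based inclusive
#' coordinates, the GFF3 convention).  Alternatively a simplified TSV dialect
#' is accepted with columns `gene`, `transcript`, `contig`, `strand`,
#' `exons`, `cds`, the interval lists written `"start-end;start-end"`.
#' Format is chosen by file extension (`.gff3`/`.gff` vs anything else).
#'
#' Every model is validated; soft violations (CDS length, start/stop codon)
#' are attached as validation warnings, structural violations are errors
#' naming the transcript.
#'
#' @param path input file (plain or gzip).
#' @param genome an `enu_genome`, used for sequence-level validation;
#'   optional.
#' @return A named list of `transcript_model` objects (names = transcript
#'   ids).
#' @export
load_transcripts <- function(path, genome = NULL) {
  stopifnot(file.exists(path))
  if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE)) {
    models <- .load_transcripts_gff3(path)
  } else {
    models <- .load_transcripts_tsv(path)
  }
  lapply(models, validate_transcript, genome = genome)
}

.load_transcripts_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  ids <- if ("ID" %in% names(md)) as.character(md$ID) else rep(NA_character_, length(gr))
  parent <- if ("Parent" %in% names(md)) {
    vapply(md$Parent, function(p) if (length(p)) as.character(p)[1] else NA_character_,
           character(1))
  } else rep(NA_character_, length(gr))

  mrna_idx <- which(type %in% c("mRNA", "transcript"))
  if (length(mrna_idx) == 0L) stop("no mRNA features in ", path)
  models <- list()
  for (i in mrna_idx) {
    tx_id <- ids[i]
    gene_id <- if (!is.na(parent[i])) parent[i] else tx_id
    child <- which(parent == tx_id)
    ex_i <- child[type[child] == "exon"]
    cds_i <- child[type[child] == "CDS"]
    if (length(cds_i) == 0L) next  # non-coding transcript: skipped
    if (length(ex_i) == 0L) ex_i <- cds_i
    strand <- as.character(BiocGenerics::strand(gr[i]))
    ph <- 0L
    phases <- if ("phase" %in% names(md)) suppressWarnings(as.integer(md$phase[cds_i])) else NULL
    if (!is.null(phases) && !all(is.na(phases))) {
      ord <- order(BiocGenerics::start(gr[cds_i]),
                   decreasing = (strand == "-"))
      first_ph <- phases[ord][1L]
      if (!is.na(first_ph)) ph <- first_ph
    }
    models[[tx_id]] <- transcript_model(
      gene = gene_id, transcript = tx_id,
      contig = as.character(GenomicRanges::seqnames(gr[i])),
      strand = strand,
      exons = cbind(BiocGenerics::start(gr[ex_i]), BiocGenerics::end(gr[ex_i])),
      cds = cbind(BiocGenerics::start(gr[cds_i]), BiocGenerics::end(gr[cds_i])),
      phase = ph)
  }
  if (length(models) == 0L) stop("no coding transcripts in ", path)
  models
}

.parse_interval_list <- function(s) {
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "-", fixed = TRUE)
  do.call(rbind, lapply(parts, function(p) as.integer(p)))
}

.format_interval_list <- function(m) {
  paste(paste0(m[, 1L], "-", m[, 2L]), collapse = ";")
}

.load_transcripts_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("gene", "transcript", "contig", "strand", "exons", "cds")
  if (!all(need %in% names(d))) {
    stop("transcript TSV must have columns: ", paste(need, collapse = ", "))
  }
  if (is.null(d$phase)) d$phase <- "0"
  models <- lapply(seq_len(nrow(d)), function(i) {
    transcript_model(d$gene[i], d$transcript[i], d$contig[i], d$strand[i],
                     .parse_interval_list(d$exons[i]),
                     .parse_interval_list(d$cds[i]),
                     as.integer(d$phase[i]))
  })
  names(models) <- d$transcript
  models
}

#' Write transcript models
#'
#' `write_transcripts_tsv()` writes the simplified transcript table dialect;
#' `write_transcripts_gff3()` writes standard GFF3 with gene/mRNA/exon/CDS
#' features linked by `Parent`.
#'
#' @param models list of `transcript_model`s.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_transcripts_tsv <- function(models, path) {
  d <- data.frame(
    gene = vapply(models, `[[`, "", "gene"),
    transcript = vapply(models, `[[`, "", "transcript"),
    contig = vapply(models, `[[`, "", "contig"),
    strand = vapply(models, `[[`, "", "strand"),
    exons = vapply(models, function(m) .format_interval_list(m$exons), ""),
    cds = vapply(models, function(m) .format_interval_list(m$cds), ""),
    phase = vapply(models, function(m) m$phase, 0L),
    stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_transcripts_tsv
#' @export
write_transcripts_gff3 <- function(models, path) {
  rows <- list()
  for (m in models) {
    span <- .gene_span(m)
    rows[[length(rows) + 1L]] <- data.frame(
      contig = m$contig, type = "gene", start = span[1], end = span[2],
      strand = m$strand, ID = m$gene, Parent = NA_character_,
      phase = NA_integer_)
    rows[[length(rows) + 1L]] <- data.frame(
      contig = m$contig, type = "mRNA", start = span[1], end = span[2],
      strand = m$strand, ID = m$transcript, Parent = m$gene,
      phase = NA_integer_)
    for (i in seq_len(nrow(m$exons))) {
      rows[[length(rows) + 1L]] <- data.frame(
        contig = m$contig, type = "exon",
        start = m$exons[i, 1], end = m$exons[i, 2],
        strand = m$strand, ID = NA_character_, Parent = m$transcript,
        phase = NA_integer_)
    }
    # GFF3 phase: bases to skip at the start of each CDS piece in
    # translation order
    ord <- if (m$strand == "-") rev(seq_len(nrow(m$cds))) else
      seq_len(nrow(m$cds))
    lens <- m$cds[ord, 2L] - m$cds[ord, 1L] + 1L
    before <- c(0L, cumsum(lens))[seq_along(lens)] - m$phase
    phases <- integer(nrow(m$cds))
    phases[ord] <- (3L - before %% 3L) %% 3L
    for (i in seq_len(nrow(m$cds))) {
      rows[[length(rows) + 1L]] <- data.frame(
        contig = m$contig, type = "CDS",
        start = m$cds[i, 1], end = m$cds[i, 2],
        strand = m$strand, ID = NA_character_, Parent = m$transcript,
        phase = phases[i])
    }
  }
  d <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = d$contig,
    ranges = IRanges::IRanges(d$start, d$end),
    strand = d$strand)
  S4Vectors::mcols(gr)$type <- d$type
  S4Vectors::mcols(gr)$ID <- d$ID
  S4Vectors::mcols(gr)$phase <- d$phase
  S4Vectors::mcols(gr)$Parent <- IRanges::CharacterList(
    lapply(d$Parent, function(p) if (is.na(p)) character(0) else p))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Keep the longest coding transcript of every gene
#'
#' Reduces a transcript set to one model per gene, chosen to maximise total
#' CDS length; ties break to the lexicographically smallest transcript id so
#' the choice is order-independent.
#'
#' @param models list of `transcript_model`s.
#' @return Named list with exactly one model per gene id.
#' @export
select_longest_cds <- function(models) {
  genes <- vapply(models, `[[`, "", "gene")
  lens <- vapply(models, function(m) sum(m$cds[, 2L] - m$cds[, 1L] + 1L), 0)
  txs <- vapply(models, `[[`, "", "transcript")
  keep <- vapply(split(seq_along(models), genes), function(idx) {
    idx <- idx[order(-lens[idx], txs[idx])]
    idx[1L]
  }, 0L)
  out <- models[sort(keep)]
  names(out) <- vapply(out, `[[`, "", "transcript")
  out
}
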