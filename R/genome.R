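#' Load a genome from a FASTA file
#'
#' Reads all records of a (possibly gzip-compressed) FASTA file into an
#' in-memory genome object.  Sequence is normalised to uppercase so lookups
#' are case-insensitive; only `A`, `C`, `G`, `T` and `N` are permitted.
#'
#' @param path path to a FASTA file (plain or `.gz`).
#' @return An object of class `enu_genome`: a named list of contig sequences
#'   (character strings) with a `lengths` attribute.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chrT", "ATGAAATGA"), fa)
#' g <- load_genome(fa)
#' genome_fetch(g, "chrT", 4, 6)  # "AAA"
load_genome <- function(path) {
  stopifnot(file.exists(path))
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  nm <- sub("\\s.*$", "", names(seqs))  # first token of the header line
  if (anyDuplicated(nm)) {
    stop("duplicate contig names in ", path, ": ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  contigs <- toupper(as.character(seqs))
  names(contigs) <- nm
  bad <- grepl("[^ACGTN]", contigs)
  if (any(bad)) {
    stop("non-ACGTN characters in contig(s): ",
         paste(nm[bad], collapse = ", "))
  }
  new_genome(as.list(contigs))
}

#' Construct a genome object from named sequences
#'
#' @param contigs named list (or named character vector) of nucleotide
#'   strings over `A,C,G,T,N`.
#' @return An `enu_genome` object.
#' @export
new_genome <- function(contigs) {
  contigs <- as.list(contigs)
  if (is.null(names(contigs)) || any(names(contigs) == "")) {
    stop("all contigs must be named")
  }
  contigs <- lapply(contigs, toupper)
  structure(contigs,
            lengths = vapply(contigs, nchar, integer(1)),
            class = "enu_genome")
}

#' @export
print.enu_genome <- function(x, ...) {
  len <- attr(x, "lengths")
  cat("Genome with", length(x), "contig(s):\n")
  for (nm in names(x)) cat(" ", nm, "\t", len[[nm]], "bp\n")
  invisible(x)
}

#' Fetch a genomic interval
#'
#' Extracts the plus-strand sequence of a 1-based inclusive interval.
#'
#' @param genome an `enu_genome`.
#' @param contig contig name.
#' @param start,end 1-based inclusive coordinates.
#' @param strand `"+"` (default) or `"-"`; for `"-"` the reverse complement
#'   is returned.
#' @return A character string.
#' @export
genome_fetch <- function(genome, contig, start, end, strand = "+") {
  seq <- genome[[contig]]
  if (is.null(seq)) stop("unknown contig: ", contig)
  if (start < 1L || end > nchar(seq) || start > end) {
    stop("interval ", start, "-", end, " out of bounds for contig ",
         contig, " (length ", nchar(seq), ")")
  }
  s <- substr(seq, start, end)
  if (identical(strand, "-")) s <- .revcomp(s)
  s
}

#' Write a genome to FASTA
#'
#' @param genome an `enu_genome`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(unlist(genome))
  names(x) <- names(genome)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

# single-base lookup, vectorised over pos
.genome_base <- function(genome, contig, pos) {
  seq <- genome[[contig]]
  if (is.null(seq)) stop("unknown contig: ", contig)
  if (any(pos < 1L | pos > nchar(seq))) {
    stop("position out of bounds for contig ", contig)
  }
  substring(seq, pos, pos)
}
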