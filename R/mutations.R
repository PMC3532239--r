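.DATASETS <- c("phenotypic", "incidental", "unlabeled")
.ZYGOSITIES <- c("hom", "het", "hemi", "unknown")

#' Read a mutation table
#'
#' Reads a tab-separated mutation table with header columns `id`, `contig`,
#' `pos`, `ref`, `alt`, `dataset`, `zygosity`, `score`.  `score` holds an
#' optional damage score in \[0, 1\] (e.g. a PolyPhen-2 value) and may be
#' `NA`.  Deletions may be written either VCF-style (`ref` longer than
#' `alt`) or with an empty `alt`.  Unknown dataset strings map to
#' `"unlabeled"` with a warning; malformed rows (non-integer position,
#' `ref == alt`, score outside \[0, 1\]) are errors reporting the line
#' number.
#'
#' @param path TSV file (plain or gzip).
#' @param genome optional `enu_genome`; when supplied, each record's `ref`
#'   is checked against the genome and mismatches are errors.
#' @return A data.frame of mutation records, one row per mutation.
#' @export
read_mutation_table <- function(path, genome = NULL) {
  stopifnot(file.exists(path))
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = NULL)
  need <- c("id", "contig", "pos", "ref", "alt", "dataset", "zygosity",
            "score")
  if (!all(need %in% names(d))) {
    stop("mutation table must have columns: ", paste(need, collapse = ", "))
  }
  # line numbers in the file: header is line 1
  line_no <- seq_len(nrow(d)) + 1L
  pos <- suppressWarnings(as.integer(d$pos))
  if (anyNA(pos)) {
    stop("non-integer pos at line(s): ",
         paste(line_no[is.na(pos)], collapse = ", "))
  }
  ref <- toupper(d$ref)
  alt <- toupper(d$alt)
  alt[alt %in% c("-", ".")] <- ""
  if (any(ref == alt)) {
    stop("ref equals alt at line(s): ",
         paste(line_no[ref == alt], collapse = ", "))
  }
  if (any(!grepl("^[ACGT]+$", ref))) {
    stop("invalid ref allele at line(s): ",
         paste(line_no[!grepl("^[ACGT]+$", ref)], collapse = ", "))
  }
  dataset <- d$dataset
  unknown <- !(dataset %in% .DATASETS)
  if (any(unknown)) {
    warning("unknown dataset label(s) ",
            paste(unique(dataset[unknown]), collapse = ", "),
            " mapped to 'unlabeled'")
    dataset[unknown] <- "unlabeled"
  }
  zyg <- d$zygosity
  zyg[!(zyg %in% .ZYGOSITIES)] <- "unknown"
  score <- suppressWarnings(as.numeric(ifelse(d$score %in% c("NA", ""),
                                              NA, d$score)))
  bad_score <- !is.na(score) & (score < 0 | score > 1)
  if (any(bad_score)) {
    stop("damage score outside [0,1] at line(s): ",
         paste(line_no[bad_score], collapse = ", "))
  }
  rec <- data.frame(id = d$id, contig = d$contig, pos = pos, ref = ref,
                    alt = alt, dataset = dataset, zygosity = zyg,
                    score = score, stringsAsFactors = FALSE)
  if (!is.null(genome)) {
    for (i in seq_len(nrow(rec))) {
      g <- genome_fetch(genome, rec$contig[i], rec$pos[i],
                        rec$pos[i] + nchar(rec$ref[i]) - 1L)
      if (g != rec$ref[i]) {
        stop("line ", line_no[i], ": ref allele ", rec$ref[i],
             " does not match genome (", g, ") at ", rec$contig[i], ":",
             rec$pos[i])
      }
    }
  }
  rec
}

#' Write a mutation table
#'
#' Inverse of [read_mutation_table()]: the write/read round trip is lossless.
#'
#' @param records mutation record data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mutation_table <- function(records, path) {
  d <- records[, c("id", "contig", "pos", "ref", "alt", "dataset",
                   "zygosity", "score")]
  d$score <- ifelse(is.na(d$score), "NA", format(d$score, digits = 15))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# constructor used by generators/tests
.mutation_record <- function(id, contig, pos, ref, alt,
                             dataset = "unlabeled", zygosity = "unknown",
                             score = NA_real_) {
  data.frame(id = id, contig = contig, pos = as.integer(pos), ref = ref,
             alt = alt, dataset = dataset, zygosity = zygosity,
             score = score, stringsAsFactors = FALSE)
}
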