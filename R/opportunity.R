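# Enumerate, per transcript, every sense-strand single-base substitution in
# the CDS together with its coding consequence, plus the critical splice
# junction substitutions.  This table is the substrate for the opportunity
# counts and for the in-silico mutagenesis sampler.
#
# Columns: gene, contig, pos (genomic), strand, region ("cds"/"splice"),
# sense_from, sense_to, category.
.site_consequences <- function(models, genome,
                               code = Biostrings::GENETIC_CODE) {
  .warn_on_overlaps(models)
  alt_sets <- lapply(.BASES, function(b) setdiff(.BASES, b))
  names(alt_sets) <- .BASES
  out <- vector("list", length(models))
  for (k in seq_along(models)) {
    m <- models[[k]]
    s <- sense_cds_seq(m, genome)
    cds_pos <- .cds_positions(m)
    n_codon <- nchar(s) %/% 3L
    L <- 3L * n_codon
    chars <- strsplit(substr(s, 1L, L), "")[[1]]
    codon_of <- rep(seq_len(n_codon), each = 3L)
    off_of <- rep(1:3, times = n_codon)
    codons <- substring(s, 3L * seq_len(n_codon) - 2L, 3L * seq_len(n_codon))
    valid <- !grepl("N", codons, fixed = TRUE)
    aa1 <- rep(NA_character_, n_codon)
    aa1[valid] <- unname(code[codons[valid]])

    keep <- which(chars %in% .BASES & valid[codon_of])  # N positions skipped
    if (length(keep)) {
      i3 <- rep(keep, each = 3L)
      to <- unlist(alt_sets[chars[keep]], use.names = FALSE)
      codon_new <- codons[codon_of[i3]]
      substr(codon_new, off_of[i3], off_of[i3]) <- to
      aa2 <- unname(code[codon_new])
      a1 <- aa1[codon_of[i3]]
      category <- ifelse(a1 == aa2, "synonymous",
                  ifelse(codon_of[i3] == 1L & codons[codon_of[i3]] == "ATG",
                         "start_loss",
                  ifelse(aa2 == "*", "nonsense",
                  ifelse(a1 == "*", "make_sense", "missense"))))
      cds_tab <- data.frame(
        gene = m$gene, contig = m$contig, pos = cds_pos[i3],
        strand = m$strand, region = "cds",
        sense_from = chars[i3], sense_to = to, category = category,
        stringsAsFactors = FALSE)
    } else {
      cds_tab <- NULL
    }

    intr <- .introns(m)
    spl_tab <- NULL
    if (nrow(intr)) {
      # the four critical bases of each intron: donor 1-2, acceptor 1-2
      if (m$strand == "+") {
        dpos <- c(intr[, 1L], intr[, 1L] + 1L)
        apos <- c(intr[, 2L] - 1L, intr[, 2L])
      } else {
        dpos <- c(intr[, 2L], intr[, 2L] - 1L)
        apos <- c(intr[, 1L] + 1L, intr[, 1L])
      }
      pos <- c(dpos, apos)
      side <- rep(c("donor", "acceptor"), each = length(dpos))
      base <- .sense_base(m, .genome_base(genome, m$contig, pos))
      ok <- base %in% .BASES
      if (any(ok)) {
        i3 <- rep(which(ok), each = 3L)
        to <- unlist(alt_sets[base[ok]], use.names = FALSE)
        spl_tab <- data.frame(
          gene = m$gene, contig = m$contig, pos = pos[i3],
          strand = m$strand, region = "splice",
          sense_from = base[i3], sense_to = to,
          category = paste0("critical_splice_", side[i3]),
          stringsAsFactors = FALSE)
      }
    }
    out[[k]] <- rbind(cds_tab, spl_tab)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.warn_on_overlaps <- function(models) {
  if (length(models) < 2L) return(invisible(0L))
  sp <- do.call(rbind, lapply(models, function(m) {
    s <- .gene_span(m)
    data.frame(contig = m$contig, start = s[1L], end = s[2L])
  }))
  n_overlap <- 0L
  for (ctg in unique(sp$contig)) {
    d <- sp[sp$contig == ctg, ]
    d <- d[order(d$start), ]
    if (nrow(d) > 1L) {
      n_overlap <- n_overlap + sum(d$start[-1L] <= d$end[-nrow(d)])
    }
  }
  if (n_overlap > 0L) {
    warning(n_overlap, " overlapping chosen transcript pair(s); ",
            "shared positions are counted once per transcript")
  }
  invisible(n_overlap)
}

#' Enumerate substitution opportunities over a transcript set
#'
#' Counts, for each of the twelve sense-strand substitution types, every
#' position-by-alternative-base event that would alter coding sense
#' (missense, nonsense, make-sense or start-loss; synonymous changes do not
#' count) and every substitution of the four critical splice-junction bases
#' of each intron (all three alternatives count, no coding filter).  Terminal
#' stop codons are part of the CDS and contribute make-sense opportunities.
#' Positions whose codon contains `N` are skipped.  Overlapping chosen
#' transcripts are counted once per transcript, with a warning.
#'
#' @param models named list of validated `transcript_model`s, one per gene.
#' @param genome an `enu_genome`.
#' @param code genetic code.
#' @return An `opportunity_table`: data.frame with columns `substitution`,
#'   `coding`, `splice`, `total` (12 rows, alphabetical type order).
#' @seealso [null_probabilities()]
#' @export
enumerate_opportunities <- function(models, genome,
                                    code = Biostrings::GENETIC_CODE) {
  tab <- .site_consequences(models, genome, code)
  types <- substitution_types()
  sub <- .sub_type(tab$sense_from, tab$sense_to)
  coding <- table(factor(sub[tab$region == "cds" &
                                tab$category != "synonymous"],
                         levels = types))
  splice <- table(factor(sub[tab$region == "splice"], levels = types))
  as_opportunity_table(data.frame(
    substitution = types,
    coding = as.integer(coding),
    splice = as.integer(splice),
    stringsAsFactors = FALSE))
}

#' Coerce per-type counts to an opportunity table
#'
#' @param df data.frame with columns `substitution`, `coding`, `splice`
#'   (and optionally `total`).
#' @return An `opportunity_table` with `total` recomputed as
#'   `coding + splice`.
#' @export
as_opportunity_table <- function(df) {
  stopifnot(all(c("substitution", "coding", "splice") %in% names(df)))
  types <- substitution_types()
  if (!setequal(df$substitution, types)) {
    stop("opportunity table must have exactly the 12 substitution types")
  }
  df <- df[match(types, df$substitution),
           c("substitution", "coding", "splice")]
  df$total <- df$coding + df$splice
  rownames(df) <- NULL
  class(df) <- c("opportunity_table", "data.frame")
  df
}

#' @export
print.opportunity_table <- function(x, ...) {
  cat("Substitution opportunities (sense strand)\n")
  y <- as.data.frame(x)
  y <- rbind(y, data.frame(substitution = "Total",
                           coding = sum(x$coding), splice = sum(x$splice),
                           total = sum(x$total)))
  print(y, row.names = FALSE)
  invisible(x)
}

#' Binomial null probabilities from an opportunity table
#'
#' For each substitution type `s`, the null probability that a mutation of
#' the `s`-or-complement pair falls on the sense strand is the proportion of
#' opportunities carried by `s`:
#' `p(s) = N_total(s) / (N_total(s) + N_total(complement(s)))`,
#' so that `p(s) + p(complement(s)) = 1`.  A zero pair denominator yields
#' `NA` with a message.
#'
#' @param table an `opportunity_table`.
#' @return Named numeric vector over the 12 substitution types.
#' @export
null_probabilities <- function(table) {
  stopifnot(inherits(table, "opportunity_table"))
  tot <- setNames(table$total, table$substitution)
  comp <- complement_substitution(names(tot))
  denom <- tot + tot[comp]
  p <- ifelse(denom > 0, tot / denom, NA_real_)
  if (anyNA(p)) {
    message("zero pair denominator for: ",
            paste(names(p)[is.na(p)], collapse = ", "))
  }
  setNames(as.numeric(p), names(tot))
}
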