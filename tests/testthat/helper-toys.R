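# Hand-drawn toy genes and independent oracles shared across the suite.

# single-exon plus-strand gene, CDS "ATGAAATGA" (M K *), at 1..9 of chrT
toy_plus <- function() {
  genome <- new_genome(list(chrT = "ATGAAATGA"))
  model <- transcript_model("gA", "gA.t1", "chrT", "+",
                            exons = cbind(1L, 9L), cds = cbind(1L, 9L))
  list(genome = genome, models = list(gA.t1 = validate_transcript(model, genome)))
}

# two-exon plus-strand gene with intron spanning 7..106:
# exon1 = 1..6 ("ATGAAA"), exon2 = 107..112 ("TGGTAA"); CDS M K W *
toy_two_exon <- function() {
  intron <- paste0("GT", strrep("C", 96), "AG")
  genome <- new_genome(list(chrT = paste0("ATGAAA", intron, "TGGTAA")))
  model <- transcript_model("gB", "gB.t1", "chrT", "+",
                            exons = rbind(c(1L, 6L), c(107L, 112L)),
                            cds = rbind(c(1L, 6L), c(107L, 112L)))
  list(genome = genome, models = list(gB.t1 = validate_transcript(model, genome)))
}

# mirror a toy: reverse-complement every contig and flip all coordinates and
# strands, so classification must be equivariant
mirror_toy <- function(genome, models) {
  lens <- attr(genome, "lengths")
  g2 <- new_genome(lapply(genome, function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))))
  flip <- function(m, L) cbind(L - m[, 2L] + 1L, L - m[, 1L] + 1L)
  m2 <- lapply(models, function(m) {
    L <- lens[[m$contig]]
    validate_transcript(transcript_model(
      m$gene, m$transcript, m$contig,
      ifelse(m$strand == "+", "-", "+"),
      flip(m$exons, L), flip(m$cds, L), m$phase), g2)
  })
  list(genome = g2, models = m2)
}

# mirror a genomic SNV record along with the toy
mirror_mutation <- function(mut, genome) {
  L <- attr(genome, "lengths")[[mut$contig]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  list(id = mut$id, contig = mut$contig, pos = L - mut$pos + 1L,
       ref = unname(comp[mut$ref]), alt = unname(comp[mut$alt]))
}

# Independent opportunity oracle: mutate every CDS position to every base,
# re-translate the WHOLE coding sequence with Biostrings, and string-compare
# the proteins.  Splice opportunities are recounted from the exon structure.
oracle_opportunities <- function(models, genome) {
  types <- substitution_types()
  coding <- setNames(integer(12), types)
  splice <- setNames(integer(12), types)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (m in models) {
    s <- sense_cds_seq(m, genome)
    L <- 3L * (nchar(s) %/% 3L)
    s <- substr(s, 1L, L)
    wt <- as.character(Biostrings::translate(Biostrings::DNAString(s),
                                             no.init.codon = TRUE))
    variants <- character(0)
    vtypes <- character(0)
    for (i in seq_len(L)) {
      from <- substr(s, i, i)
      for (to in setdiff(c("A", "C", "G", "T"), from)) {
        variants <- c(variants,
                      paste0(substr(s, 1L, i - 1L), to,
                             substr(s, i + 1L, L)))
        vtypes <- c(vtypes, paste0(from, ">", to))
      }
    }
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(variants), no.init.codon = TRUE))
    changed <- vtypes[aa != wt]
    add <- table(factor(changed, levels = types))
    coding <- coding + as.integer(add)
    ex <- m$exons
    if (nrow(ex) > 1L) {
      istart <- ex[-nrow(ex), 2L] + 1L
      iend <- ex[-1L, 1L] - 1L
      crit <- c(istart, istart + 1L, iend - 1L, iend)
      for (p in crit) {
        b <- substr(genome[[m$contig]], p, p)
        if (m$strand == "-") b <- unname(comp[b])
        for (to in setdiff(c("A", "C", "G", "T"), b)) {
          ty <- paste0(b, ">", to)
          splice[ty] <- splice[ty] + 1L
        }
      }
    }
  }
  data.frame(substitution = types, coding = as.integer(coding),
             splice = as.integer(splice),
             total = as.integer(coding + splice),
             stringsAsFactors = FALSE)
}

# opportunity counts expressed in a strand-FIXED frame (the genomic plus
# strand): each minus-strand gene's sense types complement.  Under genome
# mirroring this table must complement exactly, while the sense-space table
# is invariant (the coding strand is a physical property of each gene).
genomic_opportunities <- function(models, genome) {
  types <- substitution_types()
  tot <- setNames(integer(12), types)
  for (m in models) {
    one <- suppressWarnings(
      enumerate_opportunities(setNames(list(m), m$transcript), genome))
    key <- if (m$strand == "-") complement_substitution(one$substitution)
      else one$substitution
    tot[key] <- tot[key] + one$total
  }
  tot
}

# two-sided Fisher probability by direct hypergeometric summation: total
# probability of all tables as or less probable than the one observed
oracle_fisher2x2 <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0L, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}
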