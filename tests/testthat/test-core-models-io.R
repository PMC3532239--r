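test_that("FASTA genomes load, fetch and normalise case", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chrT", "ATGAAATGA", ">chrU", "atgtggtaa"), fa)
  g <- load_genome(fa)
  expect_equal(attr(g, "lengths")[["chrT"]], 9L)
  expect_equal(genome_fetch(g, "chrT", 4, 6), "AAA")
  # lowercase input is fetched uppercase; oracle is a plain text slice
  expect_equal(genome_fetch(g, "chrU", 1, 9), toupper("atgtggtaa"))
  expect_equal(genome_fetch(g, "chrU", 4, 6, strand = "-"),
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString("TGG"))))
  expect_error(genome_fetch(g, "chrZ", 1, 3), "unknown contig")
  expect_error(genome_fetch(g, "chrT", 5, 12), "out of bounds")
})

test_that("duplicate contigs and empty FASTA are rejected", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">c1", "ACGT", ">c1", "ACGT"), fa)
  expect_error(load_genome(fa), "duplicate contig")
  fa2 <- withr::local_tempfile(fileext = ".fa")
  writeLines(character(0), fa2)
  expect_error(load_genome(fa2))
})

test_that("reverse complement of reverse complement is the identity", {
  toy <- make_toy_transcriptome(n_genes = 3, seed = 21)
  s <- genome_fetch(toy$genome, "chr1", 11, 60)
  rc <- function(x) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(x)))
  expect_equal(rc(rc(s)), s)
})

test_that("GFF3 round trip preserves transcript structure", {
  toy <- toy_two_exon()
  d <- withr::local_tempdir()
  fa <- write_genome_fasta(toy$genome, file.path(d, "g.fa"))
  gff <- write_transcripts_gff3(toy$models, file.path(d, "a.gff3"))
  g2 <- load_genome(fa)
  m2 <- load_transcripts(gff, g2)
  expect_length(m2, 1L)
  m <- m2[[1]]
  expect_equal(nrow(m$exons), 2L)
  expect_equal(nrow(m$cds), 2L)
  expect_equal(unname(m$exons), unname(toy$models[[1]]$exons))
  expect_true(m$complete)
})

test_that("minus-strand sense CDS equals the reverse-complement oracle", {
  toy <- make_toy_transcriptome(n_genes = 6, seed = 7, p_minus = 1)
  for (m in toy$models) {
    genomic <- paste(vapply(seq_len(nrow(m$cds)), function(i) {
      genome_fetch(toy$genome, m$contig, m$cds[i, 1], m$cds[i, 2])
    }, character(1)), collapse = "")
    oracle <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(genomic)))
    expect_equal(sense_cds_seq(m, toy$genome), oracle)
    # a complete minus-strand model translates M...* with no internal stop
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAString(sense_cds_seq(m, toy$genome))))
    expect_equal(substr(aa, 1, 1), "M")
    expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1L)))
  }
})

test_that("structural violations are errors naming the transcript", {
  expect_error(
    transcript_model("g", "tX", "c", "+",
                     exons = rbind(c(1, 10), c(5, 20)),
                     cds = cbind(1, 10)),
    "tX.*overlapping|overlapping.*tX")
  expect_error(
    transcript_model("g", "tY", "c", "+", exons = cbind(1, 10),
                     cds = cbind(5, 15)),
    "tY")
  toy <- toy_plus()
  bad <- transcript_model("g", "tZ", "chrZ", "+", cbind(1, 9), cbind(1, 9))
  expect_error(validate_transcript(bad, toy$genome), "unknown contig")
})

test_that("incomplete CDS lengths attach a validation warning, not an error", {
  genome <- new_genome(list(c1 = "ATGAAATG"))
  m <- transcript_model("g", "t", "c1", "+", cbind(1, 8), cbind(1, 8))
  m <- validate_transcript(m, genome)
  expect_false(m$complete)
  expect_match(m$warnings, "multiple of 3", all = FALSE)
})

test_that("longest-CDS selection keeps one transcript per gene", {
  genome <- new_genome(list(c1 = strrep("ACGT", 200)))
  mk <- function(tx, len) transcript_model("g1", tx, "c1", "+",
                                           cbind(1L, len), cbind(1L, len))
  long <- mk("t.long", 300L); short <- mk("t.short", 150L)
  sel <- select_longest_cds(list(t.long = long, t.short = short))
  expect_equal(names(sel), "t.long")
  # single-transcript gene unchanged
  expect_equal(names(select_longest_cds(list(t.long = long))), "t.long")
  # ties break lexicographically, independent of input order
  a <- mk("t.a", 150L); b <- mk("t.b", 150L)
  expect_equal(names(select_longest_cds(list(t.b = b, t.a = a))), "t.a")
  expect_equal(names(select_longest_cds(list(t.a = a, t.b = b))), "t.a")
})

test_that("mutation tables round-trip losslessly", {
  rec <- data.frame(id = c("m1", "m2", "m3"), contig = "chrT",
                    pos = c(4L, 9L, 2L), ref = c("A", "A", "T"),
                    alt = c("T", "G", "C"),
                    dataset = c("phenotypic", "incidental", "unlabeled"),
                    zygosity = c("hom", "het", "unknown"),
                    score = c(0.99, NA, 0.5), stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_mutation_table(rec, path)
  back <- read_mutation_table(path)
  expect_equal(back, rec)
  expect_true(is.na(back$score[2]))
})

test_that("malformed mutation rows are rejected with line numbers", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tcontig\tpos\tref\talt\tdataset\tzygosity\tscore",
               "m1\tchrT\t4\tA\tA\tphenotypic\thom\tNA"), path)
  expect_error(read_mutation_table(path), "ref equals alt.*2")
  writeLines(c("id\tcontig\tpos\tref\talt\tdataset\tzygosity\tscore",
               "m1\tchrT\tfour\tA\tT\tphenotypic\thom\tNA"), path)
  expect_error(read_mutation_table(path), "non-integer pos.*2")
  writeLines(c("id\tcontig\tpos\tref\talt\tdataset\tzygosity\tscore",
               "m1\tchrT\t4\tA\tT\tweird\thom\tNA"), path)
  expect_warning(out <- read_mutation_table(path), "unlabeled")
  expect_equal(out$dataset, "unlabeled")
  # reference checked against the genome when one is supplied
  toy <- toy_plus()
  writeLines(c("id\tcontig\tpos\tref\talt\tdataset\tzygosity\tscore",
               "m1\tchrT\t4\tC\tT\tphenotypic\thom\tNA"), path)
  expect_error(read_mutation_table(path, toy$genome), "does not match")
})

test_that("transcript TSV dialect round-trips", {
  toy <- make_toy_transcriptome(n_genes = 3, seed = 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_transcripts_tsv(toy$models, path)
  back <- load_transcripts(path, toy$genome)
  expect_equal(names(back), names(toy$models))
  for (nm in names(back)) {
    expect_equal(unname(back[[nm]]$exons), unname(toy$models[[nm]]$exons))
    expect_equal(back[[nm]]$strand, toy$models[[nm]]$strand)
    expect_true(back[[nm]]$complete)
  }
})
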