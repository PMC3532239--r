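# expected codon/residue changes below were derived with a standard codon
# table by hand (CDS "ATGAAATGA" = M K *; "ATGAAA|intron|TGGTAA" = M K W *)

.rec <- function(id, pos, ref, alt, dataset = "phenotypic") {
  data.frame(id = id, contig = "chrT", pos = pos, ref = ref, alt = alt,
             dataset = dataset, zygosity = "unknown", score = NA_real_,
             stringsAsFactors = FALSE)
}

test_that("coding substitutions classify by codon change", {
  toy <- toy_plus()
  m <- toy$models[[1]]

  nonsense <- classify_mutation(list(id = "m1", contig = "chrT", pos = 4,
                                     ref = "A", alt = "T"), m, toy$genome)
  expect_equal(nonsense$category, "nonsense")
  expect_equal(nonsense$codon_from, "AAA")
  expect_equal(nonsense$codon_to, "TAA")
  expect_equal(nonsense$aa_from, "K")
  expect_equal(nonsense$aa_to, "*")
  expect_equal(nonsense$aa_pos, 2L)
  expect_true(nonsense$overt_null)

  makesense <- classify_mutation(list(id = "m2", contig = "chrT", pos = 9,
                                      ref = "A", alt = "G"), m, toy$genome)
  expect_equal(makesense$category, "make_sense")
  expect_equal(makesense$codon_from, "TGA")
  expect_equal(makesense$codon_to, "TGG")
  expect_equal(makesense$aa_to, "W")
  expect_equal(makesense$aa_pos, 3L)
  expect_false(makesense$overt_null)

  syn <- classify_mutation(list(id = "m3", contig = "chrT", pos = 6,
                                ref = "A", alt = "G"), m, toy$genome)
  expect_equal(syn$category, "synonymous")  # AAA -> AAG, both K

  start <- classify_mutation(list(id = "m4", contig = "chrT", pos = 2,
                                  ref = "T", alt = "C"), m, toy$genome)
  expect_equal(start$category, "start_loss")  # ATG -> ACG, M1T
  expect_equal(start$aa_to, "T")
  expect_false(start$overt_null)
})

test_that("splice windows classify by distance from the exon boundary", {
  toy <- toy_two_exon()
  m <- toy$models[[1]]
  cls <- function(pos, ref, alt, ...) {
    classify_mutation(list(id = "x", contig = "chrT", pos = pos, ref = ref,
                           alt = alt), m, toy$genome, ...)
  }
  don2 <- cls(8, "T", "A")  # second intronic base after the donor boundary
  expect_equal(don2$category, "critical_splice_donor")
  expect_equal(don2$splice_distance, 2L)
  expect_true(don2$overt_null)

  don5 <- cls(11, "C", "A")  # fifth intronic base
  expect_equal(don5$category, "noncritical_splice_donor")
  expect_equal(don5$splice_distance, 5L)
  expect_false(don5$overt_null)

  acc2 <- cls(105, "A", "G")
  expect_equal(acc2$category, "critical_splice_acceptor")
  expect_equal(acc2$splice_distance, 2L)
  expect_true(acc2$overt_null)

  acc7 <- cls(100, "C", "T")
  expect_equal(acc7$category, "noncritical_splice_acceptor")
  expect_equal(acc7$splice_distance, 7L)

  deep <- cls(50, "C", "T")
  expect_equal(deep$category, "deep_intronic")

  # the window is a configuration knob
  expect_equal(cls(100, "C", "T", window = 5L)$category, "deep_intronic")
  expect_equal(cls(50, "C", "T", window = 50L)$category,
               "noncritical_splice_donor")
})

test_that("splice distances follow transcript orientation", {
  toy <- toy_two_exon()
  m <- toy$models[[1]]
  expect_equal(splice_distance(7, m), list(distance = 1L, side = "donor",
                                           intron = 1L))
  expect_equal(splice_distance(106, m),
               list(distance = 1L, side = "acceptor", intron = 1L))
  expect_error(splice_distance(3, m), "not intronic")
  # mirrored gene: the genomically-rightmost intron base adjacent to a CDS
  # exon becomes donor position 1
  mir <- mirror_toy(toy$genome, toy$models)
  m2 <- mir$models[[1]]
  L <- attr(toy$genome, "lengths")[["chrT"]]
  expect_equal(splice_distance(L - 7 + 1, m2),
               list(distance = 1L, side = "donor", intron = 1L))
  expect_equal(splice_distance(L - 106 + 1, m2),
               list(distance = 1L, side = "acceptor", intron = 1L))
})

test_that("minus-strand substitution types are reported on the sense strand", {
  toy <- toy_plus()
  mir <- mirror_toy(toy$genome, toy$models)
  # genomic pos 4 A>T on the plus gene mirrors to a T>A genomic change that
  # must classify identically with sense type A>T
  mut <- list(id = "m", contig = "chrT", pos = 4, ref = "A", alt = "T")
  mmut <- mirror_mutation(mut, toy$genome)
  call <- classify_mutation(mmut, mir$models[[1]], mir$genome)
  expect_equal(call$category, "nonsense")
  expect_equal(call$sense_sub, "A>T")
  # a genomic C>T inside a minus-strand CDS is a sense G>A
  expect_equal(mmut$ref, "T")
  g_ct <- which(strsplit(mir$genome[["chrT"]], "")[[1]] == "C")[1]
  call2 <- classify_mutation(list(id = "m2", contig = "chrT", pos = g_ct,
                                  ref = "C", alt = "T"),
                             mir$models[[1]], mir$genome)
  expect_equal(substr(call2$sense_sub, 1, 1), "G")
  expect_equal(substr(call2$sense_sub, 3, 3), "A")
})

test_that("indels classify structurally", {
  toy <- toy_plus()
  m <- toy$models[[1]]
  del1 <- classify_mutation(list(id = "d1", contig = "chrT", pos = 4,
                                 ref = "A", alt = ""), m, toy$genome)
  expect_equal(del1$category, "frameshift")
  expect_true(del1$overt_null)
  del3 <- classify_mutation(list(id = "d3", contig = "chrT", pos = 4,
                                 ref = "AAA", alt = ""), m, toy$genome)
  expect_equal(del3$category, "inframe_indel")
  expect_false(del3$overt_null)
  ins1 <- classify_mutation(list(id = "i1", contig = "chrT", pos = 4,
                                 ref = "A", alt = "AG"), m, toy$genome)
  expect_equal(ins1$category, "frameshift")
})

test_that("reference mismatches and out-of-range positions are errors", {
  toy <- toy_plus()
  m <- toy$models[[1]]
  expect_error(classify_mutation(list(id = "m", contig = "chrT", pos = 4,
                                      ref = "C", alt = "T"), m, toy$genome),
               "does not match")
  expect_error(classify_mutation(list(id = "m", contig = "chrT", pos = 99,
                                      ref = "A", alt = "T"), m, toy$genome),
               "outside contig")
})

test_that("codons containing N are unresolvable", {
  genome <- new_genome(list(c1 = "ATGANATGA"))
  m <- validate_transcript(transcript_model("g", "t", "c1", "+",
                                            cbind(1, 9), cbind(1, 9)),
                           genome)
  call <- classify_mutation(list(id = "m", contig = "c1", pos = 6,
                                 ref = "A", alt = "G"), m, genome)
  expect_equal(call$category, "unresolvable")
  expect_false(call$overt_null)
})

test_that("classification partitions gene-span substitutions exhaustively", {
  toy <- make_toy_transcriptome(n_genes = 3, seed = 31)
  for (m in toy$models) {
    span <- range(m$exons)
    pos <- seq(span[1], span[2])
    for (p in pos[seq(1, length(pos), by = 5L)]) {
      ref <- genome_fetch(toy$genome, m$contig, p, p)
      alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
      call <- classify_mutation(list(id = "m", contig = m$contig, pos = p,
                                     ref = ref, alt = alt), m, toy$genome)
      expect_false(is.na(call$category))
      expect_equal(call$overt_null,
                   call$category %in% c("frameshift", "nonsense",
                                        "critical_splice_donor",
                                        "critical_splice_acceptor"))
    }
  }
})

test_that("classification is strand-equivariant under genome mirroring", {
  set.seed(42)
  toy <- make_toy_transcriptome(n_genes = 3, seed = 13)
  mir <- mirror_toy(toy$genome, toy$models)
  for (m in toy$models) {
    span <- range(m$exons)
    pos <- sample(seq(span[1], span[2]), 25L)
    for (p in pos) {
      ref <- genome_fetch(toy$genome, m$contig, p, p)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
      mut <- list(id = "m", contig = m$contig, pos = p, ref = ref, alt = alt)
      a <- classify_mutation(mut, m, toy$genome)
      b <- classify_mutation(mirror_mutation(mut, toy$genome),
                             mir$models[[m$transcript]], mir$genome)
      expect_equal(b$category, a$category)
      expect_equal(b$sense_sub, a$sense_sub)
      expect_equal(b$splice_distance, a$splice_distance)
    }
  }
})

test_that("classify_batch summarises, continues past errors, and reports ratios", {
  toy <- make_toy_transcriptome(n_genes = 5, seed = 17)
  req <- data.frame(
    category = c("missense", "synonymous", "nonsense",
                 "critical_splice_donor", "noncritical_splice_acceptor",
                 "frameshift"),
    dataset = "phenotypic", n = 1L)
  ms <- make_mutation_set(toy$models, toy$genome, req, seed = 18)
  out <- classify_batch(ms, toy$models, toy$genome)
  expect_s3_class(out, "consequence_set")
  expect_equal(nrow(out$calls), 6L)
  expect_setequal(out$calls$category, req$category)
  expect_equal(nrow(out$summary), 6L)

  # empty batch
  empty <- classify_batch(ms[0, ], toy$models, toy$genome)
  expect_equal(nrow(empty$calls), 0L)
  expect_equal(nrow(empty$summary), 0L)

  # a bad record does not abort the batch
  bad <- ms
  bad$ref[1] <- setdiff(c("A", "C", "G", "T"),
                        c(bad$ref[1], bad$alt[1]))[1]
  expect_warning(mixed <- classify_batch(bad, toy$models, toy$genome),
                 "failed")
  expect_equal(nrow(mixed$calls), 5L)
  expect_length(mixed$errors, 1L)

  # ratio rendering matches the published convention
  r <- overt_null_ratios(59, 122)
  expect_equal(r$ratio_label, "1 : 2.07")
})

test_that("start-loss is folded into missense in category summaries", {
  toy <- toy_plus()
  muts <- rbind(
    .rec("a", 2, "T", "C"),   # start loss
    .rec("b", 5, "A", "T"))   # missense K2I
  out <- classify_batch(muts, toy$models, toy$genome)
  expect_setequal(out$calls$category, c("start_loss", "missense"))
  expect_equal(out$summary$category, "missense")
  expect_equal(out$summary$n, 2L)
})
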