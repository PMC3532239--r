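---
title: "Methods: ENU mutation spectra, strand asymmetry, and missense detectability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ENU mutation spectra, strand asymmetry, and missense detectability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enuspectra)
```

## The problem

N-ethyl-N-nitrosourea (ENU) is the workhorse germline mutagen of mouse
forward genetics.  It induces essentially random single base-pair
substitutions; a screen then recovers two kinds of mutations: *phenotypic*
mutations, proven to cause an observed phenotype, and *incidental*
mutations, found by sequencing but not known to cause anything.  Comparing
the two sets answers questions the screen itself cannot: how strongly does
ENU favour particular substitutions and strands, which amino-acid exchanges
are damaging, and - the headline inference - what fraction of missense
mutations is detectable as phenotype at all.  This package implements that
comparison as a tested pipeline, exercisable end to end on synthetic
transcriptomes and on the published count tables that ship with it.

## Consequence classification

Every mutation is classified against one chosen coding transcript per gene
(the longest CDS; ties break to the lexicographically smallest transcript
id so the choice is order-independent).  Coordinates are 1-based inclusive
genomic positions, the GFF3 convention; strand is applied at classification
time, so stored records remain strand-agnostic.

The category ladder for a single-base substitution:

1. **Critical splice** - the first two intronic bases at either intron end
   (the canonical `GT`/`AG` dinucleotides), donor side 5' of the intron in
   transcript orientation.  Splice distance 1 is the first intronic base.
2. **Non-critical splice** - intronic positions 3 to `window` (default 10,
   matching the convention that coding-adjacent mutations are tallied
   "within the ten proximal or distal bases of each intron").  The window
   is a configuration knob because documented splice-affecting alleles
   occur out to 17 bp on the acceptor side.
3. **Coding change** - synonymous, missense, nonsense (residue to stop),
   make-sense (stop to residue), or start-loss (the initiator `ATG`
   mutated away from methionine).
4. **Deep intronic / intergenic** otherwise.

Indels and multi-nucleotide substitutions are classified structurally
(`frameshift` when the net length change is not a multiple of 3, otherwise
`inframe_indel`) and excluded from substitution-spectrum tallies, mirroring
the exclusion of large deletions and dinucleotide substitutions from the
published single-base sets.  Codons containing `N` classify as
`unresolvable` and are skipped by the enumerator - a conservative choice;
the source data never exercises it.

The **overt null** flag is true exactly for frameshift, nonsense and
critical-splice calls: alleles with a high prior of abolishing protein
function.  Start-loss is kept as its own category on calls but folded into
missense in Table-style summaries, where published per-allele lists place
M1 substitutions.  Novel splice-site *creation* (e.g. a donor created 57 bp
into an exon) is an experimental finding, not something a distance rule can
predict; such records are not auto-classified.

Two properties anchor the test suite: classification is equivariant under
mirroring the genome (reverse-complement plus coordinate flip), and the
overt-null flag equals category membership on every random batch.

## Opportunity enumeration and the strand-asymmetry null

Whether a substitution type is "overrepresented" on the sense strand is
judged against opportunity, not uniformity.  For each of the 12
sense-strand types `s`, the enumerator counts every CDS position x
alternative base whose substitution alters coding sense (missense,
nonsense, make-sense, start-loss - not synonymous) plus every substitution
of the four critical splice-junction bases of each intron (all three
alternatives count there; no coding filter applies).  Terminal stop codons
are inside the CDS, so make-sense opportunities are included.  Overlapping
chosen transcripts are counted once per transcript, with a logged overlap
count.

The null probability for the pair `{s, complement(s)}` is

$$p(s) = \frac{N(s)}{N(s) + N(\bar s)},$$

because a sense-strand `T>C` is an antisense `A>G`: under the null that
both strands are equally valid targets, the sense-strand count of `s` is
binomial with this `p`.  The observed test is the exact lower tail

$$P = \Pr[X \le k], \qquad X \sim \mathrm{Binomial}(n = k + k(\bar s),\ p(s)),$$

computed by direct log-space summation of the probability mass (no normal
approximation), with the focal type always the purine-reference member of
the pair.  The upper tail and a doubled-smaller-tail two-sided value are
emitted alongside for transparency.

Two numerical notes discovered while reproducing the published table.
First, the printed `P` columns were evidently computed with the 4-decimal
*rounded* `p` column: the cells with enough printed digits to tell (e.g.
0.1202, 0.6600) match the rounded-p computation exactly and the unrounded
computation only to 3 significant figures.  Second, two printed cells for
the A>G/T>C pair do not follow the lower-tail convention that reproduces
every other cell: the incidental entry (0.9425) equals the *upper* tail and
the combined entry (0.00322) is closest to a doubled smaller tail.  The
package reports its own lower-tail values and documents the discrepancy
rather than matching those two cells.

At genome scale the enumeration requires a real transcriptome; the packaged
genome-wide opportunity table stands in for it, and the enumerator itself
is verified on toy transcriptomes against an independent oracle that
mutates every position, re-translates the whole CDS and string-compares the
proteins.  On mirrored toys the sense-space table is reproduced unchanged
(the coding strand is a physical property of each gene) while the table
expressed in the strand-fixed genomic frame complements exactly.

## Amino-acid change combinatorics

Walking the 9 single-base neighbours of all 64 codons of the standard code
yields 150 distinct residue-to-residue exchange types, 10 residue-to-stop,
10 stop-to-residue, 6 start-codon eliminations (`ATG` to I, L, V, K, T, R)
and, symmetrically, 6 start-codon creations: 182 in total under the
convention that counts the start classes in both directions, as the stop
classes are.  The per-class breakdown is always printed because the
published total (182) does not state its class decomposition; the breakdown
makes any convention mismatch visible immediately.  Phenotypic and
incidental exchange spectra are compared per type with a two-sided exact
test on the 2x2 table (type vs rest, by dataset) at an unadjusted 0.05 -
no correction, matching the descriptive use of the comparison.

## The detectability estimator

Overt null alleles are enriched among phenotypic mutations because that set
is conditioned on causing phenotype.  If phenotypically *detectable*
alleles of every class are enriched by the same factor, then with
$f_p$ and $f_i$ the overt-null fractions of the phenotypic and incidental
sets,

$$E = f_p / f_i, \qquad \hat f_d = 1/E$$

estimates the fraction of missense alleles whose effect is detectable by
the screens in use.  On the published counts (59/181 vs 28/402) the direct
chain gives $E = 4.680$ and $\hat f_d = 21.4\%$; the published 4.70 and
21.3% arise from rounding the intermediate percentages (32.57%, 6.94%)
before dividing.  The package always computes the unrounded chain and
prints 3-significant-figure renderings alongside.

Uncertainty comes from a nonparametric bootstrap - resampling mutation
labels with replacement within each dataset, which for a binary label
reduces to binomial resampling of the two overt counts - with percentile
intervals (default 1000 replicates, seeded).

**What parameter recovery does and does not validate.**  The recovery
harness generates synthetic sets under the estimator's own generative
assumption: the phenotypic overt fraction equals $f_i / f_d$ (the published
numbers satisfy this identity: $6.97\%/0.213 \approx 32.6\%$).  Under that
model the estimator is consistent, bias vanishes with set size, and the
bootstrap interval covers truth at its nominal rate - this validates the
estimation and resampling machinery.  It deliberately does not validate the
equal-enrichment assumption itself: under a fully causal simulation in
which the phenotypic set is the detected mutations and the incidental set
reflects the raw sequencing spectrum, $1/E$ estimates the *mean*
detectability of the qualifying classes, $q + m f_d$ with $q$ the overt
and $m$ the missense spectrum fractions - an upward-biased estimate of
$f_d$ whenever $q > 0$.  With the observed $q \approx 0.07$ the bias is a
few points; it is inherent to the published inference, not to this
implementation.

Damage-score summaries treat PolyPhen-2-style scores purely as input data.
Two denominators are reported for the damaging fraction because the
published 37.9% divides by all 330 incidental missense mutations while the
specificity argument divides by the 317 with assignable scores.  The
expected damaging count is printed in both floor and round-half renderings:
$0.213 \times 317 = 67.52$, and the published 67 corresponds to the floor
(equivalently to carrying the unrounded $1/4.70$), giving the specificity
bound $67/125 \approx 54\%$.

## In-silico mutagenesis and saturation

The simulator draws coding-region mutation events per G1 genome from a
Poisson with mean 30 - the standard expectation that a gamete carrying
~3000 genomic mutations at roughly one per Mbp yields ~30 coding changes.
Each event draws a sense-strand substitution type from configurable weights
(default: proportional to the combined observed spectrum, 525 single-base
changes) and then a position uniformly among the transcript set's sites
whose sense base matches, so strand asymmetry enters through per-gene
orientation rather than a mechanistic transcription-coupled-repair model,
and the aggregate simulated spectrum converges to the weights by
construction (verified by chi-square goodness of fit at $10^5$ events).

Each event is classified by the consequence module, flagged
phenotype-causing with per-class probabilities (overt null 1.0, missense
and start-loss $f_d = 0.213$, make-sense likewise, non-critical splice 0
by default - the published inference concerns missense only - synonymous
0), and exposed (rendered homozygous in at least one screened G3) with
probability $1 - (1 - p_{hom})^{G3}$.  Defaults: $p_{hom} = 1/8$ under the
backcross scheme (a G2 daughter carries a given G1 mutation with
probability 1/2 and her G3 offspring is homozygous with probability 1/4
given that); the intercross alternative gives 1/16; 12 screened G3 per
pedigree, the ratio of the ~100,000 screened G3 to ~8,000 pedigrees of the
source program.  Saturation is the fraction of genes with at least one
detectable, exposed mutation in the screened population; because events
are Poisson and thinning is independent, per-gene saturation has the
closed form $1 - \exp(-\lambda_g)$, which the test suite uses as an
independent oracle (with per-gene $\lambda_g$ assembled from a brute-force
classification of every eligible site).

A mutation that is flagged and exposed lands in the simulated phenotypic
set, everything else in the incidental set.  As discussed above, that
causal partition is reported as-is; it is not forced to make the
enrichment estimator exact.

## Synthetic data

Toy transcriptomes emulate exactly the structure the pipeline depends on:
complete ORFs (`ATG` ... in-frame stop), `GT`..`AG` introns of at least 20
bp (so the critical and non-critical windows of the two intron ends never
collide), multi-exon genes on both strands, configurable GC content, all
deterministic under a seed.  They deliberately lack UTRs, realistic
chromosome structure, repeats, CpG context and the GC-flanking bias of real
ENU data - so green tests demonstrate correctness of the computations, not
fidelity of any mutational model to real genomes.

Mutation sets with known ground truth are built by sampling candidate
positions from a full enumeration of the toy and re-classifying every
sampled mutation; a disagreement between generator and classifier is an
error, so emitted labels are true by construction (closed loop).

## Numerical and design choices

- Exact binomial tails by log-space summation; verified against the
  reference distribution function for all $n \le 30$ and on published
  cells.
- Equidistant intronic positions (odd-length introns) resolve to the donor
  side; generated introns are long enough that this never affects critical
  or windowed calls.
- `p(s)` is undefined (reported `NA`, pair not testable) on a zero pair
  denominator; strand tests with $n = 0$ are marked not testable rather
  than returning a degenerate probability.
- Fixture integrity is checked against embedded totals; note the published
  combined spectrum column sums to 525 although its printed total row says
  527, and the genome-wide opportunity table's printed total row counts
  sites while its 12 type rows count position-by-alternative events.
- Test problem sizes: 50 random toy transcriptomes (up to 10 genes each)
  for the enumeration oracle sweep; 200 replicate experiments of 20,000
  mutations for estimator recovery and bootstrap coverage; $10^5$ simulated
  events for spectrum conservation - sizes chosen to make binomial /
  Monte-Carlo error small relative to the tolerances being checked.

## Limitations

The classifier handles coding and splice-window consequences only: UTR and
non-coding-transcript effects are out of scope, and splice-strength scoring
is not attempted.  The opportunity model has no trinucleotide or CpG
context - it is a strand-asymmetry null, not a mutation-rate model.  The
simulator keeps no pedigree-level Mendelian bookkeeping beyond the
homozygosity probability and no phenotype-assay noise model; "detectable"
is a Bernoulli flag, whereas real detection depends on assay sensitivity.
The detectability estimate inherits the equal-enrichment assumption of the
published inference, with the ascertainment caveat spelled out above.
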