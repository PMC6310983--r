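---
title: "Surveying non-canonical splice sites from genome annotations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surveying non-canonical splice sites from genome annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Spliceosomal introns almost always start with GT and end with AG on the
coding strand. Annotated genomes nevertheless contain a small fraction of
introns with other border dinucleotides: the major non-canonical
combinations GC-AG and AT-AC, and a long tail of minor combinations. Some
of these are real, functionally used splice sites; many are artifacts of
sequencing, assembly, annotation or read alignment. `ncsplice` implements
a survey pipeline that, given a genome (FASTA) and its annotation (GFF3),

* classifies the border combination of every CDS-flanked intron of each
  gene's representative transcript,
* relates a combination's frequency to its divergence from GT-AG,
* validates annotated splice sites against per-base RNA-Seq coverage,
* quantifies splice-site usage,
* flags combinations that are alignment artifacts of an equivalent,
  shifted intron placement (the CA-GG / GC-AG ambiguity), and
* compares the substitution spectrum implied by minor combinations with
  genome-wide substitution rates from a VCF.

A seeded synthetic-data generator produces genomes, annotations, coverage
tracks and VCFs with a complete ground-truth manifest, so every stage is
testable without external data.

## Classification model

A *splice-site combination* is the 4-letter string donor dinucleotide +
acceptor dinucleotide, read 5'&rarr;3' on the coding strand in DNA letters
(GT-AG, not GU-AG). The 256 unambiguous combinations partition into one
canonical (GT-AG), two major non-canonical (GC-AG, AT-AC) and 253 minor
non-canonical combinations; any combination containing a non-A/C/G/T IUPAC
code is *ambiguous* and is masked from diversity statistics (it still
counts toward per-sample totals, tracked separately as
`ambiguous_masked`, so either denominator convention can be computed).

Only introns lying between consecutive CDS segments of the
*representative transcript* are analysed: UTR structure is less reliably
annotated and is ignored entirely. The representative transcript is the
one encoding the longest polypeptide; because genes whose CDS length is
not a multiple of 3 are filtered out beforehand, total CDS nucleotide
length is an equivalent and simpler criterion. Equal-length ties are
broken by the lexicographically smallest transcript ID so the choice is
deterministic and order-independent.

Genes with apparent annotation errors are removed before extraction, with
per-reason accounting: no CDS, CDS out of sequence bounds, overlapping
CDS segments, total length not a multiple of 3, or an internal stop codon
in the strand-aware conceptual translation. This is the minimal rule set
under which the translation-based checks downstream are well defined.

All statistics use introns of at least `min_intron_length = 20` nt;
shorter gaps are still extracted and inspectable but never counted.

### Coordinates

Internally all intervals are 1-based and closed, the R/Bioconductor and
GFF3 convention, so annotation coordinates pass through unchanged and
`GRanges`/`Biostrings` operations need no conversion. BED and BedGraph
files are converted from their 0-based half-open convention at the I/O
boundary.

## Coverage validation and usage

RNA-Seq support is judged from four per-base depths around each intron:
the terminal exonic base and the first intronic base at the donor (5')
side, and the mirror pair at the acceptor (3') side; on the minus strand
the donor maps to the genomic right end. A site is *supported* when depth
drops by at least `min_drop = 0.2` (20%) stepping from exon into intron;
a combination is supported when both of its sites are. *Usage* is
`1 - intron_depth / exon_depth`, clipped to [0, 1], so that "supported"
is exactly "usage &ge; 0.2". With zero exonic depth the site is
unsupported with reason `no_expression` and undefined usage, and
validation ratios are reported both excluding and including such cases.
A relative tolerance of 1e-9 on the threshold comparison keeps the exact
boundary case (intron depth equal to 80% of exon depth) supported in
floating-point arithmetic.

Depth is read at single bases (the four positions), not windows; the
coverage track is a plain per-base expansion of a BedGraph file, with
uncovered positions at depth 0 and conflicting overlapping rows rejected.

## Shift-equivalent placements

Two intron placements that differ by a shift of *s* nt at both boundaries
produce the identical mature mRNA exactly when the *s* exonic bases given
up at one end equal the *s* intronic bases exposed at the other. Such
placements are indistinguishable to a spliced aligner, which is how a
GC-AG intron can be annotated as CA-GG when an extra G follows the
acceptor. `detect_shift_equivalence` enumerates shifts within
`max_shift = 3` nt, verifies mRNA identity, and reports every equivalent
placement with its combination; placements whose combination is canonical
or major are the diagnostic of interest. Note that repeated context can
make several placements equivalent at once (the bundled CA-GG example
also admits a minor GG-TA placement at shift &minus;2); the diagnosis
counts the canonical/major ones.

## Statistics

* **Divergence vs frequency.** One observation per unambiguous
  combination (n = 256): Hamming distance to GT-AG against the count
  pooled across species profiles. GT-AG itself (distance 0) is included;
  a normalised per-species mode is available. The observation unit is the
  256 pooled combinations, which is consistent with the magnitude of the
  p-values such surveys report.
* **Spearman correlations** everywhere use average ranks for ties and the
  two-sided t-approximation p-value (`stats::cor.test`, `exact = FALSE`).
  Every rank correlation in the package is tested against an independent
  rank-then-Pearson oracle.
* **Profile similarity** is the Spearman correlation of two species'
  256-long count vectors; zero-variance profiles give missing entries.
* **Length comparisons** draw `reps = 100` equal-size background samples
  without replacement and run a two-sided rank-sum (Mann-Whitney)
  test per replicate; the summary reports the median p-value and mean of
  mean differences. For independent samples the rank-sum form is the
  appropriate "Wilcoxon test". Calibration is assessed on the
  per-replicate rejection fraction, whose null expectation is the nominal
  level; a median-p decision rule would be deliberately conservative.
* **Long-intron enrichment** compares minor-combination frequencies in
  introns above vs below 5 kb with Laplace pseudocounts of 1 (avoiding
  division by zero for rare combinations), ranks by the ratio with
  lexicographic tie-break, and reports the base composition along the
  ranking.
* **Spectrum comparison** uses a Pearson chi-square with expected counts
  = observed total &times; genome-wide relative rates over the 12 ordered
  substitutions (unconditional on the ancestral base; conditioning is a
  caller-side variation). Minor combinations are assigned to the closest
  of GT-AG, GC-AG, AT-AC by Hamming distance with the preference order
  GT-AG &gt; GC-AG &gt; AT-AC on ties — the globally most frequent origin
  is the most probable one. Reported p-values are floored at the smallest
  representable double rather than printed as 0. For variant overlaps,
  majority-allele ties count as alternative-majority (conservative
  against the reference).

## The synthetic generator

`generate_genome()` emulates the *shape* of an annotated plant genome as
this kind of survey consumes it:

* genes tiled on chromosome sequences with random spacer DNA, an even
  strand mix, 1–8 CDS-flanked introns per gene (uniform; mean 4.5, near
  the 4–5 typical of plant annotations);
* CDS built from a start codon, non-stop codons and a stop codon, so the
  annotation passes the gene filter with zero losses unless error
  injection (out-of-bounds CDS, internal stops, border ambiguity
  characters) is switched on;
* intron lengths from a log-normal body with its mode near 200 nt plus a
  configurable heavy tail beyond 5 kb (1% by default) — the parameters
  are configuration, not claims about any particular genome;
* border combinations drawn from the class composition 98.7 / 1.2 / 0.06
  / 0.09 % (GT-AG / GC-AG / AT-AC / minor; weights normalised to sum
  to 1), the average composition reported across sequenced plant genomes.
  Minor combinations are uniform by default, or divergence-graded
  (probability &prop; 3^&minus;d with d the distance to GT-AG) to emulate
  the observed frequency gradient;
* per-intron spliced fractions *s* for coverage simulation: exonic depth
  at `exon_depth`, intronic depth `exon_depth * (1 - s)`, either
  deterministic or Poisson;
* homozygous biallelic SNPs drawn from a 12-category substitution
  spectrum at positions matching the reference base, avoiding splice-site
  border bases so planted spectra and planted splice sites never
  interact.

`simulate_species_profiles()` additionally emulates many species at the
count level only: per-species totals drawn log-uniformly over the span
observed across plant genomes (about 1.5&times;10^3 to 3.7&times;10^5
splice sites), and per-species log-normal jitter (sd 0.5) on the
non-canonical class weights to mimic between-species variation in
non-canonical content.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: sequencing and assembly errors, pseudogenes,
alternative isoforms and UTR introns, base-composition structure of real
genes, phylogenetic correlation between species, non-uniform exon
lengths, alignment artifacts (other than the explicit shift-equivalence
construction) and expression heterogeneity across genes. Results on real
genomes depend on annotation quality in ways the generator cannot probe.

## Determinism and problem sizes

Every stochastic function takes an explicit seed, saves and restores the
global RNG state, and produces byte-identical outputs under a fixed seed
and configuration. The test and acceptance workloads use 10,000 genes
(about 50,000 introns) for the genome-scale round trip, 121 simulated
species for profile statistics, 1,000 seeded trials at 10 replicates for
the null calibration of the length comparison, and 10,000 planted SNPs
for spectrum recovery — sizes at which the binomial/multinomial 3-SE
bands used in the checks are tight enough to be informative while the
whole suite runs in minutes on one CPU.

## Known limitations

* Only CDS-flanked introns of one transcript per gene are surveyed;
  genuine non-canonical sites in UTRs or minor isoforms are invisible.
* Coverage validation uses depth drops at four single bases; it cannot
  distinguish intron retention from overlapping transcription, and needs
  externally computed coverage tracks (BAM processing is out of scope).
* The chi-square comparison treats splice-site substitutions as
  independent draws from the genome-wide process; linked substitutions
  within one combination violate independence mildly.
* `read_coverage` materialises per-base vectors; for chromosome-scale
  tracks memory grows linearly with genome size.

## A minimal session

```{r example}
library(ncsplice)

sim <- run_simulate(generator_config(n_genes = 200, seed = 1), "demo")
cls <- run_classify(sim$paths$fasta, sim$paths$gff3, "demo/classify",
                    species = "synthetic")
val <- run_validate(cls$introns, sim$paths$coverage, "demo/validate")
sub <- run_substitution(sim$paths$vcf, cls$introns, "demo/substitution")

profile_composition(cls$profile)
val$ratios
sub$chisq
```
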