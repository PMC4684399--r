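---
title: "Methods: somatic screening statistics for tumor/normal capture panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: somatic screening statistics for tumor/normal capture panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelscreen)
```

# Scope and model

`panelscreen` re-implements, as a tested pipeline, the statistics used in
targeted-capture mutation screens of paired tumor/normal samples: a
small panel of cancer genes (coding exons, UTRs, upstream regions) is
deep-sequenced in both a tumor and its matched normal, variants are called
jointly, and the analysis asks (i) which calls are somatic and how
trustworthy they are, (ii) what each does to the protein, (iii) which are
already known in a somatic-mutation catalogue, (iv) whether the mutational
spectrum differs between coding and non-coding targeted sequence once base
composition is accounted for, and (v) which genes carry high-level copy
number changes.

The package operates downstream of alignment and genotype-likelihood
computation: its inputs are per-site paired variant calls (VCF with GT and
AD), labeled target regions (BED), a reference (FASTA), gene models,
a catalogue table, and windowed tumor/normal coverage.

# Somatic classification

Calls are first screened by GATK-style hard filters. SNVs and MNVs fail on
`QUAL < 40`, `QD < 5.0`, `HRun > 5` or `FS > 200.0`; insertions and
deletions on `QUAL < 40`, `QD < 2.0`, `ReadPosRankSum < -20.0` or
`FS > 200.0`. All comparisons are strict, so a value exactly at a threshold
passes; a missing annotation passes its criterion, mirroring the semantics
of `value < threshold` being false for an absent value. Calls below the
emit threshold (`QUAL < 10`) are rejected outright.

A call is *somatic* when the tumor genotype includes the alternate allele
while the normal genotype is homozygous reference. Somatic calls are
*high confidence* when they pass the hard filters and the read evidence
satisfies: normal informative depth (AD ref + alt) at least 10, at most one
alternate-supporting read in the normal, and at least three in the tumor.
Everything else somatic is *low confidence* — a tier that published
validation data shows is mostly noise (about a quarter of low-confidence
candidates validate, versus ~94% of high-confidence ones), which is why all
downstream spectrum statistics use high-confidence variants only.

"Informative read depth" is taken as the AD sum rather than the DP field;
DP after caller-internal read filters is not reproducible from a VCF alone,
the AD sum is.

# Effect categories

Effects are resolved against transcript models. CDS substitutions are
judged by translating the affected codon(s) on the coding strand before and
after the change (same amino acids: synonymous; new stop: stopgain; lost
stop: stoploss; otherwise nonsynonymous); CDS indels by length divisibility
by three. Variants within 2 bp inside an intron of a coding transcript are
splicing (the canonical donor/acceptor dinucleotide; configurable).
Remaining variants classify by region: UTR5, UTR3, upstream (within
1000 bp 5' of the transcription start), intronic, ncRNA for non-coding
transcripts, else intergenic. When a variant touches several transcripts
the most severe category wins; the order places frameshifts highest, then
nonframeshift indels, stopgain, stoploss, nonsynonymous, splicing,
synonymous, and the regional categories. (A naive reading of the category
vocabulary would rank synonymous above stopgain because summary tables
list it earlier; that is a table-layout order, not a severity order, and
this package deliberately uses the biological one.)

Non-silent mutations are exonic indels, nonsynonymous, stopgain, stoploss
and splicing variants.

# Catalogue matching

Matching a call set against a COSMIC-style catalogue requires a canonical
variant representation: both sides are normalized by converting `-` alleles
to anchored form, trimming shared bases, and left-aligning indels against
the reference, so representation differences (anchor choice, position
within a repeat) cannot defeat an exact match. Two loose criteria recover
matches that exact comparison misses: a *shifted* match (same alleles
within < 5 bp; flagged `context_supported` when the intervening reference
is a homopolymer or tandem repeat, `positional_only` otherwise) and a
*split MNV* match (a catalogue multi-nucleotide substitution reconstructed
from adjacent SNV calls, as unified genotypers sometimes emit them). A
variant with no exact or loose match is *novel*.

# Spectrum and enrichment statistics

Substitutions are collapsed to the six pyrimidine-centered classes
(`C>A, C>G, C>T, T>A, T>C, T>G`, reported in paired notation such as
`C/G>T/A`), and trinucleotide contexts to the 32 collapsed `X[Y]Z` forms.
The *coding* stratum is CDS bases only; *non-coding* is every other
targeted base, with class precedence CDS > UTR5 > UTR3 > upstream >
intronic flank resolving bases covered by overlapping designs. The 30 bp
intronic flanks used at variant-calling time are counted in the non-coding
denominator by default (configurable) — the design question of whether
flank bases belong to the targeted territory has no clean answer, and
including them matches how the variants themselves were called.

Mutation frequencies are composition-normalized: for a substitution class
the denominator is the stratum's G/C (or A/T) base count, each base counted
once regardless of coverage; for a context it is the count of windows whose
center lies in the stratum (flanks may extend outside). For each class or
context a 2x2 table (mutated vs eligible-minus-mutated, coding vs
non-coding, pooled over samples) gives an odds ratio `(a/b)/(c/d)`, a 95%
Woolf interval `exp(log OR ± 1.96·SE)` with
`SE = sqrt(1/a + 1/b + 1/c + 1/d)`, and a raw p-value from the Wald test of
the stratum coefficient in a binomial logistic model on the aggregated
counts (numerically the 2x2 Wald test). Bonferroni adjustment multiplies
by the family size — 6 for classes, 32 for contexts by default, the set of
simultaneously reported comparisons. A stratum-by-sample interaction
likelihood-ratio test is reported as a heterogeneity diagnostic; the
headline OR remains the pooled one because one OR per class is the
quantity of interest and six samples give the interaction test little
power.

Zero cells leave the OR flagged undefined rather than raising an error —
rare contexts legitimately have no mutations in one stratum.

Numerical caveat: the Wald p and Fisher's exact p agree closely only where
the normal approximation is valid. With all cells of moderate size and the
exact p away from the deep tail the two differ by well under 10%; in deep
tails they diverge without bound (the Wald statistic is conservative
there), so the test suite checks their agreement in the valid regime and
the package makes no claim of exactness for extreme tables.

# Copy number

Per-window log ratios are `log2((tumor·s + 0.5)/(normal + 0.5))` with `s`
the total-depth library scaling; windows with normal depth below 20 are
removed first. An optional GC correction subtracts the median log ratio
per GC decile. Segmentation is a deliberately simple greedy merge —
adjacent windows join a segment while the window's value is within 0.4 of
the running segment mean, and the segment value is the unweighted mean of
its member windows — standing in for heavier segmentation machinery;
externally segmented tracks are accepted verbatim. On a small panel with a
large planted event the total-depth scaling visibly shifts the neutral
baseline (a fraction of a copy at toy scale); at realistic panel sizes the
shift is negligible, and the gene-call thresholds (|log2| > 2) leave ample
margin either way.

Gene calls use strict thresholds: a gene (summed exon length > 400 bp) is
an *amplification* when every exon's covering-segment mean exceeds +2, and
a *homozygous deletion* when a pass-threshold (< -2) region of at least
400 bp overlaps at least one exonic base. Consecutive below-threshold
segments are coalesced before the 400 bp span test, so a deletion
fragmented by segmentation noise still counts by its spanned length — the
rule is about the extent of the deleted region, not about one segment
object. The 400 bp gene-size rule is evaluated on summed exon length
(the spanned transcript length would make the rule depend on intron sizes
the capture never sees).

Cross-platform concordance pairs each segment's genomic midpoint with the
covering segment of the comparison track and reports a Pearson
correlation, with uncovered midpoints dropped and counted.

# The synthetic cohort generator

Every stage is testable without external data because the generator emits
the exact formats the readers consume, plus ground truth. Its defaults are
the emulated study's conditions: six tumor/normal pairs; per-gene structure
of 300 bp upstream, a 5'UTR, coding exons with introns, and the leading
portion of the 3'UTR; stratum GC targets 51.1% (coding) and 47.0%
(non-coding), hit by stop-codon-aware base flipping to within ±0.01;
somatic SNV burdens of 20.6/Mbp coding and 8.7/Mbp non-coding; class
proportions chosen once so that the implied coding spectrum has a G/C
replacement share of 76.4% and Ti/Tv 0.94, and the non-coding spectrum
61.0% and ~1.3; a germline heterozygous SNP rate of 8e-4 per targeted base
with transition probability 0.727 (known-SNP Ti/Tv 2.66); mean depths 127x
tumor / 98x normal (Poisson, or negative binomial when a dispersion is
set); and 15% of somatic plants given deliberately low-confidence evidence
(shallow normal, thin tumor support, or a failing QD). CDS sequences are
built codon-wise from the 61 sense codons, so toy genes have genuine open
reading frames with start/stop codons and no internal stops.

Planted variants map one-to-one onto emitted VCF records; a configurable
fraction is copied into a synthetic catalogue along with position-shifted
and split-MNV decoys that exercise the loose matcher. CNV events scale
tumor depth by `2^log2` across a gene's transcript.

What the generator does *not* emulate — alignment artifacts, strand bias,
mapping ambiguity in repeats, contamination, subclonality — bounds what
passing tests show: they validate the statistics and bookkeeping on data
that satisfies the model assumptions, not robustness to upstream artifacts
in real sequencing.

# Test and verification design

Problem sizes were chosen to keep the full suite under a minute while
leaving the statistical checks well-powered: classifier oracle equivalence
on 10^4 randomized boundary-stressing calls against an independent
straight-line transcription of the rules; effect categories against
brute-force whole-CDS retranslation on 10^3 random coding mutations, with a
mirror-image minus-strand construct checking strand handling exhaustively;
OR/CI against the closed-form 2x2 formulas at 1e-9; planted relative risks
rho in {1, 2, 4} recovered with >= 90% CI coverage over 200 count-level
replicates (~500 mutations each), plus one full VCF-level cohort at
rho = 2; and CNV recovery of all planted >= 400 bp events with no false
calls and truth-track concordance r >= 0.95 over 20 replicates at 100x.
The acceptance script regenerates its cohorts at the study's panel scale
(1,237 genes) from the seed it is given.

The published worked numbers that the package reproduces (pooled and
per-category somatic counts, validation concordance rates) are recomputed
from shipped per-sample count tables through the same aggregation code the
pipeline uses; one cell of the shipped table resolves an off-by-one
internal inconsistency in its source in favor of the printed marginal
totals.

# Known limitations

* The segmenter is a stand-in; breakpoint placement inside long gradual
  events is crude, and the merge tolerance (0.4) is tuned for single-copy
  scale events at ~100x.
* Logistic-regression p-values are asymptotic; for contexts with very few
  mutations the Woolf CI is wide and the Wald p should not be
  over-interpreted (the Bonferroni family compounds this conservatively).
* The effect annotator handles one transcript model per gene as shipped by
  the generator; multi-isoform severity resolution is supported but only
  lightly exercised.
* Catalogue loose matching bounds the shift window at < 5 bp; larger
  caller-vs-catalogue discrepancies (long-indel representation drift) are
  reported as novel.
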