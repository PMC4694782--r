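---
title: "Methods: dimeric motif scanning and p53-dependent expression calling"
author: "p53response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dimeric motif scanning and p53-dependent expression calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis

p53 responds to DNA damage by binding a dimeric response element — two
decameric half sites of consensus RRRCWWGYYY, adjacent ("unsplit") or
separated by a short spacer — and by reprogramming transcription. This
package implements the joint analysis of both layers after ionizing
radiation (IR): where p53 binds (ChIP-seq peaks), whether a response
element underlies each site and in what geometry, what chromatin context
the site sits in, which genes respond to IR and whether that response
requires p53 (wild type versus knockout), and finally how motif geometry
crosses with regulatory mode — the intersection that defines a "core"
p53-activated program shared between cell types.

All stages run end to end on synthetic data with known ground truth, so
every claim the test suite makes is a measured recovery of a planted
signal, not a fixture comparison.

# Peak enrichment

Enrichment of a called peak is the log2 background-subtracted signal,

$$E = \log_2\!\big(\mathrm{rpm}_{\mathrm{ChIP}} - \mathrm{rpm}_{\mathrm{input}}\big),$$

with both read counts expressed as reads per million of library reads.
Both terms must be on the per-million scale: applied to raw count
fractions the difference is a number near zero and the log is a large
negative artifact. When the ChIP signal does not exceed the input the
enrichment is *undefined* (NA) and the peak is excluded from rankings —
an epsilon floor would instead park those peaks at an arbitrary rank.

# The dimeric motif model

A width-20 PWM is split into its two decameric half sites, and an array
of spacer variants is built: for spacer $s \in \{0,\dots,15\}$, a PWM of
width $20+s$ whose central $s$ columns equal the background
distribution. Because a background column contributes
$\log_2(p/p_{bg}) = 0$ to every sequence, two things follow:

* the score of any variant is the sum of the two half-site scores at
  offset $i$ and $i + 10 + s$, so one pass over the half-site score
  vectors scans all 16 variants; and
* every variant shares one null score distribution, so a single
  dynamic-programming table serves the whole array.

## Exact match p-values

The null distribution of the log-odds score under the i.i.d. background
is computed by dynamic programming: each column's four log-odds values
are rounded to a lattice of width `granularity` (default 1e-4 bits) and
the per-column mass functions are convolved. The p-value of a score is
the upper tail of that distribution. Scores are *measured on the same
lattice* — the scanner sums the rounded per-column values — so hit
p-values are exact under the method's scoring convention. For a
free-floating query score the result is bracketed by the exact tails at
the query ± width × granularity; the test suite asserts both the exact
lattice agreement against brute-force enumeration (all $4^w$ sequences,
widths 4–8) and the float bracket.

Scanning takes the 600 bases flanking each peak summit (summit ± 300 bp;
the flank is configurable because "600 bases flanking" admits both
readings), scans both strands, and keeps the single hit with the lowest
p-value below the threshold. The threshold defaults to 1e-4 per match —
the conventional per-match cutoff of PWM scanners — with no correction
across positions, which is the standard per-match semantics; a
`report_all` flag emits every passing hit for multiple-copy summaries.
Ties are broken by smaller spacer, then smaller offset, then + strand,
so results are reproducible. N bases contribute zero bits, hence
N-padded chromosome edges can never create hits. The best hit's spacer
classifies the peak: `UNSPLIT` (spacer 0), `SPACED` (1–15), `NO_MOTIF`
(no passing hit).

Note one consequence of per-match semantics: a 600 bp window offers
~1,100 positions × 2 strands × 16 correlated variants, so motif-free
windows still produce a passing hit at an appreciable rate (~30% at the
default threshold). Recovery guarantees in the tests are therefore
stated for planted unsplit/spaced sites (whose true hits have far lower
p-values than spurious ones), not for the absence calls.

# De novo discovery (ZOOPS-EM)

Discovery runs on the summit-flanking sequences of the most enriched
peaks (default top 1000; 120 bp windows — discovery benefits from
trimming to the well-centred signal, and the narrower window keeps the
posterior landscape clean). The model is ZOOPS: each sequence carries
zero or one site, on either strand, at a uniform position prior, with
i.i.d. background elsewhere. EM restarts (default 10) are seeded
deterministically from the run seed, each initialising the PWM from a
random width-20 subsequence smoothed with pseudocount 0.5. The M-step is
the pure maximum-likelihood update (with a 1e-9 floor only to keep logs
finite): any M-step pseudocount would break the guarantee that the
observed-data log-likelihood is non-decreasing, which this
implementation asserts at every iteration. After the best restart
converges, EM is retried from ±1/2-column shifted initialisations and
any higher-likelihood phase is kept — EM on motif models is prone to
off-register local optima, and this shift polish reliably recovers the
aligned frame. Strand is fundamentally unidentifiable, so recovered
consensus sequences are compared to planted ones up to reverse
complement. Information content (relative to uniform background) is
reported instead of MEME-style E-values.

# Chromatin classification

Promoters are strand-aware −5 kb/+2 kb windows around each TSS, clamped
to the chromosome. A peak overlapping any promoter window is
`PROMOTER`; otherwise a peak overlapping any H3K4me1 peak is
`ENHANCER`; everything else is `UNMARKED_DISTAL`. Promoter precedence is
part of the enhancer definition (H3K4me1-positive *and not* promoter);
enhancer precedence over unmarked follows from "everything else". The
whole peak interval is used for overlap (≥1 bp, configurable); a
`summit_only` flag restricts the query to the summit base since the
original convention is not recoverable from the definitions alone.

# Expression

RPKM uses exon-mapped totals:
$\mathrm{rpkm} = c \cdot 10^9 / (L_\mathrm{exon} \cdot N_\mathrm{exon})$.

The differential-expression engine is deliberately a transparent
simplified stand-in for a full NB GLM framework, and externally computed
DE tables (gene_id, log2fc, qvalue) can be imported in its place.
Within one genotype, IR versus mock:

* library sizes by median-of-ratios size factors;
* log2 fold change of group means with pseudo-mean 0.5;
* gene-wise NB dispersion by the method of moments within groups,
  pooled, floored at 1e-8;
* a Wald statistic on the log2 scale (delta method), referred to a
  *t* distribution with $n_1+n_2-2$ degrees of freedom. The t reference
  is the one non-obvious choice: with four replicates the plug-in
  variance is noisy and a normal reference is visibly anticonservative;
  the t correction brings the null rejection rate at 0.05 to ~0.05,
  which the suite verifies on a 10,000-gene null simulation;
* BH adjustment across genes passing an independent-filter floor of
  mean normalised count ≥ 1.

DEGs require q < 0.05, |log2FC| > 0.58 and RPKM > 1 in at least one
sample — all strict inequalities. A wild-type DEG is *p53-dependent*
when its fold change exceeds the knockout's by a factor of at least 1.5
on the linear scale (`2^(wt−ko) ≥ 1.5` for up-regulation, mirrored for
down); "at least" is read inclusively. Genes missing from the knockout
contrast take `ko_log2fc = 0` — no measured response — which biases
toward dependence; the convention is explicit and replaceable because
the original handling of such genes is not derivable from the
definitions.

Sample structure is summarised by average-linkage hierarchical
clustering of 1 − Spearman's ρ over expressed genes (RPKM > 1 in ≥ 1
sample); the linkage method is a configurable choice (rank correlations
tolerate the heavy-tailed RPKM scale, average linkage avoids single-link
chaining). Samples are ordered by id before clustering so the tree is
deterministic. Gene-set enrichment is the one-sided Fisher
(hypergeometric) test over sets holding more than 10 and fewer than
2,000 genes within the universe.

# Integration and the core response

A gene is *bound* when ≥1 peak overlaps its promoter window; among
several, the peak with the lowest motif p-value wins (then highest
enrichment, then name), and the gene inherits that single peak's motif
class — keeping the per-gene categories a partition rather than a
multiset. The mode × motif-class cross-tab, per-category fold-change
summaries (pooled t, singletons excluded from testing but reported), and
the two-cell-type intersection of genes that are UP-dependent and bound
via the unsplit element follow directly.

# The synthetic-data generators

Every generator is a pure function of its configuration: each stage
seeds the RNG from the master seed plus a fixed offset, so reruns are
byte-identical (the determinism check hashes a full rerun's manifest).
Defaults, chosen once as the study conditions:

| parameter | default | role |
|---|---|---|
| `n_peaks` | 500 | binding sites; one 16 kb locus each, so promoter windows of neighbouring loci cannot collide and chromatin classes are recoverable exactly |
| `gc_content` | 0.42 | mammalian-like background |
| `class_fractions` | 0.40 / 0.30 / 0.30 | promoter / enhancer / unmarked |
| motif rates per class | ~0.20–0.35 unsplit, 0.15–0.20 spaced | within the frequency ranges binding-site surveys report |
| `chip_rpm` | 60 / 35 / 15 (unsplit / spaced / none), input 5 | plants the enrichment ordering; lognormal noise sdlog 0.25 |
| `n_genes`, `fraction_null` | 2000, 0.7 | responsive genes split evenly across the four modes |
| effects (wt, ko) | UP_DEP 4, 1; UP_INDEP 3, 3; DOWN mirrored | fold changes under IR |
| `dispersion`, `n_replicates` | 0.05, 4 | negative-binomial counts |

The planted motif is the bundled dimeric RRRCWWGYYY model with 0.49/0.49
on degenerate positions and 0.97 on the invariant C/G — sharp enough
that sampled sites rarely carry two strong mismatches, i.e. planted
sites are actually recoverable at the default threshold, which is the
condition the recovery benchmarks state. A `consensus_only` switch
plants the exact consensus for exact-recovery designs (used by the
two-cell-type core test). Spacers are uniform on 1–15 nt. Peak read
counts are Poisson (overdispersion adds nothing at toy scale); gene
counts are negative binomial because the DE test assumes them.

For two cell types the generator reserves a shared core of genes that
own an unsplit-motif promoter peak and the UP_DEP mode in *both* cell
types, per-cell-type private equivalents, and draws the remaining
responsive genes from disjoint per-cell-type pools — so the planted
truth of the intersection is exactly the core.

What the generator does **not** emulate: read-level noise and mapping
artifacts (counts are drawn, not aligned), GC or fragment-length bias,
overlapping or nested binding sites, non-i.i.d. genomic background
(repeats, CpG islands), and correlated gene–gene expression. Passing
tests therefore demonstrate that the machinery is correct and calibrated
under its stated model, not that thresholds transfer unchanged to real
libraries.

# Numerical choices and degenerate inputs

* p-value lattice 1e-4 bits; hit p-values exact under the lattice
  convention; float queries conservative within ± width × granularity.
* Quintiles rank ascending (Q5 = most enriched), remainder peaks go to
  the lowest bins, boundary ties break by peak name.
* `overlap_fraction` is peak-wise (a peak counts once however many
  partners it touches) on half-open intervals.
* Undefined enrichment propagates as NA and excludes the peak from
  ranking; it is a value, not an error.
* Zero-variance groups in pairwise t comparisons: identical constant
  groups give t = 0, p = 1; separated constant groups give p = 0 (the
  pooled statistic is computed in closed form rather than delegated, so
  the degenerate cases are defined).
* EM convergence at log-likelihood gain < 1e-6; restarts and site
  posteriors are deterministic given the seed.
* Test and acceptance problem sizes (500 peaks, 10,000-gene null,
  2,200-gene dependence design, 500-sequence discovery, ~100–500-peak
  pipelines) are the package's chosen benchmark scale: large enough for
  the stated tolerances, small enough to run anywhere.

# Known limitations

The DE stand-in has no shrinkage, no outlier handling and no GLM — with
two or three replicates its dispersion estimates are crude, and real
analyses should import an external DE table. Per-match scanning
semantics imply a floor of spurious spaced hits in long windows (see
above); absence of a motif call is weak evidence. Discovery fits one
motif of fixed width under ZOOPS only. The gene-set test takes sets as
given, with no ontology structure.
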