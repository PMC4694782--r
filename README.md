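# p53response

Integrated analysis of p53 genomic binding and p53-dependent
transcription after ionizing radiation (IR), for computational
biologists who have ChIP-seq peak calls, chromatin-mark peak sets and an
RNA-seq count matrix from a wild-type / *Trp53*-null × mock / IR design
— or who want a fully synthetic, ground-truthed replica of such a study
to validate methods against.

## What it computes

**Binding layer.** Peak enrichment is the log2 background-subtracted
signal, `log2(ChIP_rpm − input_rpm)`, with both counts in reads per
million of library reads (undefined, and excluded from rankings, when
the difference is not positive). The p53 response element is modelled
as a dimeric PWM — two decameric half sites of consensus `RRRCWWGYYY` —
expanded into an array of 16 variants with a 0–15 nt background spacer
between the halves. The 600 bases flanking each peak summit are scanned
on both strands; match p-values are exact upper tails of the null score
distribution computed by dynamic programming (`P(score' ≥ s)` under the
i.i.d. background), and each peak keeps its single lowest-p hit, giving
it a motif class: `UNSPLIT` (spacer 0), `SPACED` (1–15 nt) or
`NO_MOTIF`. A ZOOPS-EM module (zero or one site per sequence) discovers
the motif de novo from the top-enriched peaks. Binding sites are
classified against the chromatin landscape: `PROMOTER` (overlapping a
strand-aware −5/+2 kb TSS window), `ENHANCER` (H3K4me1-positive, not
promoter), `UNMARKED_DISTAL` (everything else).

**Expression layer.** RPKM with exon-mapped totals; a simplified
negative-binomial Wald test per genotype (IR vs mock; median-of-ratios
normalisation, method-of-moments dispersion, t reference — external DE
tables can be imported instead); DEG calls at q < 0.05, |log2FC| > 0.58,
RPKM > 1 in ≥ 1 sample; and the p53-dependence rule: an up-regulated
wild-type DEG is dependent when `2^(wt_log2FC − ko_log2FC) ≥ 1.5`
(mirrored for down-regulation). Spearman hierarchical clustering of
samples and Fisher gene-set enrichment (sets of >10 and <2000 genes)
round out the layer.

**Integration.** Each gene inherits the motif class of the best peak in
its promoter window; regulatory mode × motif class cross-tabs and
per-category fold-change comparisons follow, and the intersection of
genes that are p53-dependently up-regulated *and* bound via the unsplit
element in two cell types defines the core response.

**Synthetic data.** `simulate_study()` generates a toy genome with
planted response elements, peak calls whose signal tracks the motif
class, disjoint promoter/enhancer/unmarked structure, and NB count
matrices with planted regulatory modes — every stage emits its ground
truth, and all generators are byte-reproducible functions of the seed.

## Worked example

```r
library(p53response)

cfg   <- sim_config(seed = 42)                     # 500 peaks, 2000 genes
study <- simulate_study(cfg, dir = "study")        # writes study/B/...

inputs <- list(
  genome = "study/B/genome.fa", peaks = "study/B/peaks.narrowPeak",
  peak_counts = "study/B/peak_counts.tsv", genes = "study/B/genes.tsv",
  marks = setNames(file.path("study/B/marks",
                             paste0(names(study$B$marks), ".bed")),
                   names(study$B$marks)),
  counts = "study/B/counts.tsv", meta = "study/B/samples.tsv")

res <- run_pipeline(inputs, run_config(n_restarts = 6, top_n = 300),
                    "study/out")
#> loaded 500 peaks, 2000 genes, 16 samples
#> discovered motif AGGCATGCTCGGACAAGTTT (IC 16.0 bits)
#> peak classes: PROMOTER 207, ENHANCER 147, UNMARKED_DISTAL 146
#> DEGs: 301 up, 289 down
#> wrote 11 tables to study/out (manifest 79050a47f7a556d48528746cd7da2820)
```

The discovered 20-mer is a clean dimer of two `RRRCWWGYYY` half sites.
Scanning every peak with it recovers the planted motif classes —

```r
round(res$motif_classes$frequencies, 3)
#> NO_MOTIF  UNSPLIT   SPACED
#>    0.316    0.300    0.384
```

97.9% of planted unsplit and 98.9% of planted spaced sites are called
correctly against the simulation's truth registry (the `SPACED`
fraction is inflated relative to the planted 18% because per-match
p-value semantics leave a floor of spurious spacer hits in motif-free
windows; see the methods vignette). The chromatin classes match the
planted construction exactly, with the planted mark structure visible in
the overlap table (rows: class, columns: % of peaks overlapping the
mark):

```r
round(res$landscape$mark_pct, 1)
#>                 H3K4me3 H3K4me1 H3K27ac RNApolII  DHS
#> PROMOTER           95.2      44    72.9     85.5 88.4
#> ENHANCER            0.0     100    58.5      0.0 70.7
#> UNMARKED_DISTAL     0.0       0     0.0      0.0  0.0
```

On the expression side the four planted regulatory modes are recovered
(about 150–165 each out of 590 responsive genes), and the integration
step finds the genes that are p53-dependently induced and bound via an
unsplit element:

```r
table(res$modes$mode)
#>   DOWN_DEP DOWN_INDEP  UNCHANGED     UP_DEP   UP_INDEP
#>        164        125       1410        159        142
length(res$integration$core)
#> [1] 64        # 64 of the 65 planted dependent-bound-unsplit genes
```

A two-cell-type run (`simulate_study(cfg, cell_types = c("B", "nonB"))`)
plants a shared core; `core_response()` on the two per-cell-type
candidate sets returns exactly that core in the consensus-planting
configuration.

A thin command-line wrapper is installed at
`inst/scripts/run_pipeline.R` (`simulate` and `run` subcommands).

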