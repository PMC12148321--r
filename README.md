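# werscreen

Genome-wide screening of seasonal chromatin and transcriptome time series
for **week-scale environmental response (WER) promoters** — promoters whose
repressive H3K27me3 mark changes over weeks-to-seasons in anti-phase with
the gene's expression, while the gene body itself stays unmarked. Such
promoters are candidate epigenetic "long-term thermometers": fused to a
reporter or a developmental regulator, they can confer responsiveness to
*sustained* (week-long) cold rather than to a cold night.

The package is aimed at plant epigenomics groups with windowed ChIP-seq /
RNA-seq signal collected across a season (e.g. monthly field sampling over
one year), and at anyone who wants a self-contained, tested implementation
of the screening statistics.

## What it computes

For each gene and each promoter window size (1, 2, 3 kb upstream of the
TSS, strand-aware), three criteria are evaluated:

1. **Seasonality** of mRNA, genic H3K4me3 (1 kb downstream of the TSS) and
   promoter H3K27me3: negative-binomial seasonal likelihood-ratio test
   (BH FDR < 0.05), first-harmonic cosinor F-test on
   log2(RPKM + 0.01) (P < 0.05), and peak-to-trough amplitude
   log2(max/min) > 1;
2. **Anti-correlation**: Spearman ρ of promoter H3K27me3 with mRNA and
   with genic H3K4me3, both negative, computed on smoothing-spline monthly
   values;
3. **Low gene-body H3K27me3**: maximum RPKM < 2.

Genes passing all three criteria at *every* window size are robust
candidates, ranked ascending by ρ(H3K27me3_pro, mRNA); upstream-neighbor
overlap of the candidate promoters is tested against the genome background
with a two-sided Fisher exact test.

Supporting modules: strand-aware window arithmetic and RPKM aggregation
from read tracks (GFF3/BED in, TSV out); a Needleman–Wunsch–Gotoh global
nucleotide aligner with percent-identity reporting; colorimetric
quantification of GUS-stained seedling images (reference-color pixel
windows, stained/unstained ratio); ΔCt relative quantification for RT-qPCR
and ChIP-qPCR with Welch/Bonferroni/Holm comparisons; and a synthetic-data
generator that emulates the monthly study design with known ground truth.

## Worked example

```r
library(werscreen)

cfg <- simulation_config(n_genes = 150, n_planted = 8, noise_sd = 0.2,
                         overlap_fraction = 0.5, seed = 37)
study <- simulate_wer_study(cfg)
screen <- run_wer_screen(study$signals, study$annotation)
screen
#> WER promoter screen
#>   1kb window: 8 candidate(s)
#>   2kb window: 8 candidate(s)
#>   3kb window: 8 candidate(s)
#>   robust (all_windows): 8 gene(s)
#>   top candidate: g0086 (rho = -0.993)
#>   upstream-overlap Fisher P = 0.2756 (2/8 vs 75/150)
unlist(screen_recovery(screen, study$truth))
#>            recovery false_positive_rate     n_true_positive
#>                   1                   0                   8
#>    n_false_positive
#>                   0
```

All 8 planted anti-phase genes are recovered with no false positives; the
top candidate is the gene whose promoter H3K27me3 is most strongly
anti-correlated with its mRNA (ρ = −0.993), and the candidates' 2/8
upstream-overlap frequency is not distinguishable from the genome
background (Fisher P = 0.28).

Alignment and identity reporting:

```r
p <- simulate_sequence_pair(200, substitution_rate = 0.03,
                            indel_rate = 0.01, seed = 1)
global_align(p$seq1, p$seq2)
#> Global alignment: 200 columns, 190 matches, 4 gap chars, score 905.0
#> Identity: 190/200 = 95.0%
```

A thin command-line front end over the same functions lives at
`inst/cli/werscreen.R` (subcommands `simulate`, `screen`, `align`, `gus`,
`qpcr`).

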