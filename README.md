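# chromexpress

Quantitative integration of spike-in normalized ChIP-seq with
compartment-resolved RNA-seq, for experiments that knock down a chromatin
regulator and ask how histone-mark levels and transcription move together.
The motivating design is RNAi against an MLL3/4-family methyltransferase in
FACS-sorted planarian G2/M (X1) stem cells, profiled for H3K4me3, H3K4me1
and H3K27me3 against a *Drosophila* S2 chromatin spike-in, with gene
expression classified across the X1 / X2 / Xins compartments — but every
stage is generic and works from plain tabular inputs (BED/GFF3 annotations,
fragment BEDs, TSV tables).

The package is aimed at computational biologists who need the quantitative
arm of such an analysis to be reproducible and testable: every pipeline
input can be generated synthetically with planted ground truth, so each
claim the pipeline makes (global shifts recovered, classes recovered,
correlations detected) is validated against a known answer.

## The model in brief

**Spike-in (ChIP-Rx) normalization.** Each sample *s* is scaled by
`alpha_s = R / N_spike_s` with `R = 1e6` and `N_spike_s` its deduplicated
spike-in fragment yield; binned signal is
`S_b = alpha_chip * C_chip_b − alpha_input * C_input_b`.
Because the spike-in sees the same immunoprecipitation efficiency as the
target chromatin, genuine genome-wide shifts in a mark survive; total-count
(library-size) normalization divides them away. Both factors are provided
so the contrast is demonstrable.

**Expression classes.** A gene belongs to the FACS compartment holding
strictly >50% of its expression, else `none` (optional union classes behind
a flag).

**DE selection.** From a supplied differential-expression table:
up if `log2fc >= log2(1.5)` and `p < 0.05`; down for the mirror image
(inclusive fold-change bound, strict p bound).

**Metagene profiles.** Per class, mean ± population SD of subtracted signal
in TSS ± 2 kb windows, strand-oriented; between-condition
`log2((kd + 1)/(ctrl + 1))` panels on scaled profiles.

**Integration.** Per gene, `delta = mean(kd) − mean(ctrl)` over the TSS
window (or gene body); per class and mark, Spearman's rank correlation
(average ranks; exact permutation p for n < 10, t approximation otherwise)
between `delta` and expression log2FC, with an optional `|log2fc| >= 1`
filter, significance at p < 0.001.

**Enrichment.** Exact upper-tail hypergeometric `P(X >= k)` of DE-list /
class overlaps over the classified universe (significance at p < 0.01), and
generic term enrichment ordered by mean log2FC.

## Worked example

Run the whole pipeline on a simulated experiment (3 marks + input, two
conditions, 300 genes, spike-in at 15%, an inverse mark/expression coupling
planted in class X1 for H3K4me1):

```r
library(chromexpress)
cfg <- list(seed = 42,
            simulate = list(n_genes = 300, chrom_len = 2e6,
                            spike_chrom_len = 4e5, n_fragments = 5e4,
                            n_de_up = 15, n_de_down = 15))
res <- run_pipeline(cfg, out_dir = "demo")

glance(res$de)
#> # A tibble: 1 × 5
#>   n_genes  n_up n_down fc_threshold alpha
#>     <int> <int>  <int>        <dbl> <dbl>
#> 1     300    15     15          1.5  0.05

attr(res$classes, "class_sizes")
#>   X1   X2 Xins none
#>   90   90   60   60

dplyr::filter(res$correlations, mark == "H3K4me1", filter == "none")
#>   class    mark     region filter  n          rho      p_value significant
#> 1    X1 H3K4me1 tss_window   none 90 -0.431732313 2.150256e-05        TRUE
#> 2    X2 H3K4me1 tss_window   none 90 -0.200625592 5.795711e-02       FALSE
#> 3  Xins H3K4me1 tss_window   none 60 -0.007613226 9.539620e-01       FALSE
#> 4  none H3K4me1 tss_window   none 60  0.129202556 3.251757e-01       FALSE
```

Reading the output: the planted 15 up- / 15 down-regulated genes are
recovered exactly by the threshold rule; the class sizes match the
configured 30/30/20/20% split; and the inverse coupling between promoter
H3K4me1 change and expression change planted in stem-cell-enriched (X1)
genes is recovered (rho = −0.43) and flagged significant at the p < 0.001
rule, while the uncoupled classes are not. `demo/` now contains subtracted
bedGraph tracks, per-class metagene tables, the correlation and enrichment
tables, and a `manifest.json` with an MD5 checksum of every output; a rerun
with the same config is byte-identical.

Plot helpers: `autoplot()` on a metagene profile draws the mean ± SD band
per class; on the correlation table it draws per-class rho bars with
non-significant bars faded.

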