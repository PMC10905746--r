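# calenh — spike-in calibrated occupancy analysis and enhancer classification

`calenh` is an R package for enhancer-centric regulatory genomics in a
differentiation time course: it takes CUT&Tag/CUT&RUN-style fragment counts
for a chromatin factor (here BRD4), an enhancer mark (H3K27ac) and a
transcription factor (RUNX2), together with RNA-seq counts from wild-type
and knockout lines at stem (D0), early (D3) and late (D6) osteogenic
timepoints, and produces the full classification ladder:

1. **Spike-in calibration.** Libraries spiked with exogenous (*Drosophila*)
   chromatin at a fixed per-cell ratio are calibrated with
   `factor = ((primary_reads / genome_bp) / spike_reads) × 10⁴`.
   A global occupancy collapse diverts sequencing depth into the spike
   channel, so the factor shrinks even when the primary track looks
   unchanged — the change that per-library normalizations (CPM) cannot see.
2. **Peak validation.** Broad peaks called on pooled wild-type replicates
   (local-background Poisson caller, BH-FDR over bins) are retained when
   wild-type RPKM > 1 **and** the peak is either absent from the knockout
   peak set or shows significant knockout loss (FDR < 0.05) in a
   sum-conditional negative-binomial exact test with spike-derived
   effective library sizes (`1 / factor`).
3. **Promoter / enhancer / super-enhancer annotation.** Peaks overlapping a
   TSS ± 500 bp window are promoters; otherwise overlap with an H3K27ac
   peak makes an enhancer. Super-enhancers are called on the rank-ordered
   acetylation density curve by the tangent rule (unit-slope tangent point
   on the rescaled hockey stick).
4. **Target genes and temporal classes.** Genes losing expression in both
   knockout lines (FDR < 0.05) within 50 kb of a validated peak are its
   targets; enhancers are subclassified as *stem* (D0-bound, target gene
   flat across wild-type differentiation), *early osteogenic* (D3-bound,
   gene induced) or *late osteogenic* (D6-bound, gene induced).
5. **Co-occupancy, signal loss and motifs.** Fisher's exact test (full
   hypergeometric enumeration) for BRD4–RUNX2 co-occupancy over the
   enhancer universe; per-peak RUNX2 knockout-loss flags; per-class
   unpaired Student t-tests on enhancer RUNX2 RPKM; PWM scanning (log₂-odds
   bits) with presence/absence Fisher enrichment at bound versus unbound
   enhancers.

The statistical core is a two-sided conditional NB exact test: group sums
of n i.i.d. NB(μ, φ) counts are NB(nμ, φ/n); conditioning on the total,
the p-value sums all split probabilities no larger than the observed one.
With φ = 0 it reduces to the conditional binomial test.

Every stage is exercised end-to-end on a seeded synthetic genome
(2 × 5 Mb, 200 genes, 300 enhancers) with planted ground truth — including
a knockout collapse only the spike channel can reveal — so the whole
pipeline is testable without any external data.

## Worked example

```r
library(calenh)

spike_scaling_factor(primary_reads = 2e7, spike_reads = 5e4)
#> [1] 0.001506651

b   <- simulate_bundle(generator_config(seed = 1))
res <- run_pipeline(b, pipeline_config())
res$summary$per_timepoint$D0[c("n_retained", "n_promoter", "n_enhancer",
                               "n_super_enhancer", "n_target_links")]
#> $n_retained  81   $n_promoter 30   $n_enhancer 51
#> $n_super_enhancer 33   $n_target_links 86
```

81 pooled D0 BRD4 peaks survive validation, splitting into 30 promoters and
51 enhancers (enhancer-heavy binding, as planted); 33 of the 300 H3K27ac
enhancers are super-enhancers and 86 peak–gene links fall within 50 kb of a
gene down in both knockouts. Co-occupancy and per-class RUNX2 loss:

```r
res$runx2$fisher[c("odds_ratio", "p_value")]
#> $odds_ratio 92.1   $p_value 2.49e-45
res$runx2$class_ttests
#>              class   n mean_a mean_b      t  p_value
#> 1             stem  49   1012    305  9.460 2.16e-15
#> 3 early_osteogenic  51   1098    320 13.081 2.19e-23
#> 5          unbound 150    130    151 -0.732 4.64e-01
```

RUNX2 RPKM collapses at BRD4-bound enhancer classes in the knockout
(≈3-fold mean loss, pooled-variance t-test) but not at unbound enhancers —
the planted BRD4-dependent recruitment. Scoring against the planted truth:

```r
m <- evaluate_against_truth(res, b$genome)
c(m$D0$retention$precision, m$D0$retention$recall, m$super_enhancer$jaccard)
#> [1] 1.000 1.000 0.909
```

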