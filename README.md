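# myorelax

Quantitative MRI of dystrophic skeletal muscle in small animals: a tested
R pipeline for two-echo T2 mapping, hyperintense-pixel classification,
compartment volumetry, localized water relaxometry and cohort statistics,
together with a synthetic hindlimb phantom generator that makes every stage
verifiable against known ground truth.

## The problem

In laminin-α2-deficient (DyW) mice — the standard model of congenital
muscular dystrophy type 1A — muscle pathology mixes two opposing T2
signatures: inflammation and edema *raise* transverse relaxation time,
while fibrotic collagen build-up *lowers* it. A whole-compartment mean T2
therefore confounds the two. The discrimination used in preclinical work
is pixel-wise:

1. Map T2 per pixel from a dual-echo spin-echo acquisition (TE₁ = 14 ms,
   TE₂ = 40 ms, TR = 2000 ms):

   T₂ = (TE₂ − TE₁) / ln(SI₁₄ / SI₄₀) = 26 ms / ln(SI₁₄ / SI₄₀)

2. Classify pixels with T₂ > 27 ms (control mean + 2 SD) as
   **hyperintense** — the inflammation/edema burden.
3. Average the remaining pixels: depression of this **muscle-only T2**
   below control level is the fibrosis signature.

The package implements this pipeline end to end, plus compartment
volumetry from labelled 3D gradient-echo volumes, mono-exponential and
NNLS T2-spectrum fitting of 29-echo STEAM water decays (with complex-PCA
signal extraction), ΔΔCt fold changes, Mac-1 field-count averaging, and
one-way ANOVA with Tukey-Kramer comparisons for unequal group sizes.

## Worked example

```r
library(myorelax)

# a dystrophic hindlimb phantom: muscle T2 21.20 ms, 20% lesion at 40 ms
sp  <- phantom_spec(grid = c(64, 64, 10),
                    tissues = default_tissues(muscle_t2 = 21.20,
                                              lesion_t2 = 40),
                    lesion_fraction = 0.2, snr_te14 = Inf, seed = 1)
lm  <- build_labelmap(sp)
vol <- simulate_dual_echo(lm, sp$tissues, snr_te14 = Inf)

map <- make_t2_map(vol, lm, labels = c(1, 2, 3))
roi_mean_t2(map)
#> $mean [1] 24.96   $sd [1] 7.520533   $n_pixels [1] 7060

muscle_only_t2(map)
#> $mean [1] 21.2   $sd [1] 0   $n_pixels [1] 5648
#> $excluded_fraction [1] 0.2
```

The whole-compartment mean (24.96 ms) sits between muscle and lesion T2;
after excluding pixels above the default 27 ms rule the muscle-only mean
recovers the true 21.20 ms exactly and the excluded fraction recovers the
simulated 20% lesion burden. On cohort scale:

```r
co  <- simulate_cohort(study_cohorts(), seed = 7)
res <- anova_tukey(co$table, "muscle_t2")
res$pairwise[, c("group_a", "group_b", "diff", "p_adj", "significant")]
#>   group_a group_b     diff        p_adj significant
#> 1 DyW-Los     DyW 2.825717 6.415009e-06        TRUE
#> 2      WT     DyW 3.926865 1.878682e-08        TRUE
#> 3      WT DyW-Los 1.101148 3.874231e-02        TRUE
```

The large disease (WT vs DyW) and treatment (DyW vs DyW-Los) contrasts in
lesion-free muscle T2 are detected decisively; the small residual gap
between treated and wild-type animals is borderline at this draw's group
sizes (6/8/4).

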