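# cnascreen

An R package implementing an integrative screen for **copy-number-driven,
survival-associated genes** in tumour cohorts profiled with aCGH copy-number
arrays and expression microarrays — the analysis design used to nominate
prognostic driver candidates in high-risk diffuse large B-cell lymphoma.

A gene is nominated as a driver candidate when three lines of evidence
agree:

1. **Recurrent aberration** — its locus lies in a *minimal common region*,
   a maximal genomic run where gains (or losses) overlap in at least 10% of
   samples, after excluding genes overlapped by more than 10 germline CNV
   catalogue records.
2. **Dosage effect** — expression tracks copy-number status: the
   signal-to-noise statistic
   `SNR = (μ₁ − μ₂) / (σ₁ + σ₂)` (aberrant vs non-aberrant samples) is
   significant under a label-permutation test (p < 0.05, one-sided in the
   direction implied by the aberration, ≥ 3 aberrant samples),
   with Benjamini–Hochberg FDR reported alongside.
3. **Outcome association** — for genes aberrant in ≥ 5 samples, expression
   predicts survival (Cox proportional hazards on the continuous value,
   Kaplan–Meier / log-rank on ROC-dichotomized groups with the cutoff
   maximizing Youden's J).

Upstream, probe profiles are LOWESS-normalized (30% window, 4 iterations)
and denoised with **circular binary segmentation** (permutation-tested
splits at p < 0.05, no undo), and segments are called gain/loss when their
mean lies more than 2 cohort SDs from the cohort median. The package also
quantifies **IHC staining coverage** (nearest-exemplar colour
classification into brown/blue/white/background, 15 exemplars per class)
so protein-level validation can be scored, and classifies GCB / non-GCB
molecular subtype by complete-linkage clustering of a 44-gene panel.

Because patient-level outcomes for the original cohorts are not public, the
package ships a **synthetic-cohort generator** (`sim_config()`,
`generate_cohort()`, `generate_ihc_image()`) that plants known breakpoints,
carrier sets, expression effects, hazard ratios and image compositions, so
every stage is testable against ground truth.

## Worked example

```r
library(cnascreen)

# a 40-sample cohort with one planted chr2 gain (20% carriers) whose driver
# gene gains +1 log2 expression in carriers and raises progression hazard
coh <- generate_cohort(sim_config(seed = 42))
rep <- run_screen(coh, screen_config(seed = 42))
print(rep)
#> Integrative CNA screen: 40 samples
#>   segments: 405  regions: 1 (gain 1 / loss 0)
#>   genes tested: 3  association-selected: 1
#>   survival endpoint: pfs  biomarkers: chr2_g05

rep$regions[, c("chrom", "start", "end", "direction", "n_carriers", "frequency")]
#>   chrom start      end direction n_carriers frequency
#> 1  chr2 2e+07 34500060      gain          8       0.2

rep$association[rep$association$selected, ]
#>    gene_id direction n_cna  snr        p   fdr selected
#> 1 chr2_g05      gain     8 1.19 0.000999 0.003     TRUE

rep$gene_survival
#>    gene_id direction n_cna cox_log_hr    cox_p cutoff logrank_p
#> 1 chr2_g05      gain     8          2 0.000222  0.291  0.000216
```

Reading the output: the screen found one recurrent gain region on chr2
(the planted 20 Mb–34.5 Mb interval, carried by 8/40 = 20% of samples);
within it, gene `chr2_g05` — the planted driver — shows a strong dosage
effect (SNR 1.19, permutation p ≈ 0.001) and carries survival risk (Cox
log HR 2.0 per log2 expression unit on progression-free survival, p =
2×10⁻⁴; log-rank on the ROC-dichotomized groups agrees). It is the sole
reported biomarker, with region, association and survival evidence all
traceable in the report.

IHC scoring works the same way against planted truth:

```r
field <- generate_ihc_image(100, 100, c(0.25, 0.45, 0.15, 0.15),
                            jitter_sd = 10, seed = 1)
cov <- staining_coverage(classify_pixels(field))
cov$coverage        # ~0.25, the planted brown fraction
dichotomize(c(0.05, 0.12), cutoff = 0.089)$labels
#> [1] low  high
```

A thin CLI for shell use lives in `inst/cli/cnascreen.R`
(`simulate --out DIR --seed N`, `run-all --dir DIR --seed N`).

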