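---
title: "An integrative copy-number / expression / survival screen, and how it is tested"
author: "cnascreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An integrative copy-number / expression / survival screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnascreen)
```

## The problem

In aggressive B-cell lymphomas, somatic copy-number aberrations (CNAs) are
frequent, but most are passengers. A gene is a plausible *driver* of outcome
when three independent lines of evidence line up: its locus is recurrently
gained or lost across the cohort, its expression tracks its copy-number
status, and its expression (or protein-level staining) predicts survival.
`cnascreen` implements that screen end to end for cohorts profiled with aCGH
copy-number arrays and expression microarrays, plus a quantitative scorer for
immunohistochemical (IHC) staining so the protein-level validation step can
be reproduced as well.

Because real clinical outcome data of this kind are rarely public, the
package ships a synthetic-cohort generator with planted ground truth
(breakpoints, carrier sets, driver effect sizes, hazard ratios, IHC
compositions). Every stage is tested against that truth or against
independent brute-force oracles.

## The pipeline, stage by stage

### Normalization

Probe-level log2 ratios are detrended with robust LOWESS against a per-probe
covariate (default: array position as an intensity proxy), using a 30%
window and four robustifying iterations — the standard parameters for this
preprocessing step. The generator plants a smooth sinusoidal bias (default
amplitude 0.2 log2 units, two cycles across the array) so the normalizer has
something real to remove; tests check the residual bias RMS.

### Segmentation

Denoising uses circular binary segmentation: the profile is circularized and
recursively split at the arc that maximizes the two-sample mean-difference
statistic between the arc and its complement,

$$Z_{ij} = \frac{|\bar{x}_{arc} - \bar{x}_{rest}|}{\sqrt{1/k + 1/(n-k)}},$$

with the split accepted iff its permutation p-value is below `alpha = 0.05`.
No undo/pruning step is applied. The probe variance term is a common factor
over all arcs and all permutations of the same segment, so it is omitted.
The O(n^2) arc scan and the permutation loop are compiled (Rcpp); the
permutation loop stops early once enough exceedances have accumulated that
the split can no longer reach significance — this changes no decision, only
runtime. The default of 200 permutations per split test is the smallest
round count that still resolves decisions at `alpha = 0.05` with margin
(the add-one p-value grid is 1/201); `cbs_segment(n_perm = 1000)` matches
the conventional setting when runtime is not a concern.

Known behaviour inherited from the statistic itself: a strong outlier next
to a true breakpoint can shift the estimated boundary by a probe or spawn a
one-probe fragment. We do not smooth outliers away by default; tests
therefore assert breakpoint recovery within ±2 probes rather than exact
equality.

### Noise model and calling

The cohort noise level is the median and sample SD of pooled per-probe
values across all arrays. The pipeline pools *residuals* (probe minus its
segment mean) rather than raw probes: residuals isolate measurement noise,
whereas raw probe pools inflate the SD in aberration-rich genomes. A segment
is called a gain when its mean exceeds `median + k*sd` and a loss below
`median - k*sd`, with `k = 2`. Whether the 2-SD rule should be applied to
probe-level or segment-level values is ambiguous in the screen design this
package follows; we apply it to segment means (denoising precedes calling)
and keep `estimate_noise()` agnostic about its input pool so the other
convention is one call away.

### Recurrent regions and CNV filtering

Minimal common regions are maximal genomic runs where the number of samples
carrying an aberration of one direction reaches `ceiling(min_freq * n)`,
computed by a sweep-line over segment boundaries (gains and losses
independently; default `min_freq = 0.10`). With a 51-sample cohort this
makes 6 carriers (11.8%) the smallest qualifying recurrence, which is why
reported frequencies start around 12%. Genes overlapped by more than
`max_cnv = 10` germline CNV catalogue records are excluded; raw records are
counted, not merged intervals.

### Expression integration

For every gene in a region (and surviving the CNV filter), samples are split
by CNA status and the signal-to-noise statistic
$(\mu_1-\mu_2)/(\sigma_1+\sigma_2)$ is computed on expression, with a
permutation test (labels permuted preserving group sizes, add-one p-value).
Two design choices deserve a note:

* **Sidedness.** The selection rule is directional — a gain should
  up-regulate, a loss down-regulate — so the default permutation test is
  one-sided in the implied direction; two-sided is available
  (`sided = "two"`).
* **"Stable expression in non-aberrant samples"** is enforced by the
  denominator: a noisy non-CNA group inflates $\sigma_2$ and shrinks the
  statistic. No separate stability test is invented.

A gene is selected iff p < 0.05, it is aberrant in at least 3 samples, and
the statistic's sign matches the direction. Benjamini–Hochberg FDR is
reported across all tested gene/direction pairs (the field-default FDR
procedure).

### Survival

Three endpoints are derived from clinical dates (months = days/30.44): PFS
(event at progression; other-cause deaths censored at death), OS (event at
any death) and lymphoma-specific OS (other-cause deaths censored). Survival
machinery is the `survival` package: Kaplan–Meier, log-rank, and Cox
regression with Breslow tie handling by default (Efron available). ROC
cutoffs use a rank-statistic AUC (ties 0.5), Hanley–McNeil normal-
approximation CI, and Youden's J maximized over observed marker values; high
marker is the risk direction. Whether the binary ROC label should be
"event within 5 years" or "event ever" is left as a caller choice; the
pipeline default is event-ever, the simplest label consistent with deriving
a survival cutoff. Five-year survival is read off the KM curve at 60
months.

The pipeline tests survival two ways, as the two-step design it reproduces
does: per region (carriers vs rest, log-rank, for regions with at least
`min_surv = 5` carriers) and per selected gene (expression as a continuous
Cox covariate, then ROC-dichotomized KM). Survival p-values are reported
unadjusted, with a BH column alongside for transparency.

### IHC quantification

Brightfield fields are scored by nearest-exemplar colour classification:
four classes (brown = specific stain, blue = nuclei, white, background =
faint unspecific stain), up to 15 exemplar RGB colours per class, each pixel
assigned to the class of its nearest exemplar in Euclidean RGB distance with
deterministic tie-breaking in class order. Raw RGB distance is the default
because it is the simplest reading of "nearest example colour"; a
perceptually uniform space would be a reasonable alternative but is not what
the original scorer describes. Coverage is the brown fraction; because the
original description does not name the denominator, both conventions (all
pixels; tissue pixels only) are always computed, with `all` the default.
Patient scores average 1–3 fields. Field selection is manual in practice
and out of scope — fields are inputs here. The 0.02 mm² field area is
carried as annotation only.

### Subtype classification

Samples are split into GCB / non-GCB molecular subtypes by complete-linkage
hierarchical clustering of a 44-gene panel's log ratios, cut into two
branches. Which branch is "GCB" is not decidable from the tree alone; if
per-gene signature directions are supplied the branch with the higher mean
signed panel expression is labelled GCB, otherwise neutral `cluster1/2`
labels are emitted and the caller maps them. This avoids silently inventing
signature directions.

## The synthetic cohort generator

`sim_config()` defaults encode the study conditions the screen is tested
under, chosen once:

| parameter | default | rationale |
|---|---|---|
| `n_samples` | 40 | dual-platform cohort scale (tens of samples) |
| `n_probes_per_chrom` | 200 (3 chromosomes) | enough probes for segmentation to be non-trivial while a 50-replicate study stays in minutes; tests that need denser grids raise it locally |
| `probe_noise_sd` | 0.1 | typical aCGH probe noise |
| `bias_amplitude` | 0.2 | visible but removable intensity trend |
| planted gain | chr2, 15 Mb, shift +1.0, 20% carriers | one-copy gain; ~8/40 carriers, matching the recurrence scale of reported 2p gains |
| driver `delta` | 1.0 log2 unit | expression doubles with the gain |
| driver `log_hr` | log(3.2) per log2 unit | anchored to the relapse risk ratio (~3) reported for the screen's headline marker |
| `baseline_hazard` | 0.006 / month | ~70% 5-year progression-free survival at baseline |
| `expression_sd` | 0.5 | biological + technical spread |
| `censoring_rate`, `followup_max` | 0.002 / month, 84 months | median follow-up ~4.5 years |

Survival times are exponential (constant hazard) — the simplest model
compatible with proportional hazards; nothing in the screen depends on the
baseline shape. Lymphoma death follows progression with its own hazard, and
other-cause deaths and loss to follow-up are independent, so all three
endpoints and their censoring rules are exercised. A `contamination`
multiplier (default 1) dilutes planted segment means, emulating normal-cell
admixture, because real tumour samples are rarely pure.

What the generator does **not** emulate: intensity-dependent *variance*
(only an additive trend), wavy-genome GC artefacts, batch effects across
sites, exon-level signal, subclonal (non-integer) aberrations, and spatial
structure in IHC fields (pixels are exchangeable). Passing tests therefore
show the machinery is correct and calibrated under a clean generative
model, not that the thresholds are optimal for any particular real dataset.

## Numerical choices and degenerate inputs

* Segmentation decisions use the add-one permutation convention; early
  termination never changes a decision. Segments shorter than `min_width`
  arcs are not tested; profiles shorter than `2*min_width` return one
  segment.
* `snr_statistic` returns ±Inf when both groups are constant but unequal, 0
  when constant and equal; groups need at least two values (the sample SD is
  undefined otherwise).
* Zero cohort SD makes any deviation from the median a call, with a warning.
* Gene-to-segment ties (equal base-pair overlap) break toward the larger
  absolute segment mean, i.e. toward reporting an aberration.
* ROC cutoffs are observed marker values; ties in Youden's J break toward
  the smallest qualifying cutoff. Constant markers cannot be dichotomized
  (error).
* All randomness flows from explicit seeds; `run_screen()` derives one
  sub-seed per stage from its root seed, so reports are bit-reproducible.

## Problem sizes used in the checks

The packaged checks run at: 200 simulated chromosomes for segmentation
recovery and specificity; 2,000 null genes at 1,000 permutations for
permutation-test calibration; 200 replicates for driver/passenger selection
rates; 1,000 null simulations for log-rank size; n = 500 for Cox effect
recovery; 100 random instances per brute-force oracle; and 50 replicate
cohorts for the end-to-end recovery rate. These sizes put Monte-Carlo noise
well inside the asserted bands while keeping a full run in minutes on one
core.

## Known limitations

* The CBS implementation scans all arcs exactly (O(n^2) per split); for
  very dense arrays (millions of probes per chromosome) a windowed scan
  would be needed.
* The permutation association test treats samples as exchangeable under the
  null; confounding by subtype is not adjusted for (the original screen
  reports subtype comparisons separately, as does `subgroup_frequency_test`).
* Cox fits warn on, but do not resolve, complete separation; proportional-
  hazards diagnostics beyond that are out of scope.
* The IHC scorer classifies colours only; it does not deconvolve stains or
  segment nuclei, and inherits the exemplar palette's quality.
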