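---
title: "Methods: scoring modifier screens and quantifying their follow-up assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring modifier screens and quantifying their follow-up assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenquant)
```

`screenquant` implements the quantitative backbone of an arrayed yeast
over-expression modifier screen and its follow-up assays: colony-size
scoring with a change-from-vector statistic, single-cell fluorescence
quantification, immunoblot densitometry with chase kinetics, and relative
transcript quantification. Every stage can be exercised against a bundled
synthetic-data generator with planted ground truth. This vignette explains
the models, the parameters that matter, the numerical choices, and what the
synthetic data do and do not establish about real data.

## Screen scoring

The screen arrays a deletion library (by default 187 kinase/phosphatase
deletion strains on two 96-well plates) transformed with an empty vector or
one of two α-arrestin over-expression plasmids, stamped in technical
triplicate onto several media. The scoring model is:

1. **Replicate averaging.** Technical replicates are collapsed to a mean
   and sample SD (n − 1 denominator) per strain × plasmid × condition,
   on one imaging day (default: the latest day in the table — later days
   integrate more growth signal; any day can be selected).
2. **Per-plate Z-normalization.** Strain means are Z-scored within each
   plate × plasmid × condition stratum. This removes plate- and
   condition-level scale so the vector and over-expression arms are
   comparable.
3. **Change from vector (∆V).** Per gene, the vector arm's Z-scored mean
   is subtracted from the over-expression arm's: ∆V > 0 means the strain
   grows better under over-expression. We compute ∆V on the normalized
   scale because the per-plate Z-scores are what make the two arms
   comparable; `dv_on_raw = TRUE` preserves the raw-mean alternative for
   users who prefer subtracting pixel areas directly.
4. **Z of ∆V and calling.** The ∆V values are Z-scored within the same
   strata, and a gene is called for a condition when |Z(∆V)| > 1.2 and
   (by default) its colony size also deviates from the plate norm,
   |Z(size)| > 1.25. Both cutoffs are exposed because the two-filter
   description (a size deviation *and* a vector difference) and the single
   1.2 cutoff are both legitimate readings of the screen design; the
   defaults apply both filters. Ties at a cutoff are non-candidates.
5. **Aggregation.** A gene graduates to the aggregate candidate list when
   it is called in ≥ 2 of 3 condition *groups*. The default grouping
   collapses the two NaCl arms into one "salt" group (a hit in either
   concentration counts once), alongside control and rapamycin, and pools
   the two arrestin arms per gene before counting. The condition map and
   `min_conditions` are configurable because the grouping of media into
   "conditions" is a design choice, not a mathematical necessity.

Degenerate strata (zero SD — e.g. a plate of identical sizes, or dead
strains everywhere) yield undefined Z; those strains are excluded from
calling with a warning rather than silently scored. Zero colony sizes are
kept as true zeros (dead strains), not treated as missing.

The synthetic screen generator plants multiplicative modifier effects on
chosen (gene, plasmid, condition) arms over a lognormal noise model
(colony areas are positive and right-skewed; multiplicative noise keeps
zero out of the generative path, and a separate dead-strain option plants
exact zeros). Default noise CV is 0.05, matching tight technical
triplicates of robotically stamped colonies. With 20 planted 2-fold
modifiers the scorer recovers planted arms with mean recall above 0.9 at a
false-positive rate near zero over 20 seeds (the acceptance suite measures
exactly this). Recall is not 1: when several same-signed modifiers land in
one stratum they inflate the stratum's ∆V spread, and the weakest of them
can fall under the Z cutoff — an inherent cost of within-plate
normalization, not a bug.

## Image quantification

Fields contain three registered channels: GFP (the signal being
quantified), CMAC (a vacuole-lumen dye) and trypan blue (TB, a cell-wall
stain). The pipeline is:

- **Segmentation.** A classical stand-in for the commercial AI
  segmentation used on the original instrument: the channels are combined
  (pixel-wise max of normalized channels), Gaussian-smoothed (σ = 2 px),
  thresholded with Otsu's method, hole-filled, and split by a watershed on
  the distance transform. Because smoothing lets bright wall rims bleed
  past the threshold, object boundaries are refined against the
  *unsmoothed* support and interior holes refilled; without this the
  masks inflate by a pixel or two and whole-cell means are diluted several
  percent. Segmentation accuracy is judged only against the generator's
  ground truth and is not claimed to match any commercial tool.
- **Border removal.** Labels touching the image boundary (within
  `margin`, default 1 px) are removed and the rest relabeled; partial
  cells would otherwise bias per-cell means. The operation is idempotent.
- **Whole-cell GFP.** Mean GFP over all pixels of each cell label. Means
  include the vacuole region; excluding it is a possible refinement the
  package deliberately does not apply, since whole-cell abundance is the
  quantity being summarized.
- **Compartment masks.** Per cell, the surface mask is TB-positive pixels
  within a band of ±2 px around the cell boundary (the inner band from
  the cell's distance transform with half-pixel slack for the discrete
  Euclidean metric; the outer band by dilation, never taking a
  neighboring cell's pixels); the vacuole mask is CMAC-positive pixels in
  the remaining interior. Both stains are thresholded per field with
  Otsu's method. The masks are disjoint by construction, and a cell with
  an empty vacuole mask is flagged rather than given a ratio.
- **PM/vacuole ratio.** Surface-mask mean GFP over vacuole-mask mean GFP,
  per cell; invariant to global rescaling of the GFP channel.
- **Population summaries.** Median plus a percentile-bootstrap 95% CI of
  the median (2000 resamples, seeded). The median is the location
  statistic of choice for right-skewed single-cell intensity data.
- **Subpopulation splitting.** Some genotypes yield bimodal expression
  (distinct high- and low-expressing cultures). Intensities are split
  with a 2-component Gaussian mixture on log-values fitted by EM with a
  deterministic hierarchical-clustering initialization; components are
  reported sorted by mean. Because no distribution should be split just
  because a 2-component model can be fitted, a BIC comparison against the
  1-component fit gates the report: when the single component wins, the
  fractions are flagged as unwarranted. (A dip-test diagnostic would
  serve the same purpose; BIC keeps the decision inside the same
  likelihood framework as the fit.)

The synthetic fields are deliberately minimal: non-overlapping disk cells,
a wall ring of configurable thickness, an interior vacuole disk at 0.45 of
the cell radius, uniform per-compartment GFP, Gaussian pixel noise. This
is the simplest geometry that exercises mask pairing, border handling and
compartment ratios with exactly computable truth. It does not emulate
optics (no PSF), cell crowding, buds, bud scars, vacuole fragmentation or
autofluorescence — so passing tests demonstrate the correctness of the
measurement logic, not robustness to real microscopy artifacts. Test
problem sizes (256×256 fields, 12–30 cells, noise SD up to 10% of signal,
20 seeds) were chosen to exercise the estimator at realistic densities
while keeping the suite fast.

## Blot densitometry and chase kinetics

Band quantification follows standard manual densitometry: a band box and a
background box, mean pixel intensities, corrected = band − background
floored at zero (negative densitometry is noise; flooring is flagged).
The background box is per-band by default. Loading correction divides by a
per-lane total-protein value, and steady-state abundance is expressed as
percent of a reference lane:
100 × (sample/loading) / (reference/loading) — invariant to common
rescaling of a lane.

Chase experiments (translation shutoff with cycloheximide, with or without
rapamycin or proteasome inhibition) are summarized as percent remaining:
each replicate is normalized to its own t = 0 intensity, so t = 0 is
exactly 100% in every replicate, and timepoints are summarized by mean ±
SEM. A log-linear least-squares fit of percent remaining (positive values
only) provides a decay rate and ln 2/k half-life; the fit is an extension
beyond the percent-remaining presentation and its output says so. The
free-GFP cleavage ratio (vacuole-resistant GFP fragment over full-length
fusion) is a per-lane corrected-intensity ratio. Fold-change comparisons
of t = 0 intensities use Welch's unequal-variance t-test.

The chase generator plants `I0·exp(−k·t)` series with multiplicative
lognormal noise (CV 0.05 by default, 4 replicates, timepoints 0/1/2/4 h);
the log-linear fit recovers planted rates within a few percent under those
conditions, and within 15% is the acceptance bound.

## Relative transcript quantification

The 2^−∆∆CT method with perfect-doubling amplification: per replicate,
∆CT = Ct(target) − Ct(reference gene), ∆∆CT subtracts the calibrator
strain's mean ∆CT, and RQ = 2^−∆∆CT. The default reference is the
cDNA-abundance control *YEP3* and the calibrator is wild type. With the
standard 2 biological × 2 technical design, the target and reference wells
of each technical replicate are paired, so four replicate RQs per strain
feed the mean ± sample-SD summary — matching the four-replicate accounting
of the assay design; averaging technical replicates at the ∆CT level first
(two RQs per strain) is available via `tech_reps = "average"`, since assay
descriptions rarely state which convention was used. RQ is invariant to
adding any constant to every Ct, and noise-free simulated plates return the
planted relative expression exactly. Efficiency-corrected (Pfaffl-type)
quantification is out of scope.

## Shared statistics

Group comparisons of non-normal per-cell or per-replicate values use the
Kruskal–Wallis rank-sum test with Dunn's post hoc z-tests. "Dunn's post
hoc correction" is implemented as Dunn's z with Bonferroni adjustment over
the comparisons actually made (all pairs, or versus a designated
reference), the most common reading; Holm and Šidák are selectable. Ties
get mid-ranks with the standard tie correction in both H and the Dunn
pooled variance; a fully tied pooled sample is reported as H = 0 with all
p = 1 rather than NaN. Welch's t handles unequal variances for two-group
fold-change tests.

Significance symbols default to the scheme used on the figures this
pipeline feeds — `***` p < 0.001, `**` p < 0.01, `*` p < 0.1, `ns`
otherwise — an unusually lenient single-star boundary that is reproduced
deliberately; a conventional 0.05/0.01/0.001 map is selectable.

Two numerical caveats are tested rather than assumed: the Dunn p-value is
a normal approximation, and at n = 3 per group it differs from the exact
permutation p by up to ≈ 0.07 (the tests compare against an exhaustive
permutation oracle at that tolerance while requiring the statistics
themselves to match brute-force rank formulas to 1e-12); and under a
global null the Bonferroni-adjusted rejection rate at 0.05 stays below
0.06 over 1000 simulated datasets.

## Worked example

```{r example, eval = FALSE}
mods <- random_modifiers(strain_names(187), n = 20, seed = 1001)
sim <- simulate_screen_plates(screen_sim_config(planted_modifiers = mods,
                                                noise_cv = 0.05, seed = 1))
calls <- call_condition_candidates(score_screen(sim$measurements))
evaluate_screen_calls(calls, sim$truth)
candidate_report(calls)$aggregated
```

## Known limitations

- Colony detection from plate photographs is out of scope; scoring starts
  from measured pixel areas.
- The segmentation stand-in is tuned for isolated, roughly convex cells;
  dense clumps or strongly non-circular cells would need a different
  detector behind the same interface.
- Synthetic fields omit optical and biological artifacts (see above), so
  accuracy claims transfer to real micrographs only to the extent the
  stains behave like the planted compartments.
- Mobility-shift (phospho-shift) calling, automatic band detection and
  efficiency-corrected qPCR are deliberately not implemented.
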