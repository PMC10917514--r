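---
title: "Dual-reporter colony-array screen analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-reporter colony-array screen analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsga)
```

## The experimental design this package models

Reporter synthetic genetic array (R-SGA) screening crosses a fluorescent
reporter strain into an arrayed yeast deletion collection, producing plates
of colonies in which every colony carries one gene deletion plus the
reporter. Here the reporter is bidirectional: GFP is fused (via a 2A
peptide) to an ORF that either carries a premature termination codon (the
NMD reporter) or does not (the OPT control reporter), while RFP is driven
from the same inducible promoter in the opposite direction. The per-colony
quantity of interest is the GFP/RFP intensity ratio: RFP cancels overall
expression differences, and the PTC-containing construct reports on
nonsense-mediated decay. A deletion that disables NMD raises the NMD
reporter's GFP/RFP without touching the OPT reporter's.

The deletion collection is arrayed in 1536 format — 32 rows by 48 columns
per plate — with each strain pinned as a 2×2 block of four replicate
colonies, so a plate holds 16 × 24 = 384 strains, of which the outermost
ring of blocks are border controls. Plates are scanned by fluorimetry
(GFP, RFP per spot) and photographed for colony size.

## The analysis chain

For each reporter screen independently:

1. **Filter** (`filter_colonies()`): drop border strains and colonies whose
   size falls outside (1500, 6000) pixels. The cutoffs are strict
   inequalities — a colony of exactly 1500 or 6000 pixels is retained.
   Border strains grow larger from the nutrient edge effect; out-of-range
   colonies are unreliable quantifications. Every exclusion is counted by
   reason; nothing is dropped silently.
2. **Aggregate** (`aggregate_strain()`): per strain, means and medians of
   GFP and RFP over the surviving colonies, and
   `log2_ratio = log2(mean GFP / mean RFP)` computed from the means.
   Medians are diagnostics only. Strains with a nonpositive mean in either
   channel are flagged unusable, never coerced to numbers.
3. **Per-plate LOESS** (`loess_normalize_plate()`): a locally weighted
   regression surface of `log2_ratio` over the strain's block-centroid
   `(row, col)` is fitted with tricube weights, and the residual is kept as
   the normalized value. Normalization is strictly per plate; no
   information crosses plates.
4. **Z-scores** (`zscore_screen()`): the normalized values of all usable
   strains, pooled across plates, are standardized with the population
   (n-denominator) standard deviation. Per-plate standardization is
   available behind `per_plate = TRUE`. No multiple-testing correction is
   applied at any point.
5. **Hit calling** (`call_hits()`): after collapsing duplicate strains per
   gene (keeping the record with maximal |Z| by default), a gene is an NMD
   **candidate** when `|z_nmd| > 2` and `|z_opt| <= 2`. Genes that are
   outliers in both screens are classed `shared` — their GFP/RFP change is
   not specific to the premature stop codon — and outliers in the control
   screen only are `opt_only`. "Not also an outlier" is interpreted
   sign-blind; a same-sign variant of the shared count is available via
   `hit_config(same_sign_shared = TRUE)`.

Downstream, `strain_fold_change()` reproduces the triplicate
flow-cytometry validation (fold change of the mean GFP/RFP ratio versus a
HIS3-deletion control, Welch t-test on per-replicate ratios), and
`hypergeom_enrich()` performs fixed-target hypergeometric term enrichment
of the candidate list against the universe of genes for which screen data
were acquired.

## Design choices where the design was open

**LOESS covariate.** Per-plate normalization needs a covariate; plate
position is the standard one for colony arrays, where uneven illumination,
agar thickness and incubation gradients imprint smooth spatial trends on
intensity. The default is a 2-D surface over `(row, col)`; a 1-D smoother
over column index is available (`covariate = "col"`) for sensitivity
analysis.

**LOESS settings.** Defaults are span 0.15, local degree 2, tricube
weights, `family = "symmetric"` with two robustness reweightings. Degree 2
matters: plate artifacts are dome- and ramp-shaped, and a local-linear fit
leaves curvature bias in the residuals that is still correlated with the
artifact even when the residual variance is tiny. The short span (about 46
strains per local window on a 1536-format plate) is needed to follow the
steep intensity gradients adjacent to the (already removed) border ring.
Robustness iterations keep genuine hits — large, spatially unstructured
deviations — from dragging the surface. All settings are exposed.

**Aggregation order.** Colonies are filtered, then aggregated to strain
level, then normalized at the strain-centroid position. Normalizing at
colony level before aggregation would be equally defensible; strain-level
fitting is cheaper and makes the LOESS input one point per strain, so
quadruplicate blocks do not get fourfold weight.

**Population SD for Z-scores.** With thousands of usable strains the
n vs n−1 distinction is negligible; the population form makes the
"mean 0, sd 1" identity exact, which the tests assert to 1e-9.

**Duplicate strains.** The deletion collection contains duplicated gene
entries. Before classification each screen keeps, per gene, the record with
the largest |Z| (configurable: `first`, `mean`). Keeping the extreme record
is conservative for candidate *exclusion* (a gene that is an outlier in any
OPT-screen entry is treated as an OPT outlier).

**Degenerate inputs.** Zero-variance screens raise a degenerate-screen
error; plates with fewer than 10 usable strains skip LOESS with a warning
and carry the raw ratio forward flagged un-normalized; two-sample tests on
zero-variance replicate sets return p = 1 when the means agree and p = 0
when they do not, instead of erroring as `t.test()` would.

**Flow gating.** The instrument's size gate is not recoverable from
tabulated event data, so gating retains events inside the closed
[0.05, 0.95] empirical quantile band of each sample's size channel (type-7
quantiles, inclusive bounds). **Validation test.** Welch's t-test on the
three per-replicate GFP/RFP ratios versus the control's three, the minimal
test consistent with triplicate design; Student and Wilcoxon variants are
exposed. Fold changes are means of per-replicate ratios divided by the
control's mean ratio — not ratios of pooled means — matching how triplicate
flow averages are normally reported.

**Enrichment.** A fixed-target hypergeometric upper tail for a thresholded
hit list against an explicit universe. Ranked-list (mHG-style) statistics,
ontology-graph propagation and multiple-testing correction are deliberately
out of scope.

## What the simulators emulate — and what they do not

`generate_screen()` produces matched NMD/OPT plate tables over one shared
strain layout with: quadruplicate 2×2 blocks; a border ring; per-channel
baselines (the NMD reporter baseline ratio is −log2 3, the roughly 3-fold
repression a PTC construct shows); planted reporter-specific and shared
effects of configurable magnitude with random sign; three designated
"strong" NMD strains at twice the base effect (emulating the canonical
UPF1/2/3 deletions, which dominate real NMD screens); smooth per-plate
spatial artifacts; multiplicative log-normal channel noise; and colony
sizes with a configurable fraction planted strictly outside the
(1500, 6000) pixel window while regular colonies are drawn truncated
inside it, so exclusion counts are exactly checkable.

The spatial artifact is a random low-order polynomial plus an exponentially
decaying edge component (decay length a quarter of the plate's short
dimension), centred and scaled to a target log2-scale standard deviation —
**per channel**: GFP and RFP are scanned with different lasers and filters
and their artifacts do not cancel in the ratio, which is precisely why
per-plate normalization of the ratio is needed. The generator exposes the
net ratio field (GFP field minus RFP field, block-averaged) as planted
truth for recovery tests.

Default study conditions: 16 plates (≈4.9k non-border strains, the scale
of the non-essential deletion collection), 3% NMD-only, 3% OPT-only and 1%
shared hit strains at |log2 effect| 1.0, channel noise sd 0.1 (log2),
spatial amplitude 0.2, 5% size outliers. These were fixed once as
field-realistic values and are not tuned per analysis.

`generate_flow()` produces per-event (size, GFP, RFP) tables, 10,000
events × 3 replicates per strain, with per-event log-normal spread
(sd 0.35 log2) and a small per-replicate drift (sd 0.01 log2 per channel).
A strain with ratio shift *s* has expected mean-GFP/mean-RFP equal to the
control's times 2^*s*; across 100 seeds the recovered fold change for
*s* = 1 stays within 5% of 2.

Not emulated: colony images and their quantification, growth kinetics,
pinning/mating/sporulation robotics, missing colonies (the readers handle
missing values; the generator does not plant them), cross-plate batch
structure, fluorescence spillover/compensation, and any real genetic
interaction structure. Passing recovery tests therefore demonstrates that
the statistical chain recovers effects *under its own model assumptions* —
spatially smooth artifacts, independent log-normal noise — not that it is
robust to every failure mode of real plate data.

## Numerical behavior and known limitations

* Simulation sizes used by the test-suite and acceptance checks — one- and
  two-plate screens for recovery loops, 100 seeds for sensitivity, 20 for
  detrending, 500–1000 null strains for the type-I check — are the
  package's choice of smallest sizes at which the quantities stabilize.
* Detrending fidelity: under a planted field of amplitude 0.5 with noise
  0.05, the residual variance is below a few percent of the raw variance
  and the residual–field correlation stays below 0.1 on the tested seeds;
  for occasional adversarial field draws dominated by the sharp edge
  component it can reach ≈0.12. A residual correlation this size on a
  residual that small is cosmetic for hit calling, but users normalizing
  plates with pathologically steep edge gradients should inspect the
  per-plate diagnostics.
* The robust (symmetric-family) surface tracks the *null* core of a plate.
  On screens with many strong hits the residual distribution is therefore
  offset from the globally centered raw ratios by a small constant; this is
  intentional (hits must not recentre the plate) and is absorbed by the
  screen-wide Z-scoring.
* `loess_value` plate means are near but not exactly zero (robust weights);
  |mean| is typically below 0.01 on simulated plates.
* Read∘write identity on tables holds to full double precision (readr
  writes shortest round-trippable representations).

## A worked example

```{r example, eval = FALSE}
library(rsga)

cfg <- pipeline_config(
  screen_sim = screen_sim_config(n_plates = 4),
  seed = 42, out_dir = "rsga_demo")
run <- run_pipeline(cfg)

unlist(run$overlap)
head(run$candidates[, c("gene_name", "z_nmd", "z_opt", "class")])
run$validation
head(run$enrichment)
```

The output directory holds the Z-scored score tables for both reporters,
the classified hit table, the overlap counts as JSON, the candidate list,
the simulated triplicate flow validation of the top candidates, the
enrichment table, and `manifest.json` recording the seed, a hash of the
scientific configuration, per-stage row counts and a checksum per output
file; re-running the same configuration reproduces identical files.
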