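---
title: "Collagen fingerprint identification: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collagen fingerprint identification: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zoomsid)
```

This vignette is the package's own account of the science it implements:
the identification model and its assumptions, the parameters that matter,
what the synthetic-data generator does and does not emulate, and the design
choices made where more than one reasonable realization existed.

## The identification model

A ZooMS identification treats a MALDI-TOF collagen fingerprint as a bag of
peptide-marker observations. The reference library supplies, for each of
the panel's markers (here 9, lettered P, A, B, C, E, D, H, F, G, each a
COL1a1/COL1a2 tryptic peptide with a nominal m/z window in 800–3600 Da),
the expected singly-protonated monoisotopic masses per leaf taxon. Matching
is per marker: the picked peak inside the marker's window whose distance to
some expected value is smallest (ties to the more intense peak) becomes
that marker's single match, carrying the union of all leaf taxa whose
expected values lie within the tolerance of that peak.

The candidate set of a spectrum is the **intersection over matched markers
of each match's leaf union**. Markers absent from the spectrum impose no
constraint — this is exactly how diagenetic loss broadens an
identification: with marker C absent, the 1550/1580 Da contrast cannot
split the deer group from chamois, and the candidate set keeps both. The
reported call is the smallest named category of the library's lattice
covering the candidates (ties broken lexicographically, so results are
deterministic); a sample is *identified* only if at least `min_markers = 4`
distinct markers matched and the candidate set is nonempty. A nonempty
match set whose intersection is empty is reported as a *fail* flagged
`conflict` — never as a root-category identification — mirroring the binary
identified/fail accounting of assemblage tables.

Assumptions worth stating explicitly:

* masses are [M+H]+ monoisotopic values; no charge states beyond +1;
* deamidation (~+0.984 Da) is not expanded into extra expected values — the
  0.5 Da tolerance absorbs sub-Dalton shifts;
* no deisotoping: the most intense peak of an envelope is taken, and the
  simulator correspondingly plants single Gaussians rather than isotope
  envelopes;
* the library's category lattice is trusted: a pair of taxa that no marker
  separates must share a named category (validated by
  `validate_library()`).

## Replicate consensus

Samples are spotted in (up to) triplicate. Each spot is identified
independently; candidate sets of two spots are *consistent* when one
contains the other or a named non-root category covers their union. Under
the default union-consistent rule, consistent spots pool their marker
matches (best match per marker) and the pool is re-resolved — this
maximises marker recovery, e.g. two spots that each caught a different
subset of markers can jointly clear the 4-marker criterion. Disjoint
candidate sets are a genuine disagreement: the combination is flagged
`conflict`, falls back to strict intersection, and fails. The
strict-intersection rule (markers matched in every usable spot, leaf sets
intersected per marker) is available via
`match_config(consensus_rule = "strict-intersection")` for conservative
reporting. The 4-marker criterion is applied to the combined,
post-consensus marker count, since the success criterion is per sample,
not per spot.

## Preprocessing parameters

| parameter | default | unit | role |
|---|---|---|---|
| `baseline_precision` | 15 | segments | number of equal-width m/z segments anchoring the baseline |
| `baseline_relative_offset` | 25 | % | lift of each anchor above the segment minimum, relative to the robust spread (median − minimum) |
| `smooth_window` | 0.3 | Da | Savitzky–Golay window (order 2), converted to an odd point count |
| `smooth_cycles` | 2 | — | smoothing passes |
| `snr_threshold` | 3.0 | ratio | minimum apex height / local noise |
| `picking_height` | 0.75 | fraction | height at which the two crossings defining the centroid are taken |
| `noise_window` | 100 | Da | window of the running MAD noise / median background estimate |

The first six defaults are the standard mMass-style screening settings for
collagen fingerprints; their names are kept even where the exact internal
semantics of the original software are unpublished, and the realization
here is documented as this package's own:

* **Baseline.** Anchors are the per-segment minima lifted by
  `relative_offset` % of the segment's *robust* spread, defined as median
  minus minimum. A non-robust spread (max − min) would scale with the
  tallest peak in the segment and carve away up to a quarter of every peak
  apex; the robust spread tracks only the noise band, so planted apexes
  survive correction to within a few percent. The piecewise-linear baseline
  is extrapolated linearly at the axis ends (constant extension would leave
  a ramp residual in the outermost segments), subtracted, and negative
  residuals are clipped to zero. A constant spectrum maps exactly to zero.
* **Ordering.** The chain is baseline → noise estimate → smoothing →
  picking. The noise level is deliberately estimated *before* smoothing:
  an order-2/0.3 Da Savitzky–Golay pass attenuates white noise roughly
  two-fold, and referencing S/N = 3 to the attenuated scale would re-admit
  pure noise maxima as peaks (empirically ~60 spurious peaks per synthetic
  spectrum at realistic settings). Calibrating the threshold to the
  pre-smoothing noise keeps its meaning independent of the smoothing
  window.
* **S/N and apex measurement.** Both are measured above the residual local
  background (the windowed running median of the corrected profile). With
  segment-minimum anchors a pedestal of roughly the noise band's half-width
  survives correction by construction; apex-over-noise without background
  subtraction would then pass everywhere. When the baseline is ideally
  removed the background is zero and the definition reduces to plain
  apex/noise.
* **Peak locality.** An apex must dominate its ± `smooth_window`
  neighbourhood. Noise ripples on the flank of a strong peak otherwise
  inherit the peak's height and pass any S/N threshold.
* **Centroid.** The two crossings of the profile at 75 % of apex height are
  found by linear interpolation walking outward from the apex (truncated at
  the valley for overlapping neighbours); the centroid is their midpoint.
  This is deterministic and resolution-independent; at the default 0.02 Da
  grid and 10× noise, planted centroids are recovered to ≈ 0.01 Da, an
  order of magnitude inside the 0.5 Da matching tolerance.

Degenerate inputs are repaired or refused loudly: spectra shorter than the
segment count fall back to a single-segment baseline with a warning,
windows that cannot fit make smoothing a warning no-op, an all-zero
spectrum gets a machine-epsilon noise floor, and picking a raw spectrum
warns about the violated pipeline order.

## The reference library

The packaged default library is reference data, not a measurement: a
9-marker panel over 25 leaf taxa assembled in the style of published ZooMS
marker compilations, with the handful of diagnostic contrasts that anchor
this package's worked examples stored with provenance `"paper-anchor"`
(3017/3033 for red/fallow/giant deer vs 3043/3059 for roe deer on marker G;
1550 vs 1580 on marker C for deer vs chamois; 1576.8 on COL1a2 889–906
present in *Canis*/*Cuon* and absent in *Vulpes*). All other values are
flagged `"literature"` and are plausible, internally consistent stand-ins
chosen so that every named category of the lattice is reachable; real
analyses should load a curated library (`load_library()`, TSV or JSON).
Two structural devices deserve mention because they mirror how real panels
behave:

* *Missing markers encode indistinguishability.* Felids carry no COL1a2
  889–906 value and share all other values with *Ursus*; a full-panel bear
  thus resolves to "Ursus sp." while a cat/lynx spectrum resolves to
  "Felis/Lynx/Ursus" — the bear cannot be excluded without the marker the
  felids lack.
* *Shared values keep broadened categories reachable.* Cervids and
  chamois share four markers (P, D, H, F), so a spectrum missing C and G
  legitimately resolves to "Cervid/Rupicapra" with four markers — the
  category printed in assemblage tables cannot otherwise clear the
  4-marker criterion.

## Assemblage conventions

ZNISP tables count identified specimens per category × stratum with a Fail
row; percentages are computed on the stratum total *including* fails and
rounded half-up to one decimal (18 of 210 → 8.6 %), headline success rates
half-up to integers (192/210 → 91). Broad-category mapping is a plain
named vector and must cover every category (counts are conserved, which is
asserted). For the ZooMS-vs-morphology comparison the package computes,
per cultural complex, a Spearman rank correlation across broad categories
with a one-sided permutation p-value (10 000 permutations, seeded) and the
OLS slope of morphological NISP on ZNISP; these two statistics are this
package's choices — the underlying publications typically report "an
association" without fixing the test. Spatial success grids report
per-square (optionally per square × layer) sampled and identified counts;
cells never sampled are absent from the output rather than 0 %, and
samples without square labels are tallied separately.

The packaged Castelcivita fixture transcribes the ZNISP columns of the
published assemblage table (which sum consistently to 210/840/213 with
18/108/23 fails); the companion morphological NISP transcription is
best-effort — several printed cells are typographically ambiguous and two
row totals do not match their cells — and is used only for rank
association, never for exact arithmetic. Known text/table discrepancies in
the source (caprine 223 vs 110; *Bos*/*Bison* "nearly 145" vs 156;
Uluzzian preservation 81 % vs 87 %) are deliberately not reconciled: the
fixture follows the table.

## The simulator: what it emulates, and what it does not

`simulation_config()` defines the generative model: per-layer sample
counts with taxon compositions shaped like the site's stratigraphic
faunal shift (cervid-dominant early Mousterian layers turning
equid-dominant through the Uluzzian and Protoaurignacian — qualitative
defaults, not values fitted to any figure); twelve excavation squares with
preservation probabilities spanning 0.7–1.0; per-marker peak dropout at
0.05 for preserved and 0.9 for degraded samples (diagenesis acting
marker-wise); Gaussian peaks of σ = 0.08 Da with lognormal amplitudes
(meanlog log 50, sdlog 0.4, i.e. apexes ~50× the unit noise); a gentle
polynomial baseline; additive Gaussian noise; triplicate spotting; and a
mandatory seed. The m/z grid is 800–3600 Da at 0.02 Da.

What passing synthetic tests *does* show: the pipeline's bookkeeping is
correct end to end — peaks are found where planted, matches intersect to
categories that contain the true taxon, identification rates track planted
preservation within binomial error, rates fall monotonically with dropout,
and the marker-count histogram concentrates at 9 of 9 when dropout is
rare. What it does *not* show: robustness to real MALDI artefacts. The
simulator has no isotope envelopes, no adducts or matrix clusters, no mass
calibration drift, no deamidation shifts, no intensity suppression between
co-spotted peptides, and its noise is white Gaussian rather than
heteroscedastic detector noise. Real spectra will stress the matching
tolerance and the reference library in ways these tests cannot.

## Problem sizes and numerical choices

The shipped test-and-validation runs use deliberately modest sizes chosen
to exercise each claim at meaningful statistical power: 60 triplicate
samples for the exact-recovery check, 500 single-spot samples for the
preservation-tracking check (binomial SE ≈ 1.8 % at p = 0.8), 100 samples
per dropout level for the monotonicity check, and 10 000 permutations for
association p-values. Determinism everywhere comes from a single seed per
run; the generator refuses to run without one. Floating-point ties in
marker matching are resolved by intensity, category ties lexicographically,
and percentage rounding is half-up (not banker's) to match how assemblage
tables are printed.

## Known limitations

* The default library's `"literature"` values are placeholders at realistic
  spacings, not published measurements; identifications on real data
  require a curated library.
* Mass recalibration against calibrant spots is out of scope; spectra are
  assumed calibrated to well under the 0.5 Da tolerance.
* The category lattice is flat set-cover, not a phylogeny; "smallest
  category" is by member count, which is the field's reporting convention
  but has no likelihood interpretation.
* MNI, body-size and fragmentation modelling, and taphonomic statistics
  are outside the package's scope.
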