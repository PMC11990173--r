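---
title: "Annotating oligosaccharides from negative-mode LC-MS/MS: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating oligosaccharides from negative-mode LC-MS/MS: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycoladder)
```

## The problem

Underivatized plant oligosaccharides — fructans such as the inulin-type
GFn series, arabinans, and mixed hexose/pentose species — are screened by
hydrophilic-interaction chromatography coupled to high-resolution MS in
negative mode, where they appear as singly deprotonated `[M − H]⁻` ions.
Accurate mass alone fixes only the molecular formula; within one formula,
positional and anomeric isomers co-elute in clusters, and the
monosaccharide identities (glucose vs. fructose vs. galactose; arabinose
vs. xylose) are mass-degenerate. The practical identification strategy in
this field therefore layers four kinds of evidence: accurate precursor
mass, diagnostic MS2 fragment ladders, the monosaccharide composition of
the bulk sample, and authentic standards. `glycoladder` implements that
strategy as a deterministic, testable pipeline.

## Mass model

Element masses are monoisotopic (C = 12 exactly, H = 1.007825032,
O = 15.994914620, N = 14.003074005 Da). An intact oligomer of `a` hexose
and `b` pentose residues has neutral mass

\[ M(a,b) = a \cdot 162.052823 + b \cdot 132.042259 + 18.010565\ \mathrm{Da}, \]

where the residue masses are those of the dehydrated units C6H10O5 and
C5H8O4 and one water restores the reducing/terminal ends; the package
derives both from the element table, so the constants cannot drift apart.
Deprotonation subtracts the proton mass 1.007276466 Da (the molecule
keeps its electrons — the standard negative-ESI convention). All
arithmetic is done in double precision; printed tables round half away
from zero at 4 decimals (m/z) and 2 decimals (ppm) only at output time.
Nominal "162 / 132 / 18 Da" losses are treated as display vocabulary:
ppm-level matching is impossible at nominal precision.

Nitrogen is accepted by the formula grammar (amino sugars occur in
monosaccharide screens), but the composition model is strictly
hexose/pentose: formulas that do not decompose as `(a, b)` with
`a + b ≥ 2` are reported as non-oligosaccharide.

## Composition enumeration

For an observed precursor m/z the engine scans the full lattice
`dp_min ≤ a + b ≤ dp_max` and keeps every composition whose theoretical
`[M − H]⁻` lies within `ms1_tol_ppm`. Results are sorted by |ppm|, with
ties broken toward fewer pentoses, then lower DP; ambiguity is *reported*,
never resolved silently, because MS1 alone cannot adjudicate it. For this
residue pair the lattice is well separated — the smallest non-zero
distance between distinct compositions in the DP ≤ 12 range is several
Da — so at single-digit ppm tolerances enumeration returns at most one
candidate below m/z 2000.

Defaults and rationale:

| parameter | default | unit | rationale |
|---|---|---|---|
| `dp_min` | 2 | residues | disaccharide lower bound of "oligosaccharide" |
| `dp_max` | 12 | residues | deepest series routinely reported for fructans on this platform; configurable upward |
| `ms1_tol_ppm` | 5 | ppm | routine external-calibration Orbitrap accuracy; a documented wider setting (10 ppm) is appropriate for runs with a known negative mass drift |
| `scan_mz_min`, `scan_mz_max` | 150, 2000 | m/z | the acquisition range of the reference method |
| `intensity_threshold` | 10 000 | counts | the screening cutoff used to select chromatographic peaks for identification (strictly greater-than; the boundary case is excluded by design) |

The PRM inclusion-list generator simply exports the same lattice clipped
to the scan range, sorted by m/z, one `1−` target per composition —
hexose-only, pentose-only and mixed alike — so that trace compounds that
never trigger data-dependent MS2 can be re-acquired in targeted mode.

## The fragment-ladder model

Negative-mode CID of oligosaccharides is dominated by glycosidic (Y-type)
cleavage. The model therefore predicts, for composition `(a, b)`:

* **Y rungs:** one ion for every distinct multiset of remaining residues;
  for single-class compositions this is a linear ladder losing one
  residue mass per step, for mixed compositions a branched set of
  `(a+1)(b+1) − 1` rungs (losses of either class allowed at every step,
  deduplicated by m/z). Observed mixed-species evidence such as a double
  pentose loss falls out of this rule without fixing a loss order.
* **Water-loss companions:** each Y rung minus 18.010565 Da.

The ladder terminates at the deprotonated monosaccharides (m/z 179.056
and 149.045); it is never extended to bare water. Cross-ring (A/X) ions
are deliberately out of the model. The model is purely theoretical:
observed fragment masses are reconciled by the matcher's tolerance, never
by adjusting ladder values.

Matching pairs ladder values inside `[scan_mz_min, precursor]` with
observed peaks, greedily by smallest |ppm| and one-to-one — deterministic,
and on ladders this sparse equivalent to optimal assignment. The fragment
tolerance is `ms2_tol_ppm = 10` ppm with an absolute floor
`mz_floor_da = 0.003` Da: reported low-mass fragments in carbohydrate
work commonly sit 1–3 mDa off theory (several ppm at m/z 161–180, tens of
ppm at m/z 131), and the floor absorbs that without loosening matching at
high m/z. The matcher reports matched/total rung counts, per-match ppm
deviations, and the longest chain of consecutive single-loss Y fragments
below the precursor — the quantity that distinguishes a genuine
sequential-loss series from scattered coincidental matches.

## Confidence levels and isomer series

MSI-style levels, restricted to the three that this evidence model can
support:

* **Level 1** — composition match to an authentic standard *and*
  retention time within `rt_window_min = 0.30` min. The window is small
  against the ≥ 0.4 min spacing of isomer clusters on 40-min HILIC
  gradients; standards without an observed retention time (e.g. a
  disaccharide below the detected range) are carried in the table but
  never matched.
* **Level 3** — no standard, but at least `min_rungs = 2` matched ladder
  values. A single matched fragment is not accepted as ladder evidence.
* **Level 4** — formula-only (no MS2, or fewer than 2 rungs matched).

Level 2 (library spectral match) is deliberately absent: no public
spectral libraries cover these series. Evidence can only raise a level:
adding a standard, or MS2, never demotes an annotation.

Isomer assembly groups best annotations by composition. A group with a
Level-1 member keeps the canonical name there and renames the rest
"`<name> isomer`"; groups without one keep the plain series name for all
members (the convention used for deep-DP series where no standards
exist). Peak numbers follow elution order, ties broken by m/z.

Naming follows field conventions: canonical fructan names through DP7
(sucrose, 1-kestose, nystose, 1F-fructofuranosyl nystose,
1,1,1,1-kestohexaose, fructoheptasaccharide), `fructo-oligosaccharide
DPn/GF(n−1)` beyond; Greek-suffixed arabino-oligosaccharide names; and
ratio names (`2Fru:1Ara`, dominant residue first) for mixed species. The
hexose→Fru and pentose→Ara identities are *palette labels*, assumptions
recorded on the palette object and echoed in each annotation's evidence
string as "FOS (palette-assumed)"; with an ambiguous palette the mixed
naming falls back to neutral `hex<i>pent<j>`.

## The curated benchmark

`pch_benchmark()` transcribes a literature-reported characterization of
the *Polygonatum cyrtonema* rhizome oligosaccharide fraction: 44 features
(27 FOS, 10 AOS, 7 mixed), with retention times, observed masses,
formulas, names and confidence flags. Three transcription decisions are
worth recording:

* One observed mass is internally inconsistent as reported (it disagrees
  with its own row's ppm error by ~118 ppm and transposes the digits of a
  neighbouring row's mass); the fixture reconstructs it from the row's
  theoretical mass and reported ppm error and flags it in `note`.
* Four reported theoretical masses are truncations rather than roundings
  of the computed values; the package's mass-reproduction tests allow
  5 × 10⁻⁴ Da for exactly this reason and assert exact 4-decimal equality
  only where the reported value is a true rounding.
* MS2 stubs for Level-1/3 features combine the handful of individually
  reported fragment m/z values with the theoretical ladder of the
  assigned composition (a synthetic completion — most spectra were not
  reported peak by peak). Level-4 features carry only their reported
  fragments; several of those are themselves typographic outliers
  (20 + ppm off any ladder value), and it is precisely the failure to
  match ≥ 2 rungs that keeps these features at Level 4, mirroring the
  reported flags.

Two reported precursor masses carry −5.3 and −8.5 ppm errors; the
benchmark annotation run therefore uses the documented 10 ppm precursor
setting rather than the 5 ppm default, which covers 42 of 44 rows.

## The synthetic generator

`generate_dataset()` emulates the acquisition this pipeline targets: one
MS1 feature per planted compound at its theoretical `[M − H]⁻` perturbed
by Gaussian ppm error (`mass_jitter_ppm = 1.5`, unbiased by default —
setting `mass_bias_ppm ≈ −2.5` reproduces the small systematic negative
offset typical of externally calibrated runs), plus an MS2 spectrum
containing the full ladder with geometrically decaying intensities
(`decay = 0.6` per rung, water companions at half their parent rung —
arbitrary but inert, since matching uses intensities only for
nearest-peak tie-breaks) and 20 uniform-m/z noise peaks per spectrum at
0.1–2 % of the precursor intensity. A fixed seed determines everything;
the generator saves and restores the caller's RNG state.

The default plan plants every single-class composition with DP 2–8 plus
six mixed compositions, three isomer replicates each (60 features,
distinct retention times), with standards flagged for hexose-only DP 2–7.

What the generator does **not** emulate — and therefore what passing
recovery tests cannot certify on real data: chromatographic peak shape
and co-elution artifacts, isotope envelopes, in-source fragmentation,
adducts and multimers, cross-ring fragments, intensity-dependent mass
error, and retention-time drift between runs. It validates the inference
machinery, not the instrument physics.

## Verification sizes

The test suite works at deliberately small, fixed sizes: exhaustive
composition/formula round trips over the full DP 2–12 lattice;
enumeration checked against a brute-force double-loop oracle on 200
uniform random m/z values at 1, 5 and 20 ppm; neutral masses checked
against values frozen from an independent mass calculator (pyteomics);
jitter calibration on 1200 simulated features; recovery on the 60-feature
default plan; and the full 44-feature benchmark end to end. The complete
suite runs in well under a minute.

## Known limitations

* Glycosidic-linkage and anomeric configuration (e.g. β-2→1 vs. β-2→6
  fructans) are invisible to this evidence model; "1-kestose isomer" is
  the strongest claim MS can make for a co-eluting DP3 fructan.
* Monosaccharide identity within a mass class rests entirely on the
  palette; a sample containing xylose alongside arabinose would make
  every pentose call ambiguous.
* Only singly deprotonated species are modeled; multiply charged ions and
  adducts are out of scope (none are observed for these series at this
  m/z range).
* mzML feature extraction is deliberately simple (one feature per MS1
  scan at its base peak, MS2 linked by precursor scan); the CSV feature
  table is the contract-stable entry point for real data processed by a
  dedicated feature finder.
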