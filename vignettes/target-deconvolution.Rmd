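---
title: "Target deconvolution with DARTS protection scoring and t-LiP-MRM"
author: "LiPDARTS authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Target deconvolution with DARTS protection scoring and t-LiP-MRM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(LiPDARTS)
```

# The problem

A small molecule with cellular activity but no known target can be
deconvolved label-free by exploiting a simple biophysical fact: ligand
binding locally stabilises its target protein, so bound regions resist
limited proteolysis. This package implements the two complementary
readouts of that idea and the quantitative pharmacology that surrounds
them:

* **DARTS** (drug affinity responsive target stability) identifies *which*
  protein is the target. A native lysate is incubated with the compound at
  several doses, nicked briefly with a broad-specificity protease
  (subtilisin), and the surviving proteins are identified and scored by
  LC-MS/MS. A protein whose identification score recovers with dose is
  protected — a candidate target.
* **t-LiP-MRM** (targeted limited proteolysis with multiple reaction
  monitoring) identifies *where* on that target the compound sits. After
  the limited proteolysis step, samples are denatured and digested to
  completion with trypsin; the areas of fully tryptic peptides, quantified
  by MRM, drop wherever subtilisin could cut. A ligand that shields a
  region raises those areas back toward the trypsin-only control.

Both assays are driven here by a seeded synthetic-data generator with
planted ground truth, so every inferential step is testable end to end
without any mass-spectrometer output.

# DARTS protection scoring

Each replicate carries an undigested control (no protease), a
vehicle-digested control, and one digested sample per ligand dose. For a
protein with identification scores $S_u$ (undigested), $S_v$ (vehicle)
and $S_d$ (dose), the protection percentage is the normalised recovery

$$
\mathrm{protection} = 100 \cdot \frac{S_d - S_v}{S_u - S_v},
$$

clipped to $[0, 100]$. Both controls enter the normalisation: the vehicle
digest defines 0% (everything the protease could remove was removed) and
the undigested control defines 100% (nothing removed). Design choices
worth stating explicitly:

* **Degenerate controls** ($S_u \le S_v$) make protection undefined and
  raise an error (single-protein call) or `NA` with a warning (table-wide
  call). A digestion that did not reduce the score carries no signal.
* **Missing identifications** in a dose condition score as $S_d = 0$
  rather than being dropped: in DARTS, failure to identify a protein after
  digestion is itself evidence of non-protection.
* Protection is a ratio of score differences, so it is invariant under
  uniform rescaling of a replicate's scores — spectral counts can stand in
  for search-engine scores without changing anything.

Candidate targets must be protected (above a configurable floor, default
0%) at one or more doses in *every* replicate; `intersectReplicates()`
also returns the full Venn partition so the cost of that requirement is
visible. `rankTargets()` orders the intersection by mean protection across
replicates and doses, with deterministic tie-breaks (number of protected
replicates, then lexicographic id). Because it is not knowable from a
published ranked list whether percentages were pooled across doses or not,
the ranking reports both the pooled mean and per-dose means.

Validation densitometry (`densitometryTrend()`) divides band intensities
by a loading-control lane and flags a dose series as monotone when the
Spearman correlation with dose is positive and no consecutive relative
drop exceeds a tolerance (default 5%).

# Peptide chemistry

The t-LiP arm needs an in-silico model of the peptides the instrument can
see.

* **Cleavage rule.** Trypsin cuts C-terminal to K or R, suppressed when
  the next residue is proline — the default rule of the common search
  engines. Protein N- and C-termini count as tryptic termini, so
  protein-terminal peptides are fully tryptic.
* `digestTryptic()` enumerates all fully tryptic peptides up to a missed-
  cleavage budget; its 0-missed output tiles the protein exactly.
  `enumerateSemitryptic()` lists peptides with exactly one tryptic
  terminus — the products of one subtilisin cut plus trypsin — and is
  disjoint from the fully tryptic listing by construction. Both are tested
  against an exhaustive substring-classification oracle.
* **Masses.** Monoisotopic and average residue masses are tabulated to
  five decimals; water is 18.010565 Da and the proton 1.007276 Da
  (monoisotopic). Carbamidomethylation of cysteine (+57.02146 Da) is the
  default fixed modification, matching the usual alkylation; methionine
  oxidation (+15.99491 Da) and S/T phosphorylation are available by name.
  Fragment b/y ions obey the complementarity identity
  $m/z(b_i) + m/z(y_{n-i}) = M + 2 \times 1.007276$ at charge 1, which the
  tests verify wholesale.
* **Transition design.** `selectTransitions()` stands in for a spectral-
  library lookup: fully tryptic peptides with 0 missed cleavages, length
  6–25, precursor charges 2+/3+, and per peptide the top 3 singly charged
  y-ions above m/z 300, ranked by fragment index descending (longer y-ions
  first). No public criteria exist for this step in the workflows the
  package models, so all of these are exposed configuration with
  conventional defaults, and the selection is deterministic.

# t-LiP-MRM inference

Transition areas are rolled up to peptides by summation (configurable to
means). Two contrasts then run per peptide:

1. **LiP selection.** A peptide is subtilisin-sensitive ("LiP") when its
   double-digest vehicle area is significantly *lower* than its
   trypsin-only area: one-sided Welch t-test on log2 areas at
   $\alpha = 0.05$, plus a mean ratio below 1. Only LiP peptides can carry
   a conformational signal; everything downstream is gated on this.
2. **Ligand fold change.** Within the double-digest arm,
   $FC = \bar A_{\mathrm{dose}} / \bar A_{\mathrm{vehicle}}$ over
   replicate means, with a two-sided Welch t-test on log2 areas.

A peptide is called protected when it is LiP, $FC \ge 1.5$ and
$p \le 0.05$ at one or more doses. The Welch test on log-areas was chosen
because MS peak areas are approximately log-normal; a Mann–Whitney
alternative is available by argument. No multiple-testing correction is
applied by default — the reference workflows report raw p-values — but
Benjamini–Hochberg is one flag away. The significance threshold is never
hard-coded above 0.05 anywhere.

Numerical edge cases are handled as limits of vanishing noise: zero areas
are floored at half the smallest positive area in the table (with a
warning), and when both groups of a contrast are exactly constant the
p-value becomes 0 if they are separated in the tested direction and 1
otherwise, so noise-free synthetic data flow through the same code path
as real data.

`mapRegions()` merges overlapping or bookended protected peptides
(IRanges reduction) and intersects the merged intervals with the
protein's annotation track, reporting per-overlap residue counts; point
annotations such as a key tyrosine are reported as hit when they fall
inside a merged interval. The merged intervals cover exactly the union of
the input peptides — a conservation property the tests check.

```{r tlip-demo}
prot <- makeProtein(11)
sim <- simulateTlipAreas(seed = 11, protein = prot)
pip <- tlipPipeline(sim$areas, prot, sim$peptides)
pip$report
```

# Supporting pharmacology

* **Percent growth and GI50.** Viability is normalised as
  $\%\,\mathrm{growth} = 100\,(T - T_0)/(C - T_0)$; negative values
  (cytotoxicity below the seeding density) are legitimate. Growth curves
  are fitted with a four-parameter logistic in log10 dose via
  Levenberg–Marquardt; GI50 is the concentration where the *fitted* curve
  crosses 50% (the growth-assay convention of the common curve-fitting
  packages), not the curve midpoint, and the fit is rejected when the
  curve never crosses 50% in the tested range. Because an exact-fit
  problem started exactly at the data extremes can present a degenerate
  Jacobian, the fitter tries a small deterministic ladder of starting
  points and keeps the lowest-RSS fit. Confidence intervals come from a
  seeded parametric bootstrap (default 500 draws; the seed is a required
  argument). A model-free log-linear interpolation estimator is provided
  as a fallback.
* **PAMPA.** The two-compartment single-time-point model: the wells
  equilibrate toward $C_{eq} = C_D(0)V_D/(V_D+V_A)$ and
  $P_e = -\ln(1 - C_A(t)/C_{eq}) \cdot
  \frac{V_D V_A}{(V_D+V_A)\,A\,t}$ with $t$ in seconds. Reported as
  $-\log_{10} P_e$ with the usual classification (permeable below 6,
  impermeable above 6.5). The protocol literature also measures the donor
  side; the donor-side form converts the residual donor concentration to
  its acceptor equivalent by mass balance and applies the same
  expression, so both single-point variants are available and agree
  exactly on consistent inputs. Geometry defaults (150/300 µL, 0.3 cm²,
  24 h) are arguments, not constants.
* **Coupled kinetic assay.** For an NADPH-coupled glycogenolysis readout
  at 340 nm, `activityDeltaAbs()` reports the blank-corrected absorbance
  increment at a chosen readout time (default 30 min, interpolated
  between samples) and the initial rate as the least-squares slope of the
  blank-corrected trace over an early window.
* **Docking energetics.** $K_d = \exp(\Delta G / RT)$ with
  $R = 1.9872 \times 10^{-3}$ kcal mol⁻¹ K⁻¹ and a default temperature of
  298 K; a −7.884 kcal/mol binding free energy gives a predicted Kd of
  about 1.65 µM.

```{r kd}
kdFromDg(-7.884) * 1e6  # uM
```

# What the synthetic generator emulates — and what it does not

`simulateDartsTables()` draws per-protein baseline scores from a
log-normal, applies a digestion-survival fraction of 0.25 to form the
vehicle control, and interpolates dose scores toward the undigested
control so that the *noiseless* protection equals the planted value:
40/60/80% across doses 1/10/100 µM for targets, a 0–10% uniform
background for everything else, under multiplicative log-normal noise at
CV 15% with 3 replicates. These are the package's study conditions; they
are fixed defaults, not tuning knobs.

`simulateTlipAreas()` plants protection on residue intervals 71–78,
193–206 and 279–290 of a seeded 900-residue protein whose K+R frequency
(~11%) matches real proteomes and whose annotation track carries the
dimer-interface features of brain glycogen phosphorylase (helix 2 49–77,
cap loop 41–48, β4/β5 loop 180–198, tower helices 259–278, gate loop
279–289, the two domains, Tyr75 and Tyr196 — forced to tyrosine in the
sequence). Planted intervals are snapped to the nearest quantifiable
fully tryptic peptide (largest overlap, else smallest gap), because only
fully tryptic peptides are measurable by the targeted double-digestion
design; the realised truth is returned with the data. LiP suppression is
0.2, the planted fold change 2.0, noise CV 10%, 3 replicates, doses 1 and
10 µM, and a fifth of the remaining peptides are decoy LiP peptides with
no ligand response.

What the generator deliberately does **not** emulate: retention-time
drift and chromatographic interference, search-engine scoring internals
and identification FDR, peptide-level missingness patterns, ionisation
competition, or any correlation structure between neighbouring peptides.
Passing tests therefore demonstrate that the inference is correct *under
the stated noise model*, not that the pipeline is robust to every
pathology of real MS data.

# Problem sizes and runtime posture

The shipped checks run the study conditions at full size where that is
cheap (200 DARTS simulations of 300 proteins; 100 t-LiP simulations on a
900-residue protein; 200 GI50 refits) and keep unit-level property loops
to a few dozen random cases each; the whole suite completes in about a
minute on a single core. These sizes are the package's own choice of
statistical resolution: recovery rates quoted at the 90–95% level are
estimated from 100–200 draws, which bounds their standard error near 2–3
percentage points.

# Known limitations

* The protection formula assumes scores scale monotonically with protein
  amount within a replicate; saturated score regimes would compress
  protection toward the controls.
* LiP selection and fold changes use per-peptide tests with n = 3
  replicates; power at FC 1.5 and CV above ~20% drops quickly, and the
  default raw-p policy trades false positives for sensitivity exactly as
  the reference workflows do.
* The 4PL fitter reads GI50 off the fitted curve; for very shallow Hill
  slopes with doses that barely bracket 50%, the bootstrap CI — not the
  point estimate — is the honest summary.
* mzML ingestion is out of scope; chromatogram traces enter as long-form
  tables and are integrated with a trapezoid after optional
  endpoint-anchored linear baseline subtraction.
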