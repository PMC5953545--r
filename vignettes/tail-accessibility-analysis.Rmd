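---
title: "Quantifying histone tail-DNA collapse and reader access: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying histone tail-DNA collapse and reader access: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tailscape)
```

## The scientific problem

The N-terminal tail of histone H3 protrudes from the nucleosome core and
is the docking site for reader domains such as PHD fingers. On the intact
nucleosome the tail does not float freely: its dense basic charge drives
it to collapse onto the nucleosomal DNA, and that collapse competes with
reader binding. Quantifying the competition takes three kinds of
measurements, each with its own estimator:

1. **NMR chemical-shift-perturbation (CSP) titrations** give per-residue
   binding isotherms for a labelled reader domain titrated with tail
   peptide or nucleosome.
2. **Biolayer interferometry (BLI)** gives equilibrium response curves
   versus analyte concentration when kinetics are too fast for rate
   fits.
3. **Trajectory metrics** summarise simulated conformational ensembles
   of the tail against the DNA: compaction (Rg), surface localisation
   (voxel occupancy), secondary structure (DSSP categories), exposure
   (SASA), and per-residue tail-DNA interaction energies.

`tailscape` implements all three estimators plus the sequence-level
bookkeeping (extinction coefficients) used to put samples on an absolute
concentration scale, and ships generators that produce synthetic data
with the statistical structure each estimator assumes.

## The CSP titration model

For each backbone amide the composite shift difference relative to the
apo spectrum is

$$\Delta\delta = \sqrt{\Delta\delta_H^2 + (0.154\,\Delta\delta_N)^2},$$

the 0.154 factor rescaling ¹⁵N to the ¹H range. Because the observed
protein sits at concentrations comparable to the dissociation constant,
free-ligand approximations fail and the bound fraction follows the
quadratic (ligand-depleted) isotherm

$$f = \frac{(L+P+K_d) - \sqrt{(L+P+K_d)^2 - 4PL}}{2P},
\qquad \Delta\delta = \Delta\delta_{max}\, f,$$

fitted with *both* per-point concentrations as independent variables so
that dilution of the protein across the titration is explicit
(`titration_schedule()` carries `p_conc` and `l_conc` per point).

The full pipeline in `fit_titration()`:

* **Significance selection.** A residue is significant when its
  $\Delta\delta$ at the evaluation point strictly exceeds
  $\text{mean} + k\,\text{sd}$ over all observable residues, with
  $k = 0.5$ by default — a permissive cutoff appropriate for small
  domains whose binding surface is a large fraction of the structure.
  Two genuinely open choices are made explicit and configurable:
  the evaluation point is the *final* titration point (the highest
  ligand concentration reached), and both this rule and the outlier
  screen use the population ($1/n$) standard deviation.
* **Per-residue fits.** Each significant residue is fitted
  independently for $(K_d, \Delta\delta_{max})$; a shared-Kd global fit
  is available (`global = TRUE`) but labelled as an extension, because
  per-residue fitting followed by aggregation is the protocol the
  estimator mirrors.
* **Aggregation.** The reported $K_d$ is the mean over retained
  residues after a *single* $\pm 2$ sd screen. The screen is run once
  because, in a well-behaved titration, at most one isolated residue
  fit strays; iterating the screen on tight clusters would begin to
  trim legitimate values (the property tests exercise exactly the
  single-stray regime).
* **Broadened peaks** (unobservable at the evaluation point) are
  flagged and excluded, never imputed.

### Numerical choices

Fits use bounded Levenberg-Marquardt (`minpack.lm::nls.lm`), with
$K_d \in (0, 10^6]\ \mu M$, $\Delta\delta_{max} \in (0, 10]$ ppm and an
objective tolerance of $10^{-10}$. The quadratic isotherm has a shallow
false minimum at $K_d \to 0$ when $K_d \ll P$ (the stoichiometric
regime), so the optimiser starts from the best of a coarse log-spaced
$K_d$ grid with $\Delta\delta_{max}$ profiled linearly. Flat series and
non-converged fits are returned flagged (`converged = FALSE`), never as
silent numbers. Standard errors in `fit_equilibrium()` are asymptotic,
from the analytic Jacobian at the solution.

## The BLI steady-state model

Fast exchange precludes kinetic fitting, so the estimator is purely
equilibrium: after processing, the mean response over the last 20 s of
the association phase, $r_{eq}$, is fitted against analyte
concentration $x$ with the single-site hyperbola

$$r_{eq} = r_0 + (r_{max} - r_0)\,\frac{x}{K_d + x}.$$

Processing order in `run_bli_analysis()` matches instrument practice:
reference subtraction (single: loaded sensor vs buffer; double:
additionally unloaded sensor vs analyte), alignment to the mean of the
last 10 s of baseline (the conventional window is 5-10 s), then
Savitzky-Golay smoothing. The filter parameters — window 15 points
(1.5 s at 10 Hz), order 2 — are package defaults chosen to suppress
sampling noise without biasing a plateau; both are configurable.
Channels whose association has not plateaued (last-20-s mean still
moving relative to the preceding 20 s, judged against block-resampled,
detrended standard errors) are flagged in the result but not dropped:
exclusion is the analyst's call, not the estimator's.

## Trajectory metrics

All metrics operate on a plain `trajectory()` container (atom table +
coordinate array) with a small selection language
(`"chain A resid 1-44 backbone"`); residue indices are 1-based and
ranges closed.

* **Rg** is mass-weighted by default.
* **RMSD** uses Kabsch superposition with the proper-rotation guard
  ($\det R = +1$), and separates the *fit* selection (e.g. the ordered
  core backbone) from the *measurement* selection (e.g. tail backbone).
  `end_state_rmsd()` averages all-pairs RMSD over the strict upper
  triangle, with per-group means for runs sharing a starting
  conformation. The implementation is cross-checked in the tests
  against an independent quaternion-method oracle.
* **Secondary structure** follows Kabsch-Sander hydrogen-bond energies
  ($E = 0.084 \cdot 332\,(1/r_{ON} + 1/r_{CH} - 1/r_{OH} - 1/r_{CN})$,
  bond at $E < -0.5$ kcal/mol, amide H built from the preceding
  carbonyl when absent), collapsed to four categories: helix (G/H/I),
  sheet (E/B), turn (T), coil. Deliberate simplifications, each chosen
  because the four-category summary is insensitive to them: chain
  breaks end ladders and turns; assignment priority is 4-helix >
  bridge/ladder > 3-helix > 5-helix > turn (so bridge/turn overlaps
  resolve sheet-over-turn); bends are not assigned. Ensemble summaries
  report, per residue, the percentage of frames in each category, and
  overall values as the mean of those per-residue percentages, so every
  residue carries equal weight.
* **Voxel occupancy** uses 1.0 Å isotropic voxels after rigid
  alignment (first frame by default; an external reference may be
  supplied). "Occupancy" is ambiguous between fraction-of-frames and
  mean atom count; the default is fraction-of-frames (bounded in
  [0, 1]), with `mode = "count"` available. Grids auto-size with a 2 Å
  margin and export to OpenDX text.
* **SASA** is Shrake-Rupley (probe 1.4 Å, 960 golden-spiral points,
  occlusion tested against *all* atoms). It replaces analytic LCPO-type
  approximations on purpose: LCPO needs a force-field-specific
  atom-type parameterisation, while Shrake-Rupley is fully specified by
  geometry alone. No downstream quantity depends on matching another
  algorithm's absolute SASA values.
* **Interaction energies** use a screened Coulomb sum,
  $E = \sum 332.0636\, q_i q_j / (\epsilon(r) r)$ with
  $\epsilon(r) = 4r$ by default (constant-ε and optional
  Lennard-Jones available). This is a deliberately simple surrogate for
  solvation-model decompositions: its magnitudes are qualitative only,
  but the *aggregation statistics* are exact — each tail copy in a
  simulation is one observation (two samples per two-tail simulation),
  per-residue means and SEMs are taken across the samples of a group,
  and group totals are sums of per-residue means. A single sample
  reports SEM as absent (`NA`), not zero.

## What the generators emulate — and what they do not

* `simulate_titration()` draws fast-exchange peak positions
  interpolating apo→bound by the quadratic isotherm plus Gaussian
  noise. Defaults: 0.002 ppm ¹H noise and 0.013 ppm ¹⁵N noise
  (0.002/0.154, so both dimensions contribute comparably to the
  composite). A slow-exchange flag emits two fixed peaks per residue
  with complementary intensities linear in the bound fraction. No
  lineshapes, relaxation, or exchange broadening are simulated, so
  passing tests say nothing about lineshape-limited data.
* `simulate_bli()` produces 1:1 association/dissociation kinetics
  (default $k_{on} = 0.1\ \mu M^{-1}s^{-1}$, fast enough that 300 s
  association plateaus across the default 0.3-20 μM ladder) plus the
  two artifacts the referencing pipeline exists to remove: linear
  sensor drift on loaded channels and a concentration-proportional bulk
  offset during association. Instrument step artifacts and non-1:1
  surface effects are not modelled.
* `simulate_tail_trajectory()` is an *ensemble* generator, not
  dynamics: each frame is an independent self-avoiding bead chain
  (bond 3.8 Å, hard-sphere radius 1.9 Å) relaxed by Metropolis moves
  (crankshaft, end-pivot, whole-chain translation) against fixed
  pseudo-phosphate sites (charge −1) on a 10 Å cylinder, with
  acceptance $\exp(-\text{collapse}\cdot\Delta E / kT)$. 150 sweeps
  per frame were chosen so that fully collapsed ensembles concentrate
  ≥ 90% of occupied-voxel mass within 5 Å of the cylindrical surface
  while `collapse = 0` remains an unbiased confined ensemble; with all
  charges zero the biased and unbiased draws coincide stream-for-stream
  under a shared seed, which is what makes matched charge-variant
  comparisons exact. The default bead charges
  `c(1, 1.5, 0, 1, 0, 0, 1.5, 1, 1, 1.5)` mimic an H3-like mix of
  lysine-like (+1.0), arginine-like (+1.5, reflecting the stronger
  per-residue DNA coupling of guanidinium groups) and neutral sites.
* `build_backbone()` places N/Cα/C/O atoms from ideal internal
  coordinates (N-Cα 1.458, Cα-C 1.525, C-N 1.329 Å; ω = 180°), giving
  exact, assumption-free fixtures for the secondary-structure and
  geometry code.

All generators draw from a single seeded stream per spec, so every
synthetic dataset is reproducible from `(spec, seed)`.

## Problem sizes

The shipped tests and the acceptance script run at sizes a laptop
handles in about a minute per stage, chosen as the smallest sizes at
which the stochastic checks are stable: 20 replicate seeds for each
Kd-recovery study (44 residues with 14 responders for NMR; the
seven-step analyte ladder at 10 Hz for BLI), 40-100 frames for ensemble
metrics, and 960-1920 sphere points for SASA convergence.

## Known limitations

* Absolute tail-DNA energies are qualitative by construction (screened
  Coulomb surrogate); only comparisons across matched systems and the
  aggregation statistics are meaningful.
* The DSSP implementation targets the four-category summary; its
  letter-level output omits bends and resolves overlaps by the fixed
  priority above, so it is not a drop-in replacement for a full DSSP
  assignment.
* Ensemble realism of the tail generator is limited to what the
  analyses consume (distances, occupancy, energies); it has no
  excluded-volume DNA groove geometry, sequence specificity, or
  solvent.
* `duplex_e260()` implements the published nearest-neighbor
  (Cantor-Warshaw) single-strand sums with composition-linear duplex
  hypochromicity ($h = 0.287 f_{AT} + 0.059 f_{GC}$). Vendor web tools
  based on the same formulation have not always been reproducible from
  the published dialect for long sequences, so printed tool outputs and
  this model can disagree at the percent level there; the model here is
  the one validated exactly on short duplexes.
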