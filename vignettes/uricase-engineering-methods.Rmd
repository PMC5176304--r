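---
title: "Methods: computational engineering of a PEGylated therapeutic uricase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: computational engineering of a PEGylated therapeutic uricase}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uoxkit)
```

## The problem

Urate oxidase (uricase) converts uric acid to the soluble product allantoin.
Humans lack a functional uricase, and in severe gout an injected microbial
uricase can clear the body's urate burden. Making a bacterial enzyme into a
tolerable chronic therapeutic raises a chain of computational questions, each
of which this package implements as a reusable, tested stage:

1. **Where can polyethylene glycol (PEG) be attached?** Cysteines engineered
   into a homotetramer must sit on solvent-exposed surface, away from all
   four active sites, and far enough from each other that one PEG chain does
   not block conjugation of the next.
2. **Which sequence liabilities should be edited out?** An integrin-binding
   RGD tripeptide and an unpaired C-terminal cysteine are removed guided by a
   family consensus.
3. **Is the enzyme still active?** Michaelis–Menten parameters are estimated
   from substrate-depletion progress curves.
4. **How long does it last in vivo?** Mono-exponential elimination fits give
   half-life, volume of distribution and clearance.
5. **Will patients' T cells react?** Per-donor stimulation indices with a
   fixed responder rule summarize a PBMC proliferation panel.

Every stage has a synthetic-data generator with planted ground truth, so the
complete workflow runs and is tested without any external downloads.

## Conjugation-site selection

### Solvent-accessible surface area

SASA is computed by the Shrake–Rupley construction, implemented in this
package: each atom's van der Waals sphere is inflated by the probe radius
(default 1.4 Å, a water molecule) and covered with a deterministic
golden-spiral lattice of `n_points` quasi-uniform directions (default 960);
the accessible area is the inflated-sphere area times the fraction of lattice
points not inside any other atom's inflated sphere. A cell-list neighbor
search makes the cost near-linear in atom count and is exact — the test suite
verifies bit-identical agreement with a naive all-pairs implementation.

Numerical properties worth knowing:

* The lattice is deterministic (no RNG), so areas are exactly reproducible.
* Translation invariance is exact. **Rotation invariance is not**: the
  lattice has a fixed orientation in space, so rotating the molecule
  re-samples the binary occlusion test. At 960 points per atom the per-atom
  deviation under rotation is about 1 Å² (roughly one lattice point's worth
  of area); totals agree much more tightly. This is inherent to any
  fixed-lattice Shrake–Rupley and is documented rather than hidden; tests
  assert rotation agreement at the sampling resolution and translation
  agreement at 1e-6.
* Accuracy against closed forms: an isolated sphere is exact to < 0.1% at
  960 points; the two-overlapping-spheres cap formula is matched within 2%.

Two van der Waals radii sets ship (`vdw_radii("default")`: C 1.70 / N 1.55 /
O 1.52 / S 1.80 Å, and `"chothia"`), because published per-residue SASA
values are sensitive to the radii convention and the original site scan did
not record which set produced it. Every report stamps the set used.

Hydrogens and waters are always excluded (heavy-atom convention). By default
**only protein atoms occlude**: the bound substrate is stripped before the
scan so that a candidate surface patch is not counted as buried merely
because the crystal caught a ligand nearby. `occlude_hetero = TRUE` restores
the alternative.

### The three criteria

A residue position is a candidate conjugation site when, **in every
subunit**:

* total residue SASA (backbone + side chain) is strictly `> 100` Å², and
* the distance from its Cα to the C5 atom of *every* bound ligand copy is
  strictly `> 25` Å.

The strict/non-strict distinction mirrors the decision rule exactly
(`> 100`, `> 25`, but `≥ 19.5` for pair separation). Positions lacking a Cα
in any chain are excluded and reported, and the scan reports its own
denominator (the number of positions shared by all chains), which in a real
crystal can differ from the construct's nominal length.

Mutual separation uses the minimum Cα–Cα distance over **all** chain
combinations — same chain and different chains — because a PEG clash is a
physical whole-oligomer constraint. The distance between copies of the *same*
position on different subunits (`self_pair`) is reported as a diagnostic but
does not reject a site: every copy of a chosen site gets conjugated, so
same-position copies are evidently tolerated by design.

`select_sites()` enumerates subsets exhaustively (candidate counts are order
ten, so this is exact and instant). Among equal-size feasible subsets the one
with the largest summed per-position minimum-over-chains SASA wins; exact
ties go to the lexicographically smallest residue numbers. The tie-break is a
package convention — in practice the final choice among feasible sites is a
judgment call (the published tri-cysteine construct swapped one
computationally preferred site for another feasible one without stating
why), so the report retains the full pair matrix and per-site metrics for a
human to re-rank rather than claiming a unique answer.

The structure reader requires the oligomer to be present in the coordinate
file; no symmetry expansion is attempted. Residue correspondence across
subunits is by residue number only — chains whose residue names disagree at
a shared number are an error, never silently realigned.

## Sequence engineering

* **Identity**: Needleman–Wunsch global alignment (Biostrings; BLOSUM62,
  gap open 10, extend 0.5) with identity defined as identical columns over
  the full alignment length including gap columns. Published identity tables
  rarely state their alignment program, matrix or denominator, and values
  can shift by a few percentage points between conventions — so identity
  matrices computed here are comparable to published ones only loosely, and
  the package's own tests assert structural properties (symmetry, diagonal
  100) rather than third-party numbers.
* **Consensus**: per column the most frequent non-gap residue; columns with
  a gap majority are dropped; frequency ties go to the alphabetically first
  residue (an arbitrary but fixed rule, recorded here).
* **Motif repair**: `scan_and_replace_motif()` finds every occurrence of a
  motif (default RGD) and substitutes a residue at a fixed offset within it
  (default R→S, turning RGD into the innocuous SGD).
* **Mass and absorbance**: average masses from the standard residue-mass
  table plus one water, reported in kDa; molar extinction at 280 nm by the
  Gill–von Hippel sum 5500·nTrp + 1490·nTyr + 125·n(cystine). The theoretical
  tetramer mass is four times the monomer's.

The real lead sequence is not redistributed here. A clearly-labelled
synthetic stand-in (`synthetic_uricase_sequence()`, 302 residues) carries the
engineered features — RGD at 49–51, a single C-terminal cysteine inside the
tail `HPIWSNIAGFC` — so the liability-engineering path is exercised end to
end; conclusions about the real protein's composition obviously do not
transfer from it.

## Enzyme kinetics

The substrate-depletion assay reads uric-acid absorbance at 292 nm every
20 s for 10 min at seven substrate levels (400 µM diluted 1:1.6 down to
23.8 µM; `dilution_series()` reproduces the ladder). `initial_rate()`
converts absorbance to concentration via the molar absorptivity (default
12 300 M⁻¹cm⁻¹, the literature convention — the assay's own value was not
recorded; it cancels identically in generator→fit round trips) and takes
minus the OLS slope over an initial window: up to 120 s or 10% substrate
depletion, whichever comes first, minimum 4 points. The window rule is a
package convention, configurable and logged.

`mm_fit()` does Levenberg–Marquardt least squares of v = kcat·E₀·S/(KM+S),
started from kcat₀ = max(v)/E₀ and KM₀ = median(S), unweighted by default
(the generic fitting-software default; weights are exposed). Enzyme
concentration is **monomer-equivalent** µM by default — the published
turnover basis (monomer vs tetramer) was not stated, so the basis is simply
a parameter; kcat is invariant to jointly rescaling E₀ and the rates, which
the tests pin down.

Round-trip design: the synthetic generator integrates dS/dt =
−kcat·E₀·S/(KM+S) by fixed-step RK4 on a 1-s grid (deSolve), far more
accurate than the fit tolerance. For the exact-recovery round trip the
enzyme is set to 1e-3 µM so that less than 0.3% of substrate is consumed
inside the fitting window even at the lowest substrate level — the standard
initial-rate design regime — which makes the OLS rate estimator unbiased to
well below the 0.1% recovery check. At the bench-realistic 0.03 µM
(≈ 1 µg/mL) the estimator picks up a small depletion bias, visible in the
noisy demonstration in `analysis/03_kinetics.R`.

Under 5% multiplicative Gaussian noise on the seven rates, the median
absolute kcat error measures 3–4% across seeds (unweighted or
1/v²-weighted alike); the test asserts the recovery stays inside that
sampling band (< 5%).

The serum assay variant cannot monitor absorbance continuously (serum
absorbs at 292 nm), so reactions are acid-quenched at 0/1/2/4/6 min and read
after deproteinization; `quench_rates()` turns those few points per
concentration into rates by the same slope rule and feeds `mm_fit()`
unchanged.

## Pharmacokinetics

IV profiles are assumed monophasic: `fit_iv_monophasic()` regresses
log-concentration on time over **all** positive-concentration points (no
terminal-phase picking), giving λz, t½ = ln2/λz, back-extrapolated c0,
Vd = dose/c0 and CL = λz·Vd. Concentration units are the caller's; Vd in
L/kg requires conc in mg/L (≡ µg/mL) against a dose in mg/kg. Two exact
points already determine the line, and the fit accepts them. A profile that
is not log-linear (r² < 0.95 by default) triggers a lack-of-fit warning:
biphasic or immune-cleared profiles should not be summarized by this model.
How the published Vd/CL were derived (nominal vs fitted c0, NCA vs
regression) was not stated; this package's convention — fitted c0 — implies
CL = ln2/t½ · Vd, which reproduces the published clearance to within the
rounding of the printed half-life and Vd (≈ 5%).

Subcutaneous profiles confound absorption with elimination, so
`fit_sc_terminal()` only reports the terminal half-life: it locates tmax and
regresses the last `terminal_points` (≥ 3) post-peak samples; Vd and CL are
deliberately omitted for SC data.

## Stimulation-index statistics

Each donor contributes replicate wells (typically 8) of proliferating
CD3⁺CD4⁺ counts per condition. `donor_si()` fits the two condition means by
OLS with condition as the factor — the linear-model formulation — and forms
SI = mean(treated)/mean(reference). The ratio's standard error comes from
the delta method with the model's pooled residual variance; the SI = 1 test
is a two-sided t, and a 95% CI is reported on the same scale. A responder is
SI ≥ 2 **and** p < 0.05; no multiple-testing correction is applied across
donors (the rule is a fixed per-donor threshold, by design). A log-count
analysis would be a reasonable alternative formulation; the plate layout and
any transformation used originally were not printed, so this package's
choice is a documented stand-in.

Two properties of the implementation worth knowing:

* The pooled-variance delta method is conservative when the treated counts
  are much more variable than reference counts (as with strongly stimulated
  wells under negative-binomial noise): at a true SI of 4.2 with dispersion
  0.1 and n = 8, individual-donor p-values hover near 0.05 and roughly half
  the donors clear both gates, even though the population mean SI is
  recovered within a percent. The published positive-control responder rate
  (91%) is therefore not a target the synthetic panel reproduces — the
  original per-well variance structure was not published.
* Reported fractions are unrounded (181/202 = 89.6%, even where a rounded
  "91%" appears in print).

The count generator is negative binomial (variance µ + dispersion·µ²,
dispersion default 0.1 — overdispersed counts are the realistic null for
per-well cell counts), degenerating to Poisson at dispersion 0.

## What the synthetic generators do and do not emulate

The toy oligomer is a Cₙ-symmetric arrangement of three-atom pseudo-residues
with planted surface, buried (cage-enclosed) and exposed-but-near-ligand
sites and a single-atom ligand copy per subunit. It exercises every decision
rule — exposure, distance, all-subunit agreement, pair separation — with
exactly known truth, but has no real protein geometry (no rotamers,
secondary structure, or crystallographic artifacts such as missing loops and
alternate conformations beyond what the reader handles). Passing on it shows
the *rules* are implemented correctly, not that any particular real
structure yields a particular site set. Likewise the kinetic, PK and PBMC
generators produce exactly the model each fitting stage assumes (plus
controlled noise); they validate estimator correctness and calibration, not
model adequacy for real assays.

All generators are pure functions of their parameters and an explicit
integer seed, restore the caller's RNG state, and their defaults are the
study designs themselves: 20-s/10-min sampling at the 7-level dilution
series; rat IV sampling at 0.5–144 h with dose 5 mg/kg; canine SC sampling
at 0.5 h–56 days; 8 replicate wells per condition.

## Problem sizes used by the tests

The test suite runs the sphere-lattice at 96–960 points depending on the
check's tolerance, sweeps 50 randomized toy oligomers against brute-force
enumeration, and simulates 100-replicate noise studies and 200–1000-donor
panels; the whole suite completes in about a minute of CPU. The
`analysis/` drivers use the full 960-point lattice and the complete study
designs.
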