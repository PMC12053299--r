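---
title: "Alignment tensor analysis of residual dipolar couplings"
author: "rdctensor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment tensor analysis of residual dipolar couplings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdctensor)
```

## The model

A small molecule dissolved in a weakly orienting medium (for instance a
lyotropic liquid-crystalline phase of a helical polymer) no longer tumbles
isotropically. The residual dipolar coupling (RDC) between two nuclei then
survives the orientational average, and for a one-bond pair it enters the
total observed splitting as

$$ {}^1T = {}^1J + 2\,{}^1D, $$

so the RDC is extracted as $D = (T - J)/2$ with error
$\sigma_D = \sqrt{\sigma_J^2 + \sigma_T^2}/2$. The orientational average is
captured by the Saupe order matrix $S$, a symmetric traceless $3\times 3$
tensor with five independent elements. For an internuclear unit vector
$\mathbf{e}$ (in the molecular frame) and dipolar prefactor

$$ \kappa = -\frac{\mu_0 \gamma_i \gamma_j h}{16 \pi^3 r^3}, $$

the predicted RDC is $D = \kappa\, \mathbf{e}^{\mathsf T} S\, \mathbf{e}$.
With $n \ge 5$ measured couplings this is a linear system in the unknowns
$(S_{xx}, S_{yy}, S_{xy}, S_{xz}, S_{yz})$ (with
$S_{zz} = -S_{xx} - S_{yy}$); the package solves it by singular value
decomposition after scaling each row by $1/\sigma_D$, so precisely
measured couplings dominate the fit. This is the
single-conformer–single-tensor (SCST) fit, valid for rigid molecules.

Agreement between experiment and structural model is summarized by the
Cornilescu quality factor

$$ Q = \sqrt{\frac{\sum_i (D_{\mathrm{exp},i} - D_{\mathrm{calc},i})^2}
                  {\sum_i D_{\mathrm{exp},i}^2}}, $$

which is reported on unweighted residuals even when the fit itself is
error-weighted; a weighted variant is kept alongside because weighting
conventions differ between established fitting programs. Derived tensor
descriptors follow the conventions dominant in the RDC literature:
principal values ordered by magnitude
($|S_{zz}'| \ge |S_{yy}'| \ge |S_{xx}'|$), generalized degree of order
$\mathrm{GDO} = \sqrt{(2/3)\sum_{ab} S_{ab}^2}$, axial component
$D_a = S_{zz}'/2$ and rhombicity $R = |2(S_{xx}'-S_{yy}')/(3S_{zz}')|
\in [0, 2/3]$.

## Flexible molecules: MCST and the population scan

When a molecule interconverts between conformers faster than it tumbles
(or the conformers are structurally similar), a single common order
tensor can describe the whole ensemble provided all conformers are
expressed in one common reference frame — the Eckart frame. The package
realizes the Eckart conditions through the mass-weighted
RMSD-minimizing proper rotation (the Kabsch construction), which
satisfies the rotational Eckart condition for similar structures. The
multi-conformer–single-tensor (MCST) design matrix is then the
population-weighted sum of the per-conformer design matrices, and one
tensor is fitted exactly as in SCST. With a population vector of
$(1, 0, \dots)$ the MCST fit reduces to the SCST fit bitwise.

For a two-conformer ensemble the population of conformer 1 is scanned
exhaustively over $\{0, 0.01, \dots, 1\}$ and $Q(p_1)$ is minimized;
ties are resolved toward the smaller $p_1$. The default grid step of
0.01 matches the two-decimal precision at which such populations are
conventionally reported; no derivative-based optimizer is used because
the objective is cheap and the exhaustive scan is exact on the grid.
Generalization to more than two conformers is available through
`fitMCST` with an explicit population vector; the scan itself remains
the two-conformer case, which avoids an untested simplex search.

## Comparing tensors: the 5D angle

Two alignment tensors of the same analyte — for example fitted in the
two enantiomers of a chiral alignment medium — are compared through the
generalized angle between their five-dimensional irreducible
representations,

$$ \beta = \arccos\!\left(
   \frac{\langle S_1, S_2\rangle_F}{\|S_1\|_F \, \|S_2\|_F}\right), $$

computed with the numerically stable two-argument arctangent form so
that 0° and 180° are exact. $\beta = 0°$ means the two media orient the
molecule identically (no observable enantiodifferentiation); 90° is
maximal enantiodifferentiation. By default no mirror operation is
applied to either tensor — the two fits are compared directly. A mirror
convention (equivalent to negating the $y$ coordinates of the structure
before one fit, i.e. flipping the signs of $S_{xy}$ and $S_{yz}$) is
exposed as an option because published comparisons differ in this
choice; both conventions are available and the report records which was
used.

## Conformer populations

Conformer-ensemble bookkeeping mirrors standard practice downstream of
conformer sampling: raw Boltzmann-weighted populations are *consumed as
given* rather than recomputed from the relative energies, because
sampling tools fold rotamer degeneracies into their populations that
plain Boltzmann factors of the printed energies do not reproduce.
`boltzmannPopulations` (with $k_B = 0.0019872041$ kcal mol$^{-1}$
K$^{-1}$, default 298.15 K, max-shift stabilized) is provided for
synthetic work. Pruning removes conformers that are *both* above the
energy cutoff (default 2.2 kcal/mol) *and* below the population cutoff
(default 1 %) — the rule is deliberately conjunctive, so a well-populated
high-energy conformer survives. Grouping of conformers that share the
conformation of the analysed fragment is a chemical judgement and is
therefore user-supplied, never inferred; group populations are summed
and renormalized over the retained groups.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `sigmaFloor` | 0.1 | Hz | error floor for records lacking an error estimate; a realistic coupling-extraction precision |
| `svCutoff` | 1e-10 | relative | singular values below this fraction of the largest are truncated; real datasets are far from this regime |
| `weighted` | TRUE | — | rows scaled by $1/\sigma_D$; with equal errors identical to the unweighted fit |
| `step` | 0.01 | population | scan resolution, matching reported precision |
| `eMax`, `pMin` | 2.2, 0.01 | kcal/mol, fraction | conjunctive pruning rule |
| `temperature` | 298.15 | K | Boltzmann weighting |
| `mirror` | FALSE | — | tensor comparison convention |
| `fixedDistance` | none | Å | per-class effective bond length overriding coordinates |

Units are fixed package-wide: Å for coordinates, Hz for couplings,
kcal/mol for energies.

## Numerical choices and degenerate inputs

- The unknown vector is fixed to $(S_{xx}, S_{yy}, S_{xy}, S_{xz},
  S_{yz})$; any five-parameterization is equivalent, and fixing one makes
  fits bit-reproducible.
- Rank-deficient design matrices (e.g. all bonds parallel) are not an
  error: the minimum-norm pseudo-inverse solution is returned with a
  warning flag and an infinite condition number.
- Q is undefined for all-zero experimental RDCs and raises a named
  error, as does a fit on fewer than five included records.
- Methyl groups are modeled by projection on the three-fold rotation
  axis: the effective vector is C(methyl)→C(neighbour) and the averaging
  factor is $P_2(\cos\theta)$ averaged over the three protons (exactly
  $-1/3$ for ideal tetrahedral geometry), with the prefactor taken at
  the mean C–H distance. How established fitting software models methyl
  RDCs is not always documented; this axis-projection choice is the
  common textbook treatment and is validated against constructed ideal
  geometries in the tests.
- Diastereotopic CH$_2$ protons are two independent rigid records;
  exclusion of flexible fragments is done by flagging records
  (`include = FALSE`), never by automatic detection.
- The Eckart superposition subset defaults to all shared heavy atoms
  (hydrogens contribute little mass and their placement is the least
  reliable part of computed geometries); it is configurable to any label
  list. The reference frame defaults to the lowest-energy conformer —
  an arbitrary but reproducible choice; results are frame-covariant.
- $\beta$ is computed as $2\,\mathrm{atan2}(\|u-v\|, \|u+v\|)$ on the
  normalized tensors, avoiding the precision loss of $\arccos$ near its
  endpoints.

## What the synthetic generator emulates — and what it does not

The generator reproduces the statistical regime the analysis assumes:
8–20 C–H vectors in general position (minimum 5° angular separation, so
design matrices are rank 5), alignment strengths GDO $10^{-4}$–$10^{-3}$
giving one-bond CH RDCs in the tens of Hz, homoscedastic Gaussian
coupling noise of 0.1–1 Hz (default 0.3 Hz), scalar couplings
$J \sim N(145, 10^2)$ Hz with $T = J + 2D$, and two-conformer mixtures
generated by rotating half of the vectors by a 40° dihedral about a
common axis — large enough to give clearly distinguishable $Q(p_1)$
curvature at 15 RDCs and 0.3 Hz noise. All generators are
bit-reproducible from a single integer seed, with one offset stream per
generator, and the caller's RNG state is left untouched.

What it does **not** emulate: chemically realistic covalent geometry
(the skeleton is a loose helix, not an optimized structure), strong
proton–proton coupling artifacts in coupling extraction, heteroscedastic
or systematic errors, anisotropic vibrational corrections to effective
bond lengths, and conformer ensembles beyond the two-state dihedral
model. Passing the synthetic tests therefore demonstrates the
correctness of the linear-algebraic machinery and the population scan,
not the adequacy of any particular experimental structural model —
judging that requires real coupling tables and optimized geometries
supplied by the user.

## Problem sizes used in the tests

The shipped test-suite and the acceptance script use 5–20 vectors per
molecule, 100 random systems for the solver cross-check, 1000 random
rotations for the superposition minimality check, and 50 simulated
two-conformer datasets ($p_1$ uniform on $[0.1, 0.9]$, 15 RDCs, 0.3 Hz
noise) for the population-recovery study, where the median absolute
population error is required to stay within 0.05 — comfortably achieved
(typically below 0.03). These sizes were chosen to exercise every code
path at tight tolerances while keeping a full run in the order of
seconds.

## A worked example

```{r example}
spec <- simulationSpec(nVectors = 15, noiseSigma = 0.1, seed = 11,
                       geometry = "two-conformer-dihedral")
sys <- makeTwoConformerSystem(spec)
S <- randomSaupe(5e-4, seed = 11)
confs <- list(sys$conformerA, sys$conformerB)
ds <- simulateRDCs(confs, S, pops = c(0.8, 0.2), spec = spec,
                   pairs = sys$pairs)
scan <- scanPopulations(confs, ds, step = 0.01)
scan
```

The scan recovers the mixing fraction from the minimum of $Q(p_1)$;
the endpoint fits correspond to the two single-conformer hypotheses.

## Known limitations

- Only $^{13}$C–$^1$H and $^{13}$C–$^{13}$C prefactors are tabulated;
  RCSA and quadupolar observables are out of scope.
- No bootstrap or Monte-Carlo error ellipsoids on tensor elements.
- No homonuclear $^1$H–$^1$H RDCs and no treatment of vibrational
  corrections to effective distances beyond the fixed-distance option.
- The population scan is two-conformer; larger ensembles require an
  explicit population vector.
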