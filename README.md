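# rdctensor

Alignment tensor analysis of residual dipolar couplings (RDCs) for small
molecules in weakly orienting media.

## The problem

One-bond RDCs measured in a partially aligning medium (for example a
lyotropic liquid-crystalline phase of a helical polymer) carry global
orientational information about a molecule: each coupling reports on the
direction of its internuclear vector relative to the molecule's average
orientation. That average is encoded by the Saupe order matrix **S**, a
symmetric traceless 3×3 tensor with five independent elements. For a
structural model with unit bond vectors **e**ᵢ and dipolar prefactors
κᵢ = −μ₀γᵢγⱼh/(16π³r³), the measured couplings obey the linear model

    Dᵢ = κᵢ eᵢᵀ S eᵢ ,    with D = (T − J)/2  from  ¹T = ¹J + 2¹D.

`rdctensor` is aimed at practitioners of anisotropic NMR who need to

- extract RDCs from scalar/total coupling tables with error propagation,
- fit **S** to a rigid conformer by error-weighted SVD
  (single-conformer–single-tensor, **SCST**) and judge the structural
  model by the Cornilescu quality factor
  Q = √(Σ(D_exp − D_calc)² / ΣD_exp²),
- fit one common tensor to a population-weighted conformer ensemble
  superposed in an Eckart frame (multi-conformer–single-tensor,
  **MCST**) and locate the population minimizing Q(p₁),
- compare two alignment tensors through the generalized 5D angle β
  (0° = no enantiodifferentiation, 90° = maximal),
- handle conformer-population bookkeeping (Boltzmann weights, conjunctive
  energy/population pruning, grouping, normalization),
- and generate synthetic structures, tensors and coupling tables to
  validate every stage without experimental data.

The methods vignette (`vignettes/rdc-tensor-analysis.Rmd`) documents the
model, conventions and numerical choices in detail.

## Worked example

Simulate a two-conformer mixture (80 % / 20 %) with 15 C–H RDCs, 0.1 Hz
Gaussian noise and GDO 5×10⁻⁴, then recover the mixing fraction by an
MCST population scan:

```r
library(rdctensor)

spec <- simulationSpec(nVectors = 15, noiseSigma = 0.1, seed = 11,
                       geometry = "two-conformer-dihedral")
sys  <- makeTwoConformerSystem(spec)
S    <- randomSaupe(5e-4, seed = 11)
confs <- list(sys$conformerA, sys$conformerB)
ds   <- simulateRDCs(confs, S, pops = c(0.8, 0.2), spec = spec,
                     pairs = sys$pairs)

scan <- scanPopulations(confs, ds, step = 0.01)
scan
#> EnsembleFit: population scan over 101 points
#>   Q(p1=1) = 0.0709, Q(p1=0) = 0.1918
#>   minimum: Q(0.75) = 0.0161

fitTensor(bestFit(scan))
#> SaupeTensor
#>   principal values: 1.052e-04 3.702e-04 -4.754e-04
#>   GDO = 4.994e-04, Da = -2.377e-04, R = 0.372
```

Reading the output: either single-conformer hypothesis fits worse
(Q = 0.071 for conformer 1 alone, Q = 0.192 for conformer 2 alone) than
the ensemble at the scanned minimum p₁ = 0.75 (Q = 0.016), close to the
true 0.80 — the expected behaviour for a genuine two-state mixture. The
fitted tensor's GDO (4.99×10⁻⁴) recovers the simulated alignment
strength.

File-based workflows (`runFit`, `runScan`, `runCompare`, `runExtract`,
`runSimulate`, `runPopulations`) read XYZ/PDB structures and
tab-delimited coupling tables and write JSON plus aligned-text reports;
a thin command-line dispatcher is installed at
`inst/scripts/rdctensor.R`:

```sh
Rscript inst/scripts/rdctensor.R simulate --out sim --seed 3
Rscript inst/scripts/rdctensor.R fit --structure sim/conf.xyz \
        --couplings sim/couplings.tsv --out fit
```

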