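# cdftools

Conceptual-DFT reactivity descriptors and Koopmans-compliance diagnostics
for molecular prospection.

## What it is for

Screening candidate molecules — here, marine cyclodepsipeptides of the
apratoxin family, but the machinery is molecule-agnostic — by their
chemical-reactivity profile computed from quantities any Kohn–Sham DFT run
already produces: the frontier-orbital energies ε<sub>H</sub> (HOMO) and
ε<sub>L</sub> (LUMO) of the neutral molecule, optionally the SOMO energy of
its radical anion, and optionally the ground-state total energies of the
N−1, N and N+1 electron systems. The package is the descriptor layer on top
of those numbers; it runs no electronic-structure calculations itself.

For computational medicinal chemists it answers, per molecule:

* **Can the orbital energies be trusted?** The "Koopmans in DFT" (KID)
  residuals J<sub>I</sub> = ε<sub>H</sub> + E(N−1) − E(N),
  J<sub>A</sub> = ε<sub>L</sub> + E(N) − E(N+1),
  J<sub>HL</sub> = √(J<sub>I</sub>² + J<sub>A</sub>²) and
  ΔSL = ε<sub>SOMO</sub>(anion) − ε<sub>L</sub> quantify how well the model
  chemistry fulfils the ionization-energy and Janak theorems
  (`kidAssess()`).
* **How reactive, and in which direction?** Electronegativity
  χ = −(ε<sub>H</sub>+ε<sub>L</sub>)/2, chemical potential μ = −χ, global
  hardness η = ε<sub>L</sub>−ε<sub>H</sub>, softness S = 1/η,
  electrophilicity ω = χ²/2η, electrodonating/electroaccepting powers
  ω<sup>−</sup> = (3ε<sub>H</sub>+ε<sub>L</sub>)²/16η,
  ω<sup>+</sup> = (ε<sub>H</sub>+3ε<sub>L</sub>)²/16η, net electrophilicity
  Δω<sup>±</sup> = ω<sup>−</sup>+ω<sup>+</sup>, and the nucleophilicity
  index N = ε<sub>H</sub> − ε<sub>H</sub>(tetracyanoethylene), with
  strong/moderate/marginal class labels on the standard scales
  (`computeGlobalDescriptors()`).
* **Roughly how acidic?** A linear hardness QSAR,
  pK<sub>a</sub> = 16.3088 − 0.8268 η (`pkaFromHardness()`).
* **Where on the molecule?** Finite-difference Fukui functions
  f<sup>±</sup> and the dual descriptor
  Δf = ρ<sub>N+1</sub> − 2ρ<sub>N</sub> + ρ<sub>N−1</sub> on electron-density
  grids read from Gaussian cube files, with sign-partitioned cube export
  for visualization (`dualDescriptor()`, `signPartition()`).

A deterministic synthetic-data generator (`generateEnergyRecords()`,
`generateDensityTriplet()`) produces energy records with known injected
Koopmans residuals and density triplets with exact electron counts, so the
whole pipeline is testable without quantum-chemistry software.

## Worked example

The seven apratoxins A–G, with frontier-orbital energies at
MN12SX/Def2TZVP in SMD water, ship with the package:

```r
library(cdftools)
bundle <- runPipeline(records = apratoxinFixture())
print(bundle)
```

```
ReportBundle: 7 molecule(s)

KID diagnostics (tolerance 0.15 eV):
 id ji ja jhl delta_sl tolerance passed
  A NA NA  NA     0.04      0.15   TRUE
  B NA NA  NA     0.04      0.15   TRUE
  C NA NA  NA     0.03      0.15   TRUE
  D NA NA  NA     0.00      0.15   TRUE
  E NA NA  NA     0.02      0.15   TRUE
  F NA NA  NA     0.03      0.15   TRUE
  G NA NA  NA     0.02      0.15   TRUE

Global reactivity descriptors (eV; softness eV^-1):
 id  chi  eta omega softness nucleophilicity omega_minus omega_plus
  A 3.73 5.02  1.39     0.20            2.55        4.95       1.22
  B 3.97 4.46  1.77     0.22            2.59        5.80       1.83
  C 3.90 4.28  1.78     0.23            2.75        5.77       1.87
  D 3.80 4.84  1.49     0.21            2.57        5.19       1.39
  E 3.88 4.39  1.72     0.23            2.71        5.65       1.77
  F 3.80 4.79  1.50     0.21            2.60        5.20       1.41
  G 3.96 4.33  1.81     0.23            2.67        5.86       1.91
 net_electrophilicity    mu electrophile_class nucleophile_class
                 6.17 -3.73           moderate          moderate
                 7.63 -3.97             strong          moderate
                 7.64 -3.90             strong          moderate
                 6.57 -3.80           moderate          moderate
                 7.42 -3.88             strong          moderate
                 6.61 -3.80             strong          moderate
                 7.77 -3.96             strong          moderate

pKa (hardness QSAR):
 id  eta pka_qsar
  A 5.02    12.16
  B 4.46    12.62
  C 4.28    12.77
  D 4.84    12.31
  E 4.39    12.68
  F 4.79    12.35
  G 4.33    12.73

Class counts - electrophile: strong:5 moderate:2 marginal:0 
             nucleophile: strong:0 moderate:7 marginal:0
```

Reading it: the ground-state energies of the ionic states were not
published for this set, so the J columns are absent and compliance rests on
ΔSL, which is at most 0.04 eV — far inside the 0.15 eV band. Apratoxin A is
the hardest (η = 5.02 eV, least reactive) and C the softest; all seven are
moderate nucleophiles; A and D sit in the moderate electrophile band (D's
recomputed ω = 1.49 eV falls just below the strict 1.5 eV cutoff — a
boundary case discussed in the vignette). The QSAR pK<sub>a</sub> values of
12.2–12.8 mark the peptides as very weak acids.

`runPipeline(pipelineConfig(output_dir = "report"))` additionally writes
each table as full-precision CSV and JSON plus display-rounded Markdown,
deterministically.

## Where things live

| Need | Entry point |
|---|---|
| Read/write energy records (CSV/TSV, eV or hartree) | `readEnergyRecords()`, `writeEnergyRecords()` |
| Parse the minimal QM log dialect | `parseSimpleLog()`, `generateLogText()` |
| Gaussian cube I/O | `readCube()`, `writeCube()` |
| KID compliance | `computeJI()`, `computeJA()`, `computeJHL()`, `computeDeltaSL()`, `kidAssess()` |
| Global descriptors + classes | `computeGlobalDescriptors()` and the per-descriptor functions |
| Nucleophilicity reference | `calibrateNucleophilicityReference()`, `defaultNucleophilicityReference()` |
| pKa QSAR | `pkaFromHardness()`, `pkaModel()` |
| Local fields | `fukuiPlus()`, `fukuiMinus()`, `dualDescriptor()`, `condensedDual()`, `signPartition()`, `fieldIntegral()` |
| Synthetic data | `syntheticSpec()`, `generateEnergyRecords()`, `generateDensityTriplet()` |
| Orchestration | `pipelineConfig()`, `runPipeline()`, `summarizeClasses()` |

The methods vignette (`vignettes/conceptual-dft-reactivity.Rmd`) documents
the model, the sign and boundary conventions, the calibration of the
nucleophilicity reference, the rounding-propagation limits of reproducing
printed tables, and the known discrepancy between the hardness QSAR and
externally predicted pK<sub>a</sub> values.
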