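# fepnet

Analysis toolkit for **relative binding free-energy (RBFE) perturbation
networks** on congeneric ligand series — the kind of dataset produced by
alchemical free-energy protocols in hit-to-lead drug discovery.

Alchemical calculations morph ligand *X* into ligand *Y* along a coupling
parameter λ, once free in solvent and once bound to the protein, giving

ΔΔG(X→Y) = ΔG_complex(X→Y) − ΔG_free(X→Y).

`fepnet` takes the raw per-λ reduced-potential samples of every leg and
carries them through the complete analysis chain:

* **MBAR estimation** of per-leg free energies (self-consistent solver
  with Newton acceleration, log-sum-exp throughout, asymptotic
  uncertainties; BAR and exponential averaging included as two-state
  cross-checks) — implemented in compiled code via Rcpp;
* **network assembly**: leg subtraction, repeat aggregation
  (mean ± s/√n), Boltzmann collapse of racemic ligands measured per
  enantiomer: ΔΔG = −kT·ln[½(exp(−ΔΔG_R/kT) + exp(−ΔΔG_S/kT))];
* **reconstruction of absolute ΔG** by weighted least squares over all
  directed edges, anchored at a reference ligand via
  ΔG = RT·ln(Ki/C⁰), C⁰ = 1 mol/L;
* **diagnostics**: hysteresis (forward + reverse), thermodynamic cycle
  closures over all simple cycles up to length 4, threshold flagging
  (default |closure| ≥ 0.8 kcal/mol) and a ranking of implicated
  ligands — a pose-problem detector that needs no experimental data;
* **benchmarking**: R², MUE and slope against experimental inhibition
  constants, with parametric-bootstrap uncertainties under an assumed
  experimental error (0.4 kcal/mol default) and the achievable-R² upper
  bound that error implies;
* a **synthetic-data generator** with exactly solvable Gaussian λ-states
  and known ground truth, emulating a 15-ligand two-batch kinase
  (ACK1-style) network with configurable pose/water biases and repeat
  noise, used to validate the whole pipeline end to end.

The package ships the published cycle-closure table of the ACK1 inhibitor
benchmark (`ack1_cycle_closures()`) for demonstrating threshold flagging
on real reported values.

## Worked example

Simulate a deliberately degraded scenario (preset "A": misposed ligands
and a missing binding-site water), analyse it, and look at what the
diagnostics find:

```r
library(fepnet)

cfg      <- protocol_scenario("A", samples_per_state = 200L, seed = 42)
scenario <- generate_scenario(cfg)
analysis <- analyze_scenario(scenario, n_boot = 1000, boot_seed = 1)
print(analysis)
#> <fepnet_analysis>
#> <fepnet_network> 17 ligands, 44 directed edges, reference 3 (-6.86 kcal/mol)
#> <flag_report> 14 of 42 cycles flagged at |closure| >= 0.80 kcal/mol
#> top implicated ligands: 6 (5), 3 (4), 16 (3), 2 (3), 4 (3)
#> <metrics_report A> n = 15
#>   R2    0.61 +/- 0.07
#>   MUE   0.97 +/- 0.10 kcal/mol
#>   slope 0.73 +/- 0.06
```

Reading the output: 14 thermodynamic cycles close worse than
0.8 kcal/mol, and the implication ranking points at ligands 6 and 16 —
ligand 6 is one of the generator's true water-defect ligands and 16 one
of its misposed ligands, so the detector works without ever seeing the
experimental affinities. The benchmark metrics (R² 0.61, MUE ~1 kcal/mol
against the noisy synthetic assay) quantify how much the injected set-up
problems cost; rerunning with `protocol_scenario("D", ...)` (both
problems fixed) recovers R² = 0.89 and drops the MUE to 0.45 kcal/mol.

Per-ligand reconstructed binding free energies live in `analysis$dg`:

```r
head(analysis$dg)
#>   id         dg      sigma resolvable
#> 2  2  -8.964752 0.07596286       TRUE
#> 1  3  -6.863546 0.00000000       TRUE
#> 3  4 -11.995933 0.07055812       TRUE
#> 4  5  -7.582473 0.07559930       TRUE
#> 5  6  -9.825312 0.05906060       TRUE
#> 6  7  -9.939439 0.04681223       TRUE
```

The same steps are scriptable from a shell through the thin CLI at
`inst/scripts/fepnet-cli.R` (`simulate`, `estimate`, `network`,
`diagnose`, `evaluate` subcommands). Its `demo-ack1` subcommand applies
the 0.8 kcal/mol threshold to the packaged published closures:

```text
$ Rscript inst/scripts/fepnet-cli.R demo-ack1
protocol A: 6 of 12 cycles at |closure| >= 0.8 kcal/mol  [ 2-6-5, 3-4-7-6, 4-6-7, 3-4-7, 3-4-6, 45-16-44 ]
protocol B: 1 of 12 cycles at |closure| >= 0.8 kcal/mol  [ 45-16-44 ]
protocol C: 4 of 12 cycles at |closure| >= 0.8 kcal/mol  [ 3-4-7-6, 3-7-6, 4-6-7, 45-16-44 ]
protocol D: 1 of 12 cycles at |closure| >= 0.8 kcal/mol  [ 45-16-44 ]
protocol E: 1 of 10 cycles at |closure| >= 0.8 kcal/mol  [ 3-2-5-6 ]
```

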