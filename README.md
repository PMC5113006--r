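# sidepop

Multiscale simulation and analysis of the Hoechst 33342 **side-population
(SP) assay**.

The SP assay detects cells with active ABC-transporter (ABCG2/BCRP) dye
efflux: a sample is split into a transporter-inhibited (+FTC) and an
uninhibited (−FTC) half, both are stained with Hoechst 33342, and the cells
that stain *less without inhibitor* — the side population, enriched for
stem-like and drug-resistant phenotypes — appear as a dim tail in the
Hoechst Red/Blue plane of a flow cytometer. The assay readout depends on
staining kinetics, transporter expression heterogeneity and gating
conventions in ways that are hard to disentangle experimentally; `sidepop`
provides the full in-silico counterpart, for systems biologists and
cytometrists who want to ask *which kinetic regimes can produce an SP at
all, and what single-cell behaviour hides under a population gate*.

## What it does

* **Single-cell kinetics** — each cell is a three-compartment mass-action
  ODE system in five Hoechst species (cytosolic free `x1`, DNA-bound `x2`,
  cytosolic transporter-bound `x3`, nuclear free `x4`, nuclear
  transporter-bound `x5`), e.g.
  `dx1/dt = r1 − r4 + r6/V_C + (V_N/V_C)·r8` with
  `r1 = k3·(A_C/V_C)·(H_e − x1)` the membrane influx and `r5 = k5·x3` the
  efflux to the bath; conserved DNA-site and transporter totals enter
  algebraically. Integration uses a compiled right-hand side with a
  stiff-capable solver, and cells/populations that exhaust their work or
  time budget are *aborted and flagged*, never silently dropped.
* **Population heterogeneity** — Latin hypercube sampling of gridded
  reference distributions (joint cell/nuclear radii, DNA content,
  transporter expression), with three transporter heterogeneity modes:
  concentration-uniform (I), number-uniform (II) and
  experimental-distribution with Hill cooperativity
  `θ(T) = T^k8/(k9^k8 + T^k8)` (III).
* **In-silico flow cytometry** — DNA-bound vs free amounts mapped to
  Hoechst Red/Blue signals through a 2×2 spectral matrix (quantum yield ×
  excitation efficiency × emission overlap).
* **Analysis** — Hoechst Score z-transforms anchored to the +FTC condition,
  automated %SP by projection gating (`H_proj = (HRS+HBS)/√2`, gate at the
  +FTC 1st percentile), Whittaker-smoothed 2D score densities, ΔFTC/ΔSP
  difference surfaces, overlap and cross-correlation metrics.
* **Ensemble screening** — log-space LHCS designs over the kinetic
  parameter ranges, a five-part qualitative SP-response selection battery,
  NRMSE fit scoring `1 − ‖sim − ref‖/‖ref − mean(ref)‖`, and single-cell
  response classification by standardized skewness and the bimodality
  coefficient `BC = (skew² + 1)/kurtosis`.
* **Synthetic references** — a seeded generator for reference
  distributions and experimental-like event tables (all defaults declared
  synthetic), including self-consistent ground-truth references built by
  the simulator itself for parameter-recovery testing.

## Worked example

```r
library(sidepop)

ref    <- generate_reference_distributions(seed = 42)  # synthetic reference bundle
pop    <- sp_population(ref, 100, seed = 42)           # 100-cell in-silico population
pop
#> In-silico cell population: 100 cells (seed 42)
#>   cell radius   6.67-14.67 um, nuclear radius 3.22-8.54 um
#>   DNA level     0.79-2.31 (mode-normalized)

params <- sp_demo_params()                             # efflux-competent kinetics
ens    <- run_ensemble(params, pop, mode = "III", ref = ref)
ens
#> SP ensemble (mode III, 100 cells/condition):
#>   %SP by condition:       24.00  12.00  2.00  1.00
#>   mean dHRS by condition: -0.655  -0.369  -0.077  -0.002
```

The four conditions are the untreated control (highest transporter
expression) down to the highest TGFβ dose; the SP shrinks from 24% to ~1%
as expression falls, and the mean Hoechst Red Score shift `dHRS` shows the
uninhibited population staining progressively less than its inhibited
twin. The selection battery and fit score against the reference:

```r
evaluate_selection_criteria(ens, ref)$criteria
#>   staining_decrease             overlap   shift_correlation surface_correlation
#>                TRUE                TRUE                TRUE                TRUE
#>             sp_size
#>                TRUE
nrmse_fit_score(ens$percent_sp, ref$exp_sp)
#> [1] 0.4215328

ens$conditions[[1]]$response
#> Single-cell SP response: 100 cells, skewness 2.314, kurtosis 7.856, BC 0.809 (Subpopulation)
```

This ensemble passes all five criteria, fits the reference %SP vector with
an NRMSE score of 0.42 (1 would be perfect), and its control-condition
single-cell responses form a *Subpopulation*-type distribution: a distinct
strongly-effluxing minority (high skewness, bimodality coefficient 0.81)
rather than a uniform population-wide shift.

A full screen of random kinetic parameter space:

```r
scr <- sp_screen(ref, M = 100, N = 100, mode = "III", seed = 1)
scr
#> LHCS side-population screen: M = 100 parameter sets, mode III, N = 100 cells
#>   aborted: 2 | passing: 3 | failing: 95 (96.9% of non-aborted)
#>   best fit score among passing sets: 0.1806
```

Most random kinetic regimes cannot produce a coherent SP response — the
selection battery exists precisely to find the rare ones that can.

A thin command-line wrapper over these functions is included:
`Rscript inst/scripts/sidepop screen --M 100 --N 100 --seed 1 --out results/`
(see `--help` for the `synth` and `screen` subcommands).

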