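# clathrakit

Thermokinetic and spectral characterization of host–guest inclusion
complexes (clathrates), built around the classic evidence triad used for
cyclodextrin complexes such as anabasine–β-cyclodextrin:

* **Decomposition kinetics.** Four model-fitting estimators of the Arrhenius
  triplet (activation energy *E*, reaction order *n*, pre-exponential factor
  *A*) of a thermogravimetric decomposition step under linear heating
  dα/dT = (A/β)·e^(−E/RT)·(1−α)^n — **Freeman–Carroll** (difference plot,
  slope −E/2.303R, intercept n), **Sharp–Wentworth**
  (log₁₀[(dc/dT)/(1−c)] vs 1/T, first order assumed), **Achar**
  (differential model fitting over an order grid) and **Coats–Redfern**
  (integral fitting of ln[g(α)/T²] vs 1/T) — plus a cross-method consensus
  check on *E*.
* **NMR shift displacements.** Δδ = δ(complex) − δ(free) per nucleus/site,
  ranking of host cavity protons (H-3/H-5 for cyclodextrins), guest-moiety
  attribution, and an audit that flags printed table cells inconsistent with
  their own arithmetic.
* **FTIR band shifts.** Tolerance-bounded nearest-pair matching of band
  maxima between free host and complex, with a covalent-change flag.

Because experimental TGA curves behind published kinetic tables are rarely
deposited, the package includes a forward simulator (fixed-step RK4, seeded
noise, ground-truth metadata) so every estimator is validated by parameter
recovery on synthetic curves with known *E*, *n*, *A*.

## Worked example

Simulate the default two-step clathrate curve (bound-water dehydration +
main decomposition, 10 K/min), run all three evidence streams, and print the
assembled report:

```r
library(clathrakit)
rep <- run_pipeline(list(
  tga  = list(synthetic = list(seed = 1)),   # defaults: dehydration + E=150 kJ/mol main step
  nmr  = list(builtin = TRUE),               # published anabasine/β-CD shift tables
  ftir = list(builtin = TRUE)
), verbose = FALSE)
print(rep)
```

```
<evidence_report>
<consensus_report> 4 methods | E = 149.94 +/- 0.17 kJ/mol | spread 0.2% | in agreement
<kinetic_fit:freeman_carroll> E = 150.03 kJ/mol | n = 1 | A = - /min | R^2 = 1.00000 | 132 pts
<kinetic_fit:sharp_wentworth> E = 150.03 kJ/mol | n = 1 | A = 1e+12 /min | R^2 = 1.00000 | 232 pts
<kinetic_fit:achar> E = 150.00 kJ/mol | n = 1 | A = 1e+12 /min | R^2 = 1.00000 | 232 pts
<kinetic_fit:coats_redfern> E = 149.69 kJ/mol | n = 1 | A = 8.81e+11 /min | R^2 = 1.00000 | 232 pts
<inclusion_evidence> top host sites: 3, 5 | cavity {3,5} hit: TRUE | guest moiety: piperidine
<ftir> 6 matched bands | max |shift| 12.0 cm^-1 | covalent suspicion: FALSE
evidence supports inclusion-complex formation (kinetic methods agree on E; cavity protons
carry the largest host shifts; FTIR shifts consistent with non-covalent inclusion)
```

Reading it: the four kinetic methods recover the simulated step's true
activation energy (150 kJ/mol) within a 0.2% spread, so the consensus flag
is up; the largest host proton displacements sit on H-3 (+0.125 ppm) and
H-5 (+0.110 ppm), the two protons lining the cyclodextrin cavity — the NMR
signature of a guest inside the cone, with the guest's piperidine ring the
inserted moiety; and the host O–H band shift (3387 → 3375 cm⁻¹, i.e.
12 cm⁻¹) is small, consistent with non-covalent inclusion.

The individual stages are plain functions when you want them separately:

```r
spec  <- sim_spec(decomposition_step(E_a = 150, A = 1e12, n = 1),
                  T_start = 465, T_end = 775, n_points = 2000)
curve <- simulate_tga(spec)                      # or read_tga("run.csv")
dtg   <- compute_dtg(curve)                      # Savitzky–Golay DTG
steps <- segment_steps(curve, dtg)               # step boundaries
conv  <- compute_conversion(curve, unlist(steps[1, c("T_lo", "T_hi")]), dtg)
coats_redfern(conv)
#> <kinetic_fit:coats_redfern> E = 149.70 kJ/mol | n = 1 | A = 8.86e+11 /min | R^2 = 1.00000 | 673 pts
```

A thin command-line wrapper with subcommands `simulate`, `dtg`, `kinetics`,
`shifts`, `ftir`, `report` lives at `inst/cli/clathrakit.R`
(`system.file("cli", "clathrakit.R", package = "clathrakit")` after
installation).

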