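# sirteq

Radiobiological equivalence of yttrium-90 radioembolisation (SIRT) and
external-beam radiotherapy (EBRT), for radiation biologists and medical
physicists working with clonogenic survival data from protracted
beta-particle exposures.

Y-90 SIRT delivers its dose over days as the source decays
(T<sub>phys</sub> = 64.1 h), so sublethal-damage repair during delivery
suppresses the quadratic term of the linear-quadratic (LQ) survival
model. `sirteq` implements the full chain needed to compare such an
exposure with acute EBRT:

- **Dosimetry** — cumulated absorbed dose for a cell monolayer exposed
  to a decaying Y-90 source whose S-value drifts linearly as medium
  evaporates:
  D(T) = (A0/λ)[(S_f − S_i)/(λT)·(1 − (1 + λT)e^(−λT)) + S_i(1 − e^(−λT))],
  with packaged monolayer S-values per dish position and formulation.
- **LQ survival fitting** — −ln(SF) = αD + βD² fitted as a
  random-intercept mixed model (one intercept per biological repeat) by
  restricted maximum likelihood, with delta-method standard errors for
  α/β and Wald tests of α and β.
- **Dose protraction** — the Lea–Catcheside factor G for a
  mono-exponentially decaying dose rate, in closed form for finite
  exposures; its fully-decayed limit G<sub>∞</sub> = T_rep/(T_rep + T_phys);
  and inversion of G for the repair half-time T_rep from the β ratio of
  the protracted and acute fits.
- **BED / EQD conversion** — BED = nd(1 + d/(α/β)) for fractionated
  EBRT, BED = D(RBE_max + G∞·D/(α/β)) for Y-90, and the equivalent
  EBRT dose in d-Gy fractions, EQD = BED/(1 + d/(α/β)).
- **Simulation** — a clonogenic-assay generator (Poisson colony counts,
  plating efficiency, replicate-level random effects, dose ladders built
  from the stack dosimetry) so every stage is testable end to end.

## Worked example

Derive the Y-90 modelling parameters of the two colorectal cancer cell
lines (DLD-1, HT-29) from the packaged LQ constants:

```r
library(sirteq)
equivalence_table(D = 60, d = c(2, 10))
#>  cell_line rbe_max      g_T t_rep_h    g_inf ab_ebrt ab_y90_inf  eqd2 eqd10
#>      DLD-1  0.3883 0.057672  2.5139 0.037739  14.444      148.6 28.73 19.32
#>      HT-29  1.8000 0.005109  0.2143 0.003331   1.812      978.8 54.48 17.58
```

Reading the DLD-1 row: Y-90 beta particles have 0.39 times the
intrinsic per-Gy effectiveness of 6 MV x-rays (`rbe_max`); the ratio of
the quadratic coefficients implies a 6 d protraction factor of 0.058
(`g_T`), which the Lea–Catcheside inversion turns into a 2.5 h repair
half-time and a fully-decayed factor of 0.038 (`g_inf`). A 60 Gy Y-90
absorbed dose is then biologically equivalent to only 28.7 Gy of EBRT
in 2 Gy fractions (`eqd2`) — protraction makes Y-90 much less potent
per Gy for this line. For radioresistant HT-29 (α/β = 1.8 Gy) the same
60 Gy corresponds to 54.5 Gy in 2 Gy fractions.

The analysis scripts run the same machinery as a narrative workflow:

```sh
Rscript analysis/01_dose_tables.R    # stack dosimetry: 0.67-30.9 Gy ladder
Rscript analysis/02_simulate_assays.R
Rscript analysis/03_fit_survival.R   # mixed-model fits + T_rep recovery
Rscript analysis/04_equivalence.R    # the table above + EQD curves
```

each writing its tables under `results/`.

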