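# cscdyn

Population dynamics of interconverting cancer stem cells (CSCs) and
non-stem cancer cells (NSCCs), for researchers studying tumour
heterogeneity and phenotypic plasticity. Two classic pictures compete:
the hierarchical (CSC) model, where a distinct stem compartment feeds the
bulk by differentiation, and the stochastic model, where phenotypes
interconvert. `cscdyn` implements a model that coordinates both — a
hierarchy *plus* spontaneous NSCC-to-CSC transitions — and the analyses
that discriminate between them, parameterised by in-situ measurements on
the SW620 colon cancer line (CD133+ = CSC).

## The model

CSCs divide at rate $K_C$/day: self-renewal ($P_S$, two CSCs), asymmetric
($P_A$, one of each), differentiation ($P_D$, two NSCCs). NSCCs divide at
$K_N$, both daughters ageing one generation, and senesce at generation
$M$ (death rate $d$); any NSCC converts to a CSC at rate $K_T$,
independent of mitosis. With $C$ CSCs and $N_i$ NSCCs of generation $i$:

$$\dot C = K_C e C + K_T \sum_i N_i, \qquad
\dot N_1 = K_C(1-e)C - (K_N+K_T)N_1,$$
$$\dot N_i = 2K_N N_{i-1} - (K_N+K_T)N_i, \qquad
\dot N_M = 2K_N N_{M-1} - (d+K_T)N_M,$$

where $e = P_S - P_D$ is the only combination of division probabilities
that matters. The package provides:

* the structured ODE model with equilibrium and ±1% sensitivity analysis
  of the long-run CSC proportion;
* a radiation extension: DSB induction $kD$, exponential repair ($r_C$,
  $r_N$), pairwise lethal mis-repair hazard $m U(t)^2/2$, and the survival
  inversion $m = -\ln S \cdot 4r/(kD)^2$;
* a compiled 200×200 lattice cellular automaton counterpart (von Neumann
  neighbourhoods, quiescence when crowded, serial-passage protocol for
  multi-week runs);
* simulated-annealing fitting of $(K_C, K_N, e)$ under $K_T = 0$ to test
  whether imperfect flow sorting ($\theta\%$ contamination) alone explains
  phenotypic equilibrium;
* synthetic-data generators (division-event counts, one-day sorted counts,
  noisy proportion time courses) with matching estimators for recovery
  studies.

## Worked example

Culture purified NSCCs and watch the CSC share return:

```r
library(cscdyn)
kp <- kinetic_params()   # measured SW620 values
tr <- integrate_model(kp, population_state(csc = 0, nscc = 1000, m_gen = 50),
                      t_end = 26, dt_out = 2)
round(tr[c(1:5, 13:14), ], 4)
#>    time_days    csc_count   nscc_total csc_proportion
#> 1          0 0.000000e+00 1.000000e+03         0.0000
#> 2          2 1.537484e+03 2.515820e+03         0.3793
#> 3          4 9.665656e+03 8.433251e+03         0.5340
#> 4          6 4.941375e+04 3.444308e+04         0.5893
#> 5          8 2.392876e+05 1.542707e+05         0.6080
#> 13        24 6.004046e+10 3.721155e+10         0.6174
#> 14        26 2.836158e+11 1.757771e+11         0.6174
```

Even from a CSC-free start, transitions ($K_T = 0.269$/day) regenerate the
stem compartment and the proportion settles at ~0.617 by day 26 — the
same value reached from pure-CSC or mixed starts. The 1-D reduction finds
the same attractor analytically:

```r
find_equilibria(kp, method = "reduced")
#>           R stability
#> 1 0.6173711    stable
```

How delicate is it? One-percent parameter perturbations move the
equilibrium by at most ~1.1%, and the senescence lifespan barely matters:

```r
sensitivity_analysis(kp)
#>    parameter direction percent_change
#> 1        K_T       -1%          -0.30
#> 2        K_T       +1%           0.30
#> 3        K_N       -1%           0.45
#> 4        K_N       +1%          -0.46
#> 5        K_C       -1%          -0.16
#> 6        K_C       +1%           0.15
#> 7          e       -1%          -1.09
#> 8          e       +1%           1.11
#> 9          M        -1           0.00
#> 10         M        +1           0.00
```

The radiation module ties cell kill to DSB kinetics; inverting the
measured 2 Gy CSC survival gives the mis-repair rate:

```r
misrepair_from_survival(0.95, k_dsb = 25, dose_gy = 2, r = 15)
#> [1] 0.001231039   # 0.0012 at two significant figures
```

A command-line wrapper covering all stages (ODE and automaton simulation,
equilibrium, sensitivity, radiation, sorting fits, synthetic data) is
installed at `inst/cli/cscdyn`; every run writes a YAML manifest with its
configuration and seed.

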