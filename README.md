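# nanotarget

Spatiotemporal modelling of combination cancer therapy delivered by
two-stage nanoparticles ("nanocells"): a lipid envelope releases an
antiangiogenic agent (combretastatin) quickly, then the particle core
releases a chemotherapeutic (doxorubicin) slowly, after the tumour
vasculature has collapsed. The package is for modellers in mathematical
oncology who want a tested, reusable implementation of this coupled
tumour–vasculature–therapy system: reproducing the treatment-arm
comparison, interrogating the synergy mechanism by ablation, calibrating
parameters to tumour-volume curves, and running sensitivity scans.

## The model

Tumour-cell density `n` and vessel density `m` evolve on a 3D no-flux grid
(dimensionless units):

    dn/dt = lap(n) + n(1 - n) + a1*m*n          - A_D*d*n   (chemo arms)
    dm/dt = D2*lap(m) + m(-1 + 3m - 2m^2) + a2*n*m - A_C*c*m  (anti arms)

Vasculature lifts the tumour carrying capacity to `n* = 1 + a1*m*`; with
the fitted couplings `a1 = 1.1`, `a2 = 0.9` the stable vessel state rises
from 1 (normal tissue) to about 1.97 (dense abnormal tumour vasculature).
Carriers administered at days 8, 10, 12, 14, 16 extravasate at rate
`delta * Gamma_i(t) * m * exp(-(m/m_lim)^2)` — delivery requires vessels
but degrades in dense abnormal vasculature — and release each agent with a
gamma-kernel profile `(t - t_i)^p exp(-(t - t_i)/tau)`, normalized so every
arm delivers the same total of each drug over the 17-day protocol
(nanocell core: `p = 0.3, tau = 15 d`; liposome: `p = 0.1, tau = 2 d`).
Free doxorubicin is reabsorbed into vessels at rate `mu*m*d` — so
antiangiogenic vascular collapse *traps* it in the tissue.

Six treatment arms are built in: untreated control `V`, single agents
`NC_D` and `L_C`, the co-encapsulating liposome `L_CD`, the nanocell
`NC_CD`, and a delayed-release nanocell `NC_CD_mod` (`p = 0.8`).

## A worked example

```r
library(nanotarget)

p <- paper_defaults("lung")
vasculature_fixed_points(p)
#> [1] 0.02538568 1.96961432     # printed in the source as 0.02, 1.97

g <- sim_grid(25, h = 1)        # smoke-scale grid (production: sim_grid(50))
vols <- sapply(arm_names(), function(a)
  tail(run_arm(a, p, g, seed = 1, t_end_days = 17)$volume_mm3, 1))
round(vols, 1)
#>         V      NC_D       L_C      L_CD     NC_CD NC_CD_mod
#>    5016.3    4330.0    3406.9    2955.8    2478.4    2311.4
```

Day-17 volumes (mm³) reproduce the reported ordering: each single agent
helps modestly, the co-encapsulating liposome beats both, the nanocell
beats the liposome with the same total drug, and delaying the core release
further improves it. The untreated curve crosses the 50 mm³ treatment
threshold near day 8 on a calibrated grid:

```r
cal <- calibrate_grid(p, npts = 50, h_values = c(0.5, 0.8, 0.95, 1.05))
c(cal$h, cal$crossing_day)
#> [1] 0.950000 8.010111
```

Calibration and synthetic data close the loop end to end:

```r
g  <- sim_grid(16, h = 1.3)
ds <- generate_volumes(paper_defaults("melanoma"),
                       arms = c("V", "L_C", "NC_D"), noise_rel = 0.05,
                       n_replicates = 5, seed = 21, grid = g)
fit_sequential(list(D1   = list(bounds = c(0.2, 0.8), arm = "V"),
                    AC_t = list(bounds = c(0.02, 1),  arm = "L_C"),
                    AD_t = list(bounds = c(1, 6),     arm = "NC_D")),
               ds$data, params = ds$truth, grid = g,
               seeds = ds$sim_seeds)$estimates
#>        D1      AC_t      AD_t
#> 0.4549527 0.3078828 2.9270316   # truth: 0.46, 0.3, 3
```

A thin command-line wrapper writes volume curves and a full run manifest:

```sh
Rscript scripts/simulate.R --arm NC_CD --cancer lung --seed 1 --t-end 17 --out run/
```

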