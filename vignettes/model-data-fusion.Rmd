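---
title: "Model-data fusion with a linear carbon-cycle emulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-data fusion with a linear carbon-cycle emulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carbonfuse)
```

## The model

Process-based vegetation models disagree with observational datasets of
land carbon storage, and the disagreement can originate in the carbon
influx (productivity), in turnover, or in the reference data themselves.
`carbonfuse` separates these contributions by emulating a model's carbon
cycle as a linear compartment system and swapping its components for
data-derived estimates one at a time.

The emulator state is a vector of pool stocks $X$ (gC m$^{-2}$) per grid
cell. Each year,

$$X_{t+1} = X_t + b\,u_t + A F_t - F_t, \qquad
  F_{t,j} = K_j\,\xi_{t,j}\,X_{t,j},$$

where $u_t$ is the annual carbon influx (NPP), $b$ the allocation
fractions over vegetation pools ($\sum_p b_p = 1$), $K$ the baseline exit
rates (yr$^{-1}$), $\xi > 0$ dimensionless environmental rate scalars, and
$A_{ij}$ the fraction of the outflux of pool $j$ entering pool $i$. The
remainder $1 - \sum_i A_{ij}$ of every outflux is respired out of the
system. Flows are acyclic from vegetation through litter into soil:
everything a process model resolves about demography, disturbance,
nutrient limitation or climate sensitivity of decomposition enters only
through $u$, $\xi$ and $K$, while the relative flows between stocks are
preserved.

Because the system is linear, initialisation needs no long spin-up
simulation: the equilibrium under constant forcing is the exact solve

$$(I - A)\,\mathrm{diag}(K\xi)\,X^{*} = b\,u_0 ,$$

and `steady_state()` applies it per cell. `spinup_state()` uses the mean
of the first 30 forcing years (configurable) as $u_0$ and $\xi_0$, i.e. an
early-20th-century climatology. Net biome production is the area-weighted
global sum of influx minus respired efflux (PgC yr$^{-1}$), which by mass
balance equals the year-over-year change of total storage.

### Numerical choices

* The timestep is annual and explicit, matching the annual analysis. An
  effective exit fraction $K\xi > 1$ would lose mass in an explicit step;
  `step_annual()` treats it as an error rather than silently sub-stepping.
* Mass balance is enforced by construction and verified in the tests to
  about $10^{-13}$ relative; the suite's contract is $10^{-8}$.
* The default eight-pool network (leaf, wood, root; above-/belowground
  litter; fast/slow/passive soil) gives mid-latitude stocks of a few
  kgC m$^{-2}$ AGB and roughly 13 kgC m$^{-2}$ soil carbon at an influx of
  500 gC m$^{-2}$ yr$^{-1}$, with residence times from 2.5 yr (leaf) to
  500 yr (passive soil). Nothing in the code assumes this particular
  network; any acyclic `pool_system()` works.

## Replacing the influx

Empirical GPP products are converted to NPP with the simulated
respiration ratio, $\widehat{\mathrm{NPP}} = \mathrm{GPP}_{emp} \cdot
\mathrm{NPP}_{sim}/\mathrm{GPP}_{sim}$, per year and cell
(`gpp_to_npp()`).

`refine_npp()` then splices the empirical series onto the simulation. Up
to the merge year (the first observed year) the refined series *is* the
simulated one, so the emulator can be initialised in the data-free epoch.
From the merge year on,

$$\mathrm{refined}(t) = \mathrm{emp}(t) +
  (s_{sim} - s_{emp})\,(t - \bar t),$$

with $s$ the per-cell ordinary-least-squares slopes over the common
period and $\bar t$ its mid-year. This keeps the empirical interannual
variability *and* the empirical magnitude while replacing the empirical
trend with the simulated one. The design was genuinely open here — a
"trend" swap could also transplant the full fitted line, which would
impose the simulated mean level — but fusing data is pointless if the
observed magnitude is discarded, so only the slope is exchanged. Both
variants satisfy the same contracts (refined slope equals the simulated
slope; detrended residuals equal the empirical residuals; refining a
model with its own series is an exact identity). Consequences of the
choice: a step discontinuity at the merge year is possible wherever the
model's level is biased; it is measured and logged
(`diagnostics$merge_step`) rather than smoothed away, because smoothing
would re-introduce level information from the model. Years after the
empirical coverage revert to the simulated series. Negative refined
values (possible when a steep simulated slope is extrapolated backwards)
are floored at zero and counted.

## Replacing turnover

The *apparent* turnover rate of a compartment is window-mean influx over
window-mean stock (yr$^{-1}$); its inverse is the apparent residence
time. The quotient is an exact rate only at steady state, so the same
formula and window are applied to the observations and to the emulator's
own trajectory, and only the ratio is used:

$$\xi_p \leftarrow \xi_p \cdot
  \frac{\widehat{\tau}^{-1}_{obs}}{\widehat{\tau}^{-1}_{sim}}
  \quad \text{for all pools } p \text{ in the compartment.}$$

Transient biases common to both quotients cancel. Three conventions are
worth stating:

* **Uniform rescaling within a compartment.** An AGB observation cannot
  constrain leaf, wood and root turnover separately, so a single per-cell
  scalar is applied to all vegetation pools (roots included); relative
  flows stay untouched.
* **"Soil" means litter + soil.** Observed soil-carbon stocks do not
  separate litter from mineral soil, and the emulator's soil-carbon
  summary lumps them identically, so the soil scalar spans both. This
  keeps the fusion algebra exact: at equilibrium, rescaling drives the
  aggregate compartment stock exactly to the observed stock when the same
  NPP dataset feeds both quotients.
* **Per-cell fallback.** Cells where a rate is undefined (zero/missing
  stock or influx) or where the rescaled $K\xi$ of any pool would exceed
  the annual explicit limit keep their simulated rates and are counted —
  data that cannot be represented are logged, not clipped.

Observed soil carbon is depth-adjusted first (`adjust_soil_c()`):
vegetation is assumed to interact with only the top 40 cm of peat soils
and, under permafrost, only with carbon inside the active layer. Per
cell, the peat area fraction keeps carbon above 0.40 m and the remaining
fraction keeps carbon above the active layer where one exists; truncation
is linear within layers. The peat-fraction mixing rule is the package's
choice (the assumption itself does not prescribe one); the adjustment
never increases a stock and is idempotent.

## The realization ensemble

A *realization* is one fusion configuration. `build_ensemble()`
enumerates six categories — influx only; vegetation turnover only; soil
turnover only; influx + vegetation; influx + soil; influx + both — with
exactly one NPP dataset per realization (the same dataset corrects the
influx and feeds both turnover quotients). With 5 influx, 2 AGB and 2
soil datasets this is $5 + 10 + 10 + 10 + 10 + 20 = 65$ realizations, of
which $40$ combine influx with turnover.

## Evaluation and baseline knowledge

Agreement uses Willmott's index

$$d = 1 - \frac{\sum (P_i - O_i)^2}
  {\sum (|P_i - \bar O| + |O_i - \bar O|)^2} \in [0, 1],$$

Pearson correlation and RMSE, per land-cover class and globally, on the
cells shared by all datasets in a comparison. Cells are weighted equally
within a class (area weighting is available behind a flag). $d$ is not
symmetric — the denominator is centred on the reference — so the
data-vs-data *baseline knowledge* reports both directions and uses their
mean. A model is then classified against the baseline: below it
(situation 1, room for improvement), comparable (2), or above it (3,
to be interpreted with caution since the data themselves disagree). The
comparability band defaults to $\pm 0.02$ IoA units; no principled
threshold exists for this, so it is an explicit, configurable convention.
A zero denominator (both fields constant and identical) returns $d = 1$
by convention. Degenerate variance makes $r$ a masked `NA` with a reason,
never a propagated `NaN`.

## The synthetic world

The generator builds every input the pipeline needs, under one seed:

* **Domain**: 20 × 20 equal-area cells (3·10$^{11}$ m$^2$ each, summing
  to about the global land area) in six contiguous land-cover classes;
  10% of cells are peatland (peat fraction 0.3–0.9) and 15% permafrost
  (active layer 0.4–1.5 m), placed in the two "high-latitude" classes.
* **Truth**: NPP is a smooth spatial gradient (200–1100 gC m$^{-2}$
  yr$^{-1}$) plus a linear trend (0.5 gC m$^{-2}$ yr$^{-2}$, about 0.1%
  yr$^{-1}$ — a modest greening) times multiplicative lognormal AR(1)
  interannual variability (sd 0.05, lag-1 correlation 0.3; real products'
  IAV structure varies, this is a plausible middle). Stocks follow from
  the emulator itself over 1901–2014; soil carbon is spread over depth
  with a 0.5 m e-folding profile.
* **Model world**: truth times per-class bias factors on influx
  (0.85–1.25) and on vegetation and soil turnover scalars (0.85–1.2),
  with class 1 (tundra-like) overestimating influx — the shape of bias
  the real analysis diagnosed. GPP is NPP over a per-class carbon-use
  efficiency (0.45–0.55), so the GPP-to-NPP conversion is exercised.
* **Pseudo-observations**: truth times independent mean-one lognormal
  noise (multiplicative, because stocks and fluxes are positive and
  skewed; additive Gaussian behind a flag): influx datasets at sd 0.10
  (one NPP-like product over 2000–2014, four GPP-like over 1982–2011),
  AGB pairs at 0.15/0.20, soil pairs at 0.25/0.30 — soil products
  disagreeing most, as their real counterparts do. Each dataset masks 2%
  of cells independently so shared-area logic is exercised.
* **Net-flux reference**: truth NBP plus additive noise (sd 0.2 PgC
  yr$^{-1}$) with a stated ±0.8 PgC yr$^{-1}$ half-width.

What this emulates is the *statistical* structure of the real setting:
independent noisy references, class-structured model bias, products with
different spans and kinds. What it does not emulate: real spatial
resolution and regridding, retrieval physics, soil-profile databases,
process-level climate sensitivity of turnover. Passing tests therefore
certify the fusion and evaluation machinery, not any claim about a real
model's fidelity.

## The recovery check

The analysis-level correctness test fuses influx and both turnover rates
derived from *exact* observations of a synthetic truth and requires the
realization to reproduce the truth's AGB, soil carbon and NBP. It is run
under equilibrium forcing (zero trend and IAV, no peat/permafrost, model
influx unbiased, turnover biased): the apparent-rate quotient is an exact
rate only at steady state, and trend-preserving refinement deliberately
leaves the model's pre-merge influx epoch uncorrected, so equilibrium is
the regime where the chain must be exact — and it is, to machine
precision (the contract is $10^{-3}$ relative). Under transient forcing
the same chain is exercised qualitatively: with per-class influx bias and
exact observations, the influx-fused realization agrees with observed
AGB at least as well as the unfused model.

## Problem sizes

The default grid (400 cells, 114 years, 8 pools) runs a realization in
about 0.2 s and the full 65-member ensemble with evaluation in under a
minute; the test suite uses a 40-cell world for pipeline-level cases.
These sizes give stable class statistics while keeping the whole analysis
interactive.

## Worked example

```{r example}
cfg <- synth_config(seed = 1)
dom <- make_domain(cfg)
truth <- make_truth(cfg, dom)
world <- make_model_world(truth, cfg, dom)
obs <- make_pseudo_obs(truth, cfg, dom)

ens <- build_ensemble(names(obs$influx), names(obs$agb), names(obs$soil))
nrow(ens)

real <- ens[ens$category == "influx+both", ][1, ]
res <- run_realization(real, world, obs, dom,
                       stock_window = cfg$stock_window)
ref <- make_net_flux_reference(truth, cfg, dom)
yrs <- as.character(cfg$common_period)
c(unfused = ioa(nbp_series(world$trajectory, dom)[yrs], ref[yrs]),
  fused = ioa(res$nbp[yrs], ref[yrs]))
```

## Known limitations

* Allocation fractions `b` and the transfer structure `A` are never
  fused; if a model's relative flows are wrong, no realization can
  correct them — by design, since the framework's premise is preserving
  them.
* The merge-year discontinuity is reported, not resolved; analyses of
  year-over-year change across the merge year should use the
  diagnostics.
* A single merge/trend convention (OLS slope over the common period) is
  implemented; other trend estimators would give slightly different
  refined series.
* Cells reverted by the annual-step limit bias turnover fusion towards
  the simulated rates exactly where observed turnover is fastest relative
  to the model; counts are in the diagnostics.
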