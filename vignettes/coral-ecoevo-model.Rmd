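---
title: "An eco-evolutionary metacommunity model of coral cover and thermal adaptation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An eco-evolutionary metacommunity model of coral cover and thermal adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefevo)
```

## The model

`reefevo` simulates four competing coral assemblages — fast- and slow-growing
variants of a high-diversity "reef" class and a lower-diversity "nonreef"
class — on a network of discrete habitat sites indexed $i$, forced by monthly
sea-surface temperature $T_{ik}$ (°C), pH $P_{ik}$ and benthic
photosynthetically available radiation (PAR) $R_{ik}$ (mol m⁻² day⁻¹). Two
prognostic fields evolve per site and assemblage $j$: fractional cover
$C_{ij}$ and the population-mean thermal-optimum trait $z_{ij}$ (°C).

### Growth and mortality

Between spawning events cover obeys

$$\frac{dC_{ij}}{dt} = \Big(g_{ij} + \tfrac12 V_j
  \frac{\partial^2 g}{\partial z^2}\Big)\,C_{ij},$$

where the second term is the genetic load: trait variance $V_j$ around the
population mean depresses mean fitness in proportion to the local curvature
of the growth function. The growth rate itself is additive in its
environmental modifiers,

$$g = g_0\,(1 + G_{SST} + G_{pH} + G_I + G_C) -
      m_0\,(M_N + M_H + M_C + M_A),$$

with a Gaussian thermal performance term
$G_{SST} = e^{-(T-z)^2/2w^2} - 1$, a linear pH response
$G_{pH} = r_{pH}(P - P_0)$ (a one-unit pH drop halves the extension rate at
the default sensitivity 0.5), a saturating light response
$G_I = \tanh(R/R_{sat}) - 1$ (growth is impossible in darkness), and linear
competition $G_C = -\sum_f \alpha_{fj} C_{if}$. The modifier sum may fall
below $-1$; the resulting negative growth acts as additional mortality and
is deliberately not clamped. Mortality combines a constant background term
with three one-sided quadratic stress penalties — heat stress above
$z + z_H$, cold stress below $z - z_C$, and an absolute lower limit below
$z_A$ that does not move with the evolving trait. All three are continuous
(zero) at their activation thresholds, so $g$ is continuous in $T$ and $z$
everywhere.

The cover growth coefficient $g_0 = 2\pi s_0 c_0
\exp(-\mu/2 - 3\sigma^2/8)$ converts a colony linear extension rate $s_0$
(m yr⁻¹) into a fractional-cover rate assuming log-normal colony size
structure with fixed shape $(\mu, \sigma)$; with the default fast-growing
parameters it evaluates to ≈0.663 yr⁻¹. The exponent is validated in the
test suite against the log-normal moment identity
$E[\sqrt r]/E[r] = \exp(-\mu/2 - 3\sigma^2/8)$ by Monte Carlo.

### Evolution

The trait responds to stabilizing selection,

$$\frac{dz_{ij}}{dt} = q_{ij} V_j \frac{\partial g}{\partial z}, \qquad
  q_{ij} = \max\!\Big[0,\; 1 -
  \frac{C_{throttle}}{\max(C_{throttle}, 2C_{ij})}\Big],$$

where the throttle $q$ suppresses the selection response at very low cover,
a stand-in for founder effects and bottlenecks; selection is fully off for
$2C \le C_{throttle}$. The selection gradient and the load curvature are
analytic piecewise expressions (Gaussian term everywhere; heat- and
cold-stress terms where active; the absolute limit contributes nothing), and
are verified against central finite differences at a thousand random
points. At activation thresholds the one-sided stress-free value is used:
the threshold delta-contributions of the piecewise quadratics are not
pointwise integrable and are ignored.

### Reproduction and connectivity

Once per year (by default the month after each site's climatological warmest
month, hemisphere-aware), all sites sharing that spawning month release
larvae. Transport uses a per-lag potential-connectivity kernel
$M'_{him}$ (probability that a larva from $h$ is at $i$ after
$\tau_m = 2, 4, \dots, 60$ days), collapsed to an effective matrix by
competency weighting,

$$M_{hi} = \frac{\sum_m M'_{him}\, p_m}{\sum_m p_m},$$

with $p_m$ the proportion of larvae alive and competent at lag $\tau_m$.
Larval supply at a destination is area-weighted,
$I_{ij} = (f_j / A_i) \sum_h M_{hi} C_{hj} A_h$, with effective fecundity
$f_j$ absorbing egg production, fertilization, larval survival, settlement
and survival to maturity (and the size of a newly settled colony).
Settlement fills free space with the closed form

$$\Delta C_{ij} = \frac{I_{ij}}{\mathbb{I}_i}\,(1 - \mathbb{C}_i)\,
  \big(1 - e^{-\mathbb{I}_i}\big),$$

the exact solution of $dC_j/dt = I_j (1 - \sum_f C_f)$ over a unit settling
period — checked in the tests against numerical integration of that ODE.
Post-settlement the trait is admixed,
$z' = (Cz + \Delta C\, \breve z)/(C + \Delta C)$, where $\breve z$ is the
cover-area-weighted mean immigrant trait; an empty site colonized by
immigrants inherits their trait exactly. Cover $C = 0$ is absorbing for
growth but *not* for settlement — this is what makes range expansion
possible.

## Parameters

Defaults follow the standard four-assemblage parameterization (see
`default_assemblage_params()`): extension rates 0.05/0.01 m yr⁻¹
(fast/slow), thermal tolerance breadth 6 °C for reef and 8 °C for nonreef
corals, heat-stress thresholds $z_H$ of 1.5 °C (reef) and 3.5 °C (nonreef)
with tolerances $w_H$ of 0.5 °C (fast) and 1.0 °C (slow), cold-stress
thresholds 8/10 °C with tolerances 0.75/1.5 °C, absolute limits
$z_A$ = 24.2/21.3/22.9/19.1 °C with $w_A = w$, additive genetic variance
$V = 0.05$ °C² (heritability ≈ 0.36 times a phenotypic variance of
0.10–0.15 °C²), reference pH 8.1, saturation PAR 15 mol m⁻² day⁻¹,
log-normal size shape $\mu = -4.2$, $\sigma = 1.9$, natural mortality 0, and
habitable fraction $r_f = 0.125$. Competition is class-level: reef on
nonreef 1.2, nonreef on reef 0.8, within reef 2, within nonreef 10 — reef
corals hold the competitive advantage, and strong nonreef self-limitation
keeps nonreef communities sparse. Cross fast/slow pairs within a class use
the within-class coefficient, since only class-level values are defined.

Effective fecundity defaults to 0.008 (fast) and 0.1 (slow); an alternative
preset (`fecundity = "conservative"`: 4×10⁻⁴ and 5×10⁻³) reflects more
conservative egg-to-recruit conversion assumptions. The choice affects
recruitment-dominated transients (colonization speed) far more than
equilibrium covers, which competition controls.

Two numerical-floor parameters have no empirical constraint and are set by
convention: minimum nonzero cover $C_{min} = 10^{-9}$ (cells below it are
clamped to extinct after each monthly step) and the selection throttle
$C_{throttle} = 10^{-3}$.

## Numerics

Cover and trait are advanced jointly with a deterministic fixed-step
classical Runge–Kutta (RK4) scheme, 4 substeps per month by default,
forcing held constant within a month. A fixed-step scheme was chosen over
adaptive stepping because bit-for-bit reproducibility across platforms and
across checkpoint-resume matters more here than integrator efficiency;
the substep count is configuration-exposed, and halving the step changes a
smooth month by less than 10⁻⁹ relative. Cover is integrated in log space,
which makes $C = 0$ an exact absorbing state and guarantees non-negativity
under arbitrary forcing; the monthly result agrees with a dense-output
reference integration to better than 10⁻⁸ relative. If total cover at a
site ever exceeded 1 it would be rescaled proportionally with a warning —
under default parameters competition self-limits well below that and the
clamp never fires.

Kernel sampling at spawning uses a counter-based hash of (seed, absolute
month index) rather than R's global RNG stream, so resuming from a
checkpoint reproduces the remaining draws exactly; runs are bit-identical
under a fixed seed.

Degenerate inputs are handled explicitly: zero larval supply leaves the
trait untouched (the immigrant-trait 0/0 is carried as a missing marker and
admixture is skipped); an all-zero competency curve, an empty kernel bank,
gap months in forcing files, and negative PAR are errors, never silent
fills.

## Synthetic study conditions

The forcing generator emulates the structure of climate-model output on an
idealized latitudinal domain: mean SST declining linearly from 28 °C at the
equator to 16 °C at 45°, seasonal amplitude growing from 2 to 6 °C,
hemisphere-aware phase, piecewise-linear secular warming/acidification
trajectories across named phases, AR(1) interannual noise (default
σ = 0.3 °C, lag-1 correlation 0.6), and a repeating monthly PAR climatology
from a seasonal surface-insolation curve attenuated exponentially with
depth (0.08 m⁻¹). Delta-method bias correction and a stabilized
post-scenario extension (scenario-minus-control anomaly added to the looped
control) mirror standard climate-forcing practice. The dispersal generator
lays sites on a 1-D coastline and spreads larvae as a Gaussian plume with
alongshore advection (default 2 km day⁻¹, modulated seasonally across the
12-kernel monthly bank), $\sqrt{\tau}$ diffusive growth (8 km day⁻½) and
exponential larval loss (5% per 2-day lag step); site masses are exact
integrals over disjoint coastline segments, so no row ever gains mass.
The competency curves are a parametric competence-acquisition/loss ×
exponential-survival model; the two presets ("AM"-like long-competency
broadcaster for fast growers, "GR"-like short-competency curve for slow
growers) are synthetic calibrations, not published species data.

What this emulation deliberately omits: mesoscale eddies and realistic
bathymetry, 2-D connectivity topology, cloud-driven PAR variability,
photoacclimation, temperature-dependent larval competency, delayed sexual
maturity, stochastic demography and size-structured dynamics. Passing tests
therefore demonstrate that the mechanisms are implemented correctly and
interact as designed — not that the package reproduces any observed reef
trajectory.

## Experiment protocol and problem sizes

`initialize_state()` sets the trait to the 90th percentile of the monthly
control SST at each site and cover to a uniform 0.01 (the convergent state
is insensitive to initial cover — verified in the tests at 1% — so the
value only sets the convergence path; no observational cover map ships with
the package). `spin_up()` loops the control series, recording century-block
means of class-total cover; convergence is declared at the first century
differing by less than 1% (relative) from its predecessor for every class —
a criterion chosen here, conservative relative to the multi-century
equilibration the model exhibits. Cover converges within a few centuries on
the idealized domain; the trait keeps adjusting for millennia (slow-growing
corals have the smallest $V g_0 / w^2$ relaxation rate, and immigrant
admixture from warmer upstream sites continually counteracts local
selection), which is why trait-sensitive experiments use multi-thousand-year
spin-ups.

Packaged experiments use desk-scale problem sizes chosen to resolve each
mechanism: single-site trait equilibration runs 5000 model years (the
slow-grower relaxation time); the spin-up convergence experiment uses
100 sites × 5000 years; the range-expansion experiment uses 60 sites with
an 80-year +3 °C warming ramp followed by ~5 centuries of stabilized
climate. On one CPU each completes in under two minutes.

## Known limitations

* The four assemblages are abstractions; no per-species parameterization is
  provided or intended.
* Connectivity is consumed, never computed: the package generates idealized
  kernels or reads externally produced ones, and performs no particle
  tracking.
* Forcing I/O is long-format CSV; gridded NetCDF products should be
  flattened to (site, month) series upstream.
* The absolute-limit floor implies minimum growth temperatures of ≈17 °C
  (reef) and ≈14–15 °C (nonreef) under the default $g_0$; the test suite
  asserts the closed-form floor $z_A - w_A\sqrt{2 g_0/m_0}$ rather than any
  externally quoted value.
* Fast-growing assemblages persist through disturbance (they die more in
  heat events but recover faster); under weak interannual variability they
  can be competitively excluded at equilibrium by the higher-fecundity
  slow growers. The default AR(1) noise (σ = 0.3 °C) is at the low end of
  observed interannual SST variability on reefs.
* Fractional cover is capped implicitly by competition, not by $r_f$; the
  habitable fraction enters area reporting and the settlement area weights
  consistently (reported reef area = $C\, r_f A$).

## A minimal run

```{r example, eval = FALSE}
sites <- site_table(paste0("s", 1:20),
                    lat = seq(1, 44, length.out = 20), lon = 150,
                    A = 8e6, depth = 10)
ctl <- synth_forcing(sites, scenario_spec(), seed = 1)
model <- reef_model(sites, kernels = synth_kernel_bank(sites),
                    config = reef_config(seed = 1))
run <- simulate(model, control = ctl, spinup_years = 1000,
                plan = list(list(name = "control", forcing = ctl)))
summary(run)
plot(run)
composition_by_band(run$state, sites, band_width = 5)
```
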