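---
title: "A depth-resolved shallow-lake model and its regime-shift machinery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A depth-resolved shallow-lake model and its regime-shift machinery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question the package is built around

Whether shallow lakes flip abruptly between a turbid,
phytoplankton-dominated state and a clear, macrophyte-dominated state —
and how much hysteresis separates the two — depends in part on how the
lake is represented. A box (0D) model puts the whole sediment surface at
one depth: either that depth receives enough light for plants or it does
not, so the simulated transition is all-or-nothing. If instead the water
column is discretised on the lake's hypsograph, every depth stratum has
its own sediment area and its own light climate; margins clear first,
colonisation advances downslope, and the aggregate response smooths out.
`lakeshift` implements one ecosystem model that can be run in both
geometries — `build_grid(hyps, 16)` versus
`build_grid(hypsograph_box(area, mean_depth), 1, 0)` — so the
geometric effect can be isolated with everything else held fixed.

## Vertical grid

The hypsograph is a level–area table (level 0 = deepest point). Layer
heights follow a geometric bottom refinement
`h_k = h_1 (1 + zoom)^(k-1)` (layer 1 at the bottom) normalised to the
maximum depth; the default `zoom = 0.03` gives a 16-layer grid of
roughly 13–20 cm layers over 2.6 m. Layer volumes are exact integrals of
the piecewise-linear hypsograph. The benthic (sediment-contact) area of
a layer is the hypsograph area at its top interface minus that at its
bottom interface, with the area at level 0 assigned to the bottom
layer; benthic areas therefore telescope exactly to the surface area,
and the one-layer grid has benthic area equal to surface area (the box
configuration).

## Physics

The physics is deliberately parameterised rather than closed from
turbulence theory, because the claims under study hinge on
depth-resolved light and benthic area, not on mixing fidelity:

* **Temperature** relaxes towards `max(0, T_air + c_swr·SWR)` with a
  time constant growing with depth (default 4 d at the surface); the
  wind-mixed column then homogenises, giving polymictic behaviour.
  Sub-zero water is clamped to 0 °C; there is no ice module (sampling
  schedules treat ≤ 0.1 °C surface water as ice cover).
* **Light**: daily shortwave from solar geometry × `(1 − 0.7·cloud)`,
  PAR = 50% of shortwave; within the column Lambert–Beer attenuation
  with `K_d = k_bg + Σ k_i C_i` over phytoplankton, POM, suspended
  inorganic matter and an areal macrophyte-shading term. Rooted plants
  respond to the PAR at the bottom of their layer.
* **Mixing** is implicit diffusion with `D = D_0 + c_w·wind³`
  (unconditionally stable, conservative, contractive).
* **Waves**: a dimensionless shear proxy `(w/w_ref)²·sqrt(fetch/f_ref)·
  exp(−depth/z_wave)` drives resuspension above a critical value
  (damped inside dense beds, one of the self-stabilising feedbacks of
  the vegetated state) and scours the standing macrophyte canopy in
  shallow water.

## Ecosystem kernel

Per layer, the water column carries NH4, NO3, PO4, DOM-N/P, POM
(dry mass, N, P), inorganic matter, oxygen, three phytoplankton groups
(dry mass + internal N and P stores), zooplankton, and three fish groups;
each layer's sediment carries POM, humus, inorganic matter, iron-bound
phosphate (PAIMS), porewater NH4/NO3/PO4, zoobenthos, and macrophytes.

Process forms, chosen to match the qualitative process web while keeping
each claim testable:

* **Phytoplankton** grow by the Droop cell-quota law
  `μ = μ_max f_T f_I min(1 − q_min/q)` over N and P, with
  quota-regulated Michaelis–Menten uptake (NH4 preferred over NO3 by a
  weight) and a light-dependent chl-a:DM ratio between group-specific
  bounds. Diatoms are parameterised cold/low-light adapted with high
  growth and settling; cyanobacteria slow, buoyant, warm, with high P
  affinity; "other algae" intermediate. Temperature niches are Gaussian;
  abiotic rates use `θ^(T−20)`.
* **Zooplankton** filter at `F_max f_T/(1 + F/h_food)` with
  preference-weighted food `F` (ranking diatoms > other algae >
  cyanobacteria > POM), assimilating a fixed fraction and egesting the
  rest to POM.
* **Fish** are layer-bound: juveniles eat zooplankton, adults eat
  zoobenthos, piscivores eat both age classes with a saturating
  coverage bonus (`c_cov_veg_min` at bare sediment, half-saturation
  `h_d_veg_pisc`); aging (juvenile→adult) and spawning (adult→juvenile)
  transfers occur on 1 January, and an optional winter kill moves a
  configured fraction of all fish pools to sediment POM. The spawning
  transfer is a structural necessity: with aging alone the juvenile pool
  goes extinct and with it the whole food-web top. Fish are not flushed
  by the outflow.
* **Macrophytes** are rooted: production saturates with the PAR at
  their layer's bed, discounted for the stand's own within-layer shade
  (the canopy harvests light above the microhabitat it darkens, so a
  dense bed does not extinguish itself while it still shades the
  phytoplankton below and around it), and is limited logistically by
  biomass. Temperature enters production and maintenance respiration as
  two exponentials whose difference creates an interior optimum. Roots
  mine the whole sedimentary P stock — porewater, iron-bound (PAIMS)
  and organic-bound P — so rooted plants are nutrient-limited only when
  the sediment is truly exhausted and their load response is
  light-driven, the trait that separates them from phytoplankton. A
  small propagule bank germinates under the same environmental factors,
  so colonisation restarts whenever light returns to a bed. Coverage is
  `100(1 − exp(−B/b_cov))` per layer and benthic-area-weighted for the
  lake; losses are background mortality plus wave scour acting on the
  standing canopy (shoots are present in proportion to light-driven
  activity, so overwintering organs escape the waves). Waves thus clear
  the exposed margins while light sets the lower limit: vegetation
  occupies a depth belt whose extent responds to water clarity.
* **Sediment** processes: humification, θ-modified mineralisation with
  an oxic modifier, nitrification (O2-limited), denitrification (to a
  tracked N₂ ledger), porewater–water diffusion, Langmuir-style P
  sorption onto the iron fraction of inorganic matter with first-order
  relaxation and an oxic factor (anoxia releases P — the internal
  loading lag), shear-driven resuspension and slow burial into tracked
  deep-sink pools.
* **Inlets** deliver dissolved nutrients plus organic N and P
  partitioned between DOM (90%) and POM, and a small live plankton
  inoculum (0.02 g DM m⁻³ per phytoplankton group, 0.005 for
  zooplankton) carved out of the organic load so total N and P loads
  are unchanged; stream-fed lakes are continuously re-seeded, and
  without this the minor groups cannot recover from their winter
  minima.

## Positivity and closure

All sources and sinks advance with a first-order Modified Patankar
update: destruction of a pool is scaled by its own new/old ratio and
every internal transfer by its donor's ratio, which yields a linear
M-matrix system per layer (solved in compiled code). The update is
unconditionally positive and exactly conservative over internal
transfers at any time step, and converges to explicit Euler at first
order — the property tests pin this against a brute-force Euler oracle.
Whether "extended" or plain first-order Modified Patankar is the right
reading of the source scheme is unresolvable from the description; the
first-order scheme is implemented and the oracle test defines
correctness here.

Boundary fluxes (inflow, outflow, denitrified N₂, deep burial) are
first-class ledger entries, so closure is asserted, not assumed:
`budget_residual()` of any run must be zero to round-off, and the test
suite checks 1000-day closed-lake runs at 1e-9 relative.

Transport happens after the biogeochemical update each step: inflow to
and outflow from the surface layer, implicit upwind settling that
deposits on each layer's benthic area (telescoping exactly), then
implicit mixing. The internal step is one day. The original design
called for an hourly step out of concern for settling and mixing
stability on decimetre layers; because both transports are implicit
(unconditionally stable and positivity-preserving) and sources/sinks use
the Patankar update, daily stepping is stable, and it is what makes
150-run bifurcation experiments and thousand-run calibrations feasible
on a desktop. `dt` remains a parameter of `simulate_lake()`.

## Default parameterisation

The defaults (see `default_parameters()`, with units, bounds and
descriptions) were chosen once to make the synthetic lake behave like a
small, eutrophic, wind-exposed temperate lake: summer chlorophyll of
order 100 µg/L in the turbid state at the baseline load
(~9 mg P m⁻² d⁻¹), a spring diatom bloom followed by a
zooplankton-driven clear-water phase and late-summer diatom/cyanobacteria
peaks, fish biomass dominated by plankti-benthivores, macrophyte depth
limits under a metre in turbid water. They also place the box
configuration inside a bistable regime across part of the 0.02–1.5×
load range, which is the regime the bifurcation demonstration probes; a
substantially different parameterisation could move or remove that
regime, which is why hysteresis is reported as a property of this
parameterisation, not a universal constant.

## Bifurcation machinery

A scenario is a branch (turbid or clear start), a load multiplier, a
baseline window, a repetition count, and (clear branch) an
establishment period at the −98% multiplier. The default design is the
full grid: multipliers −98% to +50% in 2% steps (75 scenarios), a 5-yr
baseline looped 12× (60 yr), 20 establishment years, i.e. 150 runs.
Looping uses the canonical 365-day year so blocks tile exactly. The
multiplier scales inlet P concentrations only; N, discharge and
meteorology are untouched, so the areal P load scales exactly linearly
(tested to 1e-12).

Extraction takes summer (1 May–30 September) means over the final five
years, the mean areal P load over the same window, and the August-mean
coverage profile's depth limit at the 0.1% coverage threshold (the
profile mean is used rather than a single survey date). A stabilisation
diagnostic — the relative change of key summer means between the last
two five-year blocks — is reported with each point and warns rather than
errors, because slow pools (PAIMS in particular) are not expected to
equilibrate fully.

Hysteresis is detected as the largest contiguous load interval where the
branches disagree by more than `rel_tol = 0.2` relatively on
chlorophyll a; any such rule is a declaration, and this one is exposed
as an argument.

The packaged demonstration (in the acceptance tests) is the desk-scale
version: 15 multipliers over 0.02–1.50, a 1-yr baseline looped 20×, a
1-yr warm-up history, and a clear branch started from the clear initial
state with a 3-yr establishment segment. Those sizes were chosen as the
smallest at which the contrast is unambiguous; the full-size design
remains the default of `run_bifurcation()`.

## Calibration

Model–observation comparison happens in observation space: the
simulated counterpart of a depth-pooled sample is the volume-weighted
mean over the layers intersecting the pooled depth range on the sample
day. Fit quality uses R², MARE, RE, RMSE and percentage bias; MARE
averages per-pair relative errors and is therefore inflated by
seasonally depleted (near-zero) observations while RE is not — the
signature the metric-consistency test locks in.

The optimiser is canonical DE/rand/1/bin (F = 0.5, CR = 0.9,
population 10× dimension by default) with reflection at the bounds,
maximising a per-variable profiled Gaussian log-likelihood summed with
equal weights — the weighting is a declared choice. The stepwise
procedure runs DE per step over that step's parameter subset and target
variables, carries the best values forward and narrows the bounds to the
expanded envelope of the top decile before the next step; narrowing
never widens a range. The default seven-step schedule goes bottom-up:
physics (temperature), mineralisation (oxygen), N processes, P
interactions, plankton, macrophytes (evaluated over the whole period),
then a combined refinement.

The twin experiment is the accountability device for all of this:
observations are generated from known parameters (with the monitoring
schedule, depth pooling, and lognormal analytical noise of 15% for
nutrients, 20% for chlorophyll and 2% for temperature), eight sensitive
parameters are perturbed uniformly within their bounds, and a four-step
schedule with a 1000-evaluation total budget must recover at least six
of the eight within 20% and reach the truth objective within 5%. The
schedule ends with a combined all-parameter step because the bottom-up
steps run while the plankton parameters are still wrong, which biases
the nutrient-rate estimates until the final polish; the twin uses
gentler range narrowing (keep 25%, expand 50%) so that the polish can
still reach values an early, polluted step steered away from. The
parameters were chosen for identifiability: pairs that trade off
against each other along a likelihood ridge (maximum growth against
self-shading, or against the light half-saturation) cannot both be in
the set, a limit of the observation density rather than of the
optimiser. The twin runs on the one-layer box with 220-day runs so the
budget fits a desktop.

## Synthetic data generator

The generator emulates the input classes of a monitored lake:

* **Morphometry**: power-law hypsograph `A(z) = A_s (z/z_max)^p` with
  `p` solved so the tabulated mean depth matches (1.2 m at 2.6 m
  maximum).
* **Meteorology** (3-hourly): seasonal sinusoid calibrated so the
  Oct–Apr and May–Sep means equal 3.7 and 14.5 °C exactly in the
  noise-free limit, a 2 °C diurnal cycle, and AR(1) noise; AR(1) wind
  components around a 4 m/s mean; bounded cloud.
* **Inflow** (monthly, three inlets): winter-high discharge calibrated
  to 16 d winter / 32 d summer residence times, concentrations scaled so
  noise-free annual loads hit the targets (120 Mg N, 3 Mg P per year),
  partitioned 75% organic P / 90% organic N, with the inorganic N
  remainder split 4:1 NO3:NH4; lognormal month-to-month variability.
  Inlets are drawn iid around shared seasonal means (nothing
  characterises inlet-specific differences).
* **Observations**: one sampling per winter month (skipped under the
  ice proxy), two per summer month; pooling depth twice the Secchi
  proxy (1.7/K_d), clipped to the typical 0.2–1.0 m band;
  multiplicative lognormal noise with σ = 0.15 (nutrients) or 0.20
  (chlorophyll).

Every generator is a pure function of its spec and seed. What the
generator does **not** emulate: weather regimes and storms beyond AR(1)
noise, inter-annual load trends, inlet-specific chemistry, ice
phenology, and observation error correlated in time — so passing tests
show the machinery works under the stated statistical conditions, not
that the model is validated against any real lake.

## Numerical choices and degenerate inputs

Zero-safe denominators (1e-12 floors) guard quota and stoichiometry
ratios of vanishing pools; the Patankar denominators are floored at
1e-300 so identically zero pools pass through unchanged; porewater↔water
diffusion and sorption are split into opposing non-negative rates so
either direction remains a valid production–destruction pair; a zero
discharge day skips in/outflow entirely; the coverage threshold must lie
strictly inside (0, 100)%. Non-finite states abort the run with the day
of failure.

## Known limitations

* One macrophyte, one zooplankton and one zoobenthos guild; no
  periphyton; no component-specific critical shear stress.
* The physics is a parameterisation; stratification events shorter than
  the relaxation time scale are not resolved, and there is no heat
  budget closure.
* Lake level is fixed (outflow mirrors inflow); no marsh zone.
* Sunny mid-summers overshoot the top of the ~0-25 degC observed
  temperature span by a few degrees; the radiative term of the
  relaxation physics trades this against a realistic seasonal heat
  budget.
* TN in the synthetic lake runs above typical field concentrations
  because the 90%-organic inflow partition routes most N through a
  slowly mineralising DOM pool; the N cycle is closed regardless.
* The hysteresis range and critical loads reported by the demonstration
  are properties of the packaged synthetic lake and parameterisation,
  not estimates for any real lake.
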