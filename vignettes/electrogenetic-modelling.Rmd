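---
title: "Modelling an electrogenetic device: from electrode potential to gene expression, motility and population structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling an electrogenetic device}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(electrogenetics)
```

# The system

An electrogenetic device couples an electrode to a bacterial gene circuit
through a diffusible redox mediator. In the configuration this package
models, the hexacyanoferrate couple — ferricyanide Fcn(O) and ferrocyanide
Fcn(R), standard potential E0 of about +0.2 V vs Ag/AgCl — is
interconverted by bulk electrolysis in a small stirred chamber (3 ml of
5 mM mediator). The oxidized form amplifies pyocyanin-driven activation of
the SoxR regulator, which transcribes a reporter (the flavin-based
fluorophore phiLOV) from the PsoxS promoter. An ssrA (DAS) degradation tag
gives the reporter a short half-life, so expression can be switched OFF as
well as ON. Downstream of the same promoter, the motility effector CheZ
converts the electronic signal into swimming behaviour, and a LuxI/LuxR
relay converts it into a quorum-sensing signal that lights up a second,
receiver, population.

The package implements the quantitative machinery this system needs, end
to end, with a seeded synthetic-data generator for every input so that
every stage can be validated against known ground truth:

1. **electrochemistry** — Nernst endpoints, Faraday charge accounting,
   first-order bulk interconversion with a cell-mediated reduction term;
2. **circuit model** — charge-dependent reporter synthesis with first-order
   degradation, ON/OFF cycling, and deconvolution of cumulative synthesis
   from a fluorescence trace;
3. **motility video analysis** — Otsu segmentation, nearest-neighbour
   linking, drift and stuck-cell handling, velocities, trajectory roses,
   and two-sample statistics;
4. **flow-cytometry summarisation** — scatter gating, mean fluorescence,
   and detection of an emergent bright subpopulation;
5. **pipelines** — file formats, configuration, manifests and a
   `run_pipeline()` driver with deterministic stage seeds.

# Electrochemistry

The mediator pool is described by its total concentration and oxidized
fraction `f`; total moles are conserved. Under an applied potential E the
equilibrium fraction is the Nernst logistic

$$f_{eq}(E) = \frac{1}{1 + e^{-nF(E - E_0)/RT}},$$

with n = 1 for ferri/ferrocyanide and T = 310.15 K by default. Bulk
electrolysis is modelled as first-order relaxation toward that endpoint,

$$\frac{df}{dt} = k_e\,(f_{eq}(E) - f) - k_{cell}\,\rho\,f,$$

where `k_e` lumps electrode kinetics and stirring-limited mass transport
into one rate, and the second term is reduction of Fcn(O) by respiring
cells at density $\rho$ (OD units), reflecting the observation that
mediator reduction scales with both cell amount and Fcn(O) concentration.
Butler–Volmer kinetics, electrode geometry and diffusion are deliberately
not modelled: at the device's operating points (+0.5 V for oxidation,
−0.3 V for reduction, both far beyond the voltammetric peaks) conversion is
transport-limited and a single relaxation rate captures the observed
behaviour. The default `k_e = ln(100)/900` s⁻¹ makes 99% conversion take
15 minutes, the bulk-interconversion time scale of the physical set-up; it
is a calibration to that time scale, not a measured rate constant (none is
reported for the apparatus). Likewise `k_cell` is a free parameter with
default 0 (no cells in the chamber).

The emitted current covers the electrode term only,
$I(t) = -nFVC\,k_e(f_{eq}-f)$, with the convention that oxidation carries
negative current, so measured charge is negative during ON signals (the
device operates between 0 and about −1.45 C, the Faraday capacity of the
3 ml, 5 mM pool). `integrate_charge()` is a cumulative trapezoid;
because the current is discontinuous at potential switches, the simulator
emits a double sample (1 µs apart) at each switch so the trapezoid stays
exact across boundaries — integrated charge matches the Faraday equivalent
of net conversion to ~10⁻⁴% (the acceptance suite checks 0.5% over random
schedules).

Integration is fixed-step RK4 with `dt = 1` s. Within a segment the ODE is
linear, so the RK4 update is an affine recurrence applied in closed form —
bit-identical to stepwise RK4 but vectorised. A schedule segment with `NA`
potential means *open circuit*: the electrode term is off but the cell
term keeps acting. This models the experimental protocol in which cells
are pulsed for a fixed time and then incubated away from the electrode.

```{r electro-demo}
sim <- simulate_bulk_electrolysis(electrolysis_state(),
                                  signal_schedule(0.5, 900))
round(tail(sim$frac_ox, 1), 4)                       # ~0.99 of the pool
round(tail(integrate_charge(sim$trace), 1), 3)       # ~ -1.43 C
```

# The reporter circuit

Synthesis is gated by pyocyanin and amplified by the oxidized mediator:

$$s(f) = \frac{pyo}{K_{pyo}+pyo}\left(s_0 + s_{max}\,\frac{f}{K_{fcn}+f}\right),
\qquad \frac{dP}{dt} = s(f(t)) - k_{deg}\,P.$$

No synthesis occurs without pyocyanin; Fcn(O) alone induces nothing. The
defaults encode three observations: (i) the full-ON to basal steady-state
ratio is ~17× (`s_max = 16 s_0 (K_{fcn}+1)`); (ii) the dose response in
Fcn(O) keeps rising across the tested range and the charge–fluorescence
relation stays near-linear to about a third of pool conversion, which
places the half-saturation at full pool oxidation (`K_fcn = 1`; a much
smaller value would saturate the response at a few percent conversion,
contradicting both observations); (iii) visible reporter decay inside
45 minutes of switching OFF, encoded as a 25-minute half-life
(`k_deg = ln 2 / 1500` s⁻¹) — a calibration default, not a measured value.
Fluorescence is identified with protein amount in arbitrary units; phiLOV
needs no oxygen-dependent chromophore maturation, so the maturation lag
defaults to zero (the parameter exists for other reporters). OFF is purely
the removal of the amplified synthesis term; the tag does not accelerate
degradation further. Growth dilution and mRNA dynamics are out of scope.

## Deconvolving synthesis from degradation

Because the reporter is unstable, measured fluorescence understates how
much protein was made. If $P$ obeys the equation above, the cumulative
degradation-free synthesis is recoverable from data alone:

$$S(t) = P(t) - P(0) + k_{deg}\int_0^t P\,d\tau,$$

computed with the trapezoid rule (`integrated_synthesis()`). On noiseless
traces this identity is exact to integration error (<10⁻⁵ relative at 1 s
steps). For measured traces an optional centred running mean
(`smooth_window = 5`) is applied first; without it the endpoint sample
contributes its full measurement noise to $S$. The degradation rate itself
is estimated from an OFF-phase segment by log-linear least squares
(`fit_degradation_rate()`), which recovers a 25-min half-life to ~2%
(median) from traces with 5% multiplicative noise.

Two protocol-level experiments wrap the simulator. A *cycle sweep*
(`cycle_experiment()`) applies ON for half of each cycle and OFF for the
rest: half-cycle fluorescence grows monotonically with cycle time, short
cycles keep accumulating through OFF (15 min of interconversion leaves
Fcn(O) present most of a 30-min cycle), and cycles of 90 min and beyond
lose half their signal by cycle end. A *charge–synthesis relation*
(`charge_synthesis_relation()`) solves for the program delivering each
target charge — either +0.5 V for a computed duration, or a computed
potential for a fixed 15-min pulse — simulates a pulse-then-incubate
protocol, and fits synthesis against |charge|: the two delivery modes
agree within ~1%, and the relation is linear (R² > 0.99) through −0.5 C.

```{r charge-demo}
rel <- charge_synthesis_relation(-c(0.1, 0.2, 0.3, 0.4))
round(rel$fit$r_squared, 4)
```

# Motility video analysis

The tracker mirrors a centroid-based bacterial tracking pipeline:

* **Segmentation.** Each frame is thresholded with Otsu's method computed
  on its own 256-bin histogram (per-frame thresholds absorb slow
  illumination changes; 16-bit input would be min–max rescaled to 8 bit
  first). The returned threshold is the lowest level of the foreground
  class, ties broken downward, and it provably equals exhaustive
  maximisation of the between-class variance. Foreground pixels are
  labelled by 8-connected components; components below `min_area = 4` px
  (noise) or above `max_area` (flooded background) are dropped; centroids
  are unweighted pixel means. Coordinates are (x = column, y = row),
  origin top-left. Otsu has a known failure mode when the foreground is a
  tiny fraction of a noisy histogram (it then splits the background mode);
  the synthetic scenarios keep blobs bright and backgrounds quiet, which
  is what a GFP-filter fluorescence video of dilute cells looks like.
* **Linking.** Detections in consecutive frames are joined greedily in
  ascending cost, each detection used once, where the cost combines
  closeness, size similarity and intensity similarity with weights
  (1, 0.5, 0.25) and a hard gate. The gate defaults to 20 px ≈ 3× the
  expected per-frame displacement of the default scenario (20 µm/s at
  10 fps and 0.32 µm/px is 6.25 px/frame). Greedy assignment equals the
  exhaustive minimum-cost matching when motion respects the gate and cells
  are separated — the regime the algorithm is built for — but not on
  arbitrary point clouds, where optimal assignment can trade a cheap pair
  for two moderate ones. Tracks may bridge up to `max_gap = 1` missing
  frame (the gate grows with the elapsed frames) and must contain at least
  `min_length = 10` detections. All of these are configurable; none has a
  counterpart measured for the original apparatus.
* **Drift.** Background flow is estimated per frame pair as the
  componentwise median displacement over all links — robust because the
  swimming component is direction-random. Two refinements are layered on
  by `track_video()` (the primitive `estimate_drift()` is unchanged):
  the per-pair estimates are replaced by their temporal median, because
  flow is steady over a ~10 s acquisition while per-pair medians carry
  heading noise that decays only slowly with cell number (headings persist
  between tumbles, so the effective sample count is runs, not links); and
  the estimate is *anchored* on coherently advected cells where they
  exist — a stuck cell rides the flow exactly, while every swimmer's
  displacement sits a full swim step away from it, so trajectories whose
  residual from the initial estimate is far below the typical residual
  (and below an absolute 2.5 px cap) re-measure the flow to centroid
  accuracy. Anchor displacements are gated per pair against the initial
  estimate so a track spliced onto a swimmer by a crossing cannot poison
  the estimate. With neither tumbling nor anchor cells, flow estimation
  from a handful of straight swimmers is ill-posed; for such videos
  disable `drift_correction`.
* **Stuck cells.** A trajectory is stuck when its drift-corrected net
  displacement over the whole track, or over every sliding 1 s window,
  falls below 2 µm; windows individually below the threshold flag a
  *partially* stuck cell and only its moving segments enter the velocity
  statistics. Crossing events occasionally splice a stuck cell's track
  onto a swimmer's; the stuck half is then excluded by exactly this
  windowed mechanism.
* **Velocity.** Mean over frame pairs of the drift-corrected displacement
  magnitude, converted by pixel size and frame rate; gap pairs divide by
  elapsed frames. Pairs whose detection area is inconsistent with the
  track median (a merged blob) or whose detection has a neighbour within
  12 px (halo-biased centroid) are excluded. Stuck tracks are excluded
  entirely. `trajectory_rose()` translates the first 3 s of each track to
  the origin for the conventional rose display, and
  `velocity_statistics()` reports means, standard errors and two-tailed
  pooled-variance Student t comparisons (the degenerate identical-group
  case returns t = 0, p = 1).

On synthetic run-and-tumble videos (below) with 10–30 cells, 10% stuck and
flow up to 30% of swim speed, the tracker recovers over 95% of true
frame-to-frame links, per-cell mean speeds within 5% on cleanly tracked
cells, flags every stuck cell, and changes no corrected speed by more than
2% when a uniform translation is added to every frame.

# Flow cytometry

`gate_events()` applies a rectangular forward/side-scatter gate (the
conventional first step before fluorescence summarisation; the physical
instrument's gate shape is not modelled beyond that). `mean_fluorescence()`
is the arithmetic mean of the green channel, the summary used for
population-level dose responses. `population_split()` detects an emergent
bright subpopulation — the signature of a relay/receiver co-culture in
which only receivers light up — by applying the same audited Otsu
machinery to the histogram of log10 fluorescence and scoring the split by
between-class over total variance. A single log-normal population cannot
score above ~0.64 on that ratio (the optimum for a Gaussian is
$\varphi(0)^2/\tfrac14 \approx 0.637$, attained at a median split), while
well-separated mixtures score above 0.8, so the bimodality cutoff is 0.75:
above it the split marks two populations; below it the sample is treated
as unimodal and the reported fractions are not meaningful. Nonpositive
fluorescence values (possible after instrument baseline subtraction) are
handled by shifting before the log, with a warning.

# Synthetic data and what passing tests mean

Every generator is seeded and emits machine-readable ground truth:

* `gen_expression_trace()` integrates the reporter ODE *exactly*
  (piecewise closed form for piecewise-constant synthesis) and adds
  multiplicative (CV) noise — so deconvolution is tested against truth,
  not against another numerical integrator.
* `gen_motility_video()` renders run-and-tumble swimmers as Gaussian
  blobs (σ = 2 px) with per-cell brightness variation on a noisy
  background (additive Gaussian, σ = 3 grey levels — a high-SNR
  fluorescence acquisition), ~100 frames at 10 fps and 0.32 µm/px (20×
  objective scale; the true acquisition parameters are not reported, so
  these are declared assumptions). Swimmers move at constant speed with
  exponential run lengths; tumbles redirect uniformly at frame boundaries,
  so a mover's per-frame displacement is exactly one swim step and
  ground-truth speed is well defined. There is no directional persistence
  at tumbles. A `stuck_fraction` of cells is immobile; uniform drift is
  applied to *all* cells (stuck cells ride the flow, as adhered debris
  does in a flowing slide chamber). Initial positions are
  rejection-sampled so no two cells begin merged, and seeded upwind of the
  net drift. Motion clamps at the field border with heading reversal.
* `gen_cytometry_events()` draws log-normal fluorescence and Gaussian
  scatter per population; the default is the 1:1 two-population design of
  a relay:receiver co-culture with 10× median separation, 50,000 events.
* `gen_current_trace()` adds Gaussian noise to the simulated current and
  reports the noiseless total charge.

What the generators deliberately do not emulate: optics beyond a Gaussian
point-spread function (no depth of field, photobleaching, or non-uniform
illumination), hydrodynamic cell–cell interactions, cytometer
compensation/spillover, growth and division during a video, and the
intracellular redox chemistry lumped into the saturating amplification
term. Passing tests therefore demonstrate that the *algorithms* are
correct and well-calibrated on data matching their stated assumptions, not
that those assumptions exhaust real microscope or cytometer data.

# Pipelines and reproducibility

`run_pipeline()` executes a list of named stages (generation, simulation,
deconvolution, tracking, statistics, gating) from a configuration list or
YAML file. All parameters are validated against the type invariants before
any stage runs. One global seed is declared; each stage derives its own
seed deterministically from the global seed and the stage name, so stages
can be re-run independently. Every run writes a JSON manifest with
parameters, seeds, package version, and MD5 checksums of all outputs:
identical configuration and seed reproduce identical checksums. Formats
are deliberately plain: two-column CSV for time series, CSV for schedules,
events, trajectories and speeds (comma-separated, '.' decimal, UTF-8,
mandatory header; malformed files are rejected with the offending row),
YAML for configuration, and multi-page 16-bit grayscale TIFF with a YAML
sidecar for videos (bit-exact round trips). Native cytometry formats (FCS)
are not parsed.

A thin command-line wrapper over `run_pipeline()` ships in
`inst/scripts/electrogenetics-cli.R` for shell use; the R functions are
the primary interface.

# Numerical choices, sizes and limitations

* RK4 with `dt = 1` s everywhere; halving `dt` changes trajectories by
  <10⁻⁶. Trapezoid rule for all integrals; discontinuities carry double
  samples.
* Root finding for charge-matched programs uses `uniroot` on the simulated
  charge (tolerance 10⁻⁶ s in duration, 10⁻⁹ V in potential).
* The test and acceptance suites use 50 expression traces, 100 random
  schedules, 20 videos of ~100 frames at 512×512 px, 1000 histograms, 500
  linking instances, 100 degradation fits and 10,000-event mixtures —
  sizes at which every Monte-Carlo bound in the suite is stable across
  seeds while the whole suite runs in a few minutes on one core.
* Known limitations: centroid tracking cannot resolve cells during a merge
  (crossings can swap identities; the QC flags mitigate, not eliminate,
  the effect on statistics); drift estimation needs tumbling or anchor
  cells; Otsu needs a non-negligible foreground fraction; the circuit
  model's parameters are calibrations to reported observations, not fitted
  constants, so its outputs are in arbitrary units and only shapes and
  ratios are meaningful.
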