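---
title: "Cylinder hydrodynamics of fragmented amyloid fibrils: models, conventions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cylinder hydrodynamics of fragmented amyloid fibrils}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrilhydro)
```

# The problem

Amyloid fibrils made from beta-lactoglobulin (BLG) are micrometre-long,
nanometre-thin protein assemblies. After controlled fragmentation in a
rotor--stator disperser they become short, rigid, cylinder-like rods whose
length distribution controls their functionality (and, for pathological
amyloids, their cytotoxicity). Counting fibrils one by one in AFM images is
accurate but slow; sedimentation-velocity analytical ultracentrifugation
(AUC) characterizes the whole population in solution within hours. This
package implements the machinery that connects the two measurements:

1. a forward/inverse hydrodynamic model linking a rigid cylinder's length
   and height to its sedimentation coefficient,
2. weighted-distribution algebra to move distributions between length space
   and sedimentation-coefficient space and between number, mass and
   extinction weighting,
3. a Brownian-dynamics simulator of constant-speed gravitational-sweep
   experiments (to quantify when slow, non-aggregated material can be
   ignored),
4. a 2D length-by-height analysis quantifying how a distributed fibril
   height broadens the sedimentation-coefficient distribution, and
5. power-law fitting of comminution (size-reduction) kinetics.

# The cylinder model

A rod of length $l$ and height (cross-sectional diameter) $h$ with aspect
ratio $q = l/h$ sediments with

$$ s \;=\; \frac{d_\mathrm{eq}^2\,(\rho_{F,\mathrm{eff}} - \rho_S)}
                {18\,\eta\,(f/f_0)},\qquad
   d_\mathrm{eq} = \Big(\tfrac{3}{2} h^2 l\Big)^{1/3}, $$

where $d_\mathrm{eq}$ is the diameter of the equal-volume sphere,
$\rho_{F,\mathrm{eff}}$ the effective (hydrated) fibril density, $\rho_S$
and $\eta$ the solvent density and viscosity, and the frictional ratio is
Hansen's polynomial in $k = \ln q$:

$$ f/f_0 = 1.0304 + 0.0193k + 0.06229k^2 + 0.00476k^3 + 0.00166k^4
           + 2.66\times10^{-6}k^7 . $$

Two conventions deserve comment.

**Equivalent-sphere form.** Some printed forms of the rearranged cylinder
equation carry $(3h^3/(2q^2))^{2/3}$, which would make $s$ *decrease* with
length. Equality of cylinder and sphere volumes
($\pi h^2 l/4 = \pi d_\mathrm{eq}^3/6$) requires
$d_\mathrm{eq} = (3h^2l/2)^{1/3} \equiv (3h^3q/2)^{1/3}$, which is what
this package implements; it reproduces the expected monotone increase of
$s$ with $l$ at fixed $h$.

**Units.** All internal computation is SI (m, s, kg m$^{-3}$, Pa s).
Exported functions speak the field's units -- nm for lengths and Svedberg
($1\,\mathrm{S} = 10^{-13}\,$s) for sedimentation coefficients -- so that a
$10^{13}$ slip cannot occur silently.

## Parameters and defaults

| parameter | default | unit | rationale |
|---|---|---|---|
| base density | 1331.6 | kg m$^{-3}$ | inverse partial specific volume of BLG |
| densification | 1.02 | -- | cross-beta cores pack ~2 % tighter than native BLG (a molecular-dynamics result consumed here as a constant) |
| solvent density | 998.2 | kg m$^{-3}$ | water at 20 °C; pH-2 HCl at these concentrations is indistinguishable |
| solvent viscosity | 1.002e-3 | Pa s | water at 20 °C |
| fibril height | 4.7 | nm | 4.0 nm dry AFM height + two bound water layers (0.7 nm) |
| minimum AFM length | 50 | nm | image-analysis detection limit |

The inverse model `length_from_s()` exploits monotonicity: a bracketed root
search on $q \in [1, 10^6]$ (expanded if needed) with a relative tolerance
of $10^{-12}$ on $s$; the forward-then-inverse round trip reproduces lengths
to $10^{-9}$ relative over the 50--2000 nm range.

A worked curiosity: the often-quoted "~31 MDa for a 500 nm fibril with a
5 nm cross-section" is only consistent if 5 nm is the cross-sectional
*radius* (`cylinder_molar_mass(500, 10)` $\approx$ 31.5 MDa); taking it as
the diameter gives 7.9 MDa. Both values are exposed and tested.

# Weighted distributions

`weighted_distribution` stores a density tabulated on a strictly increasing
grid plus an explicit weighting basis (`number`, `mass`, `extinction`). Two
numerical conventions make every conversion exactly conservative:

* The integral is always the trapezoid rule, so a density vector and its
  vector of *node weights* (half-spacing at the ends, mid-spacings inside)
  convert between density values and point masses exactly.
* Axis transforms ($l \leftrightarrow s$) carry point masses through the
  monotone map and divide by the node weights of the image grid -- a
  discrete Jacobian. Total weight is conserved to machine precision rather
  than to the accuracy of a sampled $|\mathrm{d}l/\mathrm{d}s|$.

Weighting conversions multiply or divide by the relative fibril mass
($\propto h^2 l$, i.e. $\propto l$ at constant height) and renormalize.
Extinction weighting equals mass weighting under the assumption that every
subunit of a fibril contributes equally to the optical signal; the package
treats the two as synonyms with distinct tags.

Quantile summaries report the mode (grid point of maximum density), the
weighted mean, the median, and Q10/Q90 by linear interpolation of the
cumulative. Because "width" is used loosely in the experimental literature,
both $(Q_{90}-Q_{10})/2$ and the weighted standard deviation are reported;
where a single number is needed the package uses $(Q_{90}-Q_{10})/2$.
Similarly Q50 is reported as the weighted mean, with the median alongside.

Density-shape fits (`fit_lognormal`, `fit_weibull`) are least squares on
the tabulated density -- matching the classed-data workflow of microscopy
and AUC practice -- not maximum likelihood on raw records; starting values
come from weighted moments and optimization uses `minpack.lm::nlsLM`.

# The gravitational-sweep simulator

In a gravitational sweep the rotor spins at constant speed (30,000 rpm
here) and a detector at fixed radius $r_\mathrm{fix}$ records the signal
over time; a species' boundary arrival time maps to its sedimentation
coefficient via $s = \ln(r_\mathrm{fix}/r_m)/(\omega^2 t)$.

Particles follow the overdamped step
$\mathrm{d}r = s\omega^2 r\,\mathrm{d}t + \sqrt{2D\,\mathrm{d}t}\,\xi$ with
reflection at the meniscus and accumulation at the cell bottom; initial
positions are drawn proportional to $r$ (sector geometry), so radial
dilution emerges from the dynamics rather than being imposed. Diffusion
coefficients derive from $s$ and $f/f_0$ through the equivalent sphere
(Stokes drag $f = 3\pi\eta d_\mathrm{eq} (f/f_0)$, $D = k_BT/f$). The
per-species detector signal is the particle count in a radial window at
$r_\mathrm{fix}$, normalized by its *expected* initial count (using the
realized count instead would imprint a common $O(N_\mathrm{window}^{-1/2})$
scale error on the whole trace). The default integration step is 0.5 s --
the fastest species of the study configuration advances ~3.5 µm per step,
far less than the detector window -- and the simulator refuses steps that
move the fastest species more than 0.1 mm.

The particle loop is a small C++ kernel with a dedicated counter-based RNG
(xoshiro256++ seeded via splitmix64), so runs are bit-reproducible for a
given seed and independent of R's RNG state.

## Recovering the distribution from the trace

In a sector cell the plateau concentration of a species decays as
$e^{-2s\omega^2 t}$ (radial dilution), so the raw signal drop does *not*
read off the cumulative distribution: for the three-species study mixture
the naive reading misplaces the mid-plateau cumulative by ~0.1. The default
analysis therefore fits the trace by non-negative least squares with
single-species model traces

$$ B_s(t) = e^{-2s\omega^2 t}\;
   \Phi\!\left(\frac{r_\mathrm{fix} - r_m e^{s\omega^2 t}}
                   {\sigma_s(t)}\right),\qquad
   \sigma_s^2(t) = \frac{D(s)}{s\omega^2}\left(e^{2s\omega^2 t}-1\right)
                  + \frac{w_\mathrm{det}^2}{12}, $$

the radially diluted plateau times a boundary broadened by diffusion (with
the exact variance of the linear drift--diffusion process, which the
$r$-proportional drift stretches) and by the finite detector window. As in
c(s)-style boundary modeling, $D(s)$ is tied to $s$ through a fixed
frictional ratio (default 1.5, the fibril-like value). The fitted class
weights are the extinction-weighted distribution; classes below the cutoff
(default 10 S) are discarded and the result renormalized.

One structural point: a sweep of duration $T$ only resolves species whose
boundary traverses meniscus-to-detector within the run, i.e.
$s \ge \ln(r_\mathrm{fix}/r_m)/(\omega^2 T)$ (~22 S for the study
configuration). Slower classes produce no front at the detector; their
basis functions are near-degenerate slow decays that can only absorb noise.
The default recovery grid therefore spans only the resolvable range in
10 S classes (wide enough that diffusional boundary spreading of
fibril-scale species stays within one class), plus a few slow catch-all
components below the cutoff that absorb the gradual dilution of
non-aggregated material. The naive drop reading remains available
(`method = "naive"`) as a diagnostic of the size of the dilution
correction.

The default detector window is 1 mm. This is a statistics/resolution
compromise for the particle-count detector: the window must hold enough
particles that low-frequency count wander (particles enter and leave the
window slowly) does not masquerade as slow-sedimenting signal, yet stay
narrow against the boundary spacing of neighbouring s classes. One mm puts
~8100 particles per $10^5$ in the window, while a 100 S boundary crosses it
in ~150 s -- an order of magnitude below the front-time spacing of adjacent
10 S classes at 100 S, and modeled exactly by the window term in
$\sigma_s(t)$ anyway. Convergence checks across windows of 50 µm to 1 mm
show the recovered staircase stabilizing (sup-distance to the input
distribution falling from ~0.03-0.05 at 50 µm to ~0.01 at 1 mm for
$10^5$ particles per species) because the estimator is
count-statistics-limited, not resolution-limited, at these sizes.

# The 2D length-by-height analysis

AFM shows fibril heights are distributed (a dominant population near
4.0 ± 1.0 nm dry). `build_2d` forms the independent product of a
mass-weighted length distribution with a normal height distribution
truncated at 0.5 nm, on a 41-point grid spanning mean ± 4 sd. Because the
marginals of an outer product must reproduce the generating distributions,
the joint weight is exactly (mass-weighted length marginal) × (height
probability); a number-weighted input is converted to the mass basis first.

Consistency requires the same hydration convention on both sides of any 1D
vs 2D comparison: the dry heights get the same +0.7 nm two-water-layer
offset that turns the constant 4.0 nm into the standard 4.7 nm, so the
effective height distribution is N(4.7, 1.0) nm. `map_2d_to_s` evaluates
the forward model per cell and accumulates cell weights into 128 linear s
bins up to 1.1 × the largest cell value, dropping (and reporting) cells
with aspect ratio below 1.

What this analysis shows, on an AFM-like lognormal length fixture: the
induced s-distribution is several-fold wider than the constant-height one
(ratio ~5 with the defaults, against a reported ~sevenfold jump), its mode
shifts slightly to lower s, and it tails above the 1D maximum. The *mean*
of the induced distribution sits ~3 % above the 1D mean: averaging
$s \sim h^{1.75}$ (the $h^{4/3}$ of the equivalent sphere times the
aspect-ratio dependence of $f/f_0$) over heights with a 21 % coefficient of
variation is convex, and no truncation or grid choice removes that. The
median agrees to well under 1 %. So "the mean remains approximately
constant" holds at the few-percent level here, not at the 1--2 % level; the
package reports both central values and leaves the judgement explicit. The
low-s corner of the 2D result (short *and* thin rods) is flagged rather
than removed: such combinations arise from the independence assumption and
are not observed experimentally.

# Comminution scaling

Rotor--stator stressing at speed $\omega_\mathrm{stress}$ (rpm) for time
$t_\mathrm{stress}$ is indexed by its rotation count
$n = (\mathrm{rpm}/60)\,t_\mathrm{stress}$. In the turbulent regime
(Re > $10^4$, where the Newton number is constant) the volume-specific
energy input scales as $E_V \propto n^3$, so a size-reduction law
$x \propto E_V^{-b}$ appears as $l \propto n^{-3b}$. `fit_size_reduction`
is ordinary least squares of $\ln l$ on $\ln n$ with $b = -\mathrm{slope}/3$;
exclusions are explicit and echoed (by default the 11,000 rpm / 5 s
condition, where the flow pattern around the stirrer has not developed),
and there is no automatic outlier rejection. Typical fluid-stress
comminution has $b$ between 0.3 and 0.8; values outside that band are
noted in the printout, never enforced.

# What the synthetic fixtures emulate -- and what they do not

`generate_afm_fixture` draws lognormal lengths truncated to [80, 810] nm
with the log-scale location solved (at fixed shape $\sigma_{\ln} = 0.4$, a
realistic polydispersity for fragmented fibrils) so the truncated mean is
395 nm -- the reported statistics of a stressed AFM sample. Heights, when
requested, are N(4.0, 1.0) nm truncated at 0.5 nm.
`generate_sweep_fixture` emits the exact three-species simulation study
(NAM at 4 S, f/f0 1.26, native density; fibril-like 50 S and 100 S,
f/f0 1.5, 2 % densified; equal signal thirds; 10 S cutoff).
`generate_comminution_fixture` draws $l = a n^{-3b}$ over the studied
stressing grid with optional multiplicative lognormal noise.

These fixtures reproduce the *statistical shape* of the study inputs, not
real data: real AFM tables carry tracing and drying artifacts, real AUC
traces carry optical noise and concentration non-ideality, and real fibril
length and height are likely weakly correlated where the fixtures assume
independence. Passing tests therefore validate the transformations and
estimators, not instrument behaviour.

# Numerical choices and degenerate inputs

* Binning of raw length tables: 64 linear bins over the surviving records
  (distinct values are used directly when fewer); densities live at bin
  centers.
* Zero-sd heights collapse `build_2d` to the 1D pipeline exactly (same
  binning, bit-for-bit).
* Neutral buoyancy returns s = 0 with a warning rather than an error.
* An s grid partly below the rod limit $s(q{=}1)$ is truncated with the
  excluded weight reported; entirely below is an error.
* Problem sizes in the test suite: $10^5$ particles per species and 0.5 s
  steps for the full sweep reproduction (the simulator's convergence is
  additionally checked by a seeded sqrt-n error-scaling test at
  4--32 × 10^3 particles); 2000-fibril AFM samples; 200-point density
  grids for fit recovery.

# Known limitations

* Rigid right cylinders only: no flexibility, twist, or bead-model
  cross-sections; beyond ~700 nm contour length real fibrils bend and the
  cylinder inversion under-resolves the upper distribution tail.
* Constant-height inversion: AUC-to-length conversion assumes one height
  for all lengths; the 2D module quantifies what that hides but cannot be
  inverted from a 1D measurement.
* The sweep analysis assumes non-interacting species at high dilution --
  no concentration-dependent s, no optical physics beyond
  equal-per-subunit extinction.
* Ramped-speed sweeps and rotor acceleration are out of scope; the rotor
  speed is constant.
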