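---
title: "Methods: from float fluorescence to hydrothermal iron delivery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from float fluorescence to hydrothermal iron delivery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ventbloom)
```

ventbloom implements the observational chain used to argue that hydrothermal
vents on a mid-ocean ridge can fuel open-ocean phytoplankton blooms far from
the classical Southern Ocean iron sources (shelves, islands, sea ice). The
chain has five quantitative stages, each of which this vignette describes
together with the modeling choices behind it and what the synthetic tests do
— and do not — demonstrate about real data.

## 1. Float-profile processing and bloom phenology

**Fluorescence to chlorophyll.** Raw fluorescence counts are converted as
`chl = max(fluo - dark, 0) * slope * f490`. `dark` and `slope` are the
factory calibration; `f490` is a Southern-Ocean radiometric correction
factor. The adopted conservative value `f490 = 0.3` implies that
factory-calibrated chlorophyll overestimates truth by 1/0.3 = 3.3. Negative
dark-corrected counts clamp to zero because concentrations are nonnegative.

**Quenching correction.** Daytime near-surface fluorescence is suppressed by
non-photochemical quenching. On daytime casts the maximum raw fluorescence at
or above the mixed layer depth is extrapolated to the surface (every
shallower level is overwritten); night casts pass through unchanged. The
correction runs on raw counts before calibration; since the calibration is
affine with a clamp, the order matters only where counts fall below the dark
value, and a unit test documents that boundary.

**Mixed layer depth.** The depth where potential density first exceeds its
10 m value by 0.03 kg m⁻³. Two choices were genuinely open:

* the crossing is located by *linear interpolation* between the bracketing
  sampled levels rather than reported as the first discrete level past the
  threshold — this makes the estimate independent of the sampling grid (the
  analytic case, stratification of 0.001 kg m⁻³ per meter below 10 m, gives
  40 m to within millimetres on a 5 m grid);
* the 10 m reference density is interpolated to 10 dbar; if the shallowest
  level lies between 10 and 15 dbar it is used with a flag, deeper casts get
  an undefined MLD. Pressure is treated as depth (1 dbar = 1 m) at these
  scales.

Density itself comes from in-package EOS-80 routines (potential temperature
by Runge–Kutta integration of the adiabatic lapse rate, then the UNESCO
density polynomial at zero pressure); both are pinned to the published
check values in the unit tests.

**Euphotic depth.** The 1% light depth from surface chlorophyll via the
standard case-1-water cubic in log10(chl), coefficients
(1.524, −0.436, −0.0145, 0.0186), configurable. "Surface" chlorophyll is the
mean over the top 10 m (a documented choice — the definition is not fixed by
the processing conventions this package follows).

**Phenology.** Float records are split into austral years starting 1 July
(half-open intervals). A season qualifies when at least 8 casts fall inside
1 November – end of February (leap-aware). Casts are binned into 20-day bins
*anchored at 1 July* so bin edges reproduce across floats; the bloom
magnitude is the maximum over bins of the per-bin *mean* depth-integrated
chlorophyll, integrated from the surface to max(MLD, Zeu). Bin means rather
than bin maxima implement the smoothing intent of the 20-day decorrelation
binning; anchoring and the mean/max choice are both configuration-visible.

**Type comparison.** Bloom types (island/plateau-influenced, ice-influenced,
ridge-influenced, HNLC) are assigned from gridded masks with the precedence
island/plateau > ice > ridge > HNLC; the delivery-zone mask can be computed
from the Lagrangian stage, while ice and ridge zones are configured
polygons/grids (there is no algorithmic rule for the ridge class; it is
reproducible-but-configured). Magnitudes are compared across types with the
Kruskal–Wallis H test (`stats::kruskal.test`, tie-corrected). Note that the
chi-square approximation is mildly conservative at small group sizes: with
four groups of ten the empirical size at nominal 5% is about 0.041, so
Monte-Carlo size estimates over 5000 simulations scatter around that value.

## 2. Eddy kinetic energy

Deep velocities come from park-depth float displacements:
u = Δlon·cos(lat̄)·(π/180)·R/Δt, v = Δlat·(π/180)·R/Δt with R = 6371 km
(all great-circle geometry in the package uses this radius). Each velocity is
attributed to the *start fix* of its cycle: attributing to the displacement
midpoint sorts fast parcels into downstream boxes and biases within-box
variances low by order (displacement/box)², which at 1° boxes and 10-day
cycles is a large effect.

Velocities are pooled into 1° boxes; EKE = ½(var u′ + var v′) with
*population* (1/n) variances — the n vs n−1 choice is not fixed by the
method's description and is below 20% at the retained counts. Boxes with 5
or fewer samples are masked (strictly more than 5 required). The coarse field
is interpolated to a fine grid by a count-weighted Gaussian kernel
exp(−d²/2r²) with r = 100 km (the alternative convention exp(−d²/r²) only
rescales r). Surface EKE applies the same anomaly definition per node of a
gridded velocity time series; both are reported in cm² s⁻².

## 3. Density climatology and alongstream isopycnal shoaling

Quality-flag-1 T/S profiles are interpolated to 25 dbar standard levels
(0–2000), converted to σ₀, and mapped per level onto a 0.5° grid with an
*isotropic* Gaussian optimal interpolation of 550 km scale (weighted mean;
n_eff = total weight with a 0.2 floor). The anisotropic isobath-following,
front-sharpening and recency-weighted machinery of the full published
mapping is deliberately not reproduced; the consequences are visible in the
tests (below). The final climatology is convectively sorted so σ₀ is
non-decreasing with pressure, with sorted nodes flagged.

Two meridional sections (28°E and 38°E, 47–55°S) are compared *alongstream*:
each is resampled from latitude to dynamic height via the dh(lat) relation
along its own meridian, and Δσ(P, dh) = σ_downstream − σ_upstream, so
positive Δσ at depth means isopycnals shoal downstream. The dh axis maps
back to a pseudo-latitude through the inverted sector-mean dh(lat)
(piecewise linear; isotonic regression is applied first if the sector mean
is non-monotone, and non-monotone section dh restricts to the largest
monotone envelope with excluded latitudes flagged). Dynamic height is always
an *input* (the altimetric product for real runs, the prescribed
streamfunction for synthetic runs); the package never derives it from T/S.

Two test regimes separate the two claims involved:

* *tilt recovery through the full chain*: a prescribed alongstream contrast
  of 0.2 kg m⁻³ per 10° longitude peaking at 750 dbar is recovered at
  0.197 kg m⁻³ through binning → OI → section extraction → dh differencing
  (3000 profiles, 1% density noise);
* *meander invariance*: a front displaced northward downstream with no
  water-mass change gives a large fixed-latitude difference but an
  alongstream difference at machine precision — demonstrated on analytically
  constructed sections. Pushed through the isotropic OI the same case leaves
  a residual of order 0.05 kg m⁻³ near the domain's latitude edges; that
  residual is a property of the simplified smoother, not of the coordinate
  transform, and is the main known limitation of this stage.

## 4. Lagrangian iron delivery

Particles seeded on a regular grid (default ¼°) are integrated *backward*
through linearly (space and time) interpolated velocities with classical
RK4 at 6 h steps; the first source contact encountered backward in time is
the particle's most recent contact, its age converts to a delivered-iron
fraction exp(−age/τ), and seeding every 10 days through each November–March
season yields climatological mean age and mean delivery maps (non-contacting
node-seasons are excluded from means, with counts recorded). Sources are
(1) bathymetry shallower than 500 m and (2) the ridge-upwelling region
represented by two overlapping 1°-radius disks centered at (30°E, 50°S) and
(30.5°E, 49.5°S); membership is tested by great-circle angular distance, and
beached particles keep no-contact status rather than inheriting a shelf
contact.

The scavenging e-folding time τ is *not* fixed by the method's sources: a
90-day default is exposed in the configuration, but transit regimes in which
10–30% of iron survives 1–2 month journeys imply τ ≈ 20–35 days; both
regimes are left to the user and the acceptance computation uses τ = 20 d
for the closed-form contour check (the 10% delivery contour in steady flow
at speed U lies U·τ·ln 10 downstream of the source edge).

Two integrator details matter for testing. The synthetic "solid-body" flow
is a rigid rotation of the lon/lat *coordinate plane* scaled to m/s by the
local metric, so its orbits close exactly and the one-period return error
isolates the integrator (< 10⁻³ of the orbit radius at 6 h steps). And the
integrator accepts an analytic velocity function as well as a gridded
series: on a bilinearly interpolated grid the interpolation error
(~7×10⁻⁵, set by the curvature of cos lat across grid cells) floors the
RK4 error (~4×10⁻⁷), so fourth-order convergence (error ratio ≈ 16 under
step halving) is only measurable against the analytic field.

## 5. Tracer sections

Helium-isotope (δ³He) station profiles are gridded into depth × along-track
sections with *linear* interpolation only — first to the depth grid within
each station's sampled range, then along cumulative great-circle distance
between stations — so the section can never overshoot the station data, an
invariant the tests assert. Cells beyond the end stations or below a
station's deepest sample stay missing. Stations where surface EKE at the
nearest fine-grid node strictly exceeds 150 cm² s⁻² are flagged as
high-energy environments.

## The synthetic generators

Every input kind has a seeded generator returning the inputs plus a ground
truth sufficient for a recovery assertion; all generators are pure functions
of (parameters, seed) and restore the caller's RNG state.

* **Float series** — chlorophyll is a Gaussian pulse in time (default peak
  1 January, 40-day standard deviation) that is vertically homogeneous
  within a 100 m prescribed mixed layer and decays with a 15 m e-folding
  below it; the prescribed magnitude (default 80 mg m⁻²) is the peak
  integral over the mixed layer. T/S are a two-layer structure whose
  density-threshold MLD equals the prescribed one; counts are
  chl/(f490·slope)+dark so the calibration chain is exercised end to end;
  daytime casts are quenched above (strictly) the mixed layer. With 10-day
  cadence and 20-day bins the binned maximum underestimates the prescribed
  peak by ~0.5% (bin-average of the pulse), well inside the 5% recovery
  tolerance the tests assert. A deliberately deep mixed layer keeps Zeu
  shallower than the MLD at bloom amplitudes so the integration depth is
  known; real floats have shallower, time-varying mixed layers, so the
  recovery test validates the chain's arithmetic, not its skill on real
  stratification.
* **Velocity fields** — zonal jet (sech² profile), jet plus a propagating
  eddy train whose true EKE is A²/2 analytically, and the solid-body
  rotation above.
* **Displacements** — endpoints consistent with velocity = mean flow +
  isotropic Gaussian noise over a 10-day cycle, constructed to invert
  exactly through the displacement-velocity formula; true deep EKE is
  noise_sd².
* **Hydrography** — σ₀(P, lat, lon) = background(P) + meridional gradient +
  tilt·(lon−28°)/10°·shape(P) with shape Gaussian around 750 dbar, plus
  noise, realized as T profiles at fixed salinity by inverting the equation
  of state; an optional meander displaces density and dynamic height
  together. The default region is the 0–55°E, 55–45°S sector at the real
  archive's profile density scale (3000 profiles in the recovery runs).
* **Tracer stations** — δ³He Gaussian in depth about a 2300 m core, decaying
  east of the ridge with a 1500 km scale, with a background that vanishes
  above a 500 m thermocline (air–sea equilibration).
* **Bathymetry** — 4000 m plain, Gaussian ridge (1500 m crest), and a
  < 500 m shelf at the eastern edge, exercising both source kinds.

Problem sizes in the tests and the acceptance script (3000 hydrographic
profiles, 10⁴ displacement cycles, 10 eddy periods, ¼° seed rows, 5000
Kruskal–Wallis null simulations) were chosen so each recovery's sampling
error sits well inside its stated tolerance while the whole suite completes
in about a minute.

## What the synthetic tests do not show

The generators emulate structure, not realism: no Argo sampling
irregularities beyond cadence, no correlated sensor drift, no
dynamically consistent flow–density coupling (velocities and hydrography
are generated independently), no vertical advection (the upwelling argument
remains diagnostic), and the tilt/meander fields are smooth by construction.
Passing recovery tests therefore demonstrates that the pipeline computes its
definitions correctly and that its diagnostics respond to the signals they
target — not that those signals are separable in real observations at the
same signal-to-noise.
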