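# ventbloom

Diagnostics linking mid-ocean-ridge hydrothermal activity to open-ocean
phytoplankton blooms in the Southern Ocean.

Most of the Southern Ocean is iron-limited (high-nutrient, low-chlorophyll
water). Blooms are classically attributed to island/plateau iron, sea-ice
melt, or shelf sources — yet massive blooms also occur directly downstream
of hydrothermally active ridge segments, where topographically enhanced
mixing can upwell iron-rich deep water into the path of the Antarctic
Circumpolar Current. `ventbloom` implements, as one tested R package, the
full observational chain needed to make (or test) that argument:

1. **BGC-Argo profile processing** — fluorescence calibration
   `chl = max(F − dark, 0)·slope·F₄₉₀` (F₄₉₀ = 0.3, i.e. a 3.3× factory
   overestimation), daytime non-photochemical-quenching correction, density
   mixed-layer depth (Δσ₀ = 0.03 kg m⁻³ against the 10 m reference),
   euphotic depth from surface chlorophyll, and depth-integrated biomass
   ∫₀^max(MLD, Zeu) chl dz.
2. **Bloom phenology** — annual cycles from 1 July, qualification (≥ 8 casts
   in the Nov–Feb window), 20-day binning, bloom magnitude
   = max bin-mean integrated chlorophyll, bloom-type classification, and
   Kruskal–Wallis comparison across types.
3. **Eddy kinetic energy** — deep EKE = ½(u′² + v′²) from float park-depth
   displacements in 1° boxes (> 5 samples), Gaussian-smoothed at 100 km;
   surface EKE from gridded velocity time series.
4. **Alongstream isopycnal diagnosis** — 0.5°/25 dbar potential-density
   climatology by Gaussian optimal interpolation (550 km), meridional
   sections at 28°E/38°E differenced in dynamic-height coordinate,
   Δσ(P, dh) mapped to pseudo-latitude.
5. **Lagrangian iron delivery** — backward RK4 advection (6 h steps) to each
   particle's most recent contact with an iron source (bathymetry < 500 m,
   or ridge-upwelling disks at 30°E/50°S and 30.5°E/49.5°S, 1° radius), with
   exponential scavenging exp(−age/τ).
6. **Tracer sections** — δ³He station profiles gridded into vertical
   sections; stations in high surface EKE (> 150 cm² s⁻²) flagged.

A seeded synthetic-data generator emulates every input kind with prescribed
ground truth (bloom magnitude, EKE level, isopycnal tilt, plume shape), so
the whole chain is testable end to end without external data. All file
formats are plain text (CSV with a small metadata header).

## Worked example

```r
library(ventbloom)

# a synthetic float season: 80 mg m^-2 bloom, 40% daytime quenching
fs     <- gen_float_series(bloom_magnitude = 80, quench_fraction = 0.4, seed = 3)
proc   <- process_profiles(fs$profiles)
cycles <- bloom_cycles(proc)
cycles[, c("float_id", "season_start", "magnitude", "magnitude_date", "qualified")]
#>   float_id season_start magnitude magnitude_date qualified
#> 1  SYN0001   2014-07-01  79.60528     2015-01-07      TRUE
```

The prescribed 80 mg m⁻² bloom is recovered at 79.6 (the 0.5% deficit is
the 20-day bin averaging of the bloom pulse), dated early January — the
quenching correction has restored the daytime casts exactly.

```r
# deep EKE from 10^4 synthetic displacement cycles with 0.1 m/s noise
gd   <- gen_displacements(n = 1e4, noise_sd = 0.1, seed = 11)
deep <- bin_deep_eke(displacement_velocity(gd$displacements))
deep
#> <vb_eke 1 x 1 boxes, 1 unmasked, EKE 100.6..100.6 cm2 s-2>
```

The box variance recovers the generating truth of 100 cm² s⁻² within
sampling error.

```r
# where was this water 4 weeks ago, and how much iron is left?
steady_east <- velocity_series(lon = 20:46, lat = seq(-56, -44), time = 0:80,
                               u = array(0.1, c(27, 13, 81)),   # m/s
                               v = array(0,   c(27, 13, 81)))
tr <- trace_last_contact(35, -50, t_seed = 80, series = steady_east,
        masks = list(disk_mask(data.frame(lon = 30, lat = -50, radius_deg = 1))),
        lookback_days = 60, efold = 20)
tr
#> <vb_trajectory seed (35.000, -50.000)  contact 'ridge_upwelling' 28.50 d ago, iron fraction 0.241>
```

A command-line front end covers the same stages
(`simulate | blooms | eke | climatology | advect | sections | report`):

```sh
Rscript inst/scripts/ventbloom simulate --seed 7 --out fixtures/
Rscript inst/scripts/ventbloom blooms --profiles fixtures/profiles.csv --out blooms.csv
```

Identical seed and configuration give byte-identical outputs.

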