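---
title: "Methods: from pseudo-colored thermal imagery to evapotranspiration maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from pseudo-colored thermal imagery to evapotranspiration maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(etmap)
```

# The problem

A thermal camera on a UAV delivers surface brightness temperature at a far
finer grain (~8 cm from 60 m) than any satellite product, which makes it
attractive for plot-scale evapotranspiration (ET) mapping. Two practical
obstacles stand between the raw data and an ET map. First, many thermal
cameras do not export physical temperature: each snapshot is a
pseudo-colored 8-bit image whose palette spans only that frame's
temperature range, so the radiometric information has to be recovered by
inverting the palette and harmonizing the per-frame ranges across the
flight. Second, an energy-balance model needs co-registered surface
parameters (LAI, cover fractions) and accurately geotagged imagery, and
its output needs an independent check — here, eddy-covariance (EC) tower
fluxes averaged over the flux footprint.

`etmap` implements that chain end to end, with a synthetic-flight
generator in place of undeposited field data, so every stage carries
executable tests.

# Thermal codec

## Palette inversion

Each pixel color is collapsed to a single integer key
$$k = (256^3-1)\,R + (256^2-1)\,G + 255\,B .$$
The key is injective over 8-bit triples: the blue term is at most
$255 \cdot 255 < 256^2-1$, and the green plus blue terms stay below
$256^3-1$, so distinct triples can never collide. Exact lookup of the key
among the 239 colorbar entries gives a level index $i \in \{0,\dots,238\}$,
and the temperature is the linear map
$$T = T_{\min} + i\,\frac{T_{\max}-T_{\min}}{238},$$
with level 0 (darkest entry) at the frame minimum and level 238
(brightest) at the frame maximum. The quantization step of a frame
spanning $\Delta T$ is $\Delta T/238$; a decode–encode round trip is
accurate to half that step, which the tests assert as a hard bound.

## Common flight range and mosaics

Because every frame is scaled to its own range, frames must be re-expressed
on a common flight range — the envelope (min of minima, max of maxima) of
all logged frame ranges — before mosaicking. Re-encoding uses
round-half-away-from-zero quantization so the error is symmetric, and
decoding a rescaled frame reproduces the original temperature within half
a *common-range* step. Mosaicking software blends colors at seam lines, so
the mosaic-to-temperature conversion attributes each color to the nearest
palette key within a tolerance (default $3\cdot255$ key units — i.e., up to
three intensity steps on the blue channel, the least-significant term of
the key) and marks anything farther as nodata. Note that the key metric is
deliberately lexicographic rather than perceptual: a one-step change in red
moves the key by $256^3-1$. The tolerance therefore mainly admits
quantization noise, not arbitrary color blends; heavily blended seams
correctly become nodata rather than wrong temperatures.

Two choices here are ours, not dictated by the data format: the colorbar
travels as a separate 239×1 PPM strip per flight (keeping snapshots pure
pixel data), and the synthetic palette is a monotone grayscale ramp — it
has exactly the two properties the codec relies on (distinct keys, dark-to-
bright ordering) without committing to any proprietary palette. A
scrambled-palette mode exercises the lookup's independence from key order.
Temperatures outside the common range (possible when clamping is enabled
for sensor spikes, or for scene extremes never imaged during the flight)
clamp to the range ends with a reported count.

# Geotagging camera events

The onboard logger writes, per snapshot: serial, frame min/max
temperature, and the NMEA GGA sentence polled at trigger time. The PPK
track (`.pos`, 5 Hz, quality flags Q1 = fix, Q2 = float, Q5 = single) is on
GPS time while NMEA time is UTC; the two scales are reconciled by an
explicit leap-second offset (default 18 s, the GPST–UTC offset since 2017).
Events are joined to the *nearest* track point — a pick, not an
interpolation — with ties resolved to the earlier point and a 0.2 s default
tolerance (one track interval); with a 5 Hz track this bounds the time
mismatch by 0.1 s and the position mismatch by the flight speed times
0.1 s. Quality flags convert to the fixed accuracies 0.5 / 2 / 10 m
expected by mosaicking software.

GCP distances use the haversine formula on a sphere of radius 6 378 137 m
(the `geosphere` default, sub-millimetre-equivalent at field scales), with
a full-geodesic option. Error summaries are restricted to held-out GCPs —
markers excluded from mosaicking — since only those estimate accuracy
without circularity; which GCPs are held out is caller-specified. The
thermal-to-RGB alignment is an ordinary least-squares 2-D affine transform
on tie points, reported with its residual RMS.

# Surface parameters

The visible-band indices are
$$\mathrm{VI} = \frac{G-R}{G+R}, \qquad
  \mathrm{VARI} = \frac{G-R}{G+R-B},$$
computed on channels normalized to $[0,1]$; being ratios they are invariant
to uniform illumination scaling. LAI comes from an OLS regression of
ceptometer LAI on whichever index attains the higher $R^2$ (ties go to
VARI, for determinism), applied per pixel and floored at zero. Green
classification thresholds VARI at 0.05 by default (an automatic Otsu
split is available); cover fractions are the mean of the binary mask's
sub-pixels per thermal-grid cell. Site modes encode the standing
assumptions: grassland has total cover ($f_c \equiv 1$, the fraction is
$f_g$); cropland vegetation is all green ($f_g \equiv 1$, the fraction is
$f_c$). Index values at point locations are sampled as a 5×5-pixel window
mean.

# The two-source energy balance (TSEB-PT)

Per pixel, with micromet state (air temperature $T_a$, wind $u$, pressure
$P$, vapor pressure $e_a$, solar radiation $S{\downarrow}$) and surface
inputs ($T_{rad}$, LAI, $f_c$, $f_g$):

1. **Radiation.** $R_n = (1-\alpha)S{\downarrow} +
   \varepsilon\,(L{\downarrow} - \sigma T_{rad}^4)$ with clear-sky
   $L{\downarrow}$ from the Brutsaert emissivity
   $1.24\,(e_a/T_{aK})^{1/7}$ (a measured value can be supplied instead)
   and surface emissivity composited from canopy (0.98) and soil (0.95)
   by cover. Beer-law extinction splits it:
   $R_{n,s} = R_n e^{-\kappa_s \mathrm{LAI}}$, $R_{n,c} = R_n - R_{n,s}$.
2. **Priestley–Taylor canopy initialization.**
   $LE_c = \alpha_{PT} f_g \frac{\Delta}{\Delta+\gamma} R_{n,c}$, so the
   canopy sensible-heat target is $H_c = R_{n,c}(1 - \alpha_{PT} f_g
   \Delta/(\Delta+\gamma))$.
3. **Temperature decomposition.** The nadir vegetation view fraction is
   $f_\theta = f_c\,(1 - e^{-0.5\,\mathrm{LAI}/f_c})$ (capped at 0.95 so
   the soil temperature stays identifiable), and
   $T_{rad}^4 = f_\theta T_c^4 + (1-f_\theta) T_s^4$.
4. **Series resistance network.** Air at the measurement height connects
   to an in-canopy air node through the aerodynamic resistance $R_a$
   (log profile with Businger–Dyer stability corrections), the canopy
   through the leaf boundary-layer resistance $R_x = C'/\mathrm{LAI}\,
   \sqrt{s/u_d}$, and the soil through $R_s = 1/(a' + b' u_s)$, with the
   within-canopy wind profile attenuated exponentially (Goudriaan form).
   The canopy temperature is found by a scalar root solve of
   $\rho c_p (T_c - T_{ac})/R_x = H_c$ subject to the decomposition; the
   in-canopy air temperature $T_{ac}$ is the resistance-weighted mean of
   the three nodes.
5. **Soil residual and drying.** $G = c_g R_{n,s}$ and
   $LE_s = R_{n,s} - G - H_s$. A negative $LE_s$ (condensation on drying
   soil) triggers stepwise reduction of $\alpha_{PT}$ by 0.1; at
   $\alpha_{PT} = 0$ the soil evaporation is zeroed and $H_s$ becomes the
   residual.
6. **Stability iteration.** The Obukhov length
   $L = -\rho c_p u_*^3 T_{aK} / (k g H)$ is iterated by damped successive
   substitution on $1/L$ (damping 0.5, relative tolerance $10^{-3}$,
   at most 100 iterations); near-zero $H$ maps to neutral. Non-convergence
   is flagged per pixel, with fluxes from the last iterate.

By construction the outputs satisfy $R_n = H + LE + G$ to machine
precision on every pixel — latent heat is a residual, exactly as in the
measured-flux closure below.

## Parameter defaults

| parameter | default | unit | role |
|---|---|---|---|
| `alpha_pt` | 1.26 | – | Priestley–Taylor coefficient (equilibrium-evaporation multiplier) |
| `kappa_s` | 0.45 | – | net-radiation extinction through the canopy |
| `c_g` | 0.35 | – | ground heat flux as fraction of soil net radiation |
| `emis_c`, `emis_s` | 0.98, 0.95 | – | canopy / soil emissivity |
| `albedo` | 0.23 | – | shortwave surface albedo |
| `z0m_ratio`, `d_ratio` | 0.125, 0.65 | – | roughness length and displacement as fractions of canopy height |
| `kB_inv` | 2 | – | $\ln(z_{0m}/z_{0h})$, excess resistance for heat |
| `leaf_size` | 0.1 | m | characteristic leaf dimension in $R_x$ |
| `c_prime` | 90 | s$^{1/2}$ m$^{-1}$ | boundary-layer resistance coefficient |
| `rss_a`, `rss_b` | 0.004, 0.012 | m s$^{-1}$, – | soil-surface resistance coefficients |
| `f_theta_max` | 0.95 | – | cap on the vegetation view fraction |
| `l_tolerance`, `max_iterations` | 1e-3, 100 | – | stability-iteration controls |

These are the classical defaults of the Priestley–Taylor two-source family;
the resistance formulations and $G$ parameterization differ across
published variants of the model, so every constant is exposed in
`tseb_parameters()` and in the key = value run-configuration file. Wind is
floored at 0.1 m/s and the momentum/heat log terms at 0.1 to keep the
network non-singular; temperatures are degrees Celsius at every interface
and Kelvin inside radiative terms.

# Validation against eddy covariance

EC towers systematically under-close the energy balance. Since the model
assigns the residual to latent heat by definition, the measured fluxes are
closed the same way, $LE_{closed} = R_n - G - H$, before comparison — a
deliberately asymmetric-but-consistent convention. The footprint is a 10 m
diameter disk centred at the footprint peak; the wind direction follows the
meteorological convention (direction the wind comes *from*, clockwise from
north) and the peak lies upwind of the tower along that bearing. A pixel
belongs to the disk if its centre does — unbiased at 8 cm against a 10 m
disk. The half-hour record whose averaging interval contains the flight
midpoint is used. Reported statistics: RMSE, its decomposition
RMSE² = bias² + RMSD², the OLS fit of modelled on measured, and Pearson's
r with a two-sided p value. Degenerate inputs (zero variance) flag the
correlation as undefined instead of erroring.

# What the synthetic scenes emulate — and what they do not

`scene_spec()` builds smooth random fields (blurred white noise, pure
functions of the seed) for LAI, cover and soil warming over a default
60 × 60 m scene; `forward_fluxes()` prescribes the soil temperature excess,
solves the same energy-balance equations *forward* (closed-form linear
canopy-temperature solve at fixed resistances, iterated with radiation and
stability to a fixed point, in a code path separate from the inverse
solver) and synthesizes the radiometric temperature those components
imply. `simulate_flight()` then images that field along a serpentine path
with the 1.9 s trigger cadence and a 5 Hz track, writing the exact file
formats the parsers read. Default micromet (25 °C, 2.5 m/s, 1010 hPa,
15 hPa vapor pressure, 800 W/m² solar, 0.3 m canopy) represents a clear
mid-season midday flight.

Passing tests on these scenes demonstrate that the codec is exact to
quantization, the geotagging is exact to the nearest-point pick, and the
solver inverts its own physics consistently. They do **not** demonstrate
that the physics matches real canopies: no sensor noise beyond optional
additive Gaussian terms, no emissivity or atmospheric correction error, no
mosaicking artefacts beyond palette clamping of never-imaged extremes, no
footprint-model error (the disk is a stated simplification), and LAI/cover
fields that are smoother than real vegetation. Field validation of this
model family typically lands at RMSE of tens of W/m² against EC towers;
nothing in the synthetic suite should be read as contradicting that.

# Numerical choices and degenerate inputs

* Quantization rounds half away from zero; level indices are 0-based with
  divisor $N-1 = 238$, endpoints mapping exactly to the range ends.
* The canopy-temperature root solve brackets $T_c$ between
  $\min(T_a, T_{rad}) - 60$ K and the decomposition limit
  $(T_{rad}^4/f_\theta)^{1/4}$; if no sign change exists (extreme states),
  the admissible endpoint closer to balance is taken and the residual flows
  into the soil component, preserving closure.
* Bare pixels (LAI or $f_c \le 10^{-6}$) bypass the canopy: $T_s = T_{rad}$
  and the network collapses to $R_a + R_s$ in series. This is also the
  configuration in which the zero-gradient limit ($T_{rad} = T_a \Rightarrow
  H = 0$) is exact; with vegetation the Priestley–Taylor initialization
  intentionally moves heat between components, so the strict limit is
  asserted on the bare configuration.
* Matching ties (event exactly between two track points) go to the earlier
  point; event-log lines that fail parsing or the NMEA checksum are
  collected in a rejects report, never silently dropped.
* Problem sizes in the tests and acceptance script — 16–64 px scene edges,
  100 random frames, 10⁵ color pairs, 25 noise replicates — were chosen as
  the smallest sizes at which each property is sharply testable (e.g., the
  64×64 scene exercises the full spread of the smooth fields; the 8 cm
  footprint grid makes the 2 % disk-area bound meaningful).

# Known limitations

* Single nadir view; no dual-angle or time-differencing variants, no
  clumped row-crop geometry, no aerodynamic-temperature calibration.
* Clear-sky longwave unless a measured value is supplied.
* Only residual-to-LE closure of the measured balance; Bowen-ratio and
  H-side variants are recognized names that refuse with "not implemented".
* The raster layer is deliberately minimal (axis-aligned, square pixels,
  single CRS label); reprojection and irregular grids are out of scope.
* Real Optris palettes must be supplied as a colorbar strip; none ship
  with the package.
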