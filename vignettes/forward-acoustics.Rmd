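---
title: "Forward modeling of sound-scattering-layer spectra: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forward modeling of sound-scattering-layer spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sslspectra)
```

This vignette is the package's account of the science it implements: the
scattering models and their assumptions, the parameters that matter, what
the synthetic-data generator does and does not emulate, and the numerical
and design choices made where the problem left them open. Everything
quantitative stated here is computed by the test suite or by
`scripts/acceptance.R`; nothing is quoted from elsewhere.

## The forward problem

Broadband echosounders measure, per echo-integration cell, a volume
backscattering spectrum $S_v(f)$ (dB re 1 m$^{-1}$). The forward approach
predicts that spectrum from a biological sample: every taxon $j$ is assigned
a physics-based target-strength model $TS_i(f)$ per length class $i$, and
the sampled densities $D_i$ (ind m$^{-3}$) aggregate in natural (linear)
scale,

$$S_{vj}(f) = 10\log_{10}\sum_i 10^{(TS_i(f) + 10\log_{10} D_i)/10},
\qquad
S_v^{pred}(f) = 10\log_{10}\sum_j 10^{S_{vj}(f)/10}.$$

Both identities are exact algebra and are tested to $10^{-9}$ dB, together
with their consequences (associativity of splitting/merging length classes,
a +10 dB shift under a tenfold density increase, attribution fractions
summing to one).

The comparison side extracts, along a net track, the per-frequency median
of the cells located below the top of the net (two cells by default, the
standard compromise between net-mouth coverage and depth uncertainty), with
25/75 % quantile bands.

## Scattering models

### Fluid-like organisms (DWBA)

Euphausiids, decapod shrimps, copepods and swimbladderless fish scatter
weakly: their tissue differs from seawater by a density contrast $g$ and a
sound-speed contrast $h$ within a few percent of unity. For such bodies the
distorted-wave Born approximation reduces to a line integral along the body
axis with circular cross sections $a(s)$:

$$f_{bs} = \frac{k_1}{4}\left(\gamma_\kappa - \gamma_\rho\right)
\int a(s)\,\frac{J_1\!\left(2 k_2 a(s)\cos\beta\right)}{\cos\beta}\,
e^{2i\mathbf{k}_2\cdot\mathbf{r}(s)}\,ds,
\qquad \sigma_{bs} = |f_{bs}|^2,$$

with $\gamma_\kappa = (1-gh^2)/(gh^2)$, $\gamma_\rho = (g-1)/g$ and interior
wavenumber $k_2 = k_1/h$. Two shapes are provided: a prolate spheroid
(copepods) and a uniformly bent, tapered cylinder (shrimp-like bodies),
with radius of curvature $3L$ and taper order 10 — the conventional values
in the DWBA literature, both configurable. The orientation angle $\beta$ is
the tilt of the body axis from broadside incidence; the cross section is
averaged in *linear* scale over a normal orientation distribution
$N(\bar\theta, s_\theta)$, because the average of intensities, not of dB
values, is what an ensemble of animals returns.

Assumptions worth keeping in mind: single scattering only (the Born
approximation is first order), homogeneous tissue, and no shadowing. At
zero contrast ($g = h = 1$) the model returns the zero-backscatter sentinel
(`-Inf` dB, exactly 0 in linear scale) rather than failing.

### Elastic-shell organisms

Thecosome pteropods carry a hard aragonite shell and scatter far more
strongly than fluid-like organisms of the same size in the geometric
regime. They are modeled with a single-parameter high-pass dense-fluid
sphere,

$$\sigma_{bs} = \frac{R^2}{4}\,a^2\,\frac{(ka)^4}{1+(ka)^4},$$

which rises as $(ka)^4$ (Rayleigh), saturates at the geometric limit
$a^2R^2/4$, and is monotone in frequency. $R = 0.5$ is the empirically
derived reflection coefficient for pteropod shells; $a$ is the radius of a
disc with the organism's silhouette area. The model deliberately ignores
the shell's modal structure (opercular opening, thickness resonances): with
only $R$ constrained by data, a more elaborate model would be false
precision.

### Gas-bearing organisms

A millimetric gas inclusion — a physonect siphonophore's pneumatophore or a
larval fish's swimbladder — is a resonant monopole whose backscattering can
exceed that of everything else in a layer by orders of magnitude near its
resonance. The model treats the inclusion as a gas prolate spheroid with
semi-axes $b = L/2$ and $a = b/(L/2a)$ and evaluates

$$\sigma_{bs}(f) = \frac{a_{eq}^2}{\left(f_0^2/f^2 - 1\right)^2 + \delta^2},
\qquad a_{eq} = (a^2 b)^{1/3},$$

where the resonance $f_0$ is the Minnaert frequency of the equal-volume
sphere modified by three physical effects:

* **prolate shape**: the breathing-mode stiffness scales with the
  electrostatic capacitance of the shape (for a sphere, its radius) — an
  elongation at fixed volume raises $f_0$ slightly;
* **surface tension** $\tau$: an effective tissue-interface stiffening
  $2\tau(3\gamma-1)/a_{eq}$ added to the gas stiffness $3\gamma P$ — for
  sub-millimeter inclusions with the tissue-scale values used here this
  shifts $f_0$ by tens of percent;
* **gas thermal behaviour**: the polytropic exponent is the complex
  $\Gamma(\omega)$ interpolating isothermal to adiabatic; its imaginary
  part supplies the thermal damping.

Total damping $\delta$ sums the thermal term, radiation damping $k a_{eq}$
and viscous damping $4\eta/(\rho\omega a_{eq}^2)$, so the cross section is
finite at exact resonance under any parameter setting. Ambient pressure
follows $P(z) = 101325\,(1 + z/10)$ Pa; the gas is air ($\gamma = 1.4$,
ideal-gas density at ambient pressure, 283 K). These medium conventions are
package defaults (seawater $c = 1500$ m s$^{-1}$, $\rho = 1026$ kg
m$^{-3}$), all overridable in the configuration, since hydrographic
profiles vary by survey.

The model is a Rayleigh-regime approximation, reliable for $kb < 0.1$
(with $a<b$ this is the binding constraint). Frequencies beyond that bound
are still computed — full-band predictions need them — but flagged in the
spectrum's validity mask, and the high-frequency tail (a plateau at the
geometric value $a_{eq}^2$) should be read as an extrapolation. The
sphere-limit equivalence test ($L/2a = 1$ against an independently coded
damped-bubble oracle, within 0.2 dB across 18–420 kHz) pins the
implementation; the prolate correction is a $\le$ few-percent frequency
shift at the aspect ratios involved, so transcription ambiguities in the
shape correction cannot hide behind it.

With the package defaults, the two siphonophore populations used throughout
the examples resonate at 30 kHz (1.23 mm pneumatophore at 83 m) and 104 kHz
(0.27 mm at 17 m); `scripts/acceptance.R` recomputes both.

### Morphometric conventions

Fish swimbladders are measured directly when the species is transparent
(species-specific $L/2a$ in the configuration: 1.63, 2.75, and 1.5 for
other fish). Otherwise the body is a prolate spheroid with minor axis $L/6$
and the swimbladder takes 2.5 % of the body volume at $L/2a = 1.5$.
Silhouette areas from imagery map to model radii as: rectangle of equal
area for the cylinder ($a = A/2L$), ellipse for the spheroid
($a = 2A/\pi L$), disc for the shell ($a = \sqrt{A/\pi}$). A silhouette
implying $a > L/2$ is flagged with a warning but still returned: the data,
not the code, should decide what to do with a deformed specimen.

Swimbladderless fish default to the fluid-like model; a configuration
switch (`fish_no_swimbladder_as_gas`) re-runs them as gas-bearing without
code changes, because the swimbladder development stage of some juveniles
is genuinely uncertain and the two assumptions differ by tens of dB at low
frequency.

## Uncertainty propagation

Scattering parameters taken from the literature (contrasts, aspect ratios,
damping constants, the reflection coefficient) carry uncertainty that the
forward prediction must expose. Each parameter gets a normal or lognormal
prior; a Latin hypercube design (`lhs_sample`, seeded and logged) draws
$n = 1000$ parameter sets per length class so that every probability
stratum of every prior is hit exactly once; the model is evaluated at each
draw, and the 5/50/95 % quantiles of the simulated *linear* cross sections
form the predictive envelope, converted to dB afterwards. Quantiles are
taken in the linear domain so that envelope components still aggregate like
Eq. (1); lengths are treated as measured, never sampled; and the
orientation distribution of fluid-like organisms is part of the model
itself, so it is excluded from the sampled parameters.

Two reporting conventions are fixed deliberately: the 5/95 % normal deviate
is the constant 1.645 (so printed intervals match tabulated
median/CI values), and tabulated roundings use round-half-up. Envelopes can
be computed per length class or after community aggregation; the package
exposes the per-class form and labels outputs accordingly, since the two
do not commute through the quantile.

## Echogram segmentation

Cell spectra are standardized before clustering (Eq. 3/4 form): each cell's
$S_v(f)$ minus the dB value of the mean of its per-transducer linear band
means. This removes overall intensity — standardized spectra are invariant
to uniform dB offsets, a tested property — and leaves shape, which is what
distinguishes scatterer communities. The feature space keeps the unmasked
band frequencies, excludes the 240–260 kHz interval and the 280–420 kHz
band (limited range), and by default includes the narrowband 18/38 kHz
points (a flag drops them, for users who consider CW and FM calibrations
incommensurable).

Segmentation is Gaussian-mixture EM with diagonal covariance, initialized
deterministically from $k$ equal horizontal depth bands (the working
hypothesis is vertical stratification; the first M-step recovers exactly
the band means). Diagonal covariance is forced by dimensionality: at 2 kHz
resolution a cell spectrum has ~150 usable bins, comparable to the number
of cells, and a full covariance would be singular. Convergence is a
relative log-likelihood tolerance of $10^{-6}$ with at most 500 iterations;
a degenerate (emptied) cluster is re-seeded once from the cells farthest
from their centers, with a message. Cluster median spectra and their
25/75 % bands are computed from the *raw* spectra — standardization exists
only to define the feature space — and the suite asserts this by
reconstructing the medians independently.

### Choosing the number of clusters

The number of clusters is chosen to maximize the diversity of spectral
shapes while minimizing $k$. The implementation makes that operational:
among candidate $k$, accept the largest whose fitted cluster mean spectra
are all pairwise distinct — differing somewhere by more than twice the
pooled within-cluster standard deviation — and fall back to the smallest
candidate when none qualifies (a homogeneous grid). BIC is computed and
reported in the selection trace but is *not* the criterion: standardization
divides each cell by its own noisy band mean, which for peaked spectra is
dominated by the single-bin CW bands and injects a common-mode factor of
order 1 dB across all feature dimensions. A diagonal Gaussian cannot
represent such a factor, so EM gains thousands of log-likelihood units by
splitting a genuine layer along it, and no $\log n$ penalty catches up at
realistic cell counts (an entropy-penalized criterion fares no better: in
150 dimensions even spurious splits are crisp). The shape-diversity rule is
immune to this failure because the spurious sub-clusters differ by well
under the cell noise — on the synthetic fixtures, true layers separate by
~30 dB against spurious splits of ~3.5 dB at a threshold of ~4 dB.

## The synthetic-data generator

Real surveys of this kind leave no deposited raw data, so the generator
stands in for them with known ground truth. It emulates: vertically
stratified, horizontally homogeneous layers on a regular echo-integration
grid (1.5 m × ping blocks); per-layer communities drawn as truncated-normal
lengths around preset means with exact density bookkeeping (preset tables
ship the surface and deep communities used in the examples, including the
weak scatterers that are carried but excluded from prediction); noiseless
layer spectra computed by the package's own forward model at the layer
depth midpoint; and additive, independent normal noise in the dB domain,
default SD 2 dB, chosen so synthetic cell-quantile bands resemble measured
ones — a fixture choice, not a calibrated noise model.

It does *not* emulate: horizontal patchiness or gradients within a layer,
correlated (frequency-coherent) noise, ping-to-ping motion, beam geometry,
attenuation, or catchability bias between the community and the echogram.
Consequently, passing closed-loop tests demonstrates that the pipeline is
self-consistent — segmentation recovers constructed layers (ARI ≥ 0.9 at
2 dB noise and ≥ 6 dB spectral separation), track extraction recovers
forward spectra within the noise standard error, and discrepancies vanish
as noise goes to zero — not that any particular field survey satisfies the
generator's assumptions.

## Numerical choices

* Orientation averaging: 61-node Gauss–Legendre rule over mean ± 3 SD with
  normal-density weights, in linear scale; a zero SD collapses to the
  single-angle evaluation (tested).
* DWBA axis integral: Gauss–Legendre with a node count scaled to the
  maximum phase excursion $k_2 L$ (33–129 nodes), verified against an
  independently coded adaptive quadrature to 0.1 dB on parameter sets
  spanning both shapes and the full band.
* End-on incidence: the $J_1(x)/x \to 1/2$ limit replaces the removable
  singularity when $|\cos\beta| < 10^{-8}$.
* Zero backscatter is the explicit sentinel `-Inf` dB; conversions map it
  to an exact linear 0, so aggregation, standardization (which passes
  sentinel spectra through) and file round trips treat it as "nothing
  there" without NaN arithmetic.
* Resonance location: grid argmax over unmasked frequencies, ties broken
  toward the lowest frequency.
* Grid CSV I/O prints 17 significant digits so float64 spectra round-trip
  bit-identically, mask included.
* Problem sizes used by the suite: communities of 50–60 records per taxon,
  echograms of 24 ping blocks × 8–24 depth bins on the ~160-frequency band
  grid, envelopes at $n = 1000$ for the closed-form models; these sizes
  make every stochastic check stable under its fixed seed while keeping a
  full run under a minute.

## Known limitations

* The gas-bearing tail beyond $kb = 0.1$ is an extrapolation (flagged, not
  hidden); a gaseous-cylinder model would be the next step when gas
  scatterers dominate the whole band.
* The elastic-shell model cannot produce the interference structure real
  pteropod ensembles may show at high $ka$.
* Densities carry no catchability or avoidance correction; the forward
  prediction inherits every bias of the nets, and the uncertainty analysis
  deliberately excludes sampling error (it propagates model-parameter
  priors only).
* Swimbladder morphometry for damaged specimens rests on a fixed
  volume-fraction rule; species for which that fraction is wrong will be
  off by a constant factor in $f_0$ of roughly its cube root.
* The EM feature space treats frequency bins as independent; spectrally
  smooth deviations (like the standardization common mode) are outside the
  model family, which is exactly why `select_k` does not trust likelihood
  criteria alone.
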