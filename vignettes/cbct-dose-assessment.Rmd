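---
title: "Dual-method dose assessment for dental cone-beam CT"
author: "cbctdose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-method dose assessment for dental cone-beam CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbctdose)
```

# The problem

Dental cone-beam CT (CBCT) units differ widely in geometry and technique
factors, and so do the patient doses they deliver. Two routes are in use
for estimating the ICRP 103 effective dose of a given machine and
examination mode:

1. a **measurement arm**: optically stimulated luminescence dosimeters
   (OSLDs) placed at anatomical sites of a head-and-neck phantom, read out
   after exposure and aggregated into organ equivalent doses; and
2. a **simulation arm**: Monte Carlo photon transport of the rotating cone
   beam around a computational phantom, normalized by the measured
   dose-area product (DAP) of the exposure.

`cbctdose` implements both arms over a shared tissue registry and a
comparison stage that reports the symmetric percent difference of the two
effective doses per mode,

$$d(a, b) = 100\,\frac{|a - b|}{(a + b)/2},$$

which lies in $[0, 200)$, is symmetric, and is invariant under a common
rescaling of both doses. Agreement between a dosimetric and a computed
effective dose is conventionally called *good* when the difference stays
below about 25%.

# The tissue registry and the effective dose

Only head-and-neck tissues are in the exposed region; out-of-field
ICRP 103 tissues (lung, stomach, colon, breast, gonads, bladder, liver)
are treated as zero-dose and omitted. The weights represented in the
bundled registry — bone marrow 0.12, thyroid 0.04, esophagus 0.04,
skin 0.01, bone surface 0.01, salivary glands 0.01, brain 0.01, and the
remainder set 0.12 — sum to 0.36; the missing 0.64 belongs to tissues
whose dose is taken as zero. The effective dose is

$$E = \sum_T W_T H_T,$$

with the equivalent dose $H_T$ numerically equal to the absorbed dose
(photon radiation weighting factor 1). Internally everything is carried
as unrounded doubles in mGy $\equiv$ mSv; results are reported in µSv and
rounded to one decimal only at presentation.

Aggregation rules per tissue:

* **Multi-dosimeter organs** (brain over six sites, thyroid, eyes, the
  salivary subsites) use the arithmetic mean of their sites.
* **Distributed skeletal tissues** use fraction-weighted sums over
  subsites: bone marrow over mandible (0.8%), calvaria (7.7%) and
  cervical spine (3.8%); bone surface over 1.3%, 11.8% and 3.4%. The
  marrow subsites sum to 12.3%; a printed total of 12.2% circulates, and
  the registry derives the total from the subsites rather than enforcing
  the rounded figure.
* The **bone surface** additionally carries the bone-to-muscle mass
  energy absorption coefficient ratio
  $\mathrm{MEACR}(kVp) = -0.0618\cdot\tfrac{2}{3}\,kVp + 6.9406$
  (3.2326 at 90 kVp, 3.6446 at 80 kVp). Two printed forms of this formula
  circulate, with and without the leading minus; the negative-slope form
  is used here because the positive one yields ratios above 10 at
  diagnostic potentials, far outside the physical range of a
  bone-to-muscle absorption ratio, and because the ratio must decrease
  with increasing effective energy.
* **Partial-body tissues** scale the site mean by the fraction of the
  tissue inside the field: skin, lymph nodes and muscle 5%, esophagus
  10%. The fraction is applied to the repeat-averaged mean (the two
  operations commute; the order is fixed for clarity).
* The **remainder** contributes the arithmetic mean of its five
  components (lymph nodes, muscle, extrathoracic airways, oral mucosa,
  eyes) under the single shared weight 0.12.

One site-map ambiguity is worth flagging: the bone-surface cervical-spine
row is mapped to dosimeter site 19 (the cervical-spine slot, as for bone
marrow) by default. Some tabulations print site 21, which is a thyroid
slot and almost certainly a typographical slip;
`loadTissueRegistry(boneSurfaceCspineSite = 21)` selects that mapping for
anyone wanting to reproduce it.

# The measurement arm

Readings arrive as photon counts or directly in mGy. Counts are converted
through a linear calibration; the vendor quality-control calibration
coefficients are not public, so the bundled default (slope $10^{-3}$
mGy/count, intercept 0) is an explicit synthetic stand-in — supplying
doses in mGy bypasses it. Conversions outside the calibrated range
(0–30 mGy by default) are flagged, not rejected. Each site's repeats
(two, in the emulated campaign) are averaged; sites with a single repeat
or no reading are flagged or (optionally) fatal. Whether organ doses
should be rounded before the effective-dose sum is unspecified in common
practice; this package never rounds internally.

The full arm is linear in the readings, monotone in every site dose, and
its per-tissue breakdown sums exactly to $E$ — these are tested
properties, with the weighted sum independently recomputed by brute-force
accumulation on randomized registries.

# The simulation arm

The Monte Carlo arm is a deliberately compact, fully documented transport
kernel — not a reimplementation of any commercial package and not
intended to reproduce one.

**Phantom.** A bespoke stylized head-and-neck geometry of 22 primitives
(spheres, cylinders, ellipsoids, boxes) in three materials (soft tissue
1.06 g/cm³, bone 1.40 g/cm³, air), defined in
`inst/extdata/phantom_head_neck.yaml`. Earlier entries shadow later ones,
which expresses shells (brain inside calvaria) and embedded viscera.
Organ masses are derived at load time by midpoint-grid integration of the
shadowed geometry at 0.25 cm resolution, so a carved organ's mass matches
the volume the transport kernel actually assigns to it. The reference
point (rotation center) defaults to the jaw centroid at the coordinate
origin; published campaigns determine it from prior literature without
printing coordinates, so it is configurable.

**Spectrum.** A Kramers-form bremsstrahlung fluence $(kVp - E)/E$ on a
1 keV grid from 5 keV to the endpoint, attenuated by the protocol's
aluminium filtration and renormalized. Beam hardening behaves correctly
by construction: the mean energy rises monotonically with filtration and
approaches the endpoint in the heavy-filtration limit.

**Cross sections.** Two channels: Compton scattering with the exact
closed-form Klein–Nishina total cross section (times electrons per gram,
$N_A Z/A$) and Klein–Nishina angle sampling by rejection; photoelectric
absorption as a per-material power law $\mu_{PE}/\rho \propto E^{-3.1}$
anchored at 10 keV to standard attenuation compilations (soft tissue
4.70, cortical-bone-like 27.5, air 4.54, aluminium 25.4 cm²/g). Rayleigh
scattering and characteristic X-rays are omitted; photoelectric plus
incoherent scattering dominate transport in tissue at 40–90 kVp, and the
omission keeps sampled physics and tabulated attenuation exactly
self-consistent (the closed-form slab-attenuation check uses the same
$\mu$ the kernel samples from).

**Transport.** Event-based vectorized Woodcock (delta) tracking with the
bone linear attenuation as majorant; collisions resolve the local
material by point lookup. Photons below 5 keV deposit locally (no
electron transport; charged-particle equilibrium assumed). The region
outside the phantom's bounding sphere is treated as vacuum — over the
~50 cm source-to-phantom air path the attenuation is below $10^{-2}$% and
ignoring it avoids pointless delta steps.

**Source and scoring.** Source positions are sampled uniformly over the
protocol's orbit (360° for the bundled modes) at the source-to-reference
distance; directions target a uniform point of the beam rectangle
(width × height at the rotation center). The dose-area product is scored
analytically in the entrance plane as the air collision kerma–area
product of the sampled photons, $\sum_i E_i (\mu_{tr}/\rho)_{air}(E_i)$
— every source photon crosses the reference plane inside the beam area by
construction, so no area term survives. Organ doses are energy deposited
over derived mass, divided by the simulated DAP; scaling by a measured
DAP (mean of the two meter readings per mode) gives absolute organ doses,
which then run through the same registry aggregation as the measurement
arm. Standard errors come from batch statistics (10 batches by default);
energy balance (deposited + escaped = emitted) closes to better than
$10^{-9}$ per batch and is asserted at $10^{-6}$.

**What this arm can and cannot say.** Per-DAP organ doses are invariant
to photon count within statistics, errors shrink as $1/\sqrt{n}$, results
are bit-for-bit reproducible per seed, bilateral organs agree under a
full orbit, and a collimated beam deposits nothing in excluded organs
without scatter. Absolute published effective doses of a real campaign
are *not* reproducible here: they depend on the physical phantom, the
dosimeter placement, and the commercial simulation's proprietary
anthropomorphic phantom. The package therefore validates structure and
statistics, not those absolute numbers, and the comparison stage
reproduces the published percent-difference column from the published
effective-dose pairs taken as inputs.

# The synthetic-data generator

The generator emulates the structure of the measurement campaign: 22
sites, two repeats per exposure, and reader noise of ±2% interpreted as a
1σ relative coefficient of variation, drawn from a normal law truncated
at zero (at 2% the truncation is negligible). `profileFromMc()` closes
the loop between the arms: it evaluates simulated organ doses at each
dosimeter's host organ, producing the site truth an idealized campaign
would read. With zero noise the measurement arm then reproduces the
simulation arm exactly for every tissue whose dosimeters sit in the organ
itself (thyroid, brain, eyes, esophagus, skin, salivary glands); tissues
whose dosimeters proxy a different structure (marrow read at soft-tissue
sites near the mandible, the remainder's surface tissues) differ by that
sampling structure — the same "sampling error" that makes physical
campaigns with different dosimeter layouts disagree. What the generator
does **not** emulate: OSLD fading, re-read depletion, energy- and
angle-dependent dosimeter response, or phantom positioning error; closed
tests therefore validate the aggregation chain, not those physical
effects.

The closed-loop acceptance check runs 200 generator seeds and requires
the noise-propagated 3σ interval around the recovered effective dose to
cover the profile-implied truth in at least 95% of runs; the propagation
uses the pipeline's exact linearity (unit-impulse site coefficients).

# Numerical and design choices

* Exposure-time and beam-height values that are merged across modes in
  the manufacturers' tables are assigned by FOV alignment: 20/12/14/14 s
  and 13.5/10/10/10 cm across facial / dual jaw / large jaw / jaw.
* Tube current × time is carried for provenance but unused — DAP is the
  input dose quantity.
* Problem sizes: the default test suite runs simulations at
  $5\times10^3$–$1.6\times10^5$ photons and the acceptance script at
  $4\times10^4$ photons per mode with 10 batches; at these sizes
  per-organ standard errors are a few percent, which is what the 3σ
  assertions are calibrated against.
* Ties and degenerate inputs: zero readings give $E = 0$; a site with all
  contributing dosimeters missing is an error naming the tissue; a DAP of
  zero is rejected; percent difference is undefined (and raises) at
  $a + b = 0$.
* Stochastic entry points require an explicit seed; there is no silent
  default in the simulation arm, and generator profiles embed their seed.

# Known limitations

* The stylized phantom is not anthropometric; absolute organ doses carry
  its geometry, so only DAP-normalized structure and method comparison
  travel to other phantoms.
* Two-channel physics slightly overestimates penetration at the lowest
  energies where Rayleigh scattering is a few percent of the total.
* The calibration default is a stand-in; real campaigns must supply their
  reader's calibration.
* The measurement arm's organ sampling follows one specific 22-site
  layout; other layouts will show different sampling structure.
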