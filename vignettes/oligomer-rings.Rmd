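---
title: "Classifying membrane-protein ring oligomers from simulated AFM topographs and exciton-coupled CD"
author: "oligoscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying membrane-protein ring oligomers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligoscope)
```

## The problem

Microbial rhodopsins — seven-transmembrane photoreceptor proteins carrying a
retinal chromophore — assemble into ring-shaped oligomers in the membrane,
predominantly trimers or pentamers (occasionally hexamers). Which ring a
given protein forms is surprisingly hard to pin down: crystallography, gel
filtration and spectroscopy often disagree, because detergents, pH and
crystal packing can all remodel the assembly. Two measurements that probe
oligomers *in a lipid bilayer* are high-speed AFM topographs (which resolve
the ring directly, at roughly 2 nm lateral resolution) and visible
circular dichroism (whose bisignate "couplet" reports exciton coupling
between the retinals of neighboring protomers).

`oligoscope` implements the computational side of that joint argument:

1. **Topograph simulation** — given an atomic structure, predict the AFM
   image a hard tip would record from either membrane face, so real images
   can be compared against candidate oligomer models.
2. **Ring analysis** — from a height map (simulated or experimental-style),
   detect subunit peaks, estimate the rotational symmetry order, fit the
   ring diameter, and score the central protrusion/pore that distinguishes
   the two membrane faces.
3. **Exciton CD prediction** — from the retinal positions and orientations,
   compute the coupled-state rotational strengths and synthesize the CD
   band shape, classifying it as a normal couplet (trimer signature), an
   inverted couplet (pentamer signature) or a single shifted peak.
4. **Synthetic ground truth** — generate parametric ring oligomers and
   noisy height maps so every stage is testable end to end without any
   structure download.

## Hard-sphere tip model

The probe is a cone of half angle $\alpha$ ending in a spherical apex of
radius $R$ (defaults $\alpha = 5^\circ$, $R = 0.5$ nm — a sharp simulation
probe). Its surface height above the apex at lateral offset $x$ is

$$s(x) = \begin{cases}
R - \sqrt{R^2 - x^2} & x \le R\cos\alpha\\[2pt]
R(1-\sin\alpha) + (x - R\cos\alpha)\cot\alpha & x > R\cos\alpha ,
\end{cases}$$

continuous and once-differentiable at the blend point. Each atom is a hard
sphere (united-atom-like heavy-atom radii: C 0.17, N 0.155, O 0.152,
S 0.18, P 0.18 nm; hydrogens are omitted and absorbed into these radii).
The recorded height at a pixel is the lowest apex position at which the tip
touches any atom sphere — exactly the grayscale dilation of the
union-of-spheres top surface by the reflected tip. Both contact branches
are evaluated in closed form: apex-sphere contact at lateral distance
$d \le (R+r)\cos\alpha$ gives $h = z_a - R + \sqrt{(R+r)^2 - d^2}$, and the
cone flank gives $h = z_a + (R+r)/\sin\alpha - d\cot\alpha - R$, which join
continuously at the switch point. (A cone-flank formula without the
$R$-terms, sometimes seen as a shorthand, does not join the sphere branch
and is not a dilation; the tests pin the implementation to the dilation
contract with an independent support-function oracle.) Heights are clipped
at the support plane $z = 0$, which stands in for the membrane surface
since only the protein is simulated.

The finite instrument resolution is emulated by a Fourier low-pass filter
with a 2 nm cutoff wavelength. The kernel shape is not dictated by the
physics; the default is a Gaussian with attenuation 0.5 at the cutoff,
because an ideal (hard) kernel rings on the sharp edges of simulated maps.
Ideal and Butterworth kernels are selectable, and are used in the spectral
unit tests where exact passband/stopband identities are wanted. Mirror
padding by one cutoff wavelength suppresses wrap-around; `pad = "none"`
treats the map as periodic (used by those exactness tests). The DC
component is preserved exactly by every kernel.

## Ring measurement

Subunit peaks are local maxima with a **topographic prominence** above
`minProminence` (default 0.15 nm), computed by a union-find flood from the
top — each candidate's prominence is its height above the highest saddle
that connects it to higher ground. Peaks closer together than
`minSeparation` (default 1 nm) are merged, the higher one surviving; ties
break by scan order. Positions are refined to sub-pixel precision with a
separable quadratic fit on the 3×3 neighborhood, which matters because the
rings of interest (2.8–4.9 nm diameter) span few pixels.

Two diameter conventions are reported side by side, because usage in the
field varies and is rarely defined:

* **peak-circle diameter** — the diameter of the algebraic least-squares
  circle through the subunit peak maxima (used when comparing against
  pentamer "ring diameters");
* **outer diameter** — where the azimuthally averaged radial profile falls
  to half the ring-crest height above background, beyond the crest (used
  for trimer "outer diameters").

The **central feature** is the height at the ring center minus the mean
height on the peak circle: positive marks a protrusion (pooled C-terminal
His-tags at the pentamer center image as a central bump on the C-face),
negative a pore (the N-face of the same ring). The face call uses a
±0.2 nm threshold, about four times the synthetic noise floor. The
symmetry order is the $n \in \{2..8\}$ maximizing the rotational
autocorrelation $C(n) = \mathrm{cor}\,(h, \mathrm{rot}_{2\pi/n} h)$ on an
annulus around the ring crest; the winner's margin over the runner-up is
the classification confidence, and a rotationally uniform ring (all
$C(n)$ equal) is flagged low-confidence.

Maps that have not been resolution-limited yet are pre-smoothed with the
same 2 nm filter as the simulator, so simulated and experimental-style
maps are treated identically. Maps that are *already* at the 2 nm
resolution limit (e.g. a filtered simulation subsequently corrupted with
pixel noise) should not be smoothed at 2 nm again — double filtering
erases the hexamer subunit modulation, whose circumferential spacing is
only about 2.2 nm. For those maps the validation suite uses a lighter
1.2 nm noise-suppression smoothing, which leaves the ring geometry
unbiased (the noise-free bias of the recovered diameter is below 0.012 nm
across the diameter range).

When a tall central protrusion is present it is itself a local maximum and
the "higher ground" for every subunit peak, so the star-face subunits
carry little topographic prominence; `analyzeHeightMap()` recognizes a
peak at the ring center by its distance from the peak centroid and
excludes it from the circle fit, and such faces are best analyzed with a
finer `minProminence` (the pipeline exposes this per run).

## Exciton-coupled CD

Each retinal contributes one transition dipole: origin at the midpoint of
the polyene chain (mean of atoms C5–C15), direction the unit vector from
the Schiff-base end (C15, "tail") to the beta-ionone end (C5, "head").
Within an oligomer the site energies are taken equal (degenerate exciton
model, one $\lambda_{max}$ per protein) and the off-diagonal couplings use
the point-dipole interaction

$$V_{ij} = D\,\frac{\hat\mu_i\cdot\hat\mu_j -
3(\hat\mu_i\cdot\hat R_{ij})(\hat\mu_j\cdot\hat R_{ij})}{d_{ij}^3},$$

with $D$ the squared dipole strength in reduced units and $d_{ij}$ in nm;
pairs closer than 0.3 nm violate the point-dipole approximation and are
flagged. Diagonalizing the Hamiltonian (energies are reduced wavenumbers,
$1/\lambda$) gives states $k$ with rotational strengths

$$R_k = -\frac{\pi}{\bar\lambda}\sum_{i<j} c_{ik}c_{jk}\,
\mathbf R_{ij}\cdot(\boldsymbol\mu_i\times\boldsymbol\mu_j),$$

which sum to zero exactly (orthonormal eigenvectors), the degenerate
exciton sum rule. The spectrum is a sum of unit-area Gaussian bands (40 nm
full width by default — visible retinal bands are broad) at
$\lambda_k = 1/E_k$ scaled by $R_k$, plus an optional intrinsic
(monomer-like) band at $\lambda_{max}$. A **normal couplet** is positive
on the blue side of $\lambda_{max}$ and negative on the red side; the
**inverted couplet** is the reverse.

All amplitudes are reduced — no absolute CD magnitudes are contracted,
only signs, orderings and peak positions. Consequently the intrinsic band
amplitude must be chosen on the same scale as the rotational strengths
(which are of order $10^{-5}$ for the default dipole strength 0.02);
passing an amplitude comparable to $\max_k |R_k|$ reproduces the
characteristic single *redshifted* peak of a weak inverted couplet riding
on positive intrinsic CD: the apparent maximum sits to the red of
$\lambda_{max}$, the blue-side dip does not cross zero, and the shift
grows with couplet amplitude until the lobes separate. The default dipole
strength keeps the exciton splitting at a few nm to a few tens of nm,
the scale seen for retinal proteins.

## The synthetic generator and its conventions

`makeRingOligomer()` builds $n$ cylinder-like protomers (vertical stacks
of overlapping spheres, radius 1.1 nm, transmembrane height 4 nm) with
centers on a circle, already in the membrane frame and grounded at
$z = 0$. Options add a thin central sphere stack anchored to the top face
(a His-tag bundle mimic, so the opposite face keeps its pore) or keep the
center guaranteed empty. Residue numbers increase from the base to the top
of each protomer so face selection by terminus works, and each planted
chromophore is also written as a pseudo-retinal residue (atoms C5..C15
along the dipole axis) so the retinal-extraction path can be exercised on
synthetic structures. Exact ground truth (peak positions, diameter
$= 2\times$ ring radius, dipole vectors, class) is returned with every
artifact, so recovery tests never re-derive it from the fixture.

Two dipole azimuth modes encode the two retinal packings of interest:

* `head_to_tail` — tangential circulation (each head pointing at the next
  protomer's tail), clockwise when viewed from the scan side: the
  trimer-like arrangement;
* `tail_to_tail` — heads pointing outward, rotated 25° off pure radial:
  the pentamer-like arrangement.

The azimuthal offset is essential, not cosmetic: a perfectly radial fan is
achiral — every $R_k$ vanishes identically — so "radially outward" taken
literally would predict no pentamer couplet at all. Real near-radial
retinal fans keep a fixed azimuthal offset, and that offset supplies the
chirality. The circulation handedness and offset sign are the generator's
convention, fixed once so that the head-to-tail trimer fixture reproduces
the experimentally known normal couplet and the tail-to-tail pentamer
fixture the inverted one; the convention-free content — azimuth-mode
reversal flips the couplet class, mirror reflection negates every
$R_k$ — is what the property tests assert across a sweep of tilt angles.
The default dipole tilt is 20° from the membrane plane, a typical retinal
inclination.

`makePatchScene()` places rings with random centers and orientations in a
circular patch (a nanodisc-like confinement) by rejection sampling with a
bounded retry budget, one RNG stream per artifact derived from
`(seed, index)`. `corruptHeightMap()` adds seeded pixelwise Gaussian noise
and per-scanline offsets; noise may undercut the support plane.

What the generator does **not** emulate: real protein surface relief
(side-chain corrugation, inter-protomer grooves), lipid background
texture, tip contamination or feedback artifacts, and drift. Passing the
recovery tests therefore demonstrates that the measurement chain is
unbiased and noise-robust for idealized rings at realistic geometry and
noise levels — not that segmentation of crowded experimental movies is
solved.

## Validation conditions and problem sizes

The end-to-end recovery suite draws 100 rings with $n \in \{3,5,6\}$ and
per-class diameters matching the measured ranges for these proteins —
trimers 2.8–4.0 nm, pentamers 4.1–4.9 nm, hexamers 4.4–4.9 nm (a 2.8 nm
hexamer cannot physically hold six 1.1 nm protomers) — images them with
the 5°/0.5 nm tip at 0.1 nm pixels, filters at 2 nm, adds 0.05 nm pixel
noise, and requires the symmetry order in at least 95 cases and the
peak-circle diameter within 0.15 nm in at least 90. The dilation oracle is
checked per-pixel against an exhaustive contact scan on 50 random 32×32
scenes, and the closed-form sphere example (apex height $2r$, footprint
$2\sqrt{Rr}$) to $10^{-6}$ nm. The exciton sum rule is checked on 1000
random geometries. A synthetic pentamer stand-in at ring radius 2.15 nm
(peak-circle diameter 4.3 nm, the printed value for the sodium-pump
pentamer) serves as the worked example for the full chain; the real
crystal-structure path (`readStructure()` on a PDB/mmCIF file) is
exercised on synthetic PDB fixtures, since no structure download is
assumed.

## Numerical choices

* Coordinates are nm everywhere after parsing; the scan normal is $+z$.
* Default simulation pixel 0.1 nm; the analysis requires
  `minSeparation >=` pixel size and a filter cutoff above Nyquist
  ($2\times$ pixel).
* Circle fit: algebraic (Kåsa) least squares; collinear peaks raise a
  degenerate-fit error rather than returning an absurd circle.
* Symmetry annulus: 0.55–1.45 × the fitted peak-circle radius, polar
  sampling 720 angles × 16 radii, bilinear interpolation; the crest search
  ignores radii below 0.6 nm so a central protrusion is not mistaken for
  the ring.
* The eigenvector matrix from `eigen(symmetric = TRUE)` is orthonormal to
  machine precision, so the rotational-strength sum rule holds to
  ~$10^{-18}$ without enforcement; a residual above $10^{-9}$ aborts.
* All generator and noise randomness is seeded; identical specs give
  bit-identical artifacts, and pipeline reruns overwrite outputs
  bit-identically (no timestamps in data files).

## Limitations

* The tip is rigid and the sample undeformable: no tapping dynamics,
  elastic indentation or tip–sample forces.
* Only model 1 of a multi-model structure file is read, and the input must
  already contain the assembled oligomer (no symmetry-mate generation).
* The exciton treatment is point-dipole with equal site energies; no
  vibronic structure, no extended-dipole refinement, no absolute CD
  scale — couplet class, lobe signs and shift directions are the only
  contracted outputs.
* Trimer face assignment by height difference is not implemented: the
  evidence that the two height populations of packed trimers reflect a
  fixed face-dependent offset is not quantified enough to build a rule on.
* Movie-frame tracking, 2D-crystal lattice analysis and scan-line
  artifact correction for real instrument data are out of scope.
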