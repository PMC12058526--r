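---
title: "Relative-orientation landscapes from paired focused refinements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relative-orientation landscapes from paired focused refinements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rotascape)
```

## The model

A large two-body macromolecule — the motivating case is a homodimeric
megasynthase whose condensing and modifying wings rotate against each other
around a central pivot — cannot be refined to high resolution as a single
rigid object. The standard remedy is two *focused refinements* of the same
particle stack, one mask per body, which leaves every particle with two
Euler-angle triples `(rot, tilt, psi)`, one per body.

Each triple defines a rotation matrix under the z-y-z convention of the
refinement package,

$$R = R_z(\psi)\, R_y(\theta_{tilt})\, R_z(\phi_{rot}),$$

with right-handed, counter-clockwise-positive elementary rotations. The
relative orientation of the condensing body in the frame of the modifying
body is the product of the inverse (transpose) of one matrix with the other,

$$R_{rel} = R_{mod}^{\top} R_{cond},$$

which cancels the shared viewing direction: pre-multiplying both bodies by
any common rotation leaves $R_{rel}$ unchanged (this invariance is asserted
over random pre-rotations in the test suite). $R_{rel}$ is decomposed into
Tait-Bryan z-y-x angles,

$$R_{rel} = R_z(\alpha)\, R_y(\beta)\, R_x(\gamma),$$

with $\alpha, \gamma \in (-180°, 180°]$ and $\beta \in [-90°, 90°]$.
$\alpha$ is the swivel about the long (z) axis — the dominant motion for an
elongated dimer — and $\beta, \gamma$ are the two swing angles. Plotting
every particle at the point $(\alpha, \beta, \gamma)$ gives the
*conformational landscape*: local particle density is proportional to the
population of that relative orientation.

Which body supplies the inverse matrix is a pure convention; we fix the
modifying wing as the reference frame and expose `reference = "cond"` in
`compute_orientations()` to flip it (flipping transposes $R_{rel}$).

### Numerical conventions

* Angles are degrees end-to-end; radians exist only inside the
  trigonometric kernels.
* Orthonormality and duplicate-orientation collapse use a `1e-9` tolerance;
  double-precision products of 3×3 matrices are accurate to ~`1e-13`, so
  `1e-9` separates genuine violations from round-off with a wide margin.
* Gimbal lock ($|\beta| = 90°$, detected at `1e-7` degrees via
  $\cos\beta$) leaves only $\alpha \mp \gamma$ determined; we set
  $\gamma = 0$ and let $\alpha$ absorb the free degree of freedom, so the
  rebuilt matrix always reproduces the input.
* `wrap180()` maps angles to the half-open interval $(-180°, 180°]$;
  $-180°$ and $+180°$ are the same orientation and the closed end was
  chosen once so that binning is unambiguous.

## C2 symmetry and substates

For a homodimer refined with C2 symmetry, symmetry expansion duplicates
each particle so the two asymmetric units can be classified independently.
Composing the relative rotation with the internal C2 operator of either
body's reference map yields up to four equivalent orientations
$S_{mod}^{\top} R_{rel} S_{cond}$; `canonicalize_orientation()` picks the
representative minimising $(|\beta|, |\alpha|, |\gamma|)$
lexicographically (signed values break ties), a choice that is arbitrary
but deterministic and idempotent.

Focused classification of each expanded monomer yields one condensing-wing
label (five functional groups: ACP on the KS site, ACP on the MAT site,
ACP in transition, no ACP, dynamic MAT) and one modifying-wing label
(pseudo-domains resolved or not). Restoring intact dimers gives unordered
condensing pairs — $5 \cdot 6 / 2 = 15$ — crossed with *sided* modifying
combinations (both, either single side, neither: 4), i.e. 60 dimeric
substates. The asymmetry (unordered condensing pairs but sided modifying
combinations) follows the field's reporting convention; the
`collapse_sides` flag gives the fully unordered alternative (3 modifying
combinations). After sorting the condensing labels, "side A" is the copy
whose condensing label sorts first; when the condensing labels tie, the
copy with resolved pseudo-domains is side A. This makes substate ids
invariant to the order in which the two expanded copies arrive.

## Landscape construction and interrogation

`build_landscape()` bins orientations on a regular grid (default
`bin_width = 2°`, so the grid is 180 × 90 × 180) with periodic wrapping in
$\alpha$ and $\gamma$ and a clamped $\beta$ axis, then applies separable
Gaussian smoothing (default `smooth_sigma = 1` bin; circular convolution
on the periodic axes, zero padding on $\beta$) and normalises the density
to sum to 1 so landscapes with different particle counts are directly
comparable. The 2° bin was chosen so that the ~14° selection radii used
for subset reconstruction span at least seven bins; the one-bin smoothing
is the smallest width that suppresses single-particle shot noise without
displacing a 5°-wide mode.

`find_hotspots()` defines a hotspot as a strict local density maximum
(26-connected, with wrap) at or above a percentile of the nonzero-density
bins (default 97.5), greedily pruned to a minimum mutual separation
(default 10°) and ranked by density. This definition assumes the landscape
is densely sampled: with tens of thousands of particles concentrated in a
few modes the percentile threshold isolates the genuine peaks, whereas a
sparse landscape (a few thousand particles spread over a broad
background) leaves many isolated single-particle blobs that are formally
local maxima; for such data raise the percentile or the smoothing rather
than trusting the tail of the hotspot list. Uniform density has no strict
maxima and returns an empty list.

`select_within_radius()` selects particles with
$\sqrt{\Delta\alpha_w^2 + \Delta\beta^2 + \Delta\gamma_w^2} \le r$
(wrapped differences on the periodic axes, boundary inclusive). The
coordinate-space Euclidean reading of "radius" mirrors the landscape's own
axes; a geodesic SO(3) metric (rotation angle between the two relative
orientations) is available via `metric = "geodesic"` but is not the
default. Exports carry the condensing-body angles plus all pass-through
columns, ready for an external back-projection tool, e.g.

```
relion_reconstruct --i subset.star --o subset.mrc --ctf
```

Selections below 200 particles are flagged (strictly fewer than 200):
around that count a reconstruction still resolves the two wings at roughly
20 Å, which is the practical floor for verifying that a selected
coordinate produced the expected relative orientation.

## Tether reach

Whether the carrier protein can engage a catalytic site at a given swivel
angle is a geometry question: the anchor (the residue linking the carrier
domain to the static wing) is fixed; each site rides the condensing body,
rotated by $\alpha$ about the pivot axis through the pivot point. For a
site at cylinder radius $b$, anchor radius $a$ and height offset $c$, the
anchor-site distance obeys the law of cosines,

$$d(\alpha)^2 = a^2 + b^2 - 2ab\cos(\alpha - \varphi) + c^2,$$

and `reach_scan()` recovers the accessible-$\alpha$ interval endpoints to
within one scan step of the analytic crossing (asserted in the tests). The
tether budget defaults to 80 Å — the estimated maximum reach of the
phosphopantetheine arm (linker stretch + carrier-domain size + arm
length) — and is a configuration value, never recomputed. The scan varies
$\alpha$ alone ($\beta = \gamma = 0$), matching how reach is usually
presented against the swivel angle; pivot point and axis are user inputs
derived from the two body reference maps. The default anchor atom is the
residue's Cα and sites are the catalytic side-chain atoms, both
configurable through the `chain/resno/atom` selectors of `load_sites()`.

## The synthetic-scene generator

`simulate_scene()` emulates the *metadata* of two focused refinements with
known ground truth; it never touches image space (no projections, CTF or
image noise). Body-1 orientations are uniform over SO(3) (unit-quaternion
sampling); each particle draws a mixture component by weight and a
relative orientation from per-axis wrapped Gaussians around the component
center; body 2 is body 1 composed with that relative rotation; finally
each body is perturbed by an independent small rotation (uniform axis,
half-normal angle of scale `noise_sigma`, default 1°) emulating the
angular-assignment error of two separate refinements. Per-axis wrapped
Gaussians were chosen over a matrix-Fisher distribution because the
landscape itself lives in per-axis coordinates, so truth centers and
recovered modes are directly comparable. With `c2_expand = TRUE` each
particle is emitted twice, composed with the C2 operator (axis z) of both
bodies and carrying the second monomer's class labels, reproducing the
bookkeeping of symmetry expansion.

The default scene places a tight component at $(13°, 0°, 14°)$ (carrier
domain on the condensing site of one monomer), a second at
$(-3°, -8°, -8°)$ (carrier domain on the transferase site) and a broad
unengaged background at the origin — the geography reported for the real
enzyme. Scene outputs are byte-identical under a fixed seed.

What passing the recovery tests shows — and what it does not: the pipeline
recovers modes, weights and selections from metadata whose noise is purely
angular and isotropic. Real refinements have orientation errors that are
anisotropic, defocus- and size-dependent, and correlated between the two
bodies through the shared images; none of that is modelled, so the tests
validate the algebra and the bookkeeping, not the refinement software
upstream.

## Problem sizes and reproducibility

The validation suite uses scenes of 8,000–50,000 particles, a 10,000-case
round-trip sweep of the Euler algebra, and 1°-step reach scans; these
sizes put every mode-recovery statistic well inside its tolerance
(e.g. a 5°-wide mode sampled 20,000 times locates its 2° bin with large
margin) while keeping the whole suite fast. All stochastic tests fix their
seeds; `scripts/acceptance.R` derives every stream from its `--seed`
argument and recomputes all reported numbers from scratch.

## Known limitations

* Only C2 symmetry is handled; higher point groups would need the full
  coset enumeration in `c2_equivalents()`.
* The landscape is a histogram density, not a free-energy estimate; no
  kinetic or path interpretation is offered.
* `read_particle_star()` handles loop-style particle blocks (legacy and
  optics-group layouts) with whitespace-separated tokens; exotic STAR
  features (quoted strings with spaces, multi-line values) are out of
  scope.
* Upstream focused classification is taken as given: class labels are
  inputs, and the grouping of raw 3D classes into functional groups is a
  user-supplied mapping.
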