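---
title: "Global mechanics and enzyme accessibility of DNA origami: methods"
author: "origamiAccess"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Global mechanics and enzyme accessibility of DNA origami: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(origamiAccess)
```

## The scientific problem

DNA origami nanostructures — a long circular scaffold strand folded into shape
by hundreds of short staple oligonucleotides — are not rigid objects. On the
microsecond-to-millisecond scale they breathe: whole substructures flex
between alternative conformations, and the spacing between neighbouring
double helices fluctuates by nanometres. These fluctuations matter chemically.
A restriction endonuclease can only cleave its recognition sequence when the
docked enzyme does not clash sterically with the DNA helices adjacent to the
site, so local geometry and its fluctuations set the reactivity of every site,
and global conformational changes (for example a distant staple omission) can
modulate that reactivity allosterically.

`origamiAccess` implements two linked analyses for coarse-grained (oxDNA)
trajectories of such structures:

1. a **global-mechanics pipeline**: rigid-body alignment, per-nucleotide RMSF,
   covariance eigenmodes (essential dynamics), mode collinearity between
   structure variants, trajectory projections, free-energy profiles by
   Boltzmann inversion, two-state statistics and substructure
   synchronization;
2. a **steric-accessibility scorer**: a rigid enzyme model, anchored once to
   an ideal B-DNA helix, is docked onto every recognition site in every frame
   and each (frame, strand side) is classified accessible or blocked from
   maximum/minimum distance maps.

## Containers and conventions

All coordinates are held in nm; the oxDNA length unit (0.8518 nm) is applied
once, when a configuration file is read, and removed when one is written. The
intrinsic time unit (0.7 ns) is recorded as metadata only; no analysis depends
on it. All indices are 1-based, the natural R convention; the 0-based indices
of the oxDNA topology dialect are converted at the file boundary. Site and
base-pair numbers in reports are therefore directly the 1-based numbers a
reader of the accessibility histograms expects.

The central S4 classes are `OxTopology` (strand membership, neighbour links,
optional pairing table), `OxTrajectory` (dense `n x 3 x T` coordinate and
versor arrays over one topology), `ParticleCloud` (labelled protein or DNA
point sets), `DesignMap` (cadnano routing, staple footprints, crossovers),
`ModeSpectrum`, `ProjectionSeries`, `FEProfile`, `TwoStateStats`,
`RecognitionSite`, `DockingTemplate`, `DistanceMaps` and
`AccessibilityResult`. Each has a validity method enforcing its invariants
(mutual neighbour links, pairing as a complementary involution, unit versors,
orthonormal mode vectors, nonnegative sorted eigenvalues, and so on).

oxDNA topology files carry no base-pairing table. When a design map is not
available the pairing is inferred geometrically: two nucleotides are paired
when their hydrogen-bonding sites are mutually nearest, closer than 0.15 nm,
with antiparallel base normals and complementary bases. In the package's
coarse-grained geometry (nucleotide centre 0.6 nm from the duplex axis,
hydrogen-bond site on the axis, backbone site 0.2 nm outward) paired
hydrogen-bond sites coincide exactly, so the threshold is comfortable; for
trajectories from other parameterizations it is an exposed argument.

## The global-mechanics pipeline

**Alignment and RMSF.** Every frame is superposed on the *first* frame over a
selection (by default the scaffold strand) with the Kabsch algorithm — the
proper rotation and translation minimizing RMSD, with reflections excluded by
the usual sign correction on the smallest singular vector. The mean structure
is the single-pass average of the aligned frames; RMSF per nucleotide is
$\sqrt{\langle \lVert r_i(t) - \langle r_i \rangle \rVert^2 \rangle}$. An
iterative align–average–realign scheme was considered and rejected: on the
planted-mode fixtures the single-pass mean is already converged to well below
the fluctuation scale, and a single pass keeps the procedure deterministic
and cheap.

**Covariance eigenmodes.** With $x(t)$ the 3N-vector of deviations from the
trajectory mean over the selection (layout $x_1, y_1, z_1, x_2, \dots$), the
covariance is $C_{nm} = \frac{1}{T} \sum_t x_n(t)\, x_m(t)$ and the
`ModeSpectrum` holds its full eigendecomposition $\{\lambda_n, p_n\}$,
eigenvalues descending, with total mean-square fluctuation
$\sum_n \lambda_n = \mathrm{tr}\, C$. Eigenvector signs are fixed so the
largest-magnitude component is positive — this makes collinearity matrices
and projections reproducible across runs and platforms, but note the
convention acts on components in the *aligned* frame, so two analyses that
align to differently oriented references can still disagree by a global sign.

**Collinearity.** Conservation of fluctuation directions between two
structures is measured by $|\langle p_i^A | p_j^B \rangle|$ over the leading
modes, requiring identical selections. Projecting a trajectory on a mode from
a *different* structure requires an explicit nucleotide index mapping; no
automatic sequence matching is attempted, because a silent misalignment there
would corrupt every downstream free-energy profile.

**Free energy and two-state statistics.** The projection
$s_t = \langle x_t | p \rangle$ is histogrammed over its range (default 100
bins, exposed) and inverted, $F = -\ln(\text{count}/\text{total})$ in units
of $k_BT$, offset to zero at the minimum. Zero-count bins are masked, never
interpolated, and barriers are read from the raw masked histogram — no kernel
smoothing. Well detection requires a second local minimum separated from the
global one by at least 2 bins and a barrier of at least 0.5 $k_BT$ (exposed
as `minBarrier`); this prominence filter is what makes the detection robust
to bin-level shot noise at realistic sample sizes. The divider is the barrier
top; populations, mean residence times (mean run length of the state labels)
and divider crossings follow from the labelled series. Profiles with no
second well return a single-state result rather than an error.

## The accessibility method

**Docking template.** One anchor per nucleotide (the residue centroid for a
crystal duplex, the nucleotide centre for the ideal helix) defines a
correspondence between a bound protein–DNA structure and an ideal 10-bp
coarse-grained helix (rise 0.34 nm, twist 360/10.5°); the Kabsch transform
of the anchors is applied to the protein heavy atoms, leaving the enzyme
expressed once and for all in the helix frame. A superposition RMSD above
0.5 nm warns but does not fail: crystal duplexes are bent, and the docking
only needs a consistent rigid relative geometry. When no crystal structure is
available a synthetic probe cloud (a uniform ball of stated radial extent)
stands in for the enzyme; it is labelled synthetic everywhere.

**Per-frame docking.** For each site the 10-bp window (3 bp flank + 4 bp
motif + 3 bp flank; the registration knob `flankLeft` is exposed because the
exact centring of the enzyme on the motif is a modelling choice) provides 20
target positions. For the scaffold side the engaged helix strand maps onto
the scaffold strand 5'→3'; for the staple side the strand-swapped
correspondence is used — geometrically the pseudo-dyad flip of the duplex,
which the ideal helix possesses exactly. Frames in which a window nucleotide
is unpaired are skipped and counted, not scored inaccessible: the method has
no evidence either way there, and skipping is the conservative choice.

**Distance maps.** Every particle — placed protein or adjacent-DNA
interaction centre — is assigned to a cell $(i, \theta)$: $i$ the window
base-pair row whose centre is nearest along the site axis (particles beyond
the ends are clamped to the end rows so near-window clashes are still
caught), $\theta$ its azimuth about the axis in the site's local frame, in 72
bins of 5° (about 0.4 nm of arc at typical helix–helix distances; exposed).
Distances are measured from the assigned base-pair *centre*, not from a
global axis line, which keeps rows meaningful when the window bends. The max
map holds the farthest protein particle per cell, the min map the nearest
environment particle; a frame is accessible iff max < min in every cell, with
empty cells never blocking. Particles are points — no radii — because the
max < min criterion already compares like with like, and adding radii would
double-count excluded volume.

**Environment.** The environment is every interaction centre (backbone and
base site) of every nucleotide outside the window plus a 2-bp margin along
the same duplex: the site's own helix must not block itself. One consequence
worth knowing: with a spherical probe whose axial extent exceeds the window,
the helical *continuation* of the site's own duplex beyond the margin is
legitimate environment under end-row clamping and will block a ball-shaped
probe on long helices. A real enzyme envelope hugs the helix and does not
have this pathology; for isolated-duplex demonstrations the fixtures
therefore use a 14-bp helix, which the window plus margins covers entirely.

**Aggregation.** Per-site accessibility is the fraction of classified frames
that are accessible, per strand side, plus the fraction with *both* sides
accessible in the same frame (the interpretation adopted for "both strands
simultaneously"; the alternative — a product of independent per-side
fractions — was rejected because the per-frame AND is what the trajectory
actually measures, and the identity
$r_\mathrm{both} \le \min(r_\mathrm{scaffold}, r_\mathrm{staple})$ is then
guaranteed rather than approximate). The in-plane occupancy view projects
neighbouring-helix centres of mass into the plane perpendicular to the site
axis, with the reference direction taken from a *caller-designated* window
nucleotide — the choice of nucleotide is a required argument, not a default,
because the published figures do not pin it down and the azimuthal origin
changes the picture. Theoretical accessibility can finally be correlated
(Pearson) with experimental per-site cleavage fractions, after excluding
crossover-overlapping sites, which are not substrates.

## Site catalog

Recognition sites are motif occurrences on the scaffold sequence threaded
along the cadnano scaffold path, restricted to fully paired regions and
reported at every offset (overlapping occurrences included). Windows that
would extend into unpaired or absent scaffold are kept but flagged truncated;
truncated sites are excluded from docking. A site is crossover-flagged when
any motif base pair lies within 1 bp (exposed margin) of a scaffold or staple
crossover on its helix — a junction shares the geometry of its flanking base
pairs. Only the square-lattice cadnano dialect is accepted; the characteristic
junction spacing of that lattice (32 bp per 3 turns) is also what
`designImpliedPitch()` reads back from a design, giving the familiar
10.67 bp/turn of square-lattice origami.

## Synthetic scenes: what they emulate, and what they do not

The generators produce every input class the pipeline needs, deterministically
for a given (parameters, seed):

- `makeDuplexScene`: an ideal duplex with isotropic Gaussian jitter —
  an isolated, fully accessible site; per-nucleotide RMSF has the closed form
  $\sigma\sqrt{3}$.
- `makeRaftScene`: parallel rigid duplexes in a plane, the central one
  carrying the motif, neighbours following a per-frame surface-to-surface gap
  schedule. Helices are rigid rods per frame by design: flexibility enters
  only through the schedule, so the block/clear ground truth stays analytic.
  For a centred probe of radial extent $\rho$ the nearest environment site
  approaches the helix axis to gap $+\,0.4$ nm, so the analytic threshold is
  gap $> \rho - 0.4$ nm; schedules should keep about 0.3 nm clear of that
  threshold, inside which finite probe sampling and 5° binning make the
  outcome legitimately uncertain. The test ladders are chosen accordingly.
- `makeTwoStateTrajectory`: overdamped Euler–Maruyama dynamics (step 0.01,
  10 steps per recorded frame — small enough that well populations match the
  analytic Boltzmann weights of the planted potential to within the sampling
  error of the transition count) in a quartic double well, emitted along a
  planted unit mode that is orthogonalized against the six rigid-body motions
  of the base structure so alignment cannot absorb it. Ground truth stores
  the per-frame coordinate, the state labels and the potential itself.
- `makeProbeCloud`: a uniform ball of particles at a stated offset — the
  synthetic enzyme stand-in.

What passing on these scenes shows: that the bookkeeping, geometry, linear
algebra and classification logic are exact, equivariant under rigid motions,
and statistically calibrated against closed forms. What it does not show:
anything about force-field realism. The scenes have no sequence-dependent
elasticity, no junction mechanics, no electrostatics; quantitative claims
about a real origami still require real trajectories, and the published
headline numbers (multi-$k_BT$ barriers, RMSF above 6.5 nm at vertices,
per-site fractions on a 14,000-nucleotide triangle) come from
cluster-scale simulations that a desk run does not reproduce. The test-suite
problem sizes — up to 50,000 frames for 1D statistics, a few thousand frames
for 3N-mode recovery at N ≤ 20, 10-frame rafts for accessibility — are the
package's choice of the smallest sizes at which every statistical tolerance
is meaningful.

## Numerical choices and edge cases

- Kabsch degeneracy: a *collinear* reference (second-smallest singular value
  of the centred coordinates below $10^{-9}$) is an error; planar sets are
  deliberately allowed, since the proper-rotation sign correction handles
  them and site windows are never truly collinear.
- Weights in superposition default to uniform; no mass weighting anywhere.
- Eigenvalues are clamped at zero from below (they can come out at
  $-10^{-17}$ numerically); the spectrum keeps all 3N modes so Parseval
  holds exactly.
- Histogram bin edges span exactly the sample range; the extreme sample is
  included in the last bin (`rightmost.closed`).
- `twoStateStats` on an even number of identical-length runs gives residence
  times that are exact integers; the transition-count parity always matches
  the start/end state labels.
- All stochastic fixtures restore the caller's RNG state; nothing in the
  package touches the global seed as a side effect.

## Limitations

Enzyme flexibility, induced fit, energetic scoring, divalent-ion structural
effects and cleavage kinetics beyond the accessible fraction are out of
scope. The cadnano reader handles the square lattice only and ignores
loop/skip insertions. Cross-structure projections rely on the caller's index
mapping. The accessibility criterion is binary per frame; partial overlaps
score as blocked.
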