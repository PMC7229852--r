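# origamiAccess

Mechanics and restriction-enzyme accessibility of DNA origami nanostructures
from coarse-grained (oxDNA) molecular-dynamics trajectories.

DNA origami — a long scaffold strand folded by short staples — fluctuates on
the microsecond-to-millisecond scale, and those fluctuations control chemistry:
a restriction endonuclease cleaves a recognition site only when the docked
enzyme does not clash sterically with the neighbouring double helices, so
local geometry sets per-site reactivity and distant structural perturbations
(such as omitted staples) can modulate it allosterically. This package is for
structural-bioinformatics and DNA-nanotechnology researchers who have such
trajectories and want to connect global mechanics to local site reactivity.

It provides two linked analyses behind Bioconductor-style S4 containers:

**Global mechanics.** Frames are Kabsch-aligned to the first frame over a
selection (typically the scaffold); per-nucleotide RMSF and the positional
covariance

&nbsp;&nbsp;&nbsp;&nbsp;*C*<sub>nm</sub> = (1/*T*) Σ<sub>t</sub> *x*<sub>n</sub>(*t*) *x*<sub>m</sub>(*t*)

are computed on the 3N deviation vectors, giving eigenmodes {λ<sub>n</sub>,
**p**<sub>n</sub>} with total mean-square fluctuation Σλ<sub>n</sub>. Mode
conservation between structure variants is measured by the collinearity matrix
|⟨**p**<sub>i</sub><sup>A</sup>|**p**<sub>j</sub><sup>B</sup>⟩|; trajectories
are projected on modes, s<sub>t</sub> = ⟨**x**<sub>t</sub>|**p**⟩, and free
energy is reconstructed by Boltzmann inversion, *F* = −k<sub>B</sub>T ln
*p*(s), with two-state statistics (populations, residence times, transition
counts, barrier heights) read from the raw masked histogram.

**Steric accessibility.** An enzyme model (crystal heavy atoms, or a synthetic
probe cloud) is anchored once to an ideal 10-bp B-DNA helix, then docked onto
each recognition site in each frame — scaffold side directly, staple side via
the duplex pseudo-dyad flip. Every particle is binned on a (base pair i,
azimuth θ) grid; max<sub>i,θ</sub> holds the farthest protein particle and
min<sub>i,θ</sub> the nearest adjacent-DNA particle per cell, and a frame is
*accessible* iff max<sub>i,θ</sub> < min<sub>i,θ</sub> everywhere. The
per-site accessibility r is the accessible fraction of frames, per strand
side and for both sides simultaneously, and can be correlated with
experimental per-site cleavage fractions.

File I/O covers oxDNA topology/configuration (with the 0.8518 nm/unit
conversion applied at the boundary), PDB (via bio3d), square-lattice cadnano
JSON (scaffold routing, staples, crossovers, design-implied pitch), and TSV
reports. Deterministic synthetic-scene generators (jittered duplexes,
multi-helix rafts with scheduled gaps, planted double-well trajectories,
probe clouds) make the whole pipeline testable offline with analytic ground
truth.

## Worked example

A three-helix raft whose inter-helix gap alternates between 0.5 nm (blocked)
and 10 nm (clear), probed by a synthetic 3-nm enzyme stand-in:

```r
library(origamiAccess)

scene <- makeRaftScene(nHelices = 3, gapSchedule = rep(c(0.5, 10), 5), seed = 0)
site <- scanRecognitionSites(scene$design, scene$topology)[[1]]
site
#> RecognitionSite 1 (GCGC): path start 6

enzyme <- probeTemplate(makeProbeCloud(extent = 3, nParticles = 20000, seed = 1))
siteAccessibility(scene$trajectory, site, enzyme)
#> AccessibilityResult site 1: scaffold=0.500, staple=0.500, both=0.500 (frames used 10, skipped 0)
```

The site is accessible in exactly the five wide-gap frames, from either
strand side. On the mode-analysis side, a planted two-state trajectory
(quartic double well, 3 k<sub>B</sub>T barrier, minima at ±2 nm) is recovered
from the covariance spectrum and the inverted histogram:

```r
set.seed(42)
base <- matrix(rnorm(60, sd = 3), 20, 3)
ts <- makeTwoStateTrajectory(base, barrier = 3, minima = c(-2, 2), noise = 0.2,
                             nFrames = 20000, seed = 0)
aligned <- alignAndAverage(ts$trajectory, 1:20)
spectrum <- covarianceModes(aligned$aligned, 1:20)
spectrum
#> ModeSpectrum: N = 20 nucleotides, 60 modes; total MSF 5.714 nm^2
#>   leading eigenvalues (nm^2): 3.588 0.04474 0.04405

proj <- projectOntoMode(aligned$aligned, spectrum, mode = 1)
twoStateStats(proj, freeEnergyProfile(proj, nBins = 80))
#> TwoStateStats: divider 0.141 nm; populations 0.503/0.497; barriers 3.05/3.06 kBT; 199 transitions
```

The first eigenvalue carries the planted two-state variance (the remaining
modes sit at the 0.2-nm noise floor), |⟨**p**₁|planted mode⟩| = 0.9998, and
the recovered barriers bracket the planted 3 k<sub>B</sub>T.

`runPipeline()` ties the stages together from a YAML config and writes TSV
reports (sites, RMSF, eigenvalues, projection, free energy, accessibility,
correlation) with the config hash in every header; `inst/scripts/origami-access`
is a thin command-line wrapper (`synth`, `sites`, `modes`, `access`,
`correlate`, `run`).

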