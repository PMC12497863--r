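---
title: "Methods: contact kinetics, SDI, membrane transfer and crosstalk screening"
author: "SynapseKinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contact kinetics, SDI, membrane transfer and crosstalk screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SynapseKinetics)
```

# The problem

When a cytotoxic CD8 T cell meets an NK cell it can form an immune
synapse: the T cell stops migrating, the membranes appose, and material —
membrane patches carrying receptors such as CD25 and CD69 — is exchanged
by trogocytosis. Three quantitative signatures of this event are
computable from ordinary two-channel time-lapse movies: a sharp drop in
the T cell's speed while in contact, a high Speed–Distance Index for the
pair, and transferred-fluorescence pixels inside the recipient cell. A
fourth, orthogonal line of evidence is molecular: which ligand–receptor
pairs both cell types actually express. This package implements all four
analyses plus the synthetic data needed to validate them.

# Contact kinetics

## Model and definitions

A track is a time-ordered list of centroid positions. For a focal T cell
and a contact episode `[s, e]` (frames, inclusive on both ends) we define
Ph1 = frames `< s`, Ph2 = frames in `[s, e]`, Ph3 = frames `> e`. The
three phases always partition the track's span; Ph1 or Ph3 may be empty,
in which case the cell is flagged and excluded from ratio statistics
(the ratio needs a finite, positive pre-contact velocity).

Phase velocity divides "total displacement" by elapsed time. *Total* is
read as the summed path length over successive steps (mode `"path"`, the
default) because accumulation is what "total" most naturally means for a
migrating cell; the straight endpoint-to-endpoint reading is exposed as
mode `"net"`. For uniformly sampled tracks, path-mode velocity equals the
mean frame-wise speed, so the two plausible readings of "average
velocity" coincide under the default.

The deceleration ratio is `v(Ph2) / v(Ph1)`; `ratio <= 0.2` is the
5-fold-slowdown criterion. Ranking sorts ascending, breaking ties by
track id so output is deterministic.

## Contact detection

The underlying studies confirm contact visually (membrane overlap). The
reproducible surrogate used here is: centroid distance at or below
`contactDistance` for at least `minFrames` consecutive common frames.
Defaults are `contactDistance = 10` µm — the sum of two nominal 5 µm cell
radii — and `minFrames = 2`, the shortest run distinguishable from a
single-frame crossing. Both are exposed in `pipelineConfig()`. When a
cell has several episodes, Ph2 is the longest one (ties: earliest start,
then smallest partner id); the alternatives are visible via
`detectContacts()` directly.

# Speed–Distance Index

`sdi(v_rel, d, epsilon) = v_rel / (d + epsilon)`. Velocity vectors are
estimated by backward finite differences, consistent with phase
velocities; the first frame of a pair therefore has no sample. We use
`epsilon = 1e-6` in the active distance unit: no published value exists,
and at 6 orders of magnitude below a cell radius it changes nothing
except removing the 1/0 singularity (the ε-limit property test pins this:
for `epsilon = 1e-12·d` the index equals `v_rel/d` to 1e-9 relative
tolerance). The index is reported in 1/time units, which is what the
formula yields; published axis labels occasionally use other unit names,
which are not derivable from the formula and are not adopted.

Time-binned summaries use half-open bins `[k·w, (k+1)·w)`. Within a bin
each pair contributes its mean SDI once, and the median/quartiles are
taken over pairs — pooling raw frames instead would let long series
dominate the median, and no published pooling rule exists. Bin origin is
absolute time by default; `origin = "pair"` re-zeroes each pair at its
first sample for "time since first observation" analyses.

Proximity classification is pixel-based: close means `distance <= 250` px
(inclusive), the histogram uses fixed 10 px half-open bins. Kinetics are
in µm; pixel distances are obtained only through the configured
`pixelSize`.

# Imaging

Channels are thresholded by Otsu's method (fixed threshold available,
since dim uniform backgrounds can defeat any automatic threshold) and
grouped by 8-connectivity — the standard choice for blob-like cells —
with components below `minArea` discarded and labels assigned in
raster-scan order for determinism. Centroids are unweighted pixel means.
Frame-to-frame linking is greedy nearest-first with a hard displacement
gate; this is exact when inter-cell spacing exceeds twice the per-frame
displacement (a tested invariant) and is documented as a limitation at
high densities, where optimal assignment would be needed. Membrane
transfer is quantified as a binary pixel count (transfer-channel pixels
at or above threshold inside a recipient mask) rather than integrated
intensity, matching the "pixel counts" readout; whether counts are
reported per cell, per frame or per video is not standardized, so
`averageTransfer()` offers all three granularities.

# Ligand–receptor screen

A pair passes at TPM threshold `t` iff **every** ligand subunit reaches
`t` (inclusive, per the "expressed ≥" convention) in the
ligand-expressing cell type and every receptor subunit in the
receptor-expressing cell type. Which cell type supplies the ligand is not
fixed by the biology — crosstalk is bidirectional — so the default
direction is `"either"` (pass in at least one direction), with
`"forward"`/`"reverse"` available. Genes absent from the expression table
make a pair *unevaluable*, a third state, rather than a fail: silently
treating a vocabulary mismatch as TPM 0 would deflate counts
undetectably. The packaged 16-row crosstalk table carries its published
pass flags (16 at ≥ 2 TPM, 9 at ≥ 10 TPM); full database-scale screens
(thousands of pairs) require the user to supply the pair and expression
CSVs, as those database snapshots are not redistributable here. The
published prose counts "proteins" where the table footer counts
interactions; this package counts interactions (rows).

# Phospho-flow fold change

`(pX_co / X_co) / (pX_mono / X_mono)` — the co-culture phospho/total
ratio normalized to the monoculture ratio. Inputs may be percent-positive
fractions or MFI; the formula only needs the within-condition ratio to be
meaningful, and the published heatmaps do not disclose which readout fed
them, so neither is asserted. The raw ratio is canonical;
`log2 = TRUE` adds the display transform. Zero or negative inputs are
rejected naming the offending field, since the ratio is undefined there.

# The synthetic-data generator

`simulateTracks()` is the package's ground-truth instrument, not a
biophysical model. Design choices:

* **Motion**: isotropic step-wise random walk — per frame a uniform
  direction and a step of length
  `speed · Δt · max(0, 1 + N(0, noiseSdFrac))`. The simplest model whose
  per-phase speeds are exactly recoverable; it has no persistence or
  chemotaxis.
* **Contacts are scripted, not emergent**: each T cell gets one contact
  window in the middle of the movie during which its speed is multiplied
  by its per-cell deceleration factor and its partner NK cell is held at
  0.4 × contact radius (toward the arena centre, so it never leaves the
  arena) with 0.1 × radius positional jitter — cells in a synapse still
  wiggle, and a rigid tether would make the pair's relative speed
  unrealistically near zero. At the window's end the partner is displaced
  to 2.5 × radius: contact *ends*, so detected episodes terminate where
  the ground truth says they do.
* **Boundaries reflect** (a closed imaging chamber, not a torus).
* **Defaults are the study conditions**: 100 frames; 20 T and 20 NK
  cells; deceleration factors 0.1 for 75% of T cells and 0.5 for the
  rest (the regime in which more than 70% of cells show a ≥ 5-fold
  slowdown); 10% step noise. Frame interval (30 s), pixel size
  (0.5 µm/px), arena (400 µm) and speeds (0.15/0.10 µm/s, typical
  lymphocyte crawling speeds) are unstated in the source material; they
  were chosen once as realistic values and are configurable.
* **Rendering** paints cells as filled disks per type channel and moves
  a configured number of transfer-channel pixels into the recipient mask
  (the mask pixels nearest the donor centroid) for each contact event;
  per-type ground-truth label masks are returned. No point-spread
  function, photobleaching or intensity noise is simulated — passing
  segmentation tests therefore demonstrates correctness of the
  geometry/counting logic, not robustness to real microscope noise.
* **Determinism**: every generator takes a mandatory seed and restores
  the RNG state afterwards; identical seeds give bit-identical output.

What the generator does *not* emulate — 3D scaffolds, emergent
chemotaxis, photophysics, segmentation ambiguity, cell division or death
— bounds what green tests mean: they validate the analysis pipeline's
arithmetic and contracts, not its performance on noisy real movies.

# Numerical and degenerate-input conventions

Frames are 0-based; frame ranges are inclusive on both ends; pixel
origin is top-left with x rightward (columns) and y downward (rows).
Phases with fewer than two frames have `NA` velocity, distinct from a
true zero. `v(Ph1) = 0` makes the ratio undefined, and such cells are
excluded and counted in a message. Blank frames segment to zero labels
without error; empty track sets, empty pair tables and empty SDI series
lists return empty results of the right shape. Quartiles use the default
type-7 estimator.

# Problem sizes

The bundled tests run the full cohort analysis at the study scale (20 + 20
cells × 100 frames), property suites at 100–1000 random cases, and image
tests on 40–80 px frames; the whole suite completes in well under a
minute on a laptop core. Larger cohorts scale linearly in cells × frames
for kinetics and in pixels × frames for imaging.

# Known limitations

Greedy linking is not globally optimal; contact detection is centroid
distance, blind to actual membrane overlap; the SDI's published unit
label cannot be reconciled with its formula and is reported as 1/time;
database-scale ligand–receptor counts depend on external snapshots and
are out of scope. None of these affect the within-package ground-truth
guarantees, which are what the test suite certifies.
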