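---
title: "Methods: template-guided TM docking and co-localization statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: template-guided TM docking and co-localization statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette explains the models and procedures implemented in `groovedock`,
the assumptions behind them, the parameters that matter, and the design
choices made where the design was genuinely open. Everything quantitative said
here is computed by the package's test suite or by `scripts/acceptance.R`;
nothing is quoted from elsewhere.

## The structural problem

A "short" transmembrane helix bundle (eleven TM helices in the motivating
biology: the bilaterian complex I subunit ND2) carries a deep lateral groove
because three N-terminal helices of its ancestral homolog (bacterial NuoN,
fourteen TM helices) were lost; the third of those extra helices is the one
that fills the groove. A tetrameric receptor (an NMDA-receptor-like TMD)
exposes, on each subunit, an outermost M4 helix that protrudes from the
membrane-spanning core, flanked by two shallow grooves. The docking hypothesis
is purely steric: the protruding M4 inserts into the short bundle's groove.

## Template-guided docking

The pose space is deliberately small — a superposition plus one rotation:

1. **Anchor.** The template's groove-filling helix is superposed onto the
   receptor's target M4 by a Kabsch least-squares fit of the Cα traces.
   The correspondence is N-to-C in residue order; unequal lengths are
   centre-trimmed to the shorter segment, because no residue-level mapping
   between a filler helix and an M4 is defined in general. The Kabsch solution
   is constrained to proper rotations (no reflections): the determinant
   correction flips the smallest singular direction when needed.
2. **Rotation scan.** The filler superposition leaves the azimuth about the
   M4 axis as the meaningful degree of freedom (for ideal helices the Kabsch
   fit does fix an azimuth, but it is set by the arbitrary phase
   correspondence, not by packing). The template is rotated about the fitted
   M4 axis over `0, step, ..., 360 - step` degrees (default step 1°) and the
   pose with the fewest steric clashes is kept; ties break towards the
   smallest angle so results are deterministic. The M4 axis is the principal
   axis of its centred Cα coordinates, oriented N-to-C; the axis point is the
   centroid. The principal axis of a finite discrete helix deviates from the
   true axis by a tilt that decays roughly like 1/n (about 0.01 rad at 24
   residues); both the scene generator and the dock derive their frames from
   the same fit, so the deviation cancels in recovery.
3. **Transfer.** The query (short bundle) is mapped onto the oriented
   template by Kabsch superposition over the shared atoms — by default all
   atoms matched on (chain, residue number, atom name), which for a
   long/short homolog pair is exact.

**Clash criterion.** A clash is an inter-body heavy-atom pair closer than a
cutoff, strictly; the default cutoff of 2.5 Å on side-chain-stripped
structures flags severe overlap while tolerating packing contacts. The filler
helix itself is excluded from clash counting: it is the alignment proxy for
M4 and coincides with it by construction, so for identical ideal helices its
self-overlap term would swamp the profile with a spurious angular dependence.
Whether the original procedure scored clashes as a pair count, an overlap
volume, or by eye is not recoverable; the pair count is this package's
choice, and the cutoff is a parameter.

**Occlusion.** If every scan angle exceeds a hard ceiling of clashes (default
25, roughly 5% of the bundle's atoms), the dock raises a *groove occluded*
condition instead of returning a pose. This is the expected outcome when the
"receptor" is the long homolog itself with its own filler as the target: the
groove site is occupied.

**The scan implementation.** Rotating a rigid body about a fixed axis moves
each atom on a circle; in cylindrical coordinates about the axis, a mobile
atom–receptor atom pair clashes exactly on an angular interval determined by
the two radii, the height difference, and the cutoff. The scan therefore
accumulates per-pair clash intervals onto the angle grid in a single pass,
which is exact (the unit tests verify equality with direct per-angle
recounting) and removes the scan from the runtime bottleneck.

## The synthetic structure generators

Helices are ideal: Cα atoms at radius 2.3 Å from the axis, rise 1.5 Å and
twist 100° per residue (canonical α-helix values), 24 residues per TM helix,
plus a pseudo-Cβ 1.5 Å radially outward from each Cα to mimic side-chain
bulk on stripped structures. Bundles place helices on a ring (default twelve
positions, ring radius 20 Å, antiparallel up/down alternation); omitting one
position leaves the lateral groove. The long homolog adds the groove-filling
helix plus two peripheral helices outside the ring; long and short share
coordinates exactly on common atoms.

The receptor fixture is an exactly n-fold-symmetric tetramer: per subunit a
short pore-lining M2 (radius 4 Å from the pore axis), an M3, an M4 at
14 Å — the most protruding helix — and an M1 flank helix placed on the
inter-subunit diagonal, shared between neighbouring M4s, mirroring the
domain-swapped packing of tetrameric receptor TMDs in which M4 lies lateral
to the flanking helices of the *neighbouring* subunit. Exact symmetry
requires each helix's azimuthal phase to rotate with its subunit, which makes
the two flanks of any one M4 spiral differently; the flank radius (11.85 Å),
axial stagger (0.75 Å, half a rise) and phase (280°) were chosen together so
that both shallow grooves clear a docked bundle by just over the clash cutoff
(≈ 2.55 Å closest approach). That keyhole-like clearance is what registers a
docked bundle to about a degree: one degree of rotation about the M4 axis
moves the bundle's groove-flanking helices by ≈ 0.2 Å, enough to cross the
cutoff. Looser packing widens the zero-clash plateau and degrades angular
recovery; tighter packing would violate the hard-clash margin used by the
scene generator.

**Planted scenes.** `plant_complex()` must produce, for any requested angle,
a scene from which docking recovers that angle. A fixed template, receptor
and anchoring step yield one fixed clash profile, so the angle cannot live in
the bundle placement alone: it is realized as the azimuthal phase of the
receptor's M4 helix relative to the groove-registered pose. The scene's
receptor carries the target M4 spun in place about its own axis (a per-scene
rotamer of the same helix); the bundle sits in the registered pose, and the
exact placement transform is returned as ground truth. Planting verifies the
pose has no hard clashes (< 2.0 Å pairs). The bundle–M4 clearance
(≥ ≈ 2.7 Å at every relative spin) guarantees plantability at any angle.

**Occluded scenes.** `make_occluded_scene()` embeds the long bundle in a
ring of crowd helices around the filler site, emulating the ancestral
protein's native context, where the homolog packs against neighbouring
membrane-arm subunits. Without the crowd, a rotation scan can escape to the
open face of the filler helix — empty space in a minimal fixture that is
occupied in the real membrane arm — and report a spurious pose; with it,
every scan angle clashes far beyond the ceiling.

What these fixtures do **not** emulate: real backbone geometry (N, C, O
atoms), sequence-dependent side chains, helix kinks and tilts, loops,
membrane context, or crystallographic noise. Passing the recovery tests shows
the procedure is correct and well-conditioned on idealized geometry; it does
not show that a particular biological pose is right.

## Surface areas

SASA is Shrake–Rupley: for each heavy atom, the fraction of quadrature
points on its probe-expanded sphere (probe 1.4 Å) outside all other expanded
spheres, times the sphere area. The point set is a deterministic
golden-section spiral (default 960 points/atom), so no seed is involved;
doubling the point count changes fixture totals by well under 1%, and a
10^5-point Monte-Carlo oracle agrees within a fraction of a percent. Radii:
C 1.7, N 1.55, O 1.52, S 1.8 Å; the pseudo-Cβ is carbon; Cα-only (reduced)
structures use an inflated 2.4 Å Cα radius to mimic residue bulk. Buried
interface area is `[SASA(A) + SASA(B)] − SASA(AB)`, summed over both
partners, with the per-partner split from per-atom differences; small
negative quadrature noise is clamped at zero with a warning. The docked
fixture buries ≈ 2000 Å² under these radii — the same order as contact areas
reported for TM helix-bundle interfaces of this size, though no quantitative
comparison is possible against coordinates that were never deposited.

## Costes-thresholded co-localization

Per cell, the threshold line is an orthogonal regression on standardized
intensities (reduced major axis, `slope = sd2/sd1` with positive root and
`intercept = mean2 − slope·mean1`). Two deviations from common descriptions
are deliberate:

* **RMA rather than raw total least squares.** The thresholded coefficient
  should be invariant under per-channel gain and offset (the assay never
  calibrates absolute intensities). Raw TLS is not equivariant under
  anisotropic rescaling — the principal axis rotates — while RMA
  co-transforms exactly, making the invariance hold to machine precision.
  The positive root is forced because at vanishing correlation the sign of
  the fitted slope is noise, and a sign flip would send the threshold line
  into a meaningless orientation.
* **Both-above inclusion rather than either-above.** The coefficient is
  computed over pixels above threshold in *both* channels — the candidate
  co-localized pixels. Conditioning on the union ("bright in either") is a
  Berkson-type selection that makes truly independent channels score
  strongly negative (≈ −0.4 on the simulator's ρ = 0 images), an artefact of
  mutually exclusive bright pixels, whereas intersection-conditioning
  preserves independence, so ρ = 0 scores near zero. The union rule remains
  available as `rule = "either"`.

The walk lowers the channel-1 threshold from the maximum in `(max−min)/256`
decrements, with the channel-2 threshold tied to the line, and stops at the
largest threshold for which the below-threshold pixels are uncorrelated or
anti-correlated (Pearson ≤ 0; an undefined correlation keeps walking; an
exhausted walk ends at the minimum). On images with no shared signal the
walk stops high — sometimes leaving too few above-threshold pixels to score,
in which case the cell is reported as unscoreable and batch runs skip it
with a warning. This is the correct degenerate answer ("no co-localized
signal"), not a failure of the estimator.

The image simulator draws puncta centres uniformly (margin 3σ), shares a
fraction ρ of them between channels with per-punctum log-normal amplitudes
(shared puncta share their amplitude up to the channel gains, so ρ = 1 with
zero noise gives channels that are exact affine images of each other and a
thresholded PCC of exactly 1), convolves with a truncated separable Gaussian
PSF (σ 1.5 px), adds a constant background (10 photons) and Poisson photon
noise (Gaussian read noise optional). Defaults — 256 × 256 px cells, 120
puncta, punctum intensity 2000 photons — describe a realistic widefield cell
ROI (≈ 26 µm at 0.1 µm/px) dense enough in puncta that most cells remain
scoreable even at ρ = 0. At these settings the mean thresholded PCC of
scoreable ρ = 0 cells stays within ±0.1 of zero and rises strictly with ρ to
1, which is the behaviour the acceptance checks assert.

## Group statistics

Kruskal–Wallis (midranks, tie correction, chi-square p on k−1 df) and
Welch's one-way ANOVA (Welch–Satterthwaite df) are computed by the base-R
implementations (`kruskal.test`, `oneway.test`), wrapped to a common result
contract with p-values floored at the smallest representable positive
number. Dunn's post hoc has no base-R implementation and is computed from
pooled midranks with the tie term `T = Σ(t³−t)`:
`z = (R̄ᵢ − R̄ⱼ) / sqrt((N(N+1)/12 − T/(12(N−1)))(1/nᵢ + 1/nⱼ))`, two-sided
normal p, Bonferroni adjustment over all pairs by default (the multiplicity
rule used in the original graphics-software analysis is not recoverable, so
the adjustment is explicit and recorded). At total n = 8 the chi-square
approximation to the Kruskal–Wallis p deviates from the exact permutation
distribution (full enumeration, used as ground truth in the tests) by up to
about 0.1 in the mid-range and much less in the tail; both tests' type-I
error at α = 0.05 calibrates to 0.04–0.05 over 2,000 null simulations of
three normal groups of 15.

## BiFC scoring

Positivity is strict: a channel is positive iff intensity > 3.5 × the
per-cell background; equality at exactly 3.5 × is negative, because the
defining rule ("> 3.5 × or < 3.5 ×") leaves equality unassigned and silent
inclusion would be invisible. Only Cy3-positive (bait-expressing) cells enter
the analysis; Venus intensities are divided by the mean Venus of Cy3-positive
control cells, so the control group's mean normalized intensity is 1 by
construction, and groups are compared by Welch's ANOVA. The simulator draws
per-cell background with multiplicative Gaussian noise (CV default 0.1,
factors truncated at 0.05) and channel intensities as fold × background ×
noise; with 30 cells per group at CV 0.1 a twofold difference in reporter
strength is recovered within 10%.

## Alignment statistics

Global protein alignment uses the Needleman–Wunsch affine-gap optimum as
computed by `Biostrings::pairwiseAlignment` (type `"global"`, end gaps
penalized), under the gap convention of the EMBOSS global aligners: opening
a gap costs 12 and each further gapped column 2, which maps onto the engine's
opening/extension parameters as `gapOpening = gap_open − gap_extend`.
BLOSUM62 is the default matrix with the X row and column zeroed (X scores 0
against everything). Percent identity is identical columns over the full
alignment length (gap columns in the denominator only); percent similarity
counts columns whose residue pair scores > 0 in the matrix, identical
columns included, so similarity ≥ identity always. Scores are re-derived
from the returned alignment and checked against brute-force enumeration of
all alignments on short sequences in the tests. The quadratic-memory dynamic
program is appropriate at segment lengths of tens of residues; the classic
linear-space refinement is out of scope.

The published identity/similarity pair for the two receptor M4 domains can
be recomputed by placing the two sequences (from the stated GenBank records)
in `inst/extdata/m4_domains.fasta`; the package does not bundle sequences it
cannot verify, and the corresponding acceptance check reports a clear
failure rather than silently passing when the file is absent.

## Problem sizes and determinism

The test suite and the acceptance script use: 20 planted scenes for docking
recovery (bundle 528 atoms, receptor 672, 360 scan angles); 50-atom SASA
fixtures with 960-point quadrature against a 10^5-points-per-atom
Monte-Carlo oracle; 30 simulated cells per co-localized fraction on a
{0, 0.25, 0.5, 0.75, 1} grid; 2,000 null replicates for the type-I
calibrations; 30 cells per BiFC group. Every stochastic stage takes an
explicit seed; generators save and restore the caller's RNG state, and the
acceptance script derives independent sub-seeds from its single `--seed`
argument. Identical inputs give identical outputs throughout, including
bit-identical simulated images.

## Known limitations

* Poses are reported on stripped, reduced structures; side-chain rebuilding
  and refinement after docking are out of scope, as is any energetics beyond
  the clash count. No translational search is performed (an axial-offset
  scan exists as an off-by-default extension hook in the pose model's
  parameters).
* The groove/receptor fixtures are idealized; angular-recovery performance
  quantifies the procedure, not any particular biological complex.
* The Costes walk on signal-free images is intrinsically unstable near zero
  correlation; the package resolves this by reporting such cells as
  unscoreable rather than by inventing a threshold.
* mmCIF input, insertion codes, alternate locations beyond blank/'A', and
  multi-model ensembles are not supported; the PDB reader takes the first
  model and rejects insertion codes loudly.
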