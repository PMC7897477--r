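---
title: "Geometric annotation of G-quadruplexes: methods and design"
author: "g4geom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric annotation of G-quadruplexes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g4geom)
```

## The problem

A G-quadruplex (G4) is a four-stranded nucleic-acid structure built from
stacked G-tetrads: planar cyclic quartets of guanines paired by Hoogsteen
hydrogen bonds (N2–H…N7 and N1–H…O6 around the cycle). The tetrad core is
held together by four vertical guanine stacks (G-columns), and everything
outside the core is a *loop* (connecting two different columns), a *bulge*
(interrupting two stacked guanines of the same column), a *linker*
(connecting two stacked G4 blocks across a polarity-inverted interface) or
an *overhang*. G4 backbones come in two helical senses: the familiar
right-handed progression and the rarer left-handed one, in which stacked
guanines rotate by roughly 27 degrees anticlockwise per step.

`g4geom` annotates these features from atomic coordinates and quantifies
how a bulge perturbs its neighbourhood: which backbone transition
dihedrals move relative to non-bulged reference structures, and whether
the flanking sugars change pucker. A deterministic generator of idealized
G4 coordinates makes every stage of the pipeline testable without
downloading deposited structures.

## Tetrad detection

Guanines are nodes of a directed graph with an edge i → j when residue i
can donate its N2–H and N1–H to residue j's Hoogsteen face. The
heavy-atom criteria are N2→N7 ≤ 3.5 Å *and* N1→O6 ≤ 3.5 Å. The 3.5 Å
default is the 2.9 Å donor–acceptor equilibrium distance of these bonds
plus a crystallographic tolerance; it is a tunable argument. When the
model contains hydrogens, H21→N7 and H1→O6 must additionally be within
2.5 Å; crystal structures routinely lack hydrogens, so every criterion
must and does work from heavy atoms alone.

Tetrads are directed 4-cycles of this graph whose 36 ring atoms fit a
common plane with out-of-plane RMS below 1.0 Å. When two candidate
cycles share a guanine, the one with the better planarity wins (greedy
resolution); planarity is the natural criterion because tetrad planarity
is what distinguishes a genuine quartet from a coincidental contact
pattern.

## Core assembly, twist and handedness

Detected tetrads whose centroids lie within 6 Å are stacked into a core,
ordered along the principal axis of their centroids. Guanines of adjacent
tetrads are matched into G-columns by the minimum-cost C1′-distance
assignment over all 24 pairings; in idealized and deposited cores the
intra-column C1′ distance (≈ 4–5 Å) is far below the cross-column one
(≈ 7–10 Å), so the assignment is unambiguous.

The stacking axis is oriented 5′→3′ by the majority sequence direction of
the columns. The per-step twist is the mean, over the four columns, of
the signed angle between the C1′→N9 vectors of the stacked guanines,
measured about the local inter-tetrad axis:

twist = atan2( axis · (v₁ × v₂), v₁ · v₂ )

Positive twist is a right-handed step (right-hand rule about the 5′→3′
axis); this sign convention makes a helix's handedness independent of
which end you read it from. Blocks are split where the dot product of
consecutive tetrad normals (oriented by the ring-atom order of the member
bases) goes negative — the opposite-polarity stacking interface. The
handedness call averages the intra-block step twists, excluding
interfaces: below −10° is left, above +10° is right, otherwise mixed.
The ±10° margin is generous against the observed magnitudes (≈ 27–30°)
while rejecting near-zero, ill-defined stacks.

## Structural elements

Non-core nucleotides are grouped into maximal runs connected through the
backbone (same chain, consecutive numbering, O3′–P ≤ 2.5 Å; runs split
with a warning at breaks). Each run is classified from its anchoring core
guanines:

* **bulge** — anchors are consecutive members of the *same* column;
* **loop** — anchors are in different columns of the same block;
* **linker** — anchors are in different blocks;
* **overhang** — an anchor is missing.

A run whose anchors are non-consecutive members of one column is reported
as a linker (it bridges more than one step; no such element occurs in the
systems modelled here). The capping flag marks elements whose base
centroid lies within 4.5 Å of an outer-tetrad plane at a lateral offset
below 4 Å; these thresholds are tunable configuration values — the
literature describes T-capping qualitatively, not numerically.

The local sugar orientation of a residue is its C5′→C3′ vector compared
with the mean C5′→C3′ vector of the nearest tetrad's guanines: parallel
for positive cosine, antiparallel for negative, undefined below |cos| =
0.1.

## Transition angles and the comparison

The transition angles of a backbone step are ε and ζ of the 5′ residue
and α, β, γ of the 3′ residue. A reference profile pools these angles
over every intra-block core step whose guanines are sequence neighbours,
across all reference structures, weighting every step equally (a
configuration switch could average per-structure first; equal pooling is
the default because the reference sets mix crystal structures with very
different numbers of usable steps). Statistics are circular: the mean is
the resultant-vector direction and the spread is √(−2 ln R̄), because the
compared angles sit near the 0/360 wrap.

Around each bulge two records are extracted under the default `"step"`
convention: the *previous* side is the step from the 5′ core guanine into
the first bulge residue, the *next* side the step from the last bulge
residue into the 3′ core guanine. The alternative `"skip"` convention
measures all five angles on the flanking guanines themselves, ignoring
the bulge backbone. The step convention is the default because the five
angles of a record then describe one real phosphodiester linkage;
the choice is exposed because the attribution of "previous/next residue"
angles to specific atoms is genuinely ambiguous in the field's figures.

A deviation is the absolute circular difference to the profile mean,
flagged above 60° (the threshold used by the study this package follows;
it is an argument, not a constant). Raising the threshold can only ever
reduce the flagged count.

## Sugar pucker

The five endocyclic torsions ν₀…ν₄ give the pseudorotation phase by the
Altona–Sundaralingam relation

tan P = ((ν₄+ν₁) − (ν₃+ν₀)) / (2 ν₂ (sin 36° + sin 72°)),

with 180° added when ν₂ < 0. The amplitude is computed in resultant form
τₘ = √(ν₂² + ((ν₄+ν₁−ν₃−ν₀)/(2(sin36°+sin72°)))²), which is exact for
generated torsions and, unlike ν₂/cos P, stable near P = 90° or 270°.
Classes are the ten 36°-sectors of the pseudorotation wheel with
C3′-endo centred at 18° and C2′-endo at 162°.

The *z-deviation* is the signed perpendicular distance of C2′ (or C3′)
from the plane through C4′, O4′ and C1′, with normal
n = unit((C1′−C4′) × (O4′−C4′)). The cross-product order is fixed so
that positive z points towards the C5′/base face of a natural D-sugar:
an ideal C2′-endo sugar then has z_c2 > 0 and an ideal C3′-endo sugar
z_c3 > 0, which is the convention that reproduces the published
positive-versus-negative contrast for bulged right-handed G4s. Note the
orientation of this normal is a package decision — the quantity's
original description leaves it unstated. Two caveats follow from the
geometry: at an exact envelope phase the pivoting carbon of the *other*
envelope lies essentially in the plane (at C2′-endo, z_c3 ≈ 0), so its
sign is numerically meaningless below ≈ 0.02 Å; and C2′ and C3′ sit on
strictly opposite sides of the plane only for phases *between* the two
envelope points (roughly P ∈ (162°, 198°) and its antipode) — elsewhere
on the wheel, O4′-endo most visibly, both carbons pucker to the same
side. The diagnostic content is in the signed values themselves: C2′-endo
cores give z_c2 > 0, and the P ≈ 0 pucker of an altered residue gives
z_c2 < 0, reproducing the published positive-versus-negative contrast.

Mirror reflection negates every torsion, and −cos(P + 144(j−2)) =
cos(P + 180 + 144(j−2)); the pseudorotation phase of a mirrored sugar is
therefore P + 180 (mod 360) — C2′-endo becomes C2′-exo.

## Superposition

Rigid-body superposition uses the Kabsch closed form (SVD of the
covariance with a determinant correction) restricted to proper rotations,
so a reflection can never masquerade as a fit. Atom correspondence is by
(chain, residue number, atom name), optionally restricted by a selector
predicate; the selector is exposed because published "all non-H atoms
excluding the bulges" selections are not fully specified and their
sensitivity should be reportable. Ensemble RMSDs are means over all
unordered model pairs, as used for NMR ensembles.

## The synthetic generator

`g4BuildSpec()`/`buildG4()` construct idealized G4 coordinates with fully
controlled geometry. Defaults describe the four-layer, two-block,
left-handed system with single-thymine propeller loops and a
single-thymine block linker that the package's analyses target: twist
−27° per intra-block step, rise 3.3 Å, C2′-endo sugars (P = 162°,
τₘ = 35°), anti guanines.

**Tetrad.** An idealized guanine (regular-polygon ring geometry, planar
by construction) is placed so that its four-fold rotation copies about
the stack axis close the cyclic Hoogsteen pattern with N2→N7 = N1→O6 =
2.9 Å exactly; among the two exact-solution branches the one with the
realistic N9 radius (≈ 6.8 Å) is kept, and the placement is solved once
and cached.

**Sugars and chirality.** Rings are embedded from (P, τₘ) by solving the
three free bond angles of a fixed-bond-length five-ring against the five
Altona–Sundaralingam torsions. Because a five-ring with fixed bonds has
only four internal degrees of freedom, the five torsion targets are
satisfiable only to a sub-degree residual (the closure bond itself is
enforced to < 10⁻³ Å); the annotation round-trip recovers P and τₘ well
within 0.5°. Base attachment uses fixed valence geometry at C1′ with the
chirality of natural D-deoxyribose (verified against an ideal
deoxyguanosine residue from the chemical component dictionary), and C5′
is placed on the base face of the ring.

**Backbone.** Within a column, stacked guanines are joined by placing
O3′, P and O5′ from three free spin torsions optimized against the O3′–P
bond (1.607 Å), the ester angles, and optional soft step-torsion
targets. A geometric fact shapes two defaults here: with natural
D-sugars and C2′-endo pucker, the inter-guanine phosphodiester closes at
rise 3.3 Å only for right-handed steps near χ = 240° and for left-handed
steps at high-anti χ ≥ ≈ 285°. The builder therefore defaults χ to 290°
for left-handed twists and 240° for right-handed ones (both inside the
anti range), which is the generator's counterpart of the "twisted"
backbone that distinguishes real left-handed G4s. For the same reason
face-up blocks thread each column 5′→3′ top-to-bottom, and
polarity-flipped blocks are woven the way deposited left-handed blocks
are: enter the first column at its top, run the remaining columns
bottom-to-top, and exit through the entry column's bottom guanine — the
one column pair with no direct backbone link. This also means flipped
blocks are restricted to at most two tetrads, exactly as in the deposited
left-handed structures the generator emulates.

**Bulges.** A bulge thymine is placed forward from its 5′ guanine by the
five transition torsions (ε, ζ, α, β, γ) — they are therefore realized
*exactly* — with the remaining O3′ spin chosen to project the base
radially out of the core (≥ 6.5 Å). The 3′-side linkage is then closed
with soft targets at the core-step baseline, so the uncontrolled next-side
angles stay near the reference values. The default bulge torsions offset
α by +90° and β by −70° from the core-step baseline: the offset
magnitudes mirror the alterations observed around left-handed bulges, and
this sign combination is the one that closes the backbone while pointing
the base outward.

**Loops, linkers, overhangs.** Loop-like thymines are placed outside the
core and refined as rigid bodies against both linkage anchors with a
clash penalty before closure. Block junctions enter the next block at the
spatially closest column slot, keeping linkers short.

**Noise and determinism.** Optional isotropic Gaussian noise is applied
last under the spec's seed, with the session RNG state restored
afterwards; the same seed gives bit-identical coordinates.

**What the generator does not emulate** — and hence what passing tests do
not establish about deposited structures: thermal and ensemble
variability beyond isotropic noise, ions and solvent, realistic loop
conformations and T-capping geometry (synthetic loops project outward, so
the capping flag is exercised only at its thresholds), hydrogens,
sequence-dependent fine structure, and any energetics. The generator is a
geometric fixture factory, not a model builder.

## Numerical choices

* All torsions live in [0, 360) (matching how the field reports χ and P
  windows); signed quantities (twist, z-deviation) keep their natural
  signed ranges.
* Optimizations (tetrad placement, ring embedding, linkage closure, loop
  pose) use deterministic multi-starts; no randomness outside the seeded
  noise.
* The syn/anti boundary is χ ∈ (170°, 310°) → anti: the anti restraint
  window 240 ± 70° turned into a closed decision rule.
* Degenerate inputs error informatively (coincident/colinear torsion
  points, planar rings, missing atoms per angle rather than per residue).

## Problem sizes

The test-suite and acceptance script work at sizes chosen to exercise
every code path while staying comfortably interactive: two- to four-layer
cores (8–16 core guanines, 25–30 nucleotides), 10-model noisy ensembles,
20–100 noise replicates per robustness rate, and 200–500 random cases per
oracle comparison.

## Known limitations

* Left-handed building requires high-anti χ; a left-handed spec with
  χ forced to 240° will leave stretched backbone linkages (reported via
  the O3′–P distances) rather than failing.
* The run-splitting warning and classification around backbone breaks are
  exercised synthetically; deposited structures with chain breaks inside
  elements may need the `bondCutoff` argument relaxed.
* Zero-nucleotide loops (a bare phosphate connecting two columns) are
  representable in the taxonomy but not constructed by the generator.
* mmCIF writing emits a minimal single-model `atom_site` loop — enough
  for round-tripping coordinates, not a full PDBx document.
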