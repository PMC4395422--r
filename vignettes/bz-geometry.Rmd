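---
title: "Geometry of mismatch-induced B-to-Z transitions: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometry of mismatch-induced B-to-Z transitions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bzjunction)
```

`bzjunction` analyses DNA duplex geometry with one organising question: when
an A···A mismatch sits among canonical pairs — as it does at every third
position of a CAG-repeat hairpin stem — where and how does the helix leave
B-form? This vignette records the package's scientific conventions: the
observables, the classification grammar, the synthetic constructions, the
numerical choices, and the limits of what the idealized geometry can show.

## Observables

**Torsions.** Backbone torsions follow the standard nucleic-acid chain
definitions (α through ζ, plus glycosyl χ), reported in [0°, 360°);
negative notations such as −38° are accepted on input and reduced mod 360.
α is undefined for 5′-terminal residues and ε/ζ for 3′-terminal residues;
those entries are `NA`, and missing atoms elsewhere warn rather than fail.

**Helical twist.** Because a global helix axis is meaningless across a B–Z
junction, twist is computed per step from the C1′···C1′ vectors of the two
flanking pairs: the step axis `h` is the unit vector between the pair
midpoints, and the twist is the signed angle between the pair vectors
projected onto the plane perpendicular to `h`, positive for right-handed
rotation. Two consequences are worth knowing. First, the measure is
invariant under any global rigid motion. Second, the axis direction flips
when the two pairs are swapped, so the twist of a step is identical viewed
from either end — a screw looks equally right-handed from both ends. When a
sign comparison across traversal directions is wanted, `c1c1_twist()`
accepts an explicit fixed `axis`, and with a fixed axis swapping the pairs
negates the twist.

**Groove widths.** Raw cross-strand phosphate distances with offsets
−3 (minor) and +4 (major) relative to the partner position, no van der
Waals subtraction. The offsets are this package's convention, stated in
every output header; absolute groove values from other conventions are not
comparable and the package makes no claim that they are.

**RMSD and averages.** Least-squares (Kabsch) superposition before the
deviation; the default selection is all heavy atoms, with an
`exclude_termini` count for suppressing end fraying (set it to 2 to ignore
the terminal two pairs). Average structures superpose each frame onto the
first frame of a half-open time window `[start, end)` in ps — half-open so
frame counts are unambiguous.

## Classification grammar

All bins are half-open `[lo, hi)` so every angle has exactly one class and
boundary values fall upward deterministically.

| class | range (deg) |
|---|---|
| cis | [345, 15) |
| +syn | [15, 100) |
| unassigned | [100, 170) |
| anti | [170, 260) |
| high-anti | [260, 290) |
| −syn | [290, 345) |

The anti range quoted in the B/Z literature is 180–270°; the edges here are
deliberately recalibrated so that the representative values that recur in
CAG-mismatch work each land in their named class: 250° anti, 79° +syn,
309° −syn, 287° high-anti. The lower anti edge sits at 170° because anti
populations centred near 250° fluctuate tens of degrees and an edge at 180°
would shear such a population in two. 287° is sometimes written
"high-anti/−syn"; the package reports high-anti and leaves the ambiguity to
the occupancy tables rather than inventing an overlap class. Both bin sets
are exposed in `pipeline_config()` (`chi_bins`, `well_bins`).

Backbone wells are g⁺ [0°,120°), t [120°,240°), g⁻ [240°,360°). A step's
(ε, ζ) come from its 5′ residue and (α, γ) from its 3′ residue, matching
the convention that attaches a step label like A\_8G\_9 to the 3′ G. The
(ε,ζ,α) triple maps to BI (t,g⁻,g⁻), BII (g⁻,t,g⁻) or BIII (g⁻,g⁻,g⁻); the
(ε,ζ,α,γ) quadruple maps independently to ZI (g⁻,g⁺,g⁺,t), ZII
(g⁻,g⁻,g⁺,t) or ZIII (g⁻,g⁻,g⁻,g⁺). BIII and ZIII share a well pattern and
may co-occur by design.

## Step labels, junctions, events

A step is labelled **Z** when its twist is below `t_z_deg` (default 15°)
*and* at least one conformational clause holds: a Z signature, a BIII
family, or a step purine in the −syn/+syn/high-anti χ class. The 15°
threshold separates the two twist populations that bracket it in the
B/Z-context literature (Z-context steps print −4° to 12°, B-context steps
28–39°); it is a calibrated convention, exposed in the configuration. After
run formation, the boundary step of each maximal B-run adjacent to a Z-run
is relabelled **junction** — junctions are step-scale features (a low twist
adjacent to a high twist), not zero-width marks. Per-window labeling uses
circular means of torsions and plain means of twist over the window before
classification.

Event rules, each with its thresholds in `pipeline_config()`:

* **Hydrogen-bond registry**: candidate donor–acceptor atom pairs per pair
  type (for A···A: N1···N6, N6···N1, N6···N7, N7···N6, N3···N6, N6···N3)
  with a 3.4 Å heavy-atom cutoff and no angle term, since distance profiles
  are what trajectory monitoring provides.
* **Base flipping**: the χ series is unwrapped on the circle; a flip is a
  net change of at least `flip_min_deg` between stable endpoints, and its
  pathway is *cis* if the path crosses 0° and *trans* if it crosses 180°.
  The default is 100° rather than a nominal 120°: the canonical
  +syn(79°) → −syn(320°) transition via the cis pathway is a net −119° and
  a textbook 60° → 320° flip is −100°, so a 120° gate would reject flips it
  is meant to catch.
* **Base extrusion**: conjunction of registry loss (`"none"`) and a
  base-centroid lateral displacement above 2.5 Å from the line joining the
  flanking pair midpoints, sustained for at least 5 frames. Because even an
  intact stacked base sits a few Å from that line, trajectory displacement
  is measured relative to a reference frame; the raw variant is available.
  The conjunctive rule is the strict reading — a displacement-only variant
  can be emulated by setting the cutoff negative.
* **Intercalation**: near-parallel mismatched bases (interplanar angle
  < 30°), stacked (centroid separation < 4.5 Å), with the mismatch
  C1′···C1′ vector rotated more than 60° from the mean flanking pair
  vector.

## Base-pair nonisomorphism

Two pairs are compared by superposing one base of each (the anchor — the
shared nucleotide type where possible, else the strand-1 purine) over their
common ring atoms plus C1′, then measuring the angle between their
C1′···C1′ vectors projected onto the anchor base plane (**residual twist**)
and the absolute difference of their C1′···C1′ lengths (**radial
difference**). The anchor base plane, not a mean plane, is the projection
reference so the measure stays deterministic under propeller distortion.

The modeled A···A pairs deserve their own paragraph, because the
construction is genuinely under-determined: coplanar idealized bases with
one declared 2.9 Å hydrogen bond leave two rigid-body degrees of freedom
unfixed, and the reported measures depend on them. The package resolves
this the way restrained model building does. Both adenines start at the
Watson–Crick scaffold positions (where two purines overlap sterically);
each base may swing in-plane about its glycosidic nitrogen with C1′ fixed;
the partner residue frame may rotate and translate against a harmonic
restraint; and the energy combines the declared hydrogen-bond distance, a
soft per-element van der Waals exclusion (0.93 × radius sum, with 1–3
neighbours of the bond exempt) and the swing/frame restraints. The
stiffnesses are package constants chosen at physically conventional
magnitudes; across a four-fold range of each the results move by under 2°
and 0.2 Å, so the outcome is pinned by the clash geometry, not by tuning.

What this construction shows, and what it cannot. The radial signature of
the two glycosyl configurations emerges cleanly: the anti···anti pair must
open radially to relieve its head-on N1/N1 overlap (C1′···C1′ ≈ 12.3 Å,
≈1.5 Å beyond Watson–Crick), while the +syn···anti pair relieves its
lateral clash by shear and keeps near-Watson–Crick dimensions (radial
difference ≈ 0.3–0.4 Å). The residual twists come out at roughly 8°
(anti···anti) and 11° (+syn···anti): a clear, same-sense in-plane offset,
but smaller than the ~16° measured on fully three-dimensional,
crystal-structure-derived mismatch models. A planar, coplanar-base
idealization cannot encode the propeller and inherited shear of those
models, and the package reports what its own construction yields rather
than targeting the literature value; treat the twist magnitudes as
lower-bound indicators and the radial differences as quantitatively
meaningful.

## Synthetic structures and trajectories

The builders exist so that every detector has a ground truth. They are
first-class, tested code, and their defaults are the package's declared
study conditions.

**Fiber construction.** Each residue is a rigid unit in a local pair
frame: a planar base template (standard reference frame, harmonized so C1′
and the glycosidic nitrogen coincide across bases), plus sugar-phosphate
atoms grown by internal coordinates. χ, β, γ, δ are prescribed exactly;
three sugar-orientation torsions per helix class are solved once by a
deterministic least squares so that the emergent inter-residue α, ε, ζ
land in the intended wells and the O3′–P virtual bond closes near 1.6 Å
(residual closure error is accepted — the analysis reads torsions and
positions, not chemistry). Pairs are centred so the C1′···C1′ midpoint
lies on the helix axis, which makes the measured per-step twist exactly
the construction parameter. B-form uses 36°/step and 3.38 Å rise,
all-anti; Z-form uses the standard fiber dinucleotide repeat, −9° steps
into purines and −51° into pyrimidines at 3.7 Å rise, syn purines
(χ = 60°) and ZI backbone targets. Watson–Crick donor–acceptor distances
come out at 2.8–3.0 Å.

**Mismatch embedding.** At a declared mismatch position the strand-2
partner becomes an adenine whose base is placed by the restrained
pair construction above, expressed in the strand-1 residue's frame, with
its backbone regrown from the placed base.

**Trajectories.** `make_bz_trajectory()` emits frames in which a chosen
window of steps switches from B to Z geometry in stages (each frame is a
mosaic of fully-B and fully-Z stretches — the stepwise, zipper-like picture
of the transition), with optional scripted events: glycosyl flips along a
chosen pathway (which persist once complete) and extrusion excursions
(which revert). Finally i.i.d. Gaussian noise of standard deviation
`noise_sigma` is added per coordinate. Truth labels mark window steps Z and
their B neighbours junction. A single integer seed drives all randomness;
identical seeds give bitwise-identical output.

What the generator does *not* emulate: solvent and ions, sequence-dependent
step-parameter variation, sugar repuckering, correlated thermal motion, and
continuous (non-mosaic) B↔Z interconversion. Passing recovery tests on
these plants therefore demonstrates that the detectors read their defining
geometric signatures correctly and degrade gracefully under independent
coordinate noise (σ up to 0.3 Å is exercised) — not that they are
calibrated for force-field trajectories, whose noise is neither isotropic
nor independent.

**Problem sizes.** The test suite and examples run 6–18 bp duplexes and
4–20 frame trajectories, which exercise every code path; all operations
scale linearly in atoms × frames and the pipeline is routinely used on
hundreds of frames.

## Numerical choices and degenerate inputs

* Dihedral signs follow the IUPAC polymer convention; the implementation is
  property-tested against an independent plane-normal oracle and
  cross-checked against `bio3d::torsion.xyz`. Colinear triples raise an
  explicit undefined-dihedral error rather than returning an arbitrary
  angle.
* Twist is undefined for coincident pair midpoints and for pair vectors
  parallel to the step axis; both raise errors.
* Superposition uses SVD with a determinant guard, so reflections are never
  silently returned.
* RMSD ensemble segmentation splits greedily at the point of maximal mean
  separation, accepts a split when |Δmean| exceeds max(0.5 Å, pooled sd),
  and merges segments shorter than `min_dwell` into the closer neighbour —
  a deliberately simple change-point rule whose null behaviour (one
  segment on flat series) is tested.
* The trajectory frame spacing defaults to 0.1 ns when no sidecar time file
  is given, matching common reporting granularity; it is a convention, not
  a measurement.

## Known limitations

* Planar bases throughout: no propeller, buckle or sugar pucker, hence the
  conservative residual-twist magnitudes discussed above.
* Hydrogen bonds are distance-only; no angular term, no bifurcation logic.
* The step-label rule is intentionally rule-based and threshold-explicit;
  it does not learn bins from data and will misclassify geometries far from
  both fiber archetypes.
* `read_structure()` handles one duplex of standard deoxynucleotides per
  file; modified bases, triplexes and quadruplexes are out of scope.
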