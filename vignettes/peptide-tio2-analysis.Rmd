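---
title: "Methods: sequence effects in peptide adsorption on anatase TiO2 (101)"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence effects in peptide adsorption on anatase TiO2 (101)}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`surfpep` analyses molecular-dynamics trajectories of hexapeptides at a
hydroxylated anatase TiO2 (101) surface. This vignette documents the
models and procedures it implements, the parameters that matter, the
design choices made where the design was genuinely open, and what the
synthetic-data validation does and does not demonstrate.

## The binding coordinate and its state model

The binding coordinate is the surface separation distance (SSD): the
z-distance between the mass-weighted peptide centre of mass and the mean
z-plane of the outermost titanium layer, minimised over the two slab faces
under periodic wrapping. Both faces of a symmetric slab are physically
equivalent, and a peptide that drifts across the solvent half-box binds
the periodic image of the opposite face, so the two-face minimum is the
correct coordinate; its maximum, half the solvent height, is the
geometrically largest separation a peptide can reach. The outer Ti layer
is identified geometrically — all Ti within `layer_tolerance` (default
0.05 nm) of the extreme Ti z on each face — rather than by atom naming,
because slab models carry no standard residue nomenclature.

A frame is *bound* when SSD < 1 nm, strictly; `SSD >= 1 nm` is unbound.
The binding fraction (percent of bound frames over the analysed window)
ranks the peptides, descending, with lexicographic tie-break. The
conformational coordinate is the end-to-end distance (EED) between the
Cα atoms of residues 1 and 6, summarised separately over bound and
unbound frames. Standard deviations of these summaries are population
SDs (divide by N): the series are dense descriptive time series, not
independent samples; a `sd_type = "sample"` switch is provided. No
debouncing of threshold flicker is applied by default
(`min_dwell_frames = 1`); when enabled, interior runs shorter than the
dwell are merged into the surrounding state, shortest first.

The centre of mass is mass-weighted over *all* peptide atoms. Before any
COM or EED computation the peptide is made whole by a breadth-first
traversal of its bond graph, placing each atom at the minimum image of
its bonded neighbour; a bond longer than 0.25 nm after unwrapping is
treated as a broken molecule and is an error. Analyses require
orthorhombic boxes; triclinic input is rejected at the frame boundary.

## Sequence library and motif statistics

The library is every distinct ordering of the residue multiset
{R, K, L, P, D, A} (720 permutations for six distinct letters), in
lexicographic order. A sequence and its reversal contain the same
residues in opposite order; although an uncapped zwitterionic peptide is
not symmetric under reversal, the two are treated as one composition
class and a single member retained (360 classes). The default keeps the
lexicographically smaller member — a deterministic rule — and a
`keep_list` policy reproduces any other published choice of
representatives; validation rejects lists that miss a pair or contain
both members. Strong binders are selected by *strictly* more than a
threshold (default 50%) of bound frames.

Motif statistics count adjacent (not gapped) windows of length 2 or 3.
Ordered mode counts XY as written; order-agnostic mode merges XY and YX
under the alphabetically sorted key. Position scopes restrict window
starts (all; interior positions 2–5; the N-terminal start; the C-terminal
start), and positional tables count (motif, 1-based start) jointly. All
motif operations are checked against an independent brute-force window
scan in the test suite.

## Conformational clustering

Bound-state frames are clustered with the GROMOS neighbour-count
algorithm at an RMSD cutoff of 0.15 nm: among unassigned frames, the one
with the most neighbours within the cutoff (a frame neighbours itself;
ties go to the lowest frame index, for determinism) seeds a cluster; it
and its neighbours are removed; repeat. Cluster sizes are non-increasing
by construction and singletons are allowed. RMSDs use least-squares
(Kabsch) superposition with a proper rotation enforced (determinant +1),
so mirror images are *not* matched; superposition is unweighted by
default with an optional weight vector. The default selection is peptide
heavy atoms: hydrogen positions under bond constraints add noise without
information. Fitted RMSD is not a metric (no triangle inequality), which
is why clustering consumes the full pairwise matrix rather than any
indexing structure. Frames may be strided before the O(n²) matrix; the
reports carry the retained frame ids and original timestamps, and the
cluster summary reports clusters above a strict 10% population floor with
their mean SSD/EED and the centre frame's timestamp.

## Radial distribution functions

g(r) between a peptide selection A and surface-oxygen selection B is the
minimum-image pair-distance histogram normalised by
`N_A_total · 4πr²Δr · ρ_B` with ρ_B the whole-box density of B (the
GROMACS convention). In slab geometry no normalisation makes g(r) → 1 —
the B atoms are not homogeneously distributed — so peak *positions* are
the meaningful, convention-independent observable; raw pair counts are
retained in every result so any other normalisation can be applied after
the fact, and peak heights are not compared across conventions. Defaults:
bin width 0.002 nm, range 1.2 nm (must remain below half the smallest box
edge). First-peak extraction returns the global maximum of g over
(0, 0.4 nm] — 4 Å, the reporting window for direct surface contacts — and
flags when the full-range maximum lies beyond the window.

The conditional RDF restricts the A selection, per frame, to Na⁺ ions
simultaneously within 3 Å of at least one surface oxygen (OB or OF — the
criterion names both types) and within 3 Å of at least one peptide oxygen
(backbone carbonyl, carboxylate, or sidechain oxygen; the terminal
carboxylate counts). The filter is instantaneous — the bridging set
changes every frame — and the default normalisation divides pooled counts
by the summed per-frame filtered counts, so frames with no bridging ion
contribute zero counts and zero A-particles; with this convention an
always-true filter reproduces the unconditional RDF bin-for-bin. A
per-frame renormalisation (averaging per-frame g over frames with a
nonempty filter) is exposed as an alternative.

## The anatase (101) slab

The slab is cut from the anatase lattice (tetragonal, a = b = 0.37845 nm,
c = 0.95143 nm, oxygen parameter u = 0.2081) after re-basing the cell on
the lattice vectors (A − C, B, A) — a unimodular transform whose first
two vectors span the (101) plane, giving surface periods of 1.0239 and
0.37845 nm. The termination is a flat cut in the fractional stacking
coordinate at shift 0.375: a scan of the shift shows that any value in
[0.25, 0.50] cuts between trilayers, yielding the natural stoichiometric
termination whose Ti are exclusively 5-coordinated (exposed rows) or
6-coordinated (bulk). `n_layers` counts repeats of the stacking vector;
each repeat is one corrugated TiO2 double-row, 0.3517 nm of thickness.
The reference system replicates 5 × 13 surface cells and 9 stacking
repeats: 2340 Ti, 4680 O, 4.92 × 5.12 nm lateral, 3.05 nm thick, with 260
five-coordinated Ti. (Counted as Ti *atomic* z-levels this slab has 18
layers in 9 corrugated double-rows; the repeat count is the convention
used throughout because it is the builder's replication unit and fixes
both thickness and composition consistently.)

Hydroxylation draws `round(fraction × N_5c)` sites (round-half-to-even,
for determinism) uniformly without replacement from the 5-coordinated Ti
of the selected face(s), reproducibly from a seed, and places O–H along
the outward normal at Ti–O 0.18 nm and O–H 0.098 nm. These positions only
feed the geometric OF/HF classification — no energetics are computed — so
idealised bond geometry suffices. Both faces are hydroxylated by default.
The surface charge report is the closed form q·N_OH/A per face; the
effective per-hydroxyl charge is an input, not a hard-coded constant,
because it belongs to a force-field parameterisation that is out of scope
here. At 30% coverage the reference slab carries 78 hydroxyls, and a
per-OH charge of about −0.4 e reproduces the experimental −0.62 e/nm² at
neutral pH.

## What the synthetic generator emulates — and what it does not

The generator plants ground truth for every analysis stage: a
discrete-time two-state Markov chain (defaults: bind 0.08, unbind 0.02
per frame, stationary bound probability 0.8) drives the bound/unbound
sequence; bound-frame SSD is drawn from a truncated normal (mean 0.7 nm,
sd 0.1, support (0, 1)) and *imposed exactly* by translating the peptide
COM above a uniformly chosen face, making the SSD implementation testable
to machine precision; unbound SSD is uniform between 1 nm and half the
solvent height. Conformations come from rigid templates with prescribed
EEDs (0.65 and 1.40 nm, used 70/30 in the bound state and 30/70 unbound)
plus isotropic 0.01 nm jitter — small enough that within-template RMSD
stays far below the 0.15 nm cutoff while the templates sit well above it.
Bound frames plant an exact 0.28 nm contact between the first sidechain
nitrogen and a hydroxyl oxygen whenever the geometry admits one (the
anchor sidechains point at the surface, so most bound frames qualify),
and with probability 0.9 a bridging Na⁺ exactly 0.23 nm from the ASP
carboxylate oxygen and within 3 Å of a surface oxygen; the remaining ions
are decoys kept in bulk solvent where the surface criterion must fail.
Frames are wrapped on output so unwrapping is always exercised. Discrete
per-frame kinetics (rather than continuous time) match the analysis unit,
which is the frame.

The generator does *not* emulate solvent, energetics, realistic backbone
dihedrals, surface relaxation, or gradual conformational interconversion.
Passing the validation therefore demonstrates that the analysis chain
recovers known geometric and kinetic structure exactly and without bias —
not that it would extract the same numbers from force-field trajectories
whose states are less cleanly separated.

## Problem sizes and tolerances

The fixed-seed validation benchmark uses 2000 frames on a 3 × 7 × 3 slab
(about 870 atoms), chosen so the full chain — profile, clustering of up to
500 strided bound frames, RDFs — completes in seconds while leaving the
statistical checks meaningful. The binding-fraction check uses the
autocorrelation-corrected effective sample size
`n(1−ρ)/(1+ρ)` with ρ the chain's lag-1 autocorrelation
(1 − p_bind − p_unbind), and a 3-SE band; cluster populations are checked
within 5 percentage points of 70/30; RDF peaks must fall in the bin
containing the planted distance (±0.002 nm). GROMOS clustering is checked
for exact equality against an independent brute-force neighbour-count
oracle on random matrices up to 300 frames; Kabsch RMSD against a
quaternion (Horn) oracle at 1e-10; RDF normalisation against the
analytic ideal-gas limit (g = 1 within 2% over 0.3–0.5 nm, with bins wide
enough that counting noise sits well inside the band).

## Conventions and known limitations

* Units are nm and ps internally; PDB Å are converted at the boundary,
  and the 3 Å / 4 Å criteria appear as 0.3 / 0.4 nm defaults.
* Atom indices are 1-based throughout, following R convention; residue
  positions in reports are 1-based as well.
* Coordinates are stored wrapped as read; unwrapping is an explicit,
  validated operation rather than a reader side-effect.
* Structure formats: GRO and PDB (read/write). Trajectories: multi-frame
  GRO (read/write) and DCD (read, box supplied separately). XTC is not
  read: no R-level reader is available, and the multi-frame GRO path
  covers the same role at 0.001 nm text precision.
* The surface is treated as rigid: atom classes are resolved on the first
  frame of a trajectory. Trajectories with mobile surface atoms would
  need per-frame classification.
* Binding kinetics are reported descriptively (event lists, dwell
  counts); no rate-model fitting, free-energy estimation, or enrichment
  testing is performed.
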