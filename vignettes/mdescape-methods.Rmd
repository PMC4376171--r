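---
title: "Methods: multi-copy ligand escape analysis and its synthetic test bed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-copy ligand escape analysis and its synthetic test bed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Globins are "closed bottles": the crystal structure shows no permanent
tunnel from the buried heme to solvent, so a dissociated O~2~ must exploit
structural fluctuations — transient packing defects, internal cavities
(the xenon-binding Xe pockets, the distal B site), and gaps that open
between helices — to leave the protein. Locally enhanced sampling (LES)
molecular dynamics multiplies the number of observed exit attempts by
propagating *N* non-interacting ligand copies that feel the rest of the
system at a scaling factor of exactly 1/*N* (for the dimeric hemoglobin
setting that motivated this package: 14 copies, 7 per subunit, over a
10 ns production run). The raw product of such a simulation is a
trajectory; the scientific result — *which portal each copy used, which
cavities it visited, whether it crossed the subunit interface, and how
persistent the interfacial water network is* — is post-processing. That
post-processing is what `mdescape` implements, as a tested, reusable
pipeline rather than a visual inspection.

## The analysis model

**Surface criterion.** The "protein surface" is operationalized as the
minimum Euclidean distance from the ligand-copy geometric center to any
protein heavy atom. An *escape* is the first frame at which this distance
exceeds a threshold (default 5 Å) and remains above it for at least
`persistence` consecutive stored frames (default 10) or through the end of
the run. The persistence rule suppresses boundary flicker that a visual
analysis would never count as an exit; it is exposed as a parameter
because no published value exists for it. A consequence we test as an
invariant: raising the threshold can never produce an *earlier* escape.

**Portal classification.** At the last interior frame before the escape,
the minimum atom distance from the copy center to each annotated helix of
the copy's current chain is computed. The portal is the alphabetized pair
of the two nearest distinct helices ("B-G", never "G-B"; ties broken by
(distance, label)); a declared *corner* pseudo-region that is the single
nearest feature yields `corner:<XY>`; if the nearest protein atoms belong
to the opposite chain the label is `interface`; if no helix lies within
`classify_bound` (default 10 Å) the event is `unclassified` rather than
guessed.

**Cavities.** Cavities are declared, not discovered: each is a named set
of lining residues plus a cutoff (default 4.5 Å). Because cavities deform
and drift with the protein over nanoseconds, membership is measured
against the *per-frame* centroid of the lining residues' heavy atoms. A
frame belongs to the nearest cavity within its cutoff (exact ties:
alphabetical), and the `last_cavity` of an escape is the label of the
latest occupied frame before the event.

**Subunits, crossings, interface residence.** Each frame's subunit
assignment is the chain of the nearest protein atom, or `interface` when
the two chains' nearest-atom distances differ by less than an ambiguity
margin (default 1.5 Å). A crossing is a chain change whose new chain
persists for `dwell` frames (default 25); a confirmed return sets
`returned = TRUE` on the same event. A copy that never escapes and ends
the run in a terminal interface stretch of at least `dwell` frames is an
*interface resident*. Every summary obeys the accounting identity
portal counts + interface residents + non-escapers = copy count, enforced
at construction.

**Interfacial waters.** A water is interfacial when its oxygen is within
`d_int` (default 4.0 Å) of protein heavy atoms of *both* chains — the
dual-proximity reading of "sandwiched between the subunits". Persistence
is tracked by residue identity, so exchange with bulk counts against it;
`residence_min = 1` realizes "stayed in the interface throughout".
Hydrogen bonds use the conventional geometric criterion (heavy-atom
distance ≤ 3.5 Å and donor–H⋯acceptor angle ≥ 150°, both recorded in the
output); topologies without hydrogens fall back to distance-only and flag
it.

## Parameter summary

| parameter | default | unit | why |
|---|---|---|---|
| `threshold` | 5.0 | Å | published escape criterion (distance from the protein surface) |
| `persistence` | 10 | stored frames | flicker suppression; no published value, exposed |
| `window` | 20 | frames | lookback for the last interior frame |
| `dwell` | 25 | stored frames | confirmed subunit residence; no published value |
| `interface_margin` | 1.5 | Å | subunit ambiguity band defining "interface" |
| `classify_bound` | 10 | Å | beyond this, portals are `unclassified`, not guessed |
| cavity `cutoff` | 4.5 | Å | centroid-membership radius of a declared cavity |
| `d_int` | 4.0 | Å | dual-proximity interfacial-water rule |
| `d_hb`, `angle_min` | 3.5 Å, 150° | — | conventional geometric H-bond |
| `residence_min` | 1.0 | fraction | "throughout the simulation" |

The shipped HbI annotation (helix ranges A–H per chain, an FG corner, and
B/Xe1/Xe2/Xe4 lining residues) is a *reconstructed default*: the source
literature names anchors (His69 on E, Phe97 on F, Ile25 on B ↔ Xe4,
Ile114 ↔ Xe2, Val121/Ser124/Lys125 on H) but never prints full ranges, so
the file is data, clearly marked replaceable, and only the anchor
memberships are asserted by tests.

## What the synthetic generator emulates — and what it does not

`build_toy_system()` constructs a stated world in which every analysis
answer is known exactly: two ~360-atom pseudo-protein shells (radius 15 Å)
facing each other across a 4 Å interface gap; eight compact helix arcs per
chain laid out so that the wild-type portal mix (B-G, E-F, B-E, C-G) is
geometrically realizable, plus an FG corner; four interior cavities with
explicit lining pseudo-residues; an interior scaffold so the
minimum-distance surface is well defined everywhere inside; 14 two-atom
ligand copies (7 per chain); and scripted waters — a 17-molecule
interfacial cluster (12 permanent + 5 transient at 60% residence,
mirroring the published 17-water interface cluster) plus bulk beads.

`script_trajectory()` moves each copy along smooth keyframe paths through
its cavity itinerary to its scripted outcome. Escaping copies cross the
5 Å criterion *exactly* at their scripted frame (the exit radius is solved
per direction against the actual atom geometry, with ±0.4 Å guard bands);
exit routes leave the last cavity radially and swing at a radius outside
every cavity cutoff, so the scripted `last_cavity` is unambiguous.
Scripted exits are only accepted for portals the layout supports: the
generator verifies, at the solved last-interior radius, that the
classification geometry names exactly the requested label with ≥ 1.2 Å
margin against the next feature — `feasible_portals()` enumerates the
supported set, and infeasible requests error rather than silently
misplacing an event.

The generator is geometry only. It emulates *event structure* — cavity
visits, portal exits, interface crossings, water residence — with optional
i.i.d. Gaussian positional noise (ligands and waters by default; a flag
jitters the shell to exercise per-frame centroids). It does **not**
emulate forces, solvent, protein flexibility beyond jitter, correlated
motion, or periodic boundaries. A green recovery test therefore
establishes that the *analysis* is correct and noise-tolerant on data
whose answer is known; it does not establish anything about a real MD
trajectory beyond format and contract compatibility (which the PSF/DCD
round-trip tests and an MDAnalysis cross-check cover).

## The LES toy simulator

`simulate_les()` is a BAOAB-splitting Langevin integrator (kick / drift /
Ornstein–Uhlenbeck / drift / kick; reduced units, k~B~ = 1) over point
copies in a radially symmetric cage: a Gaussian well, a spherical Gaussian
barrier ridge, optional portal depressions on the ridge, optional tethered
environment particles with a softened inverse-12 repulsion, and an
optional uniform field for closed-form checks. The one contract it exists
to embody is the LES scaling: copies never interact with each other, and
every copy–environment interaction (cage included) is scaled by exactly
1/*N*, with the reaction summed over copies on the environment side.
Consequences tested: the *N* = 1 run is bit-identical to a plain unscaled
Langevin reference given the same seed; coincident copies superpose
linearly; forces match a scalar pair-sum oracle to 1 × 10⁻⁹; and the
median first passage of the best of 14 scaled copies is never slower than
a single unscaled ligand — the order-statistics heart of why LES sees
escapes a plain run would miss. All particles share one uniform
thermostat (whether the original engines thermostatted copies separately
is not documented; the choice is stated here and verified to hold the
target temperature within 5%).

Numerical choices: default timestep 0.005 in reduced units (stability
bound ω·dt ≪ 1 for the stiffest default curvature); with friction and
temperature zero the integrator reduces to velocity Verlet and the energy
drift over 4 000 steps is bounded below 0.5%; divergence beyond a box
bound aborts with an error rather than returning nonsense.

## Design decisions that were genuinely open

* **Surface = minimum heavy-atom distance**, not SASA: cheap, unambiguous,
  and faithful to a distance-from-surface criterion; a SASA-based surface
  would change absolute distances but not the event structure.
* **1-based frames** throughout, matching R convention; all reported
  frame numbers refer to stored frames.
* **Portal labels are unordered alphabetized pairs** with deterministic
  tie-breaks, so counts are reproducible run to run.
* **Declared cavities** rather than automatic detection: the scientific
  claims being reproduced are about named pockets; discovery would add a
  second, unvalidatable inference layer.
* **Deposited-trajectory criteria**: the published per-portal counts and
  the F97V water count can only be checked against the authors' deposited
  DCD/PSF dataset, which cannot ship inside a text-only package. The test
  suite contains both checks; they run when the files are placed under
  `tests/testthat/deposited/` and fail (honestly, with instructions)
  otherwise. Because window/persistence choices behind the authors'
  visual classification are unstated, the real-data test also reports a
  persistence sensitivity sweep (1/5/10/25 frames).

## Known limitations

* No periodic-boundary handling beyond orthorhombic minimum-image when a
  DCD carries a unit cell; the deposited-style inputs analyzed here are
  whole-molecule centered.
* The H-bond donor model attaches hydrogens by residue and proximity, not
  by bond topology (PSF bond records are not parsed); for waters this is
  exact, for protein donors it is an approximation.
* The toy layout supports a specific feasible portal set (including every
  pair reported for the wild type); pairs whose arcs are not adjacent on
  the toy sphere are rejected, not approximated.
* Escape-frame recovery is guaranteed only to within the persistence
  window under noise, by construction.
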