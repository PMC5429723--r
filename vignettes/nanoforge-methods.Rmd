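---
title: "Building and analysing polysaccharide-coated nanoparticle models with nanoforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and analysing polysaccharide-coated nanoparticle models with nanoforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

nanoforge builds atomistic starting structures for simulations of
polysaccharide-coated iron-oxide nanoparticles at lipid membranes, and
provides the analysis formulas used to quantify such simulations and their
companion imaging experiments. This vignette explains the models behind each
stage, the tunable parameters and their defaults, what the synthetic data
generators do and do not emulate, and the numerical choices a maintainer
would want to know about.

## The construction model

### Crystal core

The magnetite core starts from a conventional inverse-spinel Fe₃O₄ unit cell
(cubic, a = 8.3958 Å; Fe on tetrahedral and octahedral sites, O on the anion
sublattice). `read_cif()` expands the asymmetric unit with the file's
symmetry operators and merges duplicates at a 10⁻³ Å tolerance — far below
any interatomic distance, so merging can never fuse genuinely distinct
sites. The packaged cell is a *synthetic* fixture: its 192 Fd-3m (origin
choice 2) operators were generated from the standard generator set and
verified for group closure and for the 8/16/32 Wyckoff multiplicities, and
its geometry reproduces the textbook Fe–O bond lengths (1.89 Å tetrahedral,
2.06 Å octahedral). Users with a genuine crystallographic database file can
substitute it via `read_cif()`; a file without a symmetry loop is an
explicit error, never a silent P1 fallback, because a silently unexpanded
spinel cell would carve a nonsense particle.

The equilibrium particle shape is the Wulff construction: every facet
family contributes half-spaces whose distance from the particle origin is
proportional to the facet's relative surface energy, and the particle is
the inner envelope (intersection) of those half-spaces. Facet families are
expanded with the point group of the cell (the unique linear parts of its
symmetry operators), so `{100}` becomes six planes and `{111}` eight. The
defaults γ(100) = 1.0 and γ(111) = 1.15 are a documented choice, not a
measured quantity: published surface-energy orderings for magnetite make
(001) dominant with (111) truncating the corners, and 1.15 yields exactly
that cube-with-truncated-corners morphology. Any other energies can be
supplied per facet.

Two numerical points matter here. Vertices are enumerated over all plane
triples and feasibility-filtered (with a tolerance of about 10⁻⁶ of the
plane distance); a facet made redundant by the inner envelope simply
carries no boundary polygon but stays in the input. "Diameter" means the
face-to-face extent along the dominant (lowest-γ) facet normal — for a
cube-like shape that is the printed "3 nm", whereas a vertex-to-vertex
definition would be √3 larger. Carving keeps exactly the atoms satisfying
every half-space inequality, with boundary atoms *included* (≤ with a
10⁻⁶ Å slack) so the operation is deterministic and matchable against a
brute-force filter. A 3×3×3 supercell of an 8.4 Å cell (25 Å) cannot
contain a 30 Å particle plus its truncation, so `carve_core()` expands the
replication automatically and logs it; the atom-coordinate extent of the
carved core is then 3 nm minus at most one atomic-plane spacing (a/8 ≈
1.05 Å), because atoms live on lattice planes, not on the continuum
boundary.

### Surface sites and grafting

Fe sites are classified by their O-neighbour count within a 2.35 Å cutoff
(between the Fe–O bond at 1.9–2.1 Å and the next shell): six neighbours is
octahedral, four tetrahedral. Atoms at the carved surface necessarily lose
neighbours, so a surface atom's *bulk class* is recovered from its
crystallographic site label; grafting eligibility means "surface Fe whose
interior analog is octahedral" — without this rule no surface site would
ever qualify. Surface membership itself is geometric: within a 1.5 Å skin
of a boundary face, with the face normal as the outward direction (ties at
edges and corners average the normals).

Graft sites are chosen by deterministic farthest-point sampling: the seed
picks the starting candidate by index order, every subsequent site
maximises its minimum distance to the sites already chosen, and ties break
to the lowest atom id. This maximises coating uniformity and makes the
minimum pairwise spacing monotone non-increasing in the request size. Both
count mode (the default, 64 chains) and density mode (chains/nm², area
taken from the Wulff polyhedron surface) are supported. The two published
coating figures — 64 chains and 3 chains/nm² — are mutually inconsistent
for a 3-nm cube-like particle (64 chains on ≈ 42 nm² is ≈ 1.5 chains/nm²);
the package treats the chain *count* as the primary specification and
reports the realized density in the build report rather than guessing
which figure was intended.

### Polysaccharide chains

The coating polymer is the polysaccharide of acacia gum: L-arabinose,
D-galactose, L-rhamnose and D-glucuronic acid in the ratio 3:3:1:1. The
composition is fixed by that ratio, but the linkage topology is not
published, so the builder uses a documented gum-arabic-like default: per
8-residue repeat, a 4-residue backbone segment (three galactoses and one
glucuronate) carrying three arabinoses and one rhamnose as single-residue
branches. Monomer geometries are idealized planar ring templates with
literature-standard bond lengths, shipped as versioned PDB fixtures plus a
link-atom manifest; they are deliberately *not* conformationally realistic
sugars — the package's job is a well-formed, clash-free starting structure,
not an equilibrated glycan.

Chain length is met exactly by construction. The number of repeats comes
from the target length divided by the per-residue rise of a fully extended
backbone (~5.9 Å); the remaining mismatch is absorbed by tilting successive
residues by ±θ about an axis in the ring plane — the rigid-template
analogue of adjusting glycosidic torsions — which shortens the rise by
cos θ while keeping every glycosidic bond at its template length. θ is
solved by secant iteration to far below the 2% tolerance on the default
6.5 nm target. Residue placement alternates a 180° flip so branch arms swap
sides every residue (consecutive branches would otherwise overlap: an
arabinose plus its link bond spans 7.3 Å against a 5.9 Å rise), and each
branch residue then chooses the azimuth about its own axis (10° grid) that
maximises clearance to everything already placed. The net result is a flat
ribbon whose hydroxyl arms lie in parallel planes; the minimum interatomic
distance in a built chain is ≈ 0.93 Å, above the 0.9 Å overlap limit the
package enforces everywhere.

Attachment replaces the root anomeric hydroxyl with a deprotonated oxygen
bonded to the surface Fe at 1.95 Å along the site normal (the paper says
only "attached to Fe"; an alkoxide/carboxylate-like Fe–O bond is the
obvious chemistry). Charge bookkeeping is exact by construction: each
glycosidic link removes one O, one hydroxyl H and one link-hydroxyl H whose
summed charge is pushed onto the anomeric carbon, so every link is charge
neutral; root deprotonation moves exactly −1 onto the root oxygen. A chain
with *n* repeats therefore carries a formal charge of −(n+1) e (ionized
glucuronates plus the alkoxide root), and 64 default chains carry −256 e.

Dense coatings are genuinely crowded: 64 ribbons ~1 nm wide on ~42 nm²
must interdigitate. Placement therefore scans whole-chain torsions in 15°
steps (starting from a per-site golden-angle offset so neighbouring ribbons
thread rather than meet face-on), then small axis tilts (10°, 20° in four
azimuths) for hemmed-in sites, and finally — only if a site still cannot
host a chain — substitutes the next-ranked candidate site so the chain
count stays exact. Substitutions are counted in the build report (the
default build needs one). All of this is deterministic; rebuilding with the
same configuration is byte-identical.

### Topology

`enumerate_topology()` is pure graph combinatorics: angles are all simple
paths of two bonds (the central atom in the middle), proper dihedrals all
simple paths of three bonds, both in canonical orientation
(lexicographically smaller endpoint first) and deduplicated — in 3- and
4-membered rings the same central bond walked in both directions collapses
to one entry. Improper dihedrals are out of scope by design. The magnetite
core is treated as a bonded Fe–O network within the same 2.35 Å cutoff
(with a `frozen_core` switch that drops core-internal bonds for
restrained-core setups, since the published methods do not say which
convention was used). Partial charges for the ligands ride on the monomer
templates; the core scheme defaults (Fe +1.2 e, O −0.9 e) keep a
stoichiometric cell exactly neutral but are *placeholders* — the
force-field values actually used are not published — and are exposed for
overriding. A carved particle is oxygen-rich at its surface, so the core
scheme contributes a positive non-integer net charge that is reported, not
hidden. Force constants are deliberately absent: redistributing force-field
parameter files is not this package's place.

### Membrane and assembly

The bilayer is two leaflets of exactly N DPPC lipids on a near-square
tetragonal grid with pitch √(area per lipid); 0.63 nm² is the fluid-phase
DPPC convention and is configurable. The lipid template is generated
deterministically in code (idealized all-trans tails, named phosphate and
choline atoms) rather than shipped as a coordinate file — an idealized
template is fully specified by the code that writes it, and the H-bond
analysis only needs the atom-name conventions. Solvation tiles a
near-cubic lattice at 33.4 waters/nm³ (ambient bulk density) with the
rigid 3-site water geometry (O–H 0.9572 Å, H–O–H 104.52°) and removes
molecules whose oxygen is within 2.4 Å of any solute atom. Assembly places
the particle so its lowest atom sits exactly `gap` above the mean z of the
upper-leaflet phosphorus atoms (5 Å reproduces the published starting
configuration) and builds a component index (particle / lipid / water).

The published system size, 619,500 atoms, depends on unstated water-box
padding; the assembled total here is logged but never asserted. At desk
scale the pipeline defaults to `solvate_system = FALSE`: solvation is the
one stage whose cost is dominated by sheer water count, and none of the
reported build quantities (chain count, chain length, core extent, lipid
count, gap) depend on water. Passing `solvate_system = TRUE` runs it.

## Trajectory and imaging analysis

Hydrogen bonds are detected by the standard geometric criterion: donor–
acceptor distance within a cutoff and donor–H···acceptor angle above a
minimum, evaluated for every bonded hydrogen of every selected donor.
Two classes are scored: conventional OH···O (D–A ≤ 3.5 Å, angle ≥ 150°)
and the weak carbon-donor CH···O class (D–A ≤ 3.8 Å, angle ≥ 130°), the
looser thresholds reflecting its less directional character. The source
publication prints no cutoffs, so these literature-conventional defaults
are explicit, configurable arguments; every conclusion drawn from them
should be read as conditional on that choice. Summaries are normalised per
donor residue *type* — "two bonds per galactose on average" — and carry a
block-averaged standard error (5 blocks by default) rather than a naive
one, because H-bond time series are autocorrelated.

The imaging formulas are exactly the printed ones: SNR = 0.655 ×
(tumor-ROI mean / mean of background-ROI means), with 0.655 the Rayleigh
correction for single-coil magnitude MR images, and CNR = SNR_pre −
SNR_post. That subtraction order is preserved *as printed* even though it
is arguably inverted for an enhancement agent; the magnitude is reported
alongside so no information is lost. Tumor volume is the caliper ellipsoid
approximation V = (length/2) × width².

## What the synthetic generators establish — and what they do not

The published simulation itself (50 ns, 619,500 atoms) is cluster-scale
and its trajectory is not deposited, so the H-bond *averages* printed in
the paper cannot be checked from this package. What can be checked, and is,
with `synth_hbond_trajectory()`: that the detector agrees *exactly* with a
brute-force all-pairs oracle on random frames, and that the summary
recovers planted per-cell means — the generator returns the exact realized
presence fractions, so recovery is asserted to machine precision, with the
3-block-SE band reserved for the comparison against the *nominal* planted
fraction. A green test therefore establishes that the analysis machinery
is correct, not that the published biological observation is reproduced.
Likewise `synth_roi_image()` builds flat disks with known means: it
validates the formula, not any scanner physics.

## Known limitations

- Ring geometries are idealized and planar; no anomeric chemistry, ring
  pucker, or conformational sampling. Structures are *starting points*.
- Surface chemistry is geometric: no charge-compensated site chemistry, no
  surface reconstruction or relaxation of the carved particle.
- The magnetite charge scheme is a neutral-cell placeholder.
- The Wulff machinery assumes the point group of the supplied cell; facet
  sets that do not positively span space are rejected rather than patched.
- Solvation is a lattice fill, not an equilibrated liquid; it is meant to
  be energy-minimised by the downstream MD engine.
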