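# nanoforge

Atomistic model construction and analysis for polysaccharide-coated
iron-oxide nanoparticles at lipid membranes.

Magnetic nanoparticles coated with the acacia-gum polysaccharide (L-arabinose,
D-galactose, L-rhamnose and D-glucuronic acid in the ratio 3:3:1:1) are
promising theranostic agents: the coating mediates membrane penetration while
the magnetite core provides MRI contrast. Simulating such a particle requires
a starting structure no standard tool builds — a faceted Fe₃O₄ crystal carved
from the bulk, dozens of branched glycan chains grafted onto specific surface
iron sites, a DPPC bilayer, and MD topology files for the non-standard parts.
nanoforge builds all of that as tidy tibbles (one row per atom) so every
stage chains with the pipe, and adds the analysis formulas used to quantify
the simulations and their companion imaging experiments.

## What it computes

* **Wulff construction.** The equilibrium crystal shape is the inner envelope
  of half-spaces, one per symmetry-expanded facet {hkl}, with plane distance
  d ∝ γ(hkl) (the relative surface energy). For magnetite, γ(100) = 1.0 and
  γ(111) = 1.15 give the cube-with-truncated-corners morphology; the shape is
  scaled so the face-to-face extent along the dominant normal equals the
  target diameter (3 nm default).
* **Carving and grafting.** Atoms of a bulk supercell satisfying every
  half-space inequality form the core; surface octahedral Fe (6 O neighbours
  within 2.35 Å in the bulk) are grafting sites, chosen by deterministic
  farthest-point sampling (64 chains default).
* **Glycan chains.** Branched gum-arabic-like chains (per 8-residue repeat:
  Gal₃GlcA backbone carrying Ara₃Rha branches), built to a target length
  (6.5 nm) by tilting glycosidic links, and attached by Fe–O bonds (1.95 Å).
* **Topology.** Bonds, angles (all 2-bond paths) and proper dihedrals (all
  3-bond paths) in canonical orientation, plus partial charges; GRO/PDB and
  a sectioned topology text format.
* **Membrane systems.** Tetragonal-grid DPPC bilayers (489 lipids per
  leaflet default), 3-site water solvation, and assembly with the particle a
  set distance (5 Å) above the phosphate plane.
* **Analysis.** Geometric hydrogen-bond detection for conventional OH···O
  (≤ 3.5 Å, ≥ 150°) and weak CH···O (≤ 3.8 Å, ≥ 130°) bonds with per-residue
  trajectory summaries and block standard errors; particle–membrane distance
  series; MR image statistics SNR = 0.655·(ROI_tumor/averageROI_background)
  and CNR = SNR_pre − SNR_post; caliper tumor volume V = (length/2)·width².

## Worked example

```r
library(nanoforge)

build <- run_pipeline(build_config())   # the full default construction
print(build)
#> # nanoforge build
#>   core_atoms                 2267
#>   core_extent_nm             2.94676
#>   n_chains                   64
#>   grafting_density_per_nm2   1.50935
#>   chain_length_nm            6.5
#>   chain_residues             24
#>   np_atoms                   31771
#>   net_charge_e               -240.4
#>   lipids_per_leaflet         489
#>   system_atoms               156955
#>   gap_A                      5
```

Reading the report: the carved core spans 2.947 nm along <100> — the target
3 nm minus part of one atomic-plane spacing, because atoms sit on lattice
planes. Sixty-four chains of exactly 6.5 nm are grafted (24 residues each,
3:3:1:1 composition), a realized density of 1.51 chains/nm² on the 42.4 nm²
Wulff surface. The net charge collects one −4 e chain charge per chain
(three ionized glucuronates plus the alkoxide root) plus the placeholder
core scheme. The bilayer holds 489 DPPC per leaflet and the particle starts
exactly 5 Å above the upper phosphate plane. `system_atoms` excludes water
by default (`solvate_system = TRUE` adds it).

Analysis functions work on any frames shaped as atom tibbles:

```r
tr <- synth_hbond_trajectory(200, seed = 1)
sm <- hbond_summary(tr$frames, tr$bonds, tr$donors, tr$acceptors, tr$groups)
autoplot(sm)

im <- synth_roi_image(tumor_mean = 131, background_mean = 65.5, noise_sd = 0)
snr(im$image, im$tumor_mask, im$background_masks)$snr
#> [1] 1.31
```

A thin command-line interface over the same functions lives at
`inst/cli/nanoforge.R` (`build`, `core`, `sites`, `hbonds`, `snr`
subcommands).

## Acceptance script

`scripts/acceptance.R` re-runs the package end to end — the default
construction pipeline on the packaged magnetite cell, plus the imaging
formula on a noise-free synthetic image — and writes the recomputed headline
quantities as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Scope

The package builds starting structures and analyses trajectories; it does
not run MD (no force constants, integrators or force-field parameter files)
and does not model the wet-lab chemistry (drug loading, DSC, DLS, cell and
animal work) of the systems it targets. The packaged magnetite cell is a
synthetic fixture with verified Fd-3m symmetry; substitute a genuine CIF
with `read_cif()`.
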