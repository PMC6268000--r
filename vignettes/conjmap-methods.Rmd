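---
title: "Characterizing conformational ensembles of two-domain conjugates with conjmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing conformational ensembles of two-domain conjugates with conjmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conjmap)
```

## The problem

Covalently linked two-domain proteins — the motivating system is the
ubiquitin dimer (diUb), where a distal ubiquitin is joined through its
C-terminus to one of eight linkage sites on a proximal ubiquitin — do not sit
in a single structure. They populate an ensemble of relative domain
arrangements, and the identity of the linkage site biases which arrangements
are accessible. Understanding linkage-specific signaling therefore requires
characterizing and *comparing* whole conformational landscapes, typically
sampled by long coarse-grained (CG) molecular-dynamics simulations and
validated by shorter atomistic ones.

conjmap implements the analysis side of that workflow: descriptors,
dimensionality reduction, free-energy landscapes, landscape comparison, and
surface/interface analysis. It deliberately contains no MD engine; its
inputs are multi-frame coordinate files (multi-model PDB, GRO) plus a
specification of which residues belong to which subunit, and — for testing
and method validation — a synthetic rigid-body ensemble generator with known
ground truth.

## Residue-wise minimum distances

The collective variables are residue-wise minimum distances (RMD): for each
backbone site (Cα atom, or the backbone bead of a CG model) of the distal
subunit, the minimum Euclidean distance to the proximal subunit's backbone
sites, and vice versa. For two 72-residue subunits this gives a
144-dimensional descriptor per frame. Working only with backbone sites makes
the descriptor directly comparable between atomistic and CG representations
of the same molecule. The flexible C-terminal tail (residues 73–76 of
ubiquitin) is excluded from the descriptor via the topology's
`analysis_range`; those residues are still carried along for SASA analysis.

Distances are plain Euclidean by default. A minimum-image mode
(`pbc_box =`) exists for orthorhombic boxes, but a covalently linked
conjugate simulated in a box chosen to avoid periodic self-interaction never
needs it — that is why plain distances are the default.

Choices worth knowing about:

* all coordinates are stored in nm; PDB ångströms are converted on read and
  write (factor 10);
* residues are numbered 1-based within each subunit, distal block first;
* the per-subunit analysis residue count `R` is configurable — 72 matches
  ubiquitin, but nothing in the machinery depends on that value.

## Sketch-map projection

The 2R-dimensional descriptors are projected to 2D with sketch-map, a
landmark-based nonlinear multidimensional scaling. Both the high-dimensional
distances `R_ij` and the low-dimensional map distances `r_ij` are passed
through a sigmoid

F(r) = 1 − (1 + (2^{a/b} − 1)(r/σ)^a)^{−b/a},

with F(0) = 0 and F(σ) = 1/2, and the landmark positions minimize the
weighted stress

χ² = Σ_{i<j} w_i w_j [F_HD(R_ij) − F_LD(r_ij)]².

Using steep exponents in high dimension (A = 12, B = 4) and soft ones in 2D
(a = 2, b = 4) concentrates the fit on the intermediate distance range
around σ: distances much shorter or much longer than σ saturate the sigmoid
and stop dominating the stress. The defaults σ = 5.9 (on the nm scale of
raw RMD vectors), A = 12, B = 4, a = 2, b = 4 are the published values for
ubiquitin-dimer RMD data; for other systems `hd_distance_summary()` shows
the pairwise-distance distribution from which σ should be picked by the
user — the package does not auto-select it.

**Landmark selection.** The published recipe — "random in combination with
minmax, γ = 0.1" — does not pin down the staging, so the package adopts and
documents one interpretation: `ceiling(γ·n)` landmarks drawn uniformly at
random (seeded), the remainder added by greedy farthest-point selection in
high-dimensional Euclidean distance. With γ = 0 the greedy stage is seeded
with the globally farthest pair, which makes the often-quoted property "the
two most distant points are landmarks" hold by construction. Landmark
weights count how many input points are nearest to each landmark; they enter
the stress as `w_i w_j` and can be disabled (`use_weights = FALSE`) since it
is not documented whether the original implementation used them.

**Optimization.** The landmark map is initialized from classical metric MDS
(`cmdscale`) of the F_HD-transformed distance matrix and refined with
L-BFGS using analytic gradients, optionally restarted from seeded
perturbations of the initialization; the reported stress is never worse
than the initialization stress. Tolerance is a relative stress change of
1e-6, `max_iter` 1000. All randomness is confined to explicit seeds, so
identical inputs and seeds give bit-identical models.

**Out-of-sample projection.** Non-landmark frames are placed by minimizing
the same weighted mismatch against the fitted landmarks: a deterministic
grid scan over the padded landmark bounding box (resolution 1% of the box
by default) followed by vectorized gradient refinement with per-point
adaptive step sizes. The grid scan is what makes the placement robust to
the objective's multiple local minima; the refinement then sharpens the
winning candidate. Landmarks re-projected through their own model land
within 0.1 map units of their fitted positions, which is the practical
scale of placement error to keep in mind when reading the maps.

## Free-energy landscapes

Projected points are histogrammed (default 100×100 over the padded data
bounding box; Gaussian smoothing available but off by default) and
Boltzmann-inverted: F = −kT ln p per populated bin, shifted so the global
minimum is zero, with k_B = 0.0083145 kJ mol⁻¹ K⁻¹ and T = 300 K by
default. Energies are reported in both kT and kJ/mol. Unpopulated bins are
masked, not given a large finite energy.

Minima are populated bins strictly below all populated 8-neighbors; equal-
valued plateaus that are collectively lower than their surroundings count
once, at their centroid bin. Bins holding fewer than 2 samples are treated
as unpopulated during minima detection — a sampled landscape's sparse rim
otherwise sprouts single-sample "minima". Both the threshold and the bin
count are parameters, and the sensible regime depends on what is being
measured: reading *occupancy ratios* off minima depths requires bins wide
enough that a basin's mass falls into one bin (the depth difference then
equals −kT ln of the occupancy ratio up to counting error), while resolving
*basin shape* wants finer bins. The validation suite uses both regimes
deliberately.

Basin-representative frames are exported per minimum as: the frame
projected nearest the minimum, plus `n_random` frames drawn (seeded)
uniformly from all frames within `radius` of it. The defaults — 4 minima,
10 random frames each — match the scheme used to seed backmapped atomistic
simulations from CG basins.

## Comparing landscapes

Two landscapes are compared by the Earth Mover Distance between their
projected *densities* (not their free energies): the minimal mass-transport
cost between the two histograms with Euclidean ground distance between bin
centers. With a metric ground distance EMD is a true metric, so the
pairwise matrix supports embedding. The solver is an exact transportation
simplex written for this package (network-simplex with u-v pricing, an
epsilon perturbation against degenerate cycling, and a final re-solve of
the optimal basis at the unperturbed marginals, so reported costs are exact
to floating point). Cost grows quickly with populated-bin count, so
densities finer than 64×64 are aggregated (mass-conserving) before the
solve by default; `coarsen = Inf` forces full resolution.

The pairwise matrix is conventionally max-normalized — the most dissimilar
pair scores exactly 1 — and systems are arranged in 2D by classical metric
MDS of the matrix, with a deterministic sign convention (the first system
sits in the non-negative quadrant) so plots are reproducible.

## Surface and interface analysis

SASA uses Shrake–Rupley sphere sampling with a deterministic Fibonacci
point set (default 960 points per particle, accurate to well under 1% for
single spheres), with per-particle radii from the topology. Defaults: probe
0.14 nm and element-based van der Waals radii atomistically; probe 0.21 nm
and 0.23 nm beads for CG models — CG SASA conventions are not standardized,
so all of this is configurable per call and per topology.

The interface area of a frame is

SA_interface = SASA(distal alone) + SASA(proximal alone) − SASA(conjugate),

with the isolated-subunit terms evaluated at the same coordinates, partner
particles deleted. The same difference evaluated per particle attributes
the buried area, and summing the per-particle burial by polarity class
(N/O polar, C/S apolar atomistically; bead-class table for CG) splits
SA_interface exactly into apolar (a-SA) and polar (p-SA) parts — the
partition identity a-SA + p-SA = SA_interface holds to rounding, and with
a shared deterministic point set per-particle burial is non-negative by
construction.

Residue-wise ΔSASA — the mean accessibility a residue loses to the partner
subunit — uses the same attribution, so summing ΔSASA over all residues of
a frame reproduces that frame's SA_interface. With several independent
runs the error bar is the standard deviation of per-run means, following
the usual independent-replica convention.

Patch accessibility compares the SASA of named residue patches (defaults:
the Ile44, Ile36 and Phe4 patches and the TEK box of ubiquitin) in the
conjugate against a monomer reference, clipped to [0, 1]. Two decisions
here are deliberately conservative:

* the monomer reference defaults to the *same-frame isolated subunit* —
  the quantity is then exactly "what the partner buries", and no separate
  monomer ensemble is needed; a user-supplied per-residue reference table
  is accepted for comparisons against an independently simulated monomer;
* the shipped patch residue sets are editable configuration, not fixed
  truth — published patch definitions vary, and patch members beyond the
  analysis range (the 73–76 tail) are excluded.

## The synthetic ensemble generator

`sample_conjugate_ensemble()` is first-class, tested code, not a fixture
hack: it generates the ground-truth-labelled data on which every downstream
stage is validated. A subunit template is a compact serpentine lattice
chain (0.38 nm spacing — the Cα virtual bond — small seeded jitter, minimum
site distance ≥ 0.35 nm, radius of gyration ~ n^{1/3}); each basin is a
rigid-body pose of the proximal subunit with an occupancy weight and
isotropic Gaussian site noise; frames pick a basin (seeded, weight-
proportional), apply the pose and noise, and optionally reject frames whose
distal-C-terminus-to-proximal-N-terminus distance exceeds a linker cap.
Basin labels are returned with the trajectory so recovery tests never
re-infer them.

What it emulates: metastable basins with prescribed occupancies, basin
width via noise, interface burial via pose geometry. What it does not
emulate: chain flexibility within a subunit, kinetics, force-field
correlations, solvent. Passing tests on synthetic data therefore validate
the *analysis machinery* (descriptors → projection → inversion → comparison
→ SASA accounting), not any force field.

## Validation regimes and problem sizes

The package's own validation uses deliberately scaled problem sizes chosen
so the statistical assertions are sharp: oracle-equivalence checks (RMD vs
a brute-force double loop, the transport solver vs exhaustive LP solutions,
SASA vs closed-form one- and two-sphere geometry, the 3-landmark sketch-map
fit vs a 1D root-finding solution) run on instances of a few dozen
elements; occupancy-recovery runs use two- and three-basin ensembles of
16-residue subunits at 10⁵ frames, where the binomial 3σ band on a
0.7/0.3 depth difference is ±0.02 kT. The 72-residue default template
exercises the full 144-dimensional descriptor path. Basin noise in the
recovery runs is kept small (0.002 nm) so each basin occupies a single
histogram bin and the depth difference reads the occupancy ratio directly;
the limitations of that regime are discussed above.

## Known limitations

* No XTC reader: R has no native XTC support, so CG trajectories should be
  exported as multi-model PDB or GRO before analysis.
* The landmark-staging interpretation of γ and the use of landmark weights
  in the stress are documented choices where the published description is
  silent; both are parameters.
* Sketch-map stress is non-convex; the MDS initialization plus restarts is
  a reproducibility-first strategy, not a global-optimality guarantee.
* The exact transport solve is O(bins³)-ish in practice; very fine
  landscapes should stay coarsened (the default) unless exact fine-grained
  values are required.
* Patch accessibility against a static monomer reference ignores monomer
  flexibility; supply a monomer-ensemble reference table when that matters.
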