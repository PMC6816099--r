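---
title: "Free-energy analysis of DNA base flipping at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Free-energy analysis of DNA base flipping at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(baseflip)
```

# Scope and scientific question

SRA domains read methylated cytosines by rotating them out of the DNA double
helix. Two quantitative questions drive this package: how the free-energy
landscape of base flipping, expressed along pseudodihedral collective
variables, responds to restraint of the phosphate backbone (the mechanical
signature of SRA binding); and how a minimum free-energy path between an
unbound and a bound protein--DNA state can be optimized with the string
method in collective variables. Atomistic microsecond simulations of these
questions are not reproducible on a desk machine, so every method here is
built to be *validated* on synthetic systems with exactly known answers: a
1-D double well, the Muller--Brown surface, a separable periodic 2-D
potential, and a coarse-grained bead-spring DNA duplex whose flipping
thermodynamics are measurable both with and without bias.

Units are Angstrom, kJ/mol, ps, amu and Kelvin throughout, with
`kB = 0.0083145` kJ/mol/K. The simulation temperature is not dictated by the
scientific setting; 300 K (kT = 2.494 kJ/mol) is the package default and is
configurable everywhere.

# The coarse-grained duplex

`make_cg_duplex()` builds a 12-bp ladder with three beads per nucleotide:
phosphate (P, 95 amu), sugar (S, 83 amu) and base (B, 110 amu). The default
sequence is the hemimethylated CpG oligo sense `CCATG(5mC)GCTGAC` /
antisense `GTCAGCGCATGG`; the methylated cytosine (0-based sense residue 5)
is the flipping base. The 5mC modification is a bead label only --- the
flipping analysis requires no energetic asymmetry between modified and
unmodified cytosine, and none is imposed.

Energy terms and their defaults:

* harmonic backbone bonds P--S, S--B, S--P(next), `backbone_k = 300`
  kJ/mol/A^2 --- stiff bonds, ~0.09 A thermal fluctuation at 300 K;
* harmonic backbone angles P--S--P and S--P--S, `angle_k = 25`
  kJ/mol/rad^2 --- this is deliberately the softest structural scale: it
  sets how much the backbone can locally accommodate an everted base;
* breakable base-pair bonds B--B' as capped harmonic wells of depth
  `pairing_strength = 10` kJ/mol, flat (zero force) beyond
  `pairing_cutoff = 7.5` A;
* breakable stacking wells B(r)--B(r+1) of depth `stack_strength = 2`;
* soft-core excluded volume between non-bonded beads, with a larger,
  stronger core between bases and phosphates (radius 3.0 A, 100 kJ/mol
  versus 1.8 A, 10 kJ/mol elsewhere).

The last point is the model's one deliberate coupling device. An
intrahelical base never touches its phosphates (B--P distance 5.9 A), but a
fully everted base presses against the two junction phosphates P(i) and
P(i+1); the backbone yields by several tenths of an Angstrom. Flipping
therefore costs pairing (10) + two stacking wells (4) plus the accommodation
work, about 20 kJ/mol in total --- within the intended 10--25 kJ/mol
scale of base-pair rupture at 300 K --- and, crucially, the extrahelical
state has a *distinct backbone geometry*, which is what the
backbone-restraint paradigms read out. Increasing `pairing_strength`
strictly increases the measured flipping barrier (a tested invariant).

The paired ladder is planar (all beads in the y = 0 plane) with the
phosphates placed collinear with sugar and base. This makes the flip
coordinate read exactly 0 when paired and exactly pi when everted, and
keeps the eversion pathway in-plane, which stabilizes the construction of
the flipped reference. What the generator deliberately does *not* model:
helical twist, sequence-dependent energetics, electrostatics, counterions
and solvent. Passing the oracles here demonstrates the correctness of the
sampling and analysis machinery, not the realism of any particular DNA
force field.

# Collective variables

The flip coordinate `xi1` (`duplex_xi1()`) is the pseudodihedral of the four
centroids S(i), P(i), P(i+1), B(i), ordered so that the dihedral axis is the
local P--P backbone direction: the angle measures rotation of the base
around the phosphate backbone, reading ~0 intrahelical and ~pi extrahelical.
`xi2` (`duplex_xi2()`) uses B'(partner), P(i), S(i), B(i), with the
dihedral axis along the backbone--sugar bond: rotation of the base about the
sugar linkage. The literature uses xi and zeta interchangeably for these
angles; this package writes `xi1`/`xi2` everywhere. Both are evaluated as
centroid dihedrals in the IUPAC sign convention with analytic chain-rule
gradients (validated against central finite differences to 1e-5 relative
error); gradients sum to zero over particles, as translation invariance
requires. Atomistic group definitions are user-supplied via
`pseudo_dihedral_cv()`; no atomistic convention is hard-coded, because no
unambiguous published atom-group definition exists to reproduce.

# Langevin dynamics

`langevin_run()` integrates the BAOAB splitting of Langevin dynamics,
chosen for its accurate configurational sampling at moderate time steps.
Defaults: `dt = 0.01` ps, friction 5 ps^-1. With the stiffest default bond
(300 kJ/mol/A^2 on a 83--110 amu bead) the fastest period is ~0.25 ps, 25
steps per period. The integrator accepts arbitrary extra forces: harmonic
position restraints, wrapped-difference dihedral restraints, harmonic CV
restraints (for the string method) and the adaptive bias. All randomness
flows from the integer seed in `integrator_params()`; identical inputs
reproduce CV series bitwise, which the test suite asserts. Tested physical
invariants: equipartition in a harmonic well, Boltzmann statistics in a
double well (KL divergence < 0.05), and energy conservation to 0.1% over
1e4 steps when friction and temperature are zero.

# The adaptive biasing potential

The bias lives on a regular grid over one or two CVs (default 72 bins per
2 pi, i.e. 5 degrees). Every `stride = 10` steps a raised-cosine kernel of
half-width 3 cells and mass equal to `stride` is deposited at the current
CV value, scaled by the tempering factor `1 - bias(z)/cap`; the bias at a
touched cell is `min(cap, (kT/b) log(1 + b c V))` with `V` the accumulated
mollified visit mass. The three named parameters keep their conventional
roles --- `c = 0.01` sets the deposition rate, `b = 0.9` the
mollification/tempering, and `alpha = 8` the cap in kT units (19.95 kJ/mol
at 300 K, comfortably above the ~16 kJ/mol flipping scale). Bias energy is
interpolated multilinearly between cell centers and its gradient by
interpolated central differences; periodic dimensions wrap continuously
across the +/- pi seam (tested to 1e-10).

**Free-energy estimator.** At stationarity the growth-rate balance of this
rule gives `U(z) = -(1+b) bias(z) + kT log(1 - bias(z)/cap) + const`:
the raw negative bias *compresses* free-energy differences, exactly as the
bias of well-tempered metadynamics does before its scale-factor correction.
`abp_fes()` therefore inverts with the full expression rather than
returning `-bias`. On the 1-D double-well oracle (where the free energy
equals the potential identically) the corrected estimator is accurate to
~0.3 kJ/mol after 2e6 steps, while the raw negative bias errs by ~4.5
kJ/mol; the correction is a necessity, not a refinement. Cells whose bias
has reached the cap no longer accumulate information and are flagged
(`fes$capped`) and excluded from quantitative comparisons; cells never
visited are masked (`NA`), which is distinct from cells at F = 0.

# Restraint paradigms

`build_paradigm()` implements three graded levels of backbone restraint
emulating SRA contact, all referenced to the flipped conformation from
`make_flipped_reference()`: `"none"`, `"flanking"` (the 5' and 3'
phosphates of the flipping base, 2 restraints) and `"all"` (every
phosphate of both strands, 24 restraints). The flipped reference is built
by rotating the base about the local backbone axis to xi1 = pi, then
minimizing with the base fixed, the flip dihedral held, and only the
terminal base pairs anchored --- the analog of an extrahelical base held in
a bound pose while the backbone relaxes around it. The construction is
deterministic; the flip is local (residues beyond the first shell move
< 0.5 A) while the junction phosphates displace by ~0.5--0.8 A.

The default restraint constant is strong (see `build_paradigm()`):
position restraints emulate a protein clamping the backbone, and the
restraint must dominate the soft backbone modes of the coarse model for
the clamp to be mechanically meaningful; weak restraints let the backbone
yield and the paradigms blur together. With the defaults, restraining the
flanking phosphates at their flipped-accommodating positions lowers the
measured region free-energy difference F(flipped) - F(paired) by about
5 kJ/mol relative to free DNA --- the direction expected when backbone
pre-organization stabilizes the everted state. State regions default to
|xi1| < pi/3 (paired) and |xi1| > 2 pi/3 (flipped), Boltzmann-weighted
(`delta_f()`); both the region definitions and the weighting are
config-exposed, and point-wise differences can be read off the exported
surfaces directly.

One limitation deserves emphasis. Extending the restraints from the two
flanking phosphates to *all* phosphates adds little further
stabilization in this model, and can even reverse a few tenths of a
kJ/mol of it: the flip distorts the backbone only locally, so the remote
phosphate restraints carry no energetic differential, while pinning them
slightly stiffens the broken-pair (flipped) rim more than the paired
helix --- a small entropic effect of the wrong sign that persists even
with exactly matched reference positions. In the atomistic setting the
all-phosphate reference is the protein-bound DNA pose, which differs
globally from free DNA because of the protein; the protein-free toy
duplex has no such global differential, so the graded none/flanking/all
hierarchy is only partially reproduced here.

# String method in collective variables

`run_string()` iterates three exact, separately-tested operations: a
restrained mean-force estimate per image, a downhill move orthogonal to
the path, and reparametrization to equal arc length.

* `image_mean_force()` samples with harmonic CV restraints
  `0.5 k (theta(x) - z)^2` and returns `k (z - <theta>)` after a 20%
  burn-in, with block-averaged standard errors. On a harmonic system this
  estimator has the closed form `k kappa (z - mu)/(k + kappa)`, which the
  suite checks at ten restraint centers within three standard errors. At
  temperature zero the run is a deterministic damped relaxation and the
  estimate converges to the exact potential gradient.
* `string_step()` projects out the tangential component (central-difference
  tangents), moves the movable images, and reparametrizes. Endpoints are
  fixed by default (`endpoint_policy = "free"` releases them). The default
  step normalizes the largest image move to 10% of the image spacing.
* `string_profile()` integrates the mean forces along the path. The default
  quadrature interpolates path and gradients with cubic splines in arc
  length and integrates on a 20-fold refined grid; the textbook per-segment
  trapezoid (`method = "trapezoid"`) is retained, but at M = 20 images on a
  strongly curved benchmark path its endpoint error is ~4% against the
  gradient-theorem value, which would swamp the method's real accuracy ---
  the spline quadrature brings it below 0.5%.

Per-image seeds derive deterministically from the master seed, so the full
`StringResult` (path, gradient and profile history) is reproducible and
image-parallelizable. The convergence diagnostic is the RMS image
displacement per iteration; the oscillatory phase is flagged where its
running mean flattens (relative change below 10% over a 5-iteration
window). `profile_stats()` reports the per-image mean and two-sided 95%
t-interval over a chosen iteration window; on synthetic stationary
histories the interval covers the truth at the nominal rate (tested over
1000 windows). On the Muller--Brown benchmark with 20 images, fixed
endpoints at the two outer minima and zero-temperature mean forces, the
converged string lies within 0.05 of the fine-grid minimum-energy path,
passes within 0.05 of both saddle points, and reproduces the analytic
endpoint free-energy difference to well under 2%. Image restraints default
to 8 kT per squared CV unit for the duplex-scale systems; the benchmark
surface needs a much stiffer spring (its gradients are two orders of
magnitude larger), which the tests set explicitly. CV restraints act on
raw CV coordinates; no rigid-body alignment is applied before restraining.

# Unbiased surfaces, state differences, barriers

`histogram_fes()` Boltzmann-inverts sampled CV densities
(`F = -kT log(counts/max)`), masking empty cells --- the oracle against
which the adaptive bias is validated, both on analytic systems and on the
low-barrier duplex, where the two estimates agree within 2 kJ/mol over
jointly sampled cells. `barrier()` returns the maximum along the minimal
path between two points of a 1-D surface, taking the lower of the two arcs
on periodic surfaces and refusing to jump masked gaps. Surfaces serialize
to TSV with 17 significant digits (`write_fes()`/`read_fes()`; masked
cells as NaN) and round-trip bitwise.

# Structural meta-analysis

`read_structure()` parses PDB ATOM/HETATM records (through bio3d) with an
explicit altloc policy: the highest-occupancy conformer wins, ties go to
altloc A. `kabsch_superpose()` is the SVD solution of the least-squares
rigid superposition with the determinant correction excluding reflections;
the suite checks exact recovery of known transforms and optimality against
a brute-force quaternion search. `align_iterative()` adds the outlier
rejection cycle of standard structure-alignment tools (defaults: 5 cycles,
2.0 A cutoff --- these defaults mirror those tools because the original
analysis pipeline's settings are not recorded anywhere recoverable).
`flipped_base_rmsd()` superposes each complex onto a reference over all
matched protein atoms and pools the squared deviations of the shared
modified-cytosine atoms (default ring + exocyclic + C5-methyl carbon;
hydroxymethyl oxygen excluded as it has no 5mC counterpart) into a single
RMSD; a per-structure-mean variant is available (`pooled = FALSE`). The
package's tests run this machinery on synthetic complexes built in code;
reproducing the published cross-complex value requires the six deposited
coordinate files, which users must download themselves (see README).

# Reproducibility and problem sizes

Every pipeline stage is driven by one integer seed; `write_outputs()`
echoes the fully resolved configuration next to the numeric outputs and a
manifest of SHA-256 hashes, and re-running with the same configuration and
seed reproduces every numeric TSV byte for byte. Default analysis sizes,
chosen so the full validation battery runs in minutes on one core while
leaving comfortable statistical margins: 2e6 biased steps for the 1-D
oracle, 1e7 for the 2-D periodic oracle, 2e7 unbiased + 4e6 biased steps
for the duplex cross-validation, 4e6 biased steps per restraint paradigm,
and 110 string iterations of 2500 steps per image on the benchmark
surface.

# Known limitations

The coarse duplex has no twist, no electrostatics and no solvent; its
flipping pathway is planar by construction, and its flipped state is a
broad rim rather than the sharply docked pose a protein would enforce.
The adaptive-bias estimator assumes the stationary growth-balance regime;
grossly undersampled runs will show residual sweep-history artifacts. The
string implementation restrains raw CV coordinates, so Cartesian-CV
strings are only meaningful when the ends are in a common frame. None of
the acceptance-grade statements here concern real DNA energetics; they
concern the correctness of the estimators on systems where truth is
computable.
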