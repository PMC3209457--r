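---
title: "Elastic-network analysis of mutation effects on binding-motif dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Elastic-network analysis of mutation effects on binding-motif dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flexmotif)
```

## The question and the model

Missense mutations in enzymes that bind a cofactor sometimes sit well
away from the binding residues yet still abolish binding. A mechanistic
hypothesis for such cases is dynamic: the mutation softens the packing
around its own site, the softening propagates through the protein's
collective motions, and the binding motif — which must stay rigid to
hold the cofactor — becomes more mobile. flexmotif provides a
coarse-grained, fully testable version of the analysis chain used to
probe this hypothesis: normal mode analysis with residue
cross-correlation maps, per-residue B-factor profiles, and stochastic
dynamics with MD-style trajectory statistics, all on an elastic network
built from Cα coordinates alone.

The potential is the anisotropic network model (ANM): every pair of Cα
sites within a cutoff `r_c` interacts through a Hookean spring along
their equilibrium separation `d`, contributing the 3×3 Hessian
super-element `−γ_ij d dᵀ/|d|²`; diagonal blocks make each 3-column
block sum to zero, so uniform translations cost nothing. The input
structure is the energy minimum by construction — no prior minimisation
step exists or is needed, which is the key simplification relative to
force-field NMA. Diagonalizing the mass-weighted Hessian
`M^{-1/2} H M^{-1/2}` gives eigenvalues λ_k and orthonormal modes u_k.
A connected three-dimensional network has exactly six zero modes; the
package treats |λ| < 1e-8·λ_max as numerically zero, errors if more
than six such modes appear (a floppy network means the cutoff is too
small), and rejects disconnected contact graphs outright.

Thermal displacement statistics follow from the nonzero modes:
`K_ij = Σ_k (u_{k,i}·u_{k,j})/λ_k` restricted to the `n_modes` lowest
nonzero modes (the full sum is the Moore–Penrose pseudo-inverse of the
Hessian, block-traced to residue level — the identity the test suite
checks against an independent `MASS::ginv()` route). The correlation
map is the normalised form `C_ij = K_ij/sqrt(K_ii K_jj)` and B-factors
are `B_i = (8π²/3)·kT·K_ii`. Because "average correlation over modes"
is stated ambiguously in parts of the literature, the 1/λ-weighted
(thermal) accumulation is the default and an equal-weight per-mode
average is available via `weighting = "equal"`; the two genuinely
differ and neither is claimed to be bit-identical to any particular
published map.

## The mutation model

A point mutation is represented by rescaling every spring incident to
the mutated site by `spring_scale` (both endpoints mutated: the scales
multiply). This is deliberately the simplest perturbation consistent
with the physical picture of a buried hydrophobic residue replaced by a
polar one — local packing interactions weaken, nothing else changes.
The default `spring_scale = 0.5` halves the local stiffness; it is a
modelling choice, not a fitted constant, and every result that depends
on it should be read as "given a local softening of this magnitude".
Values above 1 model rigidifying substitutions. The coupling score
(mean |C| between the mutation site and the motif residues, site
excluded from the motif if inside it) summarises how strongly the two
regions move together; the package reports it without a significance
threshold, because no principled cutoff exists at this level of
coarse-graining.

## Dynamics

`simulate_enm()` integrates overdamped (Brownian) Langevin dynamics
with the Euler–Maruyama update

    x ← x − (Δt/ζ) H (x − x₀) + sqrt(2 kT Δt/ζ) η

This integrator was chosen over velocity Verlet with a thermostat
because its stationary distribution is exactly the Boltzmann
distribution of the quadratic model, which turns validation into
closed-form arithmetic: the dimer's bond-stretch normal coordinate is a
1-D Ornstein–Uhlenbeck process with variance kT/(2γ), and long-run
windowed fluctuations of any network must converge to the covariance
diagonal (equipartition). Both are asserted in the test suite — the
dimer within 5%, per-site dimer B-factors within 10%, and the 30-site
helix profile at Pearson r > 0.9 against the NMA profile.

One amendment to the bare update is essential. The six rigid-body
modes have no restoring force, so under the bare update they perform an
unbounded random walk — and because the "rotations" among them are
tangent-space linearisations, large excursions along them physically
stretch the structure (a dimer's bond length grows without limit) in a
way no after-the-fact superposition can undo. The integrator therefore
projects each step increment onto the orthogonal complement of the
rigid-body subspace (`remove_rigid = TRUE`), the Brownian analogue of
centre-of-mass motion removal in MD engines. The trajectory then stays
in the internal subspace, where the harmonic model is exact; internal
statistics are unaffected because the projection commutes with the
internal dynamics. Setting `remove_rigid = FALSE` recovers the bare
update for short-time studies.

Stability requires `Δt < 2ζ/λ_max`; the simulator warns using a
Gershgorin bound on λ_max before integrating and aborts with the step
number if any displacement exceeds 10³ length units. Noise is drawn
from R's RNG inside the compiled kernel, so a trajectory is exactly
reproducible from its recorded seed, across platforms.

Trajectory statistics mirror MD-analysis conventions: RMSD versus the
starting conformation (frame 0 is always the start), a trailing-window
mean with `window = 0.5` implementing "analyse only the second half",
and windowed B-factors. For a motif, two superposition conventions are
exposed because the right one depends on the question: `fit_all`
(default) fits on all sites and measures motif deviation in the
molecular frame — motion of the motif relative to the rest — while
`fit_motif` fits on the motif itself and measures only its internal
deformation; the least-squares property `fit_motif ≤ fit_all` holds
frame by frame. Windowed B-factors superpose every window frame onto
the first window frame, then onto an iteratively re-averaged mean
structure (3 rounds), fitting on the whole structure; per-domain
fitting is deliberately not offered at this scale.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `cutoff` | 13 | Å | common Cα-ANM practice; large enough that compact folds are rigid |
| `gamma` | 1 | energy/Å² (arbitrary) | sets the overall scale only; shapes are γ-independent |
| `n_modes` | 50 | — | low-frequency modes carry the collective motions; clamped with a warning on small systems |
| `spring_scale` | 0.5 | — | "halved local packing" softening; a modelling choice, configurable |
| `timestep` | 0.01 | reduced time | ~1/16 of the fastest mode period at default parameters; well inside the stability bound |
| `n_steps`, `save_every` | 200 000, 100 | — | many small steps, sparse saving, trailing half analysed — the usual MD bookkeeping at desk scale |
| `kT`, `friction` | 1, 1 | reduced | defines the unit system; kT = 0 gives gradient descent |
| `window` | 0.5 | fraction | discard the equilibration half |

Masses default to 1, making mass-weighting the identity; per-residue
masses are accepted for experiments and rescale the spectrum without
changing mass-weighted mode shapes.

## The synthetic structures, and what tests do and do not show

`make_structure()` generates three kinds of seeded Cα toys: ideal
helices (canonical rise 1.5 Å, twist 100°, radius 2.3 Å, giving the
textbook 3.8 Å Cα spacing), a helix–loop–helix fold whose 4-residue
connecting loop is annotated as the motif (with the loop-adjacent
residue as the default mutation site — a miniature of a binding loop
flanked by packed secondary structure), and minimum-separation random
clouds. All are compact and connected at the default cutoff, which the
test suite verifies across dozens of seeds by counting zero modes.

These toys exercise every code path, but they are geometry, not
biology: no sidechains, no anharmonicity, no solvent, no real fold
topology, and the mutation model collapses chemistry into one scalar.
Passing tests therefore demonstrate that the linear algebra, the
stochastic integrator, and the statistics are correct and internally
consistent — not that a 0.5 spring scaling quantitatively reproduces
any particular experimental mutant. On real structures the pipeline's
outputs should be read comparatively (mutant minus WT, site ranked
against site), which is how the report object presents them.

## Numerical and design choices

* Indices are 1-based throughout, following R convention; users
  address residues by author numbering (e.g. a motif "residues
  71–90"), which `resolve_selection()` maps to site indices, erroring
  on absent residues rather than silently shrinking a selection.
* PDB I/O delegates to bio3d; only Cα atoms of protein residues are
  kept, the first-listed altloc wins, insertion codes are rejected,
  and multi-model files are addressed by model number (trajectories
  are written as one MODEL per frame with a key-value sidecar carrying
  seed and parameters).
* A 2-site dimer is accepted by `build_hessian()` as the closed-form
  reference case; any larger collinear arrangement is rejected as
  degenerate, as are superpositions onto fewer than 3 or collinear
  reference points. Correlation entries are clamped to [−1, 1] against
  last-bit rounding and the diagonal is set to exactly 1.
* `run_pipeline()` always computes the WT variant; mutants are
  analysed one at a time and all variants share the same simulation
  seed (common random numbers), so variant deltas are not noise
  deltas. Reports carry a provenance block (config hash, structure
  hash, seed, package version) and `write_report()` emits every table
  as CSV before the report is returned; reruns are byte-identical.
* The Hardy–Weinberg module defaults to the rare-allele shorthand
  (carrier ≈ 2p) because that is the arithmetic clinical genetics
  papers print (p = 0.004 → 0.8%, 1:125, 1:62 500); the exact
  2p(1−p) convention is one argument away, and carrier-to-allele
  inversion in the exact convention refuses carrier > 0.5, where no
  real root exists.
* Test and validation problem sizes — networks of 10–60 sites,
  trajectories of 6×10⁴–4×10⁵ steps — were chosen so that the slowest
  relaxation time of each fixture (1/λ_min, about 18 reduced time
  units for the 30-residue helix) is covered a few hundred times over,
  which is what the equipartition assertions require statistically.

## Limitations

The elastic network sees only Cα geometry: mutations that act through
charge, specific hydrogen bonds, or backbone rearrangement are outside
the model, and absolute B-factor or RMSD magnitudes are in arbitrary
units fixed by γ and kT. Minimum distances are Cα–Cα and systematically
exceed all-atom contact distances on the same structure. The Langevin
stand-in has no solvent, no pressure coupling, and no bond constraints;
it is a sampler of the harmonic model's Boltzmann distribution, not an
approximation to all-atom MD beyond that role.
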