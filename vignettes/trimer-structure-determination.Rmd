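---
title: "Determining C3-symmetric trimer structures from ambiguous NOE restraints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Determining C3-symmetric trimer structures from ambiguous NOE restraints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prismfold)
```

## The problem

Small lectins such as the 40-residue core-fucosylation-specific peptide
whose sequence ships with this package assemble into symmetric
homotrimers.  Solution NMR of such a system faces a characteristic
degeneracy: the three chains are chemically identical, so every proton of
chain A resonates exactly where its copies on chains B and C do.  A NOESY
cross peak between, say, the amide proton of residue 29 and that of
residue 37 therefore does not say whether the contact is *within* one
chain or *between* two chains.  For a strand-swapped β-prism this is the
whole ball game: the fold is defined by which β-strand interfaces are
intermolecular.

`prismfold` implements the complete computational workflow for this
situation:

1. **Restraint construction** (`noe_peaks()`, `classify_noe()`,
   `intensity_to_bound()`, `assign_ambiguity()`, `hbond_restraints()`,
   `symmetrize()`): peaks are classed by residue separation
   (sequential, medium-range `2 ≤ |i−j| ≤ 4`, long-range `|i−j| > 4`) and
   by intensity, with upper distance bounds of 3.5, 4.5 and 6.0 Å for
   large, medium and small peaks.  Sequential peaks are always treated as
   intramolecular; medium/long-range peaks are ambiguous unless an
   interface pinning map fixes them.  Every restraint is replicated once
   per chain, so one NOE yields three constraints for the trimer.
2. **Restrained annealing** (`prepare_system()`, `anneal()`,
   `accept()`, `select_ensemble()`): a Cartesian annealer minimises a
   restraint energy under non-crystallographic symmetry, and structures
   are accepted when no distance restraint is violated by more than
   0.2 Å and no torsion restraint by more than 2°.  The conventional
   ensemble is the 20 lowest-energy accepted structures.
3. **Register resolution** (`enumerate_hypotheses()`,
   `evaluate_hypothesis()`, `resolve_register()`): competing
   intramolecular/intermolecular assignments for an interface are
   compared by their annealing acceptance counts.
4. **Ensemble analysis** (`superpose()`, `mean_structure()`,
   `ensemble_rmsd()`, `contacts()`, `contact_fractions()`, `nh_pi()`):
   precision statistics against the unminimized mean, distance-only
   binding-pocket contact maps, and NH–π geometry of aromatic triads.
5. **Binding thermodynamics** (`fraction_bound()`, `fit_kd()`,
   `delta_delta_g()`, `population_from_intensities()`,
   `std_difference()`): fast-exchange chemical-shift titration fitting
   and free-energy bookkeeping.

## The ambiguity model

Ambiguous restraints are evaluated through the sum-averaged effective
distance

$$ d_\mathrm{eff} = \Big(\sum_k d_k^{-6}\Big)^{-1/6}, $$

where the candidates $d_k$ run over the allowed chain pairings: the own
chain plus both cyclic neighbours for an ambiguous restraint, and both
neighbours for a restraint pinned as intermolecular (a peak cannot
distinguish the clockwise from the anticlockwise neighbour).  The same
machinery serves equivalent-proton groups.  Because
$d_\mathrm{eff} \le \min_k d_k$, an ambiguous restraint is satisfied
whenever any one pairing satisfies it — exactly the permissiveness the
symmetric blinding demands.  The flat-bottom well is harmonic outside
`[lower, upper]` with a continuous first derivative; the lower bound for
NOE restraints is the van der Waals contact floor of 1.8 Å (only upper
bounds carry experimental information).  Hydrogen bonds contribute two
restraints each with the conventional windows 1.8–2.3 Å (H⋯acceptor) and
2.8–3.3 Å (donor heavy atom⋯acceptor).

## The annealer

The energy model contains: covalent geometry encoded as exact distance
terms (bonds, 1–3 distances, and the omega-locked 1–4 pairs of the trans
peptide plane — a deliberately Cartesian re-expression of ideal
topology), flat-bottom NOE/hydrogen-bond wells (`k_noe`, default 30),
flat-bottom torsion wells on χ rotamers, a repulsive-only soft-sphere
nonbonded term, and a harmonic NCS penalty at 10 kcal mol⁻¹ Å⁻² measuring
each chain's deviation from the symmetry-averaged chain after optimal
superposition (exactly symmetric conformers score zero).

A trial proceeds in stages whose "temperatures" are control parameters of
the coordinate-noise amplitude, not physical temperatures; the published
full protocol (50 000 K for the high-temperature and first cooling stage,
2 000 K for the second) and the reduced complex protocol (1 000 K × 3)
are both expressible, and the desk-scale default keeps the temperature
profile with 100 steps per stage.  Three numerical choices matter:

* **Symmetry-reduced search.**  During the search phases only the
  reference chain's coordinates are free; the other chains are its exact
  120°/240° images.  This removes the chain-placement degeneracies from
  the search space.  The final refinement releases all chains under the
  NCS restraint.
* **Soft-to-hard weighting.**  The search phases run with weakened
  covalent terms and no repulsion so restraints can reorganise topology;
  the repulsive term and full covalent weights return for polishing.
* **Well-slack ramp.**  Restraint wells are widened by up to 1.5 Å at the
  hottest stage and sharpened on cooling (`slack` argument of the energy
  evaluator), the restraint-space analogue of force-constant ramping.

Each trial is a pure function of its seed (trial *k* of a series uses
`master_seed + k`), ensemble selection breaks energy ties by trial order,
and the acceptance thresholds (0.2 Å, 2°) are applied inclusively.

## The synthetic generators

`make_toy_trimer()` builds exactly C3-symmetric ground truths with ideal
covalent geometry from internal coordinates (reduced residues with
N, H, CA, HA, CB, HB, C, O; the single HB pseudo-proton stands in for the
β protons).  Two templates are provided: a head-to-tail triangle of
α-helices, and a strand-swapped β-prism in which strand 2 of each chain
pairs antiparallel — with genuine N–H⋯O=C hydrogen bonds — with strand 1
of the next chain, the minimal analogue of a swapped β-prism.  The prism's
sheet unit is solved once by a grid search over strand roll and axial
slide maximising hydrogen-bond count without steric overlap, and its turn
is rigid-placed and then refined against the covalent link template under
steric floors that keep turn protons outside NOE range of the neighbour
chains (so turn peaks are purely intramolecular, as the generating
interface map asserts).

`simulate_noes()` emits a peak for every proton pair within 5.0 Å, with
intensity classes assigned from the true distance at edges 2.7/3.6/5.0 Å
— always below the corresponding 3.5/4.5/6.0 Å bounds, so the generating
structure satisfies every emitted restraint exactly (a property the test
suite asserts).  Crucially the peaks are *blinded*: they record residue
and atom names only, and intra/intermolecular duplicates merge keeping
the tighter class.  `simulate_hbonds()` reads donors off the structure
requiring both the H⋯O and the heavy-atom window, mirroring the practice
of assigning acceptors from a calculated structure.
`simulate_titration()` adds Gaussian noise to the exact 1:1 fast-exchange
curve.

What the generators do **not** emulate: real side chains (and hence χ
torsion data, aromatic packing and the bulk of long-range contacts), peak
overlap and misassignment, spin diffusion, and realistic intensity noise.
Passing pipeline tests on these toys demonstrates the correctness of the
bookkeeping and the optimiser's behaviour, not performance on real
spectra.

## Known limitations: information content at toy scale

Two collective degeneracies of the toy systems deserve explicit
statement, because they bound what fold-recovery experiments can show.
First, the *hinge mode*: the dihedral angle between the two sheets that
share a chain is spanned by no restraint — the edge-to-edge contacts that
would pin it occupy the same residue-pair register as the sheet diagonals,
so the symmetric blinding merges them.  Second, the *neighbour gauge*:
every intermolecular restraint is sum-averaged over both cyclic
neighbours, and different restraints may be satisfied towards different
neighbours.  In consequence, structures exist that satisfy every
simulated restraint to numerical precision while differing from the
generating fold by several Å of backbone RMSD; annealing runs recover the
local structure (per-strand RMSD below 1 Å, correct hydrogen-bond
pattern) but not a unique global fold.  At the restraint density of a
real system (roughly 19 constraints per residue, with full side chains
and torsion data against ~7 per residue here) these modes are pinned; at
toy scale they are not.  The same information limit applies to
register resolution by acceptance counts: with upper-bound-only data a
self-pairing register can always be realised as a hairpin, so both
hypotheses produce acceptable structures and the resolver reports its
tie/unresolved outcome rather than the decisive contrast seen with real
data.  The package reports these experiments honestly rather than tuning
the generator towards them.

For benchmarks of the *optimiser* itself, `noe_restraints()` offers an
idealized-calibration mode (`bounds = "exact"`) restraining each blinded
pair to `[0.85 d, d]` around the generating distance, the 15% floor
absorbing the sum-averaging depression of merged symmetric duplicates.

## Binding model

Titration fitting assumes three independent, identical sites per trimer,
so the protein concentration entering `fraction_bound()` is the *site*
concentration.  The bound fraction uses the numerically stable root of
the 1:1 quadratic, which passes smoothly to the excess-ligand limit
L/(L+K_D) as the protein concentration vanishes.  `fit_kd()` profiles
the residual sum of squares over log K_D — the two shift parameters enter
linearly and are solved exactly at each trial K_D — which makes the fit
independent of starting values; standard errors come from the local
Jacobian.  Free-energy differences use ΔΔG = RT ln(K₁/K₂) with
R = 1.987×10⁻³ kcal mol⁻¹ K⁻¹ at 298.15 K by default (the reference
conversion is consistent with 298 K even though the experiments
themselves ran at 308 K; both are supported through `T_K`).

Contact maps are distance-only by definition: hydrophobic contacts are
carbon pairs within 4.5 Å, hydrogen bonds nitrogen/oxygen pairs within
3.5 Å, both inclusive, with no angular term.  Ensemble contact fractions
pool the symmetry-equivalent pockets (members × 3; 60 pockets for a
20-model trimer ensemble) and class contacts as bold (≥ 50%), thin
(≥ 20%) or omitted.  The NH–π geometry uses the least-squares plane of
the six-membered indole ring (CD2, CE3, CZ3, CH2, CZ2, CE2) and reports
both the proton-to-plane distance and whether the projection falls inside
the ring hexagon.

## Problem sizes

The shipped studies use 12 residues per chain (288 atoms per trimer),
20 annealing trials for ensemble work and 2 trials per hypothesis per
master seed across 10 seeds for register comparisons, 100 synthetic
titrations for the K_D recovery study, and the desk-scale three-stage
schedule of 100 steps per stage.  All of these are configuration, not
algorithm: the same code runs the published-scale protocols by changing
the schedule and trial counts.

## A worked example

```{r example, eval = FALSE}
conf <- make_toy_trimer(12, "beta_prism_surrogate")
peaks <- assign_ambiguity(simulate_noes(conf), toy_truth(conf)$fixed_map)
rset <- restraint_set(rbind(noe_restraints(peaks),
                            hbond_restraints(simulate_hbonds(conf))))
sys <- prepare_system(conf, rset)
trials <- anneal_trials(sys, 10, master_seed = 1)
ens <- select_ensemble(trials, n = 10)
ensemble_rmsd(ens, "backbone")

series <- simulate_titration(5.9e-3, 8.52, 8.87, 1.5e-4,
                             c(0.5, 1, 2, 5, 10, 25, 50, 100) * 1e-3,
                             noise_sd = 0.007, seed = 1)
fit_kd(series)
delta_delta_g(5.9e-3, 3e-6)   # ~4.5 kcal/mol
```
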