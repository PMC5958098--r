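# prismfold

Structure determination and binding analysis for small C3-symmetric
homotrimeric lectins from solution NMR restraints.

## What this solves

A symmetric homotrimer gives NMR spectra with a *single* set of
resonances: intra- and intermolecular NOE cross peaks between
symmetry-equivalent protons are indistinguishable.  For strand-swapped
folds — such as the 40-residue core-fucosylation-specific mushroom lectin
whose sequence ships with this package, a β-prism of three antiparallel
sheets connected by strand swapping — the fold is *defined* by which
β-strand interfaces are intermolecular, so this ambiguity must be
confronted head on.  `prismfold` implements the full workflow:

* **Restraint construction** — NOE peaks classed by residue separation
  (sequential / medium-range 2 ≤ |i−j| ≤ 4 / long-range) and intensity
  (upper bounds 3.5, 4.5, 6.0 Å), sequential peaks fixed intramolecular,
  interface pinning maps for the rest, ambiguity via the sum-averaging
  effective distance (Σ dₖ⁻⁶)^(−1/6), hydrogen-bond restraints
  (1.8–2.3 / 2.8–3.3 Å), and ×3 replication over the symmetric trimer.
* **Cartesian restrained simulated annealing** under non-crystallographic
  symmetry (10 kcal mol⁻¹ Å⁻²), with the acceptance filter "no distance
  violation > 0.2 Å, no torsion violation > 2°" and selection of the
  lowest-energy accepted structures (20 by convention).
* **Interface-register resolution** by competing annealing trials: each
  inter/intramolecular hypothesis is scored by its acceptance count.
* **Ensemble analysis** — Kabsch superposition, unminimized mean
  structures, ensemble RMSD statistics, distance-only binding-pocket
  contact maps (C–C ≤ 4.5 Å hydrophobic, N/O–N/O ≤ 3.5 Å hydrogen bonds,
  bold ≥ 50% / thin ≥ 20% of the pooled pockets), and NH–π triad
  geometry from least-squares indole ring planes.
* **Fast-exchange titration thermodynamics** — exact 1:1 binding
  (δ_obs = δ_free + (δ_bound − δ_free)·f_b with f_b from the stable
  quadratic root), profiled least-squares K_D fitting, and
  ΔΔG = RT ln(K₁/K₂).
* **Synthetic data** — exactly C3-symmetric toy trimers with ideal
  covalent geometry, symmetry-blinded NOE peak lists whose generating
  structure satisfies every emitted restraint, structure-derived hydrogen
  bond lists, and noisy titration curves.  Everything is testable with no
  external downloads.

## A worked example

```r
library(prismfold)

sequence_mass(phosl_sequence())
#> [1] 4436.98          # Da; the ~4.5 kDa monomer of the trimer

# fast-exchange titration fitting
series <- simulate_titration(5.9e-3, 8.52, 8.87, 1.5e-4,
                             c(0.5, 1, 2, 5, 10, 25, 50, 100) * 1e-3,
                             noise_sd = 0.007, seed = 1)
fit_kd(series)
#> <binding_fit> sim: K_D = 0.00554 M (se 0.00053), shifts 8.515 -> 8.87 ppm

delta_delta_g(5.9e-3, 3e-6)
#> [1] 4.49             # kcal/mol across the ~1967-fold affinity gap

# the symmetric-ambiguity machinery
pk <- noe_peaks(c(29, 5), c("H", "HA"), c(37, 6), c("H", "H"),
                c("medium", "large"))
assign_ambiguity(pk, phosl_interface_map())[, c("res_i", "res_j",
                                                "range_class", "ambiguity")]
#>   res_i res_j range_class      ambiguity
#> 1    29    37  long_range intermolecular   # pinned beta3-beta4 interface
#> 2     5     6  sequential intramolecular   # sequential peaks always intra
```

The K_D printed above means the simulated resonance reaches half its
total perturbation at a free-ligand concentration of ~5.5 mM, recovered
from the noisy curve to within the reported standard error of the 5.9 mM
generating value; the 4.49 kcal/mol is the free-energy equivalent of the
~2000-fold affinity gap between the monosaccharide and the intact
N-glycan.

A full structure run on synthetic data:

```r
conf  <- make_toy_trimer(12, "beta_prism_surrogate")
peaks <- assign_ambiguity(simulate_noes(conf), toy_truth(conf)$fixed_map)
rset  <- restraint_set(rbind(noe_restraints(peaks),
                             hbond_restraints(simulate_hbonds(conf))))
sys    <- prepare_system(conf, rset)
trials <- anneal_trials(sys, 20, master_seed = 1)
ens    <- select_ensemble(trials, n = 20)
ensemble_rmsd(ens, "backbone")
```

A command-line wrapper with the same functionality is installed at
`inst/scripts/prismfold` (subcommands `simulate`, `restraints`, `anneal`,
`resolve`, `analyze`, `fit-kd`, `report`).

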