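test_that("toy trimers are exactly C3-symmetric and structurally complete", {
  for (fold in c("beta_prism_surrogate", "three_helix_bundle_surrogate")) {
    conf <- if (fold == "beta_prism_surrogate") toy_prism() else toy_ring()
    expect_length(validate_trimer(conf)$flags, 0)
    expect_lt(ncs_energy(conf), 1e-12)
    # chain B is the exact 120-degree image of chain A
    at <- conf$atoms
    A <- as.matrix(at[at$chain == "A", c("x", "y", "z")])
    B <- as.matrix(at[at$chain == "B", c("x", "y", "z")])
    expect_equal(A %*% t(rot_z(120)), B, tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(toy_truth(conf)$fold, fold)
  }
  expect_identical(coords(make_toy_trimer(10, "three_helix_bundle_surrogate")),
                   coords(make_toy_trimer(10, "three_helix_bundle_surrogate")))
  expect_error(make_toy_trimer(4), "n_res")
  expect_error(toy_truth(toy_prism()$atoms |> conformer()), "ground truth")
})

test_that("simulated peaks are blinded, merged, and class-consistent", {
  # two protons at 3.0 A (same residue pair as a 5.8 A symmetric partner):
  # one merged peak, tighter class wins
  xyz <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 5.8, 0))
  conf <- mini_conformer(chain = c("A", "B", "C"), resno = c(1L, 5L, 5L),
                         resid = "ALA", elety = c("HA", "HA", "HA"),
                         elesy = "H", xyz = xyz)
  pk <- simulate_noes(conf, cutoff = 6.0, class_edges = c(2.7, 3.6, 5.9))
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$intensity_class, "medium")  # 3.0 A, not the 5.8 A copy
  expect_false(any(c("chain", "chain_i") %in% names(pk)))

  # class ladder from true distance
  close_pair <- mini_conformer(c("A", "A"), c(1L, 3L), "ALA", c("HA", "HA"),
                               "H", rbind(c(0, 0, 0), c(2.5, 0, 0)))
  expect_equal(simulate_noes(close_pair)$intensity_class, "large")

  expect_equal(nrow(simulate_noes(toy_prism(), false_negative_rate = 1)), 0L)
  expect_error(simulate_noes(toy_prism(), class_edges = c(2.7, 3.6, 6.5)),
               "ladder")
  noh <- conformer(toy_prism()$atoms[toy_prism()$atoms$elesy != "H", ])
  expect_error(simulate_noes(noh), "protons")
})

test_that("the generating trimer satisfies every emitted restraint", {
  for (conf in list(toy_prism(), toy_ring())) {
    sys <- prepare_system(conf, toy_restraints(conf))
    v <- compute_violations(conf, sys)
    expect_equal(v$max_dist, 0, tolerance = 1e-9)
    expect_equal(v$max_tors, 0)
  }
})

test_that("peak simulation is a pure function of its seed", {
  conf <- toy_prism()
  a <- simulate_noes(conf, false_negative_rate = 0.3, seed = 5)
  b <- simulate_noes(conf, false_negative_rate = 0.3, seed = 5)
  c <- simulate_noes(conf, false_negative_rate = 0.3, seed = 6)
  expect_identical(a, b)
  expect_false(identical(a, c))
})

test_that("hydrogen-bond detection finds the swapped-sheet bonds", {
  don <- simulate_hbonds(toy_prism())
  expect_true(any(don$ambiguity == "intermolecular"))
  # no spurious sequential 'bonds'
  expect_true(all(abs(don$res_d - don$res_a) > 2 |
                    don$ambiguity == "intermolecular"))
})

test_that("simulated titrations follow the fast-exchange model", {
  # midpoint shift at L = K_D in the dilute limit
  s <- simulate_titration(5e-3, 1, 2, 1e-9, c(1e-4, 5e-3, 1), noise_sd = 0)
  expect_equal(s$delta_obs[2], 1.5, tolerance = 1e-3)
  # two seeds: same curve, different noise
  a <- simulate_titration(5e-3, 1, 2, 1e-4, c(1, 2, 5, 10) * 1e-3, 0.01, seed = 1)
  b <- simulate_titration(5e-3, 1, 2, 1e-4, c(1, 2, 5, 10) * 1e-3, 0.01, seed = 2)
  expect_false(identical(a$delta_obs, b$delta_obs))
  expect_error(simulate_titration(5e-3, 1, 2, 1e-4, c(1e-3), -0.1),
               "noise_sd")
})
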