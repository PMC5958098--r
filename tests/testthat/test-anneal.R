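test_that("sum-averaged effective distance follows the r^-6 closed form", {
  expect_equal(effective_distance(4), 4)
  expect_equal(effective_distance(c(4, 4)), 4 * 2^(-1 / 6), tolerance = 1e-12)
  expect_equal(effective_distance(c(3, 100)), 3, tolerance = 1e-6)
  # never exceeds the smallest contributor; adding contributors shrinks it
  set.seed(9)
  for (k in 1:10) {
    d <- runif(sample(2:6, 1), 2, 9)
    eff <- effective_distance(d)
    expect_lte(eff, min(d))
    expect_lt(effective_distance(c(d, 5)), eff + 1e-12)
  }
  expect_error(effective_distance(numeric(0)), "at least one")
  expect_error(effective_distance(c(3, -1)), "positive")
})

test_that("flat-bottom restraint term is zero inside and smooth at bounds", {
  expect_equal(restraint_energy(4.0, 1.8, 4.5), 0)
  expect_equal(restraint_energy(5.0, 1.8, 4.5, k = 1), 0.25)
  expect_equal(restraint_energy(1.3, 1.8, 4.5, k = 2), 2 * 0.25)
  # numerical derivative vanishes approaching the upper bound from inside
  h <- 1e-7
  dE <- (restraint_energy(4.5 + h, 1.8, 4.5) -
           restraint_energy(4.5 - h, 1.8, 4.5)) / (2 * h)
  expect_lt(abs(dE), 1e-6)
  expect_error(restraint_energy(3, 5, 4), "lower <= upper")
})

test_that("NCS energy vanishes for exact symmetry and penalises deformation", {
  conf <- toy_prism()
  expect_lt(ncs_energy(conf), 1e-12)
  expect_equal(ncs_energy(conf, k_ncs = 0), 0)
  # deform one atom of one chain: positive, linear in the force constant
  at <- conf$atoms
  i <- which(at$chain == "B")[5]
  at$x[i] <- at$x[i] + 1.5
  bent <- conformer(at)
  e10 <- ncs_energy(bent, k_ncs = 10)
  expect_gt(e10, 0)
  expect_equal(ncs_energy(bent, k_ncs = 20), 2 * e10, tolerance = 1e-9)
  expect_error(ncs_energy(conformer(at[at$chain != "C", ])), "identical")
})

test_that("acceptance filter applies both thresholds inclusively", {
  mk <- function(dv, tv) {
    cf <- toy_prism()
    cf$max_dist_viol <- dv
    cf$max_tors_viol <- tv
    cf
  }
  expect_true(accept(mk(0.19, 1.9))$accepted)
  expect_false(accept(mk(0.21, 0))$accepted)
  expect_false(accept(mk(0.0, 2.5))$accepted)
  expect_true(accept(mk(0.2, 2.0))$accepted)   # boundary is inclusive
  # monotone: loosening a threshold never flips accept -> reject
  th1 <- acceptance_thresholds(0.2, 2)
  th2 <- acceptance_thresholds(0.3, 3)
  for (case in list(c(0.05, 1), c(0.25, 1), c(0.1, 2.4), c(0.28, 2.9))) {
    if (accept(mk(case[1], case[2]), th1)$accepted) {
      expect_true(accept(mk(case[1], case[2]), th2)$accepted)
    }
  }
})

test_that("ensemble selection keeps the n lowest-energy accepted models", {
  mk <- function(e, dv = 0) {
    cf <- toy_prism()
    cf$energy <- e
    cf$max_dist_viol <- dv
    cf$max_tors_viol <- 0
    cf
  }
  trials <- c(lapply(c(5, 3, 9, 1, 7), mk), list(mk(0.5, dv = 1)))
  ens <- select_ensemble(trials, n = 3)
  expect_length(ens$members, 3L)
  expect_equal(vapply(ens$members, `[[`, numeric(1), "energy"), c(1, 3, 5))
  # shortage branch returns all accepted with a warning
  expect_warning(short <- select_ensemble(trials, n = 20), "only 5")
  expect_length(short$members, 5L)
  # all-rejected: empty ensemble with explicit status
  none <- select_ensemble(list(mk(1, dv = 1)), n = 20)
  expect_length(none$members, 0L)
  expect_match(none$selection_note, "no acceptable")
  # ties broken by trial order (stable)
  tied <- lapply(c(2, 2, 2, 2), mk)
  tied[[2]]$model_id <- 99L
  sel <- select_ensemble(tied, n = 2)
  expect_length(sel$members, 2L)
})

test_that("the generating structure is a fixed point of the energy", {
  # conservation check for the whole restraint pipeline: the toy structure
  # scores zero on every restraint term of its own restraint set
  conf <- toy_prism()
  sys <- prepare_system(conf, toy_restraints(conf))
  v <- compute_violations(conf, sys)
  expect_equal(v$max_dist, 0, tolerance = 1e-9)
  expect_equal(v$max_tors, 0)
})

test_that("annealing is deterministic for a fixed seed and handles no data", {
  conf <- toy_prism()
  sys <- prepare_system(conf, toy_restraints(conf))
  sched <- anneal_schedule(steps = c(20, 20, 20))
  r1 <- anneal(sys, schedule = sched, seed = 42, polish_maxit = 100)
  r2 <- anneal(sys, schedule = sched, seed = 42, polish_maxit = 100)
  expect_identical(coords(r1), coords(r2))

  empty <- restraint_set(noe_restraints(assign_ambiguity(
    noe_peaks(integer(0), character(0), integer(0), character(0),
              character(0)))))
  sys0 <- prepare_system(conf, empty)
  r0 <- anneal(sys0, schedule = anneal_schedule(steps = c(5, 5, 5)),
               seed = 1, polish_maxit = 50)
  expect_equal(r0$max_dist_viol, 0)
  expect_true(accept(r0)$accepted)
})

test_that("torsion restraints contribute flat-bottom angular violations", {
  # a synthetic chi1 quadruple: N-CA-CB-CG at a known dihedral
  p1 <- c(0, 0, 0); p2 <- c(1.46, 0, 0)
  p3 <- p2 + c(0.5, 1.4, 0)
  mk_cg <- function(chi) {
    prismfold:::place_atom(p1, p2, p3, 1.52, 114, chi)
  }
  at <- data.frame(
    chain = "A", resno = 1L, resid = "LEU",
    elety = c("N", "CA", "CB", "CG"), elesy = "C",
    x = 0, y = 0, z = 0, stringsAsFactors = FALSE)
  xyz <- rbind(p1, p2, p3, mk_cg(-95))
  at[, c("x", "y", "z")] <- xyz
  conf <- conformer(at)
  tors <- torsion_restraints(1L, "chi1", -60, tolerance = 20)
  # single chain: use an order-1 'symmetry' so the chain is not triplicated
  sys <- prepare_system(conf, restraint_set(
    noe_restraints(assign_ambiguity(noe_peaks(integer(0), character(0),
                                              integer(0), character(0),
                                              character(0)))), tors),
    sym = symmetry_model(1L, "A"))
  v <- compute_violations(conf, sys)
  expect_equal(v$max_tors, 15, tolerance = 1e-4)  # |-95 - (-60)| - 20
  expect_false(accept(v)$accepted)
  # inside the tolerance window the violation vanishes
  at[4, c("x", "y", "z")] <- mk_cg(-70)
  v2 <- compute_violations(conformer(at), sys)
  expect_equal(v2$max_tors, 0)
})
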