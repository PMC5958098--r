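test_that("NOE range classes follow the residue-separation definition", {
  expect_equal(classify_noe(5, 6), "sequential")
  expect_equal(classify_noe(5, 8), "medium_range")
  expect_equal(classify_noe(5, 12), "long_range")
  expect_equal(classify_noe(5, 5), "intra_residue")
  expect_equal(classify_noe(c(1, 3, 9), c(2, 7, 2)),
               c("sequential", "medium_range", "long_range"))
  expect_error(classify_noe(-1, 4), "positive")
})

test_that("intensity classes map onto the 3.5/4.5/6.0 A bound ladder", {
  expect_equal(intensity_to_bound(c("large", "medium", "small")),
               c(3.5, 4.5, 6.0))
  expect_error(intensity_to_bound("huge"), "unknown intensity class")
})

test_that("ambiguity assignment honours sequential rule and pinned regions", {
  pk <- noe_peaks(res_i = c(5, 29, 3, 1),
                  atom_i = c("HA", "H", "H", "H"),
                  res_j = c(6, 37, 25, 20),
                  atom_j = c("H", "H", "H", "H"),
                  intensity_class = rep("medium", 4))
  out <- assign_ambiguity(pk, phosl_interface_map())
  expect_equal(out$ambiguity,
               c("intramolecular",   # sequential, always
                 "intermolecular",   # beta3-beta4 interface pin
                 "ambiguous",        # outside all pinned regions
                 "ambiguous"))
  # sequential peaks stay intramolecular under any map
  pinned_seq <- interface_map("x", 5, 5, 6, 6, "intermolecular")
  expect_equal(assign_ambiguity(pk, pinned_seq)$ambiguity[1],
               "intramolecular")
})

test_that("conflicting pins for one region pair raise an error", {
  pk <- noe_peaks(10, "H", 20, "H", "small")
  bad <- interface_map(c("i1", "i2"), c(9, 8), c(11, 12), c(19, 18),
                       c(21, 22), c("intramolecular", "intermolecular"))
  expect_error(assign_ambiguity(pk, bad), "conflicting")
})

test_that("symmetrization triples counts and is idempotent", {
  # 202 unique sequential peaks -> 606 constraints
  pk <- noe_peaks(res_i = 1:202, atom_i = "HA", res_j = 2:203,
                  atom_j = "H", intensity_class = "large")
  rs <- restraint_set(noe_restraints(assign_ambiguity(pk)))
  sym <- symmetrize(rs)
  expect_equal(restraint_counts(sym)$sequential, 606L)
  expect_equal(max(sym$groups$group), 606L)
  expect_identical(symmetrize(sym), sym)  # guarded by flag

  empty <- restraint_set(noe_restraints(assign_ambiguity(
    noe_peaks(integer(0), character(0), integer(0), character(0),
              character(0)))))
  expect_equal(nrow(symmetrize(empty)$distance), 0L)
})

test_that("ambiguity classes expand to the right candidate counts", {
  pk <- assign_ambiguity(noe_peaks(c(1, 1), "HA", c(2, 8), "H",
                                   c("large", "small")))
  sym <- symmetrize(restraint_set(noe_restraints(pk)))
  g <- sym$groups
  seq_g <- g[g$res_j == 2, ]
  amb_g <- g[g$res_j == 8, ]
  expect_equal(nrow(seq_g), 3L)           # one candidate per chain frame
  expect_equal(nrow(amb_g), 9L)           # three candidates per chain frame
  expect_equal(length(unique(amb_g$group)), 3L)
})

test_that("hydrogen-bond restraints follow the 2-per-bond, x3 rule", {
  don <- data.frame(res_d = 1:20, atom_h = "H", atom_d = "N",
                    res_a = 21:40, atom_a = "O")
  hr <- hbond_restraints(don)
  expect_equal(nrow(hr), 40L)             # 2 per bond, per monomer
  sym <- symmetrize(restraint_set(hr))
  expect_equal(restraint_counts(sym)$hbond, 120L)

  expect_equal(nrow(hbond_restraints(don[0, ])), 0L)
  one <- hbond_restraints(don[1, ])
  expect_equal(nrow(one), 2L)
  expect_equal(one$lower, c(1.8, 2.8))
  expect_equal(one$upper, c(2.3, 3.3))

  noacc <- don
  noacc$res_a[3] <- NA
  expect_warning(hbond_restraints(noacc), "without acceptor")
})

test_that("total distance counting identity holds on synthetic sets", {
  conf <- toy_prism()
  pk <- assign_ambiguity(simulate_noes(conf), toy_truth(conf)$fixed_map)
  don <- simulate_hbonds(conf)
  rs <- symmetrize(restraint_set(rbind(noe_restraints(pk),
                                       hbond_restraints(don))))
  cnt <- restraint_counts(rs)
  expect_equal(cnt$total_distance, 3L * nrow(pk) + 3L * 2L * nrow(don))
})

test_that("restraint tables round-trip byte-exactly", {
  conf <- toy_prism()
  pk <- assign_ambiguity(simulate_noes(conf), toy_truth(conf)$fixed_map)
  dist <- rbind(noe_restraints(pk), hbond_restraints(simulate_hbonds(conf)))
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_restraints(dist, f1)
  write_restraints(read_restraints(f1), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("NOE bounds off the ladder are rejected", {
  bad <- noe_restraints(assign_ambiguity(noe_peaks(1, "H", 5, "H", "large")))
  bad$upper <- 4.0
  expect_error(restraint_set(bad), "ladder")
})
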