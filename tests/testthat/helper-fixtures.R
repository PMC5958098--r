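# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, maker) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- maker()
  .fixture_env[[name]]
}

toy_prism <- function() fixture("prism", function() {
  make_toy_trimer(12, "beta_prism_surrogate")
})

toy_ring <- function() fixture("ring", function() {
  make_toy_trimer(12, "three_helix_bundle_surrogate")
})

# restraints built from a toy under its generating interface map
toy_restraints <- function(conf, hbonds = TRUE) {
  pk <- assign_ambiguity(simulate_noes(conf), toy_truth(conf)$fixed_map)
  dist <- noe_restraints(pk)
  if (hbonds) dist <- rbind(dist, hbond_restraints(simulate_hbonds(conf)))
  restraint_set(dist)
}

# a minimal conformer from explicit atom specs
mini_conformer <- function(chain, resno, resid, elety, elesy, xyz) {
  conformer(data.frame(chain = chain, resno = resno, resid = resid,
                       elety = elety, elesy = elesy,
                       x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                       stringsAsFactors = FALSE))
}

# synthetic Trp triad: three six-membered rings (unit hexagons, radius
# 1.39 A) with HE1 protons of the next chain's residue placed near each
# ring plane
trp_triad <- function(h_height = 3, within = TRUE) {
  ring_names <- c("CD2", "CE3", "CZ3", "CH2", "CZ2", "CE2")
  rows <- list()
  for (k in 0:2) {
    ctr <- c(6, 0, 0) %*% t(rot_z(120 * k))
    ang <- seq(0, 300, by = 60) * pi / 180
    ring <- cbind(ctr[1] + 1.39 * cos(ang), ctr[2] + 1.39 * sin(ang),
                  rep(0, 6))
    rows[[length(rows) + 1L]] <- data.frame(
      chain = LETTERS[k + 1], resno = 32L, resid = "TRP",
      elety = ring_names, elesy = "C",
      x = ring[, 1], y = ring[, 2], z = ring[, 3],
      stringsAsFactors = FALSE)
    # HE1 sits over the *next* chain's ring centre (or off-ring)
    hctr <- c(6, 0, 0) %*% t(rot_z(120 * (k + 1)))
    off <- if (within) c(0, 0) else c(5, 0)
    rows[[length(rows) + 1L]] <- data.frame(
      chain = LETTERS[k + 1], resno = 32L, resid = "TRP",
      elety = "HE1", elesy = "H",
      x = hctr[1] + off[1], y = hctr[2] + off[2], z = h_height,
      stringsAsFactors = FALSE)
  }
  conformer(do.call(rbind, rows))
}
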