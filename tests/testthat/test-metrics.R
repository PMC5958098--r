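test_that("superposition recovers exact transforms", {
  conf <- toy_prism()
  X <- coords(conf)
  # identical sets
  f <- superpose(X, X)
  expect_lt(f$rmsd, 1e-9)
  expect_equal(f$rotation, diag(3), tolerance = 1e-9)
  # 120-degree rotation about z is recovered
  Y <- X %*% t(rot_z(120))
  f2 <- superpose(X, Y)
  expect_lt(f2$rmsd, 1e-9)
  expect_equal(f2$rotation, t(rot_z(120)), tolerance = 1e-8)
})

test_that("Kabsch fit matches a quaternion-grid brute-force oracle", {
  set.seed(11)
  P <- matrix(rnorm(15), 5, 3)
  Q <- P %*% t(rot_z(77)) + matrix(rnorm(15, sd = 0.1), 5, 3)
  fit <- superpose(P, Q)

  quat_rot <- function(q) {
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
             2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
             2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
           3, 3)
  }
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  rms_of <- function(q) sqrt(mean(rowSums((Pc %*% quat_rot(q) - Qc)^2)))
  set.seed(12)
  qs <- matrix(rnorm(4 * 4000), ncol = 4)
  vals <- apply(qs, 1, rms_of)
  best <- stats::optim(qs[which.min(vals), ], rms_of,
                       control = list(maxit = 5000, reltol = 1e-15))
  expect_equal(fit$rmsd, best$value, tolerance = 1e-6)
})

test_that("superposition RMSD is invariant under rigid motion of both sets", {
  set.seed(3)
  P <- matrix(rnorm(30), 10, 3)
  Q <- P + matrix(rnorm(30, sd = 0.3), 10, 3)
  base <- superpose(P, Q)$rmsd
  R <- rot_z(33)
  t0 <- c(4, -2, 7)
  moved <- superpose(sweep(P %*% t(R), 2, t0, "+"),
                     sweep(Q %*% t(R), 2, t0, "+"))$rmsd
  expect_equal(base, moved, tolerance = 1e-9)
})

test_that("degenerate fits are rejected", {
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line + 1), "collinear")
  expect_error(superpose(line[1:2, ], line[1:2, ]), "at least 3")
})

test_that("mean structure is a fixed point for trivial ensembles", {
  conf <- toy_prism()
  ens <- ensemble(list(conf, conf, conf))
  m <- mean_structure(ens)
  expect_lt(superpose(coords(m), coords(conf))$rmsd, 1e-9)
  expect_false(attr(m, "minimized"))
  # global shifts are absorbed by superposition
  shifted <- set_coords(conf, sweep(coords(conf), 2, c(5, 0, 0), "+"))
  m2 <- mean_structure(ensemble(list(conf, shifted)))
  expect_lt(superpose(coords(m2), coords(conf))$rmsd, 1e-8)
  expect_error(mean_structure(ensemble(list())), "empty")
})

test_that("mean structure converges independently of member order", {
  conf <- toy_prism()
  set.seed(21)
  members <- lapply(1:6, function(k) {
    set_coords(conf, coords(conf) + matrix(rnorm(3 * nrow(conf$atoms),
                                                 sd = 0.3),
                                           ncol = 3))
  })
  m1 <- mean_structure(ensemble(members))
  m2 <- mean_structure(ensemble(rev(members)))
  expect_lt(superpose(coords(m1), coords(m2))$rmsd, 1e-5)
})

test_that("ensemble precision statistics behave on synthetic ensembles", {
  conf <- toy_prism()
  same <- ensemble(rep(list(conf), 20))
  r0 <- ensemble_rmsd(same, "backbone")
  expect_equal(r0$mean, 0, tolerance = 1e-9)
  expect_equal(r0$sd, 0, tolerance = 1e-9)

  # carbonyl oxygens more mobile than backbone N/CA/C: heavy-atom RMSD
  # must exceed backbone RMSD
  set.seed(31)
  members <- lapply(1:10, function(k) {
    at <- conf$atoms
    n <- nrow(at)
    noise <- matrix(rnorm(3 * n, sd = 0.15), ncol = 3)
    noise[at$elety == "O", ] <- noise[at$elety == "O", ] +
      matrix(rnorm(3 * sum(at$elety == "O"), sd = 0.5), ncol = 3)
    set_coords(conf, coords(conf) + noise)
  })
  ens <- ensemble(members)
  rb <- ensemble_rmsd(ens, "backbone")
  rh <- ensemble_rmsd(ens, "heavy")
  expect_gt(rh$mean, rb$mean)
  expect_error(ensemble_rmsd(same, mask = logical(nrow(conf$atoms))),
               "no atoms")
})

test_that("contact typing uses inclusive, element-restricted cutoffs", {
  xyz <- rbind(c(0, 0, 0),      # protein C
               c(0, 0, 10),     # protein N
               c(0, 0, 13.6),   # ligand O: 3.6 from N -> no hbond
               c(4.5, 0, 0),    # ligand C at exactly 4.5 -> hydrophobic
               c(3.0, 0, 10))   # ligand O at 3.0 from N -> hbond
  conf <- mini_conformer(
    chain = c("A", "A", "L", "L", "L"), resno = c(1L, 2L, 1L, 1L, 1L),
    resid = c("ALA", "ALA", "FUC", "FUC", "FUC"),
    elety = c("CB", "N", "O3", "C6", "O2"), elesy = c("C", "N", "O", "C", "O"),
    xyz = xyz)
  ct <- contacts(conf, ligand = "FUC")
  expect_setequal(ct$type, c("hydrophobic", "hbond"))
  expect_equal(nrow(ct), 2L)
  expect_equal(ct$lig_atom[ct$type == "hydrophobic"], "C6")
  # C-O pair at 3.0 A is never a contact
  expect_false(any(ct$lig_atom == "O3"))
  expect_equal(nrow(contacts(conf, ligand = "GLC")), 0L)
})

test_that("ensemble contact fractions pool pockets and class by threshold", {
  # one protein atom and one single-atom ligand copy per chain; occurrence
  # counts engineered as 33, 15, and 6 of 60 pockets
  base <- function(present) {
    rows <- list()
    for (k in 0:2) {
      ctr <- c(6, 0, 0) %*% t(rot_z(120 * k))
      rows[[length(rows) + 1L]] <- data.frame(
        chain = LETTERS[k + 1], resno = 1L, resid = "ALA", elety = "CB",
        elesy = "C", x = ctr[1], y = ctr[2], z = 0, stringsAsFactors = FALSE)
      for (lig in 1:3) {
        off <- if (present[[lig]][k + 1]) 3 else 30
        rows[[length(rows) + 1L]] <- data.frame(
          chain = "L", resno = k + 1L, resid = "FUC",
          elety = paste0("C", lig), elesy = "C",
          x = ctr[1] + off, y = ctr[2], z = 0, stringsAsFactors = FALSE)
      }
    }
    conformer(do.call(rbind, rows))
  }
  # distribute occurrences over 20 members x 3 pockets
  want <- c(33, 15, 6)
  members <- lapply(1:20, function(m) {
    pres <- lapply(1:3, function(lig) {
      got <- pmin(pmax(want[lig] - (m - 1) * 3, 0), 3)
      c(rep(TRUE, got), rep(FALSE, 3 - got))
    })
    base(pres)
  })
  cf <- contact_fractions(ensemble(members), ligand = "FUC")
  cf <- cf[order(cf$lig_atom), ]
  expect_equal(cf$fraction, c(33, 15, 6) / 60)
  expect_equal(cf$weight_class, c("bold", "thin", "omitted"))
  # nesting: every bold contact also satisfies the thin threshold
  expect_true(all(cf$fraction[cf$weight_class == "bold"] >= 0.2))
})

test_that("NH-pi geometry measures proton-to-ring-plane distance", {
  tri <- trp_triad(h_height = 3)
  g <- nh_pi(tri, 32)
  expect_equal(nrow(g), 3L)
  expect_equal(g$h_to_plane, rep(3, 3), tolerance = 1e-9)
  expect_true(all(g$within_ring))
  expect_equal(g$acceptor_chain, c("B", "C", "A"))

  flat <- trp_triad(h_height = 0)
  expect_equal(nh_pi(flat, 32)$h_to_plane, rep(0, 3), tolerance = 1e-9)

  off <- trp_triad(h_height = 2, within = FALSE)
  expect_false(any(nh_pi(off, 32)$within_ring))

  noh <- conformer(tri$atoms[tri$atoms$elety != "HE1", ])
  expect_error(nh_pi(noh, 32), "proton")
})

test_that("least-squares ring plane matches the analytic hexagon normal", {
  ang <- seq(0, 300, by = 60) * pi / 180
  hexagon <- cbind(cos(ang), sin(ang), 0)
  R <- rot_z(25) %*% matrix(c(1, 0, 0,
                              0, cos(0.7), sin(0.7),
                              0, -sin(0.7), cos(0.7)), 3, 3)
  pts <- hexagon %*% t(R)
  pl <- prismfold:::.ls_plane(pts)
  true_normal <- as.vector(R %*% c(0, 0, 1))
  expect_equal(abs(sum(pl$normal * true_normal)), 1, tolerance = 1e-9)
})

test_that("contact lists respect the C3 symmetry of exact trimers", {
  tri <- trp_triad(h_height = 3)
  lig_rows <- do.call(rbind, lapply(0:2, function(k) {
    ctr <- c(6, 0, 0) %*% t(rot_z(120 * k))
    data.frame(chain = "L", resno = k + 1L, resid = "FUC", elety = "C1",
               elesy = "C", x = ctr[1] + 3.5, y = ctr[2], z = 0,
               stringsAsFactors = FALSE)
  }))
  conf <- conformer(rbind(tri$atoms, lig_rows))
  ct <- contacts(conf, "FUC")
  per_copy <- table(ct$lig_copy)
  expect_equal(length(unique(per_copy)), 1L)
  key <- function(copy) {
    s <- ct[ct$lig_copy == copy, ]
    paste(sort(paste(s$resno, s$atom, s$lig_atom, s$type)), collapse = ";")
  }
  keys <- vapply(names(per_copy), key, character(1))
  expect_equal(length(unique(keys)), 1L)
})
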