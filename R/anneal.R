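# Cartesian restrained simulated annealing under C3 non-crystallographic
# symmetry.
#
# The annealer treats structure calculation as minimisation of a restraint
# energy: covalent geometry is encoded as exact distance terms (see
# geometry.R), NOE and hydrogen-bond restraints as flat-bottom wells on
# sum-averaged effective distances, symmetry as a harmonic NCS penalty, and
# sterics as a soft repulsive-only nonbonded term.  Each trial starts from a
# metrized distance-geometry embedding of the unambiguous bound matrix,
# explores under temperature-scaled coordinate noise across the schedule
# stages, and is polished by quasi-Newton minimisation.  A trial is
# accepted when no distance restraint is violated by more than 0.2 A and no
# torsion restraint by more than 2 degrees.

#' Sum-averaged effective distance
#'
#' Combines candidate distances \eqn{d_k} into the NOE-equivalent effective
#' distance \eqn{(\sum_k d_k^{-6})^{-1/6}}, the standard treatment for
#' ambiguous restraints and equivalent-proton groups.  Never exceeds the
#' smallest contributor.
#'
#' @param distances Numeric vector of positive distances (A).
#' @return Effective distance (A).
#' @examples
#' effective_distance(4)            # 4
#' effective_distance(c(4, 4))      # 4 * 2^(-1/6)
#' @export
effective_distance <- function(distances) {
  if (!length(distances)) stop("need at least one distance")
  if (any(distances <= 0)) stop("distances must be positive")
  sum(distances^-6)^(-1 / 6)
}

#' Flat-bottom harmonic restraint energy
#'
#' Zero inside `[lower, upper]`, harmonic outside; continuous with
#' continuous first derivative at both bounds.
#'
#' @param d_eff Effective distance(s) (A).
#' @param lower,upper Bounds (A).
#' @param k Force constant (kcal/mol/A^2).
#' @return Energy (kcal/mol), vectorised over `d_eff`.
#' @export
restraint_energy <- function(d_eff, lower, upper, k = 1) {
  stopifnot(all(lower <= upper))
  over <- pmax(0, d_eff - upper)
  under <- pmax(0, lower - d_eff)
  k * (over^2 + under^2)
}

#' Energy model parameters
#'
#' @param k_noe Force constant for NOE/hydrogen-bond flat-bottom terms.
#' @param k_torsion Force constant for torsion terms (kcal/mol/deg^2).
#' @param k_ncs Non-crystallographic symmetry force constant
#'   (kcal/mol/A^2); 10 by convention for weak NCS.
#' @param k_bond,k_angle Force constants for the covalent distance template
#'   (1-2 and 1-3/1-4 terms).
#' @param k_repel Soft-sphere repulsion force constant.
#' @param nonbonded Only "repulsive" is implemented (no attractive terms).
#' @param repel_scale Fraction of summed van der Waals radii below which
#'   the repulsion engages.
#' @return List of class `energy_model`.
#' @export
energy_model <- function(k_noe = 30, k_torsion = 0.05, k_ncs = 10,
                         k_bond = 300, k_angle = 120, k_repel = 8,
                         nonbonded = "repulsive", repel_scale = 0.8) {
  stopifnot(k_noe >= 0, k_torsion >= 0, k_ncs >= 0, k_bond >= 0,
            k_angle >= 0, k_repel >= 0, nonbonded == "repulsive")
  structure(list(k_noe = k_noe, k_torsion = k_torsion, k_ncs = k_ncs,
                 k_bond = k_bond, k_angle = k_angle, k_repel = k_repel,
                 nonbonded = nonbonded, repel_scale = repel_scale),
            class = "energy_model")
}

#' Annealing schedule
#'
#' Stages of (initial temperature, step count).  Temperatures are control
#' parameters of the coordinate-noise amplitude, not physical temperatures;
#' the published full protocol (50000 K / 2000 steps twice, then 2000 K /
#' 2000 steps) and reduced protocol (1000 K / 1000 steps three times) are
#' both expressible; the desk-scale default uses the full protocol's
#' temperature profile with shorter stages.
#'
#' @param temp Initial temperature (K) per stage, non-increasing.
#' @param steps Step count per stage.
#' @param label Optional stage labels.
#' @return `data.frame` of class `anneal_schedule`.
#' @export
anneal_schedule <- function(temp = c(50000, 50000, 2000),
                            steps = c(80, 80, 80),
                            label = c("high_temp", "cool1", "cool2")) {
  stopifnot(length(temp) == length(steps), all(temp > 0),
            all(diff(temp) <= 0) || length(temp) == 1L)
  s <- data.frame(temp = temp, steps = as.integer(steps),
                  label = rep_len(label, length(temp)),
                  stringsAsFactors = FALSE)
  class(s) <- c("anneal_schedule", "data.frame")
  s
}

#' Reduced annealing schedule used for complex refinement
#'
#' Mirrors the weakened protocol used when refining a ligand complex from a
#' good starting structure rather than folding from scratch.
#'
#' @param steps Step count per stage (desk-scale default).
#' @export
reduced_schedule <- function(steps = 60) {
  anneal_schedule(temp = c(1000, 1000, 1000), steps = rep(steps, 3),
                  label = c("anneal", "cool1", "cool2"))
}

# ---------------------------------------------------------------------------
# system compilation

.atom_index <- function(atoms) {
  paste(atoms$chain, atoms$resno, atoms$elety, sep = "|")
}

.lookup_atoms <- function(key_table, chain, resno, elety) {
  match(paste(chain, resno, elety, sep = "|"), key_table)
}

.vdw_radius <- c(H = 1.00, C = 1.70, N = 1.55, O = 1.50, S = 1.80)

.chi_defs <- list(
  chi1 = list(names = c("N", "CA", "CB"), last = c("CG", "CG1", "OG", "OG1", "SG")),
  chi2 = list(names = c("CA", "CB"), mid = c("CG", "CG1"), last = c("CD", "CD1", "SD", "OD1"))
)

# geometry (covalent template) pair list for one conformer
.geometry_pairs <- function(atoms) {
  tpl <- backbone_template()
  key <- .atom_index(atoms)
  ai <- integer(0); aj <- integer(0); d0 <- numeric(0)
  is_bond <- logical(0)
  for (ch in unique(atoms$chain)) {
    resnos <- sort(unique(atoms$resno[atoms$chain == ch]))
    for (r in resnos) {
      ii <- .lookup_atoms(key, ch, r, tpl$intra$name_i)
      jj <- .lookup_atoms(key, ch, r, tpl$intra$name_j)
      ok <- !is.na(ii) & !is.na(jj)
      ai <- c(ai, ii[ok]); aj <- c(aj, jj[ok]); d0 <- c(d0, tpl$intra$dist[ok])
      is_bond <- c(is_bond, tpl$intra$is_bond[ok])
    }
    for (r in resnos[-length(resnos)]) {
      if (!(r + 1L) %in% resnos) next
      ii <- .lookup_atoms(key, ch, r, tpl$link$name_i)
      jj <- .lookup_atoms(key, ch, r + 1L, tpl$link$name_j)
      ok <- !is.na(ii) & !is.na(jj)
      ai <- c(ai, ii[ok]); aj <- c(aj, jj[ok]); d0 <- c(d0, tpl$link$dist[ok])
      is_bond <- c(is_bond, tpl$link$is_bond[ok])
    }
  }
  list(ai = ai, aj = aj, d0 = d0, is_bond = is_bond)
}

# torsion quadruples from chi restraints; silently drops residues whose
# side-chain atoms are absent from the model
.torsion_quads <- function(atoms, torsion) {
  if (is.null(torsion) || !nrow(torsion)) {
    return(list(idx = matrix(integer(0), 0, 4), target = numeric(0),
                tol = numeric(0)))
  }
  key <- .atom_index(atoms)
  idx <- matrix(integer(0), 0, 4)
  target <- numeric(0); tol <- numeric(0)
  for (k in seq_len(nrow(torsion))) {
    tr <- torsion[k, ]
    sub <- atoms[atoms$chain == tr$chain & atoms$resno == tr$resno, ]
    nm <- if (tr$angle_name == "chi1") {
      lastn <- intersect(.chi_defs$chi1$last, sub$elety)
      if (!length(lastn)) next
      c("N", "CA", "CB", lastn[1])
    } else {
      midn <- intersect(.chi_defs$chi2$mid, sub$elety)
      lastn <- intersect(.chi_defs$chi2$last, sub$elety)
      if (!length(midn) || !length(lastn)) next
      c("CA", "CB", midn[1], lastn[1])
    }
    q <- .lookup_atoms(key, tr$chain, tr$resno, nm)
    if (any(is.na(q))) next
    idx <- rbind(idx, q)
    target <- c(target, tr$target)
    tol <- c(tol, tr$tolerance)
  }
  list(idx = idx, target = target, tol = tol)
}

#' Prepare an annealing system
#'
#' Compiles a template conformer (topology and atom ordering), a
#' symmetrized restraint set and an energy model into the indexed arrays
#' the annealer evaluates, including the smoothed distance-bound matrix
#' used for distance-geometry starts.  Preparing once and passing the
#' system to repeated [anneal()] calls avoids recompilation.
#'
#' @param template A `conformer` supplying atoms and chain layout (its
#'   coordinates are not used except as a fallback start).
#' @param restraints A `restraint_set` (symmetrized automatically).
#' @param energy An [energy_model()].
#' @param sym A [symmetry_model()].
#' @return Object of class `anneal_system`.
#' @export
prepare_system <- function(template, restraints, energy = energy_model(),
                           sym = symmetry_model()) {
  stopifnot(inherits(template, "conformer"), inherits(restraints, "restraint_set"))
  rset <- symmetrize(restraints, sym)
  atoms <- template$atoms
  n <- nrow(atoms)
  key <- .atom_index(atoms)

  geo <- .geometry_pairs(atoms)

  g <- rset$groups
  if (!is.null(g) && nrow(g)) {
    cai <- .lookup_atoms(key, g$chain_i, g$res_i, g$atom_i)
    caj <- .lookup_atoms(key, g$chain_j, g$res_j, g$atom_j)
    bad <- is.na(cai) | is.na(caj)
    if (any(bad)) {
      miss <- unique(c(paste(g$chain_i, g$res_i, g$atom_i)[is.na(cai)],
                       paste(g$chain_j, g$res_j, g$atom_j)[is.na(caj)]))
      stop("restraint atoms absent from model: ",
           paste(utils::head(miss, 5), collapse = "; "))
    }
    grp <- match(g$group, unique(g$group))
    first <- !duplicated(grp)
    glo <- g$lower[first]
    gup <- g$upper[first]
  } else {
    cai <- caj <- integer(0); grp <- integer(0)
    glo <- gup <- numeric(0)
  }

  tq <- .torsion_quads(atoms, rset$torsion)

  # nonbonded bookkeeping: radii and exclusions (all pairs within a residue
  # or between consecutive residues of the same chain)
  radius <- .vdw_radius[atoms$elesy]
  radius[is.na(radius)] <- 1.6
  r0 <- energy$repel_scale * outer(radius, radius, "+")
  restag <- paste(atoms$chain, atoms$resno, sep = "|")
  resno_num <- atoms$resno
  same_chain <- outer(atoms$chain, atoms$chain, "==")
  excl <- outer(restag, restag, "==") |
    (same_chain & abs(outer(resno_num, resno_num, "-")) <= 1L)
  r0[excl] <- 0
  r0[lower.tri(r0, diag = TRUE)] <- 0

  # chain blocks for the NCS term
  chains <- sym$chains
  blocks <- lapply(chains, function(ch) which(atoms$chain == ch))
  if (length(unique(vapply(blocks, length, integer(1)))) != 1L) {
    stop("chains have different atom counts; NCS term undefined")
  }
  bl <- do.call(cbind, lapply(blocks, function(ix) {
    paste(atoms$resno[ix], atoms$elety[ix])
  }))
  if (!all(bl[, 1] == bl[, -1])) {
    stop("chain atom sets are not identical; NCS term undefined")
  }

  structure(list(
    atoms = atoms, n = n, template_xyz = coords(template),
    geo = geo, noe = list(ai = cai, aj = caj, grp = grp, lower = glo,
                          upper = gup, n_groups = length(glo)),
    torsion = tq, r0 = r0, blocks = blocks, sym = sym, energy = energy,
    restraints = rset
  ), class = "anneal_system")
}

# ---------------------------------------------------------------------------
# energy and gradient

.dihedral_cols <- function(x, idx) {
  # vectorised dihedrals for an m x 4 index matrix
  if (!nrow(idx)) return(numeric(0))
  p1 <- x[idx[, 1], , drop = FALSE]; p2 <- x[idx[, 2], , drop = FALSE]
  p3 <- x[idx[, 3], , drop = FALSE]; p4 <- x[idx[, 4], , drop = FALSE]
  vapply(seq_len(nrow(idx)), function(m) {
    dihedral_angle(p1[m, ], p2[m, ], p3[m, ], p4[m, ])
  }, numeric(1))
}

.wrap180 <- function(a) ((a + 180) %% 360) - 180

system_energy <- function(x, sys, gradient = TRUE, slack = 0) {
  em <- sys$energy
  n <- sys$n
  E <- 0
  pr_i <- integer(0); pr_j <- integer(0); pr_c <- numeric(0)
  pr_dx <- matrix(0, 0, 3)

  pair_term <- function(ai, aj, coef_over_d, dx) {
    # coef_over_d: dE/dd / d for each pair; dx = xi - xj
    pr_i <<- c(pr_i, ai); pr_j <<- c(pr_j, aj)
    pr_c <<- c(pr_c, coef_over_d)
    pr_dx <<- rbind(pr_dx, dx)
  }

  # covalent template
  if (length(sys$geo$ai)) {
    dx <- x[sys$geo$ai, , drop = FALSE] - x[sys$geo$aj, , drop = FALSE]
    d <- sqrt(rowSums(dx * dx))
    kvec <- ifelse(sys$geo$is_bond, em$k_bond, em$k_angle)
    dev <- d - sys$geo$d0
    E <- E + sum(kvec * dev * dev)
    if (gradient) pair_term(sys$geo$ai, sys$geo$aj, 2 * kvec * dev / pmax(d, 1e-8), dx)
  }

  # NOE / hbond groups (sum-averaged)
  noe <- sys$noe
  viol_d <- numeric(0)
  if (length(noe$ai)) {
    dx <- x[noe$ai, , drop = FALSE] - x[noe$aj, , drop = FALSE]
    d <- sqrt(pmax(rowSums(dx * dx), 1e-12))
    s <- as.vector(rowsum(d^-6, noe$grp, reorder = TRUE))
    deff <- s^(-1 / 6)
    up_s <- noe$upper + slack
    lo_s <- pmax(noe$lower - slack, 0.5)
    over <- pmax(0, deff - up_s)
    under <- pmax(0, lo_s - deff)
    E <- E + em$k_noe * sum(over^2 + under^2)
    viol_d <- pmax(over, under)
    if (gradient) {
      dEdeff <- 2 * em$k_noe * (over - under)
      tpc <- dEdeff[noe$grp] * (deff[noe$grp] / d)^7
      pair_term(noe$ai, noe$aj, tpc / d, dx)
    }
  }

  # torsion terms: flat-bottom on the wrapped angular deviation; the
  # gradient is taken by central differences on the (few) violated
  # quadruples only, which keeps the common all-satisfied case free
  tq <- sys$torsion
  viol_t <- numeric(0)
  tgrad <- NULL
  if (nrow(tq$idx)) {
    ang <- .dihedral_cols(x, tq$idx)
    dev <- .wrap180(ang - tq$target)
    out <- pmax(0, abs(dev) - tq$tol)
    viol_t <- out
    E <- E + em$k_torsion * sum(out^2)
    if (gradient && any(out > 0)) {
      tgrad <- matrix(0, n, 3)
      h <- 1e-5
      for (m in which(out > 0)) {
        ids <- tq$idx[m, ]
        for (a in ids) {
          for (cc in 1:3) {
            xp <- x
            xp[a, cc] <- xp[a, cc] + h
            angp <- dihedral_angle(xp[ids[1], ], xp[ids[2], ],
                                   xp[ids[3], ], xp[ids[4], ])
            outp <- max(0, abs(.wrap180(angp - tq$target[m])) - tq$tol[m])
            xm <- x
            xm[a, cc] <- xm[a, cc] - h
            angm <- dihedral_angle(xm[ids[1], ], xm[ids[2], ],
                                   xm[ids[3], ], xm[ids[4], ])
            outm <- max(0, abs(.wrap180(angm - tq$target[m])) - tq$tol[m])
            tgrad[a, cc] <- tgrad[a, cc] +
              em$k_torsion * (outp^2 - outm^2) / (2 * h)
          }
        }
      }
    }
  }

  # soft-sphere repulsion
  D2 <- as.matrix(stats::dist(x))^2
  mask <- sys$r0 > 0 & D2 < sys$r0^2
  if (any(mask)) {
    w <- which(mask, arr.ind = TRUE)
    d <- sqrt(D2[mask])
    gap <- sys$r0[mask] - d
    E <- E + em$k_repel * sum(gap^2)
    if (gradient) {
      dx <- x[w[, 1], , drop = FALSE] - x[w[, 2], , drop = FALSE]
      pair_term(w[, 1], w[, 2], -2 * em$k_repel * gap / pmax(d, 1e-8), dx)
    }
  }

  # NCS
  ncs <- .ncs_term(x, sys$blocks, em$k_ncs, gradient = gradient)
  E <- E + ncs$E

  G <- NULL
  if (gradient) {
    G <- matrix(0, n, 3)
    if (length(pr_i)) {
      contrib <- pr_dx * pr_c
      acc <- rowsum(rbind(contrib, -contrib), c(pr_i, pr_j), reorder = FALSE)
      ids <- as.integer(rownames(acc))
      G[ids, ] <- G[ids, ] + acc
    }
    if (!is.null(tgrad)) G <- G + tgrad
    G <- G + ncs$G
  }
  list(E = as.numeric(E), G = G, viol_dist = viol_d, viol_tors = viol_t)
}

# NCS penalty: squared deviation of each chain from the symmetry-averaged
# chain after optimal superposition; gradients treat the fitted rotations
# and the mean as constants (exact at the symmetric optimum).
.ncs_term <- function(x, blocks, k_ncs, gradient = TRUE, iters = 2L) {
  nb <- length(blocks)
  G <- matrix(0, nrow(x), 3)
  if (k_ncs <= 0 || nb < 2L) return(list(E = 0, G = G))
  Xs <- lapply(blocks, function(ix) x[ix, , drop = FALSE])
  M <- Xs[[1]]
  fits <- vector("list", nb)
  for (it in seq_len(iters)) {
    aligned <- vector("list", nb)
    for (c0 in seq_len(nb)) {
      f <- kabsch_fit(Xs[[c0]], M)
      fits[[c0]] <- f
      aligned[[c0]] <- f$transformed
    }
    M <- Reduce(`+`, aligned) / nb
  }
  E <- 0
  for (c0 in seq_len(nb)) {
    dev <- fits[[c0]]$transformed - M
    E <- E + k_ncs * sum(dev * dev)
    if (gradient) {
      G[blocks[[c0]], ] <- G[blocks[[c0]], ] + 2 * k_ncs * (dev %*% fits[[c0]]$rotation)
    }
  }
  list(E = E, G = G)
}

#' Non-crystallographic symmetry energy of a conformer
#'
#' Harmonic penalty on the deviation of each chain from the
#' symmetry-averaged chain after optimal superposition.  Exactly symmetric
#' conformers score zero.
#'
#' @param conf A `conformer` with identical atom sets per chain.
#' @param sym A [symmetry_model()].
#' @param k_ncs Force constant (kcal/mol/A^2).
#' @return Energy in kcal/mol.
#' @export
ncs_energy <- function(conf, sym = symmetry_model(), k_ncs = 10) {
  at <- conf$atoms
  blocks <- lapply(sym$chains, function(ch) which(at$chain == ch))
  sizes <- vapply(blocks, length, integer(1))
  if (length(unique(sizes)) != 1L || any(sizes == 0L)) {
    stop("chains must be present with identical atom counts")
  }
  .ncs_term(coords(conf), blocks, k_ncs, gradient = FALSE)$E
}

# ---------------------------------------------------------------------------
# annealing driver

# soft variant of an energy model used during the search phases: covalent
# terms weakened so restraints can reorganise topology, sterics off
.soften <- function(em) {
  energy_model(k_noe = em$k_noe, k_torsion = em$k_torsion, k_ncs = 0,
               k_bond = em$k_bond * 0.07, k_angle = em$k_angle * 0.07,
               k_repel = 0, repel_scale = em$repel_scale)
}

# extended-conformation start for the reference chain, matched to the
# template's atom layout
.extended_chain <- function(sys) {
  at <- sys$atoms[sys$blocks[[1]], , drop = FALSE]
  r0 <- min(at$resno)
  ext <- build_peptide(max(at$resno) - r0 + 1L, -120, 120)
  ext$resno <- ext$resno + r0 - 1L
  idx <- match(paste(at$resno, at$elety), paste(ext$resno, ext$elety))
  if (anyNA(idx)) {
    stop("cannot build an extended start for this atom layout; supply `start`")
  }
  X <- as.matrix(ext[idx, c("x", "y", "z")])
  sweep(X, 2, colMeans(X))
}

#' Restraint violations of a conformer
#'
#' @param conf A `conformer` (atom ordering must match the system
#'   template).
#' @param sys An `anneal_system` from [prepare_system()].
#' @return List with `max_dist` (A), `max_tors` (degrees) and the
#'   per-group violation vectors.
#' @export
compute_violations <- function(conf, sys) {
  x <- if (inherits(conf, "conformer")) coords(conf) else conf
  ev <- system_energy(x, sys, gradient = FALSE)
  list(max_dist = if (length(ev$viol_dist)) max(ev$viol_dist) else 0,
       max_tors = if (length(ev$viol_tors)) max(ev$viol_tors) else 0,
       dist = ev$viol_dist, tors = ev$viol_tors, energy = ev$E)
}

#' Acceptance thresholds for calculated structures
#'
#' @param max_dist Maximal tolerated distance-restraint violation (A).
#' @param max_tors Maximal tolerated torsion violation (degrees).
#' @export
acceptance_thresholds <- function(max_dist = 0.2, max_tors = 2) {
  stopifnot(max_dist > 0, max_tors > 0)
  list(max_dist = max_dist, max_tors = max_tors)
}

#' Accept or reject a calculated conformer
#'
#' A structure is acceptable when its largest distance-restraint violation
#' does not exceed 0.2 A and its largest torsion-restraint violation does
#' not exceed 2 degrees.
#'
#' @param conf A `conformer` carrying `max_dist_viol`/`max_tors_viol`
#'   (as returned by [anneal()]), or a violation list from
#'   [compute_violations()].
#' @param thresholds An [acceptance_thresholds()] list.
#' @return List with `accepted` (logical) and the two maxima.
#' @export
accept <- function(conf, thresholds = acceptance_thresholds()) {
  if (inherits(conf, "conformer")) {
    md <- conf$max_dist_viol
    mt <- conf$max_tors_viol
  } else {
    md <- conf$max_dist
    mt <- conf$max_tors
  }
  if (is.na(md) || is.na(mt)) stop("violations not computed for this conformer")
  list(accepted = md <= thresholds$max_dist && mt <= thresholds$max_tors,
       max_dist = md, max_tors = mt)
}

#' One restrained simulated-annealing trial
#'
#' Runs the staged protocol: distance-geometry start (or a supplied start
#' conformer), temperature-scaled noisy gradient descent per stage, then
#' quasi-Newton polishing, and returns the final conformer annotated with
#' its restraint energy and maximal violations.  Deterministic for a fixed
#' seed.
#'
#' @param sys An `anneal_system` from [prepare_system()].
#' @param schedule An [anneal_schedule()].
#' @param seed Integer seed for this trial.
#' @param start Optional `conformer` to refine instead of an embedded
#'   start (used for complex refinement from a known structure).
#' @param polish_maxit Iteration cap for the final minimisation.
#' @return A `conformer` with `energy`, `max_dist_viol`, `max_tors_viol`.
#' @export
anneal <- function(sys, schedule = anneal_schedule(), seed = 1,
                   start = NULL, polish_maxit = 400, start_radius = c(5, 13)) {
  stopifnot(inherits(sys, "anneal_system"))
  set.seed(as.integer(seed))
  n <- sys$n
  order_k <- sys$sym$order
  na <- n / order_k
  blocks <- sys$blocks
  rots <- lapply(seq_len(order_k) - 1L, function(k) rot_z(k * 360 / order_k))
  expand <- function(xa) {
    x <- matrix(0, n, 3)
    for (k in seq_len(order_k)) x[blocks[[k]], ] <- xa %*% t(rots[[k]])
    x
  }
  redgrad <- function(G) {
    g <- matrix(0, na, 3)
    for (k in seq_len(order_k)) g <- g + G[blocks[[k]], , drop = FALSE] %*% rots[[k]]
    g
  }
  soft <- sys
  soft$energy <- .soften(sys$energy)
  nocs <- sys
  nocs$energy <- sys$energy
  nocs$energy$k_ncs <- 0
  polish <- function(x0, ss, maxit, reduced = TRUE, slack = 0) {
    if (reduced) {
      o <- stats::optim(as.vector(x0), fn = function(v) {
        system_energy(expand(matrix(v, na, 3)), ss, gradient = FALSE,
                      slack = slack)$E
      }, gr = function(v) {
        as.vector(redgrad(system_energy(expand(matrix(v, na, 3)), ss,
                                        gradient = TRUE, slack = slack)$G))
      }, method = "L-BFGS-B", control = list(maxit = maxit))
      matrix(o$par, na, 3)
    } else {
      o <- stats::optim(as.vector(x0), fn = function(v) {
        system_energy(matrix(v, n, 3), ss, gradient = FALSE,
                      slack = slack)$E
      }, gr = function(v) {
        as.vector(system_energy(matrix(v, n, 3), ss, gradient = TRUE,
                                slack = slack)$G)
      }, method = "L-BFGS-B", control = list(maxit = maxit))
      matrix(o$par, n, 3)
    }
  }
  t_ref <- max(schedule$temp)
  if (is.null(start)) {
    # de novo: random rigid placement of an extended reference chain,
    # symmetric images generated by the C3 operation about z
    xa <- .extended_chain(sys)
    q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    ctr <- c(stats::runif(1, start_radius[1], start_radius[2]), 0, 0) %*%
      t(rot_z(stats::runif(1, 0, 360)))
    xa <- xa %*% q + matrix(ctr, na, 3, byrow = TRUE)
    n_st <- nrow(schedule)
    for (s in seq_len(n_st)) {
      sigma <- 0.08 * sqrt(schedule$temp[s] / t_ref)
      # restraint wells widen at high temperature and sharpen on cooling
      slack_s <- 1.5 * (n_st - s) / max(n_st - 1, 1)
      for (it in seq_len(schedule$steps[s])) {
        ev <- system_energy(expand(xa), soft, gradient = TRUE,
                            slack = slack_s)
        g <- redgrad(ev$G)
        gmax <- max(abs(g))
        if (!is.finite(gmax) || gmax > 1e9) {
          stop(sprintf("divergent dynamics in stage '%s' (step %d)",
                       schedule$label[s], it))
        }
        xa <- xa - (0.3 / max(gmax, 10)) * g +
          matrix(stats::rnorm(3 * na, sd = sigma), na, 3)
      }
    }
    xa <- polish(xa, soft, 300, slack = 0.5)
    # graded well-sharpening with the full energy model
    for (sl in c(0.4, 0.15, 0)) {
      xa <- polish(xa, nocs, if (sl == 0) polish_maxit else 250, slack = sl)
    }
    x <- expand(xa)
  } else {
    x <- coords(start)
    for (s in seq_len(nrow(schedule))) {
      sigma <- 0.05 * sqrt(schedule$temp[s] / t_ref)
      for (it in seq_len(schedule$steps[s])) {
        ev <- system_energy(x, sys, gradient = TRUE)
        gmax <- max(abs(ev$G))
        if (!is.finite(gmax) || gmax > 1e9) {
          stop(sprintf("divergent dynamics in stage '%s' (step %d)",
                       schedule$label[s], it))
        }
        x <- x - (0.3 / max(gmax, 10)) * ev$G +
          matrix(stats::rnorm(3 * n, sd = sigma), n, 3)
      }
    }
  }
  # final refinement with free chains under the NCS restraint
  x <- polish(x, sys, 150, reduced = FALSE)
  v <- compute_violations(x, sys)
  out <- conformer(sys$atoms, model_id = as.integer(seed), energy = v$energy,
                   max_dist_viol = v$max_dist, max_tors_viol = v$max_tors)
  set_coords(out, x)
}

#' Run a series of seeded annealing trials
#'
#' Trial `k` uses seed `master_seed + k`.  Annealer failures (divergence)
#' are recorded as rejections rather than aborting the series.
#'
#' @param sys An `anneal_system`.
#' @param n_trials Number of trials.
#' @param master_seed Master seed.
#' @inheritParams anneal
#' @return List of `conformer` objects (failed trials are `NULL`).
#' @export
anneal_trials <- function(sys, n_trials, master_seed = 0,
                          schedule = anneal_schedule(), start = NULL,
                          polish_maxit = 400) {
  lapply(seq_len(n_trials), function(k) {
    tryCatch(
      anneal(sys, schedule = schedule, seed = master_seed + k,
             start = start, polish_maxit = polish_maxit),
      error = function(e) {
        warning(sprintf("trial %d failed: %s", k, conditionMessage(e)))
        NULL
      }
    )
  })
}

#' Select the final ensemble from annealing trials
#'
#' Among accepted conformers, keeps the `n` with the lowest total energy in
#' energy-ascending order (ties broken by trial order).  If fewer than `n`
#' are accepted, all accepted conformers are returned with a warning; if
#' none are accepted the ensemble is empty and carries the status in its
#' `selection_note`.
#'
#' @param trials List of `conformer`s from [anneal_trials()].
#' @param n Target ensemble size (20 by convention).
#' @param thresholds An [acceptance_thresholds()] list.
#' @return An [ensemble()].
#' @export
select_ensemble <- function(trials, n = 20, thresholds = acceptance_thresholds()) {
  trials <- Filter(Negate(is.null), trials)
  ok <- vapply(trials, function(cf) accept(cf, thresholds)$accepted, logical(1))
  acc <- trials[ok]
  if (!length(acc)) {
    return(ensemble(list(),
                    selection_note = "no acceptable structures obtained"))
  }
  en <- vapply(acc, function(cf) cf$energy, numeric(1))
  ord <- order(en)  # stable: ties keep trial order
  keep <- utils::head(ord, n)
  if (length(acc) < n) {
    warning(sprintf("only %d of the requested %d structures were acceptable",
                    length(acc), n))
  }
  members <- acc[keep]
  for (k in seq_along(members)) members[[k]]$model_id <- k
  ensemble(members, selection_note = sprintf(
    "%d lowest-energy of %d accepted (of %d trials)",
    length(members), length(acc), length(trials)))
}
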