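# Synthetic-data generators: idealized C3-symmetric toy trimers with exact
# ground truth, symmetry-blinded NOE peak lists, and noisy fast-exchange
# titration curves.  These supply every statistical feature the pipeline
# assumes (indistinguishable intra/inter peaks, bound ladder consistent
# with true distances, seeded reproducibility) without external data.

#' Ground-truth annotation of a synthetic trimer
#'
#' @param conf A conformer built by [make_toy_trimer()].
#' @return List with the fold name and the generating [interface_map()].
#' @export
toy_truth <- function(conf) {
  tr <- attr(conf, "truth")
  if (is.null(tr)) stop("conformer carries no synthetic ground truth")
  tr
}

.sheet_unit_cache <- new.env(parent = emptyenv())

# Idealized antiparallel two-stranded sheet unit in a local frame: strand
# axes along +/- z at lateral x = +/- 2.4 A, the sheet in the xz-plane.
# The descending strand is the two-fold image of the ascending strand; the
# roll of the strand about its own axis and the axial slide between the
# two are chosen (once, by grid search) to maximise the number of genuine
# N-H...O=C hydrogen bonds without steric overlap.
.sheet_pair_unit <- function(m) {
  key <- as.character(m)
  if (!is.null(.sheet_unit_cache[[key]])) return(.sheet_unit_cache[[key]])
  st <- build_peptide(m, -120, 120, chain = "A")
  xyz <- as.matrix(st[, c("x", "y", "z")])
  ca <- xyz[st$elety == "CA", , drop = FALSE]
  mu <- colMeans(ca)
  v <- svd(sweep(ca, 2, mu))$v[, 1]
  if (sum((ca[m, ] - ca[1, ]) * v) < 0) v <- -v
  w <- ca[1, ] - mu
  a1 <- vunit(w - sum(w * v) * v)
  loc0 <- sweep(xyz, 2, mu) %*% cbind(a1, vcross(v, a1), v)
  hsel <- st$elety == "H"
  osel <- st$elety == "O"
  heavy <- st$elesy != "H"
  best <- NULL
  for (roll in seq(0, 350, by = 10)) {
    up <- loc0 %*% t(rot_z(roll))
    up[, 1] <- up[, 1] + 2.4
    for (dz in seq(-3.5, 3.5, by = 0.25)) {
      dn <- cbind(-up[, 1], up[, 2], -up[, 3])
      dn[, 3] <- dn[, 3] + dz
      dh <- sqrt(outer(rowSums(up[hsel, ]^2), rowSums(dn[osel, ]^2), "+") -
                   2 * up[hsel, , drop = FALSE] %*% t(dn[osel, , drop = FALSE]))
      dh2 <- sqrt(outer(rowSums(dn[hsel, ]^2), rowSums(up[osel, ]^2), "+") -
                    2 * dn[hsel, , drop = FALSE] %*% t(up[osel, , drop = FALSE]))
      cnt <- sum(dh <= 2.3) + sum(dh2 <= 2.3)
      cross <- sqrt(outer(rowSums(up[heavy, ]^2), rowSums(dn[heavy, ]^2), "+") -
                      2 * up[heavy, , drop = FALSE] %*% t(dn[heavy, , drop = FALSE]))
      if (min(cross) < 2.6) next
      if (is.null(best) || cnt > best$cnt) {
        best <- list(cnt = cnt, up = up, down = dn)
      }
    }
  }
  if (is.null(best)) stop("could not construct a clash-free sheet unit")
  out <- list(atoms = st, up = best$up, down = best$down)
  .sheet_unit_cache[[key]] <- out
  out
}

# rigid-body refinement of the turn block: minimise the covalent-link
# strain (bond and 1-3 template distances) at the two strand junctions
.refine_turn <- function(turn, s1, s2, m) {
  tpl <- backbone_template()$link
  xyz0 <- as.matrix(turn[, c("x", "y", "z")])
  ctr <- colMeans(xyz0)
  get1 <- function(df, r, n) {
    as.numeric(df[df$resno == r & df$elety == n, c("x", "y", "z")])
  }
  strand_xyz <- rbind(as.matrix(s1[, c("x", "y", "z")]),
                      as.matrix(s2[, c("x", "y", "z")]))
  strand_h <- c(s1$elesy, s2$elesy) == "H"
  turn_h <- turn$elesy == "H"
  # symmetry mates of the strands: turn protons must stay outside NOE
  # range of the neighbouring chains so turn peaks are purely
  # intramolecular
  other_xyz <- rbind(strand_xyz %*% t(rot_z(120)),
                     strand_xyz %*% t(rot_z(240)))
  other_h <- rep(strand_h, 2)
  linked_names <- c(paste(m + 1L, tpl$name_j), paste(m + 2L, tpl$name_i))
  turn_key <- paste(turn$resno, turn$elety)
  strain <- function(xyz) {
    tt <- turn
    tt[, c("x", "y", "z")] <- xyz
    s <- 0
    for (k in seq_len(nrow(tpl))) {
      pa <- get1(s1, m, tpl$name_i[k])          # strand1 -> turn res m+1
      pb <- get1(tt, m + 1L, tpl$name_j[k])
      s <- s + (sqrt(sum((pa - pb)^2)) - tpl$dist[k])^2
      pa <- get1(tt, m + 2L, tpl$name_i[k])     # turn res m+2 -> strand2
      pb <- get1(s2, m + 3L, tpl$name_j[k])
      s <- s + (sqrt(sum((pa - pb)^2)) - tpl$dist[k])^2
    }
    # steric floor against the strands (link-template pairs excluded)
    for (a in seq_len(nrow(xyz))) {
      if (!(turn_key[a] %in% linked_names)) {
        d <- sqrt(colSums((t(strand_xyz) - xyz[a, ])^2))
        floor_d <- ifelse(strand_h | turn_h[a],
                          ifelse(strand_h & turn_h[a], 1.95, 2.2), 2.7)
        s <- s + 50 * sum(pmax(0, floor_d - d)^2)
      }
      d2 <- sqrt(colSums((t(other_xyz) - xyz[a, ])^2))
      floor2 <- if (turn_h[a]) ifelse(other_h, 5.2, 2.6) else
        ifelse(other_h, 2.6, 3.0)
      s <- s + 50 * sum(pmax(0, floor2 - d2)^2)
    }
    s
  }
  obj <- function(p) {
    R <- rot_z(p[4]) %*%
      matrix(c(1, 0, 0, 0, cos(p[5] * .deg), sin(p[5] * .deg),
               0, -sin(p[5] * .deg), cos(p[5] * .deg)), 3, 3) %*%
      rot_z(p[6])
    xyz <- sweep(sweep(xyz0, 2, ctr) %*% R, 2, ctr + p[1:3], "+")
    strain(xyz)
  }
  o <- stats::optim(rep(0, 6), obj, control = list(maxit = 800))
  p <- o$par
  R <- rot_z(p[4]) %*%
    matrix(c(1, 0, 0, 0, cos(p[5] * .deg), sin(p[5] * .deg),
             0, -sin(p[5] * .deg), cos(p[5] * .deg)), 3, 3) %*%
    rot_z(p[6])
  turn[, c("x", "y", "z")] <- sweep(sweep(xyz0, 2, ctr) %*% R, 2,
                                    ctr + p[1:3], "+")
  turn
}

# rigid-place a peptide fragment: map its CA-trace principal frame onto a
# target frame (origin, direction of increasing residue number, in-plane
# lateral axis)
.place_fragment <- function(at, origin, along, lateral) {
  xyz <- as.matrix(at[, c("x", "y", "z")])
  ca <- xyz[at$elety == "CA", , drop = FALSE]
  mu <- colMeans(ca)
  v <- svd(sweep(ca, 2, mu))$v[, 1]
  if (sum((ca[nrow(ca), ] - ca[1, ]) * v) < 0) v <- -v
  # lateral reference: the atom with the largest perpendicular offset from
  # the axis (the first CA can lie on the axis for short fragments)
  perp <- sweep(xyz, 2, mu)
  perp <- perp - outer(as.vector(perp %*% v), v)
  w <- perp[which.max(rowSums(perp^2)), ]
  a1 <- vunit(w)
  a2 <- vcross(v, a1)
  along <- vunit(along)
  b1 <- vunit(lateral - sum(lateral * along) * along)
  b2 <- vcross(along, b1)
  out <- sweep(xyz, 2, mu) %*% cbind(v, a1, a2) %*% t(cbind(along, b1, b2))
  out <- sweep(out, 2, origin, "+")
  at[, c("x", "y", "z")] <- out
  at
}

#' Build an idealized C3-symmetric toy trimer
#'
#' Two surrogate folds with exact three-fold symmetry about z (chains B and
#' C are 120/240-degree copies of chain A) and ideal covalent geometry:
#'
#' * `three_helix_bundle_surrogate`: three alpha-helices arranged
#'   head-to-tail around a triangle, so the C-terminal residues of each
#'   chain pack against the N-terminal residues of the next.  All
#'   inter-chain contacts involve sequence-distant residues, reproducing
#'   the inter/intra blinding problem of a swapped symmetric oligomer.
#' * `beta_prism_surrogate`: each chain contributes two beta-strands joined
#'   by a turn; strand 2 of every chain pairs antiparallel with strand 1
#'   of the cyclically next chain, giving three two-stranded sheets on the
#'   faces of a triangular prism -- a minimal strand-swapped beta-prism in
#'   which every sheet-pairing contact is intermolecular.
#'
#' The returned conformer carries its generating truth (fold and interface
#' assignment map) retrievable with [toy_truth()].
#'
#' @param n_res Residues per chain (>= 8).
#' @param fold Fold template.
#' @param seed Seed (folds are deterministic; kept for interface parity
#'   with the other generators).
#' @return A `conformer` with chains A, B, C.
#' @export
make_toy_trimer <- function(n_res = 12,
                            fold = c("three_helix_bundle_surrogate",
                                     "beta_prism_surrogate"),
                            seed = 1) {
  fold <- match.arg(fold)
  if (n_res < 8) stop("need n_res >= 8")
  if (fold == "three_helix_bundle_surrogate") {
    at <- build_peptide(n_res, -57, -47, chain = "A")
    xyz <- as.matrix(at[, c("x", "y", "z")])
    ca <- xyz[at$elety == "CA", , drop = FALSE]
    mu <- colMeans(ca)
    v <- svd(sweep(ca, 2, mu))$v[, 1]
    if (sum((ca[n_res, ] - ca[1, ]) * v) < 0) v <- -v
    w <- ca[1, ] - mu
    a1 <- vunit(w - sum(w * v) * v)
    a2 <- vcross(v, a1)
    span <- sum((ca[n_res, ] - ca[1, ]) * v) - sum((ca[1, ] - ca[1, ]) * v)
    gap_ca <- 14             # vertex spacing: clash-free but contact-rich
    edge <- span + gap_ca * 2 / sqrt(3)
    R_tri <- edge / sqrt(3)
    v1 <- R_tri * c(cos(90 * .deg), sin(90 * .deg), 0)
    v2 <- R_tri * c(cos(-30 * .deg), sin(-30 * .deg), 0)
    u <- vunit(v2 - v1)
    mid <- (v1 + v2) / 2
    b1 <- vunit(-(mid - sum(mid * u) * u))
    b2 <- vcross(u, b1)
    S <- cbind(v, a1, a2)
    Tt <- cbind(u, b1, b2)
    placed <- sweep(xyz, 2, mu) %*% S %*% t(Tt)
    placed <- sweep(placed, 2, mid, "+")
    truth_map <- interface_map(
      label = "helix_junction",
      a_from = n_res - 3L, a_to = n_res, b_from = 1L, b_to = 4L,
      assignment = "intermolecular"
    )
  } else {
    m <- (n_res - 2L) %/% 2L
    rho <- 7.0                # prism face radius
    unit <- .sheet_pair_unit(m)
    theta <- 90 + 120 * (0:2)
    rhat <- lapply(theta, function(a) c(cos(a * .deg), sin(a * .deg), 0))
    that <- lapply(theta, function(a) c(-sin(a * .deg), cos(a * .deg), 0))
    zhat <- c(0, 0, 1)
    face <- function(k, loc) {
      sweep(loc %*% t(cbind(that[[k]], rhat[[k]], zhat)), 2,
            rho * rhat[[k]], "+")
    }
    # strand 1 = ascending strand of the face-0 sheet; strand 2 =
    # descending strand of the face-1 sheet (which pairs the next chain's
    # strand 1 there, giving the three swapped two-stranded sheets)
    s1 <- unit$atoms
    s1[, c("x", "y", "z")] <- face(1, unit$up)
    s2 <- unit$atoms
    s2[, c("x", "y", "z")] <- face(2, unit$down)
    s2$resno <- s2$resno + m + 2L
    a1 <- as.numeric(s1[s1$resno == m & s1$elety == "CA", c("x", "y", "z")])
    a2 <- as.numeric(s2[s2$resno == m + 3L & s2$elety == "CA", c("x", "y", "z")])
    edge_dir <- vunit(rhat[[1]] + rhat[[2]])
    turn <- build_peptide(2, -60, -30, chain = "A")
    turn <- .place_fragment(turn, (a1 + a2) / 2 + 1.5 * edge_dir + c(0, 0, 1.2),
                            a2 - a1, zhat)
    turn$resno <- turn$resno + m
    turn <- .refine_turn(turn, s1, s2, m)
    at <- rbind(s1, turn, s2)
    at <- at[order(at$resno), ]
    placed <- as.matrix(at[, c("x", "y", "z")])
    truth_map <- interface_map(
      label = c("sheet_swap", "turn"),
      a_from = c(m + 3L, m + 1L), a_to = c(n_res, m + 2L),
      b_from = c(1L, 1L), b_to = c(m, n_res),
      assignment = c("intermolecular", "intramolecular")
    )
  }
  at$x <- placed[, 1]; at$y <- placed[, 2]; at$z <- placed[, 3]
  rows <- lapply(0:2, function(k) {
    a2 <- at
    a2$chain <- c("A", "B", "C")[k + 1]
    rot <- placed %*% t(rot_z(120 * k))
    a2$x <- rot[, 1]; a2$y <- rot[, 2]; a2$z <- rot[, 3]
    a2
  })
  conf <- conformer(do.call(rbind, rows), model_id = 1L)
  attr(conf, "truth") <- list(fold = fold, fixed_map = truth_map,
                              n_res = n_res, seed = seed)
  conf
}

#' Simulate a symmetry-blinded NOE peak list
#'
#' Every proton pair (in different residues) closer than `cutoff` emits a
#' peak whose intensity class is set by the true distance via
#' `class_edges`.  Crucially, peaks record only residue and atom
#' identities, never the chain pair: intra- and intermolecular
#' contributions of the symmetric trimer are indistinguishable, and
#' duplicate peaks merge keeping the tighter (shorter-distance) class.
#' Because the class edges sit below the corresponding distance bounds
#' (2.7/3.6/5.0 vs 3.5/4.5/6.0 A), the generating conformer satisfies
#' every emitted restraint exactly.
#'
#' @param conf A proton-bearing `conformer`.
#' @param cutoff Emission cutoff (A).
#' @param class_edges Distances mapping to large/medium/small.
#' @param false_negative_rate Probability of dropping a peak.
#' @param seed Seed for the dropout draw.
#' @return Peak table as from [noe_peaks()].
#' @export
simulate_noes <- function(conf, cutoff = 5.0, class_edges = c(2.7, 3.6, 5.0),
                          false_negative_rate = 0, seed = 1) {
  stopifnot(length(class_edges) == 3, all(diff(class_edges) > 0))
  if (false_negative_rate < 0 || false_negative_rate > 1) {
    stop("false_negative_rate must be in [0, 1]")
  }
  bounds <- intensity_to_bound(c("large", "medium", "small"))
  if (any(class_edges > bounds)) {
    stop("class edges must not exceed the 3.5/4.5/6.0 A bound ladder")
  }
  at <- conf$atoms
  hsel <- which(at$elesy == "H")
  if (!length(hsel)) stop("conformer has no protons")
  hx <- as.matrix(at[hsel, c("x", "y", "z")])
  D <- as.matrix(stats::dist(hx))
  resno <- at$resno[hsel]
  nm <- at$elety[hsel]
  pair <- which(upper.tri(D) & D <= cutoff, arr.ind = TRUE)
  if (nrow(pair)) {
    same_res <- resno[pair[, 1]] == resno[pair[, 2]]
    pair <- pair[!same_res, , drop = FALSE]
  }
  if (!nrow(pair)) {
    return(noe_peaks(integer(0), character(0), integer(0), character(0),
                     character(0)))
  }
  ri <- resno[pair[, 1]]; ai <- nm[pair[, 1]]
  rj <- resno[pair[, 2]]; aj <- nm[pair[, 2]]
  d <- D[pair]
  # blind the chain identity: order each pair by (residue, atom)
  flip <- ri > rj | (ri == rj & ai > aj)
  tmp <- ri[flip]; ri[flip] <- rj[flip]; rj[flip] <- tmp
  tmpa <- ai[flip]; ai[flip] <- aj[flip]; aj[flip] <- tmpa
  key <- paste(ri, ai, rj, aj, sep = "|")
  dmin <- tapply(d, key, min)
  keys <- sort(names(dmin))
  dmin <- dmin[keys]
  parts <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
  cls <- cut(dmin, breaks = c(0, class_edges), include.lowest = TRUE,
             labels = c("large", "medium", "small"))
  pk <- noe_peaks(as.integer(parts[, 1]), parts[, 2],
                  as.integer(parts[, 3]), parts[, 4],
                  as.character(cls))
  pk$dmin <- unname(dmin)   # shortest generating distance (for exact bounds)
  if (false_negative_rate > 0) {
    set.seed(as.integer(seed))
    pk <- pk[stats::runif(nrow(pk)) >= false_negative_rate, , drop = FALSE]
    rownames(pk) <- NULL
  }
  pk
}

#' Simulate a fast-exchange titration curve
#'
#' @param K_D Dissociation constant (M).
#' @param delta_free,delta_bound Free/bound-state shifts (ppm).
#' @param P_tot Protein site concentration (M).
#' @param ligand_grid Total ligand concentrations (M), increasing.
#' @param noise_sd Gaussian noise on the observed shifts (ppm).
#' @param seed Seed.
#' @param resonance_id Label.
#' @return A [titration_series()].
#' @export
simulate_titration <- function(K_D, delta_free, delta_bound, P_tot,
                               ligand_grid, noise_sd = 0, seed = 1,
                               resonance_id = "sim") {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  f <- fraction_bound(ligand_grid, P_tot, K_D)
  mu <- delta_free + (delta_bound - delta_free) * f
  set.seed(as.integer(seed))
  titration_series(ligand_grid, mu + stats::rnorm(length(mu), sd = noise_sd),
                   P_tot, resonance_id = resonance_id)
}

#' Identify backbone hydrogen-bond donors in a structure
#'
#' Detects amide H ... carbonyl O pairs within `d_max` and returns the
#' per-monomer donor table consumed by [hbond_restraints()], with the
#' inter/intramolecular label taken from the chain identities (acceptor
#' determination from a calculated structure is the standard final stage
#' of an NMR structure determination).  Symmetry-equivalent copies are
#' reported once.
#'
#' @param conf A proton-bearing `conformer`.
#' @param d_max Maximal H...O distance (A).
#' @return `data.frame` with columns `res_d`, `atom_h`, `atom_d`, `res_a`,
#'   `atom_a`, `ambiguity`.
#' @export
simulate_hbonds <- function(conf, d_max = 2.3) {
  at <- conf$atoms
  hs <- at[at$elety == "H", , drop = FALSE]
  os <- at[at$elety == "O", , drop = FALSE]
  ns <- at[at$elety == "N", , drop = FALSE]
  if (!nrow(hs)) stop("conformer has no amide protons")
  hxyz <- as.matrix(hs[, c("x", "y", "z")])
  oxyz <- as.matrix(os[, c("x", "y", "z")])
  nxyz <- as.matrix(ns[, c("x", "y", "z")])
  nkey <- paste(ns$chain, ns$resno)
  rows <- list()
  for (k in seq_len(nrow(hs))) {
    d <- sqrt(colSums((t(oxyz) - hxyz[k, ])^2))
    near_seq <- hs$chain[k] == os$chain &
      abs(hs$resno[k] - os$resno) <= 2L
    # the donor heavy atom must also sit in its restraint window, so the
    # emitted donor list is consistent with the structure it came from
    ni <- match(paste(hs$chain[k], hs$resno[k]), nkey)
    dno <- sqrt(colSums((t(oxyz) - nxyz[ni, ])^2))
    bad_n <- dno < 2.8 | dno > 3.3
    for (j in which(d <= d_max & !near_seq & !bad_n)) {
      rows[[length(rows) + 1L]] <- data.frame(
        res_d = hs$resno[k], atom_h = "H", atom_d = "N",
        res_a = os$resno[j], atom_a = "O",
        ambiguity = if (hs$chain[k] == os$chain[j]) "intramolecular"
                    else "intermolecular",
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(res_d = integer(), atom_h = character(),
                      atom_d = character(), res_a = integer(),
                      atom_a = character(), ambiguity = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- unique(out)
  out <- out[order(out$res_d, out$res_a), , drop = FALSE]
  rownames(out) <- NULL
  out
}
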