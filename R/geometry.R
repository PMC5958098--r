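# Internal-coordinate geometry: ideal backbone construction and the distance
# template that expresses covalent geometry as exact distance restraints.
#
# The annealer works purely in Cartesian space, so bonds, bond angles and the
# trans peptide plane are all encoded as fixed-distance terms (1-2, 1-3 and
# omega-locked 1-4 pairs).  The same ideal internal coordinates drive the
# synthetic-trimer builders, so generated ground-truth models carry
# essentially zero covalent strain.

.deg <- pi / 180

# Ideal backbone internal coordinates (standard values for trans peptides).
.geo <- list(
  b_NH = 1.010, b_NCA = 1.458, b_CAHA = 1.090, b_CAC = 1.525,
  b_CO = 1.231, b_CN = 1.329,
  a_CNCA = 121.7, a_CNH = 119.5, a_NCAC = 111.2, a_NCAHA = 108.5,
  a_CACO = 120.8, a_CACN = 116.2, a_OCN = 123.0, a_CANH = 118.8,
  a_HACAC = 109.5
)

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vunit <- function(v) v / sqrt(sum(v * v))

#' Place an atom from internal coordinates (NeRF)
#'
#' Positions atom D bonded to `c` with bond length `r`, bond angle
#' `theta` = angle(b, c, D) and dihedral `chi` = dihedral(a, b, c, D).
#'
#' @param a,b,c 3-vectors of the three reference atoms.
#' @param r Bond length (A).
#' @param theta Bond angle (degrees).
#' @param chi Dihedral angle (degrees).
#' @return 3-vector position of D.
#' @keywords internal
place_atom <- function(a, b, c, r, theta, chi) {
  th <- theta * .deg
  ch <- -chi * .deg
  bc <- vunit(c - b)
  n <- vunit(vcross(b - a, bc))
  m <- vcross(n, bc)
  d2 <- c(-r * cos(th), r * sin(th) * cos(ch), r * sin(th) * sin(ch))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Dihedral angle of four points
#'
#' @param p1,p2,p3,p4 3-vectors.
#' @return Signed dihedral in degrees, in (-180, 180].
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, vunit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x) / .deg
}

# Place HA (and the CB/HB pseudo side chain) on CA by the tetrahedral
# bisector construction.  The sign of the out-of-plane component fixes a
# consistent pseudo-chirality for the reduced residue model; CB sits on
# the opposite tetrahedral position and carries a single collinear HB
# pseudo-proton standing in for the beta protons.
.place_ha <- function(n_pos, ca_pos, c_pos, sign = 1, bond = .geo$b_CAHA) {
  u1 <- vunit(n_pos - ca_pos)
  u2 <- vunit(c_pos - ca_pos)
  b <- vunit(u1 + u2)
  nn <- vunit(vcross(u1, u2))
  half <- acos(sum(u1 * b))
  # choose xi so that angle(N, CA, HA) matches the ideal value
  cx <- -cos(.geo$a_NCAHA * .deg) / cos(half)
  cx <- max(-1, min(1, cx))
  xi <- acos(cx)
  ca_pos + bond * (-cos(xi) * b + sign * sin(xi) * nn)
}

#' Build an ideal-geometry peptide chain
#'
#' Constructs a reduced backbone model (atoms N, H, CA, HA, C, O per
#' residue) from ideal bond lengths and angles with the given backbone
#' dihedrals and trans peptide bonds.  Used by the synthetic-trimer
#' generators; the chain starts in an arbitrary frame and is rigid-placed
#' by the caller.
#'
#' @param n_res Number of residues.
#' @param phi,psi Backbone dihedrals in degrees (recycled to length
#'   `n_res`).  Classic values: -57/-47 (alpha helix), -120/120 (beta
#'   strand).
#' @param chain Chain label.
#' @param sequence Optional one-letter sequence of length `n_res` used for
#'   residue names; defaults to polyalanine.
#' @return Atom `data.frame` in `conformer` column layout.
#' @export
build_peptide <- function(n_res, phi = -120, psi = 120, chain = "A",
                          sequence = NULL) {
  stopifnot(n_res >= 2)
  phi <- rep_len(phi, n_res)
  psi <- rep_len(psi, n_res)
  if (is.null(sequence)) {
    res3 <- rep("ALA", n_res)
  } else {
    letters1 <- check_sequence(sequence)
    if (length(letters1) != n_res) stop("sequence length must equal n_res")
    res3 <- unname(.aa_three[letters1])
  }
  pos <- vector("list", n_res)
  g <- .geo
  # seed residue in the xy-plane
  n1 <- c(0, 0, 0)
  ca1 <- c(g$b_NCA, 0, 0)
  ang <- (180 - g$a_NCAC) * .deg
  c1 <- ca1 + g$b_CAC * c(cos(ang), sin(ang), 0)
  h1 <- place_atom(c1, ca1, n1, g$b_NH, g$a_CANH, 180)
  o1 <- place_atom(n1, ca1, c1, g$b_CO, g$a_CACO, psi[1] + 180)
  ha1 <- .place_ha(n1, ca1, c1)
  cb1 <- .place_ha(n1, ca1, c1, sign = -1, bond = 1.53)
  hb1 <- cb1 + vunit(cb1 - ca1) * 1.0
  pos[[1]] <- list(N = n1, H = h1, CA = ca1, HA = ha1, CB = cb1, HB = hb1,
                   C = c1, O = o1)
  for (i in seq_len(n_res)[-1]) {
    p <- pos[[i - 1]]
    ni <- place_atom(p$N, p$CA, p$C, g$b_CN, g$a_CACN, psi[i - 1])
    hi <- place_atom(p$CA, p$C, ni, g$b_NH, g$a_CNH, 0)
    cai <- place_atom(p$CA, p$C, ni, g$b_NCA, g$a_CNCA, 180)
    ci <- place_atom(p$C, ni, cai, g$b_CAC, g$a_NCAC, phi[i])
    oi <- place_atom(ni, cai, ci, g$b_CO, g$a_CACO, psi[i] + 180)
    hai <- .place_ha(ni, cai, ci)
    cbi <- .place_ha(ni, cai, ci, sign = -1, bond = 1.53)
    hbi <- cbi + vunit(cbi - cai) * 1.0
    pos[[i]] <- list(N = ni, H = hi, CA = cai, HA = hai, CB = cbi, HB = hbi,
                     C = ci, O = oi)
  }
  atom_names <- c("N", "H", "CA", "HA", "CB", "HB", "C", "O")
  elements <- c("N", "H", "C", "H", "C", "H", "C", "O")
  rows <- lapply(seq_len(n_res), function(i) {
    xyz <- do.call(rbind, pos[[i]][atom_names])
    data.frame(chain = chain, resno = i, resid = res3[i],
               elety = atom_names, elesy = elements,
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Distance template for covalent geometry, measured once from an ideal
# dipeptide so every value is self-consistent with build_peptide().
# Pairs involving free dihedrals (phi, psi) are deliberately absent.
.backbone_template_cache <- new.env(parent = emptyenv())

backbone_template <- function() {
  if (!is.null(.backbone_template_cache$tpl)) return(.backbone_template_cache$tpl)
  at <- build_peptide(3, phi = -100, psi = 130)
  p <- function(res, name) {
    r <- at[at$resno == res & at$elety == name, c("x", "y", "z")]
    as.numeric(r[1, ])
  }
  d <- function(r1, n1, r2, n2) sqrt(sum((p(r1, n1) - p(r2, n2))^2))
  intra_pairs <- rbind(
    # 1-2 bonds
    c("N", "H"), c("N", "CA"), c("CA", "HA"), c("CA", "C"), c("C", "O"),
    c("CA", "CB"), c("CB", "HB"),
    # 1-3 (and rigid tetrahedral-cluster) distances
    c("H", "CA"), c("N", "C"), c("N", "HA"), c("HA", "C"), c("CA", "O"),
    c("N", "CB"), c("C", "CB"), c("HA", "CB"), c("CA", "HB"), c("N", "HB"),
    c("C", "HB"), c("HA", "HB")
  )
  intra <- data.frame(
    name_i = intra_pairs[, 1], name_j = intra_pairs[, 2],
    dist = vapply(seq_len(nrow(intra_pairs)), function(k) {
      d(2, intra_pairs[k, 1], 2, intra_pairs[k, 2])
    }, numeric(1)),
    is_bond = c(rep(TRUE, 7), rep(FALSE, 12)),
    stringsAsFactors = FALSE
  )
  link <- data.frame(
    name_i = c("C", "CA", "O", "C", "C", "CA", "O", "CA", "O"),
    name_j = c("N", "N", "N", "CA", "H", "CA", "H", "H", "CA"),
    dist = c(d(2, "C", 3, "N"), d(2, "CA", 3, "N"), d(2, "O", 3, "N"),
             d(2, "C", 3, "CA"), d(2, "C", 3, "H"), d(2, "CA", 3, "CA"),
             d(2, "O", 3, "H"), d(2, "CA", 3, "H"), d(2, "O", 3, "CA")),
    is_bond = c(TRUE, rep(FALSE, 8)),
    stringsAsFactors = FALSE
  )
  tpl <- list(intra = intra, link = link)
  .backbone_template_cache$tpl <- tpl
  tpl
}

#' Rotation matrix about the z axis
#' @param angle Rotation in degrees.
#' @return 3 x 3 rotation matrix.
#' @keywords internal
rot_z <- function(angle) {
  a <- angle * .deg
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}
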