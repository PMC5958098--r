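# Ensemble metrics: superposition, precision statistics, binding-pocket
# contacts and NH-pi triad geometry.

#' Least-squares rigid-body fit (Kabsch)
#'
#' @param P,Q n x 3 matrices (mobile, target).
#' @return List with `rotation` (right-multiplier, det +1), `translation`,
#'   `rmsd` and `transformed` (P after fitting onto Q).
#' @keywords internal
kabsch_fit <- function(P, Q) {
  stopifnot(nrow(P) == nrow(Q), ncol(P) == 3, ncol(Q) == 3)
  if (nrow(P) < 3) stop("need at least 3 atoms for a rigid-body fit")
  cp <- colMeans(P)
  cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp)
  Qc <- sweep(Q, 2, cq)
  if (svd(Pc)$d[2] < 1e-8 * max(1, svd(Pc)$d[1])) {
    stop("mobile atoms are (nearly) collinear; fit is degenerate")
  }
  H <- crossprod(Pc, Qc)
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  transformed <- Pc %*% R
  transformed <- sweep(transformed, 2, cq, "+")
  rmsd <- sqrt(mean(rowSums((transformed - Q)^2)))
  list(rotation = R, translation = cq - as.vector(cp %*% R), rmsd = rmsd,
       transformed = transformed)
}

#' Atom masks for fitting and statistics
#'
#' @param atoms Conformer atom table.
#' @param mask "backbone" (N, CA, C'), "heavy" (all non-proton atoms),
#'   "all", or a logical/integer vector.
#' @return Integer atom indices.
#' @export
atom_mask <- function(atoms, mask = "backbone") {
  if (is.logical(mask) || is.numeric(mask)) {
    idx <- if (is.logical(mask)) which(mask) else as.integer(mask)
    if (!length(idx)) stop("mask selects no atoms")
    return(idx)
  }
  idx <- switch(mask,
    backbone = which(atoms$elety %in% c("N", "CA", "C")),
    heavy = which(atoms$elesy != "H"),
    all = seq_len(nrow(atoms)),
    stop("unknown mask: ", mask)
  )
  if (!length(idx)) stop("mask selects no atoms")
  idx
}

#' Superpose one conformer onto another
#'
#' Least-squares fit over proper rotations and translations, fitted on the
#' masked atoms and applied to all atoms.
#'
#' @param mobile,target `conformer`s with matching atom ordering, or
#'   n x 3 coordinate matrices.
#' @param mask See [atom_mask()] (ignored for plain matrices).
#' @return List with `rotation`, `translation`, `rmsd` (on the mask) and
#'   `conformer` (the transformed mobile, when conformers were given).
#' @export
superpose <- function(mobile, target, mask = "backbone") {
  if (inherits(mobile, "conformer")) {
    idx <- atom_mask(mobile$atoms, mask)
    P <- coords(mobile)
    Q <- coords(target)
    fit <- kabsch_fit(P[idx, , drop = FALSE], Q[idx, , drop = FALSE])
    allP <- sweep(sweep(P, 2, colMeans(P[idx, , drop = FALSE])) %*% fit$rotation,
                  2, colMeans(Q[idx, , drop = FALSE]), "+")
    out <- set_coords(mobile, allP)
    list(rotation = fit$rotation, translation = fit$translation,
         rmsd = fit$rmsd, conformer = out)
  } else {
    kabsch_fit(mobile, target)
  }
}

#' Unminimized mean structure of an ensemble
#'
#' Iteratively superposes every member onto the running mean (fitting on
#' the masked atoms) and averages coordinates until the mean moves by less
#' than `tol`; the default tolerance is below PDB coordinate precision.
#'
#' @param ens An [ensemble()] with at least 2 members.
#' @param mask Fitting mask (see [atom_mask()]).
#' @param tol Convergence tolerance on the maximal mean shift (A).
#' @param max_iter Iteration cap.
#' @return A `conformer` holding the coordinate-wise mean, with attribute
#'   `minimized = FALSE`.
#' @export
mean_structure <- function(ens, mask = "backbone", tol = 1e-6,
                           max_iter = 200) {
  if (!length(ens$members)) stop("empty ensemble")
  if (length(ens$members) == 1L) {
    out <- ens$members[[1]]
    attr(out, "minimized") <- FALSE
    return(out)
  }
  idx <- atom_mask(ens$members[[1]]$atoms, mask)
  Xs <- lapply(ens$members, coords)
  M <- Xs[[1]]
  for (it in seq_len(max_iter)) {
    aligned <- lapply(Xs, function(X) {
      fit <- kabsch_fit(X[idx, , drop = FALSE], M[idx, , drop = FALSE])
      sweep(sweep(X, 2, colMeans(X[idx, , drop = FALSE])) %*% fit$rotation,
            2, colMeans(M[idx, , drop = FALSE]), "+")
    })
    M2 <- Reduce(`+`, aligned) / length(aligned)
    shift <- max(abs(M2 - M))
    M <- M2
    if (shift < tol) break
  }
  out <- set_coords(ens$members[[1]], M)
  out$model_id <- 0L
  out$energy <- NA_real_
  out$max_dist_viol <- NA_real_
  out$max_tors_viol <- NA_real_
  attr(out, "minimized") <- FALSE
  out
}

#' Ensemble precision: RMSD to the unminimized mean
#'
#' Each member is superposed onto the unminimized mean structure on the
#' given mask and its RMSD over the masked atoms recorded; reported as
#' mean +/- sd over members, the conventional NMR ensemble precision
#' statistic.
#'
#' @param ens An [ensemble()] with >= 2 members.
#' @param mask "backbone" (N, CA, C') or "heavy" (all non-proton atoms),
#'   or any [atom_mask()] selection.
#' @return List with `mean`, `sd` and the per-member `rmsd` vector (A).
#' @export
ensemble_rmsd <- function(ens, mask = "backbone") {
  if (length(ens$members) < 2L) stop("need at least 2 members")
  idx <- atom_mask(ens$members[[1]]$atoms, mask)
  mref <- mean_structure(ens, mask = idx)
  M <- coords(mref)[idx, , drop = FALSE]
  r <- vapply(ens$members, function(cf) {
    kabsch_fit(coords(cf)[idx, , drop = FALSE], M)$rmsd
  }, numeric(1))
  list(mean = mean(r), sd = stats::sd(r), rmsd = r)
}

#' Best RMSD over cyclic chain relabelings
#'
#' For symmetric trimers the chain labels of two independently calculated
#' structures are arbitrary up to the C3 cycle; this fits under all cyclic
#' relabelings of the second structure and returns the smallest RMSD.
#'
#' @param conf_a,conf_b `conformer`s with the same per-chain atom layout.
#' @param sym A [symmetry_model()].
#' @param mask See [atom_mask()].
#' @return List with `rmsd` (best) and `shift` (the winning relabeling).
#' @export
symmetric_rmsd <- function(conf_a, conf_b, sym = symmetry_model(),
                           mask = "backbone") {
  at <- conf_a$atoms
  blocks <- lapply(sym$chains, function(ch) which(at$chain == ch))
  idx <- atom_mask(at, mask)
  A <- coords(conf_a)
  B <- coords(conf_b)
  best <- Inf
  best_shift <- 0L
  for (s in 0:(sym$order - 1L)) {
    perm <- unlist(blocks[((seq_len(sym$order) - 1L + s) %% sym$order) + 1L])
    Bp <- B[perm, , drop = FALSE]
    r <- kabsch_fit(Bp[idx, , drop = FALSE], A[idx, , drop = FALSE])$rmsd
    if (r < best) {
      best <- r
      best_shift <- s
    }
  }
  list(rmsd = best, shift = best_shift)
}

# ---------------------------------------------------------------------------
# binding-pocket contacts

#' Protein-ligand contacts in one conformer
#'
#' Distance-only contact definitions: hydrophobic contacts are carbon pairs
#' within 4.5 A; hydrogen bonds are nitrogen/oxygen pairs within 3.5 A.
#' Cutoffs are inclusive; mixed C/O or C/N pairs are never contacts.
#'
#' @param conf A `conformer` whose atom table contains the ligand.
#' @param ligand Residue name(s) identifying ligand atoms (e.g. "FUC").
#' @param cut_hydrophobic,cut_hbond Cutoffs (A).
#' @return `data.frame` with one row per contact: protein chain/residue/
#'   atom, ligand residue copy/atom, `type` and `distance`.  Empty when the
#'   ligand is absent.
#' @export
contacts <- function(conf, ligand = "FUC", cut_hydrophobic = 4.5,
                     cut_hbond = 3.5) {
  at <- conf$atoms
  is_lig <- at$resid %in% ligand
  empty <- data.frame(chain = character(), resno = integer(),
                      resid = character(), atom = character(),
                      lig_copy = character(), lig_atom = character(),
                      type = character(), distance = numeric(),
                      stringsAsFactors = FALSE)
  if (!any(is_lig)) return(empty)
  prot <- at[!is_lig, , drop = FALSE]
  lig <- at[is_lig, , drop = FALSE]
  pxyz <- as.matrix(prot[, c("x", "y", "z")])
  lxyz <- as.matrix(lig[, c("x", "y", "z")])
  out <- empty
  for (k in seq_len(nrow(lig))) {
    d <- sqrt(colSums((t(pxyz) - lxyz[k, ])^2))
    hyd <- which(prot$elesy == "C" & lig$elesy[k] == "C" & d <= cut_hydrophobic)
    hb <- which(prot$elesy %in% c("N", "O") & lig$elesy[k] %in% c("N", "O") &
                  d <= cut_hbond)
    sel <- c(hyd, hb)
    if (!length(sel)) next
    out <- rbind(out, data.frame(
      chain = prot$chain[sel], resno = prot$resno[sel],
      resid = prot$resid[sel], atom = prot$elety[sel],
      lig_copy = paste(lig$chain[k], lig$resno[k], sep = "/"),
      lig_atom = lig$elety[k],
      type = c(rep("hydrophobic", length(hyd)), rep("hbond", length(hb))),
      distance = d[sel], stringsAsFactors = FALSE
    ))
  }
  rownames(out) <- NULL
  out
}

#' Ensemble contact fractions and display classes
#'
#' Pools the symmetry-equivalent pockets of every ensemble member (members
#' x ligand copies; 20 x 3 = 60 pockets for the conventional trimer
#' ensemble) and reports, per unique contact, the fraction of pockets in
#' which it occurs.  Contacts in at least 50% of pockets are classed
#' "bold", in at least 20% "thin", otherwise "omitted".
#'
#' @param ens An [ensemble()] whose members contain the ligand copies.
#' @param ligand Ligand residue name(s).
#' @inheritParams contacts
#' @return `data.frame` keyed by protein residue/atom and ligand atom with
#'   `type`, `n_pockets`, `fraction` and `weight_class`.
#' @export
contact_fractions <- function(ens, ligand = "FUC", cut_hydrophobic = 4.5,
                              cut_hbond = 3.5) {
  stopifnot(length(ens$members) >= 1L)
  n_copies <- length(unique(paste(
    ens$members[[1]]$atoms$chain[ens$members[[1]]$atoms$resid %in% ligand],
    ens$members[[1]]$atoms$resno[ens$members[[1]]$atoms$resid %in% ligand]
  )))
  if (n_copies == 0L) stop("ligand not found in ensemble members")
  pockets <- length(ens$members) * n_copies
  rows <- lapply(ens$members, function(cf) {
    ct <- contacts(cf, ligand, cut_hydrophobic, cut_hbond)
    if (!nrow(ct)) return(NULL)
    # one occurrence per pocket: identical contact seen once per ligand copy
    ct$key <- paste(ct$resno, ct$resid, ct$atom, ct$lig_atom, ct$type, sep = "|")
    unique(ct[, c("key", "lig_copy", "resno", "resid", "atom", "lig_atom",
                  "type")])
  })
  all <- do.call(rbind, rows)
  if (is.null(all) || !nrow(all)) {
    return(data.frame(resno = integer(), resid = character(),
                      atom = character(), lig_atom = character(),
                      type = character(), n_pockets = integer(),
                      fraction = numeric(), weight_class = character(),
                      stringsAsFactors = FALSE))
  }
  tab <- table(all$key)
  first <- all[!duplicated(all$key), , drop = FALSE]
  first <- first[match(names(tab), first$key), ]
  frac <- as.integer(tab) / pockets
  weight <- ifelse(frac >= 0.5, "bold", ifelse(frac >= 0.2, "thin", "omitted"))
  out <- data.frame(resno = first$resno, resid = first$resid,
                    atom = first$atom, lig_atom = first$lig_atom,
                    type = first$type, n_pockets = as.integer(tab),
                    fraction = frac, weight_class = weight,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$fraction, out$resno, out$atom, out$lig_atom), ]
  rownames(out) <- NULL
  out
}

# ---------------------------------------------------------------------------
# NH-pi triad geometry

# least-squares plane: centroid + unit normal (smallest principal axis)
.ls_plane <- function(points) {
  ctr <- colMeans(points)
  sv <- svd(sweep(points, 2, ctr))
  list(centroid = ctr, normal = sv$v[, 3])
}

# indole six-membered ring atoms in adjacency order
.trp_ring <- c("CD2", "CE3", "CZ3", "CH2", "CZ2", "CE2")

#' NH-pi geometry of a tryptophan triad
#'
#' For each chain of a C3 trimer, measures the distance from the indole
#' H-epsilon-1 proton of the given Trp residue to the least-squares plane
#' of the six-membered indole ring of the cyclically next chain's Trp, and
#' whether the proton's in-plane projection falls inside the ring hexagon.
#'
#' @param conf A `conformer` with Trp ring atoms and the HE1 proton.
#' @param trp_res Residue number of the tryptophan.
#' @param sym A [symmetry_model()].
#' @return `data.frame` with donor chain, acceptor chain, `h_to_plane` (A)
#'   and `within_ring` (logical).
#' @export
nh_pi <- function(conf, trp_res, sym = symmetry_model()) {
  at <- conf$atoms
  out <- data.frame(donor_chain = character(), acceptor_chain = character(),
                    h_to_plane = numeric(), within_ring = logical(),
                    stringsAsFactors = FALSE)
  for (ch in sym$chains) {
    don <- at[at$chain == ch & at$resno == trp_res & at$elety == "HE1", ]
    if (!nrow(don)) {
      stop("HE1 proton missing on chain ", ch,
           "; NH-pi geometry needs proton-bearing models")
    }
    ach <- cycle_chain(sym, ch, 1L)
    ring <- at[at$chain == ach & at$resno == trp_res &
                 at$elety %in% .trp_ring, ]
    if (nrow(ring) != 6L) {
      stop("incomplete indole ring on chain ", ach)
    }
    ring <- ring[match(.trp_ring, ring$elety), ]
    rxyz <- as.matrix(ring[, c("x", "y", "z")])
    pl <- .ls_plane(rxyz)
    h <- as.numeric(don[1, c("x", "y", "z")])
    dist <- abs(sum((h - pl$centroid) * pl$normal))
    proj <- h - sum((h - pl$centroid) * pl$normal) * pl$normal
    # point-in-convex-polygon by consistent edge-cross signs
    signs <- vapply(seq_len(6), function(k) {
      a <- rxyz[k, ]
      b <- rxyz[(k %% 6) + 1, ]
      cr <- vcross(b - a, proj - a)
      sum(cr * pl$normal)
    }, numeric(1))
    out <- rbind(out, data.frame(
      donor_chain = ch, acceptor_chain = ach, h_to_plane = dist,
      within_ring = all(signs >= 0) || all(signs <= 0),
      stringsAsFactors = FALSE
    ))
  }
  out
}
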