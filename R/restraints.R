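# Restraint engine: turns assigned NOE peaks, hydrogen-bond donor lists and
# rotamer assignments into the symmetric restraint set used by the annealer.
#
# The central difficulty for a symmetric homotrimer is that intra- and
# intermolecular NOE peaks between symmetry-equivalent protons are
# indistinguishable.  Peaks therefore carry no chain information; ambiguity
# is resolved either by explicit interface pinning (see
# [assign_ambiguity()]) or left to sum-averaged evaluation over all chain
# pairings during annealing.

.intensity_bounds <- c(large = 3.5, medium = 4.5, small = 6.0)

#' Build an NOE peak table
#'
#' @param res_i,res_j 1-based residue indices of the two protons.
#' @param atom_i,atom_j Proton atom names (e.g. "H", "HA").
#' @param intensity_class One of "large", "medium", "small" (cross-peak
#'   intensity; stronger peaks mean shorter distances).
#' @return `data.frame` with one row per peak and a derived `range_class`.
#' @export
noe_peaks <- function(res_i, atom_i, res_j, atom_j, intensity_class) {
  stopifnot(all(intensity_class %in% names(.intensity_bounds)))
  pk <- data.frame(res_i = as.integer(res_i), atom_i = atom_i,
                   res_j = as.integer(res_j), atom_j = atom_j,
                   intensity_class = intensity_class,
                   stringsAsFactors = FALSE)
  pk$range_class <- classify_noe(pk$res_i, pk$res_j)
  pk
}

#' Sequence-range class of an NOE
#'
#' Classifies proton pairs by residue separation: `|i-j| = 0` intra-residue,
#' `1` sequential, `2..4` medium-range, `> 4` long-range.
#'
#' @param res_i,res_j Residue indices (vectorised).
#' @return Character vector of range classes.
#' @examples
#' classify_noe(5, 6)   # sequential
#' classify_noe(5, 8)   # medium_range
#' classify_noe(5, 12)  # long_range
#' @export
classify_noe <- function(res_i, res_j) {
  if (any(res_i < 1) || any(res_j < 1)) {
    stop("residue indices must be positive")
  }
  sep <- abs(res_i - res_j)
  out <- character(length(sep))
  out[sep == 0] <- "intra_residue"
  out[sep == 1] <- "sequential"
  out[sep >= 2 & sep <= 4] <- "medium_range"
  out[sep > 4] <- "long_range"
  out
}

#' Distance upper bound for an NOE intensity class
#'
#' Large, medium and small cross-peak intensities translate to upper bounds
#' of 3.5, 4.5 and 6.0 A respectively.  The lower bound for all NOE
#' restraints is the van der Waals contact floor (1.8 A).
#'
#' @param intensity_class Character vector of intensity classes.
#' @return Numeric vector of upper bounds (A).
#' @export
intensity_to_bound <- function(intensity_class) {
  bad <- setdiff(unique(intensity_class), names(.intensity_bounds))
  if (length(bad)) {
    stop("unknown intensity class: ", paste(bad, collapse = ", "))
  }
  unname(.intensity_bounds[intensity_class])
}

#' Define an interface pinning map
#'
#' An interface is a pair of residue regions whose mutual NOEs are pinned to
#' a single ambiguity label (intramolecular or intermolecular) instead of
#' being sum-averaged.  This is the device used to resolve the
#' inter/intramolecular degeneracy of a symmetric oligomer region by
#' region.
#'
#' @param label Interface labels.
#' @param a_from,a_to First region (residue range, inclusive).
#' @param b_from,b_to Second region.
#' @param assignment "intramolecular" or "intermolecular" (may be `NA` for
#'   hypotheses still to be decided).
#' @return `data.frame` of class `interface_map`.
#' @export
interface_map <- function(label, a_from, a_to, b_from, b_to, assignment) {
  ok <- is.na(assignment) | assignment %in% c("intramolecular", "intermolecular")
  if (!all(ok)) stop("assignment must be intramolecular/intermolecular/NA")
  m <- data.frame(label = label,
                  a_from = as.integer(a_from), a_to = as.integer(a_to),
                  b_from = as.integer(b_from), b_to = as.integer(b_to),
                  assignment = assignment, stringsAsFactors = FALSE)
  if (anyDuplicated(m$label)) stop("duplicate interface labels")
  class(m) <- c("interface_map", "data.frame")
  m
}

#' Final interface assignments for the PhoSL trimer
#'
#' The register established for the PhoSL beta-prism: contacts between
#' beta-strands 3 and 4 and between the N- and C-terminal halves of the
#' kinked strand 1 are intermolecular (strand swapping), while the
#' strand 1/2 and strand 2/3 contacts are intramolecular.
#'
#' @return An [interface_map()].
#' @export
phosl_interface_map <- function() {
  interface_map(
    label = c("b3-b4", "b1N-b1C", "b1-b2", "b2-b3"),
    a_from = c(27L, 2L, 3L, 16L),
    a_to = c(31L, 5L, 9L, 21L),
    b_from = c(34L, 9L, 17L, 27L),
    b_to = c(39L, 12L, 23L, 34L),
    assignment = c("intermolecular", "intermolecular",
                   "intramolecular", "intramolecular")
  )
}

.in_region <- function(res, from, to) res >= from & res <= to

#' Assign inter/intramolecular ambiguity to NOE peaks
#'
#' Sequential (and intra-residue) peaks are always intramolecular.
#' Medium- and long-range peaks are ambiguous by default; if a peak's
#' residue pair falls in a pinned interface region pair, it takes the
#' pinned label instead.
#'
#' @param peaks Peak table from [noe_peaks()] or [simulate_noes()].
#' @param fixed_map Optional [interface_map()] of pinned assignments.
#' @return The peak table with an `ambiguity` column.
#' @export
assign_ambiguity <- function(peaks, fixed_map = NULL) {
  amb <- ifelse(peaks$range_class %in% c("intra_residue", "sequential"),
                "intramolecular", "ambiguous")
  pinned_by <- rep(NA_character_, nrow(peaks))
  if (!is.null(fixed_map)) {
    fixed_map <- fixed_map[!is.na(fixed_map$assignment), , drop = FALSE]
    eligible <- peaks$range_class %in% c("medium_range", "long_range")
    for (k in seq_len(nrow(fixed_map))) {
      f <- fixed_map[k, ]
      hit <- eligible &
        ((.in_region(peaks$res_i, f$a_from, f$a_to) &
            .in_region(peaks$res_j, f$b_from, f$b_to)) |
         (.in_region(peaks$res_j, f$a_from, f$a_to) &
            .in_region(peaks$res_i, f$b_from, f$b_to)))
      clash <- hit & !is.na(pinned_by) & amb != f$assignment
      if (any(clash)) {
        w <- which(clash)[1]
        stop(sprintf(
          "conflicting pinned assignments for peak %d-%d (interfaces %s and %s)",
          peaks$res_i[w], peaks$res_j[w], pinned_by[w], f$label))
      }
      amb[hit] <- f$assignment
      pinned_by[hit] <- f$label
    }
  }
  peaks$ambiguity <- amb
  peaks
}

#' Distance restraints from classified NOE peaks
#'
#' The default "class" mode applies the conventional bound ladder (large /
#' medium / small to 3.5 / 4.5 / 6.0 A) with the van der Waals floor as
#' lower bound.  The "exact" mode is the idealized calibration used for
#' annealer recovery benchmarks: it requires peaks carrying a `dmin`
#' column (see [simulate_noes()]) and restrains each pair to a tight
#' window `[0.85 d, d]` around the true generating distance -- the 15%
#' floor absorbs the sum-averaging depression of merged symmetric
#' duplicates.
#'
#' @param peaks Peak table with `ambiguity` (see [assign_ambiguity()]).
#' @param lower Lower bound for class-mode restraints (A); default is the
#'   van der Waals contact floor.
#' @param bounds "class" (intensity-class ladder) or "exact".
#' @return Unique (per-monomer) distance restraint table.
#' @export
noe_restraints <- function(peaks, lower = 1.8, bounds = c("class", "exact")) {
  bounds <- match.arg(bounds)
  if (is.null(peaks$ambiguity)) {
    stop("peaks must carry an ambiguity column; run assign_ambiguity() first")
  }
  if (bounds == "exact") {
    if (is.null(peaks$dmin)) {
      stop("exact bounds need peaks with a dmin column (simulate_noes keeps one)")
    }
    lo <- 0.85 * peaks$dmin
    up <- peaks$dmin
    icl <- rep(NA_character_, nrow(peaks))
  } else {
    lo <- lower
    up <- intensity_to_bound(peaks$intensity_class)
    icl <- peaks$intensity_class
  }
  data.frame(res_i = peaks$res_i, atom_i = peaks$atom_i,
             res_j = peaks$res_j, atom_j = peaks$atom_j,
             lower = rep_len(lo, nrow(peaks)), upper = up,
             ambiguity = peaks$ambiguity,
             origin = rep_len("noe", nrow(peaks)),
             intensity_class = icl,
             range_class = peaks$range_class, stringsAsFactors = FALSE)
}

#' Distance restraints from hydrogen-bond donors
#'
#' Each identified donor-acceptor pair yields two distance restraints with
#' conventional NMR bounds: H to acceptor 1.8-2.3 A and donor heavy atom to
#' acceptor 2.8-3.3 A.  Donors without a determined acceptor are skipped
#' with a warning.
#'
#' @param donors `data.frame` with columns `res_d` (donor residue),
#'   `atom_h` (proton, e.g. "H"), `atom_d` (heavy donor, e.g. "N"),
#'   `res_a`, `atom_a` (acceptor residue/atom; `NA` acceptor = undetermined),
#'   and optional `ambiguity` (default intramolecular).
#' @return Unique (per-monomer) distance restraint table (2 rows per bond).
#' @examples
#' don <- data.frame(res_d = 5, atom_h = "H", atom_d = "N",
#'                   res_a = 12, atom_a = "O")
#' hbond_restraints(don)  # 2 restraints for 1 donor on 1 chain
#' @export
hbond_restraints <- function(donors) {
  if (!nrow(donors)) {
    return(data.frame(res_i = integer(), atom_i = character(),
                      res_j = integer(), atom_j = character(),
                      lower = numeric(), upper = numeric(),
                      ambiguity = character(), origin = character(),
                      intensity_class = character(), range_class = character(),
                      stringsAsFactors = FALSE))
  }
  if (is.null(donors$ambiguity)) donors$ambiguity <- "intramolecular"
  drop <- is.na(donors$res_a) | is.na(donors$atom_a)
  if (any(drop)) {
    warning(sprintf("%d hydrogen-bond donor(s) without acceptor skipped",
                    sum(drop)))
    donors <- donors[!drop, , drop = FALSE]
  }
  n <- nrow(donors)
  out <- data.frame(
    res_i = rep(as.integer(donors$res_d), each = 2L),
    atom_i = as.vector(rbind(donors$atom_h, donors$atom_d)),
    res_j = rep(as.integer(donors$res_a), each = 2L),
    atom_j = rep(donors$atom_a, each = 2L),
    lower = rep(c(1.8, 2.8), n),
    upper = rep(c(2.3, 3.3), n),
    ambiguity = rep(donors$ambiguity, each = 2L),
    origin = "hbond",
    intensity_class = NA_character_,
    range_class = NA_character_,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Torsion restraints for side-chain rotamers
#'
#' @param resno Residue indices.
#' @param angle_name "chi1" or "chi2".
#' @param target Rotamer centre in degrees (one of -60, 60, 180).
#' @param tolerance Half-width of the allowed interval (degrees).
#' @return Torsion restraint table.
#' @export
torsion_restraints <- function(resno, angle_name, target, tolerance = 30) {
  stopifnot(all(angle_name %in% c("chi1", "chi2")),
            all(target %in% c(-60, 60, 180)))
  data.frame(resno = as.integer(resno), angle_name = angle_name,
             target = as.numeric(target),
             tolerance = rep_len(as.numeric(tolerance), length(resno)),
             stringsAsFactors = FALSE)
}

#' Assemble a restraint set
#'
#' @param distance Unique distance restraint table ([noe_restraints()] plus
#'   [hbond_restraints()] rows).
#' @param torsion Optional torsion restraint table.
#' @return Object of class `restraint_set` (unsymmetrized: restraints are in
#'   per-monomer "chain slot" form).
#' @export
restraint_set <- function(distance, torsion = NULL) {
  if (is.null(torsion)) {
    torsion <- torsion_restraints(integer(), character(), numeric())
  }
  stopifnot(all(distance$lower <= distance$upper))
  noe_up <- distance$upper[distance$origin == "noe" &
                             !is.na(distance$intensity_class)]
  if (length(noe_up) && !all(noe_up %in% .intensity_bounds)) {
    stop("NOE upper bounds must lie on the 3.5/4.5/6.0 A ladder")
  }
  structure(list(distance = distance, torsion = torsion, symmetrized = FALSE),
            class = "restraint_set")
}

#' Replicate restraints over the symmetric trimer
#'
#' Each unique restraint is instantiated once per chain frame, so the
#' constraint count triples.  Intramolecular restraints act within one
#' chain; intermolecular restraints are evaluated by sum-averaging over the
#' two neighbouring chains of the cycle (the peak does not say which
#' neighbour); ambiguous restraints sum-average over all three pairings
#' (own chain plus both neighbours).  Idempotent: symmetrizing a
#' symmetrized set is a no-op.
#'
#' @param rset A `restraint_set`.
#' @param sym A [symmetry_model()].
#' @return Symmetrized `restraint_set` with a `groups` candidate table.
#' @export
symmetrize <- function(rset, sym = symmetry_model()) {
  stopifnot(inherits(rset, "restraint_set"))
  if (isTRUE(rset$symmetrized)) return(rset)
  d <- rset$distance
  rows <- vector("list", nrow(d))
  gid <- 0L
  for (u in seq_len(nrow(d))) {
    r <- d[u, ]
    for (c0 in seq_len(sym$order)) {
      gid <- gid + 1L
      ch <- sym$chains[c0]
      partners <- switch(r$ambiguity,
        intramolecular = ch,
        intermolecular = c(cycle_chain(sym, ch, 1L), cycle_chain(sym, ch, -1L)),
        ambiguous = c(ch, cycle_chain(sym, ch, 1L), cycle_chain(sym, ch, -1L)),
        stop("unknown ambiguity label: ", r$ambiguity)
      )
      rows[[length(rows) + 1L]] <- data.frame(
        group = gid, unique_id = u, chain_i = ch, res_i = r$res_i,
        atom_i = r$atom_i, chain_j = partners, res_j = r$res_j,
        atom_j = r$atom_j, lower = r$lower, upper = r$upper,
        ambiguity = r$ambiguity, origin = r$origin, stringsAsFactors = FALSE
      )
    }
  }
  groups <- if (length(rows)) do.call(rbind, rows) else NULL
  tor <- rset$torsion
  if (nrow(tor)) {
    tor <- do.call(rbind, lapply(sym$chains, function(ch) {
      t2 <- tor
      t2$chain <- ch
      t2
    }))
    rownames(tor) <- NULL
  } else {
    tor$chain <- character(0)
  }
  structure(list(distance = rset$distance, torsion = tor, groups = groups,
                 symmetrized = TRUE, sym = sym),
            class = "restraint_set")
}

#' Table-1-style restraint bookkeeping
#'
#' Counts constraints per category for a symmetrized set, where each unique
#' NOE counts `order` times (three constraints per NOE for a trimer).
#'
#' @param rset A symmetrized `restraint_set`.
#' @return Named list of counts.
#' @export
restraint_counts <- function(rset) {
  stopifnot(inherits(rset, "restraint_set"))
  if (!isTRUE(rset$symmetrized)) rset <- symmetrize(rset)
  d <- rset$distance
  mult <- rset$sym$order
  noe <- d[d$origin == "noe", ]
  cnt <- function(rc, amb = NULL) {
    sel <- noe$range_class == rc
    if (!is.null(amb)) sel <- sel & noe$ambiguity == amb
    sum(sel, na.rm = TRUE) * mult
  }
  n_hbond <- sum(d$origin == "hbond") * mult
  n_tors <- nrow(rset$torsion)
  list(
    sequential = cnt("sequential"),
    medium_range = cnt("medium_range"),
    medium_range_intra = cnt("medium_range", "intramolecular"),
    medium_range_inter = cnt("medium_range", "intermolecular"),
    medium_range_ambiguous = cnt("medium_range", "ambiguous"),
    long_range = cnt("long_range"),
    long_range_intra = cnt("long_range", "intramolecular"),
    long_range_inter = cnt("long_range", "intermolecular"),
    long_range_ambiguous = cnt("long_range", "ambiguous"),
    intra_residue = cnt("intra_residue"),
    hbond = n_hbond,
    torsion = n_tors,
    total_distance = nrow(noe) * mult + n_hbond,
    total = nrow(noe) * mult + n_hbond + n_tors
  )
}

#' @export
print.restraint_set <- function(x, ...) {
  cat(sprintf("<restraint_set> %d unique distance, %d torsion restraint(s)%s\n",
              nrow(x$distance), nrow(x$torsion),
              if (isTRUE(x$symmetrized)) " [symmetrized x3]" else ""))
  invisible(x)
}

#' Write / read the restraint table dialect
#'
#' Tab-separated, one row per unique restraint with columns `res_i`,
#' `atom_i`, `res_j`, `atom_j`, `intensity_class`, `lower`, `upper`,
#' `ambiguity`, `origin`, `range_class`.  Writing then reading then writing
#' again is byte-identical.
#'
#' @param distance Unique distance restraint table.
#' @param path File path.
#' @export
write_restraints <- function(distance, path) {
  cols <- c("res_i", "atom_i", "res_j", "atom_j", "intensity_class",
            "lower", "upper", "ambiguity", "origin", "range_class")
  d <- distance[, cols]
  d$lower <- formatC(d$lower, format = "g", digits = 15)
  d$upper <- formatC(d$upper, format = "g", digits = 15)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_restraints
#' @export
read_restraints <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(res_i = "integer", atom_i = "character",
                                        res_j = "integer", atom_j = "character",
                                        intensity_class = "character",
                                        lower = "numeric", upper = "numeric",
                                        ambiguity = "character",
                                        origin = "character",
                                        range_class = "character"))
  d
}
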