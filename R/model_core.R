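# Core domain types: peptide sequences, atoms, conformers, ensembles, and
# the C3 symmetry model shared by every pipeline stage.

# Average residue masses (Da) of the 20 standard amino acids, i.e. the mass
# contributed by each residue inside a peptide chain (monomer mass minus one
# water).  Average, not monoisotopic: oligomer-size bookkeeping in this
# package is at the kDa level.
.aa_residue_mass <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)

.water_mass <- 18.0153

.aa_three <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", E = "GLU",
  Q = "GLN", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
  Y = "TYR", V = "VAL"
)

#' Amino-acid sequence of the PhoSL lectin monomer
#'
#' The 40-residue core-fucosylation-specific lectin peptide from
#' *Pholiota squarrosa*, the system this package's workflow was designed
#' around.  The chemically synthesizable monomer assembles into a
#' C3-symmetric trimer in solution.
#'
#' @return A one-letter amino-acid string of length 40.
#' @examples
#' nchar(phosl_sequence())
#' @export
phosl_sequence <- function() {
  "APVPVTKLVCDGDTYKCTAYLDYGDGKWVAQWDTAVFHTT"
}

#' Validate a one-letter peptide sequence
#'
#' @param seq One-letter amino-acid string.
#' @return The vector of single letters, invisibly usable downstream.
#' @keywords internal
check_sequence <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || nchar(seq) == 0L) {
    stop("sequence must be a non-empty one-letter amino-acid string")
  }
  letters1 <- strsplit(seq, "")[[1]]
  bad <- which(!letters1 %in% names(.aa_residue_mass))
  if (length(bad)) {
    stop(sprintf("unknown amino-acid letter '%s' at position %d",
                 letters1[bad[1]], bad[1]))
  }
  letters1
}

#' Average molecular mass of a peptide
#'
#' Sums average residue masses and adds one water (18.02 Da) for the free
#' chain termini.  For the packaged PhoSL 40-mer this gives ~4.44 kDa, the
#' monomer unit of the ~13 kDa trimer.
#'
#' @param seq One-letter amino-acid string.
#' @return Mass in daltons.
#' @examples
#' sequence_mass("G")                 # 75.07
#' sequence_mass(phosl_sequence())    # ~4437
#' @export
sequence_mass <- function(seq) {
  letters1 <- check_sequence(seq)
  sum(.aa_residue_mass[letters1]) + .water_mass
}

#' Construct a conformer
#'
#' A conformer is one coordinate model: an ordered atom table plus optional
#' bookkeeping filled in by the annealer (restraint energy, maximal
#' violations).  Atom ordering is significant: all members of one ensemble
#' must share it.
#'
#' @param atoms `data.frame` with columns `chain`, `resno`, `resid`,
#'   `elety` (PDB atom name), `elesy` (element), `x`, `y`, `z` (angstrom).
#' @param model_id Integer model number.
#' @param energy Optional restraint + geometry energy (kcal/mol).
#' @param max_dist_viol Optional maximal distance-restraint violation (A).
#' @param max_tors_viol Optional maximal torsion violation (degrees).
#' @return Object of class `conformer`.
#' @export
conformer <- function(atoms, model_id = 1L, energy = NA_real_,
                      max_dist_viol = NA_real_, max_tors_viol = NA_real_) {
  needed <- c("chain", "resno", "resid", "elety", "elesy", "x", "y", "z")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols)) {
    stop("atoms table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  atoms <- as.data.frame(atoms)[, needed]
  rownames(atoms) <- NULL
  structure(
    list(atoms = atoms, model_id = as.integer(model_id), energy = energy,
         max_dist_viol = max_dist_viol, max_tors_viol = max_tors_viol),
    class = "conformer"
  )
}

#' @export
print.conformer <- function(x, ...) {
  ch <- unique(x$atoms$chain)
  cat(sprintf("<conformer> model %d: %d atoms, %d chain(s) [%s]\n",
              x$model_id, nrow(x$atoms), length(ch),
              paste(ch, collapse = ",")))
  if (!is.na(x$energy)) cat(sprintf("  energy %.3f kcal/mol\n", x$energy))
  if (!is.na(x$max_dist_viol)) {
    cat(sprintf("  max violations: %.3f A / %.2f deg\n",
                x$max_dist_viol, x$max_tors_viol))
  }
  invisible(x)
}

#' Extract or replace conformer coordinates
#'
#' @param conf A `conformer`.
#' @return `coords()`: an n x 3 matrix in angstrom.
#' @export
coords <- function(conf) {
  stopifnot(inherits(conf, "conformer"))
  as.matrix(conf$atoms[, c("x", "y", "z")])
}

#' @rdname coords
#' @param xyz n x 3 coordinate matrix.
#' @export
set_coords <- function(conf, xyz) {
  stopifnot(inherits(conf, "conformer"), nrow(xyz) == nrow(conf$atoms))
  conf$atoms[, c("x", "y", "z")] <- xyz
  conf
}

#' Construct an ensemble of conformers
#'
#' @param members List of `conformer` objects sharing one atom set.
#' @param selection_note Free-text provenance (how members were selected).
#' @return Object of class `ensemble`.
#' @export
ensemble <- function(members, selection_note = "") {
  if (!length(members)) {
    return(structure(list(members = list(), selection_note = selection_note),
                     class = "ensemble"))
  }
  stopifnot(all(vapply(members, inherits, logical(1), "conformer")))
  ref <- members[[1]]$atoms
  for (k in seq_along(members)) {
    a <- members[[k]]$atoms
    if (nrow(a) != nrow(ref) ||
        !all(a$chain == ref$chain & a$resno == ref$resno &
             a$elety == ref$elety)) {
      stop(sprintf("ensemble member %d has a different atom set than member 1",
                   k))
    }
  }
  structure(list(members = members, selection_note = selection_note),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("<ensemble> %d member(s)", length(x$members)))
  if (nzchar(x$selection_note)) cat(" -- ", x$selection_note, sep = "")
  cat("\n")
  invisible(x)
}

#' @export
length.ensemble <- function(x) length(x$members)

#' Cyclic symmetry model for a homo-oligomer
#'
#' Describes the rotational symmetry relating the chains: for the trimers
#' handled here, order 3 with chain cycle A -> B -> C -> A.
#'
#' @param order Rotation order (3 for C3).
#' @param chains Chain labels in cycle order.
#' @return Object of class `symmetry_model`.
#' @export
symmetry_model <- function(order = 3L, chains = c("A", "B", "C")) {
  order <- as.integer(order)
  stopifnot(order >= 1L, length(chains) == order)
  structure(list(order = order, chains = chains), class = "symmetry_model")
}

#' Next chain in the symmetry cycle
#' @param sym A `symmetry_model`.
#' @param chain Chain label.
#' @param step How many cycle steps forward (may be negative).
#' @return Chain label.
#' @keywords internal
cycle_chain <- function(sym, chain, step = 1L) {
  i <- match(chain, sym$chains)
  sym$chains[((i - 1L + step) %% sym$order) + 1L]
}

#' Structural sanity report for a trimer model
#'
#' Report-only validation: counts chains and residues, checks for missing
#' backbone heavy atoms (N, CA, C), and flags any chain count other than 3.
#' Never throws; inspect `$flags`.
#'
#' @param conf A `conformer`.
#' @return List with `n_chains`, `residues_per_chain`, `flags`
#'   (character vector, empty when the model looks like a complete trimer).
#' @export
validate_trimer <- function(conf) {
  stopifnot(inherits(conf, "conformer"))
  at <- conf$atoms
  chains <- unique(at$chain)
  flags <- character(0)
  if (length(chains) != 3L) {
    flags <- c(flags, sprintf("chain count %d (expected 3)", length(chains)))
  }
  res_per_chain <- vapply(
    chains, function(ch) length(unique(at$resno[at$chain == ch])), integer(1)
  )
  names(res_per_chain) <- chains
  for (ch in chains) {
    sub <- at[at$chain == ch, ]
    for (res in unique(sub$resno)) {
      have <- sub$elety[sub$resno == res]
      lack <- setdiff(c("N", "CA", "C"), have)
      if (length(lack)) {
        flags <- c(flags, sprintf("chain %s residue %d missing backbone atom(s) %s",
                                  ch, res, paste(lack, collapse = ",")))
      }
    }
  }
  list(n_chains = length(chains), residues_per_chain = res_per_chain,
       flags = flags)
}
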