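# Interface-register resolution: decide, per beta-strand interface, whether
# its NOEs are intra- or intermolecular by running competing annealing
# trials under each hypothesis and comparing acceptance counts -- the
# decision statistic is the count contrast, not any absolute rate.

#' Enumerate interface assignment hypotheses
#'
#' Every interface with an undecided (`NA`) assignment is expanded over
#' both labels; pinned interfaces keep their assignment.  The exhaustive
#' mode grows as 2^k and is capped; the sequential strategy (resolve one
#' interface, pin it, continue) is expressed by calling this repeatedly
#' with a growing `constrain` map.
#'
#' @param interfaces An [interface_map()]; `NA` assignments are free.
#' @param constrain Optional named character vector `label = assignment`
#'   pinning a subset of the free interfaces.
#' @param cap Maximal number of free interfaces for exhaustive enumeration.
#' @return List of fully assigned `interface_map`s.
#' @export
enumerate_hypotheses <- function(interfaces, constrain = NULL, cap = 6L) {
  if (!nrow(interfaces)) stop("need at least one interface")
  m <- interfaces
  if (!is.null(constrain)) {
    bad <- setdiff(names(constrain), m$label)
    if (length(bad)) stop("unknown interface label(s): ",
                          paste(bad, collapse = ", "))
    m$assignment[match(names(constrain), m$label)] <- unname(constrain)
  }
  free <- which(is.na(m$assignment))
  if (length(free) > cap) {
    stop(sprintf(
      "%d free interfaces exceed the exhaustive cap (%d); resolve sequentially",
      length(free), cap))
  }
  if (!length(free)) return(list(m))
  labs <- c("intramolecular", "intermolecular")
  grid <- expand.grid(rep(list(labs), length(free)),
                      stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(k) {
    h <- m
    h$assignment[free] <- unlist(grid[k, ])
    h
  })
}

#' Evaluate one interface hypothesis by annealing trials
#'
#' Builds the restraint set with the hypothesis applied through
#' [assign_ambiguity()], runs `n_trials` seeded annealing trials and
#' counts how many satisfy the acceptance filter.  Annealer failures count
#' as rejections.
#'
#' @param hypothesis A fully assigned [interface_map()].
#' @param peaks NOE peak table (no ambiguity column needed).
#' @param template Template `conformer` (topology).
#' @param n_trials Number of trials.
#' @param master_seed Master seed; trial k uses `master_seed + k`.
#' @param donors Optional hydrogen-bond donor table (see
#'   [hbond_restraints()]).
#' @param schedule,energy,thresholds Annealer configuration.
#' @return List with `hypothesis`, `accepted` (count), `n_trials`,
#'   and `conformers` (the accepted structures).
#' @export
evaluate_hypothesis <- function(hypothesis, peaks, template, n_trials = 10,
                                master_seed = 0, donors = NULL,
                                schedule = anneal_schedule(),
                                energy = energy_model(),
                                thresholds = acceptance_thresholds()) {
  if (any(is.na(hypothesis$assignment))) {
    stop("hypothesis must assign every interface")
  }
  pk <- assign_ambiguity(peaks, hypothesis)
  dist <- noe_restraints(pk)
  if (!is.null(donors) && nrow(donors)) {
    dist <- rbind(dist, hbond_restraints(donors))
  }
  sys <- prepare_system(template, restraint_set(dist), energy)
  trials <- anneal_trials(sys, n_trials, master_seed, schedule = schedule)
  ok <- vapply(trials, function(cf) {
    !is.null(cf) && accept(cf, thresholds)$accepted
  }, logical(1))
  list(hypothesis = hypothesis, accepted = sum(ok), n_trials = n_trials,
       conformers = trials[ok])
}

#' Resolve interface registers by competing hypotheses
#'
#' Evaluates every hypothesis and declares the one with the most accepted
#' structures the winner; an all-zero outcome is reported as "unresolved"
#' with no guess.  The winner's accepted structures are checked for mutual
#' consistency (pairwise backbone RMSD under chain-permutation-aware
#' superposition below `consistency_rmsd`), mirroring the observation that
#' all acceptable structures should share one strand arrangement.
#'
#' @inheritParams evaluate_hypothesis
#' @param interfaces [interface_map()] with free (`NA`) assignments.
#' @param consistency_rmsd Threshold (A) for the consistency check.
#' @param ... Passed to [evaluate_hypothesis()].
#' @return List of class `register_report`: `status`
#'   ("resolved"/"unresolved"), `winner`, `table` (per-hypothesis counts),
#'   `consistent` (logical or `NA` when fewer than 2 accepted).
#' @export
resolve_register <- function(interfaces, peaks, template, n_trials = 10,
                             master_seed = 0, consistency_rmsd = 2.5, ...) {
  hyps <- enumerate_hypotheses(interfaces)
  if (length(hyps) < 2) stop("need at least two hypotheses to compare")
  evals <- lapply(hyps, function(h) {
    evaluate_hypothesis(h, peaks, template, n_trials = n_trials,
                        master_seed = master_seed, ...)
  })
  counts <- vapply(evals, function(e) e$accepted, integer(1))
  tab <- data.frame(
    hypothesis = vapply(hyps, function(h) {
      paste(sprintf("%s=%s", h$label, substr(h$assignment, 1, 5)),
            collapse = ",")
    }, character(1)),
    accepted = counts, n_trials = n_trials, stringsAsFactors = FALSE
  )
  if (all(counts == 0L)) {
    return(structure(list(status = "unresolved", winner = NULL, table = tab,
                          consistent = NA), class = "register_report"))
  }
  wi <- which.max(counts)
  win <- evals[[wi]]
  consistent <- NA
  if (length(win$conformers) >= 2L) {
    pairs_ok <- TRUE
    cf <- win$conformers
    for (a in seq_along(cf)) {
      for (b in seq_len(a - 1L)) {
        r <- symmetric_rmsd(cf[[a]], cf[[b]])$rmsd
        if (r > consistency_rmsd) pairs_ok <- FALSE
      }
    }
    consistent <- pairs_ok
  }
  structure(list(status = "resolved", winner = win$hypothesis, table = tab,
                 winner_index = wi, consistent = consistent,
                 conformers = win$conformers),
            class = "register_report")
}

#' @export
print.register_report <- function(x, ...) {
  cat("<register_report>", x$status, "\n")
  print(x$table)
  if (!is.na(x$consistent)) {
    cat("winner's accepted structures mutually consistent:", x$consistent, "\n")
  }
  invisible(x)
}
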