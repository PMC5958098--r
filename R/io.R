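# File formats: multi-model PDB (read via bio3d, written directly),
# titration and interface TSV dialects, flat key-value configs, and
# JSON-lines run logs.

#' Read a (multi-model) PDB file as an ensemble
#'
#' MODEL/ENDMDL records delimit ensemble members; single-model files yield
#' a one-member ensemble.  Hydrogens are retained.  Files whose models
#' carry different atom sets, or with unbalanced MODEL/ENDMDL records, are
#' rejected with the offending line number.
#'
#' @param path PDB file path.
#' @return An [ensemble()].
#' @export
read_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  model_open <- 0L
  n_atoms <- integer(0)
  cur <- NA_integer_
  for (i in seq_along(lines)) {
    rec <- substr(lines[i], 1, 6)
    if (rec == "MODEL ") {
      if (model_open > 0L) {
        stop(sprintf("parse error at line %d: nested MODEL record", i))
      }
      model_open <- 1L
      cur <- 0L
    } else if (rec == "ENDMDL") {
      if (model_open == 0L) {
        stop(sprintf("parse error at line %d: ENDMDL without MODEL", i))
      }
      model_open <- 0L
      n_atoms <- c(n_atoms, cur)
      cur <- NA_integer_
    } else if (rec %in% c("ATOM  ", "HETATM")) {
      if (nchar(lines[i]) < 54) {
        stop(sprintf("parse error at line %d: truncated coordinate record", i))
      }
      if (!is.na(cur)) cur <- cur + 1L
    }
  }
  if (model_open > 0L) {
    stop(sprintf("parse error at line %d: MODEL record never closed",
                 length(lines)))
  }
  if (length(n_atoms) > 1L && length(unique(n_atoms)) != 1L) {
    first_bad <- which(n_atoms != n_atoms[1])[1]
    stop(sprintf(
      "inconsistent atom sets across models: model %d has %d atoms, model 1 has %d",
      first_bad, n_atoms[first_bad], n_atoms[1]))
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  a <- pdb$atom
  elesy <- a$elesy
  if (is.null(elesy) || all(is.na(elesy)) || all(elesy == "")) {
    elesy <- substr(gsub("[0-9]", "", a$elety), 1, 1)
  }
  base <- data.frame(chain = a$chain, resno = a$resno, resid = a$resid,
                     elety = a$elety, elesy = trimws(elesy),
                     x = 0, y = 0, z = 0, stringsAsFactors = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  members <- lapply(seq_len(nrow(xyz)), function(m) {
    at <- base
    co <- matrix(xyz[m, ], ncol = 3, byrow = TRUE)
    at$x <- co[, 1]; at$y <- co[, 2]; at$z <- co[, 3]
    conformer(at, model_id = m)
  })
  ensemble(members, selection_note = sprintf("read from %s", path))
}

.format_atom_line <- function(serial, at, k) {
  name <- at$elety[k]
  name_fmt <- if (nchar(name) < 4) sprintf(" %-3s", name) else sprintf("%-4s", name)
  sprintf("ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name_fmt, at$resid[k], at$chain[k], at$resno[k],
          at$x[k], at$y[k], at$z[k], 1.0, 0.0, at$elesy[k])
}

#' Write a conformer or ensemble as (multi-model) PDB
#'
#' @param x A `conformer` or [ensemble()].
#' @param path Output path.
#' @export
write_pdb <- function(x, path) {
  members <- if (inherits(x, "ensemble")) x$members else list(x)
  if (!length(members)) stop("nothing to write")
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(members) > 1L
  for (m in seq_along(members)) {
    at <- members[[m]]$atoms
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    writeLines(vapply(seq_len(nrow(at)), function(k) {
      .format_atom_line(k, at, k)
    }, character(1)), con)
    writeLines(if (multi) "ENDMDL" else "END", con)
  }
  invisible(path)
}

#' Read / write titration tables
#'
#' Tab-separated with columns `L_tot_M` (or `L_tot_mM`) and one
#' `delta_ppm` column per resonance (suffix after `delta_ppm_` names the
#' resonance).  `P_tot_M` may be given as a header comment line
#' `# P_tot_M <value>`.
#'
#' @param path File path.
#' @param P_tot Protein site concentration (M); overrides any header.
#' @return List of [titration_series()].
#' @export
read_titration <- function(path, P_tot = NULL) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^# *P_tot_M", lines, value = TRUE)
  if (is.null(P_tot)) {
    P_tot <- if (length(hdr)) as.numeric(sub("^# *P_tot_M *", "", hdr[1])) else 0
  }
  d <- utils::read.delim(text = lines[!startsWith(lines, "#")],
                         stringsAsFactors = FALSE, check.names = FALSE)
  lcol <- intersect(c("L_tot_M", "L_tot_mM"), names(d))
  if (!length(lcol)) stop("titration table needs an L_tot_M or L_tot_mM column")
  L <- d[[lcol[1]]] * if (lcol[1] == "L_tot_mM") 1e-3 else 1
  dcols <- grep("^delta_ppm", names(d), value = TRUE)
  if (!length(dcols)) stop("titration table has no delta_ppm column")
  lapply(dcols, function(cn) {
    rid <- sub("^delta_ppm_?", "", cn)
    if (!nzchar(rid)) rid <- "resonance"
    titration_series(L, d[[cn]], P_tot, resonance_id = rid)
  })
}

#' @rdname read_titration
#' @param series A [titration_series()] or list of them sharing one
#'   ligand grid.
#' @export
write_titration <- function(series, path) {
  if (inherits(series, "titration_series")) series <- list(series)
  L <- series[[1]]$L_tot
  out <- data.frame(L_tot_M = L)
  for (s in series) {
    stopifnot(identical(s$L_tot, L))
    out[[paste0("delta_ppm_", s$resonance_id)]] <- s$delta_obs
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# P_tot_M %.10g", series[[1]]$P_tot), con)
  utils::write.table(format(out, digits = 10, trim = TRUE), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write interface maps
#'
#' Tab-separated mirror of [interface_map()]; `assignment` may be `NA`
#' for undecided interfaces.
#'
#' @param path File path.
#' @export
read_interfaces <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  interface_map(d$label, d$a_from, d$a_to, d$b_from, d$b_to, d$assignment)
}

#' @rdname read_interfaces
#' @param map An [interface_map()].
#' @export
write_interfaces <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read / write flat key-value run configuration
#'
#' One `key = value` pair per line; numeric-looking values are converted;
#' comma-separated values become vectors.  Round-trips losslessly.
#'
#' @param path File path.
#' @return Named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(num)) num else parts
  }
  out
}

#' @rdname read_config
#' @param config Named list of scalars/vectors.
#' @export
write_config <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    vtxt <- if (is.numeric(v)) paste(formatC(v, format = "g", digits = 15),
                                     collapse = ", ")
            else paste(v, collapse = ", ")
    sprintf("%s = %s", k, vtxt)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Append trial records to a JSON-lines run log
#'
#' One JSON object per line with trial index, seed, energy, maximal
#' violations and the acceptance flag -- machine-parseable with any JSON
#' reader.
#'
#' @param trials List of `conformer`s from [anneal_trials()].
#' @param path Log path (appended).
#' @param master_seed Master seed used for the series.
#' @param thresholds An [acceptance_thresholds()] list.
#' @export
write_run_log <- function(trials, path, master_seed = 0,
                          thresholds = acceptance_thresholds()) {
  con <- file(path, "a")
  on.exit(close(con))
  for (k in seq_along(trials)) {
    cf <- trials[[k]]
    line <- if (is.null(cf)) {
      sprintf(paste0('{"trial":%d,"seed":%d,"status":"failed",',
                     '"time":"%s"}'),
              k, master_seed + k, format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
    } else {
      sprintf(paste0('{"trial":%d,"seed":%d,"energy":%.6g,',
                     '"max_dist_viol":%.6g,"max_tors_viol":%.6g,',
                     '"accepted":%s,"time":"%s"}'),
              k, master_seed + k, cf$energy, cf$max_dist_viol,
              cf$max_tors_viol,
              tolower(accept(cf, thresholds)$accepted),
              format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
    }
    writeLines(line, con)
  }
  invisible(path)
}

#' Read a JSON-lines run log
#'
#' @param path Log path.
#' @return `data.frame` with one row per record.
#' @export
read_run_log <- function(path) {
  lines <- readLines(path, warn = FALSE)
  grab <- function(ln, key, num = TRUE) {
    m <- regmatches(ln, regexpr(sprintf('"%s":"?[^,"}]*', key), ln))
    if (!length(m)) return(if (num) NA_real_ else NA_character_)
    v <- sub(sprintf('"%s":"?', key), "", m)
    if (num) as.numeric(v) else v
  }
  data.frame(
    trial = vapply(lines, grab, numeric(1), key = "trial",
                   USE.NAMES = FALSE),
    seed = vapply(lines, grab, numeric(1), key = "seed", USE.NAMES = FALSE),
    energy = vapply(lines, grab, numeric(1), key = "energy",
                    USE.NAMES = FALSE),
    max_dist_viol = vapply(lines, grab, numeric(1), key = "max_dist_viol",
                           USE.NAMES = FALSE),
    max_tors_viol = vapply(lines, grab, numeric(1), key = "max_tors_viol",
                           USE.NAMES = FALSE),
    accepted = vapply(lines, grab, character(1), key = "accepted",
                      num = FALSE, USE.NAMES = FALSE) == "true",
    stringsAsFactors = FALSE
  )
}
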