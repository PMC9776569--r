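#' Model-compound pKa calibration task
#'
#' Calibration adjusts the model-compound pKa (`pkmod`) of a titratable
#' group so that a titration of a simple single-site system (an
#' alanine-based pentapeptide with the group at its center) reproduces
#' the experimental pKa.  Each round titrates the system at pH values
#' near the current guess, fits a Hill curve, and shifts `pkmod` by the
#' experimental-minus-simulated difference; iteration absorbs residual
#' bias left by sampling noise (a single-pass mode is available).
#'
#' @param experimental_pka target pKa
#' @param initial_guess starting `pkmod` (default: the experimental
#'   value)
#' @param ph_offsets pH grid offsets around the current guess
#' @param replicates titration replicates per round
#' @param tolerance convergence threshold on `|experimental -
#'   simulated|`, pK units
#' @param max_rounds round cap
#' @param single_pass apply one shift-and-correct round only
#' @return a `calibration_task`
#' @export
calibration_task <- function(experimental_pka,
                             initial_guess = experimental_pka,
                             ph_offsets = c(-1.5, -1, -0.5, 0, 0.5, 1, 1.5),
                             replicates = 3L, tolerance = 0.05,
                             max_rounds = 5L, single_pass = FALSE) {
  if (tolerance <= 0) stop("tolerance must be positive")
  if (diff(range(ph_offsets)) < 2)
    stop("ph grid must span at least 2 pK units around the guess")
  structure(list(experimental_pka = experimental_pka,
                 initial_guess = initial_guess, ph_offsets = ph_offsets,
                 replicates = as.integer(replicates), tolerance = tolerance,
                 max_rounds = as.integer(max_rounds),
                 single_pass = isTRUE(single_pass)),
            class = "calibration_task")
}

#' Calibrate a model-compound pKa against an experimental value
#'
#' @param task a `calibration_task`
#' @param engine a titration engine: `function(pkmod, task)` returning a
#'   `hill_fit` (or any list with `pka` and `converged`) for the
#'   calibration system run with that `pkmod`.  See
#'   [make_titration_engine()] for the desk-scale engine.
#' @return a `calibration_result`: `pkmod_final`, per-round log,
#'   `converged`
#' @export
calibrate <- function(task, engine) {
  pkmod <- task$initial_guess
  rounds <- data.frame(round = integer(0), pkmod_in = numeric(0),
                       pka_simulated = numeric(0), shift = numeric(0))
  converged <- FALSE
  n_rounds <- if (task$single_pass) 1L else task$max_rounds
  for (r in seq_len(n_rounds)) {
    ft <- engine(pkmod, task)
    if (is.null(ft$converged) || !isTRUE(ft$converged))
      stop("Hill fit did not converge in calibration round ", r,
           " (pkmod = ", signif(pkmod, 6), ")")
    shift <- task$experimental_pka - ft$pka
    rounds <- rbind(rounds, data.frame(round = r, pkmod_in = pkmod,
                                       pka_simulated = ft$pka,
                                       shift = shift))
    if (abs(shift) <= task$tolerance && !task$single_pass) {
      converged <- TRUE
      break
    }
    pkmod <- pkmod + shift
    if (task$single_pass) converged <- TRUE
  }
  structure(list(pkmod_final = pkmod, rounds = rounds,
                 converged = converged), class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("Calibration:", if (x$converged) "converged" else "NOT converged",
      "- final pkmod =", signif(x$pkmod_final, 6), "\n")
  print(x$rounds, row.names = FALSE)
  invisible(x)
}

#' Bead-model pentapeptide fixture
#'
#' A coarse Ala2-X-Ala2 pentapeptide: five backbone beads along the x
#' axis plus a titratable side-chain bead on the central residue.  With
#' `capped = FALSE` and residue type `NTr`/`CTr`, an all-alanine
#' pentapeptide is built instead and the corresponding terminus bead
#' titrates.
#'
#' @param residue_type residue type in the library (e.g. `"GLU"`,
#'   `"NTR"`)
#' @param capped termini capped (non-titrating)?
#' @param library a `site_library` (default [toy_site_library()])
#' @return list with `structure` and `sites` (length 1)
#' @export
make_pentapeptide_fixture <- function(residue_type, capped = TRUE,
                                      library = toy_site_library()) {
  terminus <- residue_type %in% c("NTR", "CTR")
  if (is.null(library$entries[[residue_type]]))
    stop("unknown residue type: ", residue_type)
  spacing <- 0.35
  resnames <- rep("ALA", 5)
  if (!terminus) resnames[3] <- residue_type
  bb <- data.frame(name = "CA", resname = resnames, resid = 1:5,
                   x = (0:4) * spacing, y = 0, z = 0,
                   charge = 0, radius = 0.2, stringsAsFactors = FALSE)
  if (!terminus) {
    tpl <- library$entries[[residue_type]]
    sc <- data.frame(name = tpl$member_atoms,
                     resname = residue_type, resid = 3,
                     x = 2 * spacing,
                     y = 0.25 + 0.1 * (seq_along(tpl$member_atoms) - 1),
                     z = 0, charge = 0, radius = 0.18,
                     stringsAsFactors = FALSE)
    str <- atoms_df(rbind(bb, sc))
    sites <- instantiate_sites(str, library, selection = 3)
  } else {
    if (capped) stop("terminus calibration requires capped = FALSE")
    ter <- library$entries[[residue_type]]
    at <- data.frame(name = ter$member_atoms, resname = "ALA",
                     resid = if (residue_type == "NTR") 1 else 5,
                     x = if (residue_type == "NTR") -0.13 else
                       4 * spacing + 0.13,
                     y = 0.1, z = 0, charge = 0, radius = 0.17,
                     stringsAsFactors = FALSE)
    str <- atoms_df(rbind(bb, at))
    sites <- instantiate_sites(str, library, selection = integer(0),
                               ntr = residue_type == "NTR",
                               ctr = residue_type == "CTR")
  }
  list(structure = str, sites = sites)
}

#' Desk-scale titration engine for calibration
#'
#' Builds an engine closure for [calibrate()]: for a given `pkmod` it
#' recomputes the pentapeptide's energy table by continuum
#' electrostatics, titrates the single site over the task's pH grid
#' (exact enumeration, or Metropolis sampling when `mc` is given), and
#' returns the Hill fit.
#'
#' @param fixture output of [make_pentapeptide_fixture()]
#' @param config a `pb_config`
#' @param mc optional `mc_config`; `NULL` titrates by exact enumeration
#' @return `function(pkmod, task)` returning a `hill_fit`
#' @export
make_titration_engine <- function(fixture, config = pb_config(),
                                  mc = NULL) {
  base_site <- fixture$sites[[1]]
  function(pkmod, task) {
    site <- base_site
    for (k in seq_along(site$states)) site$states[[k]]$pkmod <- pkmod
    table <- compute_energy_table(fixture$structure, list(site), config)
    ph <- pkmod + task$ph_offsets
    reps <- lapply(seq_len(task$replicates), function(r) {
      fr <- vapply(ph, function(p) {
        if (is.null(mc)) enumerate_exact(table, p)$per_site_protonation[1]
        else {
          cfg <- mc; cfg$seed <- mc$seed + 1000L * r + round(100 * p)
          run_mc(table, p, cfg)$per_site_protonation[1]
        }
      }, numeric(1))
      matrix(fr, nrow = 1, dimnames = list(NULL, ph))
    })
    fit_hill(aggregate_titration(reps, burn_in_fraction = 0))
  }
}
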