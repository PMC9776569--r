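#' Monte Carlo configuration
#'
#' @param n_cycles MC cycles (one cycle = one randomized sweep over all
#'   single-site moves plus all coupled-pair moves); default 1e5
#' @param pair_threshold couple two sites with a double move when the
#'   largest absolute interaction between any of their state
#'   combinations exceeds this value, pK units (default 2)
#' @param seed RNG seed
#' @param burn_in_cycles cycles discarded before averaging
#' @return an `mc_config`
#' @export
mc_config <- function(n_cycles = 100000L, pair_threshold = 2,
                      seed = 1L, burn_in_cycles = 0L) {
  stopifnot(n_cycles >= 0, pair_threshold >= 0, burn_in_cycles >= 0,
            burn_in_cycles <= n_cycles)
  structure(list(n_cycles = as.integer(n_cycles),
                 pair_threshold = pair_threshold, seed = as.integer(seed),
                 burn_in_cycles = as.integer(burn_in_cycles)),
            class = "mc_config")
}

## pH-dependent single-state energy term in pK units:
##   t(s) = x_s * (pH - pkmod_s) + (pkmod_s - pkint_s)
## For the usual case (reference = a deprotonated state, protonated
## states carrying pkint) this reduces to x * (pH - pkint); the extra
## term carries the transfer free energy of deprotonated tautomers.
state_terms <- function(table, pH) {
  st <- table$states
  st$x * (pH - st$pkmod) + (st$pkmod - st$pkint)
}

#' Microstate energy in pK units
#'
#' `E = sum_i [x_i (pH - pkint_i)] + sum_(i<j) W(s_i, s_j)` for the
#' usual deprotonated-reference tables (see [site_energy_table()]);
#' multiply by `kT ln 10` for energy units.  The all-reference
#' microstate has energy zero.
#'
#' @param assignment named vector `site -> state label`, or integer
#'   vector of global state indices (one per site)
#' @param pH pH value
#' @param table a `site_energy_table`
#' @return energy in pK units
#' @export
microstate_energy <- function(assignment, pH, table) {
  idx <- resolve_assignment(assignment, table)
  tt <- state_terms(table, pH)
  Wsum <- 0
  if (length(idx) > 1) {
    pairs <- utils::combn(idx, 2)
    Wsum <- sum(table$W[t(pairs)])
  }
  sum(tt[idx]) + Wsum
}

## turn either representation into global state indices (one per site)
resolve_assignment <- function(assignment, table) {
  st <- table$states
  sites <- unique(st$site)
  if (is.numeric(assignment) && is.null(names(assignment))) {
    idx <- as.integer(assignment)
    if (length(idx) != length(sites) ||
        !identical(st$site[idx], sites))
      stop("assignment must give exactly one state per site")
    return(idx)
  }
  if (is.null(names(assignment)))
    stop("assignment must be named by site or be global state indices")
  idx <- vapply(sites, function(s) {
    lab <- assignment[[as.character(s)]]
    if (is.null(lab) || is.na(lab))
      stop("no state assigned for site ", s)
    i <- which(st$site == s & st$state == lab)
    if (!length(i)) stop("state '", lab, "' missing from table for site ", s)
    i
  }, integer(1))
  unname(idx)
}

## site pairs whose strongest |W| over state combinations exceeds thr
coupled_pairs <- function(table, thr) {
  st <- table$states
  sites <- unique(st$site)
  ns <- length(sites)
  if (ns < 2) return(matrix(integer(0), nrow = 2))
  out <- NULL
  for (i in seq_len(ns - 1)) for (j in (i + 1):ns) {
    wij <- table$W[st$site == sites[i], st$site == sites[j], drop = FALSE]
    if (max(abs(wij)) > thr) out <- cbind(out, c(i, j))
  }
  if (is.null(out)) matrix(integer(0), nrow = 2) else out
}

#' Metropolis Monte Carlo sampling of protonation microstates
#'
#' Per cycle, one attempted move per site (uniform alternative state,
#' Metropolis acceptance `min(1, 10^-dE)`) and one attempted joint move
#' per coupled pair, in randomized order.  Reproducible given
#' `mc$seed` (R's Mersenne-Twister stream).
#'
#' @param table a `site_energy_table`
#' @param pH pH value
#' @param mc an `mc_config`
#' @param record_trajectory also return the per-cycle microstate matrix
#' @return an `occupancy` object: per-site protonation fractions,
#'   per-state populations, acceptance rates, sample count, final
#'   microstate, seed
#' @export
run_mc <- function(table, pH, mc = mc_config(), record_trajectory = FALSE) {
  st <- table$states
  if (!all(is.finite(st$pkint)) || !all(is.finite(table$W)))
    stop("energy table contains non-finite values")
  sites <- unique(st$site)
  if (!length(sites)) stop("energy table has no sites")
  site_states <- lapply(sites, function(s) which(st$site == s) - 1L)
  tt <- state_terms(table, pH)
  pairs <- coupled_pairs(table, mc$pair_threshold) - 1L
  init <- vapply(sites, function(s) which(st$site == s & st$ref)[1],
                 integer(1)) - 1L
  set.seed(mc$seed)
  res <- mc_run_cpp(st$site - 1L, tt, table$W, site_states,
                    matrix(as.integer(pairs), nrow = 2),
                    init, mc$n_cycles, mc$burn_in_cycles,
                    record_trajectory)
  pop <- res$state_counts / res$n_samples
  per_site <- vapply(seq_along(sites), function(i) {
    ix <- site_states[[i]] + 1L
    sum(pop[ix][st$x[ix] == 1L])
  }, numeric(1))
  if (!is.na(res$acceptance_single) && res$acceptance_single == 0)
    warning("no single-site move was accepted")
  out <- structure(list(
    per_site_protonation = stats::setNames(per_site, sites),
    per_state_population = stats::setNames(pop, rownames(table$W)),
    states = st,
    acceptance = c(single = res$acceptance_single,
                   pair = res$acceptance_pair),
    n_samples = res$n_samples,
    n_pairs = ncol(pairs),
    final_assignment = res$final_assignment + 1L,
    pH = pH, seed = mc$seed, method = "mc"),
    class = "occupancy")
  if (record_trajectory) out$trajectory <- res$trajectory + 1L
  out
}

#' @export
print.occupancy <- function(x, ...) {
  cat("Protonation occupancies at pH", x$pH, "(", x$method, ",",
      x$n_samples, "samples )\n")
  print(round(x$per_site_protonation, 4))
  invisible(x)
}

#' Exact Boltzmann enumeration of protonation microstates
#'
#' Enumerates all microstates (product of per-site state counts must not
#' exceed 1e6) and returns exact averages; used as the correctness
#' oracle for [run_mc()] on small systems.
#'
#' @inheritParams run_mc
#' @return an `occupancy` object
#' @export
enumerate_exact <- function(table, pH) {
  st <- table$states
  sites <- unique(st$site)
  site_states <- lapply(sites, function(s) which(st$site == s))
  sizes <- lengths(site_states)
  if (prod(sizes) > 1e6)
    stop("state space too large to enumerate (", prod(sizes),
         " microstates); use run_mc()")
  grid <- as.matrix(expand.grid(site_states, KEEP.OUT.ATTRS = FALSE))
  tt <- state_terms(table, pH)
  E <- rowSums(matrix(tt[grid], nrow(grid)))
  ns <- length(sites)
  if (ns > 1) {
    for (i in seq_len(ns - 1)) for (j in (i + 1):ns)
      E <- E + table$W[cbind(grid[, i], grid[, j])]
  }
  w <- exp(-LN10 * (E - min(E)))
  w <- w / sum(w)
  pop <- numeric(nrow(st))
  for (i in seq_len(ns))
    pop <- pop + vapply(seq_len(nrow(st)), function(s)
      sum(w[grid[, i] == s]), numeric(1))
  per_site <- vapply(seq_len(ns), function(i) {
    ix <- site_states[[i]]
    sum(pop[ix][st$x[ix] == 1L])
  }, numeric(1))
  structure(list(
    per_site_protonation = stats::setNames(per_site, sites),
    per_state_population = stats::setNames(pop, rownames(table$W)),
    states = st, acceptance = c(single = NA_real_, pair = NA_real_),
    n_samples = nrow(grid), n_pairs = NA_integer_,
    final_assignment = NULL, pH = pH, seed = NA_integer_,
    method = "enumeration", lnZ = log(sum(exp(-LN10 * (E - min(E))))) -
      LN10 * min(E) / 1),
    class = "occupancy")
}

#' Draw one protonation microstate
#'
#' Returns the final microstate of a Metropolis run (not an average),
#' as used by the stochastic-titration cycle to reassign protonation
#' states between conformational-sampling segments.
#'
#' @inheritParams run_mc
#' @return list with `assignment` (global state indices, one per site),
#'   `labels` (named site -> state label) and `energy` (pK units)
#' @export
sample_assignment <- function(table, pH, mc = mc_config()) {
  occ <- run_mc(table, pH, mc)
  idx <- occ$final_assignment
  st <- table$states
  list(assignment = idx,
       labels = stats::setNames(st$state[idx], st$site[idx]),
       energy = microstate_energy(idx, pH, table))
}
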