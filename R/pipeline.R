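#' Conformational-sampling providers
#'
#' The molecular-dynamics segment of the stochastic-titration cycle is
#' represented by a pluggable provider: an object with an
#' `advance(structure, assignment, n_steps, seed)` method returning a
#' new structure (atom count and identity preserved), an optional
#' `relax(structure, n_steps)` hook standing in for the short
#' solvent-relaxation step, and a `conformation_id()` method.  Three
#' desk-scale providers are included: `provider_static()` (rigid
#' structure), `provider_ensemble()` (cycles the models of a
#' conformational ensemble) and `provider_jitter()` (Gaussian coordinate
#' noise).
#'
#' @name providers
NULL

#' @rdname providers
#' @export
provider_static <- function() {
  structure(list(
    advance = function(structure, assignment, n_steps, seed) structure,
    relax = NULL,
    conformation_id = function() 1L,
    static = TRUE, cacheable = TRUE), class = "conformation_provider")
}

#' @rdname providers
#' @param structures list of structures (e.g. models of a multi-model
#'   PDB) cycled in order
#' @export
provider_ensemble <- function(structures) {
  stopifnot(length(structures) >= 1)
  env <- new.env()
  env$i <- 1L
  structure(list(
    advance = function(structure, assignment, n_steps, seed) {
      env$i <- env$i %% length(structures) + 1L
      nxt <- structures[[env$i]]
      if (nrow(nxt) != nrow(structure))
        stop("ensemble models differ in atom count")
      nxt$charge <- structure$charge   # protonation travels with the cycle
      nxt
    },
    relax = NULL,
    conformation_id = function() env$i,
    static = FALSE, cacheable = TRUE), class = "conformation_provider")
}

#' @rdname providers
#' @param sd coordinate noise, nm per step batch
#' @export
provider_jitter <- function(sd = 0.01) {
  env <- new.env(); env$i <- 1L
  structure(list(
    advance = function(structure, assignment, n_steps, seed) {
      set.seed(seed)
      n <- nrow(structure)
      structure$x <- structure$x + stats::rnorm(n, 0, sd)
      structure$y <- structure$y + stats::rnorm(n, 0, sd)
      structure$z <- structure$z + stats::rnorm(n, 0, sd)
      env$i <- env$i + 1L
      structure
    },
    relax = NULL,
    conformation_id = function() env$i,
    static = FALSE, cacheable = FALSE), class = "conformation_provider")
}

#' Stochastic-titration cycle configuration
#'
#' @param ph pH of the run
#' @param n_cycles number of titration cycles
#' @param tau_steps conformational-sampler steps per cycle (the
#'   MD-segment length; 20 ps in the full method)
#' @param relax_steps steps for the relaxation hook (0.2 ps in the full
#'   method; a no-op unless the provider defines one)
#' @param replicates replicate count used by callers
#' @param seed base RNG seed
#' @return a `cycle_config`
#' @export
cycle_config <- function(ph, n_cycles = 10L, tau_steps = 1L,
                         relax_steps = 1L, replicates = 3L, seed = 1L) {
  stopifnot(tau_steps > 0, replicates >= 1, n_cycles >= 0)
  structure(list(ph = ph, n_cycles = as.integer(n_cycles),
                 tau_steps = as.integer(tau_steps),
                 relax_steps = as.integer(relax_steps),
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)), class = "cycle_config")
}

#' Run the stochastic-titration cycle
#'
#' Per cycle: (1) continuum-electrostatics energy table on the current
#' conformation, (2) Monte Carlo draw of a protonation microstate,
#' (3) application of the drawn state charges, (4) relaxation hook,
#' (5) provider advance for `tau_steps`.  Providers that revisit exact
#' conformations (static, ensemble) advertise `cacheable = TRUE` and
#' their energy tables are computed once per conformation and reused.
#'
#' @param structure starting structure
#' @param sites instantiated sites
#' @param provider a conformation provider (see [providers])
#' @param cfg a `cycle_config`
#' @param pb a `pb_config`
#' @param mc an `mc_config` (its seed is re-derived per cycle from
#'   `cfg$seed`)
#' @return list with `records` (data frame: cycle, conformation,
#'   per-site state labels, total charge) and the final `structure`
#' @export
run_cycle <- function(structure, sites, provider, cfg, pb = pb_config(),
                      mc = mc_config(n_cycles = 1000L)) {
  stopifnot(inherits(provider, "conformation_provider"))
  structure <- apply_reference_states(structure, sites)
  recs <- vector("list", cfg$n_cycles)
  cache <- list()
  for (cyc in seq_len(cfg$n_cycles)) {
    key <- as.character(provider$conformation_id())
    if (isTRUE(provider$cacheable) && !is.null(cache[[key]])) {
      table <- cache[[key]]
    } else {
      table <- compute_energy_table(structure, sites, pb)
      if (isTRUE(provider$cacheable)) cache[[key]] <- table
    }
    mc_c <- mc
    mc_c$seed <- cfg$seed + cyc
    draw <- sample_assignment(table, cfg$ph, mc_c)
    for (i in seq_along(sites))
      structure <- apply_state(structure, sites[[i]],
                               unname(draw$labels[i]))
    if (is.function(provider$relax))
      structure <- provider$relax(structure, cfg$relax_steps)
    structure <- provider$advance(structure, draw$labels, cfg$tau_steps,
                                  seed = cfg$seed + 100000L + cyc)
    recs[[cyc]] <- data.frame(
      cycle = cyc, conformation = provider$conformation_id(),
      t(draw$assignment), charge = total_charge(structure))
  }
  records <- if (cfg$n_cycles) do.call(rbind, recs) else
    data.frame(cycle = integer(0), conformation = integer(0),
               charge = numeric(0))
  if (cfg$n_cycles) {
    names(records)[3:(2 + length(sites))] <-
      paste0("state_", vapply(sites, `[[`, "", "label"))
  }
  list(records = records, structure = structure)
}

#' Per-cycle protonation fractions from cycle records
#'
#' @param records record data frame from [run_cycle()]
#' @param table the `site_energy_table` used (for state `x` values)
#' @return named vector of mean protonation fractions per site
#' @export
cycle_protonation <- function(records, table) {
  st <- table$states
  cols <- grep("^state_", names(records))
  out <- vapply(cols, function(cl)
    mean(st$x[records[[cl]]] == 1L), numeric(1))
  stats::setNames(out, sub("^state_", "", names(records)[cols]))
}

#' Estimate pH-dependent counterion numbers
#'
#' For each pH, the mean solute charge over the supplied series is
#' neutralized by the nearest integer number of monovalent counterions
#' of opposite sign; an exact half-integer mean is broken toward fewer
#' ions (minimal perturbation).
#'
#' @param charge_series named list, pH -> numeric vector of solute
#'   charges (replicate means or pooled samples), e
#' @param solvent_capacity maximum ion count per pH
#' @return an `ion_plan` data frame: `ph`, `mean_charge`, `n_cations`,
#'   `n_anions`, `restarted`
#' @export
estimate_counterions <- function(charge_series, solvent_capacity = Inf) {
  ph <- as.numeric(names(charge_series))
  if (any(is.na(ph))) stop("charge_series must be named by pH")
  mean_q <- vapply(charge_series, mean, numeric(1))
  n <- vapply(abs(mean_q), .nearest_int_fewer, numeric(1))
  if (any(n > solvent_capacity))
    stop("counterion count exceeds solvent capacity")
  plan <- data.frame(ph = ph, mean_charge = unname(mean_q),
                     n_cations = as.integer(ifelse(mean_q < 0, n, 0)),
                     n_anions = as.integer(ifelse(mean_q > 0, n, 0)),
                     restarted = FALSE)
  class(plan) <- c("ion_plan", "data.frame")
  plan
}

## nearest integer; exact .5 rounds down (fewer ions)
.nearest_int_fewer <- function(x, tol = 1e-9) {
  fl <- floor(x)
  frac <- x - fl
  if (frac > 0.5 + tol) fl + 1 else fl + (frac > 0.5 - tol) * 0
}

#' Flag and correct counterion estimates after longer sampling
#'
#' A pH point is restarted when the running mean solute charge differs
#' from the original estimate by more than 1 absolute protonic unit
#' (strict inequality); its ion count is then recomputed from the
#' running mean.
#'
#' @param plan an `ion_plan`
#' @param running_means named numeric vector, pH -> running mean solute
#'   charge, e
#' @return updated `ion_plan`
#' @export
check_restart <- function(plan, running_means) {
  for (nm in names(running_means)) {
    i <- match(as.numeric(nm), plan$ph)
    if (is.na(i)) stop("pH ", nm, " not covered by the ion plan")
    dev <- abs(running_means[[nm]] - plan$mean_charge[i])
    if (dev > 1 + 1e-9) {   # strictly more than one protonic unit
      q <- running_means[[nm]]
      n <- .nearest_int_fewer(abs(q))
      plan$mean_charge[i] <- q
      plan$n_cations[i] <- as.integer(if (q < 0) n else 0)
      plan$n_anions[i] <- as.integer(if (q > 0) n else 0)
      plan$restarted[i] <- TRUE
    }
  }
  plan
}
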