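#' Derive an atomic radius from Lennard-Jones parameters
#'
#' The continuum-electrostatics radius of an atom is taken from its 12-6
#' Lennard-Jones interaction with a water-oxygen probe: the contact
#' distance `r*` on the repulsive branch where the pair energy equals
#' +2 RT.  Because a pair potential yields a contact *distance*, not a
#' radius, the probe's own contact radius (half its self-contact
#' distance) can be subtracted so that radii remain pairwise additive;
#' this is the default and can be disabled with `subtract_probe = FALSE`.
#'
#' @param lj_sigma atom LJ sigma, nm
#' @param lj_epsilon atom LJ epsilon, kJ/mol (must be > 0)
#' @param probe_sigma probe (water oxygen) LJ sigma, nm
#' @param probe_epsilon probe LJ epsilon, kJ/mol
#' @param temperature temperature in K (default 310)
#' @param combine_rule `"lorentz_berthelot"` (arithmetic sigma, geometric
#'   epsilon) or `"geometric"` (geometric both)
#' @param subtract_probe subtract the probe contact radius (default TRUE)
#' @return radius in nm
#' @export
derive_atomic_radius <- function(lj_sigma, lj_epsilon,
                                 probe_sigma = 0.3166,
                                 probe_epsilon = 0.6502,
                                 temperature = 310,
                                 combine_rule = c("lorentz_berthelot",
                                                  "geometric"),
                                 subtract_probe = TRUE) {
  combine_rule <- match.arg(combine_rule)
  for (v in c(lj_sigma, lj_epsilon, probe_sigma, probe_epsilon, temperature))
    if (!is.finite(v)) stop("non-finite LJ/temperature parameter")
  if (temperature <= 0) stop("temperature must be positive")
  if (lj_epsilon <= 0 || probe_epsilon <= 0)
    stop("no repulsive-wall solution: LJ epsilon must be positive")
  if (lj_sigma <= 0 || probe_sigma <= 0) stop("LJ sigma must be positive")

  rstar <- .lj_contact(lj_sigma, lj_epsilon, probe_sigma, probe_epsilon,
                       temperature, combine_rule)
  if (!subtract_probe) return(rstar)
  rprobe <- .lj_contact(probe_sigma, probe_epsilon, probe_sigma,
                        probe_epsilon, temperature, combine_rule) / 2
  rstar - rprobe
}

## contact distance where the combined 12-6 potential crosses +2RT on the
## repulsive branch (r below the potential minimum at sigma * 2^(1/6))
.lj_contact <- function(s1, e1, s2, e2, temperature, combine_rule) {
  sc <- if (combine_rule == "lorentz_berthelot") (s1 + s2) / 2
        else sqrt(s1 * s2)
  ec <- sqrt(e1 * e2)
  target <- 2 * .R_KJ * temperature
  f <- function(r) {
    sr6 <- (sc / r)^6
    4 * ec * (sr6 * sr6 - sr6) - target
  }
  rmin <- sc * 2^(1 / 6)          # location of the potential minimum
  lo <- sc * 1e-3
  stats::uniroot(f, lower = lo, upper = rmin, tol = 1e-12)$root
}

#' Assign continuum radii to a structure from LJ parameters
#'
#' Atoms with `lj_epsilon = 0` (typically force-field hydrogens with no
#' LJ well) receive a fixed small radius instead of failing.
#'
#' @param structure structure data frame with `lj_sigma`/`lj_epsilon`
#' @param hydrogen_radius radius for epsilon-zero atoms, nm
#' @inheritParams derive_atomic_radius
#' @return structure with the `radius` column filled
#' @export
assign_radii <- function(structure, probe_sigma = 0.3166,
                         probe_epsilon = 0.6502, temperature = 310,
                         combine_rule = "lorentz_berthelot",
                         subtract_probe = TRUE, hydrogen_radius = 0.05) {
  if (is.null(structure$lj_sigma) || is.null(structure$lj_epsilon))
    stop("structure lacks lj_sigma/lj_epsilon columns")
  r <- vapply(seq_len(nrow(structure)), function(i) {
    eps <- structure$lj_epsilon[i]
    if (!is.na(eps) && eps == 0) return(hydrogen_radius)
    derive_atomic_radius(structure$lj_sigma[i], eps, probe_sigma,
                         probe_epsilon, temperature, combine_rule,
                         subtract_probe)
  }, numeric(1))
  structure$radius <- r
  atoms_df(structure)
}
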