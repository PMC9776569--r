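#' Synthetic test fixtures with known-truth metadata
#'
#' Deterministic generators for the small systems used throughout the
#' package's tests and examples:
#'
#' * `born_sphere`: a single ion (params `q`, charge in e, and `a`,
#'   radius in nm); metadata carries the analytic Born solvation energy
#'   for the configured dielectrics.
#' * `two_site_rod`: two single-bead titratable sites `separation` nm
#'   apart; metadata carries the analytic Coulomb interaction in pK
#'   units at `eps` and `temperature`.
#' * `penta_bead`: the bead pentapeptide of
#'   [make_pentapeptide_fixture()] (params `residue_type`, `capped`).
#' * `nsite_random`: a random `n`-site energy table (params `n`,
#'   optional `w_scale`, `w_prob`); metadata carries the generating
#'   table so samplers can be compared against exact enumeration.
#'
#' @param kind fixture kind
#' @param params list of kind-specific parameters
#' @param seed RNG seed (fixtures are deterministic given the seed)
#' @return list with fixture components plus a `truth` entry
#' @export
generate_fixtures <- function(kind = c("born_sphere", "two_site_rod",
                                       "penta_bead", "nsite_random"),
                              params = list(), seed = 1L) {
  kind <- match.arg(kind)
  p <- params
  switch(kind,
    born_sphere = {
      q <- p$q %||% 1
      a <- p$a %||% 0.2
      eps_in <- p$eps_in %||% 2
      eps_out <- p$eps_out %||% 80
      temperature <- p$temperature %||% 310
      if (a <= 0) stop("born_sphere: radius must be positive")
      str <- atoms_df(data.frame(name = "ION", resname = "ION", resid = 1,
                                 x = 0, y = 0, z = 0, charge = q,
                                 radius = a))
      dG <- -coulomb_kT_nm(temperature) * q^2 / (2 * a) *
        (1 / eps_in - 1 / eps_out)
      list(structure = str,
           truth = list(solvation_energy_kT = dG,
                        solvation_energy_kcal = dG * kT_kcal(temperature)))
    },
    two_site_rod = {
      sep <- p$separation %||% 1.0
      eps <- p$eps %||% 80
      temperature <- p$temperature %||% 310
      if (sep <= 0) stop("two_site_rod: separation must be positive")
      lib <- toy_site_library()
      str <- atoms_df(data.frame(
        name = "SC", resname = "LYS", resid = 1:2,
        x = c(0, sep), y = 0, z = 0, charge = 0, radius = 0.15))
      sites <- instantiate_sites(str, lib, selection = 1:2)
      W <- coulomb_kT_nm(temperature) / (eps * sep) / LN10
      list(structure = str, sites = sites,
           truth = list(W_pK = W))
    },
    penta_bead = {
      fx <- make_pentapeptide_fixture(p$residue_type %||% "GLU",
                                      capped = p$capped %||% TRUE)
      c(fx, list(truth = list()))
    },
    nsite_random = {
      n <- p$n %||% 8L
      if (n < 1) stop("nsite_random: n must be >= 1")
      w_scale <- p$w_scale %||% 1.5
      w_prob <- p$w_prob %||% 0.5
      set.seed(seed)
      pkint <- stats::runif(n, 2, 12)
      W <- matrix(0, n, n)
      if (n > 1) {
        up <- upper.tri(W)
        vals <- ifelse(stats::runif(sum(up)) < w_prob,
                       stats::rnorm(sum(up), 0, w_scale), 0)
        W[up] <- vals
        W <- W + t(W)
      }
      table <- energy_table_from_values(pkint, W)
      list(table = table, truth = list(pkint = pkint, W = W))
    })
}
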