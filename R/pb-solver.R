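#' Solve the linear Poisson-Boltzmann equation on a grid
#'
#' Red-black successive over-relaxation of the 7-point finite-difference
#' stencil for `div(eps grad u) - eps_out kappa^2 lambda u = -4 pi C rho`
#' with Dirichlet boundary values.  Iteration stops when the largest
#' node update falls below `config$convergence_tol` (kT/e).
#'
#' @param maps output of [build_maps()]
#' @param config a `pb_config`
#' @param boundary full-grid array whose boundary faces supply the
#'   Dirichlet values (its interior is used as the initial guess), or
#'   `NULL` for the analytic screened-Coulomb boundary of the map's own
#'   charges (requires `structure`)
#' @param structure structure used for the analytic boundary when
#'   `boundary` is `NULL`
#' @return a `potential_grid`: list with `values` (kT/e), `spec`,
#'   `residual`, `iterations`
#' @export
solve_lpbe <- function(maps, config, boundary = NULL, structure = NULL) {
  spec <- maps$spec
  n <- spec$nodes
  if (is.null(boundary)) {
    if (config$boundary == "zero" || is.null(structure)) {
      boundary <- array(0, c(n, n, n))
    } else {
      boundary <- debye_grid(structure, spec, config)
    }
  }
  C <- coulomb_kT_nm(config$temperature)
  kap2 <- debye_kappa2(config$ionic_strength, config$eps_out,
                       config$temperature)
  src <- 4 * pi * C * maps$q / spec$spacing
  screen <- config$eps_out * kap2 * spec$spacing^2
  omega <- config$omega
  if (is.null(omega)) omega <- 2 / (1 + sin(pi / n))
  res <- sor_solve_cpp(as.numeric(maps$epsx), as.numeric(maps$epsy),
                       as.numeric(maps$epsz), as.numeric(maps$lambda),
                       as.numeric(src), as.numeric(boundary), n, screen,
                       config$convergence_tol, config$max_iter, omega)
  if (!res$converged)
    stop("PB solver did not converge in ", config$max_iter,
         " iterations (residual ", format(res$residual), " kT/e)")
  structure(list(values = array(res$u, c(n, n, n)), spec = spec,
                 residual = res$residual, iterations = res$iterations),
            class = "potential_grid")
}

#' Two-step focusing solve around a point of interest
#'
#' Solves on a coarse grid covering the whole solute (analytic
#' screened-Coulomb boundary), then on a fine grid centered on `center`
#' whose boundary values are interpolated from the coarse solution.
#' Both grids have `config$nodes` nodes per side.  The coarse spacing is
#' inflated (with a warning) when the default box does not cover the
#' solute; the fine spacing is kept as configured.
#'
#' @param structure structure carrying the dielectric geometry
#' @param center fine-grid center, nm (the titratable group)
#' @param config a `pb_config`
#' @param charge_atoms atom ids whose charges are placed in this solve
#'   (default: all charged atoms); the dielectric always comes from the
#'   full structure
#' @return list with `fine` and `coarse` `potential_grid`s
#' @export
focus_solve <- function(structure, center, config, charge_atoms = NULL) {
  charged <- structure
  if (!is.null(charge_atoms))
    charged$charge[!charged$atom_id %in% charge_atoms] <- 0

  ## coarse grid: centered on the heavy-atom centroid, covering solute
  n <- config$nodes
  cen <- c(mean(structure$x), mean(structure$y), mean(structure$z))
  rad <- ifelse(is.na(structure$radius), 0, structure$radius)
  ext <- max(sqrt((structure$x - cen[1])^2 + (structure$y - cen[2])^2 +
                  (structure$z - cen[3])^2) + rad)
  coarse_h <- config$coarse_spacing
  need <- 2 * (ext + 1)                   # solute extent + 1 nm margin each side
  if (need > (n - 1) * coarse_h) {
    coarse_h <- need / (n - 1)
    warning("coarse grid spacing inflated to ", signif(coarse_h, 3),
            " nm to cover the solute")
  }
  cspec <- grid_spec(n, coarse_h, cen)
  cmaps <- build_maps(charged, cspec, config, require_coverage = TRUE)
  coarse <- solve_lpbe(cmaps, config, boundary = NULL, structure = charged)

  ## fine grid centered on the site
  fspec <- grid_spec(n, config$fine_spacing, center)
  if (any(abs(fspec$center - cspec$center) + grid_half_extent(fspec) >
          grid_half_extent(cspec) + 1e-12))
    stop("fine grid extends beyond the coarse grid")
  fb <- array(0, c(n, n, n))
  bidx <- boundary_indices(n)
  ax <- grid_axis(fspec, 1); ay <- grid_axis(fspec, 2); az <- grid_axis(fspec, 3)
  pts <- cbind(ax[bidx[, 1]], ay[bidx[, 2]], az[bidx[, 3]])
  fb[bidx] <- potential_at(coarse, pts)
  ## initialise the interior from the coarse solution as well
  allpts <- as.matrix(expand.grid(x = ax, y = ay, z = az))
  init <- array(potential_at(coarse, allpts), c(n, n, n))
  init[bidx] <- fb[bidx]
  fmaps <- build_maps(charged, fspec, config, require_coverage = FALSE)
  fine <- solve_lpbe(fmaps, config, boundary = init)
  list(fine = fine, coarse = coarse)
}

## index matrix of all boundary nodes of an n^3 grid
boundary_indices <- function(n) {
  idx <- as.matrix(expand.grid(i = seq_len(n), j = seq_len(n),
                               k = seq_len(n)))
  on <- idx == 1L | idx == n
  idx[on[, 1] | on[, 2] | on[, 3], , drop = FALSE]
}
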