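#' Grid specification for the finite-difference PB solver
#'
#' @param nodes nodes per side (odd, >= 9; default 81)
#' @param spacing grid spacing, nm
#' @param center grid center, nm (3-vector)
#' @return a `grid_spec` object
#' @export
grid_spec <- function(nodes = 81L, spacing, center = c(0, 0, 0)) {
  nodes <- as.integer(nodes)
  if (nodes < 9L || nodes %% 2L == 0L)
    stop("nodes per side must be an odd integer >= 9")
  if (!is.numeric(spacing) || spacing <= 0) stop("spacing must be positive")
  stopifnot(length(center) == 3, all(is.finite(center)))
  structure(list(nodes = nodes, spacing = spacing, center = as.numeric(center)),
            class = "grid_spec")
}

## node coordinates along one axis
grid_axis <- function(spec, dim) {
  n <- spec$nodes
  spec$center[dim] + (seq_len(n) - (n + 1) / 2) * spec$spacing
}

## half box edge (center to boundary), nm
grid_half_extent <- function(spec) (spec$nodes - 1) / 2 * spec$spacing

#' Solver configuration for the linear PB equation
#'
#' Defaults follow common continuum-electrostatics practice for
#' protonation-state calculations: solute dielectric 2, solvent 80,
#' two-step focusing from 0.1 nm to 0.025 nm spacing on 81-node grids,
#' convergence threshold 0.01 kT/e.
#'
#' @param eps_in solute dielectric constant
#' @param eps_out solvent dielectric constant
#' @param ionic_strength mol/L (1:1 electrolyte)
#' @param temperature K
#' @param convergence_tol largest node update at convergence, kT/e
#' @param coarse_spacing,fine_spacing focusing grid spacings, nm
#' @param nodes nodes per side for both focusing grids
#' @param boundary `"coulombic_debye"` (screened analytic boundary) or
#'   `"zero"`
#' @param probe_radius dielectric-boundary inflation, nm (0 = van der
#'   Waals union of spheres)
#' @param max_iter SOR iteration cap
#' @param omega SOR relaxation factor; `NULL` uses the optimal-omega
#'   estimate for the 7-point Laplacian
#' @return a `pb_config` object
#' @export
pb_config <- function(eps_in = 2, eps_out = 80, ionic_strength = 0.1,
                      temperature = 310, convergence_tol = 0.01,
                      coarse_spacing = 0.1, fine_spacing = 0.025,
                      nodes = 81L, boundary = c("coulombic_debye", "zero"),
                      probe_radius = 0, max_iter = 20000L, omega = NULL) {
  boundary <- match.arg(boundary)
  if (!(eps_out >= eps_in && eps_in >= 1))
    stop("dielectric constants must satisfy eps_out >= eps_in >= 1")
  if (convergence_tol <= 0) stop("convergence_tol must be positive")
  if (ionic_strength < 0) stop("ionic_strength must be non-negative")
  structure(list(eps_in = eps_in, eps_out = eps_out,
                 ionic_strength = ionic_strength, temperature = temperature,
                 convergence_tol = convergence_tol,
                 coarse_spacing = coarse_spacing,
                 fine_spacing = fine_spacing, nodes = as.integer(nodes),
                 boundary = boundary, probe_radius = probe_radius,
                 max_iter = as.integer(max_iter), omega = omega),
            class = "pb_config")
}

#' Build dielectric, ion-accessibility and charge maps on a grid
#'
#' The dielectric is sampled on grid edges: an edge's value is the
#' harmonic mean of solute and solvent dielectric weighted by the
#' fraction of the edge inside the (optionally probe-inflated) union of
#' atom spheres, which gives sub-grid placement of the dielectric
#' boundary.  Ion accessibility is zero at nodes inside the solute.
#' Charges are spread to the eight surrounding nodes by trilinear
#' weights, which conserves total charge exactly.
#'
#' @param structure structure data frame (all charged atoms need radii)
#' @param spec a `grid_spec`
#' @param config a `pb_config`
#' @param require_coverage error when a charged atom lies outside the
#'   grid (the coarse-step contract); when `FALSE` such charges are
#'   skipped (focusing fine-step contract)
#' @return list with `epsx`, `epsy`, `epsz` (edge dielectric arrays),
#'   `lambda` (node ion accessibility), `q` (node charges, e), `spec`
#' @export
build_maps <- function(structure, spec, config, require_coverage = TRUE) {
  n <- spec$nodes
  h <- spec$spacing
  ax <- grid_axis(spec, 1); ay <- grid_axis(spec, 2); az <- grid_axis(spec, 3)

  fx <- array(0, c(n - 1, n, n))   # inside-fraction of x edges
  fy <- array(0, c(n, n - 1, n))
  fz <- array(0, c(n, n, n - 1))
  lambda <- array(1, c(n, n, n))
  q <- array(0, c(n, n, n))

  atoms <- structure[!is.na(structure$radius) & structure$radius > 0, ,
                     drop = FALSE]
  for (i in seq_len(nrow(atoms))) {
    R <- atoms$radius[i] + config$probe_radius
    c3 <- c(atoms$x[i], atoms$y[i], atoms$z[i])
    fx <- .edge_fraction(fx, 1, c3, R, ax, ay, az, h)
    fy <- .edge_fraction(fy, 2, c3, R, ax, ay, az, h)
    fz <- .edge_fraction(fz, 3, c3, R, ax, ay, az, h)
    lambda <- .mark_interior(lambda, c3, R, ax, ay, az)
  }
  epsx <- 1 / (fx / config$eps_in + (1 - fx) / config$eps_out)
  epsy <- 1 / (fy / config$eps_in + (1 - fy) / config$eps_out)
  epsz <- 1 / (fz / config$eps_in + (1 - fz) / config$eps_out)

  charged <- structure[structure$charge != 0, , drop = FALSE]
  half <- grid_half_extent(spec)
  for (i in seq_len(nrow(charged))) {
    p <- c(charged$x[i], charged$y[i], charged$z[i]) - spec$center
    if (any(abs(p) >= half)) {
      if (require_coverage)
        stop("charged atom ", charged$name[i], " (id ", charged$atom_id[i],
             ") lies outside the grid")
      next
    }
    g <- (p + half) / h + 1          # fractional node index, 1-based
    i0 <- pmin(pmax(floor(g), 1), n - 1)
    w <- g - i0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      wt <- (if (dx) w[1] else 1 - w[1]) *
            (if (dy) w[2] else 1 - w[2]) *
            (if (dz) w[3] else 1 - w[3])
      q[i0[1] + dx, i0[2] + dy, i0[3] + dz] <-
        q[i0[1] + dx, i0[2] + dy, i0[3] + dz] + wt * charged$charge[i]
    }
  }
  list(epsx = epsx, epsy = epsy, epsz = epsz, lambda = lambda, q = q,
       spec = spec)
}

## update the inside-fraction array for edges along dimension `dim`
## with the fraction of each edge inside the sphere (center c3, radius R);
## unions of spheres are combined by taking the maximum fraction.
.edge_fraction <- function(f, dim, c3, R, ax, ay, az, h) {
  axes <- list(ax, ay, az)
  starts <- axes
  starts[[dim]] <- axes[[dim]][-length(axes[[dim]])]
  # candidate index ranges near the sphere
  rng <- lapply(1:3, function(d) {
    v <- starts[[d]]
    pad <- if (d == dim) h else 0
    which(v >= c3[d] - R - pad & v <= c3[d] + R)
  })
  if (!all(lengths(rng))) return(f)
  idx <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
  p0 <- cbind(starts[[1]][idx[, 1]], starts[[2]][idx[, 2]],
              starts[[3]][idx[, 3]])
  d0 <- sweep(p0, 2, c3)
  # segment p(t) = p0 + t*h*e_dim, t in [0,1]; solve |p - c|^2 = R^2
  b <- d0[, dim] * h
  cc <- rowSums(d0^2) - R^2
  a <- h^2
  disc <- b^2 - a * cc
  hit <- disc > 0
  if (!any(hit)) return(f)
  sq <- sqrt(disc[hit])
  t1 <- pmin(pmax((-b[hit] - sq) / a, 0), 1)
  t2 <- pmin(pmax((-b[hit] + sq) / a, 0), 1)
  frac <- t2 - t1
  sel <- idx[hit, , drop = FALSE]
  cur <- f[sel]
  f[sel] <- pmax(cur, frac)
  f
}

## set lambda = 0 at nodes whose centers fall inside the sphere
.mark_interior <- function(lambda, c3, R, ax, ay, az) {
  ix <- which(abs(ax - c3[1]) <= R)
  iy <- which(abs(ay - c3[2]) <= R)
  iz <- which(abs(az - c3[3]) <= R)
  if (!length(ix) || !length(iy) || !length(iz)) return(lambda)
  idx <- as.matrix(expand.grid(ix, iy, iz))
  d2 <- (ax[idx[, 1]] - c3[1])^2 + (ay[idx[, 2]] - c3[2])^2 +
        (az[idx[, 3]] - c3[3])^2
  inside <- idx[d2 <= R^2, , drop = FALSE]
  if (nrow(inside)) lambda[inside] <- 0
  lambda
}

## analytic Debye-screened Coulomb potential of the structure's charges,
## evaluated at arbitrary points (rows of `pts`), kT/e
debye_potential <- function(structure, pts, config) {
  C <- coulomb_kT_nm(config$temperature)
  kap <- sqrt(debye_kappa2(config$ionic_strength, config$eps_out,
                           config$temperature))
  charged <- structure[structure$charge != 0, , drop = FALSE]
  u <- numeric(nrow(pts))
  for (i in seq_len(nrow(charged))) {
    r <- sqrt((pts[, 1] - charged$x[i])^2 + (pts[, 2] - charged$y[i])^2 +
              (pts[, 3] - charged$z[i])^2)
    r <- pmax(r, 1e-6)
    u <- u + C * charged$charge[i] * exp(-kap * r) / (config$eps_out * r)
  }
  u
}

## full-grid analytic potential array (used as boundary + initial guess)
debye_grid <- function(structure, spec, config) {
  ax <- grid_axis(spec, 1); ay <- grid_axis(spec, 2); az <- grid_axis(spec, 3)
  pts <- as.matrix(expand.grid(x = ax, y = ay, z = az))
  array(debye_potential(structure, pts, config),
        c(spec$nodes, spec$nodes, spec$nodes))
}

#' Trilinear interpolation of a potential grid at arbitrary points
#'
#' @param grid a `potential_grid` (from [solve_lpbe()] or [focus_solve()])
#' @param pts numeric matrix of points (rows), nm
#' @return numeric vector of potentials, kT/e
#' @export
potential_at <- function(grid, pts) {
  spec <- grid$spec
  n <- spec$nodes; h <- spec$spacing
  half <- grid_half_extent(spec)
  p <- sweep(as.matrix(pts), 2, spec$center)
  if (any(abs(p) > half + 1e-12))
    stop("point(s) outside the potential grid")
  g <- p / h + (n + 1) / 2
  i0 <- pmin(pmax(floor(g), 1), n - 1)
  w <- g - i0
  u <- grid$values
  out <- numeric(nrow(p))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wt <- (if (dx) w[, 1] else 1 - w[, 1]) *
          (if (dy) w[, 2] else 1 - w[, 2]) *
          (if (dz) w[, 3] else 1 - w[, 3])
    out <- out + wt * u[cbind(i0[, 1] + dx, i0[, 2] + dy, i0[, 3] + dz)]
  }
  out
}
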