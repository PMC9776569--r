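test_that("charge assignment conserves total charge to 1e-12 e", {
  set.seed(4)
  str <- atoms_df(data.frame(
    name = "X", resname = "X", resid = 1:7,
    x = runif(7, -0.4, 0.4), y = runif(7, -0.4, 0.4),
    z = runif(7, -0.4, 0.4),
    charge = round(runif(7, -1, 1), 3), radius = 0.15))
  maps <- build_maps(str, grid_spec(21L, 0.1), pb_config())
  expect_lt(abs(sum(maps$q) - sum(str$charge)), 1e-12)
})

test_that("dielectric maps mark a sphere interior consistent with its volume", {
  cfg <- pb_config()
  a <- 0.2; h <- 0.025
  str <- atoms_df(data.frame(name = "ION", resname = "ION", resid = 1,
                             x = 0, y = 0, z = 0, charge = 1, radius = a))
  maps <- build_maps(str, grid_spec(41L, h), cfg)
  inside <- sum(maps$lambda == 0)
  vol_nodes <- (4 / 3) * pi * a^3 / h^3
  shell_nodes <- 4 * pi * a^2 * h / h^3   # one-shell slack
  expect_lt(abs(inside - vol_nodes), shell_nodes)
  ## solute edges carry a reduced dielectric
  expect_lt(min(maps$epsx), cfg$eps_in * 1.01)
  expect_equal(max(maps$epsx), cfg$eps_out)
})

test_that("empty structures give uniform solvent maps and a zero solve", {
  cfg <- pb_config()
  empty <- atoms_df(data.frame(name = character(0), resname = character(0),
                               resid = integer(0), x = numeric(0),
                               y = numeric(0), z = numeric(0)))
  maps <- build_maps(empty, grid_spec(15L, 0.1), cfg)
  expect_true(all(maps$epsx == cfg$eps_out))
  expect_true(all(maps$q == 0))
  sol <- solve_lpbe(maps, cfg, boundary = array(0, c(15, 15, 15)))
  expect_true(all(sol$values == 0))
})

test_that("a charged atom outside the grid is rejected for the coarse step", {
  str <- atoms_df(data.frame(name = "X", resname = "X", resid = 1,
                             x = 5, y = 0, z = 0, charge = 1, radius = 0.2))
  expect_error(build_maps(str, grid_spec(15L, 0.1), pb_config()),
               "outside the grid")
})

test_that("point-charge potential matches Coulomb in a uniform dielectric", {
  cfg <- pb_config(eps_in = 80, eps_out = 80, ionic_strength = 0, nodes = 41L)
  str <- atoms_df(data.frame(name = "Q", resname = "Q", resid = 1,
                             x = 0, y = 0, z = 0, charge = 1,
                             radius = 0.1))
  spec <- grid_spec(41L, 0.1)
  maps <- build_maps(str, spec, cfg)
  sol <- solve_lpbe(maps, cfg, structure = str)
  C <- coulomb_kT_nm(cfg$temperature)
  ## on-axis lattice anisotropy dominates close in: ~4% at 3 spacings,
  ## decaying quadratically with distance
  r <- seq(3 * 0.1, 2.0, by = 0.1)
  phi <- potential_at(sol, cbind(r, 0, 0))
  expect_lt(max(abs(phi / (C / (80 * r)) - 1)), 0.04)
  far <- r >= 0.5
  expect_lt(max(abs(phi[far] / (C / (80 * r[far])) - 1)), 0.02)
})

test_that("the LPBE solve is linear in the source charges", {
  cfg <- pb_config(ionic_strength = 0.1, nodes = 21L,
                   convergence_tol = 1e-4)
  spec <- grid_spec(21L, 0.1)
  mk <- function(q1, q2) {
    str <- atoms_df(data.frame(name = c("A", "B"), resname = "Q",
                               resid = 1:2, x = c(-0.3, 0.3), y = 0, z = 0,
                               charge = c(q1, q2), radius = 0.15))
    solve_lpbe(build_maps(str, spec, cfg), cfg, structure = str)$values
  }
  u12 <- mk(1, -0.5)
  u1 <- mk(1, 0)
  u2 <- mk(0, -0.5)
  expect_lt(max(abs(u12 - (u1 + u2))), 0.01)
})

test_that("focusing reproduces the coarse analytic potential and is robust to coarse-grid shifts", {
  cfg <- pb_small(eps_in = 80)
  str <- atoms_df(data.frame(name = "Q", resname = "Q", resid = 1,
                             x = 0, y = 0, z = 0, charge = 1, radius = 0.1))
  sol <- focus_solve(str, c(0, 0, 0), cfg)
  C <- coulomb_kT_nm(cfg$temperature)
  r <- seq(0.25, 0.6, by = 0.05)
  phi <- potential_at(sol$fine, cbind(r, 0, 0))
  expect_lt(max(abs(phi / (C / (80 * r)) - 1)), 0.02)

  ## translating system and grids together leaves the potential unchanged
  str2 <- str; str2$x <- str2$x + 1.23; str2$y <- str2$y - 0.71
  sol2 <- focus_solve(str2, c(1.23, -0.71, 0), cfg)
  expect_lt(max(abs(sol2$fine$values - sol$fine$values)), 1e-6)

  ## half-spacing shift of the coarse grid barely moves the fine answer:
  ## add a distant uncharged atom to displace the coarse-grid centroid
  pad <- atoms_df(data.frame(name = "PAD", resname = "PAD", resid = 99,
                             x = 2 * 0.05, y = 0, z = 0, charge = 0,
                             radius = 1e-4))
  sol3 <- focus_solve(rbind(str, pad), c(0, 0, 0), cfg)
  probe_pts <- cbind(seq(0.2, 0.5, 0.05), 0, 0)
  expect_lt(max(abs(potential_at(sol3$fine, probe_pts) -
                    potential_at(sol$fine, probe_pts))),
            cfg$convergence_tol)
})

test_that("a fine grid reaching beyond the coarse grid is refused", {
  cfg <- pb_config(nodes = 15L, coarse_spacing = 0.1, fine_spacing = 0.09)
  str <- one_bead_structure()
  ## the tiny coarse box also triggers the spacing-inflation warning
  expect_error(suppressWarnings(focus_solve(str, c(0.6, 0, 0), cfg)),
               "beyond the coarse")
})

test_that("Born solvation error decreases monotonically under grid refinement", {
  fx <- generate_fixtures("born_sphere")
  truth <- fx$truth$solvation_energy_kT
  errs <- vapply(c(0.1, 0.05, 0.025), function(hf) {
    cfg <- pb_config(ionic_strength = 0, nodes = 41L, fine_spacing = hf)
    uni <- cfg; uni$eps_out <- cfg$eps_in
    dG <- 0.5 * (potential_at(focus_solve(fx$structure, c(0, 0, 0),
                                          cfg)$fine, matrix(0, 1, 3)) -
                 potential_at(focus_solve(fx$structure, c(0, 0, 0),
                                          uni)$fine, matrix(0, 1, 3)))
    abs(dG - truth)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})
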