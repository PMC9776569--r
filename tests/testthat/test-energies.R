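test_that("an isolated model compound has pkint equal to pkmod", {
  ## identity case: protein and model-compound contexts share geometry
  ## and grids, so the transfer free energy is exactly zero; this also
  ## anchors the sign convention of the pkint formula
  cfg <- pb_small(ionic_strength = 0.1)
  str <- one_bead_structure()
  sites <- instantiate_sites(str, toy_site_library(), 1)
  tab <- compute_energy_table(str, sites, cfg)
  expect_lt(max(abs(tab$states$pkint - tab$states$pkmod)), 1e-3)
  ## reference state keeps its pkmod by construction
  expect_equal(tab$states$pkint[tab$states$ref],
               tab$states$pkmod[tab$states$ref])
})

test_that("protein- and model-context terms coincide for a site alone in uniform dielectric", {
  cfg <- pb_small(eps_in = 80)
  str <- one_bead_structure()
  site <- instantiate_sites(str, toy_site_library(), 1)[[1]]
  pr <- charging_terms(str, site, "deprot", "protein", cfg)
  mo <- charging_terms(str, site, "deprot", "model_compound", cfg)
  expect_equal(pr$self_energy, mo$self_energy)
  expect_equal(pr$background_energy, 0)
  expect_equal(mo$background_energy, 0)
})

test_that("the background term of a two-charge rod matches the Coulomb energy", {
  cfg <- pb_small(eps_in = 80)
  sep <- 0.9
  str <- atoms_df(data.frame(name = "SC", resname = c("LYS", "X"),
                             resid = 1:2, x = c(0, sep), y = 0, z = 0,
                             charge = c(0, -0.7), radius = 0.15))
  site <- instantiate_sites(str, toy_site_library(), 1)[[1]]
  ct <- charging_terms(str, site, "prot", "protein", cfg)
  coulomb <- coulomb_kT_nm(cfg$temperature) * 1 * (-0.7) / (80 * sep)
  expect_lt(abs(ct$background_energy / coulomb - 1), 0.03)
})

test_that("self-energy is invariant under grid-aligned 90-degree rotations", {
  cfg <- pb_small()
  base <- atoms_df(data.frame(name = c("C1", "C2"), resname = "GL2",
                              resid = 1, x = c(0, 0.15), y = 0, z = 0,
                              charge = 0, radius = 0.18))
  rot <- base
  rot$y <- base$x; rot$x <- 0        # rotate the rod onto the y axis
  lib <- toy_site_library()
  s1 <- instantiate_sites(base, lib, 1)[[1]]
  s2 <- instantiate_sites(rot, lib, 1)[[1]]
  e1 <- charging_terms(base, s1, "deprot", "protein", cfg)$self_energy
  e2 <- charging_terms(rot, s2, "deprot", "protein", cfg)$self_energy
  expect_lt(abs(e1 - e2), 1e-6)
})

test_that("site-site interactions match Coulomb and the matrix is symmetric", {
  cfg <- pb_config(eps_in = 80, eps_out = 80, ionic_strength = 0,
                   nodes = 41L, fine_spacing = 0.05)
  fx <- generate_fixtures("two_site_rod", list(separation = 1.0))
  tab <- compute_energy_table(fx$structure, fx$sites, cfg)
  W <- tab$W["LYS-1:prot", "LYS-2:prot"]
  expect_lt(abs(W / fx$truth$W_pK - 1), 0.03)
  expect_identical(tab$W, t(tab$W))
  ## no coupling between states of one site, zero rows for references
  expect_equal(tab$W["LYS-1:prot", "LYS-1:deprot"], 0)
  expect_true(all(tab$W["LYS-1:deprot", ] == 0))
})

test_that("grid self-energy cancels between contexts when the grid is refined", {
  ## buried bead: pkint must be stable under a node-count doubling
  lib <- toy_site_library()
  shell <- expand.grid(x = c(-0.35, 0.35), y = c(-0.35, 0.35),
                       z = c(-0.35, 0.35))
  str <- atoms_df(data.frame(
    name = c("SC", rep("CB", 8)), resname = c("GLU", rep("ALA", 8)),
    resid = c(1, rep(2, 8)), x = c(0, shell$x), y = c(0, shell$y),
    z = c(0, shell$z), charge = 0, radius = 0.25))
  sites <- instantiate_sites(str, lib, 1)
  pk <- vapply(c(41L, 81L), function(nn) {
    cfg <- pb_config(ionic_strength = 0.1, nodes = nn)
    compute_energy_table(str, sites, cfg)$states$pkint[1]
  }, numeric(1))
  expect_lt(abs(diff(pk)), 0.05)
  ## burial raises the acid's pKa (desolvation of the charged form)
  expect_gt(pk[2], 4.25)
})

test_that("energy tables round-trip through TSV", {
  fx <- generate_fixtures("nsite_random", list(n = 5), seed = 3)
  prefix <- withr::local_tempfile()
  write_energy_table(fx$table, prefix)
  back <- read_energy_table(prefix)
  expect_equal(back$states$pkint, fx$table$states$pkint)
  expect_equal(unname(back$W), unname(fx$table$W))
})

test_that("malformed energy tables are rejected", {
  st <- data.frame(site = c(1, 1), site_label = "s", state = c("a", "b"),
                   x = c(1L, 0L), taut = 0L, pkmod = 4, pkint = 4,
                   ref = c(FALSE, TRUE))
  W <- matrix(c(0, 1, 2, 0), 2)    # asymmetric
  expect_error(site_energy_table(st, W), "symmetric")
  W2 <- matrix(c(0, 1, 1, 0), 2)   # same-site coupling
  expect_error(site_energy_table(st, W2), "one site")
})
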