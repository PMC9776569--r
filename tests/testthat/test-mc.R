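test_that("microstate energies reproduce an independent arithmetic oracle", {
  set.seed(9)
  pkint <- c(4.1, 6.9, 9.3)
  W3 <- matrix(0, 3, 3)
  W3[upper.tri(W3)] <- c(1.2, -0.4, 2.1)
  W3 <- W3 + t(W3)
  tab <- energy_table_from_values(pkint, W3)
  pH <- 6.2
  ## brute-force oracle over the 8 binary microstates
  for (x1 in 0:1) for (x2 in 0:1) for (x3 in 0:1) {
    x <- c(x1, x2, x3)
    E_oracle <- sum(x * (pH - pkint)) +
      x[1] * x[2] * W3[1, 2] + x[1] * x[3] * W3[1, 3] +
      x[2] * x[3] * W3[2, 3]
    idx <- ifelse(x == 1, seq(1, 6, 2), seq(2, 6, 2))
    expect_equal(microstate_energy(idx, pH, tab), E_oracle,
                 tolerance = 1e-12)
  }
  ## all-reference microstate is the zero of energy
  expect_equal(microstate_energy(c(2L, 4L, 6L), pH, tab), 0)
  ## protonated site at pH = pkint contributes nothing
  t1 <- energy_table_from_values(5.5)
  expect_equal(microstate_energy(1L, 5.5, t1), 0)
})

test_that("exact enumeration factorizes for independent sites and obeys the partition-function identity", {
  pkint <- c(3.7, 6.0, 8.8)
  tab <- energy_table_from_values(pkint)
  for (pH in c(3, 6, 9)) {
    occ <- enumerate_exact(tab, pH)
    hh <- 1 / (1 + 10^(pH - pkint))
    expect_equal(unname(occ$per_site_protonation), hh, tolerance = 1e-12)
  }
  ## coupled case: total protonation = -dlnZ/d(pH ln10) by numerical
  ## differentiation of the enumerated partition function
  W3 <- matrix(c(0, 2, 0, 2, 0, -1, 0, -1, 0), 3)
  tabc <- energy_table_from_values(pkint, W3)
  pH <- 5.5; dd <- 1e-5
  lnZp <- enumerate_exact(tabc, pH + dd)$lnZ
  lnZm <- enumerate_exact(tabc, pH - dd)$lnZ
  tot_deriv <- -(lnZp - lnZm) / (2 * dd * log(10))
  tot <- sum(enumerate_exact(tabc, pH)$per_site_protonation)
  expect_equal(tot, tot_deriv, tolerance = 1e-6)
  ## exchange symmetry of two identical strongly coupled sites
  tab2 <- energy_table_from_values(c(5, 5), matrix(c(0, 4, 4, 0), 2))
  occ2 <- enumerate_exact(tab2, 5.8)
  expect_equal(occ2$per_site_protonation[[1]],
               occ2$per_site_protonation[[2]], tolerance = 1e-12)
  ## oversized state spaces are refused
  big <- energy_table_from_values(seq_len(21))
  expect_error(enumerate_exact(big, 7), "too large")
})

test_that("Metropolis sampling reproduces closed forms and the enumeration oracle", {
  ## symmetric point: half-protonation at pH = pKa
  t1 <- energy_table_from_values(7)
  o <- run_mc(t1, 7, mc_config(n_cycles = 100000L, seed = 5))
  expect_lt(abs(o$per_site_protonation[[1]] - 0.5), 0.01)
  ## Henderson-Hasselbalch one unit above the pKa
  t2 <- energy_table_from_values(4)
  o2 <- run_mc(t2, 5, mc_config(n_cycles = 100000L, seed = 6))
  expect_lt(abs(o2$per_site_protonation[[1]] - 1 / (1 + 10)), 0.005)
  ## anticooperative 3-site system against exact enumeration
  W3 <- matrix(c(0, 3, 0, 3, 0, 0, 0, 0, 0), 3)
  t3 <- energy_table_from_values(c(5, 5.5, 6), W3)
  ex <- enumerate_exact(t3, 5.4)
  o3 <- run_mc(t3, 5.4, mc_config(n_cycles = 100000L, seed = 8,
                                  burn_in_cycles = 1000L))
  expect_lt(max(abs(o3$per_site_protonation - ex$per_site_protonation)),
            0.01)
  ## per-site state populations are a distribution
  byst <- split(o3$per_state_population, o3$states$site)
  expect_true(all(abs(vapply(byst, sum, numeric(1)) - 1) < 1e-9))
})

test_that("sampled microstates are seed-reproducible and follow titration limits", {
  fx <- generate_fixtures("nsite_random", list(n = 4), seed = 2)
  a <- sample_assignment(fx$table, 7, mc_config(n_cycles = 2000L, seed = 31))
  b <- sample_assignment(fx$table, 7, mc_config(n_cycles = 2000L, seed = 31))
  expect_identical(a$assignment, b$assignment)
  ## extreme-pH limits: all sites (de)protonated
  lo <- sample_assignment(fx$table, min(fx$truth$pkint) - 10,
                          mc_config(n_cycles = 2000L, seed = 1))
  expect_true(all(fx$table$states$x[lo$assignment] == 1L))
  ## at pH far above every pKa no protonation move is ever accepted,
  ## which run_mc reports as a warning
  hi <- suppressWarnings(
    sample_assignment(fx$table, max(fx$truth$pkint) + 10,
                      mc_config(n_cycles = 2000L, seed = 1)))
  expect_true(all(fx$table$states$x[hi$assignment] == 0L))
})

test_that("protonation decreases with pH for independent sites", {
  fx <- generate_fixtures("nsite_random", list(n = 6, w_prob = 0), seed = 5)
  ph <- seq(1, 13, 0.5)
  fr <- vapply(ph, function(p)
    enumerate_exact(fx$table, p)$per_site_protonation, numeric(6))
  expect_true(all(apply(fr, 1, function(v) all(diff(v) < 0))))
})

test_that("the sampled chain is consistent with Boltzmann balance", {
  tab <- energy_table_from_values(c(5, 6.5), matrix(c(0, 1.5, 1.5, 0), 2))
  o <- run_mc(tab, 6, mc_config(n_cycles = 100000L, seed = 42,
                                pair_threshold = 1),
              record_trajectory = TRUE)
  ## microstate frequencies match the exact distribution
  ex <- enumerate_exact(tab, 6)
  expect_lt(max(abs(o$per_site_protonation - ex$per_site_protonation)),
            0.01)
  ## net flux between each microstate pair vanishes within 3 SE
  code <- paste(o$trajectory[, 1], o$trajectory[, 2])
  tt <- table(factor(code[-length(code)]), factor(code[-1]))
  for (a in seq_len(nrow(tt) - 1)) for (b in (a + 1):ncol(tt)) {
    nab <- tt[a, b]; nba <- tt[b, a]
    if (nab + nba > 0)
      expect_lt(abs(nab - nba), 3 * sqrt(nab + nba) + 1)
  }
})

test_that("coupled-pair moves rescue sampling of strongly coupled sites", {
  ## frustrated pair: both protonation states rare individually but the
  ## doubly-protonated and doubly-deprotonated states equally likely
  tab <- energy_table_from_values(c(4, 4), matrix(c(0, -6, -6, 0), 2))
  ex <- enumerate_exact(tab, 7)$per_site_protonation
  err <- function(thr, seed) {
    o <- run_mc(tab, 7, mc_config(n_cycles = 10000L, seed = seed,
                                  pair_threshold = thr))
    max(abs(o$per_site_protonation - ex))
  }
  err_single <- vapply(1:3, function(s) err(1e9, s), numeric(1))
  err_pair <- vapply(1:3, function(s) err(2, s), numeric(1))
  expect_gt(mean(err_single), 5 * mean(err_pair))
  expect_lt(mean(err_pair), 0.02)
})
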