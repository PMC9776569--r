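test_that("replicate aggregation applies burn-in and sliding windows correctly", {
  ph <- c(3, 4, 5)
  n <- 50
  drift <- matrix(rep(seq(0, 1, length.out = n), 3), ncol = 3,
                  dimnames = list(NULL, ph))
  ## identical replicates: zero SEM everywhere
  cv <- aggregate_titration(list(drift, drift, drift))
  expect_equal(cv$sem, rep(0, 3))
  ## burn_in = 0 reduces to the full-series mean
  cv0 <- aggregate_titration(list(drift), burn_in_fraction = 0)
  expect_equal(cv0$mean_fraction, rep(mean(drift[, 1]), 3))
  ## 20% burn-in retains samples 11..50 of the linear ramp
  cv2 <- aggregate_titration(list(drift), burn_in_fraction = 0.2)
  expect_equal(cv2$mean_fraction,
               rep(mean(seq(0, 1, length.out = n)[11:50]), 3))
  ## sliding windows: one curve per window with the window mean
  wins <- aggregate_titration(list(drift), window = list(width = 10,
                                                         step = 20))
  expect_length(wins, 3)
  expect_equal(wins[[1]]$mean_fraction,
               rep(mean(seq(0, 1, length.out = n)[1:10]), 3))
  ## mismatched pH grids are refused
  other <- drift; colnames(other) <- c(3, 4, 6)
  expect_error(aggregate_titration(list(drift, other)), "pH grid")
})

test_that("noiseless Hill curves are recovered exactly", {
  ph <- 1:12
  f <- 1 / (1 + 10^(1.0 * (ph - 7)))
  ft <- fit_hill(f, ph)
  expect_true(ft$converged)
  expect_equal(unname(coef(ft)), c(7, 1), tolerance = 1e-6)
  expect_equal(predict(ft, ph), f, tolerance = 1e-6)
  ## permutation of the pH points does not change the fit
  perm <- sample(seq_along(ph))
  ft2 <- fit_hill(f[perm], ph[perm])
  expect_equal(coef(ft2), coef(ft), tolerance = 1e-9)
})

test_that("unfittable curves are flagged, not errored", {
  ph <- 1:12
  ## flat curve near 1: titration lies outside the pH range
  flat <- fit_hill(rep(0.99, 12), ph)
  expect_false(flat$converged)
  ## fewer than 3 interior points
  step <- fit_hill(c(1, 1, 1, 1, 1, 0.5, 0, 0, 0, 0, 0, 0), ph)
  expect_false(step$converged)
})

test_that("noisy synthetic Hill curves are recovered within 0.05 over 100 seeds", {
  ph <- seq(1, 12, 0.25)
  errs <- t(vapply(1:100, function(s) {
    set.seed(s)
    f <- 1 / (1 + 10^(0.9 * (ph - 7.2))) + rnorm(length(ph), 0, 0.01)
    ft <- fit_hill(f, ph)
    c(abs(ft$pka - 7.2), abs(ft$hill_n - 0.9))
  }, numeric(2)))
  expect_lt(max(errs[, 1]), 0.05)
  expect_lt(max(errs[, 2]), 0.05)
})

test_that("jackknife errors follow the leave-one-out formula", {
  ph <- seq(2, 12, 0.5)
  hill <- function(pka) 1 / (1 + 10^(ph - pka))
  ## identical replicates: zero error
  same <- titration_curve(ph, rbind(hill(7), hill(7), hill(7)))
  expect_equal(jackknife_pka(same)$pka_error, 0)
  ## hand-computed case: replicates chosen so the three leave-one-out
  ## fits give pKa {6.9, 7.0, 7.1} (noiseless curves -> exact fits)
  reps <- rbind(hill(7.0 + 0.15), hill(7.0), hill(7.0 - 0.15))
  jk <- jackknife_pka(titration_curve(ph, reps))
  loo_oracle <- vapply(1:3, function(k)
    fit_hill(colMeans(reps[-k, , drop = FALSE]), ph)$pka, numeric(1))
  expect_equal(sort(jk$loo_pka), sort(loo_oracle), tolerance = 1e-9)
  err_oracle <- sqrt(2 / 3 * sum((loo_oracle - mean(loo_oracle))^2))
  expect_equal(jk$pka_error, err_oracle, tolerance = 1e-9)
  ## one failing combination: error over the remaining two, flagged
  bad <- rbind(hill(7), hill(7.2), rep(0.999, length(ph)) )
  jk2 <- jackknife_pka(titration_curve(ph, pmin(bad, 1)))
  expect_equal(jk2$n_failed, 0)  # all three LOO means still fittable
  worse <- rbind(hill(7), rep(0.999, length(ph)), rep(0.999, length(ph)))
  jk3 <- jackknife_pka(titration_curve(ph, pmin(worse, 1)))
  expect_gt(jk3$n_failed, 0)
})

test_that("total charge curves and isoelectric points behave like the two-site closed form", {
  ph <- seq(1, 12, 0.05)
  acid <- titration_curve(ph, matrix(1 / (1 + 10^(ph - 4)), 1))
  base <- titration_curve(ph, matrix(1 / (1 + 10^(ph - 9)), 1))
  fc <- data.frame(site = c("A", "B"), z_prot = c(0, 1),
                   z_deprot = c(-1, 0))
  cc <- total_charge_curve(list(A = acid, B = base), fc)
  expect_lt(abs(isoelectric_point(cc) - 6.5), 0.01)
  ## translation equivariance: shifting both pKa values shifts the pI
  acid2 <- titration_curve(ph, matrix(1 / (1 + 10^(ph - 4.7)), 1))
  base2 <- titration_curve(ph, matrix(1 / (1 + 10^(ph - 9.7)), 1))
  cc2 <- total_charge_curve(list(A = acid2, B = base2), fc)
  expect_equal(isoelectric_point(cc2), isoelectric_point(cc) + 0.7,
               tolerance = 1e-6)
  ## one-signed curves have no pI; background shifts the curve
  cc3 <- total_charge_curve(list(B = base), fc["2", , drop = FALSE],
                            background = 2)
  expect_error(isoelectric_point(cc3), "pI undefined")
  expect_error(total_charge_curve(list(), fc), "no titratable sites")
})

test_that("charge curves agree with enumeration-derived charges for a coupled system", {
  pkint <- c(4.2, 6.1, 9.4)
  W3 <- matrix(c(0, 1.4, 0, 1.4, 0, -0.8, 0, -0.8, 0), 3)
  tab <- energy_table_from_values(pkint, W3)
  ph <- 1:12
  fr <- vapply(ph, function(p)
    enumerate_exact(tab, p)$per_site_protonation, numeric(3))
  curves <- lapply(1:3, function(i)
    titration_curve(ph, matrix(fr[i, ], 1)))
  names(curves) <- c("A", "B", "C")
  fc <- data.frame(site = c("A", "B", "C"), z_prot = c(0, 1, 0),
                   z_deprot = c(-1, 0, -1))
  cc <- total_charge_curve(curves, fc)
  ## oracle: thermodynamic total charge from the same enumeration
  oracle <- vapply(seq_along(ph), function(k)
    sum(fc$z_prot * fr[, k] + fc$z_deprot * (1 - fr[, k])), numeric(1))
  expect_equal(cc$charge, oracle, tolerance = 1e-9)
})

test_that("contact fractions count frames at or below the cutoff", {
  expect_equal(contact_fraction(rep(0.3, 10)), 100)
  expect_equal(contact_fraction(rep(c(0.3, 0.5), 25)), 50)
  set.seed(77)
  d <- runif(1e5, 0.2, 0.6)
  expect_lt(abs(contact_fraction(d) - 50), 1)
  expect_error(contact_fraction(numeric(0)), "empty")
})
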