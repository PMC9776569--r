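#' Aggregate replicate occupancy series into a titration curve
#'
#' Each replicate contributes a series of instantaneous (or short-window
#' mean) protonation values per pH; the initial `burn_in_fraction` of
#' every series is discarded as equilibration before averaging, and the
#' replicate means are combined into a mean curve with the standard
#' error of the mean across replicates.
#'
#' @param replicates list of numeric matrices (samples x pH), one per
#'   replicate, with pH values as column names; equal pH grids required
#' @param burn_in_fraction fraction of each series discarded (default
#'   0.2)
#' @param window optional `list(width, step)` in samples: returns one
#'   curve per sliding window instead (burn-in not applied)
#' @return a `titration_curve` (or list of them when `window` is given):
#'   `ph`, `replicate_fractions` (replicate x pH), `mean_fraction`,
#'   `sem`
#' @export
aggregate_titration <- function(replicates, burn_in_fraction = 0.2,
                                window = NULL) {
  stopifnot(length(replicates) >= 1)
  ph <- as.numeric(colnames(replicates[[1]]))
  if (any(is.na(ph))) stop("replicate matrices need pH column names")
  for (m in replicates)
    if (!identical(as.numeric(colnames(m)), ph))
      stop("replicates must share one pH grid")
  if (!is.null(window)) {
    n <- nrow(replicates[[1]])
    starts <- seq(1, n - window$width + 1, by = window$step)
    return(lapply(starts, function(s) {
      sub <- lapply(replicates, function(m)
        m[s:(s + window$width - 1), , drop = FALSE])
      out <- aggregate_titration(sub, burn_in_fraction = 0)
      out$window <- c(start = s, end = s + window$width - 1)
      out
    }))
  }
  reps <- do.call(rbind, lapply(replicates, function(m) {
    n <- nrow(m)
    keep <- seq.int(floor(burn_in_fraction * n) + 1, n)
    if (!length(keep) || keep[1] > n)
      stop("no samples left after burn-in")
    colMeans(m[keep, , drop = FALSE])
  }))
  titration_curve(ph, reps)
}

#' Construct a titration curve from replicate fractions
#'
#' @param ph pH values
#' @param replicate_fractions matrix replicate x pH of mean protonation
#'   fractions in \[0, 1\]
#' @return a `titration_curve`
#' @export
titration_curve <- function(ph, replicate_fractions) {
  m <- as.matrix(replicate_fractions)
  if (ncol(m) != length(ph)) stop("fractions must have one column per pH")
  if (any(m < -1e-9 | m > 1 + 1e-9)) stop("fractions must lie in [0, 1]")
  mean_fraction <- colMeans(m)
  sem <- if (nrow(m) > 1) apply(m, 2, stats::sd) / sqrt(nrow(m))
         else rep(0, ncol(m))
  structure(list(ph = as.numeric(ph), replicate_fractions = m,
                 mean_fraction = unname(mean_fraction), sem = unname(sem)),
            class = "titration_curve")
}

#' @export
print.titration_curve <- function(x, ...) {
  cat("Titration curve,", nrow(x$replicate_fractions), "replicate(s):\n")
  print(data.frame(pH = x$ph, mean = round(x$mean_fraction, 4),
                   sem = round(x$sem, 4)), row.names = FALSE)
  invisible(x)
}

#' Fit a Hill curve to a titration curve
#'
#' Least-squares fit of `f(pH) = 1 / (1 + 10^(n (pH - pKa)))` to the
#' mean protonation fractions (Levenberg-Marquardt, `n` bounded to
#' (0, 5]).  The fit is flagged unconverged when fewer than 3 pH points
#' lie strictly inside (0, 1), when the optimizer fails, or when the
#' fitted pKa falls outside `[min(pH) - 2, max(pH) + 2]` (curves
#' titrating outside the simulated pH range cannot be pinned down).
#'
#' @param curve a `titration_curve`, or a numeric vector of fractions
#' @param ph pH values (when `curve` is a plain vector)
#' @return a `hill_fit`: `pka`, `hill_n`, `pka_error` (NA until
#'   jackknifed), `converged`
#' @export
fit_hill <- function(curve, ph = NULL) {
  if (inherits(curve, "titration_curve")) {
    f <- curve$mean_fraction; ph <- curve$ph
  } else {
    f <- as.numeric(curve)
    if (is.null(ph)) stop("ph values required")
  }
  o <- order(ph); ph <- ph[o]; f <- f[o]
  fail <- function() structure(list(pka = NA_real_, hill_n = NA_real_,
                                    pka_error = NA_real_, converged = FALSE,
                                    ph = ph, fraction = f),
                               class = "hill_fit")
  inside <- f > 0 & f < 1
  if (sum(inside) < 3) return(fail())
  start_pka <- ph[which.min(abs(f - 0.5))]
  fit <- tryCatch(
    minpack.lm::nlsLM(f ~ 1 / (1 + 10^(n * (ph - pka))),
                      start = list(pka = start_pka, n = 1),
                      lower = c(pka = -1e6, n = 1e-3),
                      upper = c(pka = 1e6, n = 5),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail())
  cf <- stats::coef(fit)
  ## degenerate fits: pKa outside the resolvable window, or a collapsed
  ## slope (n -> 0 means nothing titrates inside the pH range)
  if (cf[["pka"]] < min(ph) - 2 || cf[["pka"]] > max(ph) + 2 ||
      cf[["n"]] <= 0.05) {
    out <- fail(); out$pka <- cf[["pka"]]; out$hill_n <- cf[["n"]]
    return(out)
  }
  structure(list(pka = unname(cf[["pka"]]), hill_n = unname(cf[["n"]]),
                 pka_error = NA_real_, converged = TRUE, ph = ph,
                 fraction = f, fit = fit),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  if (x$converged)
    cat(sprintf("Hill fit: pKa = %.3f%s, n = %.3f\n", x$pka,
                if (is.na(x$pka_error)) "" else
                  sprintf(" +/- %.3f", x$pka_error), x$hill_n))
  else cat("Hill fit: not converged\n")
  invisible(x)
}

#' @export
coef.hill_fit <- function(object, ...)
  c(pka = object$pka, n = object$hill_n)

#' @export
predict.hill_fit <- function(object, ph = object$ph, ...) {
  if (!object$converged) stop("cannot predict from an unconverged fit")
  1 / (1 + 10^(object$hill_n * (ph - object$pka)))
}

#' Jackknife error of a fitted pKa over replicates
#'
#' Refits the Hill curve on each leave-one-replicate-out mean curve and
#' returns `sqrt((m-1)/m * sum((pKa_(-k) - mean)^2))` over the
#' converged combinations; failing combinations are dropped and
#' reported.
#'
#' @param curve a `titration_curve` with >= 2 replicates
#' @return list with `pka_error` (NA when every combination failed),
#'   `loo_pka`, `n_failed`
#' @export
jackknife_pka <- function(curve) {
  m <- nrow(curve$replicate_fractions)
  if (m < 2) stop("jackknife needs at least 2 replicates")
  loo <- vapply(seq_len(m), function(k) {
    sub <- titration_curve(curve$ph,
                           curve$replicate_fractions[-k, , drop = FALSE])
    ft <- fit_hill(sub)
    if (ft$converged) ft$pka else NA_real_
  }, numeric(1))
  ok <- !is.na(loo)
  if (!any(ok))
    return(list(pka_error = NA_real_, loo_pka = loo, n_failed = m))
  v <- loo[ok]; mm <- length(v)
  err <- if (mm < 2) NA_real_
         else sqrt((mm - 1) / mm * sum((v - mean(v))^2))
  list(pka_error = err, loo_pka = loo, n_failed = sum(!ok))
}

#' Fit a site's pKa with jackknife error
#'
#' Convenience wrapper: Hill fit on the replicate-mean curve plus
#' [jackknife_pka()] error when >= 2 replicates are available.
#'
#' @param curve a `titration_curve`
#' @return a `hill_fit` with `pka_error` filled in
#' @export
fit_site_pka <- function(curve) {
  ft <- fit_hill(curve)
  if (ft$converged && nrow(curve$replicate_fractions) >= 2) {
    jk <- jackknife_pka(curve)
    ft$pka_error <- jk$pka_error
    ft$jackknife <- jk
  }
  ft
}

#' Total charge curve and isoelectric point
#'
#' The average charge of a site at a pH is
#' `z_prot * f + z_deprot * (1 - f)` with `f` its protonation fraction;
#' the total curve adds a fixed background charge.  The isoelectric
#' point is the root of the linear interpolation of the charge curve
#' (smallest root, with a warning, if the curve crosses zero more than
#' once).
#'
#' @param curves named list of `titration_curve`s, one per site
#' @param formal_charges data frame with columns `site`, `z_prot`,
#'   `z_deprot` (formal charge of the protonated/deprotonated forms)
#' @param background fixed non-titratable charge, e
#' @return data frame with columns `ph` and `charge`
#' @export
total_charge_curve <- function(curves, formal_charges, background = 0) {
  if (!length(curves)) {
    stop("no titratable sites; total charge is constant")
  }
  ph <- curves[[1]]$ph
  charge <- rep(background, length(ph))
  for (nm in names(curves)) {
    row <- formal_charges[match(nm, formal_charges$site), ]
    if (any(is.na(row))) stop("no formal charges for site ", nm)
    f <- curves[[nm]]$mean_fraction
    charge <- charge + row$z_prot * f + row$z_deprot * (1 - f)
  }
  data.frame(ph = ph, charge = charge)
}

#' @rdname total_charge_curve
#' @param charge_curve data frame from [total_charge_curve()]
#' @export
isoelectric_point <- function(charge_curve) {
  ph <- charge_curve$ph; q <- charge_curve$charge
  s <- sign(q)
  if (all(s >= 0) || all(s <= 0)) {
    if (any(q == 0)) return(ph[which(q == 0)[1]])
    stop("charge curve does not change sign; pI undefined")
  }
  cross <- which(s[-length(s)] * s[-1] < 0 | q[-length(q)] == 0)
  roots <- vapply(cross, function(i) {
    if (q[i] == 0) return(ph[i])
    ph[i] + (ph[i + 1] - ph[i]) * (0 - q[i]) / (q[i + 1] - q[i])
  }, numeric(1))
  roots <- sort(unique(roots))
  if (length(roots) > 1)
    warning("charge curve crosses zero ", length(roots),
            " times; returning the smallest root")
  roots[1]
}

#' Contact fraction of a distance series
#'
#' Percentage of frames in which the minimum side-chain distance is at
#' or below the cutoff (default 0.4 nm).
#'
#' @param distances numeric vector of per-frame distances, nm
#' @param cutoff nm
#' @return percentage in \[0, 100\]
#' @export
contact_fraction <- function(distances, cutoff = 0.4) {
  if (!length(distances)) stop("empty distance series")
  100 * mean(distances <= cutoff)
}
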