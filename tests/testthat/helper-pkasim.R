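## shared test helpers: small grids and toy systems keep PB solves fast

## PB settings used by most PB tests (small grid, salt-free unless the
## test wants screening); oracles with analytic forms run at 0 M
pb_small <- function(...) {
  args <- utils::modifyList(list(ionic_strength = 0, nodes = 33L,
                                 fine_spacing = 0.05), list(...))
  do.call(pb_config, args)
}

## single-bead acid at the origin
one_bead_structure <- function(resname = "GLU", radius = 0.2) {
  atoms_df(data.frame(name = "SC", resname = resname, resid = 1,
                      x = 0, y = 0, z = 0, charge = 0, radius = radius))
}

## two single-bead sites on the x axis
two_bead_structure <- function(sep = 0.8, resnames = c("GLU", "LYS")) {
  atoms_df(data.frame(name = "SC", resname = resnames, resid = 1:2,
                      x = c(0, sep), y = 0, z = 0, charge = 0,
                      radius = 0.18))
}

## independent bisection oracle for the LJ 2RT contact distance
## (deliberately not uniroot, which the production code uses)
bisect_lj_contact <- function(sigma, epsilon, temperature,
                              target = 2 * 8.31446261815324e-3 * temperature,
                              tol = 1e-9) {
  f <- function(r) {
    sr6 <- (sigma / r)^6
    4 * epsilon * (sr6^2 - sr6) - target
  }
  lo <- sigma * 0.2
  hi <- sigma * 2^(1 / 6)
  stopifnot(f(lo) > 0, f(hi) < 0)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

## synthetic pKa benchmark set (predictions, experiment, types) with
## known metric values; labelled synthetic: not measured data
synthetic_benchmark_set <- function() {
  residues <- c("Asp-1", "Glu-2", "His-3", "Lys-4", "Tyr-5")
  types <- stats::setNames(c("Asp", "Glu", "His", "Lys", "Tyr"), residues)
  experimental <- stats::setNames(c(3.0, 4.8, 6.1, 10.9, 10.2), residues)
  predicted <- stats::setNames(c(3.5, 4.3, 6.6, 10.4, 12.9), residues)
  list(predicted = predicted, experimental = experimental, types = types)
}
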