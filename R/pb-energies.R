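#' Site energy tables
#'
#' A site energy table holds, for every protonation/tautomer state of
#' every titratable site, the intrinsic pKa (`pkint`: the model-compound
#' pKa shifted by the protein-transfer electrostatic free energy) and
#' the symmetric matrix `W` of pairwise site-site interaction energies
#' in pK units, reference-subtracted so that the all-reference
#' microstate has zero energy.
#'
#' @param states data frame with columns `site`, `site_label`, `state`,
#'   `x`, `taut`, `pkmod`, `pkint`, `ref`
#' @param W numeric interaction matrix (pK units), one row/column per
#'   state in `states` order
#' @param temperature K
#' @return a `site_energy_table`
#' @export
site_energy_table <- function(states, W, temperature = 310) {
  stopifnot(nrow(states) == nrow(W), nrow(W) == ncol(W))
  if (max(abs(W - t(W))) > 1e-9)
    stop("interaction matrix must be symmetric")
  same <- outer(states$site, states$site, "==")
  if (any(abs(W[same]) > 1e-12))
    stop("interactions between states of one site must be zero")
  states$idx <- seq_len(nrow(states))
  W <- (W + t(W)) / 2
  dimnames(W) <- list(paste(states$site_label, states$state, sep = ":"),
                      paste(states$site_label, states$state, sep = ":"))
  structure(list(states = states, W = W, temperature = temperature),
            class = "site_energy_table")
}

#' @export
print.site_energy_table <- function(x, ...) {
  cat("Site energy table:", length(unique(x$states$site)), "site(s),",
      nrow(x$states), "states\n")
  print(x$states[, c("site_label", "state", "x", "pkmod", "pkint", "ref")],
        row.names = FALSE)
  strong <- max(abs(x$W))
  cat("max |W| =", format(signif(strong, 3)), "pK\n")
  invisible(x)
}

## indices of each site's states, and of reference states
table_site_states <- function(table) {
  split(table$states$idx, table$states$site)
}

#' Protein- and model-compound-context charging energies of a site state
#'
#' Solves the focused linear PB equation with only the given state's
#' charges placed.  In the protein context the dielectric geometry is
#' the full structure; in the model-compound context it is the site's
#' model-compound atoms alone.  The same fine grid (centered on the
#' model-compound centroid) is used for both contexts, so the grid
#' self-energy cancels in their difference.
#'
#' @param structure structure data frame (all radii set; other sites in
#'   their reference states)
#' @param site an instantiated site
#' @param state a `site_state` of the site (or label)
#' @param context `"protein"` or `"model_compound"`
#' @param config a `pb_config`
#' @return list with `self_energy` and `background_energy` (kT), plus
#'   the `fine`/`coarse` potential grids
#' @export
charging_terms <- function(structure, site, state,
                           context = c("protein", "model_compound"),
                           config = pb_config()) {
  context <- match.arg(context)
  if (is.character(state)) state <- get_state(site, state)
  labels <- vapply(site$states, `[[`, "", "label")
  if (!state$label %in% labels)
    stop("state '", state$label, "' does not belong to site")
  model_ids <- site$atom_ids[site$model_atoms]
  geom <- if (context == "protein") structure
          else structure[structure$atom_id %in% model_ids, , drop = FALSE]
  geom <- apply_state_partial(geom, site, state)
  center <- site_center(structure, site)
  sol <- focus_solve(geom, center, config,
                     charge_atoms = unname(site$atom_ids))
  placed <- geom$atom_id %in% site$atom_ids & geom$charge != 0
  self <- 0.5 * sum(geom$charge[placed] *
                      grid_potential(sol, geom[placed, , drop = FALSE]))
  bg_rows <- !(geom$atom_id %in% site$atom_ids) & geom$charge != 0
  background <- if (any(bg_rows))
    sum(geom$charge[bg_rows] * grid_potential(sol, geom[bg_rows, , drop = FALSE]))
  else 0
  list(self_energy = self, background_energy = background,
       fine = sol$fine, coarse = sol$coarse)
}

## apply a state's charges to whichever member atoms are present
apply_state_partial <- function(structure, site, state) {
  ids <- site$atom_ids[names(state$charges)]
  idx <- match(ids, structure$atom_id)
  keep <- !is.na(idx)
  structure$charge[idx[keep]] <- unname(state$charges)[keep]
  structure
}

site_center <- function(structure, site) {
  ids <- site$atom_ids[site$model_atoms]
  rows <- structure[match(ids, structure$atom_id), , drop = FALSE]
  c(mean(rows$x), mean(rows$y), mean(rows$z))
}

## potential of a focusing solution at atom positions: fine grid where
## the atom is well inside it, coarse grid otherwise
grid_potential <- function(sol, rows) {
  pts <- cbind(rows$x, rows$y, rows$z)
  fspec <- sol$fine$spec
  margin <- grid_half_extent(fspec) - 2 * fspec$spacing
  rel <- sweep(pts, 2, fspec$center)
  use_fine <- apply(abs(rel) <= margin, 1, all)
  out <- numeric(nrow(pts))
  if (any(use_fine))
    out[use_fine] <- potential_at(sol$fine, pts[use_fine, , drop = FALSE])
  if (any(!use_fine))
    out[!use_fine] <- potential_at(sol$coarse, pts[!use_fine, , drop = FALSE])
  out
}

#' Compute the full site energy table of a structure
#'
#' For every state of every site, solves the focused PB problem in the
#' protein and model-compound contexts and forms the intrinsic pKa
#' `pkint = pkmod - ddG / ln 10` (ddG in kT: the protein-minus-model
#' difference of state-minus-reference charging energies).  Pairwise
#' interactions are read off the protein-context potentials, double-
#' difference corrected against the reference states, converted to pK
#' units and symmetrized by averaging with the transpose.
#'
#' @param structure structure data frame
#' @param sites list of instantiated sites
#' @param config a `pb_config`
#' @return a `site_energy_table`
#' @export
compute_energy_table <- function(structure, sites, config = pb_config()) {
  structure <- apply_reference_states(structure, sites)
  ns <- length(sites)
  states <- do.call(rbind, lapply(sites, function(s) {
    data.frame(site = s$site_id, site_label = s$label,
               state = vapply(s$states, `[[`, "", "label"),
               x = vapply(s$states, `[[`, integer(1), "x"),
               taut = vapply(s$states, `[[`, integer(1), "taut"),
               pkmod = vapply(s$states, `[[`, numeric(1), "pkmod"),
               ref = vapply(s$states, `[[`, logical(1), "ref"),
               stringsAsFactors = FALSE)
  }))
  nstate <- nrow(states)
  states$idx <- seq_len(nstate)
  site_rows <- split(seq_len(nstate), states$site)

  ## raw pair energies P[a, b] = sum over atoms of state b of q * phi_a
  P <- matrix(0, nstate, nstate)
  G_prot <- numeric(nstate)
  G_model <- numeric(nstate)

  for (i in seq_len(ns)) {
    site <- sites[[i]]
    rows_i <- which(states$site == site$site_id)
    for (r in rows_i) {
      st <- get_state(site, states$state[r])
      pr <- charging_terms(structure, site, st, "protein", config)
      G_prot[r] <- pr$self_energy + pr$background_energy
      mo <- charging_terms(structure, site, st, "model_compound", config)
      G_model[r] <- mo$self_energy + mo$background_energy
      sol <- list(fine = pr$fine, coarse = pr$coarse)
      for (j in seq_len(ns)) {
        if (j == i) next
        sj <- sites[[j]]
        rows_j <- which(states$site == sj$site_id)
        pos <- structure[match(sj$atom_ids[sj$member_atoms],
                               structure$atom_id), , drop = FALSE]
        phi <- grid_potential(sol, pos)
        for (rj in rows_j) {
          stj <- get_state(sj, states$state[rj])
          qj <- unname(stj$charges[sj$member_atoms])
          P[r, rj] <- sum(qj * phi)
        }
      }
    }
  }

  ref_of <- vapply(split(states$idx, states$site), function(ix)
    ix[states$ref[ix]][1], integer(1))
  ref_row <- ref_of[as.character(states$site)]

  dd <- (G_prot - G_prot[ref_row]) - (G_model - G_model[ref_row])
  states$pkint <- states$pkmod - dd / LN10

  W <- matrix(0, nstate, nstate)
  for (a in seq_len(nstate)) for (b in seq_len(nstate)) {
    if (states$site[a] == states$site[b]) next
    W[a, b] <- (P[a, b] - P[a, ref_row[b]] - P[ref_row[a], b] +
                  P[ref_row[a], ref_row[b]]) / LN10
  }
  W <- (W + t(W)) / 2
  site_energy_table(states[, c("site", "site_label", "state", "x", "taut",
                               "pkmod", "pkint", "ref")],
                    W, temperature = config$temperature)
}

#' Assemble a site energy table directly from values
#'
#' Convenience constructor for tests, fixtures and file import: one
#' two-state (protonated/deprotonated) site per entry.
#'
#' @param pkint numeric vector of intrinsic pKa values (one per site)
#' @param W site-by-site interaction matrix in pK units (between the
#'   protonated states; reference states interact with nothing); a
#'   scalar 0 is recycled
#' @param pkmod model-compound pKa values (default = `pkint`)
#' @param site_ids integer site ids (default `seq_along(pkint)`)
#' @param temperature K
#' @return a `site_energy_table`
#' @export
energy_table_from_values <- function(pkint, W = 0, pkmod = pkint,
                                     site_ids = seq_along(pkint),
                                     temperature = 310) {
  ns <- length(pkint)
  if (length(W) == 1) W <- matrix(0, ns, ns)
  stopifnot(nrow(W) == ns, ncol(W) == ns)
  states <- data.frame(
    site = rep(site_ids, each = 2),
    site_label = rep(paste0("site-", site_ids), each = 2),
    state = rep(c("prot", "deprot"), ns),
    x = rep(c(1L, 0L), ns),
    taut = 0L,
    pkmod = rep(pkmod, each = 2),
    pkint = rep(pkint, each = 2),
    ref = rep(c(FALSE, TRUE), ns),
    stringsAsFactors = FALSE)
  Wfull <- matrix(0, 2 * ns, 2 * ns)
  prot <- seq(1, 2 * ns, by = 2)
  Wfull[prot, prot] <- (W + t(W)) / 2
  diag(Wfull) <- 0
  Wfull[cbind(prot, prot)] <- 0
  site_energy_table(states, Wfull, temperature)
}

#' Write / read a site energy table as TSV
#'
#' `<prefix>.pkint.tsv` holds the per-state table and
#' `<prefix>.interactions.tsv` the long-format nonzero interactions.
#'
#' @param table a `site_energy_table`
#' @param prefix output path prefix
#' @return invisibly, the two paths
#' @export
write_energy_table <- function(table, prefix) {
  p1 <- paste0(prefix, ".pkint.tsv")
  p2 <- paste0(prefix, ".interactions.tsv")
  utils::write.table(table$states, p1, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  idx <- which(upper.tri(table$W) & table$W != 0, arr.ind = TRUE)
  inter <- data.frame(
    site_i = table$states$site[idx[, 1]], state_i = table$states$state[idx[, 1]],
    site_j = table$states$site[idx[, 2]], state_j = table$states$state[idx[, 2]],
    W_pK = table$W[idx])
  utils::write.table(inter, p2, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(p1, p2))
}

#' @rdname write_energy_table
#' @param temperature K (not stored in the TSV)
#' @export
read_energy_table <- function(prefix, temperature = 310) {
  states <- utils::read.delim(paste0(prefix, ".pkint.tsv"))
  inter <- utils::read.delim(paste0(prefix, ".interactions.tsv"))
  n <- nrow(states)
  W <- matrix(0, n, n)
  key <- paste(states$site, states$state)
  for (r in seq_len(nrow(inter))) {
    a <- match(paste(inter$site_i[r], inter$state_i[r]), key)
    b <- match(paste(inter$site_j[r], inter$state_j[r]), key)
    W[a, b] <- W[b, a] <- inter$W_pK[r]
  }
  site_energy_table(states[, c("site", "site_label", "state", "x", "taut",
                               "pkmod", "pkint", "ref")], W, temperature)
}
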