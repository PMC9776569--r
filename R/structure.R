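#' Atomic structure tables
#'
#' Structures are plain data frames with one row per atom and columns
#' `atom_id` (integer), `name`, `resname`, `resid` (integer), `x`, `y`,
#' `z` (nm), `charge` (e) and `radius` (nm).  Optional columns `lj_sigma`
#' (nm) and `lj_epsilon` (kJ/mol) carry Lennard-Jones parameters for
#' radius derivation.  `atoms_df()` validates and normalises such a table.
#'
#' @param df data frame with at least name, resname, resid and x/y/z
#' @return validated structure data frame
#' @export
atoms_df <- function(df) {
  need <- c("name", "resname", "resid", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("structure table is missing columns: ", paste(miss, collapse = ", "))
  if (is.null(df$atom_id)) df$atom_id <- seq_len(nrow(df))
  if (is.null(df$charge)) df$charge <- rep(0, nrow(df))
  if (is.null(df$radius)) df$radius <- rep(NA_real_, nrow(df))
  xyz <- as.matrix(df[, c("x", "y", "z")])
  if (nrow(df) && !all(is.finite(xyz)))
    stop("non-finite atomic coordinates")
  if (nrow(df) && !all(is.finite(df$charge)))
    stop("non-finite atomic charges")
  bad <- !is.na(df$radius) & df$radius <= 0
  if (any(bad))
    stop("non-positive radius for atom(s): ",
         paste(df$name[bad], collapse = ", "))
  df$atom_id <- as.integer(df$atom_id)
  df$resid <- as.integer(df$resid)
  rownames(df) <- NULL
  df
}

#' Read a PQR file
#'
#' Whitespace-separated PQR (ATOM/HETATM records with charge then radius
#' as the last two fields).  Coordinates and radii are converted from
#' Angstrom to nm.
#'
#' @param path file path
#' @return structure data frame (see [atoms_df()])
#' @export
read_pqr <- function(path) {
  p <- bio3d::read.pqr(path)
  a <- p$atom
  atoms_df(data.frame(
    atom_id = as.integer(a$eleno),
    name = trimws(a$elety),
    resname = trimws(a$resid),
    resid = as.integer(a$resno),
    x = a$x / 10, y = a$y / 10, z = a$z / 10,
    charge = a$o,          # bio3d stores PQR charge in the occupancy slot
    radius = a$b / 10,     # ... and radius in the b-factor slot
    stringsAsFactors = FALSE))
}

#' Write a PQR file
#'
#' @param structure structure data frame (nm, e)
#' @param path output path
#' @return invisibly, `path`
#' @export
write_pqr <- function(structure, path) {
  structure <- atoms_df(structure)
  r <- ifelse(is.na(structure$radius), 0, structure$radius)
  lines <- sprintf(
    "ATOM  %5d %-4s %-4s %4d    %8.3f%8.3f%8.3f %7.4f %6.4f",
    structure$atom_id, structure$name, structure$resname, structure$resid,
    structure$x * 10, structure$y * 10, structure$z * 10,
    structure$charge, r * 10)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read a PDB file (multi-model allowed)
#'
#' Coordinates are converted to nm; charges and radii are left unset.
#'
#' @param path file path
#' @param multi if `TRUE`, return a list of structures, one per MODEL
#' @return a structure data frame, or a list of them when `multi = TRUE`
#' @export
read_pdb_structure <- function(path, multi = FALSE) {
  p <- bio3d::read.pdb(path, multi = multi)
  a <- p$atom
  base <- data.frame(
    atom_id = as.integer(a$eleno),
    name = trimws(a$elety),
    resname = trimws(a$resid),
    resid = as.integer(a$resno),
    x = a$x / 10, y = a$y / 10, z = a$z / 10,
    stringsAsFactors = FALSE)
  if (!multi) return(atoms_df(base))
  nmod <- nrow(p$xyz)
  lapply(seq_len(nmod), function(m) {
    xyz <- matrix(p$xyz[m, ], ncol = 3, byrow = TRUE)
    b <- base
    b$x <- xyz[, 1] / 10; b$y <- xyz[, 2] / 10; b$z <- xyz[, 3] / 10
    atoms_df(b)
  })
}

## total charge of a structure, e
total_charge <- function(structure) sum(structure$charge)
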