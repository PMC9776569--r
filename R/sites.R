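#' Titratable sites and site libraries
#'
#' A *site state* is one protonation/tautomer form of a titratable group:
#' a label, a protonation count `x` (0 or 1), a tautomer index, a
#' reference pKa (`pkmod`, the calibrated model-compound value), a
#' reference flag and a named vector of per-atom partial charges.  A
#' *titratable site* bundles the member atoms, the model-compound subset
#' and at least one protonated and one deprotonated state.  A *site
#' library* maps residue type names to site templates; templates for
#' titrating termini are kept alongside the amino-acid entries.
#'
#' @name sites
NULL

site_state <- function(label, x, taut = 0L, pkmod, ref = FALSE, charges) {
  stopifnot(x %in% c(0L, 1L), is.numeric(charges), !is.null(names(charges)))
  structure(list(label = label, x = as.integer(x), taut = as.integer(taut),
                 pkmod = pkmod, ref = isTRUE(ref),
                 charges = charges), class = "site_state")
}

site_template <- function(residue_type, states, member_atoms = NULL,
                          model_atoms = NULL) {
  if (is.null(member_atoms))
    member_atoms <- unique(unlist(lapply(states, function(s) names(s$charges))))
  if (is.null(model_atoms)) model_atoms <- member_atoms
  tpl <- structure(list(residue_type = residue_type,
                        member_atoms = member_atoms,
                        model_atoms = model_atoms, states = states),
                   class = "site_template")
  validate_site_template(tpl)
  tpl
}

validate_site_template <- function(tpl, tol = 1e-6) {
  st <- tpl$states
  id <- tpl$residue_type
  if (length(st) < 2)
    stop("site ", id, ": needs at least 2 states")
  x <- vapply(st, `[[`, integer(1), "x")
  if (!any(x == 1) || !any(x == 0))
    stop("site ", id, ": needs at least one protonated and one deprotonated state")
  if (sum(vapply(st, `[[`, logical(1), "ref")) != 1)
    stop("site ", id, ": exactly one state must be flagged reference")
  if (!all(vapply(st, function(s)
    setequal(names(s$charges), tpl$member_atoms), logical(1))))
    stop("site ", id, ": every state must charge exactly the member atoms")
  if (!all(tpl$model_atoms %in% tpl$member_atoms))
    stop("site ", id, ": model-compound atoms must be member atoms")
  qs <- vapply(st, function(s) sum(s$charges), numeric(1))
  q0 <- qs[x == 0]; q1 <- qs[x == 1]
  if (diff(range(c(q0, q0[1]))) > tol || diff(range(c(q1, q1[1]))) > tol)
    stop("site ", id, ": states with equal protonation count must have ",
         "equal total charge")
  if (abs((q1[1] - q0[1]) - 1) > tol) {
    lab <- st[[which(x == 1)[1]]]$label
    stop("site ", id, " state ", lab, ": protonated/deprotonated total ",
         "charges differ by ", format(q1[1] - q0[1]), " e, expected +1 e")
  }
  invisible(tpl)
}

#' Load a site-definition library
#'
#' Plain-text format: `SITE <residue_type>` opens a block, optionally
#' followed by `MODEL <atom names>` (model-compound subset), then one or
#' more `STATE <label> x=<0|1> taut=<k> pkmod=<float> ref=<0|1>` headers,
#' each followed by `ATOM <name> <charge>` lines.  Blocks end at a blank
#' line or the next `SITE`.
#'
#' @param path file path
#' @return a `site_library` object
#' @export
load_site_library <- function(path) {
  lines <- trimws(readLines(path))
  entries <- list()
  cur <- NULL; cur_states <- list(); cur_model <- NULL
  st <- NULL; st_atoms <- numeric(0)

  flush_state <- function() {
    if (!is.null(st)) {
      st$charges <- st_atoms
      cur_states[[length(cur_states) + 1]] <<- do.call(site_state, st)
    }
    st <<- NULL; st_atoms <<- numeric(0)
  }
  flush_site <- function() {
    flush_state()
    if (!is.null(cur)) {
      entries[[cur]] <<- site_template(cur, cur_states,
                                       model_atoms = cur_model)
    }
    cur <<- NULL; cur_states <<- list(); cur_model <<- NULL
  }

  for (ln in lines) {
    if (ln == "" || startsWith(ln, "#")) next
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    kw <- toupper(tok[1])
    if (kw == "SITE") {
      flush_site(); cur <- tok[2]
    } else if (kw == "MODEL") {
      cur_model <- tok[-1]
    } else if (kw == "STATE") {
      flush_state()
      kv <- strsplit(tok[-(1:2)], "=")
      vals <- stats::setNames(vapply(kv, `[`, "", 2),
                              vapply(kv, `[`, "", 1))
      st <- list(label = tok[2],
                 x = as.integer(vals[["x"]]),
                 taut = as.integer(if ("taut" %in% names(vals))
                   vals[["taut"]] else "0"),
                 pkmod = as.numeric(vals[["pkmod"]]),
                 ref = identical(vals[["ref"]], "1"))
    } else if (kw == "ATOM") {
      if (is.null(st)) stop("ATOM line outside a STATE block: ", ln)
      st_atoms[tok[2]] <- as.numeric(tok[3])
    } else stop("unrecognised line in site library: ", ln)
  }
  flush_site()
  structure(list(entries = entries), class = "site_library")
}

#' Write a site library
#' @param library a `site_library`
#' @param path output path
#' @return invisibly, `path`
#' @export
write_site_library <- function(library, path) {
  out <- character(0)
  for (tpl in library$entries) {
    out <- c(out, paste("SITE", tpl$residue_type))
    if (!setequal(tpl$model_atoms, tpl$member_atoms))
      out <- c(out, paste(c("MODEL", tpl$model_atoms), collapse = " "))
    for (s in tpl$states) {
      out <- c(out, sprintf("STATE %s x=%d taut=%d pkmod=%.10g ref=%d",
                            s$label, s$x, s$taut, s$pkmod, as.integer(s$ref)))
      out <- c(out, sprintf("ATOM %s %.10g", names(s$charges), s$charges))
    }
    out <- c(out, "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Built-in single-bead site library
#'
#' A coarse library for desk-scale fixtures: each titratable group is a
#' single side-chain bead (or terminus bead) with unit formal-charge
#' difference between forms.  Reference pKa values (`pkmod`) are the
#' alanine-pentapeptide scale commonly used to anchor model compounds.
#' `GL2` is a two-atom carboxylate used to exercise multi-atom charge
#' sets, and `HIS` carries two neutral tautomers.
#'
#' @return a `site_library`
#' @export
toy_site_library <- function() {
  acid <- function(type, pk, atom = "SC")
    site_template(type, list(
      site_state("prot", 1L, 0L, pk, FALSE,
                 stats::setNames(0, atom)),
      site_state("deprot", 0L, 0L, pk, TRUE,
                 stats::setNames(-1, atom))))
  base <- function(type, pk, atom = "SC")
    site_template(type, list(
      site_state("prot", 1L, 0L, pk, FALSE,
                 stats::setNames(1, atom)),
      site_state("deprot", 0L, 0L, pk, TRUE,
                 stats::setNames(0, atom))))
  his <- site_template("HIS", list(
    site_state("prot", 1L, 0L, 6.54, FALSE, c(SC = 1)),
    site_state("taut-d", 0L, 0L, 6.54, TRUE, c(SC = 0)),
    site_state("taut-e", 0L, 1L, 6.54, FALSE, c(SC = 0))))
  gl2 <- site_template("GL2", list(
    site_state("prot", 1L, 0L, 4.25, FALSE, c(C1 = 0.25, C2 = -0.25)),
    site_state("deprot", 0L, 0L, 4.25, TRUE, c(C1 = -0.3, C2 = -0.7))))
  structure(list(entries = list(
    ASP = acid("ASP", 3.94), GLU = acid("GLU", 4.25),
    CYS = acid("CYS", 8.55), TYR = acid("TYR", 9.84),
    HIS = his, LYS = base("LYS", 10.40),
    NTR = base("NTR", 8.00, atom = "N"),
    CTR = acid("CTR", 3.67, atom = "C"),
    GL2 = gl2)), class = "site_library")
}

#' Instantiate titratable sites on a structure
#'
#' @param structure structure data frame
#' @param library a `site_library`
#' @param selection residue indices (`resid`) to titrate
#' @param ntr,ctr also titrate the N-/C-terminal group of the first/last
#'   residue using the `NTR`/`CTR` library templates
#' @return list of instantiated sites (template plus `site_id`, `label`
#'   and resolved `atom_ids`)
#' @export
instantiate_sites <- function(structure, library, selection,
                              ntr = FALSE, ctr = FALSE) {
  make_site <- function(tpl, resid) {
    rows <- structure[structure$resid == resid, ]
    missing <- setdiff(tpl$member_atoms, rows$name)
    if (length(missing))
      stop("residue ", resid, " (", tpl$residue_type, ") is missing atom(s): ",
           paste(missing, collapse = ", "))
    ids <- stats::setNames(rows$atom_id[match(tpl$member_atoms, rows$name)],
                           tpl$member_atoms)
    c(tpl, list(site_id = as.integer(resid),
                label = paste0(tpl$residue_type, "-", resid),
                atom_ids = ids))
  }
  sites <- lapply(selection, function(resid) {
    rn <- unique(structure$resname[structure$resid == resid])
    if (length(rn) != 1)
      stop("residue ", resid, " not found (or ambiguous) in structure")
    tpl <- library$entries[[rn]]
    if (is.null(tpl)) stop("no site template for residue type ", rn)
    make_site(tpl, resid)
  })
  resids <- sort(unique(structure$resid))
  if (ntr) {
    tpl <- library$entries[["NTR"]]
    if (is.null(tpl)) stop("library has no NTR terminus template")
    sites <- c(sites, list(make_site(tpl, resids[1])))
  }
  if (ctr) {
    tpl <- library$entries[["CTR"]]
    if (is.null(tpl)) stop("library has no CTR terminus template")
    sites <- c(sites, list(make_site(tpl, resids[length(resids)])))
  }
  sites
}

#' Reference state of a site
#' @param site an instantiated site or template
#' @return the reference `site_state`
#' @export
reference_state <- function(site)
  site$states[[which(vapply(site$states, `[[`, logical(1), "ref"))]]

#' Look up a state of a site by label
#' @param site a site
#' @param label state label
#' @return the `site_state`
#' @export
get_state <- function(site, label) {
  i <- match(label, vapply(site$states, `[[`, "", "label"))
  if (is.na(i)) stop("site ", site$label %||% site$residue_type,
                     " has no state '", label, "'")
  site$states[[i]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply a protonation/tautomer state to a structure
#'
#' Only the charges of the site's member atoms change; the total
#' structure charge changes by the state's formal-charge difference.
#'
#' @param structure structure data frame
#' @param site an instantiated site (with `atom_ids`)
#' @param state a `site_state` of that site, or a state label
#' @return structure with updated charges
#' @export
apply_state <- function(structure, site, state) {
  if (is.character(state)) state <- get_state(site, state)
  labels <- vapply(site$states, `[[`, "", "label")
  if (!state$label %in% labels ||
      !setequal(names(state$charges), site$member_atoms))
    stop("state '", state$label, "' does not belong to site ", site$label)
  idx <- match(site$atom_ids[names(state$charges)], structure$atom_id)
  if (anyNA(idx)) stop("site atoms not present in structure")
  structure$charge[idx] <- unname(state$charges)
  structure
}

#' Put every site of a structure in its reference state
#' @param structure structure data frame
#' @param sites list of instantiated sites
#' @return structure with reference charges applied
#' @export
apply_reference_states <- function(structure, sites) {
  for (s in sites) structure <- apply_state(structure, s, reference_state(s))
  structure
}
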