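#' Benchmark pKa predictions against experimental values
#'
#' Computes RMSE, MAE, mean error (bias, predicted minus experimental),
#' and maximum absolute deviation over the residues present in both
#' sets, globally and per residue type.  Residues of excluded types
#' (tyrosines by default, whose fitted pKa values typically extrapolate
#' beyond the simulated pH range) and residues with non-finite
#' predictions are dropped and listed.  A *null model* — every residue
#' predicted at its residue-type reference pKa — is evaluated on the
#' same residue set as the baseline.
#'
#' @param predicted named numeric vector, residue id -> predicted pKa
#' @param experimental named numeric vector, residue id -> experimental
#'   pKa
#' @param residue_types named character vector, residue id -> type
#'   (e.g. `"Asp"`, `"Glu"`, `"NTr"`)
#' @param references named numeric vector, type -> reference pKa (the
#'   pentapeptide scale); required for the null model
#' @param exclude_types residue types excluded from the metrics
#' @return a `benchmark_report`
#' @export
pka_benchmark <- function(predicted, experimental, residue_types,
                          references = NULL, exclude_types = "Tyr") {
  common <- intersect(names(predicted), names(experimental))
  if (!length(common)) stop("no residues shared by the two sets")
  excluded <- data.frame(residue = character(0), reason = character(0))
  types <- residue_types[common]
  drop_type <- common[types %in% exclude_types]
  drop_na <- common[!is.finite(predicted[common])]
  if (length(drop_type))
    excluded <- rbind(excluded, data.frame(residue = drop_type,
                                           reason = "excluded type"))
  if (length(setdiff(drop_na, drop_type)))
    excluded <- rbind(excluded,
                      data.frame(residue = setdiff(drop_na, drop_type),
                                 reason = "no converged prediction"))
  keep <- setdiff(common, union(drop_type, drop_na))
  if (!length(keep)) stop("no residues left after exclusions")

  metrics <- function(pred, exp) {
    d <- pred - exp
    c(rmse = sqrt(mean(d^2)), mae = mean(abs(d)), me = mean(d),
      max_dev = max(abs(d)), n = length(d))
  }
  global <- metrics(predicted[keep], experimental[keep])
  per_type <- do.call(rbind, lapply(
    sort(unique(residue_types[keep])), function(ty) {
      ids <- keep[residue_types[keep] == ty]
      m <- metrics(predicted[ids], experimental[ids])
      data.frame(type = ty, rmse = m["rmse"], mae = m["mae"], me = m["me"],
                 max_dev = m["max_dev"], n = m["n"], row.names = NULL)
    }))
  null <- NULL
  if (!is.null(references)) {
    refs <- references[residue_types[keep]]
    if (anyNA(refs))
      stop("missing reference pKa for type(s): ",
           paste(unique(residue_types[keep][is.na(refs)]), collapse = ", "))
    null <- metrics(unname(refs), unname(experimental[keep]))
  }
  structure(list(global = global, per_type = per_type, null = null,
                 excluded = excluded, residues = keep),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  g <- x$global
  cat(sprintf("pKa benchmark over %d residues: RMSE %.2f, MAE %.2f, ME %+.2f, max %.2f\n",
              g["n"], g["rmse"], g["mae"], g["me"], g["max_dev"]))
  if (!is.null(x$null))
    cat(sprintf("null model: RMSE %.2f\n", x$null["rmse"]))
  if (nrow(x$excluded))
    cat("excluded:", paste(x$excluded$residue, collapse = ", "), "\n")
  print(x$per_type, row.names = FALSE)
  invisible(x)
}

#' RMSE between two prediction sets
#'
#' Used to compare two force fields (or two methods) over all titrating
#' residues, with no experimental values involved.
#'
#' @param a,b named numeric vectors of predictions
#' @return RMSE over the shared residues
#' @export
prediction_rmse <- function(a, b) {
  common <- intersect(names(a), names(b))
  common <- common[is.finite(a[common]) & is.finite(b[common])]
  if (!length(common)) stop("no residues shared by the two sets")
  sqrt(mean((a[common] - b[common])^2))
}

#' Pentapeptide reference pKa scale
#'
#' Reference pKa values of titratable groups measured in alanine-based
#' pentapeptides, used as model-compound anchors and as the null-model
#' predictor.  Shipped as `inst/extdata/pentapeptide_reference_pka.tsv`.
#'
#' @return named numeric vector, residue type -> pKa
#' @export
pentapeptide_references <- function() {
  path <- system.file("extdata", "pentapeptide_reference_pka.tsv",
                      package = "pkasim")
  tab <- utils::read.delim(path)
  stats::setNames(tab$pka, tab$type)
}
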