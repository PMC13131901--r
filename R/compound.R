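#' Load and validate a compound parameter set
#'
#' Reads a drug-specific YAML config (physicochemical properties, per-species
#' plasma unbound fraction `fup` and blood-to-plasma ratio `bpr`, and the
#' mouse-optimized specific permeability-surface-area product `spec_pstc`) and
#' validates it. Unbound fractions measured below the quantification limit are
#' entered in the config as 0.001 (0.1%).
#'
#' `fup` and `bpr` are stored per species; downstream simulation fails loudly
#' if the requested species has no entry rather than silently substituting.
#' `pKa` values and solubility are retained as provenance metadata only: the
#' model is IV-only and the partition-coefficient method uses logP, not logD.
#'
#' @param path Path to the YAML config file.
#' @return An object of class `pbpk_compound`: a list with fields `name`,
#'   `mw`, `logp`, `solubility_mg_ml`, `solubility_ph`, `pka`, `spec_pstc`
#'   and tibbles accessible via per-species lookups `fup` and `bpr`
#'   (named numeric vectors).
#' @examples
#' mtm <- load_compound(mtmpbpk_example("compounds/mtm.yaml"))
#' mtm$fup[["human"]]
#' @export
load_compound <- function(path) {
  if (!file.exists(path)) abort(paste0("Compound config not found: ", path))
  raw <- yaml::read_yaml(path)

  required <- c("name", "mw", "logp", "fup", "bpr", "spec_pstc")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    abort(paste0("Compound config missing fields: ",
                 paste(missing, collapse = ", ")))
  }

  cp <- list(
    name = raw$name,
    mw = as.numeric(raw$mw),
    logp = as.numeric(raw$logp),
    solubility_mg_ml = raw$solubility_mg_ml %||% NA_real_,
    solubility_ph = raw$solubility_ph %||% NA_real_,
    pka = as.numeric(unlist(raw$pka %||% numeric())),
    fup = unlist(raw$fup),
    bpr = unlist(raw$bpr),
    spec_pstc = as.numeric(raw$spec_pstc)
  )
  validate_compound(cp)
  structure(cp, class = "pbpk_compound")
}

validate_compound <- function(cp) {
  bad <- character()
  if (!is.finite(cp$mw) || cp$mw <= 0) bad <- c(bad, "mw (must be > 0)")
  if (!is.finite(cp$logp)) bad <- c(bad, "logp (must be finite)")
  if (!is.finite(cp$spec_pstc) || cp$spec_pstc <= 0)
    bad <- c(bad, "spec_pstc (must be > 0)")
  if (!length(cp$fup) || any(!is.finite(cp$fup) | cp$fup <= 0 | cp$fup > 1))
    bad <- c(bad, "fup (all values must lie in (0, 1])")
  if (!length(cp$bpr) || any(!is.finite(cp$bpr) | cp$bpr <= 0))
    bad <- c(bad, "bpr (all values must be > 0)")
  if (length(bad)) {
    abort(paste0("Invalid compound parameters: ", paste(bad, collapse = "; ")))
  }
  invisible(cp)
}

#' Write a compound parameter set back to YAML
#'
#' Round-trips with [load_compound()]; used by the calibration stage to record
#' a fitted `spec_pstc` in an annotated config.
#'
#' @param compound A `pbpk_compound`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_compound <- function(compound, path) {
  stopifnot(inherits(compound, "pbpk_compound"))
  out <- list(
    name = compound$name,
    mw = compound$mw,
    logp = compound$logp,
    solubility_mg_ml = compound$solubility_mg_ml,
    solubility_ph = compound$solubility_ph,
    pka = as.list(compound$pka),
    fup = as.list(compound$fup),
    bpr = as.list(compound$bpr),
    spec_pstc = compound$spec_pstc
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

species_param <- function(compound, what = c("fup", "bpr"), species) {
  what <- match.arg(what)
  v <- compound[[what]]
  if (!species %in% names(v)) {
    abort(paste0("Compound ", compound$name, " has no ", what,
                 " entry for species '", species, "'."))
  }
  unname(v[[species]])
}

#' Path to a bundled example data file
#'
#' @param file Relative path under the package's `extdata/` directory, e.g.
#'   `"compounds/mtm.yaml"`. With no argument, lists the available files.
#' @return A file path (or a character vector of available files).
#' @export
mtmpbpk_example <- function(file = NULL) {
  base <- system.file("extdata", package = "mtmpbpk", mustWork = TRUE)
  if (is.null(file)) {
    return(list.files(base, recursive = TRUE))
  }
  path <- file.path(base, file)
  if (!file.exists(path)) abort(paste0("No bundled file '", file, "'."))
  path
}

#' @export
print.pbpk_compound <- function(x, ...) {
  cat(sprintf("<pbpk_compound> %s (MW %.1f, logP %.3f, SpecPStc %.3g mL/s/mL)\n",
              x$name, x$mw, x$logp, x$spec_pstc))
  cat("  fup:", paste(sprintf("%s=%.4g", names(x$fup), x$fup), collapse = ", "), "\n")
  cat("  bpr:", paste(sprintf("%s=%.4g", names(x$bpr), x$bpr), collapse = ", "), "\n")
  invisible(x)
}
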