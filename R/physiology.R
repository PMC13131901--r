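#' Load a bundled species physiology
#'
#' Returns the whole-body physiology for one of the four supported species:
#' mouse (0.025 kg), rat (0.25 kg), cynomolgus monkey (5 kg) and a
#' 13-year-old, 50-kg male human. Values are bundled from open literature
#' (Brown et al. 1997 fractional organ weights and flows; Davies & Morris 1993
#' cardiac output, blood volume and GFR compilations; tissue composition from
#' Poulin & Theil 2002) and are documented in the YAML data files shipped under
#' `inst/extdata/physiology/`.
#'
#' The model topology is fixed: the lung carries the full cardiac output in
#' series between the venous and arterial blood pools; the liver receives the
#' hepatic artery plus the portal outflow of gut and spleen; a rest-of-body
#' compartment closes the volume and flow balances, so the non-lung tissue
#' flows sum exactly to cardiac output.
#'
#' @param species One of `"mouse"`, `"rat"`, `"monkey"`, `"human"`.
#' @param body_weight Body weight in kg. Defaults to the bundled value; when
#'   overridden, tissue volumes, blood volume and cardiac output are scaled
#'   proportionally (GFR is left at its absolute bundled value).
#' @param overrides Optional named list of scalar overrides applied after
#'   loading (`cardiac_output_L_h`, `gfr_L_h`, `blood_volume_L`).
#'
#' @return An object of class `pbpk_physiology`: a list with scalars
#'   `species`, `body_weight_kg`, `cardiac_output_L_h`, `gfr_L_h`,
#'   `blood_volume_L`, a `plasma_composition` list and a `tissues` tibble with
#'   columns `tissue`, `flow_L_h`, `volume_L`, `ecf`, `f_nl`, `f_ph`, `f_w`.
#'
#' @examples
#' phys <- species_physiology("human")
#' phys$tissues
#' @export
species_physiology <- function(species, body_weight = NULL, overrides = NULL) {
  supported <- c("mouse", "rat", "monkey", "human")
  if (!is.character(species) || length(species) != 1L || !species %in% supported) {
    abort(paste0("Unknown species ", deparse(species),
                 "; supported species: ", paste(supported, collapse = ", ")))
  }
  path <- system.file("extdata", "physiology", paste0(species, ".yaml"),
                      package = "mtmpbpk", mustWork = TRUE)
  raw <- yaml::read_yaml(path)

  bw0 <- raw$body_weight_kg
  bw <- body_weight %||% bw0
  stopifnot(is.numeric(bw), bw > 0)
  scale <- bw / bw0

  tis <- purrr::map_dfr(raw$tissues, function(t) {
    tibble::tibble(
      tissue = t$name,
      flow_frac = t$flow_frac,
      volume_frac = t$volume_frac,
      ecf = t$ecf,
      f_nl = t$composition$neutral_lipid,
      f_ph = t$composition$phospholipid,
      f_w = t$composition$water
    )
  })

  phys <- list(
    species = raw$species,
    body_weight_kg = bw,
    cardiac_output_L_h = raw$cardiac_output_L_h * scale,
    gfr_L_h = raw$gfr_L_h,
    blood_volume_L = raw$blood_volume_L * scale,
    plasma_composition = list(
      f_nl = raw$plasma_composition$neutral_lipid,
      f_ph = raw$plasma_composition$phospholipid,
      f_w = raw$plasma_composition$water
    )
  )
  if (!is.null(overrides)) {
    bad <- setdiff(names(overrides),
                   c("cardiac_output_L_h", "gfr_L_h", "blood_volume_L"))
    if (length(bad)) abort(paste0("Unknown physiology overrides: ",
                                  paste(bad, collapse = ", ")))
    phys <- modifyList(phys, overrides)
  }

  tis <- dplyr::mutate(
    tis,
    flow_L_h = .data$flow_frac * phys$cardiac_output_L_h,
    volume_L = .data$volume_frac * bw  # tissue density 1 kg/L
  )
  phys$tissues <- dplyr::select(
    tis, "tissue", "flow_L_h", "volume_L", "ecf", "f_nl", "f_ph", "f_w")

  validate_physiology(phys)
  structure(phys, class = "pbpk_physiology")
}

validate_physiology <- function(phys) {
  tis <- phys$tissues
  num <- c(phys$body_weight_kg, phys$cardiac_output_L_h, phys$gfr_L_h,
           phys$blood_volume_L, tis$flow_L_h, tis$volume_L)
  if (!all(is.finite(num)) || any(num <= 0)) {
    abort("Physiology contains non-positive or non-finite volumes/flows.")
  }
  if (any(tis$ecf <= 0 | tis$ecf >= 1)) {
    abort("Extracellular fractions must lie in (0, 1).")
  }
  comp <- c(tis$f_nl, tis$f_ph, tis$f_w,
            unlist(phys$plasma_composition))
  if (any(comp < 0 | comp > 1)) {
    abort("Composition fractions must lie in [0, 1].")
  }
  nonlung <- tis$flow_L_h[tis$tissue != "lung"]
  rel <- sum(nonlung) / phys$cardiac_output_L_h
  if (abs(rel - 1) > 0.01) {
    abort(sprintf(
      "Non-lung tissue flows sum to %.3f x cardiac output (must be 1 +/- 0.01).",
      rel))
  }
  invisible(phys)
}

#' @export
print.pbpk_physiology <- function(x, ...) {
  cat(sprintf("<pbpk_physiology> %s, BW %.3g kg, CO %.3g L/h, GFR %.3g L/h, blood %.3g L\n",
              x$species, x$body_weight_kg, x$cardiac_output_L_h,
              x$gfr_L_h, x$blood_volume_L))
  print(x$tissues, n = Inf)
  invisible(x)
}
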