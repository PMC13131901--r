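#' Predict tissue-to-plasma partition coefficients (Poulin & Theil,
#' extracellular-protein variant)
#'
#' Implements the tissue-composition method of Poulin & Theil. For non-adipose
#' tissue
#' \deqn{Kp_t = \frac{P V_{nl,t} + (0.3P + 0.7) V_{ph,t} + V_{w,t}}
#'              {P V_{nl,p} + (0.3P + 0.7) V_{ph,p} + V_{w,p}}
#'       \times \frac{fu_p}{fu_t}}
#' with \eqn{P = 10^{logP}}, where the tissue unbound fraction is derived from
#' the plasma unbound fraction through the tissue-to-plasma extracellular
#' protein ratio \eqn{RA}:
#' \deqn{fu_t = 1 / (1 + RA (1 - fu_p)/fu_p).}
#' Adipose uses the method's adipose variant: the vegetable-oil/water partition
#' \eqn{D^* = 10^{1.115 logP - 1.35}} replaces \eqn{P} and \eqn{fu_t = 1}.
#'
#' `RA` is bundled per tissue (0.5 for all tissues, i.e. interstitial albumin
#' at about half the plasma concentration, except brain at 0.15 to reflect the
#' low protein content of brain interstitial fluid). Ionization (pKa) is not
#' used: the method as published uses logP.
#'
#' @param compound A `pbpk_compound` (see [load_compound()]).
#' @param physiology A `pbpk_physiology` (see [species_physiology()]); supplies
#'   tissue and plasma composition.
#' @param species Species label used to select `fup`.
#' @param logp,fup Optional overrides of the compound logP and species `fup`
#'   (used by the sensitivity analysis).
#' @return A tibble of class `pbpk_kpset` with columns `tissue`, `kp`, `fut`
#'   and attribute `method = "poulin-theil-extracellular"`.
#' @examples
#' mtm <- load_compound(mtmpbpk_example("compounds/mtm.yaml"))
#' predict_kp(mtm, species_physiology("human"), "human")
#' @export
predict_kp <- function(compound, physiology, species,
                       logp = NULL, fup = NULL) {
  stopifnot(inherits(compound, "pbpk_compound"),
            inherits(physiology, "pbpk_physiology"))
  logp <- logp %||% compound$logp
  fup <- fup %||% species_param(compound, "fup", species)
  if (!is.finite(fup) || fup <= 0 || fup > 1) {
    abort("fup must lie in (0, 1] for Kp prediction.")
  }

  tis <- physiology$tissues
  pl <- physiology$plasma_composition
  ra <- kp_protein_ratio(tis$tissue)

  P <- 10^logp
  Dstar <- 10^(1.115 * logp - 1.35)  # vegetable oil:water, adipose variant

  fut <- 1 / (1 + ra * (1 - fup) / fup)
  fut[tis$tissue == "adipose"] <- 1

  lip <- function(p, nl, ph, w) p * nl + (0.3 * p + 0.7) * ph + w
  num <- ifelse(tis$tissue == "adipose",
                Dstar * (tis$f_nl + 0.3 * tis$f_ph) + (tis$f_w + 0.7 * tis$f_ph),
                lip(P, tis$f_nl, tis$f_ph, tis$f_w))
  den <- ifelse(tis$tissue == "adipose",
                Dstar * (pl$f_nl + 0.3 * pl$f_ph) + (pl$f_w + 0.7 * pl$f_ph),
                lip(P, pl$f_nl, pl$f_ph, pl$f_w))
  kp <- num / den * fup / fut

  if (any(!is.finite(kp) | kp <= 0)) {
    abort("Kp prediction produced non-positive or non-finite values.")
  }
  out <- tibble::tibble(tissue = tis$tissue, kp = kp, fut = fut)
  attr(out, "method") <- "poulin-theil-extracellular"
  class(out) <- c("pbpk_kpset", class(out))
  out
}

# Tissue-to-plasma extracellular protein ratios (RA), bundled constants.
kp_protein_ratio <- function(tissues) {
  ra <- rep(0.5, length(tissues))
  ra[tissues == "brain"] <- 0.15
  ra
}
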