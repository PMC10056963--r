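#' qSIP physical constants
#'
#' The constants linking DNA buoyant density, GC content, nucleotide
#' molecular weight and maximal \eqn{^{18}}O substitution, shared by the
#' forward simulator and the EAF estimator so that round-trip
#' (simulate-then-estimate) checks are exact. Densities are g mL\eqn{^{-1}},
#' molecular weights g mol\eqn{^{-1}} per average nucleotide.
#'
#' @format A named list:
#' \describe{
#'   \item{density_intercept, density_slope}{unlabeled buoyant density
#'     \eqn{\rho = 1.646057 + 0.083506\,G} for GC content \eqn{G \in [0,1]}.}
#'   \item{mw_intercept, mw_slope}{light (unlabeled) molecular weight
#'     \eqn{M_{light} = 0.496\,G + 307.691}.}
#'   \item{mw_o18_gain}{\eqn{M_{heavymax} - M_{light} = 12.07747}, the mass
#'     gain of a fully \eqn{^{18}}O-substituted average nucleotide.}
#'   \item{natural_o18}{natural abundance of \eqn{^{18}}O (0.002000429),
#'     subtracted so EAF is excess over natural abundance.}
#'   \item{version}{constants-table version string, recorded in run
#'     manifests.}
#' }
#' @export
qsip_constants <- function() {
  list(
    density_intercept = 1.646057,
    density_slope     = 0.083506,
    mw_intercept      = 307.691,
    mw_slope          = 0.496,
    mw_o18_gain       = 12.07747,
    natural_o18       = 0.002000429,
    version           = "qsip-constants-1"
  )
}

#' GC content from unlabeled weighted average density
#'
#' Inverts the linear density-GC relation
#' \eqn{G = (W_{light} - 1.646057) / 0.083506}. Results outside \eqn{[0,1]}
#' are clamped and flagged with a warning rather than raising an error:
#' noisy light-tube WADs near the gradient edges routinely map slightly
#' outside the physical range.
#'
#' @param w_light numeric vector of unlabeled WADs (g mL^-1).
#' @return numeric vector of GC contents in \eqn{[0,1]}, with attribute
#'   `"clamped"` (logical vector) marking values that were out of range.
#' @export
gc_from_density <- function(w_light) {
  stopifnot(is.numeric(w_light))
  k <- qsip_constants()
  if (any(w_light < 1.64 | w_light > 1.76, na.rm = TRUE))
    warning("w_light outside the physically plausible range [1.64, 1.76]")
  g <- (w_light - k$density_intercept) / k$density_slope
  clamped <- !is.na(g) & (g < 0 | g > 1)
  if (any(clamped))
    warning(sum(clamped), " GC estimate(s) outside [0,1]; clamped")
  g <- pmin(pmax(g, 0), 1)
  attr(g, "clamped") <- clamped
  g
}

#' Unlabeled buoyant density from GC content
#'
#' @param gc numeric vector of GC contents in \eqn{[0,1]}.
#' @return unlabeled buoyant density (g mL^-1).
#' @export
density_from_gc <- function(gc) {
  stopifnot(is.numeric(gc), all(gc >= 0 & gc <= 1))
  k <- qsip_constants()
  k$density_intercept + k$density_slope * gc
}

#' Light and maximally heavy nucleotide molecular weights
#'
#' \eqn{M_{light} = 0.496\,G + 307.691};
#' \eqn{M_{heavymax} = M_{light} + 12.07747} (full \eqn{^{18}}O
#' substitution of the average nucleotide).
#'
#' @param gc GC content in \eqn{[0,1]}.
#' @return data.frame with columns `m_light`, `m_heavymax` (g mol^-1 per
#'   average nucleotide).
#' @export
molecular_weights <- function(gc) {
  stopifnot(is.numeric(gc))
  if (any(gc < 0 | gc > 1, na.rm = TRUE))
    stop("gc must lie in [0, 1]")
  k <- qsip_constants()
  m_light <- k$mw_slope * gc + k$mw_intercept
  data.frame(m_light = m_light, m_heavymax = m_light + k$mw_o18_gain)
}

#' Excess atom fraction 18O from a weighted-average-density shift
#'
#' Converts the shift in a taxon's weighted average density between a
#' labeled (\eqn{^{18}}O) tube and its unlabeled (\eqn{^{16}}O) reference
#' into the excess atom fraction of \eqn{^{18}}O in its DNA:
#' \deqn{M_{lab} = (\Delta W / W_{light} + 1)\, M_{light}, \quad
#'   EAF = \frac{M_{lab} - M_{light}}{M_{heavymax} - M_{light}}
#'         (1 - 0.002000429)}
#' with \eqn{\Delta W = W_{label} - W_{light}} and \eqn{M_{light}},
#' \eqn{M_{heavymax}} derived from the GC content implied by
#' \eqn{W_{light}}. The raw estimate may be negative; truncation at zero is
#' a downstream aggregation policy, not applied here.
#'
#' @param w_label labeled-tube WAD (g mL^-1).
#' @param w_light unlabeled-tube WAD (g mL^-1). Recycled against `w_label`.
#' @param gc optional GC content; defaults to [gc_from_density]`(w_light)`.
#' @return raw EAF (unitless), zero when `w_label == w_light`, strictly
#'   increasing in the density shift.
#' @seealso [wad_shift_from_eaf] for the inverse used by the simulator.
#' @export
eaf_from_wad_shift <- function(w_label, w_light, gc = NULL) {
  stopifnot(is.numeric(w_label), is.numeric(w_light), all(w_light > 0))
  k <- qsip_constants()
  if (is.null(gc)) gc <- suppressWarnings(gc_from_density(w_light))
  mw <- molecular_weights(as.numeric(gc))
  m_lab <- ((w_label - w_light) / w_light + 1) * mw$m_light
  (m_lab - mw$m_light) / (mw$m_heavymax - mw$m_light) * (1 - k$natural_o18)
}

#' Labeled buoyant density implied by a true EAF (simulator inverse)
#'
#' Round-trip inverse of [eaf_from_wad_shift]: given a taxon's GC content
#' and true EAF, returns the buoyant density its fully equilibrated DNA
#' attains in a labeled tube,
#' \eqn{\rho_{lab} = \rho_{light} \, M_{lab} / M_{light}}.
#'
#' @param eaf true excess atom fraction in \eqn{[0, 1)}.
#' @param gc GC content in \eqn{[0,1]}.
#' @return labeled buoyant density (g mL^-1).
#' @export
wad_shift_from_eaf <- function(eaf, gc) {
  stopifnot(is.numeric(eaf), all(eaf >= 0 & eaf < 1))
  k <- qsip_constants()
  mw <- molecular_weights(gc)
  m_lab <- mw$m_light + eaf / (1 - k$natural_o18) * (mw$m_heavymax - mw$m_light)
  density_from_gc(gc) * m_lab / mw$m_light
}
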