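#' @include energy-records.R
NULL

.checkGap <- function(eps_homo, eps_lumo) {
  stopifnot(is.finite(eps_homo), is.finite(eps_lumo))
  if (any(eps_homo >= eps_lumo))
    stop("precondition error: eps_homo must lie strictly below eps_lumo")
}

#' Global Conceptual-DFT reactivity descriptors
#'
#' Frontier-orbital (Koopmans-style) realizations of the global CDFT
#' descriptors, all in eV for eV inputs:
#' \describe{
#'   \item{electronegativity}{\eqn{\chi = -(\epsilon_H + \epsilon_L)/2},
#'     reported with the positive sign convention; the electronic chemical
#'     potential is \eqn{\mu = -\chi}.}
#'   \item{hardness}{\eqn{\eta = \epsilon_L - \epsilon_H}, the HOMO-LUMO
#'     gap; resistance to change in electron number.}
#'   \item{softness}{\eqn{S = 1/\eta} (eV^-1).}
#'   \item{electrophilicity}{\eqn{\omega = \chi^2/(2\eta) =
#'     (\epsilon_H+\epsilon_L)^2 / (8\eta)}, the stabilization on taking up
#'     electrons from an ideal reservoir.}
#'   \item{electrodonatingPower}{\eqn{\omega^- = (3\epsilon_H +
#'     \epsilon_L)^2 / (16\eta)}.}
#'   \item{electroacceptingPower}{\eqn{\omega^+ = (\epsilon_H +
#'     3\epsilon_L)^2 / (16\eta)}.}
#'   \item{netElectrophilicity}{\eqn{\Delta\omega^\pm = \omega^- +
#'     \omega^+}.}
#' }
#' The identities \eqn{\omega^- - \omega^+ = \chi} and
#' \eqn{S \cdot \eta = 1} hold algebraically.
#'
#' @param eps_homo,eps_lumo HOMO and LUMO energies (eV), vectorized, with
#'   \code{eps_homo < eps_lumo} strictly.
#' @return Numeric vector of descriptor values.
#' @examples
#' electronegativity(-6.24, -1.22)   # 3.73
#' electrophilicity(-6.24, -1.22)    # 1.3857...
#' @export
electronegativity <- function(eps_homo, eps_lumo) {
  .checkGap(eps_homo, eps_lumo)
  -(eps_homo + eps_lumo) / 2
}

#' @rdname electronegativity
#' @export
chemicalPotential <- function(eps_homo, eps_lumo)
  -electronegativity(eps_homo, eps_lumo)

#' @rdname electronegativity
#' @export
hardness <- function(eps_homo, eps_lumo) {
  .checkGap(eps_homo, eps_lumo)
  eps_lumo - eps_homo
}

#' @rdname electronegativity
#' @param eta Global hardness (eV), strictly positive.
#' @export
softness <- function(eta) {
  stopifnot(is.finite(eta))
  if (any(eta <= 0)) stop("domain error: hardness must be positive")
  1 / eta
}

#' @rdname electronegativity
#' @export
electrophilicity <- function(eps_homo, eps_lumo) {
  chi <- electronegativity(eps_homo, eps_lumo)
  chi^2 / (2 * hardness(eps_homo, eps_lumo))
}

#' @rdname electronegativity
#' @export
electrodonatingPower <- function(eps_homo, eps_lumo) {
  .checkGap(eps_homo, eps_lumo)
  (3 * eps_homo + eps_lumo)^2 / (16 * (eps_lumo - eps_homo))
}

#' @rdname electronegativity
#' @export
electroacceptingPower <- function(eps_homo, eps_lumo) {
  .checkGap(eps_homo, eps_lumo)
  (eps_homo + 3 * eps_lumo)^2 / (16 * (eps_lumo - eps_homo))
}

#' @rdname electronegativity
#' @param omega_minus,omega_plus Electrodonating and electroaccepting powers
#'   (eV), non-negative.
#' @export
netElectrophilicity <- function(omega_minus, omega_plus) {
  stopifnot(is.finite(omega_minus), is.finite(omega_plus),
            omega_minus >= 0, omega_plus >= 0)
  omega_minus + omega_plus
}

## ---------------------------------------------------------------------------
## Nucleophilicity index and its reference
## ---------------------------------------------------------------------------

#' Construct a nucleophilicity reference
#'
#' @param eps_homo_ref HOMO energy (eV) of the reference electrophile
#'   (tetracyanoethylene) at the working model chemistry.
#' @param provenance Free-text origin of the value.
#' @param residual_sd Calibration residual standard deviation (eV), if any.
#' @return A [NucleophilicityReference-class].
#' @export
nucleophilicityReference <- function(eps_homo_ref,
                                     provenance = "user-supplied",
                                     residual_sd = NA_real_) {
  new("NucleophilicityReference", epsHomoRef = as.numeric(eps_homo_ref),
      residualSd = as.numeric(residual_sd),
      provenance = as.character(provenance))
}

#' @export
setMethod("show", "NucleophilicityReference", function(object) {
  cat("NucleophilicityReference: eps_homo_ref =",
      format(object@epsHomoRef, digits = 6), "eV\n")
  cat("  provenance:", object@provenance, "\n")
  if (is.finite(object@residualSd))
    cat("  calibration residual sd:", format(object@residualSd, digits = 3),
        "eV\n")
  invisible(NULL)
})

#' Nucleophilicity index
#'
#' \eqn{N = \epsilon_H(\mathrm{molecule}) - \epsilon_H(\mathrm{reference})},
#' with tetracyanoethylene as the conventional reference electrophile. When
#' \code{ref} is \code{NULL} the packaged default is used, calibrated from
#' the apratoxin A-G reference table (see
#' [defaultNucleophilicityReference()]).
#'
#' @param eps_homo HOMO energies (eV), vectorized.
#' @param ref A [NucleophilicityReference-class], a single numeric reference
#'   HOMO energy (eV), or \code{NULL} for the packaged default.
#' @return Numeric vector of nucleophilicity indices (eV).
#' @export
nucleophilicity <- function(eps_homo, ref = NULL) {
  stopifnot(is.finite(eps_homo))
  if (is.null(ref)) ref <- defaultNucleophilicityReference()
  ref_val <- if (is(ref, "NucleophilicityReference")) ref@epsHomoRef
             else as.numeric(ref)
  stopifnot(length(ref_val) == 1L, is.finite(ref_val))
  eps_homo - ref_val
}

#' Calibrate the nucleophilicity reference from printed index values
#'
#' Given molecules whose HOMO energies and published nucleophilicity indices
#' are both known, the reference HOMO energy is recovered as the mean of
#' \code{eps_homo - n_printed} (the least-squares solution for a pure offset
#' model); the residual standard deviation is recorded as a calibration
#' quality measure.
#'
#' @param eps_homo HOMO energies (eV) of the calibration molecules.
#' @param n_printed Their published nucleophilicity indices (eV).
#' @param provenance Free-text origin recorded on the result.
#' @return A [NucleophilicityReference-class].
#' @export
calibrateNucleophilicityReference <- function(eps_homo, n_printed,
                                              provenance = "calibrated") {
  stopifnot(length(eps_homo) == length(n_printed))
  if (!length(eps_homo))
    stop("precondition error: at least one calibration pair is required")
  stopifnot(is.finite(eps_homo), is.finite(n_printed))
  diffs <- eps_homo - n_printed
  sd_val <- if (length(diffs) > 1L) stats::sd(diffs) else 0
  nucleophilicityReference(mean(diffs), provenance = provenance,
                           residual_sd = sd_val)
}

## ---------------------------------------------------------------------------
## Classification scales
## ---------------------------------------------------------------------------

.CLASS_LEVELS <- c("strong", "moderate", "marginal")

#' Electrophile / nucleophile classification scales
#'
#' \code{classifyElectrophile} applies the Diels-Alder-derived
#' electrophilicity scale: strong for \eqn{\omega > 1.5} eV, moderate for
#' \eqn{0.8 < \omega \le 1.5} eV, marginal otherwise. The published scale
#' uses strict inequalities on both sides and leaves the boundary points
#' unassigned; here each boundary value is assigned to the weaker class
#' (1.5 to moderate, 0.8 to marginal), configurable via the threshold
#' arguments.
#'
#' \code{classifyNucleophile} applies the polar-organic-reaction scale:
#' strong for \eqn{N > 3} eV, moderate for \eqn{2 \le N \le 3} eV (closed
#' boundaries, as published), marginal for \eqn{N < 2} eV.
#'
#' @param omega Electrophilicity indices (eV), non-negative.
#' @param n Nucleophilicity indices (eV).
#' @param strong,moderate Class boundaries (eV).
#' @return Factor with levels \code{strong}, \code{moderate},
#'   \code{marginal}.
#' @examples
#' classifyElectrophile(c(1.39, 1.81, 0.5))
#' classifyNucleophile(c(2.56, 3.5, 2.0))
#' @export
classifyElectrophile <- function(omega, strong = 1.5, moderate = 0.8) {
  stopifnot(is.finite(omega))
  if (any(omega < 0)) stop("domain error: omega must be non-negative")
  out <- ifelse(omega > strong, "strong",
                ifelse(omega > moderate, "moderate", "marginal"))
  factor(out, levels = .CLASS_LEVELS)
}

#' @rdname classifyElectrophile
#' @export
classifyNucleophile <- function(n, strong = 3.0, moderate = 2.0) {
  stopifnot(is.finite(n))
  out <- ifelse(n > strong, "strong",
                ifelse(n >= moderate, "moderate", "marginal"))
  factor(out, levels = .CLASS_LEVELS)
}

## ---------------------------------------------------------------------------
## Batch computation
## ---------------------------------------------------------------------------

#' Compute every global descriptor for a set of molecules
#'
#' One-stop evaluation of the full global-descriptor panel (see
#' [electronegativity()]) plus electrophile/nucleophile class labels, one
#' row per record, columns ordered as in the standard reactivity table
#' (\eqn{\chi}, \eqn{\eta}, \eqn{\omega}, S, N, \eqn{\omega^-},
#' \eqn{\omega^+}, \eqn{\Delta\omega^\pm}) with the chemical potential
#' \eqn{\mu} carried alongside. Values are unrounded; rounding for display
#' is the pipeline's job.
#'
#' @param records An [EnergyRecordSet-class].
#' @param ref Nucleophilicity reference (see [nucleophilicity()]);
#'   \code{NULL} for the packaged default.
#' @param ... Unused; reserved.
#' @return \code{data.frame} with columns \code{id}, \code{chi}, \code{eta},
#'   \code{omega}, \code{softness}, \code{nucleophilicity},
#'   \code{omega_minus}, \code{omega_plus}, \code{net_electrophilicity},
#'   \code{mu}, \code{electrophile_class}, \code{nucleophile_class}.
#' @examples
#' computeGlobalDescriptors(apratoxinFixture())
#' @export
setMethod("computeGlobalDescriptors", "EnergyRecordSet",
          function(records, ref = NULL, ...) {
  df <- records@data
  if (!nrow(df))
    return(data.frame(id = character(0), chi = numeric(0), eta = numeric(0),
                      omega = numeric(0), softness = numeric(0),
                      nucleophilicity = numeric(0), omega_minus = numeric(0),
                      omega_plus = numeric(0),
                      net_electrophilicity = numeric(0), mu = numeric(0),
                      electrophile_class = factor(character(0),
                                                  levels = .CLASS_LEVELS),
                      nucleophile_class = factor(character(0),
                                                 levels = .CLASS_LEVELS),
                      stringsAsFactors = FALSE))
  h <- df$eps_homo; l <- df$eps_lumo
  chi <- electronegativity(h, l)
  eta <- hardness(h, l)
  omega <- electrophilicity(h, l)
  wminus <- electrodonatingPower(h, l)
  wplus <- electroacceptingPower(h, l)
  nuc <- nucleophilicity(h, ref)
  data.frame(id = df$id, chi = chi, eta = eta, omega = omega,
             softness = softness(eta), nucleophilicity = nuc,
             omega_minus = wminus, omega_plus = wplus,
             net_electrophilicity = netElectrophilicity(wminus, wplus),
             mu = -chi,
             electrophile_class = classifyElectrophile(omega),
             nucleophile_class = classifyNucleophile(nuc),
             stringsAsFactors = FALSE)
})
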