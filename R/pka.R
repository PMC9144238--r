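#' Hardness-based pKa QSAR
#'
#' A linear quantitative structure-activity relationship linking acidity to
#' global hardness, \eqn{\mathrm{p}K_a = a - b\,\eta}, with default
#' coefficients \eqn{a = 16.3088} and \eqn{b = 0.8268} pKa units per eV
#' (fitted on amino acids and short peptides). \code{pkaModel} builds a
#' coefficient container; \code{pkaFromHardness} evaluates the relation for
#' strictly positive hardness.
#'
#' The relation is affine and strictly decreasing in \eqn{\eta}:
#' \code{pka(eta1) - pka(eta2) == -slope * (eta1 - eta2)} exactly.
#'
#' @param eta Global hardness (eV), strictly positive; vectorized.
#' @param model Coefficient list from \code{pkaModel()}.
#' @param intercept,slope QSAR coefficients (pKa units; pKa per eV).
#' @return \code{pkaFromHardness}: numeric vector of predicted pKa values.
#' @examples
#' pkaFromHardness(5.02)   # 12.158...
#' @export
pkaFromHardness <- function(eta, model = pkaModel()) {
  stopifnot(is.finite(eta))
  if (any(eta <= 0)) stop("domain error: hardness must be positive")
  model$intercept - model$slope * eta
}

#' @rdname pkaFromHardness
#' @export
pkaModel <- function(intercept = 16.3088, slope = 0.8268) {
  stopifnot(is.finite(intercept), is.finite(slope),
            length(intercept) == 1L, length(slope) == 1L)
  structure(list(intercept = intercept, slope = slope), class = "pkaModel")
}

#' @export
print.pkaModel <- function(x, ...) {
  cat(sprintf("pKa QSAR: pKa = %.4f - %.4f * eta(eV)\n",
              x$intercept, x$slope))
  invisible(x)
}
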