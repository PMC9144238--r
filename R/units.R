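## CODATA 2018 value; fixed so that unit conversion is a bit-stable bijection.
.HARTREE_EV <- 27.211386245988

#' Energy unit conversion
#'
#' Convert between hartree (atomic units) and electron-volts using the fixed
#' factor 27.211386245988 eV per hartree. All energies inside the package are
#' carried in eV; hartree is accepted on input only.
#'
#' @param x Numeric vector of energies.
#' @return Numeric vector of the same length in the target unit.
#' @examples
#' hartreeToEV(-0.22930)   # approximately -6.2396 eV
#' evToHartree(hartreeToEV(1.5)) == 1.5
#' @export
hartreeToEV <- function(x) x * .HARTREE_EV

#' @rdname hartreeToEV
#' @export
evToHartree <- function(x) x / .HARTREE_EV
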