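#' @include cube-io.R
NULL

#' Construct a DensityTriplet
#'
#' @param rho_nm1,rho_n,rho_np1 [ScalarField-class] electron densities of
#'   the N-1, N and N+1 electron systems on an identical grid.
#' @return A validated [DensityTriplet-class].
#' @export
densityTriplet <- function(rho_nm1, rho_n, rho_np1) {
  new("DensityTriplet", rhoNm1 = rho_nm1, rhoN = rho_n, rhoNp1 = rho_np1)
}

#' @export
setMethod("show", "DensityTriplet", function(object) {
  d <- dim(object@rhoN@values)
  cat("DensityTriplet on a ", d[1], " x ", d[2], " x ", d[3], " grid\n",
      sep = "")
  cat("  integrals (N-1, N, N+1):",
      format(c(fieldIntegral(object@rhoNm1), fieldIntegral(object@rhoN),
               fieldIntegral(object@rhoNp1)), digits = 8), "\n")
  invisible(NULL)
})

#' Finite-difference Fukui functions and the dual descriptor
#'
#' The Fukui function measures the density response to a change in electron
#' number at frozen geometry and external potential. With densities of the
#' N-1, N and N+1 electron systems on a common grid, the one-sided
#' finite-difference realizations are
#' \deqn{f^+(r) = \rho_{N+1}(r) - \rho_N(r)}
#' \deqn{f^-(r) = \rho_N(r) - \rho_{N-1}(r)}
#' and the dual descriptor, the second difference
#' \deqn{\Delta f(r) = f^+(r) - f^-(r)
#'       = \rho_{N+1}(r) - 2\rho_N(r) + \rho_{N-1}(r),}
#' is positive where the molecule is prone to nucleophilic attack
#' (electrophilic sites) and negative where it is prone to electrophilic
#' attack (nucleophilic sites). For exactly normalized input densities,
#' \eqn{\int f^+ = \int f^- = 1} and \eqn{\int \Delta f = 0} on the grid
#' quadrature. Output fields carry the input grid header unchanged.
#'
#' @param triplet A [DensityTriplet-class].
#' @return A [ScalarField-class] on the same grid.
#' @seealso [condensedDual()], [signPartition()], [fieldIntegral()]
#' @export
setMethod("fukuiPlus", "DensityTriplet", function(triplet)
  triplet@rhoNp1 - triplet@rhoN)

#' @rdname fukuiPlus-DensityTriplet-method
#' @export
setMethod("fukuiMinus", "DensityTriplet", function(triplet)
  triplet@rhoN - triplet@rhoNm1)

#' @rdname fukuiPlus-DensityTriplet-method
#' @export
setMethod("dualDescriptor", "DensityTriplet", function(triplet) {
  out <- triplet@rhoN
  out@values <- triplet@rhoNp1@values - 2 * triplet@rhoN@values +
    triplet@rhoNm1@values
  out
})

#' Condensed (per-atom) dual descriptor
#'
#' Second difference of per-atom electron populations across the N-1, N and
#' N+1 electron states: for atom k,
#' \eqn{\Delta f_k = p_k(N+1) - 2 p_k(N) + p_k(N-1)}. The populations may
#' come from any charge-partitioning scheme (Hirshfeld, Mulliken, NPA, ...);
#' no partitioning is performed here. When each state's populations sum to
#' its electron count, the condensed values sum to zero.
#'
#' @param populations A \code{data.frame} or matrix with columns
#'   \code{p_nm1}, \code{p_n}, \code{p_np1} (electrons per atom per state),
#'   or three equal-length vectors via \code{p_nm1}, \code{p_n},
#'   \code{p_np1}.
#' @param p_nm1,p_n,p_np1 Per-atom populations, used when
#'   \code{populations} is missing.
#' @return Numeric vector of per-atom condensed dual-descriptor values.
#' @examples
#' condensedDual(p_nm1 = c(0.5, 0.5), p_n = c(1, 1), p_np1 = c(1.8, 1.2))
#' @export
condensedDual <- function(populations = NULL, p_nm1 = NULL, p_n = NULL,
                          p_np1 = NULL) {
  if (!is.null(populations)) {
    populations <- as.data.frame(populations)
    need <- c("p_nm1", "p_n", "p_np1")
    if (!all(need %in% names(populations)))
      stop("populations needs columns: ", paste(need, collapse = ", "))
    p_nm1 <- populations$p_nm1
    p_n <- populations$p_n
    p_np1 <- populations$p_np1
  }
  if (length(p_nm1) != length(p_n) || length(p_n) != length(p_np1))
    stop("validation error: atom counts differ across states (",
         length(p_nm1), ", ", length(p_n), ", ", length(p_np1), ")")
  stopifnot(is.finite(p_nm1), is.finite(p_n), is.finite(p_np1))
  p_np1 - 2 * p_n + p_nm1
}

#' Split a field into its positive and negative parts
#'
#' Mirrors the conventional rendering of the dual descriptor as separate
#' lobes: the first returned field keeps values strictly above
#' \code{+isovalue} (zero elsewhere), the second keeps values strictly below
#' \code{-isovalue}. With \code{isovalue = 0} the two parts plus the
#' residual (here exactly zero outside the kept regions) reconstruct the
#' original field.
#'
#' @param field A [ScalarField-class].
#' @param isovalue Non-negative threshold (default 0).
#' @return Named list with [ScalarField-class] elements \code{positive} and
#'   \code{negative}, both on the input grid.
#' @export
signPartition <- function(field, isovalue = 0) {
  stopifnot(is(field, "ScalarField"), length(isovalue) == 1L,
            is.finite(isovalue))
  if (isovalue < 0) stop("domain error: isovalue must be non-negative")
  pos <- neg <- field
  pos@values <- ifelse(field@values > isovalue, field@values, 0)
  neg@values <- ifelse(field@values < -isovalue, field@values, 0)
  dim(pos@values) <- dim(field@values)
  dim(neg@values) <- dim(field@values)
  list(positive = pos, negative = neg)
}

#' Integrate a field over its grid
#'
#' Riemann quadrature: the sum of voxel values times the voxel volume (the
#' determinant of the axes matrix). For an electron density this returns
#' the electron count; the quadrature is linear in the field.
#'
#' @param x A [ScalarField-class].
#' @return A single number (electrons, for densities in electrons/bohr^3).
#' @export
setMethod("fieldIntegral", "ScalarField", function(x)
  sum(x@values) * det(x@axes))

#' Export dual-descriptor lobes as a cube-file pair
#'
#' Convenience wrapper around [dualDescriptor()], [signPartition()] and
#' [writeCube()]: writes \code{<stem>.ddpos.cube} (values > isovalue) and
#' \code{<stem>.ddneg.cube} (values < -isovalue), ready for any cube-aware
#' viewer.
#'
#' @param triplet A [DensityTriplet-class].
#' @param stem Output path stem.
#' @param isovalue Non-negative partition threshold (default 0).
#' @return Invisibly, the two file paths.
#' @export
writeDualDescriptorCubes <- function(triplet, stem, isovalue = 0) {
  dd <- dualDescriptor(triplet)
  parts <- signPartition(dd, isovalue)
  paths <- paste0(stem, c(".ddpos.cube", ".ddneg.cube"))
  writeCube(parts$positive, paths[1],
            comments = c("dual descriptor, positive part",
                         sprintf("isovalue %g", isovalue)))
  writeCube(parts$negative, paths[2],
            comments = c("dual descriptor, negative part",
                         sprintf("isovalue %g", isovalue)))
  invisible(paths)
}
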