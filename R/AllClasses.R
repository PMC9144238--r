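#' @import methods
NULL

## ---------------------------------------------------------------------------
## EnergyRecordSet
## ---------------------------------------------------------------------------

.RECORD_COLUMNS <- c("id", "label", "eps_homo", "eps_lumo", "eps_somo_anion",
                     "e_gs_nm1", "e_gs_n", "e_gs_np1")

#' Per-molecule frontier-orbital and ground-state energies
#'
#' An \code{EnergyRecordSet} holds one row per molecule with the neutral
#' system's HOMO and LUMO energies, optionally the SOMO energy of the radical
#' anion (the HOMO of the N+1 electron system), and optionally the
#' ground-state total energies of the N-1, N and N+1 electron systems.
#' All energies are stored in eV.
#'
#' Validity requires finite \code{eps_homo < eps_lumo} strictly for every
#' record and unique, non-empty ids. The three ground-state energies may be
#' absent (\code{NA}); the KID operations additionally require all three to be
#' present before any compliance descriptor is computed.
#'
#' @slot data A \code{data.frame} with columns \code{id}, \code{label},
#'   \code{eps_homo}, \code{eps_lumo}, \code{eps_somo_anion},
#'   \code{e_gs_nm1}, \code{e_gs_n}, \code{e_gs_np1} and \code{source}.
#' @seealso [energyRecords()], [readEnergyRecords()], [apratoxinFixture()]
#' @export
setClass("EnergyRecordSet", slots = c(data = "data.frame"))

setValidity("EnergyRecordSet", function(object) {
  df <- object@data
  missing_cols <- setdiff(c(.RECORD_COLUMNS, "source"), names(df))
  if (length(missing_cols))
    return(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  if (nrow(df) == 0L) return(TRUE)
  if (anyNA(df$id) || any(!nzchar(df$id)))
    return("every record needs a non-empty id")
  if (anyDuplicated(df$id))
    return("record ids must be unique")
  num_cols <- setdiff(.RECORD_COLUMNS, c("id", "label"))
  for (col in num_cols) {
    if (!is.numeric(df[[col]]))
      return(paste0("column '", col, "' must be numeric"))
    if (any(is.infinite(df[[col]])))
      return(paste0("column '", col, "' contains non-finite energies"))
  }
  if (anyNA(df$eps_homo) || anyNA(df$eps_lumo))
    return("eps_homo and eps_lumo are mandatory for every record")
  bad <- df$eps_homo >= df$eps_lumo
  if (any(bad))
    return(paste0("eps_homo must lie strictly below eps_lumo; violated by: ",
                  paste(df$id[bad], collapse = ", ")))
  TRUE
})

## ---------------------------------------------------------------------------
## ScalarField
## ---------------------------------------------------------------------------

#' Volumetric scalar field on a voxel grid
#'
#' A \code{ScalarField} carries an electron density (or a field derived from
#' one, such as a Fukui function or the dual descriptor) sampled on a regular
#' parallelepiped grid, together with the grid origin, the three voxel step
#' vectors, and the molecular frame (atom list). This mirrors the content of
#' a Gaussian cube file: positions and steps are in bohr, densities in
#' electrons per bohr^3.
#'
#' @slot origin Numeric length-3 grid origin (bohr).
#' @slot axes 3 x 3 numeric matrix; row i is the step vector of grid axis i
#'   (bohr). The determinant (the signed voxel volume) must be positive.
#' @slot atoms \code{data.frame} with columns \code{number} (atomic number),
#'   \code{charge} (nuclear charge) and \code{x}, \code{y}, \code{z} (bohr);
#'   at least one atom is required so that emitted cube files are standard.
#' @slot values 3-d numeric array of voxel values; \code{dim(values)} gives
#'   the point counts along the three axes. In cube-file order the first axis
#'   is the slowest-varying and the third the fastest.
#' @seealso [readCube()], [writeCube()], [fieldIntegral()]
#' @export
setClass("ScalarField",
         slots = c(origin = "numeric", axes = "matrix",
                   atoms = "data.frame", values = "array"))

setValidity("ScalarField", function(object) {
  if (length(object@origin) != 3L || !is.numeric(object@origin) ||
      anyNA(object@origin))
    return("origin must be a finite numeric 3-vector")
  if (!all(dim(object@axes) == c(3L, 3L)) || !is.numeric(object@axes) ||
      anyNA(object@axes))
    return("axes must be a finite numeric 3 x 3 matrix")
  if (det(object@axes) <= 0)
    return("voxel volume (determinant of the axes matrix) must be positive")
  d <- dim(object@values)
  if (length(d) != 3L || any(d < 1L))
    return("values must be a 3-d array with all extents >= 1")
  if (!is.numeric(object@values) || anyNA(object@values))
    return("values must be finite numerics")
  need <- c("number", "charge", "x", "y", "z")
  if (!all(need %in% names(object@atoms)))
    return(paste0("atoms needs columns: ", paste(need, collapse = ", ")))
  if (nrow(object@atoms) < 1L)
    return("at least one atom is required")
  TRUE
})

## ---------------------------------------------------------------------------
## DensityTriplet
## ---------------------------------------------------------------------------

#' Electron densities of the N-1, N and N+1 electron states
#'
#' The carrier for finite-difference local reactivity math: three
#' non-negative [ScalarField-class] densities of the same molecule evaluated
#' at frozen geometry with one electron removed, the neutral count, and one
#' electron added. All three grids must agree exactly in origin, axes, point
#' counts and atom list.
#'
#' @slot rhoNm1,rhoN,rhoNp1 [ScalarField-class] densities of the N-1, N and
#'   N+1 electron systems.
#' @seealso [fukuiPlus()], [fukuiMinus()], [dualDescriptor()],
#'   [generateDensityTriplet()]
#' @export
setClass("DensityTriplet",
         slots = c(rhoNm1 = "ScalarField", rhoN = "ScalarField",
                   rhoNp1 = "ScalarField"))

## Names of the header fields that differ between two fields, character(0)
## when the geometries match exactly.
.geometryMismatch <- function(a, b) {
  out <- character(0)
  if (!identical(dim(a@values), dim(b@values))) out <- c(out, "counts")
  if (!identical(a@origin, b@origin)) out <- c(out, "origin")
  if (!identical(a@axes, b@axes)) out <- c(out, "axes")
  if (!isTRUE(all.equal(a@atoms, b@atoms, check.attributes = FALSE)))
    out <- c(out, "atoms")
  out
}

setValidity("DensityTriplet", function(object) {
  for (other in c("rhoNm1", "rhoNp1")) {
    bad <- .geometryMismatch(object@rhoN, slot(object, other))
    if (length(bad))
      return(paste0("geometry mismatch between rhoN and ", other, ": ",
                    paste(bad, collapse = ", ")))
  }
  if (min(object@rhoNm1@values) < 0 || min(object@rhoN@values) < 0 ||
      min(object@rhoNp1@values) < 0)
    return("densities must be non-negative everywhere")
  TRUE
})

## ---------------------------------------------------------------------------
## NucleophilicityReference
## ---------------------------------------------------------------------------

#' Reference electrophile for the nucleophilicity index
#'
#' The nucleophilicity index N of a molecule is its HOMO energy minus the
#' HOMO energy of a reference electrophile (conventionally
#' tetracyanoethylene) computed at the same model chemistry. The reference
#' value depends on the model chemistry and is therefore an explicit,
#' calibratable object rather than a constant.
#'
#' @slot epsHomoRef HOMO energy of the reference electrophile (eV).
#' @slot residualSd Standard deviation of the calibration residuals (eV);
#'   \code{NA} when the reference was supplied rather than calibrated.
#' @slot provenance Free-text origin of the value.
#' @seealso [nucleophilicityReference()],
#'   [calibrateNucleophilicityReference()]
#' @export
setClass("NucleophilicityReference",
         slots = c(epsHomoRef = "numeric", residualSd = "numeric",
                   provenance = "character"))

setValidity("NucleophilicityReference", function(object) {
  if (length(object@epsHomoRef) != 1L || !is.finite(object@epsHomoRef))
    return("epsHomoRef must be a single finite energy (eV)")
  TRUE
})
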