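#' @include AllClasses.R
NULL

#' @export
setGeneric("recordData", function(x) standardGeneric("recordData"))
#' @export
setGeneric("recordIds", function(x) standardGeneric("recordIds"))
#' @export
setGeneric("epsHOMO", function(x) standardGeneric("epsHOMO"))
#' @export
setGeneric("epsLUMO", function(x) standardGeneric("epsLUMO"))
#' @export
setGeneric("epsSOMOAnion", function(x) standardGeneric("epsSOMOAnion"))
#' @export
setGeneric("groundStateEnergies", function(x) standardGeneric("groundStateEnergies"))

#' @export
setGeneric("gridCounts", function(x) standardGeneric("gridCounts"))
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))
#' @export
setGeneric("gridAxes", function(x) standardGeneric("gridAxes"))
#' @export
setGeneric("gridAtoms", function(x) standardGeneric("gridAtoms"))
#' @export
setGeneric("fieldValues", function(x) standardGeneric("fieldValues"))
#' @export
setGeneric("voxelVolume", function(x) standardGeneric("voxelVolume"))
#' @export
setGeneric("fieldIntegral", function(x) standardGeneric("fieldIntegral"))

#' @export
setGeneric("fukuiPlus", function(triplet) standardGeneric("fukuiPlus"))
#' @export
setGeneric("fukuiMinus", function(triplet) standardGeneric("fukuiMinus"))
#' @export
setGeneric("dualDescriptor", function(triplet) standardGeneric("dualDescriptor"))

#' @export
setGeneric("computeJI", function(records) standardGeneric("computeJI"))
#' @export
setGeneric("computeJA", function(records) standardGeneric("computeJA"))
#' @export
setGeneric("computeDeltaSL", function(records) standardGeneric("computeDeltaSL"))
#' @export
setGeneric("kidAssess", function(records, tolerance = 0.15)
  standardGeneric("kidAssess"))

#' @export
setGeneric("computeGlobalDescriptors", function(records, ref = NULL, ...)
  standardGeneric("computeGlobalDescriptors"))
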