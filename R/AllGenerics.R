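#' @export
setGeneric("imageData", function(x) standardGeneric("imageData"))

#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @export
setGeneric("imageOrigin", function(x) standardGeneric("imageOrigin"))

#' @export
setGeneric("porosity", function(x) standardGeneric("porosity"))

#' @export
setGeneric("solidMask", function(x) standardGeneric("solidMask"))

#' @export
setGeneric("viscousResistance", function(x) standardGeneric("viscousResistance"))

#' @export
setGeneric("inertialResistance", function(x) standardGeneric("inertialResistance"))

#' @export
setGeneric("meshVertices", function(x) standardGeneric("meshVertices"))

#' @export
setGeneric("meshTriangles", function(x) standardGeneric("meshTriangles"))

#' @export
setGeneric("meshArea", function(x) standardGeneric("meshArea"))

#' @export
setGeneric("meshVolume", function(x) standardGeneric("meshVolume"))

#' @export
setGeneric("isWatertight", function(x) standardGeneric("isWatertight"))

#' @export
setGeneric("sweepTable", function(x) standardGeneric("sweepTable"))

#' @export
setGeneric("speedField", function(x) standardGeneric("speedField"))
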