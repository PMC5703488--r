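#' @name fabricmap-generics
#' @title Generics for fabricmap classes
#' @description Accessor and analysis generics used across the package.
#' @param object,x an object.
#' @param ... further arguments passed to methods.
NULL

#' @rdname fabricmap-generics
#' @export
setGeneric("voxelSpacing", function(object) standardGeneric("voxelSpacing"))

#' @rdname fabricmap-generics
#' @export
setGeneric("imageOrigin", function(object) standardGeneric("imageOrigin"))

#' @rdname fabricmap-generics
#' @export
setGeneric("tensorMatrix", function(object) standardGeneric("tensorMatrix"))

#' @rdname fabricmap-generics
#' @export
setGeneric("fabricEigenvalues",
           function(object) standardGeneric("fabricEigenvalues"))

#' @rdname fabricmap-generics
#' @export
setGeneric("fabricEigenvectors",
           function(object) standardGeneric("fabricEigenvectors"))

#' @rdname fabricmap-generics
#' @export
setGeneric("degreeOfAnisotropy",
           function(object) standardGeneric("degreeOfAnisotropy"))

#' @rdname fabricmap-generics
#' @param degeneracyTol relative gap `(m3 - m2)/m3` below which the principal
#'   direction is flagged degenerate.
#' @export
setGeneric("principalDirection",
           function(object, degeneracyTol = 1e-6)
             standardGeneric("principalDirection"))

#' @rdname fabricmap-generics
#' @export
setGeneric("transformChain", function(object) standardGeneric("transformChain"))

#' @rdname fabricmap-generics
#' @export
setGeneric("controlPoints", function(object) standardGeneric("controlPoints"))

#' @rdname fabricmap-generics
#' @export
setGeneric("fieldTensors", function(object) standardGeneric("fieldTensors"))

#' @rdname fabricmap-generics
#' @export
setGeneric("fieldBVTV", function(object) standardGeneric("fieldBVTV"))
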