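#' @rdname ShgImage-class
#' @param object,x an object of the documented class.
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))

#' @rdname ShgImage-class
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))

#' @rdname ShgImage-class
#' @export
setGeneric("zStep", function(object) standardGeneric("zStep"))

#' @rdname FiberMask-class
#' @export
setGeneric("maskArray", function(object) standardGeneric("maskArray"))

#' @rdname FcmResult-class
#' @export
setGeneric("centroids", function(object) standardGeneric("centroids"))

#' @rdname FcmResult-class
#' @export
setGeneric("membership", function(object) standardGeneric("membership"))

#' Maximum-intensity projection
#'
#' Collapses a z-stack to a 2D field of view by taking, at every (y, x)
#' position, the maximum intensity (or mask union) over z. 2D inputs are
#' returned unchanged.
#'
#' @param object an [ShgImage-class] or [FiberMask-class].
#' @return an object of the same class, 2D.
#' @export
setGeneric("maxProject", function(object) standardGeneric("maxProject"))
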