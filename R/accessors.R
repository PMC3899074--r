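## Accessor generics and methods.  Slot access from user code should go
## through these rather than @.

#' @rdname accessors
#' @param object an object of the documented class.
#' @export
setGeneric("rfSamples", function(object) standardGeneric("rfSamples"))

#' Accessors for susi classes
#'
#' \code{rfSamples} returns the raw 3D RF array; \code{acqGrid} and
#' \code{transducer} the acquisition metadata; \code{scanKind} the
#' sample/reference flag; \code{analysisBand} the transducer -6 dB band in
#' MHz and \code{bandCenter} its midpoint (the frequency at which the
#' mid-band fit is evaluated); \code{thickness}, \code{soundSpeed} and
#' \code{attenuation} the bulk properties.
#'
#' @name accessors
#' @rdname accessors
#' @export
setMethod("rfSamples", "RFVolume", function(object) object@samples)

#' @rdname accessors
#' @export
setGeneric("acqGrid", function(object) standardGeneric("acqGrid"))

#' @rdname accessors
#' @export
setMethod("acqGrid", "RFVolume", function(object) object@grid)

#' @rdname accessors
#' @export
setGeneric("transducer", function(object) standardGeneric("transducer"))

#' @rdname accessors
#' @export
setMethod("transducer", "RFVolume", function(object) object@transducer)

#' @rdname accessors
#' @export
setGeneric("scanKind", function(object) standardGeneric("scanKind"))

#' @rdname accessors
#' @export
setMethod("scanKind", "RFVolume", function(object) object@kind)

#' @rdname accessors
#' @export
setGeneric("analysisBand", function(object) standardGeneric("analysisBand"))

#' @rdname accessors
#' @export
setMethod("analysisBand", "TransducerSpec",
          function(object) c(object@bandLow, object@bandHigh))

#' @rdname accessors
#' @export
setMethod("analysisBand", "RFVolume",
          function(object) analysisBand(object@transducer))

#' @rdname accessors
#' @export
setGeneric("bandCenter", function(object) standardGeneric("bandCenter"))

#' @rdname accessors
#' @export
setMethod("bandCenter", "TransducerSpec",
          function(object) mean(analysisBand(object)))

#' @rdname accessors
#' @export
setGeneric("thickness", function(object) standardGeneric("thickness"))

#' @rdname accessors
#' @export
setMethod("thickness", "BulkProperties", function(object) object@thickness)

#' @rdname accessors
#' @export
setGeneric("soundSpeed", function(object) standardGeneric("soundSpeed"))

#' @rdname accessors
#' @export
setMethod("soundSpeed", "BulkProperties", function(object) object@soundSpeed)

#' @rdname accessors
#' @export
setGeneric("attenuation", function(object) standardGeneric("attenuation"))

#' @rdname accessors
#' @export
setMethod("attenuation", "BulkProperties", function(object) object@attenuation)

#' @rdname accessors
#' @export
setGeneric("bmodeValues", function(object) standardGeneric("bmodeValues"))

#' @rdname accessors
#' @export
setMethod("bmodeValues", "BModeImage", function(object) object@values)

#' @rdname accessors
#' @export
setGeneric("mapValues", function(object) standardGeneric("mapValues"))

#' @rdname accessors
#' @export
setMethod("mapValues", "ParametricMap", function(object) object@values)

#' @rdname accessors
#' @export
setGeneric("mapMask", function(object) standardGeneric("mapMask"))

#' @rdname accessors
#' @export
setMethod("mapMask", "ParametricMap", function(object) object@mask)
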