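#' @name dyadiar-accessors
#' @title Accessor generics for dyadiar classes
#'
#' @description Small accessor generics used across the package's S4
#' classes instead of direct slot access.
#'
#' @param x an object of the documented class.
#' @return The slot value; see the individual class pages.
NULL

#' @rdname dyadiar-accessors
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))

#' @rdname dyadiar-accessors
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))

#' @rdname dyadiar-accessors
#' @export
setGeneric("sourceId", function(x) standardGeneric("sourceId"))

#' @rdname dyadiar-accessors
#' @export
setGeneric("duration", function(x) standardGeneric("duration"))

#' @rdname dyadiar-accessors
#' @export
setGeneric("windowS", function(x) standardGeneric("windowS"))

#' @rdname dyadiar-accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname dyadiar-accessors
#' @export
setGeneric("streamLabels", function(x) standardGeneric("streamLabels"))

#' @rdname dyadiar-accessors
#' @export
setGeneric("labelAlphabet", function(x) standardGeneric("labelAlphabet"))

#' @rdname dyadiar-accessors
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))

#' @rdname dyadiar-accessors
#' @export
setGeneric("utterances", function(x) standardGeneric("utterances"))

#' @rdname dyadiar-accessors
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname dyadiar-accessors
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))

#' @rdname dyadiar-accessors
#' @export
setGeneric("oobError", function(x) standardGeneric("oobError"))

#' @rdname dyadiar-accessors
#' @export
setGeneric("featureSchema", function(x) standardGeneric("featureSchema"))

#' @rdname dyadiar-accessors
#' @export
setGeneric("dyadId", function(x) standardGeneric("dyadId"))

#' @rdname dyadiar-accessors
#' @export
setGeneric("silenceThreshold", function(x) standardGeneric("silenceThreshold"))

#' @rdname dyadiar-accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname dyadiar-accessors
#' @export
setGeneric("derComponents", function(x) standardGeneric("derComponents"))
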