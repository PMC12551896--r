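#' @include AllClasses.R
NULL

#' Accessors for famcirc objects
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param x a famcirc S4 object.
#' @param i stimulus index (for `stimulusPixels`).
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("filters", function(x) standardGeneric("filters"))
#' @rdname accessors
#' @export
setMethod("filters", "SparseDictionary", function(x) x@filters)

#' @rdname accessors
#' @export
setGeneric("filterSide", function(x) standardGeneric("filterSide"))
#' @rdname accessors
#' @export
setMethod("filterSide", "SparseDictionary", function(x) x@filterSide)

#' @rdname accessors
#' @export
setGeneric("convStride", function(x) standardGeneric("convStride"))
#' @rdname accessors
#' @export
setMethod("convStride", "SparseDictionary", function(x) x@stride)

#' @rdname accessors
#' @export
setGeneric("eeWeights", function(x) standardGeneric("eeWeights"))
#' @rdname accessors
#' @export
setMethod("eeWeights", "Connectivity", function(x) x@Wee)

#' @rdname accessors
#' @export
setGeneric("eiWeights", function(x) standardGeneric("eiWeights"))
#' @rdname accessors
#' @export
setMethod("eiWeights", "Connectivity", function(x) x@Wei)

#' @rdname accessors
#' @export
setGeneric("ieWeights", function(x) standardGeneric("ieWeights"))
#' @rdname accessors
#' @export
setMethod("ieWeights", "Connectivity", function(x) x@Wie)

#' @rdname accessors
#' @export
setGeneric("eeMask", function(x) standardGeneric("eeMask"))
#' @rdname accessors
#' @export
setMethod("eeMask", "Connectivity", function(x) x@mask)

#' @rdname accessors
#' @export
setGeneric("netConfig", function(x) standardGeneric("netConfig"))
#' @rdname accessors
#' @export
setMethod("netConfig", "Connectivity", function(x) x@config)

#' @rdname accessors
#' @export
setGeneric("nExcitatory", function(x) standardGeneric("nExcitatory"))
#' @rdname accessors
#' @export
setMethod("nExcitatory", "NetworkConfig",
          function(x) x@nRows * x@nCols * x@nChannels)
#' @rdname accessors
#' @export
setMethod("nExcitatory", "Connectivity", function(x) nrow(x@Wee))

#' @rdname accessors
#' @export
setGeneric("steadyState", function(x) standardGeneric("steadyState"))
#' @rdname accessors
#' @export
setMethod("steadyState", "FixedPointRecord", function(x) x@rStar)

#' @rdname accessors
#' @export
setGeneric("stimulusInfo", function(x) standardGeneric("stimulusInfo"))
#' @rdname accessors
#' @export
setMethod("stimulusInfo", "StimulusSet", function(x) {
  data.frame(
    index = seq_along(x@stimuli),
    stimulusId = vapply(x@stimuli, function(s) s$id, character(1)),
    targetId = vapply(x@stimuli, function(s) s$targetId, character(1)),
    level = vapply(x@stimuli, function(s) s$level, numeric(1)),
    sample = vapply(x@stimuli, function(s) s$sample, integer(1)),
    stringsAsFactors = FALSE)
})

#' @rdname accessors
#' @export
setGeneric("stimulusPixels", function(x, i) standardGeneric("stimulusPixels"))
#' @rdname accessors
#' @export
setMethod("stimulusPixels", "StimulusSet", function(x, i) x@stimuli[[i]]$pixels)

#' @rdname accessors
#' @export
setGeneric("modeSpectrum", function(x) standardGeneric("modeSpectrum"))
#' @rdname accessors
#' @export
setMethod("modeSpectrum", "CollectiveModeSet", function(x) x@lambda)

#' @rdname accessors
#' @export
setGeneric("modeFilters", function(x) standardGeneric("modeFilters"))
#' @rdname accessors
#' @export
setMethod("modeFilters", "CollectiveModeSet", function(x) x@Phi)
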