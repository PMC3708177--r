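#' @title Generics for loopscape classes
#' @description Accessor generics used across the package's S4 classes.
#' @param x,object an object of the documented class.
#' @param ... further arguments passed to methods.
#' @name loopscape-generics
#' @keywords internal
NULL

#' @rdname loopscape-generics
#' @export
setGeneric("temperatures", function(x) standardGeneric("temperatures"))

#' @rdname loopscape-generics
#' @export
setGeneric("variantId", function(x) standardGeneric("variantId"))

#' @rdname loopscape-generics
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname loopscape-generics
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' @rdname loopscape-generics
#' @export
setGeneric("bathTemperature", function(x) standardGeneric("bathTemperature"))

#' @rdname loopscape-generics
#' @export
setGeneric("basins", function(x) standardGeneric("basins"))

#' @rdname loopscape-generics
#' @export
setGeneric("effectiveDepths", function(x) standardGeneric("effectiveDepths"))

#' @rdname loopscape-generics
#' @export
setGeneric("assignments", function(x) standardGeneric("assignments"))

#' @rdname loopscape-generics
#' @export
setGeneric("centers", function(x) standardGeneric("centers"))

#' @rdname loopscape-generics
#' @export
setGeneric("cutoff", function(x) standardGeneric("cutoff"))

#' @rdname loopscape-generics
#' @export
setGeneric("nConformers", function(x) standardGeneric("nConformers"))

#' @rdname loopscape-generics
#' @export
setGeneric("conformerSizes", function(x) standardGeneric("conformerSizes"))

#' @rdname loopscape-generics
#' @export
setGeneric("snapshotAt", function(x, temperature) standardGeneric("snapshotAt"))

#' @rdname loopscape-generics
#' @export
setGeneric("swapStatistics", function(x) standardGeneric("swapStatistics"))

#' @rdname loopscape-generics
#' @export
setGeneric("candidates", function(x) standardGeneric("candidates"))

#' @rdname loopscape-generics
#' @export
setGeneric("exclusions", function(x) standardGeneric("exclusions"))

#' @rdname loopscape-generics
#' @export
setGeneric("binders", function(x, target) standardGeneric("binders"))

#' @rdname loopscape-generics
#' @export
setGeneric("nonBinders", function(x, target) standardGeneric("nonBinders"))

#' @rdname loopscape-generics
#' @export
setGeneric("phenotypeCalls", function(x) standardGeneric("phenotypeCalls"))

#' @rdname loopscape-generics
#' @export
setGeneric("landscapes", function(x) standardGeneric("landscapes"))

#' @rdname loopscape-generics
#' @export
setGeneric("plantedTruth", function(x) standardGeneric("plantedTruth"))

#' @rdname loopscape-generics
#' @export
setGeneric("cloneSequences", function(x) standardGeneric("cloneSequences"))

#' @rdname loopscape-generics
#' @export
setGeneric("cloneTruth", function(x) standardGeneric("cloneTruth"))

#' @rdname loopscape-generics
#' @export
setGeneric("superpose", function(x, reference, ...) standardGeneric("superpose"))

#' @rdname loopscape-generics
#' @export
setGeneric("loopRMSD", function(x, y, ...) standardGeneric("loopRMSD"))
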