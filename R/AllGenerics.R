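#' Accessors for diffrac classes
#'
#' @param object,x an object of the documented class.
#' @name diffrac-accessors
NULL

#' @describeIn diffrac-accessors PSM count matrix of an [ElutionMatrix-class].
#' @export
setGeneric("psmCounts", function(object) standardGeneric("psmCounts"))

#' @describeIn diffrac-accessors condition label of an [ElutionMatrix-class].
#' @export
setGeneric("conditionLabel",
    function(object) standardGeneric("conditionLabel"))

#' @describeIn diffrac-accessors protein identifiers (row names).
#' @export
setGeneric("proteinIds", function(object) standardGeneric("proteinIds"))

#' @describeIn diffrac-accessors fraction labels (column names).
#' @export
setGeneric("fractionLabels",
    function(object) standardGeneric("fractionLabels"))

#' @describeIn diffrac-accessors control assay of a
#'   [DiffracExperiment-class].
#' @export
setGeneric("controlCounts", function(object) standardGeneric("controlCounts"))

#' @describeIn diffrac-accessors treated assay of a
#'   [DiffracExperiment-class].
#' @export
setGeneric("treatedCounts", function(object) standardGeneric("treatedCounts"))

#' @describeIn diffrac-accessors subunit membership list of a
#'   [ComplexSet-class].
#' @export
setGeneric("complexMembers",
    function(object) standardGeneric("complexMembers"))

#' @describeIn diffrac-accessors per-complex metadata of a
#'   [ComplexSet-class].
#' @export
setGeneric("complexInfo", function(object) standardGeneric("complexInfo"))

#' @describeIn diffrac-accessors low-throughput annotation IDs of an
#'   [AnnotationSet-class].
#' @export
setGeneric("ltAnnotated", function(object) standardGeneric("ltAnnotated"))

#' @describeIn diffrac-accessors high-throughput annotation IDs of an
#'   [AnnotationSet-class].
#' @export
setGeneric("htAnnotated", function(object) standardGeneric("htAnnotated"))
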