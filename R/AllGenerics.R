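#' @name occusens-accessors
#' @title Accessors for occusens S4 containers
#'
#' @description Slot access for the package's S4 classes. `observations()`,
#' `siteTable()`, `speciesTable()` and `surveyTruth()` read a
#' [SurveyData-class]; `climateTable()` and `baselineYears()` read a
#' [ClimateAnnual-class]; `designMatrix()`, `designKey()` and
#' `designTerms()` read an [OccupancyDesign-class]; `posteriorDraws()`,
#' `posteriorSummary()` and `isConverged()` read an [OccupancyFit-class];
#' `sensitivityTable()` reads a [SensitivityResult-class];
#' `scenarioTable()` reads a [ScenarioResult-class].
#'
#' @param x an occusens S4 object.
#' @return The corresponding slot (a data.frame, matrix, list, or scalar).
NULL

#' @rdname occusens-accessors
#' @export
setGeneric("observations", function(x) standardGeneric("observations"))
#' @rdname occusens-accessors
#' @export
setGeneric("siteTable", function(x) standardGeneric("siteTable"))
#' @rdname occusens-accessors
#' @export
setGeneric("speciesTable", function(x) standardGeneric("speciesTable"))
#' @rdname occusens-accessors
#' @export
setGeneric("surveyTruth", function(x) standardGeneric("surveyTruth"))
#' @rdname occusens-accessors
#' @export
setGeneric("climateTable", function(x) standardGeneric("climateTable"))
#' @rdname occusens-accessors
#' @export
setGeneric("baselineYears", function(x) standardGeneric("baselineYears"))
#' @rdname occusens-accessors
#' @export
setGeneric("designMatrix", function(x) standardGeneric("designMatrix"))
#' @rdname occusens-accessors
#' @export
setGeneric("designKey", function(x) standardGeneric("designKey"))
#' @rdname occusens-accessors
#' @export
setGeneric("designTerms", function(x) standardGeneric("designTerms"))
#' @rdname occusens-accessors
#' @export
setGeneric("posteriorDraws", function(x) standardGeneric("posteriorDraws"))
#' @rdname occusens-accessors
#' @export
setGeneric("posteriorSummary", function(x) standardGeneric("posteriorSummary"))
#' @rdname occusens-accessors
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))
#' @rdname occusens-accessors
#' @export
setGeneric("sensitivityTable", function(x) standardGeneric("sensitivityTable"))
#' @rdname occusens-accessors
#' @export
setGeneric("scenarioTable", function(x) standardGeneric("scenarioTable"))
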