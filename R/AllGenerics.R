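#' @import methods
NULL

#' @export
setGeneric("caseId", function(x) standardGeneric("caseId"))

#' @export
setGeneric("spacingMm", function(x) standardGeneric("spacingMm"))

#' @export
setGeneric("lesionTable", function(x) standardGeneric("lesionTable"))

#' @export
setGeneric("labelValues", function(x) standardGeneric("labelValues"))

#' @export
setGeneric("probValues", function(x) standardGeneric("probValues"))

#' @export
setGeneric("detectionPoints", function(x) standardGeneric("detectionPoints"))

#' @export
setGeneric("frocCurve", function(x) standardGeneric("frocCurve"))

#' @export
setGeneric("sensitivityAt", function(x, fpPerPatient) {
  standardGeneric("sensitivityAt")
})
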