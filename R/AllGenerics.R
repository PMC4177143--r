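#' @rdname ClinicalCohort-class
#' @param object,x a `ClinicalCohort` or `TransactionSet`.
#' @export
setGeneric("observations", function(object) standardGeneric("observations"))

#' @rdname ClinicalCohort-class
#' @export
setGeneric("refRanges", function(object) standardGeneric("refRanges"))

#' @rdname ClinicalCohort-class
#' @export
setGeneric("panelParameters",
           function(object) standardGeneric("panelParameters"))

#' @rdname ClinicalCohort-class
#' @export
setGeneric("patientIDs", function(object) standardGeneric("patientIDs"))

#' @rdname TransactionSet-class
#' @export
setGeneric("transactionItems",
           function(object) standardGeneric("transactionItems"))

#' @rdname TransactionSet-class
#' @export
setGeneric("transactionIDs",
           function(object) standardGeneric("transactionIDs"))
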