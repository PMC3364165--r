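#' @export
setGeneric("specimenIds", function(x) standardGeneric("specimenIds"))

#' @export
setGeneric("specimenData", function(x) standardGeneric("specimenData"))

#' @export
setGeneric("barcodeSequences", function(x) standardGeneric("barcodeSequences"))

#' @export
setGeneric("frameStart", function(x) standardGeneric("frameStart"))

#' @export
setGeneric("barcodeFrameLength",
    function(x) standardGeneric("barcodeFrameLength"))

#' @export
setGeneric("qcReport", function(x) standardGeneric("qcReport"))

#' @export
setGeneric("distances", function(x) standardGeneric("distances"))

#' @export
setGeneric("comparedSites", function(x) standardGeneric("comparedSites"))

#' @export
setGeneric("speciesLabels", function(x) standardGeneric("speciesLabels"))
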