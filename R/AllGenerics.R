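#' @rdname KirHapSet-accessors
#' @export
setGeneric("hapIds", function(x) standardGeneric("hapIds"))

#' @rdname KirHapSet-accessors
#' @export
setGeneric("hapMatrix", function(x) standardGeneric("hapMatrix"))

#' @rdname KirHapSet-accessors
#' @export
setGeneric("panelGenes", function(x) standardGeneric("panelGenes"))

#' @rdname KirHapSet-accessors
#' @export
setGeneric("hapsetName", function(x) standardGeneric("hapsetName"))

#' @rdname KirHapSet-accessors
#' @export
setGeneric("nomenclature", function(x) standardGeneric("nomenclature"))

#' @rdname KirHapSet-accessors
#' @export
setGeneric("variantTag", function(x) standardGeneric("variantTag"))

#' @rdname KirGenotypes-accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname KirGenotypes-accessors
#' @export
setGeneric("populationLabels", function(x) standardGeneric("populationLabels"))

#' @rdname KirGenotypes-accessors
#' @export
setGeneric("genotypeValues", function(x) standardGeneric("genotypeValues"))

#' @rdname KirGenotypes-accessors
#' @export
setGeneric("genotypeModes", function(x) standardGeneric("genotypeModes"))

#' @rdname paSignature
#' @export
setGeneric("paSignature", function(x) standardGeneric("paSignature"))

#' @rdname collapseToPA
#' @export
setGeneric("collapseToPA", function(x) standardGeneric("collapseToPA"))

#' @rdname downconvert
#' @export
setGeneric("downconvert",
    function(x, target = "PA", cnvGenes = character()) standardGeneric("downconvert"))

#' @rdname KirExpansionSet-accessors
#' @export
setGeneric("interpretable", function(x) standardGeneric("interpretable"))

#' @rdname KirExpansionSet-accessors
#' @export
setGeneric("nPairs", function(x) standardGeneric("nPairs"))

#' @rdname KirExpansionSet-accessors
#' @export
setGeneric("pairList", function(x, sample) standardGeneric("pairList"))

#' @rdname emFrequencies
#' @export
setGeneric("emFrequencies",
    function(x, hapset, tol = 1e-8, maxIter = 1000L, floor = 0, ...)
        standardGeneric("emFrequencies"))

#' @rdname KirFreqFit-accessors
#' @export
setGeneric("frequencies", function(x) standardGeneric("frequencies"))

#' @rdname KirFreqFit-accessors
#' @export
setGeneric("unRate", function(x) standardGeneric("unRate"))

#' @rdname KirFreqFit-accessors
#' @export
setGeneric("loglikTrace", function(x) standardGeneric("loglikTrace"))

#' @rdname KirFreqFit-accessors
#' @export
setGeneric("converged", function(x) standardGeneric("converged"))

#' @rdname assignments
#' @export
setGeneric("assignments", function(x, tieTol = 1e-12) standardGeneric("assignments"))
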