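#' Construct a cohort of KIR genotypes
#'
#' @param values Integer matrix (samples x genes). For genes typed at PA
#'   resolution, 1 = present, 0 = absent; for CNV resolution, the diploid
#'   copy count in [0, 8]; NA = missing.
#' @param modes Character matrix parallel to \code{values} with entries
#'   "PA"/"CNV" (NA where the value is NA), or a single string/per-gene
#'   vector recycled across samples.
#' @param sampleId Character vector of unique sample ids (default S1..Sn).
#' @param population Optional character vector of population labels.
#' @return A [KirGenotypes-class] object.
#' @examples
#' v <- rbind(c(1L, 0L), c(2L, 1L))
#' colnames(v) <- c("geneA", "geneB")
#' KirGenotypes(v, modes = c("PA", "CNV"))
#' @export
KirGenotypes <- function(values, modes, sampleId = NULL, population = NULL) {
    if (is.data.frame(values)) values <- as.matrix(values)
    storage.mode(values) <- "integer"
    n <- nrow(values); g <- ncol(values)
    if (!is.matrix(modes)) {
        modes <- matrix(rep(as.character(modes), length.out = g),
                        nrow = n, ncol = g, byrow = TRUE)
    }
    dimnames(modes) <- dimnames(values)
    modes[is.na(values)] <- NA_character_
    if (is.null(sampleId))
        sampleId <- paste0("S", seq_len(n))
    if (is.null(population))
        population <- rep(NA_character_, n)
    new("KirGenotypes", sampleId = as.character(sampleId),
        population = as.character(population),
        values = values, modes = modes)
}

#' Accessors for KirGenotypes
#'
#' \code{sampleIds} and \code{populationLabels} return per-sample metadata;
#' \code{genotypeValues} and \code{genotypeModes} the samples x genes
#' observation matrices (see [KirGenotypes()] for the encoding);
#' \code{panelGenes} the gene panel.
#'
#' @param x A [KirGenotypes-class].
#' @name KirGenotypes-accessors
NULL

#' @rdname KirGenotypes-accessors
#' @export
setMethod("sampleIds", "KirGenotypes", function(x) x@sampleId)

#' @rdname KirGenotypes-accessors
#' @export
setMethod("populationLabels", "KirGenotypes",
    function(x) stats::setNames(x@population, x@sampleId))

#' @rdname KirGenotypes-accessors
#' @export
setMethod("genotypeValues", "KirGenotypes", function(x) {
    m <- x@values
    rownames(m) <- x@sampleId
    m
})

#' @rdname KirGenotypes-accessors
#' @export
setMethod("genotypeModes", "KirGenotypes", function(x) {
    m <- x@modes
    rownames(m) <- x@sampleId
    m
})

#' @rdname KirGenotypes-accessors
#' @export
setMethod("panelGenes", "KirGenotypes", function(x) colnames(x@values))

#' @export
setMethod("length", "KirGenotypes", function(x) nrow(x@values))

#' Subset a genotype cohort by sample id or index
#' @param x A [KirGenotypes-class].
#' @param i Sample ids or indices.
#' @param j,drop,... Ignored.
#' @export
setMethod("[", "KirGenotypes", function(x, i, j, ..., drop = FALSE) {
    idx <- if (is.character(i)) match(i, x@sampleId) else i
    if (is.character(i) && anyNA(idx))
        stop("unknown sample id(s): ", paste(i[is.na(idx)], collapse = ", "))
    new("KirGenotypes", sampleId = x@sampleId[idx],
        population = x@population[idx],
        values = x@values[idx, , drop = FALSE],
        modes = x@modes[idx, , drop = FALSE])
})

setMethod("show", "KirGenotypes", function(object) {
    md <- object@modes
    res <- .sampleResolution(md)
    cat("KirGenotypes: ", length(object), " individuals x ",
        ncol(object@values), " genes\n", sep = "")
    cat("  resolution: ", paste(sprintf("%s=%d", names(table(res)), table(res)),
                                collapse = ", "), "\n", sep = "")
    pop <- object@population[!is.na(object@population)]
    if (length(pop))
        cat("  populations: ", paste(sprintf("%s=%d", names(table(pop)),
                                             table(pop)), collapse = ", "),
            "\n", sep = "")
    miss <- colMeans(is.na(object@values))
    if (any(miss > 0))
        cat("  missingness: ",
            paste(sprintf("%s=%.0f%%", names(miss)[miss > 0],
                          100 * miss[miss > 0]), collapse = ", "),
            "\n", sep = "")
})

## per-sample resolution summary: PA / CNV / mixed (over observed genes)
.sampleResolution <- function(modes) {
    apply(modes, 1L, function(r) {
        r <- r[!is.na(r)]
        if (!length(r)) return(NA_character_)
        u <- unique(r)
        if (length(u) == 1L) u else "mixed"
    })
}

#' Down-convert genotype resolution
#'
#' Converts CNV observations to PA (present iff copy count >= 1) for genes
#' not listed in \code{cnvGenes}. Missing observations stay missing.
#' Up-conversion (asking for CNV at a gene typed at PA) is an error, since
#' PA typing carries no copy-count information. Idempotent at a fixed
#' target.
#'
#' @param x A [KirGenotypes-class].
#' @param target "PA" (convert every gene not in \code{cnvGenes}) or "mixed"
#'   (synonym; the split is given by \code{cnvGenes}).
#' @param cnvGenes Genes to keep at CNV resolution.
#' @return A [KirGenotypes-class].
#' @examples
#' g <- KirGenotypes(matrix(c(2L, 1L, 0L), 1,
#'                   dimnames = list(NULL, c("a", "b", "c"))), "CNV")
#' genotypeValues(downconvert(g))        # 1 1 0 at PA
#' @rdname downconvert
#' @export
setMethod("downconvert", "KirGenotypes",
    function(x, target = "PA", cnvGenes = character()) {
    target <- match.arg(target, c("PA", "mixed"))
    genes <- panelGenes(x)
    bad <- setdiff(cnvGenes, genes)
    if (length(bad))
        stop("cnvGenes not on the panel: ", paste(bad, collapse = ", "))
    toPA <- setdiff(genes, cnvGenes)
    v <- x@values; md <- x@modes
    for (g in toPA) {
        cnv <- !is.na(md[, g]) & md[, g] == "CNV"
        v[cnv, g] <- as.integer(v[cnv, g] >= 1L)
        md[cnv, g] <- "PA"
    }
    keepCNV <- intersect(cnvGenes, genes)
    for (g in keepCNV) {
        pa <- !is.na(md[, g]) & md[, g] == "PA"
        if (any(pa))
            stop("cannot up-convert gene ", g,
                 " from PA to CNV (samples: ",
                 paste(utils::head(x@sampleId[pa], 3L), collapse = ", "), ")")
    }
    new("KirGenotypes", sampleId = x@sampleId, population = x@population,
        values = v, modes = md)
})
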