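#' Expand genotypes into compatible reference-haplotype pairs
#'
#' Enumerates, for every individual, all unordered pairs (i <= j) of
#' reference haplotypes whose diploid copy-number sum is compatible with the
#' observed genotype (see [pairCompatible()] for the per-gene rules).
#' Initial pair weights are uniform over the compatible pairs; the EM
#' expectation step replaces them with posterior probabilities. A genotype
#' with no compatible pair is uninterpretable (empty expansion).
#'
#' Individuals with identical observation vectors share one expansion,
#' computed once and weighted by multiplicity in the EM sums; this is
#' mathematically identical to expanding each individual separately.
#'
#' @param genotypes A [KirGenotypes-class].
#' @param hapset A [KirHapSet-class] on the same gene panel.
#' @return A [KirExpansionSet-class].
#' @examples
#' m <- rbind(hA = c(1L, 0L), hB = c(1L, 1L), hC = c(0L, 1L))
#' colnames(m) <- c("a", "b")
#' refs <- KirHapSet(m)
#' g <- KirGenotypes(matrix(c(1L, 1L), 1, dimnames = list(NULL, c("a", "b"))),
#'                   "PA")
#' ex <- expandGenotypes(g, refs)
#' pairList(ex, 1)   # hA+hB, hA+hC, hB+hB, hB+hC
#' @export
expandGenotypes <- function(genotypes, hapset) {
    .checkPanels(genotypes, hapset)
    v <- genotypeValues(genotypes)
    md <- genotypeModes(genotypes)
    ## distinct genotype classes: identical (value, mode) vectors share one
    ## expansion
    key <- paste(apply(v, 1L, paste, collapse = ","),
                 apply(md, 1L, paste, collapse = ","), sep = "|")
    classOf <- match(key, unique(key))
    rep1 <- which(!duplicated(key))        # one representative per class
    diplo <- .diplotypeMatrix(hapset)
    pairsIdx <- .pairIndex(length(hapset))
    pairs <- vector("list", length(rep1))
    weights <- vector("list", length(rep1))
    for (k in seq_along(rep1)) {
        r <- rep1[k]
        ok <- .compatiblePairs(v[r, ], md[r, ], diplo)
        p <- pairsIdx[ok, , drop = FALSE]
        pairs[[k]] <- p
        weights[[k]] <- if (nrow(p)) rep(1 / nrow(p), nrow(p)) else numeric()
    }
    new("KirExpansionSet",
        hapIds = hapIds(hapset),
        hapsetName = hapsetName(hapset),
        sampleId = sampleIds(genotypes),
        population = genotypes@population,
        resolution = unname(.sampleResolution(md)),
        classOf = classOf,
        classCount = as.integer(tabulate(classOf, nbins = length(rep1))),
        pairs = pairs, weights = weights)
}

#' Accessors for KirExpansionSet
#'
#' \code{interpretable} flags samples with at least one compatible pair;
#' \code{nPairs} counts compatible pairs per sample; \code{pairList} returns
#' one sample's pairs as a data.frame of haplotype ids with their current
#' weights; \code{sampleIds} and \code{populationLabels} as for genotypes.
#'
#' @param x A [KirExpansionSet-class].
#' @param sample A sample id or index.
#' @name KirExpansionSet-accessors
NULL

#' @rdname KirExpansionSet-accessors
#' @export
setMethod("sampleIds", "KirExpansionSet", function(x) x@sampleId)

#' @rdname KirExpansionSet-accessors
#' @export
setMethod("populationLabels", "KirExpansionSet",
    function(x) stats::setNames(x@population, x@sampleId))

#' @rdname KirExpansionSet-accessors
#' @export
setMethod("interpretable", "KirExpansionSet", function(x) {
    nz <- vapply(x@pairs, nrow, integer(1L)) > 0L
    stats::setNames(nz[x@classOf], x@sampleId)
})

#' @rdname KirExpansionSet-accessors
#' @export
setMethod("nPairs", "KirExpansionSet", function(x) {
    np <- vapply(x@pairs, nrow, integer(1L))
    stats::setNames(np[x@classOf], x@sampleId)
})

#' @rdname KirExpansionSet-accessors
#' @export
setMethod("pairList", "KirExpansionSet", function(x, sample) {
    k <- if (is.character(sample)) match(sample, x@sampleId) else sample
    if (is.na(k) || k < 1L || k > length(x@sampleId))
        stop("unknown sample: ", sample)
    cls <- x@classOf[k]
    p <- x@pairs[[cls]]
    data.frame(h1 = x@hapIds[p[, 1L]], h2 = x@hapIds[p[, 2L]],
               weight = x@weights[[cls]], stringsAsFactors = FALSE)
})

#' @export
setMethod("length", "KirExpansionSet", function(x) length(x@sampleId))

setMethod("show", "KirExpansionSet", function(object) {
    np <- nPairs(object)
    cat("KirExpansionSet vs '", object@hapsetName, "': ",
        length(object), " individuals, ",
        length(object@pairs), " distinct genotypes\n", sep = "")
    cat(sprintf("  unambiguous: %d, ambiguous: %d, uninterpretable: %d\n",
                sum(np == 1L), sum(np > 1L), sum(np == 0L)))
})

#' Cohort interpretability under a reference set
#'
#' Computes the fraction of individuals whose genotype no pair of reference
#' haplotypes explains, overall and per population, together with a
#' distinct-genotype contribution table: each distinct observation vector,
#' its count, and whether it is interpretable. Enlarging the reference set
#' can only leave the uninterpretable fraction unchanged or lower it.
#'
#' @param genotypes A [KirGenotypes-class].
#' @param hapset A [KirHapSet-class].
#' @return A list with elements \code{overall} (numeric fraction),
#'   \code{byPopulation} (data.frame: population, n, nUninterpretable,
#'   fraction) and \code{genotypeTable} (data.frame: one row per distinct
#'   genotype and population: population, genotype key, count, fraction of
#'   that population, interpretable flag).
#' @export
cohortInterpretability <- function(genotypes, hapset) {
    ex <- expandGenotypes(genotypes, hapset)
    ok <- interpretable(ex)
    pop <- genotypes@population
    pop[is.na(pop)] <- "ALL"
    byPop <- do.call(rbind, lapply(split(seq_along(ok), pop), function(idx) {
        data.frame(population = pop[idx[1L]], n = length(idx),
                   nUninterpretable = sum(!ok[idx]),
                   fraction = mean(!ok[idx]), stringsAsFactors = FALSE)
    }))
    rownames(byPop) <- NULL
    v <- genotypeValues(genotypes)
    key <- apply(ifelse(is.na(v), ".", v), 1L, paste, collapse = "")
    tab <- do.call(rbind, lapply(split(seq_along(ok), pop), function(idx) {
        kk <- key[idx]
        cnt <- table(kk)
        interp <- !duplicated(kk)
        data.frame(population = pop[idx[1L]],
                   genotype = names(cnt),
                   count = as.integer(cnt),
                   fraction = as.integer(cnt) / length(idx),
                   interpretable = vapply(names(cnt),
                       function(k) ok[idx[match(k, kk)]], logical(1L)),
                   stringsAsFactors = FALSE)
    }))
    rownames(tab) <- NULL
    tab <- tab[order(tab$population, -tab$count, tab$genotype), ]
    rownames(tab) <- NULL
    list(overall = mean(!ok), byPopulation = byPop, genotypeTable = tab)
}
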