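#' Simulate a KIR genotype cohort
#'
#' Generates a synthetic cohort with the statistical structure the
#' estimator assumes: each individual draws two haplotypes independently
#' from \code{truthFreqs} (Hardy-Weinberg equilibrium), their copy numbers
#' are summed into a diploid genotype, the genotype is down-converted to
#' the requested typing resolution, per-gene missingness is applied (the
#' pseudogenes KIR2DP1 and KIR3DP1 default to the missingness typical of
#' PA registry typing, 10% and 17%), and, with probability
#' \code{offRefRate}, one gene's value is perturbed so that no reference
#' pair explains the genotype (emulating cohort haplotypes absent from the
#' reference panel).
#'
#' Reproducibility: each individual has its own RNG substream derived from
#' \code{seed} and its index, so the first m individuals of a size-n run
#' are identical to a size-m run, and identical (seed, config) give
#' byte-identical cohorts.
#'
#' @param truthFreqs Named simplex vector over ids of \code{refs}.
#' @param refs A [KirHapSet-class] the truth haplotypes are drawn from.
#' @param n Number of individuals.
#' @param resolution "CNV", "PA", or "mixed" (CNV for \code{cnvGenes},
#'   PA elsewhere).
#' @param cnvGenes Genes typed at CNV resolution when
#'   \code{resolution = "mixed"}.
#' @param missingRates Named per-gene missingness probabilities; NULL
#'   disables missingness. The default applies 0.10/0.17 to
#'   KIR2DP1/KIR3DP1 where those genes are on the panel.
#' @param offRefRate Probability that an individual's genotype is
#'   perturbed to be incompatible with every pair from \code{refs}.
#' @param populations Optional named proportions of population labels.
#' @param seed Integer seed.
#' @return List with \code{genotypes} (a [KirGenotypes-class]) and
#'   \code{truth} (data.frame: sample_id, population, h1, h2, the hidden
#'   haplotype ids with h1 <= h2, and off_reference flag).
#' @examples
#' m <- rbind(hA = c(1L, 0L), hB = c(1L, 1L))
#' colnames(m) <- c("a", "b")
#' sim <- simulateCohort(c(hA = 0.5, hB = 0.5), KirHapSet(m), n = 10,
#'                       seed = 7)
#' sim$truth$h1
#' @export
simulateCohort <- function(truthFreqs, refs, n,
                           resolution = c("CNV", "PA", "mixed"),
                           cnvGenes = character(),
                           missingRates = c(KIR2DP1 = 0.10, KIR3DP1 = 0.17),
                           offRefRate = 0, populations = NULL,
                           seed = 1L) {
    resolution <- match.arg(resolution)
    genes <- panelGenes(refs)
    ids <- hapIds(refs)
    if (!all(names(truthFreqs) %in% ids))
        stop("truthFreqs name haplotypes outside refs: ",
             paste(setdiff(names(truthFreqs), ids), collapse = ", "))
    if (any(truthFreqs < 0) || abs(sum(truthFreqs) - 1) > 1e-8)
        stop("truthFreqs must be a simplex vector")
    if (offRefRate < 0 || offRefRate > 1)
        stop("offRefRate must lie in [0, 1]")
    missingRates <- missingRates[names(missingRates) %in% genes]
    if (length(missingRates) && (any(missingRates < 0) || any(missingRates > 1)))
        stop("missing rates must lie in [0, 1]")
    if (!is.null(populations) &&
        (is.null(names(populations)) || abs(sum(populations) - 1) > 1e-8))
        stop("populations must be named proportions summing to 1")
    cnvMask <- switch(resolution,
        CNV = rep(TRUE, length(genes)),
        PA = rep(FALSE, length(genes)),
        mixed = genes %in% cnvGenes)
    hm <- hapMatrix(refs)
    drawIds <- names(truthFreqs)
    prob <- unname(truthFreqs)
    V <- matrix(NA_integer_, n, length(genes),
                dimnames = list(NULL, genes))
    M <- matrix(NA_character_, n, length(genes),
                dimnames = list(NULL, genes))
    h1 <- character(n); h2 <- character(n)
    popLab <- rep(NA_character_, n)
    offRef <- logical(n)
    diplo <- .diplotypeMatrix(refs)       # for off-reference testing
    for (k in seq_len(n)) {
        set.seed(.substream(seed, k))
        pair <- sample(drawIds, 2L, replace = TRUE, prob = prob)
        pair <- pair[order(match(pair, ids))]
        h1[k] <- pair[1L]; h2[k] <- pair[2L]
        v <- hm[pair[1L], ] + hm[pair[2L], ]
        md <- ifelse(cnvMask, "CNV", "PA")
        v <- ifelse(cnvMask, v, as.integer(v >= 1L))
        names(v) <- genes
        if (length(missingRates)) {
            drop <- names(missingRates)[stats::runif(length(missingRates)) <
                                        missingRates]
            v[drop] <- NA_integer_
            md[match(drop, genes)] <- NA_character_
        }
        if (!is.null(populations))
            popLab[k] <- sample(names(populations), 1L,
                                prob = unname(populations))
        if (offRefRate > 0 && stats::runif(1L) < offRefRate) {
            pert <- .perturbOffReference(v, md, genes, diplo)
            v <- pert$v
            offRef[k] <- TRUE
        }
        V[k, ] <- as.integer(v)
        M[k, ] <- md
    }
    gts <- KirGenotypes(V, M, sampleId = sprintf("S%05d", seq_len(n)),
                        population = popLab)
    list(genotypes = gts,
         truth = data.frame(sample_id = sampleIds(gts),
                            population = popLab, h1 = h1, h2 = h2,
                            off_reference = offRef,
                            stringsAsFactors = FALSE))
}

## per-individual substream seed; Knuth multiplicative hash keeps streams
## well separated while staying inside R's 32-bit integer range
.substream <- function(seed, k) {
    as.integer((as.double(seed) * 2654435761 + as.double(k) * 40503) %%
               2147483647)
}

## perturb one gene so that no reference pair explains the genotype;
## increments a CNV value (or flips a PA state), retrying up to 100 times
.perturbOffReference <- function(v, md, genes, diplo) {
    observed <- which(!is.na(v))
    if (!length(observed))
        stop("cannot make an all-missing genotype off-reference")
    for (attempt in seq_len(100L)) {
        g <- observed[sample.int(length(observed), 1L)]
        vNew <- v
        vNew[g] <- if (md[g] == "PA") 1L - v[g]
                   else min(v[g] + 1L, .MAX_GT_COPY)
        if (vNew[g] == v[g]) next
        if (!any(.compatiblePairs(vNew, md, diplo)))
            return(list(v = vNew, gene = genes[g]))
    }
    stop("could not perturb genotype off-reference within 100 attempts; ",
         "the reference set explains every single-gene perturbation")
}
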