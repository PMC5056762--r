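#' Diploid copy numbers implied by a haplotype pair
#'
#' The genotype a pair of haplotypes produces: the element-wise sum of the
#' two per-chromosome copy-number vectors. Commutative in the two ids.
#'
#' @param hapset A [KirHapSet-class].
#' @param h1,h2 Haplotype ids (or row indices) in \code{hapset}. They may be
#'   equal (a homozygote).
#' @return Named integer vector over the panel genes.
#' @examples
#' m <- rbind(hA = c(1L, 0L), hB = c(1L, 1L))
#' colnames(m) <- c("a", "b")
#' diplotypeCopyNumbers(KirHapSet(m), "hA", "hB")  # 2 1
#' @export
diplotypeCopyNumbers <- function(hapset, h1, h2) {
    m <- hapMatrix(hapset)
    i <- if (is.character(h1)) match(h1, rownames(m)) else as.integer(h1)
    j <- if (is.character(h2)) match(h2, rownames(m)) else as.integer(h2)
    if (is.na(i) || is.na(j))
        stop("unknown haplotype id: ",
             paste(c(h1, h2)[is.na(c(i, j))], collapse = ", "))
    m[i, ] + m[j, ]
}

## All unordered pair indices i <= j over H haplotypes, plus the P x G
## diplotype copy-number matrix. Pair order is fixed (column-major over the
## upper triangle) so every downstream structure is deterministic.
.pairIndex <- function(H) {
    j <- rep.int(seq_len(H), seq_len(H))
    i <- sequence(seq_len(H))
    cbind(i = i, j = j)
}

.diplotypeMatrix <- function(hapset) {
    m <- hapMatrix(hapset)
    p <- .pairIndex(nrow(m))
    m[p[, 1L], , drop = FALSE] + m[p[, 2L], , drop = FALSE]
}

## Compatibility of one observation vector against a P x G diplotype matrix.
## values/modes: length-G vectors (NA = missing). Returns logical length P.
.compatiblePairs <- function(values, modes, diplo) {
    ok <- rep(TRUE, nrow(diplo))
    for (g in which(!is.na(values))) {
        d <- diplo[, g]
        ok <- ok & if (modes[g] == "PA") {
            if (values[g] >= 1L) d >= 1L else d == 0L
        } else {
            d == values[g]
        }
        if (!any(ok)) break
    }
    ok
}

#' Genotype / haplotype-pair compatibility
#'
#' Tests, for every individual in a cohort, whether the diploid copy-number
#' sum of a given haplotype pair explains the observed genotype: a
#' PA-present gene needs summed copies >= 1, a PA-absent gene summed copies
#' = 0, a CNV gene an exact match, and a missing gene is always satisfied.
#' This predicate is the support of the indicator delta(g, h_i, h_j) in the
#' EM expectation step; it is symmetric in the two haplotypes, and removing
#' an observation (making it missing) can only enlarge the compatible set.
#'
#' @param genotypes A [KirGenotypes-class].
#' @param hapset A [KirHapSet-class] on the same gene panel.
#' @param h1,h2 Haplotype ids in \code{hapset}.
#' @return Logical vector, one entry per individual.
#' @seealso [expandGenotypes()] for the full pair enumeration.
#' @export
pairCompatible <- function(genotypes, hapset, h1, h2) {
    .checkPanels(genotypes, hapset)
    d <- diplotypeCopyNumbers(hapset, h1, h2)
    v <- genotypeValues(genotypes)
    md <- genotypeModes(genotypes)
    vapply(seq_len(nrow(v)), function(k) {
        obs <- !is.na(v[k, ])
        all(ifelse(md[k, obs] == "PA",
                   ifelse(v[k, obs] >= 1L, d[obs] >= 1L, d[obs] == 0L),
                   d[obs] == v[k, obs]))
    }, logical(1L))
}

.checkPanels <- function(a, b) {
    pa <- panelGenes(a); pb <- panelGenes(b)
    if (!identical(pa, pb))
        stop("gene panels differ: [", paste(pa, collapse = ", "), "] vs [",
             paste(pb, collapse = ", "), "]")
    invisible(TRUE)
}
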