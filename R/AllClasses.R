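#' The KIR gene panel
#'
#' Returns the ordered names of the 16 KIR genes and pseudogenes that define
#' the coordinates of every haplotype copy-number vector and genotype
#' observation vector in this package. The order is fixed for the lifetime of
#' a session; all file readers match gene columns by name so that a file with
#' permuted columns is read correctly rather than silently misinterpreted.
#'
#' The panel comprises the twelve protein-coding genes KIR2DL1-5, KIR2DS1-5,
#' KIR3DL1-3 and KIR3DS1 plus the two pseudogenes KIR2DP1 and KIR3DP1.
#' KIR2DL5 is treated as a single locus (its A and B paralogs are not
#' distinguished at this structural resolution), and KIR2DS3 and KIR2DS5 are
#' separate panel genes; reference haplotypes whose 2DS3/2DS5 placement is
#' ambiguous are encoded as two records distinguished by a variant tag.
#'
#' @return Character vector of 16 gene names.
#' @examples
#' kirGenes()
#' @export
kirGenes <- function() {
    c("KIR2DL1", "KIR2DL2", "KIR2DL3", "KIR2DL4", "KIR2DL5",
      "KIR2DS1", "KIR2DS2", "KIR2DS3", "KIR2DS4", "KIR2DS5",
      "KIR3DL1", "KIR3DL2", "KIR3DL3", "KIR3DS1",
      "KIR2DP1", "KIR3DP1")
}

## maximum copies of one gene on a single haplotype / in one diploid genotype
.MAX_HAP_COPY <- 4L
.MAX_GT_COPY <- 8L

#' KirHapSet: a set of reference KIR haplotypes
#'
#' An S4 container for a reference set of structural haplotypes. Each
#' haplotype is a vector of per-gene copy numbers (copies on one chromosome,
#' 0-4) over a shared gene panel, with a unique identifier, an optional
#' centromeric~telomeric structural nomenclature (e.g. "cA01~tA01"), and an
#' optional variant tag separating haplotypes whose gene content is otherwise
#' ambiguous (the KIR2DS3 vs KIR2DS5 placement convention, e.g. "_2DS3").
#'
#' @slot name Label for the set (e.g. "HapSet10").
#' @slot copies Integer matrix, haplotypes x genes; rownames are haplotype
#'   ids, colnames the gene panel.
#' @slot nomenclature Character vector parallel to rows (NA when absent).
#' @slot variantTag Character vector parallel to rows (NA when absent).
#' @seealso [KirHapSet()], [readHapSet()], [collapseToPA()]
#' @export
setClass("KirHapSet",
    representation(name = "character",
                   copies = "matrix",
                   nomenclature = "character",
                   variantTag = "character"))

setValidity("KirHapSet", function(object) {
    m <- object@copies
    msg <- character()
    if (!is.integer(m))
        msg <- c(msg, "copy-number matrix must be integer")
    if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
        msg <- c(msg, "haplotype ids (rownames) must be present and unique")
    if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
        msg <- c(msg, "gene names (colnames) must be present and unique")
    if (any(is.na(m)))
        msg <- c(msg, "haplotype copy numbers may not be missing")
    else if (any(m < 0L) || any(m > .MAX_HAP_COPY))
        msg <- c(msg, sprintf("haplotype copy numbers must lie in [0, %d]",
                              .MAX_HAP_COPY))
    if (length(object@nomenclature) != nrow(m))
        msg <- c(msg, "nomenclature length must equal number of haplotypes")
    if (length(object@variantTag) != nrow(m))
        msg <- c(msg, "variantTag length must equal number of haplotypes")
    if (nrow(m) > 1L && !any(is.na(m))) {
        key <- paste(apply(m, 1L, paste, collapse = ","),
                     ifelse(is.na(object@variantTag), "", object@variantTag))
        if (anyDuplicated(key))
            msg <- c(msg, paste0("haplotypes ",
                paste(rownames(m)[duplicated(key) | duplicated(key, fromLast = TRUE)],
                      collapse = ", "),
                " share identical copy numbers and variant tag"))
    }
    if (length(msg)) msg else TRUE
})

#' KirGenotypes: a cohort of KIR genotypes
#'
#' An S4 container for per-individual KIR gene observations. Each observation
#' is one of three states: presence/absence (PA; the gene is present on at
#' least one chromosome, or absent from both), a diploid copy number (CNV;
#' total copies over both chromosomes, 0-8), or missing. Resolution may vary
#' gene-by-gene within one individual (mixed-resolution typing).
#'
#' Internally PA presence is stored as value 1 and absence as 0 with mode
#' "PA"; CNV values are stored as counts with mode "CNV"; missing
#' observations have NA in both matrices.
#'
#' @slot sampleId Character vector of unique sample identifiers.
#' @slot population Character vector of population labels (NA when absent);
#'   conventionally one of AFA, API, EUR, HIS, NAM but free text is allowed.
#' @slot values Integer matrix, samples x genes (NA = missing).
#' @slot modes Character matrix, samples x genes, "PA"/"CNV"/NA.
#' @seealso [KirGenotypes()], [readGenotypes()], [downconvert()]
#' @export
setClass("KirGenotypes",
    representation(sampleId = "character",
                   population = "character",
                   values = "matrix",
                   modes = "matrix"))

setValidity("KirGenotypes", function(object) {
    v <- object@values; md <- object@modes
    msg <- character()
    if (!identical(dim(v), dim(md)))
        msg <- c(msg, "values and modes matrices must have identical shape")
    if (length(object@sampleId) != nrow(v))
        msg <- c(msg, "sampleId length must equal number of rows")
    if (anyDuplicated(object@sampleId))
        msg <- c(msg, "sample ids must be unique")
    if (length(object@population) != nrow(v))
        msg <- c(msg, "population length must equal number of rows")
    if (is.null(colnames(v)) || anyDuplicated(colnames(v)))
        msg <- c(msg, "gene names (colnames) must be present and unique")
    if (!identical(is.na(v), is.na(md)))
        msg <- c(msg, "missing observations must be NA in both values and modes")
    known <- md %in% c("PA", "CNV") | is.na(md)
    if (!all(known))
        msg <- c(msg, "modes must be 'PA', 'CNV' or NA")
    pa <- !is.na(md) & md == "PA"
    if (any(!v[pa] %in% c(0L, 1L)))
        msg <- c(msg, "PA observations must be 0 (absent) or 1 (present)")
    cnv <- !is.na(md) & md == "CNV"
    if (any(v[cnv] < 0L) || any(v[cnv] > .MAX_GT_COPY))
        msg <- c(msg, sprintf("CNV observations must lie in [0, %d]",
                              .MAX_GT_COPY))
    if (length(msg)) msg else TRUE
})

#' KirExpansionSet: genotype / haplotype-pair compatibility expansions
#'
#' The result of interpreting a cohort of genotypes against a reference
#' haplotype set: for each genotype, the set of unordered reference-haplotype
#' pairs (i <= j in the set's haplotype order) whose diploid copy-number sum
#' is compatible with every observed gene, together with a posterior weight
#' per pair (uniform before EM, the converged pair posteriors afterwards).
#'
#' Individuals with identical observation vectors share one expansion:
#' expansions are stored per distinct genotype class with multiplicities, and
#' \code{classOf} maps each sample to its class. An empty pair set marks the
#' genotype as uninterpretable.
#'
#' @slot hapIds Haplotype ids of the reference set used.
#' @slot hapsetName Name of the reference set.
#' @slot sampleId,population,resolution Per-sample metadata; resolution is
#'   "PA", "CNV" or "mixed" summarising the observed genes' modes.
#' @slot classOf Integer vector mapping samples to distinct genotype classes.
#' @slot classCount Integer multiplicity of each class.
#' @slot pairs List of 2-column integer matrices (indices into hapIds).
#' @slot weights List of numeric weight vectors (sum to 1 when non-empty).
#' @seealso [expandGenotypes()], [emFrequencies()]
#' @export
setClass("KirExpansionSet",
    representation(hapIds = "character",
                   hapsetName = "character",
                   sampleId = "character",
                   population = "character",
                   resolution = "character",
                   classOf = "integer",
                   classCount = "integer",
                   pairs = "list",
                   weights = "list"))

setValidity("KirExpansionSet", function(object) {
    msg <- character()
    nc <- length(object@pairs)
    if (length(object@weights) != nc)
        msg <- c(msg, "pairs and weights must have equal length")
    if (length(object@classCount) != nc)
        msg <- c(msg, "classCount must have one entry per class")
    if (length(object@classOf) != length(object@sampleId))
        msg <- c(msg, "classOf must have one entry per sample")
    if (nc && any(object@classOf < 1L | object@classOf > nc))
        msg <- c(msg, "classOf out of range")
    for (k in seq_len(nc)) {
        p <- object@pairs[[k]]; w <- object@weights[[k]]
        if (!is.matrix(p) || ncol(p) != 2L) {
            msg <- c(msg, "each pair set must be a 2-column matrix")
            break
        }
        if (nrow(p) != length(w)) {
            msg <- c(msg, "weights must align with pairs")
            break
        }
        if (nrow(p)) {
            if (any(p[, 1L] > p[, 2L]))
                msg <- c(msg, "pairs must be ordered i <= j")
            if (any(w < 0) || abs(sum(w) - 1) > 1e-8)
                msg <- c(msg, "non-empty weights must be non-negative and sum to 1")
        }
    }
    if (length(msg)) msg else TRUE
})

#' KirFreqFit: a fitted haplotype-frequency model
#'
#' The result of the EM fit: haplotype frequencies (conditional on
#' interpretability, summing to 1 over the reference set), the fraction of
#' individuals whose genotype no reference pair explains, the per-iteration
#' log-likelihood trace, and the converged expansion holding per-genotype
#' pair posteriors from which per-individual assignments and typing
#' resolution scores are derived.
#'
#' @slot frequencies Named numeric vector on the simplex.
#' @slot unRate Fraction of individuals with an empty expansion.
#' @slot loglik Observed-data log-likelihood per iteration (non-decreasing).
#' @slot nIter Number of EM iterations performed.
#' @slot converged TRUE if |delta LL| fell below tol before maxIter.
#' @slot expansion The [KirExpansionSet] with converged posterior weights.
#' @seealso [emFrequencies()], [assignments()], [reportFrequencies()]
#' @export
setClass("KirFreqFit",
    representation(frequencies = "numeric",
                   unRate = "numeric",
                   loglik = "numeric",
                   nIter = "integer",
                   converged = "logical",
                   expansion = "KirExpansionSet"))

setValidity("KirFreqFit", function(object) {
    msg <- character()
    f <- object@frequencies
    if (is.null(names(f)))
        msg <- c(msg, "frequencies must be named by haplotype id")
    if (any(f < -1e-12) || abs(sum(f) - 1) > 1e-6)
        msg <- c(msg, "frequencies must be non-negative and sum to 1")
    if (object@unRate < 0 || object@unRate > 1)
        msg <- c(msg, "unRate must lie in [0, 1]")
    if (length(object@loglik) > 1L && any(diff(object@loglik) < -1e-6))
        msg <- c(msg, "log-likelihood trace must be non-decreasing")
    if (length(msg)) msg else TRUE
})
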