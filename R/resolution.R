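#' Typing resolution score (TRS)
#'
#' TRS = sum(p^2) over a set of normalized interpretation probabilities.
#' Applied per individual to the converged haplotype-pair posteriors, it is
#' 1 exactly when the assignment is unambiguous (a single compatible pair)
#' and approaches 0 under maximal ambiguity; a uniform posterior over n
#' pairs scores exactly 1/n, so TRS >= 1/n_pairs always.
#'
#' @param weights Non-negative weights summing to 1.
#' @return A number in (0, 1]. An empty weight vector (an uninterpretable
#'   individual) has no score and returns NA rather than 0.
#' @examples
#' typingResolutionScore(c(0.5, 0.5))          # 0.5
#' typingResolutionScore(rep(0.25, 4))         # 0.25
#' @export
typingResolutionScore <- function(weights) {
    if (!length(weights)) return(NA_real_)
    if (any(weights < 0) || abs(sum(weights) - 1) > 1e-6)
        stop("weights must be non-negative and sum to 1")
    sum(weights^2)
}

#' Per-individual TRS table
#'
#' Scores every interpretable individual of a fitted model (or of a raw
#' expansion, where the weights are uniform) with the typing resolution
#' score of its haplotype-pair posterior. Uninterpretable individuals are
#' excluded (they have no interpretation to score), which is distinct from
#' a score of 0.
#'
#' @param x A [KirFreqFit-class] or [KirExpansionSet-class].
#' @return data.frame: sample_id, population, resolution, hapset, n_pairs,
#'   trs.
#' @export
trsTable <- function(x) {
    ex <- if (is(x, "KirFreqFit")) x@expansion else x
    if (!is(ex, "KirExpansionSet"))
        stop("x must be a KirFreqFit or KirExpansionSet")
    trsClass <- vapply(ex@weights, typingResolutionScore, numeric(1L))
    np <- vapply(ex@pairs, nrow, integer(1L))
    cls <- ex@classOf
    out <- data.frame(sample_id = ex@sampleId,
                      population = ex@population,
                      resolution = ex@resolution,
                      hapset = ex@hapsetName,
                      n_pairs = np[cls],
                      trs = trsClass[cls],
                      stringsAsFactors = FALSE)
    out[!is.na(out$trs), , drop = FALSE]
}

#' Tukey box-plot summary of a TRS distribution
#'
#' Median, quartiles, whiskers at the most extreme points within 1.5 x IQR
#' of the quartiles, outliers beyond the whiskers, and the mean. Quartiles
#' use linear interpolation by default (\code{stats::quantile} type 7); the
#' convention is configurable via \code{qtype}.
#'
#' @param trs Numeric vector of scores, or the data.frame from
#'   [trsTable()] (optionally grouped by its resolution/hapset columns via
#'   \code{by}).
#' @param by Optional character vector of grouping column names when
#'   \code{trs} is a data.frame (default c("resolution", "hapset")).
#' @param qtype Quantile algorithm type passed to [stats::quantile()].
#' @return data.frame with columns n, mean, median, q1, q3,
#'   whisker_low, whisker_high, n_outliers (one row per group, or a single
#'   row for a plain vector).
#' @export
trsDistribution <- function(trs, by = c("resolution", "hapset"), qtype = 7) {
    summarise <- function(v) {
        stopifnot(length(v) > 0L)
        q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = qtype, names = FALSE)
        iqr <- q[3L] - q[1L]
        lo <- min(v[v >= q[1L] - 1.5 * iqr])
        hi <- max(v[v <= q[3L] + 1.5 * iqr])
        data.frame(n = length(v), mean = mean(v), median = q[2L],
                   q1 = q[1L], q3 = q[3L],
                   whisker_low = lo, whisker_high = hi,
                   n_outliers = sum(v < lo | v > hi))
    }
    if (is.data.frame(trs)) {
        by <- intersect(by, names(trs))
        groups <- if (length(by))
            split(trs$trs, trs[by], drop = TRUE)
        else list(all = trs$trs)
        out <- do.call(rbind, lapply(groups, summarise))
        out <- cbind(group = names(groups), out)
        rownames(out) <- NULL
        out
    } else {
        summarise(as.numeric(trs))
    }
}

#' Gene-content subset/superset report for a reference set
#'
#' Lists every ordered pair of reference haplotypes (a, b) whose PA
#' signatures are nested: every gene present on a is present on b, and b
#' carries at least one gene a lacks. Such pairs make many PA genotypes
#' unable to distinguish a from b, so one haplotype can hide behind the
#' other and bias EM frequency estimates at PA resolution ("hidden"
#' haplotypes); reference sets for PA data should avoid them. The report is
#' transitively consistent: a in b and b in c implies (a, c) is reported.
#'
#' @param hapset A [KirHapSet-class].
#' @return data.frame: subset_id, superset_id, n_differing,
#'   differing_genes (comma-joined genes present on the superset only).
#'   Zero rows when no signatures are nested.
#' @export
subsetReport <- function(hapset) {
    sig <- paSignature(hapset)
    ids <- hapIds(hapset)
    H <- nrow(sig)
    out <- list()
    for (a in seq_len(H)) {
        for (b in seq_len(H)) {
            if (a == b) next
            if (all(sig[a, ] <= sig[b, ]) && any(sig[a, ] < sig[b, ])) {
                diffg <- colnames(sig)[sig[b, ] & !sig[a, ]]
                out[[length(out) + 1L]] <- data.frame(
                    subset_id = ids[a], superset_id = ids[b],
                    n_differing = length(diffg),
                    differing_genes = paste(diffg, collapse = ","),
                    stringsAsFactors = FALSE)
            }
        }
    }
    if (!length(out))
        return(data.frame(subset_id = character(), superset_id = character(),
                          n_differing = integer(),
                          differing_genes = character(),
                          stringsAsFactors = FALSE))
    do.call(rbind, out)
}

#' Hidden-haplotype frequency-stealing experiment
#'
#' Demonstrates, on simulated data, how PA-resolution interpretation with a
#' reference set containing gene-content subset/superset haplotypes biases
#' frequency estimates, and how CNV resolution corrects them. A cohort is
#' simulated at CNV resolution from \code{truthFreqs} (which may name
#' haplotypes of \code{truthRefs} outside the estimation reference set
#' \code{refs} -- real cohorts contain haplotypes missing from any published
#' reference panel, and those orphan genotypes are precisely the fuel for
#' PA-resolution misestimation). The same cohort is then interpreted twice
#' against \code{refs}: once down-converted to PA, once at CNV, and the two
#' frequency estimates are tabulated against the truth.
#'
#' At PA resolution, genotypes involving off-reference fragments or masked
#' copy-number differences collapse onto the signature of a nested
#' reference haplotype, inflating it above its true frequency; at CNV
#' resolution those genotypes are rejected as uninterpretable (raising the
#' un-rate) and the surviving estimate returns to the truth within sampling
#' error. When the data leave a subset/superset split unresolved (no
#' observed genotype distinguishes the two), the likelihood is flat along
#' that direction; this is detected by profiling the log-likelihood and
#' flagged per pair in the \code{flat} attribute.
#'
#' @param truthFreqs Named simplex vector over haplotypes of
#'   \code{truthRefs}.
#' @param refs The [KirHapSet-class] used for estimation; must contain at
#'   least one subset/superset signature pair.
#' @param n Number of individuals to simulate.
#' @param seed Integer seed for the simulator.
#' @param truthRefs Optional [KirHapSet-class] the truth draws from
#'   (defaults to \code{refs}).
#' @param tol,maxIter EM controls, as in [emFrequencies()].
#' @param flatTol A subset/superset direction is declared flat when
#'   transferring 0.01 of frequency from the superset to the subset costs
#'   fewer than \code{flatTol} log-likelihood units (default 2, roughly a
#'   95% likelihood-ratio band: the data cannot tell the split apart).
#' @return data.frame: haplotype_id (PA-collapsed id over \code{refs}),
#'   truth, pa_estimate, cnv_estimate (conditional scales), with
#'   attributes \code{unRate} (named: pa, cnv), \code{nesting} (the
#'   [subsetReport()] of the PA-collapsed refs with a \code{flat} flag) and
#'   \code{fits} (the two [KirFreqFit-class] objects).
#' @export
stealingExperiment <- function(truthFreqs, refs, n = 2000L, seed = 1L,
                               truthRefs = NULL, tol = 1e-8,
                               maxIter = 1000L, flatTol = 2) {
    if (is.null(truthRefs)) truthRefs <- refs
    paRefs <- collapseToPA(refs)
    nest <- subsetReport(paRefs)
    if (!nrow(nest))
        stop("refs contain no gene-content subset/superset haplotype pair")
    sim <- simulateCohort(truthFreqs, truthRefs, n = n, resolution = "CNV",
                          missingRates = NULL, seed = seed)
    gts <- sim$genotypes
    fitCNV <- emFrequencies(gts, refs, tol = tol, maxIter = maxIter)
    fitPA <- emFrequencies(downconvert(gts), paRefs, tol = tol,
                           maxIter = maxIter)
    ## map truth and CNV estimates onto PA-collapsed ids
    member <- strsplit(hapIds(paRefs), "/", fixed = TRUE)
    truthOn <- function(ids) sum(truthFreqs[names(truthFreqs) %in% ids])
    cnvOn <- function(ids) sum(frequencies(fitCNV)[ids], na.rm = TRUE)
    out <- data.frame(
        haplotype_id = hapIds(paRefs),
        truth = vapply(member, truthOn, numeric(1L)),
        pa_estimate = unname(frequencies(fitPA)[hapIds(paRefs)]),
        cnv_estimate = vapply(member, cnvOn, numeric(1L)),
        stringsAsFactors = FALSE)
    ## flatness: transfer eps between subset and superset, refit nothing --
    ## just compare observed LL at the perturbed point
    ex <- fitPA@expansion
    p0 <- frequencies(fitPA)
    nest$flat <- vapply(seq_len(nrow(nest)), function(r) {
        a <- nest$subset_id[r]; b <- nest$superset_id[r]
        eps <- min(0.01, p0[b], 1 - p0[a])
        if (eps <= 0) return(FALSE)
        p1 <- p0
        p1[a] <- p1[a] + eps
        p1[b] <- p1[b] - eps
        (.obsLogLik(ex, .alignFreqs(p1, ex@hapIds)) -
         .obsLogLik(ex, .alignFreqs(p0, ex@hapIds))) > -flatTol
    }, logical(1L))
    attr(out, "unRate") <- c(pa = unRate(fitPA), cnv = unRate(fitCNV))
    attr(out, "nesting") <- nest
    attr(out, "fits") <- list(pa = fitPA, cnv = fitCNV)
    out
}
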