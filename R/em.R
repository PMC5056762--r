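## ---- EM for haplotype frequencies under Hardy-Weinberg pair sampling ----
##
## Model: each individual draws two haplotypes independently from the
## frequency vector p; the genotype is a deterministic (possibly lossy)
## function of the pair. For genotype class k the observed-data likelihood
## term is sum over compatible unordered pairs (i <= j) of delta * p_i * p_j,
## delta = 1 for homozygous pairs and 2 otherwise. Uninterpretable classes
## contribute no term and are surfaced through the un-rate.

.classLogLik <- function(pairs, p) {
    i <- pairs[, 1L]; j <- pairs[, 2L]
    delta <- ifelse(i == j, 1, 2)
    log(sum(delta * p[i] * p[j]))
}

.obsLogLik <- function(expansion, p) {
    keep <- vapply(expansion@pairs, nrow, integer(1L)) > 0L
    sum(vapply(which(keep), function(k)
        expansion@classCount[k] * .classLogLik(expansion@pairs[[k]], p),
        numeric(1L)))
}

#' EM expectation step
#'
#' Replaces each genotype's pair weights with the posterior probability of
#' each compatible unordered pair under the current frequencies:
#' a_kij = delta * P(h_i) P(h_j) / sum over compatible pairs of the same,
#' with delta = 1 for homozygous pairs and 2 for heterozygous pairs (the
#' Hardy-Weinberg ordering factor). Weights are scale-invariant in the
#' frequency vector. If every compatible pair of a genotype has zero prior
#' mass the weights fall back to uniform over the compatible pairs (the
#' degenerate-support rule), so zero-frequency haplotypes never produce
#' NaN posteriors.
#'
#' @param expansion A [KirExpansionSet-class].
#' @param freqs Named numeric vector over the expansion's haplotype ids.
#' @return The expansion with updated weights.
#' @export
eStep <- function(expansion, freqs) {
    p <- .alignFreqs(freqs, expansion@hapIds)
    expansion@weights <- lapply(expansion@pairs, function(pr) {
        if (!nrow(pr)) return(numeric())
        i <- pr[, 1L]; j <- pr[, 2L]
        w <- ifelse(i == j, 1, 2) * p[i] * p[j]
        s <- sum(w)
        if (s <= 0) rep(1 / nrow(pr), nrow(pr)) else w / s
    })
    expansion
}

#' EM maximization step
#'
#' Gene-counting update: each interpretable genotype contributes its two
#' chromosomes to the expected haplotype counts according to its pair
#' posteriors, P(h_i) = (1 / 2K) * sum_k c_k (2 a_kii + sum_{j != i} a_kij),
#' where c_k is the multiplicity of genotype class k and K the number of
#' interpretable individuals. The output lies on the simplex.
#'
#' @param expansion A [KirExpansionSet-class] whose weights are posteriors
#'   (each non-empty weight vector sums to 1).
#' @return Named frequency vector over the expansion's haplotype ids.
#' @export
mStep <- function(expansion) {
    H <- length(expansion@hapIds)
    counts <- numeric(H)
    K <- 0
    for (k in seq_along(expansion@pairs)) {
        pr <- expansion@pairs[[k]]
        if (!nrow(pr)) next
        ck <- expansion@classCount[k]
        w <- expansion@weights[[k]] * ck
        K <- K + ck
        ## each pair contributes one copy to each member; homozygotes two
        counts <- counts +
            tabulateWeights(pr[, 1L], w, H) + tabulateWeights(pr[, 2L], w, H)
    }
    if (K == 0)
        stop("no interpretable genotypes: every individual has an empty expansion")
    stats::setNames(counts / (2 * K), expansion@hapIds)
}

tabulateWeights <- function(idx, w, n) {
    out <- numeric(n)
    agg <- rowsum(w, idx)
    out[as.integer(rownames(agg))] <- agg[, 1L]
    out
}

.alignFreqs <- function(freqs, ids) {
    if (is.null(names(freqs))) {
        if (length(freqs) != length(ids))
            stop("unnamed frequency vector of wrong length")
        return(as.numeric(freqs))
    }
    unknown <- setdiff(names(freqs)[freqs > 0], ids)
    if (length(unknown))
        stop("frequencies name unknown haplotypes: ",
             paste(unknown, collapse = ", "))
    p <- stats::setNames(numeric(length(ids)), ids)
    hit <- names(freqs)[names(freqs) %in% ids]
    p[hit] <- freqs[hit]
    unname(p)
}

#' Estimate haplotype frequencies by EM
#'
#' Fits haplotype frequencies to a cohort of genotypes under
#' Hardy-Weinberg pair sampling, constrained to a reference haplotype set.
#' Starting from equal frequencies, the algorithm alternates the
#' expectation step ([eStep()]) and the gene-counting maximization step
#' ([mStep()]) until the observed-data log-likelihood changes by less than
#' \code{tol} or \code{maxIter} is reached. The fit is deterministic: there
#' is no randomness anywhere in the algorithm, so identical inputs give
#' bit-identical results.
#'
#' Individuals whose genotype no reference pair explains are excluded from
#' the likelihood and reported through \code{unRate}; the fitted
#' frequencies are conditional on interpretability (they sum to 1 over the
#' reference set). Use [reportFrequencies()] for the overall scale with an
#' explicit "un" row.
#'
#' @param x A [KirGenotypes-class] or a pre-computed
#'   [KirExpansionSet-class].
#' @param hapset A [KirHapSet-class]; ignored (may be missing) when
#'   \code{x} is already an expansion.
#' @param tol Absolute log-likelihood convergence tolerance (> 0).
#' @param maxIter Maximum EM iterations (>= 1). Non-convergence is reported
#'   via \code{converged(fit)}, not as an error.
#' @param floor Optional epsilon added to every frequency after
#'   convergence (then renormalized) for users needing strictly positive
#'   estimates; default 0 (frequencies may reach exactly 0).
#' @param ... Unused.
#' @return A [KirFreqFit-class].
#' @examples
#' m <- rbind(hA = c(1L, 0L), hB = c(1L, 1L), hC = c(0L, 1L))
#' colnames(m) <- c("a", "b")
#' refs <- KirHapSet(m)
#' v <- matrix(c(2L, 1L), 1, dimnames = list(NULL, c("a", "b")))
#' fit <- emFrequencies(KirGenotypes(v, "CNV"), refs)
#' frequencies(fit)   # hA and hB at 0.5
#' @rdname emFrequencies
#' @export
setMethod("emFrequencies", "KirGenotypes",
    function(x, hapset, tol = 1e-8, maxIter = 1000L, floor = 0, ...) {
        emFrequencies(expandGenotypes(x, hapset), tol = tol,
                      maxIter = maxIter, floor = floor)
    })

#' @rdname emFrequencies
#' @export
setMethod("emFrequencies", "KirExpansionSet",
    function(x, hapset, tol = 1e-8, maxIter = 1000L, floor = 0, ...) {
        stopifnot(tol > 0, maxIter >= 1L)
        H <- length(x@hapIds)
        keep <- vapply(x@pairs, nrow, integer(1L)) > 0L
        nInterp <- sum(x@classCount[keep])
        nTotal <- sum(x@classCount)
        if (nInterp == 0L)
            stop("no interpretable genotypes: every individual has an empty expansion")
        p <- rep(1 / H, H)
        ll <- .obsLogLik(x, p)
        trace <- ll
        converged <- FALSE
        iter <- 0L
        while (iter < maxIter) {
            iter <- iter + 1L
            x <- eStep(x, p)
            p <- unname(mStep(x))
            llNew <- .obsLogLik(x, p)
            trace <- c(trace, llNew)
            if (abs(llNew - ll) < tol) {
                converged <- TRUE
                ll <- llNew
                break
            }
            ll <- llNew
        }
        ## posterior weights at the final frequencies
        x <- eStep(x, p)
        if (floor > 0) {
            p <- p + floor
            p <- p / sum(p)
        }
        new("KirFreqFit",
            frequencies = stats::setNames(p, x@hapIds),
            unRate = 1 - nInterp / nTotal,
            loglik = trace, nIter = iter, converged = converged,
            expansion = x)
    })

#' Accessors for KirFreqFit
#'
#' \code{frequencies} returns the fitted haplotype frequencies (conditional
#' on interpretability); \code{unRate} the uninterpretable fraction;
#' \code{loglikTrace} the per-iteration observed-data log-likelihood;
#' \code{converged} whether the tolerance was met before maxIter.
#'
#' @param x A [KirFreqFit-class].
#' @name KirFreqFit-accessors
NULL

#' @rdname KirFreqFit-accessors
#' @export
setMethod("frequencies", "KirFreqFit", function(x) x@frequencies)

#' @rdname KirFreqFit-accessors
#' @export
setMethod("unRate", "KirFreqFit", function(x) x@unRate)

#' @rdname KirFreqFit-accessors
#' @export
setMethod("loglikTrace", "KirFreqFit", function(x) x@loglik)

#' @rdname KirFreqFit-accessors
#' @export
setMethod("converged", "KirFreqFit", function(x) x@converged)

setMethod("show", "KirFreqFit", function(object) {
    cat("KirFreqFit (", length(object@frequencies), " haplotypes, ",
        length(object@expansion), " individuals)\n", sep = "")
    cat(sprintf("  converged: %s after %d iterations (logLik %.4f)\n",
                object@converged, object@nIter,
                object@loglik[length(object@loglik)]))
    cat(sprintf("  uninterpretable: %.2f%%\n", 100 * object@unRate))
    f <- sort(object@frequencies, decreasing = TRUE)
    top <- utils::head(f[f > 0], 5L)
    cat("  top frequencies: ",
        paste(sprintf("%s=%.4f", names(top), top), collapse = ", "),
        "\n", sep = "")
})

#' Report fitted frequencies on the conditional or overall scale
#'
#' The conditional scale presents P(h_i) summing to 1 over the reference
#' set, given interpretability. The overall scale rescales by
#' (1 - unRate) and appends an explicit "un" row carrying the fraction of
#' uninterpretable individuals, so that the table sums to 1 over the whole
#' cohort. Both presentations are standard; emit both rather than guessing
#' which a downstream consumer wants.
#'
#' @param fit A [KirFreqFit-class].
#' @param scale "conditional", "overall", or "both" (default).
#' @return data.frame: haplotype_id, frequency_conditional and/or
#'   frequency_overall (with an "un" row on the overall scale, NA on the
#'   conditional scale).
#' @export
reportFrequencies <- function(fit, scale = c("both", "conditional", "overall")) {
    scale <- match.arg(scale)
    f <- frequencies(fit)
    out <- data.frame(haplotype_id = names(f),
                      frequency_conditional = unname(f),
                      stringsAsFactors = FALSE)
    if (scale != "conditional") {
        out$frequency_overall <- unname(f) * (1 - unRate(fit))
        out <- rbind(out, data.frame(haplotype_id = "un",
                                     frequency_conditional = NA_real_,
                                     frequency_overall = unRate(fit)))
    }
    if (scale == "overall")
        out$frequency_conditional <- NULL
    rownames(out) <- NULL
    out
}

#' Maximum-posterior haplotype-pair assignments
#'
#' For every interpretable individual, the compatible pair(s) of maximum
#' posterior probability under the converged frequencies. All pairs within
#' \code{tieTol} of the maximum are reported (ordered by haplotype id),
#' never a silent arbitrary choice among ties.
#'
#' @param x A [KirFreqFit-class].
#' @param tieTol Posterior tolerance for reporting ties.
#' @rdname assignments
#' @return data.frame: sample_id, population, best_pairs ("h1+h2",
#'   semicolon-joined across ties), posterior (the maximum), n_best,
#'   n_compatible_pairs. Uninterpretable individuals appear with NA pairs.
#' @export
setMethod("assignments", "KirFreqFit", function(x, tieTol = 1e-12) {
    ex <- x@expansion
    perClass <- lapply(seq_along(ex@pairs), function(k) {
        pr <- ex@pairs[[k]]
        if (!nrow(pr))
            return(list(pairs = NA_character_, post = NA_real_,
                        nBest = 0L, nPairs = 0L))
        w <- ex@weights[[k]]
        best <- which(w >= max(w) - tieTol)
        lab <- vapply(best, function(b)
            paste(ex@hapIds[pr[b, 1L]], ex@hapIds[pr[b, 2L]], sep = "+"),
            character(1L))
        lab <- lab[order(lab, method = "radix")]
        list(pairs = paste(lab, collapse = ";"), post = max(w),
             nBest = length(best), nPairs = nrow(pr))
    })
    cls <- ex@classOf
    data.frame(sample_id = ex@sampleId,
               population = ex@population,
               best_pairs = vapply(perClass, `[[`, character(1L), "pairs")[cls],
               posterior = vapply(perClass, `[[`, numeric(1L), "post")[cls],
               n_best = vapply(perClass, `[[`, integer(1L), "nBest")[cls],
               n_compatible_pairs =
                   vapply(perClass, `[[`, integer(1L), "nPairs")[cls],
               stringsAsFactors = FALSE)
})
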