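test_that("expectation step computes delta-weighted pair posteriors", {
    refs <- toyRefs2()
    genes <- panelGenes(refs)
    # single compatible pair: weight 1 regardless of frequencies
    ex1 <- expandGenotypes(gtCNV(c(2, 1), genes), refs)
    ex1 <- eStep(ex1, c(hA = 0.01, hB = 0.01, hC = 0.98))
    expect_equal(pairList(ex1, 1)$weight, 1)
    # {(hA,hB), (hC,hC)} at equal frequencies: heterozygote gets delta = 2
    m <- rbind(hA = c(1L, 0L), hB = c(0L, 1L), hC = c(1L, 1L))
    colnames(m) <- genes
    refs2 <- KirHapSet(m)
    g <- gtCNV(c(1, 1), genes)          # hA+hB = (1,1), hC+hC = (2,2)? no:
    # hC+hC = (2,2) is incompatible; use PA to admit both pairs
    gPA <- gtPA(c("geneA", "geneB"), genes)
    ex2 <- expandGenotypes(gPA, refs2)
    ex2@pairs[[1]] <- ex2@pairs[[1]][
        paste(ex2@pairs[[1]][, 1], ex2@pairs[[1]][, 2]) %in% c("1 2", "3 3"), ,
        drop = FALSE]
    ex2@weights[[1]] <- rep(0.5, 2)
    ex2 <- eStep(ex2, c(hA = 1/3, hB = 1/3, hC = 1/3))
    expect_equal(pairList(ex2, 1)$weight, c(2/3, 1/3))
    # scale invariance: unnormalized frequencies give identical weights
    ex3 <- eStep(ex2, c(hA = 2/3, hB = 2/3, hC = 2/3))
    expect_equal(pairList(ex3, 1)$weight, pairList(ex2, 1)$weight)
})

test_that("expectation step falls back to uniform when all compatible pairs
           have zero prior mass", {
    refs <- toyRefs2()
    genes <- panelGenes(refs)
    ex <- expandGenotypes(gtPA(c("geneA", "geneB"), genes), refs)
    ex <- eStep(ex, c(hA = 1, hB = 0, hC = 0))   # every pair needs hB or hC
    w <- pairList(ex, 1)$weight
    expect_equal(w, rep(0.25, 4))
})

test_that("maximization step is the gene-counting update", {
    refs <- toyRefs2()
    genes <- panelGenes(refs)
    # two unambiguous individuals: (hA,hA) and (hA,hB) -> 3/4, 1/4
    g <- bindGenotypes(gtCNV(c(2, 0), genes), gtCNV(c(2, 1), genes))
    ex <- expandGenotypes(g, refs)
    f <- mStep(ex)
    expect_equal(unname(f[c("hA", "hB")]), c(0.75, 0.25))
    # one individual, weight 1/2 on (hA,hB), 1/2 on (hC,hC) -> (1/4,1/4,1/2);
    # refs where both pairs are compatible with the same PA genotype
    m <- rbind(hA = c(1L, 0L), hB = c(0L, 1L), hC = c(1L, 1L))
    colnames(m) <- genes
    exw <- expandGenotypes(gtPA(c("geneA", "geneB"), genes), KirHapSet(m))
    keep <- paste(exw@pairs[[1]][, 1], exw@pairs[[1]][, 2]) %in%
        c("1 2", "3 3")
    expect_equal(sum(keep), 2L)
    exw@pairs[[1]] <- exw@pairs[[1]][keep, , drop = FALSE]
    exw@weights[[1]] <- c(0.5, 0.5)
    fw <- mStep(exw)
    expect_equal(unname(fw), c(0.25, 0.25, 0.5))
    # symmetric weights give symmetric frequencies
    exs <- expandGenotypes(gtPA(c("geneA", "geneB"), genes), refs)
    exs@pairs[[1]] <- rbind(c(1L, 2L), c(2L, 3L))
    exs@weights[[1]] <- c(0.5, 0.5)
    fs <- mStep(exs)
    expect_equal(fs[["hA"]], fs[["hC"]])
    # no interpretable genotypes is an error
    exEmpty <- expandGenotypes(gtPA(character(), genes), refs)
    expect_error(mStep(exEmpty), "no interpretable genotypes")
})

test_that("a fully unambiguous cohort converges immediately to observed
           chromosome proportions", {
    refs <- toyRefs2()
    genes <- panelGenes(refs)
    g <- bindGenotypes(gtCNV(c(2, 0), genes),   # hA,hA
                       gtCNV(c(2, 1), genes),   # hA,hB
                       gtCNV(c(2, 2), genes),   # hB,hB
                       gtCNV(c(1, 2), genes))   # hB,hC
    fit <- emFrequencies(g, refs)
    expect_true(converged(fit))
    expect_equal(unname(frequencies(fit)),
                 c(3, 4, 1) / 8, tolerance = 1e-12)
    expect_equal(unRate(fit), 0)
})

test_that("EM matches the brute-force simplex-grid MLE on toy instances", {
    refs <- toyRefs2()
    genes <- panelGenes(refs)
    # hand-built 8-genotype, 3-haplotype instance mixing resolutions
    g <- bindGenotypes(
        gtPA(c("geneA", "geneB"), genes), gtPA(c("geneA", "geneB"), genes),
        gtPA("geneA", genes), gtCNV(c(2, 1), genes),
        gtPA(c("geneA", "geneB"), genes), gtCNV(c(1, 1), genes),
        gtPA("geneB", genes), gtCNV(c(0, 2), genes))
    fit <- emFrequencies(g, refs, tol = 1e-12)
    orc <- oracleExpand(g, refs)
    opt <- oracleGridMLE(orc, rep(1, length(orc)), 3)
    expect_equal(unname(frequencies(fit)), unname(opt), tolerance = 1e-3)
    # random 4-haplotype instances
    set.seed(99)
    for (rep in 1:3) {
        refs4 <- randomHapSet(H = 4, G = 3)
        sim <- simulateCohort(setNames(c(0.4, 0.3, 0.2, 0.1), hapIds(refs4)),
                              refs4, n = 12,
                              resolution = if (rep %% 2) "PA" else "CNV",
                              missingRates = NULL, seed = 20 + rep)
        ex <- expandGenotypes(sim$genotypes, refs4)
        if (sum(interpretable(ex)) == 0) next
        fit4 <- emFrequencies(ex, tol = 1e-12, maxIter = 20000L)
        orc4 <- oracleExpand(sim$genotypes, refs4)
        keep <- vapply(orc4, nrow, integer(1)) >= 0
        opt4 <- oracleGridMLE(orc4, rep(1, length(orc4)), 4)
        llEM <- oracleLL(unname(frequencies(fit4)), orc4,
                         rep(1, length(orc4)))
        llGrid <- oracleLL(opt4, orc4, rep(1, length(orc4)))
        # the EM optimum must match the grid optimum in likelihood, and in
        # location wherever the maximizer is unique
        expect_gte(llEM, llGrid - 1e-6)
        if (max(abs(unname(frequencies(fit4)) - opt4)) > 1e-3)
            expect_lte(abs(llEM - llGrid), 1e-6)
    }
})

test_that("log-likelihood is non-decreasing and frequencies stay on the
           simplex every iteration", {
    refs <- syntheticHapSet()
    truth <- setNames(c(0.45, 0.12, 0.1, 0.1, 0.08, 0.05, 0.04, 0.03,
                        0.02, 0.01), hapIds(refs))
    sim <- simulateCohort(truth, refs, n = 300, resolution = "PA", seed = 3)
    fit <- emFrequencies(sim$genotypes, collapseToPA(refs))
    tr <- loglikTrace(fit)
    expect_true(all(diff(tr) >= -1e-9))
    expect_equal(sum(frequencies(fit)), 1, tolerance = 1e-9)
    expect_true(all(frequencies(fit) >= 0))
})

test_that("simulated CNV cohorts with a complete reference set are recovered
           within sampling error", {
    refs <- syntheticHapSet()
    truth <- setNames(c(0.40, 0.14, 0.12, 0.10, 0.08, 0.06, 0.04, 0.03,
                        0.02, 0.01), hapIds(refs))
    for (n in c(200, 2000)) {
        sim <- simulateCohort(truth, refs, n = n, resolution = "CNV",
                              missingRates = NULL, seed = 17)
        fit <- emFrequencies(sim$genotypes, refs)
        err <- max(abs(frequencies(fit)[names(truth)] - truth))
        expect_lt(err, if (n == 200) 0.06 else 0.02)
        expect_equal(unRate(fit), 0)
    }
})

test_that("estimates are invariant to genotype order and haplotype order", {
    refs <- syntheticHapSet()
    truth <- setNames(c(0.45, 0.12, 0.1, 0.1, 0.08, 0.05, 0.04, 0.03,
                        0.02, 0.01), hapIds(refs))
    sim <- simulateCohort(truth, refs, n = 120, resolution = "CNV",
                          missingRates = NULL, seed = 8)
    g <- sim$genotypes
    fit <- emFrequencies(g, refs)
    set.seed(1)
    perm <- sample(length(g))
    fitPermG <- emFrequencies(g[perm], refs)
    expect_equal(frequencies(fitPermG), frequencies(fit), tolerance = 1e-9)
    permH <- refs[rev(hapIds(refs))]
    fitPermH <- emFrequencies(g, permH)
    expect_equal(frequencies(fitPermH)[names(frequencies(fit))],
                 frequencies(fit), tolerance = 1e-9)
})

test_that("frequency reports scale conditional estimates by interpretability
           and conserve mass", {
    refs <- toyRefs2()
    genes <- panelGenes(refs)
    g <- bindGenotypes(gtCNV(c(2, 1), genes),     # hA+hB
                       gtCNV(c(2, 1), genes),
                       gtCNV(c(2, 1), genes),
                       gtCNV(c(2, 1), genes),
                       gtPA(character(), genes))  # uninterpretable
    fit <- emFrequencies(g, refs)
    expect_equal(unRate(fit), 0.2)
    rep <- reportFrequencies(fit, "both")
    cond <- rep$frequency_conditional[rep$haplotype_id != "un"]
    expect_equal(sum(cond), 1)
    expect_equal(sum(rep$frequency_overall), 1)
    expect_equal(rep$frequency_overall[rep$haplotype_id == "un"], 0.2)
    expect_equal(rep$frequency_overall[rep$haplotype_id == "hA"],
                 0.5 * 0.8)
    # un_rate = 0: both scales identical
    fit0 <- emFrequencies(g[1:4], refs)
    rep0 <- reportFrequencies(fit0, "both")
    noUn <- rep0[rep0$haplotype_id != "un", ]
    expect_equal(noUn$frequency_overall, noUn$frequency_conditional)
})

test_that("assignments report every pair tied at maximum posterior", {
    refs <- toyRefs2()
    genes <- panelGenes(refs)
    g <- bindGenotypes(gtCNV(c(2, 1), genes),     # unambiguous hA+hB
                       gtPA(c("geneA", "geneB"), genes),
                       gtPA(character(), genes))
    fit <- emFrequencies(g, refs)
    a <- assignments(fit)
    expect_equal(a$best_pairs[1], "hA+hB")
    expect_equal(a$posterior[1], 1)
    expect_true(is.na(a$best_pairs[3]))
    expect_equal(a$n_compatible_pairs[2], 4L)
    expect_true(a$n_best[2] >= 1L)
    # symmetric frequencies create reported ties
    m <- rbind(u = c(1L, 0L), v = c(0L, 1L))
    colnames(m) <- genes
    refs2 <- KirHapSet(m)
    g2 <- bindGenotypes(gtPA(c("geneA", "geneB"), genes),
                        gtPA(c("geneA", "geneB"), genes))
    fit2 <- emFrequencies(g2, refs2)
    a2 <- assignments(fit2)
    expect_equal(a2$best_pairs[1], "u+v")
    # now a genotype where two pairs tie exactly
    m3 <- rbind(u = c(1L, 0L), v = c(0L, 1L), w = c(1L, 1L))
    colnames(m3) <- genes
    g3 <- gtCNV(c(1, 1), genes)
    fit3 <- emFrequencies(g3, KirHapSet(m3))
    a3 <- assignments(fit3)
    expect_equal(a3$n_compatible_pairs, 1L)
})

test_that("floored fits stay on the simplex with strictly positive entries", {
    refs <- toyRefs2()
    genes <- panelGenes(refs)
    g <- bindGenotypes(gtCNV(c(2, 1), genes), gtCNV(c(2, 0), genes))
    fit <- emFrequencies(g, refs, floor = 1e-6)
    expect_true(all(frequencies(fit) > 0))
    expect_equal(sum(frequencies(fit)), 1, tolerance = 1e-12)
})
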