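test_that("TRS is sum of squared posteriors with the documented bounds", {
    expect_equal(typingResolutionScore(1), 1)
    expect_equal(typingResolutionScore(c(0.5, 0.5)), 0.5)
    expect_equal(typingResolutionScore(rep(0.25, 4)), 0.25)
    # uniform over n scores exactly 1/n
    for (n in c(2, 3, 7, 20))
        expect_equal(typingResolutionScore(rep(1 / n, n)), 1 / n)
    # 1 iff a single pair; always >= 1/n
    set.seed(2)
    for (rep in 1:20) {
        n <- sample(2:8, 1)
        w <- stats::runif(n); w <- w / sum(w)
        s <- typingResolutionScore(w)
        expect_true(s >= 1 / n - 1e-12 && s <= 1)
        expect_true(s < 1)
    }
    # uninterpretable: no score, distinct from 0
    expect_true(is.na(typingResolutionScore(numeric())))
    expect_error(typingResolutionScore(c(0.5, 0.4)), "sum to 1")
})

test_that("TRS tables score interpretable individuals and drop the rest", {
    refs <- toyRefs2()
    genes <- panelGenes(refs)
    g <- bindGenotypes(gtCNV(c(2, 1), genes),
                       gtPA(c("geneA", "geneB"), genes),
                       gtPA(character(), genes))
    fit <- emFrequencies(g, refs)
    tab <- trsTable(fit)
    expect_equal(nrow(tab), 2L)
    expect_equal(tab$trs[tab$sample_id == "S1"], 1)
    expect_true(tab$trs[tab$sample_id == "S2"] < 1)
    expect_equal(tab$n_pairs[tab$sample_id == "S2"], 4L)
})

test_that("TRS distributions follow Tukey box-plot conventions", {
    one <- trsDistribution(rep(1, 10))
    expect_equal(one$median, 1)
    expect_equal(one$q3 - one$q1, 0)
    expect_equal(one$n_outliers, 0)
    nine <- trsDistribution(seq(0.2, 1, by = 0.1))
    expect_equal(nine$median, 0.6)
    withOut <- trsDistribution(c(rep(0.9, 20), 0.1))
    expect_equal(withOut$n_outliers, 1)
    expect_equal(withOut$whisker_low, 0.9)
})

test_that("with identical frequencies, CNV typing never scores below PA for
           the same individual, and cohort medians follow", {
    refs <- syntheticHapSet()
    truth <- setNames(c(0.40, 0.14, 0.12, 0.10, 0.08, 0.06, 0.04, 0.03,
                        0.02, 0.01), hapIds(refs))
    sim <- simulateCohort(truth, refs, n = 200, resolution = "CNV",
                          missingRates = NULL, seed = 23)
    exCNV <- expandGenotypes(sim$genotypes, refs)
    exPA <- expandGenotypes(downconvert(sim$genotypes), refs)
    f <- setNames(rep(1 / 10, 10), hapIds(refs))
    exCNV <- eStep(exCNV, f)
    exPA <- eStep(exPA, f)
    tCNV <- trsTable(exCNV); tPA <- trsTable(exPA)
    shared <- intersect(tCNV$sample_id, tPA$sample_id)
    expect_gt(length(shared), 100)
    expect_true(all(tCNV$trs[match(shared, tCNV$sample_id)] >=
                    tPA$trs[match(shared, tPA$sample_id)] - 1e-12))
    # converged fits: the higher resolution keeps a higher median TRS
    fitCNV <- emFrequencies(exCNV)
    fitPA <- emFrequencies(exPA)
    expect_gte(trsDistribution(trsTable(fitCNV)$trs)$median,
               trsDistribution(trsTable(fitPA)$trs)$median)
})

test_that("subset report lists nested PA signatures with differing genes,
           transitively consistently", {
    refs <- syntheticHapSet()
    rep <- subsetReport(refs)
    r60 <- rep[rep$subset_id == "60" & rep$superset_id == "1", ]
    expect_equal(nrow(r60), 1L)
    expect_equal(r60$differing_genes, "KIR3DL3")
    r4 <- rep[rep$subset_id == "4" & rep$superset_id == "51", ]
    expect_equal(nrow(r4), 1L)
    expect_setequal(strsplit(r4$differing_genes, ",")[[1]],
                    c("KIR2DP1", "KIR2DL1"))
    # collapsed set: 4 is a subset of the merged 49/51
    pa <- collapseToPA(refs)
    repPA <- subsetReport(pa)
    r451 <- repPA[repPA$subset_id == "4" & repPA$superset_id == "49/51", ]
    expect_equal(nrow(r451), 1L)
    expect_setequal(strsplit(r451$differing_genes, ",")[[1]],
                    c("KIR2DP1", "KIR2DL1"))
    # transitive consistency on a chain a < b < c
    m <- rbind(a = c(1L, 0L, 0L), b = c(1L, 1L, 0L), c = c(1L, 1L, 1L))
    colnames(m) <- c("x", "y", "z")
    chain <- subsetReport(KirHapSet(m))
    keys <- paste(chain$subset_id, chain$superset_id)
    expect_setequal(keys, c("a b", "a c", "b c"))
    # no nesting: empty report
    m2 <- rbind(p = c(1L, 0L), q = c(0L, 1L))
    colnames(m2) <- c("x", "y")
    expect_equal(nrow(subsetReport(KirHapSet(m2))), 0L)
})

test_that("hidden-haplotype experiment: PA inflates the nested haplotype,
           CNV recovers the truth and flags the orphans", {
    refs <- nestedRefs3()[c("full", "del")]
    truthRefs <- nestedRefs3()
    truth <- c(full = 0.89, del = 0.03, frag = 0.08)
    out <- stealingExperiment(truth, refs, n = 2000, seed = 4,
                              truthRefs = truthRefs)
    sub <- out[out$haplotype_id == "del", ]
    expect_gt(sub$pa_estimate, sub$truth)
    # CNV: orphan genotypes drop out; compare to truth renormalized over refs
    condTruth <- sub$truth / (truth[["full"]] + truth[["del"]])
    expect_lt(abs(sub$cnv_estimate - condTruth), 0.02)
    un <- attr(out, "unRate")
    expect_gt(un[["cnv"]], un[["pa"]])
    nest <- attr(out, "nesting")
    expect_equal(nest$subset_id, "del")
    # refs without nesting are rejected
    m <- rbind(p = c(1L, 0L), q = c(0L, 1L))
    colnames(m) <- c("x", "y")
    expect_error(stealingExperiment(c(p = 0.5, q = 0.5), KirHapSet(m),
                                    n = 10, seed = 1),
                 "no gene-content subset/superset")
})

test_that("an unresolvable subset/superset split is flagged as flat", {
    # subset at truth 0 and no genotype distinguishing the pair: every
    # individual is a full/full homozygote at PA, so moving mass between
    # 'full' and 'del' only trades within one ambiguity class
    m <- rbind(full = c(1L, 1L, 1L), del = c(0L, 1L, 1L))
    colnames(m) <- c("gA", "gB", "gC")
    refs <- KirHapSet(m)
    out <- stealingExperiment(c(full = 1), refs, n = 100, seed = 9)
    nest <- attr(out, "nesting")
    expect_equal(nrow(nest), 1L)
    expect_true(nest$flat)
    # the full/full PA genotype admits (full,full) and (full,del): the
    # likelihood is curved in that direction, but the CNV estimate is exact
    expect_equal(out$cnv_estimate[out$haplotype_id == "full"], 1,
                 tolerance = 1e-6)
})
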