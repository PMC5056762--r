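# Shared toy fixtures, built in code.

# 2-gene toy reference set used throughout the compatibility/expansion tests
toyRefs2 <- function() {
    m <- rbind(hA = c(1L, 0L), hB = c(1L, 1L), hC = c(0L, 1L))
    colnames(m) <- c("geneA", "geneB")
    KirHapSet(m, name = "toy2")
}

# single-row genotype helpers on an arbitrary panel
gtPA <- function(present, genes, sampleId = "S1", population = NA) {
    v <- matrix(as.integer(genes %in% present), 1,
                dimnames = list(NULL, genes))
    KirGenotypes(v, "PA", sampleId = sampleId, population = population)
}

gtCNV <- function(counts, genes, sampleId = "S1", population = NA) {
    v <- matrix(as.integer(counts), 1, dimnames = list(NULL, genes))
    KirGenotypes(v, "CNV", sampleId = sampleId, population = population)
}

# stack several single-row KirGenotypes into one cohort
bindGenotypes <- function(...) {
    gs <- list(...)
    v <- do.call(rbind, lapply(gs, function(g) unname(genotypeValues(g))))
    md <- do.call(rbind, lapply(gs, function(g) unname(genotypeModes(g))))
    colnames(v) <- colnames(md) <- panelGenes(gs[[1]])
    KirGenotypes(v, md,
                 sampleId = paste0("S", seq_len(nrow(v))),
                 population = unlist(lapply(gs, function(g)
                     unname(populationLabels(g)))))
}

# 3-gene set with a subset/superset pair (full haplotype, its deleted form,
# and a fragment), the hidden-haplotype testbed
nestedRefs3 <- function() {
    m <- rbind(full = c(1L, 1L, 1L),
               del  = c(1L, 1L, 0L),
               frag = c(1L, 0L, 0L))
    colnames(m) <- c("gA", "gB", "gC")
    KirHapSet(m, name = "nested3")
}

# random small hapset + genotype cohort for property-style loops
randomHapSet <- function(H, G, maxCopy = 2L) {
    m <- matrix(sample(0:maxCopy, H * G, replace = TRUE,
                       prob = c(0.45, 0.45, rep(0.1 / (maxCopy - 1), maxCopy - 1))),
                H, G, dimnames = list(paste0("h", seq_len(H)),
                                      paste0("g", seq_len(G))))
    # avoid duplicate copy vectors (invalid without distinct variant tags)
    key <- apply(m, 1, paste, collapse = ",")
    while (anyDuplicated(key)) {
        r <- which(duplicated(key))[1]
        m[r, ] <- sample(0:maxCopy, G, replace = TRUE)
        key <- apply(m, 1, paste, collapse = ",")
    }
    storage.mode(m) <- "integer"
    KirHapSet(m, name = "rand")
}
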