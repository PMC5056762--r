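# Independent oracles. Everything here recomputes quantities from first
# principles with plain loops, sharing no code path with the package.

# compatibility of one observation vector with one haplotype pair
oracleCompatible <- function(values, modes, hap1, hap2) {
    for (g in seq_along(values)) {
        if (is.na(values[g])) next
        s <- hap1[g] + hap2[g]
        ok <- if (modes[g] == "PA") {
            if (values[g] >= 1) s >= 1 else s == 0
        } else {
            s == values[g]
        }
        if (!ok) return(FALSE)
    }
    TRUE
}

# all compatible unordered pairs (i <= j) for one genotype row, by brute force
oraclePairs <- function(values, modes, hapmat) {
    H <- nrow(hapmat)
    out <- NULL
    for (i in seq_len(H)) for (j in i:H) {
        if (oracleCompatible(values, modes, hapmat[i, ], hapmat[j, ]))
            out <- rbind(out, c(i, j))
    }
    if (is.null(out)) matrix(integer(), 0, 2) else out
}

# observed-data log-likelihood: sum_k c_k log(sum_pairs delta p_i p_j)
oracleLL <- function(p, pairsList, counts) {
    ll <- 0
    for (k in seq_along(pairsList)) {
        pr <- pairsList[[k]]
        if (!nrow(pr)) next
        s <- 0
        for (r in seq_len(nrow(pr))) {
            d <- if (pr[r, 1] == pr[r, 2]) 1 else 2
            s <- s + d * p[pr[r, 1]] * p[pr[r, 2]]
        }
        ll <- ll + counts[k] * log(s)
    }
    ll
}

# all compositions of N into H non-negative parts, as rows / N (H <= 4)
simplexGrid <- function(H, N) {
    if (H == 2) {
        i <- 0:N
        cbind(i, N - i) / N
    } else if (H == 3) {
        g <- expand.grid(i = 0:N, j = 0:N)
        g <- g[g$i + g$j <= N, ]
        cbind(g$i, g$j, N - g$i - g$j) / N
    } else if (H == 4) {
        g <- expand.grid(i = 0:N, j = 0:N, k = 0:N)
        g <- g[g$i + g$j + g$k <= N, ]
        cbind(g$i, g$j, g$k, N - g$i - g$j - g$k) / N
    } else stop("simplexGrid supports H <= 4")
}

# vectorized LL over a matrix of simplex points (rows)
oracleLLGrid <- function(P, pairsList, counts) {
    ll <- numeric(nrow(P))
    for (k in seq_along(pairsList)) {
        pr <- pairsList[[k]]
        if (!nrow(pr)) next
        s <- numeric(nrow(P))
        for (r in seq_len(nrow(pr))) {
            d <- if (pr[r, 1] == pr[r, 2]) 1 else 2
            s <- s + d * P[, pr[r, 1]] * P[, pr[r, 2]]
        }
        ll <- ll + counts[k] * ifelse(s > 0, log(s), -Inf)
    }
    ll
}

# brute-force simplex-grid maximizer of the log-likelihood: full coarse grid,
# then local refinement around the incumbent down to `finalStep`
oracleGridMLE <- function(pairsList, counts, H,
                          coarseN = if (H <= 3) 100 else 40,
                          finalStep = 1e-4) {
    P <- simplexGrid(H, coarseN)
    best <- P[which.max(oracleLLGrid(P, pairsList, counts)), ]
    step <- 1 / coarseN
    while (step > finalStep) {
        step <- step / 5
        offs <- as.matrix(do.call(expand.grid,
                                  rep(list(-6:6 * step), H - 1)))
        cand <- matrix(rep(best[-H], each = nrow(offs)), nrow(offs)) + offs
        cand <- cbind(cand, 1 - rowSums(cand))
        cand <- cand[apply(cand, 1, function(r) all(r >= -1e-12)), ,
                     drop = FALSE]
        cand[cand < 0] <- 0
        best <- cand[which.max(oracleLLGrid(cand, pairsList, counts)), ]
    }
    best
}

# oracle expansion of a whole cohort (distinct rows NOT merged; slow, simple)
oracleExpand <- function(genotypes, hapset) {
    v <- genotypeValues(genotypes)
    md <- genotypeModes(genotypes)
    hm <- hapMatrix(hapset)
    lapply(seq_len(nrow(v)), function(k) oraclePairs(v[k, ], md[k, ], hm))
}
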