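## TSV is the canonical dialect throughout: UTF-8, '.' decimal, no quoting
## (gene names and pair lists never need it). Frequencies print with 6
## decimals; comparisons belong in code with tolerances, never on strings.

.readTsv <- function(path) {
    if (!file.exists(path))
        stop("file not found: ", path)
    utils::read.delim(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE, check.names = FALSE,
                      colClasses = "character", na.strings = NULL)
}

.writeTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, na = "")
    invisible(path)
}

.fmtFreq <- function(x) ifelse(is.na(x), NA_character_, sprintf("%.6f", x))

#' Read a reference haplotype set from TSV
#'
#' Expected columns: \code{haplotype_id}, optional \code{nomenclature} and
#' \code{variant_tag}, and one integer column per panel gene (matched by
#' name, in any order; default panel [kirGenes()]). Unknown columns,
#' missing gene columns, duplicate ids and copy numbers outside [0, 4] are
#' each rejected with a diagnostic naming the offender.
#'
#' @param path TSV file path.
#' @param genes Gene panel the file must cover (default [kirGenes()]).
#' @param name Set label (defaults to the file name).
#' @return A [KirHapSet-class].
#' @seealso [writeHapSet()]
#' @export
readHapSet <- function(path, genes = kirGenes(), name = NULL) {
    df <- .readTsv(path)
    if (!"haplotype_id" %in% names(df))
        stop("hapset file lacks a 'haplotype_id' column: ", path)
    meta <- c("haplotype_id", "nomenclature", "variant_tag")
    unknown <- setdiff(names(df), c(meta, genes))
    if (length(unknown))
        stop("unknown column(s) in hapset file: ",
             paste(unknown, collapse = ", "))
    missingGenes <- setdiff(genes, names(df))
    if (length(missingGenes))
        stop("hapset file lacks gene column(s): ",
             paste(missingGenes, collapse = ", "))
    ids <- df$haplotype_id
    if (anyDuplicated(ids))
        stop("duplicate haplotype id(s): ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    m <- matrix(NA_integer_, nrow(df), length(genes),
                dimnames = list(ids, genes))
    for (g in genes) {
        val <- suppressWarnings(as.integer(df[[g]]))
        bad <- which(is.na(val) | val < 0L | val > .MAX_HAP_COPY)
        if (length(bad))
            stop(sprintf(
                "invalid copy number for gene %s, haplotype '%s' (row %d): '%s' (must be an integer in [0, %d])",
                g, ids[bad[1L]], bad[1L], df[[g]][bad[1L]], .MAX_HAP_COPY))
        m[, g] <- val
    }
    KirHapSet(m, name = if (is.null(name)) basename(path) else name,
              nomenclature = if ("nomenclature" %in% names(df))
                  ifelse(df$nomenclature == "", NA, df$nomenclature),
              variantTag = if ("variant_tag" %in% names(df))
                  ifelse(df$variant_tag == "", NA, df$variant_tag))
}

#' Write a reference haplotype set to TSV
#' @param x A [KirHapSet-class].
#' @param path Output path.
#' @return The path, invisibly.
#' @seealso [readHapSet()]
#' @export
writeHapSet <- function(x, path) {
    df <- data.frame(haplotype_id = hapIds(x),
                     nomenclature = ifelse(is.na(x@nomenclature), "",
                                           x@nomenclature),
                     variant_tag = ifelse(is.na(x@variantTag), "",
                                          x@variantTag),
                     stringsAsFactors = FALSE, check.names = FALSE)
    df <- cbind(df, as.data.frame(hapMatrix(x), check.names = FALSE))
    .writeTsv(df, path)
}

#' Read a genotype cohort from TSV
#'
#' Expected columns: \code{sample_id}, optional \code{population}, and one
#' column per panel gene. Cells are "Y"/"N" (presence/absence), a
#' non-negative integer (diploid copy number), or empty (missing);
#' resolution may vary cell by cell. Unparseable cells and duplicate sample
#' ids are rejected with row/column context.
#'
#' @param path TSV file path.
#' @param genes Gene panel the file must cover (default [kirGenes()]).
#' @return A [KirGenotypes-class].
#' @seealso [writeGenotypes()]
#' @export
readGenotypes <- function(path, genes = kirGenes()) {
    df <- .readTsv(path)
    if (!"sample_id" %in% names(df))
        stop("genotype file lacks a 'sample_id' column: ", path)
    meta <- c("sample_id", "population")
    unknown <- setdiff(names(df), c(meta, genes))
    if (length(unknown))
        stop("unknown column(s) in genotype file: ",
             paste(unknown, collapse = ", "))
    missingGenes <- setdiff(genes, names(df))
    if (length(missingGenes))
        stop("genotype file lacks gene column(s): ",
             paste(missingGenes, collapse = ", "))
    ids <- df$sample_id
    if (anyDuplicated(ids))
        stop("duplicate sample id(s): ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    n <- nrow(df)
    V <- matrix(NA_integer_, n, length(genes),
                dimnames = list(NULL, genes))
    M <- matrix(NA_character_, n, length(genes),
                dimnames = list(NULL, genes))
    for (g in genes) {
        cell <- trimws(df[[g]])
        pa <- cell %in% c("Y", "N")
        blank <- cell == ""
        num <- suppressWarnings(as.integer(cell))
        cnv <- !pa & !blank & !is.na(num) & num >= 0L & num <= .MAX_GT_COPY
        bad <- which(!pa & !blank & !cnv)
        if (length(bad))
            stop(sprintf(
                "unparseable genotype cell at row %d (sample '%s'), gene %s: '%s' (expected Y, N, an integer in [0, %d], or empty)",
                bad[1L], ids[bad[1L]], g, df[[g]][bad[1L]], .MAX_GT_COPY))
        V[pa, g] <- as.integer(cell[pa] == "Y")
        M[pa, g] <- "PA"
        V[cnv, g] <- num[cnv]
        M[cnv, g] <- "CNV"
    }
    KirGenotypes(V, M, sampleId = ids,
                 population = if ("population" %in% names(df))
                     ifelse(df$population == "", NA, df$population))
}

#' Write a genotype cohort to TSV
#'
#' PA observations print as "Y"/"N", CNV observations as integers, missing
#' as empty cells, so [readGenotypes()] recovers the object exactly.
#'
#' @param x A [KirGenotypes-class].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeGenotypes <- function(x, path) {
    v <- genotypeValues(x); md <- genotypeModes(x)
    cell <- matrix("", nrow(v), ncol(v), dimnames = dimnames(v))
    pa <- !is.na(md) & md == "PA"
    cell[pa] <- ifelse(v[pa] >= 1L, "Y", "N")
    cnv <- !is.na(md) & md == "CNV"
    cell[cnv] <- as.character(v[cnv])
    pop <- x@population
    df <- data.frame(sample_id = sampleIds(x),
                     population = ifelse(is.na(pop), "", pop),
                     stringsAsFactors = FALSE)
    df <- cbind(df, as.data.frame(cell, check.names = FALSE,
                                  stringsAsFactors = FALSE))
    .writeTsv(df, path)
}

#' Write a fitted frequency table to TSV
#'
#' One row per haplotype plus an "un" row, with conditional and overall
#' frequencies at 6 decimals; an optional population column labels fits run
#' per population.
#'
#' @param fit A [KirFreqFit-class], or a named list of fits (one per
#'   population).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeFrequencies <- function(fit, path) {
    fits <- if (is(fit, "KirFreqFit")) list(ALL = fit) else fit
    tab <- do.call(rbind, lapply(names(fits), function(popn) {
        df <- reportFrequencies(fits[[popn]], "both")
        cbind(population = popn, df)
    }))
    tab$frequency_conditional <- .fmtFreq(tab$frequency_conditional)
    tab$frequency_overall <- .fmtFreq(tab$frequency_overall)
    .writeTsv(tab, path)
}

#' Write per-individual haplotype-pair assignments to TSV
#' @param fit A [KirFreqFit-class].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeAssignments <- function(fit, path) {
    a <- assignments(fit)
    a$posterior <- .fmtFreq(a$posterior)
    .writeTsv(a, path)
}

#' Write a per-individual TRS table to TSV
#' @param x A [KirFreqFit-class], [KirExpansionSet-class], or the
#'   data.frame from [trsTable()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeTrs <- function(x, path) {
    tab <- if (is.data.frame(x)) x else trsTable(x)
    tab$trs <- .fmtFreq(tab$trs)
    .writeTsv(tab, path)
}

#' Write a diagnostic expansion dump to TSV
#'
#' One row per individual: sample id, number of compatible pairs, the pair
#' list ("h1+h2", semicolon-joined), and the interpretable flag.
#'
#' @param x A [KirExpansionSet-class].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeExpansions <- function(x, path) {
    perClass <- vapply(seq_along(x@pairs), function(k) {
        pr <- x@pairs[[k]]
        if (!nrow(pr)) return("")
        paste(paste(x@hapIds[pr[, 1L]], x@hapIds[pr[, 2L]], sep = "+"),
              collapse = ";")
    }, character(1L))
    np <- vapply(x@pairs, nrow, integer(1L))
    cls <- x@classOf
    .writeTsv(data.frame(sample_id = x@sampleId,
                         n_pairs = np[cls],
                         pairs = perClass[cls],
                         interpretable = np[cls] > 0L,
                         stringsAsFactors = FALSE), path)
}

#' Read a simulation configuration (YAML or key:value)
#'
#' Accepts a YAML file (fields: truth_freqs (map), n_individuals,
#' resolution, cnv_genes, missing_rates (map), off_reference_rate,
#' populations (map), seed) and returns a validated argument list for
#' [simulateCohort()]. The count field is spelled \code{n_individuals}
#' because a bare \code{n} is a YAML 1.1 boolean.
#'
#' @param path Config file path.
#' @return Named list of simulateCohort arguments.
#' @export
readSimConfig <- function(path) {
    if (!requireNamespace("yaml", quietly = TRUE))
        stop("reading simulation configs requires the 'yaml' package")
    cfg <- yaml::yaml.load_file(path)
    need <- c("truth_freqs", "n_individuals")
    miss <- setdiff(need, names(cfg))
    if (length(miss))
        stop("simulation config lacks field(s): ", paste(miss, collapse = ", "))
    out <- list(truthFreqs = unlist(cfg$truth_freqs),
                n = as.integer(cfg$n_individuals),
                resolution = if (is.null(cfg$resolution)) "CNV"
                             else toupper(cfg$resolution),
                cnvGenes = as.character(cfg$cnv_genes %||% character()),
                missingRates = if (is.null(cfg$missing_rates))
                    c(KIR2DP1 = 0.10, KIR3DP1 = 0.17)
                    else unlist(cfg$missing_rates),
                offRefRate = cfg$off_reference_rate %||% 0,
                populations = if (!is.null(cfg$populations))
                    unlist(cfg$populations),
                seed = as.integer(cfg$seed %||% 1L))
    if (out$resolution == "MIXED") out$resolution <- "mixed"
    out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The synthetic example reference haplotype set
#'
#' Loads the reference set shipped with the package
#' (\code{inst/extdata/hapset_synthetic.tsv}). It is a synthetic
#' illustration, not a transcription of any published table: ten
#' haplotypes built from the structural motifs of the KIR literature
#' (the canonical cA01~tA01 haplotype; its KIR3DL3-deleted form, a
#' gene-content subset; cB02~tA01; its KIR2DP1~KIR2DL1-carrying extension
#' in one- and two-copy KIR3DL1 forms, which are distinct at CNV but share
#' a PA signature; cA01~tB01; cB01~tA01; cB02~tB01; and a cB03~tA01
#' variant pair tagged _2DS3/_2DS5). It exercises every feature the
#' package models: PA-equivalent haplotypes, subset/superset nesting, and
#' variant-tag splitting.
#'
#' @return A [KirHapSet-class] of 10 haplotypes over [kirGenes()].
#' @export
syntheticHapSet <- function() {
    readHapSet(system.file("extdata", "hapset_synthetic.tsv",
                           package = "kirfreq", mustWork = TRUE),
               name = "synthetic10")
}
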