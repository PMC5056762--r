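#' Construct a reference haplotype set
#'
#' @param copies Integer matrix or data.frame, haplotypes x genes. Rownames
#'   (or the \code{ids} argument) give haplotype ids; colnames name the gene
#'   panel. Copy numbers are copies per gene on one chromosome, in [0, 4].
#' @param ids Optional character vector of haplotype ids overriding rownames.
#' @param name Label for the set.
#' @param nomenclature Optional per-haplotype structural labels
#'   (centromeric~telomeric convention, e.g. "cA01~tB02").
#' @param variantTag Optional per-haplotype tag distinguishing alternative
#'   encodings of a structurally ambiguous haplotype (e.g. "_2DS3"/"_2DS5").
#' @return A [KirHapSet-class] object.
#' @examples
#' m <- rbind(hA = c(1L, 0L), hB = c(1L, 1L))
#' colnames(m) <- c("geneA", "geneB")
#' KirHapSet(m, name = "toy")
#' @export
KirHapSet <- function(copies, ids = NULL, name = "hapset",
                      nomenclature = NULL, variantTag = NULL) {
    if (is.data.frame(copies))
        copies <- as.matrix(copies)
    storage.mode(copies) <- "integer"
    if (!is.null(ids))
        rownames(copies) <- ids
    n <- nrow(copies)
    if (is.null(nomenclature)) nomenclature <- rep(NA_character_, n)
    if (is.null(variantTag)) variantTag <- rep(NA_character_, n)
    new("KirHapSet", name = name, copies = copies,
        nomenclature = as.character(nomenclature),
        variantTag = as.character(variantTag))
}

#' Accessors for KirHapSet
#'
#' \code{hapIds} returns haplotype ids; \code{hapMatrix} the haplotypes x
#' genes integer copy-number matrix; \code{panelGenes} the gene panel;
#' \code{hapsetName} the set label; \code{nomenclature} and \code{variantTag}
#' the optional per-haplotype annotations (named by haplotype id).
#'
#' @param x A [KirHapSet-class].
#' @name KirHapSet-accessors
NULL

#' @rdname KirHapSet-accessors
#' @export
setMethod("hapIds", "KirHapSet", function(x) rownames(x@copies))

#' @rdname KirHapSet-accessors
#' @export
setMethod("hapMatrix", "KirHapSet", function(x) x@copies)

#' @rdname KirHapSet-accessors
#' @export
setMethod("panelGenes", "KirHapSet", function(x) colnames(x@copies))

#' @rdname KirHapSet-accessors
#' @export
setMethod("hapsetName", "KirHapSet", function(x) x@name)

#' @rdname KirHapSet-accessors
#' @export
setMethod("nomenclature", "KirHapSet",
    function(x) stats::setNames(x@nomenclature, hapIds(x)))

#' @rdname KirHapSet-accessors
#' @export
setMethod("variantTag", "KirHapSet",
    function(x) stats::setNames(x@variantTag, hapIds(x)))

#' @export
setMethod("length", "KirHapSet", function(x) nrow(x@copies))

#' Subset a haplotype set by id or index
#' @param x A [KirHapSet-class].
#' @param i Haplotype ids or indices.
#' @param j,drop,... Ignored.
#' @export
setMethod("[", "KirHapSet", function(x, i, j, ..., drop = FALSE) {
    idx <- if (is.character(i)) match(i, hapIds(x)) else i
    if (is.character(i) && anyNA(idx))
        stop("unknown haplotype id(s): ", paste(i[is.na(idx)], collapse = ", "))
    new("KirHapSet", name = x@name,
        copies = x@copies[idx, , drop = FALSE],
        nomenclature = x@nomenclature[idx],
        variantTag = x@variantTag[idx])
})

setMethod("show", "KirHapSet", function(object) {
    cat("KirHapSet '", object@name, "': ", length(object), " haplotypes x ",
        ncol(object@copies), " genes\n", sep = "")
    ids <- hapIds(object)
    shown <- utils::head(ids, 8L)
    cat("  ids: ", paste(shown, collapse = ", "),
        if (length(ids) > 8L) ", ..." else "", "\n", sep = "")
})

#' Is one haplotype set nested in another?
#'
#' Reference sets are often published as nested supersets of one another
#' (e.g. a 10-haplotype core contained in a 24- and a 63-haplotype set).
#' \code{isSubsetOf} tests nesting by haplotype id.
#'
#' @param a,b [KirHapSet-class] objects.
#' @return TRUE iff every haplotype id of \code{a} occurs in \code{b}.
#' @export
isSubsetOf <- function(a, b) all(hapIds(a) %in% hapIds(b))

#' Presence/absence signature of haplotypes
#'
#' Thresholds each copy number at 1, giving the per-gene presence indicator
#' a haplotype contributes under PA-resolution typing. Haplotypes that are
#' distinct at CNV resolution (e.g. one vs two copies of a gene) share a
#' signature and are indistinguishable at PA resolution.
#'
#' @param x A [KirHapSet-class].
#' @return Logical matrix, haplotypes x genes.
#' @seealso [collapseToPA()], [subsetReport()]
#' @rdname paSignature
#' @export
setMethod("paSignature", "KirHapSet", function(x) x@copies >= 1L)

## deterministic total order on haplotype ids: numeric ids sort numerically,
## everything else lexicographically after them (radix = locale-stable)
.hapIdOrder <- function(ids) {
    num <- suppressWarnings(as.numeric(ids))
    order(is.na(num), num, ids, method = "radix")
}

#' Collapse a reference set to PA resolution
#'
#' Groups haplotypes by (PA signature, variant tag) and replaces each group
#' by a single haplotype whose copy numbers are the 0/1 signature and whose
#' id is the member ids joined by "/" in ascending order (e.g. "49/51" for
#' two haplotypes differing only in copy number of one gene). Groups of size
#' one keep their id. Idempotent.
#'
#' @param x A [KirHapSet-class].
#' @return A [KirHapSet-class] at PA resolution.
#' @rdname collapseToPA
#' @export
setMethod("collapseToPA", "KirHapSet", function(x) {
    sig <- paSignature(x)
    tag <- ifelse(is.na(x@variantTag), "", x@variantTag)
    key <- paste(apply(sig, 1L, paste, collapse = ""), tag, sep = "|")
    groups <- split(seq_len(length(x)), key)
    ids <- hapIds(x)
    rows <- lapply(groups, function(g) {
        gid <- ids[g][.hapIdOrder(ids[g])]
        list(id = paste(gid, collapse = "/"),
             sig = sig[g[1L], ],
             nom = {
                 nm <- unique(x@nomenclature[g][!is.na(x@nomenclature[g])])
                 if (length(nm) == 1L) nm else NA_character_
             },
             tag = x@variantTag[g[1L]])
    })
    ## keep original encounter order of groups (first member's position)
    first <- vapply(groups, `[`, integer(1L), 1L)
    rows <- rows[order(first)]
    m <- do.call(rbind, lapply(rows, function(r) as.integer(r$sig)))
    rownames(m) <- vapply(rows, `[[`, character(1L), "id")
    colnames(m) <- panelGenes(x)
    new("KirHapSet", name = paste0(x@name, "_PA"), copies = m,
        nomenclature = vapply(rows, `[[`, character(1L), "nom"),
        variantTag = vapply(rows, `[[`, character(1L), "tag"))
})
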