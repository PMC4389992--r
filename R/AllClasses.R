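#' PairedCountExperiment: paired tumor/normal read counts
#'
#' A thin extension of \linkS4class{SummarizedExperiment} holding a gene x
#' sample matrix of integer read counts in which every subject contributes
#' exactly one tumor and one normal library. The pairing lives in
#' \code{colData} (columns \code{subject_id}, \code{sample_id},
#' \code{tissue}).
#'
#' @slot .Data inherited SummarizedExperiment representation.
#' @seealso [PairedCountExperiment()] for construction,
#'   [tumorCounts()] / [normalCounts()] for subject-aligned matrices.
#' @export
setClass("PairedCountExperiment", contains = "SummarizedExperiment")

setValidity("PairedCountExperiment", function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    cd <- SummarizedExperiment::colData(object)
    need <- c("subject_id", "sample_id", "tissue")
    if (!all(need %in% colnames(cd))) {
        msg <- c(msg, sprintf("colData must contain %s",
                              paste(need, collapse = ", ")))
        return(msg)
    }
    if (!all(cd$tissue %in% c("tumor", "normal")))
        msg <- c(msg, "tissue must be 'tumor' or 'normal'")
    tab <- table(cd$subject_id, cd$tissue)
    if (!(ncol(tab) == 2L && all(tab == 1L)))
        msg <- c(msg, "every subject needs exactly one tumor and one normal sample")
    m <- SummarizedExperiment::assay(object, "counts")
    if (anyNA(m) || any(m < 0))
        msg <- c(msg, "counts must be non-negative and non-missing")
    if (length(msg)) msg else TRUE
})

#' Construct a PairedCountExperiment
#'
#' @param counts integer matrix, genes x samples; rownames are feature ids,
#'   colnames are sample ids.
#' @param sampleSheet data.frame with columns \code{subject_id},
#'   \code{sample_id}, \code{tissue} (\code{"tumor"}/\code{"normal"}), one row
#'   per column of \code{counts} (matched by \code{sample_id}).
#'
#' @return A \linkS4class{PairedCountExperiment}.
#' @examples
#' cnt <- matrix(rpois(20, 50), nrow = 5,
#'               dimnames = list(paste0("g", 1:5),
#'                               c("s1_T", "s1_N", "s2_T", "s2_N")))
#' sheet <- data.frame(subject_id = rep(c("s1", "s2"), each = 2),
#'                     sample_id = colnames(cnt),
#'                     tissue = rep(c("tumor", "normal"), 2))
#' pce <- PairedCountExperiment(cnt, sheet)
#' @export
PairedCountExperiment <- function(counts, sampleSheet) {
    counts <- as.matrix(counts)
    if (is.null(colnames(counts)))
        stop("'counts' needs column names (sample ids)")
    sampleSheet <- as.data.frame(sampleSheet)
    idx <- match(colnames(counts), sampleSheet$sample_id)
    if (anyNA(idx))
        stop("every counts column must appear in sampleSheet$sample_id")
    cd <- S4Vectors::DataFrame(sampleSheet[idx, , drop = FALSE])
    rownames(cd) <- colnames(counts)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts), colData = cd)
    methods::new("PairedCountExperiment", se)
}

#' @describeIn PairedCountExperiment compact display
#' @param object a PairedCountExperiment
#' @export
setMethod("show", "PairedCountExperiment", function(object) {
    cat(sprintf("PairedCountExperiment: %d features x %d subjects (%d libraries)\n",
                nrow(object), length(subjectIds(object)), ncol(object)))
    d <- libDepths(object)
    cat(sprintf("library depths: %s - %s reads\n",
                format(min(d), big.mark = ","), format(max(d), big.mark = ",")))
})

#' GeneSetCollection: named gene sets (GMT semantics)
#'
#' Named pathways mapping to member gene identifiers, mirroring the plain-text
#' GMT format: one set per line with a name, a free-text description and its
#' members.
#'
#' @slot sets named list of character vectors (member gene ids).
#' @slot description character vector parallel to \code{sets}.
#' @seealso [readGmt()], [writeGmt()]
#' @export
setClass("GeneSetCollection",
         representation(sets = "list", description = "character"))

setValidity("GeneSetCollection", function(object) {
    msg <- character()
    nm <- names(object@sets)
    if (length(object@sets)) {
        if (is.null(nm) || anyDuplicated(nm) || any(!nzchar(nm)))
            msg <- c(msg, "set names must be unique and non-empty")
        if (!all(vapply(object@sets, function(s)
                is.character(s) && length(s) > 0L, logical(1))))
            msg <- c(msg, "every set must have at least one member gene id")
    }
    if (length(object@description) != length(object@sets))
        msg <- c(msg, "one description per set is required")
    if (length(msg)) msg else TRUE
})

#' Construct a GeneSetCollection
#'
#' @param sets named list of character vectors of member gene ids.
#' @param description optional character vector of per-set descriptions.
#' @return A \linkS4class{GeneSetCollection}.
#' @examples
#' gsc <- GeneSetCollection(list(cellCycle = c("g1", "g2"), apoptosis = "g3"))
#' names(gsc); gsc[["cellCycle"]]
#' @export
GeneSetCollection <- function(sets = list(), description = NULL) {
    if (is.null(description))
        description <- rep("", length(sets))
    methods::new("GeneSetCollection", sets = sets,
                 description = as.character(description))
}

#' @describeIn GeneSetCollection number of sets
#' @param x a GeneSetCollection
#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@sets))

#' @describeIn GeneSetCollection set names
#' @export
setMethod("names", "GeneSetCollection", function(x) names(x@sets))

#' @describeIn GeneSetCollection extract one set's members
#' @param i set name or index
#' @export
setMethod("[[", "GeneSetCollection", function(x, i) x@sets[[i]])

#' @describeIn GeneSetCollection subset to several sets
#' @param j,...,drop ignored
#' @export
setMethod("[", "GeneSetCollection", function(x, i, j, ..., drop = FALSE) {
    GeneSetCollection(x@sets[i], x@description[
        if (is.character(i)) match(i, names(x@sets)) else i])
})

#' @describeIn GeneSetCollection compact display
#' @export
setMethod("show", "GeneSetCollection", function(object) {
    cat(sprintf("GeneSetCollection with %d sets\n", length(object)))
    if (length(object)) {
        sz <- lengths(object@sets)
        cat(sprintf("set sizes: %d - %d genes (median %g)\n",
                    min(sz), max(sz), stats::median(sz)))
    }
})

#' Member list of a GeneSetCollection
#'
#' @param gsc a \linkS4class{GeneSetCollection}.
#' @return named list of character vectors.
#' @export
geneSets <- function(gsc) gsc@sets

#' Per-set descriptions of a GeneSetCollection
#'
#' @param gsc a \linkS4class{GeneSetCollection}.
#' @return character vector, one entry per set.
#' @export
setDescriptions <- function(gsc) {
    stats::setNames(gsc@description, names(gsc@sets))
}
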