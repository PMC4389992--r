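#' @importFrom BiocGenerics counts
NULL

#' Count matrix of a PairedCountExperiment
#'
#' @param object a \linkS4class{PairedCountExperiment}.
#' @return integer matrix, genes x samples.
#' @export
setMethod("counts", "PairedCountExperiment", function(object) {
    SummarizedExperiment::assay(object, "counts")
})

#' Subject identifiers of a paired experiment
#'
#' Subjects in a stable order (first appearance in the sample sheet); this is
#' the column order of [tumorCounts()] and [normalCounts()].
#'
#' @param pce a \linkS4class{PairedCountExperiment}.
#' @return character vector of subject ids.
#' @export
subjectIds <- function(pce) {
    unique(as.character(SummarizedExperiment::colData(pce)$subject_id))
}

.tissueMatrix <- function(pce, tissue) {
    cd <- SummarizedExperiment::colData(pce)
    subj <- subjectIds(pce)
    sel <- as.character(cd$sample_id)[cd$tissue == tissue][
        match(subj, as.character(cd$subject_id)[cd$tissue == tissue])]
    m <- counts(pce)[, sel, drop = FALSE]
    colnames(m) <- subj
    m
}

#' Subject-aligned tumor and normal count matrices
#'
#' @param pce a \linkS4class{PairedCountExperiment}.
#' @return genes x subjects matrix with subjects as columns, in
#'   [subjectIds()] order, so \code{tumorCounts(x) - normalCounts(x)} is the
#'   within-pair difference.
#' @export
tumorCounts <- function(pce) .tissueMatrix(pce, "tumor")

#' @rdname tumorCounts
#' @export
normalCounts <- function(pce) .tissueMatrix(pce, "normal")

#' Library depths (total counts per sample)
#'
#' @param pce a \linkS4class{PairedCountExperiment}.
#' @return named numeric vector of per-library total read counts.
#' @export
libDepths <- function(pce) colSums(counts(pce))

#' Subset a paired experiment to a set of subjects
#'
#' Keeps both libraries of each requested subject.
#'
#' @param pce a \linkS4class{PairedCountExperiment}.
#' @param subjects character vector of subject ids.
#' @return a \linkS4class{PairedCountExperiment}.
#' @export
subsetSubjects <- function(pce, subjects) {
    cd <- SummarizedExperiment::colData(pce)
    missing <- setdiff(subjects, cd$subject_id)
    if (length(missing))
        stop("unknown subjects: ", paste(missing, collapse = ", "))
    keep <- cd$subject_id %in% subjects
    methods::new("PairedCountExperiment", pce[, keep])
}

# counts per million on each library's own depth
.cpm <- function(m, depths = colSums(m)) {
    sweep(m, 2L, depths, "/") * 1e6
}
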