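#' Per-subject differential expression profile
#'
#' For every subject and gene, the log2 ratio of normalized tumor to normal
#' expression: \code{log2((t + c) / (n + c))} on a common scale. This is the
#' individual-level "level of differential expression" that the quartile
#' scoring discretizes.
#'
#' The default normalization is median-of-ratios size factors (the DESeq
#' estimator): when many genes change in one direction, total-count (CPM)
#' scaling shifts the apparent expression of every unchanged gene in the
#' other direction, which leaks a tumor's overall de-regulation load into
#' the profile of pathways that are not de-regulated at all. Size factors
#' anchored on the majority of unchanged genes remove that compositional
#' bias; \code{"cpm"} is retained for comparison.
#'
#' @param pce a \linkS4class{PairedCountExperiment}.
#' @param pseudocount added to both normalized values (default 0.5); must
#'   be > 0.
#' @param normalization \code{"medianRatio"} (default) or \code{"cpm"}.
#' @return subjects x genes numeric matrix.
#' @export
computeDeltaProfile <- function(pce, pseudocount = 0.5,
                                normalization = c("medianRatio", "cpm")) {
    if (pseudocount <= 0) stop("pseudocount must be > 0")
    normalization <- match.arg(normalization)
    tum <- tumorCounts(pce)
    nor <- normalCounts(pce)
    if (normalization == "cpm") {
        tumN <- .cpm(tum)
        norN <- .cpm(nor)
    } else {
        sf <- DESeq2::estimateSizeFactorsForMatrix(cbind(tum, nor))
        nS <- ncol(tum)
        tumN <- sweep(tum, 2L, sf[seq_len(nS)], "/")
        norN <- sweep(nor, 2L, sf[nS + seq_len(nS)], "/")
    }
    delta <- log2((tumN + pseudocount) / (norN + pseudocount))
    t(delta)
}

#' Differential gene expression scores (DGES) from population quartiles
#'
#' Scores every subject 1, 2 or 3 per gene: the per-subject differential
#' expression is first oriented by the gene's cohort-level direction
#' (multiplied by +1 for up-regulated genes, -1 for down-regulated ones) so
#' that larger always means more de-regulated — the bottom quartile is
#' "closer to normal" for both directions. A subject scores 1 below the
#' 25th percentile of the cohort distribution of the oriented value, 3
#' strictly above the 75th percentile, and 2 otherwise (boundary values fall
#' in the middle bin). Quartiles use linear-interpolation sample quantiles
#' over the full analysis cohort.
#'
#' @param delta subjects x genes matrix from [computeDeltaProfile()].
#' @param direction per-gene direction: named vector of \code{"up"}/
#'   \code{"down"} or +1/-1, covering the columns of \code{delta}.
#' @return subjects x genes integer matrix with values in {1, 2, 3}.
#' @export
assignDGES <- function(delta, direction) {
    if (nrow(delta) < 4L)
        stop("need at least 4 subjects to form quartiles")
    if (is.character(direction))
        direction <- ifelse(direction == "up", 1, -1)
    if (!is.null(names(direction))) {
        miss <- setdiff(colnames(delta), names(direction))
        if (length(miss))
            stop("direction missing for gene(s): ",
                 paste(utils::head(miss, 5L), collapse = ", "))
        direction <- direction[colnames(delta)]
    } else if (length(direction) != ncol(delta)) {
        stop("direction must cover every gene column")
    }
    oriented <- sweep(delta, 2L, as.numeric(direction), "*")
    q <- apply(oriented, 2L, stats::quantile, probs = c(0.25, 0.75),
               names = FALSE, type = 7)
    score <- matrix(2L, nrow(delta), ncol(delta),
                    dimnames = dimnames(delta))
    score[sweep(oriented, 2L, q[1L, ], "<")] <- 1L
    score[sweep(oriented, 2L, q[2L, ], ">")] <- 3L
    score
}

#' Differential pathway expression scores (DPES)
#'
#' Sums each subject's DGES over a pathway's member genes; a higher DPES
#' means more of the pathway's genes are de-regulated in that subject. Set
#' members are restricted to scored genes; pathways with no scored member
#' are dropped with a warning. For a pathway with G scored genes the score
#' lies in [G, 3G].
#'
#' @param dges subjects x genes integer matrix from [assignDGES()].
#' @param gsc a \linkS4class{GeneSetCollection}.
#' @return subjects x pathways integer matrix.
#' @export
computeDPES <- function(dges, gsc) {
    sets <- lapply(geneSets(gsc), intersect, colnames(dges))
    empty <- lengths(sets) == 0L
    if (any(empty)) {
        warning("dropping pathway(s) with no scored genes: ",
                paste(names(sets)[empty], collapse = ", "))
        sets <- sets[!empty]
    }
    out <- vapply(sets, function(g)
        rowSums(dges[, g, drop = FALSE]), numeric(nrow(dges)))
    out <- matrix(as.integer(out), nrow(dges), length(sets),
                  dimnames = list(rownames(dges), names(sets)))
    out
}

#' Tertile labels for a score distribution
#'
#' Cuts at the 33.3rd and 66.7th percentiles (linear-interpolation sample
#' quantiles) of the cohort distribution; ties at a cut point go to the
#' lower tertile, so T3 ("most de-regulated") is conservative. Labels are
#' monotone in the score.
#'
#' @param x numeric vector (one pathway's DPES values across subjects).
#' @return ordered factor with levels T1 < T2 < T3 and attribute
#'   \code{degenerate} (TRUE when all values are identical, in which case a
#'   single tertile is returned with a warning).
#' @export
tertileAssign <- function(x) {
    if (length(x) < 3L) stop("need at least 3 subjects for tertiles")
    cuts <- stats::quantile(x, probs = c(1, 2) / 3, names = FALSE, type = 7)
    degenerate <- length(unique(x)) == 1L
    if (degenerate)
        warning("all scores identical: single degenerate tertile")
    lab <- ifelse(x <= cuts[1L], "T1", ifelse(x <= cuts[2L], "T2", "T3"))
    out <- factor(lab, levels = c("T1", "T2", "T3"), ordered = TRUE)
    names(out) <- names(x)
    attr(out, "degenerate") <- degenerate
    out
}

#' Tertile labels for every pathway of a DPES matrix
#'
#' @param dpes subjects x pathways matrix from [computeDPES()].
#' @return subjects x pathways character matrix of labels "T1"-"T3".
#' @export
dpesTertiles <- function(dpes) {
    out <- apply(dpes, 2L, function(x)
        as.character(suppressWarnings(tertileAssign(x))))
    matrix(out, nrow(dpes), ncol(dpes), dimnames = dimnames(dpes))
}
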