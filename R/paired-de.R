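#' Depth-equalizing binomial thinning
#'
#' Down-samples every library to a common target depth: each count c in a
#' library of depth d is replaced by a Binomial(c, target/d) draw, removing
#' sequencing depth as a confounder of the paired comparison. Libraries
#' already at the target pass through unchanged. Repeated \code{nResamples}
#' times; downstream statistics are averaged across the resamples.
#'
#' @param counts genes x samples integer matrix.
#' @param targetDepth common depth; defaults to the minimum library depth.
#' @param nResamples number of independent thinning draws (default 1).
#' @param seed optional integer seed.
#' @return list of \code{nResamples} thinned matrices.
#' @export
thinCounts <- function(counts, targetDepth = NULL, nResamples = 1L,
                       seed = NULL) {
    counts <- as.matrix(counts)
    depths <- colSums(counts)
    if (is.null(targetDepth)) targetDepth <- min(depths)
    if (any(targetDepth > depths))
        stop("targetDepth exceeds the depth of at least one library")
    if (nResamples < 1L) stop("nResamples must be >= 1")
    if (!is.null(seed)) set.seed(seed)
    lapply(seq_len(nResamples), function(r)
        .thinOnce(counts, depths, targetDepth))
}

.thinOnce <- function(counts, depths, targetDepth) {
    p <- targetDepth / depths
    out <- counts
    for (j in seq_along(p)) {
        if (p[j] < 1)
            out[, j] <- stats::rbinom(nrow(counts), counts[, j], p[j])
    }
    out
}

# Standardized Wilcoxon signed-rank statistic of paired differences.
# Zero differences are dropped; tied absolute differences get mid-ranks;
# under independent sign flips W = sum(rank * sign) has mean 0 and variance
# sum(rank^2), so W / sqrt(sum(rank^2)) is the standardized statistic.
.signedRanks <- function(d) {
    out <- numeric(length(d))
    nz <- d != 0
    if (any(nz)) out[nz] <- rank(abs(d[nz])) * sign(d[nz])
    out
}

#' Standardized paired signed-rank statistic
#'
#' The Wilcoxon signed-rank statistic of the within-pair tumor minus normal
#' differences, standardized to mean 0 and unit variance under the
#' label-flip null. Zero differences are dropped and tied absolute
#' differences receive mid-ranks. If every difference is zero the statistic
#' is 0 and carries attribute \code{degenerate = TRUE}.
#'
#' @param tumor,normal numeric vectors of one gene's counts per subject,
#'   aligned by subject.
#' @return numeric statistic with attribute \code{degenerate}.
#' @examples
#' pairedSignedRank(c(9, 1, 5), c(4, 3, 4))   # differences +5, -2, +1
#' @export
pairedSignedRank <- function(tumor, normal) {
    if (length(tumor) != length(normal))
        stop("tumor and normal must cover the same subjects")
    if (length(tumor) < 2L) stop("need at least 2 pairs")
    a <- .signedRanks(tumor - normal)
    v <- sum(a^2)
    stat <- if (v > 0) sum(a) / sqrt(v) else 0
    attr(stat, "degenerate") <- v == 0
    stat
}

# signed mid-rank matrix (genes x pairs) for one resample's differences
.signedRankMatrix <- function(D) {
    t(apply(D, 1L, .signedRanks))
}

# all 2^n sign vectors (pairs x 2^n), first column the identity
.signMatrixExact <- function(n) {
    g <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
    t(g[order(rowSums(g == -1)), , drop = FALSE])
}

#' Paired differential expression by resampling and permutation
#'
#' The paired two-class test: counts are depth-equalized by binomial
#' thinning \code{nResamples} times; for each gene and resample the
#' standardized signed-rank statistic of the tumor minus normal differences
#' is computed and averaged across resamples. The null distribution flips
#' the tumor/normal labels independently within each pair, recomputing the
#' averaged statistic on the same resample stream (common random numbers).
#' Two-sided permutation p-values use the add-one rule
#' \code{p = (1 + #(|null| >= |obs|)) / (nPerm + 1)}; when the number of
#' pairs is at most \code{exactMax} all label flips are enumerated instead
#' and \code{p = #(|null| >= |obs|) / 2^n}. Fold changes are ratios of mean
#' tumor to mean normal expression on the counts-per-million scale with a
#' pseudocount.
#'
#' @param pce a \linkS4class{PairedCountExperiment}.
#' @param nResamples thinning resamples (default 20).
#' @param targetDepth common depth (default: minimum library depth).
#' @param nPerm number of sampled permutations (default 1000).
#' @param pseudocount added to mean CPMs before the fold-change ratio
#'   (default 0.5).
#' @param exactMax enumerate all 2^n sign flips when pairs <= this
#'   (default 10).
#' @param seed optional integer seed governing thinning and permutations.
#' @return data.frame with one row per feature: \code{feature_id},
#'   \code{statistic} (averaged standardized signed-rank score),
#'   \code{p_perm}, \code{q_value} (Benjamini-Hochberg over the batch),
#'   \code{fold_change}, \code{direction} (\code{"up"} iff fold change > 1),
#'   \code{n_pairs}, \code{degenerate} (all differences zero in all
#'   resamples).
#' @export
runPairedDE <- function(pce, nResamples = 20L, targetDepth = NULL,
                        nPerm = 1000L, pseudocount = 0.5, exactMax = 10L,
                        seed = NULL) {
    if (nPerm < 1L) stop("nPerm must be >= 1")
    if (nResamples < 1L) stop("nResamples must be >= 1")
    tum <- tumorCounts(pce)
    nor <- normalCounts(pce)
    nG <- nrow(tum); nP <- ncol(tum)
    if (nP < 2L) stop("need at least 2 subject pairs")
    if (!is.null(seed)) set.seed(seed)

    depths <- libDepths(pce)
    if (is.null(targetDepth)) targetDepth <- min(depths)
    if (any(targetDepth > depths))
        stop("targetDepth exceeds the depth of at least one library")
    dTum <- colSums(tum); dNor <- colSums(nor)

    exact <- nP <= exactMax
    E <- if (exact) .signMatrixExact(nP) else
        matrix(sample(c(-1, 1), nP * nPerm, replace = TRUE), nP, nPerm)
    nCol <- ncol(E)

    obsSum <- numeric(nG)
    nullSum <- matrix(0, nG, nCol)
    degen <- rep(TRUE, nG)
    for (r in seq_len(nResamples)) {
        tR <- .thinOnce(tum, dTum, targetDepth)
        nR <- .thinOnce(nor, dNor, targetDepth)
        A <- .signedRankMatrix(tR - nR)
        v <- sqrt(rowSums(A^2))
        ok <- v > 0
        degen <- degen & !ok
        s <- numeric(nG)
        s[ok] <- rowSums(A[ok, , drop = FALSE]) / v[ok]
        obsSum <- obsSum + s
        nullR <- A %*% E
        nullR[ok, ] <- nullR[ok, , drop = FALSE] / v[ok]
        nullR[!ok, ] <- 0
        nullSum <- nullSum + nullR
    }
    observed <- obsSum / nResamples
    nullMat <- nullSum / nResamples

    ge <- abs(nullMat) >= abs(observed) - 1e-12
    p <- if (exact) rowMeans(ge) else (1 + rowSums(ge)) / (nPerm + 1)

    fc <- foldChange(pce, pseudocount = pseudocount)
    data.frame(
        feature_id = rownames(tum),
        statistic = observed,
        p_perm = p,
        q_value = bhAdjust(p),
        fold_change = fc$fold_change,
        direction = fc$direction,
        n_pairs = nP,
        degenerate = degen,
        stringsAsFactors = FALSE, row.names = NULL)
}

#' Fold change as the ratio of mean tumor to mean normal expression
#'
#' Means are taken over the counts-per-million normalized values of each
#' library (depth differences would otherwise bias a ratio of raw means); a
#' pseudocount is added to both means before the ratio.
#'
#' @param pce a \linkS4class{PairedCountExperiment}.
#' @param pseudocount added to each mean CPM (default 0.5). With 0, a zero
#'   normal mean is an error.
#' @return data.frame with \code{feature_id}, \code{fold_change},
#'   \code{direction} (\code{"up"} iff fold change > 1).
#' @export
foldChange <- function(pce, pseudocount = 0.5) {
    tum <- .cpm(tumorCounts(pce))
    nor <- .cpm(normalCounts(pce))
    mT <- rowMeans(tum); mN <- rowMeans(nor)
    if (pseudocount == 0 && any(mN == 0))
        stop("zero normal mean with zero pseudocount")
    fc <- (mT + pseudocount) / (mN + pseudocount)
    data.frame(feature_id = rownames(tum), fold_change = fc,
               direction = ifelse(fc > 1, "up", "down"),
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Cross-validated selection of differentially expressed features
#'
#' A feature is selected when it is significant (permutation p below
#' \code{pThreshold}) in both discovery groups and shows more than a
#' \code{fcThreshold}-fold change in the same direction in both.
#'
#' @param resultsA,resultsB [runPairedDE()] results over the same feature
#'   universe.
#' @param pThreshold permutation p cutoff (default 0.05).
#' @param fcThreshold fold-change cutoff (default 2; down-regulation means
#'   fold change below \code{1/fcThreshold}).
#' @param requireConsistentDirection drop features whose direction disagrees
#'   between groups (default TRUE).
#' @return list with \code{up} and \code{down} (character vectors of
#'   feature ids, disjoint) and \code{table} (per-feature flags
#'   \code{selected_A}, \code{selected_B}, \code{selected_both}).
#' @export
selectDEFeatures <- function(resultsA, resultsB, pThreshold = 0.05,
                             fcThreshold = 2, requireConsistentDirection = TRUE) {
    if (!setequal(resultsA$feature_id, resultsB$feature_id))
        stop("feature universes of the two groups differ")
    b <- resultsB[match(resultsA$feature_id, resultsB$feature_id), ]
    a <- resultsA

    upA <- a$fold_change > fcThreshold
    dnA <- a$fold_change < 1 / fcThreshold
    upB <- b$fold_change > fcThreshold
    dnB <- b$fold_change < 1 / fcThreshold
    sigA <- a$p_perm < pThreshold
    sigB <- b$p_perm < pThreshold

    selA <- sigA & (upA | dnA)
    selB <- sigB & (upB | dnB)
    if (requireConsistentDirection) {
        both <- (sigA & sigB) & ((upA & upB) | (dnA & dnB))
    } else {
        both <- selA & selB
    }
    up <- a$feature_id[both & upA & upB]
    down <- a$feature_id[both & dnA & dnB]
    list(up = up, down = down,
         table = data.frame(feature_id = a$feature_id,
                            selected_A = selA, selected_B = selB,
                            selected_both = both, stringsAsFactors = FALSE))
}
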