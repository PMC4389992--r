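#' Filter the feature manifest to analyzable protein-coding features
#'
#' Retains exactly the features that are coding, have a known function and
#' are expressed in the tissue, preserving input order. Applied to the full
#' 51,041-feature annotation this reproduces the 17,165-feature analysis
#' universe (33,876 excluded).
#'
#' @param features data.frame with columns \code{feature_id},
#'   \code{gene_id}, and logical \code{is_coding}, \code{has_known_function},
#'   \code{is_expressed}.
#' @return character vector of retained feature ids.
#' @export
filterFeatures <- function(features) {
    need <- c("feature_id", "gene_id", "is_coding", "has_known_function",
              "is_expressed")
    miss <- setdiff(need, colnames(features))
    if (length(miss))
        stop("feature manifest lacks columns: ", paste(miss, collapse = ", "))
    if (anyDuplicated(features$feature_id))
        stop("duplicate feature_id in manifest")
    flags <- features[, c("is_coding", "has_known_function", "is_expressed")]
    if (anyNA(flags))
        stop("missing annotation flags in feature manifest")
    keep <- features$is_coding & features$has_known_function &
        features$is_expressed
    as.character(features$feature_id[keep])
}

#' Retain subjects whose tumor and normal libraries both pass QC
#'
#' @param qc data.frame with columns \code{subject_id} and logical
#'   \code{tumor_pass}, \code{normal_pass}; one row per subject.
#' @return character vector of retained subject ids.
#' @export
qcSubjects <- function(qc) {
    need <- c("subject_id", "tumor_pass", "normal_pass")
    miss <- setdiff(need, colnames(qc))
    if (length(miss))
        stop("QC table lacks columns: ", paste(miss, collapse = ", "))
    if (anyDuplicated(qc$subject_id))
        stop("duplicate subject_id in QC table")
    if (anyNA(qc$tumor_pass) || anyNA(qc$normal_pass))
        stop("missing QC flag")
    as.character(qc$subject_id[qc$tumor_pass & qc$normal_pass])
}

#' Compute an expression flag from counts when the manifest lacks one
#'
#' A feature counts as expressed when its normalized abundance reaches
#' \code{cpmThreshold} counts per million in at least \code{minFrac} of
#' libraries.
#'
#' @param counts genes x samples count matrix.
#' @param cpmThreshold CPM cutoff (default 1).
#' @param minFrac minimum fraction of libraries at or above the cutoff
#'   (default 0.1).
#' @return logical vector, one flag per feature.
#' @export
flagExpressed <- function(counts, cpmThreshold = 1, minFrac = 0.1) {
    cpm <- .cpm(as.matrix(counts))
    rowMeans(cpm >= cpmThreshold) >= minFrac
}

.ageCategory <- function(age, width = 5) {
    lo <- pmin(pmax(floor(age / width) * width, 30), 80)
    sprintf("%02d", as.integer(lo))
}

#' Split the cohort into balanced, matched discovery groups A and B
#'
#' Subjects who died of the cancer are divided at random into two groups
#' whose death counts differ by at most one. Each deceased subject is then
#' matched, where possible, to a distinct alive subject of the same age
#' category and sex; the matched alive subject inherits the deceased
#' subject's group. Remaining subjects stay unassigned (they still enter the
#' full-cohort survival and stage analyses). Other-cause deaths and subjects
#' with unknown vital status are not treated as deceased for this split.
#'
#' @param clinical data.frame with columns \code{subject_id},
#'   \code{vital_status}, \code{age}, \code{sex}.
#' @param ageBinWidth width of the age category bins in years (default 5;
#'   bins run from 30 to 80+).
#' @param seed optional integer seed for the random assignment.
#' @return data.frame with columns \code{subject_id}, \code{group}
#'   (\code{"A"}/\code{"B"}/\code{"unassigned"}), \code{matched_to},
#'   \code{age_category}, \code{sex}. Strata whose alive pool cannot cover
#'   the deceased are reported via \code{message()}.
#' @export
splitDiscoveryGroups <- function(clinical, ageBinWidth = 5, seed = NULL) {
    need <- c("subject_id", "vital_status", "age", "sex")
    miss <- setdiff(need, colnames(clinical))
    if (length(miss))
        stop("clinical table lacks columns: ", paste(miss, collapse = ", "))
    if (!is.null(seed)) set.seed(seed)

    out <- data.frame(
        subject_id = as.character(clinical$subject_id),
        group = "unassigned", matched_to = NA_character_,
        age_category = .ageCategory(clinical$age, ageBinWidth),
        sex = as.character(clinical$sex), stringsAsFactors = FALSE)
    deceased <- clinical$vital_status == "crc_death"
    if (!any(deceased))
        stop("no deceased subjects: discovery split undefined")

    dIdx <- sample(which(deceased))
    out$group[dIdx] <- rep(c("A", "B"), length.out = length(dIdx))

    alive <- clinical$vital_status == "alive"
    stratum <- paste(out$age_category, out$sex)
    shortfall <- 0L
    for (s in unique(stratum[deceased])) {
        dS <- which(deceased & stratum == s)
        aS <- which(alive & stratum == s)
        k <- min(length(dS), length(aS))
        if (k < length(dS)) shortfall <- shortfall + (length(dS) - k)
        if (k > 0L) {
            dPick <- if (length(dS) > 1L) sample(dS, k) else dS
            aPick <- if (length(aS) > 1L) sample(aS, k) else aS
            out$group[aPick] <- out$group[dPick]
            out$matched_to[aPick] <- out$subject_id[dPick]
        }
    }
    if (shortfall > 0L)
        message(sprintf(
            "discovery split: %d deceased subject(s) left unmatched (no alive subject in stratum)",
            shortfall))
    out
}
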