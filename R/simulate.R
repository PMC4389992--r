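#' Simulation settings for a paired tumor/normal cohort
#'
#' Holds every knob of the synthetic-cohort generator. Defaults describe a
#' population-based colon-cancer cohort: 175 subjects with paired tumor and
#' adjacent-normal libraries over 17,141 protein-coding genes, ~10% of genes
#' truly de-regulated at fold changes between 2 and 6 (62% of them
#' up-regulated), negative-binomial counts with dispersion 0.2, library
#' depths uniform on 1-3 million reads, and survival driven by the subject's
#' true pathway de-regulation tertile (log hazard ratios -0.9 and -1.1 for
#' tertiles 2 and 3 vs 1 on a 0.004/month baseline), with a mixture of
#' cancer deaths, other-cause deaths, administratively censored survivors and
#' subjects lost to follow-up.
#'
#' @slot nSubjects number of subjects (one tumor + one normal library each).
#' @slot nGenes number of genes.
#' @slot nPathways number of simulated gene sets.
#' @slot genesPerPathway members per set.
#' @slot fracDE fraction of genes truly differentially expressed.
#' @slot fracUp fraction of DE genes that are up-regulated.
#' @slot fcRange lower/upper bound of true fold changes (both > 1).
#' @slot dispersion negative-binomial dispersion (1/size), > 0.
#' @slot depthRange lower/upper bound of expected library depth (reads).
#' @slot deHeterogeneity half-width w of the per-subject de-regulation
#'   multiplier m ~ U(1-w, 1+w) applied to each DE gene's log fold change;
#'   the subject's true tertile is the tertile of m.
#' @slot tertileLogHR log hazard ratios for true tertiles 2 and 3 vs 1.
#' @slot baselineHazard events per month in tertile 1.
#' @slot fracOtherDeath fraction of deaths due to causes other than the
#'   cancer.
#' @slot fracUnknown fraction of subjects with unknown vital status
#'   (censored at a uniformly drawn last-contact month).
#' @slot censorMonths administrative censoring time (months).
#' @slot stageProbs probabilities of AJCC stages 1-4 (sum to 1).
#' @slot covariatePrevalences named fractions for tp53, kras, msi, cimp and
#'   male sex.
#' @slot ageMeanSD mean and SD of age at diagnosis (years).
#' @slot fracLinked fraction of pathways that are survival-linked (built
#'   from DE genes).
#' @slot enrichmentWeight fraction of a survival-linked pathway's members
#'   drawn from DE genes.
#' @slot allowOverlap may pathways share genes?
#' @slot seed integer master seed; the counts, clinical and gene-set
#'   generators use seed, seed + 1 and seed + 2.
#' @export
setClass("SimulationConfig", representation(
    nSubjects = "integer", nGenes = "integer", nPathways = "integer",
    genesPerPathway = "integer", fracDE = "numeric", fracUp = "numeric",
    fcRange = "numeric", dispersion = "numeric", depthRange = "numeric",
    deHeterogeneity = "numeric", tertileLogHR = "numeric",
    baselineHazard = "numeric", fracOtherDeath = "numeric",
    fracUnknown = "numeric", censorMonths = "numeric", stageProbs = "numeric",
    covariatePrevalences = "numeric", ageMeanSD = "numeric",
    fracLinked = "numeric", enrichmentWeight = "numeric",
    allowOverlap = "logical", seed = "integer"))

setValidity("SimulationConfig", function(object) {
    msg <- character()
    frac <- c(fracDE = object@fracDE, fracUp = object@fracUp,
              fracOtherDeath = object@fracOtherDeath,
              fracUnknown = object@fracUnknown, fracLinked = object@fracLinked,
              enrichmentWeight = object@enrichmentWeight,
              object@covariatePrevalences)
    bad <- frac < 0 | frac > 1
    if (any(bad))
        msg <- c(msg, sprintf("fractions out of [0,1]: %s",
                              paste(names(frac)[bad], collapse = ", ")))
    if (object@nSubjects < 1L || object@nGenes < 1L)
        msg <- c(msg, "nSubjects and nGenes must be positive")
    if (length(object@stageProbs) != 4L ||
        abs(sum(object@stageProbs) - 1) > 1e-9)
        msg <- c(msg, "stageProbs must be 4 probabilities summing to 1")
    if (length(object@fcRange) != 2L || object@fcRange[1] <= 1 ||
        diff(object@fcRange) < 0)
        msg <- c(msg, "fcRange must be increasing with lower bound > 1")
    if (object@dispersion <= 0)
        msg <- c(msg, "dispersion must be > 0")
    if (length(object@depthRange) != 2L || object@depthRange[1] <= 0 ||
        diff(object@depthRange) < 0)
        msg <- c(msg, "depthRange must be positive and increasing")
    if (object@baselineHazard <= 0)
        msg <- c(msg, "baselineHazard must be > 0")
    if (object@censorMonths <= 0)
        msg <- c(msg, "censorMonths must be > 0")
    if (object@deHeterogeneity < 0 || object@deHeterogeneity >= 1)
        msg <- c(msg, "deHeterogeneity must be in [0, 1)")
    if (length(object@tertileLogHR) != 2L)
        msg <- c(msg, "tertileLogHR needs two values (tertiles 2 and 3 vs 1)")
    if (object@genesPerPathway > object@nGenes)
        msg <- c(msg, "genesPerPathway cannot exceed nGenes")
    if (!object@allowOverlap &&
        object@nPathways * object@genesPerPathway > object@nGenes)
        msg <- c(msg, paste("nPathways x genesPerPathway exceeds nGenes;",
                            "set allowOverlap = TRUE to permit shared genes"))
    need <- c("tp53", "kras", "msi", "cimp", "male")
    if (!all(need %in% names(object@covariatePrevalences)))
        msg <- c(msg, sprintf("covariatePrevalences must name %s",
                              paste(need, collapse = ", ")))
    if (length(object@ageMeanSD) != 2L || object@ageMeanSD[2] < 0)
        msg <- c(msg, "ageMeanSD must be (mean, sd) with sd >= 0")
    if (object@seed < 0L || object@seed > .Machine$integer.max - 10L)
        msg <- c(msg, "seed must be a small non-negative integer")
    if (length(msg)) msg else TRUE
})

#' @describeIn SimulationConfig constructor with cohort-scale defaults
#' @param nSubjects,nGenes,nPathways,genesPerPathway,fracDE,fracUp,fcRange
#'   see slots.
#' @param dispersion,depthRange,deHeterogeneity,tertileLogHR,baselineHazard
#'   see slots.
#' @param fracOtherDeath,fracUnknown,censorMonths,stageProbs see slots.
#' @param covariatePrevalences,ageMeanSD,fracLinked,enrichmentWeight see
#'   slots.
#' @param allowOverlap,seed see slots.
#' @return a validated \code{SimulationConfig}.
#' @export
SimulationConfig <- function(nSubjects = 175L, nGenes = 17141L,
        nPathways = 30L, genesPerPathway = 16L, fracDE = 0.1, fracUp = 0.62,
        fcRange = c(2, 6), dispersion = 0.2, depthRange = c(1e6, 3e6),
        deHeterogeneity = 0.5, tertileLogHR = c(-0.9, -1.1),
        baselineHazard = 0.004, fracOtherDeath = 0.30, fracUnknown = 0.086,
        censorMonths = 120,
        stageProbs = c(0.23, 0.32, 0.33, 0.12),
        covariatePrevalences = c(tp53 = 0.44, kras = 0.274, msi = 0.183,
                                 cimp = 0.257, male = 0.537),
        ageMeanSD = c(65.2, 10.2), fracLinked = 0.5, enrichmentWeight = 0.9,
        allowOverlap = FALSE, seed = 1L) {
    methods::new("SimulationConfig",
        nSubjects = as.integer(nSubjects), nGenes = as.integer(nGenes),
        nPathways = as.integer(nPathways),
        genesPerPathway = as.integer(genesPerPathway),
        fracDE = fracDE, fracUp = fracUp, fcRange = as.numeric(fcRange),
        dispersion = dispersion, depthRange = as.numeric(depthRange),
        deHeterogeneity = deHeterogeneity,
        tertileLogHR = as.numeric(tertileLogHR),
        baselineHazard = baselineHazard, fracOtherDeath = fracOtherDeath,
        fracUnknown = fracUnknown, censorMonths = censorMonths,
        stageProbs = as.numeric(stageProbs),
        covariatePrevalences = covariatePrevalences,
        ageMeanSD = as.numeric(ageMeanSD), fracLinked = fracLinked,
        enrichmentWeight = enrichmentWeight, allowOverlap = allowOverlap,
        seed = as.integer(seed))
}

#' @describeIn SimulationConfig compact display
#' @param object a SimulationConfig
#' @export
setMethod("show", "SimulationConfig", function(object) {
    cat(sprintf(paste0(
        "SimulationConfig: %d subjects x %d genes, %d pathways\n",
        "fracDE = %.3g (fc %g-%g), dispersion = %g, seed = %d\n"),
        object@nSubjects, object@nGenes, object@nPathways, object@fracDE,
        object@fcRange[1], object@fcRange[2], object@dispersion, object@seed))
})

.geneIds <- function(n) sprintf("gene%05d", seq_len(n))
.subjIds <- function(n) sprintf("subj%04d", seq_len(n))

# Jensen correction so that E[fc^m] over m ~ U(1-w, 1+w) equals fc exactly
.fcCalibration <- function(fc, w) {
    if (w == 0) return(rep(1, length(fc)))
    (fc^w - fc^(-w)) / (2 * w * log(fc))
}

#' Generate a paired tumor/normal count cohort with known truth
#'
#' Draws per-gene relative abundances from a log-normal, per-library expected
#' depths uniform on \code{depthRange}, and negative-binomial counts with the
#' configured dispersion. For truly DE genes the tumor mean is the normal
#' mean times \code{fc^(direction * m)}, where \code{m} is a per-subject
#' de-regulation multiplier; a closed-form calibration keeps the cohort-level
#' ratio of means at the nominal fold change. Fully reproducible from
#' \code{config@seed}.
#'
#' @param config a [SimulationConfig()].
#' @return list with \code{experiment} (a
#'   \linkS4class{PairedCountExperiment}), \code{sampleSheet} (data.frame)
#'   and \code{truth} (list with per-gene and per-subject ground truth; see
#'   Details).
#' @details \code{truth$genes} has columns \code{gene_id}, \code{is_de},
#'   \code{direction} (+1/-1, NA for non-DE genes) and \code{fold_change};
#'   \code{truth$subjects} has \code{subject_id}, the latent multiplier
#'   \code{dereg} and \code{true_tertile} ("T1"-"T3", the tertile of
#'   \code{dereg} that drives the simulated hazard).
#' @export
generatePairedCounts <- function(config) {
    methods::validObject(config)
    set.seed(config@seed)
    nG <- config@nGenes; nS <- config@nSubjects
    genes <- .geneIds(nG); subj <- .subjIds(nS)

    ab <- stats::rlnorm(nG, meanlog = 1, sdlog = 1.5)
    wAb <- ab / sum(ab)

    nDE <- round(config@fracDE * nG)
    deIdx <- if (nDE > 0) sort(sample.int(nG, nDE)) else integer()
    dirn <- rep(NA_real_, nG)
    fc <- rep(NA_real_, nG)
    if (nDE > 0) {
        dirn[deIdx] <- sample(c(1, -1), nDE, replace = TRUE,
                              prob = c(config@fracUp, 1 - config@fracUp))
        fc[deIdx] <- stats::runif(nDE, config@fcRange[1], config@fcRange[2])
    }

    w <- config@deHeterogeneity
    m <- stats::runif(nS, 1 - w, 1 + w)
    depths <- matrix(stats::runif(2 * nS, config@depthRange[1],
                                  config@depthRange[2]), nrow = 2L)

    normalMean <- outer(wAb, depths[2L, ])
    tumorFactor <- matrix(1, nG, nS)
    if (nDE > 0) {
        K <- .fcCalibration(fc[deIdx], w)
        tumorFactor[deIdx, ] <- (fc[deIdx]^outer(dirn[deIdx], m)) / K
    }
    tumorMean <- outer(wAb, depths[1L, ]) * tumorFactor

    size <- 1 / config@dispersion
    tum <- matrix(stats::rnbinom(nG * nS, size = size, mu = tumorMean), nG, nS)
    nor <- matrix(stats::rnbinom(nG * nS, size = size, mu = normalMean), nG, nS)

    cnt <- cbind(tum, nor)
    storage.mode(cnt) <- "integer"
    sampleIds <- c(paste0(subj, "_T"), paste0(subj, "_N"))
    dimnames(cnt) <- list(genes, sampleIds)
    sheet <- data.frame(
        subject_id = rep(subj, 2L), sample_id = sampleIds,
        tissue = rep(c("tumor", "normal"), each = nS),
        stringsAsFactors = FALSE)

    truth <- list(
        genes = data.frame(gene_id = genes,
                           is_de = seq_len(nG) %in% deIdx,
                           direction = dirn, fold_change = fc,
                           stringsAsFactors = FALSE),
        subjects = data.frame(subject_id = subj, dereg = m,
                              true_tertile = as.character(tertileAssign(m)),
                              stringsAsFactors = FALSE))
    list(experiment = PairedCountExperiment(cnt, sheet),
         sampleSheet = sheet, truth = truth)
}

#' Generate clinical covariates and cause-specific survival outcomes
#'
#' Survival times follow an exponential proportional-hazards model whose log
#' hazard depends on the subject's true de-regulation tertile:
#' \code{h_i = baselineHazard * exp(tertileLogHR[tier_i])} (tertile 1 at the
#' baseline). Deaths are assigned to other causes with probability
#' \code{fracOtherDeath}; survivors are administratively censored at
#' \code{censorMonths}; a fraction \code{fracUnknown} of subjects is lost to
#' follow-up at a uniformly drawn last-contact month and recorded as
#' \code{"unknown"}. Times are reported as whole months (minimum 1), which
#' deliberately produces tied event times as registry data do.
#'
#' @param config a [SimulationConfig()].
#' @param truth truth record from [generatePairedCounts()] (needs
#'   \code{truth$subjects$true_tertile}).
#' @return data.frame with one row per subject: \code{subject_id},
#'   \code{age}, \code{sex} ("M"/"F"), \code{stage} (1-4),
#'   \code{vital_status} (\code{alive}/\code{crc_death}/\code{other_death}/
#'   \code{unknown}), \code{follow_months}, and 0/1 \code{tp53}, \code{kras},
#'   \code{msi}, \code{cimp}.
#' @export
generateClinicalSurvival <- function(config, truth) {
    methods::validObject(config)
    st <- truth$subjects
    if (is.null(st$true_tertile))
        stop("truth$subjects must carry true_tertile")
    set.seed(config@seed + 1L)
    nS <- nrow(st)
    tier <- match(st$true_tertile, c("T1", "T2", "T3"))
    lhr <- c(0, config@tertileLogHR)[tier]
    rate <- config@baselineHazard * exp(lhr)
    tDeath <- stats::rexp(nS, rate)

    unknown <- stats::runif(nS) < config@fracUnknown
    lastContact <- stats::runif(nS, 0, config@censorMonths)
    died <- !unknown & tDeath <= config@censorMonths
    otherCause <- stats::runif(nS) < config@fracOtherDeath

    vital <- ifelse(unknown, "unknown",
             ifelse(!died, "alive",
             ifelse(otherCause, "other_death", "crc_death")))
    timeRaw <- ifelse(unknown, lastContact,
               ifelse(died, tDeath, config@censorMonths))
    followMonths <- pmax(1, round(timeRaw))

    prev <- config@covariatePrevalences
    data.frame(
        subject_id = st$subject_id,
        age = round(stats::rnorm(nS, config@ageMeanSD[1],
                                 config@ageMeanSD[2]), 1),
        sex = ifelse(stats::runif(nS) < prev[["male"]], "M", "F"),
        stage = sample(1:4, nS, replace = TRUE, prob = config@stageProbs),
        vital_status = vital,
        follow_months = followMonths,
        tp53 = as.integer(stats::runif(nS) < prev[["tp53"]]),
        kras = as.integer(stats::runif(nS) < prev[["kras"]]),
        msi = as.integer(stats::runif(nS) < prev[["msi"]]),
        cimp = as.integer(stats::runif(nS) < prev[["cimp"]]),
        stringsAsFactors = FALSE)
}

#' Generate pathway gene sets with a built-in enrichment signal
#'
#' Survival-linked pathways draw \code{enrichmentWeight} of their members
#' from truly DE genes (so overrepresentation and DPES signal exist by
#' construction); background pathways draw only non-DE genes. Without
#' \code{allowOverlap}, genes are sampled without replacement across sets.
#' Each set's description records its role (\code{"survival_linked"} or
#' \code{"background"}).
#'
#' @param config a [SimulationConfig()].
#' @param truth truth record from [generatePairedCounts()].
#' @return a \linkS4class{GeneSetCollection} with \code{nPathways} sets of
#'   exactly \code{genesPerPathway} genes each.
#' @export
generateGeneSets <- function(config, truth) {
    methods::validObject(config)
    if (config@genesPerPathway > config@nGenes)
        stop("genesPerPathway exceeds nGenes")
    set.seed(config@seed + 2L)
    nP <- config@nPathways
    if (nP == 0L) return(GeneSetCollection())
    G <- config@genesPerPathway
    nLinked <- round(config@fracLinked * nP)
    linked <- sample(rep(c(TRUE, FALSE), c(nLinked, nP - nLinked)))

    dePool <- truth$genes$gene_id[truth$genes$is_de]
    bgPool <- truth$genes$gene_id[!truth$genes$is_de]
    kDE <- round(config@enrichmentWeight * G)

    sets <- vector("list", nP)
    for (p in seq_len(nP)) {
        if (linked[p]) {
            if (length(dePool) < kDE || length(bgPool) < G - kDE)
                stop("not enough genes to fill survival-linked pathways ",
                     "without overlap; reduce nPathways/genesPerPathway or ",
                     "set allowOverlap = TRUE")
            de <- sample(dePool, kDE)
            bg <- if (G - kDE > 0) sample(bgPool, G - kDE) else character()
            members <- sample(c(de, bg))
            if (!config@allowOverlap) {
                dePool <- setdiff(dePool, de)
                bgPool <- setdiff(bgPool, bg)
            }
        } else {
            if (length(bgPool) < G)
                stop("not enough non-DE genes to fill background pathways ",
                     "without overlap")
            members <- sample(bgPool, G)
            if (!config@allowOverlap) bgPool <- setdiff(bgPool, members)
        }
        sets[[p]] <- members
    }
    names(sets) <- sprintf("pathway%02d", seq_len(nP))
    GeneSetCollection(sets, ifelse(linked, "survival_linked", "background"))
}

#' Simulate a complete cohort
#'
#' Runs [generatePairedCounts()], [generateClinicalSurvival()] and
#' [generateGeneSets()] under the config's seed and assembles the truth
#' record (including per-pathway survival-linked flags).
#'
#' @param config a [SimulationConfig()].
#' @return list with elements \code{experiment}, \code{sampleSheet},
#'   \code{clinical}, \code{geneSets}, \code{truth}.
#' @examples
#' cfg <- SimulationConfig(nSubjects = 12L, nGenes = 200L, nPathways = 4L,
#'                         genesPerPathway = 8L, seed = 7L)
#' cohort <- simulateCohort(cfg)
#' cohort$experiment
#' @export
simulateCohort <- function(config) {
    pc <- generatePairedCounts(config)
    clinical <- generateClinicalSurvival(config, pc$truth)
    gsc <- generateGeneSets(config, pc$truth)
    truth <- pc$truth
    truth$pathways <- data.frame(
        pathway = names(gsc),
        is_survival_linked = unname(setDescriptions(gsc) == "survival_linked"),
        stringsAsFactors = FALSE)
    list(experiment = pc$experiment, sampleSheet = pc$sampleSheet,
         clinical = clinical, geneSets = gsc, truth = truth)
}

#' Write / read a plain-text fixture bundle
#'
#' Serializes a simulated cohort as a counts TSV (first column
#' \code{feature_id}), sample sheet and clinical CSVs, a GMT file, and a
#' truth JSON; [readFixtureBundle()] reconstructs the in-memory objects.
#' Writing the same cohort twice yields byte-identical files.
#'
#' @param cohort list as returned by [simulateCohort()].
#' @param dir output directory (created if absent).
#' @return invisibly, the named vector of file paths written.
#' @export
writeFixtureBundle <- function(cohort, dir) {
    if (!dir.exists(dir) &&
        !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
        stop("cannot create directory ", dir)
    paths <- c(counts = file.path(dir, "counts.tsv"),
               sample_sheet = file.path(dir, "sample_sheet.csv"),
               clinical = file.path(dir, "clinical.csv"),
               gene_sets = file.path(dir, "gene_sets.gmt"),
               truth = file.path(dir, "truth.json"))
    cnt <- counts(cohort$experiment)
    df <- data.frame(feature_id = rownames(cnt), cnt, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, paths[["counts"]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.csv(cohort$sampleSheet, paths[["sample_sheet"]],
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(cohort$clinical, paths[["clinical"]],
                     row.names = FALSE, quote = FALSE)
    writeGmt(cohort$geneSets, paths[["gene_sets"]])
    jsonlite::write_json(cohort$truth, paths[["truth"]], auto_unbox = TRUE,
                         digits = NA, na = "null")
    invisible(paths)
}

#' @rdname writeFixtureBundle
#' @return for \code{readFixtureBundle}, a cohort list mirroring
#'   [simulateCohort()] output.
#' @export
readFixtureBundle <- function(dir) {
    cnt <- utils::read.delim(file.path(dir, "counts.tsv"),
                             check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(cnt[, -1, drop = FALSE])
    rownames(m) <- cnt$feature_id
    storage.mode(m) <- "integer"
    sheet <- utils::read.csv(file.path(dir, "sample_sheet.csv"),
                             stringsAsFactors = FALSE)
    clinical <- utils::read.csv(file.path(dir, "clinical.csv"),
                                stringsAsFactors = FALSE)
    gsc <- readGmt(file.path(dir, "gene_sets.gmt"))
    truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                                 simplifyVector = TRUE)
    list(experiment = PairedCountExperiment(m, sheet), sampleSheet = sheet,
         clinical = clinical, geneSets = gsc, truth = truth)
}
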