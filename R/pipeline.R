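.paramDefaults <- list(
    n_resamples = 20L, n_perm = 1000L, p_threshold = 0.05,
    fc_threshold = 2.0, pseudocount = 0.5, age_bin_width = 5,
    bh_alpha = 0.05, qc_min_depth = 1e5, cpm_threshold = 1,
    expressed_min_frac = 0.1)

.inputKeys <- c("counts", "sample_sheet", "clinical", "feature_manifest",
                "gene_sets")

.checkRange <- function(params) {
    chk <- function(cond, what) if (!cond) stop("parameter out of range: ", what)
    chk(params$n_resamples >= 1, "n_resamples must be >= 1")
    chk(params$n_perm >= 1, "n_perm must be >= 1")
    chk(params$p_threshold > 0 && params$p_threshold <= 1,
        "p_threshold must be in (0, 1]")
    chk(params$fc_threshold > 1, "fc_threshold must be > 1")
    chk(params$pseudocount >= 0, "pseudocount must be >= 0")
    chk(params$age_bin_width > 0, "age_bin_width must be > 0")
    chk(params$bh_alpha > 0 && params$bh_alpha < 1,
        "bh_alpha must be in (0, 1)")
    invisible(params)
}

#' Validate a pipeline configuration file
#'
#' Reads a YAML config, fills parameter defaults (20 thinning resamples,
#' 1,000 permutations, p < 0.05 with a two-fold change, BH alpha 0.05),
#' range-checks every parameter, rejects unknown keys by name, and checks
#' that referenced input files exist. A config may either point at existing
#' inputs (\code{inputs:} block) or request simulation (\code{simulate:}
#' block with [SimulationConfig()] field overrides in snake_case).
#'
#' @param path YAML file path.
#' @return a validated config list of class \code{PipelineConfig} with
#'   elements \code{inputs}, \code{params}, \code{simulate}, \code{seed}.
#' @export
validateConfig <- function(path) {
    if (!file.exists(path)) stop("config file not found: ", path)
    raw <- yaml::read_yaml(path)
    known <- c("inputs", "params", "simulate", "seed")
    bad <- setdiff(names(raw), known)
    if (length(bad))
        stop("unknown config key(s): ", paste(bad, collapse = ", "))

    inputs <- raw$inputs %||% list()
    bad <- setdiff(names(inputs), .inputKeys)
    if (length(bad))
        stop("unknown input key(s): ", paste(bad, collapse = ", "))
    for (k in names(inputs))
        if (!file.exists(inputs[[k]]))
            stop("input path does not exist: ", k, " = ", inputs[[k]])

    params <- raw$params %||% list()
    bad <- setdiff(names(params), names(.paramDefaults))
    if (length(bad))
        stop("unknown parameter key(s): ", paste(bad, collapse = ", "))
    params <- utils::modifyList(.paramDefaults, params)
    .checkRange(params)

    sim <- raw$simulate
    if (!is.null(sim)) {
        simKnown <- c("n_subjects", "n_genes", "n_pathways",
                      "genes_per_pathway", "frac_de", "frac_up", "fc_range",
                      "dispersion", "depth_range", "de_heterogeneity",
                      "tertile_log_hr", "baseline_hazard", "frac_other_death",
                      "frac_unknown", "censor_months", "stage_probs",
                      "frac_linked", "enrichment_weight", "allow_overlap")
        bad <- setdiff(names(sim), simKnown)
        if (length(bad))
            stop("unknown simulate key(s): ", paste(bad, collapse = ", "))
    } else if (!all(c("counts", "sample_sheet", "clinical") %in%
                    names(inputs))) {
        stop("config needs either a simulate block or counts, sample_sheet ",
             "and clinical inputs")
    }

    seed <- raw$seed %||% 1L
    if (!is.numeric(seed) || seed < 0 || seed > .Machine$integer.max - 10)
        stop("seed must be a small non-negative integer")

    structure(list(inputs = inputs, params = params, simulate = sim,
                   seed = as.integer(seed)),
              class = "PipelineConfig")
}

.snakeToSimConfig <- function(sim, seed) {
    map <- c(n_subjects = "nSubjects", n_genes = "nGenes",
             n_pathways = "nPathways", genes_per_pathway = "genesPerPathway",
             frac_de = "fracDE", frac_up = "fracUp", fc_range = "fcRange",
             dispersion = "dispersion", depth_range = "depthRange",
             de_heterogeneity = "deHeterogeneity",
             tertile_log_hr = "tertileLogHR",
             baseline_hazard = "baselineHazard",
             frac_other_death = "fracOtherDeath",
             frac_unknown = "fracUnknown", censor_months = "censorMonths",
             stage_probs = "stageProbs", frac_linked = "fracLinked",
             enrichment_weight = "enrichmentWeight",
             allow_overlap = "allowOverlap")
    args <- stats::setNames(sim, map[names(sim)])
    args <- lapply(args, function(x) if (is.list(x)) unlist(x) else x)
    args$seed <- seed
    do.call(SimulationConfig, args)
}

.stageOrder <- c("simulate", "qc", "split", "de", "enrich", "score",
                 "survive", "stage")

.log <- function(stage, ...) {
    kv <- c(...)
    message(sprintf("[dpes] stage=%s %s", stage,
                    paste(names(kv), unname(kv), sep = "=", collapse = " ")))
}

.artifact <- function(outdir, name) file.path(outdir, name)

.needArtifact <- function(outdir, name, stage) {
    p <- .artifact(outdir, name)
    if (!file.exists(p))
        stop(sprintf("stage '%s' needs missing upstream artifact %s", stage,
                     name))
    p
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order: \code{simulate}
#' (synthetic fixture), \code{qc} (feature filter + subject QC), \code{split}
#' (discovery groups A/B), \code{de} (paired resampling/permutation test per
#' group + cross-validated selection), \code{enrich} (overrepresentation),
#' \code{score} (DGES/DPES + tertiles for enriched pathways), \code{survive}
#' (per-pathway Cox models, Kaplan-Meier plot for the top pathway) and
#' \code{stage} (per-pathway stage summaries). Every stage writes plain-text
#' artifacts under \code{outdir} and logs its input/output record counts; a
#' JSON manifest with md5 checksums of all artifacts is written at the end.
#' Identical config + seed reproduce identical artifacts.
#'
#' @param config a \code{PipelineConfig} from [validateConfig()].
#' @param outdir output directory (created if needed).
#' @param stages subset of stage names, or \code{"all"}.
#' @param seed overrides the config seed when given. Per-stage substreams
#'   are derived as seed + a fixed stage offset.
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(config, outdir, stages = "all", seed = NULL) {
    if (!inherits(config, "PipelineConfig"))
        stop("config must come from validateConfig()")
    if (identical(stages, "all")) stages <- .stageOrder
    bad <- setdiff(stages, .stageOrder)
    if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
    stages <- .stageOrder[.stageOrder %in% stages]
    if (!dir.exists(outdir))
        dir.create(outdir, recursive = TRUE)
    seed <- if (is.null(seed)) config$seed else as.integer(seed)
    prm <- config$params

    manifest <- list(seed = seed, params = prm, stages = list(),
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    artifacts <- character()
    record <- function(stage, files, nIn, nOut) {
        artifacts <<- union(artifacts, files)
        manifest$stages[[stage]] <<- list(
            artifacts = basename(files), n_in = nIn, n_out = nOut)
        .log(stage, n_in = nIn, n_out = nOut)
    }

    inputs <- config$inputs
    if ("simulate" %in% stages) {
        simCfg <- .snakeToSimConfig(config$simulate %||% list(), seed)
        cohort <- simulateCohort(simCfg)
        fixDir <- file.path(outdir, "fixture")
        paths <- writeFixtureBundle(cohort, fixDir)
        inputs <- utils::modifyList(inputs, list(
            counts = paths[["counts"]], sample_sheet = paths[["sample_sheet"]],
            clinical = paths[["clinical"]], gene_sets = paths[["gene_sets"]]))
        record("simulate", unname(paths), simCfg@nSubjects,
               nrow(cohort$clinical))
    }

    readCounts <- function() {
        cnt <- utils::read.delim(inputs$counts, check.names = FALSE,
                                 stringsAsFactors = FALSE)
        m <- as.matrix(cnt[, -1, drop = FALSE])
        rownames(m) <- cnt[[1L]]
        sheet <- utils::read.csv(inputs$sample_sheet, stringsAsFactors = FALSE)
        PairedCountExperiment(m, sheet)
    }

    if ("qc" %in% stages) {
        if (is.null(inputs$counts))
            stop("stage 'qc' needs a counts input (run simulate or provide paths)")
        pce <- readCounts()
        if (!is.null(inputs$feature_manifest)) {
            man <- utils::read.delim(inputs$feature_manifest,
                                     stringsAsFactors = FALSE)
            keepFeat <- filterFeatures(man)
        } else {
            expressed <- flagExpressed(counts(pce), prm$cpm_threshold,
                                       prm$expressed_min_frac)
            keepFeat <- rownames(pce)[expressed]
        }
        depths <- libDepths(pce)
        cd <- SummarizedExperiment::colData(pce)
        byTissue <- function(t) {
            sel <- cd$tissue == t
            depths[sel][match(subjectIds(pce), cd$subject_id[sel])]
        }
        qcTab <- data.frame(subject_id = subjectIds(pce),
                            tumor_pass = byTissue("tumor") >= prm$qc_min_depth,
                            normal_pass = byTissue("normal") >= prm$qc_min_depth)
        keepSubj <- qcSubjects(qcTab)
        f1 <- .artifact(outdir, "features_retained.txt")
        f2 <- .artifact(outdir, "subjects_retained.txt")
        writeLines(keepFeat, f1)
        writeLines(keepSubj, f2)
        record("qc", c(f1, f2),
               nIn = nrow(pce) + length(subjectIds(pce)),
               nOut = length(keepFeat) + length(keepSubj))
    }

    if ("split" %in% stages) {
        clin <- utils::read.csv(inputs$clinical, stringsAsFactors = FALSE)
        subjFile <- .needArtifact(outdir, "subjects_retained.txt", "split")
        keepSubj <- readLines(subjFile)
        clin <- clin[clin$subject_id %in% keepSubj, ]
        split <- splitDiscoveryGroups(clin, prm$age_bin_width,
                                      seed = seed + 11L)
        f <- .artifact(outdir, "split.csv")
        utils::write.csv(split, f, row.names = FALSE)
        record("split", f, nrow(clin), sum(split$group != "unassigned"))
    }

    if ("de" %in% stages) {
        splitFile <- .needArtifact(outdir, "split.csv", "de")
        featFile <- .needArtifact(outdir, "features_retained.txt", "de")
        split <- utils::read.csv(splitFile, stringsAsFactors = FALSE)
        keepFeat <- readLines(featFile)
        pce <- readCounts()
        pce <- pce[rownames(pce) %in% keepFeat, ]
        files <- character()
        results <- list()
        for (g in c("A", "B")) {
            sub <- subsetSubjects(pce, split$subject_id[split$group == g])
            res <- runPairedDE(sub, nResamples = prm$n_resamples,
                               nPerm = prm$n_perm,
                               pseudocount = prm$pseudocount,
                               seed = seed + 21L + (g == "B"))
            f <- .artifact(outdir, sprintf("de_%s.tsv", g))
            utils::write.table(res, f, sep = "\t", quote = FALSE,
                               row.names = FALSE)
            files <- c(files, f)
            results[[g]] <- res
        }
        sel <- selectDEFeatures(results$A, results$B,
                                pThreshold = prm$p_threshold,
                                fcThreshold = prm$fc_threshold)
        selTab <- merge(sel$table,
                        results$A[, c("feature_id", "direction")],
                        by = "feature_id")
        f <- .artifact(outdir, "de_selected.tsv")
        utils::write.table(selTab, f, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        fUp <- .artifact(outdir, "de_up.txt")
        fDn <- .artifact(outdir, "de_down.txt")
        writeLines(sel$up, fUp); writeLines(sel$down, fDn)
        record("de", c(files, f, fUp, fDn), nrow(pce),
               length(sel$up) + length(sel$down))
    }

    if ("enrich" %in% stages) {
        if (is.null(inputs$gene_sets))
            stop("stage 'enrich' needs a gene_sets (GMT) input")
        up <- readLines(.needArtifact(outdir, "de_up.txt", "enrich"))
        dn <- readLines(.needArtifact(outdir, "de_down.txt", "enrich"))
        keepFeat <- readLines(.needArtifact(outdir, "features_retained.txt",
                                            "enrich"))
        gsc <- readGmt(inputs$gene_sets)
        enr <- hypergeometricEnrichment(c(up, dn), keepFeat, gsc,
                                        up = up, down = dn)
        f <- .artifact(outdir, "enrichment.tsv")
        utils::write.table(enr, f, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        record("enrich", f, length(gsc), sum(enr$p_bh < prm$bh_alpha))
    }

    if ("score" %in% stages) {
        enr <- utils::read.delim(.needArtifact(outdir, "enrichment.tsv",
                                               "score"),
                                 stringsAsFactors = FALSE)
        selTab <- utils::read.delim(.needArtifact(outdir, "de_selected.tsv",
                                                  "score"),
                                    stringsAsFactors = FALSE)
        keepSubj <- readLines(.needArtifact(outdir, "subjects_retained.txt",
                                            "score"))
        gsc <- readGmt(inputs$gene_sets)
        sig <- enr$set_name[enr$p_bh < prm$bh_alpha]
        if (!length(sig))
            stop("no enriched pathways at bh_alpha; nothing to score")
        selected <- selTab$feature_id[selTab$selected_both]
        dirs <- stats::setNames(selTab$direction, selTab$feature_id)[selected]
        keepFeat <- readLines(.needArtifact(outdir, "features_retained.txt",
                                            "score"))
        pce <- readCounts()
        pce <- subsetSubjects(pce, keepSubj)
        # delta on the full filtered feature space so CPM uses real depths
        sub <- pce[rownames(pce) %in% keepFeat, ]
        delta <- computeDeltaProfile(sub, prm$pseudocount)
        delta <- delta[, intersect(colnames(delta), selected), drop = FALSE]
        dges <- assignDGES(delta, dirs)
        dpes <- computeDPES(dges, gsc[sig])
        tert <- dpesTertiles(dpes)
        fD <- .artifact(outdir, "dges.tsv")
        fP <- .artifact(outdir, "dpes.tsv")
        fT <- .artifact(outdir, "tertiles.csv")
        utils::write.table(data.frame(subject_id = rownames(dges), dges,
                                      check.names = FALSE),
                           fD, sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(data.frame(subject_id = rownames(dpes), dpes,
                                      check.names = FALSE),
                           fP, sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.csv(data.frame(subject_id = rownames(tert), tert,
                                    check.names = FALSE),
                         fT, row.names = FALSE)
        record("score", c(fD, fP, fT), length(selected), ncol(dpes))
    }

    if ("survive" %in% stages) {
        dpesTab <- utils::read.delim(.needArtifact(outdir, "dpes.tsv",
                                                   "survive"),
                                     check.names = FALSE,
                                     stringsAsFactors = FALSE)
        tertTab <- utils::read.csv(.needArtifact(outdir, "tertiles.csv",
                                                 "survive"),
                                   check.names = FALSE,
                                   stringsAsFactors = FALSE)
        clin <- utils::read.csv(inputs$clinical, stringsAsFactors = FALSE)
        pathways <- setdiff(colnames(tertTab), "subject_id")
        rows <- lapply(pathways, function(pw) {
            tert <- stats::setNames(tertTab[[pw]], tertTab$subject_id)
            rec <- buildSurvivalRecords(
                clin[clin$subject_id %in% tertTab$subject_id, ], tert)
            hz <- tryCatch(fitCoxTertiles(rec), error = function(e) NULL)
            if (is.null(hz)) return(NULL)
            data.frame(pathway = pw,
                       hr_t2 = hz["T2", "hr"], lo_t2 = hz["T2", "lower"],
                       hi_t2 = hz["T2", "upper"],
                       hr_t3 = hz["T3", "hr"], lo_t3 = hz["T3", "lower"],
                       hi_t3 = hz["T3", "upper"],
                       n_events = attr(hz, "n_events"),
                       stringsAsFactors = FALSE)
        })
        surv <- do.call(rbind, rows)
        if (is.null(surv))
            surv <- data.frame(pathway = character(), hr_t2 = numeric(),
                               lo_t2 = numeric(), hi_t2 = numeric(),
                               hr_t3 = numeric(), lo_t3 = numeric(),
                               hi_t3 = numeric(), n_events = integer())
        f <- .artifact(outdir, "survival.tsv")
        utils::write.table(surv, f, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        files <- f
        if (length(pathways)) {
            tert <- stats::setNames(tertTab[[pathways[1L]]],
                                    tertTab$subject_id)
            rec <- buildSurvivalRecords(
                clin[clin$subject_id %in% tertTab$subject_id, ], tert)
            fKm <- .artifact(outdir, "km_top_pathway.png")
            kmByTertile(rec, file = fKm)
            files <- c(files, fKm)
        }
        record("survive", files, length(pathways),
               if (is.null(surv)) 0L else nrow(surv))
    }

    if ("stage" %in% stages) {
        dpesTab <- utils::read.delim(.needArtifact(outdir, "dpes.tsv",
                                                   "stage"),
                                     check.names = FALSE,
                                     stringsAsFactors = FALSE)
        clin <- utils::read.csv(inputs$clinical, stringsAsFactors = FALSE)
        idx <- match(dpesTab$subject_id, clin$subject_id)
        pathways <- setdiff(colnames(dpesTab), "subject_id")
        rows <- lapply(pathways, function(pw) {
            cbind(pathway = pw,
                  stageSummary(dpesTab[[pw]], clin$stage[idx]))
        })
        stg <- do.call(rbind, rows)
        f <- .artifact(outdir, "stage_summary.tsv")
        utils::write.table(stg, f, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        record("stage", f, length(pathways), nrow(stg))
    }

    manifest$checksums <- as.list(tools::md5sum(sort(artifacts)))
    names(manifest$checksums) <- basename(sort(artifacts))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(manifest)
}
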