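smallCfg <- function(...) {
    args <- utils::modifyList(
        list(nSubjects = 20L, nGenes = 200L, nPathways = 4L,
             genesPerPathway = 10L, seed = 42L),
        list(...))
    do.call(SimulationConfig, args)
}

test_that("config invariants are enforced", {
    expect_error(smallCfg(fracDE = 1.2), "fractions")
    expect_error(smallCfg(stageProbs = c(0.5, 0.3, 0.1, 0.2)), "summing to 1")
    expect_error(smallCfg(fcRange = c(0.8, 3)), "lower bound > 1")
    expect_error(smallCfg(dispersion = 0), "dispersion")
    expect_error(smallCfg(baselineHazard = -1), "baselineHazard")
    expect_error(SimulationConfig(nGenes = 30L, nPathways = 5L,
                                  genesPerPathway = 10L), "allowOverlap")
})

test_that("DE truth bookkeeping follows the configured fraction", {
    cohort0 <- generatePairedCounts(smallCfg(fracDE = 0))
    expect_equal(sum(cohort0$truth$genes$is_de), 0L)
    expect_true(all(is.na(cohort0$truth$genes$direction)))

    cfg <- SimulationConfig(nSubjects = 10L, nGenes = 1000L, nPathways = 2L,
                            genesPerPathway = 5L, fracDE = 0.1, seed = 3L)
    cohort <- generatePairedCounts(cfg)
    expect_equal(sum(cohort$truth$genes$is_de), 100L)
    expect_true(all(!is.na(
        cohort$truth$genes$direction[cohort$truth$genes$is_de])))
})

test_that("cohort-level fold change matches the nominal value (Monte-Carlo)", {
    # near-Poisson counts, equal expected depths, one DE gene at fold change 3
    cfg <- SimulationConfig(nSubjects = 200L, nGenes = 50L, nPathways = 1L,
                            genesPerPathway = 2L, fracDE = 1 / 50, fracUp = 1,
                            fcRange = c(3, 3), dispersion = 1e-6,
                            depthRange = c(1e6, 1e6), seed = 5L)
    cohort <- generatePairedCounts(cfg)
    de <- which(cohort$truth$genes$is_de)
    expect_length(de, 1L)
    tum <- tumorCounts(cohort$experiment)
    nor <- normalCounts(cohort$experiment)
    ratio <- mean(tum[de, ]) / mean(nor[de, ])
    expect_lt(abs(ratio - 3) / 3, 0.05)
})

test_that("non-DE genes have matching tumor/normal marginal means", {
    cfg <- SimulationConfig(nSubjects = 250L, nGenes = 150L, nPathways = 2L,
                            genesPerPathway = 10L, fracDE = 0.2, seed = 8L)
    cohort <- generatePairedCounts(cfg)
    nonDE <- !cohort$truth$genes$is_de
    d <- tumorCounts(cohort$experiment)[nonDE, ] -
        normalCounts(cohort$experiment)[nonDE, ]
    z <- rowMeans(d) / (apply(d, 1, sd) / sqrt(ncol(d)))
    expect_gt(mean(abs(z) < 3), 0.95)
})

test_that("survival outcomes respect configured mixture and bookkeeping", {
    cfg <- smallCfg()
    cohort <- generatePairedCounts(cfg)
    clin <- generateClinicalSurvival(cfg, cohort$truth)
    expect_equal(nrow(clin), 20L)
    expect_setequal(clin$subject_id, cohort$truth$subjects$subject_id)
    tab <- table(factor(clin$vital_status,
                        c("alive", "crc_death", "other_death", "unknown")))
    expect_equal(sum(tab), 20L)          # every subject accounted for
    expect_true(all(clin$follow_months >= 1))

    # no other-cause deaths when the fraction is zero
    cfgNo <- smallCfg(fracOtherDeath = 0)
    clinNo <- generateClinicalSurvival(cfgNo, generatePairedCounts(cfgNo)$truth)
    expect_false(any(clinNo$vital_status == "other_death"))
})

test_that("higher true tertile means longer survival under protective log-HRs", {
    cfg <- SimulationConfig(nSubjects = 2000L, nGenes = 20L, nPathways = 1L,
                            genesPerPathway = 5L, tertileLogHR = c(-0.9, -1.1),
                            fracUnknown = 0, censorMonths = 1e5, seed = 13L)
    truth <- generatePairedCounts(cfg)$truth
    clin <- generateClinicalSurvival(cfg, truth)
    tert <- truth$subjects$true_tertile
    expect_gt(median(clin$follow_months[tert == "T3"]),
              median(clin$follow_months[tert == "T1"]))
})

test_that("gene sets carry the constructed enrichment signal", {
    expect_equal(length(generateGeneSets(
        smallCfg(nPathways = 0L), generatePairedCounts(smallCfg())$truth)), 0L)

    cfg <- SimulationConfig(nSubjects = 10L, nGenes = 400L, nPathways = 6L,
                            genesPerPathway = 12L, fracLinked = 0.5,
                            enrichmentWeight = 1.0, seed = 21L)
    pc <- generatePairedCounts(cfg)
    gsc <- generateGeneSets(cfg, pc$truth)
    expect_true(all(lengths(geneSets(gsc)) == 12L))
    deGenes <- pc$truth$genes$gene_id[pc$truth$genes$is_de]
    roles <- setDescriptions(gsc)
    for (nm in names(gsc)) {
        inDE <- mean(gsc[[nm]] %in% deGenes)
        if (roles[[nm]] == "survival_linked") expect_equal(inDE, 1)
        else expect_equal(inDE, 0)
    }
    # no overlap by default
    expect_equal(anyDuplicated(unlist(geneSets(gsc))), 0L)
})

test_that("cohorts are deterministic and fixture bundles round-trip", {
    cfg <- smallCfg()
    c1 <- simulateCohort(cfg)
    c2 <- simulateCohort(cfg)
    expect_identical(counts(c1$experiment), counts(c2$experiment))
    expect_identical(c1$clinical, c2$clinical)
    expect_identical(geneSets(c1$geneSets), geneSets(c2$geneSets))

    d1 <- file.path(tempdir(), "fix1"); d2 <- file.path(tempdir(), "fix2")
    writeFixtureBundle(c1, d1)
    writeFixtureBundle(c2, d2)
    for (f in list.files(d1)) {
        expect_identical(unname(tools::md5sum(file.path(d1, f))),
                         unname(tools::md5sum(file.path(d2, f))),
                         info = f)
    }
    expect_equal(length(readLines(file.path(d1, "counts.tsv"))),
                 200L + 1L)   # one line per gene plus header

    back <- readFixtureBundle(d1)
    expect_identical(counts(back$experiment), counts(c1$experiment))
    expect_equal(back$clinical$follow_months, c1$clinical$follow_months)
    expect_identical(geneSets(back$geneSets), geneSets(c1$geneSets))
    expect_equal(back$truth$subjects$dereg, c1$truth$subjects$dereg)
})
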