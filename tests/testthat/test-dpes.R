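test_that("delta profile is the log2 CPM ratio and depth-invariant", {
    tum <- rbind(c(8, 8), c(2, 2))
    nor <- rbind(c(2, 2), c(8, 8))
    pce <- makePairedPCE(tum, nor)        # equal depths (10)
    delta <- computeDeltaProfile(pce, pseudocount = 1e-12)
    expect_equal(unname(delta[, 1]), c(2, 2))      # log2(8/2)
    expect_equal(unname(delta[, 2]), c(-2, -2))

    # tumor = normal -> delta 0
    pceEq <- makePairedPCE(tum, tum)
    expect_true(all(abs(computeDeltaProfile(pceEq)) < 1e-12))

    # doubling one library's depth leaves CPM deltas unchanged
    pce2 <- makePairedPCE(tum * 2L, nor)
    expect_equal(computeDeltaProfile(pce2, 1e-12), delta)
    expect_error(computeDeltaProfile(pce, pseudocount = 0), "pseudocount")
})

test_that("DGES follows the quartile rule with direction orientation", {
    # 8 subjects, one up gene with deltas 1..8: quartiles (type 7) are
    # 2.75 and 6.25 -> scores 1,1,2,2,2,2,3,3
    delta <- cbind(up = 1:8, dn = -(1:8))
    rownames(delta) <- paste0("s", 1:8)
    dges <- assignDGES(delta, c(up = "up", dn = "down"))
    expect_equal(unname(dges[, "up"]), c(1L, 1L, 2L, 2L, 2L, 2L, 3L, 3L))
    # down gene oriented by -1: most negative delta = most de-regulated
    expect_equal(unname(dges[, "dn"]), c(1L, 1L, 2L, 2L, 2L, 2L, 3L, 3L))

    # subject exactly at the median scores 2; boundary values go middle
    d2 <- cbind(g = c(0, 1, 2, 3, 4))
    rownames(d2) <- paste0("s", 1:5)
    s2 <- assignDGES(d2, c(g = 1))
    expect_equal(unname(s2[3, 1]), 2L)
    # all subjects identical -> quartiles collapse -> everyone scores 2
    dTie <- cbind(g = rep(1.5, 6)); rownames(dTie) <- paste0("s", 1:6)
    expect_true(all(assignDGES(dTie, c(g = 1)) == 2L))

    expect_error(assignDGES(delta[1:3, ], c(up = 1, dn = -1)), "4 subjects")
})

test_that("DGES bin occupancy is ~(25%, 50%, 25%) for continuous deltas", {
    set.seed(14)
    for (rep in 1:3) {
        delta <- matrix(rnorm(120 * 10), 120, 10,
                        dimnames = list(sprintf("s%03d", 1:120),
                                        paste0("g", 1:10)))
        dges <- assignDGES(delta, rep(1, 10))
        occ <- apply(dges, 2, function(x) tabulate(x, 3) / length(x))
        expect_true(all(abs(occ[1, ] - 0.25) < 0.02))
        expect_true(all(abs(occ[2, ] - 0.50) < 0.02))
        expect_true(all(abs(occ[3, ] - 0.25) < 0.02))
    }
})

test_that("DPES sums member scores with documented bounds and additivity", {
    dges <- rbind(s1 = c(1L, 2L, 3L, 3L), s2 = c(1L, 1L, 1L, 1L),
                  s3 = c(3L, 3L, 3L, 3L))
    colnames(dges) <- paste0("g", 1:4)
    gsc <- GeneSetCollection(list(pw = paste0("g", 1:4),
                                  a = paste0("g", 1:2),
                                  b = paste0("g", 3:4)))
    dpes <- computeDPES(dges, gsc)
    expect_equal(unname(dpes[, "pw"]), c(9L, 4L, 12L))  # (1+2+3+3), G, 3G
    # additivity over disjoint pathways
    expect_equal(dpes[, "pw"], dpes[, "a"] + dpes[, "b"])

    # pathway with no scored genes dropped with a warning
    gsc2 <- GeneSetCollection(list(pw = paste0("g", 1:4), ghost = "zz"))
    expect_warning(d2 <- computeDPES(dges, gsc2), "no scored genes")
    expect_identical(colnames(d2), "pw")

    # shuffling subjects permutes, never changes, scores
    perm <- c(3, 1, 2)
    expect_equal(computeDPES(dges[perm, ], gsc)[, "pw"],
                 dpes[perm, "pw"])
})

test_that("tertile assignment cuts at 1/3 and 2/3 with ties going low", {
    t9 <- tertileAssign(1:9)
    expect_equal(as.integer(table(t9)), c(3L, 3L, 3L))
    expect_true(all(as.integer(t9) == rep(1:3, each = 3)))

    tied <- tertileAssign(c(1, 1, 1, 2, 2, 2, 3, 3, 3))
    expect_equal(as.integer(table(tied)), c(3L, 3L, 3L))

    # monotone: larger score never gets a lower tertile
    set.seed(15)
    x <- sample(40, 25, replace = TRUE)
    tt <- tertileAssign(x)
    ord <- order(x)
    expect_true(all(diff(as.integer(tt)[ord]) >= 0))

    expect_warning(deg <- tertileAssign(rep(5, 10)), "degenerate")
    expect_true(all(deg == "T1"))
    expect_error(tertileAssign(c(1, 2)), "3 subjects")
})

test_that("a truly de-regulated pathway has higher DPES variance than a null one", {
    cfg <- SimulationConfig(nSubjects = 120L, nGenes = 300L, nPathways = 2L,
                            genesPerPathway = 10L, fracLinked = 0.5,
                            enrichmentWeight = 1.0, seed = 31L)
    cohort <- simulateCohort(cfg)
    delta <- computeDeltaProfile(cohort$experiment)
    truthG <- cohort$truth$genes
    dirs <- ifelse(is.na(truthG$direction), 1, truthG$direction)
    names(dirs) <- truthG$gene_id
    dges <- assignDGES(delta, dirs)
    dpes <- computeDPES(dges, cohort$geneSets)
    linked <- cohort$truth$pathways$pathway[
        cohort$truth$pathways$is_survival_linked]
    nullpw <- setdiff(colnames(dpes), linked)
    expect_gt(var(dpes[, linked[1]]), var(dpes[, nullpw[1]]))
})
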