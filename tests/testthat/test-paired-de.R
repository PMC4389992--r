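test_that("thinning preserves totals in expectation and passes equal depths through", {
    cnt <- matrix(c(100, 200, 300, 50, 150, 250), ncol = 2,
                  dimnames = list(paste0("g", 1:3), c("s1", "s2")))
    # both libraries already at the target: every resample is the input
    same <- thinCounts(cnt, targetDepth = min(colSums(cnt)) - 0,
                       nResamples = 3, seed = 1)
    # library 2 has depth 450 = min; library 1 has depth 600
    expect_true(all(vapply(same, function(m)
        identical(m[, "s2"], cnt[, "s2"]), logical(1))))

    eq <- thinCounts(cnt[, 1, drop = FALSE], targetDepth = 600,
                     nResamples = 2, seed = 1)
    expect_identical(eq[[1]], cnt[, 1, drop = FALSE])

    # depth twice the target: resampled totals average to the target
    set.seed(2)
    col <- matrix(rpois(200, 100), ncol = 1,
                  dimnames = list(NULL, "s"))
    target <- sum(col) / 2
    res <- thinCounts(col, targetDepth = target, nResamples = 1000, seed = 3)
    totals <- vapply(res, sum, numeric(1))
    expect_lt(abs(mean(totals) - target) / target, 0.01)

    # zeros stay zero; target above a depth is an error
    zero <- matrix(0L, 3, 1, dimnames = list(NULL, "z"))
    expect_error(thinCounts(cnt, targetDepth = 1000), "exceeds")
    expect_true(all(thinCounts(rbind(zero, 10L), targetDepth = 5,
                               seed = 1)[[1]][1:3, ] == 0))
})

test_that("signed-rank statistic matches its definition and extremes", {
    # all tumor > normal, no ties: maximal standardized value for n
    n <- 6
    stat <- pairedSignedRank(10 * (1:n) + (1:n), 10 * (1:n))
    W <- n * (n + 1) / 2
    expect_equal(as.numeric(stat), W / sqrt(sum((1:n)^2)))

    expect_equal(as.numeric(pairedSignedRank(c(5, 7), c(5, 7))), 0)
    expect_true(attr(pairedSignedRank(c(5, 7), c(5, 7)), "degenerate"))

    # differences (+5, -2, +1) against the from-scratch oracle
    expect_equal(as.numeric(pairedSignedRank(c(9, 1, 5), c(4, 3, 4))),
                 oracleSignedStat(c(5, -2, 1)))
    expect_equal(oracleSignedStat(c(5, -2, 1)), 2 / sqrt(14))

    # antisymmetry: swapping labels negates the statistic
    set.seed(4)
    t0 <- rpois(12, 60); n0 <- rpois(12, 40)
    expect_equal(as.numeric(pairedSignedRank(t0, n0)),
                 -as.numeric(pairedSignedRank(n0, t0)))
})

test_that("exact permutation p matches brute-force enumeration at small n", {
    # no thinning noise (equal depths 30), single resample, 3 pairs -> 8 flips
    tum <- rbind(c(9, 1, 5), c(21, 29, 25))   # filler row equalizes depths
    nor <- rbind(c(4, 3, 4), c(26, 27, 26))
    pce <- makePairedPCE(tum, nor)
    res <- runPairedDE(pce, nResamples = 1, nPerm = 10, seed = 1)
    d <- c(5, -2, 1)
    expect_equal(res$statistic[1], oracleSignedStat(d))
    expect_equal(res$p_perm[1], oracleExactP(d))

    # 8 pairs, mixed signs, equal depths (no thinning noise): exact p agrees
    # with enumeration gene by gene
    set.seed(9)
    t8 <- matrix(rpois(3 * 8, 80), nrow = 3)
    n8 <- matrix(rpois(3 * 8, 80), nrow = 3)
    t8 <- rbind(t8, 400 - colSums(t8))       # equalize depths with a filler
    n8 <- rbind(n8, 400 - colSums(n8))
    pce8 <- makePairedPCE(t8, n8)
    res8 <- runPairedDE(pce8, nResamples = 1, nPerm = 5, seed = 2)
    pOracle <- apply((t8 - n8)[1:3, ], 1, oracleExactP)
    expect_equal(res8$p_perm[1:3], unname(pOracle))
    expect_true(all(abs(res8$p_perm * 256 - round(res8$p_perm * 256)) < 1e-9))
})

test_that("sampled permutation p obeys the add-one rule and determinism", {
    set.seed(11)
    nG <- 40; nS <- 15
    tum <- matrix(rpois(nG * nS, 200), nG, nS)
    nor <- matrix(rpois(nG * nS, 100), nG, nS)   # strong signal per gene
    # filler row equalizes depths so thinning cannot erase the signal
    tum <- rbind(tum, 12000 - colSums(tum))
    nor <- rbind(nor, 12000 - colSums(nor))
    pce <- makePairedPCE(tum, nor)
    r1 <- runPairedDE(pce, nResamples = 3, nPerm = 200, seed = 7)
    r2 <- runPairedDE(pce, nResamples = 3, nPerm = 200, seed = 7)
    expect_identical(r1, r2)
    expect_gte(min(r1$p_perm), 1 / 201)
    # doubled genes: observed statistic beats every sampled permutation
    expect_true(mean(r1$p_perm[1:nG] == 1 / 201) > 0.9)
})

test_that("fold change is the ratio of mean CPMs with pseudocount", {
    # equal depths so CPM ratio equals raw ratio
    tum <- matrix(c(30, 20), ncol = 2, nrow = 1)
    tum <- rbind(c(30, 30), c(10, 10))
    nor <- rbind(c(10, 10), c(30, 30))
    pce <- makePairedPCE(tum, nor)   # depths all 40
    fc0 <- foldChange(pce, pseudocount = 0)
    expect_equal(fc0$fold_change[1], 3.0)
    expect_identical(fc0$direction, c("up", "down"))

    # identical tumor and normal -> FC 1
    pceEq <- makePairedPCE(tum, tum)
    expect_true(all(foldChange(pceEq, 0)$fold_change == 1))

    # swapping labels gives the reciprocal
    pceSwap <- makePairedPCE(nor, tum)
    expect_equal(foldChange(pceSwap, 0)$fold_change,
                 1 / fc0$fold_change)

    # zero normal mean with zero pseudocount errors
    pce0 <- makePairedPCE(rbind(c(5, 5), c(35, 35)),
                          rbind(c(0, 0), c(40, 40)))
    expect_error(foldChange(pce0, pseudocount = 0), "zero normal mean")
    expect_gt(foldChange(pce0, pseudocount = 0.5)$fold_change[1], 1)
})

test_that("cross-validated selection applies the two-group rule", {
    mk <- function(p, fc) data.frame(
        feature_id = paste0("g", seq_along(p)), p_perm = p, fold_change = fc,
        direction = ifelse(fc > 1, "up", "down"), stringsAsFactors = FALSE)
    # g1 selected up; g2 fails p in B; g3 inconsistent direction; g4 down both
    a <- mk(c(0.01, 0.01, 0.02, 0.001), c(2.5, 3.0, 2.5, 0.30))
    b <- mk(c(0.02, 0.20, 0.04, 0.010), c(2.8, 2.6, 0.40, 0.45))
    sel <- selectDEFeatures(a, b)
    expect_identical(sel$up, "g1")
    expect_identical(sel$down, "g4")
    expect_false(sel$table$selected_both[3])
    # conservation: up + down + excluded = universe
    expect_equal(length(sel$up) + length(sel$down) +
                 sum(!sel$table$selected_both), nrow(a))
    expect_error(selectDEFeatures(a, b[-1, ]), "universes")
})

test_that("rejection rate rises with true fold change (power monotonicity)", {
    set.seed(21)
    nS <- 12; per <- 60
    fcs <- c(1, 1.5, 2, 4)
    tum <- do.call(rbind, lapply(fcs, function(f)
        matrix(rnbinom(per * nS, size = 8, mu = 100 * f), per, nS)))
    nor <- matrix(rnbinom(length(fcs) * per * nS, size = 8, mu = 100),
                  length(fcs) * per, nS)
    # equal depths by a filler row: power is then a clean function of FC
    tum <- rbind(tum, 80000 - colSums(tum))
    nor <- rbind(nor, 80000 - colSums(nor))
    pce <- makePairedPCE(tum, nor)
    res <- runPairedDE(pce, nResamples = 3, nPerm = 200, seed = 22)
    rate <- tapply(res$p_perm[seq_len(per * 4)] < 0.05,
                   rep(fcs, each = per), mean)
    expect_true(all(diff(rate) > -0.05))
    expect_lt(rate[["1"]], 0.15)
    expect_gt(rate[["4"]], 0.9)
})
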