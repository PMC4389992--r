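# Small in-code fixtures and independent oracles shared across tests.

# paired experiment from explicit tumor/normal matrices (genes x subjects)
makePairedPCE <- function(tumor, normal, genes = NULL) {
    nS <- ncol(tumor)
    subj <- sprintf("s%02d", seq_len(nS))
    if (is.null(genes)) genes <- sprintf("g%03d", seq_len(nrow(tumor)))
    cnt <- cbind(tumor, normal)
    dimnames(cnt) <- list(genes, c(paste0(subj, "_T"), paste0(subj, "_N")))
    sheet <- data.frame(subject_id = rep(subj, 2),
                        sample_id = colnames(cnt),
                        tissue = rep(c("tumor", "normal"), each = nS))
    PairedCountExperiment(cnt, sheet)
}

# null paired cohort: same NB law in tumor and normal, equal expected depths
makeNullPCE <- function(nGenes, nSubjects, mu = 50, size = 5, seed = 1) {
    set.seed(seed)
    tum <- matrix(rnbinom(nGenes * nSubjects, size = size, mu = mu),
                  nGenes, nSubjects)
    nor <- matrix(rnbinom(nGenes * nSubjects, size = size, mu = mu),
                  nGenes, nSubjects)
    makePairedPCE(tum, nor)
}

# Oracle: standardized signed-rank statistic, written from the definition
oracleSignedStat <- function(d) {
    d <- d[d != 0]
    if (!length(d)) return(0)
    r <- rank(abs(d))
    sum(r * sign(d)) / sqrt(sum(r^2))
}

# Oracle: exact two-sided permutation p by enumerating all sign assignments
oracleExactP <- function(d) {
    n <- length(d)
    obs <- oracleSignedStat(d)
    signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
    null <- apply(signs, 1, function(s) oracleSignedStat(d * s))
    mean(abs(null) >= abs(obs) - 1e-12)
}

# Oracle: hypergeometric upper tail by enumerating all draws of size n
oracleHyperP <- function(N, K, n, k) {
    draws <- utils::combn(N, n)
    inSet <- seq_len(K)   # WLOG the first K universe elements form the set
    hits <- colSums(matrix(draws %in% inSet, nrow = n))
    mean(hits >= k)
}

# tiny clinical table for split/survival tests
makeClinical <- function(n, nDead, seed = 1) {
    set.seed(seed)
    data.frame(
        subject_id = sprintf("p%03d", seq_len(n)),
        age = round(runif(n, 40, 85), 1),
        sex = sample(c("M", "F"), n, replace = TRUE),
        stage = sample(1:4, n, replace = TRUE),
        vital_status = sample(c(rep("crc_death", nDead),
                                rep("alive", n - nDead))),
        follow_months = sample(6:120, n, replace = TRUE),
        tp53 = rbinom(n, 1, 0.4), kras = rbinom(n, 1, 0.3),
        msi = rbinom(n, 1, 0.2), cimp = rbinom(n, 1, 0.25),
        stringsAsFactors = FALSE)
}
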