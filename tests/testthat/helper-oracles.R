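# Independent oracles and small fixture builders shared across tests. The
# oracles deliberately re-derive every quantity with explicit loops and never
# call the implementation they check.

# Literal term-by-term evaluation of the response-informed score.
bruteForceScore <- function(resistant, sensitive, profile, tau) {
    r <- c(resistant, sensitive)
    G <- names(r)[names(r) %in% names(profile)]
    nG <- length(G)
    s <- 0
    for (g in G) s <- s - profile[[g]] * r[[g]]
    gR <- 0L
    for (g in names(resistant))
        if (g %in% G && !(profile[[g]] >= tau) && profile[[g]] <= -tau)
            gR <- gR + 1L
    gS <- 0L
    for (g in names(sensitive))
        if (g %in% G && profile[[g]] >= tau) gS <- gS + 1L
    gcUp <- 0L; gcDown <- 0L
    for (v in profile) {
        if (v >= tau) gcUp <- gcUp + 1L
        else if (v <= -tau) gcDown <- gcDown + 1L
    }
    if (nG == 0L || gcUp == 0L || gcDown == 0L) return(0)
    (s / nG) * (gR + gS) * (gR / gcDown) * (gS / gcUp)
}

# Exhaustive hypergeometric upper tail: enumerate every possible draw of
# listSize items from the universe and count draws with >= overlap hits.
enumerateOraP <- function(universeSize, setSize, listSize, overlap) {
    draws <- utils::combn(universeSize, listSize)
    inSet <- seq_len(setSize)
    hits <- apply(draws, 2L, function(d) sum(d %in% inSet))
    mean(hits >= overlap)
}

# Tanimoto from indicator vectors over an explicit universe.
indicatorTanimoto <- function(a, b, universe) {
    ia <- universe %in% a
    ib <- universe %in% b
    u <- sum(ia | ib)
    if (u == 0L) return(0)
    sum(ia & ib) / u
}

# Hand-rolled DSGSet for scoring tests (bypasses identifyDsgs).
makeDsg <- function(drugId, resistant, sensitive, threshold = 0.4) {
    new("DSGSet", drugId = drugId, resistant = resistant,
        sensitive = sensitive, correlations = data.frame(),
        params = list(threshold = threshold))
}

# Random scoring instance on <= maxGenes genes, mixing measured/unmeasured
# DSGs and off-target genes.
randomScoreInstance <- function(maxGenes = 20L) {
    nDsg <- sample(2:8, 1L)
    nOff <- sample(0:(maxGenes - nDsg), 1L)
    genes <- paste0("g", seq_len(nDsg + nOff + 3L))
    dsgGenes <- genes[seq_len(nDsg)]
    rs <- round(stats::runif(nDsg, 0.4, 0.95), 3L) *
        sample(c(-1, 1), nDsg, replace = TRUE)
    resistant <- stats::setNames(rs[rs > 0], dsgGenes[rs > 0])
    sensitive <- stats::setNames(rs[rs < 0], dsgGenes[rs < 0])
    # some DSGs may be unmeasured in the profile
    measured <- sample(dsgGenes, max(1L, nDsg - sample(0:2, 1L)))
    profGenes <- c(measured, genes[nDsg + seq_len(nOff)])
    profile <- stats::setNames(round(stats::rnorm(length(profGenes)), 3L),
                               profGenes)
    tau <- sample(c(0, 0.25, 0.5, 1), 1L)
    list(resistant = resistant, sensitive = sensitive, profile = profile,
         tau = tau)
}

# Precision/recall of identified DSGs against the planted truth.
plantedRecovery <- function(dsgSets, truth) {
    tp <- fp <- fn <- 0L
    for (d in names(truth$planted)) {
        hit <- Filter(function(x) drugIds(x) == d, dsgSets)[[1L]]
        predRes <- names(resistantGenes(hit))
        predSen <- names(sensitiveGenes(hit))
        trueRes <- truth$planted[[d]]$resistant
        trueSen <- truth$planted[[d]]$sensitive
        tp <- tp + length(intersect(predRes, trueRes)) +
            length(intersect(predSen, trueSen))
        fp <- fp + length(setdiff(c(predRes, predSen),
                                  c(trueRes, trueSen)))
        fn <- fn + length(setdiff(c(trueRes, trueSen),
                                  c(predRes, predSen)))
    }
    c(precision = if (tp + fp) tp / (tp + fp) else NA_real_,
      recall = tp / (tp + fn))
}

# One full synthetic pipeline run: generate, identify, score, and return the
# rank of each planted sensitizer for its target drug.
sensitizerRanks <- function(seed, tau = 0.5, lambda = 2) {
    ds <- makePharmacogenomicDataset(seed = seed)
    pp <- makePerturbationProfiles(ds$truth, lambda = lambda,
                                   seed = seed + 1000L)
    vapply(names(pp$sensitizers), function(d) {
        dsg <- identifyDsgs(ds$expr, ds$resp, d)
        rk <- scoreCandidates(dsg, pp$pset, tau = tau)
        rk$rank[rk$d2_id == pp$sensitizers[[d]]]
    }, 0L)
}
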