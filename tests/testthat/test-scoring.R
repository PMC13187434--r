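workedDsg <- function() {
    makeDsg("D1", c(gA = 0.5, gB = 0.6), c(gC = -0.5, gD = -0.7))
}

test_that("the worked score examples evaluate exactly", {
    dsg <- workedDsg()
    prof <- c(gA = -1, gB = -1, gC = 1, gD = 1)
    sc <- computeScore(dsg, prof, tau = 0.5)
    expect_equal(sc$sum_term, 2.3)
    expect_identical(sc$genes_evaluated, 4L)
    expect_identical(c(sc$g_r, sc$g_s, sc$g_m), c(2L, 2L, 4L))
    expect_identical(c(sc$gc_down, sc$gc_up), c(2L, 2L))
    expect_equal(sc$selectivity, 1)
    expect_equal(sc$score, 2.3)
    # 8 extra off-target downregulated genes dilute selectivity to 0.2
    off <- stats::setNames(rep(-1, 8), paste0("off", 1:8))
    sc2 <- computeScore(dsg, c(prof, off), tau = 0.5)
    expect_identical(sc2$gc_down, 10L)
    expect_equal(sc2$selectivity, 0.2)
    expect_equal(sc2$score, 0.46)
})

test_that("degenerate profiles yield flagged zero scores, never errors", {
    dsg <- workedDsg()
    zero <- stats::setNames(rep(0, 4), c("gA", "gB", "gC", "gD"))
    sc <- computeScore(dsg, zero, tau = 0.5)
    expect_equal(sc$score, 0)
    expect_identical(sc$reason, "no modulation")
    unmeasured <- c(other1 = 1, other2 = -1)
    sc2 <- computeScore(dsg, unmeasured, tau = 0.5)
    expect_identical(sc2$reason, "no DSGs measured")
    expect_equal(sc2$score, 0)
    onlyUp <- c(gC = 1, gD = 1)
    sc3 <- computeScore(dsg, onlyUp, tau = 0.5)
    expect_identical(sc3$reason, "no downregulated genes")
    expect_equal(sc3$score, 0)
})

test_that("computeScore matches the brute-force oracle on random instances", {
    set.seed(202)
    for (i in 1:40) {
        inst <- randomScoreInstance()
        dsg <- makeDsg("d1", inst$resistant, inst$sensitive)
        sc <- computeScore(dsg, inst$profile, tau = inst$tau)
        expected <- bruteForceScore(inst$resistant, inst$sensitive,
                                    inst$profile, inst$tau)
        expect_equal(sc$score, expected, tolerance = 1e-12)
    }
})

test_that("the score's sign tracks the inversion sum", {
    dsg <- workedDsg()
    inv <- c(gA = -1, gB = -1.2, gC = 1.1, gD = 0.9)   # sensitizing
    scPos <- computeScore(dsg, inv, tau = 0.5)
    expect_gt(scPos$score, 0)
    # a fully anti-sensitizing profile leaves no well-inverted DSG at all:
    # selectivity collapses to zero and the score is zero, not negative
    scFlip <- computeScore(dsg, -inv, tau = 0.5)
    expect_equal(scFlip$sum_term, -scPos$sum_term)
    expect_identical(scFlip$g_m, 0L)
    expect_equal(scFlip$selectivity, 0)
    expect_equal(scFlip$score, 0)
    # a mixed profile (one DSG per class well-inverted, one resistance DSG
    # strongly upregulated) keeps selectivity positive but turns the
    # inversion sum negative -> negative score
    mixed <- c(gA = -0.6, gB = 3, gC = 0.6, gD = -0.1)
    scMix <- computeScore(dsg, mixed, tau = 0.5)
    expect_gt(scMix$selectivity, 0)
    expect_lt(scMix$sum_term, 0)
    expect_lt(scMix$score, 0)
})

test_that("off-target breadth strictly penalizes the score", {
    dsg <- workedDsg()
    base <- c(gA = -1, gB = -1, gC = 1, gD = 1)
    scores <- vapply(c(0L, 4L, 8L), function(nOff) {
        prof <- base
        if (nOff > 0L)
            prof <- c(base, stats::setNames(rep(-1, nOff),
                                            paste0("off", seq_len(nOff))))
        computeScore(dsg, prof, tau = 0.5)$score
    }, 0)
    expect_true(all(diff(scores) < 0))
})

test_that("classifyModulation applies the direction thresholds per class", {
    dsg <- workedDsg()
    prof <- c(gA = -1, gB = 0, gC = 1, gX = 5)   # gD unmeasured
    m <- classifyModulation(dsg, prof, tau = 0.5)
    res <- m[m$class == "resistant", ]
    sen <- m[m$class == "sensitive", ]
    expect_identical(c(res$down, res$unchanged, res$unmeasured),
                     c(1L, 1L, 0L))
    expect_identical(c(sen$up, sen$unmeasured), c(1L, 1L))
    expect_equal(res$frac_down + res$frac_up + res$frac_unchanged, 1)
    # fractions exclude unmeasured DSGs
    expect_equal(sen$frac_up, 1)
    # boundary convention: at tau = 0 a zero logFC counts as "up"
    m0 <- classifyModulation(dsg, c(gA = 0), tau = 0)
    expect_identical(m0[m0$class == "resistant", "up"], 1L)
    mPos <- classifyModulation(dsg, c(gA = 0), tau = 0.5)
    expect_identical(mPos[mPos$class == "resistant", "unchanged"], 1L)
})

test_that("z-scores use the population standard deviation", {
    expect_equal(zscoreScores(c(1, 2, 3)),
                 c(-sqrt(3 / 2), 0, sqrt(3 / 2)))
    expect_identical(zscoreScores(c(5, 5, 5)), c(0, 0, 0))
    expect_identical(zscoreScores(7), 0)
})

test_that("rankCandidates orders by z, raw score, then compound id", {
    df <- data.frame(d1_id = "D1", d2_id = c("C", "A", "B"),
                     score = c(-1, 2, 1), zscore = c(-1.2, 1.1, 0.1))
    rk <- rankCandidates(df)
    expect_identical(rk$d2_id, c("A", "B", "C"))
    expect_identical(rk$rank, 1:3)
    expect_true(all(diff(rk$zscore) <= 0))
    tie <- data.frame(d1_id = "D1", d2_id = c("B", "A"),
                      score = c(1, 1), zscore = c(0.5, 0.5))
    expect_identical(rankCandidates(tie)$d2_id, c("A", "B"))
    mixed <- data.frame(d1_id = c("D1", "D2"), d2_id = c("A", "B"),
                        score = c(1, 2), zscore = c(0, 0))
    expect_error(rankCandidates(mixed), "single primary drug")
})

test_that("replicate signatures aggregate by per-gene median before scoring", {
    dsg <- workedDsg()
    p1 <- c(gA = -2, gB = -1, gC = 1, gD = 1)
    p2 <- c(gA = 0, gB = -1, gC = 3, gD = 1)
    p3 <- c(gA = -1, gB = -1, gC = 2, gD = 1)
    pset <- PerturbationSet(list(p1, p2, p3, c(gA = 1, gB = 1, gC = -1, gD = -1)),
                            compoundIds = c("cmpd1", "cmpd1", "cmpd1", "anti"),
                            signatureIds = c("s1", "s2", "s3", "s4"))
    rk <- scoreCandidates(dsg, pset, tau = 0.5)
    med <- c(gA = -1, gB = -1, gC = 2, gD = 1)
    expect_equal(rk$score[rk$d2_id == "cmpd1"],
                 computeScore(dsg, med, tau = 0.5)$score)
    expect_identical(rk$d2_id[1L], "cmpd1")   # sensitizing beats inverse
    perSig <- scoreCandidates(dsg, pset, tau = 0.5,
                              aggregate = "per-signature")
    expect_identical(nrow(perSig), 2L)        # one row per compound
})

test_that("topkRecurrence counts appearances by exact rank", {
    mk <- function(ids, zs) rankCandidates(
        data.frame(d1_id = "D", d2_id = ids, score = zs, zscore = zs))
    r1 <- mk(c("X", "Y", "Z"), c(3, 2, 1))
    r2 <- mk(c("X", "Z", "Y"), c(5, 4, 3))
    r3 <- mk(c("Y", "W", "X"), c(9, 8, 7))
    out <- topkRecurrence(list(r1, r2, r3), k = 5L)
    x <- out[out$d2_id == "X", ]
    expect_identical(x$total, 3L)
    expect_identical(c(x$rank_1, x$rank_3), c(2L, 1L))
    expect_identical(out$d2_id[1L], "X")   # sorted by total
    zeroK <- topkRecurrence(list(r1, r2), k = 0L)
    expect_true(all(zeroK$total == 0L))
    single <- topkRecurrence(list(r1), k = 2L)
    expect_identical(single[single$d2_id == "Z", "total"], 0L)
    expect_identical(single[single$d2_id == "Y", "total"], 1L)
})
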