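test_that("pearsonR matches hand computations and handles degenerate input", {
    expect_equal(pearsonR(c(1, 2, 3), c(2, 4, 6)), 1)
    expect_equal(pearsonR(c(1, 2, 3), c(-1, -2, -3)), -1)
    expect_equal(pearsonR(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
    expect_error(pearsonR(1:3, 1:4), "length mismatch")
    expect_true(is.na(pearsonR(c(1, 1, 1), c(1, 2, 3))))   # constant x
    expect_true(is.na(pearsonR(c(1, NA), c(1, 2))))        # < 2 complete pairs
    # pairwise-complete filtering drops the NA pair only
    expect_equal(pearsonR(c(1, 2, 3, NA), c(2, 4, 6, 1)), 1)
})

test_that("extremeSubset selects the stated tails deterministically", {
    v <- stats::setNames(1:10, sprintf("CL%02d", 1:10))
    # floor(0.2 * 10) = 2 per tail when the minimum tail is lowered
    expect_identical(extremeSubset(v, 0.2, minPerTail = 2L),
                     c(1L, 2L, 9L, 10L))
    # default minimum of 3 per tail takes over when floor(f * n) < 3
    expect_identical(extremeSubset(v, 0.2), c(1L, 2L, 3L, 8L, 9L, 10L))
    v7 <- stats::setNames(1:7, sprintf("CL%d", 1:7))
    expect_length(extremeSubset(v7, 0.2), 6L)   # floor(1.4)=1 -> 3+3
    expect_error(extremeSubset(v7[1:5], 0.2), "too few")
    # ties broken by cell-line id: all-equal values still yield both tails
    tied <- stats::setNames(rep(1, 10), sprintf("CL%02d", 1:10))
    idx <- extremeSubset(tied, 0.2, minPerTail = 2L)
    expect_length(idx, 4L)
    expect_identical(idx, extremeSubset(tied, 0.2, minPerTail = 2L))
    expect_error(extremeSubset(v, 0.6), "fraction")
})

test_that("identifyDsgs recovers planted genes with correct classes", {
    ds <- makePharmacogenomicDataset()   # defaults, seed 7
    dsgs <- lapply(drugIds(ds$resp), function(d)
        identifyDsgs(ds$expr, ds$resp, d))
    rec <- plantedRecovery(dsgs, ds$truth)
    expect_identical(unname(rec["precision"]), 1)   # 0 false positives
    expect_identical(unname(rec["recall"]), 1)      # all 20 per drug found
    # class/sign consistency is guaranteed by the DSGSet validity contract
    d1 <- dsgs[[1L]]
    expect_true(all(resistantGenes(d1) >= 0.4))
    expect_true(all(sensitiveGenes(d1) <= -0.4))
    expect_setequal(names(resistantGenes(d1)),
                    ds$truth$planted$D01$resistant)
})

test_that("degenerate genes are skipped with a recorded reason", {
    ds <- makePharmacogenomicDataset(nGenes = 50L, nLines = 40L,
                                     nDrugs = 1L, nDsgPerClass = 5L,
                                     seed = 3L)
    em <- exprValues(ds$expr)
    em["G0030", ] <- 1                      # constant expression
    em["G0031", seq_len(35L)] <- NA         # > 20% missing
    expr <- ExpressionMatrix(em)
    dsg <- identifyDsgs(expr, ds$resp, "D01")
    rec <- dsgCorrelations(dsg)
    expect_identical(rec$reason[rec$gene_id == "G0030"], "degenerate")
    expect_identical(rec$reason[rec$gene_id == "G0031"], "missing")
    expect_false("G0030" %in% dsgGenes(dsg))
})

test_that("identifyDsgs validates its inputs", {
    ds <- makePharmacogenomicDataset(nGenes = 50L, nLines = 40L,
                                     nDrugs = 1L, nDsgPerClass = 5L,
                                     seed = 3L)
    expect_error(identifyDsgs(ds$expr, ds$resp, "nope"), "not present")
    expect_error(identifyDsgs(ds$expr, ds$resp, "D01", minN = 50L),
                 "40 shared cell lines.*minimum 50")
    # unattainable threshold yields an empty set, not an error
    none <- identifyDsgs(ds$expr, ds$resp, "D01", threshold = 1.0)
    expect_length(dsgGenes(none), 0L)
})

test_that("raising the threshold never grows the DSG set", {
    ds <- makePharmacogenomicDataset(nGenes = 100L, nLines = 60L,
                                     nDrugs = 2L, nDsgPerClass = 5L,
                                     seed = 5L)
    sizes <- vapply(c(0.2, 0.4, 0.6, 0.8), function(thr)
        length(dsgGenes(identifyDsgs(ds$expr, ds$resp, "D01",
                                     threshold = thr))), 0L)
    expect_true(all(diff(sizes) <= 0L))
})

test_that("permuting IC50 across cell lines drives DSG counts to the null", {
    ds <- makePharmacogenomicDataset(seed = 19L)
    set.seed(42)
    ic <- ic50Values(ds$resp)
    perm <- ic[, sample(ncol(ic))]
    colnames(perm) <- colnames(ic)
    respPerm <- ResponseTable(perm, logTransformed = TRUE)
    fpRates <- vapply(drugIds(respPerm), function(d) {
        length(dsgGenes(identifyDsgs(ds$expr, respPerm, d))) /
            length(geneIds(ds$expr))
    }, 0)
    expect_true(all(fpRates < 0.01))
})

test_that("dsgLandscape tabulates gene-drug counts as enumerated", {
    dA <- makeDsg("dA", c(a = 0.5, b = 0.6), stats::setNames(numeric(0), character(0)))
    dB <- makeDsg("dB", c(b = 0.7), c(c = -0.5))
    ls <- dsgLandscape(list(dA, dB))
    expect_identical(ls$histogram, c(`1` = 2L, `2` = 1L))
    expect_identical(ls$uniqueToOne, 2L)
    expect_identical(unname(ls$perDrugCounts), c(2L, 2L))
    expect_identical(ls$geneDrugCounts[["b"]], 2L)

    single <- dsgLandscape(list(makeDsg("d1", c(a = 0.9),
                                        stats::setNames(numeric(0), character(0)))))
    expect_identical(single$histogram, c(`1` = 1L))

    none <- makeDsg("dx", stats::setNames(numeric(0), character(0)),
                    stats::setNames(numeric(0), character(0)))
    empty <- dsgLandscape(list(none))
    expect_length(empty$histogram, 0L)
    expect_identical(empty$meanPerDrug, 0)
})

test_that("subset-only and full-AND-subset readings are both available", {
    ds <- makePharmacogenomicDataset(seed = 23L)
    strict <- identifyDsgs(ds$expr, ds$resp, "D01", requireFull = TRUE)
    loose <- identifyDsgs(ds$expr, ds$resp, "D01", requireFull = FALSE)
    # the conjunction can only remove genes relative to the subset-only rule
    expect_true(all(dsgGenes(strict) %in% dsgGenes(loose)))
})
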