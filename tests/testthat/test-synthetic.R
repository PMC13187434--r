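test_that("the generator is deterministic and internally consistent", {
    a <- makePharmacogenomicDataset(nGenes = 60L, nLines = 30L, nDrugs = 1L,
                                    nDsgPerClass = 4L, seed = 99L)
    b <- makePharmacogenomicDataset(nGenes = 60L, nLines = 30L, nDrugs = 1L,
                                    nDsgPerClass = 4L, seed = 99L)
    expect_identical(exprValues(a$expr), exprValues(b$expr))
    expect_identical(ic50Values(a$resp), ic50Values(b$resp))
    expect_identical(a$truth$planted, b$truth$planted)
    # planted ids exist in the emitted matrices and are disjoint per drug
    ds <- makePharmacogenomicDataset(seed = 7L)
    for (d in names(ds$truth$planted)) {
        pl <- ds$truth$planted[[d]]
        expect_true(all(c(pl$resistant, pl$sensitive) %in% geneIds(ds$expr)))
        expect_length(intersect(pl$resistant, pl$sensitive), 0L)
    }
    # disjoint across drugs at the default shareGenes = FALSE
    all <- unlist(lapply(ds$truth$planted, unlist))
    expect_false(any(duplicated(all)))
    expect_error(makePharmacogenomicDataset(nGenes = 10L, nDrugs = 2L,
                                            nDsgPerClass = 5L),
                 "shareGenes")
})

test_that("planted correlations sit near their analytic value", {
    ds <- makePharmacogenomicDataset(seed = 7L)
    em <- exprValues(ds$expr)
    ic <- ic50Values(ds$resp)
    rObs <- unlist(lapply(names(ds$truth$planted), function(d) {
        pl <- ds$truth$planted[[d]]
        c(vapply(pl$resistant, function(g) cor(em[g, ], ic[d, ]), 0),
          -vapply(pl$sensitive, function(g) cor(em[g, ], ic[d, ]), 0))
    }))
    expect_equal(mean(rObs), ds$truth$expectedR, tolerance = 0.1)
    expect_true(all(rObs > 0))   # signs match the planted class
})

test_that("a null generator yields DSG counts at the threshold's null level", {
    ds <- makePharmacogenomicDataset(beta = 0, seed = 41L)
    counts <- vapply(drugIds(ds$resp), function(d)
        length(dsgGenes(identifyDsgs(ds$expr, ds$resp, d))), 0L)
    expect_true(all(counts <= 0.01 * length(geneIds(ds$expr))))
})

test_that("planted sensitizers invert exactly the planted genes", {
    ds <- makePharmacogenomicDataset(seed = 7L)
    pp <- makePerturbationProfiles(ds$truth, lambda = 2, seed = 8L)
    k <- ds$truth$params$nDsgPerClass
    for (d in names(pp$sensitizers)) {
        prof <- profiles(pp$pset)[[pp$sensitizers[[d]]]]
        pl <- ds$truth$planted[[d]]
        expect_true(all(prof[pl$resistant] == -2))
        expect_true(all(prof[pl$sensitive] == 2))
        # with the true DSGs and tau < lambda, all 2k genes are well-inverted
        dsg <- makeDsg(d, stats::setNames(rep(0.8, k), pl$resistant),
                       stats::setNames(rep(-0.8, k), pl$sensitive))
        sc <- computeScore(dsg, prof, tau = 0.5)
        expect_identical(sc$g_m, 2L * k)
        expect_gt(sc$score, 0)
    }
    # decoys with no off-target perturbation are all-zero -> flagged zero score
    quiet <- makePerturbationProfiles(ds$truth, offtargetRate = 0,
                                      seed = 9L)
    dec <- profiles(quiet$pset)[[quiet$decoys[1L]]]
    expect_true(all(dec == 0))
    dsg1 <- makeDsg("D01",
                    stats::setNames(rep(0.8, k),
                                    ds$truth$planted$D01$resistant),
                    stats::setNames(rep(-0.8, k),
                                    ds$truth$planted$D01$sensitive))
    sc0 <- computeScore(dsg1, dec, tau = 0.5)
    expect_equal(sc0$score, 0)
    expect_identical(sc0$reason, "no modulation")
    # determinism
    pp2 <- makePerturbationProfiles(ds$truth, lambda = 2, seed = 8L)
    expect_identical(profiles(pp2$pset), profiles(pp$pset))
})

test_that("compound SMILES assignment is reproducible and chemically valid", {
    ct <- makeCompoundSmiles(c("c1", "c2", "c3"), seed = 5L)
    ct2 <- makeCompoundSmiles(c("c1", "c2", "c3"), seed = 5L)
    expect_identical(smilesOf(ct), smilesOf(ct2))
    for (s in smilesOf(ct))
        expect_s4_class(chemicalFingerprint(s), "Fingerprint")
    # distinct library structures are distinguishable by fingerprint
    lib <- unique(resensitizer:::.smilesLibrary)
    set.seed(6)
    pick <- sample(length(lib), 4L)
    for (i in pick) for (j in pick) if (i < j)
        expect_lt(chemicalTanimoto(lib[i], lib[j]), 1)
    expect_error(makeCompoundSmiles(c("a", "a")), "duplicate")
})

test_that("fixture files round-trip through the package readers", {
    dir <- tempfile("fixtures")
    files <- writeSyntheticFixtures(dir, seed = 7L, nGenes = 60L,
                                    nLines = 30L, nDrugs = 1L,
                                    nDsgPerClass = 4L)
    expect_true(all(file.exists(files)))
    em <- readExpressionMatrix(files[["expression"]])
    expect_identical(dim(exprValues(em)), c(60L, 30L))
    rt <- readResponseTable(files[["response"]])
    expect_identical(drugIds(rt), "D01")
    ps <- readPerturbationProfiles(files[["profiles"]], "long_tsv")
    expect_true("SENS_D01" %in% compoundIds(ps))
    gc <- readGeneSets(files[["gene_sets"]])
    expect_true("PROGRAM_D01" %in% names(geneSets(gc)))
    ct <- readCompoundTable(files[["compounds"]])
    expect_true(all(compoundIds(ps) %in% compoundIds(ct)))
    # emitted values survive the text round trip bit-exactly at 15 digits
    ds <- makePharmacogenomicDataset(seed = 7L, nGenes = 60L, nLines = 30L,
                                     nDrugs = 1L, nDsgPerClass = 4L)
    expect_equal(exprValues(em), exprValues(ds$expr), tolerance = 1e-6)
})

test_that("the full synthetic pipeline ranks the planted sensitizer first", {
    ranks <- sensitizerRanks(seed = 7L)
    expect_true(all(ranks == 1L))
})
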