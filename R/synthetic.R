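## Synthetic pharmacogenomic fixtures with planted structure. Each drug gets
## a latent response-program activity f (one value per cell line); planted
## resistance genes load on f with weight sqrt(rho) (sensitivity genes with
## -sqrt(rho)), keeping every gene marginally standard normal, and ln IC50 is
## beta * f + noise. The population correlation of a planted gene with ln
## IC50 is therefore analytic: r = +/- sqrt(rho) * beta / sqrt(beta^2 +
## sigma^2) (about 0.67 at the defaults), comfortably above the 0.4
## classification threshold, while decoy genes are exactly null. A planted
## sensitizer compound inverts its target drug's planted genes at magnitude
## lambda; decoy compounds carry only off-target noise.

.syntheticIds <- function(nGenes, nLines, nDrugs) {
    list(genes = sprintf("G%04d", seq_len(nGenes)),
         lines = sprintf("CL%03d", seq_len(nLines)),
         drugs = sprintf("D%02d", seq_len(nDrugs)))
}

#' Generate a pharmacogenomic dataset with planted drug-specific genes
#'
#' Emits a basal expression matrix (marginally standard normal per gene per
#' line), a ln-IC50 response table driven by a per-drug latent response
#' program, and the ground truth of which genes were planted. Identical seed
#' and parameters reproduce identical outputs.
#'
#' @param nGenes number of genes (default 500).
#' @param nLines number of cell lines (default 100).
#' @param nDrugs number of drugs (default 5).
#' @param nDsgPerClass planted resistance and sensitivity genes per drug
#'   (default 10 each).
#' @param beta effect size of the latent program on ln IC50 (default 1.5).
#' @param noiseSd response noise standard deviation (default 0.5).
#' @param geneLoading squared loading rho of planted genes on the latent
#'   program, in (0, 1) (default 0.5).
#' @param shareGenes allow planted genes to be reused across drugs (default
#'   FALSE: planted sets are disjoint across drugs, which requires
#'   \code{nGenes >= 2 * nDsgPerClass * nDrugs}).
#' @param seed integer seed (default 7).
#' @return A list: \code{expr} ([ExpressionMatrix-class]), \code{resp}
#'   ([ResponseTable-class], ln scale), \code{truth} (list with per-drug
#'   planted \code{resistant}/\code{sensitive} gene ids, the latent factors,
#'   all parameters and the analytic planted correlation
#'   \code{expectedR}).
#' @export
makePharmacogenomicDataset <- function(nGenes = 500L, nLines = 100L,
                                       nDrugs = 5L, nDsgPerClass = 10L,
                                       beta = 1.5, noiseSd = 0.5,
                                       geneLoading = 0.5,
                                       shareGenes = FALSE, seed = 7L) {
    stopifnot(nGenes >= 1L, nLines >= 2L, nDrugs >= 1L, nDsgPerClass >= 1L,
              beta >= 0, noiseSd >= 0, geneLoading > 0, geneLoading < 1)
    if (!shareGenes && nGenes < 2L * nDsgPerClass * nDrugs)
        stop(sprintf(
            "nGenes = %d cannot host %d disjoint planted genes; set shareGenes = TRUE",
            nGenes, 2L * nDsgPerClass * nDrugs))
    ids <- .syntheticIds(nGenes, nLines, nDrugs)
    set.seed(seed)
    expr <- matrix(stats::rnorm(nGenes * nLines), nGenes, nLines,
                   dimnames = list(ids$genes, ids$lines))
    ic50 <- matrix(NA_real_, nDrugs, nLines,
                   dimnames = list(ids$drugs, ids$lines))
    factors <- matrix(stats::rnorm(nDrugs * nLines), nDrugs, nLines,
                      dimnames = list(ids$drugs, ids$lines))
    pool <- if (shareGenes) NULL else sample(ids$genes)
    planted <- vector("list", nDrugs)
    names(planted) <- ids$drugs
    sr <- sqrt(geneLoading)
    se <- sqrt(1 - geneLoading)
    for (d in seq_len(nDrugs)) {
        if (shareGenes) {
            pick <- sample(ids$genes, 2L * nDsgPerClass)
        } else {
            take <- ((d - 1L) * 2L * nDsgPerClass + 1L):(d * 2L * nDsgPerClass)
            pick <- pool[take]
        }
        res <- pick[seq_len(nDsgPerClass)]
        sen <- pick[nDsgPerClass + seq_len(nDsgPerClass)]
        f <- factors[d, ]
        expr[res, ] <- sr * matrix(f, nDsgPerClass, nLines, byrow = TRUE) +
            se * expr[res, , drop = FALSE]
        expr[sen, ] <- -sr * matrix(f, nDsgPerClass, nLines, byrow = TRUE) +
            se * expr[sen, , drop = FALSE]
        ic50[d, ] <- beta * f + stats::rnorm(nLines, sd = noiseSd)
        planted[[d]] <- list(resistant = res, sensitive = sen)
    }
    truth <- list(planted = planted, factors = factors,
                  params = list(nGenes = nGenes, nLines = nLines,
                                nDrugs = nDrugs,
                                nDsgPerClass = nDsgPerClass, beta = beta,
                                noiseSd = noiseSd,
                                geneLoading = geneLoading,
                                shareGenes = shareGenes, seed = seed),
                  expectedR = sr * beta / sqrt(beta^2 + noiseSd^2))
    list(expr = ExpressionMatrix(expr),
         resp = ResponseTable(ic50, logTransformed = TRUE),
         truth = truth)
}

#' Generate perturbation profiles with planted sensitizers
#'
#' For every target drug in \code{truth}, one planted sensitizer compound
#' gets logFC \code{-lambda} on the drug's planted resistance genes,
#' \code{+lambda} on its planted sensitivity genes, off-target noise on a
#' random fraction of the remaining genes, and 0 elsewhere. Decoy compounds
#' carry only the off-target component. All profiles cover the full gene
#' space with explicit zeros.
#'
#' @param truth the \code{truth} element of [makePharmacogenomicDataset()].
#' @param nDecoys number of decoy compounds (default 20).
#' @param lambda inversion magnitude of the planted sensitizer (> 0,
#'   default 2).
#' @param offtargetRate fraction of non-planted genes perturbed off-target
#'   (default 0.05).
#' @param offtargetSd off-target logFC standard deviation (default 1).
#' @param seed integer seed (default 11).
#' @return A list: \code{pset} ([PerturbationSet-class]),
#'   \code{sensitizers} (named character vector, target drug -> planted
#'   sensitizer compound id), \code{decoys} (character vector of decoy ids).
#' @export
makePerturbationProfiles <- function(truth, nDecoys = 20L, lambda = 2,
                                     offtargetRate = 0.05,
                                     offtargetSd = 1, seed = 11L) {
    stopifnot(lambda > 0, offtargetRate >= 0, offtargetRate <= 1,
              offtargetSd >= 0, nDecoys >= 0L)
    p <- truth$params
    ids <- .syntheticIds(p$nGenes, p$nLines, p$nDrugs)
    set.seed(seed)
    offtarget <- function(exclude) {
        v <- stats::setNames(numeric(p$nGenes), ids$genes)
        rest <- setdiff(ids$genes, exclude)
        nOff <- round(offtargetRate * length(rest))
        if (nOff > 0L) {
            hit <- sample(rest, nOff)
            v[hit] <- stats::rnorm(nOff, sd = offtargetSd)
        }
        v
    }
    profs <- list(); cmpd <- character(0)
    sensitizers <- character(0)
    for (d in names(truth$planted)) {
        id <- paste0("SENS_", d)
        v <- offtarget(c(truth$planted[[d]]$resistant,
                         truth$planted[[d]]$sensitive))
        v[truth$planted[[d]]$resistant] <- -lambda
        v[truth$planted[[d]]$sensitive] <- lambda
        profs[[length(profs) + 1L]] <- v
        cmpd <- c(cmpd, id)
        sensitizers[d] <- id
    }
    decoys <- sprintf("DECOY%03d", seq_len(nDecoys))
    for (id in decoys) {
        profs[[length(profs) + 1L]] <- offtarget(character(0))
        cmpd <- c(cmpd, id)
    }
    list(pset = PerturbationSet(profs, compoundIds = cmpd,
                                signatureIds = cmpd),
         sensitizers = sensitizers, decoys = decoys)
}

## Small built-in library of valid structures (alkanes, simple aromatics,
## amines/amides, esters) for chemistry fixtures.
.smilesLibrary <- c(
    "CC", "CCC", "CCCC", "CCCCC", "CC(C)C",
    "CCO", "CCN", "CC(C)O", "CC(=O)O", "CCOC(C)=O",
    "c1ccccc1", "Cc1ccccc1", "Oc1ccccc1", "Nc1ccccc1", "c1ccncc1",
    "CC(=O)N", "CC(=O)NC", "NC(=O)c1ccccc1", "CNC(C)=O", "O=C(N)c1ccncc1")

#' Assign SMILES structures to compound ids
#'
#' Draws each compound a structure from a small built-in library of valid
#' SMILES (alkanes, simple aromatics, amines and amides), with replacement,
#' deterministically under the seed.
#'
#' @param compoundIds unique character ids.
#' @param seed integer seed (default 13).
#' @return A [CompoundTable-class].
#' @export
makeCompoundSmiles <- function(compoundIds, seed = 13L) {
    msg <- .checkIds(compoundIds, "compound")
    if (!is.null(msg)) stop(msg)
    set.seed(seed)
    CompoundTable(compoundIds,
                  sample(.smilesLibrary, length(compoundIds),
                         replace = TRUE))
}

#' Generate a gene-set collection with planted response programs
#'
#' One "program" set per drug holds that drug's planted genes padded with
#' random genes (so DSG lists are strongly overrepresented in it), plus a
#' number of random sets that should not enrich.
#'
#' @param truth the \code{truth} element of [makePharmacogenomicDataset()].
#' @param nRandomSets number of random gene sets (default 10).
#' @param setSize size of each set (default 50; program sets are at least
#'   large enough to hold the planted genes).
#' @param seed integer seed (default 17).
#' @return A [GeneSetCollection-class].
#' @export
makeGeneSetCollection <- function(truth, nRandomSets = 10L, setSize = 50L,
                                  seed = 17L) {
    p <- truth$params
    ids <- .syntheticIds(p$nGenes, p$nLines, p$nDrugs)
    set.seed(seed)
    sets <- list()
    for (d in names(truth$planted)) {
        core <- c(truth$planted[[d]]$resistant, truth$planted[[d]]$sensitive)
        pad <- max(0L, setSize - length(core))
        sets[[paste0("PROGRAM_", d)]] <-
            c(core, sample(setdiff(ids$genes, core), pad))
    }
    for (k in seq_len(nRandomSets))
        sets[[sprintf("RANDOM%02d", k)]] <- sample(ids$genes, setSize)
    GeneSetCollection(sets)
}

#' Write a complete synthetic fixture directory
#'
#' Generates the full input suite (expression TSV, response TSV, long-form
#' perturbation TSV, GMT gene sets, SMILES compound table) in the formats the
#' readers accept, plus a ground-truth summary TSV of the planted genes.
#'
#' @param dir output directory (created if needed).
#' @param seed integer master seed; sub-seeds for the perturbation, gene-set
#'   and SMILES generators are derived from it deterministically.
#' @param ... passed to [makePharmacogenomicDataset()].
#' @return Invisibly, a named character vector of the files written.
#' @export
writeSyntheticFixtures <- function(dir, seed = 7L, ...) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    ds <- makePharmacogenomicDataset(seed = seed, ...)
    pp <- makePerturbationProfiles(ds$truth, seed = seed + 1L)
    gs <- makeGeneSetCollection(ds$truth, seed = seed + 2L)
    ct <- makeCompoundSmiles(unique(compoundIds(pp$pset)), seed = seed + 3L)
    files <- c(expression = file.path(dir, "expression.tsv"),
               response = file.path(dir, "response.tsv"),
               profiles = file.path(dir, "profiles.tsv"),
               gene_sets = file.path(dir, "gene_sets.gmt"),
               compounds = file.path(dir, "compounds.tsv"),
               truth = file.path(dir, "truth.tsv"))
    writeExpressionMatrix(ds$expr, files["expression"])
    writeResponseTable(ds$resp, files["response"])
    writePerturbationProfiles(pp$pset, files["profiles"])
    writeGeneSets(gs, files["gene_sets"])
    writeCompoundTable(ct, files["compounds"])
    tr <- do.call(rbind, lapply(names(ds$truth$planted), function(d)
        data.frame(drug_id = d,
                   gene_id = c(ds$truth$planted[[d]]$resistant,
                               ds$truth$planted[[d]]$sensitive),
                   class = rep(c("resistant", "sensitive"),
                               each = ds$truth$params$nDsgPerClass),
                   sensitizer_id = pp$sensitizers[[d]])))
    utils::write.table(tr, files["truth"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(files)
}
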