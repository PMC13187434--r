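## Drug-drug similarity along three axes: Tanimoto overlap of DSG sets,
## Pearson correlation of the continuous gene-correlation profiles, and
## chemical-structure Tanimoto on folded circular fingerprints from SMILES.

#' Tanimoto coefficient of two gene sets
#'
#' \eqn{|a \cap b| / |a \cup b|}; defined as 0 when both sets are empty.
#'
#' @param a,b character vectors (treated as sets).
#' @return Similarity in \[0, 1\].
#' @examples
#' tanimotoSets(c("a", "b", "c"), c("b", "c", "d"))   # 0.5
#' @export
tanimotoSets <- function(a, b) {
    a <- unique(a); b <- unique(b)
    u <- length(union(a, b))
    if (u == 0L) return(0)
    length(intersect(a, b)) / u
}

#' Similarity of two gene-correlation profiles
#'
#' Pearson correlation of the per-gene correlation coefficients of two drugs,
#' over the genes where both are defined; captures direction and strength of
#' the gene-drug associations, unlike the set-based Tanimoto.
#'
#' @param rA,rB named numeric vectors (gene id -> r).
#' @return Pearson r in \[-1, 1\], or \code{NA} with a warning when fewer
#'   than two genes are shared.
#' @export
correlationProfileSimilarity <- function(rA, rB) {
    shared <- intersect(names(rA)[is.finite(rA)], names(rB)[is.finite(rB)])
    if (length(shared) < 2L) {
        warning("fewer than 2 genes with defined r in both drugs")
        return(NA_real_)
    }
    pearsonR(rA[shared], rB[shared])
}

.dsgRVector <- function(dsg, restrictTo = NULL) {
    rec <- dsgCorrelations(dsg)
    v <- stats::setNames(rec$r, rec$gene_id)
    v <- v[is.finite(v)]
    if (!is.null(restrictTo)) v <- v[names(v) %in% restrictTo]
    v
}

#' Pairwise DSG-set Tanimoto similarity matrix
#'
#' By default class is ignored: each drug contributes the union of its
#' resistant and sensitive genes, quantifying shared response-linked genes
#' independently of effect direction. With \code{classAware = TRUE} a gene
#' only matches when it carries the same class in both drugs.
#'
#' @param dsgSets list of [DSGSet-class] objects.
#' @param classAware match genes within resistance/sensitivity class.
#' @return A [SimilarityMatrix-class] of kind \code{"tanimoto_sets"}.
#' @export
dsgSetSimilarity <- function(dsgSets, classAware = FALSE) {
    ids <- vapply(dsgSets, drugIds, "")
    items <- lapply(dsgSets, function(d) {
        if (classAware)
            c(paste0("R:", names(resistantGenes(d))),
              paste0("S:", names(sensitiveGenes(d))))
        else dsgGenes(d)
    })
    n <- length(ids)
    m <- diag(1, n)
    dimnames(m) <- list(ids, ids)
    if (n > 1L) {
        for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
            m[i, j] <- m[j, i] <- tanimotoSets(items[[i]], items[[j]])
        }
    }
    SimilarityMatrix(m, "tanimoto_sets")
}

#' Pairwise correlation-profile similarity matrix
#'
#' @param dsgSets list of [DSGSet-class] objects; the per-gene classification
#'   correlations from [dsgCorrelations()] form each drug's profile.
#' @param dsgUnionOnly restrict the profiles to the union of all drugs' DSGs
#'   instead of every gene with a defined r (the default uses all genes).
#' @return A [SimilarityMatrix-class] of kind \code{"correlation_profile"}.
#' @export
correlationProfileMatrix <- function(dsgSets, dsgUnionOnly = FALSE) {
    ids <- vapply(dsgSets, drugIds, "")
    restrict <- if (dsgUnionOnly)
        unique(unlist(lapply(dsgSets, dsgGenes))) else NULL
    vecs <- lapply(dsgSets, .dsgRVector, restrictTo = restrict)
    n <- length(ids)
    m <- diag(1, n)
    dimnames(m) <- list(ids, ids)
    if (n > 1L) {
        for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
            m[i, j] <- m[j, i] <-
                suppressWarnings(correlationProfileSimilarity(vecs[[i]],
                                                              vecs[[j]]))
        }
    }
    SimilarityMatrix(m, "correlation_profile")
}

.foldBits <- function(bits, nBits) {
    n <- length(bits)
    if (n == nBits) return(as.logical(bits))
    if (n < nBits || n %% nBits != 0L)
        stop(sprintf(
            "cannot fold a %d-bit fingerprint to %d bits (not a multiple)",
            n, nBits))
    folded <- matrix(as.logical(bits), nrow = nBits)
    as.logical(rowSums(folded) > 0L)
}

#' Circular-substructure fingerprint of a molecule
#'
#' Computes an OpenBabel fingerprint (default \code{"ECFP4"}: circular
#' substructures of radius 2) via \pkg{ChemmineOB} and folds it by bitwise OR
#' to \code{nBits}.
#'
#' @param smiles SMILES string.
#' @param type OpenBabel fingerprint name (\code{"ECFP4"}, \code{"ECFP2"},
#'   \code{"FP2"}, \code{"MACCS"}, ...).
#' @param nBits folded width; must divide the native width (2048 default).
#' @return A [Fingerprint-class], deterministic for a given structure and
#'   parameters.
#' @export
chemicalFingerprint <- function(smiles, type = "ECFP4", nBits = 2048L) {
    stopifnot(is.character(smiles), length(smiles) == 1L, nzchar(smiles))
    raw <- ChemmineOB::forEachMol("SMILES", smiles, function(m)
        ChemmineOB::fingerprint_OB(list(m), type))[[1L]]
    new("Fingerprint", bits = .foldBits(raw, nBits), smiles = smiles,
        params = list(type = type, nBits = as.integer(nBits)))
}

.bitTanimoto <- function(a, b) {
    u <- sum(a | b)
    if (u == 0L) return(NA_real_)
    sum(a & b) / u
}

#' Chemical Tanimoto similarity of two SMILES
#'
#' Tanimoto coefficient on the folded circular fingerprints of the two
#' structures. An unparseable SMILES yields \code{NA} with a warning naming
#' the offending string rather than an error, so matrix construction can
#' proceed.
#'
#' @param smilesA,smilesB SMILES strings.
#' @inheritParams chemicalFingerprint
#' @return Similarity in \[0, 1\], or \code{NA} for unparseable input or two
#'   empty fingerprints.
#' @export
chemicalTanimoto <- function(smilesA, smilesB, type = "ECFP4",
                             nBits = 2048L) {
    fp <- lapply(c(smilesA, smilesB), function(s) {
        tryCatch(chemicalFingerprint(s, type, nBits),
                 error = function(e) {
                     warning(sprintf("unparseable SMILES '%s': %s", s,
                                     conditionMessage(e)), call. = FALSE)
                     NULL
                 })
    })
    if (any(vapply(fp, is.null, TRUE))) return(NA_real_)
    t <- .bitTanimoto(fp[[1L]]@bits, fp[[2L]]@bits)
    if (is.na(t))
        warning("both fingerprints are empty; similarity undefined",
                call. = FALSE)
    t
}

#' Pairwise chemical similarity matrix for a compound table
#'
#' @param compounds a [CompoundTable-class].
#' @inheritParams chemicalFingerprint
#' @return A [SimilarityMatrix-class] of kind \code{"tanimoto_chemical"};
#'   pairs involving an unparseable SMILES are \code{NA}.
#' @export
chemicalSimilarityMatrix <- function(compounds, type = "ECFP4",
                                     nBits = 2048L) {
    ids <- compoundIds(compounds)
    smis <- smilesOf(compounds)
    fps <- lapply(ids, function(id) {
        tryCatch(chemicalFingerprint(smis[[id]], type, nBits),
                 error = function(e) {
                     warning(sprintf(
                         "compound '%s': unparseable SMILES '%s'", id,
                         smis[[id]]), call. = FALSE)
                     NULL
                 })
    })
    n <- length(ids)
    m <- diag(1, n)
    dimnames(m) <- list(ids, ids)
    for (i in seq_len(n)) {
        if (is.null(fps[[i]])) m[i, i] <- NA_real_
        if (i == n) break
        for (j in (i + 1L):n) {
            m[i, j] <- m[j, i] <-
                if (is.null(fps[[i]]) || is.null(fps[[j]])) NA_real_
                else .bitTanimoto(fps[[i]]@bits, fps[[j]]@bits)
        }
    }
    SimilarityMatrix(m, "tanimoto_chemical")
}

#' Agglomerative clustering of drugs from a similarity matrix
#'
#' Clusters on distance \code{1 - s} for Tanimoto kinds and \code{(1 - s)/2}
#' for correlation profiles (mapping r in \[-1, 1\] to \[0, 1\]). The matrix
#' must be complete; missing entries raise an error instructing the caller to
#' impute or subset.
#'
#' @param sim a [SimilarityMatrix-class].
#' @param linkage \code{"average"} (default), \code{"complete"} or
#'   \code{"single"}.
#' @param k number of flat clusters to cut (default 2).
#' @return A list: \code{hclust} (the tree), \code{clusters} (named integer
#'   labels at the k-cut), \code{order} (leaf order).
#' @export
clusterDrugs <- function(sim, linkage = c("average", "complete", "single"),
                         k = 2L) {
    stopifnot(is(sim, "SimilarityMatrix"))
    linkage <- match.arg(linkage)
    v <- simValues(sim)
    if (any(is.na(v)))
        stop("similarity matrix has missing entries; impute or subset first")
    d <- if (simKind(sim) == "correlation_profile") (1 - v) / 2 else 1 - v
    hc <- stats::hclust(stats::as.dist(d), method = linkage)
    k <- min(k, nrow(v))
    list(hclust = hc, clusters = stats::cutree(hc, k = k),
         order = hc$order)
}

#' Partition drugs into a high-similarity group and the rest
#'
#' A drug belongs to the high group when it shares a similarity of at least
#' \code{cutoff} with at least one other drug; the remaining drugs form the
#' low group. The two groups always partition the id set.
#'
#' @param sim a [SimilarityMatrix-class] of a Tanimoto kind.
#' @param cutoff similarity cutoff (e.g. 0.4).
#' @return A list with character vectors \code{high} and \code{low}.
#' @export
similarityPartition <- function(sim, cutoff) {
    stopifnot(is(sim, "SimilarityMatrix"))
    v <- simValues(sim)
    diag(v) <- NA_real_
    hasMate <- apply(v, 1L, function(row) any(!is.na(row) & row >= cutoff))
    ids <- rownames(v)
    list(high = ids[hasMate], low = ids[!hasMate])
}
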