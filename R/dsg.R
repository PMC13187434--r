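## Drug-specific gene (DSG) identification: basal expression is correlated
## with IC50 across cell lines, the correlation is computed on the cell lines
## with extreme expression for each gene (top and bottom 20% by default), and
## genes passing |r| >= 0.4 are classified as resistance (r > 0) or
## sensitivity (r < 0) markers.

#' Pearson correlation with pairwise-complete filtering
#'
#' Thin, strict wrapper around [stats::cor()]: pairs with a missing value in
#' either vector are dropped first; fewer than two complete pairs or a
#' constant vector yield \code{NA} rather than an error, so degenerate genes
#' can be skipped with a recorded reason.
#'
#' @param x,y numeric vectors of equal length.
#' @return Pearson r in \[-1, 1\], or \code{NA} when undefined.
#' @examples
#' pearsonR(c(1, 2, 3), c(2, 4, 6))   # 1
#' pearsonR(c(1, 2, 3, 4), c(1, 3, 2, 4))   # 0.8
#' @export
pearsonR <- function(x, y) {
    if (length(x) != length(y))
        stop(sprintf("length mismatch: %d vs %d", length(x), length(y)))
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 2L) return(NA_real_)
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
}

#' Select the extreme-expression cell lines for one gene
#'
#' Returns the indices of the \code{floor(fraction * n)} highest- and
#' lowest-expression cell lines (at least \code{minPerTail} per tail). Ties
#' are broken deterministically: within the top tail by descending value then
#' lexicographic cell-line id, within the bottom tail by ascending value then
#' lexicographic id.
#'
#' @param values named numeric vector of one gene's expression across the
#'   eligible cell lines (names are cell-line ids; no missing values).
#' @param fraction tail fraction in (0, 0.5).
#' @param minPerTail minimum number of lines per tail (default 3).
#' @return Integer indices into \code{values} (sorted, both tails combined).
#' @examples
#' v <- stats::setNames(1:10, paste0("CL", sprintf("%02d", 1:10)))
#' extremeSubset(v, 0.2)   # lines holding values 1,2 and 9,10
#' @export
extremeSubset <- function(values, fraction = 0.2, minPerTail = 3L) {
    if (!(fraction > 0 && fraction < 0.5))
        stop("fraction must lie in (0, 0.5)")
    n <- length(values)
    k <- max(minPerTail, floor(fraction * n))
    if (n < 2L * k)
        stop(sprintf(
            "too few eligible cell lines: %d available, %d needed for 2 tails of %d",
            n, 2L * k, k))
    ids <- names(values)
    if (is.null(ids)) ids <- as.character(seq_len(n))
    top <- order(-values, ids)[seq_len(k)]
    ## the bottom tail draws from the remaining lines so heavy ties cannot
    ## collapse the two tails onto the same cell lines
    rest <- setdiff(order(values, ids), top)
    bottom <- rest[seq_len(k)]
    sort(c(top, bottom))
}

#' Identify drug-specific genes for one drug
#'
#' For each gene, expression and IC50 are restricted to the cell lines
#' measured in both inputs; the Pearson correlation is computed on the
#' extreme-expression subset of those lines ([extremeSubset()]); and the gene
#' is classified as a resistance marker when r >= \code{threshold} or a
#' sensitivity marker when r <= -\code{threshold}. With
#' \code{requireFull = TRUE} (the default) the full-set correlation must also
#' pass the same threshold with the same sign, which keeps the null
#' false-positive rate of the extreme-subset statistic in check; set it to
#' \code{FALSE} for the subset-only reading.
#'
#' Genes are skipped, with the reason recorded in the correlation table, when
#' expression is missing in more than \code{maxMissingFrac} of eligible lines
#' (\code{"missing"}), too few lines remain for the two tails
#' (\code{"too_few"}), or expression is constant (\code{"degenerate"}).
#'
#' @param expr an [ExpressionMatrix-class].
#' @param resp a [ResponseTable-class]. IC50 values are used on their stored
#'   scale; for GDSC-style raw IC50, read with \code{logTransform = TRUE}
#'   since Pearson on the raw scale is dominated by outliers.
#' @param drugId drug to analyse (must be present in \code{resp}).
#' @param threshold absolute correlation cutoff (default 0.4).
#' @param fraction extreme-tail fraction (default 0.2).
#' @param minN minimum shared cell lines per (gene, drug) computation
#'   (default 30).
#' @param requireFull require the full-set r to pass as well (default TRUE).
#' @param maxMissingFrac maximum tolerated fraction of missing expression
#'   among eligible lines (default 0.2).
#' @return A [DSGSet-class]; the per-gene records (including skipped genes)
#'   are available via [dsgCorrelations()].
#' @export
identifyDsgs <- function(expr, resp, drugId, threshold = 0.4,
                         fraction = 0.2, minN = 30L, requireFull = TRUE,
                         maxMissingFrac = 0.2) {
    stopifnot(is(expr, "ExpressionMatrix"), is(resp, "ResponseTable"))
    if (!drugId %in% drugIds(resp))
        stop(sprintf("drug '%s' not present in the response table", drugId))
    ic50 <- ic50Values(resp)[drugId, ]
    shared <- intersect(cellLineIds(expr), names(ic50)[!is.na(ic50)])
    if (length(shared) < minN)
        stop(sprintf(
            "only %d shared cell lines with measured IC50 for '%s' (minimum %d)",
            length(shared), drugId, minN))
    em <- exprValues(expr)[, shared, drop = FALSE]
    y <- ic50[shared]
    genes <- rownames(em)
    nG <- length(genes)
    r <- rFull <- rep(NA_real_, nG)
    nUsed <- rep(NA_integer_, nG)
    reason <- character(nG)
    for (i in seq_len(nG)) {
        x <- em[i, ]
        ok <- !is.na(x)
        if (mean(!ok) > maxMissingFrac) { reason[i] <- "missing"; next }
        xi <- x[ok]; yi <- y[ok]
        if (length(xi) < minN) { reason[i] <- "too_few"; next }
        k <- max(3L, floor(fraction * length(xi)))
        if (length(xi) < 2L * k) { reason[i] <- "too_few"; next }
        if (min(xi) == max(xi)) { reason[i] <- "degenerate"; next }
        idx <- extremeSubset(xi, fraction)
        rs <- pearsonR(xi[idx], yi[idx])
        if (is.na(rs)) { reason[i] <- "degenerate"; next }
        r[i] <- rs
        rFull[i] <- pearsonR(xi, yi)
        nUsed[i] <- length(idx)
    }
    records <- data.frame(gene_id = genes, r = r, r_full = rFull,
                          n_used = nUsed, subset = "extreme",
                          reason = reason, stringsAsFactors = FALSE)
    pass <- !is.na(r) & abs(r) >= threshold
    if (requireFull)
        pass <- pass & !is.na(rFull) & abs(rFull) >= threshold &
            sign(rFull) == sign(r)
    res <- pass & r > 0
    sen <- pass & r < 0
    new("DSGSet", drugId = drugId,
        resistant = stats::setNames(r[res], genes[res]),
        sensitive = stats::setNames(r[sen], genes[sen]),
        correlations = records,
        params = list(threshold = threshold, fraction = fraction,
                      minN = as.integer(minN), requireFull = requireFull,
                      ic50Scale = if (isLogTransformed(resp)) "ln" else "raw"))
}

#' Summarize the DSG landscape across drugs
#'
#' Counts, for every gene appearing in any DSG set, the number of drugs whose
#' set contains it; tabulates the distribution of that count (how many genes
#' are specific to exactly 1, 2, ... drugs); and reports per-drug DSG totals.
#'
#' @param dsgSets list of [DSGSet-class] objects (one per drug).
#' @return A list: \code{geneDrugCounts} (named integer vector),
#'   \code{histogram} (genes per drug-count, names are the drug counts),
#'   \code{perDrugCounts}, \code{meanPerDrug}, \code{uniqueToOne} (number of
#'   genes found for exactly one drug), \code{totalUnique}.
#' @export
dsgLandscape <- function(dsgSets) {
    if (length(dsgSets) == 0L)
        stop("at least one DSGSet is required")
    stopifnot(all(vapply(dsgSets, is, TRUE, "DSGSet")))
    perDrug <- vapply(dsgSets, function(d) length(dsgGenes(d)), 0L)
    names(perDrug) <- vapply(dsgSets, drugIds, "")
    allGenes <- unlist(lapply(dsgSets, dsgGenes), use.names = FALSE)
    if (length(allGenes) == 0L) {
        return(list(geneDrugCounts = integer(0),
                    histogram = integer(0),
                    perDrugCounts = perDrug, meanPerDrug = 0,
                    uniqueToOne = 0L, totalUnique = 0L))
    }
    counts <- table(allGenes)
    geneDrugCounts <- stats::setNames(as.integer(counts), names(counts))
    hist <- table(geneDrugCounts)
    histogram <- stats::setNames(as.integer(hist), names(hist))
    list(geneDrugCounts = geneDrugCounts,
         histogram = histogram,
         perDrugCounts = perDrug,
         meanPerDrug = mean(perDrug),
         uniqueToOne = sum(geneDrugCounts == 1L),
         totalUnique = length(geneDrugCounts))
}
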