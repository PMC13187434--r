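## Hallmark-style overrepresentation analysis of each drug's DSG list:
## hypergeometric upper-tail test against a gene universe (the genes present
## in the expression matrix), BH adjustment within each drug across its gene
## sets, and the drug x pathway matrix with a ranking of pathways by the
## proportion of drugs showing significant enrichment.

#' Hypergeometric overrepresentation test for one gene set
#'
#' Upper-tail probability \eqn{P(X \ge \mathrm{overlap})} under
#' hypergeometric(universe, set, list): the chance of drawing at least the
#' observed overlap when \code{length(dsgGenes)} genes are sampled from the
#' universe without replacement. Both the gene set and the DSG list are
#' intersected with the universe first; genes never testable cannot enrich.
#'
#' @param dsgGenes character vector, the drug's DSG list.
#' @param geneSet character vector, one pathway's members.
#' @param universe character vector of all testable genes (non-empty).
#' @return One-row data.frame: \code{overlap}, \code{dsg_list_size},
#'   \code{set_size}, \code{universe_size}, \code{p}.
#' @examples
#' u <- paste0("g", 1:10)
#' hypergeometricOra(u[1:4], u[1:5], u)$p   # 5/210
#' @export
hypergeometricOra <- function(dsgGenes, geneSet, universe) {
    universe <- unique(universe)
    if (length(universe) == 0L) stop("the gene universe is empty")
    dsgGenes <- intersect(unique(dsgGenes), universe)
    geneSet <- intersect(unique(geneSet), universe)
    ov <- length(intersect(dsgGenes, geneSet))
    p <- stats::phyper(ov - 1L, length(geneSet),
                       length(universe) - length(geneSet),
                       length(dsgGenes), lower.tail = FALSE)
    data.frame(overlap = ov, dsg_list_size = length(dsgGenes),
               set_size = length(geneSet),
               universe_size = length(universe), p = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values via [stats::p.adjust()], with input range
#' validation. Monotone-enforced and capped at 1 by construction.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return numeric vector of adjusted values, same order as the input.
#' @export
bhAdjust <- function(p) {
    stopifnot(is.numeric(p))
    if (any(!is.finite(p) | p < 0 | p > 1))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Overrepresentation analysis of DSG lists across drugs and gene sets
#'
#' Runs [hypergeometricOra()] for every (drug, gene set) pair and adjusts
#' p-values with Benjamini-Hochberg within each drug across its sets. The
#' DSG list is the union of resistant and sensitive genes by default;
#' \code{perClass} tests the two classes separately.
#'
#' @param dsgSets list of [DSGSet-class] objects.
#' @param collection a [GeneSetCollection-class].
#' @param universe character vector of testable genes (typically
#'   \code{geneIds()} of the expression matrix).
#' @param perClass test resistant and sensitive lists separately.
#' @return data.frame with one row per (drug, set) (and per class when
#'   \code{perClass}): \code{drug_id}, \code{set_name}, optional
#'   \code{class}, the [hypergeometricOra()] columns and \code{q}.
#' @export
enrichDsgs <- function(dsgSets, collection, universe, perClass = FALSE) {
    stopifnot(all(vapply(dsgSets, is, TRUE, "DSGSet")),
              is(collection, "GeneSetCollection"))
    sets <- geneSets(collection)
    lists <- list()
    for (d in dsgSets) {
        if (perClass) {
            lists[[length(lists) + 1L]] <-
                list(drug = drugIds(d), class = "resistant",
                     genes = names(resistantGenes(d)))
            lists[[length(lists) + 1L]] <-
                list(drug = drugIds(d), class = "sensitive",
                     genes = names(sensitiveGenes(d)))
        } else {
            lists[[length(lists) + 1L]] <-
                list(drug = drugIds(d), class = NA_character_,
                     genes = dsgGenes(d))
        }
    }
    out <- do.call(rbind, lapply(lists, function(l) {
        res <- do.call(rbind, lapply(names(sets), function(nm)
            hypergeometricOra(l$genes, sets[[nm]], universe)))
        res <- cbind(data.frame(drug_id = l$drug, set_name = names(sets),
                                stringsAsFactors = FALSE), res)
        if (perClass) res <- cbind(res[, 1L, drop = FALSE],
                                   class = l$class,
                                   res[, -1L, drop = FALSE])
        res$q <- bhAdjust(res$p)
        res
    }))
    rownames(out) <- NULL
    out
}

#' Drug x pathway enrichment matrix and pathway ranking
#'
#' Builds the matrix of \code{-log10(q)} values (drugs in rows, pathways in
#' columns) plus a separate significance mask at \code{alpha}, and ranks
#' pathways by the proportion of drugs significantly enriched.
#'
#' @param results data.frame from [enrichDsgs()] (without \code{perClass});
#'   must cover a full rectangular drug x set design with no duplicates.
#' @param alpha significance level on the adjusted q (default 0.05).
#' @return A list: \code{matrix} (-log10 q), \code{significant} (logical
#'   mask), \code{ranking} (data.frame with \code{set_name},
#'   \code{proportion_enriched}, sorted descending with set-name
#'   tie-break).
#' @export
drugPathwayMatrix <- function(results, alpha = 0.05) {
    stopifnot(is.data.frame(results),
              all(c("drug_id", "set_name", "q") %in% colnames(results)))
    key <- paste(results$drug_id, results$set_name, sep = "\r")
    if (anyDuplicated(key))
        stop("duplicated (drug, set) pair in the enrichment results")
    drugs <- unique(results$drug_id)
    sets <- unique(results$set_name)
    if (nrow(results) != length(drugs) * length(sets))
        stop("results must cover a rectangular drug x set design")
    m <- matrix(NA_real_, length(drugs), length(sets),
                dimnames = list(drugs, sets))
    m[cbind(match(results$drug_id, drugs),
            match(results$set_name, sets))] <- -log10(results$q)
    sig <- matrix(FALSE, length(drugs), length(sets),
                  dimnames = list(drugs, sets))
    sig[cbind(match(results$drug_id, drugs),
              match(results$set_name, sets))] <- results$q < alpha
    prop <- colMeans(sig)
    ranking <- data.frame(set_name = sets,
                          proportion_enriched = unname(prop),
                          stringsAsFactors = FALSE)
    ranking <- ranking[order(-ranking$proportion_enriched,
                             ranking$set_name), , drop = FALSE]
    rownames(ranking) <- NULL
    list(matrix = m, significant = sig, ranking = ranking)
}
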