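## The response-informed score. For a primary drug D1 with DSG correlations
## r_{D1,g} and a candidate compound D2 with gene-level log fold-changes
## LogFC_{D2,g}, the score is
##
##   S_D2D1 = [ -sum_{g in G} LogFC_{D2,g} * r_{D1,g} / #G ]
##            * G_m * (G_R,D1 / GC_down) * (G_S,D1 / GC_up)
##
## where G is the set of D1 DSGs measured in the D2 profile, G_m the number
## of well-inverted DSGs (resistance DSGs downregulated + sensitivity DSGs
## upregulated at the direction threshold tau), and GC_up / GC_down the total
## up-/downregulated genes in the profile, penalizing broad non-specific
## perturbations. Higher scores mark compounds expected to shift the
## transcriptional state of resistant cells toward sensitivity to D1.

## Direction at threshold tau: "up" wins at the boundary (lfc >= +tau is up
## even when tau = 0 and lfc = 0, by convention).
.direction <- function(lfc, tau) {
    ifelse(lfc >= tau, "up", ifelse(lfc <= -tau, "down", "unchanged"))
}

#' Classify how a compound modulates a drug's DSGs
#'
#' Each DSG measured in the profile is classified as upregulated
#' (logFC >= +tau), downregulated (logFC <= -tau) or unchanged; DSGs absent
#' from the profile are counted as unmeasured and excluded from the
#' fractions. At the boundary \code{tau = 0}, a zero logFC counts as "up"
#' (the >= convention).
#'
#' @param dsg a [DSGSet-class].
#' @param profile named numeric vector of log fold-changes (gene -> logFC).
#' @param tau direction threshold, in the profile's log units (default 0.5).
#' @return data.frame with one row per class (resistant, sensitive): counts
#'   \code{up}, \code{down}, \code{unchanged}, \code{unmeasured} and the
#'   corresponding fractions among measured DSGs.
#' @export
classifyModulation <- function(dsg, profile, tau = 0.5) {
    stopifnot(is(dsg, "DSGSet"), is.finite(tau), tau >= 0)
    oneClass <- function(genes) {
        measured <- intersect(genes, names(profile))
        d <- .direction(profile[measured], tau)
        n <- length(measured)
        data.frame(n_dsg = length(genes),
                   up = sum(d == "up"), down = sum(d == "down"),
                   unchanged = sum(d == "unchanged"),
                   unmeasured = length(genes) - n,
                   frac_up = if (n) sum(d == "up") / n else NaN,
                   frac_down = if (n) sum(d == "down") / n else NaN,
                   frac_unchanged = if (n) sum(d == "unchanged") / n else NaN)
    }
    out <- rbind(oneClass(names(resistantGenes(dsg))),
                 oneClass(names(sensitiveGenes(dsg))))
    cbind(data.frame(class = c("resistant", "sensitive")), out)
}

#' Compute the response-informed score of a compound against one drug's DSGs
#'
#' Evaluates every component of the score (see the package vignette for the
#' model): the inversion sum over the DSGs measured in the profile, the
#' well-inverted count, and the selectivity penalty computed over all genes
#' in the profile at the same direction threshold. Degenerate inputs (no DSG
#' measured, or no up-/downregulated gene in the profile) yield a zero score
#' with a machine-readable \code{reason} instead of an error, so rankings
#' stay total.
#'
#' @param dsg a [DSGSet-class] for the primary drug.
#' @param profile named numeric vector of log fold-changes for the candidate
#'   compound.
#' @param tau direction threshold (default 0.5 log2 units); governs the
#'   well-inverted counts and the up/down totals alike.
#' @param d2Id identifier to record for the candidate compound.
#' @return One-row data.frame: \code{d1_id}, \code{d2_id},
#'   \code{genes_evaluated}, \code{sum_term}, \code{g_m}, \code{g_r},
#'   \code{g_s}, \code{gc_up}, \code{gc_down}, \code{selectivity},
#'   \code{score}, \code{reason} ("" when the score is regular).
#' @examples
#' dsg <- new("DSGSet", drugId = "D1",
#'            resistant = c(gA = 0.5, gB = 0.6),
#'            sensitive = c(gC = -0.5, gD = -0.7),
#'            correlations = data.frame(), params = list(threshold = 0.4))
#' prof <- c(gA = -1, gB = -1, gC = 1, gD = 1)
#' computeScore(dsg, prof, tau = 0.5, d2Id = "cmpd")$score   # 2.3
#' @export
computeScore <- function(dsg, profile, tau = 0.5, d2Id = "D2") {
    stopifnot(is(dsg, "DSGSet"), is.finite(tau), tau >= 0,
              is.numeric(profile))
    rvec <- c(resistantGenes(dsg), sensitiveGenes(dsg))
    measured <- intersect(names(rvec), names(profile))
    nG <- length(measured)
    lfc <- profile[measured]
    r <- rvec[measured]
    sumTerm <- if (nG) -sum(lfc * r) else 0
    up <- lfc >= tau
    down <- !up & lfc <= -tau
    isRes <- measured %in% names(resistantGenes(dsg))
    gR <- sum(isRes & down)
    gS <- sum(!isRes & up)
    gM <- gR + gS
    pUp <- profile >= tau
    gcUp <- sum(pUp)
    gcDown <- sum(!pUp & profile <= -tau)
    reason <- ""
    if (nG == 0L) reason <- "no DSGs measured"
    else if (gcUp == 0L && gcDown == 0L) reason <- "no modulation"
    else if (gcUp == 0L) reason <- "no upregulated genes"
    else if (gcDown == 0L) reason <- "no downregulated genes"
    if (nzchar(reason)) {
        selectivity <- NA_real_
        score <- 0
    } else {
        selectivity <- (gR / gcDown) * (gS / gcUp)
        score <- (sumTerm / nG) * gM * selectivity
    }
    data.frame(d1_id = drugIds(dsg), d2_id = d2Id,
               genes_evaluated = nG, sum_term = sumTerm,
               g_m = gM, g_r = gR, g_s = gS,
               gc_up = gcUp, gc_down = gcDown,
               selectivity = selectivity, score = score,
               reason = reason, stringsAsFactors = FALSE)
}

#' Z-score a vector of raw scores
#'
#' Standardizes with the population standard deviation (divisor n); a
#' zero-variance input maps to all zeros. Used per primary drug across all
#' candidate compounds, which is the comparison the ranking needs.
#'
#' @param scores numeric vector (length >= 1).
#' @return numeric vector of z-scores.
#' @examples
#' zscoreScores(c(1, 2, 3))   # -1.2247, 0, 1.2247
#' @export
zscoreScores <- function(scores) {
    stopifnot(is.numeric(scores), length(scores) >= 1L)
    s <- stats::sd(scores) * sqrt((length(scores) - 1) / length(scores))
    if (length(scores) == 1L || is.na(s) || s == 0) return(rep(0, length(scores)))
    (scores - mean(scores)) / s
}

#' Rank scored candidates for one primary drug
#'
#' Sorts by z-score descending, breaking ties by raw score descending and
#' then compound id ascending, and assigns ranks 1..n.
#'
#' @param components data.frame of score rows (as produced by
#'   [computeScore()], plus a \code{zscore} column; [scoreCandidates()]
#'   produces both). All rows must share one \code{d1_id}.
#' @return The data.frame sorted, with a \code{rank} column (1 = best).
#' @export
rankCandidates <- function(components) {
    stopifnot(is.data.frame(components), nrow(components) >= 1L)
    if (length(unique(components$d1_id)) != 1L)
        stop("rankCandidates expects candidates for a single primary drug")
    if (is.null(components$zscore))
        components$zscore <- zscoreScores(components$score)
    o <- order(-components$zscore, -components$score, components$d2_id)
    out <- components[o, , drop = FALSE]
    out$rank <- seq_len(nrow(out))
    rownames(out) <- NULL
    out
}

## Aggregate replicate signatures of one compound: per-gene median logFC
## across the signatures measuring that gene.
.aggregateProfiles <- function(profileList) {
    genes <- unique(unlist(lapply(profileList, names)))
    vapply(genes, function(g) {
        v <- unlist(lapply(profileList, function(p) p[[g]]))
        stats::median(v)
    }, 0)
}

#' Score and rank all candidate compounds against one drug's DSGs
#'
#' Evaluates [computeScore()] for every compound in the perturbation set,
#' z-scores the raw scores across candidates and ranks them. Compounds with
#' several signatures (replicate cell lines or doses) are handled according
#' to \code{aggregate}: \code{"median"} (default) collapses them to a
#' per-gene median logFC before scoring; \code{"per-signature"} scores each
#' signature separately and keeps each compound's best z-score.
#'
#' @param dsg a [DSGSet-class] for the primary drug.
#' @param pset a [PerturbationSet-class] of candidate compounds.
#' @param tau direction threshold (default 0.5).
#' @param aggregate replicate-signature policy; see Details.
#' @return Ranked data.frame (one row per compound) with all score
#'   components, \code{zscore} and \code{rank}.
#' @export
scoreCandidates <- function(dsg, pset, tau = 0.5,
                            aggregate = c("median", "per-signature")) {
    stopifnot(is(dsg, "DSGSet"), is(pset, "PerturbationSet"))
    aggregate <- match.arg(aggregate)
    cmpds <- unique(compoundIds(pset))
    if (aggregate == "median") {
        rows <- lapply(cmpds, function(cp) {
            pl <- pset@profiles[compoundIds(pset) == cp]
            prof <- if (length(pl) == 1L) pl[[1L]] else .aggregateProfiles(pl)
            computeScore(dsg, prof, tau = tau, d2Id = cp)
        })
        comp <- do.call(rbind, rows)
        comp$zscore <- zscoreScores(comp$score)
    } else {
        rows <- lapply(seq_along(pset@profiles), function(i)
            computeScore(dsg, pset@profiles[[i]], tau = tau,
                         d2Id = compoundIds(pset)[i]))
        comp <- do.call(rbind, rows)
        comp$zscore <- zscoreScores(comp$score)
        best <- vapply(cmpds, function(cp) {
            idx <- which(comp$d2_id == cp)
            idx[which.max(comp$zscore[idx])]
        }, 0L)
        comp <- comp[best, , drop = FALSE]
    }
    rankCandidates(comp)
}

#' Top-k recurrence of secondary compounds across primary drugs
#'
#' Counts, for every candidate compound, in how many primary-drug rankings it
#' appears within the top k positions, broken down by exact rank; the view
#' behind "which compounds are broad-spectrum sensitizers".
#'
#' @param rankings list of ranked data.frames (one per primary drug, as
#'   returned by [scoreCandidates()] or [rankCandidates()]).
#' @param k rank cutoff (default 5).
#' @return data.frame with \code{d2_id}, \code{total} and columns
#'   \code{rank_1} .. \code{rank_k}, sorted by total descending (compound id
#'   breaks ties).
#' @export
topkRecurrence <- function(rankings, k = 5L) {
    stopifnot(length(rankings) >= 1L,
              all(vapply(rankings, is.data.frame, TRUE)))
    allIds <- sort(unique(unlist(lapply(rankings, `[[`, "d2_id"))))
    mat <- matrix(0L, nrow = length(allIds), ncol = max(k, 0L),
                  dimnames = list(allIds, NULL))
    for (rk in rankings) {
        hit <- rk[rk$rank <= k, , drop = FALSE]
        for (i in seq_len(nrow(hit)))
            mat[hit$d2_id[i], hit$rank[i]] <- mat[hit$d2_id[i], hit$rank[i]] + 1L
    }
    total <- if (k > 0L) rowSums(mat) else rep(0L, length(allIds))
    out <- data.frame(d2_id = allIds, total = as.integer(total),
                      stringsAsFactors = FALSE)
    if (k > 0L) {
        colnames(mat) <- paste0("rank_", seq_len(k))
        out <- cbind(out, as.data.frame(mat, row.names = FALSE))
    }
    out <- out[order(-out$total, out$d2_id), , drop = FALSE]
    rownames(out) <- NULL
    out
}
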