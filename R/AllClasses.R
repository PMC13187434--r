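#' @import methods
NULL

.checkIds <- function(ids, what) {
    if (is.null(ids) || any(is.na(ids)) || any(!nzchar(ids)))
        return(sprintf("%s identifiers must be non-empty and non-missing", what))
    if (anyDuplicated(ids)) {
        dup <- unique(ids[duplicated(ids)])
        return(sprintf("duplicate %s identifier(s): %s", what,
                       paste(utils::head(dup, 5L), collapse = ", ")))
    }
    NULL
}

#' Basal gene-expression matrix
#'
#' Container for a genes x cell-lines matrix of (typically z-scored) basal
#' expression values. Missing entries are allowed and stored as \code{NA};
#' every present value must be finite. Gene and cell-line identifiers are the
#' dimnames and must be unique.
#'
#' @slot values numeric matrix, genes in rows, cell lines in columns.
#'
#' @seealso [ExpressionMatrix()], [readExpressionMatrix()]
#' @name ExpressionMatrix-class
#' @aliases ExpressionMatrix-class
#' @exportClass ExpressionMatrix
setClass("ExpressionMatrix", slots = c(values = "matrix"))

setValidity("ExpressionMatrix", function(object) {
    v <- object@values
    if (!is.numeric(v)) return("expression values must be numeric")
    msg <- .checkIds(rownames(v), "gene")
    if (!is.null(msg)) return(msg)
    msg <- .checkIds(colnames(v), "cell-line")
    if (!is.null(msg)) return(msg)
    if (any(is.infinite(v))) return("expression values must be finite or NA")
    TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix with unique rownames (gene ids) and unique
#'   colnames (cell-line ids); \code{NA} marks missing entries.
#' @return An [ExpressionMatrix-class] object.
#' @examples
#' m <- matrix(rnorm(6), 3, 2,
#'             dimnames = list(c("g1", "g2", "g3"), c("CL1", "CL2")))
#' ExpressionMatrix(m)
#' @export
ExpressionMatrix <- function(values) {
    new("ExpressionMatrix", values = as.matrix(values))
}

#' Drug-response (IC50) table
#'
#' IC50 values per drug (rows) and cell line (columns). Values are stored on
#' the scale provided; whether a natural-log transform was applied at read
#' time is recorded so downstream correlation analyses know the scale.
#'
#' @slot values numeric matrix, drugs in rows, cell lines in columns.
#' @slot logTransformed logical scalar; \code{TRUE} if values are ln(IC50).
#'
#' @seealso [ResponseTable()], [readResponseTable()]
#' @name ResponseTable-class
#' @aliases ResponseTable-class
#' @exportClass ResponseTable
setClass("ResponseTable",
         slots = c(values = "matrix", logTransformed = "logical"))

setValidity("ResponseTable", function(object) {
    v <- object@values
    if (!is.numeric(v)) return("IC50 values must be numeric")
    msg <- .checkIds(rownames(v), "drug")
    if (!is.null(msg)) return(msg)
    msg <- .checkIds(colnames(v), "cell-line")
    if (!is.null(msg)) return(msg)
    if (any(is.infinite(v))) return("IC50 values must be finite or NA")
    if (length(object@logTransformed) != 1L || is.na(object@logTransformed))
        return("logTransformed must be TRUE or FALSE")
    TRUE
})

#' Construct a ResponseTable
#'
#' @param values numeric matrix with unique rownames (drug ids) and unique
#'   colnames (cell-line ids).
#' @param logTransformed logical scalar recording whether values are ln(IC50).
#' @return A [ResponseTable-class] object.
#' @export
ResponseTable <- function(values, logTransformed = FALSE) {
    new("ResponseTable", values = as.matrix(values),
        logTransformed = isTRUE(logTransformed))
}

#' Set of compound perturbation profiles
#'
#' A collection of gene-level log fold-change vectors, one per perturbation
#' signature. Several signatures may belong to the same compound (replicate
#' cell lines); signature ids are unique, compound ids need not be. Within a
#' single profile each gene appears once and all log fold-changes are finite.
#'
#' @slot profiles list of named numeric vectors (gene id -> log fold-change).
#' @slot compoundIds character vector parallel to \code{profiles}.
#' @slot signatureIds unique character vector parallel to \code{profiles}.
#' @slot metadata data.frame of per-signature annotations (cell line, dose,
#'   duration, ...), one row per profile; may have zero columns.
#'
#' @seealso [PerturbationSet()], [readPerturbationProfiles()]
#' @name PerturbationSet-class
#' @aliases PerturbationSet-class
#' @exportClass PerturbationSet
setClass("PerturbationSet",
         slots = c(profiles = "list", compoundIds = "character",
                   signatureIds = "character", metadata = "data.frame"))

setValidity("PerturbationSet", function(object) {
    n <- length(object@profiles)
    if (length(object@compoundIds) != n || length(object@signatureIds) != n)
        return("compoundIds and signatureIds must parallel profiles")
    msg <- .checkIds(object@signatureIds, "signature")
    if (!is.null(msg)) return(msg)
    if (nrow(object@metadata) != n)
        return("metadata must have one row per profile")
    for (i in seq_len(n)) {
        p <- object@profiles[[i]]
        if (!is.numeric(p) || is.null(names(p)))
            return(sprintf("profile %d is not a named numeric vector", i))
        if (anyDuplicated(names(p)))
            return(sprintf("profile '%s' lists a gene more than once",
                           object@signatureIds[i]))
        if (any(!is.finite(p)))
            return(sprintf("profile '%s' contains non-finite log fold-changes",
                           object@signatureIds[i]))
    }
    TRUE
})

#' Construct a PerturbationSet
#'
#' @param profiles list of named numeric vectors (gene id -> log fold-change).
#' @param compoundIds character vector of compound ids, recycled from
#'   \code{names(profiles)} when omitted.
#' @param signatureIds unique character ids per profile; defaults to
#'   \code{compoundIds} (must then be unique).
#' @param metadata optional data.frame of per-profile annotations.
#' @return A [PerturbationSet-class] object.
#' @export
PerturbationSet <- function(profiles, compoundIds = names(profiles),
                            signatureIds = compoundIds, metadata = NULL) {
    if (is.null(compoundIds))
        stop("compoundIds are required when profiles are unnamed")
    if (is.null(metadata))
        metadata <- data.frame(row.names = seq_along(profiles))
    new("PerturbationSet", profiles = unname(profiles),
        compoundIds = as.character(compoundIds),
        signatureIds = as.character(signatureIds), metadata = metadata)
}

#' Named collection of gene sets
#'
#' @slot sets named list of character vectors; set names unique, sets
#'   non-empty, members deduplicated.
#'
#' @seealso [GeneSetCollection()], [readGeneSets()]
#' @name GeneSetCollection-class
#' @aliases GeneSetCollection-class
#' @exportClass GeneSetCollection
setClass("GeneSetCollection", slots = c(sets = "list"))

setValidity("GeneSetCollection", function(object) {
    s <- object@sets
    if (length(s)) {
        msg <- .checkIds(names(s), "gene-set")
        if (!is.null(msg)) return(msg)
        for (nm in names(s)) {
            if (!is.character(s[[nm]]) || length(s[[nm]]) == 0L)
                return(sprintf("gene set '%s' is empty or not character", nm))
            if (anyDuplicated(s[[nm]]))
                return(sprintf("gene set '%s' has duplicated members", nm))
        }
    }
    TRUE
})

#' Construct a GeneSetCollection
#'
#' @param sets named list of character vectors; members are deduplicated.
#' @return A [GeneSetCollection-class] object.
#' @export
GeneSetCollection <- function(sets = list()) {
    sets <- lapply(sets, function(s) unique(as.character(s)))
    new("GeneSetCollection", sets = sets)
}

#' Compound table with SMILES structures
#'
#' @slot compoundIds unique character ids.
#' @slot smiles character SMILES strings, non-empty (chemical validity is
#'   checked at fingerprint time, not at read time).
#' @slot labels optional common names (\code{NA} where absent).
#'
#' @seealso [CompoundTable()], [readCompoundTable()]
#' @name CompoundTable-class
#' @aliases CompoundTable-class
#' @exportClass CompoundTable
setClass("CompoundTable",
         slots = c(compoundIds = "character", smiles = "character",
                   labels = "character"))

setValidity("CompoundTable", function(object) {
    msg <- .checkIds(object@compoundIds, "compound")
    if (!is.null(msg)) return(msg)
    n <- length(object@compoundIds)
    if (length(object@smiles) != n || length(object@labels) != n)
        return("smiles and labels must parallel compoundIds")
    if (any(is.na(object@smiles)) || any(!nzchar(object@smiles)))
        return("SMILES strings must be non-empty")
    TRUE
})

#' Construct a CompoundTable
#'
#' @param compoundIds unique character compound ids.
#' @param smiles SMILES strings, one per compound.
#' @param labels optional common names.
#' @return A [CompoundTable-class] object.
#' @export
CompoundTable <- function(compoundIds, smiles, labels = NA_character_) {
    new("CompoundTable", compoundIds = as.character(compoundIds),
        smiles = as.character(smiles),
        labels = rep_len(as.character(labels), length(compoundIds)))
}

#' Drug-specific gene set for one primary drug
#'
#' Genes whose basal expression correlates with the drug's IC50 at
#' \eqn{|r| \ge} threshold: positive r marks resistance, negative r marks
#' sensitivity. Carries the full per-gene correlation records (all genes, not
#' only DSGs) and the identification parameters.
#'
#' @slot drugId character scalar.
#' @slot resistant named numeric vector of r values, all positive.
#' @slot sensitive named numeric vector of r values, all negative.
#' @slot correlations data.frame with one row per gene examined: gene_id, r
#'   (classification coefficient), r_full (all shared lines), n_used, subset
#'   ("extreme" or "full"), reason ("" for evaluated genes, otherwise why the
#'   gene was skipped).
#' @slot params list: threshold, fraction, minN, requireFull, ic50Scale.
#'
#' @seealso [identifyDsgs()]
#' @name DSGSet-class
#' @aliases DSGSet-class
#' @exportClass DSGSet
setClass("DSGSet",
         slots = c(drugId = "character", resistant = "numeric",
                   sensitive = "numeric", correlations = "data.frame",
                   params = "list"))

setValidity("DSGSet", function(object) {
    if (length(object@drugId) != 1L) return("drugId must be a single id")
    if (length(object@resistant) && (is.null(names(object@resistant)) ||
        any(object@resistant <= 0)))
        return("resistant genes must be named and have r > 0")
    if (length(object@sensitive) && (is.null(names(object@sensitive)) ||
        any(object@sensitive >= 0)))
        return("sensitive genes must be named and have r < 0")
    if (length(intersect(names(object@resistant), names(object@sensitive))))
        return("a gene cannot be both resistant and sensitive")
    thr <- object@params$threshold
    if (!is.null(thr) &&
        any(abs(c(object@resistant, object@sensitive)) < thr))
        return("all DSG |r| must reach the threshold")
    TRUE
})

#' Symmetric drug-drug similarity matrix
#'
#' @slot values symmetric numeric matrix with identical row/col ids.
#' @slot kind one of \code{"tanimoto_sets"}, \code{"correlation_profile"},
#'   \code{"tanimoto_chemical"}. Tanimoto kinds live in [0, 1] with unit
#'   diagonal; correlation kind lives in [-1, 1].
#'
#' @name SimilarityMatrix-class
#' @aliases SimilarityMatrix-class
#' @exportClass SimilarityMatrix
setClass("SimilarityMatrix",
         slots = c(values = "matrix", kind = "character"))

setValidity("SimilarityMatrix", function(object) {
    v <- object@values
    kinds <- c("tanimoto_sets", "correlation_profile", "tanimoto_chemical")
    if (length(object@kind) != 1L || !object@kind %in% kinds)
        return(paste("kind must be one of:", paste(kinds, collapse = ", ")))
    if (nrow(v) != ncol(v) || !identical(rownames(v), colnames(v)))
        return("matrix must be square with identical row/col identifiers")
    msg <- .checkIds(rownames(v), "item")
    if (!is.null(msg)) return(msg)
    if (!isTRUE(all.equal(v, t(v), check.attributes = FALSE,
                          tolerance = 1e-8)))
        return("matrix must be symmetric")
    ok <- v[is.finite(v)]
    if (object@kind == "correlation_profile") {
        if (any(ok < -1 - 1e-8 | ok > 1 + 1e-8))
            return("correlation similarities must lie in [-1, 1]")
    } else {
        if (any(ok < -1e-8 | ok > 1 + 1e-8))
            return("Tanimoto similarities must lie in [0, 1]")
        d <- diag(v)
        if (any(is.finite(d) & abs(d - 1) > 1e-8))
            return("Tanimoto diagonal must equal 1")
    }
    TRUE
})

#' Construct a SimilarityMatrix
#'
#' @param values symmetric numeric matrix with identical row and column ids.
#' @param kind similarity kind; see [SimilarityMatrix-class].
#' @return A [SimilarityMatrix-class] object.
#' @export
SimilarityMatrix <- function(values,
                             kind = c("tanimoto_sets", "correlation_profile",
                                      "tanimoto_chemical")) {
    new("SimilarityMatrix", values = as.matrix(values),
        kind = match.arg(kind))
}

#' Fixed-length chemical fingerprint
#'
#' Folded circular-substructure (ECFP-style) fingerprint of a molecule.
#'
#' @slot bits logical vector of length \code{params$nBits}.
#' @slot smiles the SMILES string the fingerprint was derived from.
#' @slot params list: \code{type} (OpenBabel fingerprint name, e.g.
#'   \code{"ECFP4"} = circular, radius 2) and \code{nBits} (folded width).
#'
#' @seealso [chemicalFingerprint()]
#' @name Fingerprint-class
#' @aliases Fingerprint-class
#' @exportClass Fingerprint
setClass("Fingerprint",
         slots = c(bits = "logical", smiles = "character", params = "list"))

setValidity("Fingerprint", function(object) {
    if (any(is.na(object@bits))) return("fingerprint bits must be TRUE/FALSE")
    nb <- object@params$nBits
    if (!is.null(nb) && length(object@bits) != nb)
        return("bit vector length must equal params$nBits")
    TRUE
})
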