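#' @rdname accessors
setMethod("geneIds", "ExpressionMatrix", function(x) rownames(x@values))

#' @rdname accessors
setMethod("cellLineIds", "ExpressionMatrix", function(x) colnames(x@values))

#' @rdname accessors
setMethod("exprValues", "ExpressionMatrix", function(x) x@values)

#' @rdname accessors
setMethod("drugIds", "ResponseTable", function(x) rownames(x@values))

#' @rdname accessors
setMethod("cellLineIds", "ResponseTable", function(x) colnames(x@values))

#' @rdname accessors
setMethod("ic50Values", "ResponseTable", function(x) x@values)

#' @rdname accessors
setMethod("isLogTransformed", "ResponseTable", function(x) x@logTransformed)

#' @rdname accessors
setMethod("compoundIds", "PerturbationSet", function(x) x@compoundIds)

#' @rdname accessors
setMethod("signatureIds", "PerturbationSet", function(x) x@signatureIds)

#' @rdname accessors
setMethod("profiles", "PerturbationSet", function(x) {
    p <- x@profiles
    names(p) <- x@signatureIds
    p
})

#' @rdname accessors
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)

#' @rdname accessors
setMethod("compoundIds", "CompoundTable", function(x) x@compoundIds)

#' @rdname accessors
setMethod("smilesOf", "CompoundTable",
          function(x) stats::setNames(x@smiles, x@compoundIds))

#' @rdname accessors
setMethod("drugIds", "DSGSet", function(x) x@drugId)

#' @rdname accessors
setMethod("resistantGenes", "DSGSet", function(x) x@resistant)

#' @rdname accessors
setMethod("sensitiveGenes", "DSGSet", function(x) x@sensitive)

#' @rdname accessors
setMethod("dsgGenes", "DSGSet",
          function(x) c(names(x@resistant), names(x@sensitive)))

#' @rdname accessors
setMethod("dsgCorrelations", "DSGSet", function(x) x@correlations)

#' @rdname accessors
setMethod("dsgParams", "DSGSet", function(x) x@params)

#' @rdname accessors
setMethod("simValues", "SimilarityMatrix", function(x) x@values)

#' @rdname accessors
setMethod("simKind", "SimilarityMatrix", function(x) x@kind)

setMethod("show", "ExpressionMatrix", function(object) {
    cat(sprintf("ExpressionMatrix: %d genes x %d cell lines (%d missing)\n",
                nrow(object@values), ncol(object@values),
                sum(is.na(object@values))))
})

setMethod("show", "ResponseTable", function(object) {
    cat(sprintf("ResponseTable: %d drugs x %d cell lines (%s scale)\n",
                nrow(object@values), ncol(object@values),
                if (object@logTransformed) "ln IC50" else "IC50"))
})

setMethod("show", "PerturbationSet", function(object) {
    cat(sprintf(
        "PerturbationSet: %d profiles, %d distinct compounds\n",
        length(object@profiles), length(unique(object@compoundIds))))
})

setMethod("show", "GeneSetCollection", function(object) {
    cat(sprintf("GeneSetCollection: %d sets\n", length(object@sets)))
})

setMethod("show", "CompoundTable", function(object) {
    cat(sprintf("CompoundTable: %d compounds with SMILES\n",
                length(object@compoundIds)))
})

setMethod("show", "DSGSet", function(object) {
    cat(sprintf(
        "DSGSet for drug '%s': %d resistant, %d sensitive (|r| >= %s)\n",
        object@drugId, length(object@resistant), length(object@sensitive),
        format(object@params$threshold)))
})

setMethod("show", "SimilarityMatrix", function(object) {
    cat(sprintf("SimilarityMatrix (%s): %d x %d\n", object@kind,
                nrow(object@values), ncol(object@values)))
})

setMethod("show", "Fingerprint", function(object) {
    cat(sprintf("Fingerprint (%s, %d bits): %d set\n",
                object@params$type, length(object@bits), sum(object@bits)))
})
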