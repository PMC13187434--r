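#' Accessors for resensitizer data containers
#'
#' Small accessor family used across the package's S4 classes. Accessors are
#' preferred over direct slot access.
#'
#' @param x an object of one of the package's S4 classes.
#' @return \code{geneIds}, \code{cellLineIds}, \code{drugIds},
#'   \code{compoundIds}, \code{signatureIds}: character vectors of
#'   identifiers. \code{exprValues}, \code{ic50Values}, \code{simValues}:
#'   numeric matrices. \code{isLogTransformed}, \code{simKind}: scalars.
#'   \code{profiles}, \code{geneSets}: named lists. \code{smilesOf}:
#'   named character vector. \code{resistantGenes}, \code{sensitiveGenes}:
#'   named numeric vectors of correlation coefficients. \code{dsgGenes}:
#'   character union of the two classes. \code{dsgCorrelations}: data.frame
#'   of per-gene records. \code{dsgParams}: list of identification
#'   parameters.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname accessors
#' @export
setGeneric("cellLineIds", function(x) standardGeneric("cellLineIds"))

#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname accessors
#' @export
setGeneric("drugIds", function(x) standardGeneric("drugIds"))

#' @rdname accessors
#' @export
setGeneric("ic50Values", function(x) standardGeneric("ic50Values"))

#' @rdname accessors
#' @export
setGeneric("isLogTransformed", function(x) standardGeneric("isLogTransformed"))

#' @rdname accessors
#' @export
setGeneric("compoundIds", function(x) standardGeneric("compoundIds"))

#' @rdname accessors
#' @export
setGeneric("signatureIds", function(x) standardGeneric("signatureIds"))

#' @rdname accessors
#' @export
setGeneric("profiles", function(x) standardGeneric("profiles"))

#' @rdname accessors
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname accessors
#' @export
setGeneric("smilesOf", function(x) standardGeneric("smilesOf"))

#' @rdname accessors
#' @export
setGeneric("resistantGenes", function(x) standardGeneric("resistantGenes"))

#' @rdname accessors
#' @export
setGeneric("sensitiveGenes", function(x) standardGeneric("sensitiveGenes"))

#' @rdname accessors
#' @export
setGeneric("dsgGenes", function(x) standardGeneric("dsgGenes"))

#' @rdname accessors
#' @export
setGeneric("dsgCorrelations", function(x) standardGeneric("dsgCorrelations"))

#' @rdname accessors
#' @export
setGeneric("dsgParams", function(x) standardGeneric("dsgParams"))

#' @rdname accessors
#' @export
setGeneric("simValues", function(x) standardGeneric("simValues"))

#' @rdname accessors
#' @export
setGeneric("simKind", function(x) standardGeneric("simKind"))
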