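## Readers and writers for the tabular formats the pipeline touches:
## expression / response matrices (TSV or CSV, ids in the first column),
## perturbation profiles (long-form TSV or GCT v1.3 text), GMT gene sets and
## SMILES compound tables. Missing values on disk are "NA" or an empty cell;
## in memory they are NA. Identifier matching is exact and case-sensitive.

.sepFor <- function(dialect) switch(dialect, tsv = "\t", csv = ",")

## Parse a character matrix block to numeric, reporting the first offending
## cell with its row/column identifiers instead of coercing silently.
.parseNumericBlock <- function(chr, rowIds, colIds, path) {
    chr[chr == "" | chr == "NA"] <- NA_character_
    suppressWarnings(num <- as.numeric(chr))
    bad <- which(is.na(num) & !is.na(chr))
    if (length(bad)) {
        i <- ((bad[1L] - 1L) %% length(rowIds)) + 1L
        j <- ((bad[1L] - 1L) %/% length(rowIds)) + 1L
        stop(sprintf(
            "non-numeric value '%s' in %s at row '%s', column '%s'",
            chr[bad[1L]], path, rowIds[i], colIds[j]))
    }
    matrix(num, nrow = length(rowIds),
           dimnames = list(rowIds, colIds))
}

.readIdMatrix <- function(path, dialect, what) {
    if (!file.exists(path)) stop(sprintf("file not found: %s", path))
    df <- utils::read.table(path, sep = .sepFor(dialect), header = TRUE,
                            check.names = FALSE, colClasses = "character",
                            quote = "\"", comment.char = "",
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2L)
        stop(sprintf("%s: expected an id column plus at least one value column",
                     path))
    ids <- df[[1L]]
    msg <- .checkIds(ids, what)
    if (!is.null(msg)) stop(sprintf("%s: %s", path, msg))
    colIds <- colnames(df)[-1L]
    .parseNumericBlock(as.matrix(df[, -1L, drop = FALSE]), ids, colIds, path)
}

#' Read a basal expression matrix
#'
#' Expects gene identifiers in the first column and cell-line identifiers in
#' the header row. Missing cells may be empty or \code{"NA"}.
#'
#' @param path path to the file.
#' @param dialect \code{"tsv"} (default) or \code{"csv"}.
#' @param uppercaseGenes normalize gene ids to upper case (off by default;
#'   identifier matching elsewhere is exact and case-sensitive).
#' @return An [ExpressionMatrix-class].
#' @export
readExpressionMatrix <- function(path, dialect = c("tsv", "csv"),
                                 uppercaseGenes = FALSE) {
    dialect <- match.arg(dialect)
    m <- .readIdMatrix(path, dialect, "gene")
    if (uppercaseGenes) {
        rownames(m) <- toupper(rownames(m))
        msg <- .checkIds(rownames(m), "gene")
        if (!is.null(msg)) stop(sprintf("%s (after uppercasing): %s", path, msg))
    }
    ExpressionMatrix(m)
}

#' Write an expression matrix
#'
#' @param x an [ExpressionMatrix-class].
#' @param path output path.
#' @param dialect \code{"tsv"} or \code{"csv"}.
#' @return \code{path}, invisibly.
#' @export
writeExpressionMatrix <- function(x, path, dialect = c("tsv", "csv")) {
    dialect <- match.arg(dialect)
    df <- data.frame(gene_id = geneIds(x), exprValues(x),
                     check.names = FALSE)
    utils::write.table(df, path, sep = .sepFor(dialect), quote = FALSE,
                       row.names = FALSE, na = "NA")
    invisible(path)
}

#' Read a drug-response (IC50) table
#'
#' Drugs in rows and cell lines in columns by default; \code{transpose = TRUE}
#' for the flipped layout. With \code{logTransform = TRUE} the natural log is
#' applied to strictly positive values; non-positive values become missing
#' with a warning (GDSC-style distributions are usually already ln IC50, in
#' which case leave the flag off and the stored scale is recorded as raw).
#'
#' @param path path to the file.
#' @param dialect \code{"tsv"} or \code{"csv"}.
#' @param logTransform apply natural log at read time.
#' @param transpose set when the file has cell lines in rows.
#' @return A [ResponseTable-class].
#' @export
readResponseTable <- function(path, dialect = c("tsv", "csv"),
                              logTransform = FALSE, transpose = FALSE) {
    dialect <- match.arg(dialect)
    m <- .readIdMatrix(path, dialect, if (transpose) "cell-line" else "drug")
    if (transpose) m <- t(m)
    if (logTransform) {
        bad <- which(!is.na(m) & m <= 0)
        if (length(bad)) {
            warning(sprintf(
                "%d non-positive IC50 value(s) set to missing under log transform",
                length(bad)))
            m[bad] <- NA_real_
        }
        m <- log(m)
    }
    allMissing <- rownames(m)[rowSums(!is.na(m)) == 0L]
    if (length(allMissing))
        warning(sprintf("drug(s) with no measured IC50 retained: %s",
                        paste(allMissing, collapse = ", ")))
    ResponseTable(m, logTransformed = logTransform)
}

#' Write a response table
#'
#' @param x a [ResponseTable-class].
#' @param path output path.
#' @param dialect \code{"tsv"} or \code{"csv"}.
#' @return \code{path}, invisibly.
#' @export
writeResponseTable <- function(x, path, dialect = c("tsv", "csv")) {
    dialect <- match.arg(dialect)
    df <- data.frame(drug_id = drugIds(x), ic50Values(x),
                     check.names = FALSE)
    utils::write.table(df, path, sep = .sepFor(dialect), quote = FALSE,
                       row.names = FALSE, na = "NA")
    invisible(path)
}

.readLongTsvProfiles <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            check.names = FALSE, quote = "\"",
                            comment.char = "", stringsAsFactors = FALSE)
    need <- c("compound_id", "gene_id", "logfc")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop(sprintf("%s: missing required column(s): %s", path,
                     paste(miss, collapse = ", ")))
    if (!is.numeric(df$logfc))
        stop(sprintf("%s: logfc column is not numeric", path))
    sigCol <- if ("signature_id" %in% colnames(df)) df$signature_id
              else df$compound_id
    key <- paste(sigCol, df$gene_id, sep = "\r")
    if (anyDuplicated(key)) {
        d <- strsplit(key[duplicated(key)][1L], "\r", fixed = TRUE)[[1L]]
        stop(sprintf("%s: duplicated (compound/signature, gene) pair: (%s, %s)",
                     path, d[1L], d[2L]))
    }
    sigs <- unique(sigCol)
    profs <- lapply(sigs, function(s) {
        sel <- sigCol == s
        stats::setNames(df$logfc[sel], df$gene_id[sel])
    })
    cmpd <- df$compound_id[match(sigs, sigCol)]
    metaCols <- setdiff(colnames(df),
                        c(need, "signature_id"))
    meta <- df[match(sigs, sigCol), metaCols, drop = FALSE]
    rownames(meta) <- NULL
    PerturbationSet(profs, compoundIds = cmpd, signatureIds = sigs,
                    metadata = meta)
}

.readGctProfiles <- function(path) {
    lines <- readLines(path)
    if (length(lines) && startsWith(lines[1L], "\x89HDF"))
        stop(sprintf(
            "%s: binary GCTX is not supported; convert to GCT v1.3 text first",
            path))
    if (length(lines) < 3L || !identical(trimws(lines[1L]), "#1.3"))
        stop(sprintf("%s: not a GCT v1.3 text file (missing '#1.3' header)",
                     path))
    dims <- suppressWarnings(as.integer(strsplit(lines[2L], "\t")[[1L]]))
    if (length(dims) != 4L || any(is.na(dims)) || any(dims < 0L))
        stop(sprintf(
            "%s: malformed GCT dimension line (need 4 non-negative integers)",
            path))
    nr <- dims[1L]; nc <- dims[2L]; nrm <- dims[3L]; ncm <- dims[4L]
    if (length(lines) < 3L + ncm + nr)
        stop(sprintf("%s: truncated GCT: expected %d lines after the header",
                     path, 1L + ncm + nr))
    hdr <- strsplit(lines[3L], "\t")[[1L]]
    if (length(hdr) != 1L + nrm + nc)
        stop(sprintf("%s: GCT header row has %d fields, expected %d",
                     path, length(hdr), 1L + nrm + nc))
    colIds <- hdr[(2L + nrm):(1L + nrm + nc)]
    ## column-metadata rows: field name, nrm filler cells, then nc values
    meta <- data.frame(row.names = seq_len(nc))
    for (k in seq_len(ncm)) {
        f <- strsplit(lines[3L + k], "\t")[[1L]]
        meta[[f[1L]]] <- f[(2L + nrm):(1L + nrm + nc)]
    }
    dataLines <- lines[(4L + ncm):(3L + ncm + nr)]
    fields <- strsplit(dataLines, "\t")
    ids <- vapply(fields, `[`, "", 1L)
    vals <- vapply(fields, function(f) {
        suppressWarnings(as.numeric(f[(2L + nrm):(1L + nrm + nc)]))
    }, numeric(nc))
    vals <- matrix(vals, nrow = nc)   # columns of vals = genes
    cmpd <- if ("compound_id" %in% colnames(meta)) meta$compound_id
            else if ("pert_id" %in% colnames(meta)) meta$pert_id
            else colIds
    profs <- lapply(seq_len(nc), function(j) {
        v <- stats::setNames(vals[j, ], ids)
        v[!is.na(v)]
    })
    PerturbationSet(profs, compoundIds = cmpd, signatureIds = colIds,
                    metadata = meta)
}

#' Read compound perturbation profiles
#'
#' Two text formats are supported. \code{"long_tsv"}: columns
#' \code{compound_id}, \code{gene_id}, \code{logfc}, an optional
#' \code{signature_id} (replicate signatures for one compound) and arbitrary
#' metadata columns. \code{"gct"}: GCT v1.3 text with genes in rows and
#' signatures in columns; a column-metadata field named \code{compound_id} or
#' \code{pert_id} supplies compound ids, otherwise column ids are used.
#' Binary GCTX is not supported and is rejected with a clear error.
#'
#' @param path path to the file.
#' @param format \code{"long_tsv"} or \code{"gct"}.
#' @return A [PerturbationSet-class].
#' @export
readPerturbationProfiles <- function(path, format = c("long_tsv", "gct")) {
    format <- match.arg(format)
    if (!file.exists(path)) stop(sprintf("file not found: %s", path))
    if (format == "long_tsv") .readLongTsvProfiles(path)
    else .readGctProfiles(path)
}

#' Write perturbation profiles as long-form TSV
#'
#' @param x a [PerturbationSet-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePerturbationProfiles <- function(x, path) {
    sigs <- signatureIds(x)
    cmpd <- compoundIds(x)
    pl <- x@profiles
    df <- do.call(rbind, lapply(seq_along(pl), function(i) {
        data.frame(compound_id = cmpd[i], signature_id = sigs[i],
                   gene_id = names(pl[[i]]), logfc = unname(pl[[i]]))
    }))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated \code{name}, description,
#' members. Members are deduplicated; blank sets are skipped with a warning;
#' duplicated set names are an error.
#'
#' @param path path to the GMT file.
#' @return A [GeneSetCollection-class].
#' @export
readGeneSets <- function(path) {
    if (!file.exists(path)) stop(sprintf("file not found: %s", path))
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    sets <- list()
    for (ln in lines) {
        f <- strsplit(ln, "\t")[[1L]]
        nm <- f[1L]
        members <- unique(f[-c(1L, 2L)])
        members <- members[nzchar(members)]
        if (length(members) == 0L) {
            warning(sprintf("gene set '%s' is empty and was skipped", nm))
            next
        }
        if (nm %in% names(sets))
            stop(sprintf("%s: duplicated gene-set name '%s'", path, nm))
        sets[[nm]] <- members
    }
    GeneSetCollection(sets)
}

#' Write a GMT gene-set collection
#'
#' @param x a [GeneSetCollection-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGeneSets <- function(x, path) {
    s <- geneSets(x)
    lines <- vapply(names(s), function(nm) {
        paste(c(nm, "na", s[[nm]]), collapse = "\t")
    }, "")
    writeLines(lines, path)
    invisible(path)
}

#' Read a compound table with SMILES
#'
#' TSV with columns \code{compound_id}, \code{smiles} and an optional
#' \code{name}. SMILES are only checked for non-emptiness here; chemical
#' validity is checked at fingerprint time.
#'
#' @param path path to the file.
#' @return A [CompoundTable-class].
#' @export
readCompoundTable <- function(path) {
    if (!file.exists(path)) stop(sprintf("file not found: %s", path))
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            check.names = FALSE, quote = "\"",
                            comment.char = "", stringsAsFactors = FALSE,
                            colClasses = "character")
    need <- c("compound_id", "smiles")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop(sprintf("%s: missing required column(s): %s", path,
                     paste(miss, collapse = ", ")))
    labels <- if ("name" %in% colnames(df)) df$name else NA_character_
    CompoundTable(df$compound_id, df$smiles, labels)
}

#' Write a compound table
#'
#' @param x a [CompoundTable-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeCompoundTable <- function(x, path) {
    df <- data.frame(compound_id = x@compoundIds, smiles = x@smiles,
                     name = x@labels)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    invisible(path)
}

#' Validate an input file
#'
#' Attempts to parse \code{path} as the given format and reports success or
#' the first validation failure; the machine-readable result backs the
#' command-line \code{validate} subcommand.
#'
#' @param path path to the file.
#' @param format one of \code{"expression"}, \code{"response"},
#'   \code{"long_tsv"}, \code{"gct"}, \code{"gmt"}, \code{"smiles"}.
#' @param dialect matrix dialect for expression/response files.
#' @return list with elements \code{valid} (logical) and \code{message}.
#' @export
validateFile <- function(path,
                         format = c("expression", "response", "long_tsv",
                                    "gct", "gmt", "smiles"),
                         dialect = c("tsv", "csv")) {
    format <- match.arg(format)
    dialect <- match.arg(dialect)
    res <- tryCatch({
        obj <- switch(format,
            expression = readExpressionMatrix(path, dialect),
            response   = readResponseTable(path, dialect),
            long_tsv   = readPerturbationProfiles(path, "long_tsv"),
            gct        = readPerturbationProfiles(path, "gct"),
            gmt        = readGeneSets(path),
            smiles     = readCompoundTable(path))
        list(valid = TRUE,
             message = paste(utils::capture.output(show(obj)),
                             collapse = "\n"))
    }, error = function(e) list(valid = FALSE,
                                message = conditionMessage(e)))
    res
}
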