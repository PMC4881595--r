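#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

#' StudyExpression: one study's expression matrix with group labels
#'
#' Container for a single study's features-by-samples expression matrix
#' together with the per-sample group assignment (MCAO or sham).  Extends
#' \link[SummarizedExperiment]{SummarizedExperiment}; the expression values
#' live in the \code{"exprs"} assay and the group labels in
#' \code{colData()$group}.  \code{level} records whether rows are probes or
#' genes: probe-level objects may carry duplicate row names (several probes
#' of one array can interrogate the same transcript), gene-level objects
#' must not.
#'
#' @slot studyId single string identifying the study (e.g. a GEO series id).
#' @slot level \code{"probe"} or \code{"gene"}.
#'
#' @seealso [StudyExpression()] for the constructor, [collapseProbes()] for
#'   the probe-to-gene transition.
#' @exportClass StudyExpression
setClass("StudyExpression",
    contains = "SummarizedExperiment",
    representation(studyId = "character", level = "character"))

.validStudyExpression <- function(object) {
    msg <- character()
    if (length(object@studyId) != 1L || !nzchar(object@studyId))
        msg <- c(msg, "'studyId' must be a single non-empty string")
    if (length(object@level) != 1L || !object@level %in% c("probe", "gene"))
        msg <- c(msg, "'level' must be \"probe\" or \"gene\"")
    if (!"group" %in% colnames(colData(object))) {
        msg <- c(msg, "colData must contain a 'group' column")
    } else {
        grp <- as.character(colData(object)$group)
        bad <- setdiff(unique(grp), c("MCAO", "sham"))
        if (length(bad))
            msg <- c(msg, paste0("unknown group label(s): ",
                                 paste(bad, collapse = ", ")))
        if (!all(c("MCAO", "sham") %in% grp))
            msg <- c(msg, "both 'MCAO' and 'sham' groups must be present")
    }
    if (is.null(rownames(object)))
        msg <- c(msg, "feature identifiers (rownames) are required")
    else if (identical(object@level, "gene") &&
             anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicate feature ids are not allowed at gene level")
    if (length(msg)) msg else TRUE
}
setValidity("StudyExpression", .validStudyExpression)

#' Construct a StudyExpression object
#'
#' @param values numeric matrix, features in rows, samples in columns.
#'   Missing entries are \code{NA}.
#' @param groups character or factor of length \code{ncol(values)} with
#'   values in \code{c("MCAO", "sham")}.
#' @param studyId single string.
#' @param level \code{"probe"} or \code{"gene"}.
#' @param alreadyLog logical flag recorded in \code{metadata()}; see
#'   [log2Transform()].
#' @return A [StudyExpression-class] object.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' se <- StudyExpression(m, c("MCAO", "MCAO", "sham", "sham"), "demo")
#' studyId(se)
#' @export
StudyExpression <- function(values, groups, studyId,
                            level = c("gene", "probe"),
                            alreadyLog = TRUE) {
    level <- match.arg(level)
    values <- as.matrix(values)
    if (length(groups) != ncol(values))
        stop("'groups' must have one label per sample column")
    cd <- DataFrame(group = factor(as.character(groups),
                                   levels = c("sham", "MCAO")),
                    row.names = colnames(values))
    se <- SummarizedExperiment(assays = SimpleList(exprs = values),
                               colData = cd)
    metadata(se)$alreadyLog <- isTRUE(alreadyLog)
    new("StudyExpression", se, studyId = as.character(studyId),
        level = level)
}

#' @describeIn StudyExpression study identifier accessor.
#' @param x,object a \code{StudyExpression} object.
#' @export
setGeneric("studyId", function(x) standardGeneric("studyId"))

#' @rdname StudyExpression
#' @export
setMethod("studyId", "StudyExpression", function(x) x@studyId)

#' @describeIn StudyExpression feature level (\code{"probe"}/\code{"gene"}).
#' @export
setGeneric("featureLevel", function(x) standardGeneric("featureLevel"))

#' @rdname StudyExpression
#' @export
setMethod("featureLevel", "StudyExpression", function(x) x@level)

#' @describeIn StudyExpression per-sample group factor (sham, MCAO).
#' @export
setGeneric("groups", function(x) standardGeneric("groups"))

#' @rdname StudyExpression
#' @export
setMethod("groups", "StudyExpression", function(x) colData(x)$group)

#' @describeIn StudyExpression the expression matrix (the \code{"exprs"}
#'   assay).
#' @export
setGeneric("exprs", function(x) standardGeneric("exprs"))

#' @rdname StudyExpression
#' @export
setMethod("exprs", "StudyExpression", function(x) assay(x, "exprs"))

setMethod("show", "StudyExpression", function(object) {
    cat("StudyExpression '", object@studyId, "' (", object@level,
        " level)\n", sep = "")
    cat(" ", nrow(object), " features x ", ncol(object), " samples (",
        sum(groups(object) == "MCAO"), " MCAO / ",
        sum(groups(object) == "sham"), " sham)\n", sep = "")
    nmiss <- sum(is.na(assay(object, "exprs")))
    if (nmiss)
        cat("  missing entries:", nmiss, "\n")
    invisible(NULL)
})

#' GeneSetCollection: named gene sets for enrichment analysis
#'
#' A collection of uniquely named, non-empty gene sets (upper-cased
#' symbols) with one description per set, as read from a GMT file or
#' produced by [simulateGeneSets()].
#'
#' @slot sets named list of character vectors (gene symbols, upper case).
#' @slot descriptions character vector parallel to \code{sets}.
#' @seealso [readGMT()], [hypergeomEnrich()]
#' @exportClass GeneSetCollection
setClass("GeneSetCollection",
    representation(sets = "list", descriptions = "character"))

setValidity("GeneSetCollection", function(object) {
    msg <- character()
    if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
        msg <- c(msg, "set ids must be unique and non-NULL")
    if (any(lengths(object@sets) == 0L))
        msg <- c(msg, "every gene set must be non-empty")
    if (length(object@descriptions) != length(object@sets))
        msg <- c(msg, "one description per set is required")
    if (length(msg)) msg else TRUE
})

#' Construct a GeneSetCollection
#'
#' @param sets named list of character vectors of gene symbols.
#' @param descriptions optional character vector of per-set descriptions.
#' @return A [GeneSetCollection-class].
#' @export
GeneSetCollection <- function(sets, descriptions = NULL) {
    sets <- lapply(sets, function(s) unique(toupper(as.character(s))))
    if (is.null(descriptions))
        descriptions <- rep("", length(sets))
    new("GeneSetCollection", sets = sets,
        descriptions = as.character(descriptions))
}

#' @describeIn GeneSetCollection the named list of member vectors.
#' @param x,object a \code{GeneSetCollection}.
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname GeneSetCollection
#' @export
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)

#' @describeIn GeneSetCollection per-set descriptions, named by set id.
#' @export
setGeneric("setDescriptions",
           function(x) standardGeneric("setDescriptions"))

#' @rdname GeneSetCollection
#' @export
setMethod("setDescriptions", "GeneSetCollection", function(x)
    stats::setNames(x@descriptions, names(x@sets)))

#' @rdname GeneSetCollection
#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@sets))

#' @rdname GeneSetCollection
#' @export
setMethod("names", "GeneSetCollection", function(x) names(x@sets))

setMethod("show", "GeneSetCollection", function(object) {
    cat("GeneSetCollection of", length(object@sets), "sets; sizes",
        paste(range(lengths(object@sets)), collapse = "-"), "\n")
    invisible(NULL)
})

#' @rdname GeneSetCollection
#' @param i set id or index.
#' @export
setMethod("[[", "GeneSetCollection", function(x, i) x@sets[[i]])
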