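#' Log2-transform a study's expression values
#'
#' Identity when the object's already-log flag is set (summarized
#' intensities from most pipelines arrive on the log2 scale already).
#' Otherwise every non-missing value must be positive.
#'
#' @param x a [StudyExpression-class].
#' @return a [StudyExpression-class] on the log2 scale with the
#'   already-log flag set.
#' @export
log2Transform <- function(x) {
    stopifnot(is(x, "StudyExpression"))
    if (isTRUE(S4Vectors::metadata(x)$alreadyLog))
        return(x)
    vals <- exprs(x)
    bad <- which(!is.na(vals) & vals <= 0, arr.ind = TRUE)
    if (nrow(bad))
        stop("non-positive value at feature '", rownames(vals)[bad[1L, 1L]],
             "', sample '", colnames(vals)[bad[1L, 2L]],
             "': cannot log2-transform")
    StudyExpression(log2(vals), groups(x), studyId = studyId(x),
                    level = featureLevel(x), alreadyLog = TRUE)
}

#' Quantile-normalize the columns of a matrix
#'
#' Forces all columns (samples) to share one value distribution: the
#' sorted values of each column are replaced by the row means of the
#' column-sorted matrix, preserving within-column rank order.  Tied values
#' receive the mean of the reference values at their tied ranks.  The
#' computation is delegated to \code{limma::normalizeQuantiles(ties =
#' TRUE)}, whose tie dialect matches.  A single-column matrix is returned
#' unchanged.
#'
#' @param x numeric matrix (samples in columns).
#' @return matrix of the same shape and dimnames.
#' @export
quantileNormalize <- function(x) {
    x <- as.matrix(x)
    if (ncol(x) <= 1L)
        return(x)
    out <- limma::normalizeQuantiles(x, ties = TRUE)
    dimnames(out) <- dimnames(x)
    out
}

#' Impute missing values by k-nearest neighbours
#'
#' Each missing cell (g, j) is replaced by the mean of column j over the
#' k rows nearest to row g.  Candidate neighbours are rows observed in
#' column j; distance is Euclidean over the columns where both rows are
#' observed, rescaled by \code{sqrt(n_total / n_shared)} so rows sharing
#' few columns are not spuriously close.  Observed entries are returned
#' bit-identical.
#'
#' @param x numeric matrix with \code{NA} for missing cells.
#' @param k number of neighbours (classic imputation default 10).
#' @return the completed matrix.
#' @export
knnImpute <- function(x, k = 10L) {
    x <- as.matrix(x)
    stopifnot(k >= 1L)
    miss <- is.na(x)
    if (!any(miss))
        return(x)
    if (any(rowSums(!miss) == 0L))
        stop("row(s) entirely missing cannot be imputed: ",
             paste(rownames(x)[rowSums(!miss) == 0L], collapse = ", "))
    p <- ncol(x)
    out <- x
    warned <- FALSE
    for (g in which(rowSums(miss) > 0L)) {
        xg <- x[g, ]
        obsG <- !miss[g, ]
        shared <- (!miss) %*% as.numeric(obsG)  # per-row shared columns
        diffs <- sweep(x, 2L, xg)
        diffs[miss] <- 0
        diffs[, !obsG] <- 0
        d2 <- rowSums(diffs^2) * p / pmax(shared, 1L)
        d2[shared == 0L] <- Inf
        d2[g] <- Inf
        for (j in which(miss[g, ])) {
            cand <- which(!miss[, j] & is.finite(d2))
            if (!length(cand))
                stop("no candidate neighbour for row ", rownames(x)[g],
                     ", column ", colnames(x)[j])
            kUse <- k
            if (length(cand) < k) {
                kUse <- length(cand)
                if (!warned) {
                    warning("fewer than k candidate neighbours; ",
                            "using all available")
                    warned <- TRUE
                }
            }
            nb <- cand[order(d2[cand])[seq_len(kUse)]]
            out[g, j] <- mean(x[nb, j])
        }
    }
    out
}

#' Collapse probe-level values to gene level by the mean
#'
#' Per gene and sample, the value is the arithmetic mean of that gene's
#' probe values.  Probes absent from the map are dropped (a message
#' reports how many).
#'
#' @param x a probe-level [StudyExpression-class].
#' @param map named character vector probe id -> gene symbol
#'   (many-to-one).
#' @return a gene-level [StudyExpression-class].
#' @export
collapseProbes <- function(x, map) {
    stopifnot(is(x, "StudyExpression"))
    if (featureLevel(x) == "gene")
        return(x)
    vals <- exprs(x)
    mapped <- rownames(vals) %in% names(map)
    if (!all(mapped))
        message(sum(!mapped), " unmapped probe(s) dropped in study ",
                studyId(x))
    vals <- vals[mapped, , drop = FALSE]
    gene <- map[rownames(vals)]
    sums <- rowsum(ifelse(is.na(vals), 0, vals), gene)
    counts <- rowsum((!is.na(vals)) * 1, gene)
    out <- sums / counts
    out[counts == 0] <- NA
    out <- out[order(rownames(out)), , drop = FALSE]
    StudyExpression(out, groups(x), studyId = studyId(x), level = "gene",
                    alreadyLog = isTRUE(S4Vectors::metadata(x)$alreadyLog))
}

#' Standardize each gene (row) to mean 0 and unit sample variance
#'
#' Uses the sample variance (denominator n - 1).  Idempotent to numerical
#' tolerance.  Constant rows have no scale and raise an error naming the
#' offending gene(s).
#'
#' @param x numeric matrix, genes in rows.
#' @return matrix of the same shape.
#' @export
standardizeGenes <- function(x) {
    x <- as.matrix(x)
    mu <- rowMeans(x)
    centered <- x - mu
    s <- sqrt(rowSums(centered^2) / (ncol(x) - 1L))
    if (any(s == 0))
        stop("constant row(s) cannot be standardized: ",
             paste(rownames(x)[s == 0], collapse = ", "))
    centered / s
}

#' Genes measured in every study of a collection
#'
#' @param studies list of gene-level [StudyExpression-class] objects.
#' @return sorted character vector, the intersection of all studies' gene
#'   sets.  An empty intersection is an error (nothing downstream could
#'   run).
#' @export
commonGenes <- function(studies) {
    stopifnot(length(studies) >= 1L)
    lv <- vapply(studies, featureLevel, character(1))
    if (!all(lv == "gene"))
        stop("all studies must be at gene level; collapse probes first")
    common <- Reduce(intersect, lapply(studies, rownames))
    if (!length(common))
        stop("no genes are common to all studies")
    sort(common)
}

#' Relative log expression (RLE) quality summary
#'
#' For each sample j, the RLE values are \code{x[g, j] - median_g(x[g, ])}
#' (deviation of every gene from its across-sample median); the per-sample
#' median and IQR of those deviations summarize array-level shifts and
#' spread.  Well-behaved samples have RLE medians near 0.  Reported only
#' -- never used to drop samples automatically.
#'
#' @param x log-scale numeric matrix (probe or gene level).
#' @return data.frame with columns \code{sample}, \code{rle_median},
#'   \code{rle_iqr}.
#' @export
qcRLE <- function(x) {
    x <- as.matrix(x)
    med <- apply(x, 1L, stats::median, na.rm = TRUE)
    rle <- x - med
    data.frame(sample = colnames(x) %||% as.character(seq_len(ncol(x))),
               rle_median = apply(rle, 2L, stats::median, na.rm = TRUE),
               rle_iqr = apply(rle, 2L, stats::IQR, na.rm = TRUE),
               row.names = NULL, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full preprocessing chain on a study collection
#'
#' Order of operations: log2 transform, quantile normalization, KNN
#' imputation, probe-to-gene collapse, restriction to the common-gene
#' intersection, per-gene standardization.  Imputation runs on normalized
#' log-scale values so probe means are complete before the collapse.  Two
#' gene-level matrices are kept per study: the unstandardized one (on
#' which log2 fold changes are computed) and the standardized one (on
#' which test statistics and effect sizes are computed); standardization
#' rescales every gene, so fold changes taken after it would lose their
#' units.
#'
#' @param studies list of [StudyExpression-class] objects.
#' @param probeMap named character vector probe -> gene; required when any
#'   study is probe-level.
#' @param k neighbours for [knnImpute()].
#' @return list with \code{studies} (gene-level [StudyExpression-class]
#'   restricted to common genes, unstandardized), \code{standardized}
#'   (list of standardized matrices), \code{common} (gene vector) and
#'   \code{qc} (per-study RLE summaries).
#' @export
preprocessStudies <- function(studies, probeMap = NULL, k = 10L) {
    prepped <- lapply(studies, function(s) {
        s <- log2Transform(s)
        vals <- quantileNormalize(exprs(s))
        if (anyNA(vals))
            vals <- knnImpute(vals, k = k)
        s <- StudyExpression(vals, groups(s), studyId = studyId(s),
                             level = featureLevel(s), alreadyLog = TRUE)
        if (featureLevel(s) == "probe") {
            if (is.null(probeMap))
                stop("probe-level study '", studyId(s),
                     "' requires a probeMap")
            s <- collapseProbes(s, probeMap)
        }
        s
    })
    common <- commonGenes(prepped)
    prepped <- lapply(prepped, function(s)
        StudyExpression(exprs(s)[common, , drop = FALSE], groups(s),
                        studyId = studyId(s), level = "gene",
                        alreadyLog = TRUE))
    standardized <- lapply(prepped, function(s) standardizeGenes(exprs(s)))
    qc <- lapply(prepped, function(s) qcRLE(exprs(s)))
    names(prepped) <- names(standardized) <- names(qc) <-
        vapply(prepped, studyId, character(1))
    list(studies = prepped, standardized = standardized, common = common,
         qc = qc)
}
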