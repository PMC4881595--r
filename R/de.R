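#' Per-gene two-sample t-tests (MCAO vs sham)
#'
#' Vectorized classical (pooled-variance) or Welch t-tests per gene, with
#' the convention MCAO minus sham.  Genes with zero variance in both
#' groups get p = 1 when the means are equal; otherwise the variance is
#' floored at 1e-12 and a warning is emitted.
#'
#' @param x numeric matrix, genes in rows, or a [StudyExpression-class].
#' @param groups per-sample labels in \code{c("MCAO", "sham")}; ignored
#'   when \code{x} is a [StudyExpression-class].
#' @param variant \code{"welch"} (default; group sizes here are tiny and
#'   variances rarely equal) or \code{"student"}.
#' @return data.frame with columns \code{t}, \code{df}, \code{p}
#'   (two-sided), rownames = genes.
#' @export
geneTTest <- function(x, groups = NULL, variant = c("welch", "student")) {
    variant <- match.arg(variant)
    if (is(x, "StudyExpression")) {
        groups <- groups(x)
        x <- exprs(x)
    }
    groups <- as.character(groups)
    stopifnot(length(groups) == ncol(x),
              all(groups %in% c("MCAO", "sham")))
    st <- .groupStats(x, groups)
    if (st$n1 < 2L || st$n2 < 2L)
        stop("at least 2 samples per group are required")
    v1 <- st$s1^2; v2 <- st$s2^2
    n1 <- st$n1; n2 <- st$n2
    diff <- st$m1 - st$m2
    if (variant == "student") {
        sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
        se2 <- sp2 * (1 / n1 + 1 / n2)
        df <- rep(n1 + n2 - 2, length(diff))
    } else {
        se2 <- v1 / n1 + v2 / n2
        df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
        df[se2 == 0] <- n1 + n2 - 2
    }
    zero <- se2 == 0
    if (any(zero & diff != 0)) {
        warning(sum(zero & diff != 0),
                " gene(s) with zero variance and unequal means; ",
                "variance floored at 1e-12")
        se2[zero & diff != 0] <- 1e-12
    }
    t <- diff / sqrt(se2)
    t[zero & diff == 0] <- 0
    p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
    p[zero & diff == 0] <- 1
    data.frame(t = t, df = df, p = p, row.names = rownames(x))
}

.groupStats <- function(x, groups) {
    mc <- x[, groups == "MCAO", drop = FALSE]
    sh <- x[, groups == "sham", drop = FALSE]
    list(n1 = ncol(mc), n2 = ncol(sh),
         m1 = rowMeans(mc), m2 = rowMeans(sh),
         s1 = apply(mc, 1L, stats::sd), s2 = apply(sh, 1L, stats::sd))
}

#' Per-gene log2 fold change (MCAO mean minus sham mean)
#'
#' Must be computed on the unstandardized gene-level log2 matrix:
#' per-gene standardization rescales rows and destroys the fold-change
#' units.
#'
#' @inheritParams geneTTest
#' @return named numeric vector of log2 fold changes.
#' @export
log2FoldChange <- function(x, groups = NULL) {
    if (is(x, "StudyExpression")) {
        groups <- groups(x)
        x <- exprs(x)
    }
    groups <- as.character(groups)
    rowMeans(x[, groups == "MCAO", drop = FALSE]) -
        rowMeans(x[, groups == "sham", drop = FALSE])
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validated wrapper around \code{stats::p.adjust(method = "BH")}.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values, clipped at 1.
#' @export
bhAdjust <- function(p) {
    if (any(is.na(p)) || any(p < 0) || any(p > 1))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Call per-study DEGs from fold changes and p-values
#'
#' A gene is called \code{up} when \code{log2fc >= lfcThreshold} and the
#' chosen p-value is below \code{pThreshold}; \code{down} symmetrically;
#' otherwise \code{none}.  The fold-change bound is on the log2
#' difference itself (1.5 on the log2 scale is about a 2.8-fold change).
#'
#' @param log2fc named vector from [log2FoldChange()].
#' @param pRaw raw two-sided p-values.
#' @param pFdr BH-adjusted p-values (computed from \code{pRaw} when
#'   omitted).
#' @param pThreshold significance threshold (default 0.05).
#' @param lfcThreshold bound on |log2 fold change| (default 1.5).
#' @param useFdr gate on the FDR-adjusted p instead of the raw p.
#'   Default \code{FALSE}: the selection criterion is a raw p-value cut
#'   with the adjusted values reported alongside (see the vignette for
#'   the rationale; both readings are supported).
#' @param studyId optional study label stored in the result.
#' @return a \code{DEResult}: data.frame with columns \code{log2fc},
#'   \code{p_raw}, \code{p_fdr}, \code{call}, plus attributes
#'   \code{counts} (named vector \code{count}, \code{n_up},
#'   \code{n_down}) and \code{studyId}.
#' @export
callDEGs <- function(log2fc, pRaw, pFdr = NULL, pThreshold = 0.05,
                     lfcThreshold = 1.5, useFdr = FALSE,
                     studyId = NA_character_) {
    stopifnot(length(log2fc) == length(pRaw))
    if (is.null(pFdr))
        pFdr <- bhAdjust(pRaw)
    pUse <- if (useFdr) pFdr else pRaw
    call <- rep("none", length(log2fc))
    call[log2fc >= lfcThreshold & pUse < pThreshold] <- "up"
    call[log2fc <= -lfcThreshold & pUse < pThreshold] <- "down"
    out <- data.frame(log2fc = log2fc, p_raw = pRaw, p_fdr = pFdr,
                      call = call,
                      row.names = names(log2fc) %||%
                          as.character(seq_along(log2fc)))
    attr(out, "counts") <- c(count = sum(call != "none"),
                             n_up = sum(call == "up"),
                             n_down = sum(call == "down"))
    attr(out, "studyId") <- studyId
    class(out) <- c("DEResult", "data.frame")
    out
}

#' Run the per-study differential expression analysis
#'
#' Test statistics are computed on the standardized matrix (they are
#' invariant to per-gene affine rescaling, so this equals testing the
#' unstandardized values) and log2 fold changes on the unstandardized
#' matrix.
#'
#' @param lfcMatrix unstandardized gene-level log2 matrix.
#' @param testMatrix standardized matrix (defaults to
#'   \code{standardizeGenes(lfcMatrix)}).
#' @param groups per-sample group labels.
#' @param variant t-test variant, see [geneTTest()].
#' @inheritParams callDEGs
#' @return a \code{DEResult} as from [callDEGs()] with an extra column
#'   \code{t}.
#' @export
deAnalyze <- function(lfcMatrix, groups, testMatrix = NULL,
                      variant = c("welch", "student"), pThreshold = 0.05,
                      lfcThreshold = 1.5, useFdr = FALSE,
                      studyId = NA_character_) {
    if (is.null(testMatrix))
        testMatrix <- standardizeGenes(lfcMatrix)
    tt <- geneTTest(testMatrix, groups, variant = match.arg(variant))
    lfc <- log2FoldChange(lfcMatrix, groups)
    out <- callDEGs(lfc, tt$p, pThreshold = pThreshold,
                    lfcThreshold = lfcThreshold, useFdr = useFdr,
                    studyId = studyId)
    out$t <- tt$t
    out
}

#' Cross-study consensus DEGs
#'
#' Genes called (up or down) in at least \code{minSupport} studies.
#' Direction conflicts (up in one study, down in another) are retained --
#' presence is what is counted -- but flagged.
#'
#' @param calls list of per-study call vectors: each element a named
#'   character vector gene -> \code{"up"}/\code{"down"} covering only the
#'   called genes (see [degCalls()]), or a \code{DEResult}.
#' @param minSupport minimum number of supporting studies.
#' @return data.frame with columns \code{gene}, \code{support},
#'   \code{n_up}, \code{n_down}, \code{conflict}, sorted by decreasing
#'   support.
#' @export
consensusDEGs <- function(calls, minSupport = 3L) {
    calls <- lapply(calls, degCalls)
    if (minSupport > length(calls))
        stop("minSupport exceeds the number of studies")
    allGenes <- unique(unlist(lapply(calls, names)))
    if (!length(allGenes))
        return(data.frame(gene = character(), support = integer(),
                          n_up = integer(), n_down = integer(),
                          conflict = logical()))
    up <- rowSums(vapply(calls, function(cl)
        allGenes %in% names(cl)[cl == "up"], logical(length(allGenes))))
    dn <- rowSums(vapply(calls, function(cl)
        allGenes %in% names(cl)[cl == "down"], logical(length(allGenes))))
    support <- up + dn
    keep <- support >= minSupport
    out <- data.frame(gene = allGenes, support = as.integer(support),
                      n_up = as.integer(up), n_down = as.integer(dn),
                      conflict = up > 0 & dn > 0,
                      stringsAsFactors = FALSE)[keep, , drop = FALSE]
    out <- out[order(-out$support, out$gene), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Extract the called genes of a DEResult as a named direction vector
#'
#' @param x a \code{DEResult} (or an already-extracted named vector,
#'   returned unchanged).
#' @return named character vector gene -> \code{"up"}/\code{"down"}.
#' @export
degCalls <- function(x) {
    if (inherits(x, "DEResult") || is.data.frame(x)) {
        keep <- x$call != "none"
        return(stats::setNames(as.character(x$call[keep]),
                               rownames(x)[keep]))
    }
    x
}
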