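#' Read a study manifest
#'
#' The manifest is a tab-separated table with one row per microarray series
#' and (at least) the columns \code{series_id}, \code{species},
#' \code{n_mcao}, \code{n_sham} and \code{platform}.  Optional columns:
#' \code{ischemic_period_min} (number or NA), \code{reperfusion_period_h}
#' (comma-separated list or NA) and \code{path} (location of the study's
#' expression matrix).  \code{species} must be \code{"mouse"} or
#' \code{"rat"}; "NA" cells are parsed as missing.
#'
#' @param path path to the manifest TSV.
#' @return a \code{data.frame} of class \code{StudyManifest}, one row per
#'   series, with \code{reperfusion_period_h} as a list column of numeric
#'   vectors.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("series_id\tspecies\tn_mcao\tn_sham\tplatform",
#'              "GSE1\tmouse\t5\t5\tchipA"), tf)
#' readManifest(tf)
#' @export
readManifest <- function(path) {
    if (!file.exists(path))
        stop("manifest file not found: ", path)
    df <- utils::read.delim(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE, na.strings = "NA",
                            check.names = FALSE)
    required <- c("series_id", "species", "n_mcao", "n_sham", "platform")
    missingCols <- setdiff(required, colnames(df))
    if (length(missingCols))
        stop("manifest is missing required column(s): ",
             paste(missingCols, collapse = ", "))
    if (nrow(df)) {
        if (anyDuplicated(df$series_id))
            stop("duplicate series_id in manifest")
        if (!all(df$species %in% c("mouse", "rat")))
            stop("species must be 'mouse' or 'rat'")
        if (any(is.na(df$n_mcao)) || any(is.na(df$n_sham)) ||
            any(df$n_mcao < 1) || any(df$n_sham < 1))
            stop("sample counts n_mcao and n_sham must be >= 1")
    }
    if ("reperfusion_period_h" %in% colnames(df)) {
        df$reperfusion_period_h <- lapply(
            as.character(df$reperfusion_period_h),
            function(x) if (is.na(x)) NA_real_
                        else as.numeric(strsplit(x, ",\\s*")[[1]]))
    }
    class(df) <- c("StudyManifest", "data.frame")
    df
}

#' Write a study manifest
#'
#' Inverse of [readManifest()]: multi-valued \code{reperfusion_period_h}
#' entries are re-serialized as comma-separated lists so that
#' \code{writeManifest(readManifest(x))} round-trips.
#'
#' @param m a \code{StudyManifest}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeManifest <- function(m, path) {
    out <- as.data.frame(m)
    if ("reperfusion_period_h" %in% colnames(out))
        out$reperfusion_period_h <- vapply(out$reperfusion_period_h,
            function(x) if (all(is.na(x))) "NA"
                        else paste(x, collapse = ", "),
            character(1))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    invisible(path)
}

#' Summarize a study manifest
#'
#' Per-species and total study and sample counts, the bookkeeping usually
#' reported alongside study-characteristics tables (e.g. "65 MCAO and 36
#' sham animals across 8 series").
#'
#' @param m a \code{StudyManifest} from [readManifest()].
#' @return a \code{data.frame} with one row per species plus a
#'   \code{"total"} row and columns \code{n_studies}, \code{n_mcao},
#'   \code{n_sham}.
#' @export
summarizeManifest <- function(m) {
    species <- sort(unique(as.character(m$species)))
    rows <- lapply(species, function(sp) {
        sub <- m[m$species == sp, , drop = FALSE]
        data.frame(species = sp, n_studies = nrow(sub),
                   n_mcao = sum(sub$n_mcao), n_sham = sum(sub$n_sham),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, c(rows, list(data.frame(
        species = "total", n_studies = nrow(m),
        n_mcao = sum(m$n_mcao), n_sham = sum(m$n_sham),
        stringsAsFactors = FALSE))))
    if (!nrow(m)) out[out$species == "total", c("n_mcao", "n_sham")] <- 0L
    rownames(out) <- out$species
    out
}

#' Read an expression matrix with group labels
#'
#' Expects a tab-separated file whose first column holds feature (probe or
#' gene) identifiers and whose remaining columns are samples.  Empty cells
#' and "NA" become missing values.  Every sample column must appear in
#' \code{groupMap}.  Duplicate feature ids are legal at probe level only.
#'
#' @param path path to the TSV file.
#' @param groupMap named character vector mapping sample id to
#'   \code{"MCAO"} or \code{"sham"}.
#' @param studyId study identifier stored in the result.
#' @param level \code{"probe"} or \code{"gene"}.
#' @param alreadyLog are the values already on the log2 scale?
#' @return a [StudyExpression-class].
#' @export
readExpressionMatrix <- function(path, groupMap, studyId,
                                 level = c("gene", "probe"),
                                 alreadyLog = TRUE) {
    level <- match.arg(level)
    df <- utils::read.delim(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE,
                            na.strings = c("NA", ""), check.names = FALSE)
    features <- as.character(df[[1L]])
    vals <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(vals) <- "double"
    rownames(vals) <- features
    unmapped <- setdiff(colnames(vals), names(groupMap))
    if (length(unmapped))
        stop("sample(s) without a group label: ",
             paste(unmapped, collapse = ", "))
    if (level == "gene" && anyDuplicated(features))
        stop("duplicate feature ids at gene level: ",
             paste(unique(features[duplicated(features)]), collapse = ", "))
    StudyExpression(vals, groupMap[colnames(vals)], studyId = studyId,
                    level = level, alreadyLog = alreadyLog)
}

#' Write a StudyExpression matrix to TSV
#'
#' @param x a [StudyExpression-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeExpressionMatrix <- function(x, path) {
    df <- data.frame(feature_id = rownames(x), exprs(x),
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    invisible(path)
}

#' Read a GMT gene-set file
#'
#' Broad-dialect GMT: one set per line, tab-separated fields
#' \code{set_id}, \code{description}, members...  Member symbols are
#' upper-cased (so mouse "Timp1", rat "Timp1" and a human-centric "TIMP1"
#' collection all match) and de-duplicated within a set.
#'
#' @param path path to the GMT file.
#' @return a [GeneSetCollection-class].
#' @export
readGMT <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(fields) < 3L)
    if (length(bad))
        stop("GMT line ", bad[1L], " has fewer than 3 fields")
    ids <- vapply(fields, `[[`, character(1), 1L)
    if (anyDuplicated(ids))
        stop("duplicate set ids in GMT: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    descs <- vapply(fields, `[[`, character(1), 2L)
    sets <- lapply(fields, function(f) unique(toupper(f[-(1:2)])))
    names(sets) <- ids
    GeneSetCollection(sets, descs)
}

#' Write a GeneSetCollection to GMT
#'
#' @param x a [GeneSetCollection-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGMT <- function(x, path) {
    descs <- setDescriptions(x)
    lines <- vapply(names(x), function(id)
        paste(c(id, descs[[id]], geneSets(x)[[id]]), collapse = "\t"),
        character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Read a weighted protein-interaction edge list
#'
#' Tab-separated file with columns \code{geneA}, \code{geneB},
#' \code{score} (confidence in [0, 1]), as exported from interaction
#' databases.  The graph is undirected; self-loops are dropped and
#' duplicate edges keep the maximum score.  Node symbols are upper-cased.
#'
#' @param path path to the edge-list TSV.
#' @return an \link[igraph]{igraph} graph with a \code{score} edge
#'   attribute.
#' @export
readEdgeList <- function(path) {
    df <- utils::read.delim(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE, check.names = FALSE)
    if (ncol(df) < 3L)
        stop("edge list needs columns geneA, geneB, score")
    score <- as.numeric(df[[3L]])
    if (any(is.na(score)) || any(score < 0) || any(score > 1))
        stop("edge scores must lie in [0, 1]")
    edges <- data.frame(from = toupper(as.character(df[[1L]])),
                        to = toupper(as.character(df[[2L]])),
                        score = score, stringsAsFactors = FALSE)
    g <- igraph::graph_from_data_frame(edges, directed = FALSE)
    igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                     edge.attr.comb = list(score = "max"))
}

#' Write a result table to TSV
#'
#' Serializes a per-gene result table (data.frame or DataFrame) with a
#' header row; \code{NA}/\code{NaN} values are written as "NA" and
#' numeric values at full precision so a round trip through
#' [readResultTable()] recovers them to at least 10 significant digits.
#'
#' @param t table with one row per gene.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeResultTable <- function(t, path) {
    df <- as.data.frame(t)
    if (anyDuplicated(colnames(df)))
        stop("result table column names must be unique")
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(v) {
        out <- sprintf("%.15g", v)
        out[is.na(v)] <- "NA"
        out
    })
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    invisible(path)
}

#' Read a result table written by [writeResultTable()]
#'
#' @param path path to the TSV file.
#' @return a \code{data.frame}.
#' @export
readResultTable <- function(path) {
    utils::read.delim(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE, na.strings = "NA",
                      check.names = FALSE)
}
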