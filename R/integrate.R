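#' Filter meta-DEGs by per-study support
#'
#' Keeps the meta-analysis DEGs that were also called in at least
#' \code{minSupport} individual studies -- the validation step that
#' raises positive predictive power by demanding that pooled signal shows
#' up in the single datasets too.  The result is always a subset of the
#' meta set.
#'
#' @param metaDegs character vector of meta-DEG symbols.
#' @param perStudyCalls list of per-study call vectors (named
#'   gene -> direction, see [degCalls()]) or \code{DEResult} objects.
#' @param minSupport minimum number of supporting studies (0 keeps the
#'   meta set unchanged).
#' @return character vector, sorted.
#' @export
integrateSets <- function(metaDegs, perStudyCalls, minSupport = 3L) {
    perStudyCalls <- lapply(perStudyCalls, degCalls)
    if (minSupport > length(perStudyCalls))
        stop("minSupport exceeds the number of studies")
    if (!length(metaDegs)) {
        warning("empty meta-DEG set; integrated set is empty")
        return(character())
    }
    support <- rowSums(vapply(perStudyCalls,
        function(cl) metaDegs %in% names(cl), logical(length(metaDegs))))
    sort(metaDegs[support >= minSupport])
}

#' Cross-species common genes by case-insensitive symbol match
#'
#' Rodent gene symbols differ only in capitalization conventions between
#' species-specific annotations, so the intersection is taken on
#' upper-cased symbols; the original spellings are reported alongside.
#' True orthology resolution is out of scope.
#'
#' @param setA,setB character vectors of gene symbols.
#' @return data.frame with columns \code{symbol} (upper case),
#'   \code{spelling_a}, \code{spelling_b}.
#' @export
crossSpeciesCommon <- function(setA, setB) {
    ua <- toupper(setA); ub <- toupper(setB)
    common <- sort(intersect(ua, ub))
    data.frame(symbol = common,
               spelling_a = setA[match(common, ua)],
               spelling_b = setB[match(common, ub)],
               stringsAsFactors = FALSE)
}

#' Hypergeometric gene-set over-representation test
#'
#' For each set, with N = |universe|, K = |set intersected with
#' universe|, n = |query| and x = |query intersected with set|, the
#' enrichment p-value is P(X >= x) for X ~ hypergeometric(N, K, n).  Raw
#' p-values carry the conventional p < 0.05 gate; a BH-adjusted column is
#' reported alongside but not used for the gate.
#'
#' @param query character vector of gene symbols (the DEG list).
#' @param collection a [GeneSetCollection-class].
#' @param universe character vector: all genes that could have been
#'   selected (here, the common-gene intersection of the analyzed
#'   studies -- genes outside the measured matrix could never be called).
#' @return data.frame sorted by \code{p_hyper}, with columns
#'   \code{set_id}, \code{description}, \code{n_set}, \code{n_hits},
#'   \code{percent} (100 x hits / |query|), \code{p_hyper}, \code{p_adj}.
#' @export
hypergeomEnrich <- function(query, collection, universe) {
    stopifnot(is(collection, "GeneSetCollection"))
    universe <- unique(toupper(universe))
    query <- unique(toupper(query))
    if (!length(universe) || !length(query))
        stop("query and universe must be non-empty")
    outside <- setdiff(query, universe)
    if (length(outside)) {
        warning(length(outside), " query gene(s) outside the universe ",
                "dropped")
        query <- intersect(query, universe)
        if (!length(query)) stop("no query genes left in the universe")
    }
    N <- length(universe)
    n <- length(query)
    rows <- lapply(names(collection), function(id) {
        members <- intersect(geneSets(collection)[[id]], universe)
        K <- length(members)
        x <- length(intersect(query, members))
        p <- stats::phyper(x - 1L, K, N - K, n, lower.tail = FALSE)
        data.frame(set_id = id,
                   description = setDescriptions(collection)[[id]],
                   n_set = K, n_hits = x, percent = 100 * x / n,
                   p_hyper = p, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$p_adj <- bhAdjust(out$p_hyper)
    out <- out[order(out$p_hyper, out$set_id), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Extract the DEG-induced subnetwork from an interaction graph
#'
#' Induced subgraph on the given genes, keeping edges at or above a
#' confidence threshold, with per-node degrees; the maximum-degree
#' node(s) are reported as the hub (the simplest quantitative hub
#' notion).
#'
#' @param graph an \link[igraph]{igraph} graph with a \code{score} edge
#'   attribute, e.g. from [readEdgeList()].
#' @param genes character vector of gene symbols.
#' @param minScore minimum edge confidence kept (default 0.4, the common
#'   mid-confidence convention).
#' @return list with \code{graph} (the subgraph), \code{degrees} (named,
#'   sorted decreasing) and \code{hub} (character vector of
#'   maximum-degree nodes; empty for an edgeless graph).
#' @export
extractSubnetwork <- function(graph, genes, minScore = 0.4) {
    nodes <- intersect(toupper(genes), igraph::V(graph)$name)
    sub <- igraph::induced_subgraph(graph, nodes)
    keep <- igraph::E(sub)$score >= minScore
    sub <- igraph::subgraph_from_edges(sub, igraph::E(sub)[keep],
                                       delete.vertices = FALSE)
    deg <- sort(igraph::degree(sub), decreasing = TRUE)
    hub <- if (length(deg) && max(deg) > 0)
        names(deg)[deg == max(deg)] else character()
    list(graph = sub, degrees = deg, hub = hub)
}

#' Default pipeline configuration
#'
#' @param seed master seed; every stage seed is derived from it.
#' @param simulation named list of overrides for [simConfig()] (applied
#'   to both species).
#' @param ... named overrides for the remaining blocks (\code{de},
#'   \code{meta}, \code{consensus_min_support},
#'   \code{integration_min_support}, \code{enrichment}, \code{network}).
#' @return nested configuration list.
#' @export
pipelineConfig <- function(seed = 1L, simulation = list(), ...) {
    cfg <- list(
        seed = as.integer(seed),
        species = c("mouse", "rat"),
        simulation = simulation,
        de = list(p_threshold = 0.05, lfc_threshold = 1.5,
                  use_fdr = FALSE, variant = "welch"),
        meta = list(alpha = 0.05, min_methods = 4L, B = 1000L,
                    moderated = FALSE),
        consensus_min_support = 3L,
        integration_min_support = 3L,
        enrichment = list(n_sets = 20L, enriched_fraction = 0.3,
                          p_threshold = 0.05),
        network = list(min_score = 0.4, background_edges = 500L))
    dots <- list(...)
    for (nm in names(dots)) {
        if (is.list(cfg[[nm]]) && is.list(dots[[nm]]))
            cfg[[nm]] <- utils::modifyList(cfg[[nm]], dots[[nm]])
        else cfg[[nm]] <- dots[[nm]]
    }
    cfg
}

#' Run the full synthetic-data meta-analysis pipeline
#'
#' Simulates one study collection per species sharing the same true DEG
#' memberships, then runs, per species: preprocessing, per-study
#' differential expression with cross-study consensus, the five-method
#' meta-analysis with vote counting, integration of meta-DEGs with
#' per-study calls, hypergeometric enrichment of the meta set against a
#' simulated GMT, and subnetwork extraction on the integrated set; last,
#' the cross-species symbol intersection.  All randomness derives from
#' \code{config$seed}, so the same configuration reproduces identical
#' results (and byte-identical written tables).
#'
#' @param config a [pipelineConfig()] list, or the path of a YAML file
#'   holding one.
#' @param outdir optional directory; when given, per-stage result tables
#'   and a machine-readable run log (YAML) are written there.
#' @return list with one element per species (\code{de}, \code{deCounts},
#'   \code{consensus}, \code{meta}, \code{integrated}, \code{enrichment},
#'   \code{subnetwork}, \code{common}, \code{truth}), plus
#'   \code{crossSpecies} (data.frame from [crossSpeciesCommon()]),
#'   \code{recovery} (fraction of analyzable shared true DEGs present in
#'   the cross-species set) and \code{log}.
#' @export
runPipeline <- function(config = pipelineConfig(), outdir = NULL) {
    if (is.character(config))
        config <- yaml::read_yaml(config)
    cfg <- do.call(pipelineConfig,
                   c(config[setdiff(names(config), "species")],
                     list()))
    if (!is.null(config$species)) cfg$species <- config$species
    seed <- cfg$seed
    truthShared <- NULL
    speciesRes <- list()
    for (i in seq_along(cfg$species)) {
        sp <- cfg$species[[i]]
        simCfg <- do.call(simConfig, utils::modifyList(
            list(species_label = sp, seed = seed + 101L * i),
            cfg$simulation))
        sim <- simulateCollection(simCfg, truth = truthShared)
        if (is.null(truthShared)) truthShared <- sim$truth
        prep <- preprocessStudies(sim$studies, sim$probeMap)
        de <- lapply(names(prep$studies), function(id)
            deAnalyze(exprs(prep$studies[[id]]),
                      groups(prep$studies[[id]]),
                      testMatrix = prep$standardized[[id]],
                      variant = cfg$de$variant,
                      pThreshold = cfg$de$p_threshold,
                      lfcThreshold = cfg$de$lfc_threshold,
                      useFdr = cfg$de$use_fdr, studyId = id))
        names(de) <- names(prep$studies)
        deCounts <- do.call(rbind, lapply(de, function(d)
            as.data.frame(t(attr(d, "counts")))))
        deCounts <- data.frame(study = names(de), deCounts,
                               row.names = NULL)
        consensus <- consensusDEGs(de,
            minSupport = cfg$consensus_min_support)
        meta <- metaAnalyze(prep, alpha = cfg$meta$alpha,
                            minMethods = cfg$meta$min_methods,
                            B = cfg$meta$B, seed = seed + 500L + i,
                            variant = cfg$de$variant,
                            moderated = cfg$meta$moderated)
        integrated <- integrateSets(metaDegs(meta), de,
            minSupport = cfg$integration_min_support)
        enrFrac <- cfg$enrichment$enriched_fraction
        if (!length(c(sim$truth$degUp, sim$truth$degDown)))
            enrFrac <- 0  # null collection: only background sets exist
        gmt <- simulateGeneSets(sim$truth,
            nSets = cfg$enrichment$n_sets,
            enrichedFraction = enrFrac,
            seed = seed + 700L)
        enr <- hypergeomEnrich(metaDegs(meta), gmt, prep$common)
        net <- simulateEdgeList(sim$truth,
            backgroundEdges = cfg$network$background_edges,
            seed = seed + 800L)
        subnet <- extractSubnetwork(net, integrated,
            minScore = cfg$network$min_score)
        speciesRes[[sp]] <- list(de = de, deCounts = deCounts,
            consensus = consensus, meta = meta, integrated = integrated,
            enrichment = enr, subnetwork = subnet, common = prep$common,
            truth = sim$truth, qc = prep$qc)
    }
    sets <- lapply(speciesRes, `[[`, "integrated")
    cross <- crossSpeciesCommon(sets[[1L]], sets[[2L]])
    # recovery: shared true DEGs measurable in both species' universes
    truthSyms <- toupper(c(truthShared$degUp, truthShared$degDown))
    analyzable <- Reduce(intersect, lapply(speciesRes, function(r)
        intersect(truthSyms, toupper(r$common))))
    recovery <- if (length(analyzable))
        length(intersect(cross$symbol, analyzable)) / length(analyzable)
    else NA_real_
    log <- list(
        parameters = cfg,
        counts = lapply(speciesRes, function(r) list(
            common_genes = length(r$common),
            per_study = r$deCounts,
            consensus_degs = nrow(r$consensus),
            meta_degs = sum(r$meta$is_meta_deg),
            integrated_degs = length(r$integrated))),
        cross_species = nrow(cross),
        recovery = recovery)
    out <- c(speciesRes, list(crossSpecies = cross, recovery = recovery,
                              log = log))
    if (!is.null(outdir)) {
        dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
        for (sp in names(speciesRes)) {
            r <- speciesRes[[sp]]
            writeResultTable(
                data.frame(gene = rownames(r$meta),
                           as.data.frame(r$meta)),
                file.path(outdir, paste0(sp, "_meta.tsv")))
            writeResultTable(r$deCounts,
                file.path(outdir, paste0(sp, "_de_counts.tsv")))
            writeResultTable(r$consensus,
                file.path(outdir, paste0(sp, "_consensus.tsv")))
            writeResultTable(r$enrichment,
                file.path(outdir, paste0(sp, "_enrichment.tsv")))
            writeLines(r$integrated,
                file.path(outdir, paste0(sp, "_integrated.txt")))
        }
        writeResultTable(cross, file.path(outdir, "cross_species.tsv"))
        logOut <- log
        logOut$counts <- lapply(logOut$counts, function(x) {
            x$per_study <- as.list(x$per_study); x })
        yaml::write_yaml(logOut, file.path(outdir, "run_log.yaml"))
    }
    out
}
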