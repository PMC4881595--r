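#' Simulation configuration for synthetic multi-study collections
#'
#' Bundles the parameters of the synthetic-data generator.  Defaults
#' describe the study conditions the pipeline is aimed at: four series per
#' species with MCAO and sham groups sized like typical rodent ischemia
#' microarray experiments (mean group sizes of the motivating
#' eight-series collection: about 8 MCAO and 5 sham animals per series),
#' a 5% fraction of truly regulated genes with a standardized shift of 2
#' within-study SDs, mild between-study heterogeneity, and low rates of
#' missing cells and platform-specific gene dropout.
#'
#' @param n_genes number of genes in the simulated genome.
#' @param k_studies number of studies in the collection.
#' @param species_label label used in study and sample ids.
#' @param n_mcao,n_sham per-study group sizes (MCAO must be >= 2 so
#'   within-group variances exist downstream).
#' @param frac_deg fraction of genes that are truly differentially
#'   expressed (half up-, half down-regulated in MCAO).
#' @param delta true standardized effect size, in units of the
#'   within-study SD (which is 1 on the simulated log2 scale).
#' @param tau2 between-study variance of the per-study realized effect.
#' @param missing_rate fraction of cells set to \code{NA}.
#' @param platform_dropout per-study probability that a gene is absent
#'   from the platform (independent across studies and genes).
#' @param probes_per_gene single positive integer, or length-2 integer
#'   range from which each gene's per-study probe count is drawn
#'   uniformly.
#' @param seed integer seed; the same configuration always generates the
#'   same collection.
#' @return a list of class \code{SimulationConfig}.
#' @export
simConfig <- function(n_genes = 2000L, k_studies = 4L,
                      species_label = "mouse", n_mcao = 8L, n_sham = 5L,
                      frac_deg = 0.05, delta = 2, tau2 = 0.05,
                      missing_rate = 0.02, platform_dropout = 0.05,
                      probes_per_gene = 1L, seed = 1L) {
    cfg <- list(n_genes = as.integer(n_genes),
                k_studies = as.integer(k_studies),
                species_label = as.character(species_label),
                n_mcao = as.integer(n_mcao), n_sham = as.integer(n_sham),
                frac_deg = frac_deg, delta = delta, tau2 = tau2,
                missing_rate = missing_rate,
                platform_dropout = platform_dropout,
                probes_per_gene = as.integer(probes_per_gene),
                seed = as.integer(seed))
    stopifnot(cfg$n_genes >= 1L, cfg$k_studies >= 1L,
              cfg$n_sham >= 1L,
              cfg$frac_deg >= 0, cfg$frac_deg <= 1,
              cfg$delta >= 0, cfg$tau2 >= 0,
              cfg$missing_rate >= 0, cfg$missing_rate < 1,
              cfg$platform_dropout >= 0, cfg$platform_dropout < 1,
              all(cfg$probes_per_gene >= 1L),
              length(cfg$probes_per_gene) %in% 1:2)
    if (cfg$n_mcao < 2L)
        stop("n_mcao must be >= 2 (within-group variance is needed ",
             "downstream)")
    if (cfg$frac_deg > 0 && round(cfg$frac_deg * cfg$n_genes) < 1)
        stop("frac_deg * n_genes must round to at least one gene")
    class(cfg) <- "SimulationConfig"
    cfg
}

#' @export
print.SimulationConfig <- function(x, ...) {
    cat("SimulationConfig:", x$n_genes, "genes,", x$k_studies,
        "studies (", x$n_mcao, "MCAO /", x$n_sham, "sham each ),",
        sprintf("%.0f%% DEGs, delta=%g, tau2=%g, seed=%d",
                100 * x$frac_deg, x$delta, x$tau2, x$seed), "\n")
    invisible(x)
}

#' Simulate a multi-study expression collection with known truth
#'
#' Generates \code{k_studies} probe- or gene-level [StudyExpression-class]
#' objects on the log2 scale.  Null genes are Normal(baseline, 1) in both
#' groups; for each true DEG, study \emph{s} shifts its MCAO mean by a
#' per-study effect drawn from Normal(+/-delta, tau2) (sign given by
#' up/down membership).  Each study then independently loses
#' \code{platform_dropout} of genes (platform-specific content), expands
#' genes to probes (probe value = gene value + Normal(0, 0.1) measurement
#' noise) and sets \code{missing_rate} of cells to \code{NA}.
#'
#' @param cfg a [simConfig()] object.
#' @param truth optional \code{SimulatedTruth} from a previous call; when
#'   supplied, its up/down gene memberships are reused so a second species
#'   shares the same true DEGs (per-study realized effects are redrawn).
#' @param rawScale emit \code{2^x} "raw intensity" values (with the
#'   already-log flag unset) instead of log2-scale values, to exercise
#'   [log2Transform()].
#' @return a list with elements \code{studies} (list of
#'   [StudyExpression-class]), \code{truth} (class \code{SimulatedTruth}:
#'   \code{degUp}, \code{degDown}, \code{effects} gene-by-study matrix of
#'   realized shifts, \code{config}) and \code{probeMap} (named character
#'   vector probe -> gene; \code{NULL} when \code{probes_per_gene} is 1).
#' @examples
#' sim <- simulateCollection(simConfig(n_genes = 200, seed = 7))
#' length(sim$studies); head(sim$truth$degUp)
#' @export
simulateCollection <- function(cfg, truth = NULL, rawScale = FALSE) {
    stopifnot(inherits(cfg, "SimulationConfig"))
    set.seed(cfg$seed)
    genes <- sprintf("Gene%05d", seq_len(cfg$n_genes))
    nDeg <- round(cfg$frac_deg * cfg$n_genes)
    if (is.null(truth)) {
        degAll <- sample(genes, nDeg)
        degUp <- sort(degAll[seq_len(ceiling(nDeg / 2))])
        degDown <- sort(setdiff(degAll, degUp))
    } else {
        degUp <- truth$degUp
        degDown <- truth$degDown
        stopifnot(all(c(degUp, degDown) %in% genes))
    }
    baseline <- stats::runif(cfg$n_genes, 6, 10)
    names(baseline) <- genes
    sign <- numeric(cfg$n_genes)
    names(sign) <- genes
    sign[degUp] <- 1
    sign[degDown] <- -1
    effects <- matrix(0, cfg$n_genes, cfg$k_studies,
                      dimnames = list(genes, NULL))
    isDeg <- sign != 0
    nTotal <- cfg$n_mcao + cfg$n_sham
    groups <- rep(c("MCAO", "sham"), c(cfg$n_mcao, cfg$n_sham))
    studies <- vector("list", cfg$k_studies)
    probeMapAll <- character()
    for (s in seq_len(cfg$k_studies)) {
        sid <- sprintf("%s_S%d", cfg$species_label, s)
        colnames(effects) <- NULL
        if (any(isDeg))
            effects[isDeg, s] <- stats::rnorm(sum(isDeg),
                mean = sign[isDeg] * cfg$delta, sd = sqrt(cfg$tau2))
        vals <- matrix(stats::rnorm(cfg$n_genes * nTotal, mean = baseline),
                       nrow = cfg$n_genes)
        vals[, seq_len(cfg$n_mcao)] <- vals[, seq_len(cfg$n_mcao)] +
            effects[, s]
        rownames(vals) <- genes
        keep <- stats::runif(cfg$n_genes) >= cfg$platform_dropout
        vals <- vals[keep, , drop = FALSE]
        # probe expansion
        ppg <- cfg$probes_per_gene
        level <- "gene"
        if (length(ppg) == 2L) {
            pool <- seq(ppg[1L], ppg[2L])
            ppg <- pool[sample.int(length(pool), nrow(vals),
                                   replace = TRUE)]
        }
        if (any(ppg > 1L)) {
            ppg <- rep(ppg, length.out = nrow(vals))
            rows <- rep(seq_len(nrow(vals)), ppg)
            probeIds <- paste0(rownames(vals)[rows], "_p",
                               sequence(ppg))
            vals <- vals[rows, , drop = FALSE] +
                matrix(stats::rnorm(length(rows) * nTotal, sd = 0.1),
                       nrow = length(rows))
            rownames(vals) <- probeIds
            probeMapAll <- c(probeMapAll,
                stats::setNames(sub("_p[0-9]+$", "", probeIds), probeIds))
            level <- "probe"
        }
        if (cfg$missing_rate > 0) {
            drop <- stats::runif(length(vals)) < cfg$missing_rate
            vals[drop] <- NA
            # a fully missing row cannot be imputed; keep one observation
            allGone <- rowSums(!is.na(vals)) == 0L
            if (any(allGone))
                vals[allGone, 1L] <- baseline[sub("_p[0-9]+$", "",
                                              rownames(vals)[allGone])]
        }
        if (rawScale) vals <- 2^vals
        colnames(vals) <- sprintf("%s_%s%d", sid, tolower(groups),
                                  stats::ave(seq_len(nTotal), groups,
                                             FUN = seq_along))
        studies[[s]] <- StudyExpression(vals, groups, studyId = sid,
                                        level = level,
                                        alreadyLog = !rawScale)
    }
    truthOut <- structure(list(degUp = degUp, degDown = degDown,
                               effects = effects, config = cfg),
                          class = "SimulatedTruth")
    probeMap <- if (length(probeMapAll))
        probeMapAll[!duplicated(names(probeMapAll))] else NULL
    list(studies = studies, truth = truthOut, probeMap = probeMap)
}

#' @export
print.SimulatedTruth <- function(x, ...) {
    cat("SimulatedTruth:", length(x$degUp), "up /", length(x$degDown),
        "down true DEGs of", nrow(x$effects), "genes in",
        ncol(x$effects), "studies\n")
    invisible(x)
}

#' Simulate a gene-set collection matched to a simulated truth
#'
#' Builds \code{nSets} gene sets over the simulated genome.  A fraction of
#' them are constructed as truly enriched: 70% of their members are drawn
#' from the true DEGs (comfortably above the half-and-half mark), the rest
#' uniformly from the remaining genes.  Background sets draw uniformly
#' from all genes.  Which sets are enriched is recorded in the
#' descriptions (\code{"enriched"} vs \code{"background"}).
#'
#' @param truth a \code{SimulatedTruth} from [simulateCollection()].
#' @param nSets number of sets.
#' @param enrichedFraction fraction of sets built as enriched.
#' @param setSizeRange length-2 integer range of set sizes (uniform).
#' @param seed integer seed.
#' @return a [GeneSetCollection-class].
#' @export
simulateGeneSets <- function(truth, nSets = 10L, enrichedFraction = 0.3,
                             setSizeRange = c(10L, 40L), seed = 1L) {
    stopifnot(inherits(truth, "SimulatedTruth"), nSets >= 1L,
              enrichedFraction >= 0, enrichedFraction <= 1)
    universe <- rownames(truth$effects)
    deg <- c(truth$degUp, truth$degDown)
    if (!length(deg) && enrichedFraction > 0)
        stop("cannot build enriched sets from an empty truth")
    if (max(setSizeRange) > length(universe))
        stop("set size exceeds the number of simulated genes")
    set.seed(seed)
    nEnr <- round(enrichedFraction * nSets)
    sets <- vector("list", nSets)
    descs <- character(nSets)
    sizePool <- seq(setSizeRange[1L], setSizeRange[2L])
    for (i in seq_len(nSets)) {
        size <- sizePool[sample.int(length(sizePool), 1L)]
        if (i <= nEnr) {
            nFromDeg <- min(ceiling(0.7 * size), length(deg))
            members <- c(sample(deg, nFromDeg),
                         sample(setdiff(universe, deg), size - nFromDeg))
            descs[i] <- "enriched"
        } else {
            members <- sample(universe, size)
            descs[i] <- "background"
        }
        sets[[i]] <- members
    }
    names(sets) <- sprintf("SET%03d", seq_len(nSets))
    GeneSetCollection(sets, descs)
}

#' Simulate a protein-interaction edge list over the simulated genome
#'
#' Random undirected graph in which pairs of true DEGs are wired with a
#' higher probability (and higher confidence scores) than background
#' pairs, so that subnetwork extraction on recovered DEGs has edges to
#' find.
#'
#' @param truth a \code{SimulatedTruth}.
#' @param backgroundEdges number of uniformly random background edges.
#' @param degEdgeProb probability of an edge between any two true DEGs.
#' @param seed integer seed.
#' @return an \link[igraph]{igraph} graph with a \code{score} attribute.
#' @export
simulateEdgeList <- function(truth, backgroundEdges = 500L,
                             degEdgeProb = 0.2, seed = 1L) {
    stopifnot(inherits(truth, "SimulatedTruth"))
    set.seed(seed)
    universe <- toupper(rownames(truth$effects))
    deg <- toupper(c(truth$degUp, truth$degDown))
    bg <- matrix(sample(universe, 2L * backgroundEdges, replace = TRUE),
                 ncol = 2L)
    bg <- bg[bg[, 1L] != bg[, 2L], , drop = FALSE]
    edges <- data.frame(from = bg[, 1L], to = bg[, 2L],
                        score = stats::runif(nrow(bg), 0.15, 0.7),
                        stringsAsFactors = FALSE)
    if (length(deg) >= 2L) {
        pairs <- utils::combn(deg, 2L)
        pick <- stats::runif(ncol(pairs)) < degEdgeProb
        if (any(pick))
            edges <- rbind(edges, data.frame(
                from = pairs[1L, pick], to = pairs[2L, pick],
                score = stats::runif(sum(pick), 0.4, 0.99),
                stringsAsFactors = FALSE))
    }
    g <- igraph::graph_from_data_frame(edges, directed = FALSE)
    igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                     edge.attr.comb = list(score = "max"))
}
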