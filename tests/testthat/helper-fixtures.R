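# shared fixtures built in code

extdata <- function(f) system.file("extdata", f, package = "mcaoMeta")

# a tiny deterministic StudyExpression: 4 genes x (3 MCAO + 3 sham)
tinyStudy <- function(studyId = "S1", seed = 1) {
    set.seed(seed)
    m <- matrix(rnorm(24, mean = 8), 4, 6,
                dimnames = list(paste0("G", 1:4),
                                paste0(studyId, "_", 1:6)))
    StudyExpression(m, rep(c("MCAO", "sham"), each = 3), studyId)
}

# clean simulated collection used by several statistical tests
cleanSim <- function(n_genes = 400, seed = 5, ...) {
    simulateCollection(simConfig(n_genes = n_genes, missing_rate = 0,
                                 platform_dropout = 0, seed = seed, ...))
}

# bypass normalization: hand metaAnalyze the simulated matrices directly
rawPrep <- function(sim) {
    ids <- vapply(sim$studies, studyId, character(1))
    std <- lapply(sim$studies, function(s) standardizeGenes(exprs(s)))
    studies <- sim$studies
    names(studies) <- names(std) <- ids
    list(studies = studies, standardized = std,
         common = sort(rownames(exprs(studies[[1]]))))
}

writeTempTSV <- function(lines) {
    tf <- tempfile(fileext = ".tsv")
    writeLines(lines, tf)
    tf
}
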