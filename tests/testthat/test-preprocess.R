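test_that("log2 transform maps intensities and respects the already-log flag", {
    m <- matrix(c(8, 1, 2, 4), 2, 2,
                dimnames = list(c("G1", "G2"), c("a", "b")))
    se <- StudyExpression(m, c("MCAO", "sham"), "S", alreadyLog = FALSE)
    # n=1 per group is fine here; validity only needs both labels present
    out <- log2Transform(se)
    expect_equal(exprs(out), log2(m))
    expect_equal(exprs(out)["G1", "a"], 3)
    expect_equal(exprs(out)["G2", "a"], 0)
    # flagged already-log: identity
    seL <- StudyExpression(m, c("MCAO", "sham"), "S", alreadyLog = TRUE)
    expect_identical(exprs(log2Transform(seL)), m)
    # non-positive raw value names the offending cell
    m2 <- m; m2["G2", "b"] <- -1
    seB <- StudyExpression(m2, c("MCAO", "sham"), "S", alreadyLog = FALSE)
    expect_error(log2Transform(seB), "G2.*b")
})

test_that("quantile normalization equalizes column distributions", {
    m <- cbind(a = c(2, 4, 6), b = c(1, 3, 5))
    out <- quantileNormalize(m)
    expect_equal(unname(out), cbind(c(1.5, 3.5, 5.5), c(1.5, 3.5, 5.5)))
    # identical columns are a fixed point
    m2 <- cbind(c(1, 5, 9), c(1, 5, 9))
    expect_equal(quantileNormalize(m2), m2)
    # single column: no-op
    m3 <- matrix(c(3, 1, 2), 3, 1)
    expect_identical(quantileNormalize(m3), m3)
})

test_that("quantile ties receive the mean of their tied reference values", {
    m <- cbind(c(1, 1, 2), c(0, 2, 4))
    out <- quantileNormalize(m)
    # brute-force oracle: reference = sorted-row means; tied ranks 1,2 of
    # column 1 share mean(ref[1:2])
    ref <- rowMeans(apply(m, 2, sort))
    expect_equal(out[, 1], c(mean(ref[1:2]), mean(ref[1:2]), ref[3]))
    expect_equal(out[, 2], ref)
})

test_that("normalized columns share one empirical distribution exactly", {
    set.seed(42)
    m <- matrix(rnorm(200, sd = c(1, 2, 4, 8)), 50, 4)
    out <- quantileNormalize(m)
    sorted <- apply(out, 2, sort)
    # Kolmogorov distance between any two column distributions is 0
    expect_equal(max(abs(sorted - sorted[, 1])), 0, tolerance = 1e-12)
    # within-column rank order preserved
    expect_equal(apply(out, 2, rank), apply(m, 2, rank))
})

test_that("KNN imputation fills from the nearest complete neighbours", {
    # identical complete neighbours: imputed value is their shared value
    x <- rbind(A = c(1, NA, 3), B = c(1, 5, 3), C = c(1, 5, 3))
    out <- knnImpute(x, k = 2)
    expect_equal(unname(out["A", 2]), 5)
    expect_identical(out[!is.na(x)], x[!is.na(x)])  # observed untouched

    # k=1 picks the distance-0 neighbour, not the far one
    y <- rbind(A = c(0, NA, 0), B = c(0, 7, 0), C = c(9, 100, 9))
    expect_equal(unname(knnImpute(y, k = 1)["A", 2]), 7)

    # complete matrix: identity
    z <- matrix(rnorm(12), 3, 4)
    expect_identical(knnImpute(z, 2), z)

    # row entirely missing is an error; small pools warn
    w <- rbind(A = c(NA_real_, NA_real_), B = c(1, 2), C = c(2, 4))
    expect_error(knnImpute(w, 2), "entirely missing")
    expect_warning(knnImpute(rbind(A = c(1, NA), B = c(1, 5)), k = 3),
                   "fewer than k")
})

test_that("distance rescaling makes sparse overlaps comparable", {
    # neighbour B shares all 4 columns at distance 2 each ->
    # d2 = 16; C shares one column exactly (d2 = 0 over shared,
    # scaled) so C is nearer despite the tiny overlap
    x <- rbind(A = c(1, 1, 1, NA),
               B = c(3, 3, 3, 10),
               C = c(1, NA, NA, 20))
    expect_equal(unname(knnImpute(x, k = 1)["A", 4]), 20)
})

test_that("probe collapse averages a gene's probes", {
    m <- rbind(P1 = c(1, 2), P2 = c(3, 4), P3 = c(2, 2), P4 = c(6, 6),
               P5 = c(1, 1), P6 = c(10, 10))
    colnames(m) <- c("a", "b")
    se <- StudyExpression(m, c("MCAO", "sham"), "S", level = "probe")
    map <- c(P1 = "gA", P2 = "gA", P3 = "gB", P4 = "gB", P5 = "gB")
    expect_message(out <- collapseProbes(se, map), "1 unmapped")
    expect_equal(featureLevel(out), "gene")
    expect_equal(exprs(out)["gA", ], c(a = 2, b = 3))
    expect_equal(exprs(out)["gB", ], c(a = 3, b = 3))  # mean(2,6,1)=3
    # one probe per gene: identity on values
    map1 <- c(P1 = "g1", P2 = "g2", P3 = "g3", P4 = "g4", P5 = "g5",
              P6 = "g6")
    out1 <- collapseProbes(se, map1)
    expect_equal(unname(exprs(out1)[paste0("g", 1:6), ]), unname(m))
})

test_that("standardization yields mean zero, unit sample variance, idempotence", {
    m <- rbind(G1 = c(1, 2, 3), G2 = c(10, 20, 60))
    out <- standardizeGenes(m)
    expect_equal(out["G1", ], c(-1, 0, 1))
    expect_equal(unname(rowMeans(out)), c(0, 0))
    expect_equal(unname(apply(out, 1, var)), c(1, 1))
    expect_equal(standardizeGenes(out), out, tolerance = 1e-12)
    expect_error(standardizeGenes(rbind(G1 = c(1, 1, 1))), "G1")
})

test_that("common genes are the sorted intersection across studies", {
    mk <- function(genes, id) {
        m <- matrix(rnorm(2 * length(genes), 8), length(genes), 2,
                    dimnames = list(genes, c("x", "y")))
        StudyExpression(m, c("MCAO", "sham"), id)
    }
    studies <- list(mk(c("A", "B", "C"), "s1"), mk(c("D", "B", "C"), "s2"),
                    mk(c("C", "B"), "s3"))
    expect_equal(commonGenes(studies), c("B", "C"))
    same <- list(mk(c("B", "A"), "s1"), mk(c("A", "B"), "s2"))
    expect_equal(commonGenes(same), c("A", "B"))
    expect_error(commonGenes(list(mk("A", "s1"), mk("B", "s2"))),
                 "common")
})

test_that("dropout thins the common-gene set at the expected rate", {
    sim <- simulateCollection(simConfig(n_genes = 2000, k_studies = 4,
                                        platform_dropout = 0.1,
                                        missing_rate = 0, frac_deg = 0,
                                        seed = 21))
    common <- commonGenes(sim$studies)
    expec <- 2000 * 0.9^4
    sdv <- sqrt(2000 * 0.9^4 * (1 - 0.9^4))
    expect_lt(abs(length(common) - expec), 3 * sdv)
})

test_that("RLE summaries flag shifted samples", {
    m <- matrix(rep(c(1, 5, 9), 3), 3, 3)  # identical columns
    r <- qcRLE(m)
    expect_equal(r$rle_median, c(0, 0, 0))
    # one shifted column among >= 3: its RLE median is +1
    m2 <- cbind(a = c(1, 5, 9), b = c(1, 5, 9), c = c(2, 6, 10))
    r2 <- qcRLE(m2)
    expect_equal(r2$rle_median[r2$sample == "c"], 1)
    expect_equal(r2$rle_median[r2$sample == "a"], 0)
    # single gene: all RLE are zero by construction
    expect_equal(qcRLE(matrix(c(4, 4, 4), 1, 3))$rle_median, c(0, 0, 0))
})

test_that("the preprocessing chain is sample-permutation equivariant", {
    sim <- cleanSim(n_genes = 60, seed = 31)
    st <- sim$studies[[1]]
    perm <- c(4, 1, 3, 2, 5, 13, 7, 6, 12, 8, 9, 10, 11)
    stP <- StudyExpression(exprs(st)[, perm],
                           as.character(groups(st))[perm],
                           studyId = studyId(st))
    a <- preprocessStudies(list(st, sim$studies[[2]]))
    b <- preprocessStudies(list(stP, sim$studies[[2]]))
    expect_equal(exprs(b$studies[[1]])[, colnames(exprs(a$studies[[1]]))],
                 exprs(a$studies[[1]]), tolerance = 1e-12)
})

test_that("preprocessing leaves standardized complete common matrices", {
    sim <- simulateCollection(simConfig(n_genes = 150, k_studies = 3,
                                        missing_rate = 0.03,
                                        platform_dropout = 0.05,
                                        probes_per_gene = 2L, seed = 17))
    prep <- preprocessStudies(sim$studies, sim$probeMap)
    expect_equal(length(prep$studies), 3L)
    for (id in names(prep$studies)) {
        expect_identical(rownames(prep$studies[[id]]), prep$common)
        expect_false(anyNA(prep$standardized[[id]]))
        expect_equal(unname(rowMeans(prep$standardized[[id]])),
                     rep(0, length(prep$common)), tolerance = 1e-12)
    }
    expect_error(preprocessStudies(sim$studies), "probeMap")
})
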