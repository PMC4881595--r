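test_that("Hedges' g matches the hand-worked small-sample case", {
    es <- hedgesG(3, 1, 1, 3, 0, 1)  # mean diff 1, s_pooled = 1
    expect_equal(es$g, 0.8)                      # J = 1 - 3/15
    expect_equal(es$var_g, 6 / 9 + 0.64 / 12)    # = 0.72
    # equal means -> g = 0
    expect_equal(hedgesG(4, 2, 1.3, 4, 2, 0.7)$g, 0)
    # doubling both group sizes shrinks the variance
    expect_lt(hedgesG(6, 1, 1, 6, 0, 1)$var_g,
              hedgesG(3, 1, 1, 3, 0, 1)$var_g)
    # degenerate inputs
    expect_equal(hedgesG(3, 2, 0, 3, 2, 0)$g, 0)
    expect_error(hedgesG(3, 2, 0, 3, 1, 0), "zero pooled variance")
})

test_that("moderated variances interpolate between sample and prior", {
    set.seed(24)
    s2 <- rchisq(200, df = 8) / 8
    mv <- moderatedVariance(s2, df = 8)
    expect_true(mv$d0 > 0)
    # shrunken variance is a convex combination of s2 and s0^2
    lo <- pmin(s2, mv$s02); hi <- pmax(s2, mv$s02)
    expect_true(all(mv$var >= lo - 1e-12 & mv$var <= hi + 1e-12))
    # identical variances: infinite prior df, no residual spread
    flat <- moderatedVariance(rep(2.5, 50), df = 8)
    expect_equal(flat$d0, Inf)
    expect_equal(flat$var, rep(2.5, 50))
})

test_that("moderated-variance hyperparameters are recovered on simulation", {
    set.seed(25)
    d0 <- 4; s02 <- 1; df <- 8; n <- 5000
    sigma2 <- d0 * s02 / rchisq(n, df = d0)
    s2 <- sigma2 * rchisq(n, df = df) / df
    mv <- moderatedVariance(s2, df = df)
    expect_gt(mv$d0, 2.5); expect_lt(mv$d0, 6)
    expect_gt(mv$s02, 0.8); expect_lt(mv$s02, 1.25)
    # independent cross-check: limma's empirical-Bayes squeeze
    sq <- limma::squeezeVar(s2, df = df)
    expect_equal(mv$d0, sq$df.prior, tolerance = 0.05)
    expect_equal(mv$s02, sq$var.prior, tolerance = 0.02)
    expect_equal(mv$var, sq$var.post, tolerance = 0.02)
})

test_that("Fisher combination matches the closed-form chi-square tail", {
    p <- c(0.01, 0.02, 0.03, 0.04)
    fc <- fisherCombine(p)
    expect_equal(fc$S, -2 * sum(log(p)))
    # independent oracle: even-df chi-square upper tail as a finite series
    S <- fc$S; k <- length(p)
    oracle <- exp(-S / 2) * sum((S / 2)^(0:(k - 1)) / factorial(0:(k - 1)))
    expect_equal(fc$p, oracle, tolerance = 1e-12)
    expect_equal(fc$p, 1.734362e-4, tolerance = 1e-6)
    # all ones -> S = 0, combined p = 1
    expect_equal(fisherCombine(c(1, 1, 1))$p, 1)
    # single study: identity convention
    expect_equal(fisherCombine(matrix(0.2))$p, 0.2)
    # zero inputs clamped with a warning
    expect_warning(z <- fisherCombine(c(0, 0.5)), "clamped")
    expect_lt(z$p, 1e-100)
})

test_that("Stouffer combination matches normal-quantile arithmetic", {
    sc <- stoufferCombine(c(0.05, 0.05))
    expect_equal(sc$z, 2 * qnorm(0.95) / sqrt(2), tolerance = 1e-6)
    expect_equal(sc$p_one, pnorm(sqrt(2) * qnorm(0.95),
                                 lower.tail = FALSE), tolerance = 1e-10)
    expect_lt(abs(sc$p_one - 0.0100), 1e-4)
    # weight concentrated on one study returns its two-sided p
    expect_equal(stoufferCombine(c(0.025, 0.7), weights = c(1, 0))$p,
                 0.05, tolerance = 1e-10)
    # opposite evidence cancels
    cc <- stoufferCombine(c(0.05, 0.95))
    expect_equal(cc$z, 0, tolerance = 1e-10)
    expect_equal(cc$p, 1)
    expect_error(stoufferCombine(c(0.1, 0.1), weights = c(0, 0)),
                 "weights")
})

test_that("fixed-effect pooling follows inverse-variance arithmetic", {
    fe <- fixedEffectCombine(c(0.5, 0.5), c(0.1, 0.1))
    expect_equal(fe$pooled, 0.5)
    expect_equal(fe$se, sqrt(0.05))
    expect_equal(fe$z, 0.5 / sqrt(0.05))
    expect_equal(fe$p, 2 * pnorm(-0.5 / sqrt(0.05)))
    # a precise study dominates
    dom <- fixedEffectCombine(c(0.9, 0), c(1e-6, 1))
    expect_equal(dom$pooled, 0.9, tolerance = 1e-5)
    # order invariance
    a <- fixedEffectCombine(c(0.2, 0.7, -0.1), c(0.3, 0.2, 0.5))
    b <- fixedEffectCombine(c(0.7, -0.1, 0.2), c(0.2, 0.5, 0.3))
    expect_equal(a$pooled, b$pooled)
    expect_error(fixedEffectCombine(c(0.1, 0.2), c(0.1, 0)), "positive")
})

test_that("DerSimonian-Laird tau2 matches the worked two-study case", {
    re <- randomEffectCombine(c(0, 2), c(0.1, 0.1))
    expect_equal(re$Q, 20)
    expect_equal(re$tau2, 1.9)     # (20 - 1) / (20 - 200/20)
    expect_equal(re$pooled, 1)
    # homogeneous effects: tau2 = 0 and REM equals FEM
    hom <- randomEffectCombine(c(0.5, 0.5), c(0.1, 0.1))
    fe <- fixedEffectCombine(c(0.5, 0.5), c(0.1, 0.1))
    expect_equal(hom$tau2, 0)
    expect_equal(hom$Q, 0)
    expect_equal(hom[, c("pooled", "se", "z", "p")],
                 fe[, c("pooled", "se", "z", "p")])
})

test_that("FEM and REM agree with metafor on random fixtures", {
    set.seed(26)
    for (i in 1:5) {
        k <- sample(3:8, 1)
        g <- rnorm(k); v <- runif(k, 0.05, 0.5)
        fe <- fixedEffectCombine(g, v)
        rfe <- metafor::rma(yi = g, vi = v, method = "FE")
        expect_equal(fe$pooled, as.numeric(rfe$beta), tolerance = 1e-10)
        expect_equal(fe$se, rfe$se, tolerance = 1e-10)
        expect_equal(fe$p, rfe$pval, tolerance = 1e-10)
        re <- randomEffectCombine(g, v)
        rre <- metafor::rma(yi = g, vi = v, method = "DL")
        expect_equal(re$tau2, rre$tau2, tolerance = 1e-10)
        expect_equal(re$pooled, as.numeric(rre$beta), tolerance = 1e-10)
        expect_equal(re$p, rre$pval, tolerance = 1e-10)
    }
})

test_that("DL tau2 is recovered across replicated large-study ensembles", {
    set.seed(27)
    tau2 <- 0.5; k <- 50; v <- 0.01
    est <- replicate(200, {
        g <- rnorm(k, mean = 1, sd = sqrt(tau2 + v))
        randomEffectCombine(g, rep(v, k))$tau2
    })
    expect_gt(mean(est), 0.35)
    expect_lt(mean(est), 0.65)
})

test_that("RankProduct permutation p agrees with the exhaustive oracle", {
    # oracle: with k = 2 studies and n genes, null ranks are independent
    # uniform, so P(RP <= r) = #{(i, j): sqrt(ij) <= r} / n^2
    oracleP <- function(rp, n) {
        grid <- expand.grid(i = 1:n, j = 1:n)
        vapply(rp, function(r)
            mean(sqrt(grid$i * grid$j) <= r + 1e-9), numeric(1))
    }
    # 5 genes, target ranked first in both studies: P(RP <= 1) = 1/25
    lfc <- cbind(s1 = c(9, 4, 3, 2, 1), s2 = c(8, 3, 4, 2, 1))
    rownames(lfc) <- paste0("g", 1:5)
    rp <- rankProduct(lfc, "up", B = 2000, seed = 31)
    expect_equal(rp$rp[1], 1)
    expect_lt(abs(rp$p_perm[1] - 0.04), 0.01)
    # 6-gene fixture: the whole p vector tracks the oracle within 0.01
    set.seed(32)
    lfc6 <- matrix(rnorm(12), 6, 2, dimnames = list(paste0("g", 1:6)))
    rp6 <- rankProduct(lfc6, "up", B = 2000, seed = 33)
    expect_lt(max(abs(rp6$p_perm - oracleP(rp6$rp, 6))), 0.01)
    # a gene ranked last everywhere has RP = n and p near 1
    expect_equal(rp$rp[5], 5)   # lfc fixture: gene 5 lowest in both
    expect_gt(rp$p_perm[5], 0.95)
    # direction = "down" mirrors the ranking
    rpd <- rankProduct(lfc, "down", B = 50, seed = 34)
    expect_equal(rpd$rp[5], 1)
    expect_error(rankProduct(lfc, "up", B = 0), "B must")
})

test_that("combined p-values stay in [0,1] and respond monotonically", {
    set.seed(35)
    for (i in 1:20) {
        p <- matrix(runif(12), 3, 4)
        expect_true(all(fisherCombine(p)$p >= 0 & fisherCombine(p)$p <= 1))
        expect_true(all(stoufferCombine(p)$p_one >= 0 &
                        stoufferCombine(p)$p_one <= 1))
        # raising one input never lowers the combined one-sided evidence
        p2 <- p; p2[1, 2] <- min(1, p[1, 2] + runif(1, 0, 1 - p[1, 2]))
        expect_gte(fisherCombine(p2)$p[1], fisherCombine(p)$p[1])
        expect_gte(stoufferCombine(p2)$p_one[1],
                   stoufferCombine(p)$p_one[1])
    }
})

test_that("vote counting applies the at-least-m-of-5 rule", {
    v <- voteCount(rbind(c(0.01, 0.02, 0.03, 0.04, 0.9),
                         c(0.01, 0.02, 0.03, 0.06, 0.9)))
    expect_equal(v$votes, c(4L, 3L))
    expect_equal(v$is_meta_deg, c(TRUE, FALSE))
    # alpha = 0 selects nothing
    expect_false(any(voteCount(matrix(runif(25), 5, 5),
                               alpha = 0)$is_meta_deg))
    expect_error(voteCount(matrix(0.01, 2, 3), minMethods = 4),
                 "minMethods")
})

test_that("metaAnalyze assembles consistent per-gene results", {
    sim <- cleanSim(n_genes = 300, frac_deg = 0.1, seed = 36)
    prep <- preprocessStudies(sim$studies)
    meta <- metaAnalyze(prep, B = 200, seed = 37)
    pm <- as.matrix(meta[, c("p_fisher", "p_rem", "p_rankprod",
                             "p_stouffer", "p_fem")])
    expect_true(all(pm >= 0 & pm <= 1))
    expect_equal(meta$votes, unname(rowSums(pm < 0.05)))
    expect_equal(meta$is_meta_deg, meta$votes >= 4)
    # genes with a zero heterogeneity estimate: REM equals FEM
    idx <- meta$tau2 == 0
    expect_gt(sum(idx), 0)
    femP <- fixedEffectCombine(
        S4Vectors::metadata(meta)$perStudyG[idx, , drop = FALSE],
        S4Vectors::metadata(meta)$perStudyVarG[idx, , drop = FALSE])$p
    expect_equal(meta$p_rem[idx], femP, tolerance = 1e-12)
    # determinism under the seed
    meta2 <- metaAnalyze(prep, B = 200, seed = 37)
    expect_identical(as.data.frame(meta), as.data.frame(meta2))
})

test_that("the vote rule recovers strong shared signal", {
    # delta = 2 SD in 4 studies of 5 + 5: the pooled evidence is decisive
    sim <- simulateCollection(simConfig(
        n_genes = 2000, k_studies = 4, n_mcao = 5, n_sham = 5,
        frac_deg = 0.05, delta = 2, tau2 = 0, missing_rate = 0,
        platform_dropout = 0, seed = 11))
    prep <- preprocessStudies(sim$studies)
    meta <- metaAnalyze(prep, B = 1000, seed = 12)
    truth <- c(sim$truth$degUp, sim$truth$degDown)
    recall <- mean(truth %in% metaDegs(meta))
    expect_gte(recall, 0.75)   # 80% nominal with the 5-point slack
})
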