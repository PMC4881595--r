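#' Hedges' g standardized mean difference with small-sample correction
#'
#' Computes the bias-corrected standardized mean difference
#' g = J * (m1 - m2) / s_pooled with J = 1 - 3 / (4(n1 + n2 - 2) - 1),
#' and its large-sample variance
#' var_g = (n1 + n2) / (n1 n2) + g^2 / (2(n1 + n2)).
#' Group 1 is MCAO, group 2 sham, so positive g means higher in MCAO.
#' All arguments are vectorized over genes.
#'
#' @param n1,n2 group sizes (>= 2).
#' @param m1,m2 group means.
#' @param s1,s2 group standard deviations.
#' @param pooledVar optional replacement for the pooled variance (e.g. a
#'   moderated, shrunken value from [moderatedVariance()]); when supplied
#'   the raw \code{s1}/\code{s2} are not used for the denominator.
#' @return data.frame with columns \code{g}, \code{var_g}, \code{n1},
#'   \code{n2}.
#' @export
hedgesG <- function(n1, m1, s1, n2, m2, s2, pooledVar = NULL) {
    stopifnot(all(n1 >= 2L), all(n2 >= 2L))
    df <- n1 + n2 - 2
    sp2 <- if (is.null(pooledVar))
        ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df
    else pooledVar
    diff <- m1 - m2
    zero <- sp2 == 0
    if (any(zero & diff != 0))
        stop("zero pooled variance with unequal means: ",
             "effect size undefined")
    sp2[zero] <- 1  # g is 0 there anyway
    J <- 1 - 3 / (4 * df - 1)
    g <- J * diff / sqrt(sp2)
    varG <- (n1 + n2) / (n1 * n2) + g^2 / (2 * (n1 + n2))
    data.frame(g = g, var_g = varG, n1 = n1, n2 = n2)
}

#' Empirical-Bayes moderated variances
#'
#' Shrinks per-gene sample variances toward a common prior value under a
#' scaled inverse-chi-square model: s_g^2 | sigma_g^2 ~ sigma_g^2
#' chi^2_df / df and sigma_g^2 ~ s0^2 d0 / chi^2_d0.  The prior degrees
#' of freedom d0 and scale s0^2 are estimated by the method of moments on
#' the log sample variances (matching the mean and variance of the
#' log-chi-square distribution via digamma/trigamma); the posterior
#' (shrunken) variance is (d0 s0^2 + df s^2) / (d0 + df), and a moderated
#' t-statistic built on it has df + d0 degrees of freedom.
#'
#' @param s2 per-gene sample variances (>= 10 genes).
#' @param df residual degrees of freedom of each variance (scalar).
#' @return list with \code{var} (shrunken variances), \code{d0},
#'   \code{s02} and \code{dfTotal} (= df + d0, capped at 1e6 when d0 is
#'   infinite).
#' @export
moderatedVariance <- function(s2, df) {
    stopifnot(length(s2) >= 10L, df >= 1)
    if (any(s2 < 0)) stop("variances must be non-negative")
    if (diff(range(s2)) < .Machine$double.eps * max(s2, 1)) {
        # no spread: infinitely strong prior at the common value
        return(list(var = rep(s2[1L], length(s2)), d0 = Inf,
                    s02 = s2[1L], dfTotal = 1e6))
    }
    s2f <- pmax(s2, 1e-300)
    z <- log(s2f)
    e <- z - digamma(df / 2) + log(df / 2)
    emean <- mean(e)
    rhs <- stats::var(e) - trigamma(df / 2)
    if (rhs > 0) {
        d0 <- 2 * .trigammaInverse(rhs)
        s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
        shrunk <- (d0 * s02 + df * s2) / (d0 + df)
    } else {
        d0 <- Inf
        s02 <- exp(emean)
        shrunk <- rep(s02, length(s2))
    }
    list(var = shrunk, d0 = d0, s02 = s02,
         dfTotal = min(df + d0, 1e6))
}

# Newton iteration for the inverse of the trigamma function.
.trigammaInverse <- function(x) {
    if (x > 1e7) return(1 / sqrt(x))
    if (x < 1e-6) return(1 / x)
    y <- 0.5 + 1 / x
    for (i in 1:50) {
        tri <- trigamma(y)
        dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
        y <- y + dif
        if (-dif / y < 1e-8) break
    }
    y
}

#' Combine p-values by Fisher's sum of logs
#'
#' S = -2 sum_i ln p_i is chi-square with 2k degrees of freedom under the
#' joint null; the combined p-value is its upper tail.  Zero p-values are
#' clamped to 1e-300 with a warning.  With a single study the input is
#' returned unchanged (identity convention).
#'
#' @param p matrix of p-values, genes in rows and studies in columns (a
#'   vector is treated as one gene).
#' @return data.frame with columns \code{S} and \code{p}.
#' @export
fisherCombine <- function(p) {
    p <- rbindAsMatrix(p)
    if (any(p > 1, na.rm = TRUE) || any(p < 0, na.rm = TRUE))
        stop("p-values must lie in [0, 1]")
    if (any(p == 0, na.rm = TRUE)) {
        warning("p-value(s) of 0 clamped to 1e-300")
        p[p == 0] <- 1e-300
    }
    if (ncol(p) == 1L)
        return(data.frame(S = -2 * log(p[, 1L]), p = p[, 1L],
                          row.names = rownames(p)))
    S <- -2 * rowSums(log(p))
    data.frame(S = S,
               p = stats::pchisq(S, df = 2 * ncol(p), lower.tail = FALSE),
               row.names = rownames(p))
}

rbindAsMatrix <- function(p) {
    if (is.null(dim(p))) matrix(p, nrow = 1L) else as.matrix(p)
}

#' Combine one-sided p-values by the weighted Stouffer Z
#'
#' z_i = qnorm(1 - p_i); Z = sum(w_i z_i) / sqrt(sum(w_i^2)).  The
#' orientation is one-sided toward over-expression in MCAO; the two-sided
#' report doubles the smaller normal tail, capped at 1.  Weights default
#' to equal and are typically the per-study inverse effect-size variances
#' (1/var_g).  p-values of exactly 0 or 1 are clamped to (1e-15,
#' 1 - 1e-15).
#'
#' @param p matrix of one-sided p-values (genes x studies).
#' @param weights \code{NULL} (equal), a length-k vector, or a matrix
#'   conformable with \code{p}; must not be all zero.
#' @return data.frame with columns \code{z}, \code{p_one} (one-sided) and
#'   \code{p} (two-sided).
#' @export
stoufferCombine <- function(p, weights = NULL) {
    p <- rbindAsMatrix(p)
    if (is.null(weights))
        weights <- matrix(1, nrow(p), ncol(p))
    else if (is.null(dim(weights)))
        weights <- matrix(weights, nrow(p), ncol(p), byrow = TRUE)
    if (any(weights < 0) || any(rowSums(weights) == 0))
        stop("weights must be non-negative and not all zero")
    p <- pmin(pmax(p, 1e-15), 1 - 1e-15)
    z <- stats::qnorm(p, lower.tail = FALSE)
    Z <- rowSums(weights * z) / sqrt(rowSums(weights^2))
    pOne <- stats::pnorm(Z, lower.tail = FALSE)
    data.frame(z = Z, p_one = pOne,
               p = pmin(1, 2 * pmin(pOne, 1 - pOne)),
               row.names = rownames(p))
}

#' Fixed-effect (inverse-variance) combination of effect sizes
#'
#' w_i = 1/var_i; pooled = sum(w g)/sum(w); se = 1/sqrt(sum(w)); the
#' two-sided p comes from the normal reference for z = pooled/se.
#'
#' @param g matrix of per-study effect sizes (genes x studies).
#' @param varG matrix of their variances (all > 0).
#' @return data.frame with columns \code{pooled}, \code{se}, \code{z},
#'   \code{p}.
#' @export
fixedEffectCombine <- function(g, varG) {
    g <- rbindAsMatrix(g); varG <- rbindAsMatrix(varG)
    stopifnot(identical(dim(g), dim(varG)), ncol(g) >= 2L)
    if (any(varG <= 0)) stop("effect-size variances must be positive")
    w <- 1 / varG
    pooled <- rowSums(w * g) / rowSums(w)
    se <- 1 / sqrt(rowSums(w))
    z <- pooled / se
    data.frame(pooled = pooled, se = se, z = z,
               p = 2 * stats::pnorm(abs(z), lower.tail = FALSE),
               row.names = rownames(g))
}

#' Random-effects (DerSimonian-Laird) combination of effect sizes
#'
#' Cochran's Q = sum(w_i (g_i - g_FE)^2) with fixed-effect weights w_i =
#' 1/var_i; the between-study variance is tau2 = max(0, (Q - (k - 1)) /
#' (sum w - sum w^2 / sum w)); pooling then proceeds as in the
#' fixed-effect model with weights 1/(var_i + tau2).  When the estimate
#' is tau2 = 0 the result equals [fixedEffectCombine()].
#'
#' @inheritParams fixedEffectCombine
#' @return data.frame with columns \code{pooled}, \code{se}, \code{z},
#'   \code{p}, \code{tau2}, \code{Q}.
#' @export
randomEffectCombine <- function(g, varG) {
    g <- rbindAsMatrix(g); varG <- rbindAsMatrix(varG)
    stopifnot(identical(dim(g), dim(varG)), ncol(g) >= 2L)
    if (any(varG <= 0)) stop("effect-size variances must be positive")
    k <- ncol(g)
    w <- 1 / varG
    sw <- rowSums(w)
    gFE <- rowSums(w * g) / sw
    Q <- rowSums(w * (g - gFE)^2)
    C <- sw - rowSums(w^2) / sw
    tau2 <- pmax(0, (Q - (k - 1)) / C)
    wStar <- 1 / (varG + tau2)
    pooled <- rowSums(wStar * g) / rowSums(wStar)
    se <- 1 / sqrt(rowSums(wStar))
    z <- pooled / se
    data.frame(pooled = pooled, se = se, z = z,
               p = 2 * stats::pnorm(abs(z), lower.tail = FALSE),
               tau2 = tau2, Q = Q, row.names = rownames(g))
}

#' RankProduct meta-statistic with permutation significance
#'
#' Per study, genes are ranked by log2 fold change (rank 1 = most
#' up-regulated for \code{direction = "up"}, most down-regulated for
#' \code{"down"}; ties get average ranks); RP_g is the geometric mean of
#' a gene's ranks across studies.  The null distribution pools B
#' independent shuffles of each study's rank vector:
#' p_perm(g) = (1 + #\{null RP <= RP_g\}) / (B * n_genes + 1), and the
#' percentage-of-false-positives estimate is pfp = p_perm * n_genes /
#' rank(RP).
#'
#' @param lfc matrix of per-study log2 fold changes (genes x studies,
#'   shared gene index, k >= 2).
#' @param direction \code{"up"} or \code{"down"}.
#' @param B number of permutations (>= 1).
#' @param seed integer seed for the shuffles.
#' @return data.frame with columns \code{rp}, \code{p_perm}, \code{pfp}.
#' @export
rankProduct <- function(lfc, direction = c("up", "down"), B = 1000L,
                        seed = 1L) {
    direction <- match.arg(direction)
    lfc <- as.matrix(lfc)
    stopifnot(ncol(lfc) >= 2L)
    if (B < 1L) stop("B must be at least 1")
    n <- nrow(lfc)
    sgn <- if (direction == "up") -1 else 1
    logR <- apply(sgn * lfc, 2L, function(v)
        log(rank(v, ties.method = "average")))
    rp <- exp(rowMeans(logR))
    set.seed(seed)
    nullRP <- numeric(B * n)
    for (b in seq_len(B)) {
        shuffled <- apply(logR, 2L, sample)
        nullRP[(b - 1L) * n + seq_len(n)] <- exp(rowMeans(shuffled))
    }
    counts <- findInterval(rp, sort(nullRP))
    pPerm <- (1 + counts) / (B * n + 1)
    pfp <- pPerm * n / rank(rp, ties.method = "average")
    data.frame(rp = rp, p_perm = pPerm, pfp = pfp,
               row.names = rownames(lfc))
}

#' Vote counting across the five meta-analytic methods
#'
#' A gene's vote count is the number of methods whose p-value falls below
#' \code{alpha}; it is a meta-DEG when at least \code{minMethods} of them
#' agree (default: 4 of 5 at alpha = 0.05).  Missing p-values cannot
#' vote.
#'
#' @param p matrix of per-method p-values (genes x methods).
#' @param alpha per-method significance level.
#' @param minMethods minimum number of agreeing methods.
#' @return data.frame with columns \code{votes} and \code{is_meta_deg}.
#' @export
voteCount <- function(p, alpha = 0.05, minMethods = 4L) {
    p <- rbindAsMatrix(p)
    if (minMethods > ncol(p))
        stop("minMethods exceeds the number of available methods")
    votes <- rowSums(p < alpha, na.rm = TRUE)
    data.frame(votes = as.integer(votes),
               is_meta_deg = votes >= minMethods,
               row.names = rownames(p))
}

#' Five-method meta-analysis of a preprocessed study collection
#'
#' Runs, per gene on the common-gene index: (1) Fisher's sum of logs over
#' per-study two-sided t-test p-values; (2) a DerSimonian-Laird
#' random-effects combination of Hedges' g computed with moderated
#' (empirical-Bayes shrunken) within-study variances; (3) the RankProduct
#' permutation statistic, run in both directions with the smaller tail
#' doubled; (4) an inverse-variance-weighted Stouffer Z over one-sided
#' p-values; (5) a fixed-effect combination of unmoderated Hedges' g.
#' Votes are then counted at \code{alpha}.
#'
#' @param prep output of [preprocessStudies()] (or any list with elements
#'   \code{studies} -- gene-level [StudyExpression-class] on a shared
#'   gene index -- and \code{standardized}).
#' @param alpha per-method significance level.
#' @param minMethods votes required to call a meta-DEG.
#' @param B RankProduct permutations.
#' @param seed seed for the RankProduct shuffles.
#' @param variant per-study t-test variant.
#' @param moderated use moderated variances inside the random-effects
#'   route (method 2); the fixed-effect route always uses unmoderated g.
#'   Default \code{FALSE}: shrinking the denominator of g while keeping
#'   its analytic variance leaves g under-dispersed and the REM null
#'   rejection rate far below nominal (see the vignette).
#' @param weights Stouffer weighting: \code{"sqrtn"} (sqrt of study
#'   size; the classic choice, near-nominal under the null) or
#'   \code{"invvar"} (1/var_g; conservative, because var_g contains
#'   g^2/(2n) and so anti-correlates with the evidence).
#' @return a \code{MetaResult}: \link[S4Vectors]{DataFrame} with columns
#'   \code{p_fisher}, \code{p_rem}, \code{p_rankprod}, \code{p_stouffer},
#'   \code{p_fem}, \code{pooled_g}, \code{tau2}, \code{votes},
#'   \code{is_meta_deg}; per-study g and var_g (forest-plot input) and
#'   the call parameters live in \code{metadata()}.
#' @export
metaAnalyze <- function(prep, alpha = 0.05, minMethods = 4L, B = 1000L,
                        seed = 1L, variant = c("welch", "student"),
                        moderated = FALSE,
                        weights = c("sqrtn", "invvar")) {
    variant <- match.arg(variant)
    weights <- match.arg(weights)
    studies <- prep$studies
    std <- prep$standardized
    k <- length(studies)
    if (k < 2L) stop("meta-analysis needs at least 2 studies")
    genes <- rownames(std[[1L]])
    stopifnot(all(vapply(std, function(m)
        identical(rownames(m), genes), logical(1))))
    n <- length(genes)

    pTwo <- pOne <- gMat <- vMat <- gModMat <- vModMat <- lfcMat <-
        matrix(NA_real_, n, k, dimnames = list(genes, names(studies)))
    for (i in seq_len(k)) {
        grp <- groups(studies[[i]])
        tt <- geneTTest(std[[i]], grp, variant = variant)
        pTwo[, i] <- tt$p
        pOne[, i] <- stats::pt(tt$t, tt$df, lower.tail = FALSE)
        st <- .groupStats(std[[i]], as.character(grp))
        es <- hedgesG(st$n1, st$m1, st$s1, st$n2, st$m2, st$s2)
        gMat[, i] <- es$g
        vMat[, i] <- es$var_g
        if (moderated) {
            dfres <- st$n1 + st$n2 - 2
            sp2 <- ((st$n1 - 1) * st$s1^2 + (st$n2 - 1) * st$s2^2) / dfres
            mv <- moderatedVariance(sp2, dfres)
            esM <- hedgesG(st$n1, st$m1, st$s1, st$n2, st$m2, st$s2,
                           pooledVar = mv$var)
            gModMat[, i] <- esM$g
            vModMat[, i] <- esM$var_g
        }
        lfcMat[, i] <- log2FoldChange(studies[[i]], grp)
    }
    if (!moderated) {
        gModMat <- gMat
        vModMat <- vMat
    }

    fish <- fisherCombine(pTwo)
    stoufW <- if (weights == "invvar") 1 / vMat
              else matrix(rep(sqrt(vapply(studies, ncol, integer(1))),
                              each = n), n, k)
    stou <- stoufferCombine(pOne, stoufW)
    fem <- fixedEffectCombine(gMat, vMat)
    rem <- randomEffectCombine(gModMat, vModMat)
    rpUp <- rankProduct(lfcMat, "up", B = B, seed = seed)
    rpDown <- rankProduct(lfcMat, "down", B = B, seed = seed + 1L)
    pRp <- pmin(1, 2 * pmin(rpUp$p_perm, rpDown$p_perm))

    pm <- cbind(p_fisher = fish$p, p_rem = rem$p, p_rankprod = pRp,
                p_stouffer = stou$p, p_fem = fem$p)
    rownames(pm) <- genes
    vt <- voteCount(pm, alpha = alpha, minMethods = minMethods)
    out <- S4Vectors::DataFrame(pm, pooled_g = fem$pooled,
                                tau2 = rem$tau2,
                                votes = vt$votes,
                                is_meta_deg = vt$is_meta_deg,
                                row.names = genes)
    S4Vectors::metadata(out) <- list(
        alpha = alpha, minMethods = minMethods, B = B, seed = seed,
        variant = variant, moderated = moderated, weights = weights,
        perStudyG = gMat, perStudyVarG = vMat,
        rankprod = list(up = rpUp, down = rpDown))
    out
}

#' Meta-DEG gene symbols of a MetaResult
#'
#' @param meta a \code{MetaResult} from [metaAnalyze()].
#' @return character vector of genes with \code{is_meta_deg} set.
#' @export
metaDegs <- function(meta) {
    rownames(meta)[meta$is_meta_deg]
}
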