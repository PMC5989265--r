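mkAtlas <- function(n_exons = 80, seed = 5, noise_sd = 0.05) {
    simulateReference(n_exons = max(n_exons, 100), noise_sd = noise_sd,
                      seed = seed)
}

test_that("self-projection tracks a reference column and minimizes its distance", {
    # the logit-link projection is a monotone transform of the reference
    # profiles, not the identity, so per-exon agreement is approximate;
    # what must hold exactly is that the projected column is closest to
    # itself among all reference samples
    sim <- mkAtlas(seed = 5)
    atlas <- sim$atlas
    for (j in c("E14.5", "P4", "21mo")) {
        y <- psiValues(atlas)[, j]
        proj <- projectSample(y, atlas)
        err <- abs(fittedPsi(proj) - y[proj@exonIds])
        expect_lt(median(err), 0.1)
        expect_gt(cor(fittedPsi(proj), y[proj@exonIds]), 0.95)
        D <- sampleDistances(proj, atlas)
        expect_equal(names(which.min(D)), j)
    }
})

test_that("boundary inclusion values are shrunk, not fatal", {
    sim <- mkAtlas(seed = 6)
    y <- psiValues(sim$atlas)[, "P7"]
    y[1:10] <- rep(c(0, 1), 5)
    proj <- projectSample(y, sim$atlas)
    expect_true(all(is.finite(fittedPsi(proj))))
    expect_true(proj@phi > 0)
    sh <- shrinkToOpenInterval(c(0, 1), 100)
    expect_equal(sh, c(0.005, 0.995))
})

test_that("ML beta regression attains the grid-search maximum on toys", {
    set.seed(12)
    for (rep in 1:3) {
        nEx <- 10
        X <- cbind(r1 = runif(nEx, 0, 1), r2 = runif(nEx, 0, 1))
        rownames(X) <- paste0("ex", seq_len(nEx))
        betaTrue <- c(1.2, -0.8)
        mu <- plogis(drop(X %*% betaTrue))
        y <- rbeta(nEx, mu * 40, (1 - mu) * 40)
        y <- shrinkToOpenInterval(y, nEx)
        atlas <- ReferenceAtlas(X, stageMap = setNames(1:2, colnames(X)))
        proj <- projectSample(setNames(y, rownames(X)), atlas, min_exons = 5)
        grid <- betaGridOracle(
            y, X,
            list(b1 = seq(-3, 3, by = 0.1), b2 = seq(-3, 3, by = 0.1)),
            seq(log(5), log(200), length.out = 25))
        expect_gte(proj@logLik, grid$logLik - 1e-4)
    }
})

test_that("squared distances follow their closed form and symmetries", {
    X <- matrix(c(0.4, 0.6, 0.2, 0.9), 2, 2,
                dimnames = list(c("e1", "e2"), c("E14.5", "P15")))
    atlas <- ReferenceAtlas(X)
    proj <- new("BetaProjection", beta = c(E14.5 = 0, P15 = 0), phi = 10,
                muHat = c(0.5, 0.5), exonIds = c("e1", "e2"),
                logLik = 0, converged = TRUE)
    D <- sampleDistances(proj, atlas)
    expect_equal(unname(D["E14.5"]), 0.01 + 0.01, tolerance = 1e-12)
    # exon order within the atlas does not matter
    proj2 <- new("BetaProjection", beta = c(E14.5 = 0, P15 = 0), phi = 10,
                 muHat = c(0.5, 0.5), exonIds = c("e2", "e1"),
                 logLik = 0, converged = TRUE)
    expect_equal(sort(sampleDistances(proj2, atlas)), sort(D))
})

test_that("stage assignment takes the nearest reference with P15+ pooled", {
    sim <- mkAtlas(seed = 7)
    atlas <- sim$atlas
    labels <- colnames(atlas)
    mkD <- function(at) setNames(replace(rep(1, 9), match(at, labels), 0),
                                 labels)
    expect_equal(predictedStage(assignStage(mkD("P30"), atlas)), 6L)
    p <- assignStage(mkD("E14.5"), atlas)
    expect_equal(predictedStage(p), 1L)
    expect_equal(stageConfidence(p), 1)
    expect_warning(tie <- assignStage(setNames(rep(2, 9), labels), atlas),
                   "ambiguous")
    expect_equal(stageConfidence(tie), 0)
    expect_equal(predictedStage(tie), 1L)  # ties break to the younger stage
})

test_that("accuracy counts exact and adjacency-tolerant matches", {
    acc <- stageAccuracy(c(3L, 4L), c(3L, 3L))
    expect_equal(acc$exact, 0.5)
    expect_equal(acc$within_one, 1)
    expect_error(stageAccuracy(integer(0), integer(0)), "non-empty")
    expect_error(stageAccuracy(1:3, 1:2), "same length")
    set.seed(8)
    pr <- sample(1:6, 50, TRUE); tr <- sample(1:6, 50, TRUE)
    a <- stageAccuracy(pr, tr)
    expect_gte(a$within_one, a$exact)
})

test_that("PCA projection is consistent with an explicit eigen-solver", {
    sim <- mkAtlas(seed = 9)
    atlas <- sim$atlas
    xy <- pcaProject(atlas)
    # a reference sample used as a query lands on its own score
    xy2 <- pcaProject(atlas, queries = list(q = psiValues(atlas)[, "P4"]))
    expect_equal(unname(xy2["q", ]), unname(xy["P4", ]), tolerance = 1e-9)
    # the reference mean profile projects to the origin
    xy3 <- pcaProject(atlas, queries = list(q = rowMeans(psiValues(atlas))))
    expect_equal(unname(xy3["q", ]), c(0, 0), tolerance = 1e-9)
    # 5-exon toy against a dense eigen-decomposition of the covariance
    X <- matrix(runif(15), 5, 3,
                dimnames = list(paste0("e", 1:5), c("E14.5", "P0", "P15")))
    toy <- ReferenceAtlas(X)
    xyT <- pcaProject(toy)
    Xc <- sweep(t(X), 2, rowMeans(X))
    ev <- eigen(crossprod(Xc) / (nrow(Xc) - 1))
    scores <- Xc %*% ev$vectors[, 1:2]
    for (d in 1:2)  # eigenvectors are sign-arbitrary
        expect_equal(abs(unname(xyT[, d])), abs(unname(scores[, d])),
                     tolerance = 1e-9)
})

test_that("every reference sample stages as itself and subsets behave", {
    sim <- mkAtlas(seed = 10)
    atlas <- sim$atlas
    sm <- stageMap(atlas)
    for (j in colnames(atlas)) {
        p <- predictStage(psiValues(atlas)[, j], atlas)
        expect_equal(predictedStage(p), unname(sm[j]))
        expect_gt(stageConfidence(p), 0)
    }
    # subset = all atlas exons is identical to no subset
    q <- simulateQuery(sim$truth, "P7", seed = 11)
    pAll <- predictStage(q$psi, atlas)
    pSub <- predictStage(q$psi, atlas, subset = rownames(atlas))
    expect_equal(predictedStage(pAll), predictedStage(pSub))
    expect_equal(sampleDistanceVector(pAll), sampleDistanceVector(pSub))
    expect_error(predictStage(q$psi, atlas, subset = c("nope1", "nope2")),
                 "no exons in common")
})

test_that("a query generated at a reference age recovers its stage", {
    sim <- mkAtlas(seed = 12)
    q <- simulateQuery(sim$truth, "P4", coverage_mean = 100, seed = 13)
    p <- predictStage(q$psi, sim$atlas)
    expect_equal(predictedStage(p), 4L)
    expect_equal(q$stage, 4L)
})

test_that("mean confidence degrades monotonically with query noise", {
    sim <- mkAtlas(seed = 14)
    meanS <- vapply(c(0.02, 0.1, 0.25), function(ns) {
        mean(vapply(1:6, function(i) {
            q <- simulateQuery(sim$truth, refStages()[i], noise_sd = ns,
                               seed = 500 + i)
            stageConfidence(predictStage(q$psi, sim$atlas))
        }, numeric(1)))
    }, numeric(1))
    expect_true(all(diff(meanS) <= 0))
})

test_that("too few usable exons fail loudly", {
    sim <- mkAtlas(seed = 15)
    y <- psiValues(sim$atlas)[, "P0"]
    y[-(1:20)] <- NA
    expect_error(projectSample(y, sim$atlas), "insufficient module-exon")
})

test_that("stage predictions serialize to JSON with all fields", {
    sim <- mkAtlas(seed = 16)
    q <- simulateQuery(sim$truth, "P0", seed = 17)
    p <- predictStage(q$psi, sim$atlas)
    f <- tempfile(fileext = ".json")
    writeStagePredictions(list(sampleA = p), f)
    js <- jsonlite::fromJSON(f)
    expect_equal(js$sampleA$stage, predictedStage(p))
    expect_equal(js$sampleA$confidence, stageConfidence(p), tolerance = 1e-9)
    expect_equal(length(js$sampleA$distances), 9L)
    expect_equal(js$sampleA$subset_tag, "all")
})
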