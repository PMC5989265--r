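test_that("critical correlation inverts the two-sided t test", {
    expect_equal(round(criticalCorrelation(9, 0.001), 1), 0.9)
    expect_equal(criticalCorrelation(9, 0.001), 0.898, tolerance = 5e-4)
    expect_equal(criticalCorrelation(5, 0.05), 0.878, tolerance = 5e-4)
    expect_lt(criticalCorrelation(9, 0.9999), 0.01)  # alpha -> 1 gives r* -> 0
    expect_error(criticalCorrelation(2, 0.05), "at least 3")
    # the returned r really sits on the alpha boundary
    r <- criticalCorrelation(9, 0.001)
    tstat <- r * sqrt(7) / sqrt(1 - r^2)
    expect_equal(2 * pt(-tstat, 7), 0.001, tolerance = 1e-9)
})

test_that("adjacency matches a brute-force loop and flags degenerate rows", {
    set.seed(4)
    m <- matrix(runif(90), 10, 9,
                dimnames = list(paste0("ex", 1:10), refStages()))
    a <- adjacencyMatrix(m, power = 3)
    expect_equal(a, naiveAdjacency(m, 3), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_true(isSymmetric(a))
    expect_equal(unname(diag(a)), rep(1, 10))
    # |r| = 0.5 must give 0.125 under the cubed transform
    expect_equal(unname(abs(cor(m[1, ], m[2, ]))^3), a[1, 2], tolerance = 1e-12)
    m[3, ] <- 0.7
    expect_error(adjacencyMatrix(m), "ex3")
})

test_that("planted early/late modules are recovered with signed splits", {
    fx <- makeSteppedPsi(n_per_module = 60, noise_sd = 0.05, seed = 1)
    mods <- detectModules(fx$psi, min_size = 30)
    a <- moduleAssignment(mods)
    expect_equal(nrow(eigenexons(mods)), 2L)
    tab <- table(fx$truth, a$module)
    agreement <- sum(apply(tab, 1, max)) / length(fx$truth)
    expect_gte(agreement, 0.95)
    # each module contains both a + and a - group
    for (mod in rownames(eigenexons(mods))) {
        signs <- a$sign[a$module %in% mod]
        expect_setequal(unique(signs), c("+", "-"))
    }
})

test_that("noise-free planted modules are recovered perfectly", {
    fx <- makeSteppedPsi(n_per_module = 40, noise_sd = 0, seed = 2)
    # tiny jitter only to avoid zero-variance ties between identical rows
    psi <- fx$psi + matrix(rnorm(length(fx$psi), 0, 1e-6), nrow(fx$psi))
    mods <- detectModules(psi, min_size = 30)
    a <- moduleAssignment(mods)
    tab <- table(fx$truth, a$module)
    expect_equal(sum(apply(tab, 1, max)) / length(fx$truth), 1)
})

test_that("modules with eigenexon dissimilarity below 0.25 are merged", {
    fx <- makeCorrelatedModules(rho = 0.8, n_per_module = 35, seed = 2)
    merged <- detectModules(fx$psi, min_size = 30, merge_diss = 0.25)
    expect_equal(nrow(eigenexons(merged)), 1L)
    # with a stricter threshold the two planted modules stay apart
    apart <- detectModules(fx$psi, min_size = 30, merge_diss = 0.1)
    expect_equal(nrow(eigenexons(apart)), 2L)
})

test_that("too-small inputs yield no modules, with a warning", {
    set.seed(6)
    m <- matrix(runif(90), 10, 9, dimnames = list(paste0("ex", 1:10), NULL))
    expect_warning(mods <- detectModules(m, min_size = 30), "min_size")
    expect_equal(nrow(eigenexons(mods)), 0L)
    expect_true(all(is.na(moduleAssignment(mods)$module)))
})

test_that("eigenexons are exon-order invariant and merging is order-stable", {
    fx <- makeSteppedPsi(n_per_module = 40, noise_sd = 0.05, seed = 3)
    m1 <- detectModules(fx$psi, min_size = 30)
    set.seed(1)
    perm <- sample(nrow(fx$psi))
    m2 <- detectModules(fx$psi[perm, ], min_size = 30)
    a1 <- moduleAssignment(m1)
    a2 <- moduleAssignment(m2)
    a2 <- a2[match(a1$exon_id, a2$exon_id), ]
    expect_equal(a1$module, a2$module)
    expect_equal(a1$eigen_corr, a2$eigen_corr, tolerance = 1e-9)
    expect_equal(eigenexons(m1), eigenexons(m2), tolerance = 1e-9)
})

test_that("core membership follows the critical-correlation rule", {
    fx <- makeSteppedPsi(n_per_module = 40, noise_sd = 0.05, seed = 5)
    mods <- detectModules(fx$psi, min_size = 30)
    a <- moduleAssignment(mods)
    rstar <- criticalCorrelation(9, 0.001)
    expect_equal(a$core, !is.na(a$eigen_corr) & abs(a$eigen_corr) >= rstar)
    # an exon profile equal to the eigenexon is core with sign +
    eig <- eigenexons(mods)[1, ]
    psi2 <- rbind(fx$psi, exEq = 0.5 + 0.3 * eig / max(abs(eig)),
                  exNeg = 0.5 - 0.3 * eig / max(abs(eig)))
    mods2 <- coreMembers(detectModules(psi2, min_size = 30), psi2)
    a2 <- moduleAssignment(mods2)
    eqRow <- a2[a2$exon_id == "exEq", ]
    negRow <- a2[a2$exon_id == "exNeg", ]
    expect_equal(abs(eqRow$eigen_corr), 1, tolerance = 1e-6)
    expect_true(eqRow$core)
    expect_true(negRow$core)
    expect_true(eqRow$sign != negRow$sign)
})

test_that("sub-threshold correlation with nine time points is not core", {
    # build an exon correlating at exactly 0.85 with a module eigenexon
    fx <- makeCorrelatedModules(rho = 0.85, n_per_module = 35, seed = 7)
    mods <- detectModules(fx$psi, min_size = 30, merge_diss = 0.05)
    a <- moduleAssignment(mods)
    # cross correlations between the two planted shapes are ~0.85 < 0.898:
    # exons of one module can never be core for the other
    expect_true(all(abs(a$eigen_corr[a$core]) >= criticalCorrelation(9, 0.001)))
    expect_gt(criticalCorrelation(9, 0.001), 0.85)
})
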