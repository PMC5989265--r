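#' @importFrom stats rnorm runif rbinom rnbinom
NULL

.withSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
            get(".Random.seed", globalenv()) else NULL
        on.exit({
            if (is.null(old)) rm(".Random.seed", envir = globalenv())
            else assign(".Random.seed", old, envir = globalenv())
        })
        set.seed(seed)
    }
    force(expr)
}

# reflect values into [0, 1] (truncated-normal-by-reflection noise model)
.reflect01 <- function(x) {
    while (any(x < 0 | x > 1)) {
        x <- abs(x)
        x <- ifelse(x > 1, 2 - x, x)
    }
    x
}

.defaultStages <- function() c("E14.5", "E16.5", "P0", "P4", "P7",
                               "P15", "P30", "4mo", "21mo")

# evaluate true trajectories at times t: truth rows x length(t)
.trajectoryAt <- function(truth, t) {
    out <- matrix(NA_real_, nrow(truth), length(t),
                  dimnames = list(truth$exon_id, names(t)))
    for (i in seq_len(nrow(truth))) {
        r <- truth[i, ]
        if (r$module == "null") {
            out[i, ] <- rep(r$base, length(t))
        } else if (r$module %in% c("M3", "M4")) {
            # two independent switches of opposite direction; the second
            # sigmoid starts at 1 when its slope is negative (M3), at 0
            # when positive (M4), so both composites start and end at `a`
            # resp. `k` with an excursion in between
            s1 <- 1 / (1 + exp(-r$b * (t - r$m)))
            s2 <- 1 / (1 + exp(-r$b2 * (t - r$m2)))
            offset <- if (r$module == "M3") 1 else 0
            out[i, ] <- pmin(pmax(
                r$a + (r$k - r$a) * (s1 + s2 - offset), 0), 1)
        } else {
            out[i, ] <- sigmoidPsi(t, r$a, r$k, r$b, r$m)
        }
    }
    out
}

.drawSigmoidParams <- function(n) {
    list(a = runif(n, 0.02, 0.25), k = runif(n, 0.75, 0.98),
         b = runif(n, 20, 50))
}

#' Simulate a developmental reference data set
#'
#' Generates a module-structured cortex-style reference: exons are assigned
#' to temporal modules with planted sigmoidal trajectories on the log10
#' post-conception-day axis -- M2 ("early") switches around birth (midpoint
#' near P0), M1 ("late") switches between P7 and P15, each split into
#' mirrored + and - halves; M3/M4 are non-monotonic composites of an early
#' and a late switch of opposite direction; null exons are flat. True
#' inclusion levels are perturbed by reflected-Gaussian noise on \[0, 1\],
#' per-cell junction coverage is drawn negative-binomially, and reads are
#' sampled binomially given the noisy inclusion level (inclusion reads are
#' emitted doubled, one read per inclusion junction). Fully reproducible
#' from the seed.
#'
#' @param n_exons number of exons (>= 100).
#' @param stages ordered age labels (default: the nine cortex ages
#'   E14.5 ... 21mo).
#' @param coverage_mean mean junction coverage per cell (default 100).
#' @param coverage_size negative-binomial size (dispersion) parameter
#'   (default 5).
#' @param noise_sd trajectory noise SD before read sampling (default 0.05).
#' @param module_mix named proportions over M1, M2, M3, M4, null; must sum
#'   to 1.
#' @param seed integer seed.
#' @return list: `counts` ([JunctionCounts-class]), `psi`
#'   ([PsiExperiment-class] of the noisy generating inclusion levels),
#'   `atlas` ([ReferenceAtlas-class] built from those levels), `truth`
#'   (per-exon data.frame: `exon_id`, `gene_id`, `module`, `sign`, planted
#'   parameters), `catalog` (exon GRanges), `stages`.
#' @examples
#' sim <- simulateReference(n_exons = 200, seed = 1)
#' table(sim$truth$module)
#' @export
simulateReference <- function(n_exons = 1000, stages = .defaultStages(),
                              coverage_mean = 100, coverage_size = 5,
                              noise_sd = 0.05,
                              module_mix = c(M1 = 0.3, M2 = 0.3, M3 = 0.05,
                                             M4 = 0.05, null = 0.3),
                              seed = NULL) {
    stopifnot(n_exons >= 100)
    need <- c("M1", "M2", "M3", "M4", "null")
    if (!setequal(names(module_mix), need) ||
        abs(sum(module_mix) - 1) > 1e-8)
        stop("module_mix must be named over M1, M2, M3, M4, null and sum to 1")
    t <- toLog10Pcdays(stages)
    .withSeed(seed, {
        module <- sample(need, n_exons, replace = TRUE,
                         prob = module_mix[need])
        sgn <- ifelse(module %in% c("M1", "M2"),
                      sample(c("+", "-"), n_exons, replace = TRUE), NA)
        p <- .drawSigmoidParams(n_exons)
        tP0 <- toLog10Pcdays("P0")
        tP7 <- toLog10Pcdays("P7")
        tP15 <- toLog10Pcdays("P15")
        m <- ifelse(module == "M2", rnorm(n_exons, tP0, 0.02),
                    runif(n_exons, tP7, tP15))
        b <- ifelse(!is.na(sgn) & sgn == "-", -p$b, p$b)
        truth <- data.frame(
            exon_id = sprintf("g%05d.1", seq_len(n_exons)),
            gene_id = sprintf("g%05d", seq_len(n_exons)),
            module = module, sign = sgn,
            a = p$a, k = p$k, b = b, m = m,
            b2 = NA_real_, m2 = NA_real_,
            base = runif(n_exons, 0.1, 0.9))
        comp <- module %in% c("M3", "M4")
        # composite: early event at the M2 time, late event (opposite
        # direction) at the M1 time; M3 = up-then-down, M4 = down-then-up
        truth$m[comp] <- rnorm(sum(comp), tP0, 0.02)
        truth$m2[comp] <- runif(sum(comp), tP7, tP15)
        truth$b[comp] <- ifelse(module[comp] == "M3", p$b[comp], -p$b[comp])
        truth$b2[comp] <- -truth$b[comp]
        psiTrue <- .trajectoryAt(truth, t)
        psiNoisy <- .reflect01(psiTrue +
                                   rnorm(length(psiTrue), 0, noise_sd))
        cov <- matrix(rnbinom(length(psiNoisy), mu = coverage_mean,
                              size = coverage_size),
                      n_exons, dimnames = dimnames(psiNoisy))
        x <- matrix(rbinom(length(psiNoisy), as.vector(cov),
                           as.vector(psiNoisy)),
                    n_exons, dimnames = dimnames(psiNoisy))
        counts <- JunctionCounts(inc = 2 * x, skip = cov - x)
        psi <- PsiExperiment(psiNoisy)
        catalog <- .simulateCatalog(truth)
        attr(truth, "stages") <- stages
        # the reference atlas covers the module exons only (null exons carry
        # no developmental signal and would not be in a module catalog)
        modExons <- truth$exon_id[truth$module != "null"]
        list(counts = counts, psi = psi,
             atlas = ReferenceAtlas(psiNoisy[modExons, , drop = FALSE],
                                    defaultStageMap(stages)),
             truth = truth, catalog = catalog, stages = stages)
    })
}

.simulateCatalog <- function(truth) {
    n <- nrow(truth)
    start1 <- sort(sample(1e4:1e8, n))
    len <- sample(30:300, n, replace = TRUE)
    gr <- GRanges(sample(paste0("chr", 1:19), n, replace = TRUE),
                  IRanges(start1, start1 + len - 1L),
                  strand = sample(c("+", "-"), n, replace = TRUE))
    names(gr) <- truth$exon_id
    gr$gene_id <- truth$gene_id
    gr$novelty <- sample(c("known", "novel"), n, replace = TRUE,
                         prob = c(0.66, 0.34))
    gr
}

.trueStageOfAge <- function(age, stages) {
    tq <- toLog10Pcdays(age)
    tref <- toLog10Pcdays(stages)
    unname(defaultStageMap(stages)[which.min(abs(tref - tq))])
}

#' Simulate a query sample at a given developmental age
#'
#' Evaluates every exon's true trajectory at the query age, applies
#' reflected-Gaussian noise, samples junction reads (negative-binomial
#' coverage, binomial inclusion) and masks a random fraction of exons as
#' missing. The true stage is the stage of the nearest reference age.
#'
#' @param truth the `truth` component of [simulateReference()].
#' @param age an age label within the reference range (e.g. `"P4"`).
#' @param coverage_mean,coverage_size read-coverage model (as in
#'   [simulateReference()]); `Inf` coverage returns the noisy trajectory
#'   without read sampling.
#' @param noise_sd trajectory noise SD (default 0.05).
#' @param missing_frac fraction of exons masked missing (default 0).
#' @param seed integer seed.
#' @return list: `psi` (named inclusion vector with `NA` for missing),
#'   `stage` (true stage), `age`, `t` (log10 post-conception days).
#' @export
simulateQuery <- function(truth, age, coverage_mean = 100,
                          coverage_size = 5, noise_sd = 0.05,
                          missing_frac = 0, seed = NULL) {
    stages <- attr(truth, "stages")
    tq <- toLog10Pcdays(age)
    tr <- toLog10Pcdays(stages)
    if (tq < min(tr) - 1e-9 || tq > max(tr) + 1e-9)
        stop(sprintf("age '%s' lies outside the reference range %s..%s",
                     age, stages[1L], stages[length(stages)]))
    .withSeed(seed, {
        psi <- drop(.trajectoryAt(truth, stats::setNames(tq, age)))
        psi <- .reflect01(psi + rnorm(length(psi), 0, noise_sd))
        if (is.finite(coverage_mean)) {
            cov <- rnbinom(length(psi), mu = coverage_mean,
                           size = coverage_size)
            x <- rbinom(length(psi), cov, psi)
            psi <- ifelse(cov > 0, x / cov, NA_real_)
        }
        if (missing_frac > 0)
            psi[runif(length(psi)) < missing_frac] <- NA_real_
        names(psi) <- truth$exon_id
        list(psi = psi, stage = .trueStageOfAge(age, stages),
             age = age, t = tq)
    })
}

#' Simulate a sensory-neuron-like query with dissociated maturity
#'
#' Builds a query whose early-switch (M2) exons are frozen at their
#' earliest-reference (most immature) values while late-switch (M1) exons
#' sit at their adult values -- the mixed pattern expected of a mature cell
#' type whose birth-time splicing program never ran. Staging the M2 subset
#' should therefore return an early stage, the M1 subset a late stage, and
#' the full profile something in between.
#'
#' @param truth the `truth` component of [simulateReference()].
#' @param noise_sd trajectory noise SD (default 0.02).
#' @param seed integer seed.
#' @return list: `psi` (named inclusion vector), `early_exons` (M2 ids),
#'   `late_exons` (M1 ids).
#' @export
simulateSensoryQuery <- function(truth, noise_sd = 0.02, seed = NULL) {
    stages <- attr(truth, "stages")
    t <- toLog10Pcdays(stages)
    .withSeed(seed, {
        traj <- .trajectoryAt(truth, t)
        psi <- traj[, length(stages)]           # adult values by default
        isM2 <- truth$module == "M2"
        psi[isM2] <- traj[isM2, 1L]             # immature values for M2
        psi <- .reflect01(psi + rnorm(length(psi), 0, noise_sd))
        names(psi) <- truth$exon_id
        list(psi = psi,
             early_exons = truth$exon_id[isM2],
             late_exons = truth$exon_id[truth$module == "M1"])
    })
}

#' Simulate gene-set annotations with optional planted enrichment
#'
#' Background terms draw genes uniformly from the simulated genes. Planted
#' terms concentrate on the genes of exons falling in a given switch-time
#' rank interval (exons ranked by their true switch midpoint `m` among the
#' single-sigmoid modules M1/M2), so a sliding-window scan over a
#' correctly recovered ranking must light them up in that interval.
#'
#' @param truth the `truth` component of [simulateReference()].
#' @param n_terms number of background terms (default 100).
#' @param term_size integer range of background term sizes (default 10-40).
#' @param planted optional named list, term id -> `c(first_rank, last_rank)`
#'   interval in the true switch-time ranking.
#' @param planted_size genes drawn per planted term (default 50, capped by
#'   the interval size).
#' @param seed integer seed.
#' @return list: `gene_sets` ([GeneSetCollection-class]), `planted` (the
#'   interval map), `true_ranking` (exon ids, ascending true switch time).
#' @export
simulateGeneSets <- function(truth, n_terms = 100, term_size = c(10, 40),
                             planted = NULL, planted_size = 50,
                             seed = NULL) {
    genes <- unique(truth$gene_id)
    sw <- truth[truth$module %in% c("M1", "M2"), ]
    ranking <- sw$exon_id[order(sw$m, sw$exon_id)]
    .withSeed(seed, {
        sets <- lapply(seq_len(n_terms), function(i)
            sort(sample(genes, sample(term_size[1L]:term_size[2L], 1L))))
        names(sets) <- sprintf("T%04d", seq_len(n_terms))
        for (term in names(planted)) {
            iv <- planted[[term]]
            ex <- ranking[iv[1L]:min(iv[2L], length(ranking))]
            g <- unique(truth$gene_id[match(ex, truth$exon_id)])
            sets[[term]] <- sort(sample(g, min(planted_size, length(g))))
        }
        list(gene_sets = new("GeneSetCollection", sets = sets,
                             termNames = character()),
             planted = planted, true_ranking = ranking)
    })
}
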