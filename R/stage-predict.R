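#' @importFrom stats plogis qlogis dbeta var prcomp
NULL

#' Shrink values away from the \{0, 1\} boundary
#'
#' The beta density is undefined at exactly 0 and 1, so observed inclusion
#' levels are compressed by `y' = (y (n - 1) + 0.5) / n` before fitting,
#' with `n` the number of exons used. Interior values are asymptotically
#' unchanged.
#'
#' @param y values in \[0, 1\].
#' @param n sample size used for the shrink.
#' @return values in (0, 1).
#' @export
shrinkToOpenInterval <- function(y, n = length(y)) (y * (n - 1) + 0.5) / n

.betaLogLik <- function(par, y, X) {
    t <- ncol(X)
    mu <- plogis(drop(X %*% par[seq_len(t)]))
    phi <- exp(par[t + 1L])
    sum(dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
}

.betaGrad <- function(par, y, X) {
    t <- ncol(X)
    eta <- drop(X %*% par[seq_len(t)])
    mu <- plogis(eta)
    phi <- exp(par[t + 1L])
    ystar <- qlogis(y)
    mustar <- digamma(mu * phi) - digamma((1 - mu) * phi)
    gbeta <- phi * drop(crossprod(X, (ystar - mustar) * mu * (1 - mu)))
    dphi <- sum(digamma(phi) - mu * digamma(mu * phi) -
                    (1 - mu) * digamma((1 - mu) * phi) +
                    mu * log(y) + (1 - mu) * log(1 - y))
    c(gbeta, dphi * phi)
}

#' Project a query sample onto a developmental reference by beta regression
#'
#' Models each module exon's inclusion level in the query as beta
#' distributed, `y_i ~ Beta(mu_i, phi)` in the mean/precision
#' parameterization (`var = mu (1 - mu) / (1 + phi)`), with the mean tied to
#' the reference profiles through a logit link and no intercept:
#' `logit(mu_i) = sum_j x_ij beta_j`, where `x_ij` is exon `i`'s inclusion
#' level in reference time point `j`. The maximum-likelihood fit projects
#' the query into the subspace spanned by the reference columns; the fitted
#' `mu_i` are then compared to each reference column to measure
#' developmental distance.
#'
#' Only exons non-missing in the query and complete across all reference
#' columns enter the fit; boundary values are shrunk via
#' [shrinkToOpenInterval()]. Coefficients are initialized by least squares
#' on the logit scale and refined by quasi-Newton ML with analytic
#' gradients, with up to 3 damped restarts.
#'
#' @param y named query inclusion levels over (a superset of) the atlas
#'   exons, values in \[0, 1\], `NA` = missing.
#' @param atlas a [ReferenceAtlas-class].
#' @param min_exons minimum usable exons (default 50).
#' @param add_intercept include an intercept column (default FALSE, matching
#'   the projection model).
#' @return A [BetaProjection-class].
#' @export
projectSample <- function(y, atlas, min_exons = 50, add_intercept = FALSE) {
    X <- psiValues(atlas)
    complete <- rownames(X)[rowSums(is.na(X)) == 0L]
    usable <- intersect(complete, names(y)[!is.na(y)])
    if (length(usable) < min_exons)
        stop(sprintf("insufficient module-exon coverage: %d usable exons (< %d)",
                     length(usable), min_exons))
    yv <- y[usable]
    if (any(yv < 0 | yv > 1))
        stop("query inclusion levels must lie in [0, 1]")
    X <- X[usable, , drop = FALSE]
    n <- length(yv)
    ys <- shrinkToOpenInterval(yv, n)
    Xf <- if (add_intercept) cbind(`(intercept)` = 1, X) else X
    # initialization: OLS on the logit scale, method-of-moments precision
    beta0 <- tryCatch(qr.solve(Xf, qlogis(ys)),
                      error = function(e) rep(0, ncol(Xf)))
    mu0 <- plogis(drop(Xf %*% beta0))
    s2 <- max(var(ys - mu0), 1e-6)
    phi0 <- max(mean(mu0 * (1 - mu0)) / s2 - 1, 1)
    par <- c(beta0, log(phi0))
    best <- NULL
    for (attempt in 1:3) {
        o <- tryCatch(
            optim(par, fn = .betaLogLik, gr = .betaGrad, y = ys, X = Xf,
                  method = "BFGS",
                  control = list(fnscale = -1, maxit = 500, reltol = 1e-12)),
            error = function(e) NULL)
        if (!is.null(o) && (is.null(best) || o$value > best$value)) best <- o
        if (!is.null(o) && o$convergence == 0L) break
        par <- c(beta0 * 0.5^attempt, log(phi0))  # damped restart
    }
    if (is.null(best))
        stop("beta-regression optimizer failed; check the query profile for ",
             "degenerate values")
    t <- ncol(Xf)
    beta <- setNames(best$par[seq_len(t)], colnames(Xf))
    muHat <- plogis(drop(Xf %*% beta))
    new("BetaProjection", beta = beta, phi = exp(best$par[t + 1L]),
        muHat = unname(muHat), exonIds = usable, logLik = best$value,
        converged = !is.null(best) && best$convergence == 0L)
}

#' Squared distances from a projected sample to each reference time point
#'
#' `D_j = sum_i (x_ij - muHat_i)^2` over the exons used in the projection;
#' reported as the squared distance (no square root), so smaller is closer.
#'
#' @param proj a [BetaProjection-class].
#' @param atlas the [ReferenceAtlas-class] used for the projection.
#' @return named numeric vector, one entry per reference sample.
#' @export
sampleDistances <- function(proj, atlas) {
    X <- psiValues(atlas)[proj@exonIds, , drop = FALSE]
    colSums((X - proj@muHat)^2)
}

#' Assign a maturation stage from reference distances by 1-nearest neighbor
#'
#' The stage of the closest reference sample is taken (with the default
#' cortex atlas, all P15-or-older references share the terminal stage 6).
#' Confidence is `S = 1 - min(D) / max(D)`: 1 when some reference matches
#' perfectly, 0 when all references are equally distant. Ties on the minimum
#' are broken toward the earlier (younger) stage.
#'
#' @param D named distance vector from [sampleDistances()].
#' @param atlas the [ReferenceAtlas-class].
#' @param subset_tag label recorded for the exon universe used.
#' @param n_exons_used number of exons behind the distances.
#' @param pca_xy optional 2-D display coordinates.
#' @return A [StagePrediction-class].
#' @export
assignStage <- function(D, atlas, subset_tag = "all",
                        n_exons_used = NA_integer_,
                        pca_xy = c(NA_real_, NA_real_)) {
    sm <- stageMap(atlas)
    stopifnot(identical(names(D), names(sm)))
    mins <- which(D == min(D))
    if (length(mins) == length(D) && length(D) > 1L)
        warning("all reference distances equal; stage is ambiguous")
    pick <- mins[which.min(sm[mins])]
    S <- if (max(D) == 0) 0 else 1 - min(D) / max(D)
    new("StagePrediction", distances = D, stage = unname(sm[pick]),
        confidence = S, pcaXY = as.numeric(pca_xy),
        subsetTag = subset_tag,
        nExonsUsed = as.integer(n_exons_used))
}

#' Staging accuracy with and without adjacency tolerance
#'
#' @param predictions integer stages or list of [StagePrediction-class].
#' @param truths true integer stages, same length.
#' @return list with `exact` (fraction identical) and `within_one`
#'   (fraction within one stage, counting a prediction immediately adjacent
#'   to the truth as correct).
#' @export
stageAccuracy <- function(predictions, truths) {
    if (is.list(predictions))
        predictions <- vapply(predictions, predictedStage, integer(1))
    if (!length(predictions) || length(predictions) != length(truths))
        stop("predictions and truths must be non-empty and the same length")
    list(exact = mean(predictions == truths),
         within_one = mean(abs(predictions - truths) <= 1L))
}

#' PCA of the reference atlas with query projection
#'
#' Fits principal components on the reference samples only (exon-wise
#' centered by the reference mean, unscaled) and projects query profiles
#' into the plane of the first two components; query exons missing from a
#' profile are imputed with the reference mean, i.e. they contribute zero
#' after centering. Display-only: stage assignment never uses these
#' coordinates.
#'
#' @param atlas a [ReferenceAtlas-class] (complete on its exons).
#' @param queries optional named list (or single vector) of query inclusion
#'   profiles over the atlas exons.
#' @return matrix of PC1/PC2 coordinates for the reference samples followed
#'   by the queries.
#' @export
pcaProject <- function(atlas, queries = NULL) {
    X <- psiValues(atlas)
    keep <- rowSums(is.na(X)) == 0L
    X <- X[keep, , drop = FALSE]
    pc <- prcomp(t(X), center = TRUE, scale. = FALSE)
    refxy <- pc$x[, 1:2, drop = FALSE]
    out <- refxy
    if (!is.null(queries)) {
        if (!is.list(queries)) queries <- list(query = queries)
        qxy <- t(vapply(queries, function(q) {
            qv <- q[rownames(X)]
            qv[is.na(qv)] <- pc$center[is.na(qv)]
            drop((qv - pc$center) %*% pc$rotation[, 1:2])
        }, numeric(2)))
        rownames(qxy) <- names(queries)
        out <- rbind(refxy, qxy)
    }
    colnames(out) <- c("PC1", "PC2")
    out
}

#' Predict the maturation stage of a query sample
#'
#' Orchestrates the full staging pipeline: restrict to an optional exon
#' subset, project by beta regression ([projectSample()]), measure squared
#' distances to every reference time point ([sampleDistances()]), assign
#' the stage of the nearest reference ([assignStage()]) and attach PC1/PC2
#' display coordinates ([pcaProject()]). Restricting `subset` to the direct
#' targets of one RNA-binding protein stages the sample by that regulator's
#' program alone.
#'
#' @param query named inclusion levels over (a superset of) the atlas exons.
#' @param atlas a [ReferenceAtlas-class].
#' @param subset optional exon ids to restrict to; a label can be given via
#'   `subset_tag`.
#' @param subset_tag recorded label for the universe (defaults to "all", or
#'   "subset" when `subset` is given).
#' @param min_exons minimum usable exons (default 50).
#' @return A [StagePrediction-class].
#' @examples
#' sim <- simulateReference(n_exons = 300, seed = 7)
#' q <- simulateQuery(sim$truth, age = "P4", seed = 8)
#' predictStage(q$psi, sim$atlas, min_exons = 30)
#' @export
predictStage <- function(query, atlas, subset = NULL, subset_tag = NULL,
                         min_exons = 50) {
    if (!is.null(subset)) {
        keep <- intersect(rownames(atlas), subset)
        if (!length(keep))
            stop("subset has no exons in common with the reference atlas")
        atlas <- atlas[keep, ]
        if (is.null(subset_tag)) subset_tag <- "subset"
    }
    if (is.null(subset_tag)) subset_tag <- "all"
    proj <- projectSample(query, atlas, min_exons = min_exons)
    D <- sampleDistances(proj, atlas)
    xy <- pcaProject(atlas, queries = list(q = query))
    assignStage(D, atlas, subset_tag = subset_tag,
                n_exons_used = length(proj@exonIds),
                pca_xy = xy[nrow(xy), ])
}
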