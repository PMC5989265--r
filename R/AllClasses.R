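#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames rowData colData
NULL

#' PsiExperiment: exon inclusion levels with per-cell coverage
#'
#' A [SummarizedExperiment::SummarizedExperiment] with two assays:
#' `"psi"` (percent spliced in, values in \[0, 1\] or `NA` for cells that
#' failed quantification filters) and `"coverage"` (effective junction-read
#' coverage backing each estimate, `NA` exactly where `psi` is `NA`).
#' Rows are cassette exons keyed by `exon_id`, columns are samples.
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment].
#' @export
setClass("PsiExperiment", contains = "SummarizedExperiment")

.validPsiExperiment <- function(object) {
    msg <- character()
    if (!all(c("psi", "coverage") %in% assayNames(object)))
        msg <- c(msg, "assays must include 'psi' and 'coverage'")
    else {
        psi <- assay(object, "psi")
        cov <- assay(object, "coverage")
        ok <- is.na(psi) | (psi >= 0 & psi <= 1)
        if (!all(ok))
            msg <- c(msg, "all non-missing psi values must lie in [0, 1]")
        if (!identical(unname(is.na(psi)), unname(is.na(cov))))
            msg <- c(msg, "coverage must be missing exactly where psi is missing")
        if (any(cov < 0, na.rm = TRUE))
            msg <- c(msg, "coverage must be non-negative")
    }
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "exon ids (rownames) must be unique")
    if (length(msg)) msg else TRUE
}
setValidity("PsiExperiment", .validPsiExperiment)

#' Construct a PsiExperiment from a psi matrix and coverage matrix
#'
#' @param psi numeric matrix of inclusion levels in \[0, 1\] (NA = missing),
#'   exons as rows (rownames = exon ids), samples as columns.
#' @param coverage numeric matrix of the same shape; defaults to `Inf` where
#'   psi is observed, i.e. "coverage unknown but sufficient".
#' @param rowData optional per-exon annotation (e.g. `gene_id`).
#' @return A [PsiExperiment-class] object.
#' @examples
#' psi <- matrix(c(0.1, 0.9, 0.5, NA), 2, 2,
#'               dimnames = list(c("ex1", "ex2"), c("s1", "s2")))
#' PsiExperiment(psi)
#' @export
PsiExperiment <- function(psi, coverage = NULL, rowData = NULL) {
    psi <- as.matrix(psi)
    if (is.null(rownames(psi)))
        stop("psi matrix must carry exon ids as rownames")
    if (is.null(coverage)) {
        coverage <- matrix(Inf, nrow(psi), ncol(psi), dimnames = dimnames(psi))
        coverage[is.na(psi)] <- NA_real_
    }
    coverage <- as.matrix(coverage)
    args <- list(assays = SimpleList(psi = psi, coverage = coverage))
    if (!is.null(rowData)) args$rowData <- rowData
    new("PsiExperiment", do.call(SummarizedExperiment, args))
}

#' @describeIn PsiExperiment extract the psi matrix.
#' @param x a `PsiExperiment`.
#' @export
psiValues <- function(x) assay(x, "psi")

#' @describeIn PsiExperiment extract the coverage matrix.
#' @export
coverageValues <- function(x) assay(x, "coverage")

#' ReferenceAtlas: ordered developmental reference of module-exon psi
#'
#' Extends [PsiExperiment-class]: the columns are reference developmental
#' time points in chronological order, and `stageMap` assigns each to an
#' ordinal maturation stage (with the default cortex atlas,
#' E14.5/E16.5/P0/P4/P7 map to stages 1--5 and every P15-or-older time
#' point to stage 6, because post-P15 profiles are nearly identical).
#'
#' @slot stageMap named integer vector, one entry per column, values
#'   covering `1..max(stageMap)` contiguously.
#' @export
setClass("ReferenceAtlas", contains = "PsiExperiment",
         representation(stageMap = "integer"))

setValidity("ReferenceAtlas", function(object) {
    msg <- character()
    sm <- object@stageMap
    if (!identical(names(sm), colnames(object)))
        msg <- c(msg, "stageMap names must equal the column names, in order")
    if (length(sm)) {
        if (any(is.na(sm)) || any(sm < 1L))
            msg <- c(msg, "stages must be positive integers")
        else if (!setequal(unique(sm), seq_len(max(sm))))
            msg <- c(msg, "stages must cover 1..max(stage) with no gaps")
        if (is.unsorted(sm))
            msg <- c(msg, "stages must be non-decreasing in column (age) order")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a ReferenceAtlas
#'
#' @param psi exon x time-point matrix of reference inclusion levels, columns
#'   in chronological order (e.g. the nine cortex ages E14.5 ... 21mo).
#' @param stageMap named integer vector mapping each column to a maturation
#'   stage; default derives the six-stage cortex map from the column labels
#'   via [defaultStageMap()].
#' @param coverage optional coverage matrix (see [PsiExperiment()]).
#' @return A [ReferenceAtlas-class].
#' @examples
#' ref <- simulateReference(n_exons = 120, seed = 1)
#' atlas <- ref$atlas
#' stageMap(atlas)
#' @export
ReferenceAtlas <- function(psi, stageMap = NULL, coverage = NULL) {
    pe <- PsiExperiment(psi, coverage)
    if (is.null(stageMap)) stageMap <- defaultStageMap(colnames(pe))
    stageMap <- stageMap[colnames(pe)]
    new("ReferenceAtlas", pe, stageMap = as.integer(stageMap) |>
            stats::setNames(colnames(pe)))
}

#' Six-stage map for cortex-style age labels
#'
#' Maps age labels to maturation stages: the five distinct prenatal/early
#' postnatal ages get stages in chronological order and all ages at or after
#' P15 share the terminal stage.
#'
#' @param labels character age labels parseable by [toLog10Pcdays()].
#' @param adult_from post-conception days at and beyond which all ages are
#'   pooled into one terminal stage (default P15 = 34.5 pc-days).
#' @return named integer vector of stages.
#' @export
defaultStageMap <- function(labels, adult_from = 19.5 + 15) {
    pcd <- 10^toLog10Pcdays(labels)
    if (is.unsorted(pcd, strictly = TRUE))
        stop("age labels must be in strictly increasing chronological order")
    grp <- ifelse(pcd >= adult_from, Inf, pcd)
    stats::setNames(as.integer(match(grp, unique(grp))), labels)
}

#' @describeIn ReferenceAtlas the column -> stage map.
#' @param x a `ReferenceAtlas`.
#' @export
stageMap <- function(x) x@stageMap

#' @describeIn ReferenceAtlas reference time-point labels, in age order.
#' @export
timePoints <- function(x) colnames(x)

setMethod("show", "ReferenceAtlas", function(object) {
    callNextMethod()
    cat("stages:", paste0(names(object@stageMap), "=", object@stageMap,
                          collapse = " "), "\n")
})

#' JunctionCounts: inclusion/skipping junction reads per exon per sample
#'
#' A [SummarizedExperiment::SummarizedExperiment] with integer assays
#' `"inc"` (reads on the two inclusion junctions, summed) and `"skip"`
#' (reads on the skipping junction). `NA` marks (exon, sample) pairs that
#' were never observed; zero is a real observation.
#' @export
setClass("JunctionCounts", contains = "SummarizedExperiment")

setValidity("JunctionCounts", function(object) {
    msg <- character()
    if (!all(c("inc", "skip") %in% assayNames(object)))
        msg <- c(msg, "assays must include 'inc' and 'skip'")
    else {
        for (a in c("inc", "skip")) {
            v <- assay(object, a)
            if (any(v < 0, na.rm = TRUE))
                msg <- c(msg, sprintf("'%s' counts must be non-negative", a))
        }
    }
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "exon ids (rownames) must be unique")
    if (length(msg)) msg else TRUE
})

#' Construct JunctionCounts from matrices
#'
#' @param inc,skip non-negative count matrices (exons x samples), identical
#'   dimnames; `NA` where the pair is unobserved.
#' @return A [JunctionCounts-class].
#' @export
JunctionCounts <- function(inc, skip) {
    inc <- as.matrix(inc); skip <- as.matrix(skip)
    stopifnot(identical(dim(inc), dim(skip)))
    new("JunctionCounts",
        SummarizedExperiment(assays = SimpleList(inc = inc, skip = skip)))
}

#' @describeIn JunctionCounts inclusion-junction read matrix.
#' @param x a `JunctionCounts`.
#' @export
incReads <- function(x) assay(x, "inc")

#' @describeIn JunctionCounts skipping-junction read matrix.
#' @export
skipReads <- function(x) assay(x, "skip")

#' ExonModules: module assignment plus eigenexons
#'
#' Result container for temporal co-splicing module detection: a per-exon
#' assignment table and the eigenexon (first principal component of the
#' standardized member profiles) of each module.
#'
#' @slot assignment data.frame with columns `exon_id`, `module` (label or
#'   `NA` for unassigned), `sign` (`"+"`/`"-"`), `eigen_corr`, `core`.
#' @slot eigenexons numeric matrix, modules x time points, unit-norm rows.
#' @export
setClass("ExonModules",
         representation(assignment = "data.frame", eigenexons = "matrix"))

setValidity("ExonModules", function(object) {
    a <- object@assignment
    need <- c("exon_id", "module", "sign", "eigen_corr", "core")
    if (!all(need %in% names(a)))
        return(paste("assignment must have columns:", paste(need, collapse = ", ")))
    if (nrow(object@eigenexons) &&
        !all(stats::na.omit(unique(a$module)) %in% rownames(object@eigenexons)))
        return("every assigned module must have an eigenexon row")
    TRUE
})

setMethod("show", "ExonModules", function(object) {
    a <- object@assignment
    cat(class(object), "with", nrow(a), "exons in",
        nrow(object@eigenexons), "modules\n")
    if (nrow(object@eigenexons)) {
        tab <- table(a$module, a$sign)
        print(tab)
        cat(sum(a$core, na.rm = TRUE), "core members\n")
    }
})

#' @describeIn ExonModules per-exon assignment table.
#' @param x an `ExonModules`.
#' @export
moduleAssignment <- function(x) x@assignment

#' @describeIn ExonModules eigenexon matrix (modules x time points).
#' @export
eigenexons <- function(x) x@eigenexons

#' BetaProjection: beta-regression projection of a query onto the reference
#'
#' The maximum-likelihood fit of a query sample's module-exon inclusion
#' levels on the reference columns under a beta likelihood with logit link
#' and common precision: `logit(mu_i) = sum_j x_ij beta_j`.
#'
#' @slot beta coefficient per reference time point.
#' @slot phi common precision, > 0.
#' @slot muHat fitted inclusion level per exon used, in (0, 1).
#' @slot exonIds exons entering the fit.
#' @slot logLik attained log-likelihood.
#' @slot converged logical.
#' @export
setClass("BetaProjection",
         representation(beta = "numeric", phi = "numeric", muHat = "numeric",
                        exonIds = "character", logLik = "numeric",
                        converged = "logical"))

setValidity("BetaProjection", function(object) {
    msg <- character()
    if (length(object@phi) != 1L || object@phi <= 0)
        msg <- c(msg, "phi must be a single positive number")
    if (any(object@muHat <= 0 | object@muHat >= 1))
        msg <- c(msg, "fitted means must lie strictly inside (0, 1)")
    if (length(object@muHat) != length(object@exonIds))
        msg <- c(msg, "one fitted mean per exon used")
    if (length(msg)) msg else TRUE
})

setMethod("show", "BetaProjection", function(object) {
    cat(class(object), "over", length(object@exonIds), "exons\n")
    cat("beta:", paste0(names(object@beta), "=",
                        signif(object@beta, 3), collapse = " "), "\n")
    cat("phi:", signif(object@phi, 4),
        " logLik:", signif(object@logLik, 6),
        if (!object@converged) " (not converged)" else "", "\n")
})

#' @describeIn BetaProjection regression coefficients (one per reference column).
#' @param x a `BetaProjection`.
#' @export
projectionBeta <- function(x) x@beta

#' @describeIn BetaProjection common precision estimate.
#' @export
projectionPhi <- function(x) x@phi

#' @describeIn BetaProjection fitted per-exon inclusion levels.
#' @export
fittedPsi <- function(x) stats::setNames(x@muHat, x@exonIds)

#' StagePrediction: maturation-stage call for one query sample
#'
#' @slot distances squared-distance to each reference sample (named).
#' @slot stage assigned ordinal stage (1-NN over `distances`).
#' @slot confidence `1 - min(D)/max(D)`, in \[0, 1\].
#' @slot pcaXY coordinates of the query in the reference PC1/PC2 plane.
#' @slot subsetTag exon universe used ("all" or a subset label).
#' @slot nExonsUsed exons entering the projection.
#' @export
setClass("StagePrediction",
         representation(distances = "numeric", stage = "integer",
                        confidence = "numeric", pcaXY = "numeric",
                        subsetTag = "character", nExonsUsed = "integer"))

setValidity("StagePrediction", function(object) {
    msg <- character()
    if (length(object@confidence) != 1L ||
        object@confidence < 0 || object@confidence > 1)
        msg <- c(msg, "confidence must be a single value in [0, 1]")
    if (length(object@stage) != 1L || object@stage < 1L)
        msg <- c(msg, "stage must be a single positive integer")
    if (length(msg)) msg else TRUE
})

setMethod("show", "StagePrediction", function(object) {
    cat(class(object), ": stage ", object@stage,
        " (confidence ", round(object@confidence, 3), ")\n", sep = "")
    cat("nearest reference:", names(object@distances)[which.min(object@distances)],
        " exons used:", object@nExonsUsed,
        " subset:", object@subsetTag, "\n")
})

#' @describeIn StagePrediction assigned maturation stage.
#' @param x a `StagePrediction`.
#' @export
predictedStage <- function(x) x@stage

#' @describeIn StagePrediction confidence score `1 - min(D)/max(D)`.
#' @export
stageConfidence <- function(x) x@confidence

#' @describeIn StagePrediction squared distances to the reference samples.
#' @export
sampleDistanceVector <- function(x) x@distances

#' Serialize stage predictions to JSON
#'
#' @param predictions a `StagePrediction` or list of them (named by sample).
#' @param path output file; if `NULL` the JSON string is returned.
#' @return invisibly, the JSON string.
#' @export
writeStagePredictions <- function(predictions, path = NULL) {
    if (is(predictions, "StagePrediction")) predictions <- list(predictions)
    rec <- lapply(predictions, function(p) list(
        stage = p@stage,
        confidence = p@confidence,
        distances = as.list(p@distances),
        pca_xy = unname(p@pcaXY),
        subset_tag = p@subsetTag,
        n_exons_used = p@nExonsUsed))
    js <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(path)) writeLines(js, path)
    invisible(js)
}
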