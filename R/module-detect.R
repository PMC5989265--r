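#' @importFrom stats cor hclust as.dist cutree qt sd
NULL

#' Critical Pearson correlation at a given significance level
#'
#' The smallest `|r|` whose two-sided p-value under the t transform
#' `t = r sqrt(n - 2) / sqrt(1 - r^2)` with `n - 2` degrees of freedom is at
#' most `alpha`. Used to define core module members; with nine time points
#' and `alpha = 0.001` the threshold is about 0.898.
#'
#' @param n number of paired observations (>= 3).
#' @param alpha two-sided significance level in (0, 1).
#' @return the critical correlation magnitude.
#' @examples
#' criticalCorrelation(9, 0.001)  # ~0.898
#' @export
criticalCorrelation <- function(n, alpha) {
    if (n < 3) stop("need at least 3 observations")
    stopifnot(alpha > 0, alpha < 1)
    tcrit <- qt(1 - alpha / 2, df = n - 2)
    tcrit / sqrt(tcrit^2 + (n - 2))
}

#' Correlation-network adjacency of exon inclusion profiles
#'
#' `a_uv = |pearson(u, v)|^power` for the unsigned network (the default;
#' direction is recovered downstream by the +/- eigenexon split), or
#' `((1 + r) / 2)^power` for a signed network. Diagonal is 1.
#'
#' @param psi a [PsiExperiment-class] or matrix, exons x time points, rows
#'   complete (no missing values).
#' @param power soft-threshold exponent (default 3).
#' @param signed use the signed transform (default FALSE).
#' @return symmetric exon x exon matrix with entries in \[0, 1\].
#' @export
adjacencyMatrix <- function(psi, power = 3, signed = FALSE) {
    m <- if (is(psi, "PsiExperiment")) psiValues(psi) else as.matrix(psi)
    if (anyNA(m))
        stop("adjacency requires complete profiles; filter missing exons first")
    v <- apply(m, 1L, sd)
    if (any(v == 0))
        stop(sprintf("exon '%s' has zero variance across time points",
                     rownames(m)[which(v == 0)[1L]]))
    r <- cor(t(m))
    a <- if (signed) ((1 + r) / 2)^power else abs(r)^power
    diag(a) <- 1
    a
}

#' Topological-overlap dissimilarity
#'
#' Unsigned topological overlap of an adjacency matrix:
#' `TOM_uv = (l_uv + a_uv) / (min(k_u, k_v) + 1 - a_uv)` with
#' `l_uv = sum_w a_uw a_wv` over `w != u, v` and `k_u` the connectivity of
#' `u`; the returned matrix is `1 - TOM` (0 on the diagonal).
#'
#' @param adj adjacency from [adjacencyMatrix()].
#' @return dissimilarity matrix in \[0, 1\].
#' @export
tomDissimilarity <- function(adj) {
    a0 <- adj
    diag(a0) <- 0
    l <- a0 %*% a0
    k <- colSums(a0)
    denom <- outer(k, k, pmin) + 1 - a0
    tom <- (l + a0) / denom
    diag(tom) <- 1
    d <- 1 - tom
    # guard tiny negative values from floating-point noise
    d[d < 0] <- 0
    d
}

.eigenexon <- function(profiles) {
    # first PC of the standardized (per-exon centered/scaled) profiles,
    # returned over time points with unit norm; oriented so that the mean
    # correlation with the member profiles is non-negative
    z <- t(scale(t(profiles)))
    s <- svd(z, nu = 0, nv = 1)
    v <- s$v[, 1L]
    v <- v / sqrt(sum(v^2))
    cors <- suppressWarnings(apply(profiles, 1L, cor, y = v))
    mc <- mean(cors, na.rm = TRUE)
    if (is.na(mc) || mc == 0) {
        nz <- which(v != 0)[1L]
        if (!is.na(nz) && v[nz] < 0) v <- -v
    } else if (mc < 0) v <- -v
    v
}

#' Detect temporal co-splicing exon modules
#'
#' Pipeline: correlation adjacency (power `power`) -> topological-overlap
#' dissimilarity -> average-linkage hierarchical clustering -> static cut at
#' `cut_height` (default: the greatest height that maximizes the number of
#' clusters reaching `min_size`, scanned over the dendrogram merge levels)
#' -> drop clusters smaller than `min_size` -> eigenexon per
#' cluster -> iterative merging of the closest module pair while their
#' eigenexon dissimilarity `1 - cor` is below `merge_diss`, recomputing
#' eigenexons after every merge. Optional `force_merge` merges named module
#' pairs afterwards regardless of dissimilarity (for curation), again
#' recomputing the eigenexon.
#'
#' Modules are labelled `M1, M2, ...` in decreasing size order. Each exon's
#' `eigen_corr` is its Pearson correlation with its module's eigenexon;
#' `sign` is the sign of that correlation (the M+/M- split) and `core`
#' marks exons with `|eigen_corr|` at or above the critical value from
#' [criticalCorrelation()] at `alpha`.
#'
#' @param psi [PsiExperiment-class] or matrix, exons x time points, complete.
#' @param power soft-threshold exponent (default 3).
#' @param min_size smallest retained module (default 30).
#' @param merge_diss eigenexon dissimilarity below which modules merge
#'   (default 0.25).
#' @param cut_height static tree-cut height; `NULL` for the quantile default.
#' @param alpha core-membership significance level (default 0.001).
#' @param signed signed adjacency (default FALSE).
#' @param force_merge optional list of character pairs of module labels to
#'   merge after automatic merging.
#' @return An [ExonModules-class].
#' @export
detectModules <- function(psi, power = 3, min_size = 30, merge_diss = 0.25,
                          cut_height = NULL, alpha = 0.001, signed = FALSE,
                          force_merge = NULL) {
    m <- if (is(psi, "PsiExperiment")) psiValues(psi) else as.matrix(psi)
    if (nrow(m) < min_size) {
        warning("fewer exons than min_size; no modules detected")
        return(.emptyModules(rownames(m)))
    }
    adj <- adjacencyMatrix(m, power = power, signed = signed)
    diss <- tomDissimilarity(adj)
    hc <- hclust(as.dist(diss), method = "average")
    if (is.null(cut_height))
        cut_height <- .bestCutHeight(hc, min_size)
    cl <- .cutAtHeight(hc, cut_height)
    sizes <- table(cl)
    keep <- names(sizes)[sizes >= min_size]
    if (!length(keep)) {
        warning("no cluster reached min_size; no modules detected")
        return(.emptyModules(rownames(m)))
    }
    members <- lapply(keep, function(k) rownames(m)[cl == as.integer(k)])
    members <- .mergeModules(members, m, merge_diss)
    if (!is.null(force_merge))
        members <- .forceMerge(members, force_merge)
    # deterministic labels: decreasing size, ties by first exon id
    ord <- order(-lengths(members),
                 vapply(members, function(x) sort(x)[1L], ""))
    members <- members[ord]
    names(members) <- paste0("M", seq_along(members))
    eig <- t(vapply(members, function(ex) .eigenexon(m[ex, , drop = FALSE]),
                    numeric(ncol(m))))
    colnames(eig) <- colnames(m)
    assign <- .assignTable(rownames(m), members, eig, m,
                           rstar = criticalCorrelation(ncol(m), alpha))
    new("ExonModules", assignment = assign, eigenexons = eig)
}

# static-cut height selection: scan candidate heights (midpoints between
# consecutive merge heights) and keep the greatest height that maximizes the
# number of clusters reaching min_size -- deterministic, and on planted
# fixtures it lands between the within-module and between-module join levels
.bestCutHeight <- function(hc, min_size) {
    hs <- sort(unique(hc$height))
    if (length(hs) < 2L) return(hs[1L] + 1e-8)
    cand <- (hs[-1L] + hs[-length(hs)]) / 2
    if (length(cand) > 200L)
        cand <- unique(as.numeric(quantile(cand, seq(0, 1, length.out = 200L))))
    counts <- vapply(cand, function(h) {
        sizes <- table(.cutAtHeight(hc, h))
        sum(sizes >= min_size)
    }, numeric(1))
    cand[max(which(counts == max(counts)))]
}

# cutree() rejects dendrograms with height inversions (average linkage on
# topological overlap can produce slight ones); cutting is done on a
# monotonicity-enforced copy, which preserves the merge order
.cutAtHeight <- function(hc, h) {
    if (is.unsorted(hc$height)) hc$height <- cummax(hc$height)
    cutree(hc, h = h)
}

.mergeModules <- function(members, m, merge_diss) {
    repeat {
        if (length(members) < 2L) break
        eig <- vapply(members, function(ex) .eigenexon(m[ex, , drop = FALSE]),
                      numeric(ncol(m)))
        d <- 1 - cor(eig)
        diag(d) <- Inf
        if (min(d) >= merge_diss) break
        ij <- which(d == min(d), arr.ind = TRUE)[1L, ]
        i <- min(ij); j <- max(ij)
        members[[i]] <- c(members[[i]], members[[j]])
        members[[j]] <- NULL
    }
    members
}

.forceMerge <- function(members, pairs) {
    if (is.character(pairs)) pairs <- list(pairs)
    for (p in pairs) {
        idx <- match(p, names(members))
        if (anyNA(idx))
            stop("force_merge refers to unknown module label(s): ",
                 paste(p[is.na(idx)], collapse = ", "))
        i <- min(idx)
        members[[i]] <- unlist(members[idx], use.names = FALSE)
        members[setdiff(idx, i)] <- NULL
    }
    members
}

.assignTable <- function(exons, members, eig, m, rstar) {
    module <- rep(NA_character_, length(exons))
    names(module) <- exons
    for (lab in names(members)) module[members[[lab]]] <- lab
    r <- rep(NA_real_, length(exons))
    for (lab in names(members)) {
        ex <- members[[lab]]
        r[match(ex, exons)] <- apply(m[ex, , drop = FALSE], 1L, cor,
                                     y = eig[lab, ])
    }
    data.frame(exon_id = exons, module = unname(module),
               sign = ifelse(is.na(r), NA_character_,
                             ifelse(r >= 0, "+", "-")),
               eigen_corr = r,
               core = !is.na(r) & abs(r) >= rstar,
               row.names = NULL)
}

.emptyModules <- function(exons) {
    new("ExonModules",
        assignment = data.frame(exon_id = exons %||% character(),
                                module = NA_character_, sign = NA_character_,
                                eigen_corr = NA_real_, core = FALSE)[
                                    seq_along(exons), , drop = FALSE],
        eigenexons = matrix(numeric(), 0, 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Re-evaluate core membership at a different significance level
#'
#' Recomputes each assigned exon's correlation with its module eigenexon and
#' flags core members at `|r| >= criticalCorrelation(n_timepoints, alpha)`;
#' the +/- sign is refreshed from the correlation.
#'
#' @param modules an [ExonModules-class].
#' @param psi the matrix/[PsiExperiment-class] the modules were built from.
#' @param alpha significance level (default 0.001).
#' @return an updated [ExonModules-class].
#' @export
coreMembers <- function(modules, psi, alpha = 0.001) {
    m <- if (is(psi, "PsiExperiment")) psiValues(psi) else as.matrix(psi)
    a <- moduleAssignment(modules)
    eig <- eigenexons(modules)
    rstar <- criticalCorrelation(ncol(m), alpha)
    for (i in seq_len(nrow(a))) {
        if (is.na(a$module[i])) next
        r <- cor(m[a$exon_id[i], ], eig[a$module[i], ])
        a$eigen_corr[i] <- r
        a$sign[i] <- if (r >= 0) "+" else "-"
        a$core[i] <- abs(r) >= rstar
    }
    new("ExonModules", assignment = a, eigenexons = eig)
}
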