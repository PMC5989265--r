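#' @importFrom stats fisher.test p.adjust setNames
NULL

#' Estimate percent spliced in (PSI) from junction counts
#'
#' For each (exon, sample) cell, the effective inclusion count is
#' `i = inc_reads / 2` when `halve_inclusion = TRUE` (a cassette exon's
#' inclusion isoform spans two junctions while the skipping isoform spans
#' one, so the raw inclusion reads are halved to put the two isoforms on the
#' same scale), coverage is `c = i + skip_reads` and `PSI = i / c`. Cells
#' with `c < min_cov`, or whose binomial standard deviation
#' `sqrt(PSI * (1 - PSI) / c)` is `>= max_sd`, are set to missing, as are
#' cells with zero coverage.
#'
#' @param counts a [JunctionCounts-class].
#' @param min_cov minimum effective coverage to keep an estimate (default 20).
#' @param max_sd binomial standard-deviation cap (default 0.1); the filter
#'   removes estimates with `SD >= max_sd`.
#' @param halve_inclusion halve the inclusion-junction reads (default TRUE).
#' @return A [PsiExperiment-class] with assays `psi` and `coverage`.
#' @examples
#' jc <- JunctionCounts(inc = matrix(40, 1, 1, dimnames = list("ex1", "s1")),
#'                      skip = matrix(10, 1, 1, dimnames = list("ex1", "s1")))
#' psiValues(estimatePsi(jc))  # 20 / (20 + 10)
#' @export
estimatePsi <- function(counts, min_cov = 20, max_sd = 0.1,
                        halve_inclusion = TRUE) {
    stopifnot(min_cov > 0)
    i <- incReads(counts)
    if (halve_inclusion) i <- i / 2
    cov <- i + skipReads(counts)
    psi <- ifelse(cov > 0, i / cov, NA_real_)
    sd <- sqrt(psi * (1 - psi) / cov)
    drop <- is.na(psi) | cov < min_cov | (!is.na(sd) & sd >= max_sd)
    psi[drop] <- NA_real_
    covOut <- cov
    covOut[is.na(psi)] <- NA_real_
    PsiExperiment(psi, covOut)
}

#' Differential splicing between two conditions by Fisher's exact test
#'
#' Replicates within each condition are pooled by summing junction reads.
#' Each exon's pooled (inclusion, skipping) counts form a 2x2 table
#' (inclusion counts halved per the two-junction convention, then rounded
#' half-to-even to integers) tested with the standard two-sided Fisher's
#' exact test. `dpsi` is `PSI_b - PSI_a` from the pooled estimates. An exon
#' is `called` when both pooled coverages reach `min_cov`, the
#' Benjamini-Hochberg FDR is at most `fdr_max`, and `|dpsi| >= dpsi_min`.
#'
#' @param counts_a,counts_b [JunctionCounts-class] for the two conditions.
#' @param min_cov minimum pooled coverage in both conditions (default 20).
#' @param fdr_max FDR cutoff (default 0.05).
#' @param dpsi_min minimum absolute PSI change (default 0.2).
#' @param halve_inclusion halve inclusion-junction reads (default TRUE).
#' @return data.frame with one row per exon present in both conditions:
#'   `exon_id`, `psi_a`, `psi_b`, `dpsi`, `coverage_a`, `coverage_b`, `p`,
#'   `fdr`, `called`.
#' @export
fisherDiff <- function(counts_a, counts_b, min_cov = 20, fdr_max = 0.05,
                       dpsi_min = 0.2, halve_inclusion = TRUE) {
    pa <- .poolCounts(counts_a, halve_inclusion)
    pb <- .poolCounts(counts_b, halve_inclusion)
    exons <- intersect(rownames(pa), rownames(pb))
    pa <- pa[exons, , drop = FALSE]
    pb <- pb[exons, , drop = FALSE]
    cov_a <- pa[, "inc"] + pa[, "skip"]
    cov_b <- pb[, "inc"] + pb[, "skip"]
    psi_a <- ifelse(cov_a > 0, pa[, "inc"] / cov_a, NA_real_)
    psi_b <- ifelse(cov_b > 0, pb[, "inc"] / cov_b, NA_real_)
    dpsi <- psi_b - psi_a
    tabs <- round(cbind(pa, pb))  # half-to-even
    p <- vapply(seq_along(exons), function(k) {
        m <- matrix(tabs[k, ], 2L, 2L)  # rows: inc/skip, cols: condition
        if (any(rowSums(m) == 0L) || any(colSums(m) == 0L)) return(1)
        fisher.test(m)$p.value
    }, numeric(1))
    p <- pmin(pmax(p, .Machine$double.xmin), 1)  # guard numeric overshoot
    fdr <- bhFdr(p)
    dpsi0 <- ifelse(is.na(dpsi), 0, dpsi)
    called <- !is.na(dpsi) & cov_a >= min_cov & cov_b >= min_cov &
        fdr <= fdr_max & abs(dpsi) >= dpsi_min
    data.frame(exon_id = exons, psi_a = unname(psi_a), psi_b = unname(psi_b),
               dpsi = unname(ifelse(is.na(dpsi), ifelse(cov_a + cov_b == 0, 0, NA), dpsi)),
               coverage_a = unname(cov_a), coverage_b = unname(cov_b),
               p = p, fdr = fdr, called = unname(called),
               row.names = NULL)
}

.poolCounts <- function(counts, halve_inclusion) {
    inc <- rowSums(incReads(counts), na.rm = TRUE)
    skip <- rowSums(skipReads(counts), na.rm = TRUE)
    if (halve_inclusion) inc <- inc / 2
    cbind(inc = inc, skip = skip)
}

#' Benjamini-Hochberg false discovery rates
#'
#' Step-up BH q-values in the input order; ties in p get identical q.
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @return q-values, same length and order.
#' @examples
#' bhFdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bhFdr <- function(pvalues) {
    if (!length(pvalues)) return(numeric(0))
    if (any(is.na(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
        stop("p-values must lie in (0, 1]")
    p.adjust(pvalues, method = "BH")
}

#' Call developmentally regulated and monotonic exons
#'
#' Given differential-splicing tables for pairwise comparisons of ordered
#' developmental stages, an exon is `regulated` if it is called
#' differentially spliced in at least one comparison, and `monotonic` if in
#' addition all of its significant changes (oriented later-minus-earlier)
#' share one sign.
#'
#' @param diff_tables list of data.frames from [fisherDiff()], each oriented
#'   so `dpsi` is later stage minus earlier stage.
#' @return data.frame `exon_id`, `n_significant`, `regulated`, `monotonic`.
#' @export
callDevelopmental <- function(diff_tables) {
    stopifnot(length(diff_tables) >= 1L)
    sig <- do.call(rbind, lapply(diff_tables, function(d)
        d[d$called, c("exon_id", "dpsi"), drop = FALSE]))
    exons <- sort(unique(unlist(lapply(diff_tables, `[[`, "exon_id"))))
    nsig <- setNames(integer(length(exons)), exons)
    mono <- setNames(rep(FALSE, length(exons)), exons)
    if (!is.null(sig) && nrow(sig)) {
        tab <- table(factor(sig$exon_id, levels = exons))
        nsig[names(tab)] <- as.integer(tab)
        sgn <- split(sign(sig$dpsi), sig$exon_id)
        same <- vapply(sgn, function(s) all(s > 0) || all(s < 0), logical(1))
        mono[names(same)] <- same
    }
    data.frame(exon_id = exons, n_significant = unname(nsig),
               regulated = unname(nsig > 0L),
               monotonic = unname(nsig > 0L & mono), row.names = NULL)
}
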