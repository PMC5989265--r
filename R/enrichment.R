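#' @importFrom stats phyper
#' @importFrom Biostrings readDNAStringSet DNAStringSet oligonucleotideFrequency
NULL

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` items from a
#' universe of `N` of which `K` are marked, the probability of seeing at
#' least `k` marked items.
#'
#' @param k observed marked items (vectorized).
#' @param K marked items in the universe.
#' @param n draw size.
#' @param N universe size.
#' @return p-value(s) in (0, 1].
#' @examples
#' hypergeomUpper(4, 5, 4, 10)  # 5/210
#' @export
hypergeomUpper <- function(k, K, n, N) {
    if (any(k < 0 | k > pmin(K, n)) || any(K > N) || any(n > N))
        stop("hypergeometric bounds violated: need 0 <= k <= min(K, n), K <= N, n <= N")
    phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

.exonGeneMap <- function(catalog) {
    if (is(catalog, "GRanges")) {
        if (is.null(names(catalog)) || is.null(catalog$gene_id))
            stop("catalog GRanges must be named by exon id and carry gene_id")
        stats::setNames(catalog$gene_id, names(catalog))
    } else if (is.character(catalog) && !is.null(names(catalog))) {
        catalog
    } else stop("catalog must be a named GRanges or a named exon->gene vector")
}

#' Number of sliding windows over a ranked list
#'
#' @param L ranked-list length.
#' @param window window size.
#' @param step advance per window (default 1).
#' @return `floor((L - window) / step) + 1`.
#' @export
slidingWindowCount <- function(L, window, step = 1) {
    if (window > L) stop("window size exceeds the ranked-list length")
    stopifnot(step >= 1)
    (L - window) %/% step + 1L
}

#' Sliding-window gene-set enrichment over switch-time-ranked exons
#'
#' Exons ranked by switch time are scanned with a window of `window` exons
#' advancing by `step`; the deduplicated genes of each window form the
#' foreground, tested against the background (all genes of the supplied
#' catalog, or `background_genes`) with an upper-tail hypergeometric test
#' per gene-set term. Benjamini-Hochberg correction is applied jointly
#' across every (term, window) test, and rows at `fdr <= fdr_max` are
#' flagged significant.
#'
#' @param ranked_exons exon ids in rank order, or the data.frame from
#'   [rankBySwitchTime()].
#' @param catalog exon catalog ([readExonBed()] GRanges, or a named
#'   exon -> gene character vector) defining the gene of each exon and the
#'   background gene universe.
#' @param gene_sets a [GeneSetCollection-class].
#' @param window window size in exons (default 300).
#' @param step rank step between windows (default 1).
#' @param fdr_max significance cutoff on the joint FDR (default 0.005).
#' @param min_term_bg smallest background representation for a term to be
#'   tested (default 5).
#' @param background_genes optional explicit background gene universe.
#' @return data.frame: `term_id`, `window_index`, `window_start`,
#'   `window_end`, `k`, `K`, `n`, `N`, `p`, `fdr`, `significant`.
#' @export
slidingWindowEnrichment <- function(ranked_exons, catalog, gene_sets,
                                    window = 300, step = 1, fdr_max = 0.005,
                                    min_term_bg = 5, background_genes = NULL) {
    if (is.data.frame(ranked_exons)) ranked_exons <- ranked_exons$exon_id
    L <- length(ranked_exons)
    nWin <- slidingWindowCount(L, window, step)
    e2g <- .exonGeneMap(catalog)
    bg <- if (is.null(background_genes)) sort(unique(unname(e2g))) else
        sort(unique(background_genes))
    N <- length(bg)
    sets <- lapply(geneSets(gene_sets), intersect, y = bg)
    sets <- sets[lengths(sets) >= min_term_bg]
    if (!length(sets))
        stop("no term has at least min_term_bg background genes")
    memb <- vapply(sets, function(g) bg %in% g, logical(N))  # N x terms
    Ks <- colSums(memb)
    starts <- seq(1L, L - window + 1L, by = step)
    rankedIdx <- match(e2g[ranked_exons], bg)
    nTerm <- length(sets)
    kMat <- matrix(0, nWin, nTerm)
    nVec <- integer(nWin)
    for (w in seq_len(nWin)) {
        idx <- starts[w]:(starts[w] + window - 1L)
        fgIdx <- unique(rankedIdx[idx])
        fgIdx <- fgIdx[!is.na(fgIdx)]
        nVec[w] <- length(fgIdx)
        kMat[w, ] <- colSums(memb[fgIdx, , drop = FALSE])
    }
    out <- data.frame(
        term_id = rep(names(sets), each = nWin),
        window_index = rep(seq_len(nWin), nTerm),
        window_start = rep(starts, nTerm),
        window_end = rep(starts + window - 1L, nTerm),
        k = as.vector(kMat), K = rep(Ks, each = nWin),
        n = rep(nVec, nTerm), N = N, row.names = NULL)
    out$p <- hypergeomUpper(out$k, out$K, out$n, out$N)
    out <- out[order(out$term_id, out$window_index), ]
    rownames(out) <- NULL
    out$fdr <- bhFdr(out$p)
    out$significant <- out$fdr <= fdr_max
    out
}

#' Per-module gene-set enrichment
#'
#' Standard hypergeometric enrichment of each module's (core) exon genes
#' against the background gene universe, with joint Benjamini-Hochberg
#' correction across all (module, term) tests.
#'
#' @param module_exons named list, module label -> exon ids (e.g. the core
#'   members of each module), or an [ExonModules-class] (core exons used).
#' @param catalog exon catalog as in [slidingWindowEnrichment()].
#' @param gene_sets a [GeneSetCollection-class].
#' @param fdr_max significance cutoff (default 0.05).
#' @param min_term_bg smallest tested background representation (default 5).
#' @param background_genes optional explicit background universe.
#' @return data.frame: `module`, `term_id`, `k`, `K`, `n`, `N`,
#'   `fold_enrichment`, `p`, `fdr`, `significant`.
#' @export
moduleEnrichment <- function(module_exons, catalog, gene_sets, fdr_max = 0.05,
                             min_term_bg = 5, background_genes = NULL) {
    if (is(module_exons, "ExonModules")) {
        a <- moduleAssignment(module_exons)
        a <- a[a$core %in% TRUE & !is.na(a$module), ]
        module_exons <- split(a$exon_id, a$module)
    }
    stopifnot(length(module_exons) > 0, all(lengths(module_exons) > 0))
    e2g <- .exonGeneMap(catalog)
    bg <- if (is.null(background_genes)) sort(unique(unname(e2g))) else
        sort(unique(background_genes))
    N <- length(bg)
    sets <- lapply(geneSets(gene_sets), intersect, y = bg)
    sets <- sets[lengths(sets) >= min_term_bg]
    rows <- lapply(names(module_exons), function(mod) {
        fg <- intersect(unique(unname(e2g[module_exons[[mod]]])), bg)
        n <- length(fg)
        k <- vapply(sets, function(g) sum(fg %in% g), integer(1))
        K <- lengths(sets)
        data.frame(module = mod, term_id = names(sets),
                   k = unname(k), K = unname(K), n = n, N = N,
                   fold_enrichment = ifelse(K > 0 & n > 0,
                                            (k / n) / (K / N), NA_real_),
                   p = hypergeomUpper(unname(k), unname(K), n, N),
                   row.names = NULL)
    })
    out <- do.call(rbind, rows)
    out$fdr <- bhFdr(out$p)
    out$significant <- out$fdr <= fdr_max
    out
}

#' Hexamer enrichment between two sequence sets
#'
#' Counts, for each of the 4096 DNA hexamers, the number of foreground and
#' background sequences containing at least one occurrence (a
#' presence/absence model matching hypergeometric sampling; windows
#' overlapping non-ACGT letters such as N are skipped), then tests
#' enrichment with an upper-tail hypergeometric test and corrects across
#' all hexamers. The background is expected to contain the foreground
#' (e.g. flanking introns of core module exons vs all cassette exons).
#'
#' @param fg_seqs,bg_seqs foreground/background sequences: FASTA paths or
#'   [Biostrings::DNAStringSet] objects.
#' @return data.frame ordered by p: `hexamer`, `k`, `n`, `K`, `N`, `p`,
#'   `fdr`.
#' @export
hexamerEnrichment <- function(fg_seqs, bg_seqs) {
    fg <- if (is.character(fg_seqs)) readDNAStringSet(fg_seqs) else
        DNAStringSet(fg_seqs)
    bg <- if (is.character(bg_seqs)) readDNAStringSet(bg_seqs) else
        DNAStringSet(bg_seqs)
    if (!length(fg) || !length(bg))
        stop("empty sequence set")
    pres <- function(x) colSums(oligonucleotideFrequency(x, width = 6) > 0)
    k <- pres(fg)
    K <- pres(bg)
    n <- length(fg)
    N <- length(bg)
    # fg is expected to be drawn from bg; clamp guards deviations so the
    # tail probability stays defined
    p <- phyper(pmin(k, K, n) - 1, K, N - K, n, lower.tail = FALSE)
    out <- data.frame(hexamer = names(k), k = unname(k), n = n,
                      K = unname(K), N = N, p = unname(p),
                      fdr = bhFdr(unname(p)), row.names = NULL)
    out[order(out$p, out$hexamer), ]
}

#' Cluster enrichment profiles across windows
#'
#' Represents each significant term by its `-log10(fdr)` profile across all
#' windows and groups terms with similar temporal enrichment patterns by
#' average-linkage hierarchical clustering on Euclidean distance. Input
#' order does not affect the result: terms are sorted before clustering.
#'
#' @param table output of [slidingWindowEnrichment()].
#' @param k number of clusters to cut (default 2).
#' @param significant_only cluster only terms significant in >= 1 window
#'   (default TRUE).
#' @return list: `profiles` (terms x windows matrix), `hclust`, `order`
#'   (term ids in leaf order), `clusters` (named cut assignment).
#' @export
clusterEnrichmentProfiles <- function(table, k = 2, significant_only = TRUE) {
    terms <- if (significant_only)
        sort(unique(table$term_id[table$significant])) else
        sort(unique(table$term_id))
    if (!length(terms)) stop("no terms to cluster")
    sub <- table[table$term_id %in% terms, ]
    wins <- sort(unique(sub$window_index))
    prof <- matrix(0, length(terms), length(wins),
                   dimnames = list(terms, paste0("w", wins)))
    prof[cbind(match(sub$term_id, terms), match(sub$window_index, wins))] <-
        -log10(sub$fdr)
    if (length(terms) < 2L)
        return(list(profiles = prof, hclust = NULL, order = terms,
                    clusters = stats::setNames(1L, terms)))
    hc <- hclust(stats::dist(prof, method = "euclidean"), method = "average")
    cl <- cutree(hc, k = min(k, length(terms)))
    list(profiles = prof, hclust = hc, order = terms[hc$order],
         clusters = cl)
}
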