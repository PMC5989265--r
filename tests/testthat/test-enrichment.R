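test_that("upper-tail hypergeometric matches exhaustive enumeration", {
    expect_equal(hypergeomUpper(4, 5, 4, 10), 5 / 210, tolerance = 1e-12)
    expect_equal(hypergeomUpper(0, 5, 4, 10), 1)
    # tail probability decreases as k grows
    ps <- hypergeomUpper(0:4, 5, 4, 10)
    expect_true(all(diff(ps) < 0))
    expect_error(hypergeomUpper(5, 4, 10, 12), "bounds")
    set.seed(2)
    for (i in 1:200) {
        N <- sample(2:25, 1); K <- sample(0:N, 1); n <- sample(1:N, 1)
        k <- sample(0:min(K, n), 1)
        expect_equal(hypergeomUpper(k, K, n, N), hyperEnumOracle(k, K, n, N),
                     tolerance = 1e-12)
    }
})

test_that("window counting follows the closed formula", {
    expect_equal(slidingWindowCount(964, 300, 1), 665L)
    expect_equal(slidingWindowCount(300, 300, 1), 1L)
    expect_error(slidingWindowCount(200, 300), "exceeds")
    set.seed(3)
    for (i in 1:50) {
        L <- sample(10:500, 1); w <- sample(1:L, 1); s <- sample(1:10, 1)
        # oracle: count the windows by explicit generation
        expect_equal(slidingWindowCount(L, w, s),
                     length(seq(1, L - w + 1, by = s)))
    }
})

test_that("a term planted early in the ranking peaks in the early windows", {
    sim <- simulateReference(n_exons = 1000, seed = 21)
    gs <- simulateGeneSets(sim$truth, n_terms = 40,
                           planted = list(TP = c(1, 300)), seed = 22)
    e2g <- setNames(sim$truth$gene_id, sim$truth$exon_id)
    sw <- slidingWindowEnrichment(gs$true_ranking, e2g, gs$gene_sets,
                                  window = 300, step = 1)
    expect_equal(length(unique(sw$window_index)),
                 slidingWindowCount(length(gs$true_ranking), 300, 1))
    sig <- sw[sw$significant, ]
    expect_true("TP" %in% sig$term_id)
    tp <- sw[sw$term_id == "TP", ]
    expect_lte(tp$window_index[which.min(tp$fdr)], 50)
})

test_that("joint-FDR significance sets shrink as the cutoff tightens", {
    sim <- simulateReference(n_exons = 600, seed = 23)
    gs <- simulateGeneSets(sim$truth, n_terms = 30,
                           planted = list(TP = c(1, 200)), seed = 24)
    e2g <- setNames(sim$truth$gene_id, sim$truth$exon_id)
    sw1 <- slidingWindowEnrichment(gs$true_ranking, e2g, gs$gene_sets,
                                   window = 200, fdr_max = 0.05)
    sw2 <- slidingWindowEnrichment(gs$true_ranking, e2g, gs$gene_sets,
                                   window = 200, fdr_max = 0.005)
    key <- function(d) paste(d$term_id, d$window_index)[d$significant]
    expect_true(all(key(sw2) %in% key(sw1)))
})

test_that("module enrichment flags a planted term and skips absent ones", {
    set.seed(25)
    genes <- sprintf("g%04d", 1:500)
    exons <- sprintf("ex%04d", 1:500)
    e2g <- setNames(genes, exons)
    fgExons <- exons[1:50]
    # planted term: 40 of the 50 foreground genes plus 10 others -> ~5x
    sets <- list(TP = c(genes[1:40], genes[101:110]),
                 bgT = genes[sample(500, 60)],
                 absent = c("zz1", "zz2", "zz3", "zz4", "zz5"))
    gsc <- new("GeneSetCollection", sets = sets, termNames = character())
    tab <- moduleEnrichment(list(M1 = fgExons), e2g, gsc)
    expect_false("absent" %in% tab$term_id)  # no background overlap
    tp <- tab[tab$term_id == "TP", ]
    expect_true(tp$significant)
    expect_gt(tp$fold_enrichment, 4)
    # foreground = background: fold enrichment 1, nothing significant
    tabAll <- moduleEnrichment(list(M1 = exons), e2g, gsc)
    expect_equal(tabAll$fold_enrichment,
                 rep(1, nrow(tabAll)), tolerance = 1e-12)
    expect_false(any(tabAll$significant))
    expect_true(all(tabAll$p == 1))
})

test_that("hexamer enrichment finds a planted motif and handles edge cases", {
    set.seed(26)
    rseq <- function(n, len = 200)
        vapply(seq_len(n), function(i)
            paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = ""),
            "")
    bg <- rseq(200)
    fg <- bg[1:60]
    plant <- function(s) paste0(substr(s, 1, 90), "TGCATG",
                                substr(s, 97, nchar(s)))
    fg[1:48] <- vapply(fg[1:48], plant, "")          # 80% of foreground
    bgAll <- c(fg, bg[61:200])                       # fg is part of bg
    tab <- hexamerEnrichment(Biostrings::DNAStringSet(fg),
                             Biostrings::DNAStringSet(bgAll))
    expect_equal(tab$hexamer[1], "TGCATG")
    expect_lt(tab$fdr[1], 0.05)
    # fg == bg: nothing can be enriched
    same <- hexamerEnrichment(Biostrings::DNAStringSet(bg),
                              Biostrings::DNAStringSet(bg))
    expect_false(any(same$fdr < 0.5))
    # sequences shorter than 6 nt contribute no hexamers
    short <- hexamerEnrichment(Biostrings::DNAStringSet(c("ACGT", "TTTTTT")),
                               Biostrings::DNAStringSet(c("ACGT", "TTTTTT")))
    expect_equal(sum(short$k), 1L)  # only the TTTTTT sequence counts
    expect_error(hexamerEnrichment(Biostrings::DNAStringSet(character()),
                                   Biostrings::DNAStringSet("ACGTAC")),
                 "empty")
})

test_that("enrichment-profile clustering separates early from late peaks", {
    # construct a window table with two planted profile shapes
    mkRows <- function(term, peak, nWin = 60) data.frame(
        term_id = term, window_index = 1:nWin, window_start = 1:nWin,
        window_end = 1:nWin + 299, k = 10, K = 50, n = 200, N = 1000,
        p = 1, fdr = pmax(10^-(8 * exp(-((1:nWin - peak) / 8)^2)), 1e-8),
        significant = TRUE)
    tab <- rbind(mkRows("early1", 10), mkRows("early2", 12),
                 mkRows("late1", 48), mkRows("late2", 50))
    cl <- clusterEnrichmentProfiles(tab, k = 2)
    expect_equal(length(unique(cl$clusters[c("early1", "early2")])), 1L)
    expect_equal(length(unique(cl$clusters[c("late1", "late2")])), 1L)
    expect_true(cl$clusters["early1"] != cl$clusters["late1"])
    # identical profiles land in the same cluster at distance zero
    tab2 <- rbind(mkRows("t1", 20), mkRows("t2", 20))
    cl2 <- clusterEnrichmentProfiles(tab2, k = 2)
    expect_equal(unname(cl2$hclust$height[1]), 0)
    # leaf order is reproducible
    cl3 <- clusterEnrichmentProfiles(tab[sample(nrow(tab)), ], k = 2)
    expect_equal(cl3$order, cl$order)
})
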