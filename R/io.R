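#' @importFrom GenomicRanges GRanges strand
#' @importFrom IRanges IRanges
#' @importFrom utils read.delim write.table
NULL

#' Read a PSI (percent spliced in) matrix from TSV
#'
#' Expects a tab-separated table whose first column holds exon ids and whose
#' header row holds sample labels. Empty cells mean "not quantified"
#' (missing), which is distinct from a PSI of 0. An optional coverage table
#' of identical shape can accompany the matrix.
#'
#' @param path PSI TSV.
#' @param coverage_path optional coverage TSV with identical row/column ids.
#' @return A [PsiExperiment-class].
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writePsiTable(PsiExperiment(matrix(c(0.2, NA), 1, 2,
#'     dimnames = list("ex1", c("a", "b")))), f)
#' readPsiTable(f)
#' @export
readPsiTable <- function(path, coverage_path = NULL) {
    psi <- .readMatrixTsv(path, "psi")
    bad <- which(!is.na(psi) & (psi < 0 | psi > 1), arr.ind = TRUE)
    if (nrow(bad)) {
        stop(sprintf(
            "psi value %g out of [0, 1] for exon '%s', sample '%s' in %s",
            psi[bad[1, 1], bad[1, 2]], rownames(psi)[bad[1, 1]],
            colnames(psi)[bad[1, 2]], path))
    }
    coverage <- NULL
    if (!is.null(coverage_path)) {
        coverage <- .readMatrixTsv(coverage_path, "coverage")
        if (!identical(dimnames(coverage), dimnames(psi)))
            stop("coverage table must have the same exons and samples as the psi table")
        coverage[is.na(psi)] <- NA_real_
    }
    PsiExperiment(psi, coverage)
}

.readMatrixTsv <- function(path, what) {
    raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                      colClasses = "character", na.strings = c("", "NA"))
    if (ncol(raw) < 2L)
        stop(sprintf("%s table %s needs an exon-id column plus >=1 sample", what, path))
    ids <- raw[[1L]]
    dup <- ids[duplicated(ids)]
    if (length(dup))
        stop(sprintf("duplicate exon_id '%s' in %s", dup[1L], path))
    m <- as.matrix(raw[, -1L, drop = FALSE])
    num <- suppressWarnings(array(as.numeric(m), dim(m)))
    bad <- which(is.na(num) & !is.na(m), arr.ind = TRUE)
    if (nrow(bad)) {
        stop(sprintf("non-numeric %s value '%s' for exon '%s', sample '%s' in %s",
                     what, m[bad[1, 1], bad[1, 2]], ids[bad[1, 1]],
                     colnames(m)[bad[1, 2]], path))
    }
    dimnames(num) <- list(ids, colnames(m))
    num
}

#' Write a PsiExperiment to TSV (psi matrix, optional coverage sidecar)
#'
#' Missing cells are written as empty strings so that 0 stays a real value.
#'
#' @param x a [PsiExperiment-class].
#' @param path output TSV for the psi matrix.
#' @param coverage_path optional output TSV for the coverage matrix.
#' @return invisibly, `path`.
#' @export
writePsiTable <- function(x, path, coverage_path = NULL) {
    .writeMatrixTsv(psiValues(x), path)
    if (!is.null(coverage_path))
        .writeMatrixTsv(coverageValues(x), coverage_path)
    invisible(path)
}

.writeMatrixTsv <- function(m, path) {
    df <- data.frame(exon_id = rownames(m), m, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "")
}

#' Read junction counts from a long-format TSV
#'
#' Columns: `exon_id`, `sample`, `inc_reads` (reads supporting the two
#' inclusion junctions, summed), `skip_reads` (reads on the skipping
#' junction). Pairs absent from the file become `NA` cells.
#'
#' @param path counts TSV with a header row.
#' @return A [JunctionCounts-class].
#' @export
readCountTable <- function(path) {
    df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
    need <- c("exon_id", "sample", "inc_reads", "skip_reads")
    if (!all(need %in% names(df)))
        stop("counts table must have columns: ", paste(need, collapse = ", "))
    if (any(df$inc_reads < 0, na.rm = TRUE) || any(df$skip_reads < 0, na.rm = TRUE))
        stop(sprintf("negative read count for exon '%s'",
                     df$exon_id[which(df$inc_reads < 0 | df$skip_reads < 0)[1L]]))
    exons <- unique(as.character(df$exon_id))
    samples <- unique(as.character(df$sample))
    inc <- skip <- matrix(NA_real_, length(exons), length(samples),
                          dimnames = list(exons, samples))
    i <- cbind(match(df$exon_id, exons), match(df$sample, samples))
    inc[i] <- df$inc_reads
    skip[i] <- df$skip_reads
    JunctionCounts(inc, skip)
}

#' Write junction counts to a long-format TSV
#'
#' @param x a [JunctionCounts-class]; `NA` cells are omitted from the file.
#' @param path output TSV.
#' @return invisibly, `path`.
#' @export
writeCountTable <- function(x, path) {
    inc <- incReads(x); skip <- skipReads(x)
    keep <- which(!is.na(inc), arr.ind = TRUE)
    df <- data.frame(exon_id = rownames(inc)[keep[, 1L]],
                     sample = colnames(inc)[keep[, 2L]],
                     inc_reads = inc[keep], skip_reads = skip[keep])
    df <- df[order(df$exon_id, df$sample), ]
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a cassette-exon catalog from BED6
#'
#' BED coordinates are 0-based half-open; the returned
#' [GenomicRanges::GRanges] uses the usual 1-based closed convention
#' (`start+1 .. end`). The BED name field is the exon id and is the join key
#' used by every other function in the package; a `gene_id` is derived by
#' stripping a trailing `".<n>"` suffix from the name unless `gene_ids` is
#' supplied.
#'
#' @param path BED6 file.
#' @param gene_ids optional named character vector exon_id -> gene_id.
#' @return A `GRanges` named by exon id with metadata columns `gene_id` and
#'   `novelty` (from the BED score field: 0 = known, 1 = novel).
#' @export
readExonBed <- function(path, gene_ids = NULL) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 6L))
        stop(sprintf("malformed BED line %d in %s: %d field(s), need 6",
                     which(nf < 6L)[1L], path, nf[which(nf < 6L)[1L]]))
    chrom <- vapply(fields, `[[`, "", 1L)
    start0 <- as.numeric(vapply(fields, `[[`, "", 2L))
    end0 <- as.numeric(vapply(fields, `[[`, "", 3L))
    name <- vapply(fields, `[[`, "", 4L)
    score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
    strand <- vapply(fields, `[[`, "", 6L)
    if (any(is.na(start0)) || any(is.na(end0)))
        stop("non-numeric BED coordinates in ", path)
    if (any(start0 >= end0))
        stop(sprintf("BED line %d in %s: start must be < end",
                     which(start0 >= end0)[1L], path))
    if (!all(strand %in% c("+", "-")))
        stop(sprintf("BED line %d in %s: strand must be '+' or '-'",
                     which(!strand %in% c("+", "-"))[1L], path))
    if (anyDuplicated(name))
        stop(sprintf("duplicate exon id '%s' in %s", name[duplicated(name)][1L], path))
    gr <- GRanges(chrom, IRanges(bedToOneBased(start0), end0), strand = strand)
    names(gr) <- name
    gid <- if (is.null(gene_ids)) sub("\\.[0-9]+$", "", name) else
        unname(gene_ids[name])
    gr$gene_id <- gid
    gr$novelty <- ifelse(!is.na(score) & score > 0, "novel", "known")
    gr
}

#' Write an exon catalog back to BED6
#'
#' @param gr a named `GRanges` as returned by [readExonBed()].
#' @param path output BED file.
#' @return invisibly, `path`.
#' @export
writeExonBed <- function(gr, path) {
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = oneBasedToBed(GenomicRanges::start(gr)),
                     end = GenomicRanges::end(gr),
                     name = names(gr),
                     score = ifelse(!is.null(gr$novelty) & gr$novelty == "novel", 1L, 0L),
                     strand = as.character(strand(gr)))
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Convert BED (0-based half-open) starts to 1-based closed, and back
#'
#' The two converters are exact inverses; ends are identical under the two
#' conventions so only starts shift.
#'
#' @param start0 0-based start coordinate(s).
#' @return 1-based start coordinate(s).
#' @export
bedToOneBased <- function(start0) start0 + 1

#' @rdname bedToOneBased
#' @param start1 1-based start coordinate(s).
#' @export
oneBasedToBed <- function(start1) start1 - 1

#' GeneSetCollection: term -> gene-set map
#'
#' @slot sets named list, term_id -> character vector of gene ids.
#' @slot termNames optional named character vector of human-readable names.
#' @export
setClass("GeneSetCollection",
         representation(sets = "list", termNames = "character"))

setValidity("GeneSetCollection", function(object) {
    if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
        return("sets must be uniquely named by term id")
    if (any(lengths(object@sets) == 0L))
        return("empty gene sets are not allowed")
    TRUE
})

setMethod("show", "GeneSetCollection", function(object) {
    cat(class(object), "with", length(object@sets), "terms;",
        "set sizes", paste(range(lengths(object@sets)), collapse = "-"), "\n")
})

#' @describeIn GeneSetCollection the term -> genes list.
#' @param x a `GeneSetCollection`.
#' @export
geneSets <- function(x) x@sets

#' @describeIn GeneSetCollection number of terms.
#' @export
nTerms <- function(x) length(x@sets)

#' Read gene-set annotations from a two-column TSV
#'
#' Rows are `gene_id <tab> term_id` pairs (header optional, detected from
#' the literal column names); the map is inverted to term -> genes. An
#' optional sidecar TSV `term_id <tab> term_name` supplies display names.
#'
#' @param path annotation TSV.
#' @param names_path optional term-name TSV.
#' @return A [GeneSetCollection-class].
#' @export
readGeneSets <- function(path, names_path = NULL) {
    first <- strsplit(readLines(path, n = 1L), "\t")[[1L]]
    header <- identical(tolower(first[1:2]), c("gene_id", "term_id"))
    df <- read.delim(path, header = header, sep = "\t",
                     col.names = c("gene_id", "term_id"),
                     colClasses = "character")
    sets <- lapply(split(df$gene_id, df$term_id), function(g) sort(unique(g)))
    tn <- character()
    if (!is.null(names_path)) {
        nd <- read.delim(names_path, header = FALSE, sep = "\t",
                         col.names = c("term_id", "term_name"),
                         colClasses = "character")
        tn <- stats::setNames(nd$term_name, nd$term_id)
    }
    new("GeneSetCollection", sets = sets, termNames = tn)
}

#' Write gene sets back to the two-column TSV layout
#'
#' @param x a [GeneSetCollection-class].
#' @param path output TSV (`gene_id`, `term_id`, with header).
#' @return invisibly, `path`.
#' @export
writeGeneSets <- function(x, path) {
    sets <- geneSets(x)
    df <- data.frame(gene_id = unlist(sets, use.names = FALSE),
                     term_id = rep(names(sets), lengths(sets)))
    write.table(df[order(df$term_id, df$gene_id), ], path, sep = "\t",
                quote = FALSE, row.names = FALSE)
    invisible(path)
}
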