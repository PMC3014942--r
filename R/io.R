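#' Read and write GMT pathway files
#'
#' GMT is the community standard for gene sets: one pathway per
#' tab-separated line — identifier, description, then member genes.
#' Duplicate genes within a line are dropped with a message.
#'
#' @param path file path.
#' @return [readGmt()]: a [PathwayCollection-class] (empty file gives an
#'   empty collection).
#' @export
readGmt <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L)
        return(PathwayCollection(stats::setNames(list(), character(0))))
    parts <- strsplit(lines, "\t", fixed = TRUE)
    short <- which(lengths(parts) < 3L)
    if (length(short))
        stop(sprintf("malformed GMT line %d: fewer than 3 fields",
                     short[1L]))
    ids <- vapply(parts, `[[`, character(1), 1L)
    desc <- vapply(parts, `[[`, character(1), 2L)
    sets <- lapply(parts, function(p) p[-c(1L, 2L)])
    names(sets) <- ids
    names(desc) <- ids
    PathwayCollection(sets, description = desc)
}

#' @rdname readGmt
#' @param x a [PathwayCollection-class].
#' @export
writeGmt <- function(x, path) {
    stopifnot(is(x, "PathwayCollection"))
    desc <- x@description
    desc[is.na(desc)] <- "na"
    lines <- vapply(seq_along(x@sets), function(i)
        paste(c(names(x@sets)[i], desc[i], x@sets[[i]]), collapse = "\t"),
        character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Read and write the gene x sample alteration matrix
#'
#' Tab-separated layout: header row of sample identifiers, first column of
#' gene identifiers, entries in `{-1, 0, 1}` (deletion / no change /
#' amplification). Any other entry is rejected, naming the gene and
#' sample.
#'
#' @param path file path.
#' @return [readAlterationMatrix()]: an [AlterationMatrix-class].
#' @export
readAlterationMatrix <- function(path) {
    df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                            colClasses = "character")
    if (nrow(df) == 0L || ncol(df) < 2L)
        stop("empty alteration matrix: need at least one gene and one sample")
    genes <- df[[1L]]
    m <- as.matrix(df[, -1L, drop = FALSE])
    suppressWarnings(vals <- as.integer(m))
    bad <- is.na(vals) | !(vals %in% c(-1L, 0L, 1L))
    if (any(bad)) {
        i <- which(bad)[1L]
        rc <- arrayInd(i, dim(m))
        stop(sprintf(
            "invalid value '%s' for gene '%s', sample '%s' (allowed: -1, 0, 1)",
            m[i], genes[rc[1L]], colnames(m)[rc[2L]]))
    }
    out <- matrix(vals, nrow(m), ncol(m),
                  dimnames = list(genes, colnames(m)))
    AlterationMatrix(out)
}

#' @rdname readAlterationMatrix
#' @param x an [AlterationMatrix-class].
#' @export
writeAlterationMatrix <- function(x, path) {
    stopifnot(is(x, "AlterationMatrix"))
    m <- calls(x)
    df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

# BED-like readers: files are 0-based half-open; GRanges are 1-based closed
.read_bedlike <- function(path, extra) {
    df <- utils::read.delim(path, header = TRUE, check.names = FALSE)
    need <- c("chrom", "start", "end", extra)
    if (!all(need %in% colnames(df)))
        stop(sprintf("expected columns: %s", paste(need, collapse = ", ")))
    if (any(df$start >= df$end))
        stop("intervals must satisfy start < end (0-based half-open)")
    df
}

#' Read and write BED-like coordinate files
#'
#' Plain tab-separated files with a header, coordinates 0-based half-open
#' on disk (converted to the 1-based closed `GRanges` convention on
#' ingest). Gene files carry `chrom, start, end, gene_id`; BAC files add
#' `left_anchored, right_anchored` (0/1); segment files carry
#' `chrom, start, end, sample_id, state` with state `-1`/`1`.
#'
#' @param path file path.
#' @return a `GRanges` ([readGenesBed()], [readSegmentsBed()]) or a
#'   [BacMap-class] ([readBacsBed()]).
#' @export
readGenesBed <- function(path) {
    df <- .read_bedlike(path, "gene_id")
    GenomicRanges::GRanges(df$chrom,
        IRanges::IRanges(df$start + 1L, df$end),
        gene_id = as.character(df$gene_id))
}

#' @rdname readGenesBed
#' @export
readBacsBed <- function(path) {
    df <- .read_bedlike(path, c("bac_id", "left_anchored", "right_anchored"))
    BacMap(GenomicRanges::GRanges(df$chrom,
        IRanges::IRanges(df$start + 1L, df$end),
        bac_id = as.character(df$bac_id),
        left_anchored = as.logical(as.integer(df$left_anchored)),
        right_anchored = as.logical(as.integer(df$right_anchored))))
}

#' @rdname readGenesBed
#' @export
readSegmentsBed <- function(path) {
    df <- .read_bedlike(path, c("sample_id", "state"))
    if (!all(df$state %in% c(-1L, 1L)))
        stop("segment state must be -1 or 1")
    GenomicRanges::GRanges(df$chrom,
        IRanges::IRanges(df$start + 1L, df$end),
        sample_id = as.character(df$sample_id),
        state = as.integer(df$state))
}

.write_bedlike <- function(gr, path, extra_cols) {
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr) - 1L,
                     end = GenomicRanges::end(gr))
    for (nm in names(extra_cols)) df[[nm]] <- extra_cols[[nm]]
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname readGenesBed
#' @param genes,segments `GRanges` as produced by the readers or
#'   generators.
#' @export
writeGenesBed <- function(genes, path) {
    .write_bedlike(genes, path,
                   list(gene_id = mcols(genes)$gene_id))
}

#' @rdname readGenesBed
#' @param x a [BacMap-class] (raw coordinates are written).
#' @export
writeBacsBed <- function(x, path) {
    stopifnot(is(x, "BacMap"))
    r <- bacRaw(x)
    .write_bedlike(r, path,
                   list(bac_id = mcols(r)$bac_id,
                        left_anchored = as.integer(mcols(r)$left_anchored),
                        right_anchored = as.integer(mcols(r)$right_anchored)))
}

#' @rdname readGenesBed
#' @export
writeSegmentsBed <- function(segments, path) {
    .write_bedlike(segments, path,
                   list(sample_id = mcols(segments)$sample_id,
                        state = as.integer(mcols(segments)$state)))
}

#' Read a survival table
#'
#' Tab-separated columns `sample_id`, `time` (non-negative), `event`
#' (0/1).
#'
#' @param path file path.
#' @return data frame.
#' @export
readSurvival <- function(path) {
    df <- utils::read.delim(path, header = TRUE)
    need <- c("sample_id", "time", "event")
    if (!all(need %in% colnames(df)))
        stop("survival table needs columns sample_id, time, event")
    if (any(df$time < 0)) stop("negative follow-up time")
    if (!all(df$event %in% c(0L, 1L))) stop("event must be 0 or 1")
    df
}

#' Read a pathway score matrix
#'
#' Tab-separated, pathways in rows (first column `pathway_id`), samples in
#' columns: externally computed per-sample pathway metrics such as
#' activity or consistency scores.
#'
#' @param path file path.
#' @return numeric matrix, pathways x samples.
#' @export
readScoreMatrix <- function(path) {
    df <- utils::read.delim(path, header = TRUE, check.names = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df[[1L]]
    storage.mode(m) <- "double"
    m
}

# p-values in scientific notation, 6 significant digits
.fmt_num <- function(x) {
    ifelse(is.na(x), "NA",
           ifelse(x == round(x) & abs(x) < 1e15, format(x, scientific = FALSE),
                  formatC(x, digits = 6, format = "g")))
}

#' Write the per-pathway targeting report
#'
#' Tab-separated, one row per pathway: `pathway_id`, `n_genes`,
#' `omnibus_stat`, `df`, `p_population`, `p_adjusted`, `significant`.
#'
#' @param x a [TargetingResults-class].
#' @param path output file.
#' @param per_sample_path optional second file receiving the long-format
#'   per-sample detail from [perSampleTable()].
#' @export
writeTargetingReport <- function(x, path, per_sample_path = NULL) {
    stopifnot(is(x, "TargetingResults"))
    tb <- as.data.frame(resultsTable(x))
    for (cc in c("omnibus_stat", "p_population", "p_adjusted"))
        tb[[cc]] <- .fmt_num(tb[[cc]])
    utils::write.table(tb, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (!is.null(per_sample_path)) {
        ps <- perSampleTable(x)
        ps$p_ij <- .fmt_num(ps$p_ij)
        utils::write.table(ps, per_sample_path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    invisible(path)
}
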