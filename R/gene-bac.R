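#' Associate genes with BAC clones
#'
#' An association between a gene and a clone is accepted when their
#' intervals overlap and the clone span is at least one third of the gene
#' span (guarding against insubstantial overlaps where a broad gene mapping
#' brushes a short clone). Under extended (tiling) coordinates an
#' association additionally requires at least half of the gene to lie
#' inside the clone, which — because tiles partition the covered span —
#' assigns border-region genes to one clone exclusively. Clones marked
#' duplicate are not association targets (their container represents them).
#'
#' @param genes a `GRanges` with a `gene_id` metadata column.
#' @param x a [BacMap-class] with the coordinates for `mode` computed.
#' @param mode `"extended"` (default; exclusive assignment) or
#'   `"expanded"` (a gene may associate with several clones).
#' @return A `DataFrame` with columns `gene_id`, `bac_id`, `overlap`
#'   (bases), one row per accepted association.
#' @export
associateGeneBac <- function(genes, x, mode = c("extended", "expanded")) {
    mode <- match.arg(mode)
    stopifnot(is(genes, "GRanges"), is(x, "BacMap"))
    coords <- if (mode == "extended") bacExtended(x) else bacExpanded(x)
    mc <- mcols(x@raw)
    live <- is.na(bacDuplicateOf(x))
    gw <- GenomicRanges::width(genes)
    if (any(gw < 1L)) {
        message(sprintf("rejecting %d zero-length gene interval(s)",
                        sum(gw < 1L)))
    }
    hits <- GenomicRanges::findOverlaps(genes, coords)
    gi <- S4Vectors::queryHits(hits)
    bi <- S4Vectors::subjectHits(hits)
    keep <- live[bi] & gw[gi] >= 1L
    gi <- gi[keep]; bi <- bi[keep]
    ov <- GenomicRanges::width(GenomicRanges::pintersect(
        GenomicRanges::ranges(genes)[gi], GenomicRanges::ranges(coords)[bi]))
    bw <- GenomicRanges::width(coords)[bi]
    acc <- ov > 0L & bw >= gw[gi] / 3
    if (mode == "extended") acc <- acc & ov >= 0.5 * gw[gi]
    gi <- gi[acc]; bi <- bi[acc]; ov <- ov[acc]
    if (mode == "extended" && anyDuplicated(gi)) {
        # a gene split exactly in half across a tile border satisfies the
        # 50% rule on both sides; keep the larger overlap, ties leftmost
        ord <- order(gi, -ov, GenomicRanges::start(coords)[bi],
                     mcols(x@raw)$bac_id[bi])
        gi <- gi[ord]; bi <- bi[ord]; ov <- ov[ord]
        first <- !duplicated(gi)
        gi <- gi[first]; bi <- bi[first]; ov <- ov[first]
    }
    S4Vectors::DataFrame(gene_id = mcols(genes)$gene_id[gi],
                         bac_id = mc$bac_id[bi],
                         overlap = ov)
}

#' Call gene-level alterations from per-sample altered segments
#'
#' Overlays per-sample copy-number altered segments on gene intervals and
#' produces the gene x sample call matrix (`+1` amplified, `-1` deleted,
#' `0` unchanged). With a [BacMap-class] supplied, each gene is first
#' assigned to a clone under `mode` coordinates and the clone interval —
#' the resolution at which array CGH actually measures — stands in for the
#' gene, so a gene whose clone lies inside an altered segment is called
#' altered even where the gene's own span pokes past the segment edge.
#' Without a `BacMap`, gene intervals are overlaid directly (for platforms
#' with gene-level segments).
#'
#' When a gene overlaps both an amplified and a deleted segment of the same
#' sample, the state with the larger total overlap wins; an exact tie is
#' called `0` with a warning.
#'
#' @param segments a `GRanges` with metadata columns `sample_id` and
#'   `state` (`+1` amplification, `-1` deletion).
#' @param genes a `GRanges` with a `gene_id` metadata column.
#' @param bacmap optional [BacMap-class] mediating the overlay.
#' @param mode coordinate set used for clone-mediated assignment.
#' @param samples optional character vector fixing the sample set (and
#'   column order); samples without segments yield all-zero columns.
#' @return An [AlterationMatrix-class] over all input genes and samples.
#' @export
genesInAlteredSegments <- function(segments, genes, bacmap = NULL,
                                   mode = c("extended", "expanded"),
                                   samples = NULL) {
    mode <- match.arg(mode)
    stopifnot(is(segments, "GRanges"), is(genes, "GRanges"))
    state <- as.integer(mcols(segments)$state)
    if (!all(state %in% c(-1L, 1L)))
        stop("segment state must be +1 (amplification) or -1 (deletion)")
    sample_id <- as.character(mcols(segments)$sample_id)
    if (is.null(samples)) samples <- unique(sample_id)
    gene_ids <- as.character(mcols(genes)$gene_id)

    # effective interval per gene: its clone's tile, or the gene itself
    eff <- genes
    has_eff <- rep(TRUE, length(genes))
    if (!is.null(bacmap)) {
        assign <- associateGeneBac(genes, bacmap, mode = mode)
        coords <- if (mode == "extended") bacExtended(bacmap)
                  else bacExpanded(bacmap)
        bi <- match(assign$bac_id, bacIds(bacmap))
        gi <- match(assign$gene_id, gene_ids)
        has_eff <- seq_along(genes) %in% gi
        # expanded mode may assign several clones; union of their spans
        eff <- genes
        GenomicRanges::ranges(eff)[gi] <- GenomicRanges::ranges(coords)[bi]
        if (mode == "expanded" && anyDuplicated(gi)) {
            agg_s <- tapply(GenomicRanges::start(coords)[bi], gi, min)
            agg_e <- tapply(GenomicRanges::end(coords)[bi], gi, max)
            ii <- as.integer(names(agg_s))
            GenomicRanges::ranges(eff)[ii] <-
                IRanges::IRanges(as.integer(agg_s), as.integer(agg_e))
        }
    }

    mat <- matrix(0L, length(genes), length(samples),
                  dimnames = list(gene_ids, samples))
    hits <- GenomicRanges::findOverlaps(eff, segments)
    gi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    keep <- has_eff[gi] & sample_id[si] %in% samples
    gi <- gi[keep]; si <- si[keep]
    if (length(gi)) {
        ov <- GenomicRanges::width(GenomicRanges::pintersect(
            GenomicRanges::ranges(eff)[gi],
            GenomicRanges::ranges(segments)[si]))
        key <- paste(gi, match(sample_id[si], samples), sep = "\r")
        amp <- tapply(ov * (state[si] == 1L), key, sum)
        del <- tapply(ov * (state[si] == -1L), key, sum)
        parts <- do.call(rbind, strsplit(names(amp), "\r", fixed = TRUE))
        ridx <- as.integer(parts[, 1L]); cidx <- as.integer(parts[, 2L])
        call <- ifelse(amp > del, 1L, ifelse(del > amp, -1L, 0L))
        if (any(call == 0L & (amp > 0 | del > 0)))
            warning("gene(s) with equal amplified and deleted overlap ",
                    "in one sample called 0")
        mat[cbind(ridx, cidx)] <- call
    }
    AlterationMatrix(mat)
}
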