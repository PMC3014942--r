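#' Construct a BacMap
#'
#' Coordinates follow the Bioconductor convention internally (1-based,
#' closed [GenomicRanges::GRanges]); the file readers ([readBacsBed()],
#' [readGenesBed()], [readSegmentsBed()]) convert from 0-based half-open
#' BED-like input on ingest, and the writers convert back.
#'
#' @param bacs a `GRanges` with metadata columns `bac_id` (character,
#'   unique), `left_anchored` and `right_anchored` (logical: is the
#'   corresponding end fixed by a mapped end sequence).
#'
#' @return A [BacMap-class] with empty `expanded`/`extended` slots.
#' @seealso [resolveBacOverlaps()], [expandBacs()], [extendBacs()]
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1e5 + 1, 2.2e5),
#'     bac_id = "B1", left_anchored = FALSE, right_anchored = FALSE)
#' BacMap(gr)
#' @export
BacMap <- function(bacs) {
    stopifnot(is(bacs, "GRanges"))
    mc <- mcols(bacs)
    mc$bac_id <- as.character(mc$bac_id)
    mc$left_anchored <- as.logical(mc$left_anchored)
    mc$right_anchored <- as.logical(mc$right_anchored)
    mcols(bacs) <- mc
    empty <- GenomicRanges::GRanges()
    new("BacMap", raw = bacs, expanded = empty, extended = empty)
}

#' @rdname BacMap
#' @param x a `BacMap`.
#' @export
bacRaw <- function(x) x@raw

#' @rdname BacMap
#' @export
bacIds <- function(x) mcols(x@raw)$bac_id

#' @rdname BacMap
#' @export
bacExpanded <- function(x) {
    if (length(x@expanded) == 0L && length(x@raw) > 0L)
        stop("expanded coordinates not computed; run expandBacs() first")
    x@expanded
}

#' @rdname BacMap
#' @export
bacExtended <- function(x) {
    if (length(x@extended) == 0L && length(x@raw) > 0L)
        stop("extended coordinates not computed; run extendBacs() first")
    x@extended
}

#' @rdname BacMap
#' @export
bacDuplicateOf <- function(x) {
    d <- mcols(x@raw)$duplicate_of
    if (is.null(d)) rep(NA_character_, length(x@raw)) else d
}

setMethod("show", "BacMap", function(object) {
    n <- length(object@raw)
    cat(sprintf("BacMap: %d BAC clones on %d chromosome(s)\n", n,
                length(unique(as.character(
                    GenomicRanges::seqnames(object@raw))))))
    dup <- bacDuplicateOf(object)
    if (any(!is.na(dup)))
        cat(sprintf("  %d contained clone(s) marked duplicate\n",
                    sum(!is.na(dup))))
    cat(sprintf("  expanded: %s; extended: %s\n",
                if (length(object@expanded)) "yes" else "no",
                if (length(object@extended)) "yes" else "no"))
})

#' @export
setMethod("length", "BacMap", function(x) length(x@raw))
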