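#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom IRanges IRanges
#' @import GenomicRanges
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
NULL

#' Gene x sample copy-number alteration calls
#'
#' An `AlterationMatrix` holds discrete copy-number calls for a set of genes
#' across a cohort: `+1` for amplification, `-1` for deletion, `0` for no
#' significant change. It extends
#' [SummarizedExperiment::SummarizedExperiment] with a single assay named
#' `"calls"`, so the usual `dim`, `dimnames`, and subsetting machinery apply.
#'
#' @slot ... see [SummarizedExperiment::SummarizedExperiment].
#'
#' @seealso [AlterationMatrix()] for construction, [calls()],
#'   [geneIds()], [sampleIds()] for access.
#' @exportClass AlterationMatrix
setClass("AlterationMatrix", contains = "SummarizedExperiment")

setValidity("AlterationMatrix", function(object) {
    a <- SummarizedExperiment::assayNames(object)
    if (!identical(a, "calls"))
        return("an AlterationMatrix must carry exactly one assay named 'calls'")
    m <- SummarizedExperiment::assay(object, "calls")
    if (is.null(rownames(m)) || is.null(colnames(m)))
        return("gene (row) and sample (column) names are required")
    if (anyDuplicated(rownames(m)))
        return("duplicated gene identifiers")
    if (anyDuplicated(colnames(m)))
        return("duplicated sample identifiers")
    bad <- !(m %in% c(-1L, 0L, 1L))
    if (any(bad)) {
        i <- which(bad)[1L]
        rc <- arrayInd(i, dim(m))
        return(sprintf(
            "invalid call %s for gene '%s', sample '%s' (allowed: -1, 0, 1)",
            format(m[i]), rownames(m)[rc[1L]], colnames(m)[rc[2L]]))
    }
    TRUE
})

#' A collection of pathway gene sets
#'
#' Each pathway is a named set of gene identifiers; gene content of different
#' pathways may overlap. Duplicate genes within one pathway are removed at
#' construction.
#'
#' @slot sets named list of character vectors (the member genes).
#' @slot description named character vector, one free-text description per
#'   pathway.
#'
#' @seealso [PathwayCollection()], [readGmt()].
#' @exportClass PathwayCollection
setClass("PathwayCollection",
    representation(sets = "list", description = "character"))

setValidity("PathwayCollection", function(object) {
    s <- object@sets
    if (length(s) == 0L) return(TRUE)
    if (is.null(names(s)) || anyNA(names(s)) || any(names(s) == ""))
        return("every pathway must be named")
    if (anyDuplicated(names(s)))
        return("duplicated pathway identifiers")
    if (!all(vapply(s, is.character, logical(1))))
        return("pathway members must be character gene identifiers")
    if (any(vapply(s, length, integer(1)) < 1L))
        return("pathways must contain at least one gene")
    if (any(vapply(s, anyDuplicated, integer(1)) > 0L))
        return("duplicate genes within a pathway (deduplicate at construction)")
    if (!identical(names(object@description), names(s)))
        return("descriptions must parallel the pathway sets")
    TRUE
})

#' BAC clone coordinate map
#'
#' Holds the raw genomic intervals of the BAC clones on an array CGH platform
#' together with the two derived coordinate systems used to relate clones to
#' genes: *expanded* coordinates (clones grown to a minimum genomic span,
#' compensating for incomplete end-sequence mapping) and *extended*
#' coordinates (expanded clones further grown to tile the arrayed region, so
#' any position maps to exactly one clone).
#'
#' All three slots are [GenomicRanges::GRanges] of identical length and
#' order; `expanded` and `extended` are empty until [expandBacs()] /
#' [extendBacs()] have run. Metadata columns on `raw`:
#' `bac_id`, `left_anchored`, `right_anchored` (end-sequence evidence),
#' and after [resolveBacOverlaps()]: `duplicate_of` (container clone id or
#' `NA`), `frozen_left`, `frozen_right` (ends immobilised by a partial
#' overlap).
#'
#' @slot raw GRanges of as-mapped clone positions.
#' @slot expanded GRanges of expanded positions (may be length zero).
#' @slot extended GRanges of extended (tiling) positions (may be length zero).
#'
#' @seealso [BacMap()], [resolveBacOverlaps()], [expandBacs()],
#'   [extendBacs()].
#' @exportClass BacMap
setClass("BacMap",
    representation(raw = "GRanges", expanded = "GRanges",
                   extended = "GRanges"))

setValidity("BacMap", function(object) {
    r <- object@raw
    need <- c("bac_id", "left_anchored", "right_anchored")
    if (!all(need %in% colnames(mcols(r))))
        return("raw ranges need mcols bac_id, left_anchored, right_anchored")
    if (anyDuplicated(mcols(r)$bac_id))
        return("duplicated BAC identifiers")
    for (slotname in c("expanded", "extended")) {
        g <- slot(object, slotname)
        if (length(g) == 0L) next
        if (length(g) != length(r))
            return(sprintf("%s coordinates must parallel raw", slotname))
        dup <- mcols(r)$duplicate_of
        keep <- if (is.null(dup)) rep(TRUE, length(r)) else is.na(dup)
        cover <- as.character(GenomicRanges::seqnames(g)) ==
                     as.character(GenomicRanges::seqnames(r)) &
                 GenomicRanges::start(g) <= GenomicRanges::start(r) &
                 GenomicRanges::end(g) >= GenomicRanges::end(r)
        if (!all(cover[keep]))
            return(sprintf("%s coordinates must contain the raw span", slotname))
    }
    TRUE
})

#' Results of a population-level pathway targeting screen
#'
#' One record per pathway: the pathway size within the gene universe, the
#' omnibus statistic combining per-sample hypergeometric p-values, its
#' degrees of freedom, the combined population p-value, and the
#' Bonferroni-adjusted p-value with a family-wise significance flag.
#' Per-sample detail (altered-gene count `M_j`, pathway hit count `k_ij`,
#' per-sample p-value `p_ij`) is kept in matrix form and can be melted with
#' [perSampleTable()].
#'
#' @slot table `DataFrame` with one row per scored pathway.
#' @slot M named numeric, altered-gene count per sample.
#' @slot k pathway x sample matrix of hit counts.
#' @slot p pathway x sample matrix of per-sample p-values.
#' @slot parameters list echoing the analytic choices (universe size `G`,
#'   `hit_definition`, `tail`, `df_mode`, `alpha`, Bonferroni `m` and
#'   `threshold`).
#'
#' @seealso [scoreAllPathways()], [perSampleTable()].
#' @exportClass TargetingResults
setClass("TargetingResults",
    representation(table = "DataFrame", M = "numeric", k = "matrix",
                   p = "matrix", parameters = "list"))

setValidity("TargetingResults", function(object) {
    tb <- object@table
    need <- c("pathway_id", "n_genes", "omnibus_stat", "df",
              "p_population", "p_adjusted", "significant")
    if (!all(need %in% colnames(tb)))
        return(paste("results table must have columns:",
                     paste(need, collapse = ", ")))
    if (!identical(dim(object@k), dim(object@p)))
        return("k and p matrices must be congruent")
    if (nrow(object@p) != nrow(tb))
        return("per-sample matrices must have one row per pathway")
    if (length(object@M) != ncol(object@p))
        return("M must have one entry per sample")
    if (any(object@p < 0 | object@p > 1))
        return("per-sample p-values must lie in [0, 1]")
    if (any(tb$omnibus_stat < 0))
        return("omnibus statistic must be non-negative")
    TRUE
})
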