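#' Construct an AlterationMatrix
#'
#' @param calls integer-like matrix of copy-number calls, genes in rows and
#'   samples in columns, entries in `{-1, 0, 1}` (deletion / no change /
#'   amplification). Row and column names are mandatory.
#'
#' @return An [AlterationMatrix-class] object.
#' @examples
#' m <- matrix(c(1L, 0L, -1L, 0L), 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' am <- AlterationMatrix(m)
#' calls(am)
#' @export
AlterationMatrix <- function(calls) {
    calls <- as.matrix(calls)
    storage.mode(calls) <- "integer"
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(calls = calls))
    new("AlterationMatrix", se)
}

#' @rdname AlterationMatrix
#' @param x an `AlterationMatrix`.
#' @export
calls <- function(x) SummarizedExperiment::assay(x, "calls")

#' @rdname AlterationMatrix
#' @export
geneIds <- function(x) rownames(x)

#' @rdname AlterationMatrix
#' @export
sampleIds <- function(x) colnames(x)

setMethod("show", "AlterationMatrix", function(object) {
    m <- calls(object)
    cat(sprintf("AlterationMatrix: %d genes x %d samples\n",
                nrow(m), ncol(m)))
    cat(sprintf("  amplified calls: %d, deleted calls: %d (%.2f%% altered)\n",
                sum(m == 1L), sum(m == -1L),
                if (length(m)) 100 * mean(m != 0L) else 0))
})

#' Construct a PathwayCollection
#'
#' Duplicate genes within a pathway are dropped (with a message when any
#' were present).
#'
#' @param sets named list of character vectors of gene identifiers.
#' @param description optional named character vector of free-text
#'   descriptions, parallel to `sets`.
#'
#' @return A [PathwayCollection-class].
#' @examples
#' pc <- PathwayCollection(list(PW1 = c("A", "B"), PW2 = c("B", "C", "D")))
#' pathwaySizes(pc)
#' @export
PathwayCollection <- function(sets, description = NULL) {
    sets <- lapply(sets, as.character)
    ndup <- sum(vapply(sets, function(g) length(g) - length(unique(g)),
                       integer(1)))
    if (ndup > 0L) {
        message(sprintf("dropped %d duplicate gene entries within pathways",
                        ndup))
        sets <- lapply(sets, unique)
    }
    if (is.null(description)) {
        description <- rep(NA_character_, length(sets))
        names(description) <- names(sets)
    } else {
        description <- as.character(description)
        names(description) <- names(sets)
    }
    new("PathwayCollection", sets = sets, description = description)
}

#' @rdname PathwayCollection
#' @param x a `PathwayCollection`.
#' @export
pathwayIds <- function(x) names(x@sets)

#' @rdname PathwayCollection
#' @export
pathwaySets <- function(x) x@sets

#' @rdname PathwayCollection
#' @export
pathwaySizes <- function(x) vapply(x@sets, length, integer(1))

#' @export
setMethod("length", "PathwayCollection", function(x) length(x@sets))

#' @export
setMethod("names", "PathwayCollection", function(x) names(x@sets))

#' @export
setMethod("[[", "PathwayCollection", function(x, i) x@sets[[i]])

#' @export
setMethod("[", "PathwayCollection", function(x, i, j, ..., drop = TRUE) {
    new("PathwayCollection", sets = x@sets[i],
        description = x@description[i])
})

setMethod("show", "PathwayCollection", function(object) {
    n <- length(object@sets)
    cat(sprintf("PathwayCollection: %d pathways\n", n))
    if (n > 0L) {
        sz <- pathwaySizes(object)
        cat(sprintf("  sizes: %d-%d genes (median %.0f); %d distinct genes\n",
                    min(sz), max(sz), stats::median(sz),
                    length(unique(unlist(object@sets)))))
    }
})
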