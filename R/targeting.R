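#' Hypergeometric probability of a pathway hit count
#'
#' With `G` genes on the platform, `N` of them in the pathway, and `M`
#' genes altered in a sample, the number of altered pathway genes under
#' random targeting follows the hypergeometric distribution. This returns
#' `P(X = k)`, computed in log space.
#'
#' @param G gene-universe size.
#' @param N pathway size within the universe.
#' @param M number of altered genes in the sample.
#' @param k number of altered genes falling in the pathway.
#' @return `P(X = k)`; zero outside the support
#'   `[max(0, M - (G - N)), min(N, M)]`. Arguments recycle.
#' @seealso [pathwaySamplePvalue()]
#' @export
hypergeomHitPmf <- function(G, N, M, k) {
    .check_hyper_args(G, N, M, k)
    stats::dhyper(k, m = N, n = G - N, k = M)
}

.check_hyper_args <- function(G, N, M, k) {
    for (v in list(G = G, N = N, M = M, k = k)) {
        if (any(!is.finite(v)) || any(v < 0) || any(v != floor(v)))
            stop("G, N, M, k must be non-negative integers")
    }
    if (any(N > G) || any(M > G))
        stop("pathway size N and altered count M cannot exceed the universe G")
    invisible(TRUE)
}

#' Per-sample pathway targeting p-value
#'
#' The upper-tail hypergeometric probability of observing at least (or,
#' with `tail = "exclusive"`, more than) the observed number of altered
#' pathway genes, given the sample's total altered-gene count. The
#' inclusive tail `P(X >= k)` is the default, so the observed count itself
#' counts as evidence; `k = 0` always gives 1.
#'
#' @inheritParams hypergeomHitPmf
#' @param tail `"inclusive"` for `P(X >= k)` (default) or `"exclusive"`
#'   for `P(X > k)`.
#' @return p-value in `(0, 1]` (inclusive tail) or `[0, 1]` (exclusive).
#' @examples
#' pathwaySamplePvalue(10, 3, 4, 2)  # 1/3
#' @export
pathwaySamplePvalue <- function(G, N, M, k,
                                tail = c("inclusive", "exclusive")) {
    tail <- match.arg(tail)
    .check_hyper_args(G, N, M, k)
    kk <- if (tail == "inclusive") k - 1 else k
    stats::phyper(kk, m = N, n = G - N, k = M, lower.tail = FALSE)
}

#' Combine per-sample p-values with Fisher's omnibus statistic
#'
#' The statistic is `X = -2 * sum(log(p_j))` over the cohort's per-sample
#' p-values, referred to the upper tail of a chi-square distribution.
#' Standard theory gives two degrees of freedom per combined p-value
#' (`df_mode = "two_per_sample"`, the default); `"one_per_sample"` uses
#' one degree of freedom per sample instead, which treats each sample's
#' evidence as a single squared-normal contribution and is offered for
#' comparability.
#'
#' @param pvals numeric vector of per-sample p-values in `(0, 1]`; values
#'   below `1e-300` are clamped with a warning before taking logs.
#' @param df_mode `"two_per_sample"` or `"one_per_sample"`.
#' @return list with `statistic`, `p`, `df`.
#' @examples
#' fisherOmnibus(c(0.1, 0.1))  # statistic 9.21, combined p 0.056
#' @export
fisherOmnibus <- function(pvals, df_mode = c("two_per_sample",
                                             "one_per_sample")) {
    df_mode <- match.arg(df_mode)
    if (length(pvals) == 0L) stop("no p-values to combine")
    if (any(!is.finite(pvals)) || any(pvals <= 0) || any(pvals > 1))
        stop("p-values must lie in (0, 1]")
    if (any(pvals < 1e-300)) {
        warning("p-values below 1e-300 clamped before log transform")
        pvals <- pmax(pvals, 1e-300)
    }
    X <- -2 * sum(log(pvals))
    df <- if (df_mode == "two_per_sample") 2L * length(pvals)
          else length(pvals)
    list(statistic = X, p = stats::pchisq(X, df = df, lower.tail = FALSE),
         df = df)
}

#' Bonferroni adjustment over a family of pathway p-values
#'
#' @param p numeric vector of raw p-values, one per pathway tested.
#' @param alpha family-wise error level.
#' @param m size of the tested family; defaults to `length(p)`.
#' @return list with `p_adjusted` (`min(1, m * p)`), `significant`
#'   (`p < alpha / m`), and `threshold` (`alpha / m`).
#' @examples
#' bonferroniAdjust(1e-6, m = 566)$threshold  # 0.05 / 566
#' @export
bonferroniAdjust <- function(p, alpha = 0.05, m = length(p)) {
    stopifnot(m >= 1L)
    list(p_adjusted = pmin(1, m * p),
         significant = p < alpha / m,
         threshold = alpha / m)
}

#' Score every pathway for population-level CNA targeting
#'
#' For each pathway and each sample, counts the altered genes falling in
#' the pathway (`k_ij`) against the sample's altered-gene total (`M_j`)
#' within the gene universe, converts the count to an upper-tail
#' hypergeometric p-value, combines the per-sample p-values across the
#' cohort with Fisher's omnibus statistic, and applies Bonferroni
#' adjustment across pathways. Because `M_j` and `N_i` enter the null for
#' every sample and pathway, the score compensates for pathway size:
#' larger pathways need proportionally more altered genes for the same
#' p-value.
#'
#' @param x an [AlterationMatrix-class].
#' @param pathways a [PathwayCollection-class]. Pathway genes outside the
#'   universe are dropped (count logged); pathways left empty are skipped
#'   with a warning.
#' @param universe character vector of gene identifiers defining the
#'   sampling frame `G`; defaults to the matrix's genes (a whole-genome
#'   platform would have roughly 24,000). Matrix genes must be a subset.
#' @param hit_definition which calls count as hits: `"any_alteration"`
#'   (default; amplification and deletion are both targeting events),
#'   `"amplification_only"`, or `"deletion_only"`.
#' @param tail,df_mode passed to [pathwaySamplePvalue()] and
#'   [fisherOmnibus()].
#' @param alpha family-wise level for the Bonferroni flag.
#' @return A [TargetingResults-class], ordered as the input pathways.
#' @export
scoreAllPathways <- function(x, pathways, universe = NULL,
                             hit_definition = c("any_alteration",
                                                "amplification_only",
                                                "deletion_only"),
                             tail = c("inclusive", "exclusive"),
                             df_mode = c("two_per_sample",
                                         "one_per_sample"),
                             alpha = 0.05) {
    hit_definition <- match.arg(hit_definition)
    tail <- match.arg(tail)
    df_mode <- match.arg(df_mode)
    stopifnot(is(x, "AlterationMatrix"), is(pathways, "PathwayCollection"))
    m <- calls(x)
    if (is.null(universe)) universe <- rownames(m)
    universe <- unique(as.character(universe))
    if (!all(rownames(m) %in% universe))
        stop("matrix genes must be contained in the universe")
    G <- length(universe)

    H <- switch(hit_definition,
        any_alteration     = m != 0L,
        amplification_only = m == 1L,
        deletion_only      = m == -1L)
    storage.mode(H) <- "integer"
    M <- colSums(H)

    sets <- pathwaySets(pathways)
    trimmed <- lapply(sets, function(g) g[g %in% universe])
    n_out <- sum(lengths(sets) - lengths(trimmed))
    if (n_out > 0L)
        message(sprintf("%d pathway gene(s) outside the universe dropped",
                        n_out))
    N <- lengths(trimmed)
    empty <- N == 0L
    if (any(empty)) {
        warning(sprintf("%d pathway(s) with no genes in the universe skipped",
                        sum(empty)))
        trimmed <- trimmed[!empty]
        N <- N[!empty]
    }
    if (length(trimmed) == 0L) stop("no scorable pathways")

    # hit counts for all pathways at once: indicator %*% hit matrix
    gidx <- lapply(trimmed, match, table = rownames(m))
    ind <- matrix(0L, length(trimmed), nrow(m))
    for (i in seq_along(gidx)) {
        gi <- gidx[[i]]
        gi <- gi[!is.na(gi)]    # universe genes absent from the matrix: no hits
        ind[i, gi] <- 1L
    }
    k <- ind %*% H
    dimnames(k) <- list(names(trimmed), colnames(m))

    Mrow <- matrix(M, nrow(k), ncol(k), byrow = TRUE)
    kk <- if (tail == "inclusive") k - 1 else k
    p <- matrix(stats::phyper(kk, m = N, n = G - N, k = Mrow,
                              lower.tail = FALSE),
                nrow(k), ncol(k), dimnames = dimnames(k))

    pc <- pmax(p, 1e-300)
    if (any(p < 1e-300))
        warning("per-sample p-values below 1e-300 clamped")
    X <- -2 * rowSums(log(pc))
    df <- if (df_mode == "two_per_sample") 2L * ncol(p) else ncol(p)
    p_pop <- stats::pchisq(X, df = df, lower.tail = FALSE)
    adj <- bonferroniAdjust(p_pop, alpha = alpha)

    tb <- S4Vectors::DataFrame(
        pathway_id = names(trimmed),
        n_genes = as.integer(unname(N)),
        omnibus_stat = unname(X),
        df = rep(as.integer(df), length(X)),
        p_population = unname(p_pop),
        p_adjusted = unname(adj$p_adjusted),
        significant = unname(adj$significant))
    new("TargetingResults", table = tb, M = M, k = k, p = p,
        parameters = list(G = G, hit_definition = hit_definition,
                          tail = tail, df_mode = df_mode, alpha = alpha,
                          m = length(trimmed), threshold = adj$threshold))
}

#' @describeIn scoreAllPathways per-pathway results as a `DataFrame`.
#' @export
resultsTable <- function(x) {
    stopifnot(is(x, "TargetingResults"))
    x@table
}

#' @describeIn scoreAllPathways long-format per-sample detail:
#'   `pathway_id`, `sample_id`, `M_j`, `k_ij`, `p_ij`.
#' @export
perSampleTable <- function(x) {
    stopifnot(is(x, "TargetingResults"))
    data.frame(
        pathway_id = rep(rownames(x@p), times = ncol(x@p)),
        sample_id = rep(colnames(x@p), each = nrow(x@p)),
        M_j = rep(unname(x@M), each = nrow(x@p)),
        k_ij = as.vector(x@k),
        p_ij = as.vector(x@p),
        stringsAsFactors = FALSE)
}

#' @describeIn scoreAllPathways analytic choices used in the run.
#' @export
targetingParameters <- function(x) {
    stopifnot(is(x, "TargetingResults"))
    x@parameters
}

setMethod("show", "TargetingResults", function(object) {
    tb <- object@table
    pars <- object@parameters
    cat(sprintf("TargetingResults: %d pathways x %d samples (G = %d)\n",
                nrow(tb), ncol(object@p), pars$G))
    cat(sprintf("  hits: %s; tail: %s; df: %s\n", pars$hit_definition,
                pars$tail, pars$df_mode))
    cat(sprintf("  Bonferroni threshold %.4g (alpha = %g, m = %d); %d significant\n",
                pars$threshold, pars$alpha, pars$m, sum(tb$significant)))
    o <- order(tb$p_population)
    top <- utils::head(tb[o, c("pathway_id", "n_genes", "p_population",
                               "p_adjusted")], 5L)
    cat("  top pathways:\n")
    for (i in seq_len(nrow(top)))
        cat(sprintf("    %s (N=%d): p = %.3g, adj = %.3g\n",
                    top$pathway_id[i], top$n_genes[i],
                    top$p_population[i], top$p_adjusted[i]))
})
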