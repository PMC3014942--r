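#' Stratify samples into two groups from pathway scores
#'
#' Splits a cohort in two from one or more per-sample pathway scores
#' (e.g. externally computed activity and consistency metrics). The
#' default is two-cluster k-means on standardized scores with multiple
#' restarts; a median split and a hierarchical (Ward) cut are offered as
#' alternatives. Group `1` is always the group with the higher mean of the
#' first score, so labels are comparable across methods.
#'
#' @param scores numeric vector (one score per sample) or matrix with
#'   samples in rows and score types in columns.
#' @param method `"two_means"`, `"median_split"` (first score column
#'   only), or `"hierarchical_cut"`.
#' @param seed integer seed controlling the k-means restarts.
#' @param nstart number of k-means restarts.
#' @return integer vector of group labels in `{0, 1}`, named by sample
#'   where `scores` carried names.
#' @export
stratifyTwoGroups <- function(scores, method = c("two_means",
                                                 "median_split",
                                                 "hierarchical_cut"),
                              seed = 1L, nstart = 10L) {
    method <- match.arg(method)
    s <- if (is.matrix(scores)) scores else matrix(scores,
        dimnames = list(names(scores), NULL))
    if (any(!is.finite(s))) stop("scores must be finite")
    if (nrow(s) < 4L) stop("at least 4 samples required for stratification")
    if (all(apply(s, 2L, function(v) length(unique(v)) < 2L)))
        stop("constant scores: no stratification possible")
    grp <- switch(method,
        two_means = {
            z <- scale(s)
            z <- z[, is.finite(colSums(z)), drop = FALSE]  # drop constant scores
            old <- if (exists(".Random.seed", .GlobalEnv))
                get(".Random.seed", .GlobalEnv) else NULL
            set.seed(seed)
            km <- stats::kmeans(z, centers = 2L, nstart = nstart)
            if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
            km$cluster - 1L
        },
        median_split = {
            v <- s[, 1L]
            as.integer(v > stats::median(v))
        },
        hierarchical_cut = {
            z <- scale(s)
            z <- z[, is.finite(colSums(z)), drop = FALSE]
            hc <- stats::hclust(stats::dist(z), method = "ward.D2")
            stats::cutree(hc, k = 2L) - 1L
        })
    # orient: group 1 = higher mean of the first score
    if (mean(s[grp == 1L, 1L]) < mean(s[grp == 0L, 1L])) grp <- 1L - grp
    names(grp) <- rownames(s)
    grp
}

#' Kaplan-Meier product-limit survival estimate
#'
#' A thin wrapper around [survival::survfit()] returning the step
#' function as a data frame, with the `S(0) = 1` origin included. The
#' estimate is non-increasing and drops only at event times; censored
#' subjects at a time `t` remain at risk for events at `t`.
#'
#' @param time non-negative follow-up times.
#' @param event event indicator (1 = event, 0 = censored).
#' @return data frame with columns `time`, `n_risk`, `n_event`, `surv`.
#' @examples
#' kmCurve(c(1, 2, 3), c(1, 1, 1))$surv  # 2/3, 1/3, 0
#' @export
kmCurve <- function(time, event) {
    if (length(time) == 0L) stop("empty group")
    if (any(time < 0)) stop("negative follow-up time")
    fit <- survival::survfit(survival::Surv(time, event) ~ 1)
    data.frame(time = c(0, fit$time),
               n_risk = c(fit$n, fit$n.risk),
               n_event = c(0, fit$n.event),
               surv = c(1, fit$surv))
}

#' Two-group log-rank test
#'
#' @param time,event as in [kmCurve()].
#' @param group two-level group labels; both groups must be non-empty.
#' @return list with `statistic` (chi-square, 1 df) and `p`.
#' @export
logrankTest <- function(time, event, group) {
    group <- as.factor(group)
    if (nlevels(droplevels(group)) != 2L)
        stop("exactly two non-empty groups required")
    sd <- survival::survdiff(survival::Surv(time, event) ~ group)
    list(statistic = unname(sd$chisq),
         p = stats::pchisq(sd$chisq, df = 1L, lower.tail = FALSE))
}

#' Screen pathways for survival separation
#'
#' For each pathway, stratifies the cohort in two from its score vector(s)
#' and tests survival separation with the log-rank test, reporting raw
#' p-values with a flag at `p < alpha` and Bonferroni-adjusted p-values
#' with a family-wise flag — the two-stage reporting used when screening
#' hundreds of pathways.
#'
#' @param scores matrix of scores, pathways in rows and samples in
#'   columns, or a named list of such matrices (e.g. activity and
#'   consistency) used jointly for stratification.
#' @param time,event named per-sample follow-up and event indicator;
#'   samples are matched by name to the score columns, unmatched samples
#'   dropped with a warning.
#' @param pathways optional character vector restricting the screen.
#' @param alpha significance level.
#' @param method,seed passed to [stratifyTwoGroups()].
#' @return data frame with one row per pathway: group sizes, chi-square,
#'   `p`, `p_adjusted`, `significant_raw`, `significant_bonferroni`.
#' @export
survivalScreen <- function(scores, time, event, pathways = NULL,
                           alpha = 0.05, method = "two_means", seed = 1L) {
    mats <- if (is.list(scores) && !is.data.frame(scores)) scores
            else list(score = scores)
    mats <- lapply(mats, as.matrix)
    ids <- rownames(mats[[1L]])
    if (!is.null(pathways)) {
        ids <- intersect(pathways, ids)
        mats <- lapply(mats, function(m) m[ids, , drop = FALSE])
    }
    if (length(ids) == 0L)
        return(data.frame(pathway_id = character(), n_group0 = integer(),
                          n_group1 = integer(), chisq = numeric(),
                          p = numeric(), p_adjusted = numeric(),
                          significant_raw = logical(),
                          significant_bonferroni = logical()))
    samp <- intersect(colnames(mats[[1L]]), names(time))
    dropped <- setdiff(colnames(mats[[1L]]), samp)
    if (length(dropped))
        warning(sprintf("%d sample(s) without survival data dropped",
                        length(dropped)))
    out <- lapply(ids, function(pw) {
        sv <- do.call(cbind, lapply(mats, function(m) m[pw, samp]))
        ok <- stats::complete.cases(sv)
        if (sum(!ok))
            message(sprintf("%s: %d sample(s) with missing scores excluded",
                            pw, sum(!ok)))
        grp <- stratifyTwoGroups(sv[ok, , drop = FALSE], method = method,
                                 seed = seed)
        lt <- logrankTest(time[samp][ok], event[samp][ok], grp)
        data.frame(pathway_id = pw, n_group0 = sum(grp == 0L),
                   n_group1 = sum(grp == 1L), chisq = lt$statistic,
                   p = lt$p)
    })
    res <- do.call(rbind, out)
    adj <- bonferroniAdjust(res$p, alpha = alpha)
    res$p_adjusted <- adj$p_adjusted
    res$significant_raw <- res$p < alpha
    res$significant_bonferroni <- adj$significant
    rownames(res) <- NULL
    res
}
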