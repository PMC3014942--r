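# Independent oracles used across the suite. Each deliberately avoids the
# code path it checks: subset enumeration instead of phyper, per-base
# scanning instead of interval overlap, combinatorial relabelling instead
# of the chi-square reference.

# upper-tail hypergeometric by exhaustive enumeration of all C(G, M)
# equally likely altered-gene subsets (genes 1..N form the pathway)
hyper_tail_enum <- function(G, N, M, k) {
    if (M == 0L) return(as.numeric(k <= 0L))
    subsets <- utils::combn(G, M)
    hits <- colSums(subsets <= N)
    mean(hits >= k)
}

# upper-tail hypergeometric from binomial coefficients (exact arithmetic
# on modest parameters; independent of phyper's algorithm)
hyper_tail_choose <- function(G, N, M, k) {
    ks <- seq(max(0L, k), min(N, M))
    if (k <= max(0L, M - (G - N))) return(1)
    sum(exp(lchoose(N, ks) + lchoose(G - N, M - ks) - lchoose(G, M)))
}

# closed-form chi-square upper tail at even df: exp(-X/2) * sum (X/2)^i/i!
fisher_closed_form <- function(X, df) {
    stopifnot(df %% 2L == 0L)
    i <- 0:(df / 2L - 1L)
    exp(-X / 2) * sum(exp(i * log(X / 2) - lfactorial(i)))
}

# exhaustive permutation p-value of the two-group log-rank statistic
perm_logrank_p <- function(time, event, group) {
    n <- length(time)
    n1 <- sum(group == 1L)
    obs <- logrankTest(time, event, group)$statistic
    combs <- utils::combn(n, n1)
    stats <- apply(combs, 2L, function(ix) {
        g <- integer(n); g[ix] <- 1L
        tryCatch(logrankTest(time, event, g)$statistic,
                 error = function(e) NA_real_)
    })
    mean(stats >= obs - 1e-12, na.rm = TRUE)
}

# per-base brute-force overlay: for every gene (using the supplied
# effective interval), scan each base against every segment of a sample
brute_overlay <- function(seg_df, eff_df, samples) {
    m <- matrix(0L, nrow(eff_df), length(samples),
                dimnames = list(eff_df$gene_id, samples))
    for (gi in seq_len(nrow(eff_df))) {
        bases <- seq(eff_df$start[gi], eff_df$end[gi])
        for (s in samples) {
            sd <- seg_df[seg_df$sample_id == s, , drop = FALSE]
            amp <- del <- 0L
            for (si in seq_len(nrow(sd))) {
                ov <- sum(bases >= sd$start[si] & bases <= sd$end[si])
                if (sd$state[si] == 1L) amp <- amp + ov else del <- del + ov
            }
            m[gi, s] <- if (amp > del) 1L else if (del > amp) -1L else 0L
        }
    }
    m
}

# convenience: BacMap from 0-based half-open coordinates (file convention)
mk_bacmap <- function(start0, end0, left = FALSE, right = FALSE,
                      ids = sprintf("B%02d", seq_along(start0)),
                      chrom = "chr1") {
    BacMap(GenomicRanges::GRanges(chrom,
        IRanges::IRanges(start0 + 1L, end0),
        bac_id = ids,
        left_anchored = rep_len(left, length(start0)),
        right_anchored = rep_len(right, length(start0))))
}

mk_genes <- function(start0, end0,
                     ids = sprintf("g%02d", seq_along(start0)),
                     chrom = "chr1") {
    GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1L, end0),
                           gene_id = ids)
}

mk_segments <- function(start0, end0, sample_id, state, chrom = "chr1") {
    GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1L, end0),
                           sample_id = sample_id, state = as.integer(state))
}

# 0-based [start, end) view of a GRanges, for comparison with file values
coords0 <- function(gr) {
    cbind(start = GenomicRanges::start(gr) - 1L,
          end = GenomicRanges::end(gr))
}
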