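#' Resolve overlaps among raw BAC coordinates
#'
#' A clone whose raw interval lies entirely within a larger clone is marked
#' a duplicate of that clone and will adopt the container's final (expanded
#' and extended) coordinates. When two clones overlap only partially, the
#' coordinates inside the overlap are left as they are and the overlapping
#' end of each clone is frozen: neither expansion nor extension will move
#' it.
#'
#' @param x a [BacMap-class].
#' @return `x` with `duplicate_of`, `frozen_left` and `frozen_right`
#'   metadata columns filled in on the raw ranges.
#' @export
resolveBacOverlaps <- function(x) {
    stopifnot(is(x, "BacMap"))
    r <- x@raw
    n <- length(r)
    dup <- rep(NA_character_, n)
    fl <- rep(FALSE, n)
    fr <- rep(FALSE, n)
    ids <- mcols(r)$bac_id
    if (n > 1L) {
        w <- GenomicRanges::width(r)
        # containment: smaller clone marked duplicate of the largest container
        hit <- GenomicRanges::findOverlaps(r, r, type = "within")
        qi <- S4Vectors::queryHits(hit); si <- S4Vectors::subjectHits(hit)
        keep <- qi != si & (w[si] > w[qi] |
                            (w[si] == w[qi] & si < qi))   # identical spans: first wins
        qi <- qi[keep]; si <- si[keep]
        if (length(qi)) {
            best <- tapply(si, qi, function(j) j[which.max(w[j])])
            dup[as.integer(names(best))] <- ids[unlist(best)]
        }
        # transitive closure: container may itself be a duplicate
        repeat {
            parent <- match(dup, ids)
            step <- !is.na(parent) & !is.na(dup[parent])
            if (!any(step)) break
            dup[step] <- dup[parent[step]]
        }
        # partial overlaps among non-duplicates freeze the facing ends
        live <- which(is.na(dup))
        if (length(live) > 1L) {
            rl <- r[live]
            ph <- GenomicRanges::findOverlaps(rl, drop.self = TRUE,
                                              drop.redundant = TRUE)
            for (h in seq_along(ph)) {
                a <- S4Vectors::queryHits(ph)[h]
                b <- S4Vectors::subjectHits(ph)[h]
                # order the pair so 'a' starts first (ties: ends first)
                if (GenomicRanges::start(rl)[b] < GenomicRanges::start(rl)[a] ||
                    (GenomicRanges::start(rl)[b] == GenomicRanges::start(rl)[a] &&
                     GenomicRanges::end(rl)[b] < GenomicRanges::end(rl)[a])) {
                    tmp <- a; a <- b; b <- tmp
                }
                fr[live[a]] <- TRUE
                fl[live[b]] <- TRUE
            }
        }
    }
    mcols(r)$duplicate_of <- dup
    mcols(r)$frozen_left <- fl
    mcols(r)$frozen_right <- fr
    x@raw <- r
    x
}

# Growth rounds for one chromosome. Positions are 1-based closed; the
# claims on a shared gap are split ceiling-to-the-left so facing ends can
# never cross within a round.
.expand_chrom <- function(st, en, fix_l, fix_r, skip, target_span,
                          granularity) {
    n <- length(st)
    max_rounds <- 20L + 10L * ceiling(target_span / granularity)
    clamped <- FALSE
    for (round in seq_len(max_rounds)) {
        rem <- pmax(0L, target_span - (en - st + 1L))
        active <- !skip & rem > 0L & !(fix_l & fix_r)
        if (!any(active)) break
        want_l <- active & !fix_l
        want_r <- active & !fix_r
        take_l <- integer(n); take_r <- integer(n)
        for (i in which(active)) {
            # per-round claim on each side, bounded by the fair share of
            # the facing gap while the neighbour is still growing toward it
            room_l <- if (i == 1L) st[i] - 1L else {
                g <- st[i] - en[i - 1L] - 1L
                if (g <= 0L) 0L
                else if (want_r[i - 1L]) g %/% 2L else g
            }
            room_r <- if (i == n) .Machine$integer.max %/% 2L else {
                g <- st[i + 1L] - en[i] - 1L
                if (g <= 0L) 0L
                else if (want_l[i + 1L]) (g + 1L) %/% 2L else g
            }
            base_l <- if (fix_l[i]) 0L else min(granularity, room_l)
            base_r <- if (fix_r[i]) 0L else min(granularity, room_r)
            tl <- min(base_l, (rem[i] + 1L) %/% 2L)
            tr <- min(base_r, rem[i] - tl)
            tl <- min(base_l, rem[i] - tr)  # compensate a blocked side
            take_l[i] <- tl; take_r[i] <- tr
            if (!fix_l[i] && room_l < granularity && i == 1L &&
                st[i] - tl == 1L && rem[i] - tl - tr > 0L)
                clamped <- TRUE
        }
        if (all(take_l == 0L) && all(take_r == 0L)) break
        st <- st - take_l
        en <- en + take_r
    }
    if (clamped)
        message("expansion clamped at chromosome start for at least one BAC")
    list(start = st, end = en)
}

#' Expand BAC coordinates to a minimum genomic span
#'
#' Clones with incompletely mapped end sequences are grown toward a target
#' span (default 165 kb, a typical span of fully end-mapped clones) so that
#' well-mapped clones do not crowd out poorly mapped ones. A clone is left
#' untouched when both of its end sequences are mapped or when its raw span
#' already reaches `skip_span`. A single-anchored clone grows only away
#' from its anchored end; an unanchored clone grows symmetrically.
#' Growth proceeds in multi-pass rounds of at most `granularity` bases per
#' side, so that the space between closely mapped neighbours is assigned
#' equally to the clones competing for it; growth blocked on one side is
#' compensated on the other side unless that end is fixed.
#'
#' @param x a [BacMap-class]; [resolveBacOverlaps()] is applied first if it
#'   has not run (frozen ends behave like anchored ends here).
#' @param target_span total span, in bases, a clone is grown towards.
#' @param skip_span raw spans at least this long are never expanded.
#' @param granularity growth increment per side per round, in bases.
#' @return `x` with the `expanded` slot filled.
#' @export
expandBacs <- function(x, target_span = 165000L, skip_span = 100000L,
                       granularity = 1000L) {
    stopifnot(is(x, "BacMap"))
    if (is.null(mcols(x@raw)$duplicate_of)) x <- resolveBacOverlaps(x)
    r <- x@raw
    mc <- mcols(r)
    st <- GenomicRanges::start(r); en <- GenomicRanges::end(r)
    new_st <- st; new_en <- en
    live <- is.na(mc$duplicate_of)
    fix_l <- mc$left_anchored | mc$frozen_left
    fix_r <- mc$right_anchored | mc$frozen_right
    skip <- (mc$left_anchored & mc$right_anchored) |
            (en - st + 1L) >= skip_span
    for (chr in unique(as.character(GenomicRanges::seqnames(r)))) {
        idx <- which(live & as.character(GenomicRanges::seqnames(r)) == chr)
        if (!length(idx)) next
        ord <- idx[order(st[idx], en[idx], mc$bac_id[idx])]
        res <- .expand_chrom(st[ord], en[ord], fix_l[ord], fix_r[ord],
                             skip[ord], as.integer(target_span),
                             as.integer(granularity))
        new_st[ord] <- res$start
        new_en[ord] <- res$end
    }
    # contained duplicates adopt the container's expanded coordinates
    parent <- match(mc$duplicate_of, mc$bac_id)
    dup <- which(!is.na(parent))
    new_st[dup] <- new_st[parent[dup]]
    new_en[dup] <- new_en[parent[dup]]
    x@expanded <- GenomicRanges::GRanges(
        GenomicRanges::seqnames(r), IRanges::IRanges(new_st, new_en))
    x
}

#' Extend expanded BAC coordinates to tile the arrayed region
#'
#' The gap between consecutive expanded clones is split at its midpoint
#' (an odd base goes to the left clone), producing pseudo-tiling coverage:
#' every position in the covered span belongs to exactly one clone, so any
#' genomic region can be attributed to its most appropriate clone. An end
#' frozen by a partial raw overlap is never moved. The outermost clone ends
#' stay at the boundary of the arrayed (covered) span by default, or run to
#' the chromosome ends with `bounds = "chromosome"`.
#'
#' @param x a [BacMap-class] with expanded coordinates.
#' @param bounds `"array"` (default) or `"chromosome"`.
#' @param seqlengths named vector of chromosome lengths, required for
#'   `bounds = "chromosome"`.
#' @return `x` with the `extended` slot filled.
#' @export
extendBacs <- function(x, bounds = c("array", "chromosome"),
                       seqlengths = NULL) {
    stopifnot(is(x, "BacMap"))
    bounds <- match.arg(bounds)
    if (length(x@expanded) == 0L && length(x@raw) > 0L)
        stop("run expandBacs() before extendBacs()")
    r <- x@raw
    mc <- mcols(r)
    st <- GenomicRanges::start(x@expanded)
    en <- GenomicRanges::end(x@expanded)
    fix_l <- mc$frozen_left
    fix_r <- mc$frozen_right
    live <- is.na(mc$duplicate_of)
    for (chr in unique(as.character(GenomicRanges::seqnames(r)))) {
        idx <- which(live & as.character(GenomicRanges::seqnames(r)) == chr)
        if (!length(idx)) next
        ord <- idx[order(st[idx], en[idx], mc$bac_id[idx])]
        if (length(ord) > 1L) {
            for (i in seq_len(length(ord) - 1L)) {
                a <- ord[i]; b <- ord[i + 1L]
                g <- st[b] - en[a] - 1L
                if (g <= 0L) next
                if (!fix_r[a] && !fix_l[b]) {
                    en[a] <- en[a] + (g + 1L) %/% 2L
                    st[b] <- en[a] + 1L
                } else if (!fix_r[a]) {
                    en[a] <- st[b] - 1L
                } else if (!fix_l[b]) {
                    st[b] <- en[a] + 1L
                }                               # both frozen: gap unassigned
            }
        }
        if (bounds == "chromosome") {
            if (is.null(seqlengths) || is.na(seqlengths[chr]))
                stop("seqlengths required for bounds = 'chromosome'")
            first <- ord[1L]; last <- ord[length(ord)]
            if (!fix_l[first]) st[first] <- 1L
            if (!fix_r[last]) en[last] <- as.integer(seqlengths[chr])
        }
    }
    parent <- match(mc$duplicate_of, mc$bac_id)
    dup <- which(!is.na(parent))
    st[dup] <- st[parent[dup]]
    en[dup] <- en[parent[dup]]
    x@extended <- GenomicRanges::GRanges(
        GenomicRanges::seqnames(r), IRanges::IRanges(st, en))
    x
}
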