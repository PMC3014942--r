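test_that("expansion respects span, anchoring and symmetry rules", {
    # raw span >= 100 kb: never expanded
    b <- expandBacs(mk_bacmap(100000, 220000))
    expect_equal(coords0(bacExpanded(b)), cbind(start = 100000, end = 220000))
    # both ends anchored: never expanded, regardless of span
    b <- expandBacs(mk_bacmap(100000, 105000, left = TRUE, right = TRUE))
    expect_equal(coords0(bacExpanded(b)), cbind(start = 100000, end = 105000))
    # unanchored isolated clone: symmetric growth to the 165 kb target
    b <- expandBacs(mk_bacmap(100000, 105000))
    expect_equal(coords0(bacExpanded(b)), cbind(start = 20000, end = 185000))
    # single anchor: growth only away from the anchored end
    b <- expandBacs(mk_bacmap(100000, 105000, left = TRUE))
    expect_equal(coords0(bacExpanded(b)), cbind(start = 100000, end = 265000))
    b <- expandBacs(mk_bacmap(400000, 405000, right = TRUE))
    expect_equal(coords0(bacExpanded(b)), cbind(start = 240000, end = 405000))
    # growth clamps at the chromosome start, compensating rightward
    expect_message(b <- expandBacs(mk_bacmap(1000, 6000)), "clamped")
    co <- coords0(bacExpanded(b))
    expect_equal(unname(co[, "start"]), 0)
    expect_equal(unname(co[, "end"] - co[, "start"]), 165000)
})

test_that("competing clones split the intervening space equally", {
    # two unanchored 5 kb clones, 100 kb apart: each takes half the gap
    b <- expandBacs(mk_bacmap(c(500000, 605000), c(505000, 610000)))
    co <- coords0(bacExpanded(b))
    expect_equal(unname(co[1, "end"]), unname(co[2, "start"]))  # met at the midpoint
    expect_equal(unname(co[1, "end"]), 555000)
    # outer ends still free: both reach the full 165 kb target
    expect_equal(unname(co[, "end"] - co[, "start"]), c(165000, 165000))
    # a clone that stops early leaves the rest of the gap to its neighbour
    b <- expandBacs(mk_bacmap(c(500000, 605000), c(505000, 610000)),
                    target_span = c(20000)[1])
    co <- coords0(bacExpanded(b))
    expect_true(co[1, "end"] <= co[2, "start"])
    expect_equal(unname(co[, "end"] - co[, "start"]), c(20000, 20000))
    # right clone blocked on the left by a big immobile neighbour:
    # compensatory expansion goes rightward
    b <- expandBacs(mk_bacmap(c(0, 210000), c(200000, 215000)))
    co <- coords0(bacExpanded(b))
    expect_equal(unname(co[1, ]), c(0, 200000))    # >= 100 kb, untouched
    expect_true(co[2, "start"] >= 200000)
    expect_equal(unname(co[2, "end"] - co[2, "start"]), 165000)
})

test_that("overlap resolution marks contained duplicates and freezes partial overlaps", {
    # full containment: the smaller clone adopts the container's coordinates
    b <- mk_bacmap(c(0, 50000), c(200000, 120000))
    b <- extendBacs(expandBacs(resolveBacOverlaps(b)))
    expect_equal(bacDuplicateOf(b), c(NA, "B01"))
    expect_equal(coords0(bacExpanded(b))[1, ], coords0(bacExpanded(b))[2, ])
    expect_equal(coords0(bacExtended(b))[1, ], coords0(bacExtended(b))[2, ])
    # partial overlap: the overlapping ends are frozen, free ends still grow
    b <- resolveBacOverlaps(mk_bacmap(c(0, 80000), c(100000, 150000)))
    mc <- S4Vectors::mcols(bacRaw(b))
    expect_equal(mc$frozen_right, c(TRUE, FALSE))
    expect_equal(mc$frozen_left, c(FALSE, TRUE))
    b <- expandBacs(b)
    co <- coords0(bacExpanded(b))
    expect_equal(unname(co[1, "end"]), 100000)      # frozen end immobile
    expect_equal(unname(co[2, "start"]), 80000)
    expect_equal(unname(co[2, "end"] - co[2, "start"]), 165000)
    # disjoint clones are untouched by resolution
    b <- resolveBacOverlaps(mk_bacmap(c(0, 300000), c(100000, 400000)))
    expect_true(all(is.na(bacDuplicateOf(b))))
    expect_false(any(S4Vectors::mcols(bacRaw(b))$frozen_left |
                     S4Vectors::mcols(bacRaw(b))$frozen_right))
})

test_that("extension divides gaps at the midpoint and tiles the covered span", {
    b <- mk_bacmap(c(0, 300000), c(200000, 450000), left = TRUE, right = TRUE)
    b <- extendBacs(expandBacs(b))
    co <- coords0(bacExtended(b))
    expect_equal(unname(co[1, ]), c(0, 250000))
    expect_equal(unname(co[2, ]), c(250000, 450000))
    # odd gap: the extra base goes to the left clone
    b <- mk_bacmap(c(0, 200001), c(200000, 400000), left = TRUE, right = TRUE)
    b <- extendBacs(expandBacs(b))
    co <- coords0(bacExtended(b))
    expect_equal(unname(co[1, "end"]), 200001)
    expect_equal(unname(co[2, "start"]), 200001)
    # zero gap: extension changes nothing
    b <- mk_bacmap(c(0, 200000), c(200000, 400000), left = TRUE, right = TRUE)
    b <- extendBacs(expandBacs(b))
    expect_equal(coords0(bacExtended(b)), coords0(bacExpanded(b)))
    # single clone: array bounds leave it at its expanded span,
    # chromosome bounds stretch it over the whole chromosome
    b <- expandBacs(mk_bacmap(400000, 565000))
    expect_equal(coords0(bacExtended(extendBacs(b))),
                 coords0(bacExpanded(b)))
    bc <- extendBacs(b, bounds = "chromosome", seqlengths = c(chr1 = 1e6))
    expect_equal(unname(coords0(bacExtended(bc))[1, ]), c(0, 1e6))
})

test_that("coordinate invariants hold on randomized clone layouts", {
    for (seed in 1:5) {
        cfg <- simulationConfig(seed = seed, n_bacs = 25L,
                                n_contained = 2L, n_partial_overlap = 2L)
        toy <- makeGenomeAndBacs(cfg)
        bm <- extendBacs(expandBacs(resolveBacOverlaps(toy$bacs)))
        raw <- bacRaw(bm); exp_ <- bacExpanded(bm); ext <- bacExtended(bm)
        mc <- S4Vectors::mcols(raw)
        live <- is.na(mc$duplicate_of)
        # expansion monotone, extension contains expansion
        expect_true(all(GenomicRanges::start(exp_)[live] <=
                        GenomicRanges::start(raw)[live]))
        expect_true(all(GenomicRanges::end(exp_)[live] >=
                        GenomicRanges::end(raw)[live]))
        expect_true(all(GenomicRanges::start(ext)[live] <=
                        GenomicRanges::start(exp_)[live]))
        expect_true(all(GenomicRanges::end(ext)[live] >=
                        GenomicRanges::end(exp_)[live]))
        # anchored and frozen ends never move under expansion
        fixL <- live & (mc$left_anchored | mc$frozen_left)
        fixR <- live & (mc$right_anchored | mc$frozen_right)
        expect_equal(GenomicRanges::start(exp_)[fixL],
                     GenomicRanges::start(raw)[fixL])
        expect_equal(GenomicRanges::end(exp_)[fixR],
                     GenomicRanges::end(raw)[fixR])
        # overlap-frozen ends stay put under extension too
        frzL <- live & mc$frozen_left
        frzR <- live & mc$frozen_right
        expect_equal(GenomicRanges::start(ext)[frzL],
                     GenomicRanges::start(raw)[frzL])
        expect_equal(GenomicRanges::end(ext)[frzR],
                     GenomicRanges::end(raw)[frzR])
        # no expansion collision beyond pre-existing raw overlaps
        ov_raw <- GenomicRanges::findOverlaps(raw[live],
                                              drop.self = TRUE,
                                              drop.redundant = TRUE)
        ov_exp <- GenomicRanges::findOverlaps(exp_[live],
                                              drop.self = TRUE,
                                              drop.redundant = TRUE)
        key <- function(h) paste(S4Vectors::queryHits(h),
                                 S4Vectors::subjectHits(h))
        expect_true(all(key(ov_exp) %in% key(ov_raw)))
        # tiling: extended intervals of clones not involved in raw
        # overlaps are disjoint and contiguous over their span
        involved <- unique(c(S4Vectors::queryHits(ov_raw),
                             S4Vectors::subjectHits(ov_raw)))
        clean <- setdiff(seq_len(sum(live)), involved)
        ec <- ext[live][clean]
        ord <- order(GenomicRanges::start(ec))
        gaps <- GenomicRanges::start(ec)[ord][-1] -
                GenomicRanges::end(ec)[ord][-length(ec)] - 1L
        expect_true(all(gaps >= 0L))
        # exclusivity: each gene maps to at most one clone in extended mode
        assign <- associateGeneBac(toy$genes, bm, mode = "extended")
        expect_false(anyDuplicated(assign$gene_id) > 0)
    }
})

test_that("gene-clone association applies the length and overlap rules", {
    genes <- mk_genes(c(10000, 0, 0), c(20000, 300000, 100000),
                      ids = c("inside", "long", "border"))
    # containment (type-1 intersection): accepted
    b <- extendBacs(expandBacs(mk_bacmap(0, 100000, left = TRUE,
                                         right = TRUE)))
    a <- associateGeneBac(genes[1], b, mode = "expanded")
    expect_equal(as.character(a$gene_id), "inside")
    # 300 kb gene vs 90 kb clone: clone < one third of the gene, rejected
    b90 <- extendBacs(expandBacs(mk_bacmap(0, 90000, left = TRUE,
                                           right = TRUE)))
    expect_equal(nrow(associateGeneBac(genes[2], b90, mode = "expanded")), 0L)
    # extended mode: 40% of the gene inside the tile is not enough
    b2 <- extendBacs(expandBacs(mk_bacmap(c(60000, 200001),
                                          c(200000, 400000),
                                          left = TRUE, right = TRUE)))
    a <- associateGeneBac(genes[3], b2, mode = "extended")
    expect_equal(nrow(a), 0L)
    # a gene cut exactly in half at a tile border is assigned exclusively
    b3 <- extendBacs(expandBacs(mk_bacmap(c(0, 50000), c(50000, 200000),
                                          left = TRUE, right = TRUE)))
    gsplit <- mk_genes(40000, 60000, ids = "split")
    a <- associateGeneBac(gsplit, b3, mode = "extended")
    expect_equal(nrow(a), 1L)
    # expanded mode permits multiple associations for the same gene
    wide <- mk_genes(0, 120000, ids = "wide")
    b4 <- extendBacs(expandBacs(mk_bacmap(c(0, 60000), c(60000, 200000),
                                          left = TRUE, right = TRUE)))
    expect_equal(nrow(associateGeneBac(wide, b4, mode = "expanded")), 2L)
})

test_that("segment overlay produces the expected gene-level calls", {
    # one amplified segment covering 3 of 9 genes
    genes <- mk_genes(seq(0, 80000, by = 10000),
                      seq(5000, 85000, by = 10000))
    segs <- mk_segments(0, 25000, "s1", 1L)
    am <- genesInAlteredSegments(segs, genes)
    expect_s4_class(am, "AlterationMatrix")
    expect_equal(unname(calls(am)[, "s1"]),
                 c(1L, 1L, 1L, rep(0L, 6L)))
    # equal amplified and deleted overlap in one sample: called 0
    segs2 <- mk_segments(c(0, 5000), c(5000, 10000), c("s1", "s1"),
                         c(1L, -1L))
    g1 <- mk_genes(2500, 7500, ids = "tie")
    expect_warning(am2 <- genesInAlteredSegments(segs2, g1),
                   "equal amplified and deleted")
    expect_equal(unname(calls(am2)[1, 1]), 0L)
    # a sample with no segments yields an all-zero column
    am3 <- genesInAlteredSegments(segs, genes, samples = c("s1", "s2"))
    expect_equal(unname(calls(am3)[, "s2"]), rep(0L, 9L))
})

test_that("clone-mediated calls match a per-base brute-force overlay", {
    for (seed in c(11, 12)) {
        cfg <- simulationConfig(seed = seed, n_bacs = 8L, genes_per_bac = 2L,
                                n_contained = 1L, n_partial_overlap = 1L,
                                n_samples = 4L)
        toy <- makeGenomeAndBacs(cfg)
        bm <- extendBacs(expandBacs(resolveBacOverlaps(toy$bacs)))
        segs <- makeCnaSegments(cfg, toy$bacs, mean_segments = 2)
        samples <- sprintf("S%03d", seq_len(cfg$n_samples))
        am <- genesInAlteredSegments(segs, toy$genes, bacmap = bm,
                                     mode = "extended", samples = samples)
        # oracle: substitute each gene's tile, then scan base by base
        assign <- associateGeneBac(toy$genes, bm, mode = "extended")
        ext <- bacExtended(bm)
        bi <- match(assign$bac_id, bacIds(bm))
        eff <- data.frame(gene_id = assign$gene_id,
                          start = GenomicRanges::start(ext)[bi],
                          end = GenomicRanges::end(ext)[bi])
        seg_df <- data.frame(start = GenomicRanges::start(segs),
                             end = GenomicRanges::end(segs),
                             sample_id = S4Vectors::mcols(segs)$sample_id,
                             state = S4Vectors::mcols(segs)$state)
        oracle <- brute_overlay(seg_df, eff, samples)
        expect_equal(calls(am)[eff$gene_id, ], oracle)
        # direct-overlay mode agrees with brute force on gene intervals
        am_direct <- genesInAlteredSegments(segs, toy$genes,
                                            samples = samples)
        eff2 <- data.frame(gene_id = S4Vectors::mcols(toy$genes)$gene_id,
                           start = GenomicRanges::start(toy$genes),
                           end = GenomicRanges::end(toy$genes))
        expect_equal(calls(am_direct), brute_overlay(seg_df, eff2, samples))
    }
})

test_that("a gene is called through its clone even past the segment edge", {
    # clone tile [0, 100 kb); deleted segment covers the tile but stops
    # short of the gene's own right edge -> the gene is still called -1
    b <- extendBacs(expandBacs(mk_bacmap(0, 100000, left = TRUE,
                                         right = TRUE)))
    gene <- mk_genes(90000, 99000, ids = "edge")
    seg <- mk_segments(0, 95000, "s1", -1L)
    am <- genesInAlteredSegments(seg, gene, bacmap = b, mode = "extended")
    expect_equal(unname(calls(am)[1, 1]), -1L)
    # without clone mediation the direct overlay still sees the overlap
    am2 <- genesInAlteredSegments(seg, gene)
    expect_equal(unname(calls(am2)[1, 1]), -1L)
})
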