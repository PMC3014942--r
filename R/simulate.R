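#' Simulation settings for synthetic CNA cohorts
#'
#' Bundles every knob of the synthetic-data generators in one validated
#' object. The defaults describe a desk-scale cohort with the structure of
#' an array-CGH breast-cancer study: a 2,000-gene universe, 100 pathways of
#' 2-80 genes, 100 samples with about 5% of genes altered each, planted
#' driver pathways hit in most samples, and exponential survival with a
#' three-fold hazard between pathway-state groups under 20% censoring.
#'
#' @param G gene-universe size.
#' @param n_pathways number of pathways to generate.
#' @param pathway_size_range inclusive range of pathway sizes.
#' @param n_samples cohort size.
#' @param background_rate expected fraction of genes altered per sample.
#' @param background_mode `"genewise"` (independent genes) or `"segment"`
#'   (contiguous runs of altered genes, emulating CGH segment structure).
#' @param segment_length_mean mean run length (genes) in segment mode.
#' @param planted_pathways named numeric vector: excess per-gene hit
#'   probability for each planted driver pathway (names are pathway ids).
#' @param planted_sample_fraction fraction of samples in which a planted
#'   pathway receives its excess hits (drivers strike most, not all,
#'   subjects).
#' @param amp_del_ratio probability an altered gene is amplified rather
#'   than deleted.
#' @param hazard_ratio hazard ratio between stratification groups in the
#'   survival generator.
#' @param baseline_hazard event hazard of the reference group (per unit
#'   follow-up time).
#' @param censor_rate target fraction of censored subjects.
#' @param n_bacs,n_contained,n_partial_overlap,genes_per_bac,chrom
#'   toy-genome layout: clone count, number of fully-contained and
#'   partially-overlapping clone pairs to inject, genes placed per clone,
#'   chromosome name.
#' @param seed integer seed; mandatory, all generators are deterministic
#'   given it.
#' @return a `SimulationConfig` list.
#' @export
simulationConfig <- function(G = 2000L, n_pathways = 100L,
                             pathway_size_range = c(2L, 80L),
                             n_samples = 100L, background_rate = 0.05,
                             background_mode = c("genewise", "segment"),
                             segment_length_mean = 20,
                             planted_pathways = numeric(0),
                             planted_sample_fraction = 0.9,
                             amp_del_ratio = 0.5, hazard_ratio = 3,
                             baseline_hazard = 0.1, censor_rate = 0.2,
                             n_bacs = 30L, n_contained = 1L,
                             n_partial_overlap = 1L, genes_per_bac = 2L,
                             chrom = "chr1", seed) {
    if (missing(seed)) stop("a seed is mandatory for reproducibility")
    background_mode <- match.arg(background_mode)
    cfg <- list(G = as.integer(G), n_pathways = as.integer(n_pathways),
                pathway_size_range = as.integer(pathway_size_range),
                n_samples = as.integer(n_samples),
                background_rate = background_rate,
                background_mode = background_mode,
                segment_length_mean = segment_length_mean,
                planted_pathways = planted_pathways,
                planted_sample_fraction = planted_sample_fraction,
                amp_del_ratio = amp_del_ratio,
                hazard_ratio = hazard_ratio,
                baseline_hazard = baseline_hazard,
                censor_rate = censor_rate,
                n_bacs = as.integer(n_bacs),
                n_contained = as.integer(n_contained),
                n_partial_overlap = as.integer(n_partial_overlap),
                genes_per_bac = as.integer(genes_per_bac),
                chrom = chrom, seed = as.integer(seed))
    rates <- c(cfg$background_rate, cfg$planted_sample_fraction,
               cfg$amp_del_ratio, cfg$censor_rate, cfg$planted_pathways)
    if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
    if (cfg$pathway_size_range[1L] < 1L ||
        cfg$pathway_size_range[2L] > cfg$G)
        stop("pathway sizes must lie in [1, G]")
    class(cfg) <- "SimulationConfig"
    cfg
}

# run code under a derived seed without disturbing the caller's RNG stream
.with_seed <- function(seed, code) {
    old <- if (exists(".Random.seed", .GlobalEnv))
        get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
            else if (exists(".Random.seed", .GlobalEnv))
                rm(".Random.seed", envir = .GlobalEnv))
    set.seed(seed)
    force(code)
}

.gene_universe <- function(G) sprintf("g%05d", seq_len(G))

#' Generate a synthetic pathway collection
#'
#' Pathway sizes are drawn uniformly from the configured range and member
#' genes sampled without replacement per pathway from the universe, so
#' pathways overlap in gene content as curated collections do.
#'
#' @param config a [simulationConfig()].
#' @return a [PathwayCollection-class] with ids `PW001`, `PW002`, ...
#' @export
makePathways <- function(config) {
    .with_seed(config$seed + 101L, {
        uni <- .gene_universe(config$G)
        sz <- sample(seq(config$pathway_size_range[1L],
                         config$pathway_size_range[2L]),
                     config$n_pathways, replace = TRUE)
        sets <- lapply(sz, function(s) sample(uni, s))
        names(sets) <- sprintf("PW%03d", seq_along(sets))
        PathwayCollection(sets)
    })
}

.background_hits <- function(config) {
    G <- config$G; ns <- config$n_samples
    if (config$background_mode == "genewise") {
        matrix(stats::rbinom(G * ns, 1L, config$background_rate), G, ns)
    } else {
        H <- matrix(0L, G, ns)
        lm <- config$segment_length_mean
        n_seg <- stats::rpois(ns, G * config$background_rate / lm)
        for (j in seq_len(ns)) {
            if (n_seg[j] == 0L) next
            st <- sample.int(G, n_seg[j], replace = TRUE)
            len <- 1L + stats::rgeom(n_seg[j], 1 / lm)
            for (s in seq_len(n_seg[j]))
                H[st[s]:min(G, st[s] + len[s] - 1L), j] <- 1L
        }
        H
    }
}

#' Generate a synthetic CNA cohort with planted driver pathways
#'
#' Background alterations are drawn at `background_rate` over the whole
#' universe (gene-wise independent, or in contiguous segments). Each
#' planted pathway then receives excess hits — every member gene altered
#' with its configured excess probability — in a random subset of samples,
#' so different subjects target the driver pathway through different
#' member genes while the pathway as a unit is hit across most of the
#' cohort. Altered genes are amplified with probability `amp_del_ratio`,
#' deleted otherwise.
#'
#' @param config a [simulationConfig()].
#' @param pathways the [PathwayCollection-class] the planted ids refer to;
#'   defaults to [makePathways()] under the same config.
#' @return list with `matrix` (an [AlterationMatrix-class]), `pathways`,
#'   and `planted_samples` (named list: which samples carry each planted
#'   pathway's excess hits).
#' @export
makeCnaCohort <- function(config, pathways = makePathways(config)) {
    planted <- config$planted_pathways
    if (length(planted) &&
        !all(names(planted) %in% pathwayIds(pathways)))
        stop("planted pathways must be among the generated pathways")
    if (length(planted) && any(planted <= config$background_rate))
        warning("planted excess at or below the background rate ",
                "is unlikely to be detectable")
    .with_seed(config$seed + 202L, {
        uni <- .gene_universe(config$G)
        ns <- config$n_samples
        H <- .background_hits(config)
        planted_samples <- list()
        for (pw in names(planted)) {
            gi <- match(pathways[[pw]], uni)
            n_hit <- max(1L, round(config$planted_sample_fraction * ns))
            sj <- sort(sample.int(ns, n_hit))
            planted_samples[[pw]] <- sj
            extra <- matrix(stats::rbinom(length(gi) * n_hit, 1L,
                                          planted[[pw]]),
                            length(gi), n_hit)
            H[gi, sj] <- pmax(H[gi, sj], extra)
        }
        sign <- matrix(ifelse(stats::rbinom(length(H), 1L,
                                            config$amp_del_ratio) == 1L,
                              1L, -1L), nrow(H), ncol(H))
        m <- H * sign
        dimnames(m) <- list(uni, sprintf("S%03d", seq_len(ns)))
        planted_samples <- lapply(planted_samples,
                                  function(j) colnames(m)[j])
        list(matrix = AlterationMatrix(m), pathways = pathways,
             planted_samples = planted_samples)
    })
}

#' Generate a toy genome: gene and BAC clone coordinates
#'
#' Lays BAC clones along one chromosome at irregular spacing with mixed
#' end-sequence anchoring, injects the configured number of fully
#' contained and partially overlapping clone pairs (the pathologies the
#' coordinate-reconciliation code must handle), and places genes inside
#' the central half of each clone's raw span so that every non-duplicate
#' clone tile captures at least one gene.
#'
#' @param config a [simulationConfig()].
#' @return list with `genes` (a `GRanges` with `gene_id`) and `bacs` (a
#'   [BacMap-class], raw coordinates only).
#' @export
makeGenomeAndBacs <- function(config) {
    .with_seed(config$seed + 303L, {
        n <- config$n_bacs
        gap <- round(stats::runif(n, 1.5e5, 2.5e5))
        w <- round(stats::runif(n, 3e4, 1.5e5))
        st <- cumsum(gap) + c(0, cumsum(w))[seq_len(n)]
        en <- st + w - 1L
        anch <- sample(c("both", "left", "right", "none"), n,
                       replace = TRUE, prob = c(.2, .15, .15, .5))
        la <- anch %in% c("both", "left")
        ra <- anch %in% c("both", "right")
        # contained pairs: a small clone dropped inside a host clone
        for (i in seq_len(config$n_contained)) {
            host <- sample.int(n, 1L)
            cw <- max(1e4, round(w[host] / 3))
            cs <- st[host] + round((w[host] - cw) / 2)
            st <- c(st, cs); en <- c(en, cs + cw - 1L)
            la <- c(la, FALSE); ra <- c(ra, FALSE)
        }
        # partial-overlap pairs: a clone straddling a host's right end
        for (i in seq_len(config$n_partial_overlap)) {
            host <- sample.int(n, 1L)
            ow <- round(stats::runif(1, 5e4, 1e5))
            os <- en[host] - round(ow / 3)
            st <- c(st, os); en <- c(en, os + ow - 1L)
            la <- c(la, FALSE); ra <- c(ra, FALSE)
        }
        gr <- GenomicRanges::GRanges(config$chrom,
            IRanges::IRanges(as.integer(st), as.integer(en)),
            bac_id = sprintf("BAC%03d", seq_along(st)),
            left_anchored = la, right_anchored = ra)
        bm <- BacMap(gr)
        # genes: central half of each clone's raw span
        gs <- ge <- integer(0)
        for (i in seq_along(st)) {
            wi <- en[i] - st[i] + 1L
            lo <- st[i] + round(wi / 4)
            hi <- en[i] - round(wi / 4)
            k <- config$genes_per_bac
            gst <- sort(round(stats::runif(k, lo, hi - 5000)))
            gs <- c(gs, gst); ge <- c(ge, gst + 4999L)
        }
        genes <- GenomicRanges::GRanges(config$chrom,
            IRanges::IRanges(as.integer(gs), as.integer(ge)),
            gene_id = sprintf("gene%04d", seq_along(gs)))
        list(genes = genes, bacs = bm)
    })
}

#' Generate per-sample altered segments over a toy genome
#'
#' Each sample receives a Poisson number of altered segments; a segment
#' covers a contiguous run of clones (geometric run length), mirroring how
#' array CGH reports copy number in clone-resolution blocks.
#'
#' @param config a [simulationConfig()].
#' @param bacmap a [BacMap-class] (raw coordinates suffice).
#' @param mean_segments expected altered segments per sample.
#' @param mean_run mean clone-run length per segment.
#' @return `GRanges` with metadata `sample_id`, `state`.
#' @export
makeCnaSegments <- function(config, bacmap, mean_segments = 3,
                            mean_run = 3) {
    .with_seed(config$seed + 404L, {
        r <- bacRaw(bacmap)
        ord <- order(GenomicRanges::start(r))
        st <- GenomicRanges::start(r)[ord]
        en <- GenomicRanges::end(r)[ord]
        n <- length(st)
        out <- list()
        for (j in seq_len(config$n_samples)) {
            k <- stats::rpois(1L, mean_segments)
            if (k == 0L) next
            from <- sample.int(n, k, replace = TRUE)
            run <- 1L + stats::rgeom(k, 1 / mean_run)
            to <- pmin(n, from + run - 1L)
            state <- ifelse(stats::rbinom(k, 1L, config$amp_del_ratio) == 1L,
                            1L, -1L)
            out[[length(out) + 1L]] <- GenomicRanges::GRanges(
                config$chrom, IRanges::IRanges(st[from], en[to]),
                sample_id = sprintf("S%03d", j), state = state)
        }
        if (!length(out))
            return(GenomicRanges::GRanges(sample_id = character(),
                                          state = integer()))
        unlist(GenomicRanges::GRangesList(out))
    })
}

#' Generate synthetic survival data for a stratified cohort
#'
#' Event times are exponential with the configured hazard ratio between
#' groups; censoring is independent exponential calibrated to the target
#' censoring fraction in the reference group. `censor_rate = 1` censors
#' every subject.
#'
#' @param group binary labels (0 = reference, 1 = elevated hazard), named
#'   by sample.
#' @param config a [simulationConfig()].
#' @return data frame with `sample_id`, `time`, `event`, `group`.
#' @export
makeSurvival <- function(group, config) {
    .with_seed(config$seed + 505L, {
        n <- length(group)
        ids <- if (!is.null(names(group))) names(group)
               else sprintf("S%03d", seq_len(n))
        lam <- config$baseline_hazard * config$hazard_ratio^as.integer(group)
        t_event <- stats::rexp(n, lam)
        if (config$censor_rate >= 1) {
            time <- stats::rexp(n, config$baseline_hazard)
            event <- rep(0L, n)
        } else if (config$censor_rate <= 0) {
            time <- t_event
            event <- rep(1L, n)
        } else {
            cr <- config$censor_rate
            lam_c <- config$baseline_hazard * cr / (1 - cr)
            t_cens <- stats::rexp(n, lam_c)
            time <- pmin(t_event, t_cens)
            event <- as.integer(t_event <= t_cens)
        }
        data.frame(sample_id = ids, time = time, event = event,
                   group = as.integer(group), stringsAsFactors = FALSE)
    })
}
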