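#' Assemble a pipeline run configuration
#'
#' Collects every analytic choice and input path of the end-to-end
#' pipeline in one serializable list. With no input paths the pipeline
#' simulates its own fixture cohort (toy genome, clones, segments,
#' pathways, survival) from `seed`. Every default matches the
#' corresponding function default, so a config echoed to the provenance
#' log fully determines the run.
#'
#' @param outdir output directory (created if missing).
#' @param seed integer seed for the simulated flow.
#' @param bacs,genes,segments,matrix,gmt,scores,survival optional input
#'   file paths; `matrix` takes precedence over the segment flow.
#' @param mode coordinate set for clone-mediated gene assignment.
#' @param alpha,tail,df_mode,hit_definition,stratify_method analytic
#'   choices passed through to [scoreAllPathways()] and
#'   [survivalScreen()].
#' @param run_survival set `FALSE` to stop after the targeting report.
#' @param sim a [simulationConfig()] for the simulated flow; defaults to
#'   `simulationConfig(seed = seed)` with one planted driver pathway.
#' @return a `RunConfig` list.
#' @export
runConfig <- function(outdir, seed = 1L, bacs = NULL, genes = NULL,
                      segments = NULL, matrix = NULL, gmt = NULL,
                      scores = NULL, survival = NULL,
                      mode = "extended", alpha = 0.05,
                      tail = "inclusive", df_mode = "two_per_sample",
                      hit_definition = "any_alteration",
                      stratify_method = "two_means",
                      run_survival = TRUE, sim = NULL) {
    cfg <- list(outdir = outdir, seed = as.integer(seed), bacs = bacs,
                genes = genes, segments = segments, matrix = matrix,
                gmt = gmt, scores = scores, survival = survival,
                mode = mode, alpha = alpha, tail = tail,
                df_mode = df_mode, hit_definition = hit_definition,
                stratify_method = stratify_method,
                run_survival = isTRUE(run_survival), sim = sim)
    class(cfg) <- "RunConfig"
    cfg
}

#' @rdname runConfig
#' @param path YAML file with `runConfig()` fields.
#' @export
readRunConfig <- function(path) {
    y <- yaml::read_yaml(path)
    do.call(runConfig, y)
}

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop(sprintf("pipeline stage '%s' failed: %s", name,
                     conditionMessage(e)), call. = FALSE))
}

#' Run the full pathway-targeting pipeline
#'
#' Executes segment-to-gene coordinate mapping, pathway targeting
#' scoring, and (optionally) the survival screen as configured, writing
#' all reports plus a provenance log to the output directory. With no
#' input paths a fixture cohort is simulated from the seed; reruns with
#' the same config are byte-identical. Any stage failure aborts with the
#' stage name.
#'
#' @param config a [runConfig()].
#' @return (invisibly) a list with the in-memory results and the paths
#'   written.
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "RunConfig"))
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    out <- function(f) file.path(config$outdir, f)
    paths <- character(0)
    simulated <- is.null(config$matrix) && is.null(config$segments)

    sim <- config$sim
    planted_group <- NULL
    if (simulated) {
        if (is.null(sim)) {
            sim <- simulationConfig(seed = config$seed, n_bacs = 40L,
                                    genes_per_bac = 3L, n_pathways = 20L,
                                    pathway_size_range = c(2L, 20L),
                                    n_samples = 60L)
        }
        fx <- .stage("simulate", {
            toy <- makeGenomeAndBacs(sim)
            segs <- makeCnaSegments(sim, toy$bacs)
            writeGenesBed(toy$genes, out("genes.bed"))
            writeBacsBed(toy$bacs, out("bacs.bed"))
            writeSegmentsBed(segs, out("segments.bed"))
            toy$segs <- segs
            toy
        })
        paths <- c(paths, out(c("genes.bed", "bacs.bed", "segments.bed")))
        genes <- fx$genes
        bacmap <- fx$bacs
        segments <- fx$segs
    } else if (!is.null(config$segments)) {
        genes <- .stage("read-inputs", readGenesBed(config$genes))
        bacmap <- if (!is.null(config$bacs))
            .stage("read-inputs", readBacsBed(config$bacs)) else NULL
        segments <- .stage("read-inputs", readSegmentsBed(config$segments))
    }

    if (!is.null(config$matrix)) {
        am <- .stage("read-inputs", readAlterationMatrix(config$matrix))
    } else {
        am <- .stage("map-coords", {
            bm <- if (!is.null(bacmap))
                extendBacs(expandBacs(resolveBacOverlaps(bacmap)))
            else NULL
            samples <- sprintf("S%03d", seq_len(
                if (simulated) sim$n_samples
                else length(unique(mcols(segments)$sample_id))))
            if (!simulated)
                samples <- sort(unique(mcols(segments)$sample_id))
            genesInAlteredSegments(segments, genes, bacmap = bm,
                                   mode = config$mode, samples = samples)
        })
        writeAlterationMatrix(am, out("matrix.tsv"))
        paths <- c(paths, out("matrix.tsv"))
    }

    pathways <- .stage("pathways", {
        if (!is.null(config$gmt)) readGmt(config$gmt)
        else {
            # fixture pathways over the toy genes
            .with_seed(sim$seed + 606L, {
                ids <- geneIds(am)
                sz <- sample(seq(sim$pathway_size_range[1L],
                                 min(sim$pathway_size_range[2L],
                                     length(ids))),
                             sim$n_pathways, replace = TRUE)
                sets <- lapply(sz, function(s) sample(ids, s))
                names(sets) <- sprintf("PW%03d", seq_along(sets))
                PathwayCollection(sets)
            })
        }
    })
    if (is.null(config$gmt)) {
        writeGmt(pathways, out("pathways.gmt"))
        paths <- c(paths, out("pathways.gmt"))
    }

    res <- .stage("score", suppressWarnings(
        scoreAllPathways(am, pathways,
                         hit_definition = config$hit_definition,
                         tail = config$tail, df_mode = config$df_mode,
                         alpha = config$alpha)))
    writeTargetingReport(res, out("targeting_report.tsv"),
                         per_sample_path = out("targeting_per_sample.tsv"))
    paths <- c(paths, out(c("targeting_report.tsv",
                            "targeting_per_sample.tsv")))

    surv_res <- NULL
    if (config$run_survival) {
        surv_res <- .stage("survival", {
            if (!is.null(config$scores)) {
                sc <- readScoreMatrix(config$scores)
                cl <- readSurvival(config$survival)
            } else {
                # fixture flow: pathway alteration burden as the score;
                # survival driven by the top pathway's alteration status
                sc <- sweep(res@k, 1L,
                            pmax(1L, resultsTable(res)$n_genes), "/")
                top <- resultsTable(res)$pathway_id[
                    which.min(resultsTable(res)$p_population)]
                planted_group <- as.integer(res@k[top, ] > 0)
                names(planted_group) <- colnames(res@k)
                cl <- makeSurvival(planted_group, sim)
                utils::write.table(cl, out("survival_input.tsv"),
                                   sep = "\t", quote = FALSE,
                                   row.names = FALSE)
                paths <- c(paths, out("survival_input.tsv"))
            }
            time <- stats::setNames(cl$time, cl$sample_id)
            event <- stats::setNames(cl$event, cl$sample_id)
            survivalScreen(sc, time, event, alpha = config$alpha,
                           method = config$stratify_method,
                           seed = config$seed)
        })
        sv <- surv_res
        for (cc in c("chisq", "p", "p_adjusted"))
            sv[[cc]] <- .fmt_num(sv[[cc]])
        utils::write.table(sv, out("survival_report.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        paths <- c(paths, out("survival_report.tsv"))
    }

    prov <- list(
        package = "cnapath",
        version = as.character(utils::packageVersion("cnapath")),
        r_version = paste(R.version$major, R.version$minor, sep = "."),
        seed = config$seed,
        config = config[!vapply(config, is.null, logical(1)) &
                        names(config) != "sim"],
        outputs = basename(paths))
    jsonlite::write_json(prov, out("provenance.json"), auto_unbox = TRUE,
                         pretty = TRUE)
    paths <- c(paths, out("provenance.json"))

    invisible(list(matrix = am, pathways = pathways, targeting = res,
                   survival = surv_res, paths = paths))
}
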