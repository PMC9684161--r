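#' Pipeline configuration
#'
#' All workflow thresholds in one validated list. Defaults are the
#' workflow constants of the SGB construction: k = 21 and sketch size
#' 10000 for MinHash sketching, average-linkage pre-clustering at genetic
#' distance 0.05, fragment-ANI refinement of representative pairs within
#' Mash distance 0.10, the 95% ANI species boundary with aligned coverage
#' above 0.3, 1020-bp ANIb fragments, 1500-bp minimum contigs, and the
#' MIMAG medium-quality gate (completeness > 50, contamination < 10).
#'
#' @param seed Integer seed for any stochastic stage.
#' @param k,sketch_size MinHash parameters.
#' @param precluster_cutoff Average-linkage cut height.
#' @param candidate_cutoff Mash distance below which representative pairs
#'   are re-evaluated with fragment ANI.
#' @param ani_cutoff Species ANI boundary (percent).
#' @param coverage_cutoff Aligned-coverage gate (fraction).
#' @param fragment_length ANIb fragment length (bp).
#' @param min_contig Minimum contig length (bp).
#' @param min_completeness,max_contamination MAG quality gate (percent).
#' @return A named list of class `sgb_config`.
#' @export
sgbConfig <- function(seed = 1L, k = 21L, sketch_size = 10000L,
                      precluster_cutoff = 0.05, candidate_cutoff = 0.10,
                      ani_cutoff = 95, coverage_cutoff = 0.3,
                      fragment_length = 1020L, min_contig = 1500L,
                      min_completeness = 50, max_contamination = 10) {
    cfg <- list(seed = as.integer(seed), k = as.integer(k),
                sketch_size = as.integer(sketch_size),
                precluster_cutoff = precluster_cutoff,
                candidate_cutoff = candidate_cutoff,
                ani_cutoff = ani_cutoff, coverage_cutoff = coverage_cutoff,
                fragment_length = as.integer(fragment_length),
                min_contig = as.integer(min_contig),
                min_completeness = min_completeness,
                max_contamination = max_contamination)
    stopifnot(cfg$k >= 1, cfg$k %% 2 == 1, cfg$sketch_size >= 1,
              cfg$precluster_cutoff >= 0, cfg$precluster_cutoff <= 1,
              cfg$candidate_cutoff >= 0, cfg$candidate_cutoff <= 1,
              cfg$ani_cutoff > 0, cfg$ani_cutoff <= 100,
              cfg$coverage_cutoff >= 0, cfg$coverage_cutoff <= 1,
              cfg$fragment_length > 0, cfg$min_contig > 0,
              cfg$min_completeness >= 0, cfg$min_completeness <= 100,
              cfg$max_contamination >= 0)
    class(cfg) <- c("sgb_config", "list")
    cfg
}

#' Run the SGB construction pipeline end to end
#'
#' Stages, in order: MAG quality gating (reference genomes bypass the
#' gate; MAGs must pass the medium-quality standard), MinHash sketching,
#' Mash distance matrix, average-linkage pre-clustering, representative
#' selection, fragment-ANI refinement, complete-linkage merging, catalog
#' assembly, and (when a depth table is supplied) abundance profiling.
#' Stage outputs are written as plain files to `outDir` so any stage can
#' be inspected or re-entered; per-stage counts go to `run.log`.
#' Re-running with the same inputs and config is byte-identical apart
#' from timestamps.
#'
#' @param genomes A [GenomeSet-class] (MAGs plus reference genomes, with
#'   quality metrics in `genomeData`).
#' @param outDir Output directory (created if needed).
#' @param config An [sgbConfig()].
#' @param depths Optional per-contig depth table for profiling.
#' @param contigToGenome Optional named map contig id -> genome id
#'   (defaults to the `"<genome>|<i>"` naming convention).
#' @return Invisibly, a list with `catalog`, `partition`, `profiles`
#'   (or `NULL`), `quality`, and the path of every file written.
#' @export
runPipeline <- function(genomes, outDir, config = sgbConfig(),
                        depths = NULL, contigToGenome = NULL) {
    stopifnot(is(genomes, "GenomeSet"))
    if (length(genomes) == 0L) stop("empty input: no genomes to process")
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    logFile <- file.path(outDir, "run.log")
    logLine <- function(...) {
        msg <- paste0(...)
        message(msg)
        cat(msg, "\n", file = logFile, append = TRUE, sep = "")
    }
    cat("", file = logFile)
    yaml::write_yaml(unclass(config), file.path(outDir, "config.yaml"))

    ## stage 1: quality gate (MAGs only; references bypass)
    gd <- as.data.frame(genomeData(genomes))
    rownames(gd) <- gd$genome_id
    if (any(is.na(gd$completeness[!gd$is_reference])))
        stop("quality stage: missing completeness for MAG(s) ",
             paste(gd$genome_id[!gd$is_reference & is.na(gd$completeness)],
                   collapse = ", "))
    gd$tier <- NA_character_
    mags <- !gd$is_reference
    gd$tier[mags] <- classifyQuality(gd$completeness[mags], gd$contamination[mags])
    keep <- gd$genome_id[!mags | (gd$completeness > config$min_completeness &
                                  gd$contamination < config$max_contamination)]
    utils::write.table(gd[, c("genome_id", "completeness", "contamination",
                              "strain_heterogeneity", "tier")],
                       file.path(outDir, "quality_tiers.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    logLine("quality: ", sum(mags), " MAGs assessed, ",
            length(keep), "/", nrow(gd), " genomes pass into clustering")
    if (!length(keep)) stop("quality stage: no genomes pass the gate")
    gs <- genomes[keep]

    ## stages 2-7: sketch .. catalog
    res <- buildCatalog(gs, config)
    writeSketches(sketchGenomes(gs, k = config$k, s = config$sketch_size),
                  file.path(outDir, "sketches.json"))
    pre <- data.frame(genome_id = names(res$preclusters),
                      precluster = as.integer(res$preclusters),
                      sgb_cluster = as.integer(res$partition[names(res$preclusters)]))
    utils::write.table(pre, file.path(outDir, "preclusters.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(res$aniPairs, file.path(outDir, "ani_pairs.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    writeCatalog(res$catalog, file.path(outDir, "catalog.tsv"))
    logLine("precluster: ", length(unique(res$preclusters)),
            " clusters at mash distance <= ", config$precluster_cutoff)
    logLine("ani: ", nrow(res$aniPairs), " candidate representative pairs")
    logLine("catalog: ", length(sgbIds(res$catalog)), " SGBs (",
            sum(sgbData(res$catalog)$kind == "kSGB"), " kSGB / ",
            sum(sgbData(res$catalog)$kind == "uSGB"), " uSGB)")

    ## stage 8: profiling (optional)
    profiles <- NULL
    if (!is.null(depths)) {
        if (is.null(contigToGenome)) {
            cids <- unique(depths$contig_id)
            contigToGenome <- stats::setNames(sub("\\|[^|]*$", "", cids), cids)
        }
        repIds <- representativeIds(res$catalog)
        repContigs <- names(contigToGenome)[contigToGenome %in% repIds]
        depths <- depths[depths$contig_id %in% repContigs, , drop = FALSE]
        profiles <- profileSamples(depths, res$catalog,
                                   contigToGenome[repContigs])
        utils::write.table(
            data.frame(sample_id = rownames(profiles), profiles,
                       check.names = FALSE),
            file.path(outDir, "profiles.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
        logLine("profile: ", nrow(profiles), " samples x ",
                ncol(profiles), " SGBs")
    }
    invisible(list(catalog = res$catalog, partition = res$partition,
                   profiles = profiles, quality = gd,
                   files = list.files(outDir, full.names = TRUE)))
}
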