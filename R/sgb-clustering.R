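#' @importFrom stats hclust as.dist
NULL

## validate a symmetric distance matrix in [0, maxVal] with zero diagonal
.checkDistMatrix <- function(d, maxVal = 1) {
    if (!is.matrix(d) || nrow(d) != ncol(d))
        stop("distance matrix must be square")
    if (is.null(rownames(d)) || !identical(rownames(d), colnames(d)))
        stop("distance matrix needs matching row/column names")
    if (any(d < 0 | d > maxVal)) stop("distances must be in [0, ", maxVal, "]")
    if (any(abs(d - t(d)) > 1e-9)) stop("distance matrix is not symmetric")
    if (any(abs(diag(d)) > 1e-12)) stop("distance matrix diagonal must be 0")
    invisible(TRUE)
}

## cut an hclust dendrogram so that merges happen only at heights <= h
## (strict = TRUE: strictly below h). Average/complete linkage heights are
## monotone, so applying merges in order until the threshold is exact.
.cutAtHeight <- function(hc, h, strict = FALSE) {
    n <- length(hc$labels)
    comp <- seq_len(n)
    find <- function(i) {
        while (comp[i] != i) { comp[i] <- comp[comp[i]]; i <- comp[i] }
        i
    }
    rowRep <- integer(max(1L, nrow(hc$merge)))
    for (i in seq_len(nrow(hc$merge))) {
        a <- hc$merge[i, 1]; b <- hc$merge[i, 2]
        ra <- if (a < 0) find(-a) else find(rowRep[a])
        rb <- if (b < 0) find(-b) else find(rowRep[b])
        ok <- if (strict) hc$height[i] < h - 1e-12 else hc$height[i] <= h + 1e-12
        if (ok) comp[rb] <- ra
        rowRep[i] <- ra
    }
    memb <- vapply(seq_len(n), find, integer(1))
    cl <- match(memb, unique(memb))
    stats::setNames(cl, hc$labels)
}

#' Average-linkage pre-clustering of a Mash distance matrix
#'
#' Agglomerative UPGMA (average linkage) on the all-versus-all genetic
#' distance matrix, cut so that merges occur only at heights at or below
#' `cutoff` (a pair at exactly the cutoff distance merges). This is the
#' fast first stage of the two-step SGB clustering.
#'
#' @param d Symmetric distance matrix in \[0, 1\] with zero diagonal and
#'   genome ids as dimnames.
#' @param cutoff Genetic distance cutoff (default 0.05).
#' @return Named integer vector: cluster membership per genome id.
#' @export
precluster <- function(d, cutoff = 0.05) {
    .checkDistMatrix(d, maxVal = 1)
    if (nrow(d) == 1L) return(stats::setNames(1L, rownames(d)))
    hc <- hclust(as.dist(d), method = "average")
    .cutAtHeight(hc, cutoff, strict = FALSE)
}

#' kSGB / uSGB labeling
#'
#' An SGB is "known" (kSGB) iff it contains at least one reference genome;
#' clusters consisting only of MAGs are "unknown" (uSGB).
#'
#' @param members Character vector of member genome ids.
#' @param referenceIds Character vector of reference genome ids.
#' @return `"kSGB"` or `"uSGB"`.
#' @export
labelKind <- function(members, referenceIds) {
    if (length(intersect(members, referenceIds))) "kSGB" else "uSGB"
}

## competition ranking: equal values share the smallest rank
.competitionRank <- function(x, decreasing = FALSE) {
    if (decreasing) x <- -x
    rank(x, ties.method = "min")
}

#' Select the representative genome of an SGB
#'
#' kSGBs take the member with the largest genome size. uSGBs rank all
#' members by completeness (descending), contamination (ascending),
#' coverage (mean sequencing depth, descending), strain heterogeneity
#' (ascending) and N50 (descending) — competition ranking within each
#' criterion — and take the member minimizing the sum of the five ranks.
#' Ties in genome size or rank sum break lexicographically by genome id
#' so the choice is deterministic.
#'
#' @param members Character vector of member genome ids.
#' @param kind `"kSGB"` or `"uSGB"`.
#' @param metrics data.frame (or DataFrame) indexed by genome id with
#'   columns `completeness`, `contamination`, `mean_depth`,
#'   `strain_heterogeneity`, `n50` (uSGB rule) and `genome_length` (kSGB
#'   rule).
#' @return The representative genome id.
#' @examples
#' m <- data.frame(
#'   completeness = c(95, 90, 99), contamination = c(1, 0.5, 4),
#'   mean_depth = c(30, 50, 10), strain_heterogeneity = c(5, 2, 10),
#'   n50 = c(5e4, 4e4, 6e4), row.names = c("A", "B", "C"))
#' selectRepresentative(c("A", "B", "C"), "uSGB", m)  # "B"
#' @export
selectRepresentative <- function(members, kind, metrics) {
    stopifnot(length(members) >= 1L)
    members <- sort(members)
    if (length(members) == 1L) return(members)
    metrics <- as.data.frame(metrics)
    if (!all(members %in% rownames(metrics)))
        stop("metrics missing for member(s): ",
             paste(setdiff(members, rownames(metrics)), collapse = ", "))
    m <- metrics[members, , drop = FALSE]
    if (kind == "kSGB") {
        if (any(is.na(m$genome_length))) stop("genome_length required for kSGB rule")
        return(members[which.max(m$genome_length)])
    }
    need <- c("completeness", "contamination", "mean_depth",
              "strain_heterogeneity", "n50")
    if (any(is.na(as.matrix(m[, need]))))
        stop("missing quality metric for uSGB member(s)")
    rankSum <- .competitionRank(m$completeness, decreasing = TRUE) +
        .competitionRank(m$contamination) +
        .competitionRank(m$mean_depth, decreasing = TRUE) +
        .competitionRank(m$strain_heterogeneity) +
        .competitionRank(m$n50, decreasing = TRUE)
    members[which.min(rankSum)]
}

#' Representative pairs to re-evaluate with fragment ANI
#'
#' All unordered pairs of representatives whose Mash distance is at or
#' below `candidateCutoff`; only these pairs get the (expensive) fragment
#' ANI recomputation.
#'
#' @param representatives Character vector of representative genome ids.
#' @param d Mash distance matrix covering the representatives.
#' @param candidateCutoff Candidate distance cutoff (default 0.10).
#' @return data.frame with columns `id1`, `id2`, `mash_distance`.
#' @export
refinementPairs <- function(representatives, d, candidateCutoff = 0.10) {
    representatives <- sort(unique(representatives))
    if (!all(representatives %in% rownames(d)))
        stop("distance matrix does not cover all representatives")
    out <- list()
    n <- length(representatives)
    if (n >= 2) {
        for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
            dij <- d[representatives[i], representatives[j]]
            if (dij <= candidateCutoff)
                out[[length(out) + 1L]] <- data.frame(
                    id1 = representatives[i], id2 = representatives[j],
                    mash_distance = dij)
        }
    }
    if (!length(out))
        return(data.frame(id1 = character(0), id2 = character(0),
                          mash_distance = numeric(0)))
    do.call(rbind, out)
}

#' Merge pre-clusters by complete-linkage ANI clustering
#'
#' Symmetrized pair ANIs failing the coverage gate (coverage must be
#' strictly above `coverageCutoff`) or undefined are discarded — their
#' distance is treated as maximal. The representatives are then clustered
#' by complete linkage on the distance `100 - ani`, cut strictly below
#' `100 - aniCutoff` (the species rule is ANI strictly greater than the
#' cutoff), and pre-clusters whose representatives co-cluster are unioned
#' whole.
#'
#' @param partition Named integer vector (genome id -> pre-cluster).
#' @param representatives Named character vector (pre-cluster id as name ->
#'   representative genome id), e.g. from [clusterRepresentatives()].
#' @param pairAni data.frame of symmetrized results (`id1`, `id2`, `ani`,
#'   `coverage`, `defined`), e.g. from [aniPairs()].
#' @param aniCutoff Species ANI boundary in percent (default 95).
#' @param coverageCutoff Aligned-coverage gate (default 0.3).
#' @return Named integer vector: the merged partition.
#' @export
mergeByAni <- function(partition, representatives, pairAni,
                       aniCutoff = 95, coverageCutoff = 0.3) {
    reps <- representatives
    if (is.null(names(reps))) stop("representatives must be named by cluster")
    if (!all(reps %in% names(partition)))
        stop("representatives absent from the partition")
    n <- length(reps)
    if (n < 2L || !nrow(pairAni)) return(.relabel(partition))
    MAXD <- 1000
    dm <- matrix(MAXD, n, n, dimnames = list(reps, reps))
    diag(dm) <- 0
    for (i in seq_len(nrow(pairAni))) {
        a <- pairAni$id1[i]; b <- pairAni$id2[i]
        if (!(a %in% reps && b %in% reps)) next
        if (isTRUE(pairAni$defined[i]) && pairAni$coverage[i] > coverageCutoff) {
            dm[a, b] <- dm[b, a] <- 100 - pairAni$ani[i]
        }
    }
    hc <- hclust(as.dist(dm), method = "complete")
    grp <- .cutAtHeight(hc, 100 - aniCutoff, strict = TRUE)
    newPart <- partition
    clOf <- stats::setNames(names(reps), reps)   # rep genome -> pre-cluster id
    for (g in unique(grp)) {
        repsIn <- names(grp)[grp == g]
        clusters <- clOf[repsIn]
        target <- min(as.integer(clusters))
        newPart[as.character(partition) %in% clusters] <- target
    }
    .relabel(newPart)
}

.relabel <- function(partition) {
    stats::setNames(match(partition, unique(partition)), names(partition))
}

#' Per-cluster representatives for a partition
#'
#' Applies [labelKind()] and [selectRepresentative()] to every cluster of
#' a partition.
#'
#' @param partition Named integer vector (genome id -> cluster).
#' @param metrics Metrics table indexed by genome id (see
#'   [selectRepresentative()]).
#' @param referenceIds Character vector of reference genome ids.
#' @return Named character vector: cluster id -> representative genome id.
#' @export
clusterRepresentatives <- function(partition, metrics, referenceIds = character(0)) {
    vapply(split(names(partition), partition), function(members) {
        kind <- labelKind(members, referenceIds)
        selectRepresentative(members, kind, metrics)
    }, character(1))
}

#' Assemble the final SGB catalog
#'
#' One [SGBCatalog-class] record per final cluster. The representative is
#' re-selected on the merged membership (kSGB rule if the cluster contains
#' any reference genome, else the rank-sum rule); `oral` is `TRUE` iff the
#' cluster contains an oral reference genome or an oral MAG. SGB ids are
#' assigned in sorted order of representative id, so the labeling is
#' stable.
#'
#' @param partition Named integer vector (genome id -> final cluster).
#' @param genomeData Per-genome annotation (`DataFrame`/data.frame indexed
#'   by genome id) with the flag columns `is_reference`,
#'   `is_oral_reference`, `is_oral_mag` and the metric columns used by
#'   [selectRepresentative()].
#' @return An [SGBCatalog-class].
#' @export
assembleCatalog <- function(partition, genomeData) {
    gd <- as.data.frame(genomeData)
    if (!is.null(gd$genome_id)) rownames(gd) <- gd$genome_id
    if (!all(names(partition) %in% rownames(gd)))
        stop("genomeData does not cover the partition")
    if (anyDuplicated(names(partition)))
        stop("overlapping clusters: a genome appears twice in the partition")
    referenceIds <- rownames(gd)[gd$is_reference %in% TRUE]
    clusters <- split(names(partition), partition)
    recs <- lapply(clusters, function(members) {
        kind <- labelKind(members, referenceIds)
        rep <- selectRepresentative(members, kind, gd)
        oral <- any(gd[members, "is_oral_reference"] %in% TRUE) ||
                any(gd[members, "is_oral_mag"] %in% TRUE)
        list(kind = kind, representative_id = rep, oral = oral,
             members = sort(members))
    })
    ord <- order(vapply(recs, `[[`, character(1), "representative_id"))
    recs <- recs[ord]
    ids <- sprintf("SGB%04d", seq_along(recs))
    sgbData <- DataFrame(
        sgb_id = ids,
        kind = unname(vapply(recs, `[[`, character(1), "kind")),
        oral = unname(vapply(recs, `[[`, logical(1), "oral")),
        representative_id = unname(vapply(recs, `[[`, character(1),
                                          "representative_id")),
        n_members = unname(vapply(recs, function(r) length(r$members),
                                  integer(1))))
    members <- stats::setNames(lapply(recs, `[[`, "members"), ids)
    new("SGBCatalog", sgbData = sgbData, members = members)
}

#' Two-step SGB clustering of a GenomeSet
#'
#' Convenience wrapper running the full clustering stage: sketch, Mash
#' distance matrix, average-linkage pre-clustering, representative
#' selection, fragment-ANI refinement of candidate representative pairs,
#' complete-linkage merging and catalog assembly. Input genomes are
#' assumed to have passed quality gating already (see [runPipeline()]).
#'
#' @param genomes A [GenomeSet-class].
#' @param config A [sgbConfig()] list of thresholds.
#' @return List: `catalog` ([SGBCatalog-class]), `partition`,
#'   `preclusters`, `mashDistance`, `aniPairs`, `representatives`.
#' @export
buildCatalog <- function(genomes, config = sgbConfig()) {
    stopifnot(is(genomes, "GenomeSet"))
    gd <- as.data.frame(genomeData(genomes))
    rownames(gd) <- gd$genome_id
    sk <- sketchGenomes(genomes, k = config$k, s = config$sketch_size)
    d <- mashDistanceMatrix(sk)
    pre <- precluster(d, cutoff = config$precluster_cutoff)
    referenceIds <- gd$genome_id[gd$is_reference]
    reps <- clusterRepresentatives(pre, gd, referenceIds)
    cand <- refinementPairs(reps, d, candidateCutoff = config$candidate_cutoff)
    ani <- aniPairs(genomes, cand[, c("id1", "id2"), drop = FALSE],
                    fragmentLength = config$fragment_length)
    part <- mergeByAni(pre, reps, ani,
                       aniCutoff = config$ani_cutoff,
                       coverageCutoff = config$coverage_cutoff)
    catalog <- assembleCatalog(part, gd)
    list(catalog = catalog, partition = part, preclusters = pre,
         mashDistance = d, aniPairs = ani, representatives = reps)
}
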