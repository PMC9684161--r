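#' Length-weighted genome depth from a per-contig depth table
#'
#' Normalized contig depths (jgi-style normalization is assumed upstream)
#' are collapsed per genome as the length-weighted mean depth of its
#' contigs. Genomes in the map but absent from the sample get depth 0.
#'
#' @param depths data.frame with columns `sample_id`, `contig_id`,
#'   `length`, `depth`.
#' @param contigToGenome Named character vector: contig id -> genome id.
#' @param sampleId Which sample to summarize.
#' @return Named numeric vector of depths over all mapped genomes.
#' @export
genomeDepth <- function(depths, contigToGenome, sampleId) {
    rows <- depths[depths$sample_id == sampleId, , drop = FALSE]
    unmapped <- setdiff(rows$contig_id, names(contigToGenome))
    if (length(unmapped))
        stop("unmapped contig(s): ", paste(utils::head(unmapped, 5), collapse = ", "))
    if (any(rows$length <= 0)) stop("contig lengths must be positive")
    if (any(rows$depth < 0)) stop("depths must be non-negative")
    genomes <- sort(unique(contigToGenome))
    out <- stats::setNames(numeric(length(genomes)), genomes)
    if (nrow(rows)) {
        g <- contigToGenome[rows$contig_id]
        num <- tapply(rows$length * rows$depth, g, sum)
        den <- tapply(rows$length, g, sum)
        out[names(num)] <- as.numeric(num / den)
    }
    out
}

#' Convert genome depths into an SGB relative-abundance profile
#'
#' Each SGB's depth is the depth of its representative genome (profiling
#' maps reads against the representative index only); abundances are the
#' depths normalized to sum to 1. An all-zero sample yields an all-zero
#' profile carrying the attribute `flagged_empty = TRUE`.
#'
#' @param genomeDepths Named numeric vector (genome id -> depth).
#' @param genomeToSgb Named character vector: representative genome id ->
#'   SGB id.
#' @return Named numeric abundance vector over SGBs (sums to 1 unless
#'   flagged empty).
#' @export
relativeAbundance <- function(genomeDepths, genomeToSgb) {
    if (any(genomeDepths < 0)) stop("negative depth")
    if (!length(genomeDepths)) stop("at least one genome required")
    keep <- intersect(names(genomeDepths), names(genomeToSgb))
    depth <- stats::setNames(genomeDepths[keep], genomeToSgb[keep])
    total <- sum(depth)
    if (total == 0) {
        out <- depth
        attr(out, "flagged_empty") <- TRUE
        return(out)
    }
    depth / total
}

#' Abundance profiles for all samples against an SGB catalog
#'
#' @param depths Per-contig depth table (`sample_id`, `contig_id`,
#'   `length`, `depth`).
#' @param catalog An [SGBCatalog-class].
#' @param contigToGenome Named character vector: contig id -> genome id
#'   (representative genomes).
#' @return Numeric matrix, samples x SGBs, rows summing to 1.
#' @export
profileSamples <- function(depths, catalog, contigToGenome) {
    stopifnot(is(catalog, "SGBCatalog"))
    g2s <- stats::setNames(sgbIds(catalog), representativeIds(catalog))
    samples <- unique(depths$sample_id)
    prof <- matrix(0, length(samples), length(g2s),
                   dimnames = list(samples, as.character(g2s)))
    for (smp in samples) {
        gdep <- genomeDepth(depths, contigToGenome, smp)
        ab <- relativeAbundance(gdep, g2s)
        prof[smp, names(ab)] <- ab
    }
    prof
}

#' SGB richness of a profile
#'
#' Number of SGBs with relative abundance strictly above the threshold
#' (default 0.1%).
#'
#' @param profile Named numeric abundance vector.
#' @param threshold Abundance threshold (default 0.001).
#' @return Integer count.
#' @export
richness <- function(profile, threshold = 0.001) {
    sum(profile > threshold)
}

#' Unknown (uSGB) share of richness and abundance
#'
#' @param profile Named numeric abundance vector over SGB ids.
#' @param catalog An [SGBCatalog-class] covering the profile's SGBs.
#' @param threshold Richness threshold (default 0.001).
#' @return Numeric vector `c(richness_share =, abundance_share =)`: the
#'   share of above-threshold SGBs that are uSGBs, and the summed
#'   abundance of uSGBs.
#' @export
unknownFraction <- function(profile, catalog, threshold = 0.001) {
    stopifnot(is(catalog, "SGBCatalog"))
    unknown <- setdiff(names(profile), sgbIds(catalog))
    if (length(unknown))
        stop("unknown sgb id(s): ", paste(unknown, collapse = ", "))
    kind <- stats::setNames(sgbData(catalog)$kind, sgbIds(catalog))
    isU <- kind[names(profile)] == "uSGB"
    present <- profile > threshold
    richShare <- if (any(present)) sum(present & isU) / sum(present) else 0
    c(richness_share = richShare, abundance_share = sum(profile[isU]))
}

#' Bray-Curtis dissimilarity between two abundance profiles
#'
#' `sum(|p - q|) / sum(p + q)` over the union of SGB keys (missing keys
#' count as 0). Undefined (returned as `NA` with a warning) when both
#' profiles are all-zero.
#'
#' @param p,q Named numeric abundance vectors.
#' @return Distance in \[0, 1\].
#' @examples
#' brayCurtis(c(a = 0.5, b = 0.5), c(a = 1))  # 0.5
#' @export
brayCurtis <- function(p, q) {
    keys <- union(names(p), names(q))
    if (is.null(keys)) {
        stopifnot(length(p) == length(q))
        pv <- as.numeric(p); qv <- as.numeric(q)
    } else {
        pv <- stats::setNames(numeric(length(keys)), keys)
        qv <- pv
        pv[names(p)] <- p
        qv[names(q)] <- q
    }
    denom <- sum(pv + qv)
    if (denom == 0) {
        warning("both profiles are all-zero: Bray-Curtis undefined")
        return(NA_real_)
    }
    sum(abs(pv - qv)) / denom
}
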