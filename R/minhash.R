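#' Bottom-s MinHash sketch of a genome
#'
#' Enumerates all canonical k-mers (the lexicographic minimum of each
#' k-mer and its reverse complement; k must be odd so canonicalization is
#' well defined), hashes each with a fixed 64-bit mixing function under a
#' fixed seed, and keeps the `s` smallest distinct hash values. K-mers
#' containing non-ACGT characters are skipped. Hash values are reduced to
#' 53 bits so they are exact in an R double.
#'
#' @param contigs A [Biostrings::DNAStringSet] (or character vector) of
#'   contigs.
#' @param k K-mer length, odd, default 21.
#' @param s Sketch capacity, default 10000.
#' @return Sorted numeric vector of hash values (the sketch), with
#'   attributes `k` and `s`.
#' @export
sketchGenome <- function(contigs, k = 21L, s = 10000L) {
    if (is(contigs, "DNAStringSet")) contigs <- as.character(contigs)
    h <- cpp_sketch(contigs, as.integer(k), as.integer(s))
    attr(h, "k") <- as.integer(k)
    attr(h, "s") <- as.integer(s)
    h
}

#' Sketch every genome of a GenomeSet
#'
#' @param genomes A [GenomeSet-class].
#' @inheritParams sketchGenome
#' @return A [MashSketchSet-class].
#' @export
sketchGenomes <- function(genomes, k = 21L, s = 10000L) {
    stopifnot(is(genomes, "GenomeSet"))
    ids <- genomeIds(genomes)
    hashes <- lapply(ids, function(id)
        as.numeric(sketchGenome(getContigs(genomes, id), k = k, s = s)))
    new("MashSketchSet", genome_id = ids, k = as.integer(k),
        s = as.integer(s), hashes = hashes)
}

#' Mash-style Jaccard estimate from two bottom sketches
#'
#' Merges the two sorted hash sets, keeps the bottom `min(s, |union|)`
#' values of the union, and reports the fraction of those present in both
#' sketches.
#'
#' @param a,b Sorted numeric hash vectors (as returned by
#'   [sketchGenome()]). Sketch parameters `k` and `s` must match when
#'   carried as attributes.
#' @param s Sketch capacity; defaults to the `s` attribute of `a`.
#' @return Jaccard estimate in \[0, 1\].
#' @export
jaccardEstimate <- function(a, b, s = NULL) {
    ka <- attr(a, "k"); kb <- attr(b, "k")
    sa <- attr(a, "s"); sb <- attr(b, "s")
    if (!is.null(ka) && !is.null(kb) && ka != kb)
        stop("sketches built with different k")
    if (!is.null(sa) && !is.null(sb) && sa != sb)
        stop("sketches built with different s")
    if (is.null(s)) s <- if (!is.null(sa)) sa else max(length(a), length(b))
    cpp_bottom_jaccard(as.numeric(a), as.numeric(b), as.integer(s))
}

#' Mash distance from a Jaccard estimate
#'
#' `D = -(1/k) * log(2j / (1 + j))` for `j > 0`; `D = 1` for `j = 0`;
#' clamped to \[0, 1\]. Under the Poisson mutation model this estimates the
#' per-site substitution rate between the two genomes.
#'
#' @param j Jaccard estimate(s) in \[0, 1\].
#' @param k K-mer length used for sketching.
#' @return Distance(s) in \[0, 1\].
#' @examples
#' mashDistance(1/3, k = 21)  # -log(0.5)/21 = 0.03301
#' @export
mashDistance <- function(j, k = 21L) {
    if (any(j < 0 | j > 1)) stop("jaccard estimate must be in [0, 1]")
    if (k < 1) stop("k must be >= 1")
    d <- ifelse(j > 0, -(1 / k) * log(2 * j / (1 + j)), 1)
    pmin(pmax(d, 0), 1)
}

#' All-versus-all Mash distance matrix
#'
#' @param sketches A [MashSketchSet-class].
#' @return Symmetric numeric matrix of Mash distances with zero diagonal,
#'   dimnames = genome ids.
#' @export
mashDistanceMatrix <- function(sketches) {
    stopifnot(is(sketches, "MashSketchSet"))
    jm <- cpp_jaccard_matrix(sketches@hashes, sketches@s)
    d <- mashDistance(jm, k = sketches@k)
    diag(d) <- 0
    dimnames(d) <- list(sketches@genome_id, sketches@genome_id)
    d
}

#' Serialize / read sketches as JSON
#'
#' @param sketches A [MashSketchSet-class].
#' @param path Output (input) file path.
#' @return `readSketches` returns a [MashSketchSet-class].
#' @export
writeSketches <- function(sketches, path) {
    stopifnot(is(sketches, "MashSketchSet"))
    obj <- list(k = sketches@k, s = sketches@s,
                sketches = mapply(function(id, h) list(genome_id = id, hashes = h),
                                  sketches@genome_id, sketches@hashes,
                                  SIMPLIFY = FALSE, USE.NAMES = FALSE))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeSketches
#' @export
readSketches <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    new("MashSketchSet",
        genome_id = as.character(obj$sketches$genome_id),
        k = as.integer(obj$k), s = as.integer(obj$s),
        hashes = lapply(obj$sketches$hashes, as.numeric))
}
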