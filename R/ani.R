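#' Cut a genome into ANIb fragments
#'
#' Each contig is cut into consecutive non-overlapping windows of
#' `fragmentLength` bp; the terminal remainder is kept iff it is at least
#' `minFragment` bp.
#'
#' @param genome Contigs as a [Biostrings::DNAStringSet] or character
#'   vector.
#' @param fragmentLength Window size in bp (default 1020, the ANIb
#'   convention).
#' @param minFragment Minimum terminal-remainder length kept (default 100).
#' @return Character vector of fragment sequences.
#' @export
fragmentGenome <- function(genome, fragmentLength = 1020L, minFragment = 100L) {
    if (is(genome, "DNAStringSet")) genome <- as.character(genome)
    if (!length(genome) || all(nchar(genome) == 0)) stop("empty genome")
    if (fragmentLength <= 0) stop("fragmentLength must be positive")
    out <- character(0)
    for (s in genome) {
        n <- nchar(s)
        starts <- seq.int(1L, n, by = fragmentLength)
        ends <- pmin(starts + fragmentLength - 1L, n)
        keep <- (ends - starts + 1L) == fragmentLength |
                (ends - starts + 1L) >= minFragment
        if (any(keep))
            out <- c(out, substring(s, starts[keep], ends[keep]))
    }
    out
}

#' Align one fragment against a subject genome
#'
#' Best ungapped local placement of the fragment (either strand) against
#' any subject contig, found by exact-seed search and ungapped extension.
#' A placement is reported only if the aligned length is at least
#' `minLengthFrac` of the fragment length and the identity is at least
#' `minIdentity` percent (the ANIb acceptance convention); otherwise the
#' outcome is a no-hit (`NULL`).
#'
#' @param fragment A single fragment sequence (character).
#' @param subject Subject contigs (`DNAStringSet` or character).
#' @param minLengthFrac Minimum aligned fraction of the fragment (0.7).
#' @param minIdentity Minimum identity percent (30).
#' @param seedLen,seedStep Exact-seed length and spacing of the search.
#' @return `list(identity =, aligned_length =)` or `NULL` for no-hit.
#' @export
alignFragment <- function(fragment, subject, minLengthFrac = 0.7,
                          minIdentity = 30, seedLen = 13L, seedStep = 25L) {
    if (is(subject, "DNAStringSet")) subject <- as.character(subject)
    stopifnot(length(fragment) == 1L, nchar(fragment) > 0)
    res <- cpp_align_fragments(fragment, subject,
                               as.integer(seedLen), as.integer(seedStep))
    ok <- res$found[1] &&
        res$aligned_length[1] >= minLengthFrac * nchar(fragment) &&
        res$identity[1] >= minIdentity
    if (!ok) return(NULL)
    list(identity = res$identity[1], aligned_length = res$aligned_length[1])
}

#' Fragment-based ANI (ANIb-style) of a query against a subject
#'
#' The query is cut into fragments ([fragmentGenome()]), each fragment is
#' placed against the subject ([alignFragment()] contract), and accepted
#' placements (>= 70% of fragment length aligned, >= 30% identity) are
#' summarized: `ani` is the mean identity over accepted fragments and
#' `coverage` the summed accepted aligned length divided by the total
#' query length. With zero accepted fragments the result is flagged
#' undefined (`defined = FALSE`), which downstream is equivalent to
#' failing the coverage gate.
#'
#' @param query,subject Genomes (`DNAStringSet` or character contigs).
#' @param fragmentLength ANIb fragment size (default 1020 bp).
#' @param queryId,subjectId Labels carried into the result.
#' @param minLengthFrac,minIdentity Acceptance filter, see
#'   [alignFragment()].
#' @param seedLen,seedStep Seed-search parameters.
#' @return One-row data.frame: `query_id`, `subject_id`, `ani`,
#'   `coverage`, `n_fragments_aligned`, `defined`.
#' @export
anib <- function(query, subject, fragmentLength = 1020L,
                 queryId = "query", subjectId = "subject",
                 minLengthFrac = 0.7, minIdentity = 30,
                 seedLen = 13L, seedStep = 25L) {
    if (is(query, "DNAStringSet")) query <- as.character(query)
    if (is(subject, "DNAStringSet")) subject <- as.character(subject)
    frags <- fragmentGenome(query, fragmentLength)
    res <- cpp_align_fragments(frags, subject,
                               as.integer(seedLen), as.integer(seedStep))
    acc <- res$found &
        res$aligned_length >= minLengthFrac * nchar(frags) &
        !is.na(res$identity) & res$identity >= minIdentity
    n <- sum(acc)
    qlen <- sum(nchar(query))
    data.frame(query_id = queryId, subject_id = subjectId,
               ani = if (n) mean(res$identity[acc]) else NA_real_,
               coverage = if (n) sum(res$aligned_length[acc]) / qlen else 0,
               n_fragments_aligned = n,
               defined = n >= 1L)
}

#' Symmetrize the two directions of a genome pair's ANI
#'
#' Pair-level ANI is the arithmetic mean of the two directional ANIs;
#' pair-level coverage is the minimum of the two directional coverages
#' (the conservative reading of the 30%-overlap rule). If either direction
#' is undefined the pair fails.
#'
#' @param a,b One-row data.frames from [anib()], the two directions of one
#'   pair.
#' @return One-row data.frame `id1`, `id2`, `ani`, `coverage`, `defined`.
#' @export
symmetrizeAni <- function(a, b) {
    if (!(a$query_id == b$subject_id && a$subject_id == b$query_id))
        stop("a and b are not the two directions of one pair")
    defined <- isTRUE(a$defined) && isTRUE(b$defined)
    data.frame(id1 = a$query_id, id2 = a$subject_id,
               ani = if (defined) (a$ani + b$ani) / 2 else NA_real_,
               coverage = if (defined) min(a$coverage, b$coverage) else 0,
               defined = defined)
}

#' Symmetrized fragment ANI for a list of genome pairs
#'
#' Runs [anib()] in both directions for every pair and symmetrizes.
#'
#' @param genomes A [GenomeSet-class].
#' @param pairs Two-column matrix or data.frame of genome ids.
#' @param ... Passed to [anib()].
#' @return data.frame with one row per pair (`id1`, `id2`, `ani`,
#'   `coverage`, `defined`).
#' @export
aniPairs <- function(genomes, pairs, ...) {
    stopifnot(is(genomes, "GenomeSet"))
    pairs <- as.matrix(pairs)
    if (!nrow(pairs))
        return(data.frame(id1 = character(0), id2 = character(0),
                          ani = numeric(0), coverage = numeric(0),
                          defined = logical(0)))
    out <- lapply(seq_len(nrow(pairs)), function(i) {
        q <- pairs[i, 1]; s <- pairs[i, 2]
        a <- anib(getContigs(genomes, q), getContigs(genomes, s),
                  queryId = q, subjectId = s, ...)
        b <- anib(getContigs(genomes, s), getContigs(genomes, q),
                  queryId = s, subjectId = q, ...)
        symmetrizeAni(a, b)
    })
    do.call(rbind, out)
}
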