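#' MIMAG-style quality tier of a MAG
#'
#' High quality requires completeness strictly above 90% and contamination
#' strictly below 5%; medium quality requires completeness strictly above
#' 50% and contamination strictly below 10%; anything else fails. Exact
#' boundary values (90/5, 50/10) therefore resolve to the lower tier.
#'
#' @param completeness Completeness percent in \[0, 100\] (vectorized).
#' @param contamination Contamination percent >= 0 (vectorized).
#' @return Character vector with values `"high"`, `"medium"` or `"fail"`.
#' @examples
#' classifyQuality(95, 2)   # "high"
#' classifyQuality(70, 8)   # "medium"
#' classifyQuality(50, 10)  # "fail": both thresholds are strict
#' @export
classifyQuality <- function(completeness, contamination) {
    if (any(!is.finite(completeness)) || any(!is.finite(contamination)))
        stop("completeness/contamination must be finite")
    if (any(completeness < 0 | completeness > 100))
        stop("completeness must be in [0, 100]")
    if (any(contamination < 0))
        stop("contamination must be non-negative")
    ifelse(completeness > 90 & contamination < 5, "high",
    ifelse(completeness > 50 & contamination < 10, "medium", "fail"))
}

.STANDARD_AA <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly",
                  "His", "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser",
                  "Thr", "Trp", "Tyr", "Val")

#' tRNA isotype audit
#'
#' A genome passes when tRNAs decoding at least 18 of the 20 standard
#' amino acids are present. Distinct isotypes are counted, not tRNA gene
#' copies.
#'
#' @param aminoAcids Character vector of three-letter amino-acid labels
#'   (duplicates allowed).
#' @return Logical scalar.
#' @export
trnaPass <- function(aminoAcids) {
    bad <- setdiff(unique(aminoAcids), .STANDARD_AA)
    if (length(bad))
        stop("non-standard amino-acid label(s): ", paste(bad, collapse = ", "))
    length(unique(aminoAcids)) >= 18L
}

#' rRNA completeness audit
#'
#' Passes iff all three ribosomal RNA genes (5S, 16S and 23S) are present.
#'
#' @param rrnaTypes Character vector, subset of `c("5S", "16S", "23S")`.
#' @return Logical scalar.
#' @export
rrnaPass <- function(rrnaTypes) {
    bad <- setdiff(unique(rrnaTypes), c("5S", "16S", "23S"))
    if (length(bad))
        stop("unknown rRNA type(s): ", paste(bad, collapse = ", "))
    all(c("5S", "16S", "23S") %in% rrnaTypes)
}

#' Assembly N50
#'
#' The largest length L such that contigs of length >= L cover at least
#' half of the total assembly length.
#'
#' @param contigLengths Numeric vector of positive contig lengths.
#' @return N50 in bases.
#' @examples
#' n50(c(40, 30, 20, 10))  # 30
#' @export
n50 <- function(contigLengths) {
    if (!length(contigLengths)) stop("empty contig length list")
    if (any(contigLengths <= 0)) stop("contig lengths must be positive")
    x <- sort(contigLengths, decreasing = TRUE)
    x[which(cumsum(x) >= sum(x) / 2)[1]]
}

#' Read a CheckM-style quality report
#'
#' Expects a tab-separated file with at least the columns `genome_id`,
#' `completeness`, `contamination`, and optionally `strain_heterogeneity`
#' and `mean_depth`.
#'
#' @param path Path to the TSV file.
#' @return A data.frame.
#' @export
readCheckmReport <- function(path) {
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("genome_id", "completeness", "contamination")
    if (!all(need %in% colnames(d)))
        stop("quality report must have columns: ", paste(need, collapse = ", "))
    d
}

#' Tier and audit a whole quality table
#'
#' Convenience wrapper applying [classifyQuality()] per genome; audits, if
#' provided, are joined in as flags. Audit outcomes are reported, not used
#' as filters.
#'
#' @param metrics data.frame with `genome_id`, `completeness`,
#'   `contamination` columns.
#' @param trna Optional named list (by genome id) of amino-acid vectors.
#' @param rrna Optional named list (by genome id) of rRNA type vectors.
#' @return `metrics` with added `tier` (and `trna_pass`/`rrna_pass`) columns.
#' @export
qualityTable <- function(metrics, trna = NULL, rrna = NULL) {
    metrics$tier <- classifyQuality(metrics$completeness, metrics$contamination)
    if (!is.null(trna))
        metrics$trna_pass <- vapply(metrics$genome_id, function(id)
            if (is.null(trna[[id]])) NA else trnaPass(trna[[id]]), logical(1))
    if (!is.null(rrna))
        metrics$rrna_pass <- vapply(metrics$genome_id, function(id)
            if (is.null(rrna[[id]])) NA else rrnaPass(rrna[[id]]), logical(1))
    metrics
}
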