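#' @import methods
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom Biostrings DNAStringSet
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom Biostrings DNAStringSet width
NULL

#' GenomeSet: a collection of genomes or MAGs with per-genome metadata
#'
#' Container for a set of genome assemblies. All contigs live in a single
#' [Biostrings::DNAStringSet] whose names follow the `"<genome_id>|<i>"`
#' convention; per-genome annotation (source flags, planted species label,
#' CheckM-style quality metrics) is kept in a parallel
#' [S4Vectors::DataFrame].
#'
#' The `genomeData` columns used downstream are: `genome_id`, `species_id`
#' (planted truth, `NA` for real data), `is_reference`, `is_oral_reference`,
#' `is_oral_mag`, `completeness`, `contamination`, `strain_heterogeneity`,
#' `mean_depth`, `genome_length`, `n50`. `genome_length` and `n50` are
#' recomputed from the sequences by the constructor.
#'
#' @slot contigs A [Biostrings::DNAStringSet] of all contigs, named
#'   `"<genome_id>|<contig_index>"`.
#' @slot genomeData A [S4Vectors::DataFrame] with one row per genome.
#'
#' @seealso [GenomeSet()] for construction, [genomeIds()], [getContigs()].
#' @export
setClass("GenomeSet",
    slots = c(contigs = "DNAStringSet", genomeData = "DataFrame"))

setValidity("GenomeSet", function(object) {
    nm <- names(object@contigs)
    if (length(object@contigs) && is.null(nm))
        return("contigs must be named '<genome_id>|<contig_index>'")
    if (length(nm) && any(!grepl("\\|", nm)))
        return("contig names must contain '|' separating genome id and index")
    gids <- unique(sub("\\|[^|]*$", "", nm))
    if (!"genome_id" %in% colnames(object@genomeData))
        return("genomeData must have a genome_id column")
    dataIds <- object@genomeData$genome_id
    if (anyDuplicated(dataIds))
        return("duplicated genome_id in genomeData")
    if (!setequal(gids, dataIds))
        return("genomeData genome_id set does not match contig names")
    TRUE
})

#' MashSketchSet: bottom-s MinHash sketches of canonical k-mers
#'
#' One sketch per genome: the `s` smallest distinct 53-bit hash values over
#' all canonical k-mers (fewer if the genome has fewer distinct k-mers),
#' stored sorted ascending.
#'
#' @slot genome_id Character vector of genome labels.
#' @slot k K-mer length (odd, default 21).
#' @slot s Sketch capacity (default 10000).
#' @slot hashes List of sorted numeric vectors of hash values.
#' @export
setClass("MashSketchSet",
    slots = c(genome_id = "character", k = "integer", s = "integer",
              hashes = "list"))

setValidity("MashSketchSet", function(object) {
    if (length(object@genome_id) != length(object@hashes))
        return("genome_id and hashes lengths differ")
    if (anyDuplicated(object@genome_id))
        return("duplicated genome ids")
    for (h in object@hashes) {
        if (length(h) > object@s) return("sketch larger than capacity s")
        if (is.unsorted(h, strictly = TRUE)) return("hashes must be sorted, distinct")
    }
    TRUE
})

#' SGBCatalog: the final species-level genome bin catalog
#'
#' One record per SGB: its members (a partition of the input genomes), the
#' selected representative, the kind (`kSGB` if the cluster contains at
#' least one reference genome, else `uSGB`) and the oral flag (`TRUE` iff
#' the cluster contains an oral reference genome or an oral MAG).
#'
#' @slot sgbData A [S4Vectors::DataFrame] with columns `sgb_id`, `kind`,
#'   `oral`, `representative_id`, `n_members`.
#' @slot members Named list (by `sgb_id`) of member genome id vectors.
#' @export
setClass("SGBCatalog",
    slots = c(sgbData = "DataFrame", members = "list"))

setValidity("SGBCatalog", function(object) {
    d <- object@sgbData
    need <- c("sgb_id", "kind", "oral", "representative_id", "n_members")
    if (!all(need %in% colnames(d)))
        return(paste("sgbData must have columns:", paste(need, collapse = ", ")))
    if (!identical(names(object@members), as.character(d$sgb_id)))
        return("members list names must match sgb_id order")
    all_members <- unlist(object@members, use.names = FALSE)
    if (anyDuplicated(all_members))
        return("SGB memberships overlap: a genome appears in two SGBs")
    for (i in seq_len(nrow(d))) {
        if (!d$representative_id[i] %in% object@members[[i]])
            return(sprintf("representative %s not a member of %s",
                           d$representative_id[i], d$sgb_id[i]))
        if (d$n_members[i] != length(object@members[[i]]))
            return("n_members inconsistent with member list")
    }
    if (!all(d$kind %in% c("kSGB", "uSGB")))
        return("kind must be kSGB or uSGB")
    TRUE
})
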