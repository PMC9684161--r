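#' Write genomes as one multi-FASTA per genome
#'
#' Headers follow the `"<genome_id>|<contig_index>"` convention.
#'
#' @param genomes A [GenomeSet-class].
#' @param dir Output directory.
#' @return Invisibly, the written file paths.
#' @export
writeGenomeFasta <- function(genomes, dir) {
    stopifnot(is(genomes, "GenomeSet"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- vapply(genomeIds(genomes), function(id) {
        p <- file.path(dir, paste0(id, ".fasta"))
        Biostrings::writeXStringSet(getContigs(genomes, id), p)
        p
    }, character(1))
    invisible(paths)
}

#' Read genomes from multi-FASTA files
#'
#' Accepts files written by [writeGenomeFasta()] (headers
#' `"<genome_id>|<i>"`) or plain FASTA, in which case the file name
#' (without extension) becomes the genome id.
#'
#' @param paths FASTA file paths.
#' @param genomeData Optional per-genome annotation.
#' @return A [GenomeSet-class].
#' @export
readGenomeFasta <- function(paths, genomeData = NULL) {
    sets <- lapply(paths, function(p) {
        x <- Biostrings::readDNAStringSet(p)
        names(x) <- sub("\\s.*$", "", names(x))
        if (!all(grepl("\\|", names(x)))) {
            id <- sub("\\.(fa|fasta|fna)$", "", basename(p))
            names(x) <- paste0(id, "|", seq_along(x))
        }
        x
    })
    GenomeSet(do.call(c, sets), genomeData = genomeData)
}

#' Write / read an SGB catalog as TSV
#'
#' Columns: `sgb_id`, `kind`, `oral`, `representative_id`, `n_members`,
#' `member_ids` (semicolon-joined).
#'
#' @param catalog An [SGBCatalog-class].
#' @param path TSV file path.
#' @return `readCatalog` returns an [SGBCatalog-class].
#' @export
writeCatalog <- function(catalog, path) {
    stopifnot(is(catalog, "SGBCatalog"))
    utils::write.table(as.data.frame(catalog), path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname writeCatalog
#' @export
readCatalog <- function(path) {
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
    members <- stats::setNames(strsplit(d$member_ids, ";", fixed = TRUE),
                               d$sgb_id)
    new("SGBCatalog",
        sgbData = DataFrame(d[, c("sgb_id", "kind", "oral",
                                  "representative_id", "n_members")]),
        members = members)
}

#' Write / read a per-contig depth table as TSV
#'
#' @param depths data.frame with `sample_id`, `contig_id`, `length`,
#'   `depth`.
#' @param path TSV file path.
#' @export
writeDepthTable <- function(depths, path) {
    utils::write.table(depths, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    invisible(path)
}

#' @rdname writeDepthTable
#' @export
readDepthTable <- function(path) {
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("sample_id", "contig_id", "length", "depth")
    if (!all(need %in% colnames(d)))
        stop("depth table must have columns: ", paste(need, collapse = ", "))
    d
}
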