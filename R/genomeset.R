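#' Construct a GenomeSet
#'
#' @param genomes Named list of [Biostrings::DNAStringSet] objects, one per
#'   genome (names are the genome ids), or a single `DNAStringSet` whose
#'   names already follow the `"<genome_id>|<i>"` convention.
#' @param genomeData Optional `DataFrame`/`data.frame` of per-genome
#'   annotation with a `genome_id` column. Missing standard columns are
#'   filled with defaults (`is_reference = FALSE`, flags `FALSE`, metric
#'   columns `NA`).
#' @return A [GenomeSet-class] object.
#' @examples
#' g <- simulateGenome(12000, gc = 0.5, seed = 1)
#' gs <- GenomeSet(list(gA = g))
#' genomeIds(gs)
#' @export
GenomeSet <- function(genomes, genomeData = NULL) {
    if (is(genomes, "DNAStringSet")) {
        contigs <- genomes
    } else {
        if (is.null(names(genomes)) || anyDuplicated(names(genomes)))
            stop("genomes must be a uniquely named list")
        if (any(grepl("\\|", names(genomes))))
            stop("genome ids must not contain '|'")
        parts <- lapply(names(genomes), function(id) {
            x <- genomes[[id]]
            if (!is(x, "DNAStringSet")) x <- DNAStringSet(x)
            names(x) <- paste0(id, "|", seq_along(x))
            x
        })
        contigs <- do.call(c, parts)
    }
    gids <- unique(sub("\\|[^|]*$", "", names(contigs)))
    gd <- .normalizeGenomeData(genomeData, gids)
    ## recompute assembly statistics from the sequences
    w <- width(contigs)
    cg <- sub("\\|[^|]*$", "", names(contigs))
    gd$genome_length <- as.integer(vapply(gd$genome_id, function(id)
        sum(w[cg == id]), numeric(1)))
    gd$n50 <- as.integer(vapply(gd$genome_id, function(id)
        n50(w[cg == id]), numeric(1)))
    new("GenomeSet", contigs = contigs, genomeData = gd)
}

.normalizeGenomeData <- function(genomeData, gids) {
    if (is.null(genomeData)) {
        gd <- DataFrame(genome_id = gids)
    } else {
        gd <- as(genomeData, "DataFrame")
        if (!"genome_id" %in% colnames(gd))
            stop("genomeData needs a genome_id column")
        if (!setequal(gd$genome_id, gids))
            stop("genomeData genome ids do not match the sequences")
        gd <- gd[match(gids, gd$genome_id), , drop = FALSE]
    }
    defaults <- list(species_id = NA_character_, is_reference = FALSE,
                     is_oral_reference = FALSE, is_oral_mag = FALSE,
                     completeness = NA_real_, contamination = NA_real_,
                     strain_heterogeneity = NA_real_, mean_depth = NA_real_)
    for (col in names(defaults))
        if (!col %in% colnames(gd)) gd[[col]] <- defaults[[col]]
    rownames(gd) <- gd$genome_id
    gd
}

#' @rdname GenomeSet
#' @param x,object A `GenomeSet`.
#' @export
setGeneric("genomeIds", function(x) standardGeneric("genomeIds"))

#' @rdname GenomeSet
#' @export
setMethod("genomeIds", "GenomeSet", function(x) x@genomeData$genome_id)

#' @rdname GenomeSet
#' @export
setGeneric("genomeData", function(x) standardGeneric("genomeData"))

#' @rdname GenomeSet
#' @export
setMethod("genomeData", "GenomeSet", function(x) x@genomeData)

#' @rdname GenomeSet
#' @param value Replacement `DataFrame`.
#' @export
setGeneric("genomeData<-", function(x, value) standardGeneric("genomeData<-"))

#' @rdname GenomeSet
#' @export
setMethod("genomeData<-", "GenomeSet", function(x, value) {
    x@genomeData <- .normalizeGenomeData(value, genomeIds(x))
    validObject(x)
    x
})

#' @rdname GenomeSet
#' @param id A genome id.
#' @export
setGeneric("getContigs", function(x, id) standardGeneric("getContigs"))

#' @rdname GenomeSet
#' @export
setMethod("getContigs", "GenomeSet", function(x, id) {
    stopifnot(length(id) == 1L)
    if (!id %in% genomeIds(x)) stop("unknown genome id: ", id)
    x@contigs[sub("\\|[^|]*$", "", names(x@contigs)) == id]
})

#' @rdname GenomeSet
#' @export
setGeneric("genomeLengths", function(x) standardGeneric("genomeLengths"))

#' @rdname GenomeSet
#' @export
setMethod("genomeLengths", "GenomeSet", function(x)
    stats::setNames(x@genomeData$genome_length, x@genomeData$genome_id))

#' @rdname GenomeSet
#' @export
setMethod("length", "GenomeSet", function(x) nrow(x@genomeData))

#' Subset a GenomeSet by genome id
#' @param x A `GenomeSet`.
#' @param i Character vector of genome ids (or logical/integer index into
#'   `genomeIds(x)`).
#' @param j,drop,... Ignored.
#' @export
setMethod("[", "GenomeSet", function(x, i, j, ..., drop = FALSE) {
    ids <- genomeIds(x)
    keep <- if (is.character(i)) {
        if (!all(i %in% ids)) stop("unknown genome id(s)")
        i
    } else ids[i]
    cg <- sub("\\|[^|]*$", "", names(x@contigs))
    new("GenomeSet",
        contigs = x@contigs[cg %in% keep],
        genomeData = x@genomeData[match(keep, ids), , drop = FALSE])
})

setMethod("show", "GenomeSet", function(object) {
    gd <- object@genomeData
    cat("GenomeSet with", nrow(gd), "genomes,",
        length(object@contigs), "contigs\n")
    cat("  total length:", sum(gd$genome_length), "bp;",
        sum(gd$is_reference), "reference genome(s)\n")
    if (nrow(gd)) {
        shown <- utils::head(gd$genome_id, 5)
        cat("  genomes:", paste(shown, collapse = ", "),
            if (nrow(gd) > 5) "..." else "", "\n")
    }
})

setMethod("show", "MashSketchSet", function(object) {
    cat("MashSketchSet:", length(object@genome_id), "sketches (k =",
        object@k, ", s =", object@s, ")\n")
})

setMethod("show", "SGBCatalog", function(object) {
    d <- object@sgbData
    cat("SGBCatalog with", nrow(d), "SGBs (",
        sum(d$kind == "kSGB"), "kSGB /", sum(d$kind == "uSGB"), "uSGB ),",
        sum(d$n_members), "genomes,", sum(d$oral), "oral\n")
})

#' Accessors for SGBCatalog
#' @param x An [SGBCatalog-class].
#' @return `sgbIds`: character vector of SGB ids; `sgbData`: the record
#'   `DataFrame`; `sgbMembers`: named list of member genome ids;
#'   `representativeIds`: named character vector of representatives.
#' @export
setGeneric("sgbIds", function(x) standardGeneric("sgbIds"))

#' @rdname sgbIds
#' @export
setMethod("sgbIds", "SGBCatalog", function(x) as.character(x@sgbData$sgb_id))

#' @rdname sgbIds
#' @export
setGeneric("sgbData", function(x) standardGeneric("sgbData"))

#' @rdname sgbIds
#' @export
setMethod("sgbData", "SGBCatalog", function(x) x@sgbData)

#' @rdname sgbIds
#' @export
setGeneric("sgbMembers", function(x) standardGeneric("sgbMembers"))

#' @rdname sgbIds
#' @export
setMethod("sgbMembers", "SGBCatalog", function(x) x@members)

#' @rdname sgbIds
#' @export
setGeneric("representativeIds", function(x) standardGeneric("representativeIds"))

#' @rdname sgbIds
#' @export
setMethod("representativeIds", "SGBCatalog", function(x)
    stats::setNames(as.character(x@sgbData$representative_id), sgbIds(x)))

#' @rdname sgbIds
#' @param row.names,optional,... Passed to the data.frame method.
#' @export
as.data.frame.SGBCatalog <- function(x, row.names = NULL, optional = FALSE, ...) {
    d <- as.data.frame(x@sgbData)
    d$member_ids <- vapply(x@members, paste, character(1), collapse = ";")
    d
}
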