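#' @importFrom stats runif rgamma setNames
NULL

## evaluate expr under set.seed(seed), restoring the caller's RNG state
.withSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        genv <- globalenv()
        old <- if (exists(".Random.seed", envir = genv, inherits = FALSE))
            get(".Random.seed", envir = genv) else NULL
        on.exit({
            if (is.null(old)) {
                if (exists(".Random.seed", envir = genv, inherits = FALSE))
                    rm(".Random.seed", envir = genv)
            } else assign(".Random.seed", old, envir = genv)
        })
        set.seed(as.integer(seed))
    }
    force(expr)
}

.BASES <- c("A", "C", "G", "T")

#' Simulate an ancestral genome sequence
#'
#' Draws an i.i.d. base sequence of the requested length and GC content.
#' Ancestral genomes carry no repeat structure: the clustering mathematics
#' under test depends only on k-mer divergence, not on genome architecture.
#'
#' @param length Genome length in bases (> 0).
#' @param gc Target GC fraction in (0, 1).
#' @param seed Integer seed; identical seeds give byte-identical sequences.
#' @return A single-contig [Biostrings::DNAStringSet].
#' @examples
#' g <- simulateGenome(10000, gc = 0.5, seed = 7)
#' @export
simulateGenome <- function(length, gc = 0.5, seed = NULL) {
    if (!is.numeric(length) || length(length) != 1L || length < 1)
        stop("genome length must be a positive number")
    if (gc <= 0 || gc >= 1) stop("gc must be in (0, 1)")
    .withSeed(seed, {
        p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
        bases <- sample(.BASES, length, replace = TRUE, prob = p)
        DNAStringSet(paste(bases, collapse = ""))
    })
}

#' Mutate a genome into a strain at a known substitution rate
#'
#' Each site is substituted independently with probability `rate` to one of
#' the three other bases, so the expected nucleotide identity against the
#' parent is `100 * (1 - rate)`. Substitution-only mutation keeps the target
#' ANI analytically known; indels are deliberately not modelled.
#'
#' @param parent A [Biostrings::DNAStringSet] of parent contigs.
#' @param rate Per-site substitution probability in \[0, 0.3\].
#' @param seed Integer seed.
#' @return A `DNAStringSet` of the same shape as `parent`.
#' @export
mutateStrain <- function(parent, rate, seed = NULL) {
    if (!is(parent, "DNAStringSet")) parent <- DNAStringSet(parent)
    if (!is.numeric(rate) || rate < 0 || rate > 0.3)
        stop("substitution rate must be in [0, 0.3]")
    if (rate == 0) return(parent)
    .withSeed(seed, {
        out <- vapply(as.character(parent), function(s) {
            ch <- strsplit(s, "", fixed = TRUE)[[1]]
            hit <- which(runif(length(ch)) < rate)
            if (length(hit)) {
                cur <- match(ch[hit], .BASES)
                step <- sample.int(3L, length(hit), replace = TRUE)
                ch[hit] <- .BASES[(cur + step - 1L) %% 4L + 1L]
            }
            paste(ch, collapse = "")
        }, character(1), USE.NAMES = FALSE)
        res <- DNAStringSet(out)
        names(res) <- names(parent)
        res
    })
}

#' Degrade a genome into a MAG with known completeness and contamination
#'
#' Retains a uniformly placed set of non-overlapping segments totalling
#' `completeness`% of the parent length, each emitted as a contig of at
#' least `minContig` bp (the binning convention for assembled contigs), and
#' optionally appends whole foreign contigs drawn from
#' `contaminationSources` totalling `contamination`% of the retained
#' length. The realized completeness and contamination are recorded in
#' `S4Vectors::metadata()` of the result so the planted truth is available
#' downstream.
#'
#' @param genome Parent contigs (`DNAStringSet`); they are treated as one
#'   concatenated sequence.
#' @param completeness Percent of the parent to retain, in (0, 100\].
#' @param contaminationSources Optional list of `DNAStringSet` genomes to
#'   draw foreign contigs from.
#' @param contamination Percent of the retained length to add as foreign
#'   sequence, in \[0, 100).
#' @param minContig Minimum emitted contig length (default 1500 bp).
#' @param nContigs Number of retained contigs; default: random up to
#'   what `minContig` allows (capped at 40).
#' @param seed Integer seed.
#' @return A `DNAStringSet` of contigs with planted quality metrics in
#'   `metadata()` (`completeness`, `contamination`).
#' @export
degradeToMag <- function(genome, completeness, contaminationSources = NULL,
                         contamination = 0, minContig = 1500L,
                         nContigs = NULL, seed = NULL) {
    if (!is(genome, "DNAStringSet")) genome <- DNAStringSet(genome)
    if (completeness <= 0 || completeness > 100)
        stop("completeness must be in (0, 100]")
    if (contamination < 0 || contamination >= 100)
        stop("contamination must be in [0, 100)")
    parent <- paste(as.character(genome), collapse = "")
    plen <- nchar(parent)
    keep <- round(completeness / 100 * plen)
    if (keep < minContig)
        stop("completeness too low: retained length ", keep,
             " bp is below the minimum contig length ", minContig, " bp")
    .withSeed(seed, {
        nmax <- keep %/% minContig
        n <- if (is.null(nContigs)) sample.int(min(nmax, 40L), 1L)
             else as.integer(nContigs)
        if (n < 1 || n > nmax)
            stop("nContigs incompatible with minContig and retained length")
        segLens <- .splitLength(keep - n * minContig, n) + minContig
        gaps <- .splitLength(plen - keep, n + 1L)
        starts <- cumsum(gaps[seq_len(n)]) + c(0, cumsum(segLens[-n]))[seq_len(n)] + 1L
        contigs <- substring(parent, starts, starts + segLens - 1L)
        foreign <- character(0)
        if (contamination > 0) {
            if (is.null(contaminationSources) || !length(contaminationSources))
                stop("contamination requested but no contamination sources given")
            target <- contamination / 100 * keep
            got <- 0
            while (got < target) {
                src <- contaminationSources[[sample.int(length(contaminationSources), 1L)]]
                s <- paste(as.character(src), collapse = "")
                len <- min(max(minContig, round(target - got)),
                           sample(minContig:(3L * minContig), 1L), nchar(s))
                if (len < minContig) len <- minContig
                at <- sample.int(nchar(s) - len + 1L, 1L)
                foreign <- c(foreign, substring(s, at, at + len - 1L))
                got <- got + len
            }
        }
        out <- DNAStringSet(c(contigs, foreign))
        retained <- sum(nchar(contigs))
        metadata(out) <- list(
            completeness = 100 * retained / plen,
            contamination = 100 * sum(nchar(foreign)) / retained)
        out
    })
}

## split `total` into n non-negative integer parts, uniformly at random
.splitLength <- function(total, n) {
    total <- as.integer(round(total))
    if (n == 1L) return(total)
    if (total == 0L) return(integer(n))
    cuts <- sort(sample.int(total + 1L, n - 1L, replace = TRUE) - 1L)
    diff(c(0L, cuts, total))
}

#' Simulate a synthetic community with planted species/strain structure
#'
#' Builds the default evaluation community: `nSpecies` unrelated ancestral
#' genomes; for each species a strain divergence `r` is drawn from
#' `divergences` and every strain is mutated from the (hidden) ancestor at
#' rate `r/2`, so the pairwise strain ANI is approximately `100 * (1 - r)`.
#' A subset of species contributes its first strain as a reference genome
#' (optionally flagged as an oral/eHOMD reference); all remaining genomes
#' are MAGs. Plausible CheckM-style metrics are attached so representative
#' selection is exercised.
#'
#' @param nSpecies Number of planted species.
#' @param genomeLength Ancestral genome length (bases).
#' @param strainRange Integer range `c(min, max)` of strains per species.
#' @param divergences Candidate pairwise strain divergences (substitution
#'   fractions); drawn once per species.
#' @param gcRange GC content range, drawn per species.
#' @param refFraction Fraction of species contributing a reference genome.
#' @param oralRefFraction Fraction of reference genomes flagged as oral
#'   (eHOMD-like) references.
#' @param seed Integer seed.
#' @return A list with elements `genomes` (a [GenomeSet-class]) and `truth`
#'   (list with `genome_to_species`, `target_ani` data.frame of planted
#'   intra-species pairwise ANIs, and `divergence` per species).
#' @export
simulateCommunity <- function(nSpecies = 20, genomeLength = 1e5,
                              strainRange = c(2L, 6L),
                              divergences = c(0.005, 0.01, 0.02, 0.03),
                              gcRange = c(0.35, 0.60),
                              refFraction = 0.5, oralRefFraction = 0.5,
                              seed = 1) {
    stopifnot(nSpecies >= 1, genomeLength >= 1e4)
    .withSeed(seed, {
        spSeeds <- sample.int(1e8, nSpecies)
        genomes <- list()
        rows <- list()
        truthSpecies <- character(0)
        targetAni <- list()
        divergence <- numeric(nSpecies)
        for (i in seq_len(nSpecies)) {
            sp <- sprintf("sp%02d", i)
            gc <- runif(1, gcRange[1], gcRange[2])
            r <- sample(divergences, 1)
            divergence[i] <- r
            nStr <- sample(strainRange[1]:strainRange[2], 1)
            anc <- simulateGenome(genomeLength, gc, seed = spSeeds[i])
            rates <- rep(r / 2, nStr)
            ids <- sprintf("%s_g%d", sp, seq_len(nStr))
            isRef <- rep(FALSE, nStr)
            if (runif(1) < refFraction) isRef[1] <- TRUE
            oralRef <- isRef & (runif(nStr) < oralRefFraction)
            for (j in seq_len(nStr)) {
                mseed <- sample.int(1e8, 1)
                genomes[[ids[j]]] <- mutateStrain(anc, rates[j], seed = mseed)
                rows[[ids[j]]] <- data.frame(
                    genome_id = ids[j], species_id = sp,
                    is_reference = isRef[j],
                    is_oral_reference = oralRef[j],
                    is_oral_mag = !isRef[j],
                    completeness = if (isRef[j]) 100 else runif(1, 80, 100),
                    contamination = if (isRef[j]) 0 else runif(1, 0, 4),
                    strain_heterogeneity = runif(1, 0, 10),
                    mean_depth = runif(1, 5, 60))
            }
            truthSpecies[ids] <- sp
            if (nStr > 1) {
                pr <- utils::combn(seq_len(nStr), 2)
                for (c0 in seq_len(ncol(pr))) {
                    a <- pr[1, c0]; b <- pr[2, c0]
                    pa <- rates[a]; pb <- rates[b]
                    ident <- (1 - pa) * (1 - pb) + pa * pb / 3
                    targetAni[[length(targetAni) + 1L]] <- data.frame(
                        id1 = ids[a], id2 = ids[b], target_ani = 100 * ident)
                }
            }
        }
        gd <- do.call(rbind, rows)
        gs <- GenomeSet(genomes, gd)
        names(divergence) <- sprintf("sp%02d", seq_len(nSpecies))
        list(genomes = gs,
             truth = list(genome_to_species = truthSpecies,
                          target_ani = do.call(rbind, targetAni),
                          divergence = divergence))
    })
}

#' Simulate per-contig sequencing depths with known mixture weights
#'
#' Every contig of a genome of species `i` receives depth
#' `depthScale * weight_i * eps`, where `eps` is a mean-one multiplicative
#' noise term with coefficient of variation `noiseCv` (gamma-distributed so
#' depths stay positive; `noiseCv = 0` gives exact depths). The planted
#' weights are returned as the truth record.
#'
#' @param genomes A [GenomeSet-class]; `species_id` in its `genomeData`
#'   links genomes to mixture components.
#' @param weights Either a named numeric vector (one sample) or a matrix
#'   with samples as rows and species as columns; each sample's weights
#'   must be non-negative and sum to 1.
#' @param depthScale Mean depth scale (x-fold, > 0).
#' @param noiseCv Coefficient of variation of the depth noise (>= 0).
#' @param seed Integer seed.
#' @return A list: `depths` (data.frame `sample_id`, `contig_id`, `length`,
#'   `depth`) and `truth` (matrix of planted sample weights).
#' @export
simulateDepths <- function(genomes, weights, depthScale = 30, noiseCv = 0,
                           seed = NULL) {
    stopifnot(is(genomes, "GenomeSet"), depthScale > 0, noiseCv >= 0)
    if (is.null(dim(weights)))
        weights <- matrix(weights, nrow = 1,
                          dimnames = list("s1", names(weights)))
    if (any(weights < 0)) stop("negative mixture weight")
    if (any(abs(rowSums(weights) - 1) > 1e-9))
        stop("each sample's weights must sum to 1")
    gd <- genomeData(genomes)
    species <- setNames(gd$species_id, gd$genome_id)
    if (!all(colnames(weights) %in% unique(species)))
        stop("weights name species absent from the GenomeSet")
    contigs <- genomes@contigs
    cg <- sub("\\|[^|]*$", "", names(contigs))
    csp <- species[cg]
    keepC <- csp %in% colnames(weights)
    .withSeed(seed, {
        tabs <- lapply(rownames(weights), function(smp) {
            w <- weights[smp, ][csp[keepC]]
            mu <- depthScale * as.numeric(w)
            eps <- if (noiseCv == 0) rep(1, length(mu))
                   else rgamma(length(mu), shape = 1 / noiseCv^2,
                               rate = 1 / noiseCv^2)
            data.frame(sample_id = smp,
                       contig_id = names(contigs)[keepC],
                       length = width(contigs)[keepC],
                       depth = mu * eps)
        })
        list(depths = do.call(rbind, tabs), truth = weights)
    })
}
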