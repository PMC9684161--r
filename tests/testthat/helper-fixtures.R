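## shared fixtures and independent oracles, built in code

.STANDARD_AA_TEST <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu",
                       "Gly", "His", "Ile", "Leu", "Lys", "Met", "Phe",
                       "Pro", "Ser", "Thr", "Trp", "Tyr", "Val")

## brute-force N50: largest L among the observed lengths such that
## contigs >= L cover at least half the assembly
oracleN50 <- function(lengths) {
    cand <- sort(unique(lengths), decreasing = TRUE)
    for (L in cand) if (sum(lengths[lengths >= L]) >= sum(lengths) / 2) return(L)
    min(lengths)
}

## brute-force Mash-style Jaccard: bottom-min(s, |union|) of the union,
## then the fraction of those present in both sets
oracleBottomJaccard <- function(a, b, s) {
    u <- sort(union(a, b))
    m <- u[seq_len(min(s, length(u)))]
    sum(m %in% a & m %in% b) / length(m)
}

## exhaustive rank-sum representative: enumerate members, compute the five
## competition ranks column by column, return the argmin (ties -> first id
## in lexicographic order)
oracleRankSumRep <- function(metrics) {
    ids <- sort(rownames(metrics))
    m <- metrics[ids, ]
    compRank <- function(x, dec) {
        if (dec) x <- -x
        vapply(x, function(v) sum(x < v) + 1L, integer(1))
    }
    rs <- compRank(m$completeness, TRUE) + compRank(m$contamination, FALSE) +
        compRank(m$mean_depth, TRUE) + compRank(m$strain_heterogeneity, FALSE) +
        compRank(m$n50, TRUE)
    ids[which.min(rs)]
}

## exhaustive canonical k-mer enumeration (tiny sequences only)
oracleCanonicalKmers <- function(seq, k) {
    n <- nchar(seq)
    if (n < k) return(character(0))
    kmers <- substring(seq, seq_len(n - k + 1), seq_len(n - k + 1) + k - 1)
    kmers <- kmers[!grepl("[^ACGT]", kmers)]
    rc <- vapply(kmers, function(x)
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(x))),
        character(1))
    unique(pmin(kmers, rc))
}

## small planted community reused across tests
tinyCommunity <- function(nSpecies = 4, genomeLength = 3e4, seed = 42)
    simulateCommunity(nSpecies = nSpecies, genomeLength = genomeLength,
                      strainRange = c(2L, 3L), seed = seed)

## random uSGB metric table for rank-sum checks
randomMetricsTable <- function(n, allowTies = TRUE) {
    draw <- function(vals) if (allowTies) sample(vals, n, replace = TRUE)
                           else sample(vals, n)
    data.frame(
        completeness = draw(seq(50, 100, by = 0.5)),
        contamination = draw(seq(0, 10, by = 0.25)),
        mean_depth = draw(seq(1, 100, by = 1)),
        strain_heterogeneity = draw(seq(0, 50, by = 0.5)),
        n50 = draw(seq(1e3, 1e5, by = 500)),
        row.names = paste0("g", sprintf("%02d", seq_len(n))))
}
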