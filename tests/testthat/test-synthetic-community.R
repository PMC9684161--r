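test_that("simulateGenome is seeded, hits its GC target, rejects bad input", {
    g1 <- simulateGenome(10000, gc = 0.5, seed = 7)
    g2 <- simulateGenome(10000, gc = 0.5, seed = 7)
    expect_identical(as.character(g1), as.character(g2))
    expect_equal(Biostrings::width(g1), 10000)

    g <- simulateGenome(1e5, gc = 0.30, seed = 1)
    freq <- Biostrings::alphabetFrequency(g[[1]])
    gc <- sum(freq[c("C", "G")]) / 1e5
    expect_gte(gc, 0.28)
    expect_lte(gc, 0.32)

    expect_error(simulateGenome(0), "positive")
    expect_error(simulateGenome(1000, gc = 1.2))
})

test_that("mutateStrain substitutes at the requested rate, deterministically", {
    g <- simulateGenome(1e5, gc = 0.45, seed = 2)
    expect_identical(as.character(mutateStrain(g, 0, seed = 1)),
                     as.character(g))

    m1 <- mutateStrain(g, 0.05, seed = 9)
    m2 <- mutateStrain(g, 0.05, seed = 9)
    expect_identical(as.character(m1), as.character(m2))

    diffs <- sum(strsplit(as.character(g[[1]]), "")[[1]] !=
                 strsplit(as.character(m1[[1]]), "")[[1]])
    ## central 99.9% interval of Binomial(1e5, 0.05)
    expect_gte(diffs, 4775)
    expect_lte(diffs, 5225)

    expect_error(mutateStrain(g, 0.5), "rate")
    expect_error(mutateStrain(g, -0.01), "rate")
})

test_that("degradeToMag honours completeness, min contig length and truth metadata", {
    g <- simulateGenome(1e5, gc = 0.5, seed = 3)

    ## identity case: full completeness keeps the parent content
    full <- degradeToMag(g, 100, seed = 1)
    expect_identical(paste(as.character(full), collapse = ""),
                     as.character(g[[1]]))
    expect_equal(S4Vectors::metadata(full)$completeness, 100)

    mag <- degradeToMag(g, 60, seed = 4)
    tot <- sum(Biostrings::width(mag))
    expect_gte(tot, 59000)
    expect_lte(tot, 61000)
    expect_true(all(Biostrings::width(mag) >= 1500))
    expect_equal(S4Vectors::metadata(mag)$completeness, 60, tolerance = 0.011)

    ## retained segments are genuine substrings of the parent
    expect_true(all(vapply(as.character(mag), function(s)
        grepl(s, as.character(g[[1]]), fixed = TRUE), logical(1))))

    expect_error(degradeToMag(g, 1), "minimum contig")
})

test_that("contamination injects whole foreign contigs and records the truth", {
    g <- simulateGenome(5e4, gc = 0.5, seed = 5)
    src <- simulateGenome(5e4, gc = 0.5, seed = 6)
    mag <- degradeToMag(g, 80, contaminationSources = list(src),
                        contamination = 10, seed = 7)
    md <- S4Vectors::metadata(mag)
    expect_equal(md$completeness, 80, tolerance = 0.011)
    expect_gte(md$contamination, 10)      # whole contigs: slight overshoot only
    expect_lte(md$contamination, 10 + 100 * 4500 / 40000)
    expect_true(all(Biostrings::width(mag) >= 1500))
    expect_error(degradeToMag(g, 80, contamination = 10), "sources")
})

test_that("simulateDepths realizes planted weights and is seeded", {
    com <- tinyCommunity(nSpecies = 2, genomeLength = 2e4, seed = 1)
    gs <- com$genomes
    ids <- genomeIds(gs)[!duplicated(genomeData(gs)$species_id)]
    reps <- gs[ids]

    ## symmetric weights, no noise: all depths equal
    eq <- simulateDepths(reps, c(sp01 = 0.5, sp02 = 0.5), depthScale = 20,
                         noiseCv = 0, seed = 1)
    expect_true(all(eq$depths$depth == eq$depths$depth[1]))

    ## 3:1 weights: exact 3x depth ratio between species
    sk <- simulateDepths(reps, c(sp01 = 0.75, sp02 = 0.25), depthScale = 20,
                         noiseCv = 0, seed = 1)
    spOf <- setNames(genomeData(reps)$species_id, genomeIds(reps))
    d1 <- sk$depths$depth[spOf[sub("\\|.*", "", sk$depths$contig_id)] == "sp01"][1]
    d2 <- sk$depths$depth[spOf[sub("\\|.*", "", sk$depths$contig_id)] == "sp02"][1]
    expect_equal(d1 / d2, 3)

    a <- simulateDepths(reps, c(sp01 = 0.5, sp02 = 0.5), noiseCv = 0.2, seed = 5)
    b <- simulateDepths(reps, c(sp01 = 0.5, sp02 = 0.5), noiseCv = 0.2, seed = 5)
    expect_identical(a$depths, b$depths)

    expect_error(simulateDepths(reps, c(sp01 = 1.5, sp02 = -0.5)), "negative")
    expect_error(simulateDepths(reps, c(sp01 = 0.6, sp02 = 0.6)), "sum to 1")
})

test_that("planted intra-species target ANI matches the strain construction", {
    com <- tinyCommunity(nSpecies = 3, genomeLength = 3e4, seed = 8)
    ta <- com$truth$target_ani
    expect_true(all(ta$target_ani >= 97))
    ## every genome appears exactly once in the species map
    expect_setequal(names(com$truth$genome_to_species), genomeIds(com$genomes))
    expect_false(anyDuplicated(names(com$truth$genome_to_species)) > 0)
})
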