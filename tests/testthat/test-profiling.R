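test_that("genomeDepth is the length-weighted mean of contig depths", {
    tab <- data.frame(sample_id = "s1",
                      contig_id = c("gA|1", "gA|2", "gB|1"),
                      length = c(1000, 3000, 2000),
                      depth = c(10, 20, 0))
    map <- c("gA|1" = "gA", "gA|2" = "gA", "gB|1" = "gB")
    gd <- genomeDepth(tab, map, "s1")
    expect_equal(gd[["gA"]], 17.5)
    expect_equal(gd[["gB"]], 0)

    one <- genomeDepth(tab[3, ], map, "s1")
    expect_equal(one[["gB"]], 0)   # single contig: its own depth
    expect_equal(genomeDepth(tab[1, ], map["gA|1"], "s1")[["gA"]], 10)

    expect_error(genomeDepth(transform(tab, contig_id = c("x", "gA|2", "gB|1")),
                             map, "s1"), "unmapped")
})

test_that("relativeAbundance normalizes representative depths and flags empties", {
    g2s <- c(gA = "SGB0001", gB = "SGB0002")
    expect_equal(as.numeric(relativeAbundance(c(gA = 10, gB = 10), g2s)),
                 c(0.5, 0.5))
    expect_equal(as.numeric(relativeAbundance(c(gA = 30, gB = 10), g2s)),
                 c(0.75, 0.25))
    empty <- relativeAbundance(c(gA = 0, gB = 0), g2s)
    expect_true(isTRUE(attr(empty, "flagged_empty")))
    expect_error(relativeAbundance(c(gA = -1, gB = 1), g2s), "negative")
})

test_that("richness counts strictly above the 0.1% threshold", {
    expect_equal(richness(c(0.5, 0.3, 0.0005)), 2)
    expect_equal(richness(rep(0.01, 100)), 100)
    expect_equal(richness(numeric(0)), 0)
    expect_equal(richness(c(0.001, 0.999)), 1)   # exactly at threshold excluded
})

test_that("unknownFraction splits richness and abundance by uSGB membership", {
    gd <- data.frame(
        genome_id = c("k1", "k2", "u1"), is_reference = c(TRUE, TRUE, FALSE),
        is_oral_reference = FALSE, is_oral_mag = c(FALSE, FALSE, TRUE),
        completeness = 95, contamination = 1, mean_depth = 10,
        strain_heterogeneity = 1, n50 = 1e4, genome_length = 1e6)
    cat0 <- assembleCatalog(c(k1 = 1L, k2 = 2L, u1 = 3L), gd)
    kindOf <- setNames(sgbData(cat0)$kind, sgbData(cat0)$representative_id)
    sgbOf <- setNames(sgbIds(cat0), sgbData(cat0)$representative_id)

    prof <- setNames(c(0.3, 0.3, 0.4), sgbOf[c("k1", "k2", "u1")])
    uf <- unknownFraction(prof, cat0)
    expect_equal(uf[["richness_share"]], 1 / 3)
    expect_equal(uf[["abundance_share"]], 0.4)

    allU <- setNames(1, sgbOf[["u1"]])
    expect_equal(unname(unknownFraction(allU, cat0)), c(1, 1))
    noU <- setNames(c(0.5, 0.5), sgbOf[c("k1", "k2")])
    expect_equal(unname(unknownFraction(noU, cat0)), c(0, 0))
    expect_error(unknownFraction(c(SGB9999 = 1), cat0), "unknown sgb")
})

test_that("brayCurtis worked values, symmetry, and agreement with vegan", {
    p <- c(a = 0.5, b = 0.5); q <- c(a = 1)
    expect_equal(brayCurtis(p, p), 0)
    expect_equal(brayCurtis(c(a = 1), c(b = 1)), 1)   # disjoint supports
    expect_equal(brayCurtis(p, q), 0.5)
    expect_equal(brayCurtis(p, q), brayCurtis(q, p))
    expect_warning(expect_true(is.na(brayCurtis(c(a = 0), c(a = 0)))), "all-zero")

    set.seed(31)
    for (i in 1:20) {
        x <- runif(8); y <- runif(8)
        names(x) <- names(y) <- paste0("s", 1:8)
        ref <- as.numeric(vegan::vegdist(rbind(x, y), method = "bray"))
        expect_equal(brayCurtis(x, y), ref)
        expect_gte(brayCurtis(x / sum(x), y / sum(y)), 0)
        expect_lte(brayCurtis(x / sum(x), y / sum(y)), 1)
    }
})

test_that("profiles recover planted mixture weights and ignore depth rescaling", {
    com <- tinyCommunity(nSpecies = 4, genomeLength = 3e4, seed = 17)
    res <- buildCatalog(com$genomes)
    reps <- com$genomes[unname(representativeIds(res$catalog))]
    w <- matrix(c(0.4, 0.3, 0.2, 0.1,
                  0.25, 0.25, 0.25, 0.25), 2, 4, byrow = TRUE,
                dimnames = list(c("s1", "s2"), paste0("sp0", 1:4)))
    sim <- simulateDepths(reps, w, depthScale = 25, noiseCv = 0, seed = 5)
    prof <- profileSamples(sim$depths, res$catalog,
                           setNames(sub("\\|.*", "", unique(sim$depths$contig_id)),
                                    unique(sim$depths$contig_id)))
    expect_equal(rowSums(prof), c(s1 = 1, s2 = 1))
    spOf <- setNames(genomeData(reps)$species_id, genomeIds(reps))
    sgbSpecies <- spOf[representativeIds(res$catalog)[colnames(prof)]]
    for (smp in rownames(prof))
        expect_equal(unname(prof[smp, ]), unname(w[smp, sgbSpecies]),
                     tolerance = 1e-6)

    ## uniform rescaling of a sample's depths leaves the profile unchanged
    sc <- sim$depths; sc$depth <- sc$depth * 7.3
    prof2 <- profileSamples(sc, res$catalog,
                            setNames(sub("\\|.*", "", unique(sc$contig_id)),
                                     unique(sc$contig_id)))
    expect_equal(prof2, prof)
})
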