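mkDist <- function(ids, fill = 0) {
    d <- matrix(fill, length(ids), length(ids), dimnames = list(ids, ids))
    diag(d) <- 0
    d
}

test_that("average-linkage precluster cut behaves at and around the cutoff", {
    ids <- c("A", "B", "C")
    d <- mkDist(ids, 0.01)
    expect_equal(length(unique(precluster(d))), 1)   # all below cutoff

    d2 <- mkDist(ids, 0.20)
    d2["A", "B"] <- d2["B", "A"] <- 0.01
    p2 <- precluster(d2)
    expect_equal(p2[["A"]], p2[["B"]])
    expect_false(p2[["C"]] == p2[["A"]])

    d3 <- mkDist(ids, 0.5)
    expect_equal(length(unique(precluster(d3))), 3)   # all singletons

    ## boundary: a pair at exactly the cutoff distance merges
    d4 <- mkDist(c("A", "B"), 0.05)
    expect_equal(length(unique(precluster(d4, cutoff = 0.05))), 1)

    bad <- mkDist(ids, 0.1); bad["A", "B"] <- 0.2
    expect_error(precluster(bad), "symmetric")
    expect_error(precluster(mkDist(ids, 1.5)), "distances")
})

test_that("precluster matches hand-computed UPGMA on a 4-genome case", {
    ## two tight pairs, cross distances straddling the cutoff via averages:
    ## heights: (A,B)=0.02, (C,D)=0.03, ({A,B},{C,D})=mean(0.2,...)
    ids <- c("A", "B", "C", "D")
    d <- mkDist(ids, 0.2)
    d["A", "B"] <- d["B", "A"] <- 0.02
    d["C", "D"] <- d["D", "C"] <- 0.03
    p <- precluster(d, cutoff = 0.05)
    expect_equal(p[["A"]], p[["B"]])
    expect_equal(p[["C"]], p[["D"]])
    expect_false(p[["A"]] == p[["C"]])
})

test_that("kSGB/uSGB labeling follows reference membership", {
    expect_equal(labelKind(c("g1", "g2", "r1"), c("r1", "r2")), "kSGB")
    expect_equal(labelKind(c("g1", "g2"), c("r1", "r2")), "uSGB")
    expect_equal(labelKind(c("g1", "g2"), character(0)), "uSGB")
})

test_that("representative selection: worked rank-sum case and kSGB size rule", {
    m <- data.frame(
        completeness = c(95, 90, 99), contamination = c(1, 0.5, 4),
        mean_depth = c(30, 50, 10), strain_heterogeneity = c(5, 2, 10),
        n50 = c(5e4, 4e4, 6e4), genome_length = c(2e6, 1e6, 3e6),
        row.names = c("A", "B", "C"))
    ## rank sums A=10, B=9, C=11
    expect_equal(selectRepresentative(c("A", "B", "C"), "uSGB", m), "B")

    mk <- data.frame(genome_length = c(2.1e6, 1.8e6), row.names = c("x", "y"))
    expect_equal(selectRepresentative(c("x", "y"), "kSGB", mk), "x")

    expect_equal(selectRepresentative("A", "uSGB", m), "A")   # singleton
    expect_error(selectRepresentative(c("A", "Z"), "uSGB", m), "missing")
})

test_that("rank-sum winner matches exhaustive enumeration on random tables", {
    set.seed(123)
    for (i in 1:300) {
        m <- randomMetricsTable(sample(2:8, 1))
        expect_equal(selectRepresentative(rownames(m), "uSGB", m),
                     oracleRankSumRep(m))
    }
})

test_that("refinement pair listing respects the candidate cutoff", {
    ids <- c("r1", "r2", "r3")
    d <- mkDist(ids, 0.5)
    d["r1", "r2"] <- d["r2", "r1"] <- 0.02
    pr <- refinementPairs(ids, d, candidateCutoff = 0.10)
    expect_equal(nrow(pr), 1)
    expect_equal(c(pr$id1, pr$id2), c("r1", "r2"))

    expect_equal(nrow(refinementPairs(ids, d, candidateCutoff = 1.0)), 3)
    expect_equal(nrow(refinementPairs(ids, mkDist(ids, 0.5), 0.10)), 0)
})

test_that("complete-linkage ANI merging honours the 95% boundary and coverage gate", {
    part <- c(x1 = 1L, x2 = 1L, y1 = 2L, z1 = 3L)
    reps <- c("1" = "x1", "2" = "y1", "3" = "z1")
    ani <- data.frame(id1 = c("x1", "y1", "x1"), id2 = c("y1", "z1", "z1"),
                      ani = c(97, 96, 94), coverage = 0.8, defined = TRUE)
    merged <- mergeByAni(part, reps, ani)
    ## complete linkage: {X,Y} merge at 3; adding Z needs max(4,6)=6 > 5
    expect_equal(merged[["x1"]], merged[["y1"]])
    expect_equal(merged[["x2"]], merged[["x1"]])   # whole pre-cluster moves
    expect_false(merged[["z1"]] == merged[["x1"]])

    ## high ANI but low coverage: no merge
    ani2 <- data.frame(id1 = "x1", id2 = "y1", ani = 99, coverage = 0.2,
                       defined = TRUE)
    m2 <- mergeByAni(part, reps, ani2)
    expect_false(m2[["x1"]] == m2[["y1"]])

    ## no candidate pairs: partition unchanged (up to relabeling)
    m3 <- mergeByAni(part, reps, ani2[0, ])
    expect_equal(length(unique(m3)), 3)

    ## idempotence: re-running on its own output changes nothing
    reps2 <- setNames(c("x1", "z1"), c(merged[["x1"]], merged[["z1"]]))
    m4 <- mergeByAni(merged, reps2, ani)
    expect_equal(length(unique(m4)), length(unique(merged)))
})

test_that("exact 95% ANI does not merge (the boundary is strict)", {
    part <- c(a = 1L, b = 2L)
    reps <- c("1" = "a", "2" = "b")
    atBoundary <- data.frame(id1 = "a", id2 = "b", ani = 95, coverage = 0.9,
                             defined = TRUE)
    m <- mergeByAni(part, reps, atBoundary)
    expect_equal(length(unique(m)), 2)
    justAbove <- transform(atBoundary, ani = 95.01)
    expect_equal(length(unique(mergeByAni(part, reps, justAbove))), 1)
})

test_that("catalog assembly sets kind, oral flag, stable ids and partitions members", {
    gd <- data.frame(
        genome_id = c("m1", "m2", "r1", "m3"),
        is_reference = c(FALSE, FALSE, TRUE, FALSE),
        is_oral_reference = c(FALSE, FALSE, TRUE, FALSE),
        is_oral_mag = c(TRUE, TRUE, FALSE, FALSE),
        completeness = c(90, 80, 100, 70), contamination = c(1, 2, 0, 3),
        mean_depth = c(10, 20, 5, 8), strain_heterogeneity = c(1, 2, 0, 3),
        n50 = c(4e4, 3e4, 5e4, 2e4), genome_length = c(2e6, 1e6, 3e6, 1e6))
    part <- c(m1 = 1L, m2 = 1L, r1 = 1L, m3 = 2L)
    cat1 <- assembleCatalog(part, gd)
    d <- as.data.frame(cat1)
    expect_setequal(unlist(sgbMembers(cat1)), names(part))
    kcl <- d[grepl("r1", d$member_ids), ]
    expect_equal(kcl$kind, "kSGB")
    expect_equal(kcl$representative_id, "r1")   # largest genome wins for kSGB
    expect_true(kcl$oral)
    ucl <- d[!grepl("r1", d$member_ids), ]
    expect_equal(ucl$kind, "uSGB")
    expect_false(ucl$oral)    # m3 is neither oral MAG nor oral reference

    ## one genome total -> one singleton SGB
    single <- assembleCatalog(c(m1 = 1L), gd[1, , drop = FALSE])
    expect_equal(sgbData(single)$n_members, 1L)

    expect_error(assembleCatalog(c(m1 = 1L, m1 = 2L), gd), "overlap")
})

test_that("planted species are recovered exactly on a small community", {
    com <- tinyCommunity(nSpecies = 5, genomeLength = 3e4, seed = 7)
    res <- buildCatalog(com$genomes)
    truth <- com$truth$genome_to_species[names(res$partition)]
    expect_equal(mclust::adjustedRandIndex(res$partition, truth), 1.0)
    ## every genome lands in exactly one SGB
    expect_setequal(unlist(sgbMembers(res$catalog)), genomeIds(com$genomes))
})
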