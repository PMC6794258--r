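fakeSketch <- function(hashes, magId = "m", k = 21, s = 1000, seed = 42)
    new("MashSketch", magId = magId, k = k, sketchSize = s, seed = seed,
        hashes = as.numeric(sort(hashes)), nSkipped = 0)

test_that("sketching is deterministic and respects k and s", {
    g <- makeGenome(10000, seed = 1)
    a <- sketchSequence(g, magId = "a")
    b <- sketchSequence(g, magId = "b")
    expect_identical(a@hashes, b@hashes)
    # 10 kb random sequence holds far more than 1000 distinct 21-mers
    expect_length(a@hashes, 1000)
    expect_false(is.unsorted(a@hashes, strictly = TRUE))
    # sequence of length k yields exactly one hash
    one <- sketchSequence(substr(as.character(g), 1, 21))
    expect_length(one@hashes, 1)
    expect_error(sketchSequence("ACGT", k = 21), "shorter than k")
    # different seeds give different sketches
    expect_false(identical(sketchSequence(g, seed = 1)@hashes,
                           sketchSequence(g, seed = 2)@hashes))
})

test_that("ambiguous bases are skipped and counted", {
    s <- paste0(strrep("ACGT", 20), "N", strrep("ACGT", 20))
    sk <- sketchSequence(s, k = 5, s = 100)
    expect_gt(sk@nSkipped, 0)
    # hashes only from ACGT windows: same set as the N-free concatenation
    # of the two flanks' k-mers
    left <- sketchSequence(strrep("ACGT", 20), k = 5, s = 100)
    expect_true(all(sk@hashes %in% left@hashes))
})

test_that("mash distance follows the Jaccard formula with its caps", {
    a <- fakeSketch(1:1000)
    expect_equal(mashDistance(a, a), 0)
    # disjoint sketches: j = 0 is capped at distance 1
    b <- fakeSketch(2001:3000)
    expect_equal(mashDistance(a, b), 1)
    # shared 212 of the 1000 smallest union hashes: D ~ 0.0500
    c <- fakeSketch(c(1:212, 10001:10788))
    expect_equal(sketchJaccard(a, c), 0.212)
    expect_equal(mashDistance(a, c), 0.05001, tolerance = 1e-3)
    # symmetry
    expect_equal(mashDistance(a, c), mashDistance(c, a))
    # incompatible sketches error
    expect_error(mashDistance(a, fakeSketch(1:10, k = 15)), "different")
    expect_error(mashDistance(a, fakeSketch(1:10, seed = 7)), "different")
})

test_that("sketch Jaccard tracks the exact canonical k-mer Jaccard", {
    # brute-force oracle on 5 kb pairs across a divergence range
    for (i in 1:6) {
        g <- makeGenome(5000, seed = 300 + i)
        m <- mutateGenome(g, c(0.005, 0.01, 0.02, 0.03, 0.05, 0.08)[i],
                          seed = 400 + i)
        est <- sketchJaccard(sketchSequence(g), sketchSequence(m))
        exact <- exactCanonicalJaccard(g, m, k = 21)
        expect_lt(abs(est - exact), 0.05)
    }
})

test_that("mean mash distance recovers simulated divergence", {
    for (p in c(0.01, 0.03, 0.05)) {
        ds <- vapply(1:20, function(i) {
            pair <- makeGenomePair(50000, p, seed = 1000 * p * 100 + i)
            mashDistance(sketchSequence(pair$a), sketchSequence(pair$b))
        }, numeric(1))
        expect_lt(abs(mean(ds) - p), 0.01)
    }
})

test_that("single-linkage clustering forms connected components", {
    D <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
    D[upper.tri(D)] <- D[lower.tri(D)] <- 0.01
    cl <- clusterMags(D)
    expect_equal(length(unique(cl$cluster_id)), 1)

    # chain A-B 0.04, B-C 0.04, A-C 0.08: one component
    D2 <- D
    D2["A", "B"] <- D2["B", "A"] <- 0.04
    D2["B", "C"] <- D2["C", "B"] <- 0.04
    D2["A", "C"] <- D2["C", "A"] <- 0.08
    expect_equal(length(unique(clusterMags(D2)$cluster_id)), 1)
    # complete linkage splits the chain
    expect_equal(length(unique(clusterMags(D2,
        linkage = "complete")$cluster_id)), 2)

    # all pairs above threshold: singletons
    D3 <- D
    D3[upper.tri(D3)] <- D3[lower.tri(D3)] <- 0.2
    expect_equal(length(unique(clusterMags(D3)$cluster_id)), 3)

    asym <- D
    asym[1, 2] <- 0.9
    expect_error(clusterMags(asym), "symmetric")
})

test_that("cluster labels are invariant to MAG input order", {
    set.seed(77)
    n <- 8
    ids <- sprintf("mag%02d", 1:n)
    D <- matrix(runif(n * n, 0, 0.2), n, n, dimnames = list(ids, ids))
    D <- (D + t(D)) / 2
    diag(D) <- 0
    cl1 <- clusterMags(D)
    perm <- sample(n)
    cl2 <- clusterMags(D[perm, perm])
    m1 <- setNames(cl1$cluster_id, cl1$mag_id)
    m2 <- setNames(cl2$cluster_id, cl2$mag_id)
    expect_identical(m1[ids], m2[ids])
})

test_that("quality gates match the stated rules at their boundaries", {
    qual <- function(...) {
        vals <- list(...)
        data.frame(mag_id = names(vals),
                   completeness = vapply(vals, `[[`, numeric(1), 1),
                   contamination = vapply(vals, `[[`, numeric(1), 2))
    }
    clus <- function(mags, id = "mc_1")
        data.frame(mag_id = mags, cluster_id = id)

    # multi-MAG: fewer than two members at >=70% completeness -> excluded
    q1 <- qual(a = c(65, 1), b = c(60, 1), c = c(55, 1))
    expect_false(qualityFilter(clus(c("a", "b", "c")), q1)$retained)
    # exactly two at the 70 boundary -> retained (>= 70)
    q2 <- qual(a = c(70, 1), b = c(70, 1), c = c(10, 50))
    expect_true(qualityFilter(clus(c("a", "b", "c")), q2)$retained)
    q3 <- qual(a = c(90, 1), b = c(69.9, 1))
    expect_false(qualityFilter(clus(c("a", "b")), q3)$retained)

    # singleton: excluded only when completeness <= 70 AND contamination >= 10
    expect_false(qualityFilter(clus("a"), qual(a = c(50, 12)))$retained)
    expect_true(qualityFilter(clus("a"), qual(a = c(80, 5)))$retained)
    expect_true(qualityFilter(clus("a"), qual(a = c(50, 9.9)))$retained)
    expect_true(qualityFilter(clus("a"), qual(a = c(70.1, 50)))$retained)
    expect_false(qualityFilter(clus("a"), qual(a = c(70, 10)))$retained)

    expect_error(qualityFilter(clus(c("a", "zzz")), qual(a = c(80, 1))),
                 "quality record")
})

test_that("representatives are the two most complete members with tie-breaks", {
    q <- data.frame(mag_id = c("A", "B", "C"),
                    completeness = c(95, 90, 85),
                    contamination = c(1, 1, 1))
    expect_equal(pickRepresentatives(c("A", "B", "C"), q), c("A", "B"))
    expect_equal(pickRepresentatives("A", q), "A")
    qt <- data.frame(mag_id = c("A", "B", "C"),
                     completeness = c(90, 90, 80),
                     contamination = c(2, 1, 1))
    expect_equal(pickRepresentatives(c("A", "B", "C"), qt), c("B", "A"))
    qt2 <- data.frame(mag_id = c("A", "B"),
                      completeness = c(90, 90),
                      contamination = c(1, 1))
    expect_equal(pickRepresentatives(c("B", "A"), qt2), c("A", "B"))
})

test_that("abundance flags use strict thresholds", {
    expect_true(flagAbundant(c(6, 0, 0)))
    expect_false(flagAbundant(c(5, 0, 0)))      # exceeding means strictly
    expect_true(flagAbundant(c(5.01, 0)))
    expect_false(flagAbundant(rep(1, 38)))      # sum exactly 38
    expect_true(flagAbundant(rep(1, 39)))       # sum 39 > 38
    expect_false(flagAbundant(numeric(0)))      # no samples = all zero
    expect_false(flagAbundant(c(4.9, 4.9, 4.9)))
    expect_error(flagAbundant(c(-1, 2)), "negative")
})

test_that("the combined cluster table is coherent", {
    qualities <- data.frame(mag_id = c("m1", "m2", "m3", "m4"),
                            completeness = c(95, 85, 50, 92),
                            contamination = c(1, 2, 30, 3))
    D <- matrix(1, 4, 4,
                dimnames = list(qualities$mag_id, qualities$mag_id))
    diag(D) <- 0
    D["m1", "m2"] <- D["m2", "m1"] <- 0.02
    rpkm_mat <- matrix(c(6, 0, 0, 0, 1, 1, 0, 0), nrow = 4,
                       dimnames = list(qualities$mag_id, c("s1", "s2")))
    tab <- mashClusterTable(D, qualities, rpkm_mat)
    expect_equal(nrow(tab), 4)
    m12 <- tab[tab$mag_id %in% c("m1", "m2"), ]
    expect_true(all(m12$retained))
    expect_true(all(m12$representative))
    # m3 is a low-quality contaminated singleton
    expect_false(tab$retained[tab$mag_id == "m3"])
    # cluster abundance = mean of representatives: (6+0)/2 = 3, (0+1)/2 = .5
    expect_false(tab$abundant[tab$mag_id == "m1"])
    expect_true(tab$retained[tab$mag_id == "m4"])
})
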