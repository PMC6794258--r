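test_that("global-alignment identity behaves at its boundaries", {
    expect_equal(alignmentIdentity("ACGTACGT", "ACGTACGT"), 100)
    # 1 mismatch in 8 columns
    expect_equal(alignmentIdentity("ACGTACGT", "ACGTACGA"), 87.5)
    # end gaps count against identity with the alignment denominator
    expect_lt(alignmentIdentity("ACGTACGT", "ACGT"), 100)
    expect_equal(alignmentIdentity("ACGTACGT", "ACGT",
                                   denominator = "shorter"), 100)
    expect_error(alignmentIdentity("", "ACGT"), "empty")
})

test_that("greedy 95% clustering groups near-identical genes", {
    base <- as.character(makeGenome(300, seed = 50))
    # 2% diverged copies join; 10% diverged founds a new cluster
    close1 <- substituteN(base, 6, seed = 51)
    far <- substituteN(base, 30, seed = 52)
    genes <- susGeneTable(c(base, close1, far),
                          metagenomes = c("s1", "s2", "s3"))
    cl <- clusterSusGenes(genes)
    expect_equal(nrow(cl), 2)
    sizes <- sort(lengths(cl$members))
    expect_equal(as.integer(sizes), c(1L, 2L))

    # identical sequences always co-cluster
    cl2 <- clusterSusGenes(susGeneTable(c(base, base)))
    expect_equal(nrow(cl2), 1)

    expect_error(clusterSusGenes(susGeneTable(c(base, ""))), "empty")
    expect_error(clusterSusGenes(transform(genes,
        kind = c("susC", "susD", "susC"))), "separately")
})

test_that("clustering is order-stable and exact at 100% identity", {
    base <- as.character(makeGenome(240, seed = 60))
    seqs <- c(base, substituteN(base, 4, seed = 61),
              substituteN(base, 40, seed = 62),
              substituteN(base, 42, seed = 63))
    genes <- susGeneTable(seqs)
    ref <- clusterSusGenes(genes)
    memberships <- function(cl) {
        m <- lapply(cl$members, sort)
        m[order(vapply(m, `[[`, character(1), 1))]
    }
    for (perm_seed in 1:3) {
        shuffled <- withr::with_seed(perm_seed,
                                     genes[sample(nrow(genes)), ])
        expect_equal(memberships(clusterSusGenes(shuffled)),
                     memberships(ref))
    }
    # at min identity 100, clusters are exact-equality groups
    dup <- susGeneTable(c(base, base, substituteN(base, 1, seed = 64)))
    cl100 <- clusterSusGenes(dup, pulConfig(ntClusterIdentity = 100))
    expect_equal(nrow(cl100), 2)
})

test_that("representative selection follows the 4-or-3-with-expression rule", {
    base <- as.character(makeGenome(210, seed = 70))
    mkcluster <- function(n_meta) {
        genes <- susGeneTable(rep(base, n_meta),
                              metagenomes = sprintf("s%d", seq_len(n_meta)))
        clusterSusGenes(genes)
    }
    g4 <- susGeneTable(rep(base, 4), metagenomes = paste0("s", 1:4))
    c4 <- selectRepresentatives(clusterSusGenes(g4), g4)
    expect_true(c4$representative)

    g3 <- susGeneTable(rep(base, 3), metagenomes = paste0("s", 1:3))
    cl3 <- clusterSusGenes(g3)
    # three metagenomes without proteome support: not representative
    expect_false(selectRepresentatives(cl3, g3)$representative)
    # with a >=90% aa-identity proteome hit: representative
    hit <- data.frame(cluster_id = cl3$cluster_id, aa_identity = 92)
    expect_true(selectRepresentatives(cl3, g3, hit)$representative)
    # an 85% hit does not rescue it
    weak <- data.frame(cluster_id = cl3$cluster_id, aa_identity = 85)
    expect_false(selectRepresentatives(cl3, g3, weak)$representative)

    g2 <- susGeneTable(rep(base, 2), metagenomes = paste0("s", 1:2))
    cl2 <- clusterSusGenes(g2)
    hit2 <- data.frame(cluster_id = cl2$cluster_id, aa_identity = 99)
    expect_false(selectRepresentatives(cl2, g2, hit2)$representative)

    # boundary: exactly 90% identity counts as support
    edge <- data.frame(cluster_id = cl3$cluster_id, aa_identity = 90)
    expect_true(selectRepresentatives(cl3, g3, edge)$representative)
})

test_that("adding a metagenome occurrence never revokes representative status", {
    base <- as.character(makeGenome(210, seed = 75))
    for (n in 3:6) {
        genes <- susGeneTable(rep(base, n), metagenomes = paste0("s", 1:n))
        cl <- clusterSusGenes(genes)
        hit <- data.frame(cluster_id = cl$cluster_id, aa_identity = 95)
        was <- selectRepresentatives(cl, genes, hit)$representative
        genes2 <- susGeneTable(rep(base, n + 1),
                               metagenomes = paste0("s", 1:(n + 1)))
        cl2 <- clusterSusGenes(genes2)
        hit2 <- data.frame(cluster_id = cl2$cluster_id, aa_identity = 95)
        now <- selectRepresentatives(cl2, genes2, hit2)$representative
        expect_true(!was || now)
    }
})

test_that("the representative member comes from the most complete MAG", {
    base <- as.character(makeGenome(210, seed = 80))
    genes <- susGeneTable(rep(base, 4), metagenomes = paste0("s", 1:4),
                          mags = c("magA", "magB", "magC", NA))
    qual <- data.frame(mag_id = c("magA", "magB", "magC"),
                       completeness = c(80, 95, 90),
                       contamination = c(1, 1, 1))
    cl <- selectRepresentatives(clusterSusGenes(genes), genes,
                                qualities = qual)
    expect_equal(cl$representative_gene,
                 genes$gene_id[genes$source_mag == "magB"][1])
})

test_that("taxonomy voting covers its four outcomes exhaustively", {
    mags <- data.frame(mag_id = sprintf("m%02d", 1:10),
                       cluster_id = c(rep("mc_8", 6), rep("mc_5", 4)))
    clades <- data.frame(cluster_id = c("mc_8", "mc_5", "mc_12",
                                        "mc_35", "mc_40"),
                         clade = c("Formosa", "Polaribacter", "Aurantivirga",
                                   "Polaribacter", "Polaribacter"))
    # 6/10 -> assigned
    v <- voteTaxonomy(mags$mag_id, mags, clades)
    expect_equal(v, list(state = "assigned", value = "mc_8"))

    # 4/3/3 -> putative plurality
    mags2 <- data.frame(mag_id = sprintf("m%02d", 1:10),
                        cluster_id = c(rep("mc_8", 4), rep("mc_5", 3),
                                       rep("mc_12", 3)))
    v2 <- voteTaxonomy(mags2$mag_id, mags2, clades)
    expect_equal(v2, list(state = "putative", value = "mc_8"))

    # 5/5 split within one clade -> clade-level assignment
    mags3 <- data.frame(mag_id = sprintf("m%02d", 1:10),
                        cluster_id = c(rep("mc_35", 5), rep("mc_40", 5)))
    v3 <- voteTaxonomy(mags3$mag_id, mags3, clades)
    expect_equal(v3, list(state = "clade", value = "Polaribacter"))

    # 5/5 split across clades -> unassigned
    mags4 <- data.frame(mag_id = sprintf("m%02d", 1:10),
                        cluster_id = c(rep("mc_8", 5), rep("mc_5", 5)))
    expect_equal(voteTaxonomy(mags4$mag_id, mags4, clades)$state,
                 "unassigned")

    # no votes at all -> unassigned
    expect_equal(voteTaxonomy(c("x", "y"), mags, clades)$state,
                 "unassigned")

    # exactly half with a unique maximum -> assigned
    mags5 <- data.frame(mag_id = sprintf("m%02d", 1:10),
                        cluster_id = c(rep("mc_8", 5), rep("mc_5", 3),
                                       rep("mc_12", 2)))
    expect_equal(voteTaxonomy(mags5$mag_id, mags5, clades),
                 list(state = "assigned", value = "mc_8"))

    # every vote lands in exactly one state over random cases
    states <- replicate(25, {
        n <- sample(1:8, 1)
        mc <- sample(c("mc_8", "mc_5", "mc_35", "mc_40", NA), n,
                     replace = TRUE)
        mm <- data.frame(mag_id = sprintf("r%02d", seq_len(n)),
                         cluster_id = mc)
        voteTaxonomy(mm$mag_id, mm, clades)$state
    })
    expect_true(all(states %in% c("assigned", "putative", "clade",
                                  "unassigned")))
})

test_that("end-to-end dereplication attaches taxonomy and exports FASTA", {
    base <- as.character(makeGenome(300, seed = 90))
    other <- as.character(makeGenome(300, seed = 91))
    genes <- susGeneTable(c(rep(base, 4), other),
                          metagenomes = c(paste0("s", 1:4), "s1"),
                          mags = c("magA", "magA", "magB", "magB", "magC"))
    mags <- data.frame(mag_id = c("magA", "magB", "magC"),
                       cluster_id = c("mc_1", "mc_1", "mc_2"))
    cl <- derepSusGenes(genes, magAssignments = mags)
    expect_equal(nrow(cl), 2)
    big <- cl[which.max(lengths(cl$members)), ]
    expect_true(big$representative)
    expect_equal(big$tax_state, "assigned")
    expect_equal(big$tax_value, "mc_1")

    fa <- tempfile(fileext = ".fasta")
    writeRepresentativeFasta(cl, genes, fa, what = "nt")
    seqs <- Biostrings::readDNAStringSet(fa)
    expect_equal(length(seqs), sum(cl$representative))
})
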