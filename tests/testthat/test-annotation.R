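test_that("domain-hit filtering enforces model coverage and tiered e-values", {
    # 30% model coverage: ali 10-80 of a 300-position model is 0.237
    low_cov <- domHit(ali_from = 10, ali_to = 80, i_evalue = 1e-30)
    expect_equal(nrow(filterDomainHits(low_cov)), 0)
    ok <- domHit(ali_from = 10, ali_to = 250)
    expect_equal(nrow(filterDomainHits(ok)), 1)

    # long alignments (> 80 aa) need i-evalue <= 1e-5
    long_weak <- domHit(ali_from = 1, ali_to = 200, i_evalue = 1e-4)
    expect_equal(nrow(filterDomainHits(long_weak)), 0)
    # short alignments get the looser 1e-3 tier
    short_ok <- domHit(model_length = 100, ali_from = 1, ali_to = 60,
                       i_evalue = 5e-4)
    expect_equal(nrow(filterDomainHits(short_ok)), 1)
    short_weak <- domHit(model_length = 100, ali_from = 1, ali_to = 60,
                         i_evalue = 5e-3)
    expect_equal(nrow(filterDomainHits(short_weak)), 0)

    # empty input passes through
    expect_equal(nrow(filterDomainHits(domHit()[0, ])), 0)
})

test_that("overlapping same-gene hits resolve to the lowest i-evalue", {
    two <- rbind(domHit(model_id = "GH16", i_evalue = 1e-10),
                 domHit(model_id = "GH17", i_evalue = 1e-8))
    kept <- filterDomainHits(two)
    expect_equal(kept$model_id, "GH16")

    # ties: higher bitscore wins, then lexicographic model id
    tie <- rbind(domHit(model_id = "GH17", i_evalue = 1e-10, bitscore = 100),
                 domHit(model_id = "GH16", i_evalue = 1e-10, bitscore = 300))
    expect_equal(filterDomainHits(tie)$model_id, "GH16")
    tie2 <- rbind(domHit(model_id = "GH17", i_evalue = 1e-10),
                  domHit(model_id = "GH16", i_evalue = 1e-10))
    expect_equal(filterDomainHits(tie2)$model_id, "GH16")

    # non-overlapping query regions coexist on one gene
    sep <- rbind(domHit(model_id = "GH16", qry_from = 1, qry_to = 300),
                 domHit(model_id = "PF00884", model_length = 250,
                        qry_from = 400, qry_to = 649))
    expect_equal(nrow(filterDomainHits(sep)), 2)

    # hits on different genes never compete
    diff_gene <- rbind(domHit(gene_id = "g1"), domHit(gene_id = "g2"))
    expect_equal(nrow(filterDomainHits(diff_gene)), 2)
})

test_that("filtering is idempotent and rejects malformed input", {
    hits <- do.call(rbind, lapply(1:30, function(i)
        withr::with_seed(i, domHit(
            gene_id = sample(c("g1", "g2", "g3"), 1),
            model_id = sample(c("GH16", "GH3", "PF00884", "TIGR04056"), 1),
            ali_from = sample(1:150, 1), ali_to = sample(151:300, 1),
            i_evalue = 10^-sample(2:40, 1),
            bitscore = sample(50:500, 1)))))
    once <- filterDomainHits(hits)
    expect_identical(filterDomainHits(once), once)

    expect_error(filterDomainHits(domHit(), genes = data.frame(
        gene_id = "other")), "unknown gene")
    expect_error(filterDomainHits(domHit(ali_from = 1, ali_to = 400)),
                 "coverage")
})

test_that("greedy overlap resolution matches an elimination-style oracle", {
    # oracle: repeatedly take the best-ranked remaining hit and discard
    # everything overlapping it by more than half the shorter region
    oracle <- function(hits, cfg = pulConfig()) {
        len <- hits$ali_to - hits$ali_from + 1
        cov <- len / hits$model_length
        emax <- ifelse(len > cfg@shortAliLen, cfg@evalueLong,
                       cfg@evalueShort)
        hits <- hits[cov >= cfg@minCoverage & hits$i_evalue <= emax, ]
        out <- hits[0, ]
        for (g in unique(hits$gene_id)) {
            pool <- hits[hits$gene_id == g, ]
            while (nrow(pool) > 0) {
                best <- pool[order(pool$i_evalue, -pool$bitscore,
                                   pool$model_id)[1], ]
                out <- rbind(out, best)
                ov <- pmin(pool$qry_to, best$qry_to) -
                    pmax(pool$qry_from, best$qry_from) + 1
                shorter <- pmin(pool$qry_to - pool$qry_from,
                                best$qry_to - best$qry_from) + 1
                pool <- pool[ov <= shorter / 2, ]
            }
        }
        out
    }
    for (seed in 1:5) {
        hits <- do.call(rbind, lapply(1:40, function(i)
            withr::with_seed(seed * 100 + i, {
                from <- sample(1:200, 1)
                domHit(gene_id = sample(c("g1", "g2"), 1),
                       model_id = sample(c("GH16", "GH3", "GH13", "GH92"), 1),
                       ali_from = sample(1:100, 1),
                       ali_to = sample(101:300, 1),
                       qry_from = from, qry_to = from + sample(30:150, 1),
                       i_evalue = 10^-sample(2:40, 1),
                       bitscore = sample(50:500, 1))
            })))
        got <- filterDomainHits(hits)
        want <- oracle(hits)
        key <- function(d) sort(paste(d$gene_id, d$model_id, d$qry_from,
                                      d$i_evalue))
        expect_equal(key(got), key(want))
    }
})

test_that("CAZyme confirmation applies identity, coverage, e-value and family match", {
    hmm <- filterDomainHits(domHit(model_id = "GH16"))
    cfg <- pulConfig()
    expect_equal(confirmCazymes(hmm, simHit(pct = 45, qcov = 0.6,
                                            evalue = 1e-30), cfg)$family,
                 "GH16")
    # each threshold individually fails
    expect_equal(nrow(confirmCazymes(hmm, simHit(pct = 25), cfg)), 0)
    expect_equal(nrow(confirmCazymes(hmm, simHit(qcov = 0.3), cfg)), 0)
    expect_equal(nrow(confirmCazymes(hmm, simHit(evalue = 1e-19), cfg)), 0)
    # similarity hit to a different family does not confirm
    expect_equal(nrow(confirmCazymes(hmm, simHit(family = "GH13"), cfg)), 0)
    # boundary values pass (>=, >=, <=)
    expect_equal(nrow(confirmCazymes(hmm, simHit(pct = 30, qcov = 0.4,
                                                 evalue = 1e-20), cfg)), 1)
})

test_that("families compare at subfamily level only when both carry one", {
    cfg <- pulConfig()
    sub_hmm <- filterDomainHits(domHit(model_id = "GH5_46"))
    # family-level similarity subject confirms a subfamily HMM hit
    expect_equal(confirmCazymes(sub_hmm, simHit(family = "GH5"),
                                cfg)$family, "GH5_46")
    # two different subfamilies do not match
    expect_equal(nrow(confirmCazymes(sub_hmm, simHit(family = "GH5_12"),
                                     cfg)), 0)
    # same subfamily matches
    expect_equal(nrow(confirmCazymes(sub_hmm, simHit(family = "GH5_46"),
                                     cfg)), 1)
})

test_that("confirmation is monotone in its thresholds", {
    hmm <- filterDomainHits(rbind(
        domHit("g1", "GH16"),
        domHit("g2", "GH3", qry_from = 400, qry_to = 699),
        domHit("g3", "GH13")))
    sims <- rbind(simHit("g1", "GH16", pct = 35, qcov = 0.5, evalue = 1e-25),
                  simHit("g2", "GH3", pct = 80, qcov = 0.9, evalue = 1e-60),
                  simHit("g3", "GH13", pct = 31, qcov = 0.41, evalue = 1e-21))
    base <- nrow(confirmCazymes(hmm, sims, pulConfig()))
    expect_equal(base, 3)
    for (cfg in list(pulConfig(minIdentity = 50), pulConfig(minQcov = 0.6),
                     pulConfig(maxEvalue = 1e-30))) {
        expect_lte(nrow(confirmCazymes(hmm, sims, cfg)), base)
    }
})

test_that("role assignment maps models to roles and flags GT-only genes", {
    genes <- rolesTable(rep("", 4))[, 1:7]
    hits <- filterDomainHits(rbind(
        domHit(genes$gene_id[1], "PF00884", model_length = 250),
        domHit(genes$gene_id[2], "TIGR04056", model_length = 700),
        domHit(genes$gene_id[2], "PF12741", model_length = 250,
               qry_from = 800, qry_to = 1049),
        domHit(genes$gene_id[3], "GT2", model_length = 200)))
    confirmed <- confirmCazymes(hits, simHit(genes$gene_id[3], "GT2"))
    ann <- assignRoles(genes, confirmed, hits)
    expect_equal(ann$roles[1], "sulfatase")
    expect_equal(ann$roles[2], "susC,susD")
    expect_equal(ann$roles[3], "cazyme")
    expect_true(ann$is_gt_only[3])
    expect_equal(ann$roles[4], "")
    expect_false(ann$is_gt_only[4])

    # a sulfatase-domain-containing CAZyme carries both roles
    multi <- filterDomainHits(rbind(
        domHit("g1", "GH10", model_length = 300),
        domHit("g1", "PF00884", model_length = 250, qry_from = 400,
               qry_to = 649)))
    ann2 <- assignRoles(rolesTable("")[, 1:7][1, ] |>
                            transform(gene_id = "g1"),
                        confirmCazymes(multi, simHit("g1", "GH10")), multi)
    expect_equal(ann2$roles, "sulfatase,cazyme")
    expect_false(ann2$is_gt_only)
})
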