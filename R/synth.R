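## Synthetic-data generators. Every pipeline input can be produced with
## planted ground truth: random genomes and mutated copies at known
## divergence, contig gene tables with planted loci drawn from the ten
## recurrent locus templates plus decoy near-miss loci, multinomial
## read-count matrices with known true abundances, and spectral-count
## tables with known protein lengths. All randomness derives from an
## explicit seed.

#' Generate a random genome sequence
#'
#' I.i.d. nucleotides with expected GC content \code{gc}.
#'
#' @param length sequence length (bp).
#' @param gc GC fraction in [0, 1].
#' @param seed integer seed; the same seed reproduces the same sequence.
#' @return a \link[Biostrings]{DNAString}.
#' @examples
#' makeGenome(100, gc = 0.4, seed = 1)
#' @export
makeGenome <- function(length, gc = 0.5, seed = 1) {
    if (length <= 0) stop("length must be > 0")
    if (gc < 0 || gc > 1) stop("gc must be in [0, 1]")
    bases <- withr::with_seed(seed,
        sample(c("A", "C", "G", "T"), length, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)))
    Biostrings::DNAString(paste(bases, collapse = ""))
}

#' Mutate a genome at a given substitution divergence
#'
#' Each site is independently substituted to one of the three other bases
#' with probability \code{p}.
#'
#' @param sequence \code{DNAString} or character.
#' @param p per-site substitution probability in [0, 0.75).
#' @param seed integer seed.
#' @return a \code{DNAString}.
#' @export
mutateGenome <- function(sequence, p, seed = 1) {
    if (p < 0 || p >= 0.75) stop("p must be in [0, 0.75)")
    s <- strsplit(as.character(sequence), "")[[1]]
    withr::with_seed(seed, {
        hit <- which(runif(length(s)) < p)
        if (length(hit)) {
            alt <- c("A", "C", "G", "T")
            s[hit] <- vapply(s[hit], function(b)
                sample(setdiff(alt, b), 1), character(1))
        }
    })
    Biostrings::DNAString(paste(s, collapse = ""))
}

#' Generate a genome pair at known divergence
#'
#' @param length genome length (bp).
#' @param divergence per-site substitution probability (1 - ANI).
#' @param gc GC fraction.
#' @param seed integer seed.
#' @return list with \code{a}, \code{b} (\code{DNAString}s) and
#'   \code{realized_divergence} (fraction of differing sites).
#' @export
makeGenomePair <- function(length, divergence, gc = 0.5, seed = 1) {
    a <- makeGenome(length, gc, seed = seed)
    b <- mutateGenome(a, divergence, seed = seed + 1)
    ca <- strsplit(as.character(a), "")[[1]]
    cb <- strsplit(as.character(b), "")[[1]]
    list(a = a, b = b, realized_divergence = mean(ca != cb))
}

#' The ten recurrent locus templates
#'
#' Gene-content templates of the recurrent locus patterns, one per
#' substrate rule: three beta-glucan/laminarin variants, simple and
#' complex alpha-glucan, sulfated and sulfatase-free alpha-mannose-rich,
#' two sulfated-xylan patterns and alginate. Each template is a character
#' vector of gene specs; a spec is a role token (\code{susC}, \code{susD},
#' \code{sulfatase}), a CAZy family, or several joined by \code{+} for a
#' multi-domain gene (e.g. the sulfatase-domain-containing GH10 of the
#' first sulfated-xylan pattern).
#'
#' @return named list of templates; names are substrate rule names.
#' @export
pulTemplates <- function() {
    list(
        beta_glucan_A = c("susC", "susD", "GH16", "GH3", "GH2"),
        beta_glucan_B = c("susC", "susD", "GH16", "GH30_1", "GH17", "GH17"),
        beta_glucan_C = c("susC", "susD", "GH5_46+CBM6", "GH16"),
        alpha_glucan_simple = c("susC", "susD", "GH65", "GH13", "CBM48"),
        alpha_glucan_complex = c("susC", "susD", "GH13", "GH13", "GH13",
                                 "GH65", "GH43_12", "sulfatase"),
        mannose_sulfated = c("susC", "susD", "GH92", "GH92", "GH92",
                             "sulfatase", "sulfatase", "sulfatase",
                             "sulfatase", "GH2", "GH43_2"),
        mannose_sulfatase_free = c("susC", "susD", "GH92", "GH130", "GH20",
                                   "GH18"),
        sulfated_xylan_1 = c("susC", "susD", "GH10+sulfatase", "GH3",
                             "sulfatase", "sulfatase"),
        sulfated_xylan_2 = c("susC", "susD", "GH30", "sulfatase",
                             "sulfatase", "sulfatase", "PL9+CBM22", "GH10",
                             "GH43_1"),
        alginate = c("susC", "susD", "PL6", "PL7", "PL17"))
}

#' Decoy (near-miss) locus modes
#'
#' Each decoy violates exactly one retention rule:
#' \describe{
#'   \item{no_susCD}{markers and degradative CAZymes but no susC/susD
#'     gene.}
#'   \item{one_GHPL}{susC/D pair but only one GH/PL gene.}
#'   \item{sparse}{valid gene content, but the markers sit 10 genes
#'     apart, breaking the chain into fragments of fewer than 3 markers.}
#'   \item{gt_only}{three adjacent confirmed glycosyltransferases only.}
#' }
#'
#' @return character vector of mode names.
#' @export
decoyModes <- function() c("no_susCD", "one_GHPL", "sparse", "gt_only")

# Gene specs for a decoy mode. `NA` entries are plain background genes
# inserted between markers (used by the "sparse" mode to enforce the gap).
decoySpec <- function(mode) {
    switch(mode,
        no_susCD = c("GH16", "GH3", "sulfatase"),
        one_GHPL = c("susC", "susD", "GH16"),
        sparse = c("susC", "susD", rep(NA_character_, 10), "GH16", "GH3"),
        gt_only = c("GT2", "GT4", "GT2"),
        stop("unknown decoy mode: ", mode))
}

parseGeneSpec <- function(spec) {
    tokens <- strsplit(spec, "+", fixed = TRUE)[[1]]
    roles <- tokens[tokens %in% c("susC", "susD", "sulfatase")]
    fams <- tokens[!tokens %in% c("susC", "susD", "sulfatase")]
    list(roles = roles, families = fams)
}

# Truth-level role/family strings for a gene spec (matching assignRoles
# output format).
specRoleString <- function(spec) {
    p <- parseGeneSpec(spec)
    r <- p$roles
    if (length(p$families)) r <- c(r, "cazyme")
    ord <- c("susC", "susD", "sulfatase", "cazyme")
    paste(ord[ord %in% r], collapse = ",")
}

specFamilyString <- function(spec) {
    p <- parseGeneSpec(spec)
    paste(sort(p$families), collapse = ",")
}

## Synthetic evidence rows for one gene spec: domain hits that pass the
## dbCAN-style filter and similarity hits that pass confirmation.
specHits <- function(spec, gene_id) {
    p <- parseGeneSpec(spec)
    dom <- list()
    sim <- list()
    offset <- 1
    addDom <- function(model, mlen) {
        dom[[length(dom) + 1]] <<- data.frame(
            gene_id = gene_id, model_id = model, model_length = mlen,
            ali_from = 1, ali_to = mlen, qry_from = offset,
            qry_to = offset + mlen - 1, i_evalue = 1e-40, bitscore = 400,
            stringsAsFactors = FALSE)
        offset <<- offset + mlen + 10
    }
    for (r in p$roles) {
        model <- switch(r, susC = SUSC_MODEL, susD = SUSD_MODELS[1],
                        sulfatase = SULFATASE_MODEL)
        addDom(model, 250)
    }
    for (f in p$families) {
        addDom(f, 200)
        sim[[length(sim) + 1]] <- data.frame(
            query_gene_id = gene_id, subject_family = f,
            pct_identity = 60, query_coverage = 0.8, evalue = 1e-50,
            stringsAsFactors = FALSE)
    }
    list(dom = do.call(rbind, dom), sim = do.call(rbind, sim))
}

emptyDomHits <- function() data.frame(
    gene_id = character(), model_id = character(),
    model_length = numeric(), ali_from = numeric(), ali_to = numeric(),
    qry_from = numeric(), qry_to = numeric(), i_evalue = numeric(),
    bitscore = numeric(), stringsAsFactors = FALSE)

emptySimHits <- function() data.frame(
    query_gene_id = character(), subject_family = character(),
    pct_identity = numeric(), query_coverage = numeric(),
    evalue = numeric(), stringsAsFactors = FALSE)

#' Plant loci and decoys on synthetic contigs
#'
#' Builds one contig per requested template or decoy: background genes
#' with empty annotation, a planted gene block at a seeded random
#' position, truth-level role labels, and raw synthetic evidence tables
#' (domain hits and similarity hits that pass the annotation filters, plus
#' sub-threshold noise hits on background genes) so both the annotation
#' filter and the locus caller are exercised.
#'
#' @param templates character vector of template names (repeats allowed);
#'   see \code{\link{pulTemplates}}.
#' @param decoys character vector of decoy mode names (repeats allowed);
#'   see \code{\link{decoyModes}}.
#' @param background_genes background genes per contig (split around the
#'   planted block).
#' @param seed integer seed.
#' @param noise_hits number of failing (noise) evidence rows to scatter
#'   over background genes.
#' @return list with \code{genes} (truth-annotated gene table),
#'   \code{dom_hits}, \code{sim_hits} (raw evidence tables), and
#'   \code{truth} (data.frame: contig, span, item name, planted/decoy,
#'   expected substrate label for planted templates).
#' @export
plantPuls <- function(templates = names(pulTemplates()),
                      decoys = character(0), background_genes = 20,
                      seed = 1, noise_hits = 2 * length(templates)) {
    tpl <- pulTemplates()
    bad <- setdiff(templates, names(tpl))
    if (length(bad)) stop("unknown template(s): ", paste(bad, collapse = ", "))
    items <- c(lapply(templates, function(t)
                   list(name = t, type = "planted", spec = tpl[[t]])),
               lapply(decoys, function(d)
                   list(name = d, type = "decoy", spec = decoySpec(d))))
    if (length(items) == 0)
        return(list(genes = data.frame(), dom_hits = emptyDomHits(),
                    sim_hits = emptySimHits(), truth = data.frame()))

    rules <- defaultSubstrateRules()
    labelOf <- function(nm) {
        r <- rules[[which(vapply(rules, `[[`, character(1), "name") == nm)]]
        r$label
    }
    ## sanity: every template must classify as its own rule
    for (t in unique(templates)) {
        fams <- unlist(lapply(tpl[[t]], function(s) parseGeneSpec(s)$families))
        nsulf <- sum(vapply(tpl[[t]], function(s)
            "sulfatase" %in% parseGeneSpec(s)$roles, logical(1)))
        call <- classifySubstrate(fams, nsulf, rules)
        if (!identical(call$variant, t))
            stop("template '", t, "' does not classify as its own rule")
    }

    offsets <- withr::with_seed(seed,
        sample.int(max(1, background_genes), length(items), replace = TRUE))
    genes_l <- list(); dom_l <- list(); sim_l <- list(); truth_l <- list()
    for (i in seq_along(items)) {
        it <- items[[i]]
        contig <- sprintf("contig_%03d", i)
        pre <- min(offsets[i], background_genes)
        post <- background_genes - pre
        specs <- c(rep(NA_character_, pre), it$spec,
                   rep(NA_character_, post))
        n <- length(specs)
        gid <- sprintf("%s_g%03d", contig, seq_len(n) - 1)
        roles <- character(n)
        fams <- character(n)
        real <- which(!is.na(specs))
        roles[real] <- vapply(specs[real], specRoleString, character(1))
        fams[real] <- vapply(specs[real], specFamilyString, character(1))
        famlist <- strsplit(fams, ",", fixed = TRUE)
        gt_only <- vapply(seq_len(n), function(j) {
            f <- famlist[[j]]
            length(f) > 0 && all(grepl("^GT", f)) && roles[j] == "cazyme"
        }, logical(1))
        genes_l[[i]] <- data.frame(
            contig_id = contig, gene_index = seq_len(n) - 1L, gene_id = gid,
            start = (seq_len(n) - 1L) * 1000L + 1L,
            end = (seq_len(n) - 1L) * 1000L + 900L,
            strand = withr::with_seed(seed + i,
                sample(c("+", "-"), n, replace = TRUE)),
            aa_length = 300L, roles = roles, families = fams,
            is_gt_only = gt_only, stringsAsFactors = FALSE)
        for (j in which(!is.na(specs))) {
            h <- specHits(specs[j], gid[j])
            dom_l[[length(dom_l) + 1]] <- h$dom
            if (!is.null(h$sim)) sim_l[[length(sim_l) + 1]] <- h$sim
        }
        marker <- which(roles != "")
        truth_l[[i]] <- data.frame(
            contig_id = contig, name = it$name, type = it$type,
            first_index = min(marker) - 1L, last_index = max(marker) - 1L,
            substrate = if (it$type == "planted") labelOf(it$name)
                        else NA_character_,
            stringsAsFactors = FALSE)
    }
    genes <- do.call(rbind, genes_l)
    dom <- do.call(rbind, dom_l)
    sim <- if (length(sim_l)) do.call(rbind, sim_l) else emptySimHits()

    ## noise: failing evidence on background genes (low coverage or weak
    ## e-value domain hits; low-identity similarity hits)
    bg <- genes$gene_id[genes$roles == ""]
    if (noise_hits > 0 && length(bg) > 0) {
        pick <- withr::with_seed(seed + 7919,
            sample(bg, min(noise_hits, length(bg))))
        noise_dom <- data.frame(
            gene_id = pick, model_id = "GH16", model_length = 300,
            ali_from = 10, ali_to = 80, qry_from = 10, qry_to = 80,
            i_evalue = 5e-4, bitscore = 20, stringsAsFactors = FALSE)
        noise_sim <- data.frame(
            query_gene_id = pick, subject_family = "GH16",
            pct_identity = 22, query_coverage = 0.2, evalue = 1e-5,
            stringsAsFactors = FALSE)
        dom <- rbind(dom, noise_dom)
        sim <- rbind(sim, noise_sim)
    }
    rownames(genes) <- rownames(dom) <- rownames(sim) <- NULL
    list(genes = genes, dom_hits = dom, sim_hits = sim,
         truth = do.call(rbind, truth_l))
}

#' Simulate mapped-read counts
#'
#' Multinomial sampling with per-MAG probabilities proportional to true
#' relative abundance times genome length, independently per sample.
#'
#' @param true_abundances MAGs-by-samples matrix (or vector for one
#'   sample) of relative abundances.
#' @param genome_lengths per-MAG genome lengths (bp or kbp, any common
#'   unit).
#' @param total_reads reads per sample (scalar or per-sample vector).
#' @param seed integer seed.
#' @return MAGs-by-samples integer matrix of mapped-read counts.
#' @export
simulateCounts <- function(true_abundances, genome_lengths, total_reads,
                           seed = 1) {
    ab <- as.matrix(true_abundances)
    if (nrow(ab) != length(genome_lengths))
        stop("one genome length per MAG required")
    if (any(ab < 0) || any(genome_lengths <= 0))
        stop("abundances must be >= 0 and lengths > 0")
    total_reads <- rep_len(total_reads, ncol(ab))
    counts <- withr::with_seed(seed, {
        sapply(seq_len(ncol(ab)), function(s) {
            w <- ab[, s] * genome_lengths
            if (sum(w) == 0) stop("all-zero abundances in sample ", s)
            if (total_reads[s] == 0) return(integer(nrow(ab)))
            rmultinom(1, total_reads[s], w / sum(w))[, 1]
        })
    })
    counts <- as.matrix(counts)
    dimnames(counts) <- dimnames(ab)
    counts
}

#' Simulate spectral counts
#'
#' Multinomial sampling with per-protein probabilities proportional to
#' true expression times protein length (longer proteins yield more
#' spectra at equal molar abundance).
#'
#' @param lengths protein lengths (residues).
#' @param true_expression per-protein relative expression (vector, or
#'   proteins-by-samples matrix).
#' @param total_spectra spectra per sample.
#' @param seed integer seed.
#' @return integer matrix of spectral counts.
#' @export
simulateSpectra <- function(lengths, true_expression, total_spectra,
                            seed = 1) {
    ex <- as.matrix(true_expression)
    if (nrow(ex) != length(lengths))
        stop("one length per protein required")
    total_spectra <- rep_len(total_spectra, ncol(ex))
    counts <- withr::with_seed(seed, {
        sapply(seq_len(ncol(ex)), function(s) {
            w <- ex[, s] * lengths
            if (sum(w) == 0) stop("all-zero expression in sample ", s)
            rmultinom(1, total_spectra[s], w / sum(w))[, 1]
        })
    })
    counts <- as.matrix(counts)
    dimnames(counts) <- dimnames(ex)
    counts
}
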