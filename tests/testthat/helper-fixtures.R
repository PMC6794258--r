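# Fixture builders shared across test files. Everything is generated in
# code; no stored data.

domHit <- function(gene_id = "g1", model_id = "GH16", model_length = 300,
                   ali_from = 1, ali_to = model_length,
                   i_evalue = 1e-30, bitscore = 200,
                   qry_from = ali_from, qry_to = ali_to) {
    data.frame(gene_id = gene_id, model_id = model_id,
               model_length = model_length, ali_from = ali_from,
               ali_to = ali_to, qry_from = qry_from, qry_to = qry_to,
               i_evalue = i_evalue, bitscore = bitscore,
               stringsAsFactors = FALSE)
}

simHit <- function(gene_id = "g1", family = "GH16", pct = 60,
                   qcov = 0.8, evalue = 1e-50) {
    data.frame(query_gene_id = gene_id, subject_family = family,
               pct_identity = pct, query_coverage = qcov, evalue = evalue,
               stringsAsFactors = FALSE)
}

# An annotated gene table for one contig: `roles`/`families` given as
# parallel vectors ("" = background gene).
rolesTable <- function(roles, families = rep("", length(roles)),
                       contig = "c1") {
    n <- length(roles)
    if (n == 0) {
        return(data.frame(contig_id = character(), gene_index = integer(),
                          gene_id = character(), start = integer(),
                          end = integer(), strand = character(),
                          aa_length = integer(), roles = character(),
                          families = character(), is_gt_only = logical(),
                          stringsAsFactors = FALSE))
    }
    contig <- rep_len(contig, n)
    famlist <- strsplit(families, ",", fixed = TRUE)
    data.frame(
        contig_id = contig, gene_index = seq_len(n) - 1L,
        gene_id = sprintf("%s_g%02d", contig, seq_len(n)),
        start = (seq_len(n) - 1L) * 1000L + 1L,
        end = (seq_len(n) - 1L) * 1000L + 900L,
        strand = "+", aa_length = 300L,
        roles = roles, families = families,
        is_gt_only = vapply(seq_len(n), function(i) {
            f <- famlist[[i]]
            length(f) > 0 && all(grepl("^GT", f)) && roles[i] == "cazyme"
        }, logical(1)),
        stringsAsFactors = FALSE)
}

# Place markers (given as role/family spec strings, see pulTemplates())
# at chosen gene indices on a contig of given length.
markersAt <- function(indices, specs, n_genes = max(indices) + 5) {
    roles <- rep("", n_genes)
    fams <- rep("", n_genes)
    for (i in seq_along(indices)) {
        tok <- strsplit(specs[i], "+", fixed = TRUE)[[1]]
        r <- tok[tok %in% c("susC", "susD", "sulfatase")]
        f <- tok[!tok %in% c("susC", "susD", "sulfatase")]
        if (length(f)) r <- c(r, "cazyme")
        roles[indices[i] + 1] <- paste(r, collapse = ",")
        fams[indices[i] + 1] <- paste(f, collapse = ",")
    }
    rolesTable(roles, fams)
}

# Random nucleotide string with exactly n substitutions relative to base.
substituteN <- function(base, n, seed = 1) {
    s <- strsplit(as.character(base), "")[[1]]
    withr::with_seed(seed, {
        pos <- sample(length(s), n)
        alt <- c("A", "C", "G", "T")
        s[pos] <- vapply(s[pos], function(b) sample(setdiff(alt, b), 1),
                         character(1))
    })
    paste(s, collapse = "")
}

susGeneTable <- function(seqs, kind = "susC",
                         metagenomes = rep("s1", length(seqs)),
                         mags = rep(NA_character_, length(seqs)),
                         ids = sprintf("%s_%02d", kind, seq_along(seqs))) {
    data.frame(gene_id = ids, kind = kind, nt_sequence = seqs,
               aa_sequence = vapply(seqs, function(s)
                   as.character(Biostrings::translate(
                       Biostrings::DNAString(substr(s, 1,
                           3 * (nchar(s) %/% 3))),
                       if.fuzzy.codon = "solve")), character(1)),
               source_metagenome = metagenomes, source_mag = mags,
               pul_id = NA_character_, stringsAsFactors = FALSE)
}
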