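## Stage orchestration used by the command-line wrapper
## (inst/scripts/pulseeker) and by the vignette: each stage is a pure
## function of (inputs, config, seed) writing plain TSV/JSON outputs.

#' Per-Mash-cluster PUL repertoire summary
#'
#' Tabular analogue of a repertoire overview: for each Mash-cluster the
#' number of called loci per substrate class.
#'
#' @param pulAssignments data.frame with columns \code{cluster_id} (the
#'   Mash-cluster a locus belongs to) and \code{substrate}.
#' @return data.frame, one row per Mash-cluster, one column per substrate
#'   class plus \code{total}.
#' @export
pulRepertoire <- function(pulAssignments) {
    labels <- c(unname(SUBSTRATE_LABELS), "unknown")
    tab <- table(factor(pulAssignments$cluster_id),
                 factor(pulAssignments$substrate, levels = labels))
    out <- data.frame(cluster_id = rownames(tab),
                      as.data.frame.matrix(tab), check.names = FALSE,
                      row.names = NULL)
    out$total <- rowSums(tab)
    out
}

#' Run the synthetic demonstration pipeline
#'
#' Generates a planted synthetic corpus, writes its raw evidence files,
#' re-reads them, runs annotation, locus calling and substrate
#' classification, and writes the result tables. Deterministic for a
#' given seed; re-running into the same directory reproduces every file.
#'
#' @param outdir output directory (created if needed).
#' @param seed integer seed for the synthetic corpus.
#' @param config a \code{\link{pulConfig}}.
#' @param templates,decoys passed to \code{\link{plantPuls}}.
#' @return (invisibly) list with the annotated gene table, the classified
#'   \linkS4class{PULSet}, the truth table and the output file paths.
#' @export
runSyntheticPipeline <- function(outdir, seed = 1, config = pulConfig(),
                                 templates = names(pulTemplates()),
                                 decoys = decoyModes()) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(outdir, f)
    corpus <- plantPuls(templates = templates, decoys = decoys, seed = seed)
    ## emit raw dialects, then consume them through the standard readers
    bare <- corpus$genes[, c("contig_id", "gene_index", "gene_id", "start",
                             "end", "strand", "aa_length")]
    writeGeneTable(bare, p("genes.tsv"), config)
    writeDomtblout(corpus$dom_hits, p("hits.domtblout"))
    writeBlastTab(corpus$sim_hits, corpus$genes, p("hits.blast6"))
    writeTsv(corpus$truth, p("truth.tsv"))

    genes <- readGeneTable(p("genes.tsv"))
    dom <- readDomtblout(p("hits.domtblout"))
    sim <- readBlastTab(p("hits.blast6"), genes)
    annotated <- annotateGenes(genes, dom, sim, config)
    writeGeneTable(annotated, p("gene_roles.tsv"), config)

    puls <- classifySubstrates(callPuls(annotated, config))
    writePulTable(puls, p("puls.tsv"))
    writePulGff3(puls, p("puls.gff3"))

    jsonlite::write_json(list(seed = seed, n_contigs =
                                  length(unique(genes$contig_id)),
                              n_planted = sum(corpus$truth$type == "planted"),
                              n_decoys = sum(corpus$truth$type == "decoy")),
                         p("manifest.json"), auto_unbox = TRUE)
    invisible(list(genes = annotated, puls = puls, truth = corpus$truth,
                   files = list.files(outdir, full.names = TRUE)))
}

#' Locus recall and precision against planted truth
#'
#' A planted locus counts as recovered when a called locus on the same
#' contig overlaps its gene-index span; a called locus is a true positive
#' under the same condition.
#'
#' @param pulset a \linkS4class{PULSet}.
#' @param truth truth table from \code{\link{plantPuls}}.
#' @return list with \code{recall}, \code{precision}, \code{n_called}.
#' @export
scoreAgainstTruth <- function(pulset, truth) {
    lo <- loci(pulset)
    planted <- truth[truth$type == "planted", , drop = FALSE]
    hit <- function(t_row, l_row)
        lo$contig_id[l_row] == planted$contig_id[t_row] &&
        lo$first_index[l_row] <= planted$last_index[t_row] &&
        lo$last_index[l_row] >= planted$first_index[t_row]
    recovered <- vapply(seq_len(nrow(planted)), function(i)
        any(vapply(seq_len(nrow(lo)), function(j) hit(i, j), logical(1))),
        logical(1))
    true_pos <- vapply(seq_len(nrow(lo)), function(j)
        any(vapply(seq_len(nrow(planted)), function(i) hit(i, j),
                   logical(1))), logical(1))
    list(recall = if (nrow(planted)) mean(recovered) else NA_real_,
         precision = if (nrow(lo)) mean(true_pos) else NA_real_,
         n_called = nrow(lo))
}
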