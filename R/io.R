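## Readers and writers for the pipeline's external dialects: HMMER3
## domtblout, BLAST/DIAMOND tabular (outfmt 6) with a subject-to-family
## sidecar, gene/role/locus TSVs, GFF3 locus features, sketch JSON and
## cluster tables. All TSV writers stamp a provenance header line.

stampHeader <- function(con, config = NULL) {
    ver <- as.character(utils::packageVersion("pulseekR"))
    writeLines(paste0("# pulseekR v", ver,
                      if (!is.null(config))
                          paste0(" | ", configStamp(config)) else ""), con)
}

writeTsv <- function(df, path, config = NULL) {
    ## flatten list columns for TSV output
    for (nm in names(df)) {
        if (is.list(df[[nm]]))
            df[[nm]] <- vapply(df[[nm]], paste, character(1), collapse = ",")
    }
    con <- file(path, "w")
    on.exit(close(con))
    stampHeader(con, config)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

readTsv <- function(path) {
    read.table(path, sep = "\t", header = TRUE, comment.char = "#",
               stringsAsFactors = FALSE)
}

#' Read and write gene tables
#'
#' Plain TSV with columns contig_id, gene_index, gene_id, start, end,
#' strand, aa_length, and (after annotation) roles, families, is_gt_only.
#'
#' @param genes gene table.
#' @param path file path.
#' @param config optional \code{\link{pulConfig}} stamped into the header.
#' @return \code{readGeneTable} returns the data.frame.
#' @export
writeGeneTable <- function(genes, path, config = NULL)
    writeTsv(genes, path, config)

#' @rdname writeGeneTable
#' @export
readGeneTable <- function(path) {
    g <- readTsv(path)
    for (col in c("roles", "families"))
        if (col %in% names(g)) g[[col]][is.na(g[[col]])] <- ""
    g
}

#' Read a HMMER3 domtblout file
#'
#' Parses the whitespace-delimited per-domain table written by hmmscan
#' (22 fixed columns plus free-text description; \code{#} comment lines
#' ignored). Model coordinates (hmm from/to) populate
#' \code{ali_from}/\code{ali_to} (used for model coverage), query
#' alignment coordinates populate \code{qry_from}/\code{qry_to} (used for
#' overlap resolution).
#'
#' @param path domtblout file.
#' @return data.frame in the layout expected by
#'   \code{\link{filterDomainHits}}.
#' @export
readDomtblout <- function(path) {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
    if (length(lines) == 0) return(emptyDomHits())
    parts <- strsplit(trimws(lines), "[[:space:]]+")
    short <- vapply(parts, length, integer(1)) < 22
    if (any(short)) stop("malformed domtblout: fewer than 22 columns")
    getn <- function(i) as.numeric(vapply(parts, `[[`, character(1), i))
    gets <- function(i) vapply(parts, `[[`, character(1), i)
    data.frame(
        gene_id = gets(4), model_id = gets(1), model_length = getn(3),
        ali_from = getn(16), ali_to = getn(17),
        qry_from = getn(18), qry_to = getn(19),
        i_evalue = getn(13), bitscore = getn(14),
        stringsAsFactors = FALSE)
}

#' Write synthetic domain hits in domtblout dialect
#'
#' @param hits domain-hit data.frame (see \code{\link{filterDomainHits}}).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeDomtblout <- function(hits, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("# synthetic hmmscan domtblout (pulseekR)",
                 "# target_name accession tlen query_name accession qlen evalue score bias n of c_evalue i_evalue score bias hmm_from hmm_to ali_from ali_to env_from env_to acc description"),
               con)
    if (nrow(hits)) {
        qf <- if ("qry_from" %in% names(hits)) hits$qry_from else hits$ali_from
        qt <- if ("qry_to" %in% names(hits)) hits$qry_to else hits$ali_to
        lines <- sprintf(
            "%s - %d %s - %d %.2g %.1f 0.0 1 1 %.2g %.2g %.1f 0.0 %d %d %d %d %d %d 0.99 -",
            hits$model_id, as.integer(hits$model_length), hits$gene_id,
            as.integer(pmax(qt, 1)), hits$i_evalue, hits$bitscore,
            hits$i_evalue, hits$i_evalue, hits$bitscore,
            as.integer(hits$ali_from), as.integer(hits$ali_to),
            as.integer(qf), as.integer(qt), as.integer(qf), as.integer(qt))
        writeLines(lines, con)
    }
    invisible(path)
}

#' Read BLAST/DIAMOND tabular output (outfmt 6)
#'
#' Standard 12-column tabular hits (qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore). The subject's CAZy
#' family is taken from \code{familyMap} (subject id to family), or, when
#' \code{familyMap} is NULL, parsed from subject ids of the form
#' \code{...|FAMILY|...}. Query coverage is computed as aligned query
#' span / query length from \code{aaLengths} (a gene table or a named
#' vector of residue lengths).
#'
#' @param path tabular file.
#' @param aaLengths gene table with \code{gene_id} and \code{aa_length},
#'   or named numeric vector.
#' @param familyMap optional data.frame \code{subject_id}, \code{family}.
#' @return data.frame in the layout expected by
#'   \code{\link{confirmCazymes}}.
#' @export
readBlastTab <- function(path, aaLengths, familyMap = NULL) {
    tab <- tryCatch(
        read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE),
        error = function(e) NULL)
    if (is.null(tab) || nrow(tab) == 0) return(emptySimHits())
    if (ncol(tab) < 12) stop("malformed tabular file: fewer than 12 columns")
    names(tab)[1:12] <- c("qseqid", "sseqid", "pident", "length",
                          "mismatch", "gapopen", "qstart", "qend",
                          "sstart", "send", "evalue", "bitscore")
    if (is.null(familyMap)) {
        fam <- vapply(strsplit(tab$sseqid, "|", fixed = TRUE), function(x)
            if (length(x) >= 2) x[2] else x[1], character(1))
    } else {
        fam <- familyMap$family[match(tab$sseqid, familyMap$subject_id)]
        if (any(is.na(fam)))
            stop("subject id(s) missing from family map")
    }
    if (is.data.frame(aaLengths)) {
        lens <- setNames(aaLengths$aa_length, aaLengths$gene_id)
    } else lens <- aaLengths
    qlen <- lens[tab$qseqid]
    if (any(is.na(qlen))) stop("query gene(s) missing from length table")
    data.frame(query_gene_id = tab$qseqid, subject_family = fam,
               pct_identity = tab$pident,
               query_coverage = (tab$qend - tab$qstart + 1) / qlen,
               evalue = tab$evalue, stringsAsFactors = FALSE)
}

#' Write synthetic similarity hits in outfmt-6 dialect
#'
#' Subject ids encode the family as \code{cazy|FAMILY|n}, so the file is
#' self-contained for \code{\link{readBlastTab}}.
#'
#' @param simHits similarity-hit data.frame.
#' @param aaLengths gene table or named residue-length vector (used to
#'   turn query coverage back into alignment coordinates).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeBlastTab <- function(simHits, aaLengths, path) {
    if (is.data.frame(aaLengths)) {
        lens <- setNames(aaLengths$aa_length, aaLengths$gene_id)
    } else lens <- aaLengths
    qlen <- lens[simHits$query_gene_id]
    span <- pmax(1, round(simHits$query_coverage * qlen))
    lines <- sprintf("%s\tcazy|%s|%d\t%.1f\t%d\t%d\t0\t%d\t%d\t1\t%d\t%.2g\t%.1f",
                     simHits$query_gene_id, simHits$subject_family,
                     seq_len(nrow(simHits)), simHits$pct_identity,
                     span, as.integer(round(span * 0.3)),
                     1L, as.integer(span), as.integer(span),
                     simHits$evalue, 100)
    writeLines(lines, path)
    invisible(path)
}

#' Write a locus table as TSV
#'
#' @param pulset a \linkS4class{PULSet} (classified or not).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writePulTable <- function(pulset, path) {
    writeTsv(as.data.frame(loci(pulset)), path, pulset@config)
}

#' Write locus features as GFF3
#'
#' One feature of type \code{polysaccharide_utilization_locus} per called
#' locus, with substrate and variant attributes when classified.
#'
#' @param pulset a \linkS4class{PULSet}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writePulGff3 <- function(pulset, path) {
    lo <- loci(pulset)
    g <- pulset@genes
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("##gff-version 3", con)
    for (i in seq_len(nrow(lo))) {
        sel <- g$contig_id == lo$contig_id[i] &
            g$gene_index >= lo$first_index[i] &
            g$gene_index <= lo$last_index[i]
        attrs <- sprintf("ID=%s;n_markers=%d;degradative_count=%d",
                         lo$pul_id[i], lo$n_markers[i],
                         lo$degradative_count[i])
        if ("substrate" %in% colnames(lo))
            attrs <- paste0(attrs, ";substrate=", lo$substrate[i],
                            ";variant=", lo$variant[i])
        writeLines(sprintf("%s\tpulseekR\tpolysaccharide_utilization_locus\t%d\t%d\t.\t.\t.\t%s",
                           lo$contig_id[i], min(g$start[sel]),
                           max(g$end[sel]), attrs), con)
    }
    invisible(path)
}

#' Read and write sketches as JSON
#'
#' The JSON records k, sketch size, hash seed and the sorted hash values,
#' so sketches are reproducible and comparable across runs.
#'
#' @param sketch a \linkS4class{MashSketch}.
#' @param path file path.
#' @return \code{readSketchJson} returns a \code{MashSketch}.
#' @export
writeSketchJson <- function(sketch, path) {
    jsonlite::write_json(
        list(mag_id = sketch@magId, k = sketch@k, s = sketch@sketchSize,
             seed = sketch@seed, n_skipped = sketch@nSkipped,
             hashes = sketch@hashes),
        path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeSketchJson
#' @export
readSketchJson <- function(path) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    new("MashSketch", magId = x$mag_id, k = x$k, sketchSize = x$s,
        seed = x$seed, hashes = as.numeric(x$hashes),
        nSkipped = x$n_skipped)
}

#' Write a distance matrix or cluster table as TSV
#'
#' @param D symmetric distance matrix.
#' @param tab cluster table (data.frame).
#' @param path output file.
#' @param config optional \code{\link{pulConfig}} for the header stamp.
#' @return \code{path}, invisibly.
#' @export
writeDistanceMatrix <- function(D, path, config = NULL) {
    df <- data.frame(mag_id = rownames(D), as.data.frame(D),
                     check.names = FALSE)
    writeTsv(df, path, config)
}

#' @rdname writeDistanceMatrix
#' @export
writeClusterTable <- function(tab, path, config = NULL)
    writeTsv(tab, path, config)
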