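## SusC/SusD dereplication: greedy centroid clustering at >=95% nucleotide
## identity (uclust-style, deterministic by descending length then id),
## representative selection by metagenome prevalence with a
## proteome-support fallback, and Mash-cluster taxonomy voting.

#' Global-alignment percent identity
#'
#' Needleman-Wunsch identity between two sequences. With the default
#' \code{"alignment"} denominator, identity = matches / alignment columns,
#' so gaps (including end gaps) count against identity; the
#' \code{"shorter"} denominator divides by the shorter sequence length.
#'
#' @param a,b sequences (character, \code{DNAString} or \code{AAString}).
#' @param type \code{"nt"} or \code{"aa"}.
#' @param denominator \code{"alignment"} or \code{"shorter"}.
#' @return percent identity in [0, 100].
#' @examples
#' alignmentIdentity("ACGTACGT", "ACGTACGA")
#' @export
alignmentIdentity <- function(a, b, type = c("nt", "aa"),
                              denominator = c("alignment", "shorter")) {
    type <- match.arg(type)
    denominator <- match.arg(denominator)
    a <- as.character(a); b <- as.character(b)
    if (nchar(a) == 0 || nchar(b) == 0) stop("empty sequence")
    if (type == "nt") {
        aln <- Biostrings::pairwiseAlignment(
            Biostrings::DNAString(a), Biostrings::DNAString(b),
            type = "global",
            substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
                match = 1, mismatch = -1),
            gapOpening = 4, gapExtension = 1)
    } else {
        aln <- Biostrings::pairwiseAlignment(
            Biostrings::AAString(a), Biostrings::AAString(b),
            type = "global", substitutionMatrix = "BLOSUM62",
            gapOpening = 10, gapExtension = 0.5)
    }
    ## alignment columns including internal and end gaps
    denom <- if (denominator == "alignment")
                 nchar(as.character(Biostrings::alignedPattern(aln)))
             else min(nchar(a), nchar(b))
    100 * Biostrings::nmatch(aln) / denom
}

#' Greedy centroid clustering of SusC/SusD genes
#'
#' Genes (all of one kind, susC or susD) are processed in descending
#' nucleotide-length order (ties: lexicographic gene id). Each gene joins
#' the first existing cluster whose centroid (founder) it matches at
#' \code{>= ntClusterIdentity} percent global-alignment identity,
#' otherwise it founds a new cluster. The fixed processing order makes
#' memberships independent of input order.
#'
#' @param genes data.frame with columns \code{gene_id}, \code{kind}
#'   (\code{"susC"} or \code{"susD"}, all equal), \code{nt_sequence},
#'   \code{aa_sequence}, \code{source_metagenome}, \code{source_mag}
#'   (\code{NA} allowed).
#' @param config a \code{\link{pulConfig}} (uses \code{ntClusterIdentity}
#'   and \code{identityDenominator}).
#' @return \link[S4Vectors]{DataFrame}: \code{cluster_id}, \code{kind},
#'   \code{centroid}, \code{members} (CharacterList),
#'   \code{n_metagenomes}.
#' @export
clusterSusGenes <- function(genes, config = pulConfig()) {
    if (nrow(genes) == 0) stop("no genes to cluster")
    if (length(unique(genes$kind)) > 1)
        stop("cluster susC and susD genes separately")
    if (any(!nzchar(genes$nt_sequence)))
        stop("empty nucleotide sequence")
    ord <- order(-nchar(genes$nt_sequence), genes$gene_id)
    genes <- genes[ord, , drop = FALSE]
    centroid_idx <- integer(0)
    membership <- integer(nrow(genes))
    for (i in seq_len(nrow(genes))) {
        placed <- FALSE
        for (ci in seq_along(centroid_idx)) {
            pid <- alignmentIdentity(genes$nt_sequence[i],
                                     genes$nt_sequence[centroid_idx[ci]],
                                     type = "nt",
                                     denominator = config@identityDenominator)
            if (pid >= config@ntClusterIdentity) {
                membership[i] <- ci
                placed <- TRUE
                break
            }
        }
        if (!placed) {
            centroid_idx <- c(centroid_idx, i)
            membership[i] <- length(centroid_idx)
        }
    }
    kind <- genes$kind[1]
    per <- split(seq_len(nrow(genes)), membership)
    S4Vectors::DataFrame(
        cluster_id = sprintf("%s_cl_%d", kind, as.integer(names(per))),
        kind = kind,
        centroid = genes$gene_id[centroid_idx[as.integer(names(per))]],
        members = IRanges::CharacterList(
            lapply(per, function(idx) genes$gene_id[idx])),
        n_metagenomes = vapply(per, function(idx)
            length(unique(genes$source_metagenome[idx])), integer(1)))
}

#' Select representative SusC/D clusters
#'
#' A cluster becomes representative when it occurs in at least
#' \code{minMetagenomes} distinct metagenomes, or in
#' \code{altMetagenomes} metagenomes with expression support (a proteome
#' hit to the cluster at \code{>= aaLinkIdentity} percent amino acid
#' identity). The representative member is the one from the most complete
#' source MAG (ties: longest gene, then lexicographic id).
#'
#' @param clusters output of \code{\link{clusterSusGenes}}.
#' @param genes the gene table the clusters were built from.
#' @param proteomeHits data.frame with columns \code{cluster_id},
#'   \code{aa_identity} (one row per expressed-protein match), or NULL.
#' @param qualities optional MAG quality table used to rank members by
#'   source-MAG completeness.
#' @param config a \code{\link{pulConfig}}.
#' @return \code{clusters} with added columns \code{proteome_support},
#'   \code{representative} (logical) and \code{representative_gene}.
#' @export
selectRepresentatives <- function(clusters, genes, proteomeHits = NULL,
                                  qualities = NULL, config = pulConfig()) {
    support <- rep(FALSE, nrow(clusters))
    if (!is.null(proteomeHits) && nrow(proteomeHits) > 0) {
        ok <- proteomeHits$aa_identity >= config@aaLinkIdentity
        support <- clusters$cluster_id %in% proteomeHits$cluster_id[ok]
    }
    clusters$proteome_support <- support
    clusters$representative <- clusters$n_metagenomes >= config@minMetagenomes |
        (clusters$n_metagenomes >= config@altMetagenomes & support)
    comp <- function(mag) {
        if (is.null(qualities)) return(NA_real_)
        i <- match(mag, qualities$mag_id)
        ifelse(is.na(i), -Inf, qualities$completeness[i])
    }
    clusters$representative_gene <- vapply(seq_len(nrow(clusters)),
                                           function(i) {
        if (!clusters$representative[i]) return(NA_character_)
        ids <- clusters$members[[i]]
        g <- genes[match(ids, genes$gene_id), , drop = FALSE]
        cc <- vapply(g$source_mag, function(m)
            if (is.na(m)) -Inf else {
                v <- comp(m); if (is.na(v)) -Inf else v
            }, numeric(1))
        g$gene_id[order(-cc, -nchar(g$nt_sequence), g$gene_id)][1]
    }, character(1))
    clusters
}

#' Vote a cluster's taxonomy from its members' Mash-clusters
#'
#' Members vote with the Mash-cluster of their source MAG (members
#' without an assignment abstain). The outcome is exactly one of:
#' \itemize{
#'   \item \code{assigned}: a single Mash-cluster holds at least half of
#'     the votes (and is the unique maximum);
#'   \item \code{putative}: a single Mash-cluster holds a strict
#'     plurality below half;
#'   \item \code{clade}: no plurality, but all voting members'
#'     Mash-clusters belong to one clade;
#'   \item \code{unassigned}: otherwise (including no votes at all).
#' }
#'
#' @param member_mags character vector of source MAG ids of one cluster's
#'   members (\code{NA} allowed).
#' @param magAssignments data.frame \code{mag_id}, \code{cluster_id}
#'   (Mash-cluster of each MAG).
#' @param cladeMap data.frame \code{cluster_id}, \code{clade}.
#' @return list with \code{state} (one of assigned/putative/clade/
#'   unassigned) and \code{value} (Mash-cluster id, clade name, or NA).
#' @examples
#' mags <- data.frame(mag_id = c("m1", "m2", "m3"),
#'                    cluster_id = c("mc_8", "mc_8", "mc_5"))
#' clades <- data.frame(cluster_id = c("mc_8", "mc_5"),
#'                      clade = c("Formosa", "Polaribacter"))
#' voteTaxonomy(c("m1", "m2", "m3"), mags, clades)
#' @export
voteTaxonomy <- function(member_mags, magAssignments, cladeMap = NULL) {
    mc <- magAssignments$cluster_id[match(member_mags,
                                          magAssignments$mag_id)]
    mc <- mc[!is.na(mc)]
    if (length(mc) == 0)
        return(list(state = "unassigned", value = NA_character_))
    counts <- sort(table(mc), decreasing = TRUE)
    top <- counts[1]
    winners <- names(counts)[counts == top]
    if (length(winners) == 1 && top / length(mc) >= 0.5)
        return(list(state = "assigned", value = winners))
    if (length(winners) == 1)
        return(list(state = "putative", value = winners))
    if (!is.null(cladeMap)) {
        clades <- cladeMap$clade[match(unique(mc), cladeMap$cluster_id)]
        if (!any(is.na(clades)) && length(unique(clades)) == 1)
            return(list(state = "clade", value = clades[1]))
    }
    list(state = "unassigned", value = NA_character_)
}

#' Dereplicate SusC/D genes end to end
#'
#' Clusters the genes of one kind, selects representatives and votes
#' taxonomy in one call.
#'
#' @inheritParams clusterSusGenes
#' @inheritParams selectRepresentatives
#' @inheritParams voteTaxonomy
#' @return the cluster \link[S4Vectors]{DataFrame} with representative and
#'   taxonomy columns (\code{tax_state}, \code{tax_value}).
#' @export
derepSusGenes <- function(genes, proteomeHits = NULL, qualities = NULL,
                          magAssignments = NULL, cladeMap = NULL,
                          config = pulConfig()) {
    clusters <- clusterSusGenes(genes, config)
    clusters <- selectRepresentatives(clusters, genes, proteomeHits,
                                      qualities, config)
    if (!is.null(magAssignments)) {
        votes <- lapply(seq_len(nrow(clusters)), function(i) {
            ids <- clusters$members[[i]]
            voteTaxonomy(genes$source_mag[match(ids, genes$gene_id)],
                         magAssignments, cladeMap)
        })
        clusters$tax_state <- vapply(votes, `[[`, character(1), "state")
        clusters$tax_value <- vapply(votes, `[[`, character(1), "value")
    }
    clusters
}

#' Export representative sequences as FASTA
#'
#' Writes the amino acid (or nucleotide) sequences of representative
#' clusters for external alignment/tree building.
#'
#' @param clusters output of \code{\link{selectRepresentatives}}.
#' @param genes the gene table.
#' @param path output FASTA path.
#' @param what \code{"aa"} or \code{"nt"}.
#' @return \code{path}, invisibly.
#' @export
writeRepresentativeFasta <- function(clusters, genes, path,
                                     what = c("aa", "nt")) {
    what <- match.arg(what)
    reps <- clusters$representative_gene[clusters$representative]
    g <- genes[match(reps, genes$gene_id), , drop = FALSE]
    seqs <- if (what == "aa") Biostrings::AAStringSet(g$aa_sequence)
            else Biostrings::DNAStringSet(g$nt_sequence)
    names(seqs) <- g$gene_id
    Biostrings::writeXStringSet(seqs, path)
    invisible(path)
}
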